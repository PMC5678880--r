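# Independent oracles and fixture builders shared across the suite.

# Exhaustive frequent-itemset oracle: enumerate every non-empty subset of the
# item vocabulary and count it directly against the 0/1 matrix. Deliberately
# independent of the level-wise miner it checks.
brute_force_itemsets <- function(db, min_count = 1) {
  items <- sort(setdiff(names(db), "tumor_id"))
  m <- as.matrix(as.data.frame(db)[, items, drop = FALSE])
  out <- list()
  for (mask in seq_len(2^length(items) - 1)) {
    s <- items[bitwAnd(mask, 2^(seq_along(items) - 1)) > 0]
    cnt <- sum(apply(m[, s, drop = FALSE], 1, function(r) all(r == 1)))
    if (cnt >= min_count) {
      out[[length(out) + 1]] <- list(items = s, count = cnt)
    }
  }
  out
}

itemset_key <- function(items) paste(sort(items), collapse = "|")

# Canonical named count vector from either representation.
as_count_map <- function(x) {
  if (is.data.frame(x)) {
    stats::setNames(x$count, vapply(x$items, itemset_key, character(1)))
  } else {
    stats::setNames(vapply(x, `[[`, numeric(1), "count"),
                    vapply(x, function(s) itemset_key(s$items), character(1)))
  }
}

# Random transaction table over arbitrary item labels (not marker-structured);
# exercises the miner outside the cohort encoding.
random_db <- function(n_transactions, n_items, p = 0.5) {
  labs <- paste0("i", seq_len(n_items))
  db <- tibble::tibble(tumor_id = seq_len(n_transactions))
  for (l in labs) db[[l]] <- as.integer(stats::runif(n_transactions) < p)
  class(db) <- c("hypo_transactions", class(db))
  db
}

# Random realizable rule counts: 1 <= nA, nB <= N and inclusion-exclusion
# max(0, nA + nB - N) <= nAB <= min(nA, nB), so the counts could come from an
# actual transaction table.
random_rule_counts <- function() {
  N <- sample(2:200, 1)
  nA <- sample(1:N, 1)
  nB <- sample(1:N, 1)
  lo <- max(0, nA + nB - N)
  hi <- min(nA, nB)
  nAB <- if (lo == hi) lo else sample(lo:hi, 1)
  list(N = N, nA = nA, nB = nB, nAB = nAB)
}

# Independent half-up rounding at two decimals (how the benchmark table prints).
round_to_printed <- function(x) floor(x * 100 + 0.5) / 100

# A minimal 3-tumor cohort with no medium cells.
tiny_cohort <- function() {
  tibble::tibble(
    tumor_id = 1:3,
    cluster = c("hypoxic", "normoxic", "normoxic"),
    sex = "unknown", age_months = NA_real_, inss_stage = NA_character_,
    outcome = "", histology = "unknown", mycn_amplified = "unknown",
    HIF1A_percent_bin = c("71–100%", "1–20%", "<1%"),
    HIF1A_intensity = "unknown", HIF1A_medium_resolution = "not_applicable",
    PDK1_percent_bin = c("51–70%", "1–20%", "1–20%"),
    PDK1_intensity = "unknown", PDK1_medium_resolution = "not_applicable",
    PHD3_percent_bin = c("<1%", "71–100%", "51–70%"),
    PHD3_intensity = "unknown", PHD3_medium_resolution = "not_applicable")
}

# The fourteen benchmark rules with all printed metric values, frozen for
# end-to-end comparison (antecedents keyed as sorted " & " strings).
benchmark_rule_table <- function() {
  ref <- reference_rule_counts()
  ref$key <- vapply(ref$antecedent, function(a) paste(sort(a), collapse = " & "),
                    character(1))
  ref$coverage <- c(1.00, 0.88, 1.00, 1.00, 0.88, 0.88, 0.88,
                    0.82, 0.88, 0.88, 0.76, 0.71, 0.76, 0.65)
  ref$confidence <- c(0.73, 0.78, 0.8, 1, 0.88, 1, 1,
                      1, 0.94, 1, 1, 1, 1, 1)
  ref$lift <- c(2.27, 2.43, 2.5, 3.13, 2.73, 3.13, 3.13,
                1.47, 1.38, 1.47, 1.47, 1.47, 1.47, 1.47)
  ref$leverage <- c(0.18, 0.16, 0.19, 0.22, 0.18, 0.19, 0.19,
                    0.18, 0.16, 0.19, 0.17, 0.15, 0.17, 0.14)
  ref$conviction <- c(1.87, 2.04, 2.27, 5.44, 2.72, 4.76, 4.76,
                      4.48, 2.56, 4.8, 4.16, 3.84, 4.16, 3.52)
  ref
}
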