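# Level-wise frequent-itemset mining and rule generation.
#
# The miner is written from scratch: candidates of size k are joined from
# frequent (k-1)-itemsets sharing a (k-2)-prefix, pruned by support
# anti-monotonicity (every (k-1)-subset must itself be frequent), then
# counted against the 0/1 transaction matrix. At the cohort sizes this
# package targets (tens of transactions, eight items) no further
# optimization is warranted.

#' Mine frequent itemsets with APRIORI
#'
#' Returns every itemset whose absolute support (number of transactions
#' containing all its items) is at least `min_count`, with its exact
#' count.
#'
#' @param db A `hypo_transactions` tibble (see [cohort_to_transactions()]).
#' @param min_count Minimum absolute support, a positive integer.
#'   Default 1: with a small cohort every co-occurrence pattern is kept
#'   and all filtering is deferred to rule selection.
#' @return A tibble with columns `size`, `items` (list of sorted item
#'   labels) and `count`, ordered by size then items.
#' @export
#' @examples
#' tx <- cohort_to_transactions(nb_cohort())
#' sets <- apriori_frequent_itemsets(tx)
#' sets[sets$size == 1, ]
apriori_frequent_itemsets <- function(db, min_count = 1) {
  if (length(min_count) != 1 || is.na(min_count) || min_count < 1) {
    abort_parameter("min_count must be a positive integer")
  }
  m <- transaction_matrix(db)
  if (nrow(m) == 0 || ncol(m) == 0) {
    return(tibble::tibble(size = integer(), items = list(), count = integer()))
  }
  items <- sort(colnames(m))
  m <- m[, items, drop = FALSE]

  # L1
  counts1 <- colSums(m)
  frequent <- list()
  level_sets <- lapply(items[counts1 >= min_count], identity)
  level_counts <- as.integer(counts1[counts1 >= min_count])
  k <- 1L
  while (length(level_sets) > 0) {
    frequent[[k]] <- tibble::tibble(size = k, items = level_sets,
                                    count = level_counts)
    cand <- apriori_candidates(level_sets)
    if (length(cand) == 0) break
    cnt <- vapply(cand, function(s) {
      sum(rowSums(m[, s, drop = FALSE]) == length(s))
    }, numeric(1))
    keep <- cnt >= min_count
    level_sets <- cand[keep]
    level_counts <- as.integer(cnt[keep])
    k <- k + 1L
  }
  if (length(frequent) == 0) {
    return(tibble::tibble(size = integer(), items = list(), count = integer()))
  }
  dplyr::bind_rows(frequent)
}

# Join step + prune step. `sets` are sorted character vectors of equal size k;
# candidates are (k+1)-sets whose every k-subset is in `sets`.
apriori_candidates <- function(sets) {
  k <- length(sets[[1]])
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  prefix <- vapply(sets, function(s) paste(s[-k], collapse = "\r"), character(1))
  cand <- list()
  for (pfx in unique(prefix)) {
    members <- sets[prefix == pfx]
    if (length(members) < 2) next
    lasts <- sort(vapply(members, function(s) s[k], character(1)))
    base <- members[[1]][-k]
    for (i in seq_len(length(lasts) - 1)) {
      for (j in (i + 1):length(lasts)) {
        cand[[length(cand) + 1]] <- c(base, lasts[i], lasts[j])
      }
    }
  }
  if (length(cand) == 0) return(list())
  # prune: every k-subset frequent
  ok <- vapply(cand, function(s) {
    all(vapply(seq_along(s), function(drop) {
      paste(s[-drop], collapse = "\r") %in% keys
    }, logical(1)))
  }, logical(1))
  cand[ok]
}

#' Generate association rules for a fixed consequent domain
#'
#' Builds one rule per (antecedent, consequent) pair, where antecedents
#' are the frequent itemsets containing marker items only (never a
#' hypoxia-status item) and consequents range over `consequent_domain`.
#' Counts are filled from the itemset table (`nAB` is 0 when the joint
#' itemset is infrequent at the mining threshold) and the five metrics
#' are attached.
#'
#' @param itemsets Output of [apriori_frequent_itemsets()]; mine with
#'   `min_count = 1` to score every co-occurrence exactly.
#' @param db The transaction table the itemsets were mined from.
#' @param consequent_domain Item labels allowed as consequents; default
#'   the two hypoxia-status items.
#' @param conviction Conviction variant, `"smoothed"` (default) or
#'   `"classical"`.
#' @return A tibble of class `hypo_rules`: `antecedent` (list of item
#'   vectors), `consequent`, the counts `N`, `nA`, `nB`, `nAB`, and
#'   `coverage`, `confidence`, `lift`, `leverage`, `conviction`.
#' @export
#' @examples
#' tx <- cohort_to_transactions(nb_cohort())
#' rules <- generate_rules(apriori_frequent_itemsets(tx), tx)
generate_rules <- function(itemsets, db,
                           consequent_domain = c("HYPOXIA=high", "HYPOXIA=low"),
                           conviction = c("smoothed", "classical")) {
  conviction <- match.arg(conviction)
  if (length(consequent_domain) == 0) {
    abort_parameter("consequent_domain must be non-empty")
  }
  all_items <- setdiff(names(db), "tumor_id")
  missing <- setdiff(consequent_domain, all_items)
  if (length(missing) > 0) {
    abort_parameter(sprintf("consequent item(s) absent from the transaction table: %s",
                            paste(missing, collapse = ", ")))
  }
  N <- nrow(db)
  key <- function(s) paste(sort(s), collapse = "\r")
  count_of <- stats::setNames(itemsets$count,
                              vapply(itemsets$items, key, character(1)))
  lookup <- function(s) {
    cnt <- count_of[key(s)]
    if (is.na(cnt)) 0L else as.integer(cnt)
  }
  is_consequent_item <- vapply(itemsets$items,
                               function(s) any(s %in% consequent_domain),
                               logical(1))
  antecedents <- itemsets$items[!is_consequent_item]
  ante_counts <- itemsets$count[!is_consequent_item]

  rows <- purrr::map_dfr(consequent_domain, function(cq) {
    nB <- lookup(cq)
    tibble::tibble(
      antecedent = antecedents,
      consequent = cq,
      N = N,
      nA = as.integer(ante_counts),
      nB = nB,
      nAB = vapply(antecedents, function(a) lookup(c(a, cq)), integer(1))
    )
  })
  rows <- dplyr::filter(rows, .data$nA >= 1)
  out <- add_rule_metrics(rows, conviction = conviction)
  class(out) <- c("hypo_rules", class(out))
  out
}
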