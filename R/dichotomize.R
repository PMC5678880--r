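# Percentage bin -> L/M/H level -> binary high/low -> transaction table.

#' Map a percentage-positivity bin to its L/M/H level
#'
#' The five-bin scoring vocabulary collapses to three levels: "<1%" and
#' "1–20%" are low positivity (L), "21–50%" medium (M), "51–70%" and
#' "71–100%" high (H).
#'
#' @param percent_bin Character vector of bins (en-dash or ASCII-hyphen form).
#' @return Character vector over {"L", "M", "H"}.
#' @export
#' @examples
#' bin_to_level(c("<1%", "21–50%", "71–100%"))
bin_to_level <- function(percent_bin) {
  levels <- c("L", "L", "M", "H", "H")
  idx <- match(normalize_bin(percent_bin), percent_bins())
  if (anyNA(idx)) {
    bad <- percent_bin[which(is.na(idx))[1]]
    abort_value(sprintf("unknown percent bin: %s",
                        ifelse(is.na(bad), "<missing>", bad)))
  }
  levels[idx]
}

#' Resolve a marker score to binary high/low
#'
#' L bins are low and H bins high, unconditionally. Medium ("21–50%")
#' scores are resolved by the explicit `medium_resolution` when one is
#' recorded; otherwise by staining intensity under the default policy
#' strong/moderate → high, weak → low. A medium score with neither an
#' explicit resolution nor a known intensity is an error, because it
#' cannot be dichotomized.
#'
#' @param percent_bin,intensity,medium_resolution Parallel character
#'   vectors (a marker's score columns).
#' @param context Optional character vector used in error messages to
#'   identify the offending tumor/marker.
#' @return Character vector over {"high", "low"}.
#' @export
#' @examples
#' resolve_binary("1–20%")
#' resolve_binary("21–50%", intensity = "strong")
resolve_binary <- function(percent_bin, intensity = "unknown",
                           medium_resolution = "not_applicable",
                           context = NULL) {
  n <- max(length(percent_bin), length(intensity), length(medium_resolution))
  percent_bin <- rep_len(percent_bin, n)
  intensity <- rep_len(intensity, n)
  medium_resolution <- rep_len(medium_resolution, n)
  level <- bin_to_level(percent_bin)
  out <- ifelse(level == "H", "high", "low")
  med <- which(level == "M")
  for (i in med) {
    out[i] <- if (medium_resolution[i] != "not_applicable") {
      medium_resolution[i]
    } else if (intensity[i] %in% c("strong", "moderate")) {
      "high"
    } else if (intensity[i] == "weak") {
      "low"
    } else {
      where <- if (!is.null(context)) rep_len(context, n)[i] else sprintf("position %d", i)
      abort_unresolved(sprintf(
        "medium (21–50%%) score with neither an explicit resolution nor a staining intensity: %s",
        where))
    }
  }
  out
}

#' Dichotomize a cohort into a binary transaction table
#'
#' Emits one transaction per tumor over the eight-item vocabulary
#' (`MARKER=high` / `MARKER=low` for each marker, plus `HYPOXIA=high` /
#' `HYPOXIA=low` taken from the cluster label). Every transaction contains
#' exactly one polarity per marker and one hypoxia item.
#'
#' @param cohort A validated cohort tibble.
#' @return A tibble of class `hypo_transactions`: column `tumor_id`
#'   followed by one 0/1 integer column per item label.
#' @seealso [item_counts()], [apriori_frequent_itemsets()]
#' @export
#' @examples
#' tx <- cohort_to_transactions(nb_cohort())
#' item_counts(tx)
cohort_to_transactions <- function(cohort) {
  validate_cohort(cohort)
  out <- tibble::tibble(tumor_id = cohort$tumor_id)
  for (m in markers()) {
    state <- resolve_binary(cohort[[paste0(m, "_percent_bin")]],
                            cohort[[paste0(m, "_intensity")]],
                            cohort[[paste0(m, "_medium_resolution")]],
                            context = sprintf("tumor %s, marker %s",
                                              cohort$tumor_id, m))
    out[[paste0(m, "=high")]] <- as.integer(state == "high")
    out[[paste0(m, "=low")]] <- as.integer(state == "low")
  }
  out[["HYPOXIA=high"]] <- as.integer(cohort$cluster == "hypoxic")
  out[["HYPOXIA=low"]] <- as.integer(cohort$cluster == "normoxic")
  class(out) <- c("hypo_transactions", class(out))
  out
}

#' Per-item occurrence counts of a transaction table
#'
#' @param db A `hypo_transactions` tibble.
#' @return A tibble with columns `item` and `count`.
#' @export
item_counts <- function(db) {
  items <- setdiff(names(db), "tumor_id")
  tibble::tibble(item = items,
                 count = vapply(items, function(i) sum(db[[i]]), integer(1),
                                USE.NAMES = FALSE))
}

# 0/1 matrix view, transactions x items.
transaction_matrix <- function(db) {
  items <- setdiff(names(db), "tumor_id")
  m <- as.matrix(as.data.frame(db)[, items, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(db$tumor_id)
  m
}

#' Export a transaction table
#'
#' Two plain-text serializations: `"onehot"` writes the 0/1 CSV as-is;
#' `"basket"` writes one transaction per line, its items space-separated,
#' the format external miners commonly ingest.
#'
#' @param db A `hypo_transactions` tibble.
#' @param path Output path.
#' @param format `"onehot"` or `"basket"`.
#' @return `path`, invisibly.
#' @export
write_transactions <- function(db, path, format = c("onehot", "basket")) {
  format <- match.arg(format)
  if (format == "onehot") {
    readr::write_csv(tibble::as_tibble(db), path, progress = FALSE)
  } else {
    m <- transaction_matrix(db)
    lines <- apply(m, 1, function(r) paste(colnames(m)[r == 1], collapse = " "))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Occurrence counts of the fourteen benchmark rules
#'
#' The antecedent/consequent patterns and occurrence pairs (antecedent
#' count `nA`, joint count `nAB`) of the fourteen rules the packaged
#' cohort is benchmarked against. These counts are the consistency target
#' used by [resolve_by_consistency()] to derive the fixture's medium-cell
#' resolutions.
#'
#' @return A tibble with columns `antecedent` (list of item-label
#'   vectors), `consequent`, `nA`, `nAB`.
#' @export
reference_rule_counts <- function() {
  H <- "HIF1A=high"; P <- "PDK1=high"; D <- "PHD3=low"
  h <- "HIF1A=low"; p <- "PDK1=low"; d <- "PHD3=high"
  tibble::tibble(
    antecedent = list(c(H), c(P), c(D), c(H, D), c(H, P), c(P, D), c(H, P, D),
                      c(h), c(p), c(d), c(h, p), c(h, d), c(p, d), c(h, p, d)),
    consequent = rep(c("HYPOXIA=high", "HYPOXIA=low"), each = 7),
    nA = c(11L, 9L, 10L, 8L, 8L, 7L, 7L, 14L, 16L, 15L, 13L, 12L, 13L, 11L),
    nAB = c(8L, 7L, 8L, 8L, 7L, 7L, 7L, 14L, 15L, 15L, 13L, 12L, 13L, 11L)
  )
}

#' Audit the medium-cell resolutions by exhaustive consistency search
#'
#' Enumerates every high/low assignment of the cohort's "21–50%" (medium)
#' marker cells — 2^k assignments for k medium cells — and keeps those
#' whose induced transaction counts reproduce a set of printed occurrence
#' pairs exactly. For the packaged cohort and its fourteen benchmark
#' rules, exactly one of the 64 assignments survives; the fixture's
#' recorded resolutions are that assignment.
#'
#' @param cohort A cohort tibble; at most 20 medium cells.
#' @param printed_counts A tibble like [reference_rule_counts()]:
#'   `antecedent` (list of item vectors), `consequent`, `nA`, `nAB`.
#' @return A tibble with columns `assignment` (integer id, one per
#'   satisfying assignment), `tumor_id`, `marker`, `resolution`. Zero rows
#'   (with attribute `n_assignments = 1`) when the cohort has no medium
#'   cells. Attribute `n_assignments` carries the number of satisfying
#'   assignments.
#' @export
resolve_by_consistency <- function(cohort, printed_counts = reference_rule_counts()) {
  validate_cohort(cohort)
  cells <- purrr::map_dfr(markers(), function(m) {
    idx <- which(bin_to_level(cohort[[paste0(m, "_percent_bin")]]) == "M")
    tibble::tibble(row = idx, tumor_id = cohort$tumor_id[idx], marker = m)
  })
  k <- nrow(cells)
  if (k > 20) abort_parameter(sprintf("too many medium cells for exhaustive search: %d", k))

  rule_miss <- function(db) {
    m <- transaction_matrix(db)
    miss <- 0L
    for (i in seq_len(nrow(printed_counts))) {
      a <- printed_counts$antecedent[[i]]
      inA <- rowSums(m[, a, drop = FALSE]) == length(a)
      nA <- sum(inA)
      nAB <- sum(inA & m[, printed_counts$consequent[i]] == 1)
      miss <- miss + (nA != printed_counts$nA[i]) + (nAB != printed_counts$nAB[i])
    }
    miss
  }

  if (k == 0) {
    out <- tibble::tibble(assignment = integer(), tumor_id = integer(),
                          marker = character(), resolution = character())
    n_ok <- if (rule_miss(cohort_to_transactions(cohort)) == 0) 1L else 0L
    if (n_ok == 0) abort_inconsistency("no medium cells, and the cohort's counts do not match the printed counts")
    attr(out, "n_assignments") <- 1L
    return(out)
  }

  hits <- list()
  best_miss <- Inf
  nearest <- list()
  for (code in 0:(2^k - 1)) {
    states <- ifelse(bitwAnd(code, 2^(seq_len(k) - 1)) > 0, "high", "low")
    trial <- cohort
    for (j in seq_len(k)) {
      trial[[paste0(cells$marker[j], "_medium_resolution")]][cells$row[j]] <- states[j]
    }
    miss <- rule_miss(cohort_to_transactions(trial))
    assignment <- tibble::tibble(tumor_id = cells$tumor_id, marker = cells$marker,
                                 resolution = states)
    if (miss == 0) {
      hits[[length(hits) + 1]] <- assignment
    } else if (miss < best_miss) {
      best_miss <- miss
      nearest <- list(assignment)
    } else if (miss == best_miss) {
      nearest[[length(nearest) + 1]] <- assignment
    }
  }

  if (length(hits) == 0) {
    show <- nearest[seq_len(min(3, length(nearest)))]
    desc <- vapply(show, function(a) {
      paste(sprintf("(%d,%s)=%s", a$tumor_id, a$marker, a$resolution), collapse = " ")
    }, character(1))
    abort_inconsistency(sprintf(
      "no assignment of the %d medium cells reproduces the printed counts; nearest (off by %d counts): %s",
      k, best_miss, paste(desc, collapse = " | ")))
  }
  out <- dplyr::bind_rows(purrr::imap(hits, ~dplyr::mutate(.x, assignment = .y,
                                                           .before = 1)))
  attr(out, "n_assignments") <- length(hits)
  out
}
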