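# The five rule-interestingness metrics, computed from integer counts.
#
# A rule A -> B over N transactions is summarized by the counts
# (N, nA, nB, nAB): total transactions, antecedent occurrences, consequent
# occurrences, joint occurrences. All five metrics are functions of these
# four integers.

#' Build a rule-count record
#'
#' @param N Total transactions.
#' @param nA Antecedent occurrence count n(A).
#' @param nB Consequent occurrence count n(B).
#' @param nAB Joint occurrence count n(A and B).
#' @return A tibble row with the four counts, validated against
#'   0 <= nAB <= min(nA, nB) <= N.
#' @export
#' @examples
#' rule_counts(25, 11, 8, 8)
rule_counts <- function(N, nA, nB, nAB) {
  bad <- nAB > pmin(nA, nB) | pmax(nA, nB) > N | nAB < 0 | N < 0
  if (any(bad)) {
    abort_parameter("invalid rule counts: need 0 <= nAB <= min(nA, nB) <= N")
  }
  tibble::tibble(N = as.integer(N), nA = as.integer(nA),
                 nB = as.integer(nB), nAB = as.integer(nAB))
}

#' Rule interestingness metrics
#'
#' Vectorized over parallel count vectors.
#'
#' * `rule_confidence()`: nAB/nA — the rule's precision.
#' * `rule_coverage()`: nAB/nB — the fraction of consequent-positive
#'   transactions the rule captures (consequent recall). Note this is NOT
#'   the antecedent support nA/N that "coverage" often denotes elsewhere;
#'   the recall definition is the one this pipeline is benchmarked
#'   against.
#' * `rule_lift()`: (nAB/nA)/(nB/N) — 1 under independence.
#' * `rule_leverage()`: nAB/N − (nA/N)(nB/N) — 0 under independence.
#' * `rule_conviction()`: by default the smoothed variant
#'   nA(N−nB) / (N(nA−nAB+1)), whose +1 (Laplace-style) denominator keeps
#'   confidence-1 rules finite; `variant = "classical"` gives
#'   nA(N−nB) / (N(nA−nAB)), infinite at confidence 1.
#'
#' @param N,nA,nB,nAB Integer count vectors (see [rule_counts()]).
#' @param variant For `rule_conviction()`: `"smoothed"` (default) or
#'   `"classical"`.
#' @return Numeric vector.
#' @name rule_metrics
#' @export
#' @examples
#' rule_confidence(nA = 11, nAB = 8)
#' rule_conviction(N = 25, nA = 11, nB = 8, nAB = 8)
#' rule_conviction(N = 25, nA = 8, nB = 8, nAB = 8, variant = "classical")
rule_confidence <- function(nA, nAB) {
  if (any(nA < 1)) abort_parameter("confidence undefined: antecedent count nA is 0")
  nAB / nA
}

#' @rdname rule_metrics
#' @export
rule_coverage <- function(nB, nAB) {
  if (any(nB < 1)) abort_parameter("coverage undefined: consequent count nB is 0")
  nAB / nB
}

#' @rdname rule_metrics
#' @export
rule_lift <- function(N, nA, nB, nAB) {
  if (any(nA < 1) || any(nB < 1)) {
    abort_parameter("lift undefined: nA and nB must both be >= 1")
  }
  (nAB / nA) / (nB / N)
}

#' @rdname rule_metrics
#' @export
rule_leverage <- function(N, nA, nB, nAB) {
  if (any(N < 1)) abort_parameter("leverage undefined: N is 0")
  nAB / N - (nA / N) * (nB / N)
}

#' @rdname rule_metrics
#' @export
rule_conviction <- function(N, nA, nB, nAB, variant = c("smoothed", "classical")) {
  variant <- match.arg(variant)
  if (any(nA < 1)) abort_parameter("conviction undefined: antecedent count nA is 0")
  denom <- if (variant == "smoothed") nA - nAB + 1 else nA - nAB
  nA * (N - nB) / (N * denom)
}

# All five at once, appended to a counts tibble.
add_rule_metrics <- function(counts, conviction = c("smoothed", "classical")) {
  conviction <- match.arg(conviction)
  dplyr::mutate(counts,
    coverage = rule_coverage(.data$nB, .data$nAB),
    confidence = rule_confidence(.data$nA, .data$nAB),
    lift = rule_lift(.data$N, .data$nA, .data$nB, .data$nAB),
    leverage = rule_leverage(.data$N, .data$nA, .data$nB, .data$nAB),
    conviction = rule_conviction(.data$N, .data$nA, .data$nB, .data$nAB,
                                 variant = conviction))
}
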