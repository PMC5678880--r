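# Controlled vocabularies and small shared helpers.
#
# Percentage bins use an en-dash (U+2013) in canonical form, matching how
# pathology reports print them; an ASCII-hyphen alias is accepted on input.

#' Marker and item vocabularies
#'
#' `markers()` returns the three-marker panel in its fixed order;
#' `percent_bins()` the five-level percentage-positivity vocabulary;
#' `item_labels()` the full item vocabulary of the transaction encoding
#' (both polarities per marker, plus the hypoxia status items).
#'
#' @return A character vector.
#' @export
#' @examples
#' markers()
#' percent_bins()
markers <- function() c("HIF1A", "PDK1", "PHD3")

#' @rdname markers
#' @export
percent_bins <- function() {
  c("<1%", "1–20%", "21–50%", "51–70%", "71–100%")
}

#' @rdname markers
#' @export
item_labels <- function() {
  c(paste0(rep(markers(), each = 2), "=", c("high", "low")),
    "HYPOXIA=high", "HYPOXIA=low")
}

intensity_levels <- function() c("weak", "moderate", "strong", "unknown")
resolution_levels <- function() c("high", "low", "not_applicable")
cluster_levels <- function() c("hypoxic", "normoxic")
sex_levels <- function() c("male", "female", "unknown")
stage_levels <- function() c("1", "2A", "2B", "3", "4", "4S")
histology_levels <- function() c("FH", "UH", "unknown")
yesno_levels <- function() c("yes", "no", "unknown")

# Accept the ASCII-hyphen alias ("1-20%") and normalize to the en-dash form.
normalize_bin <- function(x) {
  gsub("-", "–", x, fixed = TRUE)
}

abort_schema <- function(msg) rlang::abort(msg, class = "hyporules_schema_error")
abort_value <- function(msg) rlang::abort(msg, class = "hyporules_value_error")
abort_integrity <- function(msg) rlang::abort(msg, class = "hyporules_integrity_error")
abort_unresolved <- function(msg) rlang::abort(msg, class = "hyporules_unresolved_score_error")
abort_parameter <- function(msg) rlang::abort(msg, class = "hyporules_parameter_error")
abort_inconsistency <- function(msg) rlang::abort(msg, class = "hyporules_inconsistency_error")

#' Render a metric value the way the rule table prints it
#'
#' Rounds half-up at two decimals and strips trailing zeros, so 0.7272
#' renders as "0.73", 3.125 as "3.13", 2.5 as "2.5" and 1 as "1".
#' Half-up rounding is deliberate: base `round()` rounds half-to-even,
#' which would turn 3.125 into 3.12.
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @export
#' @examples
#' render_metric(c(8 / 11, 3.125, 2.5, 1))
render_metric <- function(x) {
  rounded <- round_half_up(x, 2)
  out <- formatC(rounded, format = "f", digits = 2)
  out <- sub("0+$", "", out)
  sub("\\.$", "", out)
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
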