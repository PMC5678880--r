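# End-to-end orchestration: cohort -> transactions -> itemsets -> rules ->
# selection, with stage-by-stage logging and machine-readable output.

#' Mine and select hypoxia-classification rules from a cohort
#'
#' The one-call front end: dichotomizes the cohort, mines frequent
#' itemsets, scores every marker→hypoxia rule with the five metrics, and
#' returns the top-`k`-by-lift ∪ top-`k`-by-conviction selection per
#' consequent.
#'
#' @param cohort A cohort tibble (e.g. [nb_cohort()] or [read_cohort()]).
#' @param k Selection depth per criterion per consequent (default 7).
#' @param min_count Minimum absolute support for the miner (default 1).
#' @param conviction Conviction variant, `"smoothed"` or `"classical"`.
#' @return A `hypo_selection` tibble.
#' @export
#' @examples
#' nb_cohort() |> hypoxia_rules()
hypoxia_rules <- function(cohort, k = 7, min_count = 1,
                          conviction = c("smoothed", "classical")) {
  conviction <- match.arg(conviction)
  tx <- cohort_to_transactions(cohort)
  itemsets <- apriori_frequent_itemsets(tx, min_count = min_count)
  rules <- generate_rules(itemsets, tx, conviction = conviction)
  select_rules(rules, k = k)
}

#' Run the pipeline with logging and rendered output
#'
#' Orchestrates read/simulate → dichotomize → mine → score → select →
#' render, logging counts at every stage via `message()` when `verbose`.
#' Exactly one input source must be given.
#'
#' @param input Path to a cohort CSV, or `NULL`.
#' @param fixture If `TRUE`, use the packaged 25-tumor cohort.
#' @param simulate A [sim_spec()] to generate the cohort, or `NULL`.
#' @param k,min_count,conviction Passed through to [hypoxia_rules()].
#' @param format Rendering: `"text"`, `"csv"` or `"json"`.
#' @param out Output file path, or `NULL` to return the rendering.
#' @param verbose Log stage counts.
#' @return A list with elements `selection` (the `hypo_selection`) and
#'   `rendering` (character), invisibly when written to `out`.
#' @export
run_pipeline <- function(input = NULL, fixture = FALSE, simulate = NULL,
                         k = 7, min_count = 1,
                         conviction = c("smoothed", "classical"),
                         format = c("text", "csv", "json"),
                         out = NULL, verbose = TRUE) {
  conviction <- match.arg(conviction)
  format <- match.arg(format)
  n_sources <- (!is.null(input)) + isTRUE(fixture) + (!is.null(simulate))
  if (n_sources != 1) {
    abort_parameter("exactly one of input, fixture, simulate must be given")
  }
  say <- function(...) if (verbose) message(sprintf(...))

  cohort <- if (!is.null(input)) read_cohort(input)
            else if (isTRUE(fixture)) nb_cohort()
            else simulate_cohort(simulate)
  if (nrow(cohort) == 0) abort_value("empty cohort")
  n_medium <- sum(vapply(markers(), function(m) {
    sum(bin_to_level(cohort[[paste0(m, "_percent_bin")]]) == "M")
  }, numeric(1)))
  say("read %d tumors (%d hypoxic), %d medium marker scores to resolve",
      nrow(cohort), sum(cohort$cluster == "hypoxic"), n_medium)

  tx <- cohort_to_transactions(cohort)
  itemsets <- apriori_frequent_itemsets(tx, min_count = min_count)
  say("mined %d frequent itemsets at min_count = %d", nrow(itemsets), min_count)
  rules <- generate_rules(itemsets, tx, conviction = conviction)
  say("generated %d rules", nrow(rules))
  selection <- select_rules(rules, k = k)
  say("selected %d rules (k = %d per criterion per consequent)", nrow(selection), k)

  rendering <- switch(format,
    text = format_rules(selection),
    csv = readr::format_csv(flatten_rules(selection)),
    json = jsonlite::toJSON(flatten_rules(selection), dataframe = "rows",
                            auto_unbox = TRUE, digits = NA, pretty = TRUE))
  if (!is.null(out)) {
    writeLines(as.character(rendering), out)
    return(invisible(list(selection = selection, rendering = rendering)))
  }
  list(selection = selection, rendering = rendering)
}
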