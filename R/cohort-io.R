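# Reading, validating and writing cohort tables.

cohort_required_cols <- function() {
  c("tumor_id", "cluster", paste0(markers(), "_percent_bin"))
}

cohort_all_cols <- function() {
  c("tumor_id", "cluster", "sex", "age_months", "inss_stage", "outcome",
    "histology", "mycn_amplified",
    as.vector(t(outer(markers(), c("_percent_bin", "_intensity", "_medium_resolution"),
                      paste0))))
}

#' Read a cohort table from CSV
#'
#' Reads a delimited table of tumors, one row per tumor, carrying the
#' hypoxia cluster label and the per-marker immunohistochemistry scores
#' (percentage-positivity bin, optional staining intensity, optional
#' explicit resolution of medium bins). Validation is strict: unknown
#' vocabulary strings are rejected, never coerced. Percentage bins written
#' with an ASCII hyphen ("1-20%") are accepted and normalized to the
#' canonical en-dash form.
#'
#' @param path Path to a CSV file with a header row. Required columns:
#'   `tumor_id`, `cluster`, and `<MARKER>_percent_bin` for each of HIF1A,
#'   PDK1, PHD3. Optional: `sex`, `age_months`, `inss_stage`, `outcome`,
#'   `histology`, `mycn_amplified`, and per-marker `_intensity` and
#'   `_medium_resolution` columns (defaulted to `unknown` /
#'   `not_applicable` when absent).
#' @param delim Field delimiter, default ",".
#' @return A tibble with one row per tumor and the full column set, rows in
#'   file order.
#' @seealso [nb_cohort()] for the packaged 25-tumor cohort,
#'   [write_cohort()] for the inverse.
#' @export
read_cohort <- function(path, delim = ",") {
  if (!file.exists(path)) {
    abort_schema(sprintf("cohort file does not exist: %s", path))
  }
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(cohort_required_cols(), names(df))
  if (length(missing) > 0) {
    abort_schema(sprintf("cohort file is missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  validate_cohort(as_cohort_tibble(df))
}

# Fill optional columns, set types; no validation here.
as_cohort_tibble <- function(df) {
  n <- nrow(df)
  fill_chr <- function(col, default) {
    if (col %in% names(df)) {
      x <- as.character(df[[col]])
      dplyr::coalesce(x, default)
    } else {
      rep(default, n)
    }
  }
  out <- tibble::tibble(
    tumor_id = suppressWarnings(as.integer(df$tumor_id)),
    cluster = as.character(df$cluster),
    sex = fill_chr("sex", "unknown"),
    age_months = suppressWarnings(as.numeric(fill_chr("age_months", NA_character_))),
    inss_stage = fill_chr("inss_stage", NA_character_),
    outcome = fill_chr("outcome", ""),
    histology = fill_chr("histology", "unknown"),
    mycn_amplified = fill_chr("mycn_amplified", "unknown"),
    !!!stats::setNames(
      lapply(markers(), function(m) normalize_bin(fill_chr(paste0(m, "_percent_bin"),
                                                           NA_character_))),
      paste0(markers(), "_percent_bin")),
    !!!stats::setNames(
      lapply(markers(), function(m) fill_chr(paste0(m, "_intensity"), "unknown")),
      paste0(markers(), "_intensity")),
    !!!stats::setNames(
      lapply(markers(), function(m) fill_chr(paste0(m, "_medium_resolution"),
                                             "not_applicable")),
      paste0(markers(), "_medium_resolution"))
  )
  out[, cohort_all_cols()]
}

#' Validate a cohort table
#'
#' Checks vocabulary membership for every enum column, uniqueness of
#' `tumor_id`, presence of all three marker bins, and the structural rule
#' that an explicit medium resolution may only accompany the "21–50%" bin.
#'
#' @param cohort A cohort tibble as returned by [read_cohort()].
#' @return The cohort, invisibly unchanged, for piping.
#' @export
validate_cohort <- function(cohort) {
  check_enum <- function(x, vocab, what, allow_na = FALSE) {
    bad <- which(!(x %in% vocab | (allow_na & is.na(x))))
    if (length(bad) > 0) {
      abort_value(sprintf("invalid %s at row %d: %s", what, bad[1],
                          ifelse(is.na(x[bad[1]]), "<missing>", x[bad[1]])))
    }
  }
  if (nrow(cohort) == 0) return(invisible(cohort))
  if (anyNA(cohort$tumor_id) || any(cohort$tumor_id < 1)) {
    abort_value("tumor_id must be a positive integer for every record")
  }
  if (anyDuplicated(cohort$tumor_id)) {
    dup <- cohort$tumor_id[duplicated(cohort$tumor_id)][1]
    abort_integrity(sprintf("duplicate tumor_id: %s", dup))
  }
  check_enum(cohort$cluster, cluster_levels(), "cluster")
  check_enum(cohort$sex, sex_levels(), "sex")
  check_enum(cohort$inss_stage, stage_levels(), "inss_stage", allow_na = TRUE)
  check_enum(cohort$histology, histology_levels(), "histology")
  check_enum(cohort$mycn_amplified, yesno_levels(), "mycn_amplified")
  for (m in markers()) {
    bins <- cohort[[paste0(m, "_percent_bin")]]
    check_enum(bins, percent_bins(), sprintf("%s percent bin", m))
    check_enum(cohort[[paste0(m, "_intensity")]], intensity_levels(),
               sprintf("%s intensity", m))
    res <- cohort[[paste0(m, "_medium_resolution")]]
    check_enum(res, resolution_levels(), sprintf("%s medium resolution", m))
    stray <- which(res != "not_applicable" & bins != "21–50%")
    if (length(stray) > 0) {
      abort_value(sprintf(
        "row %d: %s has medium_resolution '%s' but percent bin '%s' (only the 21–50%% bin may carry one)",
        stray[1], m, res[stray[1]], bins[stray[1]]))
    }
  }
  invisible(cohort)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(cohort, path))`
#' reproduces the cohort field for field. Bins are written in canonical
#' en-dash form, UTF-8.
#'
#' @param cohort A cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- cohort_all_cols()
  out <- cohort[, cols[cols %in% names(cohort)]]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' The packaged 25-tumor neuroblastoma cohort
#'
#' The cohort analyzed by the package's worked example: 25 pediatric
#' neuroblastoma tumors, 8 labelled hypoxic and 17 normoxic by a prior
#' microarray expression signature (the label is taken as ground truth
#' here, not recomputed), each scored by immunohistochemistry for HIF-1α,
#' PDK1 and PHD3 as a percentage-positivity bin.
#'
#' Six marker scores fall in the ambiguous "21–50%" (medium) bin. The
#' per-tumor staining intensities that originally resolved them to
#' high/low were not recorded alongside the table, so the fixture carries
#' an explicit `medium_resolution` value for each of the six cells
#' instead. These resolutions are not guesses: they are the unique
#' assignment, found by the exhaustive search of
#' [resolve_by_consistency()] over all 64 possibilities, that reproduces
#' every occurrence pair of the fourteen benchmark rules (see
#' [reference_rule_counts()]), and that derivation is re-run in the
#' package's test suite.
#'
#' @return A 25-row cohort tibble (see [read_cohort()] for columns).
#' @export
#' @examples
#' nb_cohort()
nb_cohort <- function() {
  read_cohort(system.file("extdata", "nb_cohort_25.csv", package = "hyporules",
                          mustWork = TRUE))
}
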