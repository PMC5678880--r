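# Synthetic cohorts with known latent structure.
#
# The generator emulates what the real cohort looks like statistically:
# a latent binary hypoxia status of given prevalence, three markers whose
# binary states are conditionally independent given that status and track
# it with given sensitivity/specificity ("concordant with hypoxia" means
# HIF1A high, PDK1 high, PHD3 low), re-encoded as percentage bins with an
# occasional ambiguous medium bin carrying only an intensity grade.

#' Specify a simulated cohort
#'
#' Defaults mirror the packaged 25-tumor cohort: its size, its hypoxia
#' prevalence (8/25), each marker's observed concordance rates with the
#' cluster label, and its fraction of medium-bin scores (6 of 75).
#'
#' @param n_tumors Cohort size.
#' @param prevalence P(hypoxic), in \[0, 1\].
#' @param se Per-marker sensitivity: P(marker state concordant with
#'   hypoxia | hypoxic). Scalar or named vector over HIF1A/PDK1/PHD3.
#' @param sp Per-marker specificity: P(marker state concordant with
#'   normoxia | normoxic). Scalar or named vector.
#' @param medium_fraction Probability a score is emitted as the "21–50%"
#'   bin (with an intensity grade) instead of an unambiguous bin.
#' @param seed Integer seed; the cohort is a deterministic function of
#'   the spec including the seed.
#' @return A list of class `sim_spec`.
#' @export
#' @examples
#' sim_spec(seed = 1)
sim_spec <- function(n_tumors = 25,
                     prevalence = 8 / 25,
                     se = c(HIF1A = 1, PDK1 = 0.875, PHD3 = 1),
                     sp = c(HIF1A = 14 / 17, PDK1 = 15 / 17, PHD3 = 15 / 17),
                     medium_fraction = 6 / 75,
                     seed = 1L) {
  expand <- function(x, what) {
    if (length(x) == 1) x <- stats::setNames(rep(x, 3), markers())
    if (!all(markers() %in% names(x))) {
      abort_parameter(sprintf("%s must be a scalar or named over %s", what,
                              paste(markers(), collapse = "/")))
    }
    x[markers()]
  }
  se <- expand(se, "se"); sp <- expand(sp, "sp")
  probs <- c(prevalence, se, sp, medium_fraction)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    abort_parameter("prevalence, se, sp and medium_fraction must lie in [0, 1]")
  }
  if (length(n_tumors) != 1 || is.na(n_tumors) || n_tumors < 1) {
    abort_parameter("n_tumors must be a positive integer")
  }
  structure(list(n_tumors = as.integer(n_tumors), prevalence = prevalence,
                 se = se, sp = sp, medium_fraction = medium_fraction,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# Marker polarity concordant with hypoxia.
hypoxia_concordant_state <- function() {
  c(HIF1A = "high", PDK1 = "high", PHD3 = "low")
}

#' Simulate a cohort
#'
#' Draws latent hypoxia ~ Bernoulli(prevalence) per tumor; each marker
#' takes its hypoxia-concordant state with probability `se` under hypoxia
#' and its normoxia-concordant state with probability `sp` under
#' normoxia. A binary "high" is emitted as a bin drawn uniformly from
#' {"51–70%", "71–100%"} and a "low" from {"<1%", "1–20%"}, except that
#' with probability `medium_fraction` the bin is "21–50%" with intensity
#' strong or moderate (high) or weak (low), leaving resolution to the
#' intensity policy of [resolve_binary()].
#'
#' @param spec A [sim_spec()].
#' @return A cohort tibble; clinical covariates other than the cluster
#'   label are filled with `unknown`.
#' @export
#' @examples
#' simulate_cohort(sim_spec(n_tumors = 10, seed = 42))
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n_tumors
  hypoxic <- stats::runif(n) < spec$prevalence
  cohort <- tibble::tibble(
    tumor_id = seq_len(n),
    cluster = ifelse(hypoxic, "hypoxic", "normoxic"),
    sex = "unknown", age_months = NA_real_, inss_stage = NA_character_,
    outcome = "", histology = "unknown", mycn_amplified = "unknown")

  concordant <- hypoxia_concordant_state()
  for (m in markers()) {
    track <- ifelse(hypoxic,
                    stats::runif(n) < spec$se[[m]],
                    stats::runif(n) < spec$sp[[m]])
    # the state concordant with each tumor's true status, flipped on miss
    with_hyp <- concordant[[m]]
    against <- if (with_hyp == "high") "low" else "high"
    truth_state <- ifelse(hypoxic, with_hyp, against)
    state <- ifelse(track, truth_state,
                    ifelse(truth_state == "high", "low", "high"))
    is_medium <- stats::runif(n) < spec$medium_fraction
    upper <- stats::runif(n) < 0.5
    bin <- ifelse(is_medium, "21–50%",
                  ifelse(state == "high",
                         ifelse(upper, "71–100%", "51–70%"),
                         ifelse(upper, "1–20%", "<1%")))
    strong <- stats::runif(n) < 0.5
    intensity <- ifelse(is_medium,
                        ifelse(state == "high",
                               ifelse(strong, "strong", "moderate"), "weak"),
                        "unknown")
    cohort[[paste0(m, "_percent_bin")]] <- bin
    cohort[[paste0(m, "_intensity")]] <- intensity
    cohort[[paste0(m, "_medium_resolution")]] <- "not_applicable"
  }
  validate_cohort(cohort)
}

#' Closed-form single-marker rule metrics implied by a simulation spec
#'
#' For the rule {marker = hypoxia-concordant state} → {HYPOXIA=high}, the
#' population confidence is the positive predictive value
#' `pi*se / (pi*se + (1-pi)*(1-sp))` and the lift is that PPV divided by
#' the prevalence `pi`. The generator's bin encoding and intensity policy
#' are lossless, so mined metrics converge to these values as the cohort
#' grows.
#'
#' @param spec A [sim_spec()].
#' @return A tibble with one row per marker: `marker`, `ppv`, `lift`.
#' @export
expected_rule_metrics <- function(spec) {
  pi <- spec$prevalence
  ppv <- pi * spec$se / (pi * spec$se + (1 - pi) * (1 - spec$sp))
  tibble::tibble(marker = markers(), ppv = unname(ppv),
                 lift = unname(ppv / pi))
}

#' Parameter-recovery experiment
#'
#' Runs the full pipeline (simulate → dichotomize → mine → score) on
#' `n_replicates` cohorts drawn from `spec` with derived seeds
#' (`spec$seed + replicate index`), extracts the three single-marker
#' hypoxia-concordant rules, and summarizes their confidence and lift
#' against the closed forms of [expected_rule_metrics()].
#'
#' @param spec A [sim_spec()].
#' @param n_replicates Number of replicate cohorts.
#' @return A tibble with one row per marker: observed means and standard
#'   deviations of confidence and lift, and the expected values.
#' @export
recovery_experiment <- function(spec, n_replicates = 10) {
  if (n_replicates < 1) abort_parameter("n_replicates must be >= 1")
  concordant <- hypoxia_concordant_state()
  per_rep <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    rspec <- spec
    rspec$seed <- spec$seed + r
    tx <- cohort_to_transactions(simulate_cohort(rspec))
    rules <- generate_rules(apriori_frequent_itemsets(tx), tx)
    single <- rules[lengths(rules$antecedent) == 1 &
                      rules$consequent == "HYPOXIA=high", ]
    keys <- unlist(single$antecedent)
    target <- paste0(markers(), "=", concordant)
    idx <- match(target, keys)
    tibble::tibble(replicate = r, marker = markers(),
                   confidence = single$confidence[idx],
                   lift = single$lift[idx])
  })
  obs <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$marker),
    mean_confidence = mean(.data$confidence),
    sd_confidence = stats::sd(.data$confidence),
    mean_lift = mean(.data$lift),
    sd_lift = stats::sd(.data$lift),
    .groups = "drop")
  dplyr::left_join(obs, expected_rule_metrics(spec), by = "marker")
}
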