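# Selecting and presenting the reported rule set.

ante_key <- function(antecedent) {
  vapply(antecedent, function(a) paste(sort(a), collapse = " & "), character(1))
}

# Rank by a metric, ties broken by smaller antecedent then item order.
top_k_by <- function(rules, metric, k) {
  ord <- order(-rules[[metric]],
               lengths(rules$antecedent),
               ante_key(rules$antecedent))
  rules[ord[seq_len(min(k, nrow(rules)))], ]
}

#' Select the top rules by lift and by conviction
#'
#' For each consequent polarity, takes the union of the `k` highest-lift
#' and the `k` highest-conviction rules (deduplicated; ties broken by
#' smaller antecedent, then lexicographic item order) among rules whose
#' antecedent support clears `min_support`. Each selected rule records
#' which criterion admitted it (`"lift"`, `"conviction"` or `"both"`).
#' Rules predicting `HYPOXIA=high` precede those predicting
#' `HYPOXIA=low`, and within a block rules are ordered by antecedent size
#' then marker order, labelled R1, R2, ...
#'
#' The support floor plays the role of the minimum-support parameter any
#' APRIORI run has: without it, antecedents matching a single tumor reach
#' confidence 1 and tie the maximal lift, flooding the selection with
#' unstable one-off rules. The default of 0.15 (at least 4 of 25 tumors)
#' is the package's declared choice, validated end to end on the packaged
#' cohort, where it yields exactly the fourteen benchmark rules: over
#' three binary markers there are exactly 7 polarity-consistent
#' antecedents per consequent, so `k = 7` returns a 14-rule report.
#'
#' @param rules A `hypo_rules` tibble from [generate_rules()].
#' @param k Selection depth per criterion per consequent; default 7.
#' @param min_support Minimum antecedent support as a fraction of
#'   transactions; a rule needs `nA >= ceiling(min_support * N)` to be
#'   eligible. Set to 0 to disable.
#' @return A tibble of class `hypo_selection`: `rule_id`, the rule
#'   columns, and `selected_by`.
#' @export
#' @examples
#' tx <- cohort_to_transactions(nb_cohort())
#' select_rules(generate_rules(apriori_frequent_itemsets(tx), tx))
select_rules <- function(rules, k = 7, min_support = 0.15) {
  if (nrow(rules) == 0) abort_parameter("no rules to select from")
  if (length(k) != 1 || is.na(k) || k < 1) abort_parameter("k must be a positive integer")
  if (min_support < 0 || min_support > 1) {
    abort_parameter("min_support must lie in [0, 1]")
  }
  floor_count <- ceiling(min_support * rules$N[1])
  eligible <- dplyr::filter(rules, .data$nA >= floor_count)
  if (nrow(eligible) == 0) {
    abort_parameter("no rules clear the antecedent support floor")
  }

  consequents <- intersect(c("HYPOXIA=high", "HYPOXIA=low"),
                           unique(eligible$consequent))
  consequents <- c(consequents,
                   setdiff(unique(eligible$consequent), consequents))

  blocks <- purrr::map_dfr(consequents, function(cq) {
    sub <- dplyr::filter(eligible, .data$consequent == cq)
    if (k > nrow(sub)) {
      rlang::warn(sprintf(
        "k = %d exceeds the %d available rules for consequent %s; selecting all",
        k, nrow(sub), cq))
    }
    by_lift <- ante_key(top_k_by(sub, "lift", k)$antecedent)
    by_conv <- ante_key(top_k_by(sub, "conviction", k)$antecedent)
    keys <- ante_key(sub$antecedent)
    sel <- sub[keys %in% union(by_lift, by_conv), ]
    sel$selected_by <- dplyr::case_when(
      ante_key(sel$antecedent) %in% intersect(by_lift, by_conv) ~ "both",
      ante_key(sel$antecedent) %in% by_lift ~ "lift",
      TRUE ~ "conviction")
    # presentation order: antecedent size, then marker order
    sel[order(lengths(sel$antecedent), ante_key(sel$antecedent)), ]
  })
  blocks$rule_id <- paste0("R", seq_len(nrow(blocks)))
  out <- dplyr::relocate(blocks, "rule_id")
  class(out) <- c("hypo_selection", "hypo_rules", setdiff(class(blocks), "hypo_rules"))
  out
}

#' @export
print.hypo_selection <- function(x, ...) {
  cat(sprintf("Selected association rules (%d rules, N = %s transactions)\n\n",
              nrow(x), if (nrow(x)) x$N[1] else "?"))
  cat(format_rules(x), sep = "\n")
  invisible(x)
}

#' Render rules as an IF/THEN text table
#'
#' One line per rule in the layout
#' `R1  IF HIF1A=high THEN HYPOXIA=high  [11 8]  cov 1 conf 0.73 ...`,
#' with metrics printed at two decimals, trailing zeros stripped.
#'
#' @param x A `hypo_rules` or `hypo_selection` tibble.
#' @return A character vector, one element per rule.
#' @export
format_rules <- function(x) {
  id <- if ("rule_id" %in% names(x)) x$rule_id else paste0("r", seq_len(nrow(x)))
  vapply(seq_len(nrow(x)), function(i) {
    sprintf("%-4s IF %s THEN %s  [%d %d]  cov %s conf %s lift %s lev %s conv %s",
            id[i], paste(x$antecedent[[i]], collapse = " AND "), x$consequent[i],
            x$nA[i], x$nAB[i],
            render_metric(x$coverage[i]), render_metric(x$confidence[i]),
            render_metric(x$lift[i]), render_metric(x$leverage[i]),
            render_metric(x$conviction[i]))
  }, character(1))
}

#' Flatten a rule table for export
#'
#' Collapses the antecedent list-column to a single `" & "`-separated
#' string so the table can be written as CSV/JSON.
#'
#' @param x A `hypo_rules` or `hypo_selection` tibble.
#' @return A plain tibble.
#' @export
flatten_rules <- function(x) {
  out <- tibble::as_tibble(x)
  out$antecedent <- ante_key(out$antecedent)
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a selection report
#'
#' @param x A `hypo_selection` object.
#' @param ... Unused.
#' @return `tidy()`: one row per rule with the antecedent flattened to a
#'   string. `glance()`: a one-row summary (rule count, transactions,
#'   consequent tally).
#' @export
tidy.hypo_selection <- function(x, ...) flatten_rules(x)

#' @rdname tidy.hypo_selection
#' @export
glance.hypo_selection <- function(x, ...) {
  tibble::tibble(
    n_rules = nrow(x),
    n_transactions = if (nrow(x)) x$N[1] else NA_integer_,
    n_high = sum(x$consequent == "HYPOXIA=high"),
    n_low = sum(x$consequent == "HYPOXIA=low"),
    min_confidence = min(x$confidence),
    max_lift = max(x$lift)
  )
}

#' Plot a selection report
#'
#' Scatter of lift against conviction, one point per rule, colored by
#' consequent and labelled with the rule id; the admitting criterion maps
#' to shape. A quick visual of which rules dominate on which metric.
#'
#' @param object A `hypo_selection` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hypo_selection <- function(object, ...) {
  df <- flatten_rules(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lift, y = .data$conviction,
                                   color = .data$consequent,
                                   shape = .data$selected_by)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$rule_id),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "Lift", y = "Conviction (smoothed)",
                  color = "Consequent", shape = "Selected by") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tile plot of per-tumor marker levels
#'
#' Shows each tumor's L/M/H level per marker, faceted by cluster — the
#' cohort at a glance, medium cells standing out as the ones needing
#' resolution.
#'
#' @param cohort A cohort tibble.
#' @return A ggplot object.
#' @export
plot_marker_levels <- function(cohort) {
  df <- purrr::map_dfr(markers(), function(m) {
    tibble::tibble(tumor_id = cohort$tumor_id, cluster = cohort$cluster,
                   marker = m,
                   level = bin_to_level(cohort[[paste0(m, "_percent_bin")]]))
  })
  df$level <- factor(df$level, levels = c("L", "M", "H"))
  ggplot2::ggplot(df, ggplot2::aes(x = marker, y = factor(.data$tumor_id),
                                   fill = .data$level)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_manual(values = c(L = "#74add1", M = "#fee090",
                                          H = "#d73027")) +
    ggplot2::labs(x = NULL, y = "Tumor", fill = "Level") +
    ggplot2::theme_minimal()
}
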