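fixture_selection <- function(...) {
  tx <- cohort_to_transactions(nb_cohort())
  select_rules(generate_rules(apriori_frequent_itemsets(tx), tx), ...)
}

test_that("the fixture selection yields the fourteen benchmark patterns", {
  sel <- fixture_selection(k = 7)
  expect_equal(nrow(sel), 14)
  expect_equal(sum(sel$consequent == "HYPOXIA=high"), 7)
  expect_equal(sum(sel$consequent == "HYPOXIA=low"), 7)
  # high-hypoxia block antecedents are exactly the 7 polarity-consistent sets
  high <- sel$antecedent[sel$consequent == "HYPOXIA=high"]
  H <- "HIF1A=high"; P <- "PDK1=high"; D <- "PHD3=low"
  expected <- list(c(H), c(P), c(D), c(H, D), c(H, P), c(P, D), c(H, P, D))
  expect_setequal(purrr::map_chr(high, ~paste(sort(.x), collapse = " & ")),
                  purrr::map_chr(expected, ~paste(sort(.x), collapse = " & ")))
  # labels consecutive, high block first
  expect_equal(sel$rule_id, paste0("R", 1:14))
  expect_equal(sel$consequent[1:7], rep("HYPOXIA=high", 7))
})

test_that("selection is idempotent-sized and invariant to input order", {
  tx <- cohort_to_transactions(nb_cohort())
  rules <- generate_rules(apriori_frequent_itemsets(tx), tx)
  sel1 <- select_rules(rules, k = 7)
  set.seed(5)
  shuffled <- rules[sample(nrow(rules)), ]
  sel2 <- select_rules(shuffled, k = 7)
  expect_equal(flatten_rules(sel1), flatten_rules(sel2))
  # reselecting from the selection returns the same rules
  sel3 <- select_rules(sel1, k = 7)
  expect_setequal(flatten_rules(sel3)$antecedent, flatten_rules(sel1)$antecedent)
})

test_that("every selected rule dominates unselected eligible rules on its criterion", {
  tx <- cohort_to_transactions(nb_cohort())
  rules <- generate_rules(apriori_frequent_itemsets(tx), tx)
  sel <- select_rules(rules, k = 7, min_support = 0.15)
  floor_count <- ceiling(0.15 * rules$N[1])
  keys <- purrr::map2_chr(rules$antecedent, rules$consequent,
                          ~paste(paste(sort(.x), collapse = " & "), .y))
  sel_keys <- purrr::map2_chr(sel$antecedent, sel$consequent,
                              ~paste(paste(sort(.x), collapse = " & "), .y))
  unselected <- rules[!(keys %in% sel_keys) & rules$nA >= floor_count, ]
  for (i in seq_len(nrow(sel))) {
    rivals <- unselected[unselected$consequent == sel$consequent[i], ]
    if (nrow(rivals) == 0) next
    if (sel$selected_by[i] %in% c("lift", "both")) {
      expect_gte(sel$lift[i], max(rivals$lift))
    }
    if (sel$selected_by[i] %in% c("conviction", "both")) {
      expect_gte(sel$conviction[i], max(rivals$conviction))
    }
  }
})

test_that("a lone well-supported rule is selected once with trace both", {
  one <- generate_rules(
    apriori_frequent_itemsets(cohort_to_transactions(tiny_cohort())),
    cohort_to_transactions(tiny_cohort()))
  one <- one[1, ]
  expect_warning(sel <- select_rules(one, k = 7), "selecting all")
  expect_equal(nrow(sel), 1)
  expect_equal(sel$selected_by, "both")
})

test_that("the support floor is what excludes single-tumor lift ties", {
  sel_unfloored <- suppressWarnings(fixture_selection(k = 7, min_support = 0))
  expect_gt(nrow(sel_unfloored), 14)
  keys <- purrr::map_chr(sel_unfloored$antecedent,
                         ~paste(sort(.x), collapse = " & "))
  expect_true("HIF1A=high & PDK1=low & PHD3=low" %in% keys)
})

test_that("tidy and glance summarize a selection", {
  sel <- fixture_selection()
  td <- tidy(sel)
  expect_s3_class(td, "tbl_df")
  expect_type(td$antecedent, "character")
  gl <- glance(sel)
  expect_equal(gl$n_rules, 14)
  expect_equal(gl$n_transactions, 25)
  expect_equal(gl$n_high, 7)
})

test_that("autoplot and the marker-level plot build without error", {
  sel <- fixture_selection()
  expect_s3_class(ggplot2::autoplot(sel), "ggplot")
  expect_s3_class(plot_marker_levels(nb_cohort()), "ggplot")
})
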