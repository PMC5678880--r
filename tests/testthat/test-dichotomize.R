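test_that("bin_to_level is total on the vocabulary and order-preserving", {
  expect_equal(bin_to_level(percent_bins()), c("L", "L", "M", "H", "H"))
  # order-preserving: level rank never decreases along the bin ordering
  rank <- match(bin_to_level(percent_bins()), c("L", "M", "H"))
  expect_true(all(diff(rank) >= 0))
  expect_equal(bin_to_level("71-100%"), "H")  # hyphen alias
  expect_error(bin_to_level("70–100%"), class = "hyporules_value_error")
})

test_that("resolve_binary follows levels, explicit resolutions, then intensity", {
  expect_equal(resolve_binary(c("<1%", "1–20%", "51–70%", "71–100%")),
               c("low", "low", "high", "high"))
  # explicit resolution wins over intensity
  expect_equal(resolve_binary("21–50%", intensity = "weak",
                              medium_resolution = "high"), "high")
  # intensity policy: strong/moderate -> high, weak -> low
  expect_equal(resolve_binary("21–50%", intensity = c("strong", "moderate", "weak")),
               c("high", "high", "low"))
  expect_error(resolve_binary("21–50%", context = "tumor 9, marker PDK1"),
               "tumor 9, marker PDK1",
               class = "hyporules_unresolved_score_error")
})

test_that("the packaged resolutions resolve the six medium cells as audited", {
  co <- nb_cohort()
  pick <- function(id, m) {
    i <- which(co$tumor_id == id)
    resolve_binary(co[[paste0(m, "_percent_bin")]][i],
                   co[[paste0(m, "_intensity")]][i],
                   co[[paste0(m, "_medium_resolution")]][i])
  }
  expect_equal(pick(7, "PDK1"), "low")
  expect_equal(pick(13, "PDK1"), "high")
  expect_equal(pick(16, "PHD3"), "low")
  expect_equal(pick(23, "HIF1A"), "high")
  expect_equal(pick(24, "HIF1A"), "high")
  expect_equal(pick(24, "PDK1"), "high")
})

test_that("the fixture transaction table reproduces the benchmark item counts", {
  tx <- cohort_to_transactions(nb_cohort())
  counts <- tibble::deframe(item_counts(tx))
  expect_equal(counts[["HYPOXIA=high"]], 8)
  expect_equal(counts[["HYPOXIA=low"]], 17)
  expect_equal(counts[["HIF1A=high"]], 11)
  expect_equal(counts[["PDK1=high"]], 9)
  expect_equal(counts[["PHD3=low"]], 10)
})

test_that("every transaction carries exactly one polarity per marker and one hypoxia item", {
  for (co in list(nb_cohort(),
                  simulate_cohort(sim_spec(n_tumors = 60, medium_fraction = 0.3,
                                           seed = 3)))) {
    tx <- cohort_to_transactions(co)
    for (m in c(markers(), "HYPOXIA")) {
      expect_equal(tx[[paste0(m, "=high")]] + tx[[paste0(m, "=low")]],
                   rep(1L, nrow(tx)))
    }
  }
})

test_that("with no medium cells, transactions are invariant to intensities", {
  co <- tiny_cohort()
  alt <- co
  for (m in markers()) alt[[paste0(m, "_intensity")]] <- "strong"
  expect_identical(cohort_to_transactions(co), cohort_to_transactions(alt))
})

test_that("transaction export writes one-hot CSV and basket text consistently", {
  tx <- cohort_to_transactions(tiny_cohort())
  onehot <- withr::local_tempfile(fileext = ".csv")
  basket <- withr::local_tempfile(fileext = ".txt")
  write_transactions(tx, onehot, "onehot")
  write_transactions(tx, basket, "basket")

  back <- readr::read_csv(onehot, col_types = readr::cols())
  expect_equal(as.data.frame(back), as.data.frame(tx))

  lines <- readLines(basket)
  expect_length(lines, nrow(tx))
  expect_setequal(strsplit(lines[1], " ")[[1]],
                  c("HIF1A=high", "PDK1=high", "PHD3=low", "HYPOXIA=high"))
})
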