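test_that("metrics reproduce frozen benchmark examples from integer counts", {
  # confidence
  expect_equal(round_to_printed(rule_confidence(nA = 11, nAB = 8)), 0.73)
  expect_equal(round_to_printed(rule_confidence(nA = 16, nAB = 15)), 0.94)
  expect_equal(rule_confidence(nA = 7, nAB = 7), 1)
  # coverage is consequent recall nAB/nB, not antecedent support
  expect_equal(round_to_printed(rule_coverage(nB = 17, nAB = 14)), 0.82)
  expect_equal(round_to_printed(rule_coverage(nB = 17, nAB = 11)), 0.65)
  expect_equal(rule_coverage(nB = 8, nAB = 8), 1)
  # lift
  expect_equal(round_to_printed(rule_lift(25, 8, 8, 8)), 3.13)
  expect_equal(round_to_printed(rule_lift(25, 14, 17, 14)), 1.47)
  # leverage
  expect_equal(round_to_printed(rule_leverage(25, 8, 8, 8)), 0.22)
  expect_equal(round_to_printed(rule_leverage(25, 7, 8, 7)), 0.19)
  # smoothed conviction, exact rationals
  expect_equal(rule_conviction(25, 11, 8, 8), 187 / 100)
  expect_equal(rule_conviction(25, 8, 8, 8), 136 / 25)
  expect_equal(rule_conviction(25, 14, 17, 14), 112 / 25)
})

test_that("independence makes lift 1 and leverage 0", {
  expect_equal(rule_lift(100, 20, 50, 10), 1)
  expect_equal(rule_leverage(100, 20, 50, 10), 0)
})

test_that("metrics agree with direct arithmetic and bounds on random counts", {
  set.seed(23)
  for (i in 1:200) {
    c0 <- random_rule_counts()
    with(c0, {
      expect_equal(rule_confidence(nA, nAB), nAB / nA)
      expect_equal(rule_coverage(nB, nAB), nAB / nB)
      expect_equal(rule_lift(N, nA, nB, nAB), (nAB / nA) * N / nB)
      expect_equal(rule_leverage(N, nA, nB, nAB), (nAB * N - nA * nB) / N^2)
      expect_equal(rule_conviction(N, nA, nB, nAB),
                   nA * (N - nB) / (N * (nA - nAB + 1)))
      # bounds
      expect_true(rule_confidence(nA, nAB) >= 0 && rule_confidence(nA, nAB) <= 1)
      expect_true(rule_coverage(nB, nAB) >= 0 && rule_coverage(nB, nAB) <= 1)
      expect_gte(rule_lift(N, nA, nB, nAB), 0)
      expect_true(abs(rule_leverage(N, nA, nB, nAB)) <= 0.25)
      conv <- rule_conviction(N, nA, nB, nAB)
      expect_true(conv >= 0 && is.finite(conv))
    })
  }
})

test_that("smoothed conviction undercuts the classical value and converges to it", {
  set.seed(31)
  for (i in 1:50) {
    c0 <- random_rule_counts()
    if (c0$nAB == c0$nA) next
    smoothed <- with(c0, rule_conviction(N, nA, nB, nAB))
    classical <- with(c0, rule_conviction(N, nA, nB, nAB, variant = "classical"))
    expect_lt(smoothed, classical)
    # scaling all counts by s shrinks the +1 smoothing's share to nothing
    s <- 1000
    scaled <- with(c0, rule_conviction(N * s, nA * s, nB * s, nAB * s))
    expect_equal(scaled, classical, tolerance = 1e-2)
  }
  # confidence-1 rules: classical diverges, smoothed stays finite
  expect_equal(rule_conviction(25, 8, 8, 8, variant = "classical"), Inf)
  expect_true(is.finite(rule_conviction(25, 8, 8, 8)))
})

test_that("undefined-count cases raise parameter errors", {
  expect_error(rule_confidence(nA = 0, nAB = 0), class = "hyporules_parameter_error")
  expect_error(rule_coverage(nB = 0, nAB = 0), class = "hyporules_parameter_error")
  expect_error(rule_lift(10, 0, 5, 0), class = "hyporules_parameter_error")
  expect_error(rule_counts(10, 5, 5, 6), class = "hyporules_parameter_error")
})

test_that("metric rendering prints two decimals with trailing zeros stripped", {
  expect_equal(render_metric(c(8 / 11, 3.125, 2.5, 1, 4.8)),
               c("0.73", "3.13", "2.5", "1", "4.8"))
})
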