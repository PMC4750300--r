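test_that("ICC(A,1): perfect agreement, bias penalty, degenerate input", {
  x <- c(1, 2.5, 3.1, 4.8, 5.2)
  expect_equal(icc_absolute_agreement(x, x), 1)
  # constant offset: absolute agreement drops well below Pearson r
  y <- x + 10
  expect_lt(icc_absolute_agreement(x, y), stats::cor(x, y))
  expect_warning(icc0 <- icc_absolute_agreement(rep(2, 5), rep(2, 5)),
    "zero total variance")
  expect_equal(icc0, 1)
  expect_error(icc_absolute_agreement(c(1, NA), c(1, 2)), "non-finite")
  expect_error(icc_absolute_agreement(1, 2), "at least 2")
})

test_that("ICC matches the ANOVA mean-squares oracle on the 6-pair fixture", {
  a <- c(1, 2, 3, 4, 5, 6)
  b <- c(1.1, 1.9, 3.2, 3.8, 5.1, 6.0)
  expect_equal(icc_absolute_agreement(a, b), icc_a1_oracle(a, b),
    tolerance = 1e-12)
})

test_that("ICC equals the oracle on random paired fixtures and is exchangeable", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    a <- rnorm(n, 3, 0.8)
    b <- a + rnorm(n, 0.2, 0.3)
    expect_equal(icc_absolute_agreement(a, b), icc_a1_oracle(a, b),
      tolerance = 1e-9)
    perm <- sample(n)
    expect_equal(
      icc_absolute_agreement(a[perm], b[perm]),
      icc_absolute_agreement(a, b),
      tolerance = 1e-12
    )
    expect_lte(icc_absolute_agreement(a, b), 1)
  }
})

test_that("Landis-Koch banding follows the caption's strict inequalities", {
  expect_equal(landis_koch_label(0.74), "substantial")
  expect_equal(landis_koch_label(0.91), "almost perfect")
  expect_equal(landis_koch_label(0.15), "slight")
  # boundary values fall in the lower band
  expect_equal(
    landis_koch_label(c(0.2, 0.4, 0.6, 0.8)),
    c("slight", "fair", "moderate", "substantial")
  )
  expect_equal(landis_koch_label(-0.3), "slight")
  expect_error(landis_koch_label(NaN), "finite")
})

test_that("Bland-Altman: hand-computed fixture and antisymmetry", {
  a <- c(1, 2, 3, 4)
  b <- a - c(0.1, 0.3, -0.2, 0.4) # differences d = a - b
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, 0.15, tolerance = 1e-12)
  expect_equal(ba$sd, sqrt(0.07), tolerance = 1e-12)
  expect_equal(ba$loa_low, 0.15 - 1.96 * sqrt(0.07), tolerance = 1e-12)
  expect_equal(ba$loa_high, 0.15 + 1.96 * sqrt(0.07), tolerance = 1e-12)
  # swap antisymmetry
  ba2 <- bland_altman(b, a)
  expect_equal(ba2$bias, -ba$bias)
  expect_equal(ba2$sd, ba$sd)
  expect_equal(ba2$loa_high - ba2$loa_low, ba$loa_high - ba$loa_low)
  # identical methods
  ba3 <- bland_altman(a, a)
  expect_equal(c(ba3$bias, ba3$sd, ba3$loa_low, ba3$loa_high), rep(0, 4))
  td <- tidy(ba)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$n, 4L)
})

test_that("pooled t-test matches the closed-form oracle", {
  g1 <- c(1, 2, 3)
  g2 <- c(4, 5, 6)
  tt <- ttest_independent(g1, g2)
  # textbook pooled formula, coded independently
  sp2 <- ((length(g1) - 1) * var(g1) + (length(g2) - 1) * var(g2)) /
    (length(g1) + length(g2) - 2)
  t_oracle <- (mean(g1) - mean(g2)) /
    sqrt(sp2 * (1 / length(g1) + 1 / length(g2)))
  expect_equal(tt$t, t_oracle, tolerance = 1e-12)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 2 * pt(t_oracle, 4), tolerance = 1e-12)
  expect_equal(tt$label1, "2.00 ± 1.00")

  # identical groups and within-group permutation invariance
  same <- ttest_independent(g1, g1)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_equal(
    ttest_independent(g1, g2[c(3, 1, 2)])[, c("t", "p_value")],
    tt[, c("t", "p_value")]
  )
  expect_error(ttest_independent(1, g2), "n >= 2")
  expect_error(ttest_independent(c(1, 1), c(2, 2)), "zero pooled variance")
})

test_that("method_agreement pairs by cilium and reports ICC + Bland-Altman", {
  meas <- tibble::tibble(
    cilium_id = rep(sprintf("c%d", 1:6), 2),
    method = rep(c("PYT", "DAAS"), each = 6),
    length_um = c(1, 2, 3, 4, 5, 6, 1.1, 1.9, 3.2, 3.8, 5.1, 6.0)
  )
  ag <- method_agreement(meas, "PYT", "DAAS")
  expect_equal(ag$icc, icc_a1_oracle(meas$length_um[1:6],
    meas$length_um[7:12]), tolerance = 1e-12)
  expect_equal(ag$n, 6L)
  expect_equal(tidy(ag)$method_a, "PYT")
  expect_error(method_agreement(meas, "PYT", "MIP"), "present")
})

test_that("compare_methods reproduces trivial cohorts and validates input", {
  meas <- tidyr::expand_grid(
    cilium_id = sprintf("c%02d", 1:8),
    method = c("MIP", "PYT", "DAAS")
  )
  meas$length_um <- 3 # identical everywhere
  meas$classification <- rep(c("FLAT", "ANGLED"), each = 12)
  cmp <- suppressWarnings(compare_methods(meas))
  expect_true(all(cmp$agreement$icc == 1))
  expect_true(all(cmp$agreement$bias == 0))
  expect_equal(glance(cmp)$n_cilia, 8L)
  expect_error(compare_methods(meas[-1, ]), "every cilium")
})
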