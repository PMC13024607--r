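test_that("Welch t and d work identically from raw data and printed summaries", {
  withr::with_seed(3, {
    a <- rnorm(40, 0, 1); b <- rnorm(60, 0.5, 1.4)
  })
  raw <- welch_t(a, b)
  summ <- welch_t(list(m = mean(a), sd = sd(a), n = 40),
                  list(m = mean(b), sd = sd(b), n = 60))
  expect_equal(raw$t, summ$t, tolerance = 1e-12)
  expect_equal(raw$df_welch, summ$df_welch, tolerance = 1e-12)

  # independent cross-check against stats::t.test
  tt <- t.test(b, a)
  expect_equal(raw$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(raw$df_welch, unname(tt$parameter), tolerance = 1e-9)
  expect_equal(raw$p, tt$p.value, tolerance = 1e-9)

  # identical groups
  same <- welch_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$d, 0)
})

test_that("printed gender summaries reproduce the rounded-summary statistics", {
  # female (1.67, 0.42, 1289) vs male (2.18, 0.53, 1666)
  res <- welch_t(list(m = 1.67, sd = 0.42, n = 1289),
                 list(m = 2.18, sd = 0.53, n = 1666))
  expect_equal(res$t, 29.2, tolerance = 0.01)
  expect_equal(res$d, 1.05, tolerance = 0.005)
  expect_true(res$d_lo < res$d && res$d < res$d_hi)
})

test_that("d is antisymmetric and invariant under common affine maps", {
  withr::with_seed(5, { a <- rnorm(30); b <- rnorm(30, 1) })
  d1 <- cohens_d(a, b)$d
  expect_equal(cohens_d(b, a)$d, -d1, tolerance = 1e-12)
  expect_equal(cohens_d(2 * a + 3, 2 * b + 3)$d, d1, tolerance = 1e-12)
  expect_equal(welch_t(2 * a + 3, 2 * b + 3)$t, welch_t(a, b)$t,
               tolerance = 1e-12)
  expect_equal(effect_benchmark(0.20), "small")
  expect_equal(effect_benchmark(0.064, "eta_sq"), "medium")
})

test_that("chi-square reproduces the published demographic tests exactly", {
  tabs <- demographic_tables()
  school <- chi_square(tabs$school)
  expect_equal(round(school$chi2, 2), 56.27)
  expect_equal(school$df, 2)
  expect_equal(round(school$cramers_v, 2), 0.14)
  expect_false(school$yates_applied)
  expect_equal(round(chi_square(tabs$citizenship)$chi2, 2), 6.72) # Yates 2x2
  expect_true(chi_square(tabs$citizenship)$yates_applied)
  expect_equal(round(chi_square(tabs$only_child)$chi2, 2), 0.64)
  expect_equal(round(chi_square(tabs$parental_education)$chi2, 2), 5.94)
  expect_equal(round(chi_square(tabs$household_income)$chi2, 2), 5.48)
  expect_equal(round(chi_square(tabs$academic_performance)$chi2, 2), 2.07)
})

test_that("continuity correction only reduces the 2x2 statistic", {
  tab <- matrix(c(30, 20, 18, 32), 2, 2)
  with_c <- chi_square(tab, continuity = TRUE)$chi2
  without <- chi_square(tab, continuity = FALSE)$chi2
  expect_lt(with_c, without)
  expect_equal(chi_square(matrix(c(10, 10, 10, 10), 2), continuity = FALSE)$chi2, 0)
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})

test_that("one-way eta-squared satisfies the F identity and the trivial pole", {
  withr::with_seed(8, {
    y <- c(rnorm(50), rnorm(60, 0.4), rnorm(40, 0.8))
    g <- rep(c("a", "b", "c"), c(50, 60, 40))
  })
  res <- anova_oneway(y, g)
  expect_equal(res$eta_sq,
               res$F * res$df1 / (res$F * res$df1 + res$df2),
               tolerance = 1e-12)
  # identity applied to a published row: F=100.85 on (2, 2952)
  expect_equal(100.85 * 2 / (100.85 * 2 + 2952), 0.064, tolerance = 1e-3)

  same <- anova_oneway(rep(c(1, 2, 1, 2), 3), rep(c("a", "b", "c"), each = 4))
  expect_equal(same$eta_sq, 0, tolerance = 1e-12)
})

test_that("factorial decomposition matches the balanced-design hand computation", {
  # balanced 2x3, 2 observations per cell, additive cell means
  gender <- rep(c("F", "M"), each = 6)
  school <- rep(rep(c("academic", "technical", "vocational"), each = 2), 2)
  y <- rep(c(1, 2, 3, 2, 3, 4), each = 2) + rep(c(-0.1, 0.1), 6)
  res <- anova_factorial(y, gender, school)
  # additive cell means -> zero interaction SS
  expect_equal(res$F[res$effect == "gender:school"], 0, tolerance = 1e-9)
  # main-effect SS for gender: n_per_level * (marginal deviation)^2 summed
  ss_gender <- 6 * sum((c(2, 3) - 2.5)^2)
  ss_res <- 12 * 0.01
  expect_equal(res$partial_eta_sq[res$effect == "gender"],
               ss_gender / (ss_gender + ss_res), tolerance = 1e-9)
  # empty male-vocational cell
  keep <- !(gender == "M" & school == "vocational")
  expect_error(anova_factorial(y[keep], gender[keep], school[keep]),
               "empty cell")
})

test_that("Games-Howell flags only genuinely shifted pairs", {
  withr::with_seed(13, {
    y <- c(rnorm(200), rnorm(200), rnorm(200, 2)) # third group shifted 2 sd
    g <- rep(c("a", "b", "c"), each = 200)
  })
  gh <- games_howell(y, g)
  p_ab <- gh$p[gh$group1 == "a" & gh$group2 == "b"]
  expect_gt(p_ab, 0.05)
  expect_lt(gh$p[gh$group1 == "a" & gh$group2 == "c"], 1e-6)
  expect_lt(gh$p[gh$group1 == "b" & gh$group2 == "c"], 1e-6)

  same <- games_howell(rep(rnorm(50), 3), rep(c("a", "b", "c"), each = 50))
  expect_true(all(same$p > 0.999))
})
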