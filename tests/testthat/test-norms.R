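test_that("gender-balanced statistics reproduce the mixture identities", {
  # equal-weight mixture of the printed gender means: (1.67 + 2.18)/2
  x <- c(rnorm(300, 10), rnorm(700, 20))
  g <- rep(c("F", "M"), c(300, 700))
  w <- gender_balanced_weights(g)
  expect_equal(sum(w[g == "F"]) / sum(w), 0.5, tolerance = 1e-12)
  nt <- norm_table(x, g)
  wt_row <- nt[nt$stratum == "weighted_total", ]
  f_row <- nt[nt$stratum == "female", ]
  m_row <- nt[nt$stratum == "male", ]
  expect_equal(wt_row$mean, (f_row$mean + m_row$mean) / 2, tolerance = 1e-9)
  # 50/50 mixture variance identity (up to the finite-sample factor)
  mix_var <- (f_row$sd^2 + m_row$sd^2) / 2 +
    ((f_row$mean - m_row$mean) / 2)^2
  expect_equal(wt_row$sd^2, mix_var, tolerance = 0.01 * mix_var)

  # printed-value arithmetic: balanced mean and mixture sd
  expect_equal((1.67 + 2.18) / 2, 1.925)
  expect_equal(round(sqrt((0.42^2 + 0.53^2) / 2 + ((2.18 - 1.67) / 2)^2), 2),
               0.54)
})

test_that("equal group sizes make weighted and unweighted statistics equal", {
  x <- rnorm(400)
  g <- rep(c("F", "M"), each = 200)
  nt <- norm_table(x, g)
  wt_row <- nt[nt$stratum == "weighted_total", ]
  expect_equal(wt_row$mean, mean(x), tolerance = 1e-12)
  expect_equal(wt_row$p50, weighted_percentile(x, NULL, 0.5), tolerance = 1e-12)
})

test_that("weighted percentiles follow the left-continuous step convention", {
  x <- 17:68 # uniform over the attainable sum range
  p75 <- weighted_percentile(x, NULL, 0.75)
  expect_equal(p75, x[ceiling(0.75 * length(x))])
  expect_equal(weighted_percentile(rep(42, 50), NULL, c(0.25, 0.9)), c(42, 42))
  cuts <- percentile_cutoffs(x, gender = NULL)
  expect_equal(cuts$cutoff, c(x[ceiling(0.75 * 52)], x[ceiling(0.9 * 52)]))
  expect_true(all(diff(weighted_percentile(rnorm(500), NULL,
                                           c(0.05, 0.25, 0.5, 0.75, 0.95))) >= 0))
})

test_that("KDE antimodes appear between separated modes and not in unimodal data", {
  withr::with_seed(15, {
    uni <- rnorm(2000, 30, 5)
    bim <- c(rnorm(1000, 25, 4), rnorm(1000, 45, 4))
  })
  expect_length(kde_antimodes(uni)$antimodes, 0)
  br <- kde_antimodes(bim)
  expect_length(br$antimodes, 1)
  expect_true(br$antimodes > 30 && br$antimodes < 40)
  expect_error(kde_antimodes(rep(1:3, 5)), "distinct")
})

test_that("dip statistic equals 0.25 on the two-point distribution", {
  # brute-force oracle: any unimodal CDF G must pass within t of both the
  # pre-jump and post-jump ECDF values at 0 and 1; enumerating candidate
  # band values u = G(0), v = G(1) shows sup-dist >= 0.25, attained at
  # u = 0.25, v = 0.75.
  grid <- expand.grid(u = seq(0, 1, 0.005), v = seq(0, 1, 0.005))
  grid <- grid[grid$u <= grid$v, ]
  supdist <- pmax(grid$u,                  # before the first atom
                  abs(grid$u - 0.5),       # at x = 0
                  abs(grid$v - 0.5),       # just below x = 1
                  1 - grid$v)              # at x = 1 (no jump off-mode)
  oracle <- min(supdist)
  expect_equal(oracle, 0.25, tolerance = 1e-9)
  expect_equal(dip_stat(c(rep(0, 500), rep(1, 500))), 0.25, tolerance = 1e-8)
  expect_equal(dip_stat(c(0, 1)), 0.25, tolerance = 1e-8)
})

test_that("dip is affine-invariant, small for unimodal and large for bimodal data", {
  withr::with_seed(16, {
    uni <- rnorm(800)
    bim <- c(rnorm(400, 0), rnorm(400, 6))
  })
  expect_equal(dip_stat(3 * uni + 10), dip_stat(uni), tolerance = 1e-9)
  expect_lt(dip_stat(uni), 0.02)
  expect_gt(dip_stat(bim), 3 * dip_stat(uni))
  d <- dip_test(bim, mc_reps = 300, seed = 2)
  expect_lt(d$p, 0.01)
  expect_error(dip_test(rep(1, 50)), "constant")
})

test_that("dip p-values can reuse a precomputed null table", {
  nulls <- dip_null(100, reps = 200, seed = 3)
  x <- withr::with_seed(4, runif(100))
  d1 <- dip_test(x, null_dips = nulls)
  expect_equal(d1$p, (1 + sum(nulls >= dip_stat(x))) / 201, tolerance = 1e-12)
})

test_that("combined classification reproduces the published five bands", {
  cls <- combined_classification(percentile_cuts = c(38, 43),
                                 kde_breaks = c(26, 36),
                                 score_range = c(17, 68))
  expect_equal(cls$bands$label,
               c("Low", "Low-Medium", "High-Medium", "Elevated", "Very Elevated"))
  expect_equal(cls$bands$from, c(17, 26, 36, 38, 43))
  expect_equal(cls$bands$to, c(25, 35, 37, 42, 68))
  expect_equal(as.character(classify_scores(cls, 40)), "Elevated")
  expect_equal(as.character(classify_scores(cls, c(17, 26, 37, 68))),
               c("Low", "Low-Medium", "High-Medium", "Very Elevated"))

  # classification is exhaustive and mutually exclusive over the range
  all_scores <- 17:68
  lab <- classify_scores(cls, all_scores)
  expect_false(anyNA(lab))
  expect_equal(as.vector(table(lab)),
               c(25 - 17 + 1, 35 - 26 + 1, 2, 42 - 38 + 1, 68 - 43 + 1))

  # near-duplicate boundaries collapse, percentile provenance winning
  cls2 <- combined_classification(c(38, 43), c(37.5, 26), c(17, 68))
  expect_equal(cls2$boundaries, c(26, 38, 43))

  single <- combined_classification(30, numeric(0), c(17, 68))
  expect_equal(single$bands$label, c("Low", "Elevated"))
})

test_that("simulated elevated cutoffs land near the published threshold", {
  cuts <- vapply(1:3, function(s) {
    d <- generate_cohort(default_sim_config(n = 2955), seed = 40 + s)
    sc <- score_battery(d)
    keep <- !is.na(sc$gsas_sum)
    percentile_cutoffs(sc$gsas_sum[keep], sc$gender[keep])$cutoff[1]
  }, numeric(1))
  expect_true(all(abs(cuts - 38) <= 1))
})
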