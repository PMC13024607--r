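test_that("identical seeds give byte-identical cohorts, different seeds differ", {
  cfg <- default_sim_config(n = 400)
  a <- generate_cohort(cfg, seed = 123)
  b <- generate_cohort(cfg, seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_cohort(cfg, seed = 124)
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("cohorts carry the full battery, demographics and criteria", {
  d <- small_cohort(n = 350, seed = 22)
  expect_s3_class(d, "gab_responses")
  expect_equal(nrow(d), 350)
  expect_true(all(retained_items(REG, "GSAS") %in% names(d)))
  expect_true(all(retained_items(REG, "GRAS") %in% names(d)))
  expect_true(all(c("k10", "rses", "bpaq_total") %in% names(d)))
  expect_true(all(levels(d$gender) == c("F", "M")))
  # gender composition near the study proportions
  big <- small_cohort(n = 4000, seed = 23)
  expect_lt(abs(mean(big$gender == "F") - 0.436), 0.025)
})

test_that("the configuration is internally consistent", {
  cfg <- default_sim_config()
  ev <- eigen(cfg$Psi, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_true(all(abs(cfg$Psi) <= 1))
  expect_true(all(vapply(cfg$scales$GSAS$tau, function(t) all(diff(t) > 0),
                         logical(1))))
  expect_gt(cfg$scales$GSAS$delta, 0)
  expect_lt(cfg$k10_gap, 0) # males report lower distress
  # attribution targets are proper probability decompositions
  at <- cfg$scales$GTI$attribution_targets
  expect_equal(unname(at$p_stereo + at$p_counter + at$p_egalitarian),
               rep(1, nrow(at)), tolerance = 1e-12)
})

test_that("generated scale scores match the calibration targets", {
  d <- generate_cohort(default_sim_config(n = 6000), seed = 24)
  s <- score_battery(d)
  f <- s$gender == "F"; m <- s$gender == "M"
  expect_equal(mean(s$gsas_mean[f], na.rm = TRUE), 1.67, tolerance = 0.04)
  expect_equal(mean(s$gsas_mean[m], na.rm = TRUE), 2.18, tolerance = 0.04)
  expect_equal(mean(s$gras_mean[f], na.rm = TRUE), 1.19, tolerance = 0.03)
  expect_equal(mean(s$gras_mean[m], na.rm = TRUE), 1.42, tolerance = 0.03)
  expect_equal(mean(s$gti_mean[f], na.rm = TRUE), 0.78, tolerance = 0.04)
  expect_equal(mean(s$gti_mean[m], na.rm = TRUE), 0.83, tolerance = 0.04)
  # inter-scale pooled correlations near their configured targets
  expect_equal(cor(s$gsas_mean, s$gras_mean, use = "complete.obs"), 0.653,
               tolerance = 0.05)
  expect_equal(cor(s$gras_mean, s$gti_mean, use = "complete.obs"), 0.440,
               tolerance = 0.05)
})

test_that("within-gender criterion correlations are recovered", {
  d <- generate_cohort(default_sim_config(n = 12000, rate_acquiescent = 0,
                                          rate_straightline = 0), seed = 25)
  s <- score_battery(d)
  m <- s$gender == "M"; f <- s$gender == "F"
  expect_lt(abs(cor(s$gsas_mean[m], s$bpaq_physical[m]) - 0.271), 0.04)
  expect_lt(abs(cor(s$gsas_mean[f], s$bpaq_physical[f]) - 0.102), 0.04)
  expect_lt(abs(cor(s$gti_mean[m], s$k10[m]) - 0.110), 0.04)
  expect_lt(abs(cor(s$gsas_mean[m], s$rses[m]) + 0.075), 0.04)
})

test_that("expert rating simulation respects the profile", {
  prof <- default_expert_profile()
  r <- make_expert_ratings(prof, seed = 5)
  expect_equal(dim(r), c(12, 46))
  expect_true(all(r %in% 1:5))
  # unanimity where the profile is 1
  sure <- names(prof)[prof == 1]
  expect_true(all(colMeans(r[, sure] >= 4) == 1))
  # determinism
  expect_identical(make_expert_ratings(prof, seed = 5), r)
  # Bernoulli panels land near the published overall index
  scvis <- vapply(1:5, function(s) {
    cv <- compute_cvi(make_expert_ratings(prof, seed = s))
    cv$scales$s_cvi_ave[cv$scales$module == "overall"]
  }, numeric(1))
  expect_true(all(abs(scvis - 0.967) < 0.03))
})
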