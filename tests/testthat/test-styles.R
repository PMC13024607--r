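test_that("style indices hit the trivial poles and hand proportions", {
  d <- toy_cohort(n = 3)
  for (it in retained_items(REG, "GSAS")) d[[it]] <- c(4L, 2L, 1L)
  for (it in retained_items(REG, "GTI")) d[[it]] <- c("E", "M", "F")
  si <- style_indices(d, REG)
  gsas <- si[si$scale == "GSAS", ]
  expect_equal(gsas$ars, c(4, 2, 1))
  expect_equal(gsas$ers, c(1, 0, 1))
  gti <- si[si$scale == "GTI", ]
  expect_equal(gti$egal_rs[1], 1)
  expect_equal(gti$srs[1], 0)
  expect_equal(gti$egal_rs + gti$srs + gti$crs, rep(1, 3), tolerance = 1e-12)

  # hand-mixed vector on the likert scale
  d2 <- toy_cohort(n = 1)
  items <- retained_items(REG, "GSAS")
  vals <- c(rep(1L, 5), rep(2L, 4), rep(3L, 4), rep(4L, 4))
  for (i in seq_along(items)) d2[[items[i]]] <- vals[i]
  si2 <- style_indices(d2, REG)
  expect_equal(si2$ars[si2$scale == "GSAS"], mean(vals))
  expect_equal(si2$ers[si2$scale == "GSAS"], 9 / 17)
})

test_that("problematic-pattern rules fire as operationally defined", {
  d <- toy_cohort(n = 3)
  # person 1: same likert response everywhere (a 'somewhat agree' liner)
  for (it in retained_items(REG, "GSAS")) d[[it]] <- c(3L, 1L, 2L)
  # person 2 alternates, person 3 mixes
  d$GSAS_1 <- c(3L, 1L, 2L); d$GSAS_2 <- c(3L, 2L, 1L)
  fl <- flag_problematic(d, REG)
  g1 <- fl[fl$scale == "GSAS" & fl$person_id == "p1", ]
  expect_true(g1$zero_variance && g1$extreme_acquiescence)
  g2 <- fl[fl$scale == "GSAS" & fl$person_id == "p2", ]
  expect_false(g2$flagged)

  # straight-lining on a trichotomous scale
  d2 <- toy_cohort(n = 2)
  for (it in retained_items(REG, "GRAS")) d2[[it]] <- c("E", "M")
  d2$GRAS_2 <- c("E", "F")
  fl2 <- flag_problematic(d2, REG)
  expect_true(fl2$straight_lining[fl2$scale == "GRAS" & fl2$person_id == "p1"])
  expect_false(fl2$flagged[fl2$scale == "GRAS" & fl2$person_id == "p2"])
})

test_that("injected contamination is recovered at the configured rate", {
  # the model itself produces a few perfectly consistent responders, so the
  # injection is measured as the excess over the zero-injection baseline
  base <- generate_cohort(default_sim_config(n = 4000, rate_acquiescent = 0,
                                             rate_straightline = 0), seed = 17)
  cont <- generate_cohort(default_sim_config(n = 4000, rate_acquiescent = 0.015,
                                             rate_straightline = 0.015), seed = 17)
  fl0 <- flag_problematic(base, REG)
  fl1 <- flag_problematic(cont, REG)
  excess_gsas <- mean(fl1$flagged[fl1$scale == "GSAS"]) -
    mean(fl0$flagged[fl0$scale == "GSAS"])
  excess_gras <- mean(fl1$straight_lining[fl1$scale == "GRAS"]) -
    mean(fl0$straight_lining[fl0$scale == "GRAS"])
  expect_lt(abs(excess_gsas - 0.015), 0.005)
  expect_lt(abs(excess_gras - 0.015), 0.005)
})

test_that("sensitivity analysis reports exact zero deltas without flags", {
  d <- small_cohort(n = 250, seed = 9, rate_acquiescent = 0,
                    rate_straightline = 0)
  fl <- flag_problematic(d, REG)
  fl$flagged <- FALSE
  sens <- sensitivity_analysis(d, REG, fl)
  cleaned <- sens[sens$sample == "cleaned", ]
  expect_equal(cleaned$delta_mean, rep(0, 3))
  expect_equal(cleaned$delta_alpha, rep(0, 3))
  expect_equal(cleaned$delta_d, rep(0, 3))
  full <- sens[sens$sample == "full", ]
  expect_equal(cleaned$n + cleaned$n_excluded, full$n)
})

test_that("removing an extreme high scorer moves the mean down", {
  d <- small_cohort(n = 200, seed = 10, rate_acquiescent = 0,
                    rate_straightline = 0)
  for (it in retained_items(REG, "GSAS")) d[[it]][1] <- 4L
  fl <- flag_problematic(d, REG)
  expect_true(fl$flagged[fl$scale == "GSAS" & fl$person_id == d$person_id[1]])
  sens <- sensitivity_analysis(d, REG, fl)
  expect_lt(sens$delta_mean[sens$scale == "GSAS" & sens$sample == "cleaned"], 0)
})

test_that("default contamination leaves reliability essentially unchanged", {
  d <- generate_cohort(default_sim_config(n = 3000, rate_acquiescent = 0.015),
                       seed = 14)
  sens <- sensitivity_analysis(d, REG)
  gsas <- sens[sens$scale == "GSAS" & sens$sample == "cleaned", ]
  expect_lt(abs(gsas$delta_alpha), 0.02)
})
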