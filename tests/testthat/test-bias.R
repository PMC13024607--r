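test_that("attribution proportions sum to one and match hand counts", {
  d <- toy_cohort(n = 4) # genders F, M, F, M
  d$GTI_1 <- c("M", "E", "F", "M") # female respondents: M, F; male: E, M
  ap <- attribution_proportions(d, items = "GTI_1")
  f <- ap[ap$respondent_gender == "F", ]
  m <- ap[ap$respondent_gender == "M", ]
  expect_equal(c(f$p_male, f$p_female, f$p_egalitarian), c(0.5, 0.5, 0))
  expect_equal(c(m$p_male, m$p_female, m$p_egalitarian), c(0.5, 0, 0.5))
  expect_equal(ap$p_male + ap$p_female + ap$p_egalitarian, c(1, 1),
               tolerance = 1e-12)

  all_e <- toy_cohort(n = 6)
  for (it in retained_items(REG, "GTI")) all_e[[it]] <- "E"
  ap_e <- attribution_proportions(all_e)
  expect_true(all(ap_e$p_egalitarian == 1))
  expect_true(all(ap_e$p_male == 0 & ap_e$p_female == 0))
})

test_that("self-attribution gaps follow the published arithmetic", {
  # male self 32.5% vs female-rated 12.6% -> +19.9 points
  ap <- tibble::tibble(
    item_id = "GTI_1",
    respondent_gender = c("F", "M"),
    p_male = c(0.126, 0.325),
    p_female = c(0.202, 0.088),
    p_egalitarian = c(0.672, 0.587),
    n = c(1000, 1000)
  )
  bias <- self_attribution_gap(ap, m = 20)
  male_row <- bias[bias$target == "male", ]
  expect_equal(male_row$delta, 19.9, tolerance = 1e-9)
  female_row <- bias[bias$target == "female", ]
  expect_equal(female_row$delta, 100 * (0.202 - 0.088), tolerance = 1e-9)
  expect_lt(male_row$p_bonferroni, 0.001)

  # identical proportions give zero gaps
  ap0 <- ap
  ap0$p_male <- 0.2; ap0$p_female <- 0.3
  expect_equal(self_attribution_gap(ap0, m = 20)$delta, c(0, 0))
})

test_that("swapping respondent groups negates every gap", {
  d <- small_cohort(n = 400, seed = 6)
  ap <- attribution_proportions(d)
  swapped <- ap
  swapped$respondent_gender <- ifelse(ap$respondent_gender == "F", "M", "F")
  g1 <- self_attribution_gap(ap)
  g2 <- self_attribution_gap(swapped)
  expect_equal(g1$delta, -g2$delta, tolerance = 1e-9)
})

test_that("two-proportion z matches the pooled-SE hand computation", {
  x1 <- 325; n1 <- 1000; x2 <- 126; n2 <- 1000
  pp <- (x1 + x2) / (n1 + n2)
  z_hand <- (x1 / n1 - x2 / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  res <- two_proportion_z(x1, n1, x2, n2)
  expect_equal(res$z, z_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)

  eq <- two_proportion_z(50, 100, 50, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  expect_warning(two_proportion_z(0, 10, 0, 10), "undefined")
})

test_that("the multiplicity correction uses all target-item combinations", {
  d <- small_cohort(n = 500, seed = 8)
  bias <- self_attribution_gap(attribution_proportions(d))
  expect_equal(attr(bias, "m"), 20L)
  expect_equal(bias$p_bonferroni, pmin(1, bias$p_raw * 20), tolerance = 1e-12)
  # adjusted significance threshold: 0.05 / 20
  expect_equal(0.05 / attr(bias, "m"), 0.0025)
})

test_that("self-serving summaries implement the definition arithmetic", {
  bias <- tibble::tibble(
    item_id = c("i1", "i2"), target = "male",
    delta = c(10, -6), valence = c("positive", "negative")
  )
  s <- self_serving_scores(bias)
  expect_equal(s$sss_pos, 10)
  expect_equal(s$sss_neg, -6)
  expect_equal(s$deflection, 6)

  zero <- bias; zero$delta <- 0
  s0 <- self_serving_scores(zero)
  expect_equal(c(s0$sss_pos, s0$sss_neg), c(0, 0))
  bad <- bias; bad$valence[1] <- NA
  expect_error(self_serving_scores(bad), "valence")
})

test_that("the configured independence asymmetry is reproduced on cohorts", {
  cfg <- default_sim_config(n = 3000)
  targets <- cfg$scales$GTI$attribution_targets
  d <- generate_cohort(cfg, seed = 31)
  ap <- attribution_proportions(d, items = "GTI_1")
  for (g in c("F", "M")) {
    tg <- targets[targets$item_id == "GTI_1" & targets$respondent_gender == g, ]
    obs <- ap[ap$respondent_gender == g, ]
    # independence is male-directed: stereo attribution = to-male share
    expect_lt(abs(obs$p_male - tg$p_stereo), 0.025)
    expect_lt(abs(obs$p_egalitarian - tg$p_egalitarian), 0.025)
  }
  # the self-attribution asymmetry itself
  gaps <- self_attribution_gap(ap)
  expect_gt(gaps$delta[gaps$target == "male"], 10)
})
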