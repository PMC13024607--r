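test_that("alpha matches closed forms and a hand-computed toy value", {
  # equicorrelated construction: all pairwise covariances 0.5, unit variances
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  expect_equal(alpha_from_cor(R), 0.75, tolerance = 1e-9)

  # k exact copies of one variable
  x <- rnorm(50)
  m <- cbind(x, x, x, x)
  expect_equal(cronbach_alpha(m), 1, tolerance = 1e-12)

  # 4-person x 3-item toy matrix, frozen hand computation:
  # item vars 5/3, 5/3, 4/3; var of sum 34/3 -> alpha = 30/34
  toy <- cbind(c(1, 2, 3, 4), c(1, 3, 2, 4), c(2, 2, 4, 4))
  expect_equal(cronbach_alpha(toy), 30 / 34, tolerance = 1e-12)

  expect_error(cronbach_alpha(cbind(rep(1, 5), rep(2, 5))), "zero variance")
})

test_that("alpha is invariant to item shifts and person permutation", {
  m <- matrix(sample(1:4, 120, replace = TRUE), ncol = 4)
  a0 <- cronbach_alpha(m)
  m2 <- sweep(m, 2, c(10, -3, 0, 2), `+`)
  expect_equal(cronbach_alpha(m2), a0, tolerance = 1e-12)
  expect_equal(cronbach_alpha(m[sample(nrow(m)), ]), a0, tolerance = 1e-12)
})

test_that("Feldt interval matches the F-quantile construction and tightens with n", {
  ci <- feldt_ci(0.5, 30, 5)
  expect_equal(ci[1], 1 - 0.5 * qf(0.975, 29, 116), tolerance = 1e-12)
  expect_equal(ci[2], 1 - 0.5 / qf(0.975, 116, 29), tolerance = 1e-12)
  expect_true(ci[1] < 0.5 && ci[2] > 0.5)

  wide <- diff(feldt_ci(0.8, 50, 10))
  narrow <- diff(feldt_ci(0.8, 5000, 10))
  expect_true(narrow < wide)
  expect_lt(diff(feldt_ci(0.8, 1e5, 10)), 0.01)

  # at the published scale estimate the interval is as narrow as reported
  expect_lte(diff(feldt_ci(0.894, 2955, 17)), 0.021)
  expect_equal(feldt_ci(1, 10, 5), c(1, 1))
})

test_that("omega closed form, omega >= omega_h, and one-factor equality hold", {
  lam <- rep(0.7, 4)
  R <- tcrossprod(lam); diag(R) <- 1
  om <- omega_schmid_leiman(R, n_group_factors = 1)
  expect_equal(om$omega, 2.8^2 / (2.8^2 + 4 * 0.51), tolerance = 1e-6)
  expect_equal(om$omega, om$omega_h)

  # three correlated group factors
  lam2 <- rep(c(0.7, 0.6, 0.65), each = 4)
  kmap <- rep(1:3, each = 4)
  Phi <- matrix(0.5, 3, 3); diag(Phi) <- 1
  R2 <- outer(seq_along(lam2), seq_along(lam2), function(i, j) {
    lam2[i] * lam2[j] * ifelse(kmap[i] == kmap[j], 1, 0.5)
  })
  diag(R2) <- 1
  om2 <- omega_schmid_leiman(R2, n_group_factors = 3)
  expect_gte(om2$omega, om2$omega_h)
  expect_true(om2$omega > 0.8 && om2$omega < 1)
})

test_that("omega recovers the generating-model value on simulated ordinal data", {
  lam <- rep(0.7, 6)
  true_omega <- sum(lam)^2 / (sum(lam)^2 + sum(1 - lam^2))
  est <- vapply(1:3, function(s) {
    m <- sim_one_factor(1500, 6, 0.7, c(-1, 0, 1), seed = s)
    omega_schmid_leiman(polychoric_matrix(m), n_group_factors = 1)$omega
  }, numeric(1))
  expect_true(all(abs(est - true_omega) < 0.05))
})

test_that("item-total correlations behave at the degenerate poles and on a toy", {
  x <- rnorm(200)
  m_same <- cbind(x, x, x)
  expect_equal(unname(item_total_corrected(m_same)), rep(1, 3), tolerance = 1e-12)

  withr::with_seed(9, {
    ind <- cbind(rnorm(4000), rnorm(4000), rnorm(4000), rnorm(4000))
  })
  rit <- item_total_corrected(ind)
  expect_true(all(abs(rit) < 0.06))

  toy <- cbind(c(1, 2, 3, 4), c(1, 3, 2, 4), c(2, 2, 4, 4))
  expect_equal(unname(item_total_corrected(toy))[1],
               cor(toy[, 1], toy[, 2] + toy[, 3]), tolerance = 1e-12)
})

test_that("polychoric alpha equals the latent closed form and exceeds Pearson alpha", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  expect_equal(alpha_from_cor(R), 0.75)

  # attenuation: on discretised one-factor data the latent-metric alpha
  # dominates the observed-score alpha
  wins <- vapply(1:5, function(s) {
    m <- sim_one_factor(800, 5, 0.7, c(-0.8, 0.6), seed = 100 + s)
    polychoric_alpha(m) > cronbach_alpha(m)
  }, logical(1))
  expect_true(all(wins))
})

test_that("reliability report bundles coherent components", {
  m <- sim_one_factor(400, 5, 0.7, c(-1, 0, 1), seed = 3)
  rep <- reliability_report(m, n_group_factors = 1, polychoric = TRUE)
  expect_true(rep$alpha_ci95[1] < rep$alpha && rep$alpha < rep$alpha_ci95[2])
  expect_gte(rep$polychoric_alpha, rep$alpha)
  expect_equal(rep$omega, rep$omega_h)
  g <- glance(rep)
  expect_equal(g$alpha, rep$alpha)
  expect_equal(nrow(tidy(rep)), 5)
})
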