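# Synthetic cohort generator. Latent structure: per scale a standardised
# general factor (cross-scale correlations Psi), subscale factors loading on
# it (a_k chosen to reproduce the published inter-factor correlations),
# gender and school-track shifts on the subscale-factor means, and ordinal
# item responses by probit thresholding of lambda * factor + unique normal
# error. Thresholds are equal-spaced cut points whose location, spacing and
# gender separation are calibrated by root finding against the published
# scale-level means and SDs (analytic item moments; covariances linearised).
# Criterion scores are linear-Gaussian transforms of the general factors
# with per-gender correlation targets; the distress gender gap is calibrated
# so the pooled attitude-distress correlation reverses sign against the
# within-gender pattern.

GENDER_PROPS <- c(F = 1289, M = 1666) / 2955
SCHOOL_LEVELS <- c("academic", "technical", "vocational")
SCHOOL_BY_GENDER <- cbind(
  F = c(675, 336, 278) / 1289,
  M = c(715, 653, 298) / 1666
)
rownames(SCHOOL_BY_GENDER) <- SCHOOL_LEVELS
SCHOOL_PROPS <- c(1390, 989, 576) / 2955

GSAS_LAMBDA <- c(
  GSAS_1 = 0.73, GSAS_2 = 0.72, GSAS_3 = 0.60, GSAS_4 = 0.49, GSAS_6 = 0.67,
  GSAS_7 = 0.75, GSAS_9 = 0.50, GSAS_11 = 0.50, GSAS_18 = 0.63,
  GSAS_5 = 0.71, GSAS_8 = 0.66, GSAS_13 = 0.42, GSAS_15 = 0.58, GSAS_16 = 0.64,
  GSAS_12 = 0.71, GSAS_14 = 0.73, GSAS_17 = 0.66
)
GRAS_LAMBDA <- c(
  GRAS_7 = 0.90, GRAS_14 = 0.77, GRAS_8 = 0.79, GRAS_16 = 0.76, GRAS_17 = 0.50,
  GRAS_10 = 0.76, GRAS_9 = 0.74, GRAS_3 = 0.62, GRAS_12 = 0.70, GRAS_6 = 0.69,
  GRAS_5 = 0.61, GRAS_18 = 0.58, GRAS_11 = 0.40, GRAS_2 = 0.37
)
GTI_LAMBDA <- c(
  GTI_1 = 0.53, GTI_2 = 0.70, GTI_3 = 0.67, GTI_4 = 0.66, GTI_5 = 0.77,
  GTI_6 = 0.65, GTI_7 = 0.62, GTI_8 = 0.72, GTI_9 = 0.64, GTI_10 = 0.63
)

# second-order loadings reproducing the inter-factor correlations
# (TS-VM 0.68, TS-RC 0.50, VM-RC 0.47; GRAS latent r 0.84)
GSAS_A <- c(TS = sqrt(0.68 * 0.50 / 0.47), VM = sqrt(0.68 * 0.47 / 0.50),
            RC = sqrt(0.50 * 0.47 / 0.68))
GRAS_A <- c(LA = sqrt(0.84), SR = sqrt(0.84))

# per-item trichotomous structure for the trait inventory: pooled gendered
# (non-egalitarian) response rates and the probability that a gendered
# response follows the stereotypical direction, by respondent gender.
# Values for items 1, 7, 8 and 10 are derived from the published
# self-attribution tables; the rest are symmetric defaults.
GTI_TRI <- tibble::tibble(
  item_id = paste0("GTI_", 1:10),
  g_F = c(0.328, 0.55, 0.40, 0.45, 0.55, 0.35, 0.272, 0.515, 0.45, 0.384),
  g_M = c(0.413, 0.55, 0.40, 0.45, 0.55, 0.35, 0.397, 0.596, 0.45, 0.363),
  # stereotypical-direction split among gendered responses: the asymmetries
  # encode the published self-enhancement (positive traits claimed for the
  # in-group) and deflection (negative traits pushed to the out-group)
  pi_F = c(0.384, 0.90, 0.85, 0.66, 0.92, 0.75, 0.625, 0.942, 0.88, 0.911),
  pi_M = c(0.787, 0.84, 0.78, 0.82, 0.78, 0.55, 0.542, 0.916, 0.70, 0.576)
)

CRITERIA_SPEC <- tibble::tibble(
  name = c("bpaq_physical", "bpaq_verbal", "bpaq_anger", "bpaq_hostility",
           "k10", "rses", "paqs"),
  mean_F = c(2.2, 2.9, 2.9, 3.1, 24.0, 27.5, 19.5),
  mean_M = c(2.6, 2.9, 2.7, 2.9, NA, 30.0, 21.0), # k10 male mean calibrated
  sd = c(0.80, 0.80, 0.80, 0.80, 8.0, 5.0, 7.0),
  family = c("bpaq", "bpaq", "bpaq", "bpaq", "none", "none", "none"),
  # within-gender observed-score correlation targets with (GSAS, GRAS, GTI)
  r_F_gsas = c(0.102, -0.050, -0.040, -0.071, 0.050, 0.036, -0.013),
  r_F_gras = c(0.016, -0.020, -0.020, -0.050, 0.000, 0.020, 0.000),
  r_F_gti = c(0.120, 0.050, 0.060, 0.050, 0.087, 0.000, 0.050),
  r_M_gsas = c(0.271, 0.050, 0.050, 0.085, 0.066, -0.075, 0.095),
  r_M_gras = c(0.218, 0.020, 0.020, 0.050, 0.050, -0.050, 0.050),
  r_M_gti = c(0.215, 0.080, 0.100, 0.080, 0.110, -0.030, 0.080)
)
BPAQ_FAMILY_LOADING <- 0.45
INTER_SCALE_TARGETS <- c(gsas_gras = 0.653, gsas_gti = 0.312, gras_gti = 0.440)

# ---- analytic item moments for ordinal probit items -------------------------

# category-threshold moments for one item: latent mean mu, loading l,
# thresholds tau (ascending); scores 0..C-1. `A` holds the tetrachoric
# series coefficients A_j = sum_c He_{j-1}(tau~) phi(tau~) (j = 1..4) used
# for the covariance expansion cov(x_i, x_j) = sum_j rho^j / j! A_j A'_j.
hermite_phi <- function(z) {
  p <- dnorm(z)
  rbind(p, z * p, (z^2 - 1) * p, (z^3 - 3 * z) * p)
}
ord_item_moments <- function(l, tau, mu) {
  zt <- tau - l * mu
  p_ge <- 1 - pnorm(zt) # P(score >= j), j = 1..C-1
  m <- sum(p_ge)
  ex2 <- sum((2 * seq_along(tau) - 1) * p_ge)
  A <- rowSums(hermite_phi(zt))
  list(m = m, v = ex2 - m^2, s = l * A[1], A = A)
}

# scale-mean moments within one gender (marginalised over school):
# returns mean, var and cov(G, scale mean) of the k-item mean score
scale_cell_moments <- function(lambda, kmap, a_k, tau, mu_k_by_school,
                               school_p, base = 0) {
  k <- length(lambda)
  cell <- lapply(seq_along(school_p), function(si) {
    mo <- lapply(seq_len(k), function(i) {
      ord_item_moments(lambda[i], tau[[i]], mu_k_by_school[[si]][kmap[i]])
    })
    m_i <- vapply(mo, `[[`, numeric(1), "m")
    v_i <- vapply(mo, `[[`, numeric(1), "v")
    s_i <- vapply(mo, `[[`, numeric(1), "s")
    Amat <- vapply(mo, `[[`, numeric(4), "A") # 4 x k
    a_i <- a_k[kmap]
    psi <- outer(a_i, a_i)
    same <- outer(kmap, kmap, `==`)
    psi[same] <- 1
    rho <- psi * outer(lambda, lambda) # latent response correlations
    covsum <- 0
    for (j in 1:4) {
      Cj <- rho^j * outer(Amat[j, ], Amat[j, ]) / factorial(j)
      diag(Cj) <- 0
      covsum <- covsum + sum(Cj)
    }
    list(m = mean(m_i) + base,
         v = (sum(v_i) + covsum) / k^2,
         cg = mean(a_i * s_i)) # cov(G, mean score) is exact (normal G)
  })
  m_s <- vapply(cell, `[[`, numeric(1), "m")
  v_s <- vapply(cell, `[[`, numeric(1), "v")
  cg_s <- vapply(cell, `[[`, numeric(1), "cg")
  m <- sum(school_p * m_s)
  v <- sum(school_p * (v_s + m_s^2)) - m^2
  list(mean = m, var = v, cov_g = sum(school_p * cg_s))
}

# equal-spaced threshold template; `spread` holds fixed per-item location
# offsets (items differ in endorsement rates, which also keeps accidental
# straight-lining rare, as in real cohorts)
tau_template <- function(C, o, h, spread = 0) {
  base <- if (C == 4) h * c(-1, 0, 1) else h * c(-0.5, 0.5)
  lapply(spread, function(s) o + s + base)
}
item_spread <- function(k, width = 0.7) {
  if (k == 1) return(0)
  seq(-width, width, length.out = k)
}

# subscale-factor means per school for one gender
factor_means <- function(delta, wgt_k, gender, school_shift) {
  sgn <- if (gender == "M") 0.5 else -0.5
  lapply(seq_along(SCHOOL_LEVELS), function(si) {
    sgn * delta * wgt_k + school_shift[si]
  })
}

calibrate_ordinal_scale <- function(lambda, kmap, a_k, wgt_k, school_shift,
                                    C, base, mean_F, mean_M, var_within,
                                    spread_width = 0.7) {
  school_shift <- school_shift - sum(SCHOOL_PROPS * school_shift)
  spread <- item_spread(length(lambda), spread_width)
  moments <- function(o, h, delta) {
    tau <- tau_template(C, o, h, spread)
    lapply(c(F = "F", M = "M"), function(g) {
      scale_cell_moments(lambda, kmap, a_k, tau,
                         factor_means(delta, wgt_k, g, school_shift),
                         SCHOOL_BY_GENDER[, g], base)
    })
  }
  solve_loc <- function(h) {
    o <- 0; delta <- 1
    for (it in 1:4) {
      o <- uniroot(function(oo) {
        mo <- moments(oo, h, delta)
        (mo$F$mean + mo$M$mean) / 2 - (mean_F + mean_M) / 2
      }, c(-4, 4), extendInt = "downX", tol = 1e-8)$root
      delta <- uniroot(function(dd) {
        mo <- moments(o, h, dd)
        (mo$M$mean - mo$F$mean) - (mean_M - mean_F)
      }, c(0, 4), extendInt = "upX", tol = 1e-8)$root
    }
    list(o = o, delta = delta)
  }
  h <- uniroot(function(hh) {
    p <- solve_loc(hh)
    mo <- moments(p$o, hh, p$delta)
    (mo$F$var + mo$M$var) / 2 - var_within
  }, c(0.25, 5), tol = 1e-6)$root
  p <- solve_loc(h)
  mo <- moments(p$o, h, p$delta)
  list(tau = tau_template(C, p$o, h, spread), delta = p$delta, o = p$o, h = h,
       school_shift = school_shift, wgt_k = wgt_k, a_k = a_k,
       lambda = lambda, kmap = kmap, base = base, moments = mo)
}

# trait-inventory (gender-salience) moments: score 0 egal, 1 counter,
# 2 stereo; egal vs gendered from the latent threshold, direction split pi
gti_cell_moments <- function(lambda, tau_i, mu_by_school, school_p, pi_g) {
  k <- length(lambda)
  cell <- lapply(seq_along(school_p), function(si) {
    mu <- mu_by_school[si]
    zt <- tau_i - lambda * mu
    P <- 1 - pnorm(zt)
    m_i <- P * (1 + pi_g)
    v_i <- P * (1 + 3 * pi_g) - m_i^2
    Amat <- hermite_phi(zt) * rep((1 + pi_g), each = 4)
    s_i <- lambda * Amat[1, ]
    rho <- outer(lambda, lambda)
    covsum <- 0
    for (j in 1:4) {
      Cj <- rho^j * outer(Amat[j, ], Amat[j, ]) / factorial(j)
      diag(Cj) <- 0
      covsum <- covsum + sum(Cj)
    }
    list(m = mean(m_i), v = (sum(v_i) + covsum) / k^2, cg = mean(s_i),
         P = P)
  })
  m_s <- vapply(cell, `[[`, numeric(1), "m")
  v_s <- vapply(cell, `[[`, numeric(1), "v")
  cg_s <- vapply(cell, `[[`, numeric(1), "cg")
  m <- sum(school_p * m_s)
  list(mean = m,
       var = sum(school_p * (v_s + m_s^2)) - m^2,
       cov_g = sum(school_p * cg_s),
       P = Reduce(`+`, Map(`*`, school_p, lapply(cell, `[[`, "P"))))
}

calibrate_gti <- function(lambda, tri, school_shift, mean_F, mean_M) {
  school_shift <- school_shift - sum(SCHOOL_PROPS * school_shift)
  g_pool <- GENDER_PROPS["F"] * tri$g_F + GENDER_PROPS["M"] * tri$g_M
  tau0 <- qnorm(1 - g_pool)
  moments <- function(o, delta) {
    lapply(c(F = "F", M = "M"), function(g) {
      sgn <- if (g == "M") 0.5 else -0.5
      pi_g <- if (g == "M") tri$pi_M else tri$pi_F
      gti_cell_moments(lambda, tau0 + o, sgn * delta + school_shift,
                       SCHOOL_BY_GENDER[, g], pi_g)
    })
  }
  o <- 0; delta <- 0.1
  for (it in 1:4) {
    o <- uniroot(function(oo) {
      mo <- moments(oo, delta)
      (mo$F$mean + mo$M$mean) / 2 - (mean_F + mean_M) / 2
    }, c(-2, 2), tol = 1e-8)$root
    delta <- uniroot(function(dd) {
      mo <- moments(o, dd)
      (mo$M$mean - mo$F$mean) - (mean_M - mean_F)
    }, c(-1, 2), tol = 1e-8)$root
  }
  mo <- moments(o, delta)
  # model-implied attribution targets per respondent gender
  attr_targets <- purrr::map_dfr(c("F", "M"), function(g) {
    pi_g <- if (g == "M") tri$pi_M else tri$pi_F
    P <- mo[[g]]$P
    tibble::tibble(item_id = tri$item_id, respondent_gender = g,
                   p_gendered = P, p_stereo = P * pi_g,
                   p_counter = P * (1 - pi_g), p_egalitarian = 1 - P)
  })
  list(tau = tau0 + o, delta = delta, o = o, school_shift = school_shift,
       lambda = lambda, tri = tri, moments = mo,
       attribution_targets = attr_targets)
}

# ---- configuration ----------------------------------------------------------

#' Default simulation configuration
#'
#' Builds the generator configuration from the published study quantities:
#' sample composition, CFA loadings, inter-factor correlations, gender and
#' school-track effect sizes, scale-level means/SDs (used as calibration
#' targets for the probit thresholds), attribution asymmetries for the
#' trait items, within-gender criterion correlation targets and
#' contamination rates. All calibration is deterministic (root finding on
#' analytic moments), so the same configuration is produced every time.
#'
#' @param n Cohort size.
#' @param rate_acquiescent Proportion of persons replaced by agreement-heavy
#'   likert responders.
#' @param rate_straightline Proportion answering the same column on every
#'   trichotomous item.
#' @param missing_rate Proportion of item cells set missing.
#' @return A list of class `gab_sim_config`.
#' @export
default_sim_config <- function(n = 2955, rate_acquiescent = 0.014,
                               rate_straightline = 0.0015,
                               missing_rate = 0) {
  cache_key <- paste0("core_", signif(rate_acquiescent, 6))
  core <- .gab_cache[[cache_key]]
  if (is.null(core)) {
    reg <- gab_registry()
    gsas_kmap <- reg$subscale[match(names(GSAS_LAMBDA), reg$item_id)]
    gras_kmap <- reg$subscale[match(names(GRAS_LAMBDA), reg$item_id)]
    # The printed means/SDs describe the full sample, contaminants included;
    # the clean-core calibration targets are the mixture-inverted values
    # (acquiescent responders average 3.5 on the likert metric).
    decontaminate <- function(m_t, v_t, r, mc = 3.5, vc = 0.25 / 17 / 2) {
      m0 <- (m_t - r * mc) / (1 - r)
      v0 <- (v_t - r * (vc + (mc - m_t)^2)) / (1 - r) - (m0 - m_t)^2
      list(mean = m0, var = v0)
    }
    adjF <- decontaminate(1.67, 0.42^2, rate_acquiescent)
    adjM <- decontaminate(2.18, 0.53^2, rate_acquiescent)
    gsas <- calibrate_ordinal_scale(
      GSAS_LAMBDA, gsas_kmap, GSAS_A,
      wgt_k = c(TS = 0.95, VM = 1.04, RC = 0.56) / mean(c(0.95, 1.04, 0.56)),
      school_shift = c(academic = 0, technical = 0.54, vocational = 0.35),
      C = 4, base = 1, mean_F = adjF$mean, mean_M = adjM$mean,
      var_within = (adjF$var + adjM$var) / 2, spread_width = 0.8
    )
    gras <- calibrate_ordinal_scale(
      GRAS_LAMBDA, gras_kmap, GRAS_A,
      wgt_k = c(LA = 0.89, SR = 0.70) / mean(c(0.89, 0.70)),
      school_shift = c(academic = 0, technical = 0.32, vocational = -0.01),
      C = 3, base = 0, mean_F = 1.19, mean_M = 1.42,
      var_within = (0.22^2 + 0.28^2) / 2, spread_width = 1.1
    )
    gti <- calibrate_gti(
      GTI_LAMBDA, GTI_TRI,
      school_shift = c(academic = 0, technical = 0.13, vocational = 0.02),
      mean_F = 0.78, mean_M = 0.83
    )
    scales <- list(GSAS = gsas, GRAS = gras, GTI = gti)

    # cross-scale latent correlations from pooled observed targets
    wF <- GENDER_PROPS[["F"]]; wM <- GENDER_PROPS[["M"]]
    smom <- lapply(scales, function(s) {
      list(mF = s$moments$F$mean, mM = s$moments$M$mean,
           vF = s$moments$F$var, vM = s$moments$M$var,
           cgF = s$moments$F$cov_g, cgM = s$moments$M$cov_g)
    })
    pooled_var <- vapply(smom, function(s) {
      wF * s$vF + wM * s$vM + wF * wM * (s$mM - s$mF)^2
    }, numeric(1))
    psi_pair <- function(a, b, target) {
      sa <- smom[[a]]; sb <- smom[[b]]
      between <- wF * wM * (sa$mM - sa$mF) * (sb$mM - sb$mF)
      denom <- wF * sa$cgF * sb$cgF + wM * sa$cgM * sb$cgM
      min(0.97, max(0.02,
        (target * sqrt(pooled_var[a] * pooled_var[b]) - between) / denom))
    }
    Psi <- diag(3)
    dimnames(Psi) <- list(c("GSAS", "GRAS", "GTI"), c("GSAS", "GRAS", "GTI"))
    Psi["GSAS", "GRAS"] <- Psi["GRAS", "GSAS"] <-
      psi_pair("GSAS", "GRAS", INTER_SCALE_TARGETS["gsas_gras"])
    Psi["GSAS", "GTI"] <- Psi["GTI", "GSAS"] <-
      psi_pair("GSAS", "GTI", INTER_SCALE_TARGETS["gsas_gti"])
    Psi["GRAS", "GTI"] <- Psi["GTI", "GRAS"] <-
      psi_pair("GRAS", "GTI", INTER_SCALE_TARGETS["gras_gti"])
    ev <- eigen(Psi, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-6) stop("infeasible cross-scale correlation structure")

    att <- sapply(c("F", "M"), function(g) {
      vapply(smom, function(s) {
        if (g == "F") s$cgF / sqrt(s$vF) else s$cgM / sqrt(s$vM)
      }, numeric(1))
    })

    # criterion loadings per gender: solve Psi-weighted system so the
    # within-gender observed-score correlations hit their targets
    crit <- CRITERIA_SPEC
    bmat <- lapply(c(F = "F", M = "M"), function(g) {
      M <- Psi * matrix(att[, g], nrow = 3, ncol = 3, byrow = FALSE)
      # row a: corr with scale a = sum_t b_t Psi[a,t] * att_a
      out <- sapply(seq_len(nrow(crit)), function(i) {
        r <- as.numeric(crit[i, paste0("r_", g, c("_gsas", "_gras", "_gti"))])
        solve(M, r)
      })
      rownames(out) <- c("GSAS", "GRAS", "GTI")
      colnames(out) <- crit$name
      out
    })
    # residual variance check (shared family factor included)
    for (g in c("F", "M")) {
      for (i in seq_len(nrow(crit))) {
        b <- bmat[[g]][, i]
        q <- if (crit$family[i] == "bpaq") BPAQ_FAMILY_LOADING else 0
        res <- 1 - as.numeric(t(b) %*% Psi %*% b) - q^2
        if (res <= 0.05) stop("infeasible criterion correlation structure: ",
                              crit$name[i])
      }
    }

    # distress gender gap: calibrate so the pooled attitude-distress
    # correlation matches the published pooled value
    k10 <- which(crit$name == "k10")
    s <- smom$GSAS
    covF <- crit$r_F_gsas[k10] * crit$sd[k10] * sqrt(s$vF)
    covM <- crit$r_M_gsas[k10] * crit$sd[k10] * sqrt(s$vM)
    dS <- s$mM - s$mF
    vS <- wF * s$vF + wM * s$vM + wF * wM * dS^2
    gap <- uniroot(function(gp) {
      num <- wF * covF + wM * covM + wF * wM * dS * gp
      num / sqrt((crit$sd[k10]^2 + wF * wM * gp^2) * vS) - (-0.149)
    }, c(-40, 0), tol = 1e-8)$root
    crit$mean_M[k10] <- crit$mean_F[k10] + gap

    core <- list(scales = scales, Psi = Psi, att = att, criteria = crit,
                 bmat = bmat, k10_gap = gap)
    .gab_cache[[cache_key]] <- core
  }
  structure(
    c(core, list(n = n, gender_props = GENDER_PROPS,
                 school_by_gender = SCHOOL_BY_GENDER,
                 rate_acquiescent = rate_acquiescent,
                 rate_straightline = rate_straightline,
                 missing_rate = missing_rate)),
    class = "gab_sim_config"
  )
}

.gab_cache <- new.env(parent = emptyenv())

#' @export
print.gab_sim_config <- function(x, ...) {
  cat("Simulation config: n =", x$n, "\n")
  cat("  latent gender separations:",
      paste(sprintf("%s %.3f", names(x$scales),
                    vapply(x$scales, `[[`, numeric(1), "delta")),
            collapse = ", "), "\n")
  cat("  cross-scale latent correlations:",
      sprintf("GSAS-GRAS %.3f, GSAS-GTI %.3f, GRAS-GTI %.3f",
              x$Psi[1, 2], x$Psi[1, 3], x$Psi[2, 3]), "\n")
  cat("  distress gender gap:", sprintf("%.2f", x$k10_gap), "\n")
  invisible(x)
}

# ---- generation -------------------------------------------------------------

substream_seeds <- function(seed, n_streams = 6) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1, n_streams)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

#' Generate a synthetic cohort
#'
#' Draws demographics, latent factors, ordinal item responses, criterion
#' scores and contamination from the configuration, fully reproducibly per
#' seed (named substreams, so e.g. changing the contamination rate does not
#' perturb the item draws).
#'
#' @param config A `gab_sim_config` (default [default_sim_config()]).
#' @param seed Integer seed.
#' @return A `gab_responses` tibble with demographics, the 41 retained item
#'   columns (raw codes) and the 8 criterion columns.
#' @export
generate_cohort <- function(config = default_sim_config(), seed = 1) {
  n <- config$n
  ss <- substream_seeds(seed)
  reg <- gab_registry()

  set.seed(ss[1]) # demographics
  gender <- sample(c("F", "M"), n, replace = TRUE, prob = config$gender_props)
  school <- character(n)
  for (g in c("F", "M")) {
    idx <- which(gender == g)
    school[idx] <- sample(SCHOOL_LEVELS, length(idx), replace = TRUE,
                          prob = config$school_by_gender[, g])
  }

  set.seed(ss[2]) # general factors
  Z <- matrix(rnorm(n * 3), n, 3) %*% chol(config$Psi)
  colnames(Z) <- c("GSAS", "GRAS", "GTI")

  set.seed(ss[3]) # items
  resp <- list()
  for (sc in c("GSAS", "GRAS")) {
    cal <- config$scales[[sc]]
    k <- length(cal$lambda)
    sgn <- ifelse(gender == "M", 0.5, -0.5)
    shifts_k <- sapply(names(cal$a_k), function(kk) {
      sgn * cal$delta * cal$wgt_k[kk] +
        cal$school_shift[match(school, SCHOOL_LEVELS)]
    })
    fmat <- sapply(names(cal$a_k), function(kk) {
      cal$a_k[kk] * Z[, sc] + sqrt(1 - cal$a_k[kk]^2) * rnorm(n)
    }) + shifts_k
    colnames(fmat) <- names(cal$a_k)
    for (i in seq_len(k)) {
      l <- cal$lambda[i]
      y <- l * fmat[, cal$kmap[i]] + sqrt(1 - l^2) * rnorm(n)
      code <- findInterval(y, cal$tau[[i]]) # 0..C-1, ascending with latent
      it <- names(cal$lambda)[i]
      if (sc == "GSAS") {
        resp[[it]] <- code + 1L
      } else {
        dir <- reg$stereotype_direction[reg$item_id == it]
        stereo <- if (dir == "male") "M" else "F"
        counter <- if (dir == "male") "F" else "M"
        resp[[it]] <- c(counter, "E", stereo)[code + 1L]
      }
    }
  }
  cal <- config$scales$GTI
  sgn <- ifelse(gender == "M", 0.5, -0.5)
  mu <- cal$delta * sgn + cal$school_shift[match(school, SCHOOL_LEVELS)]
  f <- Z[, "GTI"] + mu # single factor (a = 1)
  for (i in seq_along(cal$lambda)) {
    l <- cal$lambda[i]
    y <- l * f + sqrt(1 - l^2) * rnorm(n)
    gendered <- y > cal$tau[i]
    pi_g <- ifelse(gender == "M", cal$tri$pi_M[i], cal$tri$pi_F[i])
    stereo_draw <- runif(n) < pi_g
    it <- cal$tri$item_id[i]
    dir <- reg$stereotype_direction[reg$item_id == it]
    stereo <- if (dir == "male") "M" else "F"
    counter <- if (dir == "male") "F" else "M"
    resp[[it]] <- ifelse(!gendered, "E", ifelse(stereo_draw, stereo, counter))
  }

  set.seed(ss[4]) # criteria
  crit <- config$criteria
  fam <- rnorm(n) # shared aggression-family factor
  crit_out <- list()
  for (i in seq_len(nrow(crit))) {
    q <- if (crit$family[i] == "bpaq") BPAQ_FAMILY_LOADING else 0
    val <- numeric(n)
    for (g in c("F", "M")) {
      idx <- gender == g
      b <- config$bmat[[g]][, crit$name[i]]
      res_sd <- sqrt(1 - as.numeric(t(b) %*% config$Psi %*% b) - q^2)
      lin <- as.numeric(Z[idx, , drop = FALSE] %*% b) + q * fam[idx] +
        res_sd * rnorm(sum(idx))
      mu_c <- if (g == "F") crit$mean_F[i] else crit$mean_M[i]
      val[idx] <- mu_c + crit$sd[i] * lin
    }
    crit_out[[crit$name[i]]] <- val
  }
  crit_out$bpaq_total <- (9 * crit_out$bpaq_physical + 5 * crit_out$bpaq_verbal +
    7 * crit_out$bpaq_anger + 8 * crit_out$bpaq_hostility) / 29

  out <- tibble::tibble(
    person_id = sprintf("P%05d", seq_len(n)),
    gender = gender, school = school
  )
  for (nm in names(resp)) out[[nm]] <- resp[[nm]]
  for (nm in CRITERION_COLS) out[[nm]] <- crit_out[[nm]]

  set.seed(ss[5]) # contamination
  n_acq <- round(config$rate_acquiescent * n)
  n_sl <- round(config$rate_straightline * n)
  pick <- sample.int(n, n_acq + n_sl)
  gsas_items <- retained_items(reg, "GSAS")
  tri_items <- c(retained_items(reg, "GRAS"), retained_items(reg, "GTI"))
  if (n_acq > 0) {
    for (p in pick[seq_len(n_acq)]) {
      vals <- if (runif(1) < 0.5) rep(sample(3:4, 1), length(gsas_items))
      else sample(3:4, length(gsas_items), replace = TRUE)
      out[p, gsas_items] <- as.list(as.integer(vals))
    }
  }
  if (n_sl > 0) {
    for (p in pick[n_acq + seq_len(n_sl)]) {
      col <- sample(c("M", "F", "E"), 1)
      out[p, tri_items] <- as.list(rep(col, length(tri_items)))
    }
  }

  set.seed(ss[6]) # missingness
  if (config$missing_rate > 0) {
    all_items <- c(gsas_items, tri_items)
    for (it in all_items) {
      miss <- runif(n) < config$missing_rate
      out[[it]][miss] <- NA
    }
  }

  as_gab_responses(out, registry = reg)
}

# ---- expert ratings ---------------------------------------------------------

#' Default expert relevance profile for the 46-item pool
#'
#' Per-item probabilities (in twelfths) that a panel expert rates the item
#' relevant, consistent with the published module-level content validity
#' summary (module S-CVIs 0.986 / 0.977 / 0.917, overall 0.967).
#'
#' @return Named numeric vector over the 46 items.
#' @export
default_expert_profile <- function() {
  p <- c(rep(1, 16), 11 / 12, 10 / 12)
  names(p) <- paste0("GSAS_", 1:18)
  q <- c(rep(1, 14), rep(11 / 12, 3), 10 / 12)
  names(q) <- paste0("GRAS_", 1:18)
  r <- c(rep(1, 5), rep(11 / 12, 2), rep(10 / 12, 2), 8 / 12)
  names(r) <- paste0("GTI_", c(1:6, 8:10, 7))
  c(p, q, r)
}

#' Simulate an expert rating matrix
#'
#' Each expert rates an item 4 or 5 ("relevant") with the item's profile
#' probability, else 1-3; so the expected I-CVI equals the profile value.
#' With `exact = TRUE` the number of relevant ratings is fixed to
#' `round(p * n_experts)` (shuffled across experts), reproducing the
#' profile exactly.
#'
#' @param profile Named per-item relevance probabilities
#'   ([default_expert_profile()]).
#' @param n_experts Panel size.
#' @param seed Seed.
#' @param exact Fix relevant-rating counts instead of Bernoulli sampling.
#' @return Integer matrix, experts by items.
#' @export
make_expert_ratings <- function(profile = default_expert_profile(),
                                n_experts = 12, seed = 1, exact = FALSE) {
  stopifnot(all(profile >= 0 & profile <= 1))
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  m <- sapply(names(profile), function(it) {
    rel <- if (exact) {
      sample(rep(c(TRUE, FALSE),
                 c(round(profile[it] * n_experts),
                   n_experts - round(profile[it] * n_experts))))
    } else {
      runif(n_experts) < profile[it]
    }
    ifelse(rel, sample(4:5, n_experts, replace = TRUE),
           sample(1:3, n_experts, replace = TRUE, prob = c(0.1, 0.3, 0.6)))
  })
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  rownames(m) <- paste0("expert_", seq_len(n_experts))
  m
}
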