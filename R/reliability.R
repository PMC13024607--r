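# Internal-consistency estimation: Cronbach's alpha with the Feldt interval,
# McDonald's omega via the Schmid-Leiman decomposition, polychoric alpha and
# corrected item-total correlations. Sample variances use the n-1 denominator
# throughout.

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total))`.
#'
#' @param scores Numeric matrix or data frame, persons by items (complete
#'   cases required).
#' @return Alpha as a single number.
#' @export
cronbach_alpha <- function(scores) {
  m <- as.matrix(scores)
  storage.mode(m) <- "numeric"
  if (anyNA(m)) stop("scores must be complete; apply a completeness rule first", call. = FALSE)
  k <- ncol(m)
  if (k < 2 || nrow(m) < 3) stop("need at least 2 items and 3 persons", call. = FALSE)
  vt <- var(rowSums(m))
  if (vt <= 0) stop("total score has zero variance; alpha undefined", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / vt)
}

# alpha from a correlation matrix (unit variances)
alpha_from_cor <- function(R) {
  k <- ncol(R)
  k / (k - 1) * (1 - k / sum(R))
}

#' Feldt confidence interval for Cronbach's alpha
#'
#' Classical F-distribution interval: the lower bound is
#' `1 - (1 - alpha) * F(1 - gamma/2; n-1, (n-1)(k-1))` and the upper bound
#' `1 - (1 - alpha) / F(1 - gamma/2; (n-1)(k-1), n-1)`.
#'
#' @param alpha Point estimate (must be < 1).
#' @param n Number of persons.
#' @param k Number of items.
#' @param level Confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
feldt_ci <- function(alpha, n, k, level = 0.95) {
  stopifnot(n > 1, k > 1)
  if (alpha >= 1) return(c(1, 1))
  g <- 1 - level
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  lo <- 1 - (1 - alpha) * qf(1 - g / 2, df1, df2)
  hi <- 1 - (1 - alpha) / qf(1 - g / 2, df2, df1)
  c(lo, hi)
}

#' Corrected item-total correlations
#'
#' Pearson correlation of each item with the sum of the remaining items.
#'
#' @inheritParams cronbach_alpha
#' @return Named numeric vector (NA with a warning for zero-variance items).
#' @export
item_total_corrected <- function(scores) {
  m <- as.matrix(scores)
  storage.mode(m) <- "numeric"
  if (ncol(m) < 3) stop("need at least 3 items", call. = FALSE)
  tot <- rowSums(m)
  out <- vapply(seq_len(ncol(m)), function(j) {
    if (var(m[, j]) == 0) return(NA_real_)
    cor(m[, j], tot - m[, j])
  }, numeric(1))
  names(out) <- colnames(m)
  if (anyNA(out)) warning("zero-variance item(s): ",
                          paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Polychoric alpha
#'
#' Cronbach's alpha formula applied to the polychoric correlation matrix of
#' the items (unit latent variances).
#'
#' @param scores Ordinal item matrix (persons by items).
#' @return Alpha on the latent-response metric.
#' @export
polychoric_alpha <- function(scores) {
  R <- polychoric_matrix(scores)
  alpha_from_cor(R)
}

# one-factor loadings by iterated PAF (used for single-group omega and for
# the second-order factor of the Schmid-Leiman step)
one_factor_loadings <- function(R, max_iter = 500, tol = 1e-11) {
  k <- ncol(R)
  h2 <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, k))
  h2 <- pmin(pmax(h2, 0.01), 0.99)
  for (i in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    l <- e$vectors[, 1] * sqrt(max(e$values[1], 0))
    if (sum(l) < 0) l <- -l
    h2_new <- pmin(l^2, 0.999)
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; break }
    h2 <- h2_new
  }
  l
}

#' McDonald's omega via the Schmid-Leiman decomposition
#'
#' For multidimensional scales, correlated group factors are extracted with
#' principal-axis factoring and oblimin rotation, a higher-order factor is
#' fitted to the inter-factor correlations, and the Schmid-Leiman
#' orthogonalisation splits each loading into a general and a group part.
#' `omega` (total) uses all common loadings; `omega_h` uses only the general
#' loadings. Single-factor scales use the one-factor loadings directly, in
#' which case `omega_h == omega`.
#'
#' @param R Correlation matrix of the items (Pearson or polychoric).
#' @param n_group_factors Number of group factors (1 for unidimensional).
#' @param seed Seed for the rotation's random restarts.
#' @return List with `omega`, `omega_h`, `general_loadings`,
#'   `group_loadings`, and `heywood` (TRUE if any communality was capped).
#' @export
omega_schmid_leiman <- function(R, n_group_factors = 1, seed = 1) {
  k <- ncol(R)
  heywood <- FALSE
  if (n_group_factors <= 1) {
    l <- one_factor_loadings(R)
    if (any(l^2 > 0.999)) { heywood <- TRUE; l <- pmin(l, 0.999) }
    u <- 1 - l^2
    om <- sum(l)^2 / (sum(l)^2 + sum(u))
    return(list(omega = om, omega_h = om, general_loadings = l,
                group_loadings = matrix(l, ncol = 1), heywood = heywood))
  }
  sol <- paf_oblimin(R, n_factors = n_group_factors, seed = seed)
  L <- sol$pattern
  Phi <- sol$phi
  if (n_group_factors == 2) {
    r12 <- Phi[1, 2]
    gamma <- rep(sqrt(max(min(abs(r12), 0.999), 0)), 2) * sign(r12)^c(0, 1)
    # keep both second-order loadings positive when factors correlate positively
    if (r12 >= 0) gamma <- rep(sqrt(min(r12, 0.999)), 2)
  } else {
    gamma <- one_factor_loadings(Phi)
  }
  gamma <- pmin(pmax(gamma, -0.999), 0.999)
  g <- as.numeric(L %*% gamma)
  spec <- sweep(L, 2, sqrt(pmax(1 - gamma^2, 0)), `*`)
  h2 <- diag(L %*% Phi %*% t(L))
  if (any(h2 > 1)) { heywood <- TRUE; h2 <- pmin(h2, 0.999) }
  u <- 1 - h2
  common <- sum(g)^2 + sum(colSums(spec)^2)
  total <- common + sum(u)
  list(omega = common / total,
       omega_h = sum(g)^2 / total,
       general_loadings = g,
       group_loadings = spec,
       heywood = heywood)
}

#' Reliability report for one scored scale
#'
#' Bundles Cronbach's alpha with its Feldt interval, McDonald's omega and
#' hierarchical omega (Schmid-Leiman, on the polychoric matrix for ordinal
#' items), polychoric alpha and corrected item-total correlations.
#'
#' @param scores Persons-by-items matrix of scored responses (complete
#'   cases; ordinal integer codes).
#' @param n_group_factors Group factors for the omega decomposition.
#' @param level Confidence level for the alpha interval.
#' @param polychoric Also compute the polychoric-based coefficients (slower).
#' @return A list of class `gab_reliability`.
#' @export
reliability_report <- function(scores, n_group_factors = 1, level = 0.95,
                               polychoric = TRUE) {
  m <- as.matrix(scores)
  storage.mode(m) <- "numeric"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  a <- cronbach_alpha(m)
  ci <- feldt_ci(a, nrow(m), ncol(m), level = level)
  rit <- item_total_corrected(m)
  pa <- NA_real_
  om <- list(omega = NA_real_, omega_h = NA_real_, heywood = FALSE)
  if (polychoric) {
    R <- polychoric_matrix(m)
    pa <- alpha_from_cor(R)
    om <- omega_schmid_leiman(R, n_group_factors = n_group_factors)
  } else {
    om <- omega_schmid_leiman(cor(m), n_group_factors = n_group_factors)
  }
  structure(list(alpha = a, alpha_ci95 = ci, omega = om$omega,
                 omega_h = om$omega_h, polychoric_alpha = pa,
                 item_total = rit, n = nrow(m), k = ncol(m),
                 heywood = om$heywood, level = level),
            class = "gab_reliability")
}

#' @export
print.gab_reliability <- function(x, ...) {
  cat(sprintf("alpha = %.3f [%.3f, %.3f], omega = %.3f, omega_h = %.3f (n = %d, k = %d)\n",
              x$alpha, x$alpha_ci95[1], x$alpha_ci95[2], x$omega, x$omega_h,
              x$n, x$k))
  invisible(x)
}

#' Reliability sweep over demographic subgroups
#'
#' Re-runs [reliability_report()] within each gender and school stratum.
#'
#' @param data A `gab_responses` tibble.
#' @param registry Item registry.
#' @param scale Scale id.
#' @param schema Scoring schema for trichotomous scales.
#' @param polychoric Passed through to [reliability_report()].
#' @return Tibble with one row per stratum (`stratum`, `alpha`, `alpha_lo`,
#'   `alpha_hi`, `omega`, `omega_h`, `n`).
#' @export
reliability_by_group <- function(data, registry = gab_registry(), scale = "GSAS",
                                 schema = if (scale == "GTI") "B" else "A",
                                 polychoric = FALSE) {
  items <- retained_items(registry, scale)
  nf <- length(subscale_items(registry, scale))
  if (nf == 0) nf <- 1
  m <- score_items_matrix(data, registry, items, schema)
  strata <- c(list(all = rep(TRUE, nrow(data))),
              split(seq_len(nrow(data)), data$gender) |> lapply(\(i) seq_len(nrow(data)) %in% i),
              split(seq_len(nrow(data)), data$school) |> lapply(\(i) seq_len(nrow(data)) %in% i))
  purrr::imap_dfr(strata, function(idx, nm) {
    rep <- reliability_report(m[idx, , drop = FALSE], n_group_factors = nf,
                              polychoric = polychoric)
    tibble::tibble(stratum = nm, alpha = rep$alpha,
                   alpha_lo = rep$alpha_ci95[1], alpha_hi = rep$alpha_ci95[2],
                   omega = rep$omega, omega_h = rep$omega_h, n = rep$n)
  })
}
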