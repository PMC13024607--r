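# Ordinal exploratory factor analysis: sampling adequacy, factor-number
# selection by parallel analysis, iterated principal-axis extraction,
# direct-oblimin (quartimin) rotation by gradient projection, salience
# screening and cross-group congruence.

#' Sampling adequacy: KMO and Bartlett's test of sphericity
#'
#' KMO compares squared correlations to squared anti-image partial
#' correlations (>= 0.60 acceptable, >= 0.80 good). Bartlett's chi-square is
#' `-(n - 1 - (2k + 5)/6) * log det(R)` on `k(k-1)/2` degrees of freedom.
#'
#' @param R Correlation matrix (invertible).
#' @param n Sample size behind `R`.
#' @return List of class `gab_suitability`: `kmo_overall`, `kmo_per_item`,
#'   `bartlett_chi2`, `bartlett_df`, `bartlett_p`.
#' @export
suitability <- function(R, n) {
  R <- as.matrix(R)
  k <- ncol(R)
  Ri <- tryCatch(solve(R), error = function(e)
    stop("singular correlation matrix; consider smoothing", call. = FALSE))
  S <- diag(1 / sqrt(diag(Ri)))
  P <- -S %*% Ri %*% S # anti-image partial correlations
  diag(P) <- 0
  R0 <- R
  diag(R0) <- 0
  r2 <- R0^2
  p2 <- P^2
  kmo_item <- colSums(r2) / (colSums(r2) + colSums(p2))
  names(kmo_item) <- colnames(R)
  chi2 <- -(n - 1 - (2 * k + 5) / 6) * determinant(R, logarithm = TRUE)$modulus[1]
  chi2 <- max(0, chi2)
  df <- k * (k - 1) / 2
  structure(list(
    kmo_overall = sum(r2) / (sum(r2) + sum(p2)),
    kmo_per_item = kmo_item,
    bartlett_chi2 = chi2,
    bartlett_df = df,
    bartlett_p = pchisq(chi2, df, lower.tail = FALSE)
  ), class = "gab_suitability")
}

#' @export
print.gab_suitability <- function(x, ...) {
  cat(sprintf("KMO = %.3f; Bartlett chi2(%d) = %.1f, p = %.3g\n",
              x$kmo_overall, x$bartlett_df, x$bartlett_chi2, x$bartlett_p))
  invisible(x)
}

# eigenvalues of the communality-reduced correlation matrix (SMC diagonal),
# matching the principal-axis logic used for extraction
reduced_eigenvalues <- function(R) {
  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, ncol(R)))
  Rr <- R
  diag(Rr) <- pmin(pmax(smc, 0), 1)
  eigen(Rr, symmetric = TRUE, only.values = TRUE)$values
}

#' Parallel analysis for factor retention
#'
#' Compares the eigenvalues of the reduced (communality-adjusted)
#' correlation matrix of the observed data to the same quantity computed on
#' `reps` random datasets of identical size whose columns are resampled
#' independently from each item's marginal distribution. Retains the leading
#' factors whose observed eigenvalue exceeds the reference quantile,
#' stopping at the first failure.
#'
#' @param data Ordinal data matrix (persons by items).
#' @param reps Number of reference datasets.
#' @param quantile Reference quantile of the simulated eigenvalues. The
#'   default 0.99 follows the conservative recommendation for percentile
#'   thresholds, curbing over-extraction; 0.95 is the other common choice.
#' @param seed Seed for the reference simulation.
#' @param cor_method `"pearson"` (default, fast) or `"polychoric"` for the
#'   observed and reference correlation matrices.
#' @return Integer: number of factors retained, with attributes
#'   `"eigenvalues"` (observed) and `"reference"` (quantile curve).
#' @export
parallel_analysis <- function(data, reps = 1000, quantile = 0.99, seed = 1,
                              cor_method = c("pearson", "polychoric")) {
  cor_method <- match.arg(cor_method)
  m <- as.matrix(data)
  storage.mode(m) <- "numeric"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  stopifnot(n > k)
  corfun <- if (cor_method == "pearson") cor else polychoric_matrix
  obs <- reduced_eigenvalues(corfun(m))
  ref <- matrix(NA_real_, reps, k)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  for (r in seq_len(reps)) {
    sim <- apply(m, 2, function(col) col[sample.int(n, n, replace = TRUE)])
    ref[r, ] <- reduced_eigenvalues(corfun(sim))
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  qref <- apply(ref, 2, quantile, probs = quantile, names = FALSE)
  keep <- obs > qref
  n_factors <- if (!keep[1]) 0L else which.min(c(keep, FALSE)) - 1L
  n_factors <- min(n_factors, min(k, n) - 1L)
  structure(as.integer(n_factors), eigenvalues = obs, reference = qref)
}

# quartimin criterion and gradient for gradient-projection rotation
vgq_quartimin <- function(L) {
  k <- ncol(L)
  L2 <- L^2
  N <- matrix(1, k, k) - diag(k)
  X <- L2 %*% N
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

# gradient-projection algorithm for oblique rotation (quartimin / direct
# oblimin with gamma = 0)
gpf_oblq <- function(A, Tmat, eps = 1e-6, maxit = 1000) {
  al <- 1
  L <- A %*% t(solve(Tmat))
  vg <- vgq_quartimin(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% solve(Tmat))
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G))
    s <- sqrt(sum(Gp^2))
    if (s < eps) { converged <- TRUE; break }
    al <- 2 * al
    for (i in 0:20) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)))
      L <- A %*% t(solve(Tt))
      vgt <- vgq_quartimin(L)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- vgt$f
    G <- -t(t(L) %*% vgt$Gq %*% solve(Tt))
  }
  list(loadings = A %*% t(solve(Tmat)), Phi = t(Tmat) %*% Tmat, f = f,
       converged = converged)
}

random_orthonormal <- function(k) {
  qr.Q(qr(matrix(rnorm(k * k), k, k)))
}

#' Principal-axis factoring with direct oblimin rotation
#'
#' Iterated principal-axis extraction (initial communalities from squared
#' multiple correlations, eigendecomposition of the reduced matrix until the
#' communality change falls below `tol`), followed by direct-oblimin
#' (quartimin) rotation via gradient projection with random orthogonal
#' restarts. Columns are sign-normalised (majority positive) and ordered by
#' descending sum of squared structure loadings.
#'
#' @param R Correlation matrix (typically polychoric).
#' @param n_factors Number of factors (>= 1).
#' @param gamma Oblimin parameter; only `0` (direct quartimin) is supported.
#' @param tol Convergence tolerance for the communality iteration.
#' @param max_iter Maximum communality iterations.
#' @param n_starts Random rotation restarts; the best criterion value wins.
#' @param seed Seed for the restarts.
#' @return A list of class `gab_efa`: `pattern`, `phi`, `structure`, `h2`,
#'   `variance_explained`, `prop_variance`, `n_factors`, `converged`,
#'   `heywood`.
#' @export
paf_oblimin <- function(R, n_factors, gamma = 0, tol = 1e-6, max_iter = 1000,
                        n_starts = 10, seed = 1) {
  stopifnot(n_factors >= 1, gamma == 0)
  R <- as.matrix(R)
  k <- ncol(R)
  h2 <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, k))
  h2 <- pmin(pmax(h2, 0.01), 0.99)
  converged <- FALSE
  heywood <- FALSE
  A <- NULL
  for (i in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(n_factors)], 0)
    A <- e$vectors[, seq_len(n_factors), drop = FALSE] %*% diag(sqrt(ev), n_factors)
    h2_new <- rowSums(A^2)
    if (any(h2_new > 0.999)) {
      heywood <- TRUE
      h2_new <- pmin(h2_new, 0.999)
    }
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      converged <- TRUE
      break
    }
    h2 <- h2_new
  }

  if (n_factors == 1) {
    L <- A
    if (sum(L) < 0) L <- -L
    Phi <- matrix(1, 1, 1)
    rot_conv <- TRUE
  } else {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    best <- NULL
    for (s in seq_len(n_starts)) {
      Tm <- if (s == 1) diag(n_factors) else random_orthonormal(n_factors)
      fit <- gpf_oblq(A, Tm)
      if (is.null(best) || fit$f < best$f - 1e-10) best <- fit
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    L <- best$loadings
    Phi <- best$Phi
    rot_conv <- best$converged
    # sign convention: each factor majority-positive
    for (j in seq_len(n_factors)) {
      if (sum(L[, j]) < 0) {
        L[, j] <- -L[, j]
        Phi[j, ] <- -Phi[j, ]
        Phi[, j] <- -Phi[, j]
      }
    }
    # order by descending explained variance (structure loadings)
    St <- L %*% Phi
    ord <- order(colSums(St^2), decreasing = TRUE)
    L <- L[, ord, drop = FALSE]
    Phi <- Phi[ord, ord, drop = FALSE]
  }
  St <- L %*% Phi
  # variance accounting from the orthogonal extraction (the oblique
  # structure loadings would double-count shared variance); the per-factor
  # sums of squares add up to the total communality
  ss <- sort(colSums(A^2), decreasing = TRUE)
  dimnames(L) <- list(colnames(R), paste0("F", seq_len(n_factors)))
  structure(list(
    pattern = L, phi = Phi, structure = St,
    h2 = setNames(rowSums(L * St), colnames(R)),
    variance_explained = ss, prop_variance = ss / k,
    n_factors = n_factors, converged = converged && rot_conv,
    heywood = heywood
  ), class = "gab_efa")
}

#' @export
print.gab_efa <- function(x, digits = 2, ...) {
  cat(sprintf("EFA: %d factor(s), %.1f%% total variance%s\n", x$n_factors,
              100 * sum(x$prop_variance),
              if (x$converged) "" else " (NOT converged)"))
  print(round(x$pattern, digits))
  if (x$n_factors > 1) {
    cat("Factor correlations:\n")
    print(round(x$phi, digits))
  }
  invisible(x)
}

#' Salience screening of a factor solution
#'
#' Flags items that load below `salience` on every factor, or whose
#' primary-secondary loading gap is below `cross_gap` (report only; final
#' retention integrates content and confirmatory evidence).
#'
#' @param solution A `gab_efa` object.
#' @param salience Salience threshold on absolute pattern loadings.
#' @param cross_gap Minimum gap between primary and secondary loadings.
#' @return Tibble: `item_id`, `primary_factor`, `primary_loading`,
#'   `secondary_loading`, `non_salient`, `cross_loading`, `flagged`.
#' @export
salience_filter <- function(solution, salience = 0.40, cross_gap = 0.20) {
  L <- abs(solution$pattern)
  prim <- apply(L, 1, which.max)
  pl <- L[cbind(seq_len(nrow(L)), prim)]
  sl <- vapply(seq_len(nrow(L)), function(i) {
    if (ncol(L) == 1) 0 else max(L[i, -prim[i]])
  }, numeric(1))
  non_salient <- pl < salience
  cross <- !non_salient & (pl - sl) < cross_gap & ncol(L) > 1
  tibble::tibble(
    item_id = rownames(L) %||% paste0("item_", seq_len(nrow(L))),
    primary_factor = prim,
    primary_loading = solution$pattern[cbind(seq_len(nrow(L)), prim)],
    secondary_loading = sl,
    non_salient = non_salient,
    cross_loading = cross,
    flagged = non_salient | cross
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tucker's congruence between two pattern matrices
#'
#' Factors are aligned by the best-match permutation on absolute congruence
#' and sign-aligned before reporting.
#'
#' @param L1,L2 Pattern matrices over the same items (same column count).
#' @return List of class `gab_congruence`: `phi` (per aligned factor),
#'   `pairing` (column of `L2` matched to each column of `L1`).
#' @export
tucker_phi <- function(L1, L2) {
  L1 <- as.matrix(L1); L2 <- as.matrix(L2)
  stopifnot(nrow(L1) == nrow(L2), ncol(L1) == ncol(L2))
  m <- ncol(L1)
  cong <- function(a, b) {
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) stop("zero-norm factor column; congruence undefined", call. = FALSE)
    sum(a * b) / den
  }
  C <- outer(seq_len(m), seq_len(m),
             Vectorize(function(i, j) cong(L1[, i], L2[, j])))
  # greedy best-match permutation on |phi|
  pairing <- integer(m)
  used_row <- logical(m)
  used_col <- logical(m)
  A <- abs(C)
  for (step in seq_len(m)) {
    A2 <- A
    A2[used_row, ] <- -Inf
    A2[, used_col] <- -Inf
    idx <- which(A2 == max(A2), arr.ind = TRUE)[1, , drop = TRUE]
    pairing[idx[1]] <- idx[2]
    used_row[idx[1]] <- TRUE
    used_col[idx[2]] <- TRUE
  }
  phi <- vapply(seq_len(m), function(i) {
    v <- cong(L1[, i], L2[, pairing[i]])
    abs(v) # sign-aligned
  }, numeric(1))
  structure(list(phi = phi, pairing = pairing), class = "gab_congruence")
}

#' @export
print.gab_congruence <- function(x, ...) {
  cat("Tucker's phi per aligned factor:",
      paste(sprintf("%.3f", x$phi), collapse = ", "), "\n")
  invisible(x)
}

#' Full ordinal EFA for one scale of the battery
#'
#' Convenience wrapper: scores the items, builds the polychoric correlation
#' matrix, checks suitability, selects the factor number by parallel
#' analysis (unless given) and fits the rotated principal-axis solution.
#'
#' @param data A `gab_responses` tibble.
#' @param registry Item registry.
#' @param scale Scale id.
#' @param schema Scoring schema for trichotomous items (Schema A orders the
#'   latent response as counter < egalitarian < stereotypical; Schema B as
#'   egalitarian < counter < stereotypical).
#' @param n_factors Number of factors, or `NULL` for parallel analysis.
#' @param reps,quantile Passed to [parallel_analysis()].
#' @param seed Seed for parallel analysis and rotation restarts.
#' @return List: `suitability`, `n_factors`, `solution` (`gab_efa`),
#'   `salience` and the correlation matrix `R`.
#' @export
efa_scale <- function(data, registry = gab_registry(), scale = "GSAS",
                      schema = if (scale == "GTI") "B" else "A",
                      n_factors = NULL, reps = 1000, quantile = 0.99,
                      seed = 1) {
  items <- retained_items(registry, scale)
  m <- score_items_matrix(data, registry, items, schema)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  R <- polychoric_matrix(m)
  suit <- suitability(R, nrow(m))
  if (is.null(n_factors)) {
    n_factors <- as.integer(parallel_analysis(m, reps = reps,
                                              quantile = quantile, seed = seed))
    n_factors <- max(n_factors, 1L)
  }
  sol <- paf_oblimin(R, n_factors = n_factors, seed = seed)
  list(suitability = suit, n_factors = n_factors, solution = sol,
       salience = salience_filter(sol), R = R, n = nrow(m))
}
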