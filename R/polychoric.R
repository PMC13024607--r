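# Two-step polychoric correlation: thresholds from inverse-normal cumulative
# margins, then the correlation by maximising the bivariate-normal cell
# likelihood. Zero cells receive +0.5 smoothing before threshold and
# likelihood evaluation, which stabilises boundary estimates on small
# samples.

poly_thresholds <- function(margin) {
  p <- cumsum(margin) / sum(margin)
  qnorm(p[-length(p)])
}

poly_cell_probs <- function(tx, ty, rho) {
  ax <- c(-Inf, tx, Inf)
  by <- c(-Inf, ty, Inf)
  r <- length(ax); s <- length(by)
  grid <- matrix(0, r, s)
  # boundary rows/cols reduce to univariate or trivial values
  for (i in seq_len(r)) {
    for (j in seq_len(s)) {
      a <- ax[i]; b <- by[j]
      grid[i, j] <- if (is.infinite(a) && a < 0) 0
      else if (is.infinite(b) && b < 0) 0
      else if (is.infinite(a) && is.infinite(b)) 1
      else if (is.infinite(a)) pnorm(b)
      else if (is.infinite(b)) pnorm(a)
      else NA_real_
    }
  }
  need <- which(is.na(grid), arr.ind = TRUE)
  if (nrow(need) > 0) {
    grid[need] <- pbvnorm(ax[need[, 1]], by[need[, 2]], rho)
  }
  p <- grid[-1, -1, drop = FALSE] - grid[-r, -1, drop = FALSE] -
    grid[-1, -s, drop = FALSE] + grid[-r, -s, drop = FALSE]
  pmax(p, 1e-12)
}

#' Polychoric correlation from a contingency table
#'
#' @param tab Matrix of cross-tabulated counts of two ordinal variables.
#' @param smooth Add 0.5 to zero cells before estimation.
#' @param bounds Open search interval for the correlation.
#' @return A list of class `gab_polychoric`: `rho`, `thresholds_x`,
#'   `thresholds_y`, `loglik`, `n`.
#' @export
polychoric_table <- function(tab, smooth = TRUE, bounds = c(-0.999, 0.999)) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2 ||
      any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate margins: both variables need at least 2 observed categories",
         call. = FALSE)
  }
  n <- sum(tab)
  if (smooth && any(tab == 0)) tab[tab == 0] <- 0.5
  tx <- poly_thresholds(rowSums(tab))
  ty <- poly_thresholds(colSums(tab))
  negll <- function(rho) -sum(tab * log(poly_cell_probs(tx, ty, rho)))
  opt <- optimize(negll, interval = bounds, tol = 1e-6)
  structure(
    list(rho = opt$minimum, thresholds_x = tx, thresholds_y = ty,
         loglik = -opt$objective, n = n),
    class = "gab_polychoric"
  )
}

#' Polychoric correlation of two ordinal vectors
#'
#' @param x,y Ordinal vectors (integer codes or ordered factors); pairs with
#'   missing values are dropped.
#' @inheritParams polychoric_table
#' @return A list of class `gab_polychoric` (see [polychoric_table()]).
#' @export
polychoric <- function(x, y, smooth = TRUE, bounds = c(-0.999, 0.999)) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 20) {
    stop("polychoric estimation needs at least 20 complete pairs", call. = FALSE)
  }
  polychoric_table(table(x, y), smooth = smooth, bounds = bounds)
}

#' @export
print.gab_polychoric <- function(x, ...) {
  cat(sprintf("polychoric rho = %.4f (n = %d)\n", x$rho, x$n))
  invisible(x)
}

#' Polychoric correlation matrix of an ordinal item block
#'
#' @param data Data frame or matrix of ordinal item scores (columns = items).
#' @inheritParams polychoric_table
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
polychoric_matrix <- function(data, smooth = TRUE) {
  m <- as.matrix(data)
  k <- ncol(m)
  R <- diag(k)
  dimnames(R) <- list(colnames(m), colnames(m))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      R[i, j] <- R[j, i] <- polychoric(m[, i], m[, j], smooth = smooth)$rho
    }
  }
  R
}
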