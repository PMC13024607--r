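# Gender-balanced norms and operational cutoffs: weighted descriptives and
# percentiles, P75/P90 cutoffs, kernel-density antimodes, the dip test for
# unimodality, and the combined five-category classification.

weighted_moments <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  v <- sum(w * (x - m)^2) * length(x) / (length(x) - 1)
  s <- sqrt(v)
  list(mean = m, sd = s,
       skewness = sum(w * ((x - m) / s)^3),
       kurtosis = sum(w * ((x - m) / s)^4) - 3)
}

#' Weighted percentile (inverse weighted ECDF)
#'
#' Smallest observed value whose weighted cumulative proportion reaches
#' `p`; with integer sum scores this returns integer cutpoints, matching
#' the convention used for the battery's published cutoffs.
#'
#' @param x Numeric vector.
#' @param w Weights (default equal).
#' @param p Probabilities.
#' @return Numeric vector of percentiles.
#' @export
weighted_percentile <- function(x, w = NULL, p) {
  if (is.null(w)) w <- rep(1, length(x))
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w)
  vapply(p, function(pp) x[which(cw >= pp - 1e-12)[1]], numeric(1))
}

#' Gender-balanced (50/50) person weights
#'
#' Each person receives `0.5 / proportion(own gender)`, so both gender
#' strata contribute equally to weighted totals.
#'
#' @param gender Factor/character vector with levels `F` and `M`.
#' @return Numeric weight vector (mean 1).
#' @export
gender_balanced_weights <- function(gender) {
  gender <- as.character(gender)
  tabs <- prop.table(table(gender))
  if (length(tabs) < 2) stop("both genders must be present for 50/50 weighting",
                             call. = FALSE)
  unname(0.5 / tabs[gender])
}

#' Normative table for a sum score, by gender and gender-balanced total
#'
#' @param x Sum-score vector.
#' @param gender Gender vector aligned with `x`.
#' @param probs Percentile levels to report.
#' @return Tibble with rows `female`, `male`, `weighted_total`: mean, sd,
#'   skewness, kurtosis and the requested percentiles.
#' @export
norm_table <- function(x, gender, probs = c(5, 10, 25, 50, 75, 90, 95) / 100) {
  keep <- !is.na(x) & !is.na(gender)
  x <- x[keep]; gender <- as.character(gender)[keep]
  w_bal <- gender_balanced_weights(gender)
  strata <- list(
    female = list(x = x[gender == "F"], w = rep(1, sum(gender == "F"))),
    male = list(x = x[gender == "M"], w = rep(1, sum(gender == "M"))),
    weighted_total = list(x = x, w = w_bal)
  )
  purrr::imap_dfr(strata, function(s, nm) {
    mo <- weighted_moments(s$x, s$w)
    pc <- weighted_percentile(s$x, s$w, probs)
    row <- tibble::tibble(stratum = nm, n = length(s$x), mean = mo$mean,
                          sd = mo$sd, skewness = mo$skewness,
                          kurtosis = mo$kurtosis)
    for (i in seq_along(probs)) row[[paste0("p", round(100 * probs[i]))]] <- pc[i]
    row
  })
}

#' Percentile-based operational cutoffs
#'
#' Elevated and Alert cutoffs at the requested weighted percentiles of the
#' sum-score distribution (gender-balanced weights by default).
#'
#' @param x Sum scores.
#' @param gender Gender vector (for the 50/50 weighting); `NULL` for
#'   unweighted cutoffs.
#' @param p_elevated,p_alert Percentile levels (in percent).
#' @return Tibble: `label`, `percentile`, `cutoff`.
#' @export
percentile_cutoffs <- function(x, gender = NULL, p_elevated = 75, p_alert = 90) {
  keep <- !is.na(x)
  x <- x[keep]
  w <- if (is.null(gender)) rep(1, length(x)) else
    gender_balanced_weights(as.character(gender)[keep])
  tibble::tibble(
    label = c("elevated", "alert"),
    percentile = c(p_elevated, p_alert),
    cutoff = weighted_percentile(x, w, c(p_elevated, p_alert) / 100)
  )
}

#' Kernel-density antimodes (natural breaks)
#'
#' Gaussian-kernel weighted density on a 512-point grid spanning the score
#' range padded by three bandwidths, default bandwidth
#' `0.9 min(sd, IQR/1.34) n^(-1/5)`. Antimodes are interior strict local
#' minima whose separation from the smaller neighbouring peak exceeds
#' `prominence` times the density maximum (suppressing ripple minima).
#'
#' @param x Scores (>= 10 distinct values).
#' @param w Optional weights.
#' @param bw Bandwidth (default Silverman rule-of-thumb, as above).
#' @param prominence Prominence floor as a fraction of the maximum density.
#' @return List of class `gab_breaks`: `antimodes`, `modes`, `grid`,
#'   `density`, `bw`.
#' @export
kde_antimodes <- function(x, w = NULL, bw = NULL, prominence = 0.01) {
  x <- x[!is.na(x)]
  if (length(unique(x)) < 10) stop("need at least 10 distinct values", call. = FALSE)
  if (is.null(bw)) {
    iqr <- stats::IQR(x)
    s <- min(sd(x), if (iqr > 0) iqr / 1.34 else Inf)
    if (!is.finite(s) || s == 0) stop("zero spread; density undefined", call. = FALSE)
    bw <- 0.9 * s * length(x)^(-1 / 5)
  }
  if (is.null(w)) w <- rep(1, length(x))
  d <- density(x, weights = w / sum(w), bw = bw, n = 512,
               from = min(x) - 3 * bw, to = max(x) + 3 * bw)
  y <- d$y
  n <- length(y)
  is_min <- c(FALSE, y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] < y[3:n], FALSE)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n], FALSE)
  modes <- d$x[is_max]
  anti <- numeric(0)
  floor_h <- prominence * max(y)
  for (i in which(is_min)) {
    left_peaks <- y[is_max & seq_len(n) < i]
    right_peaks <- y[is_max & seq_len(n) > i]
    if (length(left_peaks) == 0 || length(right_peaks) == 0) next
    if (min(max(left_peaks), max(right_peaks)) - y[i] >= floor_h) {
      anti <- c(anti, d$x[i])
    }
  }
  structure(list(antimodes = anti, modes = modes, grid = d$x, density = y,
                 bw = bw), class = "gab_breaks")
}

#' @export
print.gab_breaks <- function(x, ...) {
  cat("KDE bandwidth", signif(x$bw, 3), "|", length(x$modes), "mode(s);",
      "antimodes:", if (length(x$antimodes)) paste(signif(x$antimodes, 4),
                                                   collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Dip statistic of a sample
#'
#' Largest deviation between the empirical CDF and the closest unimodal
#' CDF, computed by bisection over the band width admitting a
#' convex-then-concave CDF (greatest-convex-minorant / least-concave-
#' majorant feasibility). Ties are aggregated before computation.
#'
#' @param x Numeric sample.
#' @return The dip statistic.
#' @export
dip_stat <- function(x) {
  x <- sort(x[!is.na(x)])
  if (length(x) < 2) return(0)
  ux <- unique(x)
  Fc <- cumsum(tabulate(match(x, ux))) / length(x)
  .dip_stat_cpp(ux, Fc)
}

#' Null dip distribution under the uniform reference
#'
#' @param n Sample size.
#' @param reps Monte Carlo replicates.
#' @param seed Seed.
#' @return Numeric vector of `reps` dip statistics from U(0,1) samples.
#' @export
dip_null <- function(n, reps = 2000, seed = 1) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  out <- vapply(seq_len(reps), function(i) dip_stat(runif(n)), numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out
}

#' Hartigan-type dip test for unimodality
#'
#' Monte Carlo p-value of the dip statistic against uniform samples of the
#' same size (the classical calibration for the test).
#'
#' @param x Numeric sample (n >= 10, non-constant).
#' @param mc_reps Monte Carlo replicates for the null distribution.
#' @param seed Seed for the null simulation.
#' @param null_dips Optional precomputed null statistics (from
#'   [dip_null()]) to reuse across tests of equal `n`.
#' @return Tibble row: `dip`, `p`, `n`, `mc_reps`.
#' @export
dip_test <- function(x, mc_reps = 2000, seed = 1, null_dips = NULL) {
  x <- x[!is.na(x)]
  if (length(x) < 10) stop("need n >= 10", call. = FALSE)
  if (length(unique(x)) == 1) stop("constant sample; dip undefined", call. = FALSE)
  stat <- dip_stat(x)
  if (is.null(null_dips)) null_dips <- dip_null(length(x), mc_reps, seed)
  p <- (1 + sum(null_dips >= stat)) / (length(null_dips) + 1)
  tibble::tibble(dip = stat, p = p, n = length(x), mc_reps = length(null_dips))
}

#' Combined percentile/KDE classification system
#'
#' Boundaries are the sorted union of KDE antimode breaks (rounded up to
#' the next integer score) and percentile cutoffs, deduplicated within a
#' 1-point tolerance (the percentile boundary wins a tie). Five boundaries'
#' worth of bands get the canonical labels Low, Low-Medium, High-Medium,
#' Elevated, Very Elevated.
#'
#' @param percentile_cuts Integer cutoffs (e.g. from
#'   [percentile_cutoffs()]`$cutoff`).
#' @param kde_breaks Antimode locations (e.g. `gab_breaks$antimodes`).
#' @param score_range Attainable integer score range `c(min, max)`.
#' @return List of class `gab_classification`: `bands` tibble (`label`,
#'   `from`, `to`, `provenance`) and `boundaries`.
#' @export
combined_classification <- function(percentile_cuts, kde_breaks, score_range) {
  kb <- ceiling(kde_breaks)
  cand <- dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(boundary = as.numeric(percentile_cuts), provenance = "percentile"),
    tibble::tibble(boundary = as.numeric(kb), provenance = "kde_break")
  ), .data$boundary, .data$provenance == "kde_break")
  cand <- cand[cand$boundary > score_range[1] & cand$boundary <= score_range[2], ]
  keep <- list()
  for (i in seq_len(nrow(cand))) {
    row <- cand[i, ]
    if (length(keep) > 0) {
      prev <- keep[[length(keep)]]
      if (abs(row$boundary - prev$boundary) <= 1) {
        if (prev$provenance == "kde_break" && row$provenance == "percentile") {
          keep[[length(keep)]] <- row
        }
        next
      }
    }
    keep[[length(keep) + 1]] <- row
  }
  bounds <- dplyr::bind_rows(keep)
  n_bands <- nrow(bounds) + 1
  if (n_bands < 2) warning("degenerate classification: fewer than 2 categories")
  labels <- switch(as.character(n_bands),
                   "5" = c("Low", "Low-Medium", "High-Medium", "Elevated", "Very Elevated"),
                   "4" = c("Low", "Medium", "Elevated", "Very Elevated"),
                   "3" = c("Low", "Medium", "Elevated"),
                   "2" = c("Low", "Elevated"),
                   paste0("Band ", seq_len(n_bands)))
  from <- c(score_range[1], bounds$boundary)
  to <- c(bounds$boundary - 1, score_range[2])
  bands <- tibble::tibble(label = labels, from = from, to = to,
                          provenance = c("floor", bounds$provenance))
  structure(list(bands = bands, boundaries = bounds$boundary,
                 score_range = score_range),
            class = "gab_classification")
}

#' @export
print.gab_classification <- function(x, ...) {
  print(x$bands)
  invisible(x)
}

#' Classify sum scores into the combined categories
#'
#' @param classification A `gab_classification` object.
#' @param x Integer sum scores.
#' @return Factor of band labels.
#' @export
classify_scores <- function(classification, x) {
  b <- classification$bands
  idx <- findInterval(x, c(b$from, classification$score_range[2] + 1))
  idx[idx < 1 | idx > nrow(b)] <- NA
  factor(b$label[idx], levels = b$label)
}
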