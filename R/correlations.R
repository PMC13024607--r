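# Convergent/discriminant validity: correlation panels with BH-FDR
# adjustment, gender-stratified correlations, and the Simpson-type
# aggregation diagnosis.

#' Correlation panel with BH-FDR adjustment
#'
#' Pearson correlations between two sets of columns, pooled and optionally
#' stratified by gender. Pairwise-complete observations; p-values adjusted
#' within each stratum's panel (one BH family per stratum).
#'
#' @param data Data frame holding all columns (e.g. a `gab_scores` tibble).
#' @param x_vars,y_vars Column names to correlate (every x with every y).
#' @param stratify `"none"` or `"gender"`.
#' @param min_n Minimum paired observations per cell.
#' @return Tibble: `stratum`, `var1`, `var2`, `r`, `n`, `p_raw`, `p_fdr`.
#' @export
correlation_panel <- function(data, x_vars, y_vars, stratify = c("none", "gender"),
                              min_n = 10) {
  stratify <- match.arg(stratify)
  strata <- list(pooled = rep(TRUE, nrow(data)))
  if (stratify == "gender") {
    strata$female <- data$gender == "F"
    strata$male <- data$gender == "M"
  }
  out <- purrr::imap_dfr(strata, function(idx, nm) {
    d <- data[idx, , drop = FALSE]
    grid <- expand.grid(var1 = x_vars, var2 = y_vars,
                        stringsAsFactors = FALSE)
    res <- purrr::pmap_dfr(grid, function(var1, var2) {
      x <- d[[var1]]; y <- d[[var2]]
      keep <- !(is.na(x) | is.na(y))
      n <- sum(keep)
      if (n < min_n || var1 == var2) {
        return(tibble::tibble(var1 = var1, var2 = var2,
                              r = if (var1 == var2) 1 else NA_real_,
                              n = n, p_raw = NA_real_))
      }
      if (sd(x[keep]) == 0 || sd(y[keep]) == 0) {
        return(tibble::tibble(var1 = var1, var2 = var2, r = NA_real_,
                              n = n, p_raw = NA_real_))
      }
      ct <- cor.test(x[keep], y[keep])
      tibble::tibble(var1 = var1, var2 = var2, r = unname(ct$estimate),
                     n = n, p_raw = ct$p.value)
    })
    res$stratum <- nm
    res$p_fdr <- bh_fdr(res$p_raw)
    res
  })
  dplyr::relocate(out, "stratum")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1
#' (`stats::p.adjust(method = "BH")`); `NA`s pass through.
#'
#' @param p Vector of p-values.
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p) {
  p.adjust(p, method = "BH")
}

#' Diagnose Simpson-type aggregation in stratified correlations
#'
#' Compares a pooled correlation with its within-stratum counterparts:
#' `sign_reversal` when the pooled correlation is significant with sign
#' opposite to every significant stratum correlation (and at least one
#' stratum is significant); `strata_null` when the pooled correlation is
#' significant but no stratum correlation is; `attenuated` when pooled and
#' strata agree in sign but the pooled magnitude exceeds every stratum
#' magnitude... the pooled estimate overstates within-group association;
#' `consistent` otherwise.
#'
#' @param pooled One-row tibble with `r`, `p_raw` (pooled estimate).
#' @param strata Tibble of stratum estimates with `stratum`, `r`, `p_raw`.
#' @param alpha Significance level.
#' @return Tibble row: `pooled_r`, `verdict`, plus stratum columns.
#' @export
simpson_diagnose <- function(pooled, strata, alpha = 0.05) {
  pr <- pooled$r[1]
  pp <- pooled$p_raw[1]
  sig_strata <- strata[!is.na(strata$p_raw) & strata$p_raw < alpha, ]
  verdict <- if (!is.na(pp) && pp < alpha) {
    if (nrow(sig_strata) == 0) {
      "strata_null"
    } else if (all(sign(sig_strata$r) == -sign(pr))) {
      "sign_reversal"
    } else if (all(abs(strata$r) < abs(pr))) {
      "attenuated"
    } else {
      "consistent"
    }
  } else {
    "consistent"
  }
  row <- tibble::tibble(pooled_r = pr, pooled_p = pp, verdict = verdict)
  for (i in seq_len(nrow(strata))) {
    row[[paste0("r_", strata$stratum[i])]] <- strata$r[i]
  }
  row
}

#' Gender-stratified criterion validity with aggregation diagnosis
#'
#' Builds the criterion correlation panel (pooled + by gender) and runs
#' [simpson_diagnose()] on every scale-criterion pair.
#'
#' @param scores A `gab_scores` tibble with criterion columns.
#' @param scale_vars Score columns to use.
#' @param criterion_vars Criterion columns (defaults to those present).
#' @return List: `panel` (correlations) and `diagnosis` (one row per pair).
#' @export
criterion_validity <- function(scores,
                               scale_vars = c("gsas_mean", "gras_mean", "gti_mean"),
                               criterion_vars = NULL) {
  if (is.null(criterion_vars)) {
    criterion_vars <- intersect(CRITERION_COLS, names(scores))
  }
  panel <- correlation_panel(scores, scale_vars, criterion_vars,
                             stratify = "gender")
  diagnosis <- purrr::map_dfr(scale_vars, function(sv) {
    purrr::map_dfr(criterion_vars, function(cv) {
      rows <- panel[panel$var1 == sv & panel$var2 == cv, ]
      d <- simpson_diagnose(rows[rows$stratum == "pooled", ],
                            rows[rows$stratum != "pooled", ])
      d$scale <- sv
      d$criterion <- cv
      dplyr::relocate(d, "scale", "criterion")
    })
  })
  list(panel = panel, diagnosis = diagnosis)
}
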