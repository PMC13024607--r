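# ggplot2 figures for the main result types.

#' Score distributions by gender with weighted percentile marks
#'
#' Density curves per gender with dashed vertical lines at the requested
#' gender-balanced percentiles of the total distribution.
#'
#' @param scores A `gab_scores` tibble.
#' @param outcome Score column to plot.
#' @param percentiles Percentile levels (percent) to mark.
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(scores, outcome = "gsas_sum",
                                     percentiles = c(75, 90)) {
  x <- scores[[outcome]]
  keep <- !is.na(x) & !is.na(scores$gender)
  d <- tibble::tibble(x = x[keep], gender = scores$gender[keep])
  w <- gender_balanced_weights(d$gender)
  marks <- weighted_percentile(d$x, w, percentiles / 100)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, fill = .data$gender)) +
    ggplot2::geom_density(alpha = 0.4, adjust = 1.2) +
    ggplot2::geom_vline(xintercept = marks, linetype = "dashed") +
    ggplot2::labs(x = outcome, y = "density", fill = "gender",
                  title = "Score distributions by gender",
                  subtitle = paste0("dashed: weighted P",
                                    paste(percentiles, collapse = "/P"))) +
    ggplot2::theme_minimal()
}

#' Loading heatmap for a factor solution
#'
#' @param object A `gab_efa` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gab_efa <- function(object, ...) {
  td <- tidy(object)
  td$item_id <- factor(td$item_id, levels = rev(unique(td$item_id)))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$factor, y = .data$item_id,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$loading)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Pattern loadings") +
    ggplot2::theme_minimal()
}

#' Pooled versus gender-stratified association (aggregation-effect view)
#'
#' Scatter plot of a scale score against a criterion with pooled and
#' within-gender linear trends and group centroids; the canonical display
#' for a Simpson-type aggregation effect.
#'
#' @param scores A `gab_scores` tibble.
#' @param scale_var,criterion_var Column names.
#' @return A ggplot object.
#' @export
plot_simpson <- function(scores, scale_var = "gsas_mean",
                         criterion_var = "k10") {
  d <- tibble::tibble(x = scores[[scale_var]], y = scores[[criterion_var]],
                      gender = scores$gender)
  d <- d[stats::complete.cases(d), ]
  centroids <- d |>
    dplyr::group_by(.data$gender) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$gender), alpha = 0.15,
                        size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linetype = "dashed") +
    ggplot2::geom_smooth(ggplot2::aes(colour = .data$gender), method = "lm",
                         formula = y ~ x, se = FALSE) +
    ggplot2::geom_point(data = centroids,
                        ggplot2::aes(fill = .data$gender), shape = 21,
                        size = 4, colour = "black") +
    ggplot2::labs(x = scale_var, y = criterion_var,
                  title = "Pooled (dashed) vs within-gender trends") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
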