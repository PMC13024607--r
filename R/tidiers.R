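# broom-style tidiers for the package's fitted objects.

#' Tidy a factor solution
#'
#' @param x A `gab_efa` object.
#' @param ... Unused.
#' @return Long tibble: `item_id`, `factor`, `loading`, `communality`.
#' @export
tidy.gab_efa <- function(x, ...) {
  L <- x$pattern
  tibble::tibble(
    item_id = rep(rownames(L) %||% paste0("item_", seq_len(nrow(L))),
                  ncol(L)),
    factor = rep(colnames(L), each = nrow(L)),
    loading = as.numeric(L),
    communality = rep(unname(x$h2), ncol(L))
  )
}

#' One-row summary of a factor solution
#'
#' @inheritParams tidy.gab_efa
#' @return Tibble: `n_factors`, `prop_variance`, `converged`, `heywood`.
#' @export
glance.gab_efa <- function(x, ...) {
  tibble::tibble(
    n_factors = x$n_factors,
    prop_variance = sum(x$prop_variance),
    converged = x$converged,
    heywood = x$heywood
  )
}

#' Tidy a reliability report (per-item statistics)
#'
#' @param x A `gab_reliability` object.
#' @param ... Unused.
#' @return Tibble: `item_id`, `item_total_r`.
#' @export
tidy.gab_reliability <- function(x, ...) {
  tibble::tibble(
    item_id = names(x$item_total) %||% paste0("item_", seq_along(x$item_total)),
    item_total_r = unname(x$item_total)
  )
}

#' One-row summary of a reliability report
#'
#' @inheritParams tidy.gab_reliability
#' @return Tibble with alpha (and its interval), omega, hierarchical
#'   omega, polychoric alpha, `n` and `k`.
#' @export
glance.gab_reliability <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, alpha_lo = x$alpha_ci95[1], alpha_hi = x$alpha_ci95[2],
    omega = x$omega, omega_h = x$omega_h,
    polychoric_alpha = x$polychoric_alpha,
    n = x$n, k = x$k
  )
}

#' Tidy a content validity report (item level)
#'
#' @param x A `gab_cvi` object.
#' @param ... Unused.
#' @return The item-level tibble.
#' @export
tidy.gab_cvi <- function(x, ...) x$items

#' Scale-level summary of a content validity report
#'
#' @inheritParams tidy.gab_cvi
#' @return The module/overall S-CVI tibble.
#' @export
glance.gab_cvi <- function(x, ...) x$scales
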