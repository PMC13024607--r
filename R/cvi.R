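# Content validity indices from expert rating matrices. Experts rate each
# item 1-5; an item counts as relevant for a rater at score >= 4.

#' Item- and scale-level content validity indices
#'
#' I-CVI is the proportion of experts rating an item relevant (rating of 4
#' or 5 on the 5-point relevance scale). S-CVI/Ave is the arithmetic mean of
#' the member items' I-CVIs, per module and overall. Items with
#' I-CVI below `threshold` are flagged.
#'
#' @param ratings Data frame or matrix of expert-by-item integer ratings in
#'   1-5 (rows = experts, columns = items). Ratings must be complete.
#' @param module_map Named character vector mapping item id to module;
#'   defaults to the prefix before the last underscore (so `GTI_7` maps to
#'   `GTI`).
#' @param threshold Acceptability threshold for I-CVI (0.78 for panels of
#'   more than five experts).
#' @return A list of class `gab_cvi` with tibbles `items` (`item_id`,
#'   `module`, `i_cvi`, `flagged`) and `scales` (`module`, `n_items`,
#'   `s_cvi_ave`, including an `overall` row).
#' @examples
#' set.seed(1)
#' r <- matrix(5, nrow = 12, ncol = 3,
#'             dimnames = list(NULL, c("GSAS_1", "GSAS_2", "GTI_1")))
#' r[1:4, 3] <- 2
#' compute_cvi(r)$scales
#' @export
compute_cvi <- function(ratings, module_map = NULL, threshold = 0.78) {
  m <- as.matrix(ratings)
  if (is.null(colnames(m))) stop("ratings must have item ids as column names", call. = FALSE)
  if (anyNA(m)) stop("ratings must be complete (no missing expert ratings)", call. = FALSE)
  storage.mode(m) <- "numeric"
  if (!all(m == round(m)) || any(m < 1) || any(m > 5)) {
    stop("ratings must be integers in 1-5", call. = FALSE)
  }
  if (nrow(m) < 1) stop("at least one expert required", call. = FALSE)
  if (is.null(module_map)) {
    module_map <- sub("_[^_]*$", "", colnames(m))
    names(module_map) <- colnames(m)
  }
  modules <- unname(module_map[colnames(m)])
  if (anyNA(modules)) stop("configuration error: item without module assignment", call. = FALSE)

  i_cvi <- colMeans(m >= 4)
  items <- tibble::tibble(
    item_id = colnames(m),
    module = modules,
    i_cvi = unname(i_cvi),
    flagged = unname(i_cvi) < threshold
  )
  scales <- items |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(n_items = dplyr::n(), s_cvi_ave = mean(.data$i_cvi),
                     .groups = "drop")
  if (any(scales$n_items == 0)) stop("configuration error: empty module", call. = FALSE)
  scales <- dplyr::bind_rows(
    scales,
    tibble::tibble(module = "overall", n_items = ncol(m),
                   s_cvi_ave = mean(items$i_cvi))
  )
  structure(list(items = items, scales = scales, n_experts = nrow(m),
                 threshold = threshold),
            class = "gab_cvi")
}

#' @export
print.gab_cvi <- function(x, ...) {
  cat("Content validity (", x$n_experts, " experts)\n", sep = "")
  print(x$scales)
  flagged <- x$items[x$items$flagged, ]
  if (nrow(flagged) > 0) {
    cat("Items below I-CVI threshold", x$threshold, ":",
        paste(flagged$item_id, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Overall S-CVI/Ave from module summaries
#'
#' Algebraic identity: the overall average-method S-CVI equals the
#' item-count-weighted mean of module S-CVIs.
#'
#' @param modules Tibble with columns `n_items` and `s_cvi_ave` (see
#'   [cvi_module_summary()]).
#' @return The overall S-CVI/Ave.
#' @export
overall_scvi <- function(modules) {
  sum(modules$n_items * modules$s_cvi_ave) / sum(modules$n_items)
}
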