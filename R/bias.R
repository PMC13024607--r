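# Item-level attribution analysis for trichotomous items: endorsement
# proportions by respondent gender, the Self-Attribution Gap, two-proportion
# z tests with Bonferroni control, and Self-Serving Score summaries.

# Default trait valences for the ten personality-trait items; shipped as
# configuration since only some valences are self-evident.
GTI_VALENCE <- c(
  GTI_1 = "positive",  # independence
  GTI_2 = "negative",  # aggressiveness
  GTI_3 = "negative",  # selfishness
  GTI_4 = "positive",  # self-confidence
  GTI_5 = "positive",  # sensitivity
  GTI_6 = "positive",  # reserve
  GTI_7 = "negative",  # unpredictability
  GTI_8 = "negative",  # fragility
  GTI_9 = "positive",  # cooperativeness
  GTI_10 = "positive"  # reasonableness
)

#' Attribution proportions by respondent gender
#'
#' Per item and respondent gender: the proportion of respondents attributing
#' the trait/activity to males, to females, and answering "It doesn't
#' matter". Proportions are taken over all non-missing respondents of that
#' gender, so the three sum to one.
#'
#' @param data A `gab_responses` tibble containing both genders.
#' @param items Trichotomous item ids (default: retained GTI items).
#' @param registry Item registry.
#' @return Tibble: `item_id`, `respondent_gender`, `p_male`, `p_female`,
#'   `p_egalitarian`, `n`.
#' @export
attribution_proportions <- function(data, items = NULL,
                                    registry = gab_registry()) {
  if (is.null(items)) items <- retained_items(registry, "GTI")
  if (any(!c("F", "M") %in% data$gender)) {
    stop("both respondent genders must be present", call. = FALSE)
  }
  purrr::map_dfr(items, function(it) {
    purrr::map_dfr(c("F", "M"), function(g) {
      v <- as.character(data[[it]][data$gender == g])
      v <- v[!is.na(v)]
      tibble::tibble(
        item_id = it, respondent_gender = g,
        p_male = mean(v == "M"), p_female = mean(v == "F"),
        p_egalitarian = mean(v == "E"), n = length(v)
      )
    })
  })
}

#' Self-attribution gaps with two-proportion z tests
#'
#' For each item, the male gap is the proportion of male respondents
#' attributing the trait to males minus the proportion of female respondents
#' attributing it to males (self-rating minus outgroup-rating of the same
#' target); the female gap swaps the targets. Gaps are reported in
#' percentage points with pooled-SE z tests and Bonferroni-adjusted
#' p-values over all target-item combinations.
#'
#' @param attribution Output of [attribution_proportions()].
#' @param m Number of comparisons for the Bonferroni correction; defaults
#'   to the number of item-target combinations (2 per item).
#' @param valence_map Named valence vector (`"positive"`/`"negative"`).
#' @return Tibble with one row per item and target gender: `item_id`,
#'   `target`, `p_self`, `p_other`, `delta` (points), `z`, `p_raw`,
#'   `p_bonferroni`, `valence`.
#' @export
self_attribution_gap <- function(attribution, m = NULL,
                                 valence_map = GTI_VALENCE) {
  items <- unique(attribution$item_id)
  if (is.null(m)) m <- 2L * length(items)
  out <- purrr::map_dfr(items, function(it) {
    a <- attribution[attribution$item_id == it, ]
    aF <- a[a$respondent_gender == "F", ]
    aM <- a[a$respondent_gender == "M", ]
    purrr::map_dfr(c("male", "female"), function(target) {
      if (target == "male") {
        p_self <- aM$p_male; n_self <- aM$n
        p_other <- aF$p_male; n_other <- aF$n
      } else {
        p_self <- aF$p_female; n_self <- aF$n
        p_other <- aM$p_female; n_other <- aM$n
      }
      zt <- two_proportion_z(round(p_self * n_self), n_self,
                             round(p_other * n_other), n_other)
      tibble::tibble(
        item_id = it, target = target,
        p_self = p_self, p_other = p_other,
        delta = 100 * (p_self - p_other),
        z = zt$z, p_raw = zt$p,
        valence = unname(valence_map[it])
      )
    })
  })
  out$p_bonferroni <- pmin(1, out$p_raw * m)
  attr(out, "m") <- m
  out
}

#' Two-proportion z test (pooled standard error)
#'
#' @param x1,x2 Success counts.
#' @param n1,n2 Sample sizes (>= 1).
#' @return Tibble row: `z`, `p` (two-sided). Degenerate pooled proportions
#'   (0 or 1) yield `z = NA` with a warning.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    warning("pooled proportion is 0 or 1; z undefined")
    return(tibble::tibble(z = NA_real_, p = NA_real_))
  }
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  tibble::tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Self-Serving Score summaries per gender
#'
#' Summarises self-attribution gaps by trait valence: `sss_pos` is the mean
#' gap (percentage points) over positive-valence traits, `sss_neg` over
#' negative-valence traits, and `deflection` is the negative of the mean
#' negative-trait gap (positive deflection = pushing a negative trait away
#' from one's own group).
#'
#' @param bias Output of [self_attribution_gap()] (must carry valences).
#' @return Tibble: one row per target gender with `sss_pos`, `sss_neg`,
#'   `deflection`.
#' @export
self_serving_scores <- function(bias) {
  if (anyNA(bias$valence)) {
    stop("configuration error: item without valence assignment", call. = FALSE)
  }
  bias |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(
      sss_pos = mean(.data$delta[.data$valence == "positive"]),
      sss_neg = mean(.data$delta[.data$valence == "negative"]),
      deflection = -mean(.data$delta[.data$valence == "negative"]),
      .groups = "drop"
    )
}
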