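# Response-style indices and problematic-pattern screening: acquiescence and
# extreme responding on the likert scale; egalitarian / stereotypical /
# counter-stereotypical proportions on the trichotomous scales; zero
# variance, straight-lining and extreme acquiescence flags; and the
# full-versus-cleaned sensitivity comparison.

#' Per-person response-style indices
#'
#' For the likert scale: `ars` (mean raw response) and `ers` (proportion at
#' the endpoints 1 or 4). For each trichotomous scale: `egal_rs`, `srs`,
#' `crs` (proportions of egalitarian, stereotypical and
#' counter-stereotypical responses, which sum to one).
#'
#' @param data A `gab_responses` tibble.
#' @param registry Item registry.
#' @return Tibble with one row per person and scale: `person_id`, `scale`,
#'   `ars`, `ers`, `egal_rs`, `srs`, `crs`, `n_items`.
#' @export
style_indices <- function(data, registry = gab_registry()) {
  gsas_items <- retained_items(registry, "GSAS")
  out <- list()
  g <- as.matrix(data[, gsas_items])
  storage.mode(g) <- "numeric"
  n_ok <- rowSums(!is.na(g))
  out$GSAS <- tibble::tibble(
    person_id = data$person_id, scale = "GSAS",
    ars = rowMeans(g, na.rm = TRUE),
    ers = rowSums(g == 1 | g == 4, na.rm = TRUE) / n_ok,
    egal_rs = NA_real_, srs = NA_real_, crs = NA_real_,
    n_items = n_ok
  )
  for (sc in c("GRAS", "GTI")) {
    items <- retained_items(registry, sc)
    dirs <- registry$stereotype_direction[match(items, registry$item_id)]
    stereo <- ifelse(dirs == "male", "M", "F")
    counter <- ifelse(dirs == "male", "F", "M")
    raw <- as.matrix(data[, items])
    n_ok <- rowSums(!is.na(raw))
    s_cnt <- rowSums(sweep(raw, 2, stereo, `==`), na.rm = TRUE)
    c_cnt <- rowSums(sweep(raw, 2, counter, `==`), na.rm = TRUE)
    e_cnt <- rowSums(raw == "E", na.rm = TRUE)
    out[[sc]] <- tibble::tibble(
      person_id = data$person_id, scale = sc,
      ars = NA_real_, ers = NA_real_,
      egal_rs = e_cnt / n_ok, srs = s_cnt / n_ok, crs = c_cnt / n_ok,
      n_items = n_ok
    )
  }
  res <- dplyr::bind_rows(out)
  res[res$n_items > 0, ]
}

#' Flag problematic response patterns
#'
#' Three operational rules: `zero_variance` (all responses on a scale
#' identical), `straight_lining` (the same option column selected for every
#' trichotomous item of a scale) and `extreme_acquiescence` (more than 90%
#' agreement -- codes 3 or 4 -- on the likert scale).
#'
#' @param data A `gab_responses` tibble.
#' @param registry Item registry.
#' @param acquiescence_threshold Agreement proportion above which the
#'   acquiescence flag fires.
#' @return Tibble: `person_id`, `scale`, `zero_variance`,
#'   `straight_lining`, `extreme_acquiescence`, `flagged`.
#' @export
flag_problematic <- function(data, registry = gab_registry(),
                             acquiescence_threshold = 0.90) {
  out <- list()
  for (sc in c("GSAS", "GRAS", "GTI")) {
    items <- retained_items(registry, sc)
    raw <- as.matrix(data[, items])
    complete <- rowSums(is.na(raw)) == 0
    same <- complete & apply(raw, 1, function(r) length(unique(r)) == 1)
    if (sc == "GSAS") {
      num <- raw
      storage.mode(num) <- "numeric"
      agree <- rowMeans(num >= 3, na.rm = TRUE)
      acq <- complete & agree > acquiescence_threshold
      straight <- rep(FALSE, nrow(raw))
    } else {
      acq <- rep(FALSE, nrow(raw))
      straight <- same
    }
    out[[sc]] <- tibble::tibble(
      person_id = data$person_id, scale = sc,
      zero_variance = same,
      straight_lining = straight,
      extreme_acquiescence = acq,
      flagged = same | straight | acq
    )
  }
  dplyr::bind_rows(out)
}

#' Sensitivity analysis: full versus cleaned sample
#'
#' Compares each scale's summary statistics, Cronbach's alpha and the
#' gender effect size between the full sample and a cleaned sample
#' excluding persons flagged on that scale.
#'
#' @param data A `gab_responses` tibble.
#' @param registry Item registry.
#' @param flags Output of [flag_problematic()] (computed if omitted).
#' @return Tibble with one row per scale and sample (`full` / `cleaned`):
#'   `n`, `n_excluded`, `mean`, `sd`, `alpha`, `d_gender`, and the deltas
#'   on the cleaned rows.
#' @export
sensitivity_analysis <- function(data, registry = gab_registry(), flags = NULL) {
  if (is.null(flags)) flags <- flag_problematic(data, registry)
  scores_full <- score_battery(data, registry)
  purrr::map_dfr(c("GSAS", "GRAS", "GTI"), function(sc) {
    prefix <- tolower(sc)
    col <- paste0(prefix, "_mean")
    flagged_ids <- flags$person_id[flags$scale == sc & flags$flagged]
    items <- retained_items(registry, sc)
    schema <- if (sc == "GTI") "B" else "A"
    one <- function(d, label, n_excl) {
      s <- score_battery(d, registry)
      y <- s[[col]]
      m <- score_items_matrix(d, registry, items, schema)
      m <- m[stats::complete.cases(m), , drop = FALSE]
      dG <- cohens_d(y[s$gender == "M" & !is.na(y)],
                     y[s$gender == "F" & !is.na(y)])$d
      tibble::tibble(scale = sc, sample = label, n = sum(!is.na(y)),
                     n_excluded = n_excl,
                     mean = mean(y, na.rm = TRUE), sd = sd(y, na.rm = TRUE),
                     alpha = cronbach_alpha(m), d_gender = dG)
    }
    full <- one(data, "full", 0L)
    cleaned <- one(data[!data$person_id %in% flagged_ids, ], "cleaned",
                   length(flagged_ids))
    cleaned$delta_mean <- cleaned$mean - full$mean
    cleaned$delta_alpha <- cleaned$alpha - full$alpha
    cleaned$delta_d <- cleaned$d_gender - full$d_gender
    dplyr::bind_rows(full, cleaned)
  })
}
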