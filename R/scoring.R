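# Scoring: categorical scoring schemas for trichotomous items, direct likert
# scoring for the attitude scale, subscale/total aggregation, and empirical
# verification of stereotype directions.
#
# Schema A maps stereotypical/egalitarian/counter-stereotypical responses to
# 2/1/0 (egalitarian midpoint); Schema B maps them to 2/0/1 (egalitarian
# zero-point, treating any gendered attribution as gender salience).

#' Score a single trichotomous response under a scoring schema
#'
#' @param raw Character vector of raw codes (`"M"`, `"F"`, `"E"`).
#' @param direction Stereotype direction of the item (`"male"` or
#'   `"female"`). An `"undetermined"` direction is refused: resolve it with
#'   [verify_directions()] or a registry override first.
#' @param schema `"A"` (stereotypical 2, egalitarian 1, counter 0) or
#'   `"B"` (stereotypical 2, counter 1, egalitarian 0).
#' @return Integer scores in 0-2 (`NA` propagates).
#' @examples
#' recode_response(c("M", "E", "F"), "male", "A") # 2 1 0
#' recode_response(c("M", "E", "F"), "male", "B") # 2 0 1
#' @export
recode_response <- function(raw, direction, schema = c("A", "B")) {
  schema <- match.arg(schema)
  if (length(direction) == 1) direction <- rep(direction, length(raw))
  if (any(direction == "undetermined", na.rm = TRUE)) {
    stop("cannot score an item with undetermined stereotype direction; ",
         "run verify_directions() or override the registry direction",
         call. = FALSE)
  }
  stopifnot(all(direction %in% c("male", "female")))
  stereo <- ifelse(direction == "male", "M", "F")
  counter <- ifelse(direction == "male", "F", "M")
  out <- rep(NA_integer_, length(raw))
  out[!is.na(raw) & raw == stereo] <- 2L
  if (schema == "A") {
    out[!is.na(raw) & raw == "E"] <- 1L
    out[!is.na(raw) & raw == counter] <- 0L
  } else {
    out[!is.na(raw) & raw == "E"] <- 0L
    out[!is.na(raw) & raw == counter] <- 1L
  }
  out
}

score_items_matrix <- function(data, registry, items, schema) {
  out <- matrix(NA_integer_, nrow = nrow(data), ncol = length(items),
                dimnames = list(NULL, items))
  for (it in items) {
    fmt <- registry$response_format[registry$item_id == it]
    if (fmt == "likert4") {
      out[, it] <- as.integer(data[[it]])
    } else {
      dir <- registry$stereotype_direction[registry$item_id == it]
      out[, it] <- recode_response(as.character(data[[it]]), dir, schema)
    }
  }
  out
}

#' Score the full battery
#'
#' GSAS items are scored directly from their likert codes (no reverse-keyed
#' item remains among the 17 retained); GRAS items are scored under Schema A
#' and GTI items under Schema B by default. Within each scale, persons
#' missing any retained item are dropped from that scale's scores (listwise
#' within scale) and reported via an attribute.
#'
#' @param data A `gab_responses` tibble (see [as_gab_responses()]).
#' @param registry Item registry.
#' @param gras_schema,gti_schema Scoring schema for the two trichotomous
#'   scales.
#' @return A tibble with one row per person: `person_id`, `gender`,
#'   `school`, per-scale means and sums (`gsas_mean`, `gsas_sum`, `gsas_ts`,
#'   `gsas_vm`, `gsas_rc`, `gras_mean`, `gras_sum`, `gras_la`, `gras_sr`,
#'   `gti_mean`, `gti_sum`), plus any criterion columns carried over.
#'   Persons missing a whole scale have `NA` there. The attribute
#'   `"dropped"` lists per-scale exclusion counts.
#' @export
score_battery <- function(data, registry = gab_registry(),
                          gras_schema = "A", gti_schema = "B") {
  validate_registry(registry)
  scales <- list(
    GSAS = list(items = retained_items(registry, "GSAS"), schema = NULL,
                prefix = "gsas"),
    GRAS = list(items = retained_items(registry, "GRAS"), schema = gras_schema,
                prefix = "gras"),
    GTI = list(items = retained_items(registry, "GTI"), schema = gti_schema,
               prefix = "gti")
  )
  out <- tibble::tibble(
    person_id = data$person_id,
    gender = data$gender,
    school = data$school
  )
  dropped <- integer(0)
  for (sc in names(scales)) {
    spec <- scales[[sc]]
    missing_items <- setdiff(spec$items, names(data))
    if (length(missing_items) > 0) {
      stop("configuration error: response matrix lacks retained ", sc,
           " item(s): ", paste(missing_items, collapse = ", "), call. = FALSE)
    }
    m <- score_items_matrix(data, registry, spec$items, spec$schema)
    complete <- stats::complete.cases(m)
    dropped[sc] <- sum(!complete)
    sums <- rowSums(m)
    means <- sums / length(spec$items)
    sums[!complete] <- NA_real_
    means[!complete] <- NA_real_
    out[[paste0(spec$prefix, "_mean")]] <- means
    out[[paste0(spec$prefix, "_sum")]] <- sums
    for (sub in names(subscale_items(registry, sc))) {
      sub_items <- subscale_items(registry, sc)[[sub]]
      sub_mean <- rowMeans(m[, sub_items, drop = FALSE])
      sub_mean[!complete] <- NA_real_
      out[[paste0(spec$prefix, "_", tolower(sub))]] <- sub_mean
    }
  }
  for (col in intersect(CRITERION_COLS, names(data))) out[[col]] <- data[[col]]
  attr(out, "dropped") <- dropped
  class(out) <- unique(c("gab_scores", class(out)))
  out
}

#' Empirically verify stereotype directions of trichotomous items
#'
#' For each item, counts male- and female-attributed responses (egalitarian
#' responses are excluded) and runs a two-sided exact binomial test of equal
#' proportions. The empirical direction is the majority side when the test
#' is significant at `alpha`, otherwise `"undetermined"`.
#'
#' @param data A `gab_responses` tibble.
#' @param registry Item registry.
#' @param items Item ids to verify; defaults to all retained trichotomous
#'   items.
#' @param alpha Significance level for calling a direction.
#' @return A tibble with counts, `binomial_p`, `empirical_direction` and
#'   `matches_theory` (agreement with the registry direction).
#' @export
verify_directions <- function(data, registry = gab_registry(), items = NULL,
                              alpha = 0.05) {
  if (is.null(items)) {
    items <- registry$item_id[registry$retained &
                                registry$response_format == "trichotomous"]
  }
  items <- intersect(items, names(data))
  purrr::map_dfr(items, function(it) {
    v <- as.character(data[[it]])
    n_m <- sum(v == "M", na.rm = TRUE)
    n_f <- sum(v == "F", na.rm = TRUE)
    n_e <- sum(v == "E", na.rm = TRUE)
    if (n_m + n_f == 0) {
      p <- NA_real_
      dir <- "undetermined"
    } else {
      p <- stats::binom.test(n_m, n_m + n_f, p = 0.5)$p.value
      dir <- if (p < alpha) {
        if (n_m > n_f) "male" else "female"
      } else "undetermined"
    }
    theory <- registry$stereotype_direction[registry$item_id == it]
    tibble::tibble(
      item_id = it,
      n_male_attributed = n_m,
      n_female_attributed = n_f,
      n_egalitarian = n_e,
      binomial_p = p,
      empirical_direction = dir,
      matches_theory = dir != "undetermined" & dir == theory
    )
  })
}

#' Compare scoring Schemas A and B on the same responses
#'
#' Scores the given trichotomous items under both schemas and returns
#' Cronbach's alpha of each scored matrix (complete cases).
#'
#' @param data A `gab_responses` tibble.
#' @param registry Item registry.
#' @param items Item ids (defaults to the retained GTI items).
#' @return A tibble with one row: `alpha_A`, `alpha_B`, `n`, `k`.
#' @export
compare_schemas <- function(data, registry = gab_registry(), items = NULL) {
  if (is.null(items)) items <- retained_items(registry, "GTI")
  a <- score_items_matrix(data, registry, items, "A")
  b <- score_items_matrix(data, registry, items, "B")
  keep <- stats::complete.cases(a)
  tibble::tibble(
    alpha_A = cronbach_alpha(a[keep, , drop = FALSE]),
    alpha_B = cronbach_alpha(b[keep, , drop = FALSE]),
    n = sum(keep),
    k = length(items)
  )
}
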