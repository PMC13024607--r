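# Item registry: identity, scale membership, response format and stereotype
# direction for every battery item, including items dropped during validation.

GSAS_TS_ITEMS <- paste0("GSAS_", c(1, 2, 3, 4, 6, 7, 9, 11, 18))
GSAS_VM_ITEMS <- paste0("GSAS_", c(5, 8, 13, 15, 16))
GSAS_RC_ITEMS <- paste0("GSAS_", c(12, 14, 17))
GRAS_LA_ITEMS <- paste0("GRAS_", c(7, 8, 14, 16, 17))
GRAS_SR_ITEMS <- paste0("GRAS_", c(2, 3, 5, 6, 9, 10, 11, 12, 18))
GTI_ITEMS     <- paste0("GTI_", 1:10)

# Theory-derived activity directions, shipped as data (not hard constants)
# because directions are meant to be verified empirically on each cohort.
GRAS_DIRECTIONS <- c(
  GRAS_2  = "female", # cooking
  GRAS_3  = "male",   # financially supporting the family
  GRAS_5  = "female", # childcare
  GRAS_6  = "female", # cleaning the house
  GRAS_7  = "male",   # football
  GRAS_8  = "female", # dancing
  GRAS_9  = "male",   # being in charge at work
  GRAS_10 = "male",   # earning money
  GRAS_11 = "female", # grocery shopping
  GRAS_12 = "male",   # being president
  GRAS_14 = "male",   # video games
  GRAS_16 = "male",   # combat sports
  GRAS_17 = "female", # reading books
  GRAS_18 = "male"    # police work
)

# Empirically verified trait directions. Unpredictability and Reasonableness
# run opposite to classical theoretical expectations.
GTI_DIRECTIONS <- c(
  GTI_1  = "male",   # independence
  GTI_2  = "male",   # aggressiveness
  GTI_3  = "male",   # selfishness
  GTI_4  = "male",   # self-confidence
  GTI_5  = "female", # sensitivity
  GTI_6  = "female", # reserve
  GTI_7  = "male",   # unpredictability (empirical, vs. theoretical female)
  GTI_8  = "female", # fragility
  GTI_9  = "female", # cooperativeness
  GTI_10 = "female"  # reasonableness (empirical, vs. theoretical male)
)

GTI_TRAITS <- c("independence", "aggressiveness", "selfishness",
                "self-confidence", "sensitivity", "reserve",
                "unpredictability", "fragility", "cooperativeness",
                "reasonableness")

#' Default item registry for the battery
#'
#' Returns one row per item with scale membership, subscale, response format,
#' stereotype direction and retention status. Retained counts are GSAS 17
#' (GSAS_10 excluded), GRAS 14 (items 1, 4, 13 and 15 excluded) and GTI 10.
#' GRAS directions are theory-derived defaults intended to be checked with
#' [verify_directions()]; GTI directions are the empirically verified ones.
#'
#' @param gras_directions Named character vector overriding the default
#'   activity directions (`"male"`/`"female"`/`"undetermined"`), keyed by
#'   item id. Partial overrides are allowed.
#' @return A tibble with columns `item_id`, `scale`, `subscale`,
#'   `response_format`, `stereotype_direction`, `retained`,
#'   `exclusion_reason`.
#' @examples
#' reg <- gab_registry()
#' dplyr::count(reg[reg$retained, ], scale)
#' @export
gab_registry <- function(gras_directions = NULL) {
  gsas <- tibble::tibble(
    item_id = paste0("GSAS_", 1:18),
    scale = "GSAS",
    subscale = dplyr::case_when(
      item_id %in% GSAS_TS_ITEMS ~ "TS",
      item_id %in% GSAS_VM_ITEMS ~ "VM",
      item_id %in% GSAS_RC_ITEMS ~ "RC",
      TRUE ~ "NONE"
    ),
    response_format = "likert4",
    stereotype_direction = "not_applicable",
    retained = item_id != "GSAS_10",
    exclusion_reason = dplyr::if_else(
      item_id == "GSAS_10",
      "low communality; no salient loading (reverse-keyed autonomy item)",
      NA_character_
    )
  )

  gras_dir <- GRAS_DIRECTIONS
  if (!is.null(gras_directions)) {
    bad <- setdiff(names(gras_directions), paste0("GRAS_", 1:18))
    if (length(bad) > 0) {
      stop("unknown GRAS item id in direction override: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    gras_dir[names(gras_directions)] <- gras_directions
  }
  gras_excluded <- c(
    GRAS_1 = "low item-total correlation; gender DIF (driving)",
    GRAS_4 = "low item-total correlation (teaching)",
    GRAS_13 = "low item-total correlation (scientific discoveries)",
    GRAS_15 = "low item-total correlation (talking on the phone)"
  )
  gras_ids <- paste0("GRAS_", 1:18)
  gras <- tibble::tibble(
    item_id = gras_ids,
    scale = "GRAS",
    subscale = dplyr::case_when(
      item_id %in% GRAS_LA_ITEMS ~ "LA",
      item_id %in% GRAS_SR_ITEMS ~ "SR",
      TRUE ~ "NONE"
    ),
    response_format = "trichotomous",
    stereotype_direction = dplyr::coalesce(
      unname(gras_dir[gras_ids]), "undetermined"),
    retained = !item_id %in% names(gras_excluded),
    exclusion_reason = unname(gras_excluded[gras_ids])
  )

  gti <- tibble::tibble(
    item_id = GTI_ITEMS,
    scale = "GTI",
    subscale = "NONE",
    response_format = "trichotomous",
    stereotype_direction = unname(GTI_DIRECTIONS[GTI_ITEMS]),
    retained = TRUE,
    exclusion_reason = NA_character_
  )

  out <- dplyr::bind_rows(gsas, gras, gti)
  class(out) <- c("gab_registry", class(out))
  out
}

#' Retained item ids for one scale
#'
#' @param registry A registry tibble from [gab_registry()].
#' @param scale One of `"GSAS"`, `"GRAS"`, `"GTI"`.
#' @return Character vector of retained item ids, in registry order.
#' @export
retained_items <- function(registry, scale) {
  scale <- match.arg(scale, c("GSAS", "GRAS", "GTI"))
  registry$item_id[registry$retained & registry$scale == scale]
}

#' Subscale membership map for retained items
#'
#' @inheritParams retained_items
#' @return Named list of item-id vectors keyed by subscale label.
#' @export
subscale_items <- function(registry, scale) {
  scale <- match.arg(scale, c("GSAS", "GRAS", "GTI"))
  rows <- registry[registry$retained & registry$scale == scale &
                     registry$subscale != "NONE", ]
  split(rows$item_id, rows$subscale)
}

validate_registry <- function(registry) {
  stopifnot(is.data.frame(registry))
  ok_gsas <- all(registry$response_format[registry$scale == "GSAS"] == "likert4")
  ok_tri <- all(registry$response_format[registry$scale != "GSAS"] == "trichotomous")
  if (!ok_gsas || !ok_tri) stop("registry response formats are inconsistent", call. = FALSE)
  tri_dir <- registry$stereotype_direction[registry$scale != "GSAS"]
  if (!all(tri_dir %in% c("male", "female", "undetermined"))) {
    stop("trichotomous items must have direction male/female/undetermined", call. = FALSE)
  }
  invisible(registry)
}
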