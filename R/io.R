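# Response-matrix IO. The on-disk format is plain CSV with one row per
# respondent: person_id, gender (F/M), school (academic/technical/vocational),
# one column per item (likert codes 1-4 for GSAS, letters M/F/E for
# trichotomous items) and optional criterion-score columns.

CRITERION_COLS <- c("bpaq_total", "bpaq_physical", "bpaq_verbal", "bpaq_anger",
                    "bpaq_hostility", "k10", "rses", "paqs")

#' Read a respondent-by-item response matrix from CSV
#'
#' Validates every cell against the item registry: likert items accept
#' integer codes 1-4, trichotomous items accept the letters `M`, `F`, `E`
#' (E = "It doesn't matter"). Missing responses are allowed (empty cells or
#' `NA`); each downstream analysis applies its own completeness rule.
#'
#' @param path CSV file path.
#' @param registry Item registry, see [gab_registry()].
#' @return A validated tibble (class `gab_responses`). Unknown columns are
#'   kept but reported via a message.
#' @export
read_responses <- function(path, registry = gab_registry()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  as_gab_responses(raw, registry = registry)
}

#' Coerce and validate a data frame of raw responses
#'
#' @param data Data frame with mandatory columns `person_id`, `gender`,
#'   `school` plus item columns.
#' @inheritParams read_responses
#' @return A tibble of class `gab_responses` with typed columns.
#' @export
as_gab_responses <- function(data, registry = gab_registry()) {
  validate_registry(registry)
  data <- tibble::as_tibble(data)
  mandatory <- c("person_id", "gender", "school")
  missing_cols <- setdiff(mandatory, names(data))
  if (length(missing_cols) > 0) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(data$person_id)) {
    stop("schema error: person_id values are not unique", call. = FALSE)
  }
  data$person_id <- as.character(data$person_id)
  bad_gender <- setdiff(stats::na.omit(unique(as.character(data$gender))), c("F", "M"))
  if (length(bad_gender) > 0) {
    stop("validation error: gender must be F or M; found ",
         paste(bad_gender, collapse = ", "), call. = FALSE)
  }
  bad_school <- setdiff(stats::na.omit(unique(as.character(data$school))),
                        c("academic", "technical", "vocational"))
  if (length(bad_school) > 0) {
    stop("validation error: unknown school track: ",
         paste(bad_school, collapse = ", "), call. = FALSE)
  }
  data$gender <- factor(as.character(data$gender), levels = c("F", "M"))
  data$school <- factor(as.character(data$school),
                        levels = c("academic", "technical", "vocational"))

  item_cols <- intersect(registry$item_id, names(data))
  crit_cols <- intersect(CRITERION_COLS, names(data))
  unknown <- setdiff(names(data), c(mandatory, registry$item_id, CRITERION_COLS))
  if (length(unknown) > 0) {
    message("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
  }

  for (col in item_cols) {
    fmt <- registry$response_format[registry$item_id == col]
    vals <- as.character(data[[col]])
    if (fmt == "likert4") {
      ok <- is.na(vals) | vals %in% c("1", "2", "3", "4")
      if (!all(ok)) {
        bad <- which(!ok)[1]
        stop(sprintf(
          "validation error: illegal likert code '%s' at row %d, column %s (legal: 1-4)",
          vals[bad], bad, col), call. = FALSE)
      }
      data[[col]] <- as.integer(vals)
    } else {
      ok <- is.na(vals) | vals %in% c("M", "F", "E")
      if (!all(ok)) {
        bad <- which(!ok)[1]
        stop(sprintf(
          "validation error: illegal category code '%s' at row %d, column %s (legal: M/F/E)",
          vals[bad], bad, col), call. = FALSE)
      }
      data[[col]] <- vals
    }
  }
  for (col in crit_cols) data[[col]] <- as.numeric(data[[col]])

  attr(data, "item_cols") <- item_cols
  attr(data, "criterion_cols") <- crit_cols
  class(data) <- unique(c("gab_responses", class(data)))
  data
}

#' Write a response matrix to CSV
#'
#' Inverse of [read_responses()]: `write_responses()` then
#' [read_responses()] is lossless for legal matrices.
#'
#' @param data A `gab_responses` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(data, path) {
  out <- as.data.frame(data)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

item_columns <- function(data, registry, scale = NULL, retained_only = TRUE) {
  reg <- registry
  if (!is.null(scale)) reg <- reg[reg$scale == scale, ]
  if (retained_only) reg <- reg[reg$retained, ]
  intersect(reg$item_id, names(data))
}
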