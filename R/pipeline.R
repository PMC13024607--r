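# End-to-end orchestration: stratified split-sample cross-validation and the
# full validation pipeline on one cohort.

#' Stratified random split-sample
#'
#' Randomly halves the cohort within each gender-by-school cell (odd cells
#' hand the extra person to alternating halves, deterministically per
#' seed), for EFA/CFA-style cross-validation.
#'
#' @param data A `gab_responses` tibble.
#' @param seed Seed.
#' @return List with disjoint, exhaustive `sample_a` and `sample_b`, plus
#'   an `equivalence` tibble (chi-square tests of gender and school
#'   distributions across halves).
#' @export
split_sample <- function(data, seed = 1) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  cells <- interaction(data$gender, data$school, drop = FALSE)
  in_a <- logical(nrow(data))
  extra_to_a <- TRUE
  for (cl in levels(cells)) {
    idx <- which(cells == cl)
    if (length(idx) == 0) next
    n_half <- length(idx) %/% 2
    n_a <- n_half + if (length(idx) %% 2 == 1 && extra_to_a) 1 else 0
    if (length(idx) %% 2 == 1) extra_to_a <- !extra_to_a
    in_a[sample(idx, n_a)] <- TRUE
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  a <- data[in_a, ]
  b <- data[!in_a, ]
  equiv <- purrr::map_dfr(c("gender", "school"), function(v) {
    tab <- table(c(a[[v]], b[[v]]) , rep(c("A", "B"), c(nrow(a), nrow(b))))
    cs <- chi_square(tab, continuity = FALSE)
    tibble::tibble(variable = v, chi2 = cs$chi2, df = cs$df, p = cs$p)
  })
  list(sample_a = a, sample_b = b, equivalence = equiv)
}

#' Run the full validation pipeline
#'
#' Simulates or ingests a cohort, then runs response-style screening,
#' scoring, the split-sample EFA, reliability under both scoring schemas,
#' known-groups statistics, the attribution-bias analysis,
#' gender-stratified criterion validity and the norm/cutoff construction.
#'
#' @param data A `gab_responses` tibble, or `NULL` to simulate.
#' @param config Simulation configuration used when `data` is `NULL`.
#' @param seed Seed for simulation, splitting and factor-analysis restarts.
#' @param stages Character subset of
#'   `c("styles", "scores", "split", "efa", "reliability", "known_groups",
#'   "bias", "criterion", "norms")`.
#' @param efa_reps Parallel-analysis replicates.
#' @return Named list (class `gab_pipeline`) with one element per executed
#'   stage and a `manifest` recording inputs and seed.
#' @export
run_pipeline <- function(data = NULL, config = default_sim_config(), seed = 1,
                         stages = c("styles", "scores", "split", "efa",
                                    "reliability", "known_groups", "bias",
                                    "criterion", "norms"),
                         efa_reps = 1000) {
  registry <- gab_registry()
  if (is.null(data)) data <- generate_cohort(config, seed = seed)
  out <- list()
  out$manifest <- list(n = nrow(data), seed = seed, stages = stages,
                       simulated = TRUE, timestamp = NULL)

  if ("styles" %in% stages) {
    flags <- flag_problematic(data, registry)
    out$styles <- list(indices = style_indices(data, registry),
                       flags = flags,
                       sensitivity = sensitivity_analysis(data, registry, flags))
  }
  scores <- score_battery(data, registry)
  if ("scores" %in% stages) out$scores <- scores
  if ("split" %in% stages || "efa" %in% stages) {
    sp <- split_sample(data, seed = seed)
    out$split <- sp
  }
  if ("efa" %in% stages) {
    out$efa <- efa_scale(out$split$sample_a, registry, "GSAS",
                         reps = efa_reps, seed = seed)
  }
  if ("reliability" %in% stages) {
    rel <- lapply(c(GSAS = "GSAS", GRAS = "GRAS", GTI = "GTI"), function(sc) {
      items <- retained_items(registry, sc)
      schema <- if (sc == "GTI") "B" else "A"
      m <- score_items_matrix(data, registry, items, schema)
      nf <- max(1, length(subscale_items(registry, sc)))
      reliability_report(m[stats::complete.cases(m), ], n_group_factors = nf,
                         polychoric = FALSE)
    })
    out$reliability <- list(reports = rel,
                            schema_comparison = compare_schemas(data, registry))
  }
  if ("known_groups" %in% stages) {
    out$known_groups <- lapply(
      c(gsas_mean = "gsas_mean", gras_mean = "gras_mean", gti_mean = "gti_mean"),
      function(v) known_groups(scores, v))
  }
  if ("bias" %in% stages) {
    ap <- attribution_proportions(data, registry = registry)
    bias <- self_attribution_gap(ap)
    out$bias <- list(attribution = ap, gaps = bias,
                     sss = self_serving_scores(bias))
  }
  if ("criterion" %in% stages) {
    out$criterion <- criterion_validity(scores)
  }
  if ("norms" %in% stages) {
    x <- scores$gsas_sum
    keep <- !is.na(x)
    norms <- norm_table(x[keep], scores$gender[keep])
    cuts <- percentile_cutoffs(x[keep], scores$gender[keep])
    w <- gender_balanced_weights(scores$gender[keep])
    breaks <- kde_antimodes(x[keep], w)
    dip <- dip_test(x[keep], mc_reps = 1000, seed = seed)
    cls <- combined_classification(cuts$cutoff, breaks$antimodes,
                                   score_range = c(17, 68))
    out$norms <- list(table = norms, cutoffs = cuts, breaks = breaks,
                      dip = dip, classification = cls,
                      category_shares = prop.table(table(
                        classify_scores(cls, x[keep]))))
  }
  class(out) <- "gab_pipeline"
  out
}

#' @export
print.gab_pipeline <- function(x, ...) {
  cat("Validation pipeline (n =", x$manifest$n, ", seed =", x$manifest$seed,
      ")\nstages:", paste(setdiff(names(x), "manifest"), collapse = ", "), "\n")
  invisible(x)
}
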