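# Known-groups validity statistics: Welch's t with Satterthwaite df,
# Cohen's d with a normal-approximation interval, chi-square with Cramer's V,
# one-way and 2x3 factorial ANOVA with (partial) eta-squared, and
# Games-Howell post hoc comparisons.

as_summary <- function(g) {
  if (is.list(g) && all(c("m", "sd", "n") %in% names(g))) {
    list(m = g$m, sd = g$sd, n = g$n)
  } else {
    v <- as.numeric(g)
    v <- v[!is.na(v)]
    if (length(v) < 2) stop("need at least 2 observations per group", call. = FALSE)
    list(m = mean(v), sd = sd(v), n = length(v))
  }
}

#' Welch's t-test with Cohen's d
#'
#' Works identically from raw samples or from printed summaries
#' (`list(m =, sd =, n =)`). The effect-size sign follows
#' `mean(g2) - mean(g1)`.
#'
#' @param g1,g2 Numeric vectors, or summary lists with `m`, `sd`, `n`.
#' @param level Confidence level for the d interval.
#' @return Tibble row: group means/sds/ns, `t`, `df_welch`, `p`, `d`,
#'   `d_lo`, `d_hi`.
#' @export
welch_t <- function(g1, g2, level = 0.95) {
  s1 <- as_summary(g1); s2 <- as_summary(g2)
  if (s1$sd == 0 && s2$sd == 0) stop("both groups have zero variance", call. = FALSE)
  se2 <- s1$sd^2 / s1$n + s2$sd^2 / s2$n
  t <- (s2$m - s1$m) / sqrt(se2)
  df <- se2^2 / ((s1$sd^2 / s1$n)^2 / (s1$n - 1) + (s2$sd^2 / s2$n)^2 / (s2$n - 1))
  p <- 2 * pt(-abs(t), df)
  es <- cohens_d(s1, s2, level = level)
  tibble::tibble(m1 = s1$m, sd1 = s1$sd, n1 = s1$n,
                 m2 = s2$m, sd2 = s2$sd, n2 = s2$n,
                 t = t, df_welch = df, p = p,
                 d = es$d, d_lo = es$lo, d_hi = es$hi)
}

#' Cohen's d with confidence interval
#'
#' Pooled-SD standardised mean difference `(m2 - m1) / s_pooled`; the
#' interval uses the large-sample (Hedges-Olkin) variance of d.
#'
#' @inheritParams welch_t
#' @return List with `d`, `lo`, `hi`.
#' @export
cohens_d <- function(g1, g2, level = 0.95) {
  s1 <- as_summary(g1); s2 <- as_summary(g2)
  sp2 <- ((s1$n - 1) * s1$sd^2 + (s2$n - 1) * s2$sd^2) / (s1$n + s2$n - 2)
  if (sp2 <= 0) stop("pooled standard deviation is zero; d undefined", call. = FALSE)
  d <- (s2$m - s1$m) / sqrt(sp2)
  vd <- (s1$n + s2$n) / (s1$n * s2$n) + d^2 / (2 * (s1$n + s2$n))
  z <- qnorm(1 - (1 - level) / 2)
  list(d = d, lo = d - z * sqrt(vd), hi = d + z * sqrt(vd))
}

#' Benchmark label for an effect size
#'
#' Conventional benchmarks: d of 0.20/0.50/0.80 and eta-squared of
#' 0.01/0.06/0.14 mark small/medium/large effects.
#'
#' @param value Effect size value.
#' @param type `"d"` or `"eta_sq"`.
#' @return `"negligible"`, `"small"`, `"medium"` or `"large"`.
#' @export
effect_benchmark <- function(value, type = c("d", "eta_sq")) {
  type <- match.arg(type)
  cuts <- if (type == "d") c(0.20, 0.50, 0.80) else c(0.01, 0.06, 0.14)
  lab <- c("negligible", "small", "medium", "large")
  lab[findInterval(abs(value), cuts) + 1]
}

#' Chi-square test with Cramer's V
#'
#' Pearson chi-square on a contingency table; the Yates continuity
#' correction is applied automatically to 2x2 tables (set
#' `continuity = FALSE` to disable). `V = sqrt(chi2 / (N * (min(r, c) - 1)))`.
#'
#' @param tab Contingency table (matrix of counts, at least 2x2).
#' @param continuity `"auto"` (Yates on 2x2 only), `TRUE` or `FALSE`.
#' @return Tibble row: `chi2`, `df`, `p`, `cramers_v`, `yates_applied`, `n`.
#' @export
chi_square <- function(tab, continuity = "auto") {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in contingency table", call. = FALSE)
  }
  is2x2 <- nrow(tab) == 2 && ncol(tab) == 2
  yates <- if (identical(continuity, "auto")) is2x2 else isTRUE(continuity) && is2x2
  ct <- suppressWarnings(chisq.test(tab, correct = yates))
  n <- sum(tab)
  tibble::tibble(
    chi2 = unname(ct$statistic),
    df = unname(ct$parameter),
    p = ct$p.value,
    cramers_v = sqrt(unname(ct$statistic) / (n * (min(dim(tab)) - 1))),
    yates_applied = yates,
    n = n
  )
}

#' One-way ANOVA with eta-squared
#'
#' @param y Outcome vector.
#' @param group Grouping factor (>= 2 levels, each with >= 2 observations).
#' @return Tibble row: `df1`, `df2`, `F`, `p`, `eta_sq`.
#' @export
anova_oneway <- function(y, group) {
  keep <- !(is.na(y) | is.na(group))
  y <- y[keep]; group <- droplevels(factor(group[keep]))
  stopifnot(nlevels(group) >= 2, all(table(group) >= 2))
  fit <- aov(y ~ group)
  ss <- summary(fit)[[1]]
  tibble::tibble(
    df1 = ss[1, "Df"], df2 = ss[2, "Df"],
    F = ss[1, "F value"], p = ss[1, "Pr(>F)"],
    eta_sq = ss[1, "Sum Sq"] / sum(ss[, "Sum Sq"])
  )
}

#' 2x3 factorial ANOVA with partial eta-squared
#'
#' Type III sums of squares with sum-to-zero contrasts (the conventional
#' reporting choice for unbalanced factorial designs).
#'
#' @param y Outcome vector.
#' @param gender Two-level factor.
#' @param school Three-level factor.
#' @return Tibble: one row per effect (`gender`, `school`,
#'   `gender:school`) with `df`, `F`, `p`, `partial_eta_sq`, plus the
#'   residual df as an attribute.
#' @export
anova_factorial <- function(y, gender, school) {
  keep <- !(is.na(y) | is.na(gender) | is.na(school))
  y <- y[keep]
  gender <- droplevels(factor(gender[keep]))
  school <- droplevels(factor(school[keep]))
  if (any(table(gender, school) == 0)) stop("empty cell in factorial design", call. = FALSE)
  dat <- data.frame(y = y, gender = gender, school = school)
  fit <- aov(y ~ gender * school, data = dat,
             contrasts = list(gender = "contr.sum", school = "contr.sum"))
  d1 <- drop1(fit, . ~ ., test = "F") # Type III with sum contrasts
  ss_res <- d1[1, "RSS"]
  df_res <- fit$df.residual
  eff <- d1[-1, , drop = FALSE]
  ss_eff <- eff[, "Sum of Sq"]
  tibble::tibble(
    effect = rownames(eff),
    df = eff[, "Df"],
    F = eff[, "F value"],
    p = eff[, "Pr(>F)"],
    partial_eta_sq = ss_eff / (ss_eff + ss_res)
  ) |>
    structure(residual_df = df_res)
}

#' Games-Howell post hoc comparisons
#'
#' Pairwise mean differences with Welch-type standard errors and
#' studentized-range critical values on Satterthwaite degrees of freedom;
#' robust to heteroscedasticity and unequal group sizes.
#'
#' @param y Outcome vector.
#' @param group Grouping factor with >= 3 levels.
#' @return Tibble: `group1`, `group2`, `diff`, `se`, `df`, `p`.
#' @export
games_howell <- function(y, group) {
  keep <- !(is.na(y) | is.na(group))
  y <- y[keep]; group <- droplevels(factor(group[keep]))
  lev <- levels(group)
  stopifnot(length(lev) >= 3)
  st <- lapply(split(y, group), function(v) list(m = mean(v), v = var(v), n = length(v)))
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- st[[pr[1]]]; b <- st[[pr[2]]]
    se2 <- a$v / a$n + b$v / b$n
    df <- se2^2 / ((a$v / a$n)^2 / (a$n - 1) + (b$v / b$n)^2 / (b$n - 1))
    q <- abs(b$m - a$m) / sqrt(se2 / 2)
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   diff = b$m - a$m, se = sqrt(se2), df = df,
                   p = ptukey(q, nmeans = length(lev), df = df,
                              lower.tail = FALSE))
  })
}

#' Known-groups validity panel for one scale
#'
#' Reproduces the three-panel layout of the published known-groups tables:
#' gender comparison (Welch t, d), school-type one-way ANOVA with
#' Games-Howell post hocs, and the gender-by-school factorial.
#'
#' @param scores A `gab_scores` tibble (see [score_battery()]).
#' @param outcome Score column to analyse (e.g. `"gsas_mean"`).
#' @return List with `gender`, `school`, `posthoc`, `factorial`.
#' @export
known_groups <- function(scores, outcome = "gsas_mean") {
  y <- scores[[outcome]]
  keep <- !is.na(y)
  y <- y[keep]
  gender <- scores$gender[keep]
  school <- scores$school[keep]
  list(
    gender = welch_t(y[gender == "F"], y[gender == "M"]),
    school = anova_oneway(y, school),
    posthoc = games_howell(y, school),
    factorial = anova_factorial(y, gender, school)
  )
}
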