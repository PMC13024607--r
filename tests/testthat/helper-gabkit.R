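# Shared fixtures, built in code.

REG <- gab_registry()

# small simulated cohort (config calibration is cached across tests)
small_cohort <- function(n = 300, seed = 1, ...) {
  generate_cohort(default_sim_config(n = n, ...), seed = seed)
}

# minimal hand-built response tibble covering all retained items
toy_cohort <- function(n = 4) {
  d <- tibble::tibble(
    person_id = paste0("p", seq_len(n)),
    gender = rep(c("F", "M"), length.out = n),
    school = rep(c("academic", "technical", "vocational"), length.out = n)
  )
  for (it in retained_items(REG, "GSAS")) d[[it]] <- rep(c(1, 2, 3, 4), length.out = n)
  for (it in retained_items(REG, "GRAS")) d[[it]] <- rep(c("M", "F", "E", "E"), length.out = n)
  for (it in retained_items(REG, "GTI")) d[[it]] <- rep(c("E", "M", "F", "M"), length.out = n)
  as_gab_responses(d, REG)
}

# ordinal one-factor sample: k items, loading lambda, thresholds tau
sim_one_factor <- function(n, k, lambda, tau, seed) {
  withr::with_seed(seed, {
    f <- rnorm(n)
    sapply(seq_len(k), function(i) {
      y <- lambda * f + sqrt(1 - lambda^2) * rnorm(n)
      findInterval(y, tau)
    })
  })
}
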