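# Shared fixtures: tiny panels and cohorts built in code.

# Single-metabolite spec with a TAG-like curve; noise-free by default so the
# simulator's multiplicative structure can be checked exactly.
tag_spec <- function(between_gsd = 1, within_gsd = 1, lod = 0) {
  metabolite_spec(
    "TAG", "mmol/L",
    baseline_male = 1.0, baseline_female = 0.8,
    between_gsd = between_gsd, within_gsd = within_gsd,
    knots = c(baseline = 1, "3h" = 1.27, "10h" = 0.83, "24h" = 1.13),
    lod = lod
  )
}

# Flat response curve (no time effect) for reliability checks.
flat_spec <- function(between_gsd = 1.32, within_gsd = 1.25, id = "FLAT") {
  metabolite_spec(
    id, "umol/L",
    baseline_male = 10, baseline_female = 10,
    between_gsd = between_gsd, within_gsd = within_gsd,
    knots = c(baseline = 1, "24h" = 1)
  )
}

# Small imputed record table ready for the time-course functions.
small_records <- function(n_male = 4, n_female = 4, specs = tag_spec(1.2, 1.1),
                          seed = 42) {
  cohort <- build_cohort(n_male, n_female, seed = seed)
  simulate_trajectories(cohort, specs, seed = seed)
}

# Balanced subjects x timepoints matrix under the additive random-effects
# model y_ij = s_i + t_j + e_ij with the given component SDs.
additive_matrix <- function(n, k, sd_subject, sd_time, sd_error) {
  outer(rnorm(n, 0, sd_subject), rnorm(k, 0, sd_time), `+`) +
    matrix(rnorm(n * k, 0, sd_error), n, k)
}

# Independent ICC oracle: mean squares from base R aov() on the long data,
# solved for variance components by the method of moments, then the
# absolute-agreement ratio of untruncated components.
icc_oracle_aov <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  long <- data.frame(
    y = as.vector(mat),
    subject = factor(rep(seq_len(n), times = k)),
    time = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(aov(y ~ subject + time, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]
  msc <- ms[2]
  mse <- ms[3]
  vs <- (msr - mse) / k
  vt <- (msc - mse) / n
  vs / (vs + vt + mse)
}
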