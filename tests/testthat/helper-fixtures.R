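# Shared fixtures, all built in code.

# A small, fast cohort: 4 planted effects among 40 null peaks.
small_cohort_spec <- function(seed = 11, ...) {
  cohort_spec(n_case = 20, n_control = 20,
              planted = btc_reference_effects()[c(2, 3, 5, 8), ],
              n_null_peaks = 40, qc_subjects = 0, seed = seed, ...)
}

# Noise-free single-Gaussian spectrum on an optional exponential baseline.
gaussian_spectrum <- function(center = 5805, area = 10, sigma_frac = 8e-4,
                              baseline_amp = 0, baseline_decay = 2000,
                              mz_range = c(700, 10000), grid_rel = 2e-4,
                              extra_centers = NULL, extra_areas = NULL) {
  mz <- mz_range[1] * exp(seq(0, log(mz_range[2] / mz_range[1]), by = grid_rel))
  ctr <- c(center, extra_centers)
  ar <- c(area, extra_areas)
  y <- numeric(length(mz))
  for (i in seq_along(ctr)) {
    y <- y + ar[i] * dnorm(mz, ctr[i], sigma_frac * ctr[i])
  }
  y <- y + baseline_amp * exp(-(mz - mz_range[1]) / baseline_decay)
  raw_spectrum(mz, y, subject_id = "S1", replicate_id = "r1", group = "BTC")
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# group assignments (independent oracle; ties handled by midranks).
wilcox_exact_enum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  sets <- combn(n, length(x))
  u_all <- apply(sets, 2, function(ix) {
    sum(r[ix]) - length(x) * (length(x) + 1) / 2
  })
  mu <- length(x) * length(y) / 2
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Brute-force AUROC: all case/control pairs, ties count one half.
auroc_brute <- function(values, positive) {
  x <- values[positive]; y <- values[!positive]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}
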