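#' Moment-match a log-normal to a target mean and SD
#'
#' Serum peptide peak areas are positive and right-skewed; the generator
#' draws them from log-normal distributions whose first two moments equal
#' the group means and standard deviations being emulated. Closed forms:
#' `sigma^2 = log(1 + sd^2/mean^2)`, `mu = log(mean) - sigma^2/2`.
#'
#' @param mean target arithmetic mean of the distribution (`> 0`).
#' @param sd target arithmetic standard deviation (`>= 0`).
#' @return list with log-scale parameters `mu` and `sigma`. `sigma = 0`
#'   when `sd = 0` (degenerate point mass at `mean`).
#' @examples
#' p <- moment_match_lognormal(33.0, 30.9)
#' exp(p$mu + p$sigma^2 / 2)  # recovers 33.0
#' @export
moment_match_lognormal <- function(mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0) {
    stop_invalid("mean must be a single finite value > 0 (got %s)", format(mean))
  }
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0) {
    stop_invalid("sd must be a single finite value >= 0 (got %s)", format(sd))
  }
  sigma2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

# Draw n log-normal areas with the given arithmetic mean/sd
rlnorm_matched <- function(n, mean, sd) {
  p <- moment_match_lognormal(mean, sd)
  if (p$sigma == 0) return(rep(mean, n))
  stats::rlnorm(n, meanlog = p$mu, sdlog = p$sigma)
}

#' Reference panel of discriminatory serum peptide peaks
#'
#' The eight serum peptide peaks reported to discriminate biliary tract
#' cancer (BTC) from healthy controls, with the published group means and
#' standard deviations of normalized peak areas. These are the default
#' planted effects of the cohort generator, so simulated cohorts carry the
#' same first two moments per group as the study being emulated. Peaks
#' m/z 887.2, 2903.3 and 5805.0 are up-regulated in BTC; the remainder are
#' down-regulated. (m/z 2903.3 is believed to be the doubly-charged form
#' of 5805.0; see [charge_pair_check()].)
#'
#' @return data.frame with columns `peak_mz`, `mean_case`, `sd_case`,
#'   `mean_control`, `sd_control`.
#' @export
btc_reference_effects <- function() {
  data.frame(
    peak_mz      = c(887.2, 1263.7, 1350.8, 2082.1, 2210.3, 2554.5, 2903.3, 5805.0),
    mean_case    = c(5.2,   21.8,   48.3,   10.0,   10.9,   24.8,   24.1,   33.0),
    sd_case      = c(7.1,   9.9,    25.7,   3.4,    3.8,    17.8,   10.0,   30.9),
    mean_control = c(1.8,   47.4,   117.4,  24.4,   38.2,   57.3,   11.5,   6.7),
    sd_control   = c(0.5,   22.7,   62.3,   20.5,   31.6,   20.6,   2.5,    1.6)
  )
}

#' Specify a synthetic serum peptidome cohort
#'
#' Describes the generative model for a study cohort: group sizes, planted
#' differential effects (per-group log-normal, moment-matched), a shared
#' null-peak distribution, the replicate structure of the MALDI spotting
#' design, and instrument noise. Defaults reproduce the discovery-study
#' conditions: 39 BTC cases vs 22 healthy controls, the eight reference
#' effects planted among 295 null peaks (303 aligned peaks total) over
#' m/z 700-10,000, 3 extractions x 4 spots = 12 replicate spectra per
#' subject, and an inter-assay coefficient of variation of 12.8%.
#'
#' @param n_case,n_control numbers of case (BTC) and control (healthy)
#'   subjects; each `>= 2`.
#' @param n_benign number of benign biliary-disease subjects (may be 0).
#'   Planted peaks for benign subjects are drawn from the control
#'   distribution; the generator does not model a separate benign effect.
#' @param planted data.frame of planted effects as in
#'   [btc_reference_effects()]; may have 0 rows.
#' @param n_null_peaks number of non-discriminatory peaks, drawn for every
#'   group from one shared log-normal.
#' @param null_mean,null_cv mean and coefficient of variation of the shared
#'   null-peak area distribution.
#' @param mz_range numeric length-2, low < high, in Da.
#' @param replicate_design integer length-2: extractions per subject and
#'   spots per extraction.
#' @param replicate_cv fractional coefficient of variation of the
#'   log-normal replicate (spot-to-spot) factor.
#' @param qc_subjects number of repeated measurements of a single pooled
#'   quality-control serum included in the table (group `"QC"`).
#' @param seed integer root seed; every draw in the generator flows from it.
#' @return object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_case = 39, n_control = 22, n_benign = 0,
                        planted = btc_reference_effects(),
                        n_null_peaks = 295,
                        null_mean = 20, null_cv = 0.5,
                        mz_range = c(700, 10000),
                        replicate_design = c(extractions = 3, spots = 4),
                        replicate_cv = 0.128,
                        qc_subjects = 12,
                        seed = 1) {
  if (n_case < 2 || n_control < 2) stop_invalid("n_case and n_control must be >= 2")
  if (n_benign < 0 || n_null_peaks < 0 || qc_subjects < 0) {
    stop_invalid("counts must be non-negative")
  }
  if (length(mz_range) != 2 || mz_range[1] >= mz_range[2]) {
    stop_invalid("mz_range must be (low, high) with low < high")
  }
  if (replicate_cv < 0) stop_invalid("replicate_cv must be >= 0")
  if (length(replicate_design) != 2 || any(replicate_design < 1)) {
    stop_invalid("replicate_design must give >= 1 extraction and >= 1 spot")
  }
  planted <- as.data.frame(planted)
  if (nrow(planted) > 0) {
    need <- c("peak_mz", "mean_case", "sd_case", "mean_control", "sd_control")
    if (!all(need %in% names(planted))) {
      stop_invalid("planted must have columns %s", paste(need, collapse = ", "))
    }
    if (anyDuplicated(mz_label(planted$peak_mz))) {
      stop_invalid("duplicate planted m/z labels (to 1 decimal place)")
    }
    if (any(planted$mean_case <= 0) || any(planted$mean_control <= 0)) {
      stop_invalid("planted means must be > 0")
    }
    if (any(planted$sd_case < 0) || any(planted$sd_control < 0)) {
      stop_invalid("planted sds must be >= 0")
    }
  }
  structure(list(n_case = n_case, n_control = n_control, n_benign = n_benign,
                 planted = planted, n_null_peaks = n_null_peaks,
                 null_mean = null_mean, null_cv = null_cv,
                 mz_range = as.numeric(mz_range),
                 replicate_design = as.integer(replicate_design),
                 replicate_cv = replicate_cv, qc_subjects = qc_subjects,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a subject-level synthetic cohort
#'
#' Draws one row of normalized peak areas per subject. Planted peaks are
#' drawn per group from log-normals moment-matched to the planted means and
#' SDs; null peaks are drawn for all groups from one shared log-normal.
#' Null-peak m/z positions are placed uniformly over `mz_range`, unique to
#' 1 decimal place, at least 0.3% (several instrument peak widths) away
#' from every other peak so the list emulates resolvable aligned peaks, and
#' clear of the scan edges by 0.5%. QC rows repeat a single
#' pooled-serum profile with per-peak log-normal measurement noise at
#' `replicate_cv`, emulating repeated inter-assay runs of the same control
#' serum. Bit-identical output under a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `table` (a [peak_table()]; groups `BTC`,
#'   `benign`, `healthy`, `QC`) and `truth` (data.frame with `peak_mz`,
#'   `is_discriminatory`, `direction` in `up_in_case` / `down_in_case` /
#'   `null`).
#' @export
generate_peak_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    planted_mz <- spec$planted$peak_mz
    null_mz <- draw_null_mz(spec$n_null_peaks, spec$mz_range, planted_mz)
    mz <- c(planted_mz, null_mz)
    ord <- order(mz)
    n_pk <- length(mz)

    groups <- c(rep("BTC", spec$n_case), rep("benign", spec$n_benign),
                rep("healthy", spec$n_control))
    n_sub <- length(groups)
    areas <- matrix(NA_real_, n_sub, n_pk)

    # planted peaks: per-group moment-matched draws (benign ~ control)
    for (j in seq_along(planted_mz)) {
      eff <- spec$planted[j, ]
      areas[groups == "BTC", j] <-
        rlnorm_matched(spec$n_case, eff$mean_case, eff$sd_case)
      areas[groups == "benign", j] <-
        rlnorm_matched(spec$n_benign, eff$mean_control, eff$sd_control)
      areas[groups == "healthy", j] <-
        rlnorm_matched(spec$n_control, eff$mean_control, eff$sd_control)
    }
    # null peaks: one shared distribution for every group
    n_null <- length(null_mz)
    if (n_null > 0) {
      areas[, seq_along(null_mz) + length(planted_mz)] <-
        rlnorm_matched(n_sub * n_null, spec$null_mean,
                       spec$null_mean * spec$null_cv)
    }
    rownames(areas) <- sprintf("S%03d", seq_len(n_sub))

    if (spec$qc_subjects > 0) {
      qc_base <- c(
        if (length(planted_mz) > 0)
          vapply(seq_along(planted_mz), function(j)
            rlnorm_matched(1, spec$planted$mean_control[j],
                           spec$planted$sd_control[j]), numeric(1)),
        rlnorm_matched(n_null, spec$null_mean, spec$null_mean * spec$null_cv))
      qc <- matrix(rep(qc_base, each = spec$qc_subjects),
                   spec$qc_subjects, n_pk)
      if (spec$replicate_cv > 0) {
        qc <- qc * matrix(rlnorm_matched(length(qc), 1, spec$replicate_cv),
                          nrow(qc), ncol(qc))
      }
      rownames(qc) <- sprintf("QC%02d", seq_len(spec$qc_subjects))
      areas <- rbind(areas, qc)
      groups <- c(groups, rep("QC", spec$qc_subjects))
    }

    tbl <- peak_table(areas[, ord, drop = FALSE], mz[ord], groups)
    direction <- rep("null", n_pk)
    if (length(planted_mz) > 0) {
      direction[seq_along(planted_mz)] <-
        ifelse(spec$planted$mean_case >= spec$planted$mean_control,
               "up_in_case", "down_in_case")
    }
    truth <- data.frame(peak_mz = mz,
                        is_discriminatory = seq_len(n_pk) <= length(planted_mz),
                        direction = direction)[ord, ]
    rownames(truth) <- NULL
    list(table = tbl, truth = truth)
  })
}

# Uniform null-peak positions, unique at 1 dp, kept clear of planted peaks
# and of each other by a minimum relative separation (default 0.3%, i.e.
# several peak widths: the list emulates *resolvable* aligned peaks) and of
# the acquisition-range edges (0.5% margin, so rendered profiles are not
# truncated by the scan limits).
draw_null_mz <- function(n, mz_range, planted_mz, min_rel_sep = 0.003) {
  if (n == 0) return(numeric(0))
  lo <- mz_range[1] * 1.005
  hi <- mz_range[2] * 0.995
  out <- numeric(0)
  for (attempt in seq_len(200)) {
    cand <- round(stats::runif(4 * n, lo, hi), 1)
    cand <- cand[!duplicated(mz_label(cand))]
    for (m in cand) {
      if (length(out) == n) break
      others <- c(planted_mz, out)
      if (length(others) == 0 || all(abs(others - m) > min_rel_sep * m)) {
        out <- c(out, m)
      }
    }
    if (length(out) == n) break
  }
  if (length(out) < n) {
    stop_invalid("could not place %d separated null peaks in the m/z range", n)
  }
  out
}

#' Render raw replicate spectra for one subject
#'
#' Turns one subject's true peak areas into the 12 (by default) replicate
#' spectra the spotting design would produce. Each peak is a Gaussian
#' profile centred at its m/z with width proportional to m/z; each
#' replicate multiplies every peak area by an independent log-normal factor
#' with coefficient of variation `replicate_cv`, then adds an exponentially
#' decaying baseline and white noise, and jitters the m/z axis by a small
#' per-spectrum calibration offset. The m/z grid spacing is proportional to
#' m/z (TOF-like), ~4 samples per peak width.
#'
#' @param subject_areas named numeric vector of true peak areas (names are
#'   m/z labels), e.g. one row of a generated [peak_table()].
#' @param spec a [cohort_spec()] (supplies `replicate_design`,
#'   `replicate_cv`, `mz_range`, root seed).
#' @param subject_id,group metadata attached to each spectrum.
#' @param peak_width_frac Gaussian sigma as a fraction of m/z (default
#'   0.0008, i.e. 0.08%).
#' @param baseline_frac baseline amplitude as a fraction of the tallest
#'   peak height (default 0.05).
#' @param baseline_decay baseline exponential decay constant in Da.
#' @param noise_frac additive noise SD as a fraction of the tallest peak
#'   height (default 0.005).
#' @param jitter_frac half-width of the uniform per-spectrum relative
#'   calibration offset (default 1e-4, i.e. +/-0.01%).
#' @param grid_rel relative m/z grid spacing (default 2e-4).
#' @return list of `raw_spectrum` objects, one per replicate, with
#'   replicate ids `e<extraction>s<spot>`.
#' @export
generate_raw_spectra <- function(subject_areas, spec,
                                 subject_id = "S001", group = "BTC",
                                 peak_width_frac = 8e-4,
                                 baseline_frac = 0.05,
                                 baseline_decay = 2000,
                                 noise_frac = 0.005,
                                 jitter_frac = 1e-4,
                                 grid_rel = 2e-4) {
  stopifnot(inherits(spec, "cohort_spec"))
  mz0 <- as.numeric(names(subject_areas))
  if (anyNA(mz0)) stop_invalid("subject_areas must be named by numeric m/z labels")
  areas <- as.numeric(subject_areas)
  n_rep <- prod(spec$replicate_design)
  rep_ids <- as.vector(t(outer(seq_len(spec$replicate_design[1]),
                               seq_len(spec$replicate_design[2]),
                               function(e, s) sprintf("e%ds%d", e, s))))

  # geometric grid: spacing = grid_rel * m/z
  lo <- spec$mz_range[1]; hi <- spec$mz_range[2]
  grid <- lo * exp(seq(0, log(hi / lo), by = grid_rel))

  sigma <- peak_width_frac * mz0
  height_scale <- max(areas / (sigma * sqrt(2 * pi)))  # tallest noiseless peak

  with_seed(derive_seed(spec$seed, paste0("spectra:", subject_id)), {
    lapply(rep_ids, function(rid) {
      a <- areas
      if (spec$replicate_cv > 0) {
        a <- a * rlnorm_matched(length(a), 1, spec$replicate_cv)
      }
      jit <- 1 + stats::runif(1, -jitter_frac, jitter_frac)
      y <- numeric(length(grid))
      for (j in seq_along(mz0)) {
        ctr <- mz0[j] * jit
        idx <- which(grid > ctr - 5 * sigma[j] & grid < ctr + 5 * sigma[j])
        if (length(idx)) {
          y[idx] <- y[idx] + a[j] * stats::dnorm(grid[idx], ctr, sigma[j])
        }
      }
      if (baseline_frac > 0) {
        y <- y + baseline_frac * height_scale * exp(-(grid - lo) / baseline_decay)
      }
      if (noise_frac > 0) {
        y <- y + stats::rnorm(length(grid), 0, noise_frac * height_scale)
      }
      raw_spectrum(grid, y, subject_id = subject_id, replicate_id = rid,
                   group = group)
    })
  })
}

#' Write a generated cohort to disk
#'
#' Emits `peaks.tsv` (subject-level table), `truth.tsv` and
#' `sample_sheet.csv` into `dir`; with `raw_spectra = TRUE` also renders and
#' writes per-replicate two-column text spectra under `dir/spectra/` and a
#' replicate-level sample sheet referencing them.
#'
#' @param cohort result of [generate_peak_cohort()].
#' @param spec the [cohort_spec()] used.
#' @param dir output directory (created if needed).
#' @param raw_spectra render raw replicate spectra as well (slower).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, spec, dir, raw_spectra = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tbl <- cohort$table
  write_peak_table(tbl, file.path(dir, "peaks.tsv"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- data.frame(subject_id = attr(tbl, "subject_id"),
                      group = attr(tbl, "group"))
  utils::write.csv(sheet, file.path(dir, "sample_sheet.csv"), row.names = FALSE)
  if (raw_spectra) {
    spdir <- file.path(dir, "spectra")
    dir.create(spdir, showWarnings = FALSE)
    rows <- list()
    for (i in seq_len(nrow(tbl))) {
      sid <- attr(tbl, "subject_id")[i]
      specs <- generate_raw_spectra(unclass(tbl)[i, ], spec,
                                    subject_id = sid,
                                    group = attr(tbl, "group")[i])
      for (sp in specs) {
        f <- sprintf("%s_%s.txt", sid, sp$replicate_id)
        write_spectrum(sp, file.path(spdir, f))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = sp$group,
          replicate_id = sp$replicate_id, file = file.path("spectra", f))
      }
    }
    utils::write.csv(do.call(rbind, rows),
                     file.path(dir, "replicate_sheet.csv"), row.names = FALSE)
  }
  invisible(dir)
}
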