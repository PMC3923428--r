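# Tiny FNV-1a string hash used to fingerprint run parameters in manifests
fnv_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619 %% 2^31
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the discovery phase end to end
#'
#' Orchestrates the study replica: simulate a cohort (or ingest a
#' user-supplied peak table), optionally render and re-extract raw
#' replicate spectra through the preprocessing chain, screen peaks for
#' group differences (BTC vs healthy, and BTC vs benign when benign
#' subjects are present), and search for ratio/power classifier models
#' over the surviving peaks. All outputs and a manifest recording every
#' parameter and seed are written to `out_dir`.
#'
#' @param config list (or path to a YAML file) with blocks:
#'   * `out_dir`, `seed`
#'   * `cohort`: arguments to [cohort_spec()], or `peaks`: path to an
#'     existing peak-table TSV
#'   * `raw_spectra`: logical; render replicate spectra and run the full
#'     preprocessing chain instead of using subject-level areas directly
#'   * `preprocess`: `snr_min`, `tol_ppm`, `min_presence`
#'   * `diff`: `p_cut` (0.001), `fc_cut` (2.0), `use_raw_p`,
#'     `benign_p_cut` (0.05), `benign_fc_cut` (1.5)
#'   * `search`: `enabled`, `max_numerator`, `max_denominator`,
#'     `transforms`, `power_grid` (default fixed power 1 for tractability),
#'     `top`, `exclude_charge_pairs` (drop candidates explained as
#'     doubly-charged forms of another candidate; default TRUE)
#' @return list with `table`, `qc`, `diff_healthy`, `survivors`,
#'   `diff_benign`, `models`, `manifest` (invisibly also written to disk).
#' @export
run_discovery <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir %||% tempfile("btcpep_run_")
  seed <- config$seed %||% 1
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- stage: cohort -------------------------------------------------------
  if (!is.null(config$peaks)) {
    table <- read_peak_table(config$peaks)
    spec <- NULL
    truth <- NULL
  } else {
    spec <- do.call(cohort_spec, c(config$cohort %||% list(),
                                   if (is.null(config$cohort$seed))
                                     list(seed = seed)))
    cohort <- generate_peak_cohort(spec)
    truth <- cohort$truth
    table <- cohort$table
    if (isTRUE(config$raw_spectra)) {
      pp <- config$preprocess %||% list()
      non_qc <- peak_groups(table) != "QC"
      spectra <- unlist(lapply(which(non_qc), function(i) {
        generate_raw_spectra(unclass(table)[i, ], spec,
                             subject_id = attr(table, "subject_id")[i],
                             group = peak_groups(table)[i])
      }), recursive = FALSE)
      aligned <- spectra_to_peak_table(
        spectra, snr_min = pp$snr_min %||% 3,
        tol_ppm = pp$tol_ppm %||% 1000,
        min_presence = pp$min_presence %||% 0.25)
      table <- aggregate_replicates(aligned$table)
    }
    write_cohort(cohort, spec, out_dir)
  }
  grp <- peak_groups(table)

  # --- stage: QC -----------------------------------------------------------
  qc <- NULL
  if (sum(grp == "QC") >= 2) {
    qc <- qc_cv(subset_rows(table, grp == "QC"))
  }

  # --- stage: differential screening --------------------------------------
  study <- subset_rows(table, grp != "QC")
  dcfg <- config$diff %||% list()
  diff_healthy <- compare_groups(study, "BTC", "healthy")
  survivors <- filter_discriminatory(diff_healthy,
                                     p_cut = dcfg$p_cut %||% 0.001,
                                     fc_cut = dcfg$fc_cut %||% 2.0,
                                     use_raw_p = isTRUE(dcfg$use_raw_p))
  utils::write.table(diff_healthy, file.path(out_dir, "diff_BTC_vs_healthy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(survivors, file.path(out_dir, "discriminatory_peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  diff_benign <- NULL
  if (sum(peak_groups(study) == "benign") >= 5) {
    diff_benign <- compare_groups(study, "BTC", "benign")
    utils::write.table(diff_benign, file.path(out_dir, "diff_BTC_vs_benign.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    message("benign group absent or too small; benign comparison skipped")
  }

  # --- stage: model search -------------------------------------------------
  scfg <- config$search %||% list()
  models <- NULL
  candidates <- scfg$candidates %||% survivors$ref_mz
  if (!isFALSE(scfg$enabled) && length(candidates) >= 2) {
    if (!isFALSE(scfg$exclude_charge_pairs)) {
      dbl <- vapply(candidates, function(mz) {
        higher <- candidates[candidates > mz]
        length(higher) > 0 && any(vapply(higher, charge_pair_check,
                                         logical(1), mz_double = mz,
                                         tol = 0.5))
      }, logical(1))
      candidates <- candidates[!dbl]
    }
  }
  if (!isFALSE(scfg$enabled) && length(candidates) >= 2) {
    sc <- search_config(candidates,
                        max_numerator = scfg$max_numerator %||% 1,
                        max_denominator = scfg$max_denominator %||% 3,
                        transforms = scfg$transforms %||% "linear",
                        power_grid = scfg$power_grid %||% 1,
                        scale = scfg$scale %||% 1000)
    models <- search_models(study, peak_groups(study) == "BTC", sc,
                            top = scfg$top %||% 10)
    utils::write.table(models[, setdiff(names(models), "model")],
                       file.path(out_dir, "models.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_model(models$model[[1]], file.path(out_dir, "best_model.json"))
  }

  params <- list(seed = seed, cohort = config$cohort,
                 raw_spectra = isTRUE(config$raw_spectra),
                 preprocess = config$preprocess, diff = dcfg,
                 search = scfg)
  manifest <- list(package = "btcpep",
                   version = as.character(utils::packageVersion("btcpep")),
                   seed = seed, parameters = params,
                   param_hash = fnv_hash(params),
                   n_subjects = nrow(study), n_peaks = ncol(study),
                   n_discriminatory = nrow(survivors),
                   qc_mean_cv = if (!is.null(qc)) qc$mean_cv else NA,
                   outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(table = table, truth = truth, qc = qc,
                 diff_healthy = diff_healthy, survivors = survivors,
                 diff_benign = diff_benign, models = models,
                 manifest = manifest, out_dir = out_dir))
}

#' Validate a frozen model on an independent peak table
#'
#' Applies a model exactly as stored (no refitting of threshold, powers or
#' peaks) to a validation table and reports the confusion counts, the
#' sensitivity/specificity/PPV/NPV quadruple and the score AUROC with its
#' DeLong SE and Wald interval.
#'
#' @param model a [ratio_power_model()] or path to a model JSON.
#' @param table a [peak_table()] or path to a peak-table TSV.
#' @param truth optional labels (defaults to the table's groups).
#' @return a `model_performance`.
#' @export
run_validation <- function(model, table, truth = NULL) {
  if (is.character(model)) model <- read_model(model)
  if (is.character(table)) table <- read_peak_table(table)
  if (nrow(table) == 0) stop_invalid("validation table is empty")
  evaluate_model(model, table, truth = truth)
}

# Read a YAML run config if the yaml package is available, else JSON
read_run_config <- function(path) {
  if (grepl("[.]ya?ml$", path) && requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
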