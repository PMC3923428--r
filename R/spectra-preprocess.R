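#' Raw MALDI-TOF spectrum
#'
#' A single acquired profile: strictly increasing m/z values with
#' non-negative intensities, plus subject/replicate metadata.
#'
#' @param mz numeric, strictly increasing (Da).
#' @param intensity numeric, same length as `mz`.
#' @param subject_id,replicate_id,group metadata strings.
#' @return object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(mz, intensity, subject_id = NA_character_,
                         replicate_id = NA_character_, group = NA_character_) {
  if (length(mz) != length(intensity)) {
    stop_invalid("mz and intensity must have equal length")
  }
  if (is.unsorted(mz, strictly = TRUE)) {
    stop_invalid("m/z axis must be strictly increasing")
  }
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 subject_id = subject_id, replicate_id = replicate_id,
                 group = group),
            class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("raw_spectrum: %d points, m/z %.1f-%.1f (subject %s, rep %s)\n",
              length(x$mz), min(x$mz), max(x$mz), x$subject_id, x$replicate_id))
  invisible(x)
}

#' Read / write two-column text spectra
#'
#' Plain text, one `(m/z, intensity)` pair per line, whitespace- or
#' comma-separated; lines starting with `#` are skipped.
#'
#' @param path file path.
#' @param subject_id,replicate_id,group metadata attached on read.
#' @return `read_spectrum` returns a [raw_spectrum()].
#' @export
read_spectrum <- function(path, subject_id = NA_character_,
                          replicate_id = NA_character_, group = NA_character_) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  m <- vapply(parts, function(p) as.numeric(p[1:2]), numeric(2))
  if (anyNA(m)) stop_invalid("malformed spectrum file: %s", path)
  raw_spectrum(m[1, ], m[2, ], subject_id, replicate_id, group)
}

#' @rdname read_spectrum
#' @param spectrum a [raw_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# subject=%s replicate=%s group=%s",
                     spectrum$subject_id, spectrum$replicate_id,
                     spectrum$group), con)
  utils::write.table(cbind(spectrum$mz, spectrum$intensity), con,
                     col.names = FALSE, row.names = FALSE)
  invisible(path)
}

# SNIP-style iterative minimum-filter baseline estimate: at pass k each
# point is clipped to the mean of its neighbours k points away.
snip_baseline <- function(y, iterations = 40) {
  n <- length(y)
  b <- y
  for (k in seq_len(min(iterations, (n - 1) %/% 2))) {
    i <- (k + 1):(n - k)
    b[i] <- pmin(b[i], (b[i - k] + b[i + k]) / 2)
  }
  b
}

# trapezoidal integral of y over x
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Preprocess a raw spectrum
#'
#' Emulates the vendor processing chain: SNIP-style baseline subtraction,
#' Savitzky-Golay smoothing, clipping at zero, and total-ion-current (TIC)
#' normalization so the trapezoidal integral of the processed intensities
#' equals 1. The TIC before normalization is retained as attribute
#' `tic_raw` (used later for replicate quality filtering).
#'
#' @param raw a [raw_spectrum()].
#' @param baseline_iterations SNIP passes (default 40).
#' @param smooth_window,smooth_order Savitzky-Golay filter length (odd,
#'   default 21 points) and polynomial order (default 3); `smooth_window =
#'   0` disables smoothing.
#' @param min_points minimum number of points required (default 100).
#' @return a processed `raw_spectrum` with attribute `tic_raw`.
#' @export
preprocess_spectrum <- function(raw, baseline_iterations = 40,
                                smooth_window = 21, smooth_order = 3,
                                min_points = 100) {
  stopifnot(inherits(raw, "raw_spectrum"))
  if (length(raw$mz) < min_points) {
    stop_invalid("spectrum has %d points; >= %d required",
                 length(raw$mz), min_points)
  }
  y <- raw$intensity - snip_baseline(raw$intensity, baseline_iterations)
  if (smooth_window > 1) {
    y <- signal::sgolayfilt(y, p = smooth_order, n = smooth_window)
  }
  y <- pmax(y, 0)
  tic <- trapz(raw$mz, y)
  if (tic > 0) y <- y / tic
  out <- raw_spectrum(raw$mz, y, raw$subject_id, raw$replicate_id, raw$group)
  attr(out, "tic_raw") <- tic
  out
}

#' Detect peaks in a processed spectrum
#'
#' Local maxima with signal-to-noise at least `snr_min`, where noise is the
#' median absolute deviation (scaled by 1.4826) of the baseline-subtracted
#' signal. Each peak's centroid is the intensity-weighted mean m/z over its
#' contiguous above-half-maximum region; its area is the trapezoidal
#' integral between the flanking local minima.
#'
#' @param processed a preprocessed [raw_spectrum()].
#' @param snr_min minimum signal-to-noise ratio (default 3).
#' @return data.frame with columns `centroid`, `area`, `height`, `snr`
#'   (possibly 0 rows).
#' @export
detect_peaks <- function(processed, snr_min = 3) {
  stopifnot(inherits(processed, "raw_spectrum"))
  x <- processed$mz
  y <- processed$intensity
  n <- length(y)
  empty <- data.frame(centroid = numeric(0), area = numeric(0),
                      height = numeric(0), snr = numeric(0),
                      mz_lo = numeric(0), mz_hi = numeric(0))
  if (n < 3 || all(y == 0)) return(empty)
  noise <- stats::mad(y)
  # noiseless spectra have zero MAD; fall back to a relative floor that
  # still suppresses sub-ppm baseline-subtraction residue
  thr <- if (noise > 0) snr_min * noise else max(y) * 1e-4
  apex <- which(y[-c(1, n)] > y[-c(n - 1, n)] &
                y[-c(1, n)] >= y[-c(1, 2)] &
                y[-c(1, n)] >= thr) + 1L
  if (length(apex) == 0) return(empty)
  # flanking local minima (plateau-tolerant), including endpoints
  dy <- sign(diff(y))
  nz <- which(dy != 0)
  interior_min <- integer(0)
  if (length(nz) > 1) {
    k <- which(dy[nz][-length(nz)] == -1 & dy[nz][-1] == 1)
    interior_min <- nz[k] + 1L
  }
  mins <- sort(unique(c(1L, interior_min, n)))
  out <- lapply(apex, function(i) {
    lo <- max(mins[mins <= i])
    hi <- min(mins[mins >= i])
    if (lo == hi) return(NULL)
    half <- y[i] / 2
    l <- i; while (l > lo && y[l - 1] >= half) l <- l - 1L
    r <- i; while (r < hi && y[r + 1] >= half) r <- r + 1L
    seg <- l:r
    data.frame(centroid = sum(x[seg] * y[seg]) / sum(y[seg]),
               area = trapz(x[lo:hi], y[lo:hi]),
               height = y[i],
               snr = if (noise > 0) y[i] / noise else Inf,
               mz_lo = x[lo], mz_hi = x[hi],
               lo = lo, hi = hi)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  # noise can split one peak into several maxima sharing the same valleys;
  # keep the tallest apex per (lo, hi) segment
  out <- out[order(out$lo, -out$height), ]
  out <- out[!duplicated(out[, c("lo", "hi")]), ]
  out <- out[order(out$centroid),
             c("centroid", "area", "height", "snr", "mz_lo", "mz_hi")]
  rownames(out) <- NULL
  out
}

#' Align detected peaks across spectra
#'
#' Single-linkage clustering of peak centroids on the m/z axis with a
#' relative tolerance: adjacent sorted centroids join the same cluster when
#' their gap is below `tol_ppm` parts per million. Clusters detected in at
#' least `min_presence` of the spectra become peak definitions with
#' `ref_mz` the median centroid; integration windows are the cluster
#' extent padded by half the tolerance and truncated at midpoints between
#' neighbouring peaks so windows never overlap.
#'
#' @param detections list of [detect_peaks()] data.frames, one per spectrum.
#' @param meta optional data.frame with one row per spectrum
#'   (`subject_id`, `replicate_id`, `group`) used to label the output table.
#' @param tol_ppm clustering tolerance in ppm (default 1000).
#' @param min_presence minimum fraction of spectra a cluster must appear in
#'   (default 0.25).
#' @param spectra optional list of processed spectra; when given, each
#'   table entry is re-integrated over the cluster window (0 when absent)
#'   instead of using the detection's own area.
#' @return list with `peaks` (data.frame `ref_mz`, `window_lo`,
#'   `window_hi`, `presence`) and `table` (replicate-level [peak_table()],
#'   one row per input spectrum, with per-spectrum raw TIC in attribute
#'   `tic_raw` when `spectra` carry it).
#' @export
align_peaks <- function(detections, meta = NULL, tol_ppm = 1000,
                        min_presence = 0.25, spectra = NULL) {
  ns <- length(detections)
  if (ns < 1) stop_invalid("need at least one spectrum")
  all_mz <- unlist(lapply(detections, function(d) d$centroid))
  all_area <- unlist(lapply(detections, function(d) d$area))
  all_sp <- rep(seq_len(ns), vapply(detections, nrow, integer(1)))
  if (length(all_mz) == 0) stop_invalid("no detections to align")
  ord <- order(all_mz)
  all_mz <- all_mz[ord]; all_area <- all_area[ord]; all_sp <- all_sp[ord]
  gap_ok <- diff(all_mz) <= tol_ppm * 1e-6 * all_mz[-length(all_mz)]
  cl <- cumsum(c(1L, !gap_ok))

  keep <- tapply(all_sp, cl, function(s) length(unique(s))) >= min_presence * ns
  cl_ids <- as.integer(names(keep))[keep]
  ref <- vapply(cl_ids, function(k) stats::median(all_mz[cl == k]), numeric(1))
  pres <- vapply(cl_ids, function(k) length(unique(all_sp[cl == k])) / ns,
                 numeric(1))
  # integration windows: the median detection support (flanking minima) when
  # the detections carry it, else the centroid extent padded by half the
  # clustering tolerance
  has_support <- all(vapply(detections, function(d)
    all(c("mz_lo", "mz_hi") %in% names(d)), logical(1)))
  if (has_support) {
    all_wlo <- unlist(lapply(detections, function(d) d$mz_lo))[ord]
    all_whi <- unlist(lapply(detections, function(d) d$mz_hi))[ord]
    win_lo <- vapply(cl_ids, function(k) stats::median(all_wlo[cl == k]),
                     numeric(1))
    win_hi <- vapply(cl_ids, function(k) stats::median(all_whi[cl == k]),
                     numeric(1))
  } else {
    pad <- tol_ppm * 1e-6 * ref / 2
    win_lo <- vapply(cl_ids, function(k) min(all_mz[cl == k]), numeric(1)) - pad
    win_hi <- vapply(cl_ids, function(k) max(all_mz[cl == k]), numeric(1)) + pad
  }
  o <- order(ref)
  cl_ids <- cl_ids[o]; ref <- ref[o]
  win_lo <- win_lo[o]; win_hi <- win_hi[o]; pres <- pres[o]
  if (length(ref) > 1) {
    mid <- (ref[-length(ref)] + ref[-1]) / 2
    win_hi[-length(ref)] <- pmin(win_hi[-length(ref)], mid)
    win_lo[-1] <- pmax(win_lo[-1], mid)
  }

  areas <- matrix(0, ns, length(ref))
  if (is.null(spectra)) {
    for (j in seq_along(cl_ids)) {
      sel <- cl == cl_ids[j]
      a <- tapply(all_area[sel], all_sp[sel], sum)
      areas[as.integer(names(a)), j] <- a
    }
  } else {
    for (i in seq_len(ns)) {
      sp <- spectra[[i]]
      for (j in seq_along(ref)) {
        idx <- which(sp$mz >= win_lo[j] & sp$mz <= win_hi[j])
        if (length(idx) > 1) areas[i, j] <- trapz(sp$mz[idx], sp$intensity[idx])
      }
    }
  }
  if (is.null(meta)) {
    meta <- data.frame(subject_id = sprintf("SP%03d", seq_len(ns)),
                       replicate_id = as.character(seq_len(ns)),
                       group = NA_character_)
  }
  rownames(areas) <- make.unique(paste(meta$subject_id, meta$replicate_id,
                                       sep = "_"))
  tbl <- peak_table(areas, ref, meta$group, subject_id = meta$subject_id)
  attr(tbl, "replicate_id") <- meta$replicate_id
  if (!is.null(spectra)) {
    attr(tbl, "tic_raw") <- vapply(spectra, function(s)
      attr(s, "tic_raw") %||% NA_real_, numeric(1))
  }
  list(peaks = data.frame(ref_mz = ref, window_lo = win_lo,
                          window_hi = win_hi, presence = pres),
       table = tbl)
}

#' Aggregate replicate spectra to subject level
#'
#' Subject areas are the mean of the surviving replicate rows. A replicate
#' is discarded when its pre-normalization TIC falls below `min_tic_frac`
#' of its subject's median replicate TIC; subjects left with fewer than
#' `min_replicates` surviving replicates are flagged (attribute `flagged`).
#'
#' @param replicate_table replicate-level [peak_table()] (one row per
#'   spectrum, `subject_id` attribute mapping rows to subjects).
#' @param sample_sheet optional data.frame with `subject_id` and `group`;
#'   every replicate's subject must appear in it. Defaults to the table's
#'   own metadata.
#' @param tic_raw per-replicate pre-normalization TIC; defaults to the
#'   table's `tic_raw` attribute, else all equal (no filtering).
#' @param min_tic_frac TIC filter threshold as a fraction of the subject
#'   median (default 0.25).
#' @param min_replicates minimum surviving replicates before a subject is
#'   flagged (default 3).
#' @return subject-level [peak_table()] with attribute `flagged`
#'   (character vector of flagged subject ids) and `n_replicates`.
#' @export
aggregate_replicates <- function(replicate_table, sample_sheet = NULL,
                                 tic_raw = NULL, min_tic_frac = 0.25,
                                 min_replicates = 3) {
  subj <- attr(replicate_table, "subject_id")
  grp <- attr(replicate_table, "group")
  if (!is.null(sample_sheet)) {
    miss <- setdiff(subj, sample_sheet$subject_id)
    if (length(miss)) {
      stop_invalid("replicates map to subjects absent from the sample sheet: %s",
                   paste(unique(miss), collapse = ", "))
    }
    grp <- sample_sheet$group[match(subj, sample_sheet$subject_id)]
  }
  tic <- tic_raw %||% attr(replicate_table, "tic_raw") %||%
    rep(1, nrow(replicate_table))
  if (anyNA(tic)) tic[is.na(tic)] <- 1
  uniq <- unique(subj)
  out <- matrix(NA_real_, length(uniq), ncol(replicate_table))
  n_surv <- integer(length(uniq))
  for (i in seq_along(uniq)) {
    rows <- which(subj == uniq[i])
    ok <- tic[rows] >= min_tic_frac * stats::median(tic[rows])
    n_surv[i] <- sum(ok)
    out[i, ] <- colMeans(unclass(replicate_table)[rows[ok], , drop = FALSE])
  }
  rownames(out) <- uniq
  tbl <- peak_table(out, attr(replicate_table, "mz"),
                    grp[match(uniq, subj)], subject_id = uniq)
  attr(tbl, "n_replicates") <- stats::setNames(n_surv, uniq)
  attr(tbl, "flagged") <- uniq[n_surv < min_replicates]
  tbl
}

#' Inter-assay coefficient of variation from QC measurements
#'
#' Per-peak CV (%) across repeated measurements of the same quality-control
#' serum, summarised as mean +/- SD across peaks. Peaks whose QC mean is 0
#' have undefined CV and are excluded from the summary.
#'
#' @param qc_areas matrix (or [peak_table()]) of QC measurements, one row
#'   per measurement, one column per peak. At least 2 rows.
#' @return list with `per_peak` (named CV vector, `NA` where undefined),
#'   `mean_cv`, `sd_cv`, `n_undefined`.
#' @export
qc_cv <- function(qc_areas) {
  m <- unclass(as.matrix(qc_areas))
  if (nrow(m) < 2) stop_invalid("need >= 2 QC measurements")
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, 100 * s / mu)
  names(cv) <- colnames(m)
  list(per_peak = cv,
       mean_cv = mean(cv, na.rm = TRUE),
       sd_cv = stats::sd(cv[!is.na(cv)]),
       n_undefined = sum(is.na(cv)))
}

#' Full preprocessing chain: spectra to replicate-level peak table
#'
#' Convenience wrapper: [preprocess_spectrum()] on every spectrum,
#' [detect_peaks()], then [align_peaks()] using the spectra's own metadata.
#'
#' @param spectra list of [raw_spectrum()] objects.
#' @param snr_min,tol_ppm,min_presence see [detect_peaks()] and
#'   [align_peaks()].
#' @param ... further arguments to [preprocess_spectrum()].
#' @return as [align_peaks()].
#' @export
spectra_to_peak_table <- function(spectra, snr_min = 3, tol_ppm = 1000,
                                  min_presence = 0.25, ...) {
  processed <- lapply(spectra, preprocess_spectrum, ...)
  detections <- lapply(processed, detect_peaks, snr_min = snr_min)
  meta <- data.frame(
    subject_id = vapply(spectra, `[[`, character(1), "subject_id"),
    replicate_id = vapply(spectra, `[[`, character(1), "replicate_id"),
    group = vapply(spectra, `[[`, character(1), "group"))
  align_peaks(detections, meta = meta, tol_ppm = tol_ppm,
              min_presence = min_presence, spectra = processed)
}
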