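test_that("preprocessing removes baseline and normalizes TIC to 1", {
  # flat spectrum: pure baseline, nothing left after subtraction
  mz <- seq(700, 10000, length.out = 2000)
  flat <- raw_spectrum(mz, rep(7, 2000))
  out <- preprocess_spectrum(flat)
  expect_true(all(out$intensity == 0))
  expect_equal(attr(out, "tic_raw"), 0)

  # peak on an exponential baseline: raw TIC after baseline removal is the
  # peak area, and the normalized spectrum integrates to exactly 1
  sp <- gaussian_spectrum(center = 3000, area = 10, baseline_amp = 0.2)
  out <- preprocess_spectrum(sp)
  expect_equal(attr(out, "tic_raw"), 10, tolerance = 0.02 * 10)
  tic <- sum(diff(out$mz) *
               (out$intensity[-1] + out$intensity[-length(out$mz)]) / 2)
  expect_equal(tic, 1.0, tolerance = 1e-9)
  expect_error(preprocess_spectrum(raw_spectrum(mz[1:50], rep(1, 50))),
               "points")
})

test_that("peak detection finds centroids and areas, empty when silent", {
  zero <- raw_spectrum(seq(700, 10000, length.out = 1000), rep(0, 1000))
  expect_equal(nrow(detect_peaks(zero)), 0)

  sp <- preprocess_spectrum(gaussian_spectrum(center = 5805, area = 10,
                                              baseline_amp = 0.05))
  pk <- detect_peaks(sp)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$centroid - 5805), 0.5)

  # two peaks 10 Da apart at m/z 2000 (default width sigma = 1.6 Da) resolve
  sp2 <- preprocess_spectrum(gaussian_spectrum(center = 2000, area = 5,
                                               extra_centers = 2010,
                                               extra_areas = 5))
  pk2 <- detect_peaks(sp2)
  expect_equal(nrow(pk2), 2)
  expect_equal(sort(pk2$centroid), c(2000, 2010), tolerance = 0.5)
})

test_that("alignment clusters centroids by relative tolerance", {
  det <- function(mz, area = 1) data.frame(centroid = mz, area = area,
                                           height = 1, snr = 10)
  # identical detections in 2 spectra: one peak, 2 rows
  al <- align_peaks(list(det(c(1000, 2000)), det(c(1000, 2000))))
  expect_equal(nrow(al$peaks), 2)
  expect_equal(dim(al$table), c(2, 2))
  # 5805.0 vs 5805.3 is ~52 ppm: one cluster at 1000 ppm tolerance
  al2 <- align_peaks(list(det(5805.0), det(5805.3)))
  expect_equal(nrow(al2$peaks), 1)
  expect_equal(al2$peaks$ref_mz, 5805.15)
  # 700 vs 710 is ~14000 ppm: two clusters, each present in half the spectra
  al3 <- align_peaks(list(det(700.0), det(710.0)))
  expect_equal(nrow(al3$peaks), 2)
})

test_that("alignment is idempotent on already-aligned labels", {
  ref <- c(887.2, 1263.7, 2210.3, 5805.0)
  det <- lapply(1:3, function(i) data.frame(centroid = ref, area = i,
                                            height = 1, snr = 10))
  first <- align_peaks(det)
  again <- align_peaks(list(data.frame(centroid = first$peaks$ref_mz,
                                       area = 1, height = 1, snr = 10)))
  expect_identical(sprintf("%.1f", again$peaks$ref_mz),
                   sprintf("%.1f", ref))
})

test_that("replicate aggregation averages survivors and applies the TIC rule", {
  mz <- c(1000, 2000)
  m <- matrix(rep(c(1, 2, 3), each = 2), nrow = 3, byrow = TRUE)
  rt <- peak_table(m, mz, rep("BTC", 3),
                   subject_id = rep("S1", 3))
  agg <- aggregate_replicates(rt)
  expect_equal(unname(unclass(agg)[1, ]), c(2, 2))
  expect_equal(attr(agg, "flagged"), character(0))

  # 12 identical replicates: subject row equals any replicate
  rt12 <- peak_table(matrix(5, 12, 2), mz, rep("BTC", 12),
                     subject_id = rep("S1", 12))
  agg12 <- aggregate_replicates(rt12)
  expect_equal(unname(unclass(agg12)[1, ]), c(5, 5))

  # replicate at 10% of the median raw TIC is excluded from the mean
  rt3 <- peak_table(matrix(c(10, 10, 10, 10, 100, 100), 3, 2, byrow = TRUE),
                    mz, rep("BTC", 3), subject_id = rep("S1", 3))
  attr(rt3, "tic_raw") <- c(1, 1, 0.1)
  agg3 <- aggregate_replicates(rt3)
  expect_equal(unname(unclass(agg3)[1, ]), c(10, 10))
  expect_equal(attr(agg3, "flagged"), "S1")  # only 2 survivors

  # unmapped replicate is a sample-sheet error
  sheet <- data.frame(subject_id = "OTHER", group = "BTC")
  expect_error(aggregate_replicates(rt, sheet), "absent")
})

test_that("QC coefficient of variation is computed per peak", {
  expect_error(qc_cv(matrix(1, 1, 3)), ">= 2")
  same <- matrix(4, 5, 3)
  r <- qc_cv(same)
  expect_equal(unname(r$per_peak), c(0, 0, 0))
  expect_equal(r$mean_cv, 0)
  expect_equal(r$sd_cv, 0)
  r2 <- qc_cv(cbind(a = c(9, 10, 11), b = c(0, 0, 0)))
  expect_equal(unname(r2$per_peak[1]), 10.0)
  expect_true(is.na(r2$per_peak[2]))
  expect_equal(r2$n_undefined, 1)
  expect_equal(r2$mean_cv, 10.0)
})

test_that("QC replicates reproduce the inter-assay CV they were given", {
  # repeated measurements of one pooled serum at replicate_cv = 0.128
  spec <- cohort_spec(n_case = 2, n_control = 2, planted = NULL,
                      n_null_peaks = 150, replicate_cv = 0.128,
                      qc_subjects = 24, seed = 17)
  ch <- generate_peak_cohort(spec)
  qc <- subset_rows(ch$table, peak_groups(ch$table) == "QC")
  r <- qc_cv(qc)
  expect_lt(abs(r$mean_cv - 12.8), 3)
})

test_that("normalization is invariant to intensity scaling", {
  sp <- gaussian_spectrum(center = 2500, area = 8, baseline_amp = 0.1,
                          extra_centers = 6000, extra_areas = 3)
  scaled <- raw_spectrum(sp$mz, sp$intensity * 37.5)
  a <- preprocess_spectrum(sp)
  b <- preprocess_spectrum(scaled)
  expect_equal(a$intensity, b$intensity, tolerance = 1e-9)
  pa <- detect_peaks(a); pb <- detect_peaks(b)
  expect_equal(pa$area, pb$area, tolerance = 1e-9)
})

test_that("noiseless spectra round-trip through the whole chain", {
  spec <- cohort_spec(n_case = 3, n_control = 3,
                      planted = btc_reference_effects()[c(3, 8), ],
                      n_null_peaks = 30, replicate_design = c(1, 2),
                      replicate_cv = 0, qc_subjects = 0, seed = 23)
  ch <- generate_peak_cohort(spec)
  tbl <- ch$table
  spectra <- unlist(lapply(seq_len(nrow(tbl)), function(i) {
    generate_raw_spectra(unclass(tbl)[i, ], spec,
                         subject_id = attr(tbl, "subject_id")[i],
                         group = peak_groups(tbl)[i],
                         noise_frac = 0, baseline_frac = 0.02,
                         jitter_frac = 0)
  }), recursive = FALSE)
  aligned <- spectra_to_peak_table(spectra)
  agg <- aggregate_replicates(aligned$table)
  # match recovered peaks to generator truth by nearest m/z (centroids can
  # land a grid step away from the reference label)
  truth_mz <- peak_mz(tbl)
  rec_mz <- peak_mz(agg)
  nearest <- vapply(truth_mz, function(m) which.min(abs(rec_mz - m)),
                    integer(1))
  ok <- abs(rec_mz[nearest] - truth_mz) / truth_mz < 5e-4
  expect_gte(sum(ok), 30)
  for (sid in attr(tbl, "subject_id")) {
    truth <- unclass(tbl)[sid, ok]
    got <- unclass(agg)[sid, nearest[ok]]
    expect_gte(cor(truth, got), 0.99)
  }
})

test_that("spectrum files round-trip through the two-column text format", {
  sp <- gaussian_spectrum(center = 1200, area = 4)
  f <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(sp, f)
  back <- read_spectrum(f, subject_id = "S1", replicate_id = "r1")
  expect_equal(back$mz, sp$mz, tolerance = 1e-6)
  expect_equal(back$intensity, sp$intensity, tolerance = 1e-6)
})
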