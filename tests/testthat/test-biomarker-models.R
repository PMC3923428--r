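# mean BTC / healthy profiles over the model peaks, from the reference panel
btc_profile <- c("5805.0" = 33.0, "1350.8" = 48.3, "2210.3" = 10.9,
                 "2554.5" = 24.8)
healthy_profile <- c("5805.0" = 6.7, "1350.8" = 117.4, "2210.3" = 38.2,
                     "2554.5" = 57.3)

test_that("Model A scores and classifies the published mean profiles", {
  A <- preset_models()$A
  expect_equal(round(score_model(A, btc_profile), 2), 2.53,
               ignore_attr = TRUE)
  expect_equal(round(score_model(A, healthy_profile), 3), 0.026,
               ignore_attr = TRUE)
  expect_equal(unname(classify(A, score_model(A, btc_profile))), "BTC")
  expect_equal(unname(classify(A, score_model(A, healthy_profile))),
               "healthy")
  # a score exactly at the threshold classifies negative
  expect_equal(classify(A, 0.3), "healthy")
})

test_that("the three preset models encode the printed formulas", {
  m <- preset_models()
  expect_equal(m$A$numerator, data.frame(peak = 5805.0, power = 1))
  expect_equal(m$A$denominator$peak, c(1350.8, 2210.3, 2554.5))
  expect_equal(m$A$scale, 1000)
  expect_equal(m$A$threshold, 0.3)
  expect_equal(m$A$transform, "linear")

  expect_equal(m$B$transform, "log")
  expect_equal(m$B$scale, 10)
  expect_equal(m$B$threshold, 5)
  expect_equal(m$B$log_base, 10)
  b_pw <- setNames(c(m$B$numerator$power, m$B$denominator$power),
                   sprintf("%.1f", c(m$B$numerator$peak, m$B$denominator$peak)))
  expect_equal(b_pw[["5805.0"]], 1.25)
  expect_equal(b_pw[["2210.3"]], 1.5)
  expect_equal(b_pw[["2554.5"]], 0.75)
  # alias map: 878 -> 887.2 and 2923 -> 2932.9, recorded on the model
  expect_true(887.2 %in% m$B$numerator$peak)
  expect_equal(unname(m$B$aliases["878"]), 887.2)
  expect_setequal(m$C$denominator$peak, c(2082.1, 2554.5, 2932.9))
  expect_equal(m$C$threshold, 0.4)
})

test_that("scoring is unit-consistent and errors are informative", {
  A <- preset_models()$A
  ones <- setNames(rep(1, 4), names(btc_profile))
  m1 <- ratio_power_model("ones", "linear",
                          numerator = data.frame(peak = 5805.0, power = 1.75),
                          denominator = data.frame(peak = 2210.3, power = -2))
  expect_equal(unname(score_model(m1, ones)), 1.0)
  # aliased/absent peaks refuse to run rather than silently substitute
  expect_error(score_model(preset_models()$B, btc_profile), "887.2")
  expect_error(score_model(A, btc_profile[-1]), "5805.0")
  # log domain errors name the offending subject
  tbl <- rbind(btc_profile, bad = c(0.9, rep(2, 3)))
  rownames(tbl) <- c("good", "bad")
  B <- ratio_power_model("logm", "log",
                         numerator = data.frame(peak = 5805.0, power = 1))
  expect_error(score_model(B, tbl), "bad")
  expect_equal(sum(is.na(score_model(B, tbl, on_domain_error = "na"))), 1)
  # invalid model definitions
  expect_error(ratio_power_model("x", "linear",
                                 numerator = data.frame(peak = 1, power = 3)),
               "\\[-2, 2\\]")
  expect_error(ratio_power_model("x", "linear",
                                 numerator = data.frame(peak = 1, power = 1),
                                 denominator = data.frame(peak = 1, power = 1)),
               "disjoint")
})

test_that("model JSON serialization round-trips losslessly", {
  for (m in preset_models()) {
    f <- tempfile(fileext = ".json")
    write_model(m, f)
    back <- read_model(f)
    expect_equal(unclass(back)[names(unclass(m))], unclass(m),
                 tolerance = 1e-15)
    unlink(f)
  }
})

test_that("confusion metrics reproduce the published quadruples", {
  v <- confusion_metrics(tp = 13, fp = 1, tn = 15, fn = 0)
  expect_equal(c(v$sensitivity, v$specificity, v$ppv, v$npv),
               c(100.0, 93.8, 92.9, 100.0))
  tr <- confusion_metrics(tp = 38, fp = 0, tn = 22, fn = 1)
  expect_equal(c(tr$sensitivity, tr$specificity), c(97.4, 100.0))
  z <- confusion_metrics(tp = 0, fp = 0, tn = 5, fn = 5)
  expect_equal(c(z$sensitivity, z$specificity), c(0, 100))
  expect_true(is.na(z$ppv))
  expect_error(confusion_metrics(-1, 0, 1, 1), "non-negative")
  expect_error(confusion_metrics(0, 0, 0, 0), "both classes")
})

test_that("Model A separates a moment-matched synthetic cohort", {
  ch <- generate_peak_cohort(cohort_spec(seed = 301, qc_subjects = 0))
  A <- preset_models()$A
  perf <- evaluate_model(A, ch$table)
  expect_gte(perf$sensitivity, 90)
  expect_gte(perf$specificity, 90)
  expect_gte(perf$auroc, 0.95)
  expect_length(perf$excluded, 0)
  # threshold below every score: perfectly sensitive, never specific
  low <- A; low$threshold <- 0
  pl <- evaluate_model(low, ch$table)
  expect_equal(c(pl$sensitivity, pl$specificity), c(100, 0))
})

test_that("scores carry no signal on a null cohort", {
  ch <- generate_peak_cohort(cohort_spec(n_case = 25, n_control = 25,
                                         planted = NULL, n_null_peaks = 30,
                                         qc_subjects = 0, seed = 77))
  mz <- peak_mz(ch$table)
  m <- ratio_power_model("null", "linear",
                         numerator = data.frame(peak = mz[1], power = 1),
                         denominator = data.frame(peak = mz[2:3], power = 1),
                         threshold = 1)
  perf <- evaluate_model(m, ch$table)
  expect_lt(abs(perf$auroc - 0.5), 0.15)
})

test_that("the exhaustive search matches an independent brute-force oracle", {
  set.seed(5)
  n <- 16
  tbl <- peak_table(matrix(exp(rnorm(n * 3)), n, 3), c(1000, 2000, 3000),
                    rep(c("BTC", "healthy"), each = n / 2))
  pos <- peak_groups(tbl) == "BTC"
  cfg <- search_config(c(1000, 2000, 3000), max_numerator = 1,
                       max_denominator = 2, transforms = "linear",
                       power_grid = 1)
  got <- search_models(tbl, pos, cfg, top = Inf)

  # oracle: enumerate every (numerator, denominator) split by hand and find
  # the best midpoint threshold by direct evaluation of every cut
  m <- unclass(tbl)
  best_j_oracle <- function(scores) {
    s <- sort(unique(scores))
    if (length(s) < 2) return(0)
    cuts <- (s[-1] + s[-length(s)]) / 2
    max(vapply(cuts, function(t) {
      100 * (mean(scores[pos] > t) + mean(scores[!pos] <= t) - 1)
    }, numeric(1)))
  }
  oracle <- c()
  for (num in 1:3) {
    dens <- list(integer(0))
    for (k in 1:2) dens <- c(dens, combn(setdiff(1:3, num), k,
                                         simplify = FALSE))
    for (den in dens) {
      dp <- if (length(den)) apply(m[, den, drop = FALSE], 1, prod) else 1
      oracle <- c(oracle, best_j_oracle(m[, num] / dp))
    }
  }
  expect_equal(sort(got$j, decreasing = TRUE),
               sort(oracle, decreasing = TRUE)[seq_len(nrow(got))],
               tolerance = 1e-9)
})

test_that("search finds a planted perfect separator and is deterministic", {
  set.seed(8)
  n <- 20
  x <- c(exp(rnorm(n / 2, 5, 0.5)), exp(rnorm(n / 2, 0, 0.5)))  # clean split
  noise <- exp(rnorm(n))
  tbl <- peak_table(cbind(x, noise), c(1111, 2222),
                    rep(c("BTC", "healthy"), each = n / 2))
  cfg <- search_config(c(1111, 2222), transforms = "linear", power_grid = 1,
                       max_denominator = 1)
  r <- search_models(tbl, peak_groups(tbl) == "BTC", cfg)
  expect_equal(r$j[1], 100)
  top <- r$model[[1]]
  expect_equal(top$numerator$peak, 1111)
  expect_equal(nrow(top$denominator), 0)
  r2 <- search_models(tbl, peak_groups(tbl) == "BTC", cfg)
  expect_identical(r[, setdiff(names(r), "model")],
                   r2[, setdiff(names(r2), "model")])
  # enumeration budget guard reports the candidate count
  cfg_big <- search_config(seq(1000, 2200, by = 100), max_denominator = 3,
                           power_grid = seq(-2, 2, 0.25), budget = 1e5)
  expect_error(search_models(tbl, peak_groups(tbl) == "BTC", cfg_big),
               "budget")
})

test_that("returned thresholds are Youden-optimal over all midpoints", {
  ch <- generate_peak_cohort(small_cohort_spec(seed = 41))
  pos <- peak_groups(ch$table) == "BTC"
  cfg <- search_config(btc_reference_effects()$peak_mz[c(2, 3, 8)],
                       transforms = "linear", power_grid = 1)
  r <- search_models(ch$table, pos, cfg, top = 5)
  for (i in seq_len(nrow(r))) {
    mo <- r$model[[i]]
    sc <- score_model(mo, ch$table)
    s <- sort(unique(sc))
    cuts <- (s[-1] + s[-length(s)]) / 2
    j_all <- vapply(cuts, function(t) {
      100 * (mean(sc[pos] > t) + mean(sc[!pos] <= t) - 1)
    }, numeric(1))
    expect_equal(r$j[i], max(j_all), tolerance = 1e-9)
    # no strictly-between threshold beats the returned one
    j_ret <- 100 * (mean(sc[pos] > mo$threshold) +
                      mean(sc[!pos] <= mo$threshold) - 1)
    expect_equal(j_ret, max(j_all), tolerance = 1e-9)
  }
})

test_that("label permutation destroys Model A's performance", {
  ch <- generate_peak_cohort(cohort_spec(seed = 55, qc_subjects = 0))
  A <- preset_models()$A
  sc <- score_model(A, ch$table)
  pred <- sc > A$threshold
  truth <- peak_groups(ch$table) == "BTC"
  drops <- 0
  set.seed(99)
  for (i in 1:100) {
    y <- sample(truth)
    j <- 100 * (mean(pred[y]) + mean(!pred[!y]) - 1)
    if (j < 30) drops <- drops + 1
  }
  expect_gte(drops, 95)
})

test_that("cross-validation schemes behave and are reproducible", {
  # perfectly separated cohort: perfect held-out accuracy
  set.seed(6)
  n <- 24
  x <- c(exp(rnorm(n / 2, 4, 0.3)), exp(rnorm(n / 2, 0, 0.3)))
  tbl <- peak_table(cbind(x, exp(rnorm(n))), c(1500, 2500),
                    rep(c("BTC", "healthy"), each = n / 2))
  m <- ratio_power_model("sep", "linear",
                         numerator = data.frame(peak = 1500, power = 1),
                         threshold = 1)
  cv <- cross_validate(tbl, peak_groups(tbl) == "BTC", "split75",
                       model = m, seed = 3)
  expect_equal(cv$summary$mean[cv$summary$metric == "sensitivity"], 100)
  expect_equal(cv$summary$mean[cv$summary$metric == "specificity"], 100)

  cv2 <- cross_validate(tbl, peak_groups(tbl) == "BTC", "split75",
                        model = m, seed = 3)
  expect_identical(cv$folds, cv2$folds)

  # null cohort: cross-validated J is noise around zero
  ch <- generate_peak_cohort(cohort_spec(n_case = 30, n_control = 30,
                                         planted = NULL, n_null_peaks = 6,
                                         qc_subjects = 0, seed = 13))
  mz <- peak_mz(ch$table)
  mnull <- ratio_power_model("null", "linear",
                             numerator = data.frame(peak = mz[1], power = 1),
                             denominator = data.frame(peak = mz[2], power = 1))
  cvn <- cross_validate(ch$table, peak_groups(ch$table) == "BTC", "locv20",
                        model = mnull, seed = 5)
  expect_lt(abs(cvn$summary$mean[cvn$summary$metric == "youden_j"]), 25)

  # stratification guard
  tiny <- peak_table(matrix(1:8, 4, 2), c(1000, 2000),
                     c("BTC", "BTC", "healthy", "healthy"))
  expect_error(cross_validate(tiny, peak_groups(tiny) == "BTC", "split75",
                              model = m), "stratify")
})

test_that("external classifiers plug in through the hook", {
  ch <- generate_peak_cohort(cohort_spec(seed = 61, qc_subjects = 0))
  hook <- classifier_hook(
    fit = function(table, positive) "5805.0",   # trivial single-peak scorer
    score = function(fitted, table) unclass(table)[, fitted],
    name = "peak-area")
  cv <- cross_validate(ch$table, peak_groups(ch$table) == "BTC", "locv20",
                       model = hook, seed = 9)
  expect_gte(cv$summary$mean[cv$summary$metric == "auroc"], 0.8)
})
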