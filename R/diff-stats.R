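#' Anderson-Darling normality test
#'
#' Case 3 (mean and variance estimated) Anderson-Darling test with the
#' small-sample adjusted statistic `A*^2 = A^2 (1 + 0.75/n + 2.25/n^2)` and
#' the standard piecewise p-value approximation. Used as the gate deciding
#' between the t-test and the Wilcoxon test for each peak.
#'
#' @param x numeric sample, `n >= 5`.
#' @return list with `statistic` (adjusted `A*^2`) and `p_value`.
#' @export
ad_normality <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 5) stop_invalid("Anderson-Darling gate needs n >= 5 (got %d)", n)
  s <- (x - mean(x)) / stats::sd(x)
  # log-scale tail probabilities: immune to underflow and to cancellation
  # in log(1 - Phi) at deep tails
  lz <- stats::pnorm(s, log.p = TRUE)
  luz <- stats::pnorm(s, lower.tail = FALSE, log.p = TRUE)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (lz + rev(luz)))
  AA <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (AA < 0.2) {
    1 - exp(-13.436 + 101.14 * AA - 223.73 * AA^2)
  } else if (AA < 0.34) {
    1 - exp(-8.318 + 42.796 * AA - 59.938 * AA^2)
  } else if (AA < 0.6) {
    exp(0.9177 - 4.279 * AA - 1.38 * AA^2)
  } else if (AA < 10) {
    exp(1.2937 - 5.709 * AA + 0.0186 * AA^2)
  } else {
    3.7e-24
  }
  list(statistic = AA, p_value = p)
}

#' Choose the per-peak test: t or Wilcoxon
#'
#' Applies the Anderson-Darling normality gate to each group's areas. The
#' (Welch) t-test is used only when both groups are compatible with
#' normality (both AD p > 0.05); otherwise the Wilcoxon rank-sum test.
#'
#' @param values_a,values_b numeric samples, each `n >= 5`.
#' @param alpha gate level (default 0.05).
#' @return `"t"` or `"wilcoxon"`.
#' @export
choose_test <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) < 5 || length(values_b) < 5) {
    stop_invalid("choose_test needs n >= 5 per group")
  }
  if (ad_normality(values_a)$p_value > alpha &&
      ad_normality(values_b)$p_value > alpha) "t" else "wilcoxon"
}

#' Fold change between group means
#'
#' @param mean_case,mean_control group mean areas, both `> 0`.
#' @param digits decimals for reporting (default 2).
#' @return `mean_case / mean_control`, rounded.
#' @export
compute_fold_change <- function(mean_case, mean_control, digits = 2) {
  if (any(mean_case <= 0) || any(mean_control <= 0)) {
    stop_invalid("fold change requires positive means")
  }
  round(mean_case / mean_control, digits)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted p-values (same order as input), each `>=` its raw value
#'   and capped at 1.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' AUROC with DeLong standard error and Wald interval
#'
#' Area under the ROC curve as the Mann-Whitney concordance probability
#' (ties count 1/2), oriented so the stochastically larger group scores
#' `>= 0.5`. The standard error is DeLong's placement-based estimator and
#' the 95% interval is `auc +/- 1.96 se`, deliberately not truncated at 1.
#'
#' @param values numeric scores.
#' @param labels logical or two-level vector; `TRUE` (or the second level)
#'   marks the positive class.
#' @param orient force orientation to `>= 0.5` (default TRUE).
#' @return list with `auc`, `se`, `ci95` (length-2), `flipped` (whether
#'   orientation reversed the sign of the comparison).
#' @export
auroc <- function(values, labels, orient = TRUE) {
  if (is.logical(labels)) {
    pos <- labels
  } else {
    lev <- sort(unique(as.character(labels)))
    if (length(lev) != 2) stop_invalid("labels must have exactly two classes")
    pos <- as.character(labels) == lev[2]
  }
  if (all(pos) || !any(pos)) stop_invalid("both classes must be present")
  x <- values[pos]; y <- values[!pos]
  m <- length(x); n <- length(y)
  # placements via midranks: auc = (mean rank of positives - (m+1)/2) / n
  r <- rank(c(x, y), ties.method = "average")
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  flipped <- FALSE
  if (orient && auc < 0.5) {
    x <- -x; y <- -y
    auc <- 1 - auc
    flipped <- TRUE
  }
  # DeLong: V10_i = placement of positive i among negatives, V01_j likewise
  psi <- function(a, b) (sum(b < a) + 0.5 * sum(b == a)) / length(b)
  v10 <- vapply(x, psi, numeric(1), b = y)
  v01 <- vapply(y, function(b) (sum(x > b) + 0.5 * sum(x == b)) / m, numeric(1))
  var_auc <- stats::var(v10) / m + stats::var(v01) / n
  se <- sqrt(var_auc)
  list(auc = auc, se = se, ci95 = wald_ci(auc, se), flipped = flipped)
}

#' Wald 95% confidence interval
#'
#' `estimate +/- 1.96 se`, not truncated (an AUROC upper bound may exceed 1).
#'
#' @param estimate,se point estimate and standard error.
#' @return numeric length-2 `(low, high)`.
#' @export
wald_ci <- function(estimate, se) {
  c(estimate - 1.96 * se, estimate + 1.96 * se)
}

#' Differential screening of all peaks between two groups
#'
#' Per peak: group means and SDs, fold change (group a over group b), the
#' Anderson-Darling-gated two-sided test (Welch t, or Wilcoxon rank-sum:
#' exact for small tie-free samples, else the tie-corrected normal
#' approximation), Benjamini-Hochberg adjustment across
#' all peaks, and the oriented AUROC with DeLong SE and Wald interval.
#'
#' @param table a [peak_table()].
#' @param group_a,group_b group labels present in the table (a is the case
#'   group of the fold-change convention).
#' @param compute_auroc set FALSE to skip ROC statistics (faster screens).
#' @return data.frame sorted by `p_raw` with columns `ref_mz`, `mean_a`,
#'   `sd_a`, `mean_b`, `sd_b`, `fold_change`, `test_used`, `p_raw`,
#'   `p_adj`, `auroc`, `auroc_se`, `ci_low`, `ci_high`.
#' @export
compare_groups <- function(table, group_a = "BTC", group_b = "healthy",
                           compute_auroc = TRUE) {
  grp <- peak_groups(table)
  if (!group_a %in% grp) stop_invalid("group '%s' absent from table", group_a)
  if (!group_b %in% grp) stop_invalid("group '%s' absent from table", group_b)
  a_rows <- grp == group_a
  b_rows <- grp == group_b
  if (sum(a_rows) < 5 || sum(b_rows) < 5) {
    stop_invalid("each group needs n >= 5")
  }
  m <- unclass(table)
  mz <- peak_mz(table)
  res <- lapply(seq_along(mz), function(j) {
    va <- m[a_rows, j]; vb <- m[b_rows, j]
    test <- choose_test(va, vb)
    p <- if (test == "t") {
      stats::t.test(va, vb, var.equal = FALSE)$p.value
    } else {
      # exact null distribution for small tie-free samples, tie-corrected
      # normal approximation otherwise (wilcox.test's default switch)
      suppressWarnings(stats::wilcox.test(va, vb, correct = TRUE)$p.value)
    }
    row <- data.frame(ref_mz = mz[j],
                      mean_a = mean(va), sd_a = stats::sd(va),
                      mean_b = mean(vb), sd_b = stats::sd(vb),
                      fold_change = mean(va) / mean(vb),
                      test_used = test, p_raw = p,
                      auroc = NA_real_, auroc_se = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_)
    if (compute_auroc) {
      roc <- auroc(c(va, vb), c(rep(TRUE, length(va)), rep(FALSE, length(vb))))
      row$auroc <- roc$auc; row$auroc_se <- roc$se
      row$ci_low <- roc$ci95[1]; row$ci_high <- roc$ci95[2]
    }
    row
  })
  res <- do.call(rbind, res)
  res$p_adj <- benjamini_hochberg(res$p_raw)
  res <- res[order(res$p_raw), c("ref_mz", "mean_a", "sd_a", "mean_b", "sd_b",
                                 "fold_change", "test_used", "p_raw", "p_adj",
                                 "auroc", "auroc_se", "ci_low", "ci_high")]
  rownames(res) <- NULL
  res
}

#' Filter differential results to discriminatory peaks
#'
#' Keeps peaks significant at `p_cut` with a two-sided fold change of at
#' least `fc_cut`: `max(FC, 1/FC) >= fc_cut`, so symmetric down-regulation
#' (e.g. FC 0.46, 1/0.46 = 2.17) passes a 2-fold filter. The p-value arm
#' applies to the adjusted p by default.
#'
#' @param results output of [compare_groups()].
#' @param p_cut p-value threshold (default 0.001).
#' @param fc_cut fold-change threshold (default 2.0).
#' @param use_raw_p cut on `p_raw` instead of `p_adj`.
#' @return the surviving rows of `results`.
#' @export
filter_discriminatory <- function(results, p_cut = 0.001, fc_cut = 2.0,
                                  use_raw_p = FALSE) {
  p <- if (use_raw_p) results$p_raw else results$p_adj
  keep <- p < p_cut & pmax(results$fold_change, 1 / results$fold_change) >= fc_cut
  results[keep, , drop = FALSE]
}
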