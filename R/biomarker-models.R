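#' Ratio/power threshold classifier
#'
#' The study's bespoke classifier family: a subject is called positive when
#' `scale * prod(num_area^power) / prod(den_area^power) > threshold`,
#' computed on normalized peak areas (`transform = "linear"`) or with every
#' area replaced by its logarithm (`transform = "log"`, base 10 by
#' default). Powers lie in `[-2, 2]`; numerator and denominator peak sets
#' are disjoint.
#'
#' @param name model name.
#' @param transform `"linear"` or `"log"`.
#' @param numerator,denominator data.frames with columns `peak` (reference
#'   m/z) and `power`; `denominator` may have 0 rows.
#' @param scale positive multiplier applied to the ratio.
#' @param threshold decision threshold; scores strictly above it classify
#'   positive, ties classify negative.
#' @param positive_label,negative_label group labels assigned by
#'   [classify()].
#' @param log_base base for the log transform (default 10).
#' @param aliases optional named numeric vector recording peak-label
#'   aliases applied when the model was encoded (provenance only).
#' @param notes free-text provenance.
#' @return object of class `ratio_power_model`.
#' @export
ratio_power_model <- function(name, transform = c("linear", "log"),
                              numerator, denominator = NULL,
                              scale = 1, threshold = 0,
                              positive_label = "BTC",
                              negative_label = paste0("not-", positive_label),
                              log_base = 10, aliases = NULL, notes = NULL) {
  transform <- match.arg(transform)
  numerator <- as_model_terms(numerator)
  denominator <- as_model_terms(denominator)
  if (nrow(numerator) < 1) stop_invalid("model needs >= 1 numerator peak")
  peaks <- c(numerator$peak, denominator$peak)
  if (anyDuplicated(mz_label(peaks))) {
    stop_invalid("numerator and denominator peak sets must be disjoint")
  }
  pw <- c(numerator$power, denominator$power)
  if (any(pw < -2 | pw > 2)) stop_invalid("powers must lie in [-2, 2]")
  if (!is.numeric(scale) || scale <= 0) stop_invalid("scale must be > 0")
  structure(list(name = name, transform = transform,
                 numerator = numerator, denominator = denominator,
                 scale = scale, threshold = threshold,
                 positive_label = positive_label,
                 negative_label = negative_label,
                 log_base = log_base,
                 aliases = aliases, notes = notes),
            class = "ratio_power_model")
}

as_model_terms <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return(data.frame(peak = numeric(0), power = numeric(0)))
  }
  if (is.numeric(x) && is.null(dim(x))) x <- data.frame(peak = x, power = 1)
  x <- as.data.frame(x)
  if (is.null(x$power)) x$power <- 1
  data.frame(peak = as.numeric(x$peak), power = as.numeric(x$power))
}

#' @export
print.ratio_power_model <- function(x, ...) {
  term <- function(t) {
    if (nrow(t) == 0) return("1")
    paste(sprintf("%s%s%s",
                  if (x$transform == "log") "log " else "", mz_label(t$peak),
                  ifelse(t$power == 1, "", sprintf("^%g", t$power))),
          collapse = " * ")
  }
  cat(sprintf("%s [%s]: %g * (%s) / (%s) > %g  ->  %s\n",
              x$name, x$transform, x$scale, term(x$numerator),
              term(x$denominator), x$threshold, x$positive_label))
  invisible(x)
}

#' Score subjects with a ratio/power model
#'
#' @param model a [ratio_power_model()].
#' @param areas a named numeric vector (one subject) or a matrix /
#'   [peak_table()] with m/z-labelled columns; all model peaks must be
#'   present with area `> 0`, and for `transform = "log"` the logged areas
#'   must also be `> 0`.
#' @param on_domain_error `"error"` (default) or `"na"`: whether a subject
#'   whose logged area is non-positive raises an error or scores `NA`.
#' @return numeric score(s), one per subject.
#' @export
score_model <- function(model, areas, on_domain_error = c("error", "na")) {
  on_domain_error <- match.arg(on_domain_error)
  stopifnot(inherits(model, "ratio_power_model"))
  if (is.null(dim(areas))) areas <- t(as.matrix(areas))
  m <- unclass(as.matrix(areas))
  terms <- rbind(
    data.frame(peak = model$numerator$peak, power = model$numerator$power,
               sign = rep(1, nrow(model$numerator))),
    data.frame(peak = model$denominator$peak, power = model$denominator$power,
               sign = rep(-1, nrow(model$denominator))))
  labels <- mz_label(terms$peak)
  missing <- setdiff(labels, colnames(m))
  if (length(missing)) {
    stop_invalid("model '%s' requires peaks absent from the table: %s",
                 model$name, paste(missing, collapse = ", "))
  }
  v <- m[, labels, drop = FALSE]
  if (any(v <= 0, na.rm = TRUE)) {
    bad <- rownames(m)[apply(v <= 0, 1, any)]
    stop_invalid("non-positive areas for model peaks (subjects: %s)",
                 paste(bad, collapse = ", "))
  }
  if (model$transform == "log") {
    v <- log(v, base = model$log_base)
    if (any(v <= 0)) {
      bad <- rownames(m)[apply(v <= 0, 1, any)]
      if (on_domain_error == "error") {
        stop_invalid("log-transformed area is non-positive for subjects: %s",
                     paste(bad, collapse = ", "))
      }
      v[v <= 0] <- NA
    }
  }
  expo <- terms$power * terms$sign
  scores <- model$scale * exp(log(v) %*% expo)[, 1]
  stats::setNames(scores, rownames(m))
}

#' Classify scores against the model threshold
#'
#' Positive label iff `score > threshold`; a score exactly at the threshold
#' classifies negative.
#'
#' @param model a [ratio_power_model()].
#' @param score numeric score(s) from [score_model()].
#' @return character label(s).
#' @export
classify <- function(model, score) {
  ifelse(score > model$threshold, model$positive_label, model$negative_label)
}

#' The three fixed published models
#'
#' The printed threshold classifiers, encoded exactly as published, on
#' normalized areas:
#' * Model A (BTC vs healthy): `(5805)/(1350*2210*2554)*1000 > 0.3`
#' * Model B (BTC vs benign, log-transformed areas):
#'   `((10*log 878)*log 1350*log 5805^1.25)/(log 2210^1.5*log 2554^0.75) > 5`
#' * Model C (BTC vs all controls): `(5805)/(2082*2554*2923)*1000 > 0.4`
#'
#' The shorthand tokens are resolved to full aligned-peak labels
#' (5805 -> 5805.0, 1350 -> 1350.8, 2210 -> 2210.3, 2554 -> 2554.5,
#' 2082 -> 2082.1) and two tokens that match no reported peak are mapped by
#' an explicit, user-editable alias table: 878 -> 887.2 and 2923 -> 2932.9.
#' Each model records the aliases applied. Models refuse to score a table
#' lacking any resolved peak (no silent substitution).
#'
#' @param log_base base of the log transform used by Model B (default 10;
#'   the published formula does not state one).
#' @param aliases named numeric vector mapping shorthand tokens to aligned
#'   peak m/z.
#' @return named list of three [ratio_power_model()] objects.
#' @export
preset_models <- function(log_base = 10,
                          aliases = c("878" = 887.2, "2923" = 2932.9)) {
  a <- function(tok) if (as.character(tok) %in% names(aliases)) {
    unname(aliases[as.character(tok)])
  } else tok
  list(
    A = ratio_power_model(
      "Model A", "linear",
      numerator = data.frame(peak = 5805.0, power = 1),
      denominator = data.frame(peak = c(1350.8, 2210.3, 2554.5), power = 1),
      scale = 1000, threshold = 0.3,
      positive_label = "BTC", negative_label = "healthy",
      notes = "best single-threshold model, BTC vs healthy"),
    B = ratio_power_model(
      "Model B", "log",
      numerator = data.frame(peak = c(a(878), 1350.8, 5805.0),
                             power = c(1, 1, 1.25)),
      denominator = data.frame(peak = c(2210.3, 2554.5),
                               power = c(1.5, 0.75)),
      scale = 10, threshold = 5, log_base = log_base,
      positive_label = "BTC", negative_label = "benign",
      aliases = aliases["878"],
      notes = "BTC vs benign biliary disease, log-transformed areas"),
    C = ratio_power_model(
      "Model C", "linear",
      numerator = data.frame(peak = 5805.0, power = 1),
      denominator = data.frame(peak = c(2082.1, 2554.5, a(2923)), power = 1),
      scale = 1000, threshold = 0.4,
      positive_label = "BTC", negative_label = "control",
      aliases = aliases["2923"],
      notes = "BTC vs healthy and benign combined"))
}

#' Serialize / deserialize a model as JSON
#'
#' @param model a [ratio_power_model()].
#' @param path file path.
#' @return `read_model` returns a [ratio_power_model()]; round-trips are
#'   lossless.
#' @export
write_model <- function(model, path) {
  x <- unclass(model)
  x$numerator <- lapply(seq_len(nrow(x$numerator)), function(i)
    list(peak = x$numerator$peak[i], power = x$numerator$power[i]))
  x$denominator <- lapply(seq_len(nrow(x$denominator)), function(i)
    list(peak = x$denominator$peak[i], power = x$denominator$power[i]))
  if (!is.null(x$aliases)) x$aliases <- as.list(x$aliases)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  terms <- function(t) if (length(t) == 0) NULL else data.frame(
    peak = vapply(t, function(e) as.numeric(e$peak), numeric(1)),
    power = vapply(t, function(e) as.numeric(e$power), numeric(1)))
  ratio_power_model(x$name, x$transform, terms(x$numerator),
                    terms(x$denominator), x$scale, x$threshold,
                    x$positive_label, x$negative_label,
                    log_base = x$log_base %||% 10,
                    aliases = if (!is.null(x$aliases))
                      unlist(x$aliases) else NULL,
                    notes = x$notes)
}

#' Confusion-matrix performance metrics
#'
#' @param tp,fp,tn,fn non-negative confusion counts; `tp + fn >= 1` and
#'   `tn + fp >= 1`.
#' @param digits decimals for the reported percentages (default 1).
#' @return object of class `model_performance`: counts plus `sensitivity`,
#'   `specificity`, `ppv`, `npv` in percent (NA where a margin is empty)
#'   and `youden_j`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn, digits = 1) {
  if (any(c(tp, fp, tn, fn) < 0)) stop_invalid("counts must be non-negative")
  if (tp + fn < 1 || tn + fp < 1) {
    stop_invalid("both classes must be represented")
  }
  pct <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den,
                                                              digits)
  sens <- pct(tp, tp + fn)
  spec <- pct(tn, tn + fp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 ppv = pct(tp, tp + fp), npv = pct(tn, tn + fn),
                 youden_j = sens + spec - 100,
                 auroc = NA_real_, auroc_se = NA_real_,
                 ci95 = c(NA_real_, NA_real_)),
            class = "model_performance")
}

#' @export
print.model_performance <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d tn=%d fn=%d | sens %.1f%%, spec %.1f%%, ppv %s, npv %s",
              x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity,
              ifelse(is.na(x$ppv), "undef", sprintf("%.1f%%", x$ppv)),
              ifelse(is.na(x$npv), "undef", sprintf("%.1f%%", x$npv))))
  if (!is.na(x$auroc)) {
    cat(sprintf(" | AUROC %.3f (SE %.3f, 95%% CI %.2f-%.2f)",
                x$auroc, x$auroc_se, x$ci95[1], x$ci95[2]))
  }
  cat("\n")
  if (length(x$excluded)) {
    cat("excluded subjects:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate a model on a labelled peak table
#'
#' Scores every subject, classifies against the model threshold, tabulates
#' the confusion matrix against the true labels, and computes the score
#' AUROC with DeLong SE. Subjects whose areas fall outside the model's
#' domain (non-positive log arguments) are excluded from the counts and
#' listed in the returned `excluded` field rather than silently dropped.
#'
#' @param model a [ratio_power_model()] or a classifier hook fit
#'   (see [classifier_hook()]).
#' @param table a [peak_table()].
#' @param truth logical vector (TRUE = positive class) or character labels
#'   compared against `model$positive_label`; defaults to the table's group
#'   labels.
#' @return a `model_performance` with AUROC fields filled and `excluded`.
#' @export
evaluate_model <- function(model, table, truth = NULL) {
  truth <- truth %||% peak_groups(table)
  if (!is.logical(truth)) truth <- truth == model$positive_label
  if (length(truth) != nrow(table)) {
    stop_invalid("truth must have one entry per table row")
  }
  scores <- score_model(model, table, on_domain_error = "na")
  keep <- !is.na(scores)
  excluded <- rownames(unclass(table))[!keep]
  s <- scores[keep]; y <- truth[keep]
  pred <- s > model$threshold
  perf <- confusion_metrics(tp = sum(pred & y), fp = sum(pred & !y),
                            tn = sum(!pred & !y), fn = sum(!pred & y))
  if (length(unique(y)) == 2) {
    roc <- auroc(s, y)
    perf$auroc <- roc$auc; perf$auroc_se <- roc$se; perf$ci95 <- roc$ci95
  }
  perf$excluded <- excluded
  perf
}

# Youden-optimal threshold over midpoints between adjacent distinct sorted
# scores. Returns threshold, J (percent), sens, spec at the optimum.
best_threshold <- function(scores, positive) {
  o <- order(scores)
  s <- scores[o]; y <- positive[o]
  n <- length(s)
  npos <- sum(y); nneg <- n - npos
  distinct <- which(diff(s) > 0)
  if (length(distinct) == 0) {
    return(list(threshold = s[1], j = 0, sensitivity = 0, specificity = 100))
  }
  cum_pos <- cumsum(y)
  cum_neg <- cumsum(!y)
  sens <- 100 * (npos - cum_pos[distinct]) / npos
  spec <- 100 * cum_neg[distinct] / nneg
  j <- sens + spec - 100
  k <- distinct[which.max(j)]
  list(threshold = (s[k] + s[k + 1]) / 2, j = max(j),
       sensitivity = sens[which.max(j)], specificity = spec[which.max(j)])
}

#' Configure an exhaustive ratio/power model search
#'
#' @param candidate_peaks reference m/z values to search over (`>= 2`).
#' @param max_numerator,max_denominator maximum term counts (each `>= 1`;
#'   the denominator may also be empty in any candidate model).
#' @param transforms subset of `c("linear", "log")`.
#' @param power_grid powers tried for every peak; default the arithmetic
#'   grid from -2 to 2 in steps of 0.25.
#' @param budget maximum number of candidate models enumerated (error if
#'   the configuration implies more; default 1e7).
#' @param scale fixed scale applied to every candidate (absorbed by the
#'   threshold; default 1).
#' @param positive_label label predicted above threshold.
#' @return object of class `search_config`.
#' @export
search_config <- function(candidate_peaks, max_numerator = 1,
                          max_denominator = 3,
                          transforms = c("linear", "log"),
                          power_grid = seq(-2, 2, by = 0.25),
                          budget = 1e7, scale = 1,
                          positive_label = "BTC") {
  if (length(candidate_peaks) < 2) stop_invalid("need >= 2 candidate peaks")
  if (max_numerator < 1 || max_denominator < 1) {
    stop_invalid("max term counts must be >= 1")
  }
  if (any(power_grid < -2 | power_grid > 2)) {
    stop_invalid("power grid must lie within [-2, 2]")
  }
  transforms <- match.arg(transforms, several.ok = TRUE)
  structure(list(candidate_peaks = as.numeric(candidate_peaks),
                 max_numerator = max_numerator,
                 max_denominator = max_denominator,
                 transforms = transforms, power_grid = power_grid,
                 budget = budget, scale = scale,
                 positive_label = positive_label),
            class = "search_config")
}

# number of candidate models implied by a search_config
search_size <- function(config) {
  p <- length(config$candidate_peaks)
  g <- length(config$power_grid)
  total <- 0
  for (kn in seq_len(config$max_numerator)) {
    for (kd in 0:config$max_denominator) {
      if (kn + kd > p) next
      total <- total + choose(p, kn) * choose(p - kn, kd) * g^(kn + kd)
    }
  }
  total * length(config$transforms)
}

#' Exhaustive search over ratio/power models
#'
#' Enumerates every disjoint (numerator, denominator) peak-subset pair up
#' to the configured sizes, every per-peak power on the grid, and each
#' transform; for each candidate the threshold maximizing Youden's J over
#' the midpoints between adjacent sorted scores is chosen on the supplied
#' data. Candidates are ranked by J (descending), then fewer total peaks,
#' then higher AUROC, then lexicographic peak labels; output is
#' deterministic for a fixed configuration. Log-transform candidates whose
#' logged areas are not strictly positive for every subject are skipped.
#'
#' @param table a [peak_table()] (columns must include all candidates).
#' @param positive logical vector (TRUE = positive class) or character
#'   labels compared against `config$positive_label`.
#' @param config a [search_config()].
#' @param top number of ranked models to return (default 20).
#' @return data.frame of ranked models with columns `rank`, `model`
#'   (list-column of [ratio_power_model()]), `j`, `sensitivity`,
#'   `specificity`, `auroc`, `n_peaks`, `transform`, `formula`.
#' @export
search_models <- function(table, positive, config, top = 20) {
  stopifnot(inherits(config, "search_config"))
  if (!is.logical(positive)) positive <- positive == config$positive_label
  if (length(positive) != nrow(table)) {
    stop_invalid("positive must have one entry per table row")
  }
  n_cand <- search_size(config)
  if (n_cand > config$budget) {
    stop_invalid("search would enumerate %.0f candidate models (budget %.0f)",
                 n_cand, config$budget)
  }
  labels <- mz_label(config$candidate_peaks)
  missing <- setdiff(labels, colnames(table))
  if (length(missing)) {
    stop_invalid("candidate peaks absent from table: %s",
                 paste(missing, collapse = ", "))
  }
  m <- unclass(table)[, labels, drop = FALSE]
  if (any(m <= 0)) stop_invalid("candidate areas must be > 0")
  base <- list(linear = log(m))
  if ("log" %in% config$transforms) {
    lg <- log(m, base = 10)
    base$log <- if (all(lg > 0)) log(lg) else NULL
  }

  p <- length(config$candidate_peaks)
  grid <- config$power_grid
  results <- list()
  for (transform in config$transforms) {
    X <- base[[transform]]
    if (is.null(X)) next
    for (kn in seq_len(config$max_numerator)) {
      num_sets <- utils::combn(p, kn, simplify = FALSE)
      for (num in num_sets) {
        rest <- setdiff(seq_len(p), num)
        den_sets <- list(integer(0))
        for (kd in seq_len(min(config$max_denominator, length(rest)))) {
          den_sets <- c(den_sets,
                        lapply(utils::combn(length(rest), kd,
                                            simplify = FALSE),
                               function(ix) rest[ix]))
        }
        for (den in den_sets) {
          idx <- c(num, den)
          sgn <- c(rep(1, length(num)), rep(-1, length(den)))
          pw <- expand.grid(rep(list(grid), length(idx)))
          W <- t(as.matrix(pw)) * sgn
          S <- X[, idx, drop = FALSE] %*% W   # log-scores, candidates in cols
          for (ci in seq_len(ncol(S))) {
            sc <- config$scale * exp(S[, ci])
            bt <- best_threshold(sc, positive)
            results[[length(results) + 1L]] <- list(
              num = num, den = den, power = unlist(pw[ci, ]),
              transform = transform, threshold = bt$threshold,
              j = bt$j, sensitivity = bt$sensitivity,
              specificity = bt$specificity, scores = NULL,
              auroc = auroc(sc, positive)$auc,
              n_peaks = length(idx))
          }
        }
      }
    }
  }
  if (length(results) == 0) stop_invalid("no admissible candidate models")
  key <- vapply(results, function(r) {
    paste(mz_label(config$candidate_peaks[c(r$num, r$den)]), collapse = ",")
  }, character(1))
  ord <- order(-vapply(results, `[[`, numeric(1), "j"),
               vapply(results, `[[`, numeric(1), "n_peaks"),
               -vapply(results, `[[`, numeric(1), "auroc"),
               key)
  results <- results[ord][seq_len(min(top, length(results)))]
  models <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    ratio_power_model(
      name = sprintf("search_%03d", i), transform = r$transform,
      numerator = data.frame(peak = config$candidate_peaks[r$num],
                             power = r$power[seq_along(r$num)]),
      denominator = if (length(r$den)) data.frame(
        peak = config$candidate_peaks[r$den],
        power = r$power[length(r$num) + seq_along(r$den)]) else NULL,
      scale = config$scale, threshold = r$threshold,
      positive_label = config$positive_label)
  })
  data.frame(
    rank = seq_along(results),
    j = vapply(results, `[[`, numeric(1), "j"),
    sensitivity = vapply(results, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(results, `[[`, numeric(1), "specificity"),
    auroc = vapply(results, `[[`, numeric(1), "auroc"),
    n_peaks = vapply(results, `[[`, numeric(1), "n_peaks"),
    transform = vapply(results, `[[`, character(1), "transform"),
    formula = vapply(models, function(mo)
      utils::capture.output(print(mo))[1], character(1)),
    model = I(models))
}

#' Pluggable external classifier hook
#'
#' Adapter letting any external learner take the place of a ratio/power
#' model in [cross_validate()]: supply a `fit(table, positive)` function
#' returning a fitted object and a `score(fitted, table)` function
#' returning numeric scores (higher = more case-like). The decision
#' threshold is set on the training scores by Youden's J. This is the
#' extension point for third-party panels (e.g. the published 9-peak SVM),
#' which this package does not reimplement.
#'
#' @param fit function `(table, positive) -> fitted`.
#' @param score function `(fitted, table) -> numeric`.
#' @param name label used in reports.
#' @return object of class `classifier_hook`.
#' @export
classifier_hook <- function(fit, score, name = "external") {
  stopifnot(is.function(fit), is.function(score))
  structure(list(fit = fit, score = score, name = name),
            class = "classifier_hook")
}

#' Cross-validate a model or model search
#'
#' Two schemes mirroring the study's internal validation design:
#' `"split75"` makes `permutations` (default 5) seeded stratified 75/25
#' train/test splits, fits on the training portion and evaluates on the
#' held-out 25%; `"locv20"` runs `iterations` (default 10) rounds each
#' holding out a random stratified 20%. Fitting means: a full
#' [search_models()] run when `config` is given; re-selection of the Youden
#' threshold for a fixed [ratio_power_model()]; or `fit`/`score` for a
#' [classifier_hook()].
#'
#' @param table a [peak_table()].
#' @param positive logical (TRUE = positive) or character labels.
#' @param scheme `"split75"` or `"locv20"`.
#' @param model a [ratio_power_model()] or [classifier_hook()]
#'   (threshold/score refit per fold), or NULL when `config` is given.
#' @param config a [search_config()] to rerun the search per fold.
#' @param permutations,iterations fold counts for the two schemes.
#' @param seed root seed; fold assignments derive deterministically from it.
#' @return list with `folds` (per-fold data.frame: sensitivity,
#'   specificity, ppv, npv, youden_j, auroc, n_test) and `summary`
#'   (mean and sd of each metric), plus the scheme and seed used.
#' @export
cross_validate <- function(table, positive, scheme = c("split75", "locv20"),
                           model = NULL, config = NULL,
                           permutations = 5, iterations = 10, seed = 1) {
  scheme <- match.arg(scheme)
  pos_label <- if (!is.null(model) && inherits(model, "ratio_power_model")) {
    model$positive_label
  } else if (!is.null(config)) config$positive_label else "BTC"
  if (!is.logical(positive)) positive <- positive == pos_label
  if (is.null(model) && is.null(config)) {
    stop_invalid("supply a model or a search config")
  }
  test_frac <- if (scheme == "split75") 0.25 else 0.20
  n_folds <- if (scheme == "split75") permutations else iterations
  idx_pos <- which(positive); idx_neg <- which(!positive)
  n_test_pos <- round(test_frac * length(idx_pos))
  n_test_neg <- round(test_frac * length(idx_neg))
  if (n_test_pos < 1 || n_test_neg < 1 ||
      n_test_pos >= length(idx_pos) || n_test_neg >= length(idx_neg)) {
    stop_invalid("a group is too small to stratify a %.0f%% holdout",
                 100 * test_frac)
  }
  folds <- lapply(seq_len(n_folds), function(f) {
    test <- with_seed(derive_seed(seed, sprintf("%s-fold-%d", scheme, f)), {
      c(sample(idx_pos, n_test_pos), sample(idx_neg, n_test_neg))
    })
    train_tbl <- subset_rows(table, setdiff(seq_len(nrow(table)), test))
    test_tbl <- subset_rows(table, test)
    y_train <- positive[setdiff(seq_len(nrow(table)), test)]
    y_test <- positive[test]
    fitted <- if (!is.null(config)) {
      search_models(train_tbl, y_train, config, top = 1)$model[[1]]
    } else if (inherits(model, "classifier_hook")) {
      fit_obj <- model$fit(train_tbl, y_train)
      tr_scores <- model$score(fit_obj, train_tbl)
      thr <- best_threshold(tr_scores, y_train)$threshold
      list(obj = fit_obj, threshold = thr)
    } else {
      m2 <- model
      tr_scores <- score_model(m2, train_tbl, on_domain_error = "na")
      ok <- !is.na(tr_scores)
      m2$threshold <- best_threshold(tr_scores[ok], y_train[ok])$threshold
      m2
    }
    perf <- if (inherits(model %||% fitted, "classifier_hook")) {
      sc <- model$score(fitted$obj, test_tbl)
      pred <- sc > fitted$threshold
      pf <- confusion_metrics(sum(pred & y_test), sum(pred & !y_test),
                              sum(!pred & !y_test), sum(!pred & y_test))
      if (length(unique(y_test)) == 2) {
        roc <- auroc(sc, y_test)
        pf$auroc <- roc$auc; pf$auroc_se <- roc$se; pf$ci95 <- roc$ci95
      }
      pf
    } else {
      evaluate_model(fitted, test_tbl, truth = y_test)
    }
    data.frame(fold = f, sensitivity = perf$sensitivity,
               specificity = perf$specificity, ppv = perf$ppv,
               npv = perf$npv, youden_j = perf$youden_j,
               auroc = perf$auroc, n_test = length(test))
  })
  folds <- do.call(rbind, folds)
  metrics <- c("sensitivity", "specificity", "ppv", "npv", "youden_j", "auroc")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(k) mean(folds[[k]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metrics, function(k) stats::sd(folds[[k]][!is.na(folds[[k]])]),
                numeric(1)))
  rownames(summary) <- NULL
  list(scheme = scheme, seed = seed, folds = folds, summary = summary)
}
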