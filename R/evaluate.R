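as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- !labels %in% c("healthy", "cancer")
    if (any(bad)) stop("character labels must be 'healthy' or 'cancer'")
    labels <- as.integer(labels == "cancer")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  labels
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic from midranks, so
#' tied scores are credited 0.5 per tied positive-negative pair.
#'
#' @param scores Numeric vector; higher values should indicate the positive
#'   class.
#' @param labels Binary labels (0/1, logical, or `"healthy"`/`"cancer"` with
#'   cancer positive).
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))  # 0.75
#' @export
auroc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The D statistic is the supremum absolute difference between the two
#' empirical CDFs; the p-value comes from the standard asymptotic two-sample
#' distribution.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with elements `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("inputs must be non-empty")
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(res$statistic), p = unname(res$p.value))
}

#' One-sided Mann-Whitney U test
#'
#' Tests the alternative that `greater` is stochastically larger than
#' `lesser`. Small tie-free samples use the exact null distribution;
#' otherwise the tie-corrected normal approximation applies.
#'
#' @param greater,lesser Non-empty numeric vectors.
#' @return One-sided p-value.
#' @export
mwu_one_sided <- function(greater, lesser) {
  if (length(greater) == 0L || length(lesser) == 0L)
    stop("inputs must be non-empty")
  suppressWarnings(
    stats::wilcox.test(greater, lesser, alternative = "greater")$p.value
  )
}

#' Robustness check of a dysregulation summary across noise levels
#'
#' A metric is robust if (i) at the 1.0x (null) noise level its replicate
#' summaries are consistent with the metric's no-dysregulation null — the
#' replicate mean lies within `null_tol` of `null_value` and a two-sided
#' one-sample t-test does not reject at `alpha` — and (ii) the summary
#' increases monotonically with noise, confirmed by one-sided Mann-Whitney U
#' tests (p < `alpha`) between each pair of successive levels.
#'
#' @param summaries_by_level Named list of numeric replicate summaries, one
#'   entry per noise multiplier, names coercible to the multiplier values;
#'   must include the 1.0 level and at least 2 replicates per level.
#'   Non-finite summaries are dropped with a warning.
#' @param null_value The metric's expected summary under no dysregulation.
#' @param alpha Significance level (default 0.01).
#' @param null_tol Half-width of the tolerance band around `null_value`
#'   (default 0.1).
#' @return List with logical elements `null_ok` and `monotone_ok`, plus the
#'   per-step MWU p-values (`monotone_p`) and the null-level mean
#'   (`null_mean`).
#' @export
robustness_check <- function(summaries_by_level, null_value, alpha = 0.01,
                             null_tol = 0.1) {
  levels_num <- as.numeric(names(summaries_by_level))
  if (any(is.na(levels_num)))
    stop("names of 'summaries_by_level' must be the noise multipliers")
  ord <- order(levels_num)
  levels_num <- levels_num[ord]
  vals <- lapply(summaries_by_level[ord], function(v) {
    v <- as.numeric(v)
    if (any(!is.finite(v))) {
      warning("non-finite summaries dropped from robustness testing")
      v <- v[is.finite(v)]
    }
    v
  })
  if (!any(levels_num == 1.0)) stop("the 1.0x (null) noise level is required")
  if (length(vals) < 2L || any(vapply(vals, length, 1L) < 2L))
    stop("need at least 2 noise levels with at least 2 replicates each")
  base <- vals[[which(levels_num == 1.0)]]
  null_mean <- mean(base)
  in_band <- abs(null_mean - null_value) <= null_tol
  p_null <- if (stats::sd(base) == 0) {
    if (null_mean == null_value) 1 else 0
  } else {
    stats::t.test(base, mu = null_value)$p.value
  }
  null_ok <- in_band && p_null >= alpha
  monotone_p <- vapply(seq_len(length(vals) - 1L), function(i) {
    mwu_one_sided(vals[[i + 1L]], vals[[i]])
  }, numeric(1))
  names(monotone_p) <- paste(levels_num[-length(levels_num)],
                             levels_num[-1], sep = "->")
  list(null_ok = null_ok, monotone_ok = all(monotone_p < alpha),
       monotone_p = monotone_p, null_mean = null_mean, null_p = p_null)
}

# Feature values for train/test splits; reference-dependent features
# (regulation score, distances) are computed against the TRAINING healthy
# samples only, mirroring how the scorer is deployed.
compute_feature <- function(feature_id, train, test, min_healthy = 10,
                            ridge = 0) {
  tr <- train$values
  te <- test$values
  if (feature_id %in% c("gene1", "gene2")) {
    j <- if (feature_id == "gene1") 1 else 2
    return(list(train = tr[, j, drop = FALSE], test = te[, j, drop = FALSE]))
  }
  if (feature_id == "product")
    return(list(train = cbind(tr[, 1] * tr[, 2]),
                test = cbind(te[, 1] * te[, 2])))
  if (feature_id == "ratio") {
    if (any(tr[, 2] == 0) || any(te[, 2] == 0))
      stop("gene2 contains zeros; expression ratio undefined")
    return(list(train = cbind(tr[, 1] / tr[, 2]),
                test = cbind(te[, 1] / te[, 2])))
  }
  if (feature_id == "expression")
    return(list(train = tr, test = te))
  healthy_train <- cohort_subset(train, "healthy")
  if (feature_id == "regulation_score") {
    fit <- kdereg(healthy_train, min_healthy = min_healthy)
    return(list(train = cbind(predict(fit, tr)),
                test = cbind(predict(fit, te))))
  }
  list(train = cbind(sample_distance(feature_id, healthy_train, tr,
                                     ridge = ridge)),
       test = cbind(sample_distance(feature_id, healthy_train, te,
                                    ridge = ridge)))
}

fit_logistic_auroc <- function(feat_train, y_train, feat_test, y_test) {
  df_tr <- as.data.frame(feat_train)
  names(df_tr) <- paste0("f", seq_len(ncol(df_tr)))
  df_te <- as.data.frame(feat_test)
  names(df_te) <- names(df_tr)
  df_tr$y <- y_train
  fit <- suppressWarnings(
    stats::glm(y ~ ., family = stats::binomial(), data = df_tr)
  )
  p <- suppressWarnings(
    stats::predict(fit, newdata = df_te, type = "response")
  )
  auroc(p, y_test)
}

#' Stratified k-fold cross-validated classification of cohort status
#'
#' Splits the labeled samples into stratified folds; within each fold the
#' healthy-reference model (KDE regulation score, or distance reference) is
#' fitted on the TRAINING healthy samples only and applied to both splits,
#' so the reference is always independent of the held-out data. A logistic
#' regression on the single feature (or on the raw two-gene pair for the
#' `"expression"` baseline) is fitted on the training split and evaluated by
#' AUROC on the held-out fold.
#'
#' @param x A [gene_pair_matrix] containing healthy- and cancer-labeled
#'   samples (unknown-labeled samples are ignored).
#' @param feature_id One of `"regulation_score"`, `"gene1"`, `"gene2"`,
#'   `"product"` (gene1 x gene2), `"ratio"` (gene1 / gene2),
#'   `"expression"` (both genes), or a distance metric id
#'   (`"manhattan"`, `"euclidean"`, `"chebyshev"`, `"cosine"`,
#'   `"mahalanobis"`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling the fold assignment.
#' @param min_healthy Minimum training healthy samples per fold for KDE
#'   fitting.
#' @param ridge Mahalanobis covariance ridge.
#' @return A list of class `kdereg_cv`: `feature_id`, `fold_auroc`
#'   (length-k), `mean_auroc`, `k`, `seed`.
#' @export
cross_validate <- function(x, feature_id = "regulation_score", k = 5,
                           seed = 1L, min_healthy = 10, ridge = 0) {
  feature_id <- match.arg(feature_id, FEATURE_IDS)
  stopifnot(inherits(x, "gene_pair_matrix"))
  labeled <- which(x$cohort %in% c("healthy", "cancer"))
  x <- x[labeled]
  y <- as_binary_labels(x$cohort)
  if (sum(y == 1) < k || sum(y == 0) < k)
    stop(sprintf("each class needs at least k = %d samples", k))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold_auroc <- vapply(seq_len(k), function(f) {
    tr <- x[fold != f]
    te <- x[fold == f]
    feats <- compute_feature(feature_id, tr, te, min_healthy = min_healthy,
                             ridge = ridge)
    fit_logistic_auroc(feats$train, as_binary_labels(tr$cohort),
                       feats$test, as_binary_labels(te$cohort))
  }, numeric(1))
  structure(list(feature_id = feature_id, fold_auroc = fold_auroc,
                 mean_auroc = mean(fold_auroc), k = k, seed = seed),
            class = "kdereg_cv")
}

#' @export
print.kdereg_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV, feature '%s': mean AUROC %.4f (folds: %s)\n",
              x$k, x$feature_id, x$mean_auroc,
              paste(sprintf("%.3f", x$fold_auroc), collapse = " ")))
  invisible(x)
}

# Per-replicate KDE cohort summary: dysregulation ratio
# (1 - mean cancer score) / (1 - mean healthy score), null 1, oriented so
# more dysregulation > 1.
kde_cohort_summary <- function(fit, healthy_test, cancer_test) {
  s_h <- predict(fit, healthy_test)
  s_c <- predict(fit, cancer_test)
  (1 - mean(s_c)) / (1 - mean(s_h))
}

#' Run the synthetic benchmark end-to-end
#'
#' For every (shape, noise multiplier, replicate) condition: generates
#' independent training and testing cohort pairs, fits the KDE regulation
#' model on the training healthy samples, and records (a) the cohort-level
#' dysregulation summary of the KDE score and of each comparator metric on
#' the test cohorts, and (b) held-out AUROC of a logistic classifier on each
#' sample-level feature (trained on the training cohorts, evaluated on the
#' test cohorts). Robustness flags per (shape, metric) then apply
#' [robustness_check()] across noise levels.
#'
#' @param config A [benchmark_config()].
#' @param sample_features Sample-level features to classify with; default
#'   the KDE score plus all distance metrics.
#' @param cohort_metrics Cohort-level comparator metrics to include (set to
#'   `character(0)` to skip); the KDE summary is always included as metric
#'   `"regulation_score"`.
#' @param alpha,null_tol Robustness-test parameters (see
#'   [robustness_check()]).
#' @param verbose Print progress per condition.
#' @return A list of class `kdereg_benchmark`: `config`, `summaries` (one
#'   row per condition x cohort metric), `aurocs` (one row per condition x
#'   sample feature), `robustness` (per shape x metric flags).
#' @export
run_benchmark <- function(config = benchmark_config(),
                          sample_features = c("regulation_score",
                                              DISTANCE_METRICS),
                          cohort_metrics = COHORT_METRICS,
                          alpha = 0.01, null_tol = 0.1, verbose = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  summaries <- list()
  aurocs <- list()
  for (shape in config$shapes) {
    for (mult in config$noise_levels) {
      if (verbose)
        message(sprintf("benchmark: %s x %.1f (%d replicates)", shape, mult,
                        config$replicates))
      for (rep_i in seq_len(config$replicates)) {
        train <- simulate_condition(config, shape, mult, rep_i, role = "train")
        test <- simulate_condition(config, shape, mult, rep_i, role = "test")
        fit <- kdereg(train$healthy)
        summaries[[length(summaries) + 1L]] <- data.frame(
          shape = shape, multiplier = mult, replicate = rep_i,
          metric_id = "regulation_score",
          summary = kde_cohort_summary(fit, test$healthy, test$cancer),
          null_value = 1, stringsAsFactors = FALSE)
        for (metric in cohort_metrics) {
          r <- cohort_metric(metric, test$healthy, test$cancer)
          summaries[[length(summaries) + 1L]] <- data.frame(
            shape = shape, multiplier = mult, replicate = rep_i,
            metric_id = metric, summary = r$summary,
            null_value = r$null_value, stringsAsFactors = FALSE)
        }
        if (length(sample_features) > 0L) {
          tr_all <- bind_cohorts(train$healthy, train$cancer)
          te_all <- bind_cohorts(test$healthy, test$cancer)
          y_tr <- as_binary_labels(tr_all$cohort)
          y_te <- as_binary_labels(te_all$cohort)
          for (feat in sample_features) {
            feats <- compute_feature(feat, tr_all, te_all)
            aurocs[[length(aurocs) + 1L]] <- data.frame(
              shape = shape, multiplier = mult, replicate = rep_i,
              feature_id = feat,
              auroc = fit_logistic_auroc(feats$train, y_tr, feats$test,
                                         y_te),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  summaries <- do.call(rbind, summaries)
  aurocs <- if (length(aurocs)) do.call(rbind, aurocs) else NULL
  robustness <- benchmark_robustness(summaries, alpha = alpha,
                                     null_tol = null_tol)
  structure(list(config = config, summaries = summaries, aurocs = aurocs,
                 robustness = robustness),
            class = "kdereg_benchmark")
}

benchmark_robustness <- function(summaries, alpha = 0.01, null_tol = 0.1) {
  rows <- list()
  for (shape in unique(summaries$shape)) {
    for (metric in unique(summaries$metric_id)) {
      sub <- summaries[summaries$shape == shape &
                         summaries$metric_id == metric, ]
      # robustness needs >= 2 noise levels and >= 2 replicates per level
      if (nrow(sub) == 0L || length(unique(sub$multiplier)) < 2L ||
          min(table(sub$multiplier)) < 2L) next
      by_level <- split(sub$summary, sub$multiplier)
      chk <- suppressWarnings(
        robustness_check(by_level, null_value = sub$null_value[1],
                         alpha = alpha, null_tol = null_tol)
      )
      rows[[length(rows) + 1L]] <- data.frame(
        shape = shape, metric_id = metric, null_ok = chk$null_ok,
        monotone_ok = chk$monotone_ok,
        max_monotone_p = max(chk$monotone_p), null_mean = chk$null_mean,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.kdereg_benchmark <- function(x, ...) {
  cat(sprintf("synthetic benchmark: %d shapes x %d noise levels x %d %s\n",
              length(x$config$shapes), length(x$config$noise_levels),
              x$config$replicates, "replicates"))
  cat("robustness flags (null behavior at 1.0x, monotone rise with noise):\n")
  print(x$robustness, row.names = FALSE)
  if (!is.null(x$aurocs)) {
    agg <- stats::aggregate(auroc ~ feature_id + multiplier, data = x$aurocs,
                            FUN = mean)
    cat("mean held-out AUROC by feature and noise level:\n")
    print(agg, row.names = FALSE)
  }
  invisible(x)
}
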