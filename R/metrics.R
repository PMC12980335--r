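# Equal-frequency binned mutual information (base 2). Equal-frequency
# binning keeps the estimate invariant under strictly monotone per-gene
# transforms; ties can collapse quantile breaks, in which case fewer bins
# are used.
binned_mi <- function(x, y, bins = 8) {
  bx <- unique(stats::quantile(x, seq(0, 1, length.out = bins + 1), type = 7,
                               names = FALSE))
  by <- unique(stats::quantile(y, seq(0, 1, length.out = bins + 1), type = 7,
                               names = FALSE))
  if (length(bx) < 3 || length(by) < 3)
    stop("too few distinct values for equal-frequency binning")
  cx <- cut(x, bx, include.lowest = TRUE)
  cy <- cut(y, by, include.lowest = TRUE)
  joint <- table(cx, cy) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  outer_p <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
}

# Jensen-Shannon divergence (base 2, in [0, 1]) between the 2-D histograms
# of two cohorts on a shared grid spanning the pooled range.
hist2d_probs <- function(values, bx, by) {
  cx <- cut(values[, 1], bx, include.lowest = TRUE)
  cy <- cut(values[, 2], by, include.lowest = TRUE)
  table(cx, cy) / nrow(values)
}

jsd_2d <- function(a, b, bins = 16) {
  pooled1 <- range(c(a[, 1], b[, 1]))
  pooled2 <- range(c(a[, 2], b[, 2]))
  bx <- seq(pooled1[1], pooled1[2], length.out = bins + 1)
  by <- seq(pooled2[1], pooled2[2], length.out = bins + 1)
  if (diff(pooled1) == 0) bx <- pooled1[1] + c(-1, 1)
  if (diff(pooled2) == 0) by <- pooled2[1] + c(-1, 1)
  p <- as.numeric(hist2d_probs(a, bx, by))
  q <- as.numeric(hist2d_probs(b, bx, by))
  m <- (p + q) / 2
  kl <- function(u, v) {
    nz <- u > 0
    sum(u[nz] * log2(u[nz] / v[nz]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

pc1_variance_fraction <- function(values) {
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0)) stop("constant gene column; PCA variance undefined")
  v <- stats::prcomp(values, center = TRUE, scale. = TRUE)$sdev^2
  v[1] / sum(v)
}

coef_variation <- function(values) {
  mu <- colMeans(values)
  if (any(mu == 0)) stop("zero mean expression; CV undefined")
  mean(apply(values, 2, stats::sd) / abs(mu))
}

#' Cohort-level dysregulation metric
#'
#' Computes one of the comparator metrics on a healthy and a cancer cohort
#' and summarizes dysregulation as a ratio (or, for the Jensen-Shannon
#' divergence, the divergence itself). Summaries are oriented so that more
#' dysregulation pushes the value above its null: correlation-type metrics
#' (Pearson, Spearman, canonical correlation, mutual information, PCA
#' variance) report healthy/cancer since noise weakens them in the cancer
#' cohort; the coefficient of variation reports cancer/healthy since noise
#' inflates it. The no-dysregulation null is 1 for every ratio metric and 0
#' for the divergence.
#'
#' @param metric_id One of `"mutual_information"`, `"canonical_correlation"`,
#'   `"pearson"`, `"spearman"`, `"pca_variance"`,
#'   `"coefficient_of_variation"`, `"js_divergence"`.
#' @param healthy,cancer [gene_pair_matrix] cohorts (all samples are used).
#' @param min_n Minimum per-cohort size (default 20).
#' @param mi_bins Bins per axis for the equal-frequency MI estimator.
#' @param jsd_bins Bins per axis for the shared JSD histogram grid.
#' @param null_value Override of the metric's no-dysregulation null.
#' @return A list of class `cohort_metric`: `metric_id`, `healthy_value`,
#'   `cancer_value` (both `NA` for `js_divergence`), `summary`,
#'   `null_value`. A zero denominator yields a non-finite summary with a
#'   warning rather than an error so benchmark sweeps can flag and skip it.
#' @export
cohort_metric <- function(metric_id, healthy, cancer, min_n = 20,
                          mi_bins = 8, jsd_bins = 16, null_value = NULL) {
  metric_id <- match.arg(metric_id, COHORT_METRICS)
  stopifnot(inherits(healthy, "gene_pair_matrix"),
            inherits(cancer, "gene_pair_matrix"))
  if (n_samples(healthy) < min_n || n_samples(cancer) < min_n)
    stop(sprintf("both cohorts need at least %d samples", min_n))
  hv <- healthy$values
  cv <- cancer$values
  per_cohort <- switch(metric_id,
    pearson = function(v) stats::cor(v[, 1], v[, 2], method = "pearson"),
    spearman = function(v) stats::cor(v[, 1], v[, 2], method = "spearman"),
    canonical_correlation =
      function(v) abs(stats::cor(v[, 1], v[, 2], method = "pearson")),
    mutual_information = function(v) binned_mi(v[, 1], v[, 2], mi_bins),
    pca_variance = pc1_variance_fraction,
    coefficient_of_variation = coef_variation,
    js_divergence = NULL
  )
  if (metric_id == "js_divergence") {
    summ <- jsd_2d(hv, cv, jsd_bins)
    h_val <- c_val <- NA_real_
    null_v <- if (is.null(null_value)) 0 else null_value
  } else {
    h_val <- per_cohort(hv)
    c_val <- per_cohort(cv)
    summ <- if (metric_id == "coefficient_of_variation") {
      if (h_val == 0) NaN else c_val / h_val
    } else if (metric_id %in% c("pearson", "spearman")) {
      if (abs(c_val) == 0) NaN else abs(h_val) / abs(c_val)
    } else {
      if (c_val == 0) NaN else h_val / c_val
    }
    if (!is.finite(summ))
      warning(sprintf("%s: zero denominator; summary is non-finite and %s",
                      metric_id, "should be excluded from robustness testing"))
    null_v <- if (is.null(null_value)) 1 else null_value
  }
  structure(list(metric_id = metric_id, healthy_value = h_val,
                 cancer_value = c_val, summary = summ, null_value = null_v),
            class = "cohort_metric")
}

#' @export
print.cohort_metric <- function(x, ...) {
  cat(sprintf("%s: summary=%.4g (null %.3g)", x$metric_id, x$summary,
              x$null_value))
  if (!is.na(x$healthy_value))
    cat(sprintf(" [healthy=%.4g cancer=%.4g]", x$healthy_value,
                x$cancer_value))
  cat("\n")
  invisible(x)
}

#' Sample-level distance to a healthy reference
#'
#' Distances from each query sample to the reference cohort: Manhattan,
#' Euclidean and Chebyshev distances to the reference centroid; cosine
#' distance (1 - cosine similarity) to the centroid direction; or the
#' Mahalanobis distance `sqrt((x - mu)' Sigma^-1 (x - mu))` using the
#' reference mean and covariance.
#'
#' @param metric_id One of `"manhattan"`, `"euclidean"`, `"chebyshev"`,
#'   `"cosine"`, `"mahalanobis"`.
#' @param reference A [gene_pair_matrix] (or n x 2 matrix) of reference
#'   samples, n >= 3.
#' @param queries Query samples ([gene_pair_matrix] or n x 2 matrix).
#' @param ridge Non-negative value added to the covariance diagonal when the
#'   reference covariance is singular (Mahalanobis only).
#' @return Length-n non-negative vector of distances.
#' @export
sample_distance <- function(metric_id, reference, queries, ridge = 0) {
  metric_id <- match.arg(metric_id, DISTANCE_METRICS)
  ref <- as_points(reference)
  if (nrow(ref) < 3L) stop("reference needs at least 3 samples")
  pts <- as_points(queries)
  mu <- colMeans(ref)
  d1 <- pts[, 1] - mu[1]
  d2 <- pts[, 2] - mu[2]
  switch(metric_id,
    manhattan = abs(d1) + abs(d2),
    euclidean = sqrt(d1^2 + d2^2),
    chebyshev = pmax(abs(d1), abs(d2)),
    cosine = {
      nmu <- sqrt(sum(mu^2))
      npt <- sqrt(pts[, 1]^2 + pts[, 2]^2)
      if (nmu == 0 || any(npt == 0))
        stop("cosine distance undefined at the zero vector")
      pmax(0, 1 - (pts[, 1] * mu[1] + pts[, 2] * mu[2]) / (npt * nmu))
    },
    mahalanobis = {
      S <- stats::cov(ref) + diag(ridge, 2)
      if (is_singular_2x2(S))
        stop("singular reference covariance; supply a ridge > 0")
      sqrt(stats::mahalanobis(pts, mu, S))
    }
  )
}

#' All cohort metrics as a data frame
#'
#' Convenience sweep over every cohort-level comparator metric.
#'
#' @inheritParams cohort_metric
#' @return A data frame with one row per metric: `metric_id`,
#'   `healthy_value`, `cancer_value`, `summary`, `null_value`.
#' @export
cohort_metric_table <- function(healthy, cancer, min_n = 20, mi_bins = 8,
                                jsd_bins = 16) {
  rows <- lapply(COHORT_METRICS, function(id) {
    r <- cohort_metric(id, healthy, cancer, min_n = min_n, mi_bins = mi_bins,
                       jsd_bins = jsd_bins)
    data.frame(metric_id = r$metric_id, healthy_value = r$healthy_value,
               cancer_value = r$cancer_value, summary = r$summary,
               null_value = r$null_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
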