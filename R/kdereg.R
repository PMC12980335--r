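#' Interquartile-range kernel bandwidth
#'
#' Computes the per-gene kernel bandwidth `h = 2 * IQR * m^(-1/3)` from a
#' vector of `m` reference expression values. Quantiles use the
#' linear-interpolation (type 7) convention.
#'
#' @param values Numeric vector of at least 2 finite values.
#' @return A positive bandwidth in the units of `values`.
#' @examples
#' compute_bandwidth(c(0, 1, 2, 3, 4, 5, 6, 7))  # IQR = 3.5, m = 8
#' @export
compute_bandwidth <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values)))
    stop("'values' must be at least 2 finite numbers")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr <= 0)
    stop("IQR is zero (constant or near-constant data); ",
         "supply a manual bandwidth via the 'bandwidths' argument")
  2 * iqr * length(values)^(-1 / 3)
}

#' Fit a healthy-reference KDE regulation model
#'
#' Fits a bivariate Gaussian product-kernel density estimate to the healthy
#' samples of a two-gene cohort and calibrates the density scale so that the
#' median healthy sample maps to a regulation score of 0.5: the density
#' threshold is the median of the densities evaluated at the reference
#' points themselves (midpoint of the two central order statistics for even
#' m), so exactly half of an even-sized reference cohort falls in the
#' high-density region at or above the threshold.
#'
#' Per-gene bandwidths come from [compute_bandwidth()] (`2 * IQR * m^(-1/3)`);
#' the density at a query `(x, y)` is
#' `1/(m * h1 * h2) * sum_i dnorm((x - x_i)/h1) * dnorm((y - y_i)/h2)`.
#' The score floor `density_min` is fixed at 0 (the infimum of a Gaussian
#' KDE) and `density_max` is the maximum reference-point density, so scoring
#' new cohorts never depends on the query data.
#'
#' @param healthy A [gene_pair_matrix] (its `"healthy"`-labeled samples are
#'   used; if no sample is labeled, all samples are treated as the healthy
#'   reference) or a plain n x 2 numeric matrix of healthy expression.
#' @param bandwidths Optional length-2 positive numeric overriding the
#'   IQR-based bandwidths (needed when a gene's IQR is 0).
#' @param min_healthy Minimum required reference size (default 10).
#' @return An object of class `kdereg` with elements `reference_points`,
#'   `bandwidths`, `kernel`, `kde_threshold`, `density_min`, `density_max`,
#'   `gene_names`, `n_reference`.
#' @examples
#' set.seed(1)
#' x <- cbind(OGT = rnorm(60, 10, 2), OGA = rnorm(60, 10, 2))
#' fit <- kdereg(x)
#' summary(fit)
#' @export
kdereg <- function(healthy, bandwidths = NULL, min_healthy = 10) {
  if (inherits(healthy, "gene_pair_matrix")) {
    gene_names <- healthy$gene_names
    ref <- if (any(healthy$cohort == "healthy"))
      healthy$values[healthy$cohort == "healthy", , drop = FALSE]
    else healthy$values
  } else {
    ref <- as.matrix(healthy)
    gene_names <- colnames(ref)
    if (is.null(gene_names)) gene_names <- c("gene1", "gene2")
  }
  if (ncol(ref) != 2L) stop("healthy reference must have exactly 2 columns")
  if (!all(is.finite(ref))) stop("healthy reference must be finite")
  m <- nrow(ref)
  if (m < min_healthy)
    stop(sprintf("need at least %d healthy reference samples, got %d",
                 min_healthy, m))
  if (is.null(bandwidths)) {
    bandwidths <- c(compute_bandwidth(ref[, 1]), compute_bandwidth(ref[, 2]))
  } else {
    bandwidths <- as.numeric(bandwidths)
    if (length(bandwidths) != 2L || any(!is.finite(bandwidths)) ||
        any(bandwidths <= 0))
      stop("'bandwidths' must be two positive numbers")
  }
  model <- structure(
    list(reference_points = unname(ref), bandwidths = bandwidths,
         kernel = "gaussian_product", kde_threshold = NA_real_,
         density_min = 0, density_max = NA_real_,
         gene_names = as.character(gene_names), n_reference = m),
    class = "kdereg"
  )
  ref_density <- evaluate_density(model, ref)
  model$kde_threshold <- stats::median(ref_density)
  model$density_max <- max(ref_density)
  if (model$density_max <= model$kde_threshold)
    stop("degenerate calibration: maximum reference density equals the ",
         "threshold; the reference cohort has no high-density structure")
  model
}

#' Evaluate the fitted KDE at query points
#'
#' @param model A fitted [kdereg] model.
#' @param points An n x 2 numeric matrix of query expression values.
#' @return Length-n non-negative vector of density values
#'   (units: 1 / (expression unit)^2).
#' @export
evaluate_density <- function(model, points) {
  stopifnot(inherits(model, "kdereg"))
  points <- as_points(points)
  if (!all(is.finite(points))) stop("query points must be finite")
  ref <- model$reference_points
  h1 <- model$bandwidths[1]
  h2 <- model$bandwidths[2]
  kx <- stats::dnorm(outer(points[, 1], ref[, 1], "-") / h1)
  ky <- stats::dnorm(outer(points[, 2], ref[, 2], "-") / h2)
  rowSums(kx * ky) / (nrow(ref) * h1 * h2)
}

as_points <- function(points) {
  if (inherits(points, "gene_pair_matrix")) return(points$values)
  points <- as.matrix(points)
  if (is.vector(points)) points <- matrix(points, ncol = 2)
  if (ncol(points) != 2L) stop("query points must have exactly 2 columns")
  storage.mode(points) <- "double"
  points
}

#' Map densities to regulation scores
#'
#' Piecewise-linear map from density to a score in `[0, 1]`, continuous at
#' the calibration threshold: densities at the threshold score 0.5, the
#' density floor (0) scores 0, and the maximum reference density scores 1;
#' queries denser than any training reference clamp to 1.
#'
#' @param model A fitted [kdereg] model.
#' @param density Numeric vector of non-negative densities.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
density_to_score <- function(model, density) {
  stopifnot(inherits(model, "kdereg"))
  thr <- model$kde_threshold
  dmin <- model$density_min
  dmax <- model$density_max
  if (!is.finite(thr) || dmax <= thr || thr <= dmin)
    stop("degenerate calibration: density_min < kde_threshold < density_max ",
         "is required for scoring")
  s <- ifelse(density <= thr,
              0.5 * (density - dmin) / (thr - dmin),
              0.5 + 0.5 * (density - thr) / (dmax - thr))
  pmin(pmax(s, 0), 1)
}

#' Score samples against a fitted regulation model
#'
#' @param object A fitted [kdereg] model.
#' @param newdata A [gene_pair_matrix] or n x 2 matrix of query expression.
#'   Defaults to the model's own reference points.
#' @param type `"score"` (default) for regulation scores in `[0, 1]`,
#'   `"density"` for raw KDE densities.
#' @param ... Unused.
#' @return Numeric vector, one value per query sample.
#' @export
predict.kdereg <- function(object, newdata = NULL,
                           type = c("score", "density"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$reference_points
  d <- evaluate_density(object, newdata)
  if (type == "density") d else density_to_score(object, d)
}

#' Regulation scores for a set of samples
#'
#' Convenience wrapper around [predict.kdereg()] returning scores in `[0, 1]`.
#' Scores at or above 0.5 indicate density at or above the healthy median
#' (well-regulated); scores near 0 indicate strong dysregulation.
#'
#' @inheritParams predict.kdereg
#' @param model A fitted [kdereg] model.
#' @param points Query samples ([gene_pair_matrix] or n x 2 matrix).
#' @return Numeric vector of regulation scores.
#' @export
regulation_score <- function(model, points) {
  predict(model, points, type = "score")
}

#' @export
print.kdereg <- function(x, ...) {
  cat(sprintf("kdereg model: %s / %s, %d healthy reference samples\n",
              x$gene_names[1], x$gene_names[2], x$n_reference))
  cat(sprintf("bandwidths: h1=%.6g h2=%.6g (2*IQR*m^(-1/3))\n",
              x$bandwidths[1], x$bandwidths[2]))
  cat(sprintf("density threshold (median reference density): %.6g\n",
              x$kde_threshold))
  cat(sprintf("density range for scoring: [%.6g, %.6g]\n",
              x$density_min, x$density_max))
  invisible(x)
}

#' @export
summary.kdereg <- function(object, ...) {
  ref_scores <- predict(object)
  out <- list(model = object,
              reference_score_summary = summary(ref_scores),
              frac_at_or_above_half = mean(ref_scores >= 0.5))
  class(out) <- "summary.kdereg"
  out
}

#' @export
print.summary.kdereg <- function(x, ...) {
  print(x$model)
  cat("reference regulation scores:\n")
  print(x$reference_score_summary)
  cat(sprintf("fraction of reference samples scoring >= 0.5: %.3f\n",
              x$frac_at_or_above_half))
  invisible(x)
}

#' @export
coef.kdereg <- function(object, ...) {
  c(h1 = object$bandwidths[1], h2 = object$bandwidths[2],
    kde_threshold = object$kde_threshold,
    density_min = object$density_min, density_max = object$density_max)
}

#' Contour plot of the fitted healthy density
#'
#' @param x A fitted [kdereg] model.
#' @param grid_size Grid resolution per axis.
#' @param expand Fraction by which to expand the reference range.
#' @param ... Passed to [graphics::contour()].
#' @export
plot.kdereg <- function(x, grid_size = 80, expand = 0.15, ...) {
  ref <- x$reference_points
  rx <- range(ref[, 1]); ry <- range(ref[, 2])
  rx <- rx + c(-1, 1) * expand * diff(rx)
  ry <- ry + c(-1, 1) * expand * diff(ry)
  gx <- seq(rx[1], rx[2], length.out = grid_size)
  gy <- seq(ry[1], ry[2], length.out = grid_size)
  grid <- as.matrix(expand.grid(gx, gy))
  z <- matrix(evaluate_density(x, grid), grid_size, grid_size)
  graphics::contour(gx, gy, z, xlab = x$gene_names[1],
                    ylab = x$gene_names[2], ...)
  graphics::points(ref, pch = 16, cex = 0.5,
                   col = grDevices::adjustcolor("steelblue", 0.6))
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Writes all model components (reference points, bandwidths, threshold,
#' density bounds, gene names, tool version) to a single JSON document so a
#' model fitted on one cohort can be applied to external cohorts.
#'
#' @param model A fitted [kdereg] model.
#' @param path Output path for the JSON file.
#' @return Invisibly, the path written.
#' @export
write_kdereg <- function(model, path) {
  stopifnot(inherits(model, "kdereg"))
  doc <- list(
    tool = "kdereg",
    version = as.character(utils::packageVersion("kdereg")),
    gene_names = model$gene_names,
    kernel = model$kernel,
    bandwidths = model$bandwidths,
    kde_threshold = model$kde_threshold,
    density_min = model$density_min,
    density_max = model$density_max,
    n_reference = model$n_reference,
    reference_points = model$reference_points
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a fitted model from JSON
#'
#' @param path Path to a JSON file written by [write_kdereg()].
#' @return A [kdereg] model.
#' @export
read_kdereg <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- matrix(as.numeric(doc$reference_points), ncol = 2)
  structure(
    list(reference_points = ref,
         bandwidths = as.numeric(doc$bandwidths),
         kernel = doc$kernel,
         kde_threshold = as.numeric(doc$kde_threshold),
         density_min = as.numeric(doc$density_min),
         density_max = as.numeric(doc$density_max),
         gene_names = as.character(doc$gene_names),
         n_reference = as.integer(doc$n_reference)),
    class = "kdereg"
  )
}
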