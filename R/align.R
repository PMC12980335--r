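lower_chol <- function(S, ridge = 0, label = "covariance") {
  S <- S + diag(ridge, nrow(S))
  if (is_singular_2x2(S))
    stop(sprintf("singular %s; supply a ridge > 0", label), call. = FALSE)
  t(chol(S))
}

# Relative determinant test: a numerically rank-1 covariance can still pass
# chol(), so compare det against the variance scale.
is_singular_2x2 <- function(S) {
  !is.finite(det(S)) || det(S) <= 1e-12 * abs(S[1, 1] * S[2, 2])
}

#' Fit a covariance-based joint-distribution alignment
#'
#' Computes the affine transform `x -> A (x - mu_src) + mu_ref` that maps
#' the source cohort's two-gene mean and covariance onto the reference
#' cohort's, with `A = L_ref L_src^-1` built from the lower-triangular
#' Cholesky factors of the two covariance matrices (whiten, then recolor).
#' The transform preserves within-cohort expression relationships while
#' aligning the joint distribution across datasets, so a regulation model
#' fitted on the reference cohort can score the aligned source cohort
#' without refitting.
#'
#' @param source,reference [gene_pair_matrix] cohorts (or n x 2 matrices),
#'   each with at least 3 samples.
#' @param use `"all"` (default) fits the moments on every sample of each
#'   cohort; `"healthy"` restricts both to their healthy-labeled samples
#'   (the same single transform is then applied to all samples). The choice
#'   is recorded in the returned object.
#' @param ridge Non-negative value added to the covariance diagonals when a
#'   covariance is singular.
#' @return An object of class `pair_alignment` with the means, covariances,
#'   mixing matrix `A`, its inverse, and the `use` mode.
#' @export
fit_alignment <- function(source, reference, use = c("all", "healthy"),
                          ridge = 0) {
  use <- match.arg(use)
  pick <- function(x) {
    if (use == "healthy") {
      if (!inherits(x, "gene_pair_matrix"))
        stop("use = 'healthy' requires gene_pair_matrix inputs")
      x <- cohort_subset(x, "healthy")
    }
    as_points(x)
  }
  src <- pick(source)
  ref <- pick(reference)
  if (nrow(src) < 3L || nrow(ref) < 3L)
    stop("both cohorts need at least 3 samples")
  mu_s <- colMeans(src)
  mu_r <- colMeans(ref)
  S_s <- stats::cov(src)
  S_r <- stats::cov(ref)
  L_s <- lower_chol(S_s, ridge, "source covariance")
  L_r <- lower_chol(S_r, ridge, "reference covariance")
  A <- L_r %*% solve(L_s)
  structure(
    list(source_mean = mu_s, reference_mean = mu_r,
         source_cov = S_s, reference_cov = S_r,
         mixing_matrix = A, mixing_inverse = solve(A), use = use),
    class = "pair_alignment"
  )
}

#' Apply (or invert) a fitted alignment
#'
#' @param transform A [fit_alignment()] result.
#' @param points Samples to transform ([gene_pair_matrix] or n x 2 matrix).
#' @param inverse If `TRUE`, apply the inverse map (reference -> source
#'   space).
#' @return Transformed points in the same container type as the input.
#' @export
apply_alignment <- function(transform, points, inverse = FALSE) {
  stopifnot(inherits(transform, "pair_alignment"))
  pts <- as_points(points)
  out <- if (inverse) {
    sweep(pts, 2, transform$reference_mean) %*% t(transform$mixing_inverse)
  } else {
    sweep(pts, 2, transform$source_mean) %*% t(transform$mixing_matrix)
  }
  out <- sweep(out, 2,
               if (inverse) transform$source_mean else transform$reference_mean,
               "+")
  if (inherits(points, "gene_pair_matrix")) {
    gene_pair_matrix(out, gene_names = points$gene_names,
                     sample_ids = points$sample_ids, cohort = points$cohort)
  } else {
    out
  }
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("covariance alignment (fit on %s samples)\n",
              if (x$use == "all") "all" else "healthy-only"))
  cat("mixing matrix A (source -> reference):\n")
  print(x$mixing_matrix)
  cat(sprintf("mean shift: (%.4g, %.4g) -> (%.4g, %.4g)\n",
              x$source_mean[1], x$source_mean[2],
              x$reference_mean[1], x$reference_mean[2]))
  invisible(x)
}

alignment_to_list <- function(x) {
  list(use = x$use,
       source_mean = x$source_mean, reference_mean = x$reference_mean,
       source_cov = x$source_cov, reference_cov = x$reference_cov,
       mixing_matrix = x$mixing_matrix)
}
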