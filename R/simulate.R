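default_shape_params <- function(shape, driver_mean) {
  switch(shape,
    linear = list(slope = 1.0, intercept = 0.0),
    exponential = list(rate = 0.35, scale = 0.05),
    parabolic = list(curvature = 0.25, vertex = driver_mean),
    multicluster = list(
      centers = matrix(c(7, 8, 10, 12, 13, 8), ncol = 2, byrow = TRUE),
      weights = c(1, 1, 1) / 3,
      cluster_sd = 0.8),
    stop(sprintf("unknown shape '%s'", shape))
  )
}

#' Specification of one synthetic two-gene cohort
#'
#' Describes the generative law of a simulated cohort: a driver gene
#' (gene1) marginal, a regulatory response shape for gene2, and additive
#' Gaussian noise whose standard deviation is `base_noise_sd *
#' noise_multiplier`. The cancer-like conditions of the benchmark use
#' multipliers 1.0 (none), 1.5 (moderate) and 2.0 (high) against a healthy
#' cohort fixed at 1.0.
#'
#' Default shapes (overridable through `shape_params`):
#' \itemize{
#'   \item linear: `gene2 = slope * gene1 + intercept` (slope 1, intercept 0)
#'   \item exponential: `gene2 = scale * exp(rate * gene1)` (rate 0.35,
#'     scale 0.05)
#'   \item parabolic: `gene2 = curvature * (gene1 - vertex)^2`
#'     (curvature 0.25, vertex at the driver mean)
#'   \item multicluster: a 3-component Gaussian mixture; gene1 is drawn
#'     around the cluster x-centers with fixed spread `cluster_sd`, and
#'     gene2 is the cluster y-center plus the scaled noise, so only the
#'     response spread grows with the multiplier and the gene1 marginal is
#'     identical across multipliers.
#' }
#'
#' @param shape One of `"linear"`, `"exponential"`, `"parabolic"`,
#'   `"multicluster"`.
#' @param driver_mean,driver_sd Gene1 marginal (Normal); defaults 10 and 2.
#' @param shape_params Named list of shape coefficients; missing entries
#'   take the documented defaults.
#' @param base_noise_sd Healthy residual noise SD (default 1).
#' @param noise_multiplier Noise inflation factor (>= 1).
#' @param n_samples Cohort size (default 200).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return An object of class `shape_spec`.
#' @export
shape_spec <- function(shape = c("linear", "exponential", "parabolic",
                                 "multicluster"),
                       driver_mean = 10, driver_sd = 2,
                       shape_params = list(), base_noise_sd = 1.0,
                       noise_multiplier = 1.0, n_samples = 200, seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(base_noise_sd > 0, noise_multiplier >= 1, n_samples >= 2,
            driver_sd > 0)
  params <- default_shape_params(shape, driver_mean)
  params[names(shape_params)] <- shape_params
  if (shape == "multicluster") {
    if (abs(sum(params$weights) - 1) > 1e-8)
      stop("multicluster weights must sum to 1")
    if (nrow(params$centers) != length(params$weights))
      stop("one weight per cluster center is required")
  }
  structure(
    list(shape = shape, driver_mean = driver_mean, driver_sd = driver_sd,
         shape_params = params, base_noise_sd = base_noise_sd,
         noise_multiplier = noise_multiplier,
         n_samples = as.integer(n_samples), seed = as.integer(seed)),
    class = "shape_spec"
  )
}

shape_function <- function(spec) {
  p <- spec$shape_params
  switch(spec$shape,
    linear = function(x) p$slope * x + p$intercept,
    exponential = function(x) p$scale * exp(p$rate * x),
    parabolic = function(x) p$curvature * (x - p$vertex)^2,
    multicluster = NULL
  )
}

#' Simulate one two-gene cohort
#'
#' Draws gene1 from the driver distribution and gene2 as the shape function
#' of gene1 plus Normal noise with SD `base_noise_sd * noise_multiplier`
#' (for the multicluster shape, a Gaussian mixture whose response spread is
#' scaled by the multiplier). The gene1 stream is drawn before the noise
#' stream, so cohorts sharing a seed have identical gene1 marginals across
#' multipliers.
#'
#' @param spec A [shape_spec()].
#' @param cohort Label applied to every sample (default `"unknown"`).
#' @param id_prefix Prefix for generated sample identifiers.
#' @return A [gene_pair_matrix] with genes named `"gene1"`, `"gene2"`.
#' @examples
#' x <- simulate_gene_pair(shape_spec("linear", n_samples = 50, seed = 7))
#' @export
simulate_gene_pair <- function(spec, cohort = "unknown", id_prefix = "sim") {
  stopifnot(inherits(spec, "shape_spec"))
  n <- spec$n_samples
  noise_sd <- spec$base_noise_sd * spec$noise_multiplier
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  if (spec$shape == "multicluster") {
    p <- spec$shape_params
    k <- sample.int(nrow(p$centers), n, replace = TRUE, prob = p$weights)
    x <- stats::rnorm(n, p$centers[k, 1], p$cluster_sd)
    eps <- stats::rnorm(n, 0, noise_sd)
    y <- p$centers[k, 2] + eps
  } else {
    x <- stats::rnorm(n, spec$driver_mean, spec$driver_sd)
    eps <- stats::rnorm(n, 0, noise_sd)
    y <- shape_function(spec)(x) + eps
  }
  gene_pair_matrix(cbind(gene1 = x, gene2 = y),
                   sample_ids = sprintf("%s_%04d", id_prefix, seq_len(n)),
                   cohort = rep(cohort, n))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Deterministic 31-bit seed from a master seed and a tuple of labels
# (polynomial rolling hash; keeps derived seeds valid R integers).
derive_seed <- function(master, ...) {
  parts <- paste(c(master, ...), collapse = "|")
  codes <- utf8ToInt(parts)
  h <- as.double(master %% 2147483647)
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Benchmark configuration over shapes, noise levels and replicates
#'
#' @param shapes Character vector of shape names.
#' @param noise_levels Ascending noise multipliers, must include 1.0;
#'   defaults to the benchmark's 1.0 / 1.5 / 2.0 grading.
#' @param replicates Simulations per condition (default 100).
#' @param n_healthy,n_cancer Cohort sizes (default 200 each).
#' @param master_seed Master seed; per-(shape, multiplier, replicate,
#'   cohort) seeds are derived deterministically by hashing the tuple, so
#'   any replicate can be regenerated in isolation.
#' @param base_noise_sd,driver_mean,driver_sd Generator parameters shared
#'   by all shapes.
#' @param shape_params Optional named list (by shape) of shape-parameter
#'   overrides.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(shapes = c("linear", "exponential", "parabolic",
                                        "multicluster"),
                             noise_levels = c(1.0, 1.5, 2.0),
                             replicates = 100, n_healthy = 200,
                             n_cancer = 200, master_seed = 1L,
                             base_noise_sd = 1.0, driver_mean = 10,
                             driver_sd = 2, shape_params = list()) {
  noise_levels <- sort(as.numeric(noise_levels))
  if (!any(noise_levels == 1.0))
    stop("noise_levels must include the 1.0 (null) level")
  stopifnot(replicates >= 1, n_healthy >= 2, n_cancer >= 2)
  structure(
    list(shapes = shapes, noise_levels = noise_levels,
         replicates = as.integer(replicates),
         n_healthy = as.integer(n_healthy), n_cancer = as.integer(n_cancer),
         master_seed = as.integer(master_seed),
         base_noise_sd = base_noise_sd, driver_mean = driver_mean,
         driver_sd = driver_sd, shape_params = shape_params),
    class = "benchmark_config"
  )
}

condition_spec <- function(config, shape, multiplier, replicate, cohort,
                           role = "train") {
  n <- if (cohort == "healthy") config$n_healthy else config$n_cancer
  shape_spec(
    shape = shape, driver_mean = config$driver_mean,
    driver_sd = config$driver_sd,
    shape_params = if (!is.null(config$shape_params[[shape]]))
      config$shape_params[[shape]] else list(),
    base_noise_sd = config$base_noise_sd,
    noise_multiplier = if (cohort == "healthy") 1.0 else multiplier,
    n_samples = n,
    seed = derive_seed(config$master_seed, shape, multiplier, replicate,
                       cohort, role)
  )
}

#' Generate the healthy/cancer cohort pair for one benchmark condition
#'
#' The healthy cohort is always generated at multiplier 1.0; the cancer
#' cohort at the requested multiplier. Seeds are derived from the
#' configuration's master seed and the (shape, multiplier, replicate,
#' cohort, role) tuple, so any replicate regenerated alone is identical to
#' the same replicate within a full run.
#'
#' @param config A [benchmark_config()].
#' @param shape Shape name present in `config$shapes`.
#' @param multiplier Noise multiplier present in `config$noise_levels`.
#' @param replicate Replicate index in `1:config$replicates`.
#' @param role Free-text stream tag (e.g. `"train"` / `"test"`) letting one
#'   replicate carry independent training and testing cohorts.
#' @return List with elements `healthy` and `cancer`, each a
#'   [gene_pair_matrix] labeled accordingly.
#' @export
simulate_condition <- function(config, shape, multiplier, replicate,
                               role = "train") {
  stopifnot(inherits(config, "benchmark_config"))
  if (!shape %in% config$shapes)
    stop(sprintf("shape '%s' not in the configuration", shape))
  if (!multiplier %in% config$noise_levels)
    stop(sprintf("multiplier %s not in the configuration", multiplier))
  if (replicate < 1 || replicate > config$replicates)
    stop("replicate index out of range")
  list(
    healthy = simulate_gene_pair(
      condition_spec(config, shape, multiplier, replicate, "healthy", role),
      cohort = "healthy", id_prefix = paste0("h", replicate)),
    cancer = simulate_gene_pair(
      condition_spec(config, shape, multiplier, replicate, "cancer", role),
      cohort = "cancer", id_prefix = paste0("c", replicate))
  )
}

#' Merge two cohorts into one labeled matrix
#'
#' @param a,b [gene_pair_matrix] objects with the same gene names.
#' @return A [gene_pair_matrix] stacking the samples of `a` then `b`.
#' @export
bind_cohorts <- function(a, b) {
  stopifnot(inherits(a, "gene_pair_matrix"), inherits(b, "gene_pair_matrix"))
  if (!identical(a$gene_names, b$gene_names))
    stop("cohorts must share gene names")
  ids_b <- b$sample_ids
  clash <- ids_b %in% a$sample_ids
  if (any(clash)) ids_b[clash] <- paste0(ids_b[clash], "_b")
  gene_pair_matrix(rbind(a$values, b$values), gene_names = a$gene_names,
                   sample_ids = c(a$sample_ids, ids_b),
                   cohort = c(a$cohort, b$cohort))
}
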