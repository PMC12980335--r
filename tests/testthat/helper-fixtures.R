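# Shared fixtures: small cohorts built in code.

make_healthy_cohort <- function(n = 60, seed = 42, rho = 0.6) {
  set.seed(seed)
  x <- rnorm(n, 10, 2)
  y <- rho * x + rnorm(n, 0, 1) + 4
  gene_pair_matrix(cbind(OGT = x, OGA = y),
                   cohort = rep("healthy", n))
}

make_mixed_cohort <- function(n_h = 60, n_c = 40, seed = 43, shift = 0) {
  set.seed(seed)
  xh <- rnorm(n_h, 10, 2)
  yh <- 0.6 * xh + rnorm(n_h, 0, 1) + 4
  xc <- rnorm(n_c, 10, 2)
  yc <- 0.6 * xc + rnorm(n_c, 0, 2) + 4 + shift
  gene_pair_matrix(cbind(OGT = c(xh, xc), OGA = c(yh, yc)),
                   cohort = rep(c("healthy", "cancer"), c(n_h, n_c)))
}

# A kdereg object with hand-set calibration constants, for closed-form
# score/density checks independent of the fitting path.
manual_model <- function(reference, bandwidths, threshold = NULL,
                         dmax = NULL) {
  structure(
    list(reference_points = as.matrix(reference),
         bandwidths = bandwidths, kernel = "gaussian_product",
         kde_threshold = if (is.null(threshold)) 1 else threshold,
         density_min = 0,
         density_max = if (is.null(dmax)) 2 else dmax,
         gene_names = c("gene1", "gene2"),
         n_reference = nrow(as.matrix(reference))),
    class = "kdereg")
}

write_fixture_table <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
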