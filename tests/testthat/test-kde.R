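test_that("bandwidth follows 2 * IQR * m^(-1/3) with type-7 quantiles", {
  # equally spaced m = 8 values with step 2/7 have type-7 IQR exactly 1
  vals <- seq(0, by = 2 / 7, length.out = 8)
  expect_equal(compute_bandwidth(vals), 2 * 1 * 8^(-1 / 3))
  expect_equal(compute_bandwidth(vals), 1.0)

  # homogeneity: scaling the data scales the bandwidth
  set.seed(5)
  v <- rnorm(37)
  expect_equal(compute_bandwidth(3.7 * v), 3.7 * compute_bandwidth(v))

  expect_error(compute_bandwidth(rep(2, 4)), "IQR")
  expect_error(compute_bandwidth(c(1, NA, 2)), "finite")
})

test_that("density matches the closed form for a single reference point", {
  m <- manual_model(matrix(c(0, 0), 1, 2), bandwidths = c(1, 1))
  expect_equal(evaluate_density(m, matrix(c(0, 0), 1, 2)), 1 / (2 * pi),
               tolerance = 1e-12)
  # Gaussian tails: a query 12+ bandwidths away has vanishing density
  expect_lt(evaluate_density(m, matrix(c(12, 12), 1, 2)), 1e-10)
  # symmetry: references symmetric about the origin score equally
  m2 <- manual_model(matrix(c(-1, 1, -2, 2), 2, 2), bandwidths = c(1, 1))
  d <- evaluate_density(m2, matrix(c(-1, 1, -2, 2), 2, 2))
  expect_equal(d[1], d[2], tolerance = 1e-14)
})

test_that("vectorized density equals the naive double-loop oracle", {
  set.seed(11)
  ref <- cbind(rnorm(50, 10, 2), rnorm(50, 8, 1.5))
  h <- c(compute_bandwidth(ref[, 1]), compute_bandwidth(ref[, 2]))
  m <- manual_model(ref, bandwidths = h)
  pts <- cbind(rnorm(50, 10, 3), rnorm(50, 8, 3))
  oracle <- numeric(nrow(pts))
  for (j in seq_len(nrow(pts))) {
    acc <- 0
    for (i in seq_len(nrow(ref))) {
      acc <- acc + dnorm((pts[j, 1] - ref[i, 1]) / h[1]) *
        dnorm((pts[j, 2] - ref[i, 2]) / h[2])
    }
    oracle[j] <- acc / (nrow(ref) * h[1] * h[2])
  }
  expect_equal(evaluate_density(m, pts), oracle, tolerance = 1e-10)
})

test_that("the fitted density integrates to one over a wide grid", {
  x <- make_healthy_cohort(80)
  fit <- kdereg(x)
  rx <- range(x$values[, 1]) + c(-8, 8) * fit$bandwidths[1]
  ry <- range(x$values[, 2]) + c(-8, 8) * fit$bandwidths[2]
  gx <- seq(rx[1], rx[2], length.out = 220)
  gy <- seq(ry[1], ry[2], length.out = 220)
  z <- evaluate_density(fit, as.matrix(expand.grid(gx, gy)))
  integral <- sum(z) * diff(gx)[1] * diff(gy)[1]
  expect_equal(integral, 1, tolerance = 0.01)
})

test_that("fitting calibrates the threshold to the median reference density", {
  x <- make_healthy_cohort(60)  # even m
  fit <- kdereg(x)
  d <- evaluate_density(fit, x$values)
  expect_equal(fit$kde_threshold, median(d))
  expect_equal(fit$density_min, 0)
  expect_equal(fit$density_max, max(d))
  # exactly half the (even) reference cohort is at or above the threshold
  expect_equal(mean(d >= fit$kde_threshold), 0.5)
  # the median reference score sits at 0.5 up to the branch-slope difference
  # of the piecewise map (exact for odd m, where the middle sample IS the
  # threshold)
  expect_equal(median(predict(fit)), 0.5, tolerance = 0.02)
  odd <- kdereg(x[1:59])
  expect_equal(median(predict(odd)), 0.5)
  # refitting is deterministic
  expect_identical(fit, kdereg(x))
  expect_error(kdereg(x$values[1:5, ]), "at least 10")
})

test_that("scores implement the piecewise-linear map with clamping", {
  m <- manual_model(matrix(c(0, 0), 1, 2), bandwidths = c(1, 1),
                    threshold = 2, dmax = 4)
  d <- c(0, 1, 2, 3, 4, 5)
  expect_equal(density_to_score(m, d), c(0, 0.25, 0.5, 0.75, 1, 1))
  # continuity at the threshold: both branches give 0.5
  eps <- 1e-12
  expect_equal(density_to_score(m, 2 - eps), 0.5, tolerance = 1e-9)
  expect_equal(density_to_score(m, 2 + eps), 0.5, tolerance = 1e-9)
  # monotone non-decreasing in density
  dd <- sort(runif(100, 0, 6))
  expect_true(all(diff(density_to_score(m, dd)) >= 0))
  bad <- manual_model(matrix(c(0, 0), 1, 2), c(1, 1), threshold = 2, dmax = 2)
  expect_error(density_to_score(bad, 1), "degenerate")
})

test_that("scores are invariant under per-gene affine maps of the data", {
  x <- make_healthy_cohort(50)
  q <- cbind(rnorm(20, 10, 3), rnorm(20, 10, 3))
  s1 <- regulation_score(kdereg(x), q)
  a <- c(3.2, 0.7); b <- c(-5, 12)
  mapped <- gene_pair_matrix(
    cbind(a[1] * x$values[, 1] + b[1], a[2] * x$values[, 2] + b[2]),
    gene_names = x$gene_names, sample_ids = x$sample_ids, cohort = x$cohort)
  q_mapped <- cbind(a[1] * q[, 1] + b[1], a[2] * q[, 2] + b[2])
  s2 <- regulation_score(kdereg(mapped), q_mapped)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("a fitted model round-trips through JSON serialization", {
  x <- make_healthy_cohort(40)
  fit <- kdereg(x)
  path <- tempfile(fileext = ".json")
  write_kdereg(fit, path)
  back <- read_kdereg(path)
  expect_equal(back$bandwidths, fit$bandwidths)
  expect_equal(back$kde_threshold, fit$kde_threshold)
  expect_equal(back$reference_points, fit$reference_points)
  q <- cbind(rnorm(15, 10, 2), rnorm(15, 10, 2))
  expect_equal(regulation_score(back, q), regulation_score(fit, q),
               tolerance = 1e-12)
})

test_that("model summary reports the 50% calibration fraction", {
  fit <- kdereg(make_healthy_cohort(60))
  s <- summary(fit)
  expect_equal(s$frac_at_or_above_half, 0.5)
  expect_output(print(s), "0.500")
  expect_output(print(fit), "bandwidths")
})
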