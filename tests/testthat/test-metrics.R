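test_that("identical cohorts give null summaries", {
  x <- make_healthy_cohort(50)
  expect_equal(cohort_metric("pearson", x, x)$summary, 1.0)
  expect_equal(cohort_metric("js_divergence", x, x)$summary, 0.0)
  expect_equal(cohort_metric("mutual_information", x, x)$summary, 1.0)
  expect_equal(cohort_metric("coefficient_of_variation", x, x)$summary, 1.0)
})

test_that("equal-frequency MI of a perfectly monotone pair is log2(bins)", {
  v <- 1:160
  x <- gene_pair_matrix(cbind(a = v, b = v), cohort = rep("healthy", 160))
  r <- cohort_metric("mutual_information", x, x, mi_bins = 8)
  expect_equal(r$healthy_value, 3.0, tolerance = 1e-12)
  # and MI is invariant under strictly monotone per-gene transforms
  y <- gene_pair_matrix(cbind(a = exp(v / 40), b = log(v + 1)),
                        cohort = rep("healthy", 160))
  r2 <- cohort_metric("mutual_information", y, y, mi_bins = 8)
  expect_equal(r2$healthy_value, r$healthy_value, tolerance = 1e-12)
})

test_that("JSD is symmetric, bounded, and 1 for disjoint supports", {
  set.seed(21)
  a <- gene_pair_matrix(cbind(rnorm(100, 0), rnorm(100, 0)),
                        cohort = rep("healthy", 100))
  b <- gene_pair_matrix(cbind(rnorm(100, 100), rnorm(100, 100)),
                        cohort = rep("cancer", 100))
  jsd_ab <- cohort_metric("js_divergence", a, b)$summary
  jsd_ba <- cohort_metric("js_divergence", b, a)$summary
  expect_equal(jsd_ab, 1.0)  # disjoint: base-2 maximum
  expect_equal(jsd_ab, jsd_ba)
  c_ <- gene_pair_matrix(a$values + 0.5, cohort = rep("cancer", 100))
  jsd_ac <- cohort_metric("js_divergence", a, c_)$summary
  expect_gte(jsd_ac, 0); expect_lte(jsd_ac, 1)
})

test_that("canonical correlation of a single pair equals |Pearson|", {
  x <- make_mixed_cohort(60, 40)
  h <- cohort_subset(x, "healthy"); c_ <- cohort_subset(x, "cancer")
  cc <- cohort_metric("canonical_correlation", h, c_)
  pe <- cohort_metric("pearson", h, c_)
  expect_equal(cc$healthy_value, abs(pe$healthy_value))
  expect_equal(cc$cancer_value, abs(pe$cancer_value))
})

test_that("pca variance fraction is in [0.5, 1] and ratio-oriented", {
  x <- make_mixed_cohort(80, 80)
  h <- cohort_subset(x, "healthy"); c_ <- cohort_subset(x, "cancer")
  r <- cohort_metric("pca_variance", h, c_)
  expect_gte(r$healthy_value, 0.5); expect_lte(r$healthy_value, 1)
  expect_equal(r$summary, r$healthy_value / r$cancer_value)
})

test_that("zero denominators are flagged, not fatal", {
  # checkerboard cancer cohort with exactly zero sample correlation
  xc <- rep(c(-1, -1, 1, 1), 25)
  yc <- rep(c(-1, 1, -1, 1), 25)
  h <- make_healthy_cohort(50)
  c_ <- gene_pair_matrix(cbind(xc, yc), cohort = rep("cancer", 100))
  expect_warning(r <- cohort_metric("pearson", h, c_), "non-finite")
  expect_false(is.finite(r$summary))
  expect_error(cohort_metric("pearson", h, c_[1:5]), "at least 20")
})

test_that("centroid distances satisfy their identities and inequalities", {
  ref <- matrix(c(sqrt(2), -sqrt(2), 0, 0, 0,
                  0, 0, sqrt(2), -sqrt(2), 0), ncol = 2)  # mean 0, cov = I
  expect_equal(unname(cov(ref)), diag(2), tolerance = 1e-12)
  set.seed(8)
  q <- cbind(rnorm(40), rnorm(40))
  euc <- sample_distance("euclidean", ref, q)
  man <- sample_distance("manhattan", ref, q)
  che <- sample_distance("chebyshev", ref, q)
  mah <- sample_distance("mahalanobis", ref, q)
  expect_true(all(euc <= man + 1e-12))
  expect_true(all(che <= euc + 1e-12))
  expect_equal(mah, euc, tolerance = 1e-9)  # identity covariance
  expect_true(all(c(euc, man, che, mah) >= 0))
  # query at the centroid scores 0 for all centroid distances
  centro <- matrix(colMeans(ref), 1, 2)
  for (m in c("manhattan", "euclidean", "chebyshev", "mahalanobis"))
    expect_equal(sample_distance(m, ref, centro), 0, tolerance = 1e-12)
})

test_that("mahalanobis matches the hand-evaluated quadratic form", {
  # reference with mean (0,0) and sample covariance diag(4,1)
  ref <- matrix(c(2 * sqrt(2), -2 * sqrt(2), 0, 0, 0,
                  0, 0, sqrt(2), -sqrt(2), 0), ncol = 2)
  expect_equal(unname(cov(ref)), diag(c(4, 1)), tolerance = 1e-12)
  d <- sample_distance("mahalanobis", ref, matrix(c(2, 1), 1, 2))
  expect_equal(d, sqrt(2^2 / 4 + 1^2 / 1), tolerance = 1e-12)
  expect_equal(d, sqrt(2), tolerance = 1e-12)
})

test_that("cosine distance is 0 along the centroid ray and needs nonzero input", {
  ref <- cbind(c(1, 2, 3), c(2, 4, 6))
  mu <- colMeans(ref)
  expect_equal(sample_distance("cosine", ref, rbind(mu, 5 * mu)),
               c(0, 0), tolerance = 1e-12)
  expect_error(sample_distance("cosine", ref, matrix(c(0, 0), 1, 2)),
               "zero vector")
})

test_that("singular covariance errors suggest the ridge", {
  ref <- cbind(c(1, 2, 3, 4), c(2, 4, 6, 8))  # perfectly collinear
  expect_error(sample_distance("mahalanobis", ref, matrix(c(1, 1), 1, 2)),
               "ridge")
  d <- sample_distance("mahalanobis", ref, matrix(c(1, 1), 1, 2),
                       ridge = 1e-6)
  expect_true(is.finite(d))
})

test_that("the metric sweep covers every comparator", {
  x <- make_mixed_cohort(60, 60)
  tab <- cohort_metric_table(cohort_subset(x, "healthy"),
                             cohort_subset(x, "cancer"))
  expect_setequal(tab$metric_id,
                  c("mutual_information", "canonical_correlation", "pearson",
                    "spearman", "pca_variance", "coefficient_of_variation",
                    "js_divergence"))
  expect_true(all(is.finite(tab$summary)))
})
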