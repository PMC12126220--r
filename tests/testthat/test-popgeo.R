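# Population matrix matching, PCA trajectories, Mahalanobis / Euclidean
# separation.

fake_traces <- function(n, bins = 15, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * 2 * bins), n)
  attr(m, "nt_cols") <- bins
  m
}

test_that("group matching subsamples the larger group reproducibly", {
  a <- fake_traces(20, seed = 1); b <- fake_traces(35, seed = 2)
  m1 <- build_population_matrix(a, b, match_seed = 7)
  m2 <- build_population_matrix(a, b, match_seed = 7)
  expect_identical(unclass(m1), unclass(m2))
  expect_equal(sum(attr(m1, "group") == "A"), 20)
  expect_equal(sum(attr(m1, "group") == "B"), 20)
  expect_equal(length(attr(m1, "selected")$B), 20)

  m3 <- build_population_matrix(a, b, match_seed = 8)
  expect_false(identical(attr(m1, "selected")$B, attr(m3, "selected")$B))

  # equal sizes: identity selection
  m4 <- build_population_matrix(a, fake_traces(20, seed = 3), match_seed = 1)
  expect_equal(attr(m4, "selected")$A, 1:20)
  expect_equal(attr(m4, "selected")$B, 1:20)

  # treated smaller: reference subsampled, with a warning
  expect_warning(
    m5 <- build_population_matrix(a, fake_traces(10, seed = 4),
                                  match_seed = 1),
    "subsampling reference")
  expect_equal(sum(attr(m5, "group") == "A"), 10)
  expect_error(build_population_matrix(a, b), "match_seed")
})

test_that("PCA variance fractions and loadings behave at known ranks", {
  # data exactly in a 2-plane
  set.seed(60)
  basis <- matrix(rnorm(2 * 40), 2)
  coef <- matrix(rnorm(30 * 2), 30)
  m <- coef %*% basis
  pm <- structure(m, group = rep(c("A", "B"), c(20, 20)), nt_rows = 15,
                  class = c("population_matrix", "matrix"))
  pc <- pca_reduce(pm, k = 2)
  expect_equal(sum(pc$variance_explained[1:2]), 1, tolerance = 1e-10)

  # random full-rank matrix: variances equal covariance eigenvalues
  m2 <- matrix(rnorm(30 * 40), 30)
  pm2 <- structure(m2, group = rep(c("A", "B"), c(20, 20)), nt_rows = 15,
                   class = c("population_matrix", "matrix"))
  pc2 <- pca_reduce(pm2, k = 15)
  ev <- eigen(stats::cov(m2), symmetric = TRUE, only.values = TRUE)$values
  frac <- pc2$variance_explained
  expect_equal(frac * sum(ev[ev > 1e-12]),
               ev[seq_along(frac)], tolerance = 1e-8)
  # orthonormal loadings
  g <- crossprod(pc2$rotation[, 1:15])
  expect_equal(g, diag(15), tolerance = 1e-10, ignore_attr = TRUE)

  # full rank: centered data reconstructed exactly from all components
  scores <- sweep(m2, 2, pc2$center) %*% pc2$rotation
  recon <- scores %*% t(pc2$rotation)
  expect_equal(recon, sweep(m2, 2, pc2$center), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(pca_reduce(pm2, k = 31), "exceeds")
})

test_that("group trajectories decompose the full PCA scores", {
  set.seed(61)
  a <- fake_traces(18, seed = 5); b <- fake_traces(18, seed = 6)
  pm <- build_population_matrix(a, b, match_seed = 3)
  pc <- pca_reduce(pm, k = 5)
  full <- sweep(unclass(pm), 2, pc$center) %*% pc$rotation[, 1:5]
  nt <- 1:15; cs <- 16:30
  expect_equal(pc$trajectories$A_NT + pc$trajectories$B_NT, full[nt, ],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(pc$trajectories$A_CS + pc$trajectories$B_CS, full[cs, ],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Mahalanobis reduces to Euclidean under enforced identity covariance", {
  set.seed(62)
  A <- matrix(rnorm(15 * 5), 15); B <- matrix(rnorm(15 * 5), 15)
  r <- mahalanobis_separation(A, B, cov = diag(5))
  mu <- colMeans(B)
  eu <- sqrt(rowSums(sweep(A, 2, mu)^2))
  expect_equal(r$distances, eu, tolerance = 1e-9)

  same <- mahalanobis_separation(A, A)
  # distance of each point to its own cloud stays modest and finite
  expect_true(all(is.finite(same$distances)))
  expect_error(mahalanobis_separation(A, B[, 1:4]))
})

test_that("self-distance vanishes for a degenerate identical trajectory pair", {
  A <- matrix(1:30, 15, 2)
  r <- mahalanobis_separation(A[1, , drop = FALSE][rep(1, 5), ],
                              A[1, , drop = FALSE][rep(1, 5), ],
                              cov = diag(2))
  expect_true(all(r$distances < 1e-6))
})

test_that("planted centroid separation is recovered from a unit isotropic cloud", {
  set.seed(63)
  K <- 15; delta <- 4
  B <- matrix(rnorm(500 * K), 500)
  A <- matrix(0, 500, K); A[, 1] <- delta
  r <- mahalanobis_separation(A, B)
  expect_lt(abs(r$mean_distance - delta) / delta, 0.05)
})

test_that("mean Mahalanobis separation grows with the planted centroid gap", {
  means <- vapply(c(0, 1, 2, 4), function(g) {
    mean(vapply(1:10, function(s) {
      set.seed(1000 * g + s)
      B <- matrix(rnorm(60 * 5), 60)
      A <- matrix(rnorm(60 * 5), 60); A[, 1] <- A[, 1] + g
      mahalanobis_separation(A, B)$mean_distance
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("Euclidean trajectory distance matches per-bin geometry and a loop oracle", {
  A <- matrix(c(0, 0), 1); B <- matrix(c(3, 4), 1)
  expect_equal(euclidean_trajectory_distance(A, B), 5)
  expect_equal(euclidean_trajectory_distance(A, A), 0)

  set.seed(64)
  A <- matrix(rnorm(16 * 15), 16); B <- matrix(rnorm(16 * 15), 16)
  d <- euclidean_trajectory_distance(A, B)
  for (i in 1:16) expect_equal(d[i], sqrt(sum((A[i, ] - B[i, ])^2)),
                               tolerance = 1e-12)
  expect_error(euclidean_trajectory_distance(A, B[1:10, ]), "mismatched")
})

test_that("distance series are invariant to orthogonal rotation of the basis", {
  set.seed(65)
  K <- 6
  A <- matrix(rnorm(20 * K), 20); B <- matrix(rnorm(20 * K), 20)
  Q <- qr.Q(qr(matrix(rnorm(K * K), K)))
  eu1 <- euclidean_trajectory_distance(A, B)
  eu2 <- euclidean_trajectory_distance(A %*% Q, B %*% Q)
  expect_equal(eu1, eu2, tolerance = 1e-10)
  ma1 <- mahalanobis_separation(A, B)$distances
  ma2 <- mahalanobis_separation(A %*% Q, B %*% Q)$distances
  expect_equal(ma1, ma2, tolerance = 1e-8)
})

test_that("two-group separation comparison reports pooled-variance df", {
  set.seed(66)
  r <- compare_separation(rnorm(15, 5), rnorm(15, 3))
  expect_equal(r$df, 28)
  expect_gt(r$t, 0)
})
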