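test_that("euclidean sampler draws from the unit hypercube, reproducibly", {
  pc <- sample_euclidean(5, 3, seed = 0)
  expect_equal(dim(pc$points), c(5, 3))
  expect_true(all(pc$points >= 0 & pc$points <= 1))
  expect_identical(sample_euclidean(50, 4, seed = 42)$points,
                   sample_euclidean(50, 4, seed = 42)$points)
  # uniform moments: mean 0.5, var 1/12, 4-sigma band
  pc <- sample_euclidean(10000, 2, seed = 1)
  tol <- 4 * sqrt(1 / 12) / sqrt(10000)
  expect_true(all(abs(colMeans(pc$points) - 0.5) < tol))
  expect_error(sample_euclidean(0, 3, seed = 1), "positive")
  expect_error(sample_euclidean(5, 0, seed = 1), "positive")
})

test_that("sphere sampler is uniform on the unit sphere", {
  pc <- sample_sphere(20, 400, seed = 0)
  expect_equal(sqrt(rowSums(pc$points^2)), rep(1, 20), tolerance = 1e-12)
  # isotropy: empirical mean vector near the origin
  pc <- sample_sphere(100000, 3, seed = 0)
  expect_lt(sqrt(sum(colMeans(pc$points)^2)), 0.02)
  expect_equal(dim(sample_sphere(1, 2, seed = 7)$points), c(1, 2))
  expect_error(sample_sphere(5, 1, seed = 1), "dimension")
})

test_that("hyperbolic sampler respects the Poincare radial map", {
  # literal ball reading: norms bounded by the map evaluated at r = R
  bound <- function(r) (cosh(r) - 1) / (2 + cosh(r))
  pc <- sample_hyperbolic(10, 3, R = 0.01, seed = 0, radial = "ball")
  expect_true(all(sqrt(rowSums(pc$points^2)) <= bound(0.01) + 1e-15))
  expect_lt(bound(0.01), 1.7e-5)
  pc <- sample_hyperbolic(10, 3, R = 10, seed = 0, radial = "ball")
  nrm <- sqrt(rowSums(pc$points^2))
  expect_true(all(nrm <= bound(10) + 1e-12) && all(nrm < 1))
  # origin is a fixed point of the radial map
  expect_equal(bound(0), 0)
  # curvature reading: depth bounded by rho = 1/R
  pc <- sample_hyperbolic(10, 3, R = 0.5, seed = 1)
  expect_true(all(pc$rho <= 1 / 0.5 + 1e-12))
  expect_error(sample_hyperbolic(5, 3, R = -1, seed = 1), "positive")
  expect_error(sample_hyperbolic(5, 3, R = 1e-4, seed = 1), "radial")
})

test_that("geodesic distances match closed forms on the sphere", {
  pc <- sample_sphere(2, 3, seed = 1)
  pc$points <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(distance_matrix(pc)[1, 2], pi / 2)
  expect_equal(distance_matrix(pc, "chordal")[1, 2], sqrt(2))
  pc$points <- rbind(c(1, 0, 0), c(-1, 0, 0))
  expect_equal(distance_matrix(pc)[1, 2], pi)
})

test_that("hyperbolic geodesic matches the Poincare closed form", {
  pc <- structure(list(points = rbind(c(0, 0), c(0.5, 0)),
                       geometry = "hyperbolic", ambient_dim = 2, n_points = 2,
                       seed = 0), class = "point_cloud")
  # arccosh(1 + 2 * 0.25 / 0.75) = arccosh(5/3) = log(3)
  expect_equal(distance_matrix(pc)[1, 2], log(3), tolerance = 1e-12)
  pc$points <- rbind(c(0, 0), c(1.2, 0))
  expect_error(distance_matrix(pc), "unit ball")
})

test_that("stable hyperbolic path agrees with the naive formula", {
  pc <- sample_hyperbolic(25, 6, R = 1, seed = 3)
  naive <- pc
  naive$gap <- NULL
  expect_equal(unclass(distance_matrix(pc)), unclass(distance_matrix(naive)),
               tolerance = 1e-10)
})

test_that("spherical chordal and geodesic metrics are consistent", {
  pc <- sample_sphere(25, 5, seed = 2)
  geo <- distance_matrix(pc, "geodesic")
  cho <- distance_matrix(pc, "chordal")
  expect_equal(unclass(cho), 2 * sin(unclass(geo) / 2), tolerance = 1e-10)
})

test_that("generated geodesic matrices satisfy the triangle inequality", {
  clouds <- list(sample_euclidean(15, 3, seed = 1),
                 sample_sphere(15, 4, seed = 2),
                 sample_hyperbolic(15, 3, R = 0.5, seed = 3),
                 sample_hyperbolic(15, 3, R = 2, seed = 4, radial = "ball"))
  for (pc in clouds) {
    D <- distance_matrix(pc)
    n <- nrow(D)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-10)
  }
})

test_that("distance matrices are equivariant under point permutation", {
  pc <- sample_sphere(12, 3, seed = 5)
  perm <- c(4, 1, 12, 7, 2, 9, 3, 11, 5, 10, 8, 6)
  pc2 <- pc
  pc2$points <- pc$points[perm, ]
  expect_equal(unclass(distance_matrix(pc2)),
               unclass(distance_matrix(pc))[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("curvature vanishes in the weak-curvature limit", {
  # large curvature radius: geodesics approach twice the Euclidean distance
  # between the Poincare coordinates (the metric factor at the origin)
  pc <- sample_hyperbolic(20, 3, R = 100, seed = 6)
  D <- unclass(distance_matrix(pc))
  E <- 2 * as.matrix(stats::dist(pc$points))
  off <- upper.tri(D)
  expect_true(all(abs(D[off] - E[off]) / E[off] < 0.01))
  # and identically for the literal ball reading at small R
  pc <- sample_hyperbolic(20, 3, R = 0.01, seed = 6, radial = "ball")
  D <- unclass(distance_matrix(pc))
  E <- 2 * as.matrix(stats::dist(pc$points))
  expect_true(all(abs(D[off] - E[off]) / E[off] < 0.01))
})
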