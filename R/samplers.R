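#' Uniform point clouds on constant-curvature model manifolds
#'
#' `sample_euclidean()` draws points uniformly from the unit hypercube
#' \eqn{[0,1]^{dim}}; `sample_sphere()` draws points uniformly from the unit
#' sphere \eqn{S^{dim-1} \subset R^{dim}} (normalised isotropic Gaussians);
#' `sample_hyperbolic()` draws points in the Poincare ball model of
#' hyperbolic space: a point is drawn uniformly from the Euclidean ball of
#' radius `R`, its norm is converted to a hyperbolic radial coordinate
#' \eqn{\rho} (see `radial`), and the point is rescaled so its Poincare-ball
#' norm is \eqn{(\cosh\rho - 1)/(2 + \cosh\rho)}, keeping the direction.
#' The exact radial coordinates and boundary gaps are kept alongside the
#' coordinates so geodesic distances stay accurate at depths where the
#' Poincare norms saturate in double precision.
#'
#' The `dim` argument is always the AMBIENT dimension: the sphere sampler
#' returns unit vectors in `R^dim` (the sphere `S^{dim-1}`), so a
#' length-`T` time-series analogy maps to `dim = T`.
#'
#' @param n_points number of points (positive integer).
#' @param dim ambient dimension (positive integer; at least 2 for the sphere).
#' @param R radius of the hyperbolic sampling ball (positive real).
#' @param seed integer seed; identical calls are bit-identical.
#' @param rho monotone function applied to the Euclidean radial coordinate
#'   before the `cosh` map; the default identity takes the ball norm as the
#'   hyperbolic radius directly.
#' @return a `point_cloud`: a list with `points` (n_points x dim matrix),
#'   `geometry`, `ambient_dim`, `seed`, and for the hyperbolic sampler
#'   `radius`.
#' @export
#' @examples
#' pc <- sample_sphere(10, dim = 3, seed = 1)
#' range(rowSums(pc$points^2)) # all 1
sample_euclidean <- function(n_points, dim, seed) {
  check_count(n_points, "n_points")
  check_count(dim, "dim")
  pts <- withr::with_seed(seed, matrix(stats::runif(n_points * dim), nrow = n_points))
  new_point_cloud(pts, "euclidean", seed)
}

#' @rdname sample_euclidean
#' @export
sample_sphere <- function(n_points, dim, seed) {
  check_count(n_points, "n_points")
  check_count(dim, "dim")
  if (dim < 2) stop("sphere sampling needs ambient dimension >= 2")
  pts <- withr::with_seed(seed, matrix(stats::rnorm(n_points * dim), nrow = n_points))
  pts <- pts / sqrt(rowSums(pts^2))
  new_point_cloud(pts, "sphere", seed)
}

#' @rdname sample_euclidean
#' @param radial radial convention for the hyperbolic sampler.
#'   `"curvature"` (default) treats `R` as the curvature radius: points are
#'   drawn uniformly from the unit ball of a hyperbolic space with curvature
#'   \eqn{-1/R^2}, so their radial coordinates in standard (unit-curvature)
#'   units are \eqn{\rho = r/R^2} with `r` the sampled ball norm scaled to
#'   `[0, R]`; small `R` means strong curvature and deeply hyperbolic,
#'   tree-like configurations, large `R` a nearly flat ball. `"ball"` takes
#'   the sampled Euclidean norm in \eqn{B_R} as the hyperbolic radial
#'   coordinate directly (\eqn{\rho = r}), so the configuration flattens as
#'   `R` shrinks.
#' @export
sample_hyperbolic <- function(n_points, dim, R, seed,
                              radial = c("curvature", "ball")) {
  check_count(n_points, "n_points")
  check_count(dim, "dim")
  radial <- match.arg(radial)
  if (!is.numeric(R) || length(R) != 1 || R <= 0) stop("R must be a positive real")
  if (radial == "curvature" && 1 / R > 600)
    stop("curvature radius R too small: radial coordinates exceed the numeric range")
  raw <- withr::with_seed(seed, {
    # uniform in the ball: isotropic direction times radius with CDF (r/R)^dim
    dirs <- matrix(stats::rnorm(n_points * dim), nrow = n_points)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    r <- R * stats::runif(n_points)^(1 / dim)
    list(dirs = dirs, r = r)
  })
  rho <- switch(radial, curvature = raw$r / R^2, ball = raw$r)
  # Poincare-ball radial map; gap = 1 - norm kept exactly (norms saturate in
  # double precision beyond rho ~ 36, the gap does not until rho ~ 700)
  gap <- 3 / (2 + cosh(rho))
  norm <- pmin(1 - gap, 1 - 1e-12)
  cloud <- new_point_cloud(raw$dirs * norm, "hyperbolic", seed)
  cloud$radius <- R
  cloud$radial <- radial
  cloud$rho <- rho
  cloud$gap <- gap
  cloud$directions <- raw$dirs
  cloud
}

new_point_cloud <- function(points, geometry, seed) {
  structure(
    list(points = points, geometry = geometry,
         ambient_dim = ncol(points), n_points = nrow(points), seed = seed),
    class = "point_cloud"
  )
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, %s geometry, ambient dim %d%s\n",
              x$n_points, x$geometry, x$ambient_dim,
              if (!is.null(x$radius)) sprintf(", R = %g", x$radius) else ""))
  invisible(x)
}

#' Geodesic or chordal distance matrix of a point cloud
#'
#' Geodesic distances by geometry: Euclidean clouds use the Euclidean norm;
#' spherical clouds the great-circle distance `acos(<x, y>)` (inner products
#' clamped to \eqn{[-1,1]}); hyperbolic clouds the Poincare-ball metric
#' \eqn{\mathrm{arccosh}(1 + 2\|u-v\|^2 / ((1-\|u\|^2)(1-\|v\|^2)))}.
#' The chordal metric is the plain Euclidean distance between ambient
#' coordinates for any geometry, supporting metric-variation experiments on
#' the same underlying sample.
#'
#' @param cloud a `point_cloud` with at least two points.
#' @param metric `"geodesic"` (default) or `"chordal"`.
#' @return a `symmetric_matrix` with role `"distance"`.
#' @export
distance_matrix <- function(cloud, metric = c("geodesic", "chordal")) {
  metric <- match.arg(metric)
  stopifnot(inherits(cloud, "point_cloud"))
  X <- cloud$points
  if (nrow(X) < 2) stop("need at least 2 points for a distance matrix")
  D <- if (metric == "chordal" || cloud$geometry == "euclidean") {
    as.matrix(stats::dist(X))
  } else if (cloud$geometry == "sphere") {
    G <- tcrossprod(X)
    acos(pmin(pmax(G, -1), 1))
  } else { # hyperbolic geodesic, Poincare ball
    if (!is.null(cloud$gap)) {
      # precision-safe route from the exact boundary gap s = 1 - |u|:
      # |u - v|^2 = (s_v - s_u)^2 + 2 m_u m_v (1 - cos theta),  m = 1 - s
      s <- cloud$gap
      m <- 1 - s
      C <- tcrossprod(cloud$directions)
      E2 <- outer(s, s, function(a, b) (b - a)^2) +
        2 * outer(m, m) * pmax(1 - C, 0)
      denom <- s * (2 - s) # 1 - |u|^2, computed without cancellation
      arg <- 1 + 2 * E2 / outer(denom, denom)
      acosh(pmax(arg, 1))
    } else {
      nrm2 <- rowSums(X^2)
      if (any(nrm2 >= 1)) stop("hyperbolic points must lie strictly inside the unit ball")
      E2 <- as.matrix(stats::dist(X))^2
      arg <- 1 + 2 * E2 / outer(1 - nrm2, 1 - nrm2)
      acosh(pmax(arg, 1))
    }
  }
  dimnames(D) <- NULL
  diag(D) <- 0
  symmetric_matrix(D, role = "distance", tol = 1e-9)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("%s must be a positive integer", name))
}
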