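#' Integral Betti signature of a set of Betti curves
#'
#' The area under the `i`-th Betti curve on the native per-step grid is the
#' plain sum of the Betti numbers over all `K + 1` steps; the resulting
#' vector (B0AUC, B1AUC, ...) is the integral Betti signature of the matrix.
#' Because the curve grid is shift-invariant (only the ordering of the
#' matrix entries matters), so is the signature.
#'
#' @param bc a `betti_curves` object.
#' @param geometry,dim,radius,replicate,seed optional provenance labels
#'   carried into the output row.
#' @return a one-row tibble with columns `geometry`, `radius`, `dim`,
#'   `replicate`, `seed`, `n_vertices`, `n_steps`, and `b<i>_auc` for each
#'   computed dimension.
#' @export
integral_signature <- function(bc, geometry = NA_character_, dim = NA_integer_,
                               radius = NA_real_, replicate = NA_integer_,
                               seed = NA_integer_) {
  stopifnot(inherits(bc, "betti_curves"))
  auc <- rowSums(bc$betti)
  out <- tibble::tibble(geometry = geometry, radius = radius, dim = dim,
                        replicate = replicate, seed = seed,
                        n_vertices = bc$n_vertices, n_steps = bc$n_steps)
  for (d in 0:bc$max_dim) out[[paste0("b", d, "_auc")]] <- auc[d + 1]
  out
}

#' One reference matrix by geometry label
#'
#' Generates a single reference matrix for a stratum label and returns its
#' order complex input: `"RM"` i.i.d. random symmetric, `"RC"` white-noise
#' correlation (dissimilarity `1 - C`), `"EG"`/`"SG"`/`"HG"` geodesic
#' distance matrices of uniform samples on the hypercube, sphere and
#' Poincare ball. For the geometric strata `dim` is the ambient manifold
#' dimension; for `"RC"` it is the series length.
#'
#' @param geometry one of `"RM"`, `"RC"`, `"EG"`, `"SG"`, `"HG"`.
#' @param n_vertices matrix size (number of points / series).
#' @param dim ambient dimension or series length.
#' @param radius hyperbolic radius (HG only).
#' @param seed integer seed.
#' @param metric passed to [distance_matrix()] for the geometric strata.
#' @return a `symmetric_matrix` ready for [build_order_complex()] (already
#'   dissimilarity-scaled for `"RC"`).
#' @export
reference_matrix <- function(geometry, n_vertices, dim, radius = NA_real_, seed,
                             metric = "geodesic") {
  switch(geometry,
    RM = random_symmetric(n_vertices, seed = seed),
    RC = corr_to_distance(random_correlation(n_vertices, length = dim, seed = seed)),
    EG = distance_matrix(sample_euclidean(n_vertices, dim, seed = seed), metric),
    SG = distance_matrix(sample_sphere(n_vertices, dim, seed = seed), metric),
    HG = {
      if (is.na(radius)) stop("HG stratum needs a radius")
      distance_matrix(sample_hyperbolic(n_vertices, dim, R = radius, seed = seed), metric)
    },
    stop(sprintf("unknown geometry label '%s' (use RM, RC, EG, SG, HG)", geometry))
  )
}

signature_of_matrix <- function(M, max_dim = 1, ...) {
  integral_signature(betti_curves(build_order_complex(M), max_dim = max_dim), ...)
}

#' Replicate sweep of integral Betti signatures across reference strata
#'
#' For every combination of geometry label, dimension (ambient manifold
#' dimension for the geometric strata, series length for RC; `dim` is
#' ignored for RM, which has no dimension), hyperbolic
#' radius (HG only) and replicate, generates a reference matrix, computes
#' its Betti curves and appends one signature row. Each row's seed is
#' derived deterministically from the master seed and the row labels, so the
#' table is reproducible and adding strata or replicates never changes
#' existing rows. With `cache` set to a CSV path, completed rows are
#' reloaded and skipped on rerun.
#'
#' @param geometries character vector, subset of `c("RM", "RC", "EG", "SG", "HG")`.
#' @param dims dimensions / series lengths to sweep (default powers of two
#'   from 4 to 2^15).
#' @param radii hyperbolic radii (default `c(0.01, 0.05, 0.1, 0.5, 0.7, 1, 10)`).
#' @param n_vertices matrix size (default 90).
#' @param replicates replicates per stratum (default 100).
#' @param max_dim highest Betti dimension (default 1).
#' @param seed master seed.
#' @param cache optional CSV path for resumable runs.
#' @return a tibble of signature rows with a `dim_kind` column recording
#'   whether `dim` is a manifold dimension or a series length.
#' @export
signature_sweep <- function(geometries, dims = 2^(2:15), radii = c(0.01, 0.05, 0.1, 0.5, 0.7, 1, 10),
                            n_vertices = 90, replicates = 100, max_dim = 1, seed = 1,
                            cache = NULL) {
  bad <- setdiff(geometries, c("RM", "RC", "EG", "SG", "HG"))
  if (length(bad)) stop(sprintf("unknown geometry label(s): %s", paste(bad, collapse = ", ")))
  grid <- purrr::map_dfr(geometries, function(g) {
    tidyr::expand_grid(
      geometry = g,
      radius = if (g == "HG") radii else NA_real_,
      dim = dims,
      replicate = seq_len(replicates)
    )
  })
  done <- NULL
  if (!is.null(cache) && file.exists(cache)) {
    done <- readr::read_csv(cache, show_col_types = FALSE)
    done$radius <- as.numeric(done$radius) # all-NA column reads as logical
    grid <- dplyr::anti_join(grid, done, by = c("geometry", "radius", "dim", "replicate"))
  }
  rows <- purrr::pmap(grid, function(geometry, radius, dim, replicate) {
    s <- derive_seed(seed, geometry, if (is.na(radius)) 0 else round(radius * 1000), dim, replicate)
    M <- reference_matrix(geometry, n_vertices, dim, radius, seed = s)
    signature_of_matrix(M, max_dim = max_dim, geometry = geometry, dim = dim,
                        radius = radius, replicate = replicate, seed = s)
  })
  out <- dplyr::bind_rows(done, rows)
  out$dim_kind <- ifelse(out$geometry %in% c("RC"), "series_length",
                         ifelse(out$geometry == "RM", "none", "manifold_dim"))
  out <- dplyr::arrange(out, .data$geometry, .data$radius, .data$dim, .data$replicate)
  if (!is.null(cache)) readr::write_csv(out, cache)
  out
}

#' Modularity sweep: signatures of modular copied-series systems
#'
#' For each module count `m` and replicate, generates a modular system
#' ([modular_time_series()]), takes its Pearson correlation matrix, converts
#' it to a dissimilarity (`1 - C`), and records the integral Betti
#' signature. `m = n_series` reduces to independent white noise (the RC
#' stratum); small `m > 1` produces low-rank matrices with few 1-cycles.
#'
#' @param m_values module counts to sweep (each in `1..n_series`).
#' @param n_series number of series (default 90).
#' @param length series length (default 400).
#' @param noise_sd copied-series noise level (default 0.01).
#' @param replicates replicates per `m` (default 10).
#' @param max_dim highest Betti dimension (default 1).
#' @param seed master seed.
#' @return a tibble of signature rows labelled by `m` (in the `geometry`
#'   column as `"modular"` with an `m` column).
#' @export
modularity_sweep <- function(m_values, n_series = 90, length = 400, noise_sd = 0.01,
                             replicates = 10, max_dim = 1, seed = 1) {
  if (any(m_values < 1 | m_values > n_series)) stop("every m must lie in 1..n_series")
  grid <- tidyr::expand_grid(m = as.integer(m_values), replicate = seq_len(replicates))
  rows <- purrr::pmap(grid, function(m, replicate) {
    s <- derive_seed(seed, "modular", m, replicate)
    ts <- modular_time_series(n_series, length, m = m, noise_sd = noise_sd, seed = s)
    M <- corr_to_distance(pearson_correlation(ts))
    sig <- signature_of_matrix(M, max_dim = max_dim, geometry = "modular",
                               dim = length, replicate = replicate, seed = s)
    sig$m <- m
    sig
  })
  out <- dplyr::bind_rows(rows)
  out$noise_sd <- noise_sd
  out$dim_kind <- "series_length"
  dplyr::arrange(out, .data$m, .data$replicate)
}

#' Replicate-averaged Betti curve and its peak
#'
#' Averages the dimension-`dimension` Betti curve over a list of
#' `betti_curves` objects on the shared per-step grid and reports the peak
#' (maximum of the averaged curve). All curves must share `n_steps`.
#'
#' @param curves list of `betti_curves` objects.
#' @param dimension homology dimension of interest.
#' @return list with `curve` (numeric vector, length `K + 1`), `densities`,
#'   and `peak`.
#' @export
average_betti_curve <- function(curves, dimension = 1) {
  stopifnot(length(curves) > 0)
  K <- unique(vapply(curves, function(b) b$n_steps, integer(1)))
  if (length(K) != 1) stop("curves must share the same number of steps")
  mat <- vapply(curves, function(b) as.numeric(b$betti[dimension + 1, ]), numeric(K + 1))
  avg <- rowMeans(mat)
  list(curve = avg, densities = curves[[1]]$densities, peak = max(avg))
}
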