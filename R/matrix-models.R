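#' Reference random-matrix models
#'
#' `random_symmetric()` fills the strict upper triangle of an `n x n` matrix
#' with i.i.d. Uniform(0, 1) draws and mirrors it (zero diagonal). Because
#' the Betti-curve pipeline depends only on the ordering of the entries, any
#' continuous i.i.d. law gives the same downstream distribution; uniform is
#' the simplest. `random_correlation()` returns the Pearson correlation
#' matrix of `n_series` independent standard-Gaussian series of the given
#' length — the white-noise null for correlation networks.
#'
#' @param n,n_series matrix size / number of series (at least 2).
#' @param length series length (at least 3).
#' @param seed integer seed.
#' @return a `symmetric_matrix` with role `"generic"` or `"correlation"`.
#' @export
random_symmetric <- function(n, seed) {
  check_count(n, "n")
  if (n < 2) stop("n must be at least 2")
  u <- withr::with_seed(seed, stats::runif(n * (n - 1) / 2))
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- u
  M <- M + t(M)
  symmetric_matrix(M, role = "generic")
}

#' @rdname random_symmetric
#' @export
random_correlation <- function(n_series, length, seed) {
  check_count(n_series, "n_series")
  check_count(length, "length")
  if (n_series < 2) stop("n_series must be at least 2")
  if (length < 3) stop("series length must be at least 3 for a non-degenerate correlation")
  X <- withr::with_seed(seed, matrix(stats::rnorm(length * n_series), nrow = length))
  symmetric_matrix(stats::cor(X), role = "correlation", tol = 1e-9)
}

#' Pearson correlation matrix of a set of time series
#'
#' @param ts numeric matrix, rows = time points, columns = series (a
#'   `time_series_set` or any T x N matrix with T >= 2).
#' @return a `symmetric_matrix` with role `"correlation"`.
#' @export
pearson_correlation <- function(ts) {
  X <- as.matrix(ts)
  if (nrow(X) < 2 || ncol(X) < 2) stop("need at least 2 time points and 2 series")
  if (anyNA(X)) stop("time series contain missing values")
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    labs <- colnames(X) %||% as.character(seq_len(ncol(X)))
    stop(sprintf("zero-variance series: %s", paste(labs[bad], collapse = ", ")))
  }
  symmetric_matrix(stats::cor(X), role = "correlation", tol = 1e-9)
}

#' Modular copied-series system
#'
#' Builds `n_series` time series from `m` independent standard-Gaussian base
#' series \eqn{M_1, \dots, M_m} by cyclic copying: the columns follow the
#' pattern \eqn{[M_1, \dots, M_m, M_1, \dots, M_m, \dots, M_1, \dots, M_k]}
#' with \eqn{k \equiv n\_series \bmod m} (the tail reuses the first `k` base
#' series, so module sizes differ by at most one). Independent Gaussian noise
#' of standard deviation `noise_sd` is then added to every column. Columns
#' `i` and `j` are copies of the same base series iff `i == j (mod m)`; the
#' resulting correlation matrix has numerical rank about `m`.
#'
#' @param n_series number of output series (default 90).
#' @param length series length (default 400).
#' @param m number of modules, between 1 and `n_series`.
#' @param noise_sd standard deviation of the added white noise, relative to
#'   the unit-sd base series (default 0.01, i.e. small-amplitude).
#' @param seed integer seed.
#' @return a `time_series_set`: a `length x n_series` matrix with column
#'   labels `s1..sN` and attributes `m`, `noise_sd`, `seed`.
#' @export
modular_time_series <- function(n_series = 90, length = 400, m, noise_sd = 0.01, seed) {
  check_count(n_series, "n_series"); check_count(length, "length"); check_count(m, "m")
  if (m > n_series) stop("m must not exceed n_series")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be non-negative")
  X <- withr::with_seed(seed, {
    base <- matrix(stats::rnorm(length * m), nrow = length)
    assign_idx <- ((seq_len(n_series) - 1L) %% m) + 1L
    base[, assign_idx, drop = FALSE] +
      matrix(stats::rnorm(length * n_series, sd = noise_sd), nrow = length)
  })
  colnames(X) <- paste0("s", seq_len(n_series))
  structure(X, m = m, noise_sd = noise_sd, seed = seed,
            class = c("time_series_set", "matrix", "array"))
}
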