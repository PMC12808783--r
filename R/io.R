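#' Read a time-series table or a square symmetric matrix from delimited text
#'
#' `read_time_series()` expects rows = time points, columns = series, first
#' row = labels; comma or tab delimiters are auto-detected; missing values
#' are rejected. `read_symmetric_matrix()` expects a square numeric matrix,
#' optionally with a header row and a leading label column (detected when the
#' first field is non-numeric).
#'
#' @param path file path.
#' @param role role to validate the matrix against (`"distance"`,
#'   `"correlation"`, `"generic"`).
#' @return a numeric matrix (`time_series_set`) or a `symmetric_matrix`.
#' @export
read_time_series <- function(path) {
  df <- readr::read_delim(path, delim = detect_delim(path), show_col_types = FALSE)
  X <- as.matrix(df)
  if (!is.numeric(X)) stop("non-numeric values in time-series input")
  if (anyNA(X)) stop("missing values in time-series input are not supported")
  structure(X, class = c("time_series_set", "matrix", "array"))
}

#' @rdname read_time_series
#' @export
read_symmetric_matrix <- function(path, role = "generic") {
  first <- readLines(path, n = 1)
  delim <- detect_delim(path)
  fields <- strsplit(first, delim, fixed = TRUE)[[1]]
  has_header <- suppressWarnings(anyNA(as.numeric(fields[length(fields)])))
  df <- readr::read_delim(path, delim = delim, col_names = has_header,
                          show_col_types = FALSE)
  if (!is.numeric(df[[1]])) df <- df[, -1] # leading label column
  X <- as.matrix(df)
  dimnames(X) <- NULL
  if (anyNA(X)) stop("missing values in matrix input")
  if (nrow(X) != ncol(X)) stop("matrix input is not square")
  symmetric_matrix(X, role = role, tol = 1e-9)
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Write a distance/correlation matrix, a point cloud, or an edge filtration
#'
#' Matrices are written as square CSV with `v1..vN` row/column labels; point
#' clouds as one point per row with an `x0,x1,...` header plus a JSON
#' sidecar (`<path>.json`) holding the geometry metadata; order complexes as
#' a 3-column CSV `(i, j, weight)` in filtration order.
#'
#' @param x object to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_symmetric_matrix <- function(x, path) {
  labs <- paste0("v", seq_len(nrow(x)))
  df <- as.data.frame(unclass(x))
  names(df) <- labs
  readr::write_csv(dplyr::bind_cols(tibble::tibble(label = labs), df), path)
  invisible(path)
}

#' @rdname write_symmetric_matrix
#' @export
write_point_cloud <- function(x, path) {
  stopifnot(inherits(x, "point_cloud"))
  df <- as.data.frame(x$points)
  names(df) <- paste0("x", seq_len(ncol(df)) - 1)
  readr::write_csv(df, path)
  meta <- list(geometry = x$geometry, ambient_dim = x$ambient_dim,
               n_points = x$n_points, seed = x$seed)
  if (!is.null(x$radius)) meta$radius <- x$radius
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_symmetric_matrix
#' @export
write_order_complex <- function(x, path) {
  stopifnot(inherits(x, "order_complex"))
  readr::write_csv(tibble::tibble(i = x$edges[, 1], j = x$edges[, 2],
                                  weight = x$weights), path)
  invisible(path)
}

#' Logarithmic returns of a price table
#'
#' \eqn{r_i(t) = \log(p_i(t) / p_i(t-1))}: the first differences of the
#' log-transformed prices, the standard preprocessing for stock-price series
#' before correlation analysis.
#'
#' @param prices T x N matrix of strictly positive prices (T >= 2).
#' @return a `(T-1) x N` `time_series_set` of log returns.
#' @export
#' @examples
#' log_returns(cbind(a = c(1, exp(1), exp(1))))[, 1] # 1, 0
log_returns <- function(prices) {
  X <- as.matrix(prices)
  if (nrow(X) < 2) stop("need at least 2 time points")
  bad <- which(X <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive price at row %d, column %d", bad[1, 1], bad[1, 2]))
  R <- diff(log(X))
  structure(R, class = c("time_series_set", "matrix", "array"))
}

#' End-to-end Betti-curve analysis of one input
#'
#' Runs the full pipeline on a file or in-memory object: time series are
#' correlated (Pearson) and converted to dissimilarities (`1 - C`);
#' correlation input skips the first stage; distance input goes straight to
#' the edge filtration. Betti curves and the integral signature are
#' returned, and written as CSV (long-format curves, one-row signature)
#' together with a JSON manifest when `output_dir` is given.
#'
#' @param input file path, or a matrix / `symmetric_matrix` /
#'   `time_series_set`.
#' @param input_type `"timeseries"`, `"correlation"` or `"distance"`.
#' @param max_dim highest Betti dimension (default 1).
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @param output_dir optional directory for curves/signature/manifest files.
#' @return list with `curves` (a `betti_curves`) and `signature` (one-row
#'   tibble).
#' @export
analyze_matrix <- function(input, input_type = c("timeseries", "correlation", "distance"),
                           max_dim = 1, seed = NA_integer_, output_dir = NULL) {
  input_type <- match.arg(input_type)
  obj <- if (is.character(input)) {
    if (input_type == "timeseries") read_time_series(input)
    else read_symmetric_matrix(input, role = input_type)
  } else input
  D <- switch(input_type,
    timeseries = corr_to_distance(pearson_correlation(obj)),
    correlation = corr_to_distance(symmetric_matrix(as.matrix(obj), "correlation", tol = 1e-9)),
    distance = symmetric_matrix(as.matrix(obj), "distance", tol = 1e-9)
  )
  oc <- build_order_complex(D)
  bc <- betti_curves(oc, max_dim = max_dim)
  sig <- integral_signature(bc, geometry = input_type, seed = seed)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(tidy(bc), file.path(output_dir, "betti_curves.csv"))
    readr::write_csv(sig, file.path(output_dir, "signature.csv"))
    manifest <- list(
      input = if (is.character(input)) input else "<in-memory>",
      input_type = input_type, max_dim = max_dim, seed = seed,
      n_vertices = bc$n_vertices, n_steps = bc$n_steps,
      package_version = as.character(utils::packageVersion("bettisig"))
    )
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(curves = bc, signature = sig)
}
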