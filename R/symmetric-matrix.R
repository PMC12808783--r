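#' Symmetric matrix with a declared role
#'
#' Light wrapper marking a square symmetric matrix as a distance matrix,
#' a correlation matrix, or a generic symmetric matrix, and validating the
#' corresponding conventions (zero diagonal and non-negative entries for
#' distances; unit diagonal and entries in \eqn{[-1, 1]} for correlations).
#'
#' @param values square numeric matrix, symmetric up to `tol`.
#' @param role one of `"distance"`, `"correlation"`, `"generic"`.
#' @param tol largest tolerated asymmetry `|M - t(M)|`; the matrix is
#'   symmetrised by averaging after the check.
#' @return a numeric matrix of class `symmetric_matrix` with a `role`
#'   attribute.
#' @export
#' @examples
#' symmetric_matrix(diag(3), role = "correlation")
symmetric_matrix <- function(values, role = c("generic", "distance", "correlation"),
                             tol = 1e-12) {
  role <- match.arg(role)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (anyNA(values)) stop("matrix contains missing values")
  asym <- max(abs(values - t(values)))
  if (asym > tol) stop(sprintf("matrix asymmetric beyond tolerance (max |M - t(M)| = %g)", asym))
  values <- (values + t(values)) / 2
  if (role == "distance") {
    if (any(abs(diag(values)) > tol)) stop("distance matrix must have zero diagonal")
    diag(values) <- 0
    if (any(values < 0)) stop("distance matrix must be non-negative")
  }
  if (role == "correlation") {
    if (any(abs(diag(values) - 1) > 1e-8)) stop("correlation matrix must have unit diagonal")
    if (any(values < -1 - 1e-8) || any(values > 1 + 1e-8))
      stop("correlation entries must lie in [-1, 1]")
    values <- pmin(pmax(values, -1), 1)
    diag(values) <- 1
  }
  structure(values, role = role, class = c("symmetric_matrix", "matrix", "array"))
}

#' @export
print.symmetric_matrix <- function(x, ...) {
  cat(sprintf("<symmetric_matrix> %d x %d, role = %s\n", nrow(x), ncol(x), attr(x, "role")))
  print(unclass(x)[seq_len(min(5L, nrow(x))), seq_len(min(5L, ncol(x))), drop = FALSE], ...)
  if (nrow(x) > 5L) cat(sprintf("... (%d rows/cols total)\n", nrow(x)))
  invisible(x)
}

matrix_role <- function(x) attr(x, "role") %||% "generic"

`%||%` <- function(a, b) if (is.null(a)) b else a
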