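#' Convert a correlation matrix to a dissimilarity matrix
#'
#' Applies `1 - C` entrywise, the standard step before building the
#' edge-ordered filtration from a correlation matrix: strongly correlated
#' pairs get small dissimilarities and enter the filtration first. Entries
#' land in `[0, 2]` with a zero diagonal.
#'
#' @param C a correlation matrix (`symmetric_matrix` with role
#'   `"correlation"`, or any symmetric matrix with unit diagonal and entries
#'   in `[-1, 1]`).
#' @return a `symmetric_matrix` with role `"distance"`.
#' @export
corr_to_distance <- function(C) {
  C <- symmetric_matrix(C, role = "correlation", tol = 1e-9)
  symmetric_matrix(1 - unclass(C), role = "distance", tol = 1e-9)
}

#' Order complex: the ascending edge filtration of a symmetric matrix
#'
#' Sorts all \eqn{N(N-1)/2} upper-triangle entries (the diagonal is ignored)
#' and returns the complete edge filtration: step `j` corresponds to the
#' graph `G_j` holding the `j` smallest-weight edges. Ties are broken by
#' lexicographic vertex order `(i, j)`, making the filtration deterministic
#' for any input. With `order = "descending"` edges are added from the
#' largest weight down instead — the filtration direction matters, and raw
#' correlation matrices filtered descending give the same complex sequence
#' as `1 - C` filtered ascending.
#'
#' @param D symmetric numeric matrix (any role; the diagonal is ignored).
#' @param order `"ascending"` (default; distance-like input) or
#'   `"descending"` (similarity-like input).
#' @return an `order_complex`: list with `n_vertices`, `edges` (K x 2
#'   integer matrix, `i < j`, in filtration order), `weights` (length K),
#'   `n_steps = K`, and `densities` (`0:K / K`).
#' @export
#' @examples
#' oc <- build_order_complex(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3))
#' oc$edges
build_order_complex <- function(D, order = c("ascending", "descending")) {
  order <- match.arg(order)
  D <- as.matrix(D)
  if (nrow(D) < 2) stop("need at least 2 vertices")
  if (anyNA(D)) stop("matrix contains missing values")
  if (max(abs(D - t(D))) > 1e-12) stop("matrix asymmetric beyond tolerance 1e-12")
  n <- nrow(D)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[upper.tri(D)]
  if (order == "descending") w <- -w
  ord <- order(w, idx[, 1], idx[, 2])
  structure(
    list(n_vertices = n,
         edges = cbind(i = idx[ord, 1], j = idx[ord, 2], deparse.level = 0),
         weights = if (order == "descending") -w[ord] else w[ord],
         n_steps = length(ord),
         densities = seq(0, length(ord)) / length(ord)),
    class = "order_complex"
  )
}

#' @export
print.order_complex <- function(x, ...) {
  cat(sprintf("<order_complex> %d vertices, %d edges (steps 0..%d)\n",
              x$n_vertices, x$n_steps, x$n_steps))
  invisible(x)
}

#' Tidy an order complex into its edge table
#'
#' @param x an `order_complex`.
#' @param ... unused.
#' @return tibble with columns step, i, j, weight, density.
#' @export
#' @method tidy order_complex
tidy.order_complex <- function(x, ...) {
  tibble::tibble(step = seq_len(x$n_steps),
                 i = x$edges[, 1], j = x$edges[, 2],
                 weight = x$weights,
                 density = seq_len(x$n_steps) / x$n_steps)
}
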