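#' Betti curves of a clique-complex filtration
#'
#' Computes, for every filtration step `j = 0..K`, the Betti numbers
#' \eqn{\beta_0, \dots, \beta_{max\_dim}} of the clique (flag) complex of the
#' graph holding the first `j` edges. Internally the full persistence
#' barcode of the flag filtration is computed once (GF(2) column reduction),
#' and \eqn{\beta_i(j)} is the number of dimension-`i` intervals
#' \eqn{[b, d)} with \eqn{b \le j < d} — a single pass over the barcode
#' rather than one homology computation per threshold.
#'
#' @param oc an `order_complex` from [build_order_complex()].
#' @param max_dim highest homology dimension, in `0..3`. The integral Betti
#'   signatures use only dimensions 0 and 1, the default; dimensions 2 and 3
#'   require enumerating all 4- and 5-cliques and are gated by `vertex_cap`.
#' @param vertex_cap refuse `max_dim >= 2` beyond this many vertices
#'   (default 120): clique enumeration grows combinatorially.
#' @return a `betti_curves` object: list with `betti` (integer matrix,
#'   `max_dim + 1` rows, `K + 1` columns; entry `[i + 1, j + 1]` is
#'   \eqn{\beta_i} at step `j`), `densities` (`0:K / K`), `n_vertices`,
#'   `max_dim`.
#' @export
#' @examples
#' oc <- build_order_complex(1 - random_correlation(12, 50, seed = 1))
#' bc <- betti_curves(oc, max_dim = 1)
#' bc$betti[, 1:5]
betti_curves <- function(oc, max_dim = 1, vertex_cap = 120) {
  stopifnot(inherits(oc, "order_complex"))
  if (!max_dim %in% 0:3) stop("max_dim must be one of 0, 1, 2, 3")
  if (max_dim >= 2 && oc$n_vertices > vertex_cap)
    stop(sprintf(paste0("%d vertices exceeds the cap (%d) for max_dim >= 2; ",
                        "reduce max_dim or raise vertex_cap"),
                 oc$n_vertices, vertex_cap))
  betti <- flag_betti_curves_cpp(oc$n_vertices, oc$edges, as.integer(max_dim))
  structure(
    list(betti = betti, densities = oc$densities,
         n_vertices = oc$n_vertices, max_dim = max_dim,
         n_steps = oc$n_steps),
    class = "betti_curves"
  )
}

#' @export
print.betti_curves <- function(x, ...) {
  cat(sprintf("<betti_curves> %d vertices, steps 0..%d, dimensions 0..%d\n",
              x$n_vertices, x$n_steps, x$max_dim))
  auc <- rowSums(x$betti)
  cat(paste(sprintf("  B%dAUC = %d", seq_along(auc) - 1, auc), collapse = "\n"), "\n")
  invisible(x)
}

#' Tidy Betti curves into a long table
#'
#' @param x a `betti_curves` object.
#' @param ... unused.
#' @return tibble with columns step, density, dimension, betti.
#' @export
#' @method tidy betti_curves
tidy.betti_curves <- function(x, ...) {
  K <- x$n_steps
  tibble::tibble(
    step = rep(0:K, each = x$max_dim + 1),
    density = rep(x$densities, each = x$max_dim + 1),
    dimension = rep(0:x$max_dim, K + 1),
    betti = as.integer(x$betti)
  )
}

#' One-row summary of Betti curves: per-dimension areas under the curve
#'
#' @param x a `betti_curves` object.
#' @param ... unused.
#' @return one-row tibble with `n_vertices`, `n_steps`, `max_dim` and one
#'   `b<i>_auc` column per computed dimension.
#' @export
#' @method glance betti_curves
glance.betti_curves <- function(x, ...) {
  auc <- rowSums(x$betti)
  out <- tibble::tibble(n_vertices = x$n_vertices, n_steps = x$n_steps,
                        max_dim = x$max_dim)
  for (d in 0:x$max_dim) out[[paste0("b", d, "_auc")]] <- auc[d + 1]
  out
}

#' Brute-force Betti numbers of a clique complex (test oracle)
#'
#' Enumerates every clique of the given graph up to `max_dim + 2` vertices,
#' assembles the boundary matrices over GF(2) as dense 0/1 matrices, and
#' returns \eqn{\beta_i = \dim\ker\partial_i - \mathrm{rank}\,\partial_{i+1}}
#' by direct Gaussian elimination mod 2. Deliberately naive and entirely
#' independent of the persistence engine; restricted to at most 16 vertices.
#'
#' @param edge_set two-column integer matrix (or list of pairs) of edges,
#'   1-based vertex indices.
#' @param n_vertices number of vertices (at most 16).
#' @param max_dim highest Betti number to return.
#' @return integer vector `c(beta0, ..., beta_max_dim)`.
#' @export
#' @examples
#' brute_force_betti(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)), 4, 1) # cycle: 1 1
brute_force_betti <- function(edge_set, n_vertices, max_dim) {
  if (n_vertices > 16) stop("brute-force oracle is limited to 16 vertices")
  if (is.list(edge_set)) edge_set <- do.call(rbind, edge_set)
  edge_set <- matrix(as.integer(edge_set), ncol = 2)
  A <- matrix(FALSE, n_vertices, n_vertices)
  for (r in seq_len(nrow(edge_set))) {
    A[edge_set[r, 1], edge_set[r, 2]] <- TRUE
    A[edge_set[r, 2], edge_set[r, 1]] <- TRUE
  }
  # cliques by size: simplices[[k]] = matrix with k columns, one clique per row
  simplices <- vector("list", max_dim + 2)
  simplices[[1]] <- matrix(seq_len(n_vertices), ncol = 1)
  for (k in 2:(max_dim + 2)) {
    if (n_vertices < k) { simplices[[k]] <- matrix(integer(0), ncol = k); next }
    cand <- t(utils::combn(n_vertices, k))
    keep <- apply(cand, 1, function(v) {
      pr <- utils::combn(v, 2)
      all(A[cbind(pr[1, ], pr[2, ])])
    })
    simplices[[k]] <- cand[keep, , drop = FALSE]
  }
  key <- function(m) apply(m, 1, paste, collapse = "-")
  ranks <- numeric(max_dim + 2) # ranks[k] = rank of boundary from (k-1)-simplices
  for (k in 2:(max_dim + 2)) {
    cols <- simplices[[k]]
    rows <- simplices[[k - 1]]
    if (nrow(cols) == 0 || nrow(rows) == 0) { ranks[k] <- 0; next }
    row_id <- stats::setNames(seq_len(nrow(rows)), key(rows))
    B <- matrix(0L, nrow(rows), nrow(cols))
    for (c in seq_len(nrow(cols))) {
      v <- cols[c, ]
      for (omit in seq_along(v)) {
        B[row_id[[paste(v[-omit], collapse = "-")]], c] <- 1L
      }
    }
    ranks[k] <- gf2_rank(B)
  }
  vapply(0:max_dim, function(d) {
    n_d <- nrow(simplices[[d + 1]])
    as.integer(n_d - ranks[d + 1] - ranks[d + 2])
  }, integer(1))
}

# rank of a 0/1 matrix over GF(2), straightforward elimination
gf2_rank <- function(B) {
  B <- B %% 2L
  rank <- 0L
  nr <- nrow(B); nc <- ncol(B)
  row <- 1L
  for (col in seq_len(nc)) {
    piv <- which(B[row:nr, col] == 1L)
    if (length(piv) == 0) next
    piv <- piv[1] + row - 1L
    if (piv != row) B[c(row, piv), ] <- B[c(piv, row), ]
    hits <- which(B[, col] == 1L)
    hits <- hits[hits != row]
    if (length(hits)) B[hits, ] <- (B[hits, , drop = FALSE] + rep(B[row, ], each = length(hits))) %% 2L
    rank <- rank + 1L
    row <- row + 1L
    if (row > nr) break
  }
  rank
}
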