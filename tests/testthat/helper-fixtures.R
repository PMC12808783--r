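# Shared small fixtures, all built in code.

# 4 points: square with short sides and long diagonals. After the four side
# edges the flag complex is a hollow square (beta1 = 1); the first diagonal
# fills it with two triangles.
square_matrix <- function() {
  D <- matrix(0, 4, 4)
  D[1, 2] <- D[2, 1] <- 1.0
  D[2, 3] <- D[3, 2] <- 1.1
  D[3, 4] <- D[4, 3] <- 1.2
  D[4, 1] <- D[1, 4] <- 1.3
  D[1, 3] <- D[3, 1] <- 5.0
  D[2, 4] <- D[4, 2] <- 6.0
  D
}

# 6-point octahedron: adjacent pairs at distance 1, antipodal pairs at 2.
# At the 12-edge step the flag complex is the boundary of the octahedron,
# a 2-sphere: beta = (1, 0, 1).
octahedron_matrix <- function() {
  D <- matrix(2, 6, 6)
  diag(D) <- 0
  adjacent <- rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5),
                    c(2, 3), c(3, 4), c(4, 5), c(5, 2),
                    c(6, 2), c(6, 3), c(6, 4), c(6, 5))
  for (r in seq_len(nrow(adjacent))) {
    D[adjacent[r, 1], adjacent[r, 2]] <- 1
    D[adjacent[r, 2], adjacent[r, 1]] <- 1
  }
  D
}

# independent beta0 check: straight union-find sweep over the filtration
union_find_beta0 <- function(oc) {
  parent <- seq_len(oc$n_vertices)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  b0 <- integer(oc$n_steps + 1)
  b0[1] <- oc$n_vertices
  comp <- oc$n_vertices
  for (k in seq_len(oc$n_steps)) {
    ri <- find(oc$edges[k, 1]); rj <- find(oc$edges[k, 2])
    if (ri != rj) { parent[ri] <- rj; comp <- comp - 1 }
    b0[k + 1] <- comp
  }
  b0
}
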