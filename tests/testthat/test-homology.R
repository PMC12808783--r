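test_that("brute-force oracle reproduces known clique complexes", {
  # filled triangle: contractible
  expect_equal(brute_force_betti(rbind(c(1, 2), c(2, 3), c(1, 3)), 3, 1), c(1L, 0L))
  # 4-cycle without chords: one loop
  expect_equal(brute_force_betti(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)), 4, 1), c(1L, 1L))
  # two disjoint edges
  expect_equal(brute_force_betti(rbind(c(1, 2), c(3, 4)), 4, 1), c(2L, 0L))
  # octahedron graph: 2-sphere
  adjacent <- which(octahedron_matrix() == 1, arr.ind = TRUE)
  adjacent <- adjacent[adjacent[, 1] < adjacent[, 2], ]
  expect_equal(brute_force_betti(adjacent, 6, 2), c(1L, 0L, 1L))
  expect_error(brute_force_betti(rbind(c(1, 2)), 20, 1), "16")
})

test_that("square fixture: loop appears after four sides, dies at a diagonal", {
  bc <- betti_curves(build_order_complex(square_matrix()), max_dim = 2)
  expect_equal(as.integer(bc$betti[1, ]), c(4, 3, 2, 1, 1, 1, 1))
  expect_equal(as.integer(bc$betti[2, ]), c(0, 0, 0, 0, 1, 0, 0))
  expect_equal(as.integer(bc$betti[3, ]), rep(0, 7))
})

test_that("octahedron fixture: enclosed void at the 12-edge step", {
  bc <- betti_curves(build_order_complex(octahedron_matrix()), max_dim = 2)
  expect_equal(bc$betti[, 13], c(1L, 0L, 1L))
  # complete graph at the end: contractible
  expect_equal(bc$betti[, 16], c(1L, 0L, 0L))
})

test_that("curves start at the empty graph and end contractible", {
  for (s in 1:3) {
    M <- random_symmetric(10, seed = s)
    bc <- betti_curves(build_order_complex(M), max_dim = 2)
    K <- bc$n_steps
    expect_equal(bc$betti[, 1], c(10L, 0L, 0L))
    expect_equal(bc$betti[, K + 1], c(1L, 0L, 0L))
    expect_true(all(diff(bc$betti[1, ]) <= 0)) # components never split
  }
})

test_that("persistence agrees with the brute-force oracle at every step", {
  for (s in 1:8) {
    M <- random_symmetric(9, seed = 400 + s)
    oc <- build_order_complex(M)
    bc <- betti_curves(oc, max_dim = 2)
    for (j in seq(0, oc$n_steps, by = 3)) {
      expect_identical(bc$betti[, j + 1],
                       brute_force_betti(oc$edges[seq_len(j), , drop = FALSE], 9, 2))
    }
  }
})

test_that("beta0 from persistence equals a union-find sweep", {
  for (s in 1:5) {
    oc <- build_order_complex(random_symmetric(20, seed = 30 + s))
    bc <- betti_curves(oc, max_dim = 0)
    expect_equal(as.integer(bc$betti[1, ]), union_find_beta0(oc))
  }
})

test_that("Euler characteristic matches the simplex counts", {
  # with all cliques counted (max clique size <= max_dim + 1), the
  # alternating sum of Betti numbers equals the alternating simplex count
  M <- random_symmetric(7, seed = 77)
  oc <- build_order_complex(M)
  bc <- betti_curves(oc, max_dim = 3)
  A <- matrix(FALSE, 7, 7)
  for (j in seq_len(oc$n_steps)) {
    A[oc$edges[j, 1], oc$edges[j, 2]] <- A[oc$edges[j, 2], oc$edges[j, 1]] <- TRUE
    counts <- sapply(1:5, function(k) {
      if (k == 1) return(7)
      cand <- utils::combn(7, k)
      sum(apply(cand, 2, function(v) {
        pr <- utils::combn(v, 2); all(A[cbind(pr[1, ], pr[2, ])])
      }))
    })
    if (max(which(counts > 0)) <= 4) { # all cliques lie within computed dims
      chi_b <- sum(bc$betti[, j + 1] * c(1, -1, 1, -1))
      chi_s <- sum(counts * c(1, -1, 1, -1, 1))
      expect_equal(chi_b, chi_s)
    }
  }
})

test_that("Betti curves are bit-identical under monotone transforms", {
  M <- random_symmetric(15, seed = 8)
  bc <- betti_curves(build_order_complex(M), max_dim = 1)
  for (f in list(function(x) x + 7, function(x) 3 * x, exp, function(x) x^3)) {
    bc2 <- betti_curves(build_order_complex(f(unclass(M))), max_dim = 1)
    expect_identical(bc2$betti, bc$betti)
  }
})

test_that("dimension caps are enforced", {
  oc <- build_order_complex(random_symmetric(10, seed = 1))
  expect_error(betti_curves(oc, max_dim = 4), "max_dim")
  big <- build_order_complex(random_symmetric(130, seed = 1))
  expect_error(betti_curves(big, max_dim = 2), "cap")
  expect_error(betti_curves(big, max_dim = 2, vertex_cap = 125), "cap")
})

test_that("tidy and glance expose curves and signatures coherently", {
  bc <- betti_curves(build_order_complex(square_matrix()), max_dim = 1)
  df <- tidy(bc)
  expect_equal(nrow(df), 2 * 7)
  expect_equal(sum(df$betti[df$dimension == 0]), glance(bc)$b0_auc)
  expect_equal(sum(df$betti[df$dimension == 1]), glance(bc)$b1_auc)
})
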