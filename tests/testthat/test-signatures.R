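test_that("integral signature is the plain sum of the curve", {
  bc <- structure(list(betti = rbind(c(4L, 3L, 2L, 1L, 1L, 1L, 1L), rep(0L, 7)),
                       densities = 0:6 / 6, n_vertices = 4, max_dim = 1,
                       n_steps = 6),
                  class = "betti_curves")
  sig <- integral_signature(bc)
  expect_equal(sig$b0_auc, 13)
  expect_equal(sig$b1_auc, 0)
})

test_that("signatures are invariant under weight shifts", {
  M <- random_symmetric(10, seed = 21)
  s1 <- glance(betti_curves(build_order_complex(M), max_dim = 1))
  s2 <- glance(betti_curves(build_order_complex(unclass(M) + 5), max_dim = 1))
  expect_equal(s1, s2)
})

test_that("sweeps keep stratum bookkeeping and determinism", {
  sw <- signature_sweep("EG", dims = 16, n_vertices = 20, replicates = 3, seed = 5)
  expect_equal(nrow(sw), 3)
  expect_true(all(sw$geometry == "EG" & sw$dim == 16))
  expect_equal(sw$dim_kind, rep("manifold_dim", 3))
  # the default radius list gives seven hyperbolic strata
  sw <- signature_sweep("HG", dims = 8, n_vertices = 12, replicates = 1, seed = 5)
  expect_equal(sort(unique(sw$radius)), c(0.01, 0.05, 0.1, 0.5, 0.7, 1, 10))
  # same master seed twice: identical tables
  a <- signature_sweep(c("RM", "RC"), dims = 32, n_vertices = 15, replicates = 2, seed = 9)
  b <- signature_sweep(c("RM", "RC"), dims = 32, n_vertices = 15, replicates = 2, seed = 9)
  expect_identical(a, b)
  expect_error(signature_sweep("XX", dims = 8, replicates = 1, seed = 1), "unknown geometry")
})

test_that("sweep caching resumes without recomputation drift", {
  cache <- withr::local_tempfile(fileext = ".csv")
  a <- signature_sweep("EG", dims = 8, n_vertices = 12, replicates = 2, seed = 3,
                       cache = cache)
  b <- signature_sweep("EG", dims = 8, n_vertices = 12, replicates = 4, seed = 3,
                       cache = cache)
  expect_equal(dplyr::semi_join(b, a, by = c("geometry", "dim", "replicate"))$b1_auc,
               a$b1_auc)
  expect_equal(nrow(b), 4)
})

test_that("modularity sweep labels strata by module count", {
  sw <- modularity_sweep(c(1, 5, 20), n_series = 20, length = 60, replicates = 2, seed = 7)
  expect_equal(nrow(sw), 6)
  expect_equal(sort(unique(sw$m)), c(1, 5, 20))
  expect_true(all(sw$geometry == "modular"))
  expect_error(modularity_sweep(c(0, 5), n_series = 20, length = 60, seed = 1), "1..n_series")
})

test_that("full-module systems match the white-noise correlation stratum", {
  # m = n_series reduces to independent series plus tiny noise
  rc <- sapply(1:6, function(r) {
    M <- corr_to_distance(random_correlation(20, 80, seed = 50 + r))
    glance(betti_curves(build_order_complex(M), max_dim = 1))$b1_auc
  })
  mod <- modularity_sweep(20, n_series = 20, length = 80, replicates = 6, seed = 51)
  expect_lt(abs(mean(mod$b1_auc) - mean(rc)) / mean(rc), 0.25)
})

test_that("replicate-averaged curves expose the peak", {
  curves <- lapply(1:4, function(s)
    betti_curves(build_order_complex(random_symmetric(12, seed = s)), max_dim = 1))
  avg <- average_betti_curve(curves, dimension = 1)
  expect_length(avg$curve, choose(12, 2) + 1)
  expect_equal(avg$peak, max(avg$curve))
  expect_equal(avg$curve[1], 0)
})
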