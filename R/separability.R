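#' Pairwise separability of geometry strata from integral Betti signatures
#'
#' Trains a linear support-vector classifier to distinguish two strata of a
#' signature table using only the `(b0_auc, b1_auc)` features, with a
#' balanced 50/50 train-test split per stratum, features z-scored on the
#' training half, and the conventional regularisation `cost = 1`. A single
#' split on ~100 points per class has high variance, so the accuracy is
#' averaged over `repeats` random splits and reported with its standard
#' error; `repeats = 1` gives the strict single-split variant.
#'
#' @param signatures tibble from [signature_sweep()] (or compatible) with
#'   columns `geometry`, `radius`, `dim`, `b0_auc`, `b1_auc`.
#' @param pair length-2 character vector of stratum labels. An HG stratum at
#'   a specific radius can be addressed as `"HG:0.01"`.
#' @param dim dimension / series length at which to compare.
#' @param seed integer seed for the splits.
#' @param repeats number of random splits to average (default 20).
#' @return a one-row tibble: `geometry_a`, `geometry_b`, `dim`, `accuracy`,
#'   `accuracy_se`, `n_train`, `n_test`, `repeats`, `seed`.
#' @export
pairwise_separability <- function(signatures, pair, dim, seed = 1, repeats = 20) {
  stopifnot(length(pair) == 2)
  take <- function(label) {
    if (grepl("^HG:", label)) {
      r <- as.numeric(sub("^HG:", "", label))
      dplyr::filter(signatures, .data$geometry == "HG",
                    abs(.data$radius - r) < 1e-12, .data$dim == !!dim)
    } else {
      dplyr::filter(signatures, .data$geometry == label, .data$dim == !!dim)
    }
  }
  ord <- order(pair) # canonical order: accuracy is invariant to label swaps
  a <- take(pair[ord[1]]); b <- take(pair[ord[2]])
  if (nrow(a) < 10 || nrow(b) < 10)
    stop(sprintf("need >= 10 signatures per stratum at dim %s (have %d and %d)",
                 dim, nrow(a), nrow(b)))
  X <- rbind(as.matrix(a[, c("b0_auc", "b1_auc")]), as.matrix(b[, c("b0_auc", "b1_auc")]))
  y <- factor(rep(c("a", "b"), c(nrow(a), nrow(b))))
  accs <- withr::with_seed(derive_seed(seed, "sep", pair[ord[1]], pair[ord[2]], dim), {
    vapply(seq_len(repeats), function(r) svm_split_accuracy(X, y), numeric(1))
  })
  tibble::tibble(geometry_a = pair[1], geometry_b = pair[2], dim = dim,
                 accuracy = mean(accs),
                 accuracy_se = if (repeats > 1) stats::sd(accs) / sqrt(repeats) else NA_real_,
                 n_train = length(y) %/% 2, n_test = length(y) - length(y) %/% 2,
                 repeats = repeats, seed = seed)
}

# one balanced 50/50 split, z-score on train, linear SVM, test accuracy
svm_split_accuracy <- function(X, y) {
  train <- unlist(lapply(split(seq_along(y), y), function(idx) {
    sample(idx, floor(length(idx) / 2))
  }))
  mu <- colMeans(X[train, , drop = FALSE])
  sdv <- apply(X[train, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  fit <- e1071::svm(x = Z[train, , drop = FALSE], y = y[train],
                    kernel = "linear", cost = 1, scale = FALSE)
  pred <- stats::predict(fit, Z[-train, , drop = FALSE])
  mean(pred == y[-train])
}

#' Full pairwise accuracy matrix at one dimension
#'
#' Runs [pairwise_separability()] over every unordered pair of the given
#' stratum labels and returns both the long table and a symmetric accuracy
#' matrix.
#'
#' @inheritParams pairwise_separability
#' @param labels stratum labels (e.g. `c("RM", "EG", "SG", "RC", "HG:0.01")`).
#' @return list with `table` (tibble of pair rows) and `matrix` (symmetric
#'   numeric matrix with the labels as dimnames, `NA` diagonal).
#' @export
separability_matrix <- function(signatures, labels, dim, seed = 1, repeats = 20) {
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  tab <- dplyr::bind_rows(lapply(pairs, function(p)
    pairwise_separability(signatures, p, dim = dim, seed = seed, repeats = repeats)))
  M <- matrix(NA_real_, length(labels), length(labels), dimnames = list(labels, labels))
  for (k in seq_len(nrow(tab))) {
    M[tab$geometry_a[k], tab$geometry_b[k]] <- tab$accuracy[k]
    M[tab$geometry_b[k], tab$geometry_a[k]] <- tab$accuracy[k]
  }
  list(table = tab, matrix = M)
}
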