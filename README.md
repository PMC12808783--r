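# bettisig

Integral Betti signatures of symmetric matrices and correlation networks.

High-dimensional systems — whole-brain functional connectivity, climate
station networks, stock-return correlations — are routinely summarised by a
symmetric matrix of pairwise similarities. `bettisig` asks what *hidden
geometry* such a matrix is compatible with, using topological data
analysis:

1. Sort the matrix entries ascending and add the corresponding edges one at
   a time to an empty graph on the $N$ row objects (the **order complex**
   $G_0 \subseteq G_1 \subseteq \dots \subseteq G_K$, $K = N(N-1)/2$).
2. At every step take the clique (flag) complex and its Betti numbers
   $\beta_i$ ($\beta_0$ components, $\beta_1$ loops, $\beta_2$ voids),
   giving the **Betti curves** $\beta_i(\widetilde G_j)$, $j = 0 \dots K$.
3. Reduce each curve to its area under the curve on the step grid,
   $\mathrm{B}i\mathrm{AUC} = \sum_j \beta_i(\widetilde G_j)$ — the
   **integral Betti signature**.

Because only the entry ordering matters, the signature is exactly invariant
under monotone transformations of the matrix — a natural requirement for
correlation data. The package compares observed signatures against
reference families generated under controlled geometry: i.i.d. random
symmetric matrices (RM), white-noise correlation matrices (RC), and
geodesic distance matrices of uniform samples in the unit hypercube (EG),
on the unit sphere (SG), and in the Poincaré ball of hyperbolic space at a
chosen curvature radius (HG). A modular copied-series simulator shows how
pure low-rank structure mimics hyperbolic geometry, and a linear-SVM module
quantifies which geometry pairs the two signature coordinates can actually
distinguish.

The persistent-homology engine (flag filtration over GF(2), Rcpp) is built
in, with an independent brute-force oracle used by the test suite to verify
it step-by-step.

## Worked example

Betti curves and signature of a white-noise correlation matrix at the
canonical study conditions (90 series of length 400):

```r
library(bettisig)

C   <- random_correlation(90, 400, seed = 7)
res <- analyze_matrix(C, "correlation", max_dim = 1, seed = 7)
res$curves
#> <betti_curves> 90 vertices, steps 0..4005, dimensions 0..1
#>   B0AUC = 9364
#>   B1AUC = 69323
res$signature[, c("n_vertices", "n_steps", "b0_auc", "b1_auc")]
#> # A tibble: 1 × 4
#>   n_vertices n_steps b0_auc b1_auc
#>        <int>   <int>  <dbl>  <dbl>
#> 1         90    4005   9364  69323
```

The 4005 filtration steps are the edge additions; B0AUC sums the component
counts over all steps (its minimum possible value, $K + 1$, would mean
instant connectivity), and B1AUC sums the loop counts. A white-noise
correlation matrix sits at the spherical level (B1AUC ≈ 70k at these
sizes) — correlations have an intrinsic spherical geometry — whereas an
i.i.d. random symmetric matrix runs higher (≈ 90k), a unit-hypercube sample
much lower (≈ 35k), and a strongly curved hyperbolic sample near 0.
`autoplot(res$curves)` draws the curves against edge density;
`signature_sweep()` and `plot_signatures()` reproduce the full reference
scatter; `modularity_sweep()` traces the low-rank gradient; and
`pairwise_separability()` scores stratum distinguishability. A thin CLI
over the same functions ships in `inst/cli/bettisig.R`.

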