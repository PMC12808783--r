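---
title: "Integral Betti signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integral Betti signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The method

`bettisig` characterises the hidden geometry of a symmetric matrix — a
distance matrix, a functional-connectivity correlation matrix, or any
matrix whose entries rank pairwise (dis)similarity — through the topology
of its *order complex*. Given an $N \times N$ symmetric matrix $M$, sort
the $K = N(N-1)/2$ off-diagonal entries ascending and add the corresponding
edges one at a time to an empty graph on $N$ vertices:

$$G_0 \subseteq G_1 \subseteq \dots \subseteq G_K.$$

Each graph $G_j$ determines its clique (flag) complex $\widetilde G_j$,
whose $p$-simplices are the $(p+1)$-vertex complete subgraphs. The $i$-th
*Betti curve* of $M$ is the sequence
$\beta_i(\widetilde G_0), \dots, \beta_i(\widetilde G_K)$: the number of
connected components ($i = 0$), independent loops ($i = 1$) or enclosed
voids ($i = 2$) at every step. Because only the *ordering* of the entries
enters, the curves are exactly invariant under any strictly increasing
entrywise transformation — a key robustness property for correlation data,
where monotone distortions (global scaling, nuisance monotone maps of the
coupling strength) are common.

Betti curves are reduced to the *integral Betti signature*: the area under
each curve on its native per-step grid, which for an integer-valued step
function is the plain sum

$$\mathrm{B}i\mathrm{AUC} = \sum_{j=0}^{K} \beta_i(\widetilde G_j).$$

The pair (B0AUC, B1AUC) is the working feature: it is shift-invariant,
needs no bandwidth or threshold choice, and places matrices of the same
size on a common scale.

Correlation matrices enter the pipeline through the dissimilarity
$1 - C$. Since both $1 - c$ and $\arccos(c)$ are strictly decreasing in
$c$, the order complex of $1 - C$ equals that of the angular (spherical)
distance matrix $\arccos(C)$ exactly: correlation matrices carry an
intrinsic spherical geometry, and the package's tests pin this equivalence
bit-exactly.

# The persistence engine

Rather than recomputing homology at every threshold (a $O(K)$-fold
repetition), the package computes the persistence barcode of the flag
filtration once and reads every Betti number from it:
$\beta_i(j)$ is the number of dimension-$i$ intervals $[b, d)$ with
$b \le j < d$. The engine (C++ via Rcpp) enumerates cliques up to
dimension `max_dim + 1` with bitset adjacency intersections, orders
simplices by (entry step, lexicographic vertex order), and reduces each
boundary matrix over GF(2) by left-to-right column reduction. Columns are
accumulated in a dense bit vector (no allocation or merge churn in the
inner loop) while reduced negative columns are stored sparsely; for a
$90 \times 90$ matrix at `max_dim = 1` (4005 edges, ~120k triangles) a full
curve takes on the order of 0.1–0.2 s.

Choices worth stating:

* **Coefficients** are GF(2), the standard field for flag-complex
  persistence.
* **Ties** in the input are broken lexicographically by vertex pair, so
  the filtration — and hence every downstream number — is deterministic
  for any input, including degenerate matrices with repeated entries.
* **One step per edge**, not per unique value: with ties the curve is
  still well defined through the tie-break. Step $j$ maps to edge density
  $j/K$.
* **Default `max_dim = 1`**: the signatures use only $\beta_0, \beta_1$.
  Dimensions 2–3 are available but gated by a vertex cap (default 120)
  because clique enumeration beyond triangles grows combinatorially.
* **Verification**: an entirely independent oracle (`brute_force_betti`,
  pure R: clique enumeration, dense GF(2) boundary matrices, Gaussian
  elimination) is part of the package surface, and the test suite checks
  the persistence engine against it at every filtration step of dozens of
  random matrices, along with union-find for $\beta_0$ and Euler-characteristic
  accounting.

# Reference geometries

The package situates an observed matrix against reference distributions
generated under controlled geometry, all at the study conditions used
throughout: $N = 90$ points (the parcellation size typical of
whole-brain functional networks) and ambient dimension or series length
400 (the typical fMRI series length).

* **RM** — i.i.d. symmetric: strict upper triangle filled with
  Uniform(0, 1) draws. Any continuous i.i.d. law gives the same Betti-curve
  distribution (monotone invariance), so uniform is used as the simplest.
* **RC** — Pearson correlation of independent standard-Gaussian series
  (white-noise null), converted by $1 - C$.
* **EG** — uniform samples in the unit hypercube $[0,1]^n$, Euclidean
  distances.
* **SG** — uniform samples on the unit sphere $S^{n-1} \subset R^n$
  (normalised Gaussians), great-circle distances. `dim` is the *ambient*
  dimension, so the spherical model at `dim = 400` aligns with the
  correlation geometry of length-400 series.
* **HG** — samples in the Poincaré ball model of hyperbolic space (next
  section).

Geodesic metrics are the default; a chordal option (plain Euclidean
distance between ambient coordinates) supports metric-variation
experiments on identical samples.

# The hyperbolic radius convention

The hyperbolic sampler takes a radius parameter $R$ with default
convention `radial = "curvature"`: points are drawn uniformly from the
unit ball of a hyperbolic space whose curvature is $-1/R^2$, i.e. whose
curvature radius is $R$. Expressed in standard (unit-curvature) units the
radial coordinate of a draw with ball norm $r \in [0, R]$ is
$\rho = r/R^2$, after which the point is placed at Poincaré-ball norm
$(\cosh\rho - 1)/(2 + \cosh\rho)$ along its direction.

Under this convention **small $R$ means strong curvature**: radial
coordinates reach $1/R$ standard units, distances become dominated by sums
of radial coordinates, the configuration is tree-like and carries
essentially no 1-cycles (B1AUC $\approx 0$ at $R = 0.01$). **Large $R$
means weak curvature**: the sample approaches a flat high-dimensional
ball, which orders its distances like a sphere sample (points concentrate
on the shell), so B1AUC rises to the spherical level. This is the regime
structure the reference strata are designed to span — a gradient from
"few loops, slowly merging components" to "spherical/white-noise-like".

The alternative literal convention `radial = "ball"` takes the sampled
Euclidean norm as the radial coordinate directly ($\rho = r$). It is kept
because it is the natural reading of "uniform in $B_R$, then map the
norm through the cosh transformation", and its closed-form properties
(norm bounds, the flat small-$\rho$ limit) are tested. But it cannot
produce a small-radius hyperbolic regime: for small $R$ every radial
coordinate is small, the configuration is flat, and in high ambient
dimension a flat ball sample is ordering-equivalent to a sphere sample.
With this convention the radius effect on B1AUC runs *downward*
(mildly hyperbolic only when $R \gtrsim 10$). Since the package's purpose
is a reference family whose small-radius end is deeply hyperbolic and
whose large-radius end meets the spherical/correlation strata, the
curvature convention is the default. An area-corrected radial CDF
(pushing the uniform ball draw through the hyperbolic volume measure) was
considered and rejected: $\sinh\rho \approx \rho$ at small radii, so it
changes nothing where the two conventions disagree.

Numerics: Poincaré norms saturate at 1 in double precision once
$\rho \gtrsim 36$, long before the interesting regime ends. The sampler
therefore stores the exact boundary gap $s = 3/(2 + \cosh\rho)$ and the
unit directions, and the geodesic routine evaluates
$\operatorname{arccosh}\!\big(1 + 2\|u-v\|^2/((1-\|u\|^2)(1-\|v\|^2))\big)$
from $(s, \cos\theta)$ without cancellation — valid to $\rho \approx 600$,
i.e. $R \ge 1/600$; smaller $R$ raises an explicit error. The stable and
naive routes agree to $10^{-10}$ where both are well-conditioned.

# Modular systems

To probe how low matrix rank mimics geometry, `modular_time_series`
builds 90 series from $m$ independent Gaussian base series by cyclic
copying (columns $i \equiv j \pmod m$ share a base; module sizes differ by
at most one) and adds independent Gaussian noise of standard deviation
`noise_sd` to *every* column. The noise amplitude is not fixed by any
principle beyond "small relative to the unit-sd base series"; the default
is 0.01, recorded in every sweep row, and exposed. As `noise_sd` $\to 0$
the correlation matrix has numerical rank $m$.

The resulting B1AUC profile over $m$ is non-monotone: a single module is
Euclidean-like (all points near one centroid on the correlation sphere — a
locally flat patch), a handful of modules is hyperbolic-like (the topology
is governed by a few centroids: very few loops), and $m = 90$ recovers the
white-noise correlation stratum. The test suite checks the dip at
$m = 5$ against $m = 1$ and $m = 90$, and that $m = 90$ lands within 15%
of the RC stratum.

# Separability

Pairwise distinguishability of strata is quantified by a linear SVM on the
two-dimensional (B0AUC, B1AUC) features: balanced 50/50 train-test split
per stratum, features z-scored on the training half, conventional
regularisation `cost = 1` (the features are 2-D and far from the
small-margin regime, so the result is insensitive to this choice). A
single split of 100-point strata has high variance, so the default
averages 20 random splits and reports a standard error; `repeats = 1`
gives the strict single-split variant. Per-replicate signatures (not
averaged curves) are the classified points.

# Sweeps, seeds, determinism

`signature_sweep` runs (geometry, radius, dimension, replicate) grids with
per-row seeds derived deterministically from the master seed and the row
labels, so tables are exactly reproducible, independent of evaluation
order, and stable under extension (adding replicates or strata never
changes existing rows). Rows can be cached to CSV and are skipped on
rerun. Default dimension grid: powers of two from $2^2$ to $2^{15}$,
log-scale coverage of the short-to-asymptotic range; default 100
replicates per stratum; default hyperbolic radius list
$\{0.01, 0.05, 0.1, 0.5, 0.7, 1, 10\}$.

# Problem sizes in the test suite

The suite verifies engine-vs-oracle equality on $10 \times 10$ matrices at
all 45 filtration steps (50 matrices, dimensions 0–2), and runs the
study-condition checks at $N = 90$, dimension/length 400 with 20 replicates
per stratum for curve peaks and radius effects, 100 signatures per stratum
for separability, and 10 replicates per module count for the modularity
gradient. These sizes were chosen to make the distributional checks
statistically meaningful at desk scale; the generators themselves accept
arbitrary sizes.

# What the synthetic references do and do not show

The reference strata are maximally symmetric: exact constant curvature,
exchangeable sampling, stationary white-noise nulls. Real connectivity
data are none of these — nonstationary, modular, autocorrelated, and
noisy in structured ways. Matching a reference stratum in (B0AUC, B1AUC)
therefore never certifies that the data *has* that geometry; the
modularity experiment is the in-package counterexample, producing
hyperbolic-looking signatures from pure low-rank structure. Passing tests
establish the internal correctness of the pipeline and the separation of
the reference families under their own sampling assumptions — not any
claim about a particular dataset.

# Known limitations

* Dimensions 2–3 are practical only to ~120 vertices (clique growth).
* The hyperbolic sampler is uniform in the *model ball*, not with respect
  to the hyperbolic volume measure; this is deliberate (the volume measure
  concentrates all mass at the boundary in high dimension) but means "HG"
  is a family of model configurations, not the maximum-entropy hyperbolic
  point process.
* CSV round trips preserve Betti curves exactly only while rounding does
  not create ties in the entry ordering; near-tied entries are the user's
  warning sign.
* The package ingests generic time-series or matrix CSV only; upstream
  extraction (parcellation, detrending, ticker selection) is out of scope.
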