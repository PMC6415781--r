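---
title: "Coloring by dissimilarity: the model behind scsc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coloring by dissimilarity: the model behind scsc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scsc)
```

## The model

`scsc` clusters a set of $n$ states — fluid-particle trajectories, rows of a
Markov-state-model transition matrix, or any objects with a symmetric
pairwise dissimilarity — by *amplifying dissimilarity* rather than grouping
by similarity. Given the dissimilarity adjacency matrix $A$ (zero diagonal,
$a_{ij} \ge 0$, larger = more different), the coloring merit of a scalar
assignment $x$ is

$$z \;=\; \tfrac12 \sum_i \sum_j (x_i - x_j)^2\, a_{ij},$$

and maximizing $z$ under a finite-norm constraint leads to the generalized
eigenproblem $L X = \lambda D X$ with $D = \mathrm{diag}(\text{row sums of }
A)$ and $L = D - A$. Because $A$ stores *dis*similarities, the largest
eigenvalues are the informative ones; the top eigenvector is the single most
effective separation of the most-dissimilar states, and the remaining
$D$-orthogonal eigenvectors contribute progressively weaker, orthogonal
separations.

The hierarchical step walks the eigenvectors in descending-eigenvalue order.
Each eigenvector is bifurcated *globally*: average-linkage agglomerative
clustering on the one-dimensional scalar assignments, cut at the final merge
into two clusters, gives every state one bit (our convention: 0 for the
larger cluster; ties go to the cluster with the smaller mean — all
downstream logic is invariant to bit swaps). Concatenating bits, leading bit
from the largest eigenvalue, yields a binary code per state, and the
occupied codes form a dendrogram. The pair of branches created by a split at
level $k$ inherits a length equal to the merit of $X_k$ restricted to the
members of the splitting node; with the normalization $X_k^\top D X_k = 1$
the root split's branch length is exactly $\lambda_1$, so both dendrogram
axes are in $z$ units. A group whose members all receive the same next bit
passes through a level unchanged; *unoccupied* codes are the method's
natural stopping signal, and the clusters of the data are the branches whose
member sets stop changing as more eigenvectors are included.

## Dissimilarity metrics

Two metrics are built in:

* **Trajectories** (`build_adjacency(ensemble)`): with $r_{ij}(t_k)$ the
  Euclidean separation of states $i, j$ at time $t_k$ (minimum-image in any
  periodic dimension),
  $a_{ij} = \bar r_{ij}^{-1} \bigl[\sum_{k=1}^T (\bar r_{ij} -
  r_{ij}(t_k))^2\bigr]^{1/2}$. Note the root of the *sum* over the $T$
  samples, exactly as defined: at a fixed noise level $a_{ij}$ grows like
  $\sqrt{T}$. A uniform rescaling of $A$ leaves $D^{-1}L$ — hence every
  eigenvector, eigenvalue and split — unchanged, so this only sets the unit
  of the $z$ axes. Coincident states yield $a_{ij} = 0$ with a duplicate
  warning; an all-zero row is rejected before the eigensolve.
* **Probability distributions** (`js_dissimilarity`,
  `transition_adjacency`): the square root of the Jensen–Shannon divergence
  (natural logarithm, $0\log 0 \equiv 0$), a metric bounded by
  $\sqrt{\ln 2}$, applied to rows of a row-stochastic transition matrix.
  This is the same metric used by the Ward-linkage coarse-graining (MVCA)
  that serves as the independent cross-check, so both methods see identical
  inputs.

The minimum-image convention for periodic dimensions is our choice (the
east–west-periodic jet benchmark needs it; without it a particle crossing
the seam would inject a spurious separation jump).

## Benchmark generators

The package generates every study system it is tested on:

* **Quadruple-eddy flow** — four recirculating cells on $x \in [0,2]$,
  $y \in [-1,1]$ with $u = -\pi A \sin(\pi f)\cos(\pi y)$,
  $v = \pi A \cos(\pi f)\sin(\pi y)(2ax+b)$, $f = ax^2+bx$,
  $a = \epsilon\sin\omega t$, $b = 1-2\epsilon\sin\omega t$; $A = 0.1$,
  $\epsilon = 0.1$, $\omega = 2\pi/10$, $t \in [0, 40]$ (four east–west
  oscillation periods). We implement the divergence-free stream-function
  form of the meridional velocity; the variant with $\cos(\pi y)$ in $v$ is
  not divergence-free and produces no closed eddies, so we treat it as a
  transcription slip. A finite-difference check of
  $\partial_x u + \partial_y v = 0$ is part of the test suite.
* **Bickley jet** — $\psi_0 = c_3 y - UL\tanh(y/L)$, $\psi_1 =
  UL\,\mathrm{sech}^2(y/L)\sum_{n=1}^3 \epsilon_n \cos(k_n(x-\sigma_n t))$
  with $U = 62.66$ m/s, $L = 1770$ km, $\epsilon = (0.0075, 0.15, 0.3)$,
  $c = (0.1446, 0.205, 0.461)U$, $\sigma_n = c_n - c_3$, $k_n = 2n/r_0$,
  on $x \in [0, 2\times10^7]$ m (periodic), $y \in [\pm 3\times10^6]$ m, for
  40 days in 601 saved steps. $r_0$ is taken as the Earth's mean radius
  (6371 km), which makes the wave-1 wavelength ($\pi r_0 \approx 2.0015
  \times 10^7$ m) commensurate with the domain to 0.1%. The fields are in
  the co-moving frame of the third wave, so flanking-eddy particles have
  near-zero net zonal drift, jet particles drift east at up to
  $U - c_3 \approx 33.8$ m/s, and the far field drifts west.
* **Noise control** — i.i.d. uniform positions in the unit square for every
  state and time; structureless input whose dendrogram should keep nearly
  all states in one dominant branch.
* **Planted-block transition matrices** — each row places `intra_mass` of
  its probability (Dirichlet-distributed, concentration 1) on its own block
  and the rest on the others; defaults (175 states, 9 blocks) mirror the
  scale of a protein-folding macrostate analysis. Detailed balance is not
  needed by either clustering route and is off by default; a
  stationary-flow symmetrization is available.

Advection uses a fixed-step fifth-order Cash–Karp Runge–Kutta scheme,
vectorized over the ensemble (maximum step 0.01 time units for the eddy
flow, 40 d/4000 for the jet; each save interval is covered by equal
substeps, so the saved grid is exact). The integrator's fifth-order
convergence is asserted by a Richardson step-halving test. Eddy-flow
particles are clamped to the closed domain with a warning — its boundaries
are invariant streamlines, so escape beyond roundoff indicates a step-size
failure. Positions in the periodic direction are stored unwrapped;
distances wrap.

## Numerical choices

* The generalized problem is reduced by symmetric whitening
  $M = D^{-1/2} L D^{-1/2}$ and solved densely (`eigen(symmetric = TRUE)`);
  problem sizes of interest ($n \le 3000$) need no iterative machinery. All
  returned pairs satisfy $\|L X_k - \lambda_k D X_k\| \le 10^{-8}
  \|D X_k\|$, checked at solve time; eigenvalues lie in $[0, 2]$ and the
  trailing pair is the constant vector at $\lambda = 0$ (never used for
  splitting, hence `depth <= n - 1`).
* Eigenvector sign is canonicalized (largest-magnitude entry positive) for
  reproducibility; nothing downstream depends on it.
* Degenerate eigenvalues admit any $D$-orthonormal basis; tests on
  symmetric inputs assert only invariant quantities (eigenvalues,
  partitions), not individual vectors.
* A level whose scalar field has zero range raises a degenerate-split
  error inside `bifurcate_scalar_field`; `assign_codes` converts it into an
  inert level (uniform bit) so the walk continues.
* The default walk stops after 7 eigenvectors or after the first level
  that refines nothing, whichever comes first; both are configurable, and
  an optional `min_branch_z` suppresses splits whose global merit falls
  below a user threshold. For $b$ perfectly symmetric planted blocks, $b-1$
  bifurcations are needed (each eigenvector resolves one boundary), which
  is why the protein-scale demonstration (9 blocks) uses depth 8.

## What the benchmarks do and do not show

The generators reproduce the geometry, parameters and sampling of the
study systems, but uniform random seeding of a chaotic flow makes every
ensemble a random draw: the number of drifters that happen to fall in
coherent cores, and the tails of the eigenvector distributions, vary by
seed. Our reproduction study (three seeds per condition, depth 7, converged
clusters of at least 2% of states) found:

* the **noise control** behaves as described at both the scaled test size
  (n = 500, T = 500: dominant branch 91–93%) and the full benchmark scale
  (n = 3000, T = 2000: 92%);
* the **Bickley jet** structure — flanking-eddy branch, jet branch,
  background branch — is recovered at every seed tested at n = 1000 and
  n = 3000;
* the **planted-block MSM** recovery is exact (adjusted Rand index 1.0
  against both the planted labels and the Ward/MVCA cut) across all seeds
  tested at both the small (44-state) and protein-scale (175-state)
  configurations;
* the **quadruple-eddy quadrant cores** are recovered in a majority of
  seeds at the full benchmark size (2/3 at n = 3000) but not reliably in
  scaled-down ensembles (1/3 at n = 300 and n = 1000, 2/3 at n = 500, 0/3
  at n = 2000), even though the quadrant information is demonstrably
  present in the leading eigenvectors
  (correlations of 0.8–0.9 with the hemisphere and east–west indicators
  among core drifters). The failure mode is the final-merge two-cluster cut
  of the one-dimensional average-linkage dendrogram: a handful of extreme,
  nearly-stationary boundary drifters can claim the cut, leaving a
  structural mode unsplit. We verified our chain end-to-end against an
  independent implementation (generalized symmetric eigensolver plus
  average-linkage clustering from another numerical stack agrees with ours
  to 15 decimal digits in the eigenvalues and exactly in every split), and
  we evaluated alternative readings of the two-cluster rule
  (two-largest-of-k flat clusters with nearest-mean assignment;
  most-balanced-merge sibling pair): each trades the eddy benchmark against
  the noise control, and none preserves both. We therefore keep the
  standard final-merge cut and report the eddy-core robustness as we
  measure it.

The acceptance script (`scripts/acceptance.R`) recomputes the sparse-data
robustness quantity from scratch at sizes 1000/500/300, three seeds per
size, and reports the smallest tested size that recovers the four cores in
a majority of seeds.

## Known limitations

* The two-cluster cut is outlier-sensitive (above); a robust variant is a
  natural extension but would change the method's defining procedure.
* Branch lengths restrict the *globally* normalized eigenvector to the
  branch members; re-solving a local eigenproblem per branch is a plausible
  alternative reading that we did not adopt.
* `k`-way splitting (base-k codes) is not implemented; the binary walk is
  the tested surface.
* No automatic depth selection beyond occupancy/threshold stopping is
  offered, by design.

## A compact example

```{r example, eval = FALSE}
set.seed(1)
ens <- simulate_quadruple_eddy(n = 500, seed = 1)
a <- build_adjacency(ens)
sol <- solve_coloring(a)
tree <- build_dendrogram(assign_codes(sol, 5), sol, a)
print(tree)
converged_clusters(tree)[1:3]
plot_dendrogram(tree)
```
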