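# scsc — simultaneous coherent structure coloring

`scsc` is an R package for unsupervised clustering by *amplifying
dissimilarity*. It is aimed at problems where states of a dynamical system
must be grouped without knowing how many groups exist: Lagrangian coherent
structure detection from sparse drifter or particle trajectories, and
coarse-graining Markov state models (MSMs) of molecular dynamics into
interpretable macrostates.

## The method

Given `n` states and a symmetric pairwise-dissimilarity adjacency matrix
`A` (zero diagonal, larger = more different), a scalar assignment
`x` is scored by the coloring merit

    z = 1/2 * sum_ij (x_i - x_j)^2 a_ij ,

whose constrained maximization is the generalized eigenproblem
`L X = lambda D X`, with `D` the diagonal of row sums of `A` and
`L = D - A` the graph Laplacian. Because `A` holds *dis*similarities, the
largest eigenvalues are informative. Walking the eigenvectors in descending
order, each one is bifurcated globally (average-linkage clustering on the
1-D scalar field, cut into two clusters) and contributes one bit to a
per-state binary code. Occupied codes form a dendrogram whose branch lengths
are the merit of the splitting eigenvector restricted to the branch
(z units); codes that never become occupied are the method's natural
stopping signal, and clusters are branches whose membership stops changing
as depth grows.

Two dissimilarity metrics are built in:

* trajectories: normalized standard deviation of the pair-separation time
  series, `a_ij = sqrt(sum_k (rbar - r_ij(t_k))^2) / rbar`, with
  minimum-image distances in periodic dimensions;
* probability distributions (MSM transition-matrix rows): the square root
  of the Jensen–Shannon divergence, bounded by `sqrt(ln 2)` — the same
  metric used by the Ward-linkage MVCA coarse-graining that the package
  provides as an independent cross-check.

The package also generates all of its benchmark systems: the unsteady
quadruple-eddy ocean flow and the Bickley atmospheric jet (fifth-order
Cash–Karp advection of seeded drifter ensembles), a uniform-noise control,
and planted-block synthetic transition matrices at protein-folding scale.

## Worked example

Seed 500 drifters in the quadruple-eddy flow, advect them for four
east–west oscillation periods, and color:

```r
library(scsc)
ens  <- simulate_quadruple_eddy(n = 500, seed = 3)
a    <- build_adjacency(ens)           # 500 x 500 pairwise trajectory metric
sol  <- solve_coloring(a)              # all generalized eigenpairs
print(sol)
tree <- build_dendrogram(assign_codes(sol, 5), sol, a)
print(tree)
```

```
<csc_coloring: 500 states>
top eigenvalues (z of each partition):
[1] 1.091733 1.058889 1.053073 1.043262 1.029295 1.026524 1.024355 1.023815
<scsc_tree: 500 states, depth 5, 12 leaves>
   prefix count creation_level
1   00000   207              5
2   01000   186              4
3   10000    24              4
4   11000    18              4
5   00010    17              4
6   11010    16              4
7   10010    12              4
8   01010    11              5
9   01100     4              3
10  00001     3              5
11  01011     1              5
12  11110     1              3
```

The eigenvalues are the merit `z` of each orthogonal partition (branch
lengths of the dendrogram). The two large branches (207 and 186 states)
collect the wandering drifters; the four clusters of 24, 18, 16 and 12
states under the coherent-core branch are the four eddy cores:

```r
rec <- eddy_core_recovery(tree, ens, min_frac = 0.02)
rec$n_core_clusters    #> 4
rec$quadrants          #> 3 1 2 4
round(rec$purity, 2)   #> 0.98
```

Each core cluster is 98% pure in its release quadrant. Exports:
`write_newick(tree, "tree.nwk")` (branch lengths in z units, readable by
`ape`), `dendrogram_report(tree, "report.json")`, and
`plot_dendrogram(tree, "tree.png")` (45-degree branches, line width
proportional to branch occupancy). `run_pipeline()` composes the whole
chain, and `inst/cli/scsc.R` exposes `simulate` / `adjacency` / `cluster`
subcommands for shell use. For MSM coarse-graining, see
`synthetic_transition_matrix()`, `transition_adjacency()`,
`mvca_cluster()` and `macrostate_report()`.

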