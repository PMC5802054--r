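---
title: "scamp: models, parameters, and design notes"
author: "scamp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scamp: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scamp)
```

scamp analyzes single-cell gene expression matrices around one annotated
container and one shared cell graph.  This vignette explains the models
behind each stage, the parameters that matter, the numerical conventions,
and the choices we made where more than one reasonable design exists.  It
states no empirical result that the package's tests and acceptance script
do not themselves compute.

## The annotated matrix container

An `AnnMatrix` holds an observations-by-variables matrix `X` (cells in
rows, genes in columns; dense base matrix or sparse `Matrix`), two axis
annotation tables keyed by unique names, and a free-form named list `uns`.
Sparse matrices stay sparse through construction, slicing, normalization,
and the log transform; only `scaleClip()` and `regressOut()` densify,
because standardized residuals have no zeros to exploit — both say so in
their documentation and this is the memory trade-off to plan around.

The HDF5 container stores `X` either as one 2-D dataset or, for sparse
matrices, in a compressed row-major layout (`data`/`indices`/`indptr`
plus a `shape` attribute, 0-based indices on disk).  Row-major favors
per-cell access, which is the pattern preprocessing uses.  Axis tables
keep categorical columns as integer codes plus a category list, logical
columns as integers with a `bool` tag, and strings as UTF-8.  `uns` is
mirrored as a nested group tree; sparse values inside `uns` (for example
the stored neighbor graph) reuse the same compressed layout.

With `readH5AM(path, backed = TRUE)` the matrix stays in the file: only
the CSR row pointer is cached, and a slice reads just the row runs and
columns it needs, so memory stays proportional to the slice, not the
matrix.  Backed objects are read-only for `X`; any mutation requires an
explicit `toMemory()`.  We chose read-only backing over writable backing
because it keeps the equivalence contract ("backed reads equal memory
reads elementwise") easy to state and to test, at the cost of one copy
when a pipeline needs to transform a backed matrix.

Slicing accepts logical masks, 1-based integer vectors, and name vectors.
R's native 1-based indexing is used throughout; the on-disk CSR indices
remain 0-based as the container layout requires.  Duplicate axis names
are uniquified as `name-1`, `name-2`, ... with a warning, the policy 10x
gene symbols need in practice.

Loom export follows the loom convention (genes as rows in the file);
nested `uns` values have no loom slot and are skipped with a warning
rather than flattened silently.

## Preprocessing

`normalizeTotal()` scales each cell to a common total; the default target
is the median of the pre-normalization totals, which is scale-free and
robust to outlier cells.  Zero cells are left unchanged with a warning
rather than dropped — dropping is `filterAxis()`'s job, and a normalizer
that silently changes the cell count makes pipelines hard to reason
about.

Highly variable genes are selected on normalized, un-logged values: the
dispersion of gene $g$ is $d_g = \mathrm{var}_g/\mu_g$ (0 for undetected
genes), genes are placed in `nBins = 20` equal-frequency bins of the
mean, and dispersions are standardized within each bin — by mean and
sample standard deviation (`flavor = "meanstd"`) or, by default, by
median and MAD (`flavor = "medianmad"`, robust to the heavy dispersion
tails that count data produce).  Singleton bins and bins with zero spread
yield a standardized dispersion of 0 with a warning: silently dropping
such genes would make selection depend on binning accidents.  Undetected
genes are never preferred, but `nTop = nVar` still flags every gene.

Everywhere a standard deviation appears — HVG standardization,
`scaleClip()`, PCA's explained variance — it is the sample standard
deviation (denominator $n-1$), one convention, stated once.

`runPca()` centers the data and uses an exact SVD for small problems and
a seeded truncated SVD (irlba) for large ones.  Components follow a
deterministic sign convention (the largest-magnitude loading entry is
positive), so results are reproducible across runs and solvers.

`recipeBenchmark()` chains: drop zero-count cells, normalize, select HVGs
(median/MAD), subset, re-normalize, `log1p`, scale with clipping at 10.
Clipping bounds the influence of a cell on a standardized gene at 10
standard deviations, keeping rare extreme cells from dominating PCA.

## The neighbor graph

All pairwise work is blocked: a row block $Q$ of the coordinate matrix
gives its distance block as
$\sqrt{\max(0, \|q\|^2 + \|x\|^2 - 2\,QX^\top)}$, so the dominant cost is
a dense matrix product per block and peak memory is
$O(\text{blockSize} \times n)$.  The subtraction can go negative by
round-off for near-duplicate points; clamping at zero is part of the
contract.  Exact k-nearest neighbors are selected per row with ties
broken by the lower index, which makes graphs deterministic and
block-size invariant (distances agree across block sizes to BLAS
accumulation round-off, below 1e-9).

Connectivities use an adaptive Gaussian kernel: the width $\sigma_i$ is
the distance to the $k$-th neighbor (local density scaling), each stored
pair gets $W_{ij} = \exp(-d_{ij}^2/(\sigma_i^2+\sigma_j^2))$, and the
matrix is symmetrized by elementwise maximum, keeping the union of the
two directed neighborhoods.  Cells whose $k$-th neighbor sits at distance
0 (duplicated profiles) would get a zero width; they fall back to the
smallest positive width with a warning.

The transition operator optionally removes sampling-density bias first
($\tilde K_{ij} = W_{ij}/(z_i z_j)$ with $z_i = \sum_j W_{ij}$; on by
default, since diffusion geometry should reflect the process, not where
cells were sampled densely), then row-normalizes.  The symmetric
conjugate $T_{sym} = D^{-1/2}\tilde K D^{-1/2}$ shares T's spectrum and
is what the eigensolver works on.  Isolated cells make a row of zeros
and are an error asking for a larger `k`, not a silent fix.

Kernel and symmetrization choices follow the diffusion-map literature's
locally scaled Gaussian construction; they are conventions of this
package, stated here, not unique choices.

## Diffusion maps and pseudotime

`diffusionMap()` computes the top eigenpairs of $T_{sym}$ (dense solver
up to a few hundred cells, Lanczos beyond), back-transforms by
$D^{-1/2}$ to the diffusion components used for embedding (the leading
one is constant), and applies the PCA sign convention.

Diffusion pseudotime accumulates the random walk over all lengths.  We
compute it in the orthonormal basis $u_i$ of $T_{sym}$:
$$dpt(x,y)^2 = \sum_{i \ge 1} \Big(\frac{\lambda_i}{1-\lambda_i}\Big)^2
 (u_i(x)-u_i(y))^2 ,$$
which is exactly the Euclidean distance between rows of
$M = (I - (T_{sym} - u_0 u_0^\top))^{-1} - I$; the identity is exact
only in this basis (with the $D^{-1/2}$-transformed components, cross
terms survive), which is why pseudotime uses $u_i$ while plotting uses
the components.  Components with $\lambda_i \ge 1 - 10^{-10}$ belong to
disconnected or near-invariant directions and are excluded with a
warning; by default the first 10 non-trivial components enter the sum,
enough to resolve the geometries the fixtures produce while keeping the
distance stable.  Pseudotime from a root cell is the dpt distance to the
root, normalized to $[0,1]$ (raw distances are kept).

### Branching detection

Within the segment under consideration, the first tip is the cell
farthest from the segment root in dpt, the second tip the cell farthest
from the first.  A genuine branch point separates orderings: cells
ordered by distance from one tip are *correlated* with the orderings
from the other two tips before the branch point and anti-correlated
after it.  For each of the three tips we cut where the Kendall-tau
contrast $\tau_{\text{before}} - \tau_{\text{after}}$ is largest.  Three
implementation details matter and were open design choices:

* **Precision weighting.** The raw contrast profile is a broad plateau,
  and tau estimated on a short flank is noisy enough to win by chance;
  the cut index therefore maximizes the contrast divided by its
  combined standard error scale $\sqrt{1/i + 1/(n-i)}$.  Ties pick the
  smaller index (the cell nearer the ordering's tip).
* **Validity thresholds.** A cut counts only if its raw contrast is at
  least 0.5 (half the theoretical range on a clean branch, far above
  what an unbranched segment produces), each flank holds at least 5% of
  the segment, and the three tips are mutually distant (the smallest
  pairwise tip distance at least a quarter of the largest).  On an
  unbranched segment the second tip collapses onto the root side and
  the "arm" between them is an artifact; the guard leaves such segments
  whole rather than cutting off an end.
* **Ambiguous cells.** Cells claimed by no rotation or by several —
  the region around the branch point — follow a 7-nearest-neighbor
  majority vote among uniquely claimed cells in the dpt representation,
  instead of defaulting to the trunk; near the branch point labels are
  genuinely uncertain and proximity is the least arbitrary tiebreak.

The trunk (the segment containing the root) is labeled 0, other segments
by decreasing size.  Requested splits repeat on the largest unresolved
segment.

## Graph layout

`frLayout()` is the classic force-directed scheme on the connectivity
weights: optimal length $k = \sqrt{area/n}$ with area $= n$ (unit
density, so $k = 1$), attraction $d^2/k$ per edge scaled by its weight,
repulsion $k^2/d$ between all pairs, displacement capped by a linearly
cooling temperature, seeded initial positions.  Above 2000 nodes
repulsion is grid-approximated with a cutoff of $3k$ — beyond that
radius the repulsive force is under 11% of its value at $k$ and shrinks
quadratically, so truncation changes the layout little while making the
cost near-linear.

## Louvain clustering and modularity

Modularity of a partition is
$Q = \sum_c \big[e_c/m - \gamma\,(d_c/2m)^2\big]$ with $e_c$ the
within-community weight, $d_c$ the degree sum, $m$ the total weight, and
resolution $\gamma$ (default 1).  `louvainCluster()` implements the
two-phase algorithm: local moving in a seeded shuffled order, with the
neighboring communities, the current community, *and an empty community*
as candidate targets (omitting the empty target makes all-in-one
partitions absorbing, a real failure mode on small graphs), then
aggregation, repeated to convergence, then one single-node refinement
sweep on the original graph, since nodes frozen into aggregates can be
released profitably at the end.

Greedy local moving is order-dependent, and on tiny graphs a single run
can land in a partition no single move improves even when a better one
exists.  We therefore run a small number of independently shuffled
restarts and keep the best partition by modularity: up to 10 on graphs
of a few hundred nodes or fewer — where restarts are free and traps are
concentrated — tapering to 2 on large graphs, where a single run is
reliable and restarts would dominate runtime.  Labels are renumbered by
decreasing community size so results are stable to report.

## Marker-gene ranking

`rankGenesGroups()` tests each group against all remaining cells, per
gene.  The t flavor is Welch's statistic with Welch–Satterthwaite
degrees of freedom; the rank flavor is the rank-sum z with tie
correction, using the plain normal approximation *without* continuity
correction — the convention under which complete separation of two
triples gives $z = (6-10.5)/\sqrt{5.25} = -1.964$, the reference value
the tests pin down.  Two-sided p-values are Benjamini–Hochberg adjusted
across genes within each group.  Log2 fold changes backtransform the
group means with `expm1` and a $10^{-9}$ pseudocount; they are
meaningful on log1p-normalized data and reported as `NA` when a ratio
goes nonpositive (as happens on scaled residuals).  Groups with fewer
than 2 cells on either side are skipped with a warning.

## The boolean-network cell simulator

A `GRNModel` is a set of boolean update rules over genes, made
continuous by the normalized Hill transform
$h(x) = \frac{x^n}{x^n + k^n}(1 + k^n)$, so that $h(0)=0$ and $h(1)=1$
and the attractors sit near the corners of the unit hypercube.  `NOT a`
becomes $1-h(x_a)$, `AND` a product, `OR` the probabilistic sum
$1-(1-\cdot)(1-\cdot)$ — smooth and differentiable, unlike a max.  The
normalization (rather than the raw Hill function) is a convention of
this package; the boolean-to-continuous literature also uses
unnormalized variants.  Defaults $n=2$, $k=0.5$, $\tau=0.01$,
$\sigma=0.01$ are conventional values for this model family, not fits.

States evolve by Euler–Maruyama,
$x \leftarrow \mathrm{clamp}(x + \tau(B(x)-x) + \sqrt{\tau}\,\sigma\eta,\,0,\,1)$,
seeded and clamped to the unit cube.  `sampleCells()` runs independent
noisy trajectories and snapshots each at a uniformly drawn step,
mimicking an unsynchronized population; the snapshot time and trajectory
id are kept as ground truth.

## The synthetic fixtures and what they do (not) show

Both generators draw latent cells in 10 dimensions — Gaussian clusters
with centers at pairwise distance `separation` and unit within-cluster
spread, or a Y-shaped path of length `separation` with isotropic noise —
and map them to counts through one noise model: a random nonnegative
loading matrix, entrywise cubed and column-normalized so each gene
responds predominantly to one latent program (the behavior of real
marker genes; with dense loadings every gene averages all programs and
the latent separation is washed out of the count space), a log-normal
per-gene base level, a log-normal library-size factor (sd 0.3), and
negative-binomial sampling with dispersion 0.1.  Base levels are
rescaled so the expected per-cell depth is 2500 counts regardless of the
gene count, a typical droplet-sequencing depth.  The branching fixture's
latent noise (sd 0.2 against a path of length 8) describes a clearly
resolved developmental axis; at several times this noise the branch
region becomes genuinely ambiguous and no detector can label it
reliably.  Generation is blockwise, so a 100,000-cell fixture never
materializes a dense mean matrix.

These fixtures exercise every stage offline with known truth.  They do
**not** emulate ambient RNA, doublets, batch effects, zero inflation
beyond the negative binomial, or gene-gene correlation beyond the latent
programs — passing on them shows the machinery is correct on its stated
model, not that any biological dataset will be recovered at the same
rates.

## Problem sizes in the test suite

The bundled tests and the acceptance script use: 50–80 points for the
distance and kNN oracles; 15–20 cells for the exhaustive dpt metric and
spectral-identity checks; 50 random graphs of at most 8 nodes against a
brute-force search over all partitions (Bell(8) = 4140); a 600x300,
3-cluster mixture and a 300x300 bifurcation for end-to-end recovery; and
one 100,000x1,000 sparse run of the whole clustering pipeline as the
scalability exercise.  These sizes were chosen so each property is
checked by an independent oracle where one exists and by ground truth
where the truth is generated.

## Known limitations

* Exact kNN only; no approximate-neighbor index, non-Euclidean metrics,
  or GPU path.
* Backed mode is read-only and reads cross row/column slices via a
  row-block pattern; writing into a backed matrix in place is not
  supported.
* The Wilcoxon flavor uses the normal approximation; exact enumeration
  for small groups is out of scope.
* Branch detection handles one bifurcation per split and labels at most
  three segments per pass; the generator produces two branches.
* Loom import targets the core layout (matrix, row/col attributes), not
  arbitrary third-party loom extensions.
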