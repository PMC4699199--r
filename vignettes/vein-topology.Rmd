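---
title: "Quantifying loop nesting in venation networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying loop nesting in venation networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veintop)
```

This vignette is the package's own account of its methods: the
decomposition and the metrics it computes, the growth model, the
parameters that matter, and the numerical and design choices made where
several readings were defensible.

## Input model and units

A `vein_network` is a planar embedded graph: nodes with coordinates in
**cm**, edges as straight segments carrying a vein width in **mm** (and a
length in mm, defaulting to the Euclidean endpoint distance). The package
assumes vectorization — segmentation and skeletonization of cleared-leaf
scans — has already happened upstream; curved veins must arrive
pre-discretized into segments. Crossing segments are an input error, not
something we repair. Polyline chains between junctions need not be
collapsed into single edges: the decomposition only ever selects and
removes whole shared boundaries, and collinear sub-edges of one vein carry
the same width, so chains behave identically to collapsed edges (the
length-weighted diameter `d` is likewise unaffected).

## Pruning and areole extraction

An edge lies on a cycle exactly when it is not a bridge, so
`prune_to_cycles()` deletes all bridges in one pass (via igraph) and drops
isolated nodes; free-ending veinlets and tree-like appendages vanish. If
pruning leaves several connected components — cleared-leaf damage does
this — we keep the component with the most internal faces
(`E - V + 1` per component) and warn, since the paper-scale analyses need
one dominant blade.

`extract_facets()` walks the combinatorial embedding: incident edges are
sorted by angle at every node and each directed edge is followed to the
rotationally next edge at its head. Every face is traced exactly once;
the count must equal `E - V + 2` (otherwise the input was disconnected or
non-planar). The outer face is the unique face with negative signed area
under the traversal orientation, tie-broken by maximal absolute area;
its polygon is the leaf outline and its enclosed area the leaf area. We
use the outline polygon, not a convex hull, so lobed blades are measured
correctly.

## The nesting tree

Each areole starts as a leaf. At every step the globally thinnest edge
separating two *distinct* current facets is selected — "thinnest" over
single edges by default — the two facets merge, their representatives are
joined under a new internal node, and the **entire shared boundary**
between the pair is removed. Edges that end up strictly inside a merged
facet separate nothing; they are discarded without creating tree nodes,
which corresponds to the bridges that arise when a region's last
separating vein goes. Internal node $j$ records $r_j \ge s_j$ (subtree
leaf counts), the nesting ratio $q_j = s_j / r_j \in (0, 1]$, the subtree
degree $d_j = r_j + s_j$, and the width of the selected vein.

Design choices worth stating:

* **Tie-breaking.** Real width data is quantized, so equal widths are
  common. Ties are broken by the smaller edge id — deterministic and
  seed-free, which reproducibility requires.
* **Multi-edge boundaries.** When a facet pair shares several edges the
  pair is selected through its thinnest shared edge (`pair_weight =
  "min"`, the default); `"mean"` and `"max"` are provided as options
  because the original convention is not recoverable from the published
  description. Under `"min"` the pair selection coincides with plain
  global minimum-edge selection, which is also what the edge-removal
  formulations in the hierarchical-decomposition literature do.
* **Cut vertices.** Facets that touch only at a node share no edge and
  cannot merge by edge removal; if the candidate set empties with more
  than one group left we join the remainder in deterministic order and
  warn. Grid-like venation never hits this.

Two invariances follow from the construction and are tested
property-style: any strictly increasing transform of all widths leaves
the tree unchanged (only ranks matter), and so does any deformation of
the coordinates that preserves the embedding (rigid motions, mild
affine stretch).

The implementation runs on the facet-adjacency structure with union-find
bookkeeping. The test suite checks it against a literal, independent
route: delete the thinnest separating edge from the graph, re-prune,
re-extract all faces from scratch, and track which groups of original
areoles merged — on hundreds of small random networks the two agree
exactly.

## Topological metrics

`nesting_ratios(tree, max_degree)` filters internal nodes by
$d_j \le$ `max_degree`, applied per node (not as whole-subtree
exclusion) — the literal reading of thresholding "subtrees with degree
$d \le 256$". The conventional thresholds are 256 for full leaves and 128
for fragments; they remove leaf-size effects so the metrics stay local.
The nesting numbers are the weighted means of the filtered $q_j$:
equal weights for $i_u$, $w_j \propto d_j - 1$ for $i_w$.

The topological length $L_e$ counts the steps of a greedy walk: from the
current edge move to the adjacent edge of maximal width among those
**strictly** thinner, ties again by edge id. Strictness matters: with
quantized widths a non-strict rule could cycle, while strictly decreasing
widths guarantee termination and make the successor a function of the
current edge only, so the implementation memoizes. $L_{\mathrm{top}}$ is
the plain mean over all edges, computed on the whole network.

## Geometric metrics

With facet areas $a_k$ (cm² internally, reported in mm²), leaf area $A_L$
from the outline polygon, and edge widths $w_e$/lengths $\ell_e$:
$\sigma = \sum_e \ell_e / A_L$, $A = \mathrm{mean}(a_k)$,
$\rho_A = F / A_L$, $d = \sum_e w_e \ell_e / \sum_e \ell_e$. The mean
inter-vein distance $a$ has no closed form on an arbitrary network; we
estimate it as the mean distance to the nearest vein centerline over a
uniform grid of sample points inside the outline, spacing
$\min(0.1\,\mathrm{mm}, \text{leaf diameter}/500)$, capped at
`max_points` (default 40&nbsp;000) samples to keep the cost linear in
practice; the unit-square fixture, whose exact mean boundary distance is
side/6, pins the estimator's accuracy in the tests. Both the spacing and
the cap are arguments, so convergence can be checked by refinement.

## Comparison and classification

$D_{KS}$ between nesting-ratio samples is the exact sup-difference of the
two empirical CDFs, computed directly (and cross-checked against
`stats::ks.test` in the tests). It is a statistic, not a metric — no
triangle inequality is asserted. PCA standardizes the eight metrics first
(they carry incommensurate units), i.e. works on the correlation matrix.
LDA identification uses seeded stratified k-fold cross-validation;
feature standardization is fit on the training folds only, so nothing
leaks from held-out rows — the chance-level tests on label-permuted data
guard this. Classes with fewer rows than folds are dropped with a
warning rather than merged; accuracy is the plain fraction correct.
Welch's unequal-variance $t$ compares the two fold-accuracy samples of
the geometry-only and geometry-plus-topology feature sets.

## Fragmentation

`fragment_network()` cuts the blade into an axis-aligned grid of
`tile_cm` (default 1.2 cm) squares anchored at the bounding-box corner
(a seeded random-offset mode exists for robustness experiments). Edges
are clipped geometrically at tile borders and each tile is re-pruned, so
loops cut open at a border do not count as areoles — the conservative
reading under which an areole must be whole. Tiles with fewer than
`min_areoles` (default 10) facets are dropped; nesting statistics on a
handful of areoles are noise. Fragment fingerprints use the
`max_degree = 128` threshold.

## The growth model

The simulator doubles as the package's synthetic-data generator. It
starts from one rectangular loop and iterates: (i) all coordinates scale
by $1 + g$ per step (lamina expansion, default $g = 0.05$); (ii) every
existing vein width grows by $\alpha g w_0$; (iii) each areole
independently subdivides with probability
$p = \mathrm{logistic}((A - A_0)/\sigma_A)$, $\sigma_A = \beta A_0$, at
most once per step; a subdivision inserts a new width-$w_0$ vein
perpendicular to the areole's longer axis at relative position
$\tfrac12 + \rho(u - \tfrac12)$, $u \sim U(0,1)$, so areoles remain
rectangles throughout. Growth stops at `target_areoles`; then every
width is multiplied by $1 + f_n \xi$, $\xi \sim N(0,1)$, clipped below at
$0.05\,w_0$.

Where the published description left the functional form open we chose
once and exposed the choice: the sigmoid is logistic (an erf would be
near-indistinguishable at these $\beta$), the terminal noise is
multiplicative (a width-proportional error model, and clipping keeps
widths positive), and one split per areole per step. Default scales are
$A_0 = 0.01$ cm² (a 1 mm² critical areole, the order observed in cleared
leaves), $w_0 = 0.02$ mm (a 20 µm initial vein), initial rectangle
0.1 × 0.08 cm so growth, not the initial condition, drives the first
subdivision. The defaults `target_areoles = 256` and the published
parameter fits (low noise $\alpha=0.25, \beta=0.5, \rho=0.2, f_n=0.1$;
high noise $\alpha=0.25, \beta=0.3, \rho=0.2, f_n=0.45$) are the
reference conditions used throughout.

Two structural facts make the model a sharp test instrument. Each split
adds exactly one areole, so the final tree has one leaf per split plus
one. And with $f_n = 0$ width is strictly decreasing in creation time, so
the decomposition must reconstruct the recorded split genealogy *exactly*
— the tests assert clade-level identity. With noise, width ranks shuffle
and nesting degrades: ensemble-mean $i_u$ is non-increasing across
$f_n \in \{0, 0.2, 0.45\}$, and the low-noise fit ensemble is more nested
than the high-noise one.

What the generator emulates: hierarchical loop genesis, areole-size
regulation, developmental noise in widths, and the resulting nesting and
tapering statistics. What it does not: curved veins, non-rectangular
areoles, open veinlets (it never produces bridges), secondary thickening
patterns, or lobed blade outlines. Tests passing on simulated networks
therefore validate the topological machinery and the statistical
pipeline, not the geometric idiosyncrasies of real scans; the geometric
metrics are instead pinned by closed-form fixtures.

## Problem sizes and reproducibility

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which every property is sharply testable: oracle
comparisons on networks of up to 6 areoles (200+ random instances),
growth ensembles of 20 seeds at 96–128 areoles, a synthetic
identification study of 6 developmental classes × 12 leaves of 64
areoles. All stochastic paths flow through a single integer seed;
simulations and fold assignments are bit-reproducible, and RNG state is
always restored (`with_seed`), so library calls never perturb a caller's
stream.

## Known limitations

* Parallel edges between the same node pair are rejected (as straight
  segments they would coincide); genuinely distinct parallel veins must
  be discretized with an intermediate node.
* Facets meeting only at cut vertices are joined arbitrarily (with a
  warning) rather than by a principled rule.
* The inter-vein distance estimator is sampling-based; at the default
  cap its error is well below the between-specimen variation, but it is
  an estimator, not an exact quantity.
* The published ODS supplementary tables are not parsed directly; a CSV
  conversion with the documented column names is expected instead.
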