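# veintop

Topological phenotyping of planar reticulate networks — in particular the
minor venation of angiosperm leaves.

## The problem

The higher-order veins of most dicot leaves form a reticulate network of
recursively nested loops. Classical venation phenotypes are geometric:
vein density, areole size, vein diameter. They say nothing about *how the
loops are organized* — whether small loops nest evenly inside large ones or
chain off to one side, and how far tapered vein sequences run. `veintop`
quantifies exactly that architecture, for botanists characterizing
venation phenotypes and, more generally, for anyone analyzing a weighted
(sub-)planar network with loops: retinal or cortical vasculature, slime
mold foraging nets, river deltas, street networks.

## The method

Given a planar embedded graph with node coordinates (cm) and vein widths
(mm), the package:

1. **Prunes** everything that lies on no cycle (tree-like veinlets), leaving
   the loopy backbone, and extracts the **areoles** — the internal faces of
   the embedding.
2. Builds the **nesting tree** by hierarchical decomposition: repeatedly
   remove the thinnest vein separating two distinct facets and join the
   two facets' subtrees under a new internal node, until one facet — the
   whole blade — remains. Each internal node *j* carries the leaf counts
   *r*<sub>*j*</sub> ≥ *s*<sub>*j*</sub> of its two subtrees, the **nesting
   ratio** *q*<sub>*j*</sub> = *s*<sub>*j*</sub>/*r*<sub>*j*</sub>, and the
   subtree degree *d*<sub>*j*</sub> = *r*<sub>*j*</sub> + *s*<sub>*j*</sub>.
   The tree depends only on the *rank order* of vein widths, not on their
   values nor on geometric deformation.
3. Summarizes the tree by the **nesting numbers**
   *i* = Σ*w*<sub>*j*</sub>*q*<sub>*j*</sub> (unweighted *i*<sub>u</sub>;
   degree-weighted *i*<sub>w</sub> with *w*<sub>*j*</sub> ∝ *d*<sub>*j*</sub> − 1),
   computed over internal nodes with *d*<sub>*j*</sub> ≤ 256 for full leaves
   (≤ 128 for fragments), and by the **mean topological length**
   *L*<sub>top</sub> = (1/*N*<sub>E</sub>) Σ<sub>e</sub> *L*<sub>e</sub>,
   where *L*<sub>e</sub> counts the steps of the strictly width-decreasing
   greedy walk started at edge *e*.
4. Combines these with five geometric metrics (vein density σ, mean
   inter-vein distance *a*, mean areole area *A*, areole density
   ρ<sub>A</sub>, length-weighted mean diameter *d*) into an 8-metric
   **venation fingerprint**; compares networks by the two-sample
   Kolmogorov–Smirnov statistic *D*<sub>KS</sub> between nesting-ratio
   distributions; identifies specimens from 1.2 × 1.2 cm fragments by
   linear discriminant analysis with stratified cross-validation; and
   **simulates** minor-vein development with a stochastic loop-subdivision
   growth model controlled by four dimensionless parameters
   (α width/length growth, β = σ<sub>A</sub>/*A*<sub>0</sub> subdivision
   sharpness, ρ split asymmetry, *f*<sub>n</sub> width noise).

## Worked example

Grow a synthetic leaf at the low-noise parameter fit, decompose it, and
fingerprint it:

```r
library(veintop)

sim <- simulate_growth(growth_params(alpha = 0.25, beta = 0.5, rho = 0.2,
                                     f_n = 0.1, target_areoles = 128,
                                     seed = 42))
net <- prune_to_cycles(sim$network)
fingerprint(net, max_degree = 256)
#> vein_fingerprint:
#>   sigma = 6.24 mm/mm^2   a = 0.06609 mm   A = 0.1059 mm^2
#>   rho_A = 9.444 /mm^2   d = 0.02323 mm
#>   L_top = 2.221   i_u = 0.5657   i_w = 0.1812
```

σ = 6.2 mm of vein per mm² of blade; areoles average 0.11 mm²; tapered
walks run 2.2 edges on average; and the nesting number *i*<sub>u</sub> = 0.57
says loop merges are moderately balanced. Compare against a high-noise
leaf (β = 0.3, *f*<sub>n</sub> = 0.45, same seed):

```r
hi <- simulate_growth(growth_params(alpha = 0.25, beta = 0.3, rho = 0.2,
                                    f_n = 0.45, target_areoles = 128,
                                    seed = 42))
model_leaf_comparison(net, hi$network)
#>       area      L_top          q
#> 0.23437500 0.07792208 0.09448819
```

— the KS distances between the two networks' normalized areole-area,
topological-length and nesting-ratio distributions.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/veintop.R simulate --beta 0.5 --fn 0.1 --areoles 256 --seed 1 --out sim.graphml
Rscript inst/cli/veintop.R decompose sim.graphml --newick sim.nwk
Rscript inst/cli/veintop.R fingerprint sim.graphml --max-degree 256
```

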