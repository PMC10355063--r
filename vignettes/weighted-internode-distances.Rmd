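---
title: "Species trees from weighted average internode distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species trees from weighted average internode distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wastrid)
```

## The problem

Different regions of a genome can have different evolutionary histories:
under incomplete lineage sorting (ILS), modeled by the multispecies
coalescent (MSC), a gene's genealogy need not match the species phylogeny.
Summary methods first estimate a tree per gene and then combine those gene
trees into a species tree. This package implements a distance-based
summary method: for each pair of taxa $u, v$ and each gene tree $G$
containing both, it computes an intertaxon distance $d_G(u, v)$ along the
$u$–$v$ path in $G$, averages over exactly the genes containing both taxa,

$$D[u,v] \;=\; \frac{\sum_{G \in \mathcal{G}_{u,v}} d_G(u,v)}{|\mathcal{G}_{u,v}|},$$

and estimates the species tree from $D$ under balanced minimum evolution
(BME). As the number of genes grows, the average internode distance
converges to an additive matrix for the species tree, and BME — which has
a positive safety radius — then returns the true topology; this is the
consistency argument the method rests on.

Estimated gene trees carry error, and a uniformly weighted path length
treats confidently resolved and dubious edges alike. The package
therefore supports three weightings of the path sum
$d_G(u,v) = \sum_{e \in P_G(u,v)} w(e)$:

* **internode** — $w(e) = 1$: the classic edge-count distance;
* **support** — $w(e) = s(e)$, the edge's branch support normalized to
  $[0,1]$, with $s(e) = 1$ on leaf-incident edges (a trivial bipartition
  is always correct). Poorly supported edges then contribute little, which
  discounts unreliable parts of a gene tree without any contraction
  threshold;
* **length** — $w(e) = l(e)$, the branch length in substitution units,
  by default divided per gene by that tree's maximum leaf-to-leaf path
  length (its branch-length diameter), so genes with different rates
  become comparable.

Support weighting is the recommended default; length weighting is kept as
a cheaper proxy that needs no support estimation.

## Unrooted semantics and annotation handling

Newick storage is rooted, but every computation treats trees as unrooted:
a degree-2 root is suppressed before any path sum, so no result depends on
root placement. When the root's two edges merge, their lengths add. Their
support annotations describe the *same* unrooted bipartition, so the
merged edge takes the annotated value (or the mean when both edges are
annotated — identical annotations, the common case in real files, are
unchanged). Multiplying them instead would double-count one split's
uncertainty, and would break invariance under rerooting.

Supports are read from internal node labels (the FastTree/IQ-TREE
convention) or, behind a flag, from bracketed comments. Three raw scales
are supported, each mapped affinely onto $[0,1]$: `raw01` (identity),
`percent100` ($s/100$), and `abayes` ($(s - 1/3)/(2/3)$ — the analytic
minimum of approximate-Bayes support is $1/3$, and mapping it to 0 is the
natural affine choice; the scale is configurable precisely because only
"normalized to $[0,1]$" is canonical). Internal edges with *absent*
supports receive a configurable default of 1 with a warning: trusting an
unannotated edge degrades gracefully to the unweighted method, whereas
treating it as 0 would silently erase paths.

Per-gene distances are computed by one post-order sweep that carries, for
each visited node, the accumulated weights to the leaves below it and
combines child vectors across all unordered child pairs (polytomies are
handled directly). The work is $O(L^2)$ per gene with $L$ leaves —
asymptotically optimal, since that is the size of the output — giving
$O(kn^2)$ for the whole distance stage; the test suite asserts the
pair-combination count is exactly $\binom{n}{2}$ on binary trees.

## Missing data and the two-stage completion

Genes may lack taxa. Averages use per-pair gene counts, so partially
sampled genes simply contribute to fewer pairs. When some pair co-occurs
in *no* gene, the matrix has holes and is completed in two stages:

1. **UPGMA\*** clusters the masked matrix: clusters are joinable only if
   some cross-pair distance is defined, and the cluster distance is the
   mean of the defined cross-pairs. On a complete matrix this is exactly
   average-linkage UPGMA (asserted against `hclust`). Exact ties are
   broken by the lexicographically smallest pair of cluster
   representatives, so the clustering is platform-independent.
2. Missing entries are filled with topological (edge-count) path lengths
   on the UPGMA\* tree; a BME search restricted to NNI moves is run on
   that completed matrix; and the original matrix is re-completed from
   the NNI tree's path lengths. Defined entries are never altered — the
   suite asserts bit-level preservation.

A disconnected definedness graph is a hard error naming the components:
no principled between-component distance exists, and inventing one would
produce an arbitrary tree. A complete matrix bypasses the stage entirely.

## The BME engine

The search optimizes the Pauplin (balanced) length
$\sum_{u<v} 2^{1 - p_{uv}} D[u,v]$, where $p_{uv}$ counts edges between
leaves; on an additive matrix this equals the total branch length, and
for every binary tree the leaf weights satisfy
$\sum_{v \ne u} 2^{-p_{uv}} = 1/2$ — both identities are tested. The
search is: greedy taxon insertion (each new taxon subdivides the edge
minimizing the resulting score), NNI steepest descent to a local optimum,
then — in the default "accurate" setting — full SPR passes interleaved
with NNI re-convergence until no move improves. Design choices where the
convention is genuinely open:

* *Steepest descent, not first-improvement*, with ties broken by move
  enumeration order: reproducibility across platforms matters more than
  the marginal speed of first-improvement.
* *Move acceptance threshold* is relative, $10^{-10} \times$ the current
  score, so acceptance does not depend on the scale of the input matrix.
* *Insertion order* defaults to matrix row order (deterministic); a
  seeded random order is available for robustness studies.
* *Candidates are scored by full re-evaluation* of the Pauplin sum
  ($O(n^2)$ in compiled code) rather than incremental subtree-average
  updates: at the problem sizes this package targets the simpler scheme
  is fast enough, and it cannot drift from the objective it optimizes.
* Output is a topology; branch lengths are not estimated, since
  evaluation throughout is topological (RF-based).

## Evaluation utilities

Bipartitions are encoded canonically as the sorted side not containing
the smallest label, making them root- and orientation-independent. RF is
the symmetric difference over non-trivial bipartitions; nRF divides by
$2n-6$ for binary pairs and by the total non-trivial split count in
general. For gene trees missing taxa, per-pair statistics (GTEE, average
discordance) restrict both trees to the shared leaf set first — an
extension beyond complete-tree usage, flagged here. ILS bands from AD
follow the conventional cut points (L below 25%, M to 39%, H to 59%, VH
above); the undefined 25–26% sliver maps to M, the lower bound of the
next band.

## What the simulator emulates — and what it does not

The generator exists so every stage is testable offline:

* `random_species_tree()` draws uniform rooted binary topologies
  (sequential attachment over all edges plus a root stem, which makes all
  $(2t-1)$ placements of each new taxon equally likely) with branch
  lengths in coalescent units from a configurable law. The default,
  uniform on $[0.5, 2]$, gives moderate ILS — discordance levels in the
  M–H bands, typical of the empirical datasets this class of methods is
  run on.
* `msc_simulate()` runs a Kingman coalescent within each species branch
  (rate $\binom{j}{2}$ for $j$ lineages, uniform merging pair, infinite
  root branch). Its key calibration gate: on a quartet with internal
  branch $t$, the concordant-topology frequency must match
  $1 - \tfrac{2}{3}e^{-t}$ within binomial error.
* `inject_error()` emulates gene tree estimation error at tree level:
  random NNI moves, then supports drawn from a high law
  ($0.6 + 0.4\,\mathrm{Beta}(5,1)$) on edges whose bipartition exists in
  the true tree and a low law ($0.7\,\mathrm{Beta}(2,5)$) on edges
  created by error, plus log-normal length jitter. The laws are shaped so
  support correlates with correctness while the two distributions
  overlap; their exact calibration is deliberately not fitted to any
  particular inference tool.
* `delete_iid()` removes a fixed-size uniform taxon subset per gene;
  `delete_m_clade()` retains one uniformly chosen species-tree clade of
  size at least $\lceil xn \rceil$ (non-strict threshold; the root clade
  always qualifies, so larger $x$ deletes less).

What passing tests on these fixtures do *not* show: real gene trees are
estimated from finite alignments, so their errors are correlated with
branch lengths and with each other, supports are not Beta-distributed,
and missing data is rarely exactly i.i.d. or clade-shaped. The fixtures
validate the machinery and its statistical behaviour under the MSC, not
any claim about a particular empirical dataset.

## Validation scale and numerical conventions

The shipped checks run at desk scale, chosen to finish quickly while
still exercising every code path: distance oracles on trees up to 40
leaves against independent graph search; additive and near-additive
recovery for 4–20 taxa (noise bounded by half the minimum branch length,
the max-norm safety condition); exhaustive-enumeration comparisons up to
7 taxa (at most 945 topologies); consistency and clade-deletion
experiments on 16 taxa with up to 300 genes across 50–100 seeds.
Accumulation is plain double-precision summation (documented test
tolerance $10^{-9}$; compensated summation is unnecessary at these
magnitudes). Zero-length branches are kept as-is (they contribute 0 in
length mode); an all-zero-diameter gene is an error in `max_path`
normalization. Gene trees with fewer than two leaves yield an empty table
with a warning.

## Limitations

Single-copy, single-allele gene trees only (no multi-individual mapping,
no paralogy handling); no species-tree branch supports or lengths on the
output; statistical consistency does not extend to the i.i.d.
missing-data model (a known property of this family of methods); and the
search is a local heuristic — outside the safety radius it can return a
local optimum, which is why the SPR setting is the default.

## A worked example

```{r example}
sp <- random_species_tree(12, seed = 42)
genes <- msc_simulate(sp, k = 100, seed = 42)
noisy <- inject_error(genes, count = 2, seed = 42)
run <- infer_species_tree(noisy, mode = "support", support_scale = "raw01")
run
nrf(run$tree, sp)
```
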