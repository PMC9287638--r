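---
title: "Scoring differentiation-network activity in single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring differentiation-network activity in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffact)
```

## The model

Pluripotent cells keep a broad repertoire of signalling pathways active,
while committed cells concentrate expression on lineage-specific programs.
`diffact` turns this premise into a per-cell score by asking how active the
protein–protein interaction (PPI) network of the *cell differentiation*
biological process (GO:0030154 and its descendant terms) is in each cell.

Each network edge is treated as a putative elementary biochemical reaction.
Under the law of mass action, and ignoring stoichiometric detail, the
propensity of the reaction between proteins $i$ and $j$ is proportional to
the product of the reactant concentrations, which we approximate by the
transcript levels: $W_{ij} = A_{ij}\,x_i x_j$, with $A$ the undirected,
unweighted adjacency matrix. The differentiation activity of cell $k$ is
the accumulated propensity of the whole network,

$$P_k \;=\; \sum_{i,j} A_{ij}\, x_{ik}\, x_{jk},$$

min–max scaled across the cells of the data set,
$P^{\mathrm{scaled}}_k = (P_k - \min_k P)/(\max_k P - \min_k P)$.

Assumptions worth making explicit:

* transcript abundance proxies protein abundance at the resolution the
  ranking needs;
* the network is undirected and sign-blind — activators and repressors
  contribute alike;
* absolute values of $P_k$ are meaningless across data sets; only the
  scaled, within-data-set comparison is interpretable (the min–max scaling
  makes the score population-relative by construction);
* the score accepts any non-negative matrix; zeros are fine because a zero
  simply silences the edges incident to that gene.

### Edge-counting convention

The double sum above runs over a symmetric $A$, so every undirected edge is
counted twice. Summing each unordered edge once gives exactly half the raw
value and — because min–max scaling absorbs any global factor — the *same*
scaled score. The package sums each edge once by default
(`convention = "edge_once"`); `"symmetric_double"` reproduces the literal
double sum for raw-value comparability. Self-loops, when retained at
network-build time, contribute $x_i^2$ once under either convention: a
doubled diagonal would reward isolated gene expression rather than
interaction. Scaled-score invariance between the two conventions is
asserted to $10^{-12}$ in the test suite.

### Genes missing from the matrix

Edges whose endpoint is absent from the matrix are dropped — numerically
identical to setting the missing gene to zero, but reported separately:
every result carries `gene_coverage` and `edge_coverage` so network
attrition is never silent. A gene removed by QC filtering is likewise
*absent*, not zero. Symbol matching is exact string equality after
uppercasing; no alias resolution is attempted (a documented limitation —
identifier drift between annotation snapshots and expression references
will show up as reduced coverage, not as silent mis-scoring).

## Network construction

`build_network()` assembles the edge list from two inputs: a tab-separated
GO-annotation export (symbol, GO-ID and taxon columns located by name) and
a SIF interaction dump (`participant_a TAB type TAB participant_b`, extra
columns ignored). A row survives when neither participant carries a
chemical-compound prefix (default `CHEBI:`) and both are catalog members;
survivors are deduplicated as unordered pairs and self-pairs dropped by
default. Each input row is attributed to exactly one fate (chemical,
out-of-catalog, self-loop, duplicate, retained), so the per-reason counts
always sum to the row count — the conservation law the tests assert.

Two design points were genuinely open:

* **Descendant terms.** The descendant closure of GO:0030154 changes with
  every ontology release. The builder takes the descendant list as an
  explicit argument instead of bundling ontology traversal, which keeps the
  build offline and reproducible against a frozen annotation export.
* **Self-loops.** Interaction dumps occasionally list self-associations.
  They are dropped by default (see above) and retainable with
  `keep_self_loops = TRUE`.

## Preprocessing

Cell QC retains cells with 200–3000 detected features, at most 12000 total
counts and at most 5 % mitochondrial content (`MT-` prefix); genes must be
detected in at least 3 cells (inclusive boundary). The feature bounds
remove debris/empty droplets from below and doublets from above; the count
ceiling is likewise a doublet guard. Cells are filtered before genes, and
the order matters (it is asserted in the tests: gene detection counts
change once cells are removed). All thresholds are plain arguments of
`filter_config()` and CLI flags.

Two normalizations are provided:

* `lognormalize()` — counts divided by the cell total, times a scale
  factor (default $10^4$), natural-log transformed with a pseudocount of
  one. Zeros stay zero, sparsity is preserved, and the result is invariant
  to per-cell library-size rescaling (property-tested).
* `offset_lognormalize()` — the same library-size scaling, then
  $\log_2(1.1 + \cdot)$. The offset of 1.1 makes every entry strictly
  positive ($\log_2 1.1 \approx 0.1375$ for a zero count), which matters
  only for downstream methods that reject zeros; the activity score itself
  does not need it. The base-2 log follows the convention of the
  entropy-rate tooling this variant exists to feed; offset and base are
  configurable.

### Highly variable features

`select_hvf()` implements the vst ranking: per-gene mean and variance of
the raw counts; a loess fit (span 0.3, degree 2) of $\log_{10}\sigma^2$ on
$\log_{10}\mu$ over genes with positive variance; counts standardized by
the fitted standard deviation and clipped above at $\sqrt{N_{\mathrm{cells}}}$;
genes ranked by the variance of the standardized values (computed about the
raw mean, denominator $N-1$). Span and clip are exposed as parameters;
their defaults follow the widely used single-cell implementation of this
procedure, against which our version is cross-checked in the test suite
(standardized variances agree to $10^{-10}$ on simulated counts).

`activity_hvf()` selects features on the *counts*, normalizes the *full*
matrix, and only then subsets the rows to the selection — normalization is
never recomputed from reduced totals. The reduced matrix is scored against
the same, unreduced edge list; coverage reflects the reduced run. With
`n_hvf` equal to the gene count the result is identical to the full score
(identity-tested to $10^{-12}$).

## The synthetic-data generator

`simulate_counts()` emulates just enough of droplet scRNA-seq for the
validation logic: per-gene baseline means drawn from a log-normal
(sdlog 1) around `nb_mean = 2`, counts drawn negative-binomially with size
`nb_dispersion = 5` — moderate overdispersion typical of UMI-collapsed
data — and a latent potency $p_k$ per cell (uniform, or a balanced binary
split) that multiplies the expected counts of the network genes by
$1 + \mathrm{effect}\cdot p_k$. This multiplicative mechanism is the
minimal realization of the premise that more pluripotent cells run the
differentiation network more broadly. Under these study conditions
(300 cells, 100 network genes at edge density 0.1, effect 3) the raw
activity recovers the potency ranking with Spearman $\rho \ge 0.95$, and
the null (effect 0) stays below $|\rho| < 0.2$ — both recomputed by
`scripts/acceptance.R` at run time.

What the generator does *not* emulate: batch effects, ambient RNA,
doublets, branching lineages, gene–gene correlation beyond the shared
potency factor, and the quiescent-stem-cell confounder (low-RNA stem cells
score low under any expression-sum method, transit-amplifying cells score
high). Passing tests therefore demonstrate the algorithmic contracts —
oracle equivalence, convention invariance, gradient recovery under the
stated mechanism — not biological validity on real tissues.

## Numerical choices

* Accumulation in double precision; per-cell sums follow edge-list order,
  so identical inputs give bitwise-identical outputs (the determinism
  test compares file hashes).
* Streaming evaluation: the score is computed as a sum over the edge
  index pairs against the sparse matrix; memory beyond the input is one
  vector per cell population.
* Min–max scaling of a constant raw vector is undefined; the package
  returns all zeros with a warning rather than NaN.
* Score files are written with 17 significant digits so the disk round
  trip is exact.
* Problem sizes in tests (≤ 500 genes, ≤ 300 cells, 100 random oracle
  instances) were chosen to pin the contracts tightly while keeping the
  default suite fast on a laptop.

## Limitations

* No identifier mapping: symbol mismatches silently reduce coverage
  (which is reported) rather than being resolved.
* The published node/edge census of any particular annotation snapshot is
  not reproducible from a different snapshot; the builder guarantees the
  filtering semantics, not the counts.
* The score is expression-sum-like and inherits the known failure modes of
  that family on quiescent stem cells and highly proliferative
  transit-amplifying populations.
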