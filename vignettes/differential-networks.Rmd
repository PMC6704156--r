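---
title: "Differential Spearman correlation networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential Spearman correlation networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcornet)
```

## The analysis model

`dcornet` implements a two-state differential co-expression analysis for
tumour cohorts. The scientific question is whether the correlation structure
of a gene panel — here motivated by the kynurenine pathway (IDO1/2, TDO2,
KMO, KYNU, CCBL1/2, GOT2, AADAT, ACMSD) and CD4+ T-cell-related genes in
metastatic melanoma — differs between two sample conditions such as BRAF
wild-type and BRAF V600E tumours.

The model is deliberately minimal and unweighted. Within each condition,
co-expression between genes $i$ and $j$ is summarized by Spearman's
$\rho_{ij}$ (Pearson correlation of mid-ranks; average ranks under ties;
pairwise-complete observations, since public expression tables have sporadic
gaps). A network places an edge wherever $|\rho_{ij}| \ge t$. Edges retain
the signed $\rho$ as an annotation, but all downstream topology treats the
graph as a simple unweighted graph — the metric suite (density, clustering,
centralization, heterogeneity, distances, betweenness) is the standard
unweighted one, matching how such networks are profiled in practice (e.g.
Cytoscape's NetworkAnalyzer).

No p-value filter is applied by default: the operational definition of an
edge is the absolute-correlation threshold itself. At the cohort sizes this
analysis targets (hundreds of samples per condition), $|\rho| \ge 0.5$ is
far beyond any conventional significance cutoff, so the threshold, not the
test, is the binding constraint.

## The non-fragmentation threshold rule

Rather than fixing $t$ a priori, the threshold can be chosen as the *highest
value at which the network is not fragmented*: `select_max_connected_threshold()`
scans $t \in \{0.01, 0.02, \dots, 1\}$ from the top down and returns the
largest $t$ whose network is a single connected component. Edge count is
monotone non-increasing in $t$, but connectivity is not monotone in general
(a graph can pass through several fragmented regimes), which is why the rule
is defined — and implemented — as an exhaustive grid scan rather than a
bisection.

"Fragmented" needs a node policy, and the choice matters:

* **nonisolated** (default): one component among the genes that retain at
  least one edge. Isolated genes are ignored, mirroring how correlation
  networks are usually drawn (panel genes with no surviving edge simply do
  not appear).
* **strict**: additionally every panel gene must be reachable, i.e. no gene
  may lose all its edges.

The two policies can select very different thresholds. On a panel with one
tight module and several weakly connected genes, the nonisolated policy
follows the module (high $t$), while the strict policy is pinned by the
weakest gene's strongest correlation (low $t$). Both are first-class options,
both are tested against an exhaustive scan oracle, and the pipeline reports
the selected value instead of hard-coding one; a fixed `threshold: 0.5` in
the config reproduces the melanoma study's operating point.

## Topology conventions

Several metrics have convention traps; the package pins them as follows,
chosen for compatibility with NetworkAnalyzer-style reports:

* Clustering coefficient of a degree-$<2$ node is 0 and **included** in the
  network average (a flag excludes such nodes instead).
* Freeman degree centralization is $\frac{n}{n-2}\left(\frac{k_{\max}}{n-1}
  - \text{density}\right)$ — exactly 1 for a star, 0 for any regular graph —
  and is reported as `NA` for $n < 3$, where it is undefined.
* Heterogeneity is the coefficient of variation of the degree distribution
  with the *population* variance.
* Betweenness (node and edge) is unnormalized Brandes betweenness over
  unordered pairs with endpoints excluded. Ranks (1 = highest, ties share
  the minimum rank) are what the differential comparison consumes, and ranks
  are invariant to normalization anyway.
* The degree median of an even node count is the mean of the two central
  order statistics, so half-integer medians are expected.
* On a fragmented graph, diameter, radius, eccentricity and average shortest
  path length are computed on the largest connected component and the report
  carries a `fragmented` flag; a mean over components is also reported,
  since the two readings differ and either may be wanted. Networks built at
  an auto-selected threshold are connected by construction.

## The rewiring score

Two condition networks are merged into a union graph with edge classes
`both`, `A_only`, `B_only`. For a node with $b$ incident A-only and $c$
incident B-only edges, the rewiring score is

$$D_n = \sqrt{b + c},$$

the square root of the symmetric-difference count of the node's incident
edge sets — the two-state specialization of the DyNet "most rewired nodes"
score (up to the constant two-state factor, which affects no ranking). The
degree-corrected variant divides by $\max(1, (k_A + k_B)/2)$, so hubs are
not flagged merely for having many edges, and the floor of 1 keeps scores
finite for nodes isolated in both states. Nodes absent from one condition
count degree 0 and betweenness 0 there — necessary so that a gene which
loses its entire neighbourhood (the KMO/KYNU pattern) ranks at the top
rather than dropping out of the comparison. Betweenness variation is the
absolute difference $|B_A - B_B|$, and edge-rank shifts are reported as
$\mathrm{rank}_A - \mathrm{rank}_B$ (positive = more central in condition
B).

No significance is attached to rewiring scores; the analysis is a ranking,
and a permutation null on edges is out of scope.

## Stratification

Sample stratification uses Ward linkage on Euclidean distances over the
signature genes, cut at $k = 2$; the cluster with greater mean signature
expression is *high*. Genes are ordered for heatmaps by Ward linkage on the
correlation distance $d = 1 - r$ (Pearson by default; the source analyses
say only "a correlation coefficient", so a Spearman variant is a flag).
Signature genes are z-scored per gene before clustering by default — the
standard convention for signature heatmaps, exposed as a flag because raw
and z-scored distances can split borderline samples differently. Ties in
the high/low labelling (exactly equal means) break deterministically by
cluster size, then lexicographically smallest sample id. The `ward.D2`
implementation is verified against an independent Lance–Williams
implementation on small point sets in the test suite.

## The simulator and what it does (not) show

`generate_cohort()` draws each condition's samples from a zero-mean
multivariate Gaussian whose correlation matrix is implied by disjoint gene
blocks (correlation `r_within` inside a block, `r_between` — default 0 —
elsewhere), adds independent noise of SD `noise_sd`, and shifts a fraction
`frac_high` of samples by `+shift` on every signature gene. Rewiring is
planted by moving genes from one block into a new block in condition B, so
both the moved genes and the ones they leave behind have a changed planted
neighbourhood. Ground truth is exact: independent noise attenuates the
latent correlation $r$ to $r/(1 + \sigma^2_{noise})$, and the population
Spearman correlation of a bivariate Gaussian is the closed form
$\rho_S = \frac{6}{\pi}\mathrm{asin}(r/2)$ (`population_spearman()`), which
the test suite checks against large-sample Monte-Carlo estimates. An
optional `exp()` map gives skewed, RSEM-like marginals without touching any
rank-based truth.

Defaults, fixed once as the package's study conditions: 30 genes in three
blocks of eight plus six singletons, `r_within = 0.7`, four genes moved to a
new block in condition B, 300 samples per condition, `noise_sd = 0.3`
(modest measurement noise against unit biological variance), `shift = 2`,
`frac_high = 0.5`. With these values the attenuated within-block Spearman is
$\approx 0.63$, comfortably above the 0.5 operating threshold at $n = 300$
(pair SE $\approx 0.06$), so planted edges are recovered with near-certainty
— the regime the method is meant for, where network differences reflect
structure rather than sampling noise.

Stratification-recovery checks use a separate cohort with a 20-gene
mutually-uncorrelated signature panel at `noise_sd = 1` and
`shift = 2·noise_sd` over 100 samples. This emulates the realistic setting
where the signature is a larger list than the network panel and its genes
co-vary across the cohort *because of* the phenotype split rather than
through background co-regulation; the planted group separation is then
$\approx 6\sigma$ along the signature mean and Ward recovery is essentially
deterministic (ARI $\ge 0.9$). With strongly co-correlated signature genes
and small shifts the split becomes genuinely ambiguous — a property of the
problem, not of the implementation.

What passing these tests does **not** show: the simulator has Gaussian
copulas, no count noise (no negative-binomial realism), no batch effects,
no missing-at-random structure, and block-constant correlations. Real
cohorts violate all four; the tests establish correctness of the machinery
and calibration of its statistics, not field performance on any particular
tumour dataset.

## Numerical and engineering choices

* Thresholds are compared with `>=` on a grid rounded to 10 decimals;
  correlations enter the comparison at full double precision.
* Duplicate gene symbols in expression tables collapse to the highest-mean
  row; symbols are matched case-insensitively after stripping a
  `|entrez`-style suffix.
* Expression values are used as provided; `log2(x+1)` is a flag, default
  off — it cannot change any Spearman quantity and only affects Euclidean
  stratification and heatmap export.
* Constant genes are dropped (with a warning and a record) wherever a
  correlation is undefined; constant rows in heatmap export z-score to 0.
* Pipeline outputs are byte-deterministic given config + inputs: all
  stochastic steps run under the single config seed, numeric output uses
  fixed formatting, and timing information goes to the log stream, not to
  the manifest.
* Test and simulation problem sizes (300 samples/condition for network
  recovery, 100 for stratification, 20 replicates at $n = 2000$ for the
  copula calibration, 50-seed threshold-scan equivalence) were chosen so
  each property is measured well inside its sampling tolerance while the
  whole suite stays fast.

## Known limitations

* Two states only; the multi-state DyNet generalization is not implemented.
* No weighted topology, soft thresholding (WGCNA-style), or partial
  correlations.
* No statistical test on correlation differences between conditions.
* The automatic threshold is a global connectivity criterion; on panels with
  strong modules plus stragglers the two node policies bracket, rather than
  settle, the "right" cutoff — both are reported side by side for that
  reason.
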