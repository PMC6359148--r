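---
title: "Methods and design notes for netreporter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for netreporter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`netreporter` implements a network-based biomarker workflow for
case/control transcriptomes: differential expression, mutual-DEG
intersection across cohorts, gene-set overrepresentation, PPI hub and
module mining, reporter-regulator scoring, prognostic risk
stratification, and hypergeometric drug repositioning. This vignette
records the statistical models behind each stage, the tunable parameters
and their defaults, the design decisions that were genuinely open, and
what the synthetic-data generator does and does not emulate.

## Differential expression

`gene_statistics()` fits, per gene, the two-sample contrast of
log2-expression means (case − control). The default statistic is an
empirical-Bayes **moderated t**: with per-gene pooled variance
$s_g^2$ on $d = n_1 + n_2 - 2$ degrees of freedom, a scaled
inverse-chi-square prior $(d_0, s_0^2)$ is fitted by method of moments on
$\log s_g^2$ — the excess of $\mathrm{var}(\log s_g^2)$ over
$\psi'(d/2)$ identifies $d_0$ through the trigamma function, inverted by
Newton iteration — and the posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d\, s_g^2) / (d_0 + d)$ replaces $s_g^2$ in
the t statistic, which gains $d_0$ degrees of freedom. Moderation
matters here because the emulated designs have very few controls (5 and
9); a plain Welch t is available via `method = "welch"`.

Numerical edge cases: a gene with zero variance in both groups and equal
means gets $p = 1$; if every gene has zero variance the statistic
degenerates to a sign test on the mean difference ($p = 1$ when the
difference is 0, otherwise ~0).

DEG calling (`call_degs()`) uses **adj-p < 0.01 (strict) and
|log2 FC| ≥ 1** (fold-change cutoff 2) by default. The fold-change
filter is applied to the difference of log2 means, not to the ratio of
anti-logged means — the data are modelled on the log scale, where the
group mean is the natural location parameter; the two conventions
coincide for exact shifts and differ only through the noise distribution.
Benjamini–Hochberg adjustment is the standard step-up procedure
(`stats::p.adjust`, validated in the test suite against an independent
brute-force implementation).

`mutual_degs()` intersects same-direction calls across all cohorts.
Genes absent from any cohort are dropped with a message (platform
universes rarely coincide exactly); a gene up in one cohort and down in
another lands in neither output.

## Overrepresentation

`enrich()` performs the one-sided Fisher exact test: the probability of
an overlap at least as large as observed is the upper hypergeometric
tail $P(X \ge k)$ with parameters (universe $N$, set size $K$, query
$n$). The **universe defaults to the genes annotated in the collection**
(the convention of annotation web services), not the assay universe;
pass `universe=` to `gene_set_collection()` to override. Query genes
outside the universe are dropped, with a message, *before* the query
size is computed, and **coverage is reported as $100\,k/n$ over the
mapped query**. Up- and downregulated queries are tested separately, as
their biology usually differs. Plain Fisher is used rather than the
jackknifed (EASE-style) variant some services apply; with the moderate
set sizes simulated here the difference is immaterial, and the plain
test is the one with exact finite-sample guarantees.

## Network analysis

`induce_subnetwork()` keeps the DEG-encoded proteins plus (by default)
their first neighbors — the common interactive-network practice; set
`neighbors = 0` for the strict induced subgraph. Centralities come from
igraph: degree, and exact unnormalized Brandes betweenness with
fractional counting over tied geodesics. The largest connected component
is *not* extracted first; disconnected pairs simply contribute no
betweenness.

**Hub selection** (`select_hubs()`) combines a local metric (degree) and
a global one (betweenness). The default rule is top-list intersection:
both rankings are cut at length $m$, starting at `n_hubs` and growing
$m$ until the intersection reaches `n_hubs` nodes; final ordering is by
degree rank, ties by betweenness rank, then node id, making the result
independent of node insertion order. A rank-sum combination is available
(`method = "ranksum"`) because the literature uses both and they can
disagree on graphs where the two metrics diverge.

**Module detection** (`mcode_modules()`) re-implements the MCODE
procedure: each vertex is weighted by the highest k-core of its closed
neighborhood (core number × core density); seeds are processed in
descending weight; neighbors are recruited while their weight is at
least $(1 - \mathrm{vwp})$ × seed weight; each node joins at most one
module. Post-processing discards modules without a 2-core, the haircut
iteratively trims members with intra-module degree < 2, and optional
fluff adds dense neighbors. Defaults are the established plugin
defaults: `vwp = 0.2`, haircut on, fluff off, minimum size 3. Modules
are scored by density × size.

One documented consequence of the recruitment rule: two equal-size
cliques joined by a single bridge edge have *identical* vertex weights
everywhere, so greedy expansion crosses the bridge and returns one
merged module. This is the behavior of the published procedure; the
synthetic generator therefore keeps planted cliques non-adjacent to
other dense regions (see below) so that module recovery measures the
detector, not bridge artifacts.

## Reporter regulators

`reporter_table()` scores each TF and miRNA by how perturbed its target
set is relative to chance. Gene-level two-sided differential-expression
p-values (raw, not BH-adjusted — adjustment would distort the
transform's null distribution; `use_adjusted = TRUE` is available) are
transformed to $z_g = \Phi^{-1}(1 - p_g)$, clamped to $\pm 8$ (p = 0 is
clamped to the machine floor with a warning). A regulator with $k$
scored targets gets

$$z_{\mathrm{raw}} = \frac{\sum_{g \in \mathrm{targets}} z_g}{\sqrt{k}},$$

which is standard normal for independent null targets, and is then
**background-corrected** against the empirical null of uniformly drawn
size-$k$ gene sets: $z_{\mathrm{corr}} = (z_{\mathrm{raw}} - \mu_k) /
\sigma_k$ with $\mu_k, \sigma_k$ estimated from `n_samples = 10000`
Monte-Carlo draws (seeded per $k$, so results do not depend on regulator
processing order). The correction absorbs the heavy tails that clamping
and real p-value distributions induce; under permuted gene labels the
corrected scores are standard normal to within Monte-Carlo error (tested:
mean within ±0.1, SD within (0.9, 1.1) over 1000 pooled null
regulators).

p-values are the upper normal tail of $z_{\mathrm{corr}}$, BH-adjusted
**within regulator type** (TF and miRNA separately, as the two lists are
reported separately and have very different network sizes), significant
at adj-p < 0.01. `min_targets = 2` keeps the √k aggregation meaningful;
regulators below it are skipped with a message. The default transform is
direction-agnostic (regulators of coherently up- or downregulated
targets both score high); `signed = TRUE` multiplies each target's z by
the sign of its log fold change for the directional variant.
`mutual_reporters()` intersects significant sets across cohorts,
mirroring the mutual-DEG design.

## Survival stratification

`cox_fit()` maximizes the Cox partial likelihood with the **Efron tie
correction** (the better approximation under heavy ties; ties are common
in registry data) via `survival::coxph`, with explicit failures on zero
events, constant covariates and collinear designs, and a non-convergence
flag rather than a silent result. `prognostic_index()` computes the
uncentered linear predictor $\mathrm{PI}_i = \sum_g \beta_g x_{ig}$.

`partition_and_test()` splits the cohort at the **median PI** (high PI =
high risk). An optimized split point is a known alternative, but it
inflates the apparent contrast unless cross-validated, so the median is
the default and any quantile can be passed instead. The high-vs-low
hazard ratio is reported two ways, since either could be meant by a
"signature hazard ratio": from a univariate Cox fit on the group
indicator (`hazard_ratio`, with 95% CI), and as
$\exp(\overline{\mathrm{PI}}_{\mathrm{high}} -
\overline{\mathrm{PI}}_{\mathrm{low}})$ implied by the multivariate
model (`hr_model`). Group separation is tested by the standard two-group
log-rank statistic (χ², 1 df; α = 0.05), and per-covariate expression
differences between risk groups by **Welch's t** (the equal-variance
assumption buys nothing here and costs robustness).

## Drug repositioning

`associate_drugs()` tests each drug's target set against the disease
gene set with the same upper hypergeometric tail as the enrichment
stage, BH-adjusted across drugs at α = 0.05 (a conventional screening
level). The **universe defaults to all genes in the drug–target table**
(the convention of drug–gene interaction databases) and is configurable.
The disease set is the mutual DEGs by default; restricting to hubs plus
reporter TFs — treating the network-prioritized proteins as the
druggable targets — is a supported variant (pass that gene set
directly). `intersect_sources()` keeps drugs supported by two evidence
sources (significant in both by default; `rule = "either"` relaxes one
side), because agreement between independent databases is the practical
filter against database-specific artifacts. Connectivity-map-style
signature-reversal scoring is *not* implemented; the second source
enters purely as a drug–gene evidence table. `classify_drugs()` tallies
unique drugs by development status and ATC class with percentages
rounded to two decimals.

## The synthetic-data generator

`simulate_bundle()` creates every pipeline input with planted truth.
Defaults mirror the emulated study conditions: two cohorts of 74/5 and
132/9 case/control samples (206 cases, 14 controls in total), 2000
genes with 150 + 50 planted up/down genes at log2 fold change 2 and
Gaussian log-scale noise (SD 0.5 — array-like per-gene noise), a
500-node preferential-attachment PPI graph, 50 TFs + 30 miRNAs with 20
targets each, 10 + 10 planted reporters whose targets are drawn from
planted DEGs at fraction 0.8, a 467-patient survival cohort, and 10
planted drugs among 200 decoys with 8 of 10 targets inside the DEG set.

Design choices worth recording:

* **Noise is Gaussian on the log2 scale** — the pipeline consumes
  normalized log expression, so probe-level simulation is out of scope.
  Baselines are uniform on [4, 12] per dataset; each dataset has its own
  noise stream but all share one truth, mirroring a two-accession
  mutual-DEG design.
* **PPI topology is preferential attachment** (scale-free, heavy-tailed
  degrees, small-world) — the stylized facts of biological interactomes.
  Planted hubs occupy the topologically central positions (the
  highest-degree attachment nodes) and receive 80 extra edges each to
  DEG-encoded nodes, so they dominate both hub metrics by construction.
  Hubs are kept pairwise non-adjacent: their neighborhoods stay
  star-like, which keeps hub status a property of centrality rather than
  of local density.
* **Planted modules are cliques on low-degree nodes**, kept as separate
  dense units: chance edges between cliques, from cliques to the
  boosted-hub region, and all but one anchoring edge to the sparse
  background are removed, and the anchor's endpoint must itself sit in a
  sparse spot (core-clustering weight ≤ 2, below a size-4 clique's
  recruitment threshold). Without this, greedy module expansion can
  legitimately chain a clique into a foreign dense region through a
  single boundary vertex — a property of the detector that the module
  recovery benchmark should not conflate with detection failure.
* **Survival times are exponential** with hazard
  $h_0 \exp(\sum_g \beta_g x_g)$ over the planted hub genes' simulated
  expression. The common coefficient is derived from a target
  median-split hazard ratio: a median split of a Gaussian PI separates
  the group means by $2\sqrt{2/\pi}\,\mathrm{sd}(\mathrm{PI})$, so
  $\beta = \log(\mathrm{HR}) / (2\sqrt{2/\pi}\,\sigma_x \sqrt{k})$
  targets the configured `signature_hr = 2.5`. Censoring is independent
  and uniform within each patient's follow-up at an expected rate of
  0.3 (registry-like); the realized group hazard ratio is mildly
  attenuated relative to the target by within-group PI dispersion, which
  the `hr_model` output makes visible.
* **Drug status frequencies** (49% approved / 48% investigational / 3%
  experimental) and a small ATC class palette echo the composition of
  repositioning screens.

What the generator does **not** emulate: real marginal expression
distributions, batch or platform effects, probe→gene many-to-one
mapping, correlated co-expression structure, dependence between
regulators' target sets and the PPI, non-proportional hazards, and
informative censoring. Passing tests therefore demonstrate that each
stage recovers the signal class it is designed for under its own model
assumptions — not that those assumptions hold in any particular public
dataset.

## Verification strategy and problem sizes

The test suite checks exact kernels against independent brute-force
oracles (hypergeometric tails by full enumeration up to N = 12,
betweenness by pair-counting path enumeration on graphs up to 30 nodes,
BH against a direct step-up implementation), hand-computed small cases
(product-limit survival, log-rank tabulation, prognostic-index
arithmetic), cross-checks against an independent empirical-Bayes
implementation for the moderated t, and recovery/calibration simulations:
200 two-cohort replicates (10 vs 10, 2000 genes) for mutual-DEG
sensitivity and FDR; 5 × 200 permuted-label regulators with 10,000
background draws for reporter calibration (pooling permutations keeps
the Monte-Carlo error of the mean near 0.03, well inside the ±0.1
calibration band); 50 replicates each for planted-reporter ranking,
survival power at n = 400 and planted-drug ranking; and 200 Cox fits at
n = 1000 for coefficient recovery. These sizes were chosen so the whole
suite runs in about two minutes on one CPU while leaving binomial noise
well below every margin tested.

## Known limitations

* The moderated t assumes a common variance prior across the genome; a
  single strongly heteroskedastic block can shift the prior fit.
* Monte-Carlo background correction adds seed-dependent noise of order
  $1/\sqrt{n_{\mathrm{samples}}}$ to each $z_{\mathrm{corr}}$; raise
  `n_samples` for tighter reporter p-values near a threshold.
* MCODE module boundaries depend on the vertex-weight percentage; with
  `vwp = 0.2`, modules bridged by high-weight vertices merge (by
  design of the procedure).
* The median-PI split estimates the group hazard ratio without
  cross-validation; treat it as descriptive, not as an unbiased effect
  estimate, when covariates were themselves selected on the same data.
* `run_pipeline()` writes a timestamped manifest; stage *outputs* are
  byte-reproducible under a fixed seed, the manifest is not.
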