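# netreporter

Systems-biomedicine biomarker discovery for case/control transcriptomes,
implemented as a tested, reusable R pipeline. Given two (or more)
log2-expression cohorts, a protein–protein interaction (PPI) network, a
TF/miRNA→target regulatory network, clinical survival data and a
drug–target table, the package chains:

1. **Differential expression** — per-gene empirical-Bayes moderated
   *t*-statistics (gene-wise variances shrunk toward a method-of-moments
   prior), Benjamini–Hochberg FDR control, and calling of DEGs at
   adj-*p* < 0.01 with a fold-change cutoff of 2; genes called in the same
   direction in every cohort form the **mutual DEG** sets.
2. **Overrepresentation** — one-sided Fisher exact (upper hypergeometric
   tail) tests of the mutual DEGs against a GMT gene-set collection,
   BH-adjusted, significant at adj-*p* < 0.05.
3. **Network mining** — the PPI subnetwork induced on DEG-encoded proteins
   plus first neighbors; **hub proteins** as the intersection of the top
   lists by degree (local metric) and betweenness centrality (global
   metric); dense modules by an MCODE-style algorithm
   (core-clustering-coefficient vertex weights, greedy seed expansion,
   haircut post-processing).
4. **Reporter regulators** — each gene's differential-expression *p*-value
   is transformed to *z* = Φ⁻¹(1 − *p*); a regulator with *k* scored
   targets gets *z*_raw = Σ*z*/√*k*, standardized against Monte-Carlo
   random same-size gene sets, *z*_corr = (*z*_raw − μ_k)/σ_k; TFs and
   miRNAs are BH-adjusted separately and reported at adj-*p* < 0.01.
5. **Survival stratification** — multivariate Cox proportional-hazards fit
   (Efron ties), per-patient prognostic index PI = Σβ·x, median-PI split
   into low/high-risk groups, hazard ratio of the group indicator,
   Kaplan–Meier curves, log-rank test (α = 0.05) and per-gene Welch
   *t*-tests between risk groups.
6. **Drug repositioning** — per-drug upper-tail hypergeometric association
   of drug-target sets with the disease gene set, BH-adjusted,
   intersected across two evidence sources, and tallied by development
   status and ATC class.

A first-class **synthetic-data module** generates every one of these
inputs with planted ground truth (known DEGs, hubs, clique modules,
reporter regulators, prognostic effect sizes and enriched drugs), so the
full chain is testable end to end without any external database.

## Worked example

```r
library(netreporter)

cfg    <- sim_config(seed = 42)      # two cohorts: 74/5 and 132/9 case/control
bundle <- simulate_bundle(cfg)       # expression, PPI, regnet, survival, drugs

stats <- lapply(bundle$datasets, gene_statistics)
degs  <- lapply(stats, call_degs, alpha = 0.01, fc_cutoff = 2)
mut   <- mutual_degs(degs)
length(mut$up); length(mut$down)
#> 150 mutual up, 50 mutual down        (all 200 planted DEGs, no false calls)

sub  <- induce_subnetwork(bundle$network, c(mut$up, mut$down))
hubs <- select_hubs(centralities(sub), n_hubs = 10)
setequal(hubs, bundle$truth$planted_hubs)
#> TRUE                                  (dual-metric hubs = the 10 planted)

rep1 <- reporter_table(stats[[1]], bundle$regnet, seed = 1)
head(rep1[, c("regulator", "type", "k", "z_corr", "adj_p")], 5)
#>   regulator  type  k   z_corr        adj_p
#> 1    miR008 miRNA 20 10.24932 1.787694e-23
#> 2     TF020    TF 20 10.14144 6.838418e-23
#> 3    miR026 miRNA 20 10.14008 1.916718e-23
#> 4    miR021 miRNA 20 10.13577 1.916718e-23
#> 5    miR015 miRNA 20 10.08011 2.536910e-23

fit  <- cox_fit(bundle$survival)
part <- partition_and_test(fit, bundle$survival)
part
#> risk_partition: 234 low / 233 high risk
#>   group hazard ratio 2.941 (95% CI 2.315-3.737); model-implied 3.078
#>   log-rank chi2 84.011, p = 4.92e-20 (significant at 0.05)
```

The reporter table ranks the planted regulators (enriched for planted
DEG targets) above every decoy; the risk partition splits the 467-patient
cohort at the median prognostic index and quantifies the high-vs-low
hazard contrast two ways (a Cox fit on the group indicator, and the
ratio implied by the multivariate model's group-mean PIs).

One call runs everything and writes per-stage TSV/JSON outputs plus a run
manifest:

```r
run_pipeline(pipeline_config(seed = 42), outdir = "results_run")
```

or from a shell:

```sh
Rscript inst/scripts/netreporter.R run --outdir results_run --seed 42
```

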