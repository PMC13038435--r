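# lpmd: local promoter methylation disorder analysis

`lpmd` quantifies **local methylation disorder** — the loss of coordinated CpG
methylation within small genomic regions — from DNA methylation beta-value
matrices (450K-style arrays or WGBS aggregated to probe positions). Most
methylation analyses compare *mean* levels between groups; `lpmd` instead asks
how *heterogeneous* neighbouring CpGs are within a sample, a dimension of
epigenetic dysregulation relevant to DNMT3A-mutant AML and to predicting
response to hypomethylating agents such as azacitidine.

The package is aimed at epigenomics analysts who have normalized beta
matrices, a probe manifest and a sample sheet, and want to (i) profile
disorder genome-wide, (ii) call regions where disorder differs between groups,
(iii) build and honestly evaluate a small biomarker panel, and (iv) track
disorder over treatment time.

## The method

**Windows and disorder.** A fixed grid of 1 kb windows advancing in 500 bp
steps tiles each chromosome (windows start at multiples of the step; a probe
with 1-based position *p* belongs to window \[s, s+size) iff s ≤ p−1 <
s+size). Windows with at least 3 CpGs are analysed. For every
(window, sample) pair the package computes n, mean, median, SD, q75, q90 and
max of the member betas. The window-level disorder score **LPMD(w, s)** is the
within-window SD across CpGs — zero when neighbours agree, large when they
are a mosaic.

**Seven genome-wide metrics** summarise each sample: `window_mean`,
`window_median`, `window_q75`, `window_q90`, `window_max` (the SD, across a
sample's windows, of the corresponding per-window statistic), `window_std`
(the mean of within-window SDs) and `multiscale_lpmd` (a weighted average of
`window_std` recomputed on 500 bp / 1 kb / 2 kb grids, default weights
0.25/0.50/0.25).

**DMDR calling** (differentially methylated disorder regions) is
effect-size-first: per window, pooled-SD Cohen's *d* (case minus control) and
a Welch t-test; Benjamini–Hochberg FDR across tested windows; windows with
|d| > 0.5 are DMDRs regardless of FDR, stratified into tiers
(|d| > 1.5 / 1.0 / 0.8 / 0.5) and ranked by the priority score
|d| × (−log10 FDR) × w, with w = 1.5 for promoter windows, 1.3 for CpG-island
windows, 1.0 otherwise.

**Panel construction** runs four feature selections (random forest
importance, Wilcoxon univariate, RFE on a ridge-logistic learner, LASSO at
λ_min), ranks features by how many methods agree, fits a ridge-stabilised
logistic panel on the top features, and reports stratified 5-fold CV AUC,
sensitivity/specificity/PPV/NPV at Youden-J thresholds, the train-vs-CV
overfit gap per panel size, LOOCV, bootstrap CIs and DeLong AUC comparisons.

**Treatment dynamics** bins samples into five timepoints (diagnosis, <3, 3–5,
6–11, ≥12 months), computes relative change from baseline, tests monotone
decrease with a tie-corrected Jonckheere–Terpstra test, and fits a
patient-random-intercept mixed model for the slope per bin.

A seeded synthetic-methylome generator (`simulate_manifest()`,
`simulate_cohort()`, `simulate_longitudinal()`, `simulate_wgbs()`) emulates
all of these data shapes so the full pipeline is testable offline.

## Worked example

```r
library(lpmd)

spec <- simulation_spec(n_chrom = 1, chrom_length_bp = 60000,
                        n_mutant = 10, n_wildtype = 14,
                        implanted_dmdrs = data.frame(chrom = "chr1",
                                                     start = 25000, end = 26000,
                                                     kappa_ratio = 0.25))
manifest <- simulate_manifest(spec, seed = 101)
sim      <- simulate_cohort(manifest, spec, seed = 102)

grid   <- build_windows(manifest, size = 1000, step = 500, min_cpg = 3)
tensor <- window_stats(sim$beta, grid)
labels <- annotate_windows(grid, manifest)
res    <- call_dmdrs(window_lpmd(tensor), sim$sheet$group, labels = labels)
head(res$dmdrs[, c("window", "d", "p_value", "fdr", "direction", "tier", "priority")], 3)
```

```
            window    d  p_value      fdr direction tier priority
1 chr1:24500-25500 3.76 2.53e-08 2.88e-06 increased    1    31.28
2 chr1:25000-26000 4.19 1.86e-07 1.06e-05 increased    1    27.10
3 chr1:25500-26500 1.73 7.56e-04 2.87e-02 increased    1     3.46
```

The implanted region (kappa ratio 0.25 means the mutant group's beta
concentration is quartered there, i.e. disorder is raised) is recovered by
the windows overlapping chr1:25000–26000, with positive *d* ("increased"
disorder in mutants), tier 1 effect sizes, and priority scores boosted by the
1.5× promoter weight. Per-sample genome metrics from the same tensor:

```r
round(genome_metrics(tensor)[1:2, ], 4)
```

```
     window_mean window_median window_std window_q75 window_q90 window_max
S001      0.2017        0.2246     0.1726     0.2169     0.2045     0.1889
S002      0.2005        0.2193     0.1633     0.2081     0.1929     0.1767
```

Design-level power calculations for a 15 vs 53 comparison:

```r
round(100 * power_two_sample_t(0.675, 15, 53))   # 62 (%)
round(min_detectable_d(0.80, 15, 53), 2)         # 0.83
```

## Command line

A thin CLI over the same functions ships in `inst/exec/lpmd`:

```sh
lpmd simulate --what cohort --seed 7 --out-dir sim/
lpmd compute  --beta sim/beta.tsv --manifest sim/manifest.tsv \
              --out profile.tsv --windows-out windows.tsv
lpmd dmdr     --windows windows.tsv --sheet sim/samples.tsv --out dmdrs.tsv
lpmd power    --d 0.675 --power-target 0.8 --n1 15 --n2 53
```

Subcommands: `simulate`, `compute`, `dmdr`, `stratify`, `panel`, `dynamics`,
`concordance`, `power`, `wgbs-aggregate`. Any flag can be preset from a YAML
file via `--config`; explicit flags win. Stochastic subcommands record their
seed and the package version in their JSON output.

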