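---
title: "Quantifying local methylation disorder: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying local methylation disorder: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpmd)
```

## The quantity being measured

A methylation array or WGBS experiment yields, per sample, a beta value in
[0, 1] for each CpG: the fraction of molecules methylated at that site. In a
healthy regulatory region, neighbouring CpGs tend to agree — a promoter is
coherently unmethylated, a gene body coherently methylated. *Local
methylation disorder* is the breakdown of this agreement: adjacent CpGs in
one sample scatter across the beta scale, producing a mosaic of epialleles.
Disorder is distinct from hypo- or hypermethylation — a region can keep its
mean while losing its coherence — and it is the dimension this package
measures.

The operational definition is deliberately simple: within a genomic window,
disorder is the standard deviation of the member CpGs' beta values for one
sample. Zero when the window is coherent; up to ~0.5 for a half-and-half
mosaic of fully methylated and unmethylated sites. Everything else in the
package is built from this window tensor.

### Assumptions

* Beta values are already normalized; the package performs probe-level QC
  (detection p, missingness, SNP probes, sex chromosomes) but no
  normalization or batch correction.
* Probes measure single CpGs at known 1-based coordinates, and within-window
  SD across probes is a meaningful heterogeneity summary — i.e. probe-level
  technical noise is small relative to the biological scatter being measured.
* For WGBS input, strand merging has been handled upstream; the package pools
  reads within ±25 bp of each probe coordinate and requires 10× coverage per
  CpG, but never merges opposite-strand calls itself, because merging policy
  is pipeline-specific.

## The window grid

Windows are fixed genomic tiles: width `size` (default 1000 bp), starting at
every non-negative multiple of `step` (default 500 bp) per chromosome, kept
only if they contain at least `min_cpg` (default 3) probes. A probe with
1-based position *p* belongs to [s, s+size) iff s ≤ p−1 < s+size. Anchoring
the grid at coordinate 0 rather than at CpGs makes the grid deterministic and
platform-independent: two datasets on the same genome build get identical
window keys, which is what makes cross-platform window-level comparison and
Jaccard/directional-consistency statistics well-defined. The cost is that a
CpG-anchored analysis of the same data would produce a different (roughly
half-overlapping) window set; window counts are therefore not comparable
across anchoring conventions.

With the default 2:1 size:step ratio each probe belongs to two windows, so
neighbouring windows share CpGs and their statistics are correlated. The
DMDR caller treats windows as the unit of reporting, not as independent
tests; the BH adjustment is a pragmatic ranking device (the calling rule is
effect-size-first precisely because window FDRs are conservative under this
overlap).

## Per-window statistics and the seven profile metrics

For each (window, sample): n of non-missing betas, mean, median, SD (n−1
denominator), 75th and 90th percentiles, and max. Quantiles use linear
interpolation between order statistics (R type 7) — one convention had to be
pinned for cross-ecosystem reproducibility, and type 7 is R's default.
Entries with fewer than `min_cpg` valid CpGs are missing.

Per sample, across its valid windows:

| metric | definition | captures |
|---|---|---|
| `window_mean` | SD of per-window means | variability of local methylation *level* |
| `window_median` | SD of per-window medians | as above, robust to outlier CpGs |
| `window_std` | **mean** of per-window SDs | average local *incoherence* |
| `window_q75`, `window_q90`, `window_max` | SDs of the upper-tail statistics | variability of local extremes |
| `multiscale_lpmd` | weighted mean of `window_std` at 500/1000/2000 bp | scale-integrated disorder |

Two readings of "SD of mean beta values" are possible — across windows within
a sample, or across samples within a window. The package uses the per-sample
reading (one value per sample), because group comparison of the metrics
requires exactly that, and because per-sample distributions are what the
metric names describe. These SD-based metrics are shift-invariant and scale
equivariantly (both properties are tested).

`multiscale_lpmd` recomputes the base metric on grids at 500, 1000 and
2000 bp (step = scale/2, same `min_cpg`) and averages with weights
(0.25, 0.50, 0.25). The weights are a package choice — centred on the
primary 1 kb scale, symmetric to its half and double — and configurable; a
scale with no valid windows is dropped and the remaining weights
renormalized. The base metric is `window_std` (configurable): it is the only
one of the six that is itself a disorder measure at single-window
resolution, so its multiscale average remains interpretable as disorder.

The per-window, per-sample score used for DMDR testing is the within-window
SD, for the same reason; `window_lpmd()` exposes the other tensor statistics
behind a `metric` argument for sensitivity analysis.

## Regional features

Eleven per-sample features summarise where disorder sits: mean window
disorder in eight categories — CpG Island, Shore, Shelf (from the window's
majority CpG relation), Promoter (TSS1500 ∪ TSS200), 5'UTR/Exon 1, Gene
Body, 3'UTR, Other (enhancer ∪ intergenic, from the majority functional
class) — plus the 90th percentile and median of the sample's window-disorder
distribution and `multiscale_lpmd`. Window labels come from a majority vote
over member probes with a fixed tie precedence (Promoter > 5'UTR/Exon 1 >
Gene Body > 3'UTR > Other; Island > Shore > Shelf > open sea): ties must
break deterministically, and breaking them toward the more
regulatory-proximal class matches how a window containing any promoter
probes is used downstream (the 1.5× priority weight). Note a window
contributes to one functional category and one CpG category, so the eight
"regional" features are not mutually exclusive across the two axes.

## DMDR calling

Per testable window (≥2 non-missing values per group): pooled-SD Cohen's
d (case minus control, so d > 0 = more disorder in cases) and a Welch
t-test. Mixing a pooled-SD effect size with an unequal-variance test is
intentional: d is the field's standardized effect-size convention, while the
test should not assume equal variances precisely because disorder differences
*are* variance differences. BH adjustment runs over tested windows only —
windows untestable through missingness never enter the family, so m reflects
actual tests. Calling is |d| > 0.5 regardless of FDR; tiers at |d| > 1.5 /
1.0 / 0.8 / 0.5 with strict boundaries ("greater than"); priority =
|d| × (−log10 max(FDR, 1e-300)) × w. The FDR floor keeps scores finite
without reordering ranks; log base 10 matches the usual volcano-plot axis.
The functional weight prefers promoter (1.5) over island (1.3): a window can
be both, and the precedence is resolved toward the category the score is
named for.

## Panel construction and evaluation

Candidate features are window-disorder values (typically at DMDR windows).
Four selectors run independently: random-forest mean-decrease-in-impurity
(ntree 500, mtry √p), two-sided Wilcoxon rank-sum at p < 0.05, backward RFE
on a ridge-logistic learner (dropping the weakest ~10% of features per step
by standardized coefficient, CV-AUC recorded per visited size), and LASSO at
λ_min from 10-fold CV deviance. λ_min rather than the 1-SE rule keeps more
features — appropriate here because the consensus step, not the LASSO, does
the final pruning. Consensus ranks features by (method count, mean
within-method rank, lexicographic key); the fitted panel takes the top k
(default 5). The final-panel rule is a package decision — the consensus
ordering is deterministic and uses nothing but the four selections.

The panel itself is logistic regression with a small L2 ridge (1e-4 on
slopes, fitted by IRLS) so that separable small-sample data still yield
finite coefficients. Evaluation: stratified 5-fold CV with pooled
out-of-fold scores; AUC by the mid-rank Mann–Whitney relation (tested to
1e-12 against trapezoidal ROC integration); classification thresholds by
Youden's J on each training fold; the overfit gap is mean training AUC minus
pooled CV AUC, reported per panel size. LOOCV uses the same machinery with
n single holdouts. DeLong's test compares correlated AUCs via mid-rank
structural components. All resampling takes an explicit seed and is
bit-reproducible.

## Longitudinal dynamics

Samples bin into diagnosis, <3, 3–5, 6–11, ≥12 months; the diagnosis bin is
set only by an explicit flag, because month-0 on-treatment samples belong to
"<3 months" and no numeric rule separates the two. Relative change is
100 × (value − baseline)/baseline. The trend test is Jonckheere–Terpstra
with ties counted ½ and the tie-corrected normal approximation for Z; the
default alternative is one-sided decreasing (the clinical hypothesis is that
effective hypomethylating treatment reduces disorder), with two-sided
available. On tiny instances the normal approximation is within 0.08 of the
exact enumeration p (tested); for clinical bin sizes (≥17 per bin) the
approximation error is negligible. The mixed model codes time as the ordinal
bin index 0–4 with a patient random intercept (lmerTest, Satterthwaite p),
falling back to ordinary regression with a warning when random intercepts
are inestimable (e.g. one sample per patient).

## The synthetic-data generator

The generator exists so that every analysis step has ground truth. Its model:
disjoint 1 kb blocks each receive a mean beta μ (0.05 + 0.9·Beta(2, 2)) and
per-group concentration κ; each CpG's beta is drawn Beta(μκ, (1−μ)κ).
Parameterising by (mean, concentration) makes disorder controllable
independently of methylation level — within-block SD ≈ √(μ(1−μ)/(κ+1)) — so
implants change coherence without changing level, mirroring the claim the
disorder metrics are meant to test. Defaults, chosen once as realistic study
conditions: background CpG spacing 150 bp with 30 bp inside islands
(450K-like promoter density), one gene per 10 kb with a ±500 bp island at
each TSS and 2 kb shore/shelf bands, κ_wt = 8 (within-window SD ≈ 0.17 at
μ = 0.5), a per-sample lognormal κ factor (sdlog 0.15) for between-patient
variation, cohort 15 mutant vs 53 wild-type, implant κ ratio 0.25, and
longitudinal bin disorder factors (1, 0.994, 0.963, 0.965, 0.968) — a step
decrease in the 3–5-month bin followed by a plateau. A disorder factor r is
implemented as κ/r², from the SD–κ relation above. Response labels, when
requested, come from a logistic model on the z-scored block-specific latent
disorder (the per-(sample, block) lognormal deviation, sdlog 0.5), so the
predictive signal is localized to the designated panel windows and not to a
sample's global disorder level.

What the generator does **not** emulate: chromatin-state-dependent
methylation landscapes, read-level epialleles (WGBS simulation is
per-CpG binomial), probe cross-hybridization, batch effects, or correlated
missingness. Passing the recovery tests therefore shows the pipeline
correctly inverts its own generative model at realistic sizes and noise —
it does not certify performance on real cohorts, where normalization
dialects and annotation differences add variance the generator omits.

## Recovery benchmarks and problem sizes

The end-to-end checks run at deliberately moderate sizes: two 125 kb
chromosomes (~500 analysis windows, ~2200 probes), 68 samples, 10 implanted
windows at κ ratio 0.25, 20 simulation seeds for DMDR recovery and 5 for
panel recovery; property suites use ~100 random micro-fixtures per
statistic, 10,000 Monte-Carlo replicates for the power oracle, and reduced
resampling (99–300 iterations) for the calibration suites. A recovered
implant is counted when a top-k window (k = number of implants) overlaps an
implanted span with the implanted sign — overlapping grid windows share the
implanted CpGs and legitimately carry the signal.

## Numerical choices and degenerate inputs

* Quantiles: R type 7 everywhere (tensor and bootstrap percentiles).
* Zero pooled SD: d = 0 when means agree, signed infinity (flagged) when not.
* Zero variance in both Welch groups with equal means: t = 0, p = 1.
* FDR of exactly 0 entering the priority score: clamped to 1e-300, warning.
* Quartile ties: stable ordering (ties keep input order), remainder samples
  to the lower quartiles; relative risk is missing when the lower-half rate
  is 0 or labels are constant, rather than infinite.
* ICC is the two-way random-effects, absolute-agreement, single-measure
  ICC(2,1) — the standard flavour for method comparison; zero-variance pairs
  give a missing ICC.
* Permutation p uses the add-one estimator, never exactly zero.
* PCA: centered/scaled, constant features dropped with a warning, loading
  signs fixed by making the largest-magnitude loading positive per component.
* All file writes are atomic (temp file + rename).

## Known limitations

* Window-level disorder from 3–7 CpGs is a noisy SD estimate; DMDR
  effect sizes at sparse windows shrink toward 0 and the caller's power
  concentrates at CpG-dense (island/promoter) windows.
* The fixed-anchor grid means absolute window counts and keys depend on the
  anchoring convention; analyses comparing against CpG-anchored pipelines
  must re-key.
* `heterogeneity_cv`'s inter-gene and inter-region axes are explicit
  stand-in definitions (gene-mean of group-mean window disorder; CV of the
  group-mean regional feature vector); other definitions are defensible.
* The detection-p QC rule defaults to the strict any-sample mode; cohorts
  with a failing outlier sample may prefer `frac:<x>`.
* Mixed-model p-values use Satterthwaite approximation; with very few
  patients the OLS fallback ignores clustering and understates uncertainty.
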