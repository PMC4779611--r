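---
title: "Assessing X-chromosome dosage compensation from RNA-seq counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing X-chromosome dosage compensation from RNA-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xacomp)
```

## The question and the statistic

In species with heterogametic males (XY), Y degeneration leaves males with a
single copy of every X-linked gene. Whether transcription from that single X
is upregulated to autosomal levels — dosage compensation — is assessed here
the way it is usually done with bulk RNA-seq: by comparing the **median
expression of X-linked genes to the median expression of autosomal genes
within one sex** (the X:A ratio), and by comparing males with females. An X:A
ratio near 1.0 in males indicates complete compensation; a ratio near 0.5
indicates none. `xacomp` implements this analysis for a karyotype with two
autosomes and an X, as in anopheline mosquitoes, where chromosome arms
(2L/2R, 3L/3R) are merged into chromosomes 2 and 3.

Because non-homologous genes are being compared, chromosome-wide medians can
differ even under perfect compensation. Two safeguards are built in:

* the **chr3:2 ratio** — the same statistic between the two autosomes —
  serves as an empirical band of natural between-chromosome variation; an
  X:A value is only interpreted relative to it;
* the whole analysis is swept across **minimum-expression thresholds**
  (default grid 0–40 RPKM), because which weakly expressed genes are included
  can move the ratios substantially; conclusions should be stable across a
  sensible threshold range rather than read off a single filter choice.

Male–female comparisons use two deliberately different constructions:
**Method 1** forms each sex's chromosomal ratio first and divides male by
female; **Method 2** forms a per-gene male:female ratio first and then takes
chromosome-wise medians. Method 2 cancels gene-specific baselines and is more
robust to expression heterogeneity; agreement between the two is itself a
useful consistency check.

## Normalization

Counts are converted to RPKM: count divided by exon-union length in kb (the
union of a gene's exons, overlaps counted once) and by library size in
millions. Three library-size definitions are available: the total count, the
75th percentile of expressed-gene values (upper-quartile), and the median.
Total-count scaling is vulnerable to a few extremely expressed genes;
upper-quartile is the default, and median scaling behaves very similarly.
Three numerical choices deserve note:

* quantiles are computed by linear interpolation between order statistics
  (`h = (n-1)q + 1`, R's type 7), frozen in tests;
* quantiles are taken over **positive** values only — with zero-inflated
  data a raw 75th percentile can be 0, leaving the scale undefined;
* after rescaling, samples are anchored to the geometric mean of the
  per-sample quantiles. Any common anchor preserves every within-analysis
  ratio; only the absolute RPKM scale depends on it. Consequently the
  rescaled matrix is *equivariant* (not invariant) under a global rescaling
  of its input — all downstream ratios are invariant, which is what matters
  and what the tests assert.

`ma_values()` provides standard MA diagnostics for judging residual
between-sample bias, and `downsample_counts()` implements binomial thinning —
the count-level analogue of re-sequencing at lower depth — used to check that
conclusions are not driven by depth differences between sample groups.

## Bootstrap confidence intervals

CIs for every ratio come from a nonparametric bootstrap, resampling genes
with replacement **within chromosome strata** (stratum sizes preserved), with
10,000 replicates by default and percentile intervals. Two design choices:

* In a male–female contrast the same resampled gene multiset is applied to
  both sexes, preserving the paired structure that makes a per-gene M:F
  ratio meaningful; independent per-sex resampling is available via
  `resample = "independent"` for sensitivity analysis.
* Percentile intervals were chosen as the simplest defensible interval type;
  the choice is frozen in the tests, and empirical coverage of the 95%
  interval is verified by simulation (200 data sets; coverage must land in
  95% ± 5%).

CIs are reported for thresholds in 0.2–15 RPKM; outside this range so few
(or so noisy) genes remain that the intervals are meaninglessly wide.
Undefined ratios (empty stratum after filtering, zero denominator median) are
always explicit flagged values with a reason, never silent `NaN`s.

## Sliding-window profile of the X

`window_density()` and `window_xa()` profile the X chromosome in 1-Mb windows
stepping 100 kb: genes expressed above thresholds are counted per window, and
each window's median X expression is divided by the global autosomal median.
Genes are assigned to windows by their midpoint (rounded down), which gives
every gene a well-defined membership multiplicity of `ceiling(window/step)`
away from the chromosome ends; trailing partial windows are emitted and
flagged. Windows with fewer than `min_genes` (default 5) expressed genes are
flagged undefined instead of contributing noise.
`density_departure_correlation()` quantifies whether strong X:A departures
concentrate in gene-poor windows, correlating the per-window gene count with
`|log2(ratio)|`; the departure metric is a package choice, as the magnitude
of deviation from parity regardless of direction.

## Sex-biased genes and X-linkage enrichment

A gene is called sex-biased when its q-value is below 0.005 **and** its
male:female fold change clears 50% (ratio ≥ 1.5 or ≤ 2/3). q-values from an
external differential-expression engine are accepted as input and take
precedence; otherwise the package fits a moderated two-sample test (limma,
with mean–variance trend and robust hyperparameter estimation) on
`log2(RPKM + 0.01)` across replicates and adjusts with Benjamini–Hochberg.
The moderated test is the field-standard choice at 2–3 replicates per sex,
where an unmoderated t-test has so few degrees of freedom that q < 0.005 is
essentially unreachable. Genes expressed in males but silent in females have
an undefined fold and are classified by the q-rule with a direction flag;
genes silent in both sexes are `undefined`.

Enrichment of bias direction by chromosomal location is tested with a
two-sided Fisher's exact test on the X/autosome × male-/female-biased table
(minimum-likelihood convention for two-sidedness; sample odds ratio ad/bc
reported, flagged when a zero cell makes it 0 or infinite). Ratio-set
comparisons between conditions (`compare_ratio_sets()`) use the Mann–Whitney
U test — enumerated exactly below a combined n of 20, with mid-ranks so that
tied data still yield exact p-values, and the tie-corrected normal
approximation above.

## Replicate quality control

Divergent replicates are detected from the sum of squared per-gene expression
differences between each replicate and its peers, with significance from
random permutations of each gene's values across replicates (gene-wise
shuffling; whole-column permutation would leave the statistic unchanged).
p-values use the add-one convention `p = (1 + #{ssd* ≥ ssd}) / (1 + n_perm)`,
so they are never exactly zero; replicates with p < 0.001 are flagged. The
number of permutations defaults to 10,000. Downstream, `run_pipeline()`
emits ratio tables both with all replicates and with flagged replicates
excluded, so the effect of exclusion is always visible.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates an annotated genome (chr2, chr3, X, plus an
unplaced scaffold bin), exon structures, and negative-binomial counts with
known ground truth, so every stage of the analysis can be validated against
planted effects. The default conditions:

| parameter | default | rationale |
|---|---|---|
| genes per chromosome | chr2 860, chr3 760, X 110, unplaced 20 | ~1/10 of the *A. gambiae* gene complement, keeping relative chromosome sizes |
| chromosome lengths | 10, 9, 2.5, 1 Mb | ~1/10 of the genome, preserving gene density so 1-Mb windows stay meaningful |
| exon-union length | log-normal, median 1.5 kb, sdlog 0.6 | typical insect gene lengths |
| baseline expression | log-normal, median 15 RPKM, sdlog 0.1; 10% inactive genes near 0.05 RPKM | see below |
| NB dispersion | 0.1 | typical biological overdispersion for bulk RNA-seq replicates |
| library size | 2×10⁶ reads ± 20% jitter | desk-scale depth with realistic sample-to-sample variation |
| compensation factor c | 1.0 (complete); 0.5 models absence | the male-X multiplier |
| sex-bias effect law | log2 fold ~ N(2.5, 0.5) | sex-biased insect genes are typically strongly biased |

The narrow across-gene baseline spread (sdlog 0.1) is a deliberate
scaled-down design: at 1/10 of the gene complement, chromosome medians would
otherwise carry ~3× the sampling error of the genome-scale setting, and
parameter-recovery bands of a few percent would be statistically
unattainable. With this choice the sampling error of the desk-scale median
matches the few-percent precision of the full-scale analysis, while the
*observed* per-gene spread is still dominated by count overdispersion
(~0.33 log-sd per sample). What the simulator does **not** emulate: isoform
structure and length biases within genes, positional autocorrelation of
expression along chromosomes, GC/mappability effects, and the heavy right
tail of real expression distributions. Passing tests therefore demonstrate
that the estimators recover planted chromosome-level effects under realistic
count noise — not that any particular biological data set is free of those
additional artifacts.

Presets encode the canonical scenarios: `pupae_complete` (c = 1, three
time-point samples per sex treated as stage replicates), `no_compensation`
(c = 0.5), `larvae_female_high` (female-X overexpression, factor 1.3 — an
illustrative magnitude for a qualitative phenomenon), and `testes_like`
(c = 0.5, male-only, with a reduced expressed-X fraction mimicking germline
X demasculinization).

## Worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(sim_preset("pupae_complete", seed = 42))
expr <- normalize_rpkm(sim$counts, sim$annotation, method = "uq")
sweep <- ratio_sweep(expr, sim$annotation, sim$samples,
                     thresholds = c(1, 2, 5), n_boot = 2000, seed = 7)
autoplot(sweep)

qc <- permutation_test(expr, c("M1", "M2", "M3"), n_perm = 2000, seed = 1)
rec <- classify_bias(expr, sim$annotation,
                     c("M1", "M2", "M3"), c("F1", "F2", "F3"))
fisher_enrichment(rec)
```

## Problem sizes, tie-breaks and degenerate inputs

* Thresholds compare with `>=`; a gene exactly at the threshold is included.
* Decile bins are equal-count with any remainder spread over the lowest
  bins; decile 1 is the least expressed.
* Ratios with an empty numerator or denominator stratum, or a zero
  denominator median, are `NA` with a machine-readable `note`.
* Bootstrap strata of size 1 collapse the resampled stratum to a constant
  and are flagged.
* The validation suite runs the simulation studies at desk scale — e.g.
  200 data sets for bootstrap coverage at 1,000 bootstrap replicates, 100
  runs for QC power at 2,000 permutations, 1,000-case oracle sweeps — sizes
  chosen so the whole suite completes in minutes on one core while leaving
  each check statistically decisive.

## Known limitations

* The X:A statistic compares non-homologous gene sets; even with the chr3:2
  control, compensation inferences are chromosome-wide averages and say
  nothing about individual genes.
* The in-house differential-expression test is a convenience: with external
  q-values available (e.g. from a dedicated DE engine run on the raw data),
  those should be supplied.
* Counting reads per gene, read trimming and alignment are out of scope; the
  pipeline starts from a gene-level count matrix.
* The permutation QC statistic is sensitive to broad multiplicative
  divergence of a replicate; it is not a general outlier detector.
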