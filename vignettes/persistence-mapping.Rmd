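---
title: "Mapping fungal persistence QTL from pooled barcode sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping fungal persistence QTL from pooled barcode sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`persistqtl` maps quantitative trait loci (QTL) that control how well
barcoded haploid yeast segregants persist in host organs, from pooled
barcode-sequencing counts. This vignette is the package's account of the
models it implements, the choices that were genuinely open, and what its
synthetic-data generator does and does not emulate.

## The measurement model

Each segregant of a BY × 3S cross carries one or more chromosomally
integrated 20-mer barcodes. The pool is sequenced at the time of injection
(T0), after growth on rich-medium control plates, and after recovery from
each organ sample. With `f` denoting a barcode's read-count frequency
within a sample, the raw phenotype of a segregant in a sample is

    (f_TF − f_T0) / f_T0,

the fractional change relative to the injected pool. Recovery from organs
requires homogenization and plating, so differences in on-plate growth
contaminate the raw phenotype identically in organ samples and plate
controls. The package therefore regresses, per organ sample, the raw
phenotypes across segregants on the mean raw control phenotype (OLS with
intercept) and takes the residuals as **persistence**. Residuals are
orthogonal to the control regressor and sum to zero within each sample; if
the control regressor is constant the fit degrades to centering. A
segregant absent from the T0 pool (`f_T0 = 0`) is unmeasurable (NA)
everywhere; a segregant absent from one sample (`f_TF = 0`) has persistence
−1 before correction — extinction is treated as signal, not missingness,
because the sequencing depth is far above one read per expected barcode.

### Heritability and sample filtering

Eighty-six segregants carry three distinct barcodes, giving within-sample
replication. Broad-sense heritability is the one-way sum-of-squares ratio

    H² = SS_genotype / SS_total,

with the genotype F-test P-value attached. Samples whose replicated
barcodes show no significant among-genotype variation (P above a
Bonferroni-corrected `α / n_samples`, default α = 0.05) are excluded, as
are organs left with fewer than `min_replicates = 2` significant samples
(in practice the gonads, where recovery is lowest). Note the SS ratio with
`r` replicates per genotype has expectation
`(G−1)(r·vg + ve) / ((N−1)(vg + ve))`, which exceeds the underlying genetic
variance fraction at small `r`; with triplicates it is a filtering and
ranking statistic, not an unbiased variance-component estimate, which is
exactly how the pipeline uses it. The estimator-recovery checks in the test
suite therefore run it at 200 genotypes × 50 replicates, where the closed
form puts its bias below 0.015 for fractions 0.2–0.8, alongside a separate
assertion of the biased closed-form expectation at the 86 × 3 design.

### Aggregation

Organ samples split into two reproducible clusters, brain versus nonbrain
(kidney, liver, spleen). For the aggregate phenotypes the raw values are
first time-corrected (divided by days since injection, so a day-5 change is
on the same per-day scale as a day-1 change), then plate-corrected, then
averaged per segregant over the significant brain samples and over the
significant nonbrain samples; the brain − nonbrain difference isolates
organ-contrasting effects. Time correction is applied only in this
aggregation path; per-sample scans use uncorrected residuals.

## Linkage mapping

Scans use the fixed-effects model
`phenotype ~ known_locus_1 + … + known_locus_N + locus` over segregants
(one barcode per segregant; missing phenotypes dropped listwise). The
implementation residualizes both the phenotype and every marker against
the covariates once and computes all marker P-values from squared partial
correlations (`t² = r²·df / (1 − r²)`), which makes a 1,000-permutation
threshold a single matrix product instead of a million `lm()` calls.
Markers colinear with the covariates — including admitted peaks — get
P = 1 by construction (residual norm below 1e−7), so a chromosome never
re-admits its own peak.

Forward regression proceeds in stages: each stage recomputes a permutation
threshold *with the current covariates included* (phenotype shuffled,
genotypes and covariates fixed; threshold = the `floor(q·n_perm)`-th order
statistic of the per-permutation minimum P-values, q = 0.05), scans, and
admits per chromosome the minimum-P marker (ties broken toward the lowest
index, an arbitrary but deterministic rule) if its P-value passes the
threshold and is below 1. The stage-1 threshold construction makes the family-wise error of
a null scan approximately q, which the acceptance suite verifies over 200
null scans. Confidence intervals are the maximal contiguous marker run
around a peak within `drop = 2` units of −log10(P) — the LOD-drop
analogue; the alternative reading of "2 ×" as a multiplicative factor on
−log10(P) was rejected as implausible (it would make intervals grow with
significance).

Detections across scans consolidate per chromosome by confidence-interval
overlap. Overlap is treated as transitive (connected components of the
closed-interval overlap graph): a pairwise rule leaves chains ambiguous,
and a single consolidated region per chain matches how consolidated locus
counts are reported. A chain can have an empty common intersection; the
locus is then flagged (`intersection_empty`) and the crossed bounds
(max start, min end) delimit the fractionated sub-intervals rather than
raising an error, mirroring linked loci that resolve into two intervals.
Each consolidated locus's effect marker is the peak of its smallest-P
member detection.

Variance explained by a scan's loci is the R² of the joint OLS fit on all
admitted peaks divided by the across-sample H² of that phenotype. For the
brain − nonbrain difference no replicate samples exist, so its H² comes
from deterministic sorted pairing of brain with nonbrain samples (recycling
the shorter list), treating per-pair differences as replicates; this is the
package's own construction, chosen for determinism over random pairing.
Because the numerator R² comes from a many-peak fit and the denominator H²
is itself noisy, the ratio can exceed 100%.

## Pleiotropy classification and combinatorics

A locus's effect in a context is `mean(3S carriers) − mean(BY carriers)`,
with a percentile bootstrap interval (class-wise resampling, 1,000
replicates, 2.5th/97.5th percentiles). Same-sign brain and nonbrain
effects ⇒ *general*; opposite signs ⇒ *antagonistically pleiotropic*. An
exactly zero delta sits on a measure-zero quadrant boundary: the locus is
classified by the other context's sign and flagged degenerate, rather than
erroring. Per segregant, the package counts beneficial alleles across
general loci and brain-favoring alleles across antagonistic loci, with
enrichment thresholds defaulting to the study's cutoffs (≥7 / <3 general,
≥6 / <3 brain); `tune_enrichment_thresholds()` implements the alternative
rule of choosing the most permissive thresholds that keep each class under
25% of segregants. Dose regressions are simple OLS `phenotype ~ count`;
the 2×2 enrichment-versus-increasing-persistence test is a plain Pearson
χ² (no continuity correction, matching how such χ² values are usually
reported; correction is exposed as an option); time slopes are per-segregant
OLS on days post-injection. For the nonbrain context the
"context-appropriate" pleiotropic enrichment is *depletion* of
brain-favoring alleles.

## The synthetic-data generator

The generator exists so that every stage is testable end to end with known
ground truth. It emulates:

* **Meiosis** — Poisson crossover counts per chromosome (default mean 3,
  roughly a yeast-scale genetic map on 750 kb chromosomes), uniform
  breakpoint positions, no interference, fair starting phase: marginal
  allele frequencies ≈ 0.5 and Markov-mosaic chromosomes.
* **Effect models** — `n_general` + `n_antagonistic` loci at distinct
  markers (configurable minimum spacing and per-chromosome cap).
  `effect_scale` is the per-day log-frequency selection coefficient; each
  organ's coefficient is the scale up to U[0.9, 1.1] jitter, same-signed
  across organs for general loci and brain-opposed for antagonistic ones.
* **The sampling cascade** — equimolar pooling with mild log-normal jitter
  (σ = 0.1; the exact T0 evenness is not specified anywhere, so a mild
  jitter was chosen once as realistic); a per-segregant on-plate growth
  coefficient (σ = 0.2) shared between plate controls and organ samples,
  which makes the plate correction identifiable by construction; selection
  acting multiplicatively on log-frequency,
  `E[f] ∝ p0 · exp(g + t · Σ s·allele)`, the simplest model consistent
  with frequency-change phenotypes that keeps closed-form expectations
  available; a multinomial recovery bottleneck at each organ's expected
  CFU (brain 1741, gonad 69, kidney 3843, liver 69150, spleen 32032 —
  the scale of recoveries in this design, and the mechanism that makes
  brain and gonad samples noisier); and multinomial read sampling at the
  design depth (default 5 × 10⁵ reads/sample).
* **Genotyping noise** — per-site Poisson depth, per-read miscall
  probability, observed 3S fractions, zero-depth sites missing.

It does **not** emulate: PCR amplification bias or chimeras, index
hopping, overdispersion beyond the multinomial, immune dynamics or
within-host spatial structure, host-to-host variability in clearance, or
outright sample failure (the design's lost samples appear here only
indirectly, as low-recovery samples failing the significance filter).
Passing tests on simulated data therefore demonstrate the statistical
machinery under the stated noise model, not robustness to every artifact
of real libraries.

Default dimensions mirror the study design — 822 segregants, 86
triplicated, 16 chromosomes, 5 organs × 2 sexes × 2 treatments × 3 days ×
3 replicates plus one T0 and 3 plate controls — and all are configurable.

## Numerical and design choices

* **HMM** (genotype correction): two states, transition matrix
  (0.9999, 0.0001), emission (0.75, 0.25) with the orientation
  P(observed = hidden state) = 0.75 (the symmetric alternative merely
  relabels states); uniform initial distribution; Viterbi decoding, which
  returns a legal parental mosaic, rather than posterior decoding, which
  need not. Observed fractions strictly above/below 0.5 call 3S/BY;
  exactly 0.5 and zero-depth sites are missing and imputed (both-state
  emission likelihood 1); an all-missing chromosome decodes to state 0
  (BY) by tie-break. The strong persistence prior presupposes read-level
  SNP density — blocks spanning many markers. On maps much sparser than
  ~1 marker per few kb the model smooths away short true blocks, so the
  HMM-benefit checks run at 150 markers per chromosome, not on the
  collapsed map.
* **Collapsing**: maximal runs of adjacent, genotypically identical
  columns reduce to their first marker; per-chromosome scan minima are
  provably unchanged, which a test asserts.
* **Barcode assignment**: reads assign to the unique whitelist barcode
  within `max_hamming` (2 for library determination, 3 for sample
  quantification); the generator guarantees, and the quantifier checks,
  pairwise whitelist separation > 2·max_hamming, so radius assignment is
  exact and unambiguous — a whitelist replaces de novo centroid
  clustering because the barcode library is known. The quality threshold
  keeps reads at exactly 30 (the removal rule is "below 30").
* **Seeds**: every stochastic function takes an explicit seed and restores
  the caller's RNG state; the pipeline derives per-stage seeds
  deterministically from one master seed, so a run manifest (config echo +
  seed) suffices to reproduce a run byte for byte.
* **Problem sizes**: the test suite and acceptance script use 16 × 40 =
  640-marker maps for mapping checks, 16 × 150 for HMM-density checks,
  200 null scans for error calibration, and 3 replicate simulations for
  recovery scoring — sizes chosen so the full suite exercises the
  study-scale design (822 segregants, 1,000 permutations) while each
  check completes in seconds to a couple of minutes.
* **Recovery benchmark**: planted loci for the recovery checks are spaced
  ≥300 kb apart. Closer pairs on a 750 kb chromosome are in strong
  linkage, where "one locus recovered per planted locus" stops being well
  defined — a single peak legitimately represents both; the spacing knob
  exists in the generator precisely to keep the benchmark's notion of
  locus-level recovery meaningful. The benchmark scores a detection
  against the planted locus nearest its peak, so a wide interval cannot
  claim a linked neighbour, and classifies at the matched peak marker.

## Limitations

Persistence is a ratio phenotype: under strong selection its distribution
is heavy-tailed, and the additive per-marker scan loses power even as true
effects grow (the package's power checks show recall peaking at moderate
selection coefficients, ~0.15/day, under the default noise model). The
plate correction removes only the linear component of on-plate growth
effects. The forward-scan thresholds control family-wise error per stage,
not across stages. Classification by the sign of two noisy deltas can
misclassify loci whose effect in one context is near zero; bootstrap
intervals for the deltas are reported so such loci are visible. The
pipeline assumes one haploid mating type, no mating in the host, and a
known barcode→segregant assignment.
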