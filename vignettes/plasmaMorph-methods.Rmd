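---
title: "Methods: rare plasma-cell morphogenomics with plasmaMorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare plasma-cell morphogenomics with plasmaMorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaMorph)
```

## The problem

Multiple myeloma is a clonal plasma-cell malignancy diagnosed from bone
marrow, yet malignant plasma cells also circulate in peripheral blood at
very low frequency. An enrichment-free liquid-biopsy workflow plates every
nucleated cell from a blood or marrow sample (millions of cells per slide),
stains four channels (DAPI, CD138, CD56, CD45), classifies each DAPI+ cell
into plasma-cell morphotypes, sequences candidate cells at low coverage
after whole-genome amplification (WGA), and asks whether the single-cell
copy-number profiles carry the same cytogenetic events that the clinical
FISH panel reports from the marrow.

`plasmaMorph` implements that analysis chain as reusable, tested components:

1. marker-threshold calibration, morphotype classification and cells/mL
   enumeration (`calibrate_thresholds()`, `classify_cells()`,
   `enumerate_subtypes()`, `score_outliers()`);
2. single-cell copy-number calling — normalization, segmentation, integer
   ploidy fitting, altered/normal calling, clone grouping (`fit_cnv()`,
   `group_clones()`);
3. mapping per-cell integer profiles onto a 12-event clinical FISH panel
   with per-patient discordance reporting (`call_events()`,
   `discordance_report()`, `cooccurrence_sets()`);
4. cohort statistics (`exact_rank_sum_test()`,
   `percent_altered_by_morphotype()`, `ploidy_distribution()`,
   `sequencing_outcome_summary()`);
5. a seeded synthetic-data generator with ground truth
   (`simulate_if_cohort()`, `simulate_cnv_cells()`,
   `simulate_fish_panel()`) that defines the conditions under which the
   pipeline is validated.

## Rare-cell classification

Positivity per channel is a strict `>` comparison against a cutoff
calibrated as `median + k × MAD` of `log1p` intensities over all admitted
cells (default `k = 5`). On an enrichment-free slide the rare positives are
a negligible minority, so the bulk defines the negative distribution; the
rule is robust to the spiked positives and is equivariant under a global
intensity gain, so re-scanning at a different exposure does not change
classifications. One caveat is CD45: the bulk of nucleated blood cells is
CD45-positive, so the automated CD45 cutoff sits above the positive bulk
and is conservative. This does not affect any rare subtype that requires
CD45 *negativity* (in particular the CD138+CD56+CD45− candidate malignant
plasma cells); it only shifts unremarkable cells between the "common WBC"
and "other rare" bookkeeping classes.

The eight plasma-cell candidate subtypes overlap (a binucleated CD138+CD56+
cell is both "binucleated PC" and "CD138+CD56+"), but enumeration needs a
partition, so assignment uses a fixed precedence among CD138+ cells —
apoptotic > cluster > binucleated > marker combination — and the raw
positivity triple is kept alongside so no information is lost. "Larger than
surrounding WBCs" is operationalized as area above the 95th percentile of
CD45+CD138− cells in the same sample (the assay literature gives no
absolute size cutoff), and the nuclear-eccentricity cutoff defaults to 0.6.
The k-nearest-neighbor outlier score (mean distance to the k nearest cells
in robust-standardized feature space) replaces the workflow's manual-review
stage as a ranked review list; it never overrules marker rules.

Enumeration divides counts by the blood-volume equivalent of the slide
(cells/mL); patient stratification uses the strict `> 3` CD138+ cells/mL
rule.

## Copy-number calling

Per-cell bin counts (default 5,000 genome bins, about 500,000 mapped reads
per cell, so roughly 100 reads per bin) are divided by bin width, corrected
for GC bias by dividing out a lowess fit of rate on GC fraction, and scaled
to genome mean 1. Counts are modeled in simulation as negative-binomial
with variance `mu + phi mu^2`; the default validation dispersion
`phi = 0.1` gives a per-bin coefficient of variation of about 33%, typical
of WGA material.

Segmentation is per-chromosome recursive binary splitting on squared-error
reduction with a BIC-like penalty, `3 log(n) sigma^2` per breakpoint, with
`sigma` estimated robustly from first differences. The factor charges each
breakpoint's location, new mean and variance share; an under-penalized
segmentation fragments chromosomes into noise blobs at fractional copy
levels, which we measured to destabilize the downstream integer fit. The
practical floor on a reliably segmentable hemizygous event is about 15 bins
(~10 Mb at the default binning); all events used in validation span at
least 35 bins. Segments never cross chromosome boundaries and respect a
5-bin minimum.

### Integer ploidy

Scaling normalized ratios to integer copies is the only genuinely
ill-posed step: ratios are relative, so a perfectly flat genome is
consistent with any ploidy, and a lattice at twice the true scale fits any
profile the true scale fits. The fitter makes four choices, each adopted
after measuring a concrete failure mode on synthetic data:

* **Lattice-normalized objective.** The fit minimizes the weighted squared
  distance of observed levels to the lattice `k/s`, not of `s×level` to
  integers. In the un-normalized form the noise term grows with `s²` and
  drags genuinely high-ploidy genomes toward spuriously low scales (a
  pentaploid with one lost chromosome collapses to a near-diploid fit at
  validation noise).
* **Chromosome means carry the evidence.** Baseline ploidy is a
  whole-genome property; per-chromosome mean ratios are immune to spurious
  within-chromosome splits whose fractional levels a fine harmonic lattice
  would otherwise absorb. Chromosomes with real sub-chromosomal structure
  contribute larger variance and are automatically down-weighted by the
  noise debiasing. The flip side is that ploidy scaling leans on
  whole-chromosome copy levels — well matched to myeloma, whose hallmark
  is whole-chromosome trisomies and monosomies; a genome whose only
  aberrations are high-fraction arm-level events is scaled less reliably.
* **Integer-anchored candidates.** Candidate scales place the modal
  chromosome level on each integer ploidy in turn (each refined within
  ±1%); free refinement over all scales lets doubled lattices win by
  absorbing segment noise.
* **Parsimony prior and lowest-ploidy tie-break.** Each candidate pays
  `5 × noise-floor × mean |CN − P|`: a noisy diploid chromosome dipping
  3 sigma should not be explained as seven copies on a pentaploid
  background. Among candidates within `0.25 × noise-floor` of the best,
  the lowest ploidy wins, so harmonics are rejected. Both terms are scaled
  by the estimated noise floor and vanish on noise-free input.
* **Statistically flat profiles are diploid by convention.** When no
  chromosome mean sits more than 4 sigma from the modal level, the profile
  carries no absolute ploidy information at all (relative ratios cannot
  distinguish a flat diploid from a flat triploid), so the fit reports
  ploidy 2 with the `degenerate` flag set rather than letting a fine
  lattice absorb noise.

Under the validation conditions (100 cells per ploidy in 2–5, 500k reads,
5,000 bins, dispersion 0.1, clone architectures with at least two deviating
chromosomes) baseline-ploidy recovery is 98–100% and whole-chromosome event
recall and precision are at or near 1.0. A pentaploid whose only event is a
single lost chromosome is intrinsically harder — the decision rests on one
chromosome level measured at ~2 sigma — and is kept as a qualitative,
noise-free check rather than a quantitative one.

A cell is **altered** when its baseline ploidy differs from 2 or any
autosomal segment with integer copy number ≠ 2 spans at least
`min_event_bins` (default 10) bins; two copies are normal, matching
interphase-FISH copy counting. Sex chromosomes are excluded from ploidy
fitting and altered-calling because patient sex is not modeled.

### Clones

Cell-to-cell similarity is the fraction of bins with identical integer copy
number; altered cells are grouped by average-linkage hierarchical
clustering cut at `1 − threshold` (default threshold 0.95, so profiles
within 5% differing bins share a clone — one typical chromosome is 3–8% of
bins, placing single-chromosome differences near the boundary by design).
Normal cells take the reserved label `"normal"`; consensus profiles are
per-bin modal copy numbers, and per-compartment counts make clones shared
between blood and marrow visible.

## FISH concordance

The default 12-event panel mirrors a clinical myeloma FISH workup: CN
probes for CCND1 (11q13), RB1 (13q14), 13q34, TP53 (17p13), CKS1B (1q21),
CDKN2C (1p32), FGFR3 (4p16), IGH (14q32) and CEP17, plus the t(4;14),
t(11;14) and t(14;16) translocations. Intervals are hg19-approximate
band/arm coordinates, hardcoded, with a BED-like panel file as the override
mechanism. The observed copy number at a locus is the bin-length-weighted
median integer CN over overlapping bins (the median resists boundary bins);
gain means CN > 2 and loss means CN < 2 in absolute copies, matching how
interphase FISH counts signals ("three copies of CCND1"), with a
`relative_to_ploidy` option off by default. Translocations cannot be seen
in low-pass coverage and always return `not_evaluable`; they are excluded
from discordance lists.

Per-patient discordance compares events present in at least one cell with
the clinical panel: `cell_only` events are the pipeline's added value
(subclones invisible to a bulk assay with a ~20% positivity cutoff), and
`clinical_only` events flag sampling or sensitivity gaps. The end-to-end
validation plants a 15% subclone carrying a 17p loss beneath a 20% FISH
cutoff and checks that the report lists the 17p loss as cell-only.

## Statistics

Cohort comparisons on a handful of samples need exact tests: the rank-sum
test enumerates all `choose(n, n_a)` group assignments (midranks for ties)
up to pooled `n = 12` and falls back to seeded Monte-Carlo permutation
above that. With 4 vs 4 samples and complete separation the two-sided p is
exactly `2/70 ≈ 0.029`. Percentages round half-away-from-zero to one
decimal, the convention that reproduces the printed worked fractions
(36/44 → 81.8, 19/22 → 86.4).

## What the generator does and does not emulate

The synthetic immunofluorescence cohort draws log-normal channel
intensities (negative location log 50, ~25% log-scale spread, positives
separated tenfold), normal-like area and eccentricity models for WBCs
versus plasma cells, and spikes rare subtypes at configurable frequencies
(default slides are scaled down to 50,000 cells from the real ~3 million).
The CNV generator draws negative-binomial counts proportional to
CN × width × GC-factor per bin over an hg19-like genome with hardcoded
chromosome lengths, autocorrelated GC, a quadratic multiplicative GC bias,
and clone mixtures with integer events; sex chromosomes are simulated at
CN 2 (female-like) so unmodeled sex does not confound ploidy fitting. A
truth table accompanies every cell.

What passing these tests shows is that the implementation recovers known
structure under a realistic noise model. What it cannot show: real WGA
noise is locus-correlated and wave-like rather than independent
negative-binomial; real marker distributions overlap more and drift between
slides; segmentation artifacts of real mappability/repeat structure are
absent; and translocation detection is out of reach of low-pass coverage by
construction. Manual review of ranked outliers replaces the human
confirmation step of the laboratory workflow.

## Numerical choices and degenerate inputs

Ratios are normalized to genome mean 1 (to 1e-9); an all-zero profile is an
error. A constant channel (MAD 0) calibrates to an epsilon cutoff above the
median with a warning, so no cell is positive under the strict comparison.
A flat genome segments to one segment per chromosome and is called diploid
by the tie-break with a `degenerate` flag. Clone grouping of zero altered
cells returns an empty assignment, not an error. Problem sizes in tests and
in the acceptance script — 100 cells per ploidy class, 50,000-cell slides,
60-cell patient simulations — were chosen to keep the full validation
suite within a few minutes on a single core while leaving binomial noise
on recovery metrics well below the asserted margins.
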