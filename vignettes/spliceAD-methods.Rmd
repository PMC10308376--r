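---
title: "Methods: transcript-level splicing analysis of AD cohorts"
author: "spliceAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript-level splicing analysis of AD cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceAD)
```

## The analysis model

`spliceAD` analyses a transcript × sample TPM matrix from a brain RNA-seq
cohort stratified by Alzheimer's-disease neuropathology. The pipeline has
six statistical stages, each behind one exported function, all orchestrated
by `runPipeline()`.

### Cohort classification

Samples carry three scores: CERAD (1–4, a semiquantitative neuritic-plaque
measure where lower means more pathology), Braak stage (0–6, tangle
spread), and MMSE (0–30, cognition; dementia is MMSE < 24). The three
diagnostic groups are defined as control = CERAD 3–4 ∧ Braak 0–3 ∧ no
dementia; AsymAD = CERAD 1–3 ∧ Braak 3–6 ∧ no dementia; AD = CERAD 1–2 ∧
Braak 3–6 ∧ dementia. These printed ranges genuinely overlap at
CERAD 3 / Braak 3 without dementia, which satisfies both the control and the
AsymAD rule. We resolve the overlap with a fixed precedence, AD → AsymAD →
control, i.e. a pathology-forward reading under which the ambiguous cell
becomes AsymAD. The precedence is an argument of `classifySamples()` and
every sample landing in the overlap is reported. `filterLowExpression()`
implements the "TPM > 0.1 in no less than 5% of all samples" rule with a
ceiling on the supporting-sample count (the conservative reading of "no
less than"), applied jointly over all samples, never per group.

### Differential transcript expression

`detTest()` uses the two-sided Wilcoxon rank-sum test per transcript.
Because the thresholds are stated on the fold change but no estimator is
printed, we use the ratio of group means with a pseudocount
(`(mean_b + 0.01) / (mean_a + 0.01)`): means keep recovery of a
multiplicative planted effect unbiased, and the pseudocount (configurable)
protects against zero denominators at the bottom of the TPM scale. FDR is
Benjamini–Hochberg — the field default where only "FDR" is stated. Calls
require fold change > 1.5 (up) or < 0.67 (down) and FDR < 0.05.

Host-gene correlation (`hostGeneCorrelation()`) computes Pearson r between
each transcript and its gene across all samples, classifying at |r| > 0.3
with p < 0.05. Gene expression is the sum of the member transcripts' TPM
from the same matrix: summation guarantees consistency between the two
profiles and keeps the analysis self-contained; an independently quantified
gene matrix can be supplied instead. Correlation is computed on TPM as is —
log axes are presentation, not statistics.

### Splicing events and PSI

`inferEvents()` re-implements local-event inference in the style of
transcript-structure comparison tools: for every transcript pair of a gene
it detects the seven event types from shared/differing splice sites
(strand-aware; the same genomic configuration is A5 on "+" and A3 on "−"),
deduplicates events by (gene, type, sorted splice-site coordinates) and
unions the supporting transcripts into inclusion and exclusion sets. The
inclusion form is always the transcript whose mature product contains the
variable region; for MX the inclusion exon is the 5'-most of the pair, and
for AF/AL the alternative terminal exon lying furthest 5'/3'. Alternative
terminal exons that overlap are the alternative-donor/acceptor case and are
typed A5/A3, so no ambiguous AF/AL events are emitted.

PSI is transcript-based: Σ TPM(inclusion) / Σ TPM(inclusion ∪ exclusion),
missing where the event is entirely unexpressed (0/0 carries no usage
information). The event-support filter keeps events with PSI > 0.1 in at
least 5% of samples.

Two readings of the printed differential-splicing rule were possible:
"median PSI > 0.1" taken literally is a pure expression filter and cannot
define "differential", so `testDiffSplice()` defaults to
|Δ median PSI| > 0.1 between groups (with `literal_median = TRUE`
available). Similarly, the named signed-rank test is a paired test but the
groups are independent donors; the default is the unpaired rank-sum, with
`test = "signed_rank"` offered for equal-sized groups paired by position.

The frame check (`intactCodon()`) asks whether the variable region's
genomic length is divisible by 3. It deliberately uses genomic span, not a
CDS projection — no CDS records are required as input — so it is an
approximation for events overlapping non-coding portions of a coding gene;
it is reported only for protein-coding genes.

### Isoform switches

`computeIF()` forms isoform fractions IF = TPM_t / Σ_gene TPM; samples where
the gene is unexpressed are missing rather than zero (absence of a gene is
not evidence about relative usage). `detectSwitches()` tests IF with the
pooled-variance Student t-test as printed (Welch by flag), dIF being the
difference of group means; BH is applied across all transcripts in one
family per comparison (per-gene pooling by flag). Thresholds: |dIF| > 0.1,
FDR < 0.05; a gene switches if any member isoform does.
`switchVsGeneExpression()` then tests the summed gene profile with the DET
machinery to flag the headline class — switching genes with no gene-level
change.

### RBP–ASE networks

`buildRbpNetwork()` restricts to RBPs whose mean expression changes by
≥ 10% (relative to the reference-group mean, inclusive boundary) and to
differentially spliced events; a pair is only tested when at least one CLIP
binding interval overlaps the merged ±300 bp windows around the event's
defining splice sites (windows are merged first so one peak never counts
twice). Spearman correlation is computed across the samples of the two
compared groups — matching the per-comparison networks — with an
all-samples option. Edges require |rho| > 0.5 and raw p < 0.05; no FDR is
applied to edges by default because the printed rule uses raw p, but BH is
available by flag.

### Shared statistics

`bhFdr()` delegates to the standard step-up implementation with input
validation; `oraTest()` is the exact hypergeometric upper tail
(`P(X ≥ k)`) against a stated universe, with BH across sets. The universe
for DET enrichment is the protein-coding host genes surviving the
expression filter, not the whole annotation — never-expressed genes would
otherwise inflate enrichment. `rankTest()` uses the exact rank-sum null
distribution up to a combined n of 25 and the tie-corrected normal
approximation beyond, with midranks for ties.

## The synthetic cohort generator

`simulateCohort()` emulates the five inputs — annotation (GTF), expression
(TSV), metadata (TSV), binding sites (BED), gene sets (GMT) — with planted,
recorded effects. Its defaults are the package's study conditions: 60
samples per group, 500 two-to-three-isoform genes cycling through the seven
event types on alternating strands, log-normal expression
(`tpm_log_mean = 2`, between-gene sd 1, per-sample sd 0.5 — a spread that
keeps most transcripts comfortably above the 0.1 TPM filter while leaving a
realistic low tail), planted fold change 3 in 10% of genes, reciprocal
switches with dIF 0.3 in 15% of genes, 30 RBPs with drivers of strength 0.8
on 25% of switched events, and ±300 bp binding windows. One third of
variable-region lengths are forced to a multiple of three, so the majority
of events are frame-disrupting, as observed in real catalogues.

Design choices worth knowing:

- **Gene totals first.** Each gene's per-sample TPM total is drawn first and
  isoforms receive shares of it. A planted switch therefore redistributes
  expression within an unchanged total — the per-sample gene sums are
  *identical* between a switched and an unswitched run at the same seed —
  which is exactly the biology the switch detector must not confuse with
  differential expression.
- **Fold changes are planted per gene**, multiplying all isoforms in the
  affected group. Planting on single transcripts would silently shift
  isoform fractions and contaminate the switch detector's ground truth;
  gene-level planting keeps the three detectors' truths orthogonal. The
  recorded truth distinguishes the fold-change sets (`det_up`/`det_down`)
  from the complete expression-shifted sets (`expr_up`/`expr_down`, which
  add the switch isoforms — a switch genuinely moves the two isoforms'
  own expression in opposite directions).
- **Inclusion balance on the logit scale.** The within-pair inclusion
  fraction is `plogis(shift + strength·z + noise)` with a latent per-sample
  driver variable z. This keeps fractions in (0,1) without clipping, stays
  monotone in z (the property Spearman correlation needs), and makes a
  planted dIF of 0.3 land within a few percent of 0.3.
- **Aligned driver components.** Driver RBPs covary with z and carry a
  group shift in the same direction as their event's usage shift, so the
  within-group and between-group association components add instead of
  cancelling — a driver is a coherent regulator, not two competing signals.
- **Metadata by inverse classification.** Scores are drawn uniformly from
  each intended group's defining ranges, never from the ambiguous
  CERAD 3 / Braak 3 cell, so `classifySamples()` recovers the intended
  groups exactly and cohort construction is invertible on synthetic data.
- **Affected groups.** Effects are planted in the AD group by default
  (`affected_groups`), leaving AsymAD as a second null group — useful for
  checking comparison-specific calls.

What the generator does *not* emulate: read-level noise and mapping
ambiguity, sequencing-depth and batch effects, covariate structure (age,
sex), realistic genome coordinates, or correlated co-regulation beyond one
driver per event. Passing tests on these cohorts therefore demonstrate the
correctness and calibration of the statistics under a clean generative
model, not performance on real ROSMAP data, whose headline counts depend on
controlled-access inputs.

## Numerical choices and degenerate inputs

- Coordinates are GTF-native 1-based inclusive everywhere; BED input is
  converted on read. Version-suffixed identifiers are kept verbatim.
- Constant rows (no variance anywhere) get p = 1; zero-variance transcripts
  or genes are "irrelevant" in correlation; zero denominators yield missing
  PSI/IF values and excluded transcripts in ratio-based summaries, each
  logged.
- Ties in rank tests use midranks with the variance correction — TPM data
  contain zeros, so this is the norm, not the exception.
- BH q-values are computed on ranks and returned in input order; equal
  p-values share a q-value.
- Event deduplication keys on (gene, type, sorted defining coordinates);
  many transcript pairs supporting one local event union into one record.

## Problem sizes

The shipped tests run the detectors on cohorts of 500–1,000 genes
(1,000–2,500 transcripts) with 60 samples per group, and calibration checks
pool 20 independent null cohorts of 2,000 transcripts; these sizes give the
binomial precision needed to bound a 5% type-I rate within ±2 points while
keeping a laptop run in minutes. `scripts/acceptance.R` reproduces the
headline quantities at the same sizes from a single seed.

## Known limitations

- PSI is transcript-abundance-based; junction-read PSI (BAM input) is out
  of scope, as are nested/complex event graphs and transcript assembly.
- The frame check ignores CDS phase and UTR overlap.
- The network is correlational: binding co-occurrence plus monotone
  association, with no causal claim.
- No covariate adjustment is performed in any test.
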