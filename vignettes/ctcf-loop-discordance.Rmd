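---
title: "Predicting CTCF loops and scoring cross-condition discordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CTCF loops and scoring cross-condition discordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

CTCF loops form, under the loop-extrusion model, between a
forward-strand CTCF motif at the upstream anchor and a reverse-strand
motif at the downstream anchor, with both sites occupied by CTCF and
cohesin (RAD21) retained at the loop base. `ctcfloops` treats loop
formation as binary classification of candidate anchor pairs:

* **Candidates.** Loop calls (bedpe) are quality-filtered — fewer than
  2 supporting PETs or FDR above 0.05 removes a call, with both
  boundaries read strictly so PET = 2 and FDR = 0.05 survive — and each
  survivor defines three windows: a window of full width 1000 bp
  (configurable) centred on each anchor midpoint, plus the interloop
  region between them. Only spans in [2 kb, 2 Mb] (both ends inclusive;
  span measured midpoint-to-midpoint, the only anchor-size-invariant
  choice) are kept, the range in which the vast majority of human loops
  live.
* **Labels.** A candidate is a high-confidence positive when (a) its
  anchor motifs are convergently oriented, (b) both anchor motifs
  overlap a CTCF ChIP-seq peak by at least 1 bp, and (c) RAD21 overlaps
  at least one of the loop windows. Negatives are sampled pairs of
  *unbound* motifs with no RAD21 in any of the three windows,
  span-matched to the positives (decile bins of log-span) so that span
  carries no label signal. RAD21 informs the label only; the trainer
  refuses any feature schema containing it.
* **Features.** The FIMO log-odds score of each anchor motif (a proxy
  for binding-site conservation), the loop span, and one 0/1 presence
  flag per mark per window. Presence is deliberately binary — one peak
  or many makes no difference — because the presence of a feature in a
  window is taken to be more informative than its exact position or
  strength at this resolution.
* **Classifier.** Gradient-boosted trees (XGBoost, logistic objective)
  with 300 rounds, depth 4, learning rate 0.1; all exposed in the API.
  Training is single-threaded and seeded, so fits are exactly
  reproducible. An auxiliary random-forest binding predictor (500
  trees, √p features per split) operates on 500-bp site regions tiled
  into twenty 25-bp bins per track; its per-site probabilities can
  *replace* the binary CTCF ChIP flags at the anchors (default) or be
  *added* alongside them, for settings without CTCF ChIP-seq.

Two mark presets reflect the two data situations the pipeline serves:
`"cellline"` (CTCF, h3k4me1, h3k9me3, h3k27me3, h3k27ac; 1000-bp
windows) and `"ad"` (CTCF, DNase accessibility, h3k4me3, h3k27me3,
h3k27ac; 500-bp windows, as used for brain tissue). The window
"width" named in configuration is the full width; the stored
half-width is half of it.

## Discordance between conditions

For a case sample against a panel of controls the pipeline trains on
the pooled control candidates, scores every candidate loop in every
control sample and in the case sample, and aggregates the control
scores by their mean (the controls are assumed to share one loop
landscape; the mean is the simplest consistent estimator and the
per-sample scores are retained alongside). The discordant loop score is

\[ D = (s_{control} - s_{case})^2 , \]

symmetric, zero iff the conditions agree, and bounded by 1. A loop is
**lost** when the control score is essentially 1
(`s_control ≥ 0.9995`) and the case score below 0.0005, **gained** in
the mirrored situation (`s_control ≤ 0.0005`, `s_case > 0.999`). The
"essentially 1 / essentially 0" tolerances exist because a
probabilistic classifier almost never emits exact 0 or 1; 0.0005 is
the same width as the stated case-score threshold, and all four
thresholds are arguments.

Each discordant loop is annotated with the single gene whose body has
the longest overlap with the inter-anchor span (midpoint to midpoint);
ties break to the leftmost gene start, and a `k = 2` option reports
the two best genes per loop. Genes are then ranked, separately for
lost and gained loops, by the sum of `D` over their loops, and the top
5 per class reported.

A practical note on the extreme thresholds: with a logistic objective,
leaf updates stall once the per-leaf Hessian falls below the default
minimum child weight, which floors the predicted probabilities at
roughly `1/n` of the per-class training size. Reaching scores beyond
the 0.0005/0.9995 gates therefore requires at least ~2000 training
examples per class; the discordance workflow is designed around pooled
control panels of that size, and smaller studies should widen the
thresholds accordingly.

## Numerical and interface choices

* Coordinates are 0-based half-open everywhere internally; FIMO and
  GTF inputs (1-based inclusive) are shifted on read (`start − 1`) and
  shifted back on write. Overlap means ≥ 1 shared bp; there is no
  minimum-fraction rule.
* Anchor windows with several motif hits are represented by the
  highest FIMO score, ties to the leftmost start.
* bedpe anchors are normalised so anchor 1 has the smaller midpoint;
  inter-chromosomal rows are dropped (and counted) since span is
  intra-chromosomal by definition. PET and FDR column positions
  default to the ChIA-PET2 interaction layout (columns 7 and 9) and
  are arguments.
* Malformed data lines (inverted coordinates, unstranded motif hits)
  are skipped with counted warnings; structural problems (wrong column
  count, missing header fields, duplicate gene ids) are fatal.
* Candidate loops whose anchor windows touch (span ≤ window width)
  get an empty, flagged interloop whose presence flags are all zero.
* At predict time an absent anchor motif score is imputed as the
  training minimum of that column minus one — a sentinel below the
  observed range, so trees can route such rows away from genuine
  scores. Training data must be complete.
* ROC AUC is the trapezoid over the ROC curve with tied scores
  collapsed to one operating point (numerically the pairwise
  concordance probability with ties at ½); PR AUC is step-wise average
  precision, since trapezoidal interpolation is biased for PR curves.
  One-class inputs yield `NA` AUCs, not 0. Importance is total gain,
  normalised to sum to one.
* Tables are written tab-separated with fixed column orders and floats
  at six decimals, the precision at which discordance scores are
  reported; score tables round-trip through their readers at that
  tolerance.

## What the synthetic studies emulate

`simulate_loop_study()` draws a genome of `n_chroms` × `chrom_length`
(default 4 × 30 Mb), plants `n_true_loops` (default 2000) convergent
motif pairs with log-uniform spans on [2 kb, 2 Mb], and emits
per-sample peak tracks: CTCF over anchor motifs of intact loops with
probability `ctcf_emission[1]` (default 1.0 — occupancy is what
defines a planted loop) and over background motifs with
`ctcf_emission[2]` (default 0.1); RAD21 at the base of occupied loops;
histone marks in each loop window with `mark_emission[1]` (default
0.9) against a scattered background giving roughly `mark_emission[2]`
(default 0.1) per kilobase-window. Planted anchor motifs carry higher
FIMO scores (N(18, 2) versus N(12, 2)), standing in for the higher
conservation of structural CTCF sites. Decoy loop calls straddle the
PET/FDR/span filters, so the filters are exercised at their
boundaries. Case samples replay the control generative model with the
CTCF/RAD21 occupancy of a `case_disruption` fraction (default 10%) of
true loops deleted; a cluster of eight disrupted loops shares one
"hub" gene so the gene ranking has a unique planted answer.

Two geometric guarantees keep the planted truth identifiable: anchors
of distinct loops stay more than 1.2 kb apart (no anchor window can
capture another loop's motif), and background motifs are kept out of
anchor windows (the planted anchor site is its window's only
candidate). The binding-study generator similarly places sites on a
600-bp grid so site regions never overlap and ChIP overlap recovers
exactly the planted occupancy.

The fixtures deliberately do **not** emulate: nucleotide sequence,
signal strengths (only presence), heavy-tailed empirical span
distributions, overlapping/nested loop anchors, chromatin-state
autocorrelation along the genome, or batch effects between samples.
Passing tests on these fixtures therefore demonstrate that the
machinery recovers a planted dependency under controlled noise — not
that real cross-cell-type or case/control performance will match.

### Study sizes used by the checks

The test suite runs the full pipeline at sizes a desk machine handles
in seconds to minutes, stated here as the package's reference
problems: classification under moderate noise uses 2000 positives +
2000 span-matched negatives with all emissions at 0.9/0.1 and
ground-truth labels (the planted status), stratified 2/3–1/3 split;
the noiseless limit (emissions 1/0) uses 800 + 800 and must reach an
F-score of exactly 1. The importance check uses 1000 + 1000 with
marks at 0.5/0.5 (pure noise) so that only motif scores and CTCF
occupancy carry label signal. The disruption study uses 2000 loops on
4 × 60 Mb with deterministic occupancy (`ctcf_emission = c(1, 0)`),
*uninformative* marks and equal motif-score distributions
(`mark_emission = c(0, 0)`, means 15/15), because the property being
asserted — deleting CTCF occupancy in the case condition flips its
loops to lost — is only well-posed when occupancy is not confounded
with other class-separating features: if marks or scores shadowed
occupancy perfectly, an equally good classifier could ignore CTCF
entirely and no method could detect its deletion. This mirrors the
working assumption that loop loss in disease reflects binding loss
rather than wholesale epigenomic remodelling at the same sites.

## Limitations

* Presence-only features discard peak strength and position; binned
  within-window features for loops (as opposed to binding sites) are
  out of scope.
* The discordance thresholds target near-saturated classifiers; they
  are conservative by construction and will report nothing for weakly
  separated studies (see the probability-floor note above).
* Gene annotation considers the single longest-overlap gene per loop
  (optionally two); loops spanning many genes are reduced to one
  representative.
* Benchmarking against other loop predictors, upstream ChIA-PET
  processing, Hi-C matrix handling and genome-wide motif scanning are
  all outside the package; it consumes their standard outputs.
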