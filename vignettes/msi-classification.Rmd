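---
title: "Calling microsatellite instability from somatic mutation catalogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling microsatellite instability from somatic mutation catalogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msicall)
```

## The model

Mismatch-repair deficiency leaves two fingerprints in a tumor's somatic
mutation catalog: an elevated substitution burden, and — diagnostically —
somatic length changes in simple sequence repeats. `msicall` turns that
fingerprint into a call. Its unit of analysis is the per-tumor rate
vector computed by `compute_features()`: substitution and microindel
counts, overall and restricted to simple repeats, each divided by the
length of sequence that was actually searched for mutations (the capture
design), in Mb. Using the targeted length as denominator is what makes
rates comparable across exomes, panels and genomes; it is also why
off-target mutation calls are excluded from the numerators (they would
inflate a rate whose denominator never saw them). Excluded calls are
tallied and reported, never silently dropped.

The classifier itself is a decision tree. The packaged exome tree is a
single split — MSI-H iff `S.ind` > 0.395 microindels in repeats per Mb —
because on whole-exome training data every other candidate variable was
redundant once `S.ind` was available. The threshold is a property of the
repeat density of the sequence examined: simple repeats are denser
genome-wide than in exome targets, so the packaged whole-genome tree
uses the higher cutoff 0.909. Both rules are strict inequalities;
equality is called non-MSI-H. The same strictness applies to the
POLE-deficiency screen, which flags samples with `T.sns` > 60/Mb and
`S.ind` < 0.18/Mb: ultra-hypermutated tumors whose repeats are stable
are more plausibly polymerase-proofreading mutants than MMR mutants, and
the flag is reported alongside — never instead of — the MSI call.

Laboratory MSI categories are tri-level (MSI-H, MSI-L, MSS). Throughout
the package MSI-L and MSS are grouped as "Non-MSI-H" before any
training or comparison; the biology separating MSI-L from MSS is not
resolvable from these variables and the clinical question is binary.

## Coordinate conventions

All interval arithmetic is 0-based half-open. Conversions happen at file
boundaries only: MAF is 1-based inclusive (an SNS at position *p* spans
`[p-1, p)`; a deletion of *k* bases spans `[p-1, p-1+k)`; an insertion,
which MAF records by its two flanking bases, spans both flanks), while
BED and simpleRepeats tables are already half-open. `chr` prefixes are
stripped on read so TCGA-style and UCSC-style naming interoperate. A
mutation is "in repeat" if its span overlaps the merged repeat track at
one or more bases (any-overlap): a length change that touches a repeat
changes the repeat's length. Two refinements are exposed but off by
default, because the published rule mentions neither: `pad` grows every
repeat interval before the test, and `ins_rule = "within"` requires both
flanks of an insertion inside a repeat rather than one.

## The repeat annotation

The track merges two sources: homopolymer runs of length ≥ 5 scanned
from the reference sequence, and di-/tri-/tetranucleotide tandem repeats
imported from a UCSC-style `simpleRepeats` table, filtered on the
table's `period` column only (no motif-length inference). The scan is
case-insensitive — soft-masking marks repeats, and masked repeats are
exactly the ones this method needs — and `N` both breaks a run and never
counts toward one, since an ambiguity base is not evidence of a repeat.
Merging is coverage-level union (overlapping and abutting intervals
coalesce), and overlap queries run through an interval index rather than
linear scans.

## Retraining

`msi_train()` grows a binary tree by greedy top-down induction in the
C4.5 tradition:

* splits are scored by information-gain ratio (gain in bits divided by
  the split's own entropy);
* numeric thresholds are midpoints between consecutive distinct sorted
  values; ties in score go to the smallest threshold, and between
  features to the earlier feature in the canonical column order, so a
  fit is a deterministic function of its inputs;
* `cancer_type` is offered as one-vs-rest categorical splits;
* growth stops at `min_leaf` (default 2 samples per child), `max_depth`
  (default 5) or zero gain, and the grown tree is post-pruned by
  collapsing any subtree whose majority-class leaf does not increase
  training error;
* a row missing a feature value is down-weighted in that feature's gain
  (by the observed fraction) and routed to the larger child; the routing
  branch is stored in the node, so a trained tree also tolerates missing
  values at prediction time. The packaged default trees contain no such
  branch, so a missing `S.ind` there is an error naming the sample —
  with a one-variable rule, silently guessing would be worse.

This is a principled reimplementation of the family of algorithms behind
the published thresholds, not a bit-exact clone of any particular
toolkit's pruning heuristics; the packaged thresholds themselves are
carried verbatim, so retraining only needs to be reproducible and
well-behaved. Zero-denominator ratios are `NA` (never 0 or ∞): the
default classifier ignores them, and fabricating zeros would bias any
retraining that does not.

Degenerate inputs: single-class training data yields a one-leaf tree
with a warning; empty input is an error; a class with fewer members than
`k` in `cross_validate()` degrades stratification with a warning. Folds
are stratified by class and fully determined by the seed.

## Evaluation utilities

`fisher_exact_one_sided()` is the exact hypergeometric tail for
enrichment of the top-left cell (the direction of the POLE hypothesis:
signature ⇒ mutation), summed exactly. `roc_auc()` uses the pair-count
definition (ties ½, computed via the rank-sum identity) with `S.ind` as
the natural ranking score, and returns the (FPR, TPR) point at every
distinct threshold so curves can be re-plotted from the numbers.
`subset_experiment()` emulates gene panels by sampling whole target
regions without replacement until the requested length is first reached
— resampling partial regions would fabricate breakpoints — keeping the
final region's overshoot and using the achieved length as the
denominator. `repeat_density()` summarizes repeats per Kb over
consecutive groups of target regions (default 1000 regions per group),
the granularity at which regional density variation matters for panel
design.

## What the synthetic cohorts emulate — and what they do not

`cohort_spec()` defines three sample classes by their mean rates per Mb,
with per-sample counts drawn from a negative binomial:

| parameter | default | rationale |
|---|---|---|
| non-MSI-H `T.sns`, `S.ind` | 3.0, 0.05 /Mb | typical MMR-proficient colorectal/endometrial burden; `S.ind` far below 0.395 |
| MSI-H `T.sns`, `S.ind` | 30, 1.5 /Mb | hypermutated with strong repeat instability, well above the threshold |
| POLE-like `T.sns`, `S.ind` | 80, 0.05 /Mb | ultra-hypermutated, repeats stable: above the 60/Mb flag cutoff, below 0.18 |
| off-repeat microindel rate | 0.3 /Mb | small, class-independent background |
| dispersion (NB `size`) | 50 | mild within-class overdispersion; class structure carries most of the variance |
| capture | 30 Mb, 2 kb exon-like regions | a typical whole-exome design |
| repeat density | 5.6 /Kb | exome-like simple-repeat density |

Placement is cross-consistent by construction: every mutation lies in
the capture, in-repeat microindels are placed uniformly on repeat
intervals, off-repeat mutations are rejection-sampled off the track.
Because placement is deterministic given the drawn counts, the feature
engine must recover each sample's planted counts *exactly*, and the test
suite asserts that.

For threshold-recovery experiments the cohort specification takes a
`boundary` argument.
Planting a decision boundary at *b* means the generator guarantees class
separation there: in-repeat indel counts are drawn uniformly on the
integer ranges strictly below / strictly above `b × capture_mb`, and
substitution and off-repeat rates are equalized across classes so
`S.ind` is the only planted signal. With 2 kb targets on 30 Mb the count
granularity is 1/30 Mb⁻¹, so the midpoint learned by retraining sits at
*b* up to that granularity.

What the generator does **not** emulate: variant-caller error profiles,
sequencing depth (and its effect on indel sensitivity), mutation
clustering along the genome, signature-specific substitution spectra,
inter-class label noise in laboratory assays, and real inter-tumor
heterogeneity of repeat density. Passing tests on synthetic cohorts
therefore demonstrate the correctness of the computations — counting,
normalization, threshold logic, training dynamics — not the clinical
accuracy of the thresholds on any particular real cohort.

## Problem sizes and numerical choices

The test suite and the acceptance script run cohorts of 25–400 samples
on 2–30 Mb captures, 20 retraining replicates for boundary recovery,
10 kb–1 Mb references for scanner checks, full enumeration of 2×2
tables with margins ≤ 12 for the Fisher oracle, and 25–50 replicates
per length in subset experiments — sizes at which every oracle is exact
or its sampling error is negligible relative to the asserted tolerance.
Entropy is computed in bits with the 0·log 0 := 0 convention; split
candidates require both children ≥ `min_leaf`; gain must exceed 10⁻¹²
to split; leaf ties label as Non-MSI-H (the conservative call).
Serialization is JSON with full double precision, and a
serialized-then-restored classifier predicts identically by
construction (the tests assert byte-identical re-serialization).

## Known limitations

* MSI-L is not a predicted class; the binary grouping is part of the
  method's definition.
* Multi-nucleotide substitutions (DNP/TNP/ONP) are excluded from the
  variables (and tallied), as the rate definitions cover SNSs and
  microindels only.
* The homopolymer scanner is exact but sequence-based; it will not
  recover repeats absent from the provided reference build, and no
  liftover is attempted.
* `fisher_exact_one_sided()` and `roc_auc()` are small-cohort exact
  tools, not replacements for a full statistics stack.
* Retrained trees are only as good as the laboratory labels supplied;
  with very few POLE-deficient examples in any realistic cohort, the
  POLE screen is a fixed published rule here, not a trainable model.
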