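---
title: "Methods: meiotic UTR isoform discovery and URS1 enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meiotic UTR isoform discovery and URS1 enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the model behind
each stage, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and the
numerical conventions adopted where the underlying procedure leaves choices
open.

## The calling model and its assumptions

A meiotic UTR extension (mUTR) is operationally defined here as an
expression segment that (i) does not overlap any annotated transcript class
on its own strand, (ii) is expressed above background only in sporulating
diploid cells, (iii) lies within 100 bp of the TSS (5′ candidates) or the
terminator (3′ candidates) of a same-strand protein-coding gene that is
itself expressed during vegetative growth, and (iv) shows no significant
expression correlation with that gene across growth and sporulation
conditions. The last criterion encodes the biological picture: a UTR
extension transcribed as part of a meiosis-specific isoform is regulated
independently of the constitutive mRNA, so the *absence* of correlation is
the selection signal.

The correlation is computed on 14 averaged condition values — YPD, YPA and
SPII 1–12 h of the MATa/α diploid — giving a t statistic with 12 degrees of
freedom. Because the full sample design contains 45 arrays (28 synchronized
MATa time points, the two growth media, 12 sporulation hours and 3
starvation controls), but the mitotic time course and the MATα/α controls
only enter the sporulation-specificity filter, the correlation step sees
exactly 14 values per row; replicates, when present, are averaged per
condition first. The design is deliberately frozen: changing the condition
set would silently change the degrees of freedom of every P-value.

Selecting candidates with adjusted *P* > α inherits a known weakness: low
power (few informative conditions, noisy rows) favours selection. The
package implements the criterion exactly as stated rather than "fixing" it,
flags degenerate zero-variance correlations (`cc` set to 0, *P* = 1,
`degenerate = TRUE`), and reports the full candidate table via `tidy()` so
the rejected, significantly-correlated candidates remain visible.

### Caller parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `tau` | 6 | log2 signal | background threshold; arrays define no absolute background, so τ is a config scalar and the synthetic truth fixes it (expressed level 10 vs background 4 makes 6 a clean separator) |
| `max_gap` | 100 | bp | segments farther from an anchor risk being independent transcripts |
| `min_spii_timepoints_above_tau` | 2 | samples | one SPII point above τ can be single-array noise |
| `alpha` | 0.05 | — | conventional level; candidates with adjusted *P* > α are selected |
| `require_orf_expressed_in` | `either` | — | a cognate gene must be expressed in YPD or YPA (or specifically one of them) |
| `overlap_tolerance` | 0 | bp | any same-strand overlap with an annotated feature excludes |

Benjamini–Hochberg adjustment is applied jointly over 5′ and 3′ candidates.
Whether the two families should be adjusted separately is genuinely open;
the joint family is the more conservative single-family choice for a
selection rule that rewards *large* adjusted P-values, and it keeps the
procedure a single ranked experiment.

Coordinates are 0-based half-open everywhere inside the package; GFF3's
1-based closed convention is converted at the file boundary only. The gap
counts bases strictly between the segment boundary and the anchor; a
segment abutting or overlapping the anchor has gap 0 provided it does not
extend past the opposite ORF boundary (segments swallowing the whole ORF
are not UTR candidates). Ties between qualifying genes are broken by
smallest gap, then lexicographic gene id, then 5′ before 3′ — an arbitrary
but fixed total order that makes calls independent of input row order.

## PWM scoring

Scoring follows the information-weighted scheme of the MATCH family, the
convention in which core and matrix score similarity cut-offs are defined;
outside that scheme the customary thresholds (CSS ≥ 0.9, MSS ≥ 0.7) are
meaningless. Frequencies use a pseudocount of 0.25 per cell, avoiding
−∞ log weights for zero-count columns; the information weight uses the
natural log (min–max normalisation cancels the base). The core is the
window of 5 consecutive columns with maximal summed information, leftmost
on ties; matrices shorter than 5 use their full length. For an all-uniform
matrix the score range collapses and MSS is defined as 1 — every word is
equally (maximally) consistent with a motif that prefers nothing.

Proprietary URS1 matrices cannot be redistributed, so the package ships a
synthetic consensus-derived matrix (`urs1_pwm()`, also in
`inst/extdata/urs1_synthetic.transfac`): 7 observations of the consensus
base TAGCCGCCGA and 1 of each alternative per column. This mildly
degenerate logo has a useful property under the default thresholds: a
single substitution outside the 5-column core still passes (MSS = 0.9),
while a core substitution fails CSS — so exact and near-exact sites are
distinguished the way stringent versus lenient filtration distinguishes
them. Licensed TRANSFAC matrices can be supplied through `read_transfac()`.

## Motif enrichment

The permutation test scores each sequence by the mean, over all windows and
both strands, of the likelihood ratio Π f(i, w_i)/bg(w_i) against an
i.i.d. background (uniform 0.25 by default, configurable). The observed
statistic is the mean per-sequence score over targets; the null recomputes
it on `n_perm` target-size subsets of the background, drawn without
replacement when possible (with replacement otherwise, flagged). The
add-one rule `p = (1 + #(null ≥ obs))/(1 + n_perm)` keeps P strictly
positive and makes the test exact under exchangeability.

An important calibration caveat: the null resamples the *background* set
only. When the target set is itself a subset of (or exchangeable with) the
background — the setting under which the test is calibrated, and which the
calibration tests verify — rejection rates match the nominal level. When
targets are disjoint sequences from a separate pool, the heavy-tailed
likelihood-ratio statistic makes the test anti-conservative (a chance
near-hit among few targets cannot be matched by background subsets). For
the pipeline's question — are the meiotic-TSS windows enriched relative to
the cognate promoters — this one-background-mode comparison is exactly the
intended contrast, and planted-signal datasets yield P ≤ 0.01 at
`n_perm = 999`.

The count-based alternative (`fisher_enrichment()`) is a one-sided
hypergeometric test on motif-containing sequence counts at the scan
thresholds; it stands in for web-service protocols that cannot be re-run
offline, reducing them to their statistical core (thresholded scan + exact
count test).

## Isoform statistics

Length summaries compare called mUTR lengths to the published aggregate
mitotic UTR medians (68 bp for 5′, 91 bp for 3′) by a one-sample Wilcoxon
signed-rank test. A gene-paired test would be preferable but per-gene
mitotic UTR lengths are not available as inputs, so the one-sample form
against the aggregate median is used and documented as an interpretation.
Fold changes are reported to one decimal, the customary precision for such
summaries.

The signed-rank test is implemented in the package rather than delegated,
because the contract requires an exact null *with* averaged tied ranks:
zero differences are dropped, tied absolute differences receive mean ranks,
and for n ≤ 25 the null distribution of the positive-rank sum is computed
exactly by a generating-function convolution over doubled ranks (doubling
makes half-integer mean ranks integral), which is arithmetically identical
to enumerating all 2^n sign assignments. Above n = 25 the normal
approximation with continuity and tie corrections takes over —
at that size its error is far below any decision threshold used here.
`stats::wilcox.test` cannot compute an exact tied-rank null; it serves as
an independent cross-check on tie-free data in the test suite.

Timing classification takes the SPII 1–12 h profile (replicates averaged),
finds the peak hour (smallest hour on ties — a fixed, deterministic rule
whose main consumer is the flat-profile degenerate case), and assigns
early (≤ 4 h), middle (5–8 h) or late (≥ 9 h). The boundaries mirror the
staggered early/middle/late induction classes of meiotic transcription and
the behaviour of canonical middle genes peaking at 6–8 h; they are
configurable because the literature draws them differently by strain and
synchrony. The score (peak minus median SPII value) is 0 for flat rows,
which are flagged low-confidence rather than dropped.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
the physics of tiling arrays. Its defaults define the study conditions:

* 45-sample design exactly as above (`sample_design()`), one replicate;
* 2 chromosomes × 60 kb, 40 non-overlapping genes in fixed-pitch blocks
  (packing is validated, and infeasible configurations fail explicitly);
* 10 planted 5′ and 8 planted 3′ mUTR segments with log-normal lengths of
  median 241 and 173 bp (the reported medians), truncated to [56, 800] bp
  so segments and their 100-bp promoter windows always fit their blocks;
* gaps to the anchor drawn from 0–80 bp; timing classes drawn from equal
  early/middle/late proportions;
* log2 expression: constitutive level 10, background 4, τ = 6, Gaussian
  noise with sd 0.5. Background draws are clamped to τ − 0.5 and expressed
  draws to τ + 0.5, so planted rows satisfy the selection criteria *by
  construction* and tests can assert exact recovery rather than a noisy
  approximation of it;
* 12 decoys cycling through four classes, each violating exactly one
  criterion: expressed in mitosis; > 100 bp from any anchor; overlapping a
  planted ncRNA feature; or expression-correlated with the cognate ORF.
  The correlated class requires its host ORF to carry a deliberate SPII
  trend (slope 0.4 log2 units/h) that the decoy mirrors 6 log2 units
  lower — the only way a segment can be sporulation-specific *and*
  correlated with its gene. Host ORFs of correlated decoys are therefore
  the one exception to "ORF rows are flat at the expressed level";
* URS1 planting: the consensus TAGCCGCCGA — or, with probability 0.3, a
  uniformly chosen single-substitution variant, so both exact and
  near-exact sites occur — written into the 100-bp window upstream of each
  planted meiotic TSS with probability 0.66 (the lenient observed
  URS1-containing fraction) and upstream of every ORF TSS with probability
  0.1. Planted words and absolute positions are recorded and recoverable
  by exact string search; collisions between plants are avoided by
  rejection sampling.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: probe-level intensity noise and normalisation
artefacts, segmentation boundary error, overlapping or nested gene
structures, condition-correlated noise, non-Gaussian heavy tails, and
biological coupling between isoform classes. Recovery statistics on this
generator certify the correctness of the procedure's logic under its own
assumptions, not its sensitivity on arrays.

Determinism is part of the contract: every dataset is a pure function of
its `sim_config()` (genome and expression use two derived seeds), and
rerunning any pipeline configuration reproduces byte-identical files.

## Problem sizes

The test suite and the acceptance script run at sizes chosen to exercise
every code path at comfortable margins: recovery statistics aggregate 20
simulated datasets (360 planted mUTRs); BH and signed-rank oracles run
exhaustively for vectors of length ≤ 6 and samples of n ≤ 10; score
similarity is verified against direct formula evaluation over all 4^L words
for L up to 6; permutation calibration uses 200 null datasets at
`n_perm = 99` and planted detection uses `n_perm = 999`.

## Known limitations

* Segments are inputs; the package neither re-derives them from probes nor
  resolves complex segmentation patterns over ambiguous or overlapping loci.
* Selection by non-significant correlation rewards low power; treat calls
  with few informative conditions (flagged degenerate) with suspicion.
* The permutation test's calibration guarantee applies to the
  background-exchangeable null; disjoint-pool comparisons can be
  anti-conservative (see above).
* The shipped URS1 matrix is a synthetic consensus-derived stand-in; site-
  level predictions with it are illustrative, and licensed matrices should
  be used for biological claims about individual promoters.
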