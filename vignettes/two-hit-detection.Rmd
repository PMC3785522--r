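---
title: "Integrative two-hit detection in 1p/19q-codeleted gliomas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative two-hit detection in 1p/19q-codeleted gliomas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligotwohit)
```

## The problem

Oligodendroglial tumors defined by the 1p/19q co-deletion lose one copy of
two chromosome arms in a single translocation event, exposing the tumor
suppressors *CIC* (19q13.2) and *FUBP1* (1p31.1) to complete inactivation
by a second hit on the remaining allele. The second hit is usually a point
mutation, found by sequencing — but an exon-spanning microdeletion is
invisible to Sanger sequencing (the primers fall inside the deleted region,
so only the intact stromal allele amplifies) and can also evade vendor aCGH
callers, which conventionally require five or more consecutive aberrant
probes. `oligotwohit` implements the integrative strategy that closes this
gap: a purity-aware copy-number model over aCGH probes, expression-outlier
screening over RNA-seq counts, mutation-consequence classification, qPCR
breakpoint fine-mapping, and a calling layer that combines them into
per-sample two-hit calls.

## The copy-number mixture model

A tumor specimen is a mixture of tumor cells (fraction $f$, the purity)
and stromal cells that are diploid everywhere. A locus at integer copy
state $c$ in the tumor produces the expected probe log2 ratio

$$L(c, f) = \log_2 \frac{(1-f)\,2 + f\,c}{2}.$$

Two consequences drive everything downstream:

* at $c = 0$ the stroma is the only template, so $L = \log_2(1-f)$: a
  homozygous deletion at 75% purity sits at exactly $-2$;
* the map is invertible for $c \ne 2$:
  $f = (2 - 2^{L+1}) / (2 - c)$, which is how `infer_purity()` turns the
  log2 ratio of a known one-copy arm into a purity estimate.

```{r}
expected_log2(0, 0.75)
infer_purity(-2, 0)
```

Arm states are called by thresholding per-arm median log2 ratios
(`call_arm_states()`, defaults: loss at or below $-0.3$, gain at or above
$+0.25$). With tumor content of at least 80% — the floor in the cohorts
this package models — a true one-copy arm sits near $-0.7$ or lower, so
the cutoffs are deliberately loose and exposed as arguments. One open
point is worth stating: arrays in practice report one-copy arms anywhere
from $-0.7$ to $-1$ depending on vendor normalization and re-centering,
slightly steeper than the mixture model predicts at 75–80% purity; the
thresholds are configurable for exactly this reason.

Subtype classification applies the field's precedence: combined 1p and 19q
loss defines the *oligo* subtype regardless of other lesions; otherwise a
whole-chromosome-7 gain (with or without chromosome-10 loss) defines
*astro*; everything else is *other*.

## Focal homozygous-deletion candidates

`detect_focal_deletions()` scans loss-called arms for runs of consecutive
probes at or below $L(0, \hat f) + 0.3$. The default minimum run length is
**2**, deliberately below the five-probe vendor convention: the motivating
event spanned exactly two probes. The price of that sensitivity is paid in
a structured way — candidates under five probes are marked
`requires_corroboration` and only reach confirmed status with independent
support (an expression outlier; in the lab, qPCR).

Extent conventions: all file and report coordinates are 1-based inclusive.
Deletion extents, however, are reported as *coordinate differences*
(`end - start`), i.e. breakpoint-to-breakpoint distances, because that is
the arithmetic that reproduces published extents: the two deleted probes at
chr19:42,795,949–42,796,008 and 42,804,518–42,804,577 span
$42{,}804{,}577 - 42{,}795{,}949 = 8{,}628$ bp ("8.6 kb"), and the qPCR
outer bounds span $42{,}808{,}040 - 42{,}790{,}756 = 17{,}284$ bp
("17.3 kb"). Interval *widths* elsewhere use the inclusive `end - start + 1`
convention; the BED export shifts starts down by one for BED's 0-based
half-open coordinates.

```{r}
probes <- bt1_probes()
cand <- detect_focal_deletions(probes, call_arm_states(probes),
                               purity = 0.75, annotation = bt1_genes())
cand[c("inner_span_bp", "n_probes", "genes", "requires_corroboration")]
```

## Expression screening

Counts are normalized to RPKM
($\mathrm{counts} \times 10^9 / (\mathrm{length} \times \mathrm{libsize})$).
`flag_low_outliers()` flags a sample whose RPKM lies more than 2.5-fold
below the cohort median for that gene — the threshold used to screen
public glioma cohorts for marked down-regulation. Two deliberate choices:

* the median is computed leaving the tested sample out, so a single
  extreme value cannot mask itself in a 13–17-sample cohort;
* the 2.5-fold cutoff is strict (`>`), matching "more than 2.5-fold".

Group comparisons (`compare_expression()`) report the ratio of group
geometric means and a two-sided t-test on $\ln(\mathrm{RPKM} + 0.5)$; the
pseudocount keeps zeros finite and is the only zero-handling applied. The
pooled-variance test is the default (Welch via `var_equal = FALSE`); raw
p-values are Bonferroni-adjusted across the tested gene set.

## Mutation classification

HGVS parsing is deliberately minimal — substitutions with optional
intronic offsets, duplications, and exon-range deletions; anything else
raises an error naming the token, because a silent misparse is worse than
a failure. Consequences are decided in a fixed order (frameshift before
nonsense, so `p.(Ser1117Lysfs*34)` is a frameshift despite its `*`), with
a ±2 nt splice-site window around exon boundaries. Somatic status is
simply presence in tumor but not blood.

Damaging assessment: truncating classes are damaging unconditionally;
silent/intronic are not; missense changes get a majority vote over the
available predictor annotations (PolyPhen-2 at a 0.95 cutoff — the
"probably damaging" convention, below every score observed in the damaging
set it must admit — Mutation Taster by verdict, Mutation Assessor by any
non-neutral class). A missense with no annotations, or a tie, is
*undetermined*, never silently damaging, because the published two-of-three
rule is undefined for even splits.

## qPCR fine-mapping

With perfect efficiency (fixed at 2, as no efficiency calibration is
modeled), the Ct offset against a two-copy reference estimates dosage:
$\Delta Ct(c, f) = \log_2 (2 / ((1-f)2 + fc))$. At $f = 0.75$ the three
copy classes sit at 0, 0.68 and 2.0 cycles, separations comfortably above
run-to-run noise; amplicons are assigned the nearest class (midpoint
boundaries), a missing Ct is the "no amplification" sentinel and maps to
class 0 with a flag. A one-copy reference sample, when provided, is used
only as a calibration check (within 0.5 cycles of its class-1 prediction,
else a warning). Breakpoints are then localized to the gaps between the
last retained and first deleted amplicon on each side, giving minimum and
maximum extents; runs touching the tiling edge are flagged unbounded.

## Cohort statistics

The statistics layer is self-contained rather than delegated: the
two-sided Fisher exact test enumerates the full feasible range of the
(1,1) cell, sums hypergeometric point probabilities not exceeding the
observed one (relative tolerance $1 + 10^{-7}$, the convention of
mainstream software), and works in log space via `lgamma` so no table can
overflow. The Mann–Whitney U test enumerates all assignments exactly up to
12 pooled observations (average ranks for ties) and otherwise uses the
tie-corrected normal approximation with the standard 0.5 continuity
correction, which keeps it within 0.02 of exact enumeration at $n = 6+6$.
Bonferroni and Benjamini–Hochberg adjustments are implemented directly.
Unit tests hold all of these against independent oracles: brute-force
margin enumeration (exhaustively, for every 2×2 table with total ≤ 25) and
the base-R reference implementations.

## Two-hit integration

For each gene of interest (default *CIC* on 19q, *FUBP1* on 1p) in each
sample whose arm is lost (hit 1), `call_two_hits()` looks for hit 2:

* a damaging somatic point mutation → **confirmed**; truncating classes
  with a low-expression flag are annotated as consistent with
  nonsense-mediated decay;
* a focal-deletion candidate overlapping the gene → **confirmed** if it
  has ≥ 5 probes or an expression corroboration, otherwise **candidate**.

The confirmed/candidate distinction encodes one defensible reading of how
much corroboration a short candidate needs: detection (the event is found
and reported) is separated from confirmation (enough independent evidence
to act on). In the validation experiments below, sensitivity is measured
at the detection level, while the zero-false-positive requirement applies
to the confirmed tier — short candidates near the purity floor can
legitimately await validation, exactly as the motivating deletion awaited
qPCR.

## The synthetic cohort generator

No raw data accompany the study this package models, so the generator is
first-class, tested code that emulates the cohort's statistical structure:
17 samples mixing subtypes 12:3:2, purity uniform on $[0.80, 0.95]$ (the
80% floor is the cohort's histological tumor content), arm-level 1p/19q
loss, chromosome-7 gain ± chromosome-10 loss, focal 2–3-probe homozygous
CIC deletions inside the 19q loss (rate 0.1, matching the observed 1 in
12), somatic CIC point mutations at rate 7/12 with a 4:1:1:1
missense:nonsense:frameshift:splice mix, dosage-coupled negative-binomial
expression with 80% NMD knockdown of truncating alleles, and Ct values
following the log2 dosage model.

Where the study is silent, defaults were chosen once on field conventions:
per-probe log2 noise SD 0.15 (typical for modern 60-mer CGH arrays),
negative-binomial dispersion 0.05 (biological CV around 22%), Ct noise SD
0.1 cycles, and a depth scale emulating a 25-million-read run. Probes live
on a miniature genome (chromosomes 1, 7, 10, 19; 500 probes per arm at
10 kb spacing) so that full cohorts simulate in under a second; the BT1
worked example (`bt1_probes()`, `bt1_qpcr()`, `bt1_genes()`) retains real
hg19 coordinates.

Reproducibility is structural: one top-level seed, with per-sample
substreams derived from an FNV-1a hash of the sample id, so regenerating a
cohort is byte-identical and adding a sample never perturbs the others.

What the simulations do *not* show: real aCGH suffers GC waves and
segmental artifacts; real expression cohorts carry batch effects and
far heavier inter-tumor dispersion for many genes; real deletions need not
align with probe boundaries; and germline CNV polymorphisms are absent.
Passing recovery tests therefore demonstrates the machinery is correct
under its stated model, not that the thresholds are optimal on any given
platform.

## Validation experiments and problem sizes

The test suite runs three tiers, sized for a desk machine:

* **exact reproduction** — the five published Fisher p-values from the
  packaged cohort table, the mixture-model purity example, the 8,628 /
  17,284 bp deletion extents, and the cohort tallies (12/3/2 subtypes,
  IDH1 14/17 = 82.4%, CIC somatic SNVs 7/12 = 58.3%, spectrum 4/1/1/1);
* **oracle equality** — exhaustive Fisher agreement over all 2×2 tables
  with total ≤ 25, the purity round-trip grid, and zero-noise cohorts with
  100% subtype and two-hit recovery;
* **noise robustness** — 200 default-noise cohorts (fixed seeds), in which
  purity is recovered within ±0.05 for ≥ 95% of oligo samples,
  planted focal deletions are detected with sensitivity ≥ 0.9, and no
  unplanted sample ever receives a confirmed focal call.

## Known limitations

Breakpoint placement is bounded by probe and amplicon spacing; no BAF or
allele-specific modeling, no segmentation of multi-megabase sub-arm
events, no GC correction, no efficiency-calibrated or reference-gene
normalized qPCR, and predictor scores are consumed as annotations, never
computed. The published fold-change comparisons that depend on per-sample
supplementary values are reproducible in code path but not in data, as
those values are distributed only as a spreadsheet supplement.
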