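---
title: "Quantifying MMEJ mutation replacement: models, corrections, and their assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying MMEJ mutation replacement: models, corrections, and their assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmejquant)
```

# The measurement problem

Dual-cut mutation replacement corrects a pathogenic deletion by excising
the mutant segment between two SaCas9 cut sites and knocking in a donor
copy through microhomology-mediated end joining (MMEJ). The genomic
readout is colony sequencing: the edited locus is PCR-amplified, the
product subcloned, and tens of single-colony clones sequenced. Each clone
is one sampled allele, and the quantities of interest — what fraction of
alleles were repaired, what fraction suffered the competing simple
deletion — are functions of the clone category counts.

Two systematic effects separate the clone counts from the underlying
allele fractions:

* **Detection bias.** The repaired (Success) amplicon is the longest
  product (670 bp vs 611 bp mutant and 524 bp deletion with the default
  geometry), and longer templates clone and re-amplify less efficiently,
  so Success is under-counted.
* **Cell-type dilution.** Editing is restricted to rod photoreceptors,
  but the template DNA comes from whole retina; a rod fraction converts
  whole-tissue rates to rod-level rates.

`mmejquant` implements the full chain — locus/allele modelling, clone
classification, bias correction, efficiency statistics, off-target
screening — together with seeded generators for every input.

# The locus and allele model

A locus is described by the wildtype reference, the deletion interval,
two guide sites, and the genotyping primer positions; everything is
0-based, half-open, plus-strand (I/O converts to 1-based VCF coordinates
at the boundary). From it, `build_allele_set()` derives four expected
sequences by splicing:

* mutant = reference minus the deletion;
* success = reference with the recut-proof substitutions applied
  (equivalently: mutant with the inter-cut segment replaced by the donor
  core);
* deletion = reference minus the whole inter-cut interval.

Two identities hold for any valid geometry, and are tested as exact
integer properties on randomized loci:
`len(success) − len(mutant) = deletion size` and
`len(mutant) − len(deletion) = inter-cut distance on the mutant allele`.
The canonical geometry (59-bp deletion, 87-bp mutant inter-cut span,
670-bp wildtype amplicon) reproduces the 670/611/524 amplicon arithmetic.

The exact sequence of the real target locus is not reproduced; the
canonical fixture is a synthetic locus with matching geometry. This is a
deliberate choice: every quantity the pipeline computes depends on the
geometry (lengths, cut positions, intervals), not on the base identity of
the flanks, and a synthetic locus makes all fixtures generable in code.

Cut-site placement follows the SaCas9 convention — blunt cut 3 bp 5' of
the `NNGRRT` PAM, 21-nt protospacer — since the assay itself does not pin
these down; both are parameters. Recut-proofing is verified by a
multiplicative per-mismatch score in the CFD style. We ship a
conservative all-or-none default (any protospacer or PAM mismatch gives
score 0) rather than embedding published CFD weight tables; a full table
can be supplied as a TSV (`position`, `ref_base`, `alt_base`, `weight`),
and a mismatch absent from a user table scores 0, again the conservative
reading. The default donor carries 4 substitutions in the 5' target site
and 1 in the 3' site, mirroring the canonical design.

# Clone classification

`classify_clone()` applies a fixed precedence:

1. an indel-free match to the success amplicon within the substitution
   tolerance is **Success**;
2. likewise for the deletion amplicon, **Deletion**;
3. an inserted segment of ≥ `min_aav_match` bp matching the vector
   fragment is **AAVIntegration**;
4. if the mutation is still absent (mutant-like) and an indel falls
   within `cut_window` of either cut site, **CleavageSiteIndel**;
5. any other above-tolerance variant is **OtherIndel**;
6. otherwise **Unedited**.

The precedence is not stated by the assay definition itself; we fix it in
this order and document one consequence: a clone combining successful
replacement with junction indels (which repeated cleavage could in
principle produce) is classified OtherIndel rather than given a hybrid
category.

Tolerances, all configurable via `clone_tolerances()`:

| parameter | default | unit | rationale |
|---|---|---|---|
| `max_sub_frac` | 0.01 | fraction of amplicon | Sanger clone error plus residual PCR error is well below 1% per base |
| `cut_window` | 10 | bp | NHEJ indels concentrate within a few bp of the cut; 10 bp absorbs alignment ambiguity |
| `min_aav_match` | 20 | bp | a 20-mer is effectively unique against a kb-scale vector |
| `min_clone_len` | 100 | bp | shorter reads cannot span any informative junction; flagged `Unclassifiable`, excluded from counts |

Numerical choices. Comparison uses global affine-gap alignment (match 1,
mismatch −1, gap open 10, gap extend 0.5) — gap opening is expensive so
isolated sequencing errors are modelled as substitutions, not spurious
1-bp gaps. Two implementation details are worth documenting. First,
steps 1–2 require an *indel-free* match, which forces equal length, so
they are decided by direct Hamming comparison; alignment is only computed
(against the mutant amplicon, relative to which the remaining categories
are defined) for clones whose length matches no template. Second, the
vector-insert test uses a *local* alignment of the inserted segment
against the AAV fragment requiring `min_aav_match` matched bases (with a
2-base slack), because a global aligner may legally shift an insertion's
boundary into coincidentally matching flank bases; an exact substring
test would miss genuine inserts.

# Detection-bias correction

The calibration experiment mixes Success and mutant templates at known
molecular ratios (5, 10, 20, 50%), subclones, and types the clones.
`fit_detection_model()` regresses observed percent Success on true
percent Success by ordinary least squares, both on the percent scale —
the scale on which the canonical worked example operates (intercept
−0.154 is added to 4.7 directly). `correct_observed()` inverts the line:
`(observed − intercept)/slope`.

Assumptions, surfaced rather than silently applied:

* the detection-efficiency difference is **constant across mixing
  ratios** — the linear model is exactly this assumption;
* the correction applies only to the Success and Unedited-mutant shares
  (the pair whose mutual bias the calibration measured);
  `efficiency_report()` shifts the Unedited share by the amount added to
  Success so shares still sum to 1, leaves other categories' observed
  shares untouched, and renormalizes;
* corrected values can overshoot `[0, 100]` when the model is applied
  far from its calibration range; they are clamped with a warning, never
  silently.

A single-point variant, `detection_factor()`, reproduces the balanced
1:1 mixture arithmetic (16 observed of 53 expected 26.5 gives 0.60;
16 of 61 against the deletion amplicon gives 0.52).

Absolute rod-level rates divide by `rod_fraction = 0.75`, the assumed rod
share of retinal cells. The remaining estimators are closed-form:
T7E1 percent indels `100(1 − √(1 − f))`, relative Success among edited
clones `100·S/edited`, qPCR rescue efficiency via a CT-vs-log10-quantity
standard curve, ERG rescue relative to a 41.5 µV control mean, and the
flash-VEP light-sensitivity threshold (dimmest intensity exceeding
25 µV).

# Off-target and integration screening

The candidate filter applies pure set algebra on variant keys
(chrom, pos, ref, alt): selected = present in **all** post-treatment
samples and in **no** pre-treatment sample (canonically 3 post, 1 pre).
Presence means any record; an optional minimum-VAF threshold is exposed
because the underlying callers report VAF, but the default imposes none.
`screen_sites()` counts variant records overlapping BED intervals; a
clean site has zero.

`detect_integrations()` consumes alignment segments (the tabular form of
soft-clipped dual mappings): a read supporting a junction has one host
and one vector segment with adjacent read intervals; the junction is the
adjacent reference boundary. Junctions cluster within 10 bp; the reported
position is the cluster median. The minimum support of 1 read and the
10-bp window are explicit configuration, not inferred from data — the
screening context wants maximal sensitivity, and 10 bp spans typical
soft-clip jitter. Segments are assumed plus-strand host mappings, which
is what the bundled generator emits; strand-aware breakpoint polarity is
a known limitation.

# What the generators emulate — and what they do not

`simulate_clone_set()` draws clones from category templates: exact
amplicons for Success/Deletion/Unedited; uniform 1–10 bp indels at a cut
site for CleavageSiteIndel; 20–100 bp vector substrings inserted at a cut
for AAVIntegration; 1–10 bp indels placed well clear of the cut windows
for OtherIndel; i.i.d. substitution errors on top. Category counts use
largest-remainder allocation (exact when proportions × n are integers;
residuals assigned in the fixed category order). The canonical fixtures
(`fixture_clone_spec()`) encode reconstructed per-category counts: only
the summary rates and totals of each study condition are published, so
the Success/edited/Unedited counts are forced by those rates while the
split among non-Success edited categories is a documented choice
(deletion the major outcome, then vector integration, then cut-site
indels).

The generators deliberately do **not** emulate: PCR chimeras and
polymerase slippage, base-quality profiles or chromatogram artefacts,
microhomology-dependent indel spectra (real cut-site indels are not
uniform in size), or clone-count overdispersion from colony picking. A
green classifier test on synthetic clones therefore demonstrates that the
decision procedure implements its definitions correctly — not that real
Sanger data are this clean. Mixture simulation samples clones binomially
with probability `p·w_s/(p·w_s + (1−p)·w_m)`; the bias weight defaults to
exponential decay per 100 bp with strength calibrated so
`w(670)/w(611) = 0.60`, echoing the empirically measured factor. The
functional form is a modelling choice — only the direction of the bias
is established empirically — so `power` and `none` forms are provided.

All generators are pure functions of (parameters, seed).

# Problem sizes and tolerances used in the test suite

Property tests run at sizes chosen to bound sampling error well below
the asserted effects: classifier label recovery on 10,000 clones
(5 randomized loci × 2,000 clones; 100% required error-free, ≥ 99% at
0.2% substitution error), the off-target filter against brute-force set
algebra on 100 seeded scenarios of 59 noise sites, 100 junction-free
seeds for the integration detector's false-positive check, and 200
replicate mixture-series fits for the end-to-end correction recovery
(mean corrected estimate within 3 standard errors of truth). Algebraic
identities (regression/correction round trip) are asserted at 1e-9;
splicing identities as exact integer equality.

One numerical discrepancy is handled explicitly: the published worked
example's inputs (observed 4.7, slope 0.528, intercept −0.154) evaluate
to 9.193, while the published result is printed as ~9.185 — consistent
with unrounded regression coefficients upstream of the printed ones.
Tests assert the exact closed form and agreement with the printed value
at its display precision.

# Known limitations

* Classification is reference-bounded: a clone carrying a rearrangement
  entirely outside the amplicon is invisible, as in the real assay.
* The bias correction extrapolates linearly outside the 5–50% calibration
  range; clamping warns when this matters.
* `Unclassifiable` clones are excluded from denominators, which assumes
  truncation is independent of category.
* The integration detector reports breakpoint pairs, not orientation-
  resolved junction sequences; minus-strand host segments are not given
  special treatment.
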