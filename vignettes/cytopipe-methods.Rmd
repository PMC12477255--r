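---
title: "Models and methods behind cytopipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cytopipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytopipe)
```

# What the package models

cytopipe implements the analysis chain for multiplexed mass cytometry
(CyTOF) immune profiling of the kind used in vaccine challenge studies:
samples from several treatment groups and tissues are stimulated ex vivo,
barcoded with palladium isotopes, pooled, acquired with spiked
normalization beads, and then computationally normalized, debarcoded,
gated and summarised into population frequencies, pseudo-absolute counts
and phospho-signaling responses, which feed a group-comparison and
outcome-correlation statistical layer.

Because instrument data are large and external, the package carries a
first-class synthetic-data generator that emulates the full study design:
three treatment groups (an unvaccinated "mock" control and two vaccine
platforms, mRNA and adjuvanted protein; 8 animals per group), two tissues
(PBMC and lung-draining lymph node), three 15-minute stimulation
conditions (PBS control, PMA/ionomycin, R848), 13 annotated mononuclear
populations, 15 intracellular signaling markers, 3-of-6 palladium
barcoding, five dedicated bead channels and smooth acquisition-time
sensitivity drift. Every simulated event carries ground-truth labels in a
sidecar table that never enters the event matrix or FCS output, so the
pipeline cannot cheat and every stage can be tested as a
parameter-recovery problem.

# The generator

## Marker model

Marker intensities are Gaussian on the arcsinh scale with cofactor 5
(`z = asinh(x/5)`), back-transformed as `x = max(0, 5 sinh(z))`. This is
the simplest model consistent with the transform used throughout the
analysis: medians commute with the monotone transform, so an arcsinh-scale
location shift of δ appears as a response of exactly δ. Each of the 13
populations (plus an unannotated "other" remainder) has a profile of
"high" phenotype markers (location 4.0) against a background location of
0.5, both with SD 0.3 — roughly 12 SD of separation, so hierarchical
gating with cutoffs at the mode midpoint (2.25) is essentially exact and
test failures indicate pipeline defects rather than overlap ambiguity.
Real CyTOF data are messier (heavy tails, zero inflation, partial marker
overlap); passing recovery tests here demonstrates correctness of the
computations, not robustness of gating to ambiguous biology.

## Composition and effect sizes

Population fractions of the CD45+CD66− mononuclear pool are configured per
(tissue, group). The vaccinated groups share a base composition; the mock
group differs in the features the study design highlights: more activated
(HLA-DR+Ki67+) CD8 T cells and fewer plasmacytoid dendritic cells in
blood, and more intermediate monocytes, B cells and IgM+ B cells in the
lymph node. Per-animal compositions multiply the group composition by
`exp(beta * (severity - reference) + N(0, sigma))` with `sigma = 0.10`,
giving a between-animal coefficient of variation of roughly 10–20% so the
seeded group differences are at least 1.5 pooled SD at n = 8 per group —
comparable to clearly significant effects in animal studies of this size.

## Severity and outcomes

Each animal carries a latent severity with group-dependent mean (mock 2.5,
mRNA 1.2, protein 0.8; SD 0.5). Clinical outcomes are linear in severity
with Gaussian noise, clipped to their clinical ranges: lung viral RNA
(log10 copies per 30 mg tissue, slope 1.6), lung pathology score (0–4,
slope 0.75) and radiograph score (0–3, slope 0.55). The same latent
severity feeds back into designated cellular features (the composition
links above, plus signaling links such as stronger PMA/I-induced IκB loss
in lymph-node IgM+ B cells and higher pCREB in blood CD56+CD16− NK cells),
which is what makes "features correlate with outcomes" a recoverable truth
rather than an accident of sampling.

## Acquisition artifacts

Acquisition times are uniform over a 600 s window. Instrument sensitivity
follows a smooth monotone decline `g(t) = 1 / (1 + (range - 1) t/T)`
shared by all channels (the model the bead-normalization literature
assumes), with a default dynamic range of 2. Normalization beads are
spiked at a 5% default fraction with their signature on five dedicated
channels disjoint from all marker metals — the real panel's metal
collisions (e.g. Lu175) are deliberately avoided in the synthetic panel so
bead identification is unambiguous. Doublets are simulated as channel-wise
raw-intensity sums of two events with different barcodes, so more than k
barcode channels are high by construction.

# Preprocessing

## Bead identification

An event is a bead iff it exceeds a data-driven threshold on *every* bead
channel. Per channel the threshold is the valley between background and
bead modes (maximal between-class variance on the arcsinh scale); a
channel that is unimodal-high counts as all-bead, and when no bead mode
exists at all the function warns and returns an empty mask. A quantile
fallback (`min_quantile`, default 0.98 of positive events) covers
marginal cases.

## Bead-standard normalization

Bead events sorted by time are summarised by per-channel medians in
overlapping windows of 500 beads (step 250); the correction multiplier at
each window knot is `reference median / local median`, linearly
interpolated between knots and held flat outside them. The reference
defaults to the run's global bead median; passing the pooled cross-batch
medians normalizes several batches to a common scale. Bead channels get
their own fitted multiplier; all other channels use the geometric mean of
the bead-channel multipliers, which is exact under the shared-sensitivity
drift model and is the standard operating assumption of bead
normalization. A local median of zero is an error (it would produce an
infinite multiplier), and multipliers are validated strictly positive.

## Debarcoding

Barcode channels are rescaled to [0, 1] by their within-run 1st–99th
percentile range *on the arcsinh scale*; rescaling raw ion counts instead
makes the separation statistic hostage to the multiplicative spread of
high intensities and costs a third of the events (we measured exactly
that before switching). A channel whose within-run spread is under 1
arcsinh unit has no high/low structure (a code position used by no pooled
sample, or a pathological stream); it is pinned to constant 0 or 1
instead of being stretched noise — without this, a degenerate stream can
hand out spurious assignments.

Per event, the separation is the gap between the k-th and (k+1)-th
highest rescaled channels; the preliminary code is the indicator of the
top k. Events whose code is absent from the scheme or whose separation is
below the cutoff (default 0.3) stay unassigned. Doublets fail by
construction: summing two codes lights more than k channels, so the k-th
and (k+1)-th values are both "high" and the separation collapses.

The Mahalanobis purity filter estimates each assigned sample's mean and
covariance of rescaled barcode values in a single pass (no iteration, for
determinism) and unassigns events beyond `max_dist` (default 30 on the
squared-distance convention; the convention is explicit and switchable).
Singular covariances are ridge-regularized with a warning; samples with
fewer events than channels + 1 are skipped with a warning. Note a
structural property of this filter: a *tight coherent* contaminant cluster
of fraction p cannot exceed squared distance ~(1−p)/p under single-pass
estimation (≈19 at 5%), so the filter's value is against diffusely spread
contamination and stray events, not against a coherent mislabeled block.

# Gating and features

The gate tree is plain data: named nodes with a parent link and a
conjunction of single-channel threshold predicates on the arcsinh scale.
The default tree roots at CD45+CD66− and reports 13 populations — CD4 T,
CD8 T, activated (HLA-DR+Ki67+) CD8 T, CD3+CD4−CD8− T, B, IgM+ B,
CD56+CD16− NK, CD16+ NK, pDC, mDC and classical / intermediate /
non-classical monocytes. The exact roster of reported populations and all
cutoffs are configuration, not code; the default cutoffs sit at the
midpoint of the synthetic modes because the underlying study's gating was
manual and no numeric cutoffs exist to copy. The CD16+ NK subset
complements the named CD56+CD16− NK population to reach the 13 reported
populations; both are overridable.

Frequencies are percentages of the mononuclear root; events matching no
reported leaf stay "other mononuclear" but remain in every denominator.
Frequency and pseudo-absolute-count comparisons use the unstimulated
condition only. Pseudo-absolute counts multiply each PBMC frequency by the
CBC-derived mononuclear count `wbc − (neutrophils + eosinophils)`
(cells/µL); lymph node cellularity is undefined and no counts are
produced there. For nested reported populations, alluvial-style corrected
frequencies subtract reported children from their parent (e.g. B minus
IgM+ B).

Signaling features are per-sample medians of `asinh(x/5)` per (population,
marker), flagged missing below `min_cells = 20` events — medians of
smaller gated populations are too unstable to difference, and the floor is
configuration. Responses are stimulated-minus-unstimulated differences of
matched medians within animal/tissue/population/marker; missingness
propagates and is never imputed.

# Statistical layer

Pairwise group comparisons use the two-sided equal-variance Student t
(pairing only for stimulated-vs-unstimulated contrasts of the same
sample); multi-group comparisons use one-way ANOVA; correlations are
Pearson. All three are computed through base R (`t.test`, `oneway.test`,
`cor.test`) and are verified in the test suite against from-scratch
oracles built only from sums and the incomplete-beta CDF.
Benjamini–Hochberg adjustment is applied within declared families:
frequency tests per tissue (populations × two vaccine-vs-mock
comparisons), selected-feature ANOVAs per (tissue, stimulation), and
outcome correlations per (tissue, feature family, outcome). Degenerate
statistics (zero variance, too few observations) are flagged and excluded
from a family's hypothesis count rather than silently dropped or forced.

Volcano classification uses the uncorrected paired-t p-value with cutoffs
p < 0.05 and |mean arcsinh change| > 0.1 — the uncorrected choice is
deliberate and documented in the figure conventions this layer mirrors;
every other significance statement is BH-adjusted. The "top responding
feature" selection ranks features by p-value and by |mean change|, sums
the two ranks and keeps the top 20% per (tissue, stimulation), with
deterministic tie-breaking (smaller combined rank, then larger |change|,
then lexicographic id). Group Z-scores are group means minus the grand
mean of all animal values, divided by the SD of all animal values; the SD
convention (population vs sample denominator) is not standardised in the
field, so it is a documented switch with population as default. log2
ratios versus the mock group are undefined (flagged, not fudged) when
either mean is nonpositive.

Outcome correlations are pooled across groups by default — the relevant
question is whether a feature tracks severity across the whole cohort —
with an optional per-group mode appended for inspection; BH applies to
the pooled family only.

# Numerical and design choices

- **Determinism.** Every stochastic step derives its seed from the
  experiment seed and stable labels (animal, tissue, stimulation, batch),
  so any sample can be regenerated in isolation and full runs are
  byte-reproducible. RNG state is saved and restored around all seeded
  sections.
- **FCS I/O.** The package includes a compact FCS 3.1 writer/reader
  (list-mode, 32-bit float, little-endian) sufficient for its own files
  and for interchange with standard tools; parse failures name the
  offending offset or keyword. Values round-trip to single precision.
- **Ties and order statistics.** Rank ties use mid-ranks; selection ties
  break deterministically as above. Barcode top-k extraction handles ties
  by first occurrence; a tie exactly at the k-th position yields a
  near-zero separation and the event is dropped rather than guessed.
- **Degenerate inputs.** Zero-variance t-tests return t = 0, p = 1 when
  means agree (flagged degenerate) and p = 0 otherwise; empty samples and
  zero-mononuclear samples are excluded with warnings; empty FCS files are
  valid.

# Problem sizes used in the checks

The test suite and the acceptance script size their simulations to the
statistical requirements of each check rather than to the full study
volume: debarcoding exactness uses a 16-sample batch of 50,000 singlets
plus 2% doublets in the separated regime; normalization recovery uses
50,000 events with 10% beads under 2-fold drift; frequency recovery uses
50,000-event samples (binomial SEs small enough to resolve 4-SE bands for
a 0.8% population); signaling recovery uses 8 animals × stimulated and
unstimulated aliquots; the end-to-end pattern check runs the full
pipeline at n = 8 animals per group with 1,500 events per sample across
20 (tests) or 10 (script) seeds. At these sizes all recovery bands are
set by the stated oracles (binomial SEs, Monte-Carlo resampling of median
differences, Fisher intervals), never tuned to observed outcomes.

# Known limitations

- The generator omits spillover/oxide interference, acquisition dead
  time, staining chemistry and zero-inflation by default; gating
  performance on real, overlapping populations will be worse than the
  near-exact recovery seen here.
- Bead normalization corrects a shared sensitivity drift exactly; truly
  channel-specific drift is corrected exactly only on channels with their
  own bead fit.
- The Mahalanobis filter's coherent-contamination bound (above) is
  inherent to single-pass estimation; an iterated or robust covariance
  would change it but break single-pass determinism.
- UMAP embedding and figure styling are out of scope; the result tables
  are the interface.
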