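---
title: "Quantifying mitochondrial turnover: models, parameters and validation"
author: "mitoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial turnover: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoquant)
```

## The problem

Mitochondrial turnover — the balance between mitophagy (selective
degradation of damaged mitochondria) and biogenesis — is read out in
high-content imaging studies through a small set of per-cell statistics:
mitolysosome counts from the tandem mCherry–GFP mito-QC reporter,
counts of individualized depolarized mitochondria from TMRE/MitoTracker
Green co-staining, vesicle–mitochondrion contact counts, the radial
distribution of lysosomes, nuclear enrichment of transcriptional
regulators, cristae density along STED transects, and mito-stress-test
respirometry parameters.  In practice these numbers are produced inside
interactive tools whose thresholds are not recorded.  `mitoquant`
implements each procedure as a deterministic classical pipeline in which
every derived value is logged (JSON-lines provenance), and pairs it with
seeded simulators that provide ground truth for validation.

## The classical segmentation pipeline

All imaging assays share one backbone:

1. **Projection.**  Morphology and counting channels use the maximum
   Z-projection; integrated-intensity readouts (TMRE, DQ-BSA) use the sum
   projection, so total rather than peak signal is measured.
2. **Cell-by-cell segmentation.**  Nuclei: Otsu threshold of the DAPI
   projection, hole filling, 8-connected labeling, and removal of objects
   below `min_nucleus_area_um2` (default 5 µm²).  Cells: Gaussian blur
   (default sigma 8 px) of a cell-filling channel, Otsu threshold, then
   geodesic growth from the nucleus seeds, so each cell inherits its
   nucleus label.  Cells touching the field border are excluded; for
   reporter assays, cells below the 0.10 or above the 0.90 quantile of
   per-cell mean reporter intensity are excluded (scale-free restatement of
   "keep medium-intensity cells"; ties are retained).
3. **Structure masks.**  A white top-hat (disk radius 5 px) flattens the
   diffuse background before Otsu thresholding; puncta masks are
   additionally watershed-split (seeds: local maxima of the Euclidean
   distance transform separated by ≥ 3 px).  Organelle labelings that feed
   a size-based classification apply a debris floor
   (`min_object_area_um2`, default 0.2 µm²): on a channel with a bright
   cytoplasmic baseline, isolated shot-noise pixels occasionally survive
   the top-hat/Otsu step, and a 1–2-pixel "object" is segmentation debris
   at any realistic magnification, far below both the diffraction limit
   and the smallest organelles being classified.
4. **Measurement.**  Per-object area (µm²), centroid, per-channel mean and
   summed intensity; objects belong to the cell whose label lies under
   their centroid.

Thresholding uses a strict `>` so a zero threshold can never produce an
all-foreground mask on integer images.  Foreground pixels are always
partitioned exactly by the watershed (no pixel created or lost), and a mask
of well-separated blobs reduces to plain connected components.

Two numerical details are worth recording.  The Otsu criterion is
maximized exactly over the unique intensity values for discrete images;
continuous-valued inputs (e.g. blurred projections) are binned to 4096
levels first.  And the distance transform is lightly smoothed (Gaussian,
0.8 px) *for seed detection only*: a noise-jagged object boundary otherwise
produces spurious ridge maxima that oversplit single puncta, while the
well-separated maxima of genuinely merged objects survive the smoothing.
Pixel assignment itself always uses the unsmoothed geodesic growth.

## Assay-specific statistics

**Mitolysosomes and flux.**  An mCherry object counts for its cell iff no
pixel of it overlaps or is 8-adjacent to the GFP network mask.  "Touching"
is deliberately a single shared predicate — used with opposite polarity for
mitophagosome (LC3 touching mitochondria) and LAMP1-contact counting — since
no physical contact distance is identifiable from pixel data alone.  The
flux is the ratio of arm means, not the mean of per-cell ratios: cells are
not paired across inhibitor conditions, so per-cell ratios are undefined.
`flux_ratio` is flagged undefined when the uninhibited arm's mean is zero.

**Depolarization.**  The TMRE cutoff is formalized as `mean + k·sd`
(default `k = 3`) of sum-projected TMRE over non-mitochondrial pixels
inside retained cells.  This makes the classification exactly invariant to
a uniform additive TMRE offset, which the tests assert bit-for-bit.  The
1 µm² area cutoff for "individualized small" mitochondria is exposed as a
parameter.

**Peripheral lysosomes.**  Distances are vesicle centroid to nearest
nucleus pixel, in µm.  The 75th-percentile threshold is taken from a
*declared reference condition* (default: the control arm) and applied to
all arms, so the statistic is comparable across conditions.  The percentile
uses exclusive linear interpolation (R `quantile` type 6): with the strict
`>` rule this bounds the self-referenced peripheral fraction by 25% for
every sample size, a guarantee the inclusive (type 7) convention provably
violates for some n (e.g. 21/82 = 25.6%).  Intensity gating, by contrast,
uses the conventional inclusive quartiles.

**Cristae.**  Peaks are local maxima (first sample of a plateau) with
prominence at least `min_prominence_frac` (default 0.2) of the profile's
full range and pairwise separation at least `min_separation_um` (default
0.06 µm, two acquisition pixels at the 30 nm STED sampling); conflicts are
resolved tallest-first with ties to the lower index.  Density is peak
count divided by `(n − 1) × pixel_size_um`.  Manual "peak counting" is
thereby replaced with an explicit, configurable rule.

**Respirometry.**  Phase summaries follow the standard mito-stress-test
conventions — last basal measurement, oligomycin minimum, FCCP maximum
(covering both sequential FCCP additions), rotenone/antimycin-A mean — and
are injectable for protocol variants.  The decomposition is built bottom-up
(`atp_linked = basal_raw − oligo_raw`, `proton_leak = oligo_raw − nonmito`,
`basal = atp_linked + proton_leak`) so the accounting identities hold
bit-exactly rather than to rounding; corrected parameters are invariant to
a uniform OCR offset.  The ATP production rate uses the
oligomycin-sensitive OCR conversion, `atp_linked × 2 O/O₂ × 2.75 ATP/O`,
with both constants exposed — kit-specific equation variants can be
recovered by changing them.  ECAR is summarized per phase but not
decomposed into glycolytic ATP.

## The synthetic fields

The generators emulate the *statistical structure* each assay measures,
not micrograph texture: cells are disks on a jittered grid (radius
10 ± 0.45 µm, nucleus 2.1 µm, 16 cells on a 416 × 416 field at 0.3 µm/px),
mitochondrial networks are random-walk tubules of 0.5 µm width, and puncta
are Gaussian spots planted at controlled per-cell counts — Poisson(λ) for
the mito-QC minus arm, Poisson(λ × flux_ratio) for the plus arm, with an
optional fraction planted on the network to exercise the exclusion rule.
Noise is Poisson shot noise plus additive Gaussian read noise (sd 2), the
standard camera model.  Amplitudes (network 120, puncta 200, cytoplasmic
baseline 60 over background 8) put the default fields in a high-SNR regime
in which Otsu recovers essentially all planted foreground — deliberately,
since the acceptance properties quantify the *counting rules*, not
robustness to arbitrary noise.  Every generator is a pure function of its
parameters and seed; raising the noise level changes pixels but never the
recorded ground truth.

Placement uses minimum separations (5 px between puncta, 4.5 px from the
network for "off-network" puncta, 8 px between the TMRE assay's small
mitochondria) so that planted truth is unambiguous under the pipeline's
touching and splitting rules.  The nuclear-translocation generator
compensates its drawn amplitudes for the camera background so the *total*
nuclear/cytoplasmic mean ratio equals the requested fold.  The cristae
generator synthesizes a raised-cosine comb with exactly
`round(density × length)` equally spaced maxima and enforces Nyquist
sampling.

What passing these tests shows: the counting, classification, distance and
trace rules recover known contrasts at realistic per-cell rates and sizes.
What it does not show: robustness to out-of-focus light, uneven
illumination, textured mitochondrial networks, cell shapes far from convex,
or segmentation transfer to real micrographs — those require real annotated
data, which the upstream studies do not deposit.

## Validation strategy and study sizes

Every operator with a closed-form or enumerable reference is tested against
an independent brute-force oracle: connected components vs. queue flood
fill, top-hat vs. exhaustive neighborhood min/max, object measurement vs.
per-pixel accumulation, quantile gating vs. a sort-based rule, peak
detection vs. an exhaustive prominence scan — exact agreement on dozens of
random instances each.  End-to-end acceptance tests regenerate each study
at its stated size: mitolysosome recovery over ~100 cells at λ = 6 (±10%),
flux-ratio recovery over ~200 generated cells/arm for five seeds (within
[1.8, 2.2] for truth 2.0), exact (8, 3) depolarization recovery in ≥ 95% of
~50 cells, peripheral-statistic ordering over five seed pairs, nuclear fold
within 5% over ~100 cells, cristae density exact on the noiseless comb and
within ±0.5 µm⁻¹ at SNR 20, and bit-exact respirometry identities over
1000 random traces.  These sizes keep the full suite to a few minutes on
one CPU while holding the Monte-Carlo error of each check well inside its
tolerance.

## Known limitations

* Segmentation is 2-D on projections; overlapping cells in dense cultures
  and 3-D organelle geometry are out of scope, as are deconvolution and
  learned pixel classification.
* The touching predicate is resolution-bound (one pixel of adjacency); at
  coarser sampling it under-detects contacts.
* Flux as a ratio of arm means inherits the sampling error of both arms;
  single small fields are noisy by design and should be pooled (~200 cells
  per arm for a 10% bound at flux 2).
* The respirometry phase summaries assume the canonical four-phase
  protocol; traces missing a phase are rejected rather than imputed.
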