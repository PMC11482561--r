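---
title: "Counting CSF cells from chip images: models, calibration and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting CSF cells from chip images: models, calibration and validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfscan)
```

## The measurement problem

Cerebrospinal fluid normally carries at most a handful of white blood cells
per microlitre and no red blood cells, so a clinically useful counter must be
accurate down to a few cells × 10⁶/L — far below the validated range of most
hematology analyzers. Chip-based fluorescence imaging addresses this by
photographing a known fluid volume: a stained aliquot is loaded into a
100 µm-deep microfluidic channel, the instrument tiles the channel with
fields of view, and every stained cell in the imaged column is counted
individually. With WBCs carrying a nucleic-acid stain (green channel, GF)
and RBCs an anti-glycophorin-A label (cyan channel, CF), class assignment is
a two-channel intensity gate rather than a morphology call.

`csfscan` implements that pipeline — synthetic field generation, circle
Hough detection, quadrant gating, concentration conversion — together with
the statistics used to validate such counters (linearity, LOB, LOD,
precision) and to compare counting methods (Pearson, Passing–Bablok,
Bland–Altman).

## The synthetic field generator

Every downstream stage is testable against exact ground truth because the
generator, not a deposited data set, defines the study conditions.

A default `field_spec()` is a 488 × 488 px raster at 1 µm/px over a 100 µm
channel depth, i.e. exactly 488² × 1 µm² × 100 µm = 23.8144 nL per field —
the calibrated volume per image of the modeled instrument. Per-field cell
numbers are Poisson with mean `conc × volume_nl / 1000`, the physically
forced counting distribution for a well-mixed suspension. Cells are discs
with a 1-px linear edge ramp: the ramp makes image gradients at the rim
well defined (the property the Hough detector votes on) without claiming
optics fidelity — there is no point-spread function, no depth-of-field
blur, no illumination shading. Class amplitudes are log-normal
(`intensity_model()`): WBC GF median 1000 (σ_log 0.25) over background 100,
RBC CF median 800, with the off-channel near background. These are
arbitrary-unit choices that reproduce the qualitative picture of strongly
separated stain populations; they are deliberately generous compared with
real staining variability, which is why a perfect gate on synthetic fields
does not certify gating on real images.

Cell placement is uniform with a border margin and, by default, rejection
sampling against overlap; `overlap_allowed = TRUE` switches to fully random
placement. Artifacts come in three kinds seen in practice: sub-cellular
debris (below the cell size range), large fluorescent aggregates (well
above it), and cell-sized specks equally bright in both channels. Additive
Gaussian noise (σ = 5 on background 100) is the only sensor noise modeled.

Per-field RNG streams are derived from `(master seed, field index)`, so a
42-field sample renders identically regardless of evaluation order, and an
identical seed + spec reproduces the raster bit for bit.

## Detection

`detect_circles()` is a gradient-voting circle Hough transform: pixels whose
central-difference gradient magnitude exceeds `edge_threshold` (default 60,
far above the ~4 intensity-unit noise gradients and far below the ~400
cell-rim gradients) cast votes along ± their gradient direction at every
radius in the configured range. Accumulators are consolidated with a 3 × 3
box sum and normalized by circumference, making the score radius-fair: a
soft-edged disc rim contributes two concentric gradient rings, so true
cells score ≈ 2 while rim ghosts stay below 1; the default
`accumulator_threshold` of 1.2 sits between the two populations. Peaks are
local maxima, greedily suppressed within `nms_min_distance_px` (higher
score wins; ties resolved by smaller `(y, x)` so runs are reproducible).
The radius estimate is the vote-weighted mean radius within one step of the
per-center best; no sub-pixel refinement is attempted and tests declare a
1 px tolerance.

Intensity measurement subtracts, per channel, the median of a concentric
annulus (inner radius r + 2 px, width 3 px) from the disc mean. Annulus
pixels covered by any other detection are excluded, which keeps a
neighbor's skirt out of the background estimate; the median (rather than
the mean) makes the remainder robust. Discs clipped by the raster border
are measured on the clipped support and flagged `edge`.

## Gating and the double-positive zone

Events are gated on the (CF, GF) plane into quadrants C1 (double-negative),
C2 (GF⁺, WBC), C3 (CF⁺, RBC) and C4 (double-positive). Events exactly on a
cut go to the non-positive side, making assignment a total function. In
`auto` mode the cuts are Otsu thresholds on `log1p` intensity — the log
compresses the bright tail so the background/signal split dominates — with
a flagged median-of-positives fallback when a channel is degenerate.

The modeled instrument resolves C4 with an image-review step that is not
publicly available, so `csfscan` replaces it with ordered deterministic
rules (`c4_rules()`): an event whose radius falls in the doublet band
(1.5–2.2 × the largest single-cell radius) is an overlapping WBC+RBC pair
and contributes one count to each class; outside that band a radius not in
either class interval is an artifact; otherwise the event joins the class
with the larger cut-normalized intensity, with exact ties resolved to
artifact. The band's lower edge (1.5×) is the conventional "too big for one
cell" cutoff; the upper edge (2.2×) caps it just above the theoretical
maximum for two touching cells — beyond that only aggregates occur. Both
factors are configuration, not constants, because no published numeric rule
exists. Double-negative (C1) events are counted as artifacts, which is the
only bookkeeping under which adjusted WBC + adjusted RBC + artifacts −
doublets equals the number of gated events.

## Concentration arithmetic

All concentrations are cells × 10⁶/L ≡ cells/µL, with volumes carried
explicitly in nL/µL. The chip formula is

count × 1000 / (volume-per-image[nL] × n_images) × sample dilution × stain dilution,

with the stain dilution 84 µL / 40 µL = 2.1 by default. The Neubauer path
divides by `squares × 0.1 µL` (standard large-square geometry; the
five-square low-count protocol is just `squares_counted = 5`) and averages
duplicate reads. The bead-calibrated formulas follow the protocols' stated
forms; note the Trucount variant divides bead concentration by tested
sample volume, which differs from the conventional beads-per-tube kit
formula — the implementation follows the stated form and documents the
discrepancy.

## Measurement-noise calibration

The replicate simulator (`simulate_measurement()`) needs a dispersion model
per modality; the protocols specify procedures but not noise, so the
presets in `modality_preset()` are calibrated against the published
verification tables:

* **Chamber (Neubauer)** — Poisson counting in 0.4 µL plus a 45%
  multiplicative examiner CV. Published chamber CVs run 17–70% even at
  counts where Poisson error alone would be a few percent, and literature
  inter-examiner CVs reach ~45%; a single mean-one log-normal term
  reproduces that with one parameter.
* **Chip imager** — Poisson counting over the default 1 µL imaged volume
  (42 × 23.8144 nL) plus a 20% instrument CV, matching the published
  18–39% precision column.
* **Flow** — Poisson cell and bead events (5000 beads expected at
  1000 beads/µL, i.e. 5 µL analyzed) plus a 3% instrument CV, matching the
  2.8–21% column. The bead draw contributes its own 1/√5000 share. A draw
  with zero beads is flagged invalid rather than silently reported as zero.
* **Chip imager, detection-limit protocol** (`"microscanner_lod"`) — the SD
  column of the published LOD table implies an effective counted volume of
  expected/SD² ≈ 1.5–2.2 µL across levels, so this preset images 176
  fields (2.00 µL); and the published replicates reporting zero at nominal
  levels where a Poisson zero is essentially impossible (P ≈ 0.5% at
  nominal 2.67) imply a minimum reportable object count — 3 objects
  reproduces the observed exceedance pattern. Both parameters are stated
  calibrations, not fits to any test outcome.

Because every multiplicative term has mean one, all modalities remain
unbiased estimators of the true concentration; the models differ only in
dispersion, which is exactly what the precision comparison measures.

## Validation statistics

* **Linearity** correlates expected concentrations with per-level replicate
  means (pre-averaged series may be passed directly); r² is reported to
  4 dp at the report layer.
* **LOB** is the CLSI nonparametric percentile — rank 0.5 + (p/100)·N with
  linear interpolation, clipped to the observed range (this is `quantile()`
  type 5). The convention is exposed because "95th percentile" alone does
  not pin down a rank rule.
* **LOD** is the smallest level whose fraction of measurements strictly
  above the LOB strictly exceeds 0.95 — so 19/20 does not qualify — and is
  clamped to be no smaller than the LOB. Undefined LODs are flagged, not
  zero-filled.
* **Precision** reports per-level mean, n−1 SD and CV%; a zero-mean level
  flags CV as undefined rather than infinite.

## Method comparison

Passing–Bablok regression is authored here (no installed dependency
provides it): all C(n,2) pairwise slopes with x-ties excluded and slopes of
exactly −1 removed, the shifted median at offset K = #(slopes < −1), and the
normal-approximation rank CIs with variance n(n−1)(2n+5)/18. Intercept
limits are recomputed from the slope limit endpoints. The estimator's
symmetry (swap x, y ↦ slope 1/b) is exact when the slope count is odd and
none are excluded, which is how the property is tested. Bland–Altman uses
1.96 × SD limits of agreement and a t-based bias CI (z optional), and
`subrange()` re-runs any comparison on a clinical concentration window, by
default defined on the comparator method's values.

## Problem sizes and what the tests show

The suite renders hundreds of 488 × 488 fields and simulates tens of
thousands of replicate draws; the sizes were chosen so Monte-Carlo checks
resolve a 3-SE band: 200 seeds for the Poisson law, 2000 draws for
unbiasedness, 100 simulated 42-field measurements (~1 µL each) for
end-to-end recovery at 50 cells/µL, 50 seeded runs for the LOD decision
band, and 20 × 6 replicates per level for the precision ordering, whose
per-seed CV estimates are themselves ~30% noisy and are therefore compared
as means over seeds. Detection quality (recall and precision ≥ 0.95 with a
brute-force circle-search cross-check) holds on clean, non-overlapping
synthetic fields; real chip images add focus drift, shading, debris spectra
and overlap patterns the generator does not emulate, so those results bound
the algorithmic, not the optical, error.

## Known limitations

The C4 rules are an auditable stand-in for image-level review and will
misattribute doublets whose merged outline is not circular. The generator's
artifact model is a plausible family, not a measured one. Edge-clipped
cells are flagged but still counted, a small positive bias at high density.
No limit-of-quantitation is estimated, and no FCS ingestion or Deming
regression is provided.
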