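---
title: "Quantifying actin cytoskeleton organisation with actinmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying actin cytoskeleton organisation with actinmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(actinmorph)
library(dplyr)
```

# The measurement problem

Fibroblasts reorganise their actin cytoskeleton when contractility
signalling is perturbed: stress fibres change in number, thickness and
orientation, focal adhesions mature or shrink, non-muscle myosin IIA
(NMIIA) decorates contractile bundles with periodic puncta, and collective
migration into a scratch wound speeds up or slows down. Quantifying these
phenotypes from fluorescence microscopy requires a chain of small,
well-defined image measurements, most of which historically lived in ImageJ
macros. `actinmorph` implements that chain as tested, scriptable R code:

* **Reference-cell averaging** of cells grown on crossbow micropatterns:
  filter, threshold, centre every cell on the printed pattern, exclude
  multinucleate/mitotic/off-pattern cells, register channel stacks, and
  average into a per-channel 0–255 *frequency map* showing where a stain
  recurrently localises.
* **Filament morphometrics**: per-filament centre, length, width and
  orientation; branch/junction counts of the actin network skeleton;
  structure-tensor orientation distributions; distance of filaments to the
  pattern's curved (leading) edge; maps of thick (width > 2 px) fibres.
* **Focal-adhesion morphometrics** from vinculin staining and
  **PLA foci counting** (median filter, Gaussian blur, maximum-entropy
  threshold, particle count).
* **Line-scan periodicity**: intensity profiles across NMIIA staining and
  prominence-based peak counting, reported as peaks per 100 px.
* **Wound-healing kinetics**: per-frame wound area and width, closure
  percentage `(A_0 − A_t)/A_0 × 100`, and migration rate `(W_i − W_f)/t`
  in µm/h.
* **Group statistics**: Kruskal–Wallis on biological-replicate means with
  Dunn's pairwise tests and Holm adjustment.

Because the microscopy data such pipelines are normally run on are not
publicly deposited, the package ships a seeded synthetic-image generator
with complete ground truth; every detector is validated against it.

# Coordinate and unit conventions

Images are numeric matrices indexed `img[x, y]`: x runs rightward (first
index), y downward (second index), from the top-left pixel `(1, 1)`. This
is the storage convention of EBImage, which provides the standard filters
underneath. Coordinates are 1-based pixel centres — the idiomatic choice
for an R package whose consumers are R functions; the axis directions
match the usual image-analysis convention (x along the horizontal border,
y along the vertical border). Orientations are degrees in `[-90, 90)`,
measured from the +x axis towards +y (downward), so a horizontal fibre is
0° regardless of sign conventions elsewhere. Physical lengths are
micrometres via a `pixel_size` (µm/px) argument; intensities are arbitrary
camera counts clipped to the configured bit depth.

# The synthetic generator

`generate_micropattern_cell()`, `generate_foci_image()` and
`generate_wound_series()` render every image class the pipeline consumes,
additively: object profiles + uniform background + i.i.d. Gaussian noise,
clipped to the bit depth. All randomness flows from one integer seed per
call, and the caller's RNG state is restored afterwards, so the same spec
is bit-reproducible.

Key modelling choices:

* **Fibres** are straight segments with a Gaussian cross-section whose
  full width at half maximum (FWHM) equals the declared width
  (`sigma = width/2.355`) — the width a half-maximum measurement should
  recover — with sharp end caps, so the apparent length does not depend on
  the threshold level. Intensity is truncated at 1.5 widths from the axis;
  the truth records both this exact support mask and the FWHM "core"
  footprint.
* **Adhesions** are elliptical Gaussian puncta with FWHM axes equal to the
  declared major/minor axes. **Nuclei** are flat discs with a 1 px
  Gaussian rim. **PLA foci** are round Gaussian spots placed by rejection
  sampling with a guaranteed minimum separation (> 4 spot sigmas, so
  resolvability is by construction).
* **The crossbow pattern** is a parametric circular arc (220° span by
  default) plus a straight stem. Commercial micropattern geometries are
  proprietary, so this arc-and-stem is the package's reference geometry;
  edge distances are defined against it and its parameters are stored in
  every ground truth.
* **Wound series** are vertical cell-free bands closing symmetrically at a
  constant per-front velocity `v`: the true width at 0-based frame `k` is
  `max(0, W_0 − 2·v·k·dt)`, clamped at zero. Cell regions carry i.i.d.
  intensity texture; the wound is near background. Defaults emulate the
  common experiment: ~500 µm initial wound, 2 µm pixels, hourly frames.
* Default intensity scales (background 10, object amplitudes 150–190,
  noise sd 5 on an 8-bit range) give signal-to-noise ratios around 30–40,
  typical of well-stained fixed-cell epifluorescence.

What the generator deliberately does **not** emulate: optical
point-spread-function blur beyond the object profiles themselves,
shot/Poisson noise, uneven illumination, out-of-focus light, curved or
branching fibres, overlapping adhesions, and cell-shape variability. Tests
passing on these fixtures therefore demonstrate that the estimators are
correct and unbiased under their stated model, not that they are robust to
every real-microscopy artefact; on real data the binarisation step is the
component most sensitive to those artefacts, and it is configurable
throughout.

# Numerical choices that matter

**Automatic thresholds.** `auto_threshold()` implements Huang's
fuzzy-entropy method and the Kapur maximum-entropy criterion on a 256-bin
histogram (the two methods named by classic macro pipelines), plus Otsu, a
median (percentile) threshold, and `half_max` — background median plus
half the robust dynamic range, which by construction cuts Gaussian-profile
objects at their FWHM. Foreground is strictly above the threshold; a
constant image has no threshold and yields an empty mask with a warning.

**Skeletonisation and branches.** Binary masks are thinned with the
Zhang–Suen two-subiteration algorithm. Branching points are pixels whose
8-neighbour ring contains ≥ 3 distinct arms (the crossing number) —
a raw neighbour count misclassifies diagonal staircase pixels as
junctions. Adjacent junction pixels merge into one junction; branches are
the 8-connected segments left after removing them (connected-component
labelling is an own union-find implementation, since the available
labeller is 4-connected and severs diagonal runs). Terminal spurs shorter
than `min_spur` (default 5 px) hanging off junctions are pruned as
thinning artefacts of ragged masks.

**Filament length** is the length of the traced branch polyline after a
5-point moving-average smoothing — the raw 8-connected chain overestimates
oblique continuous lines by up to ~8% and noise zigzag inflates it further
— plus one binary width, because the medial axis of an elongated object
retracts about half a width at each end.

**Filament width** is measured on the *raw* image, not the binary mask:
at ~15 points along the smoothed trace the background-subtracted intensity
is sampled perpendicular to the local direction, and the width is
`2.355 ×` the median intensity-weighted standard deviation of the offset
(the FWHM of the equivalent Gaussian), minus the 1/6 variance contributed
by bilinear reconstruction. Noise residuals are deliberately *not* clipped
at zero: zero-mean noise leaves moments unbiased, whereas clipping adds a
positive pedestal across the window. A distance-transform estimate
(2 × mean − 1 px) from the binary mask serves as the initial gauge and as
the fallback for very short branches; on its own it proved biased low by
10–30% after binarisation, which is why the intensity-moment estimator is
the reference. Adhesion axes use the same idea as 1-D moment profiles
along the principal axes of the component.

**Orientation** of a filament is the principal axis of its traced pixels;
image-level orientation distributions come from the smoothed structure
tensor (gradient energy weighting, dominant direction perpendicular to the
gradient eigenvector), with an energy-weighted circular mean and a
coherence in [0, 1].

**Wound segmentation.** In bright-field texture mode the frame's local
standard deviation (Gaussian moments, window sigma 3 px) separates
textured cells from the smooth wound. The local sd peaks *at* the
cell–wound boundary (maximal mixing inside the window), so after a coarse
low-variance candidate region is found, each row's wound edges are
localised at the flanking variance peaks with parabolic subpixel
refinement — a plain threshold crossing would sit several window-sigmas
inside the wound and bias every width low. Guards report a closed wound
(area 0, with a warning) when no candidate region exists, when the largest
one is negligible, or when it is not separable from the cell texture
(confluent frame). In fluorescence mode (live F-actin stain) the wound is
simply the largest low-intensity region. If the wound closes before the
last frame, the migration-rate clock stops at the first closed frame, so
the rate reflects time-to-closure; with `t0` the first analysed frame can
be placed at any offset after wounding (imaging often starts a few hours
later, and either convention for `t` is supported).

**Foci counting** follows the macro recipe — median prefilter, Gaussian
blur, maximum-entropy threshold, 8-connected particle count with area
gates (default 4–10,000 px²) — plus one guard the macro leaves implicit: a
particle must also rise at least six robust standard deviations above the
smoothed background, because blurred sensor noise alone can form
above-threshold blobs on an otherwise empty field.

**Peaks.** `find_peaks()` keeps local maxima by topographic prominence
(default 10% of the profile's dynamic range), which is invariant to affine
intensity transforms when the prominence is scaled accordingly; plateau
maxima report their centre. Frequency is peaks per 100 px of scan, the
convention for NMIIA periodicity along arcs (the classic scan length is
150 px).

**Statistics.** Observations are averaged within biological replicate
before ranking (pseudo-replication would otherwise inflate n); a flag
ranks raw observations instead. The Kruskal–Wallis H (tie-corrected, χ²
reference) comes from `stats::kruskal.test`; Dunn's z uses the
tie-corrected pooled-rank variance
`(N(N+1)/12 − Σ(t³−t)/(12(N−1)))·(1/nᵢ+1/nⱼ)` with two-sided normal
p-values (sidedness is a convention choice; two-sided is the conservative
default) and Holm step-down adjustment via `p.adjust`. An all-tied data
set returns H = 0, p = 1 rather than NaN.

# QC rules

A cell passes QC only with exactly one nucleus of at least `min_area`
pixels: none means off-pattern, two or more means multinucleate. The
mitotic flag — condensed chromatin — is declared, not taken from any
published criterion: a single nucleus whose area is below half the cohort
median *and* whose solidity exceeds 0.95. It is applied only when a
reference area is available (`qc_cohort()` supplies the cohort median) and
both constants are arguments. The frequency map uses the *mean* projection
by default — a pixel-intensity frequency across cells — with `max`
available; maps are min–max rescaled to integer 0–255.

# A worked mini-example

```{r example}
spec <- cell_spec("crossbow", image_size = 128,
                  fibres = list(fibre_spec(c(64, 80), 50, 3, 5)),
                  n_nuclei = 1, nucleus_radius = 10, noise_sd = 4, seed = 1)
cell <- generate_micropattern_cell(spec)
qc_cell(cell$channels$dapi)
detect_filaments(cell$channels$actin) |>
  dplyr::select(length_px, width_px, orientation_deg)
```

```{r wound}
sim <- generate_wound_series(
  wound_spec(frame_size = 200, pixel_size = 2.5, initial_width = 400,
             edge_velocity = 10, dt = 2, n_frames = 8, seed = 2))
series <- measure_wound_series(sim$frames, dt = 2, pixel_size = 2.5)
glance(wound_kinetics(series))
```

# Problem sizes used for validation

The test suite validates filament recovery on 100 single-fibre images
(256² px; lengths 20–200 px, widths 2–8 px, all orientations, noise sd 5),
foci counting on 0–50 spots per 256² image with ten noisy repeats at
signal-to-noise 5, wound kinetics on 21-frame 300² series, and the
statistics on 2,000 null simulations of three groups of twenty. These
sizes keep a full run in well under a minute per module while giving the
medians and rates enough support to be stable across seeds.

# Known limitations

* Registration and centring are translation-only and integer-pixel;
  rotation/affine alignment is out of scope for centred micropattern
  cells.
* Crossing fibres are split at junctions into separate records; a fibre
  passing through k junctions contributes k+1 records unless merged
  downstream.
* Width measurements assume an approximately Gaussian cross-section;
  flat-topped saturated fibres will read slightly narrow.
* The wound segmenter assumes one dominant, roughly vertical wound band.
* Foci assignment to cells uses the whole image (or a caller-supplied
  mask); no cell segmentation is attempted.
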