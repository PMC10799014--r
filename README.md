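# actinmorph

Quantitative morphometrics of the actin cytoskeleton from fluorescence
microscopy, for cell biologists studying contractility phenotypes in
fibroblasts (and anyone who has ever chained ImageJ macros to measure
stress fibres). The package turns the standard measurement chain into
tested, scriptable R functions that take images in, return tibbles, and
validate themselves against a seeded synthetic-image generator with full
ground truth.

## What it measures

| Assay | Functions | Output |
|---|---|---|
| Reference-cell averaging on crossbow micropatterns | `preprocess()`, `qc_cell()`/`qc_cohort()`, `center_on_pattern()`, `register_stack()`, `build_frequency_map()` | 0–255 frequency map per channel |
| Single-filament morphometrics | `detect_filaments()`, `edge_distance()`, `thick_object_map()`, `skeleton_stats()`, `orientation_distribution()` | one row per filament: centre, length, width, orientation |
| Focal adhesions / PLA foci | `detect_adhesions()`, `count_foci()` | per-adhesion ellipse morphometrics; foci per cell |
| NMIIA periodicity | `sample_profile()`, `find_peaks()` | peak positions, spacing, peaks per 100 px |
| Wound healing | `segment_wound()`, `measure_wound_series()`, `wound_kinetics()` | per-frame area/width, closure %, migration rate |
| Group comparisons | `kruskal_wallis()`, `dunn_holm()`, `kw_dunn()` | H, Dunn z, Holm-adjusted p per pair |
| Synthetic ground truth | `cell_spec()` + `generate_micropattern_cell()`, `generate_foci_image()`, `wound_spec()` + `generate_wound_series()` | images + exact object tables and masks |

The two wound-kinetics quantities follow the standard scratch-assay
equations: the cell migration rate

    rate = (W_i − W_f) / t        [µm/h]

with `W_i`/`W_f` the initial/final mean wound width, and the wound closure

    closure = (A_0 − A_t) / A_0 × 100   [%]

with `A_0` the initial and `A_t` the current wound area. Group statistics
are Kruskal–Wallis on biological-replicate means followed by Dunn's
pairwise z tests with Holm step-down adjustment.

Fitted/statistical results support broom-style `tidy()`/`glance()`, and
each result type has an `autoplot()` method (frequency maps, orientation
histograms, filament maps, wound kinetics, line profiles).

## Worked example

```r
library(actinmorph)
library(dplyr)

# a synthetic micropatterned cell with one stress fibre and one nucleus
spec <- cell_spec("crossbow", image_size = 128,
                  fibres = list(fibre_spec(c(64, 80), 50, 3, 5)),
                  n_nuclei = 1, nucleus_radius = 10, noise_sd = 4, seed = 1)
cell <- generate_micropattern_cell(spec)

qc_cell(cell$channels$dapi)
#> [1] "passed"

detect_filaments(cell$channels$actin) |>
  select(length_px, width_px, orientation_deg)
#> # A tibble: 1 × 3
#>   length_px width_px orientation_deg
#>       <dbl>    <dbl>           <dbl>
#> 1      47.8     2.80            4.84
```

The declared fibre was 50 px long, 3 px wide at 5°; the detector recovers
47.8 px, 2.80 px and 4.84° from a noisy 8-bit rendering — within a few
percent on every axis. A wound-healing series generated with a 10 µm/h
per-front edge velocity (so both fronts together close 20 µm/h):

```r
sim <- generate_wound_series(
  wound_spec(frame_size = 200, pixel_size = 2.5, initial_width = 400,
             edge_velocity = 10, dt = 2, n_frames = 8, seed = 2))
series <- measure_wound_series(sim$frames, dt = 2, pixel_size = 2.5)
glance(wound_kinetics(series))
#> # A tibble: 1 × 5
#>   migration_rate_um_h t_span_h final_closure_pct closed n_frames
#>                 <dbl>    <dbl>             <dbl> <lgl>     <int>
#> 1                20.0       14              70.0 FALSE         8
```

and the canonical two-group rank comparison:

```r
d <- tibble::tibble(value = 1:6, group = rep(c("ctrl", "mut"), each = 3))
kw_dunn(d, value, group)
#> Kruskal-Wallis chi-squared = 3.8571, df = 1, p = 0.04953 (n = 6)
#> Group medians:
#>  group n median
#>   ctrl 3      2
#>    mut 3      5
#> Dunn pairwise (Holm-adjusted):
#>  group1 group2 mean_rank_diff         z    p_value     p_holm
#>    ctrl    mut             -3 -1.963961 0.04953461 0.04953461
```

A thin CLI over the same functions ships in
`inst/scripts/actinmorph-cli` (subcommands `simulate`, `refcell`,
`filaments`, `adhesions`, `foci`, `profile`, `wound`, `stats`).

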