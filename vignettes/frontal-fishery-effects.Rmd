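---
title: "Frontal hotspot and barrier effects on fisheries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frontal hotspot and barrier effects on fisheries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frontfish)
```

`frontfish` measures how mesoscale sea-surface temperature (SST) fronts
shape the spatial distribution of fishing catch and effort. This vignette is
the package's own account of the science: the models and statistics, the
tunable parameters and their defaults, what the synthetic generator does and
does not emulate, and the numerical decisions made where the design was
genuinely open.

## 1. The problem

An ocean front is a narrow boundary between water masses with contrasting
temperature; the surrounding high-gradient band (the *frontal zone*) is
among the most biologically active habitat in the ocean. The conventional
way to quantify a front's effect on a fishery is the *hotspot* contrast:
catch density inside versus outside frontal zones. But the two flanks of a
front are different habitats. A warm-affinity species concentrates on the
warm flank and avoids the cold one; a cold-affinity species does the
opposite. When flank responses are antisymmetric they cancel in the
frontal/non-frontal contrast, and the hotspot statistic reports "no effect"
for a fishery the front is in fact strongly structuring. The package
therefore computes, side by side, the hotspot contrast and the *barrier*
contrast (warm zone versus cold zone), plus an *underestimation rate* that
quantifies how much the first understates the larger single-flank signal.

## 2. Front detection and zone partition

`detect_fronts()` implements the windowed histogram approach standard for
single-image SST edge detection. For each square window (default 32 px,
about 160 km on a 0.05° grid — deliberately mesoscale: basin-scale fronts
do not fit a window and sub-window noise is rejected):

1. **Preprocessing** — a 3×3 median despike (`median_filter = TRUE`), the
   conventional treatment for isolated noisy pixels.
2. **Histogram analysis** — the SST histogram (0.1 °C bins) is split at the
   threshold τ maximizing the between-population variance; the window is
   *bimodal* when between/total variance ≥ `theta_crit` (default 0.70).
3. **Cohesion testing** — each population must be spatially compact: the
   fraction of its pixels whose valid 4-neighbours are majority
   same-population must reach `cohesion_crits` (default 0.90, 0.90).
4. **Frontal pixel identification** — pixels with a 4-neighbour on the
   opposite side of τ mark the population boundary. Of each crossing pair
   we keep the pixel whose SST is closer to τ (ties to the cold side), so
   the front line stays about one pixel wide; without thinning the line
   itself swallows the narrow high-gradient band that should become the
   zones.
5. **Multi-window integration** — windows advance by `stride_px` (default
   half a window) and candidates are pooled by union.
6. **Front pruning** — 8-connected components shorter than `min_length_px`
   (default 15 px) are discarded; survivors get deterministic ids ordered
   by first pixel.

The window size is the only externally fixed quantity; θ, the cohesion
criteria, bin width, stride and pruning length are reimplementation choices
in the range conventional for this algorithm family, and all are exposed as
arguments.

`partition_zones()` then grows the frontal zone outward from each frontal
pixel over pixels whose gradient magnitude (central differences, °C/km,
zonal step scaled by cos-latitude) is at least `threshold_frac` (default
1/2; 1/4 and 3/4 are the standard sensitivity settings) of the magnitude at
the seeding pixel, stopping `max_extent_km` (default 100 km) away; a
fixed-width mode (40 or 80 km) is the alternative sensitivity definition.
Zone pixels attach to their nearest frontal pixel by great-circle distance
and are labelled **warm** if strictly warmer than it, **cold** if strictly
colder. Decisions worth recording:

- The "logarithmic gradient" phrasing in parts of the literature is
  implemented as a threshold on the gradient magnitude itself, the only
  reading consistent with the ¼/¾ sensitivity convention; a log-space
  option exists (`log_space = TRUE`) but is not the default.
- Warm/cold classification uses the despiked field (`despike = TRUE`):
  under observation noise the raw single-pixel comparison misassigns thin
  slivers along the line.
- An exact SST tie goes to the warm zone — measure-zero on real data, but a
  deterministic rule is required for reproducible tests.
- Nearest-frontal-pixel ties break to the smallest (row, column) index;
  when several fronts compete for a pixel, the nearest frontal pixel wins.
- Records landing on frontal-line pixels count toward the frontal zone,
  and for warm/cold contrasts are assigned to the side suggested by the
  line pixel's 4-neighbour mean temperature, so no catch is discarded.

## 3. The background null and significance

The large-scale fishery background is built by `randomize_records()`: each
record is relocated uniformly at random within a 2° × 2° window (default R
= 1000 replicates; dates and catches untouched, so totals are conserved
exactly). This erases mesoscale structure while preserving the large-scale
pattern. Windows are centred on each record by default; whether the
original design centred windows or used a fixed 2° tiling is ambiguous, so
a `center = "tile"` mode is provided for comparison. Draws falling outside
the domain or on masked water are redrawn, never clamped (clamping would
pile probability mass on boundaries). A kernel-density null is deliberately
not offered: it reintroduces smoothed mesoscale structure.

Significance is reported in two conventions by `percentile_pvalue()` and
the effect estimators: (a) the percentile rule traditional in this
literature — significant when the observed statistic exceeds the null's
95th percentile or falls below its 5th — and (b) a standard two-sided
Monte-Carlo p-value `p = 2·min(r⁺+1, r⁻+1)/(R+1)`. The two differ: the
percentile rule is a 10%-level two-tailed test. The `significant` field
uses `p < 0.05` (5% nominal), and the percentile flag is reported alongside
as `significant_percentile`; calibration checks in the test suite hold the
5%-nominal flag to its nominal rate.

## 4. Effect statistics

With `OF(i)`/`SF(i)` the observed/simulated catch in zone *i* and
`F(i)`, `A(i)` zone totals and areas (cos-latitude-weighted km²):

- `frad()` evaluates
  `FRAD(i,j) = [(OF(i)−SF(i))/SF(i) − (OF(j)−SF(j))/SF(j)]·100%`
  against every replicate (the distributional form; an ensemble-mean form
  is available via `per_replicate = FALSE`). The point estimate is the
  replicate median with the 25th–75th percentile spread. Replicates with a
  zero simulated total in either zone are dropped; more than 10% dropped
  aborts.
- `rd_fpa()` computes
  `RD_FPA(i,j) = [(F(i)/A(i) − F(j)/A(j))/(F(all)/A(all))]·100%`,
  where *all* aggregates frontal and non-frontal zones.
  `spatial_rd_fpa()` evaluates it per 1° cell (cells with fewer than 5
  records are no-data — density ratios are unstable below that) and smooths
  with a Gaussian kernel. A "3° kernel" is ambiguous; we read it as the
  full width at half maximum, σ = 3°/(2√(2 ln 2)), configurable.
- `underestimation_rate()` computes
  `UR = [max(|WZ|,|CZ|) − |FE|]/max(max(|WZ|,|CZ|),|FE|)·100%`;
  positive UR means the single-flank response exceeds the hotspot response.
  The degenerate all-zero case is defined as UR = 0 (limit convention).

Both indices are antisymmetric in their zones and invariant to rescaling
all catches — properties the suite asserts to 1e-12.

## 5. Front-composite profiles

`normalized_distance()` maps each record to a signed normalized distance:
the great-circle distance to the nearest frontal pixel, divided by the
local frontal-zone width — the distance from that frontal pixel to the
nearest zone-boundary pixel *on the record's side* — positive on the warm
side. Side-matching the boundary pixel is a deliberate choice: with an
unrestricted nearest boundary, ND = +1 would not coincide with the warm
boundary whenever the two flanks have unequal widths (the unrestricted
variant remains available via `side_matched = FALSE`). Records outside the
zones still get an ND up to a cap of |ND| = 3, beyond which they are
excluded from profiles.

`composite_profile()` bins catch by ND (bin width 0.15) and reports the
relative anomaly `(OF(b) − SF_r(b))/SF_r(b)·100%` per bin as the median
over replicates with 25–75 and 5–95 percentile envelopes. Observed and
null records are binned through the same per-pixel ND raster, so both
sides of each anomaly see identical geometry at grid resolution; a bin
whose simulated total is zero in more than 10% of replicates is no-data.

## 6. The thermal niche model

`bin_catch_by_sst()` aggregates total catch per 0.5 °C SST bin (record SSTs
by bilinear interpolation of the daily grid) and normalizes by the maximum
bin. `fit_thermal_gaussian()` fits `C_n(T) ≈ A·exp(−(T−μ)²/2σ²)` by
Levenberg–Marquardt least squares, initialized at the catch-weighted mean
and SD with unit amplitude (parameter tolerance 1e-8; non-convergence is an
error carrying the initialization). The suitability index is the unit-peak
curve `THSI(T) = exp(−(T−μ)²/2σ²)` ∈ (0, 1]: a suitability index, not a
probability density. A literal density form (with the 1/(σ√2π) prefactor)
is available behind `density_form = TRUE`, but the unit-peak convention is
what keeps THSI comparable across species and bounded by 1, and the
amplitude is a free fit parameter that the index deliberately ignores.
`compare_zone_thermal()` contrasts the top 50% CPUE records per zone
(threshold configurable; a zone with fewer than 10 qualifying records is
refused) on |SST − μ| and predicted THSI with a two-sided t-test, and
`split_by_date()` provides the conventional before/after-August seasonal
stratification.

## 7. Environmental zonal contrasts

`smooth_profile()` regrids vertical profiles to 5 m, then applies a 25 m
(5-level) running median followed by a running mean. The length of the mean
window after the median stage is not standardized; we use the same 5-level
window (configurable). Window truncation at the profile ends means only
values ≥ 4 levels from an end are invariant for linear profiles — the
suite pins this down exactly. `zonal_env_difference()` averages
zone-matched profiles per 2° cell per month and reports warm-minus-cold
differences at a requested depth; `zonal_chl_relative_difference()` does
the analogous surface-chlorophyll contrast per 1° cell, normalized by the
cell mean. Cells represented by a single zone are no-data.

## 8. The synthetic generator: what it emulates, and what it does not

`make_sst_field()` builds a front as a parametric axis (optionally
sinusoidally meandering) with a tanh cross-front transition:
`SST = T_cold + ΔT·(1 + tanh(d/w))/2 + ε`, `d` the signed cross-axis
distance (positive warm-side, by nearest-segment projection and
cross-product sign) and `ε` i.i.d. Gaussian noise. tanh was chosen as the
smooth single-parameter saturating transition matching the "transition
zone" intuition. The grid carries its ground truth: the signed distance
raster and a warm/cold/axis label per pixel (axis = centre within half a
pixel of the polyline; for side-accuracy scoring, a pixel's generative side
is the sign of its true distance).

`sample_fishing_records()` draws record locations by rejection sampling
from `background(x) · exp(−(SST(x)−μ)²/2σ²)` — the generative inverse of
the thermal niche model — with an optional antisymmetric side weight
(`1 ± zone_amp` within `zone_band_km` of the axis) that emulates a fishery
preferring one flank with no net frontal enrichment; this is the mechanism
behind the offset experiment. Catches are log-normal (meanlog 0, sdlog
0.5 tons — right-skewed, positive, like real catch distributions), one
record-day each, so CPUE equals catch in tons/day. Rejection sampling is
capped at 1000× the requested count and fails informatively (e.g. μ far
outside the field's SST range). `sample_profiles()` places float-like
profiles in labelled zones with a prescribed warm-minus-cold offset.

The generator deliberately does **not** emulate eddies, interacting
fronts, cloud masks, AIS gaps, vessel behaviour or day-to-day front
evolution. Passing tests therefore demonstrate that the chain recovers
known structure under clean, single-front conditions with realistic
observation noise — they do not certify performance on real multi-front
scenes.

## 9. Study conditions and problem sizes

The validation experiments (test suite and `scripts/acceptance.R`) use, as
their standard conditions: a 200×200-pixel 0.05° grid (10°×10°,
mid-latitude), ΔT = 2 °C, width 10 km, meander amplitude 60 km, noise
0.1 °C; fisheries of n = 2000 records; null ensembles of R = 100–200
replicates; 20–50 seeds per experiment; thermal recovery at n = 5000 on a
linear 10–20 °C ramp (flat background, so catch-per-bin is availability-
free) with μ* = 15 °C, σ* = 1.5 °C. Composite-geometry checks use a
broader 30 km front so the normalized-distance raster resolves fractional
bins. These sizes give stable statistics in minutes on a single CPU; every
stochastic stage takes an explicit seed and is bit-reproducible.

## 10. Known limitations

- Zones a single pixel wide (sharp fronts at coarse resolution) quantize
  ND heavily; profiles are then only interpretable near |ND| ∈ {0, 1}.
- The percentile significance rule inherited from the literature is a 10%
  two-tailed test; we report it but base `significant` on the 5%-nominal
  Monte-Carlo p.
- `spatial_rd_fpa()` recomputes zone totals per cell per replicate and is
  the slowest path; use modest R for maps.
- Gridded I/O is plain long-format CSV (`write_grid_csv()`); the package
  does not read NetCDF directly — convert upstream if needed.
- Daily matching assumes one label map per record date; multi-day
  composites must be assembled by the caller (`run_pipeline()` handles the
  single-date demo end to end).
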