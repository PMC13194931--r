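# frontfish

Quantifying the influence of mesoscale ocean fronts on fishery
distributions.

Sea-surface temperature (SST) fronts — the sharp boundaries between water
masses — concentrate nutrients, prey and predators, and commercial fleets
visibly aggregate around them. But a front is not one habitat: its warm and
cold flanks differ in temperature, stratification and food supply, and a
species with a warm or cold thermal affinity may favour one flank and avoid
the other. A fishery analysis that only contrasts "frontal" against
"non-frontal" waters (the *hotspot effect*) can then badly understate the
front's true influence, because opposite responses on the two flanks cancel.
`frontfish` implements an analysis chain that measures both the hotspot
effect and the warm-versus-cold *barrier effect*, and quantifies how much
the former understates the latter.

## The statistics at its core

For zones *i*, *j* (frontal, warm, cold, non-frontal), with `OF(i)` the
observed catch (or effort) in zone *i* and `SF(i)` the catch placed there by
a spatially randomized background replicate:

- **FRAD** — catch relative-anomaly difference:
  `FRAD(i,j) = [ (OF(i) − SF(i))/SF(i) − (OF(j) − SF(j))/SF(j) ] × 100%`,
  evaluated against each of R replicates in which every record is
  redistributed uniformly within a 2° × 2° window (preserving large-scale
  structure, erasing mesoscale structure).
- **RD_FPA** — relative difference in catch per unit area:
  `RD_FPA(i,j) = [ F(i)/A(i) − F(j)/A(j) ] / [ F(all)/A(all) ] × 100%`.
- **UR** — underestimation rate:
  `UR = [ max(|WZ|,|CZ|) − |FE| ] / max(max(|WZ|,|CZ|), |FE|) × 100%`,
  where `WZ`, `CZ`, `FE` are the warm-, cold- and whole-frontal-zone
  contrasts against non-frontal waters.
- **THSI** — thermal habitat suitability: total catch per 0.5 °C SST bin is
  normalized to 0–1 and fitted with a Gaussian
  `C_n(T) ≈ A·exp(−(T−μ)²/2σ²)`; the suitability index is the unit-peak
  Gaussian `THSI(T) = exp(−(T−μ)²/2σ²)` with thermal optimum μ and niche
  breadth σ.

Fronts are detected on daily SST grids with a windowed histogram algorithm
(32-pixel windows: bimodality by maximal between-population variance,
spatial cohesion testing, multi-window integration, pruning of short
fronts), zones are grown where the gradient magnitude exceeds half that at
the nearest frontal pixel, and each record gets a signed normalized
distance to the front (positive warm-side) for composite profiles.

## Worked example

Everything below runs on synthetic data with known ground truth: a
meandering tanh front (2 °C contrast, 10 km half-width) under 0.1 °C
observation noise, fished by a warm-preferring fleet.

```r
library(frontfish)

dom   <- list(lon = c(150, 160), lat = c(35, 45), res = 0.05)
field <- make_sst_field(dom,
           front_spec(delta_T = 2, width_km = 10, T_cold = 12,
                      meander_amplitude_km = 60, meander_wavelength_km = 300),
           noise_sd = 0.1, seed = 1)

fronts <- detect_fronts(field)
labels <- partition_zones(field, fronts = fronts)
labels
#> <front_labels> 2019-10-15, 200 x 200 px (relative mode)
#> non_frontal frontal_line    warm_zone    cold_zone       masked
#>       38950          226          409          415            0

rec  <- sample_fishing_records(field,
          fishery_spec(2000, mu_pref = 14, sigma_pref = 0.5, seed = 7))
null <- randomize_records(rec, window_deg = 2, R = 200, mask = field, seed = 8)

obs_tot  <- assign_records_to_zones(rec, labels)$totals
null_tot <- lapply(null$replicates, function(tb)
  assign_records_to_zones(tb, labels, quiet = TRUE)$totals)

frad(obs_tot, null_tot, "warm", "cold")
#> <effect_estimate> FRAD(warm, cold) = 102.46%  (p = 0.00995, significant)

frad(obs_tot, null_tot, "frontal", "non_frontal")
#> <effect_estimate> FRAD(frontal, non_frontal) = -45.45%  (p = 0.00995, significant)
```

The barrier contrast is large and positive — the warm-preferring fleet
fishes the warm flank far above its background rate. The hotspot contrast
is actually *negative* here (this fleet's optimum lies in the open warm
water beyond the narrow frontal band), a concrete illustration of why the
flank-resolved barrier statistic, not the frontal/non-frontal contrast, is
the informative one; `underestimation_rate()` turns the difference between
the two into the UR statistic.

The full chain (simulate → detect → partition → nullify → effects →
composite → thermal), with CSV outputs and a run manifest, is one call:

```r
res <- run_pipeline(demo_config(), out_dir = "demo_run")
res$thermal_fit
#> <thermal_fit> mu = 13.98 degC, sigma = 0.26 degC, A = 1.497 (R2 = 0.995)
```

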