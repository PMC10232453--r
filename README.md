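# vhiopt

Per-pixel calibration of the Vegetation Health Index (VHI) for vegetation
drought monitoring.

## What this solves

The VHI blends two satellite signals into one drought monitor:

- **VCI** (Vegetation Condition Index): NDVI scaled between its historical
  extremes, `VCI = (NDVI − NDVI_min) / (NDVI_max − NDVI_min) × 100`;
- **TCI** (Thermal Condition Index): land surface temperature scaled
  inversely, `TCI = (LST_max − LST) / (LST_max − LST_min) × 100`;
- **VHI** `= a·VCI + (1 − a)·TCI`, conventionally with `a = 0.5`.

Whether drought shows up first as browning vegetation or as surface
heating depends on climate, vegetation type, and soil, so a fixed equal
weight is a compromise. `vhiopt` estimates the contribution weight `a`
**per pixel**: it grid-searches the 49 candidates `a = 0.02, 0.04, …, 0.98`
and keeps the one whose blended series has the largest Pearson correlation
with a reference meteorological drought index (an sc-PDSI-like series that
integrates precipitation, temperature, and soil moisture). The resulting
`a_opt` map defines the optimized index `VHI_opt`.

Around that core the package provides: GeoTIFF cube I/O with −9999 nodata
masking (`read_cube()` / `write_cube()`, `VHIopt_{year}.tif` naming, six
decimal places), weekly→monthly→annual mean aggregation and
nearest-neighbor resampling of a coarse reference grid, the seven-class
drought scale and threshold-40 drought masks, event scoring (1 / 0.5 / 0
by the flagged fraction of an event region: >80%, >40%, otherwise) with
detection efficiency `DTE = 100·S/TDE`, Theil–Sen / Mann–Kendall trend
maps, a synthetic-scene generator with known true weights for validation,
and a configuration-driven pipeline (`run_pipeline()`, plus a thin CLI in
`inst/cli/vhiopt.R`).

## Worked example

A synthetic scene with known per-pixel true weights (32 × 32 pixels, 41
annual steps, signal-to-noise 10, three injected drought events):

```r
library(vhiopt)

sc  <- synthetic_scenario(seed = 42)
sim <- generate_cubes(sc)

cmap <- optimize_contribution(sim$vci, sim$tci, sim$ref)
cmap
#> contribution_map: 32 x 32 grid, 49 candidates, 100.0% valid pixels
#>   a_opt: median 0.48  |  r_max: median 0.995

mean(abs(cmap$a_opt - sim$truth$a_true))
#> [1] 0.0099513

unlist(dominance_summary(cmap))
#> frac_tci_dominated frac_vci_dominated
#>          0.5136719          0.4697266

vhi_opt <- compute_vhi_opt(sim$vci, sim$tci, cmap)
vhi_ori <- compute_vhi(sim$vci, sim$tci)          # a = 0.5 baseline

cmp <- compare_indices(vhi_opt, vhi_ori, generate_event_catalog(sim)$events)
cmp$report_a
#> detection_report: 3 events, total score 1.5, DTE 50.00%

classify_vhi(c(8, 35, 72))
#> [1] ExtremelyDry MildDry      Excellent
```

Reading: the optimizer recovers the true mixing weights to about one grid
step on average (0.0099 against the 0.02 candidate spacing); roughly half
the pixels are TCI-dominated (`a_opt < 0.5`) and half VCI-dominated; the
three injected events (severe, moderate, null) score 1, 0.5, and 0, giving
a detection efficiency of 50% — and the optimized index never scores below
the equal-weight baseline on the same events.

The methods vignette (`vignettes/vhi-weight-optimization.Rmd`) documents
the model, the design decisions, and what the synthetic scenes do and do
not emulate.

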