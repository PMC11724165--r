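# fissureflux

Earthquake surface fissures on the Qinghai-Tibet Plateau expose deep,
carbon-rich (often frozen) soil to the atmosphere: each crack adds two
vertical sidewalls and a bottom that emit CO2 until the fissure heals.
`fissureflux` estimates how much that adds to the plateau's soil carbon
budget. It is aimed at carbon-cycle and permafrost researchers who have
an earthquake catalog and chamber-measured surface emission rates and
want a reproducible, parameterized emission budget.

## The model

For each earthquake k at or above the magnitude threshold (M ≥ 6.9):

- **Initial geometry.** Total fissure length scales with coseismic
  surface-rupture length, `L_k = (l_k / l_M) × L_M`, anchored on the
  2021 Maduo earthquake survey (653 fissures, representative length
  942 m, `L_M = 615,126 m`). Unrecorded rupture lengths come from
  inverting `M = 5.92 + 0.88 log10(l_k)` (l in km); initial width from
  inverting `M = 6.81 + 0.78 log10(W_k)` (W in m).
- **Healing.** Each representative fissure shortens at
  `r_L = 0.49 m/a` — so `L_k(t) = L_k0 · max(1 − r_L t / L′, 0)`,
  full recovery after `L′/r_L ≈ 1922 a` — while the open width widens
  at `r_W = 0.05 m/a` until infill. Depth is fixed at `D = 3 m`.
- **Areas.** U-shaped cross-section: sidewall `S_w(t) = 2 D L_k(t)`,
  bottom `S_b(t) = L_k(t) W_k(t)`, averaged in closed form over the
  time since the event.
- **Budget.** `E = S_w E_w + S_b E_b` with chamber-measured rates
  `E_w = 968.53` and `E_b = 514.79 g CO2 m⁻² a⁻¹`, plus the
  plateau-wide rate increase `E / (2.57 × 10¹² m²)`.

Chamber campaigns themselves are processed by replicate averaging,
equal-weight timepoint means, annualization (44.01 g/mol, 365-day
year) and group-to-control ratios. Seeded generators produce synthetic
catalogs (truncated Gutenberg-Richter magnitudes) and campaigns with
known ground truth. See the vignette
(`vignettes/fissure-carbon-model.Rmd`) for assumptions and limitations.

## Worked example

Estimate the budget for the packaged demo catalog (9 synthetic events,
labelled `DEMO*`; one falls below the M 6.9 threshold):

```r
library(fissureflux)
cst    <- model_constants()
events <- read_catalog(system.file("extdata", "synthetic_catalog.csv",
                                   package = "fissureflux"))
kept   <- filter_by_threshold(events, cst)   # 8 of 9 events
budget <- catalog_area_budget(kept, cst)
budget$totals
#> Time-averaged fissure exposure areas
#>   sidewall: 8.544e+07 m^2
#>   bottom:   4.886e+08 m^2
#>   total:    5.741e+08 m^2 (averaged over per-event a)
emissions_from_areas(budget$totals, cst)
#> Annual fissure CO2 emission budget
#>   sidewall component: 8.27e+10 g CO2/a
#>   bottom component:   2.52e+11 g CO2/a
#>   total:              3.34e+11 g CO2/a
#>   plateau rate increase: 0.13 g CO2 m-2 a-1
```

The sidewall and bottom areas are multi-year averages (each event
averaged from its own date to the reference year 2022); the total of
3.34 × 10¹¹ g CO2/a is what these eight synthetic events would add
annually, i.e. a 0.13 g CO2 m⁻² a⁻¹ increase spread over the plateau.

A synthetic chamber campaign with known group effects, recovered from
noisy data:

```r
s <- summarize_groups(generate_campaign(n_days = 30, noise_cv = 0.2,
                                        seed = 42))
s
#>      group n_timepoints mean_flux_umol_m2_s annual_rate_g_m2_a ratio_to_control
#> 1  control          300              1.2962             1799.0           1.0000
#> 2 sidewall          300              0.8311             1153.5           0.6412
#> 3   bottom          300              0.4437              615.8           0.3423
```

The generating multipliers were 0.6351 and 0.3376; with replicate noise
at cv 0.2 the recovered ratios land within about 1%.

There is also a thin command-line wrapper at `inst/cli/fissureflux`
(subcommands `estimate`, `chamber`, `simulate`), which writes JSON/CSV
reports plus a reproducibility manifest.

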