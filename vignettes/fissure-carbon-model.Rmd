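---
title: "Estimating soil CO2 emissions from earthquake surface fissures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating soil CO2 emissions from earthquake surface fissures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fissureflux)
```

## The problem

Large earthquakes on the Qinghai-Tibet Plateau open surface fissures
that expose deep, carbon-rich and often frozen soil to the atmosphere.
Each fissure adds two kinds of emitting surface that did not exist
before: the two vertical **sidewalls** and the **bottom** of the crack.
Both emit CO2 until the fissure heals — its length shrinks as the ends
close, while slumping sidewall material widens and eventually fills it.
`fissureflux` turns an earthquake catalog plus field-measured emission
rates into a time-averaged exposure area and an annual CO2 emission
budget for the plateau.

## Model

### Surface emission rates (chamber campaigns)

Paired chamber campaigns measure the CO2 efflux of a control (uncracked)
surface and of fissure sidewalls and bottoms, hourly from 8:00 to 17:00
with three replicate chambers per timepoint. `collapse_replicates()`
averages the replicates, `summarize_groups()` averages all timepoints of
a group equally and forms each group's ratio to control, and
`annualize_flux()` converts the instrument units (µmol CO2 m⁻² s⁻¹) to
g CO2 m⁻² a⁻¹ using the CO2 molar mass (44.01 g mol⁻¹) and a 365-day
year, i.e. assuming the campaign mean represents the annual mean. That
assumption is the whole annualization model; it is isolated in one
function so a season-weighted alternative can be swapped in. The
resulting default rates are 1524.95 (uncracked), 968.53 (sidewall,
63.51% of control) and 514.79 (bottom, 33.76%) g CO2 m⁻² a⁻¹.

### From magnitude to initial fissure geometry

The anchor is the fissure survey of the 2021 Maduo earthquake: 653
fissures along five faults. The unweighted mean of the per-fault
minimum and maximum fissure lengths gives the length range
76.6–942 m (`mean_length_range()`); to bound emissions from above, the
upper value is taken as the representative single-fissure length L′, so
the Maduo total is L_M = 942 × 653 = 615,126 m
(`maduo_total_length()`).

Every other event k is scaled by coseismic surface-rupture length:
L_k = (l_k / l_M) × L_M. A recorded rupture length is used when
available; otherwise it is derived by inverting the empirical
magnitude-rupture-length relation M = 5.92 + 0.88 log10(l), with l in
km (a regional regression for western China; about 48.1 km at M 7.4).
The initial average fissure width comes from inverting
M = 6.81 + 0.78 log10(W), with W in m (a surface-displacement scaling
relation read as fissure aperture). Both logs are base-10, the standard
convention for seismological scaling laws; the km/m units follow the
source regressions and are the only choices that give plausible
geometry at these magnitudes.

### Healing and time-averaged areas

Remote-sensing statistics of single fissures give a length-shrink rate
r_L = 0.49 m a⁻¹ and a width-widening rate r_W = 0.05 m a⁻¹. The rates
are *per fissure*, so the package treats an event's total length as
L_k0 / L′ identical fissures of length L′ shrinking at r_L:

L_k(t) = L_k0 · max(1 − r_L t / L′, 0),

which makes every event fully heal after t_rec = L′ / r_L ≈ 1922 a.
Applying the 0.49 m a⁻¹ rate to the event *total* instead would make
healing time scale with event size by orders of magnitude; that reading
is still available via `healing_model = "total_length"`. Width grows as
W_k(t) = W_k0 + r_W t while the fissure is open and is set to zero at
t_rec — an infilled fissure has no exposed bottom. Depth is constant at
D = 3 m (the layer holding most of the plateau's soil organic carbon);
depth healing is unobserved and not modelled.

With a U-shaped cross-section the instantaneous areas are
S_w(t) = 2 D L_k(t) and S_b(t) = L_k(t) W_k(t). Reported areas are
time averages from the event date to the reference year
(T_k = reference_year − event year, per event):
`time_averaged_areas()` evaluates the integrals in closed form (the
sidewall integrand is linear, the bottom integrand quadratic in t) and
the test suite checks them against brute-force trapezoid quadrature.
Catalog totals are plain sums over events (`catalog_area_budget()`).

### Emission budget

`emissions_from_areas()` applies E = S_w E_w + S_b E_b and attaches the
per-plateau-area rate increase E / A with A = 2.57 × 10¹² m². With the
published catalog area totals as inputs this reproduces the published
budgets: 1.83 × 10¹² g CO2 a⁻¹ (101 events, rate increase 0.71 g CO2
m⁻² a⁻¹) and 1.42 × 10¹¹ g CO2 a⁻¹ (12 events, 0.06 g CO2 m⁻² a⁻¹).
Note one inconsistency in the published totals: the 12-event bottom
area is printed as 0.28 × 10⁹ m², but sidewall (1.32 × 10⁸) plus bottom
must equal the printed total 1.60 × 10⁸, so the bottom area is read as
0.28 × 10⁸ (total minus sidewall) when reproducing the printed budget.
`comparison_ratio()` expresses a budget against user-supplied reference
fluxes (regional sinks, provincial inventories), as a percentage or
percentage range.

## Tunable parameters

All constants live in one validated object, `model_constants()`:

| field | default | units | meaning |
|---|---|---|---|
| `sidewall_rate_Ew` | 968.53 | g CO2 m⁻² a⁻¹ | sidewall emission rate |
| `bottom_rate_Eb` | 514.79 | g CO2 m⁻² a⁻¹ | bottom emission rate |
| `uncracked_rate` | 1524.95 | g CO2 m⁻² a⁻¹ | control-surface rate |
| `depth_D` | 3.0 | m | fissure depth |
| `length_heal_rate_rL` | 0.49 | m a⁻¹ | per-fissure length shrink |
| `width_widen_rate_rW` | 0.05 | m a⁻¹ | per-fissure widening |
| `unit_fissure_length_Lprime` | 942 | m | representative fissure length |
| `maduo_fissure_count_NM` | 653 | — | surveyed Maduo fissures |
| `maduo_magnitude` | 7.4 | — | Maduo anchor magnitude |
| `maduo_rupture_length_lM` | derived (≈48.1) | km | Maduo rupture length |
| `magnitude_threshold` | 6.9 | — | inclusive cutoff M ≥ 6.9 |
| `plateau_area` | 2.57e12 | m² | Qinghai-Tibet Plateau area |
| `reference_year` | 2022 | a (astronomical) | "now" for elapsed time |

`load_constants()` overlays a flat YAML/JSON file on these defaults and
rejects unknown keys. The Maduo magnitude is reported as both 7.2 and
7.4 in the source material; 7.4, the value used in the published
results, is the default and is overridable. The Maduo rupture length is
not printed anywhere, so by default it is derived from the anchor
magnitude through the same inversion used for other events, which keeps
the model self-contained; users with the literature value (about 70 km
of mapped rupture) can override it. Years use astronomical numbering
(326 B.C. = −325) so elapsed time is a subtraction; catalog files may
instead carry an `era` column (`BC`/`AD`) that is converted on read.

## Synthetic data: what it emulates, what it does not

`generate_catalog()` draws magnitudes from a doubly truncated
Gutenberg-Richter distribution (density ∝ 10^(−bM), default b = 1, the
canonical seismicity slope) on a magnitude range, years uniformly over
the catalog span, and gives a configurable fraction of events an
explicit rupture length with lognormal scatter around the scaling
relation. `generate_campaign()` builds hourly chamber records with a
half-sinusoid diurnal cycle peaking at 13:00 (solar-driven soil
warming), fixed group multipliers (defaults 0.6351 for sidewall and
0.3376 for bottom — the measured fractions of the control rate, with
the control mean chosen to annualize to 1524.95 g CO2 m⁻² a⁻¹),
30 measurement days, and multiplicative lognormal replicate noise with
unit mean (default cv 0.2, a typical chamber-measurement spread).

Both generators are pure functions of their arguments and seed.
They emulate the *statistical shape* of the study inputs, not the
field: no spatial structure, no temperature or moisture covariates, no
seasonal trend, no correlated replicate errors. Passing tests therefore
demonstrate that the pipeline recovers known ground truth under the
stated noise model — not that the model is unbiased on real campaigns.

## Numerical choices and degenerate inputs

- Time averages are closed-form; no quadrature is used at run time.
  The tests verify agreement with a 10⁵-step trapezoid rule to 1e-6
  relative on random geometries.
- Healing rates of zero are legal and give the constant-geometry limit
  (recovery time becomes infinite; handled as `1/t_rec = 0`, no
  division by infinity).
- An event dated in the reference year (elapsed time 0) contributes its
  initial areas, the analytic T → 0⁺ limit, rather than dividing by
  zero; events dated after the reference year are errors.
- Threshold comparison is inclusive (M ≥ 6.9). Filtering is idempotent
  and order-preserving.
- Replicate collapsing errors on more than three replicates per
  timepoint and warns (then averages what exists) on fewer.
- Reported budgets keep full precision; rounding to printed precision
  happens only in display and tests.

## Problem sizes

The shipped tests run the full property suites at moderate sizes chosen
to be statistically decisive: 100 random geometries against 10⁵-step
quadrature, 5000-event catalogs for b-value recovery (maximum-likelihood
estimate within ±0.05), and 200 seeded 30-day campaign replications for
ratio recovery (±3% of truth in ≥95% of runs). The whole suite runs in
a few seconds.

## Known limitations

- The healing model is linear and deterministic; real fissures heal at
  rates depending on substrate, moisture and slope, and the two rates
  come from a single fault system observed by remote sensing.
- Width widening at 0.05 m a⁻¹ truncated only at full recovery means
  bottom area can dominate sidewall area for events several centuries
  old; whether widening really continues to near t_rec (a ~96 m mean
  aperture just before infill) is unobserved. The published
  catalog-level totals suggest a more conservative width treatment, but
  the event lists needed to reproduce them are external, so this
  package follows the stated area equations literally and exposes every
  rate as a constant a user can change.
- Annualization from daytime, growing-season chamber means likely
  overstates the annual mean flux; all group *ratios* are unaffected.
- One emission-rate pair is applied plateau-wide; no vegetation-type or
  regional stratification, no carbonate/hydrothermal degassing, no
  ice-wedge or thermo-erosion feedbacks.
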