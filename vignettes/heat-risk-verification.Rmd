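---
title: "Verifying occupational heat-stress forecasts with WBGT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying occupational heat-stress forecasts with WBGT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatrisk)
library(dplyr)
```

## The problem

Heat–health warning systems for outdoor workers issue risk forecasts a day
or more ahead. Before such a system goes operational, the forecast chain
must be verified: does the risk level predicted from a numerical weather
model's surface fields agree with the risk level computed from what weather
stations actually measured? `heatrisk` implements that validation chain —
heat-stress index, worker risk model, and categorical/continuous
verification — together with a synthetic data generator, so every stage can
be exercised and tested with a fully known error structure.

## The heat-stress index

The Wet Bulb Globe Temperature combines three temperatures:

* **Tnwb**, the natural wet-bulb temperature — a wetted sensor exposed to
  the actual wind and radiation; the dominant term,
* **Tg**, the black-globe temperature — a 150 mm matt-black globe, a proxy
  for radiant load,
* **Ta**, the dry-bulb air temperature.

$$\mathrm{WBGT}_{shade} = 0.7\,T_{nwb} + 0.3\,T_g,\qquad
  \mathrm{WBGT}_{sun} = 0.7\,T_{nwb} + 0.2\,T_g + 0.1\,T_a$$

Stations and forecast models report neither Tnwb nor Tg, so both are
estimated from hourly air temperature, relative humidity, wind speed and
downward shortwave radiation:

* saturation vapor pressure uses the Magnus form with WMO coefficients
  ($6.112\,e^{17.62 t/(243.12+t)}$ hPa), chosen because it is standard and
  table-verifiable;
* the psychrometric wet bulb $T_{pwb}$ solves
  $e_s(T_w) - \gamma (T_a - T_w) = e$ by vectorized bisection
  ($\gamma = 0.667$ hPa/K);
* the shade natural wet bulb uses the Bernard wind function
  $T_{nwb} = T_a - C(v)(T_a - T_{pwb})$ with
  $C(v) = 0.96 + 0.069 \log_{10} v$, clamped to $[0.85, 1]$ — the clamps
  are the published low- and high-wind regimes and keep the function
  continuous across them;
* the globe temperature solves the steady energy balance of a 150 mm globe
  (shortwave absorption $\alpha S / 4$ with $\alpha = 0.95$, longwave
  exchange with surroundings at $T_a$ with $\varepsilon = 0.95$, sphere
  convection $h = 6.3 v^{0.6} / d^{0.4}$) by bisection;
* under direct sun the wick's radiant load adds $0.25\,(T_g - T_a)$ to the
  shade natural wet bulb.

The estimation literature offers more than one defensible assignment of
these sub-methods to the two exposures; the assignment above is this
package's documented choice (the wind-function wet bulb everywhere, the
energy-balance globe and its radiant increment for the sun branch). It
guarantees the physically required ordering
$\mathrm{WBGT}_{sun} \ge \mathrm{WBGT}_{shade}$ whenever shortwave flux is
positive, with equality at zero flux.

Numerical choices: both root-finders use a bisection tolerance of
$10^{-3}\,°C$ (capped at 100 halvings) and fail loudly with the offending
record if the root is not bracketed. Wind speeds below 0.1 m/s are clamped
to 0.1 m/s before entering the log/power-law formulas, which are undefined
at calm; clamps can be surfaced with `quiet = FALSE`. Saturated air
(RH = 100%) and zero solar flux short-circuit to their exact limits
($T_{pwb} = T_a$, $T_g = T_a$) rather than relying on the solver. Station
wind is used at its measurement height without correction, mirroring the
nearest-grid-point extraction policy of taking model output "as is".

## The worker risk model

The predicted WBGT is corrected for clothing,
$\mathrm{WBGT}_{eff} = \mathrm{WBGT} + \mathrm{CAV}$, and compared with a
reference limit that depends on the metabolic rate MR (W):

$$\mathrm{RAL} = 59.9 - 14.1\log_{10}\mathrm{MR} \quad(\text{acclimatized}),
\qquad \mathrm{REL} = 56.7 - 11.5\log_{10}\mathrm{MR}
\quad(\text{unacclimatized})$$

The risk percentage $\mathrm{RL}(\%) = 100\,\mathrm{WBGT}_{eff}/\text{limit}$
maps onto four classes: 0 (green, $\le 80$), 1 (yellow, $80$–$100$),
2 (orange, $100$–$120$), 3 (red, $\ge 120$). The published inequalities are
strict on both sides of 100, leaving that single value unassigned; this
package attaches boundaries upward (100 → class 2), consistent with the
closed bound at 120, and isolates the rule in `classify_risk()`.

The default worker is the standard profile the chain is designed around:
75 kg, 175 cm, acclimatized, engaged in intense physical activity, in
normal working overalls. The exact MR and CAV behind "intense activity"
and "normal overalls" are not fixed by the class definitions; the defaults
here are MR = 415 W (the high metabolic-rate class midpoint of ISO 7243)
and CAV = 0 °C (reference clothing). Both are configurable and every
class-dependent output is interpretable only together with the MR/CAV used.

A worker counts as **acclimatized** once five days with at least moderate
risk (daily maximum class ≥ 2) have accrued within the running warm season.
Whether those days must be consecutive, and whether the flag decays, is not
fixed by the five-day rule itself; `update_acclimatization()` counts
cumulatively by default (flag monotone within a season, reset at the season
start, default May), with `consecutive = TRUE` as the stricter variant.

```{r}
worker_profile()
classify_risk(c(79, 85, 105, 125))
```

## Verification

Hourly observed and predicted classes populate a 4×4 contingency table
(rows observed, columns predicted; the diagonal counts correct forecasts).
From it: hit rate HR, critical success index CSI (events only), per-class
probabilities of detection POD1–3, extended POD1x/POD2x crediting
higher-class forecasts, lack-alarm NA and false-alarm FA ratios, and their
variants NA*/FA* normalized by all hours. ME, MAE and RMSE are computed on
the continuous WBGT values. Scores with an empty denominator are carried as
`NA` (e.g. POD3 when class 3 was never observed), never as zero.

Three printed-formula idiosyncrasies are handled explicitly: the HR
denominator is all 16 cells and the CSI denominator is total − C00 (the
published expressions contain evident transcription slips, which
`strict = TRUE` reproduces literally for audit); the RMSE takes the square
root its verbal definition and units imply; and POD1x is implemented
exactly as printed — its numerator excludes C13, so a class-3 forecast of
an observed class-1 hour is *not* credited — with `include_higher = TRUE`
as the text-consistent alternative.

Per-area values are unweighted means over the defined per-station scores;
stations flagged `excluded` in the registry (e.g. a complex-topography site
whose model grid point sits hundreds of metres too high) keep their
per-station rows but never enter area means.

## The study design

`run_validation()` reproduces the design end to end: May–September, four
six-hour local-time slots (0–6, 6–12, 12–18, 18–24, half-open, daylight
saving time), forecast runs at 00 UTC with 72 h of hourly leads, verified
on lead day 2 (tomorrow) and optionally day 3; day 1 is supported but
flagged, since it gives less than 24 h of warning. Each slot is analysed
both on all its hours and on its maximum (observed and predicted maxima
taken independently, then classified). Slot completeness defaults to 5 of
6 hours for the all-hours mode and 6 of 6 for the slot-max mode, and a
station enters verification only if at least 80% of its season hours pair
up — the archives behind real networks state no numeric criterion, so both
gates are explicit configuration. The local calendar day is anchored to the
00 UTC run in local civil time (Europe/Rome), a documented convention: at
Central European Summer Time the run starts at 02:00 local, so "day 2" is
simply the next local calendar date.

## The synthetic generator

`synthetic_scenario()` emulates the study's data, not its climate: 28
stations by default (7 inland-plain A, 12 coastal B, 9 central-south inland
C), hourly May–September series in which temperature is a seasonal plus
diurnal sinusoid with AR(1) residuals, humidity is anti-phased, wind is
log-normal and solar is a day-length-aware clear-sky half-sine times an
autocorrelated cloud factor. One area-A station is a "narrow valley"
analogue: its matched grid point sits 788 m too high (a ~262 m valley floor
modelled at ~1050 m) and it is excluded from area means. Forecasts are
fabricated from the observations by adding per-variable bias, AR(1) noise
(defaults 0.8 °C for temperature, 5% RH, 0.3 m/s wind, 60 W/m² solar,
lag-1 correlation 0.6 — typical magnitudes for surface fields of
limited-area models) and a lapse-rate term −0.65 °C per 100 m of
grid-elevation offset. Per-station substreams are seeded independently, so
adding a station never perturbs another's series.

What this generator does *not* emulate: spatial correlation between
stations, realistic cloud physics or radiation geometry, wind-direction
effects, or model error that depends on weather regime. Tests passing on
synthetic data therefore demonstrate the correctness of the chain's
arithmetic and bookkeeping — not the skill of any real forecast model.

```{r}
sc <- synthetic_scenario(
  n_stations = c(A = 1, B = 1, C = 1),
  start = as.Date("2019-06-01"), end = as.Date("2019-06-10"),
  error_model = forecast_error_model(bias = c(ta = 1)),
  complex_station = FALSE, seed = 42
)
ds <- generate_dataset(sc)
v <- run_validation(ds$obs, ds$fcst, ds$registry,
                    validation_config(lead_days = 2))
glance(v)
```

```{r, fig.width = 7, fig.height = 4}
autoplot(v)
```

## Problem sizes and limitations

The examples and tests run on deliberately small problems — single-station
ten-day series for parameter-recovery checks (50 seeds), and one full
28-station season for the end-to-end identity property — sizes chosen so
the whole suite re-runs in minutes while still exercising every code path
at season scale. Known limitations: the globe scheme is the only radiant
model (no mean-radiant-temperature alternatives, no UTCI/PET); no
microclimate or surface-type modelling; no bias correction or downscaling
of forecasts; verification is deterministic and categorical — no ensemble
or probabilistic scores; and the acclimatization rule is a day-counting
heuristic, not a physiological model.
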