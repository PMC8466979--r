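# heatrisk

Validation tools for occupational heat–health warning chains.

Warning systems for outdoor workers forecast heat-stress risk a day or more
ahead from the surface fields of limited-area weather models. Before trusting
such a system, the whole chain needs verification against station
observations. `heatrisk` implements that chain for analysts of heat–health
warning systems:

1. **WBGT estimation** — the Wet Bulb Globe Temperature in shade
   (0.7 T<sub>nwb</sub> + 0.3 T<sub>g</sub>) and in sun
   (0.7 T<sub>nwb</sub> + 0.2 T<sub>g</sub> + 0.1 T<sub>a</sub>), with the
   natural wet-bulb and black-globe temperatures estimated from hourly air
   temperature, relative humidity, wind speed and shortwave radiation
   (Bernard wind function on the psychrometric wet bulb; iterative 150 mm
   globe energy balance).
2. **Worker risk model** — effective WBGT (clothing adjustment), reference
   limits RAL = 59.9 − 14.1 log₁₀MR / REL = 56.7 − 11.5 log₁₀MR (°C, MR the
   metabolic rate in W), the risk percentage
   RL(%) = 100 · WBGT<sub>eff</sub>/limit, four risk classes with boundaries
   at 80 / 100 / 120%, and the five-qualifying-day acclimatization rule.
3. **Forecast verification** — 4×4 observed-vs-predicted contingency tables
   and the full score suite (HR, CSI, POD1–3, POD1x/2x, lack- and
   false-alarm ratios NA/FA and normalized NA\*/FA\*), plus ME/MAE/RMSE on
   the WBGT values; per-station scores averaged over geographical
   macro-areas, undefined scores carried as `NA`, never as zero.
4. **Study-design pipeline** — May–September seasons, four six-hour local
   time slots, 00 UTC runs verified on lead days 2–3, all-hours and
   slot-max analysis modes, nearest-grid-point matching with recorded
   elevation mismatch.
5. **Synthetic data** — a 28-station, three-area network generator with a
   controllable forecast error model (bias, AR(1) noise, lapse-rate
   elevation effects), so every stage is testable without external data.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on results, `autoplot()` for area score summaries.

## Worked example

Three hot hours, from raw meteorology to risk classes:

```r
library(heatrisk)
library(dplyr)

df <- tibble::tibble(
  ta_c = c(28, 33, 36), rh_pct = c(65, 50, 40),
  wind_ms = c(0.8, 1.5, 2), solar_wm2 = c(300, 850, 950)
)
w <- compute_wbgt(df)
w
#>    ta_c rh_pct wind_ms solar_wm2 tnwb_c  tg_c wbgt_shade_c wbgt_sun_c
#> 1    28     65     0.8       300   24.2  32.0         24.6       26.1
#> 2    33     50     1.5       850   26.9  41.6         27.2       30.4
#> 3    36     40     2         950   27.1  44.3         28.3       31.4
```

The globe runs 4–8 °C above the air under strong sun, and the sun-exposed
WBGT exceeds the shade value by 1.5–3 °C. For the default worker (75 kg,
175 cm, acclimatized, MR = 415 W → reference limit 23.0 °C, CAV = 0):

```r
assess_risk(w) |> select(exposure, wbgt_c, rl_percent, rl_class)
#>   exposure wbgt_c rl_percent rl_class
#> 1 shade      24.6       107.        2
#> 2 sun        26.1       114.        2
#> 3 shade      27.2       119.        2
#> 4 sun        30.4       132.        3
#> 5 shade      28.3       123.        3
#> 6 sun        31.4       137.        3
```

All six assessments land in the moderate (2, orange) or high (3, red) risk
classes — work/rest management territory.

End-to-end verification on synthetic data with a known +1 °C warm bias:

```r
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
#>   n_stations n_skipped n_pairs    hr   csi    me   mae  rmse
#> 1          3         0    1512  77.4  75.5 0.859  1.04  1.29
```

The injected warm bias surfaces as a positive WBGT mean error (+0.86 °C),
an MAE near 1 °C and a hit rate of 77% — and disappears entirely (HR = 100,
ME = MAE = RMSE = 0) when the error model is zeroed, the package's core
end-to-end identity property. `tidy(v, level = "area")` returns the long
per-area score table and `autoplot(v)` plots it.

See the vignette (`vignettes/heat-risk-verification.Rmd`) for the model
details, parameter choices and limitations.

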