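# thermopulse

Label-free, real-time monitoring of cell sedimentation and proliferation
with a pulsed, DC transient-plane-source (TPS-derived) foil sensor — as a
fully synthetic, end-to-end simulation and analysis pipeline in R.

A planar copper meander on a 40 µm polyimide foil sits at the bottom of a
culture reservoir. Constant-current pulses (0.5 W, 1 s, repeated every 61 s
or 301 s) Joule-heat the structure, and the 4-wire voltage transient is a
thermometer through

    R(T) = Rref · [1 + α (T − Tref)],       α = 3.818e-3 K⁻¹ (copper)

The heater over a semi-infinite medium of thermal effusivity
`e = √(k·ρ·cp)` warms as `ΔT(t) = (2q/e)·√(t/π)` — linear in `√t` with
slope `2q/(e√π)`. Cells conduct heat worse than the medium, so a settling
or growing cell layer insulates the sensor and steepens the early
transient. The read-out is the OLS slope of each pulse against `√t` inside
the fixed window `[0.16, 0.56] √s` (25.6–313.6 ms), reported as percent
change relative to the first pulse,

    pct_i = 100 · (s_i − s_0) / s_0

which cancels sensor-to-sensor differences in the cold resistance
(7–10 Ω). Endpoint percent change is linear in suspension concentration
(response line `y = 0.7806·x − 0.2194`, % vs mg/mL), and proliferation
renders the familiar lag / exponential / stationary growth curve, from
which a logistic fit recovers the doubling time (`Td = 60·ln2 / rate` min).

The package provides, with no external data:

* `thermal_core` physics — effusivity, probing depth, the closed-form
  half-space oracle, and an implicit finite-difference solver (Rcpp) for
  the layered heater/substrate/cell/medium stack;
* an electrical sensor model — resistance thermometry, drive-current
  computation, noisy 4-wire pulse synthesis;
* synthetic cultures — Stokes sedimentation of a dilution series
  (8 → 0.125 mg/mL plus blank) and lag+logistic yeast growth under varying
  glucose (10.00 / 2.50 / 0.16 g/L) and starting density (OD600 0.1–0.8),
  rendered into raw pulse datasets;
* the analysis pipeline — voltage→temperature conversion, `√t`-window
  regression, percent-change slope series, endpoint statistics, plateau
  detection;
* quantification — calibration with inverse prediction, and growth fitting
  including a physics-informed variant (`slope_response()` +
  `fit_growth(..., response = )`) that removes the bias of assuming slope
  change proportional to biomass;
* CSV/YAML/JSON I/O and a CLI (`exec/thermopulse`) with subcommands
  `simulate | analyze | calibrate | growthfit`.

## Worked example

```r
library(thermopulse)

# 2 h sedimentation of an 8 mg/mL yeast suspension, pulsed every 61 s
scenario   <- culture_scenario("sedimentation", concentration = 8)
protocol   <- pulse_protocol(power = 0.5, pulse_duration = 1,
                             cooling_time = 60, total_duration = 2 * 3600)
experiment <- generate_experiment(scenario, sensor_spec(), protocol, seed = 1)
#> <pulse_experiment> 119 pulses (0.5 W, 1 s @ 500 Hz), period 61 s

series <- slope_series(experiment)   # sqrt(t)-window regression per pulse
head(series, 3)
#>   pulse_index        t_h    slope  intercept        r2 pct_change
#> 1           0 0.00000000 4.309437 -0.2078780 0.9973398  0.0000000
#> 2           1 0.01694444 4.334662 -0.2173288 0.9972047  0.5853460
#> 3           2 0.03388889 4.302999 -0.2019270 0.9964443 -0.1494047

endpoint_statistic(series, t_from = 1.5, t_to = 2)
#> $mean  3.516417   $sd  0.5309667   $n  30
plateau_time(series, tolerance_pct = 1.5)
#> [1] 0.7286111
```

Every slope is a clean regression (R² ≈ 0.997) in physical units
(K s⁻¹/²); the percent change climbs while the cells settle and plateaus
at ~3.5% once the 5.3 mm column has cleared (≈ 0.7–1.1 h at the Stokes
velocity of a 2.5 µm cell), after which the signal is drift-free.

Calibration against synthetic endpoints, then inverse prediction:

```r
pts <- calibration_endpoints(dilution_series(), replicates = 4, seed = 7)
fit <- fit_calibration(pts$concentration, pts$endpoint_pct)
#> <calibration_fit> pct = 0.7770 * conc -0.2425  (n = 32)
#>   residual sd 0.231 %, inverse-prediction sd 0.298 mg/mL
predict_concentration(fit, endpoint_pct = 3.1)
#>   concentration        sd
#> 1       4.30192 0.2976428
```

The fitted line recovers the generating response (slope 0.7806, intercept
−0.2194) within its standard errors, and an observed 3.1% endpoint reads
back as 4.3 ± 0.3 mg/mL.

The same pipeline from the shell:

```sh
./exec/thermopulse simulate --config inst/extdata/demo_sedimentation.yaml \
    --seed 1 --out raw.csv
./exec/thermopulse analyze raw.csv --window 0.16:0.56 \
    --domain temperature --out slopes.csv
```

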