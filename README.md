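# firebias

Stochastic simulation of the **wildfire suppression bias**: the skew in
realized fire behavior and ecological effects that arises because fire
suppression removes low-intensity fire far more effectively than
high-intensity fire. `firebias` simulates thousands of independent wildfires
under identical biophysical conditions that differ *only* in their
suppression scenario, and measures what the surviving fires look like:
burned area and its concentration, burn severity, the diversity of fire
effects, and how fast burned area grows along gradients of fuel aridity
(vapor pressure deficit, VPD) and fuel loading.

The package is for fire ecologists and disturbance modelers who want a
transparent, fully seeded implementation of this experiment — every fire is
reproducible from one master seed, and every component is exposed as an
ordinary R function returning a tibble.

## The model in brief

Each fire is one draw from a generative chain:

1. **Season weather** — a 150-day season; daily windspeed `W ~ Weibull(k, c)`
   with one wind direction per fire; daily fuel moistures driven by a latent
   VPD signal (seasonal sinusoid + AR(1) noise) through a negative
   exponential `m = a e^{-b·VPD} + c`.
2. **Fire behavior** — Rothermel steady-state surface spread
   `R = I_R ξ (1 + φ_w + φ_s) / (ρ_b ε Q_ig)` for an Anderson Fuel Model 10
   complex on 40% slope; Van Wagner crown-fire initiation at
   `I_0 = (0.01·CBH·(460 + 25.9·FMC))^{3/2}` with a Cruz-style active crown
   rate; Byram intensity `I = H·R` and flame length `L = 0.0775·I^{0.46}`.
3. **Elliptical growth** — Huygens-style expansion from the rear focus of a
   wind-elongated ellipse; growth at angle θ from the heading is
   `g(θ) = (1−e)/(1−e cos θ)`; local fireline intensity is `I·g(θ)`;
   perimeter points burning < 5 m/day are permanently extinguished.
4. **The suppression filter** — stochastic initial attack (engagement after
   1/2/4 h for Maximum/High/Moderate; containment probability logistic in
   log intensity and log size), then daily containment curves that remove a
   proportion of each perimeter point's spread as a function of its local
   intensity — decreasing in intensity for regressive scenarios, increasing
   for the progressive scenario, and zero for every scenario above
   10,000 kW/m, where suppression is impossible.
5. **Severity** — flame length → tree mortality (logistic) → Composite Burn
   Index (CBI ∈ [0, 3]); CBI ≥ 2.25 is high severity.

Scenario contrasts use common random numbers: the same weather, ignition
day, and initial-attack draw are replayed for all 25 gradient levels and
all five scenarios (`none`, `moderate`, `high`, `maximum`, `progressive`),
so differences between scenarios are differences in the filter alone.

## A worked example

Simulate 200 baseline ignitions (VPD 1.17 kPa, 100-h load 11.23 Mg/ha)
under all five scenarios and summarize:

```r
library(firebias)
library(dplyr)

cfg <- experiment_config(axis = "vpd", n_levels = 1, span_years = 0,
                         n_ignitions = 200, n_replicates = 1, seed = 42)
records <- run_experiment(cfg)

records |>
  group_by(scenario) |>
  summarise(pct_spreading = 100 * mean(!smoldered),
            mean_area_ha = mean(final_area),
            top1_share = 100 * top_share(final_area, 0.01),
            mean_cbi = sum(mean_cbi * final_area, na.rm = TRUE) /
              sum(final_area[!is.na(mean_cbi)]))
```

```
# A tibble: 5 × 5
  scenario    pct_spreading mean_area_ha top1_share mean_cbi
  <chr>               <dbl>        <dbl>      <dbl>    <dbl>
1 high                 98.5        41.6       96.4      2.86
2 maximum              98.5         8.91      96.8      2.89
3 moderate             98.5       806.        67.9      2.83
4 none                 98.5     87553.         5.31     2.25
5 progressive          98.5     61863.         5.00     2.15
```

Reading the table: without suppression the average fire is enormous (the
landscape is uniform and unbounded, so sizes are model quantities, not
predictions), and the largest 1% of fires hold only a few percent of the
burned area. Under Maximum suppression the mean fire is orders of magnitude
smaller, but nearly all surviving burned area comes from a handful of
escapes that burned as crown fire — higher mean CBI and extreme
concentration. That asymmetry is the suppression bias.

Useful figures:

```r
plot_containment_curves()          # the suppression filter
plot_lorenz(records)               # burned-area inequality by scenario
fire <- simulate_fire(simulate_weather(1.17), fuel_complex(),
                      default_scenarios()$none, keep_rings = TRUE)
plot_perimeter(fire)               # one fire, intensity-colored perimeter
```

A thin command-line interface wraps the same functions:

```sh
inst/cli/firebias run --preset paper-aridity-small --seed 7 --out out/
inst/cli/firebias summarize --records out/records.csv --out out/
inst/cli/firebias export-curves --out out/curves.csv
```

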