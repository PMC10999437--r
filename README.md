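# spumaphen

Temperature-driven phenology modelling for the meadow spittlebug
*Philaenus spumarius*, the principal European vector of *Xylella
fastidiosa*. The package is aimed at quantitative entomologists and
plant-health modellers who need to predict, from an air-temperature
record alone, when overwintering eggs leave diapause, when each nymphal
instar (N1–N5) appears on the herbaceous cover, and when the first
adults emerge — the timing information that drives monitoring and
control scheduling against *X. fastidiosa* outbreaks.

## The model

Each developing stage *i* (egg, N1–N5) advances in physiological age
*x* ∈ [0, 1] at the Brière development rate

    v_i(T) = a_i · T · (T − T_inf,i) · sqrt(T_sup,i − T),   T_inf,i ≤ T ≤ T_sup,i

and zero outside the thresholds. Overwintering eggs are held in diapause
until the degree-day sum Σ max(0, T̄_d − T_e) from 1 January reaches
DD_e (calibrated values for Italy: T_e = 6.5 °C, DD_e = 120 DD); their
initial ages follow Beta(5.67, 1.05), i.e. 90% of eggs have completed
58–99% of embryonic development before winter. Stage densities are
transported along age by an advection (Kolmogorov forward) system solved
with a conservative upwind scheme in which each stage advances at
Courant number 1 — mass-conserving to machine precision and verified
against the exact method-of-characteristics solution.

On top of the forward simulator the package provides:

* `fit_development_params()` — chamber parameterization: blockwise +
  joint least-squares fit of the six Brière triples and the Beta age
  distribution to constant-temperature cohort curves;
* `calibrate_rates()` / `calibrate_diapause()` — two-step field
  calibration, ending in an exhaustive (T_e, DD_e) grid search scored on
  the N3–N5 curves;
* `generate_temperature_series()`, `generate_chamber_experiment()`,
  `generate_field_survey()` — seeded synthetic-data generators mimicking
  the chamber design (4 temperatures × 9 replicates, thrice-weekly
  census) and weekly March–May field surveys;
* `evaluate_fit()` and CSV/YAML readers and writers, plus a thin command
  line tool (`exec/spumaphen`) with `simulate | fit | generate |
  evaluate` subcommands.

## A worked example

```r
library(spumaphen)

model   <- spuma_preset("calibrated")      # field-calibrated parameters
weather <- generate_temperature_series(weather_spec(seed = 11), days = 160)

diapause_termination_day(weather, model$diapause)
#> [1] 62

traj <- simulate(model, temps = weather)
traj
#> Phenology trajectory, days 1-160; diapause termination day: 62
#> Final cumulative emergence (% of initial eggs):
#>    N1    N2    N3    N4    N5 adult
#>   100   100   100   100   100   100

summary(traj)
#> Emergence dates (Julian day at 1/50/95% cumulative emergence):
#>       N1   N2    N3    N4    N5 adult
#> 1%  61.2 75.2  90.1  98.4 107.1 118.1
#> 50% 69.8 81.9  95.3 103.5 111.2 121.9
#> 95% 86.0 95.4 106.6 113.7 120.7 130.4
```

Under this Mediterranean-like synthetic winter, diapause ends on Julian
day 62 (≈ 3 March); eggs hatch through March (N1), the late instars
N3–N5 run from early April to late May, and the first adults (1%
emergence, day 118) appear at the end of April — the seasonal pattern
reported for Italian olive groves. A full calibration round-trip:

```r
surveys <- generate_field_survey(model, weather_spec(), n_sites = 4, seed = 101)
fit <- calibrate_diapause(surveys, model$stages, model$age_dist)
fit
#> Diapause grid search: Te = 6.5 degC, DDe = 120 DD (objective 374.3 over 165 pairs)
```

The grid search recovers the generating diapause pair exactly from noisy
weekly observations.

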