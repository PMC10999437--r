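---
title: "Modelling the temperature-driven phenology of the meadow spittlebug"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the temperature-driven phenology of the meadow spittlebug}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spumaphen)
```

## The biological problem

The meadow spittlebug *Philaenus spumarius* is the main European vector of
*Xylella fastidiosa*, the bacterium behind olive quick decline syndrome and
several other severe plant diseases. Control acts on the juvenile stages:
nymphs live on the herbaceous ground cover, and the window around the peak
of the late instars (N3–N5) is when monitoring and treatment are most
effective. Scheduling those actions needs a phenological model — given a
temperature record, when do eggs leave diapause, when does each nymphal
instar appear, when do the first adults emerge?

`spumaphen` implements a physiologically-based, temperature-driven model of
the preimaginal phenology of *P. spumarius*, with the estimation machinery
to parameterize it from climatic-chamber cohorts, calibrate it on field
surveys, and generate fully synthetic chamber/field datasets so that every
procedure can be exercised and tested without access to restricted field
data.

## Model structure

Seven stages are represented: egg, nymphal instars N1–N5, and adult. The
adult stage is a pure accumulator — only the flux of individuals out of N5
is modelled; adult-specific processes (parapause, ovary maturation,
oviposition) and mortality are deliberately out of scope.

**Development rates.** Each developing stage $i$ (egg, N1–N5) advances in
*physiological age* $x \in [0,1]$ at the Brière rate

$$v^i(T) = a^i\, T\,(T - T^i_{inf})\sqrt{T^i_{sup} - T},
  \qquad T^i_{inf} \le T \le T^i_{sup},$$

and $v^i(T) = 0$ outside the thresholds. The optimum temperature has a
closed form (the larger root of $5T^2 - (4T_{sup} + 3T_{inf})T +
2\,T_{inf}T_{sup} = 0$), which `briere_optimum()` uses instead of a
numerical search; `scale_from_max()` converts a published peak rate
$v_{max}$ into the raw constant $a$.

**Diapause.** Overwintering eggs are developmentally arrested until they
accumulate $DD_e$ degree-days above a threshold $T_e$, counted from
1 January on daily mean temperatures: $\sum_d \max(0, \bar T_d - T_e)$.
All eggs terminate together on the first day the sum reaches $DD_e$, and
development begins on the termination day itself. The calibrated pair for
Italian populations is $T_e = 6.5$ °C, $DD_e = 120$ DD. An hourly
accumulation variant is available behind `degree_days(method = "hourly")`
for sensitivity checks; the daily-mean form is the default because the
degree-day definition is stated in terms of a daily threshold exceedance.

**Initial condition.** On 1 January the cohort is 100 diapausing eggs with
physiological ages drawn from Beta($\alpha$, $\beta$); the estimate
Beta(5.67, 1.05) puts 90% of eggs between ages 0.58 and 0.99 — embryonic
development is mostly complete before winter, which is why hatching
follows soon after diapause ends.

**Transport.** Population density in each stage obeys an advection
(Kolmogorov forward) equation along age with the time-dependent velocity
$v^i(T(t))$; mass reaching $x = 1$ transfers instantaneously to $x = 0$ of
the next stage. The related literature sometimes includes a stochastic
(diffusion) term; no magnitude is available for this system and the
observed spread is carried entirely by the initial Beta distribution, so
the baseline model is pure advection. A constant-diffusivity term is kept
behind the `diffusivity` argument (default 0) for future use.

## Numerics

The solver is a conservative first-order upwind scheme on a uniform age
grid (default 200 cells), sub-stepped so that every stage satisfies its
CFL condition. Because the velocity is uniform in age, an upwind step at
Courant number exactly 1 is a pure one-cell shift with no numerical
diffusion; the implementation therefore gives each stage its own phase
accumulator $\phi_i \mathrel{+}= v_i\,\Delta t/\Delta x$ and shifts that
stage by one cell whenever $\phi_i \ge 1$. Each stage thus advances at
Courant number 1 at its own rhythm. A shared-timestep upwind update
(Courant $\ll 1$ for the slow egg stage) would smear the egg cohort by
several days over a season; the per-stage formulation keeps the phase
error below one cell per stage, which the test suite verifies against the
exact method-of-characteristics solution. Mass is conserved to machine
precision by construction (the tests require 1e-6 relative over a
150-day season; observed error is ~1e-15).

Temperature forcing: hourly series are linearly interpolated to substep
midpoints; daily series are held constant within each day. Boundary flux
between stages happens within the same substep as the shift that produced
it. Degenerate inputs behave predictably: temperatures below every
$T_{inf}$ freeze the state exactly; a diapause requirement never met
returns an all-zero trajectory with a warning (not an error); a violated
CFL bound in the single-step API reports the maximal admissible step.

The exact characteristics solution (`characteristics_curve()`,
`characteristics_entry_times()`) integrates individuals of fixed initial
age through the cumulative development integrals. It serves as the
independent oracle for the gridded solver and as the exact engine for
constant-temperature work.

## Estimation procedures

**Chamber parameterization** (`fit_development_params()`): cohorts of
post-storage eggs reared at 10/18/24/30 °C (nine replicates, censused
three times a week) give cumulative emergence curves for hatch and each
instar. The fit minimizes the summed squared difference between observed
and modelled cumulative percentages over all stages, temperatures, and
census dates, jointly over the six Brière triples and the Beta
parameters. The minimization follows the iterative scheme used for this
model class: evaluate the objective at the starting point and stop
immediately if it is below the objective-change tolerance (0.1);
otherwise blockwise Nelder-Mead (egg + Beta block against the hatch
curves, then one 3-parameter block per instar against its entry curves,
each from several starting points), followed by a joint refinement pass.
Step tolerance 1e-6 and objective-change tolerance 0.1 are the stopping
rules, and the final objective never exceeds the initial one. Bounds:
$T_{inf} \in [0, 15]$, $T_{sup} \in [25, 40]$ °C, $v_{max} \in (0, 1]$
day⁻¹, Beta shapes in (0, 50].

Because the chambers run at constant temperature, the model there has an
exact solution; the default objective engine evaluates it directly
(`engine = "characteristics"`), which is fast and free of grid error.
`engine = "pde"` runs the gridded solver inside the objective instead and
is useful to confirm that the grid resolution is adequate. Whether to fit
the raw censored curves or Gamma-smoothed versions is genuinely open;
the raw curves are the default target, and `fit_gamma_emergence()` is
provided as the descriptive smoothing layer. On noiseless synthetic
chambers the procedure recovers thresholds to within ~0.01 °C and peak
rates to within ~3%.

**Field calibration** is two-step, run once in the order (i) → (ii):

1. `calibrate_rates()` refines the six Brière triples against weekly
   field emergence curves (all five instars), with the first-adult date
   entering as a half-weighted squared-error term on the simulated
   1%-adult day — first adult appearances are the only adult information
   a ground-cover survey yields. Blockwise Nelder-Mead sweeps; the age
   distribution and a provisional diapause pair stay fixed.
2. `calibrate_diapause()` then grid-searches $T_e \in [3, 10]$ °C and
   $DD_e \in [30, 130]$ DD exhaustively (default steps 0.5 °C and 10 DD,
   chosen so the published pair (6.5, 120) is on-grid), scoring only the
   N3–N5 curves — the early-instar field counts are the least reliable.
   A pair that never terminates within a series scores against zero
   simulated emergence, a natural penalty rather than an exception. Ties
   break deterministically: objective, then smaller $DD_e$, then smaller
   $T_e$. Since the pair affects the simulation only through the
   termination day, simulations are memoized by that day; the 165-pair
   search costs tens of forward runs per survey and finishes in seconds.

A caution on identifiability: with March–May surveys in a mild climate,
the egg lower threshold trades off against the egg peak rate (both
control spring development speed), so its refined value is only weakly
determined; in a cooler climate where egg development happens at 5–9 °C
the threshold becomes identifiable, which is how the test suite checks
the expected downward shift from the chamber value.

## Synthetic data

The generators stand in for data-logger/reanalysis weather and for the
original chamber and field campaigns (available only on request):

* `generate_temperature_series()` — sinusoidal annual + diurnal cycles
  with Gaussian noise. The default "Mediterranean" preset (mean 15 °C,
  annual amplitude 8, diurnal amplitude 4, noise s.d. 1.5 °C) yields
  diapause termination in late February / early March and first adults
  from late April, consistent with the reported Italian field phenology.
* `generate_chamber_experiment()` — individual stage-entry times sampled
  through the exact characteristics solution (independent of the gridded
  solver, so solver tests remain non-circular), censored to a
  Monday/Wednesday/Friday census. Default 9 replicates × 25 eggs at
  10/18/24/30 °C; the cohort size per replicate is not published, and 25
  is a realistic choice for this rearing design. The 10 °C chamber is
  observed for 250 days (development there is several-fold slower), the
  others for 80. `analytic = TRUE` returns the infinite-cohort curves.
* `generate_field_survey()` — the full forward model run on per-site
  weather (site offsets −1…+2 °C around the preset mean by default),
  read weekly from early March to late May (days 63–147), with binomial
  observation noise for a 100-egg cohort. One latent uniform per cohort
  member is shared across stages and dates, so observed cumulative
  curves are monotone in time and ordered across stages by construction
  while each single count keeps its Binomial(N, p) margin.

What the generators do *not* emulate: weather autocorrelation and fronts,
microclimate of the ground cover, stage-specific detectability,
mortality, and between-site variation in the initial age distribution.
Passing recovery tests on these data therefore demonstrates correctness
of the estimation machinery under the model's own assumptions, not
robustness to the full messiness of field data — notably, the published
difficulty of fitting the N1/N2 field curves is a property of real
surveys that these generators do not reproduce.

## Bundled presets

`spuma_preset("parameterized")` carries the chamber-derived rates (egg:
thresholds 6.5/32.0 °C, peak 0.0373 day⁻¹ at 26.3 °C; nymphal thresholds
≈3.0/33.0 °C — N3: 2.1 °C — with peaks 0.1747–0.2382 day⁻¹);
`spuma_preset("calibrated")` the field-refined set (egg: 3.0/35.0 °C,
peak 0.0519 day⁻¹ at 28.3 °C; N5 lower threshold 5.0 °C, peak 0.1441
day⁻¹) plus the diapause rule (6.5 °C, 120 DD) and Beta(5.67, 1.05).
Entries not individually published (parameterized N5 peak; calibrated
N1/N2/N4 peaks and the N4 lower threshold) are filled with values
consistent with the published directions of change and flagged in
`?spuma_preset`.

## A worked season

```{r season}
model <- spuma_preset("calibrated")
weather <- generate_temperature_series(weather_spec(seed = 11), days = 160)
diapause_termination_day(weather, model$diapause)
traj <- simulate(model, temps = weather)
summary(traj)
```

```{r plot, fig.width = 6, fig.height = 4}
plot(traj)
```

## Problem sizes and determinism

The shipped tests and the acceptance script use: 200 age cells for solver
accuracy checks (100 cells inside iterative calibration objectives, where
a coarser grid is accurate enough and halves the cost), 150–170 day
seasonal windows, 4 site-years for the diapause grid recovery, and the
full 15 × 11 diapause grid. All stochastic steps flow through explicit
seeds; generators restore the caller's RNG state. The forward model
itself is deterministic.

## Known limitations

* Diapause termination is a single population-level switch; no
  among-egg variation in $(T_e, DD_e)$, no chilling or photoperiod
  effects.
* Pure advection: all spread comes from the initial age distribution, so
  within-stage developmental variability beyond that is not represented.
* The calibration refines rates and diapause in one pass (i) → (ii), not
  jointly or iteratively.
* Adult biology ends at emergence; seasonal adult dynamics need a
  different model.
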