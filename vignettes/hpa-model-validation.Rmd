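---
title: "Verifying and validating HPA-axis models with hpavv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying and validating HPA-axis models with hpavv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpavv)
library(ggplot2)
```

## The problem

Differential-equation models of the hypothalamic-pituitary-adrenal (HPA)
axis describe the hormonal cascade CRH → ACTH → cortisol, its negative
glucocorticoid feedback, circadian forcing from the suprachiasmatic
nucleus, and the acute response to stressors. Such models are routinely
published with hand-tuned parameters and qualitative figure comparisons;
deciding whether a given model actually represents stress-test data — and
whether parameters fitted to one subject transfer to another — requires a
reproducible verification-and-validation (V&V) pipeline: a solver that
handles both ODE and delay (DDE) systems, a cost function that is
comparable across models living on different concentration scales, a
global optimizer for bounded parameter calibration, and a protocol for
repeating and aggregating fits across subjects.

`hpavv` packages that pipeline. Models enter through a declarative plugin
contract (`model_spec()`): states, a parameter table with bounds and
optimization flags, delays, drivers and an output map tying observable
hormones (ACTH, cortisol) to state variables. Three demonstration models
ship with the package — a minimal three-state cascade, a receptor-feedback
variant in which repression is sensed through the bound-receptor complex
with a positive receptor-production loop, and a delayed variant of the
minimal cascade. They are structural stand-ins: fully specified, tested,
and exercising every framework feature (Hill feedback, receptor dynamics,
delays), with defaults that are implementation constants rather than
literature estimates.

## The integrator

`solve_ode()` implements an explicit embedded Dormand–Prince 5(4) pair
with standard step control against the mixed tolerance
`atol + rtol * |y|` (defaults `rtol = 1e-6`, `atol = 1e-9`: well below
hormone-assay noise, well above double-precision granularity). Each
accepted step stores the quartic continuous extension, so the solution is
a piecewise polynomial evaluable anywhere in the span (`dense_eval()`),
exactly at mesh nodes. That dense output serves two masters: delayed-state
lookup for DDEs (method of steps) and the cost function's need to read the
simulation at the exact data times even though the step sequence is
adaptive.

Three details matter for correctness:

* **Forced mesh points.** Driver discontinuities — the on/off switches of
  a stress episode — are forced onto the mesh, so no step integrates
  across a jump in the right-hand side.
* **Lag-capped steps.** With declared positive lags the step size never
  exceeds the smallest lag, so a delayed lookup always lands in
  already-accepted history (or the user-supplied history function for
  times at or before the start).
* **Propagated breakpoints.** A DDE's derivative discontinuity at the
  start propagates to `t0 + k1*tau1 + k2*tau2 + ...`; these points are
  forced onto the mesh up to total order 4, beyond which the solution is
  smoother than the method order. On the classic test problem
  `y'(t) = -y(t-1)` with constant history this yields the method-of-steps
  polynomial to machine precision at default tolerances.

Stiff systems, state-dependent or distributed delays, and event detection
are out of scope; the demonstration models are non-stiff by construction.
Integration failures (step-size underflow under blow-up) are explicit
errors naming the time reached, which the calibration layer converts to an
infinite cost rather than an abort.

```{r dde}
sol <- solve_ode(function(t, y, lag) -lag(t - 1), y0 = 1, span = c(0, 3),
                 lags = 1)
c(y_1.5 = dense_eval(sol, 1.5), y_2 = dense_eval(sol, 2))
```

## The cost function

Validation compares splined simulation output against data on the
sampling grid of the Trier Social Stress Test (TSST): 11 blood draws at
−30, −15, 0, 10, 20 minutes around the 20-minute stressor and every
15 minutes for the following 90 (`tsst_time_grid()`). `sse_cost()`
fits a cubic interpolating spline through the simulated mesh values of
each hormone, reads it at the data times, normalizes, and accumulates
squared residuals.

Two conventions are genuinely ambiguous, so both are implemented and the
choice is recorded in every `CostBreakdown`:

* **Normalization referent.** The default (`"data"`) divides both the
  data and the simulation by the data mean — the literal reading of
  "normalized to the mean concentration of the respective data set": the
  absolute simulated scale is compared against the data scale. The
  alternative (`"shape"`) divides each side by its own mean, making the
  cost scale-free so models on arbitrary concentration scales become
  comparable purely by shape. Neither is asserted to be the "right"
  reading; the switch exists because both are defensible.
* **Averaging.** The default divides the sum of squared normalized
  residuals by both the number of time points N and the number of
  hormones H, giving a mean that is comparable across datasets of
  different lengths; `averaging = "printed"` divides by H only (the sum
  over points, halved for two hormones). Cortisol-only basal records are
  the degenerate case H = 1 of the same formula.

The spline uses base R's exact-cubic (Forsythe–Malcolm–Moler) end
conditions, which reproduce affine and cubic polynomials exactly — the
property that matters for interpolation fidelity between solver mesh
points. Two alternative distance measures, `max_max_cost()` and
`mean_max_cost()` (the maximum and the mean over hormones of the largest
absolute normalized residual), are provided for comparison; the
squared-error cost is the default throughout because it is the one the
repeated-fit protocol aggregates.

## Calibration and the validation protocol

`differential_evolution()` is a self-contained rand/1/bin implementation:
uniform initialization within bounds, per-candidate dithered mutation
factor in [0.5, 1), binomial crossover at rate 0.7, greedy selection,
candidates clipped to bounds, non-finite objective values treated as
+∞ and counted. The default population size of 10 matches the validation
protocol; the generation budget is configurable because wall-clock cost is
dominated by repeated integration.

`evaluate_params()` defines the objective: initialize at the flat-driver
steady state (`steady_state()`, a damped Newton iteration with numerical
Jacobian, residual below 1e−10), pre-roll the model for a burn-in
(default one simulated day) so the state reaches the periodic attractor of
the circadian drive before the stressor, then integrate across the
subject's grid and score. The model's default parameter vector is injected
into every initial DE population, which guarantees the optimized cost
never exceeds the default-parameter cost — the qualitative comparison the
validation table is built on.

`run_validation()` repeats the optimization (default five independent
repeats with distinct seeds); `batch_over_subjects()` runs the protocol
over a dataset selection — by default subjects 1, 10, 20, 30, 40, 50 and
the cohort mean profile, i.e. seven datasets and 35 runs — and aggregates
per-dataset mean ± SD and best single cost plus the overall score, the
mean of per-dataset means, so every dataset weighs equally.
`generalization_matrix()` evaluates saved parameter sets against every
subject of a cohort, with group-wise summaries, to ask whether parameters
fitted to one subject transfer to others; failures become `Inf` cells
rather than aborts.

```{r validate, eval = FALSE}
model <- hpa_model_minimal()
cohort <- synth_tsst_cohort(58, seed = 1)
report <- batch_over_subjects(model, cohort, repeats = 5, popsize = 10,
                              generations = 40, base_seed = 1)
glance(report)
autoplot(report)
```

## The synthetic cohort generator

No clinical data ships with the package; the generator emulates the
structure of a TSST study so the whole pipeline is testable offline.
Per subject it draws log-normal baselines (medians 20 pg/mL ACTH,
8 µg/dL cortisol — units are metadata only, since normalization makes
downstream numbers unit-free), a response amplitude, a peak time inside
the 10–35 min window with the ACTH peak drawn first and the cortisol peak
5–10 minutes later, and an exponential return rate chosen so the final
110-minute sample lands within a drawn 3–12% of baseline. Measurement
noise is multiplicative log-normal (CV 12% by default), reflecting
scale-proportional assay error and guaranteeing positivity. Group effects
are coarse literature-motivated contrasts: elevated baseline cortisol with
larger responses in melancholic depression, blunted responses in atypical
depression. The default composition is 15 controls and 43 MDD subjects
(the subtype split 15/14/14 is a package choice; the study design this
emulates does not publish per-subtype counts).

A configurable fraction of subjects are *anomalous responders* modeled on
the study's patient 1: ACTH strictly decreasing across the entire grid
while cortisol peaks 30 minutes after the stressor ends (grid point +50).
Anomalous ACTH is drawn as a noisy exponential decline and then sorted
decreasing — the sorting is what makes the monotonicity strict, a
deliberate idealization. The anomalous subjects occupy the first ids, so
subject "1" is the anomaly in a default 58-subject cohort.

`synth_basal_series()` generates 24-hour resting profiles: a cosine
circadian envelope peaking at 8 AM modulates 12–18 Gaussian secretory
pulses whose spacing is proportional to draws from the 60–90 min ultradian
period range (scaled to fit the day — twelve episodes cannot literally be
60–90 minutes apart over 24 hours), with ACTH leading cortisol by about
10 minutes and little secretion between pulses, sampled at the 10-minute
basal schedule. The default series carries no measurement noise: it is a
secretion profile, and the episode count is read off its local maxima.

What passing tests on these cohorts do **not** show: real assay error is
not exactly log-normal, real anomalies are not sorted-monotone, real
group differences are richer than two multipliers, and the generator's
peak-and-return shape is built in rather than emergent — so shape-recovery
tests validate the pipeline, not any biological claim.

## Demonstration-model defaults and identifiability

The demonstration models' defaults are implementation constants chosen for
two properties: a strictly positive flat-driver steady state with a
peak-and-return response to the canonical 20-minute stressor (cortisol
peaks within the sampling window and returns to within 5% of baseline by
four hours), and *practical identifiability* of the three free parameters
of the minimal model (`k_c`, CRH drive gain; `K_i`, feedback constant;
`w_f`, cortisol clearance) from a single TSST record.

Identifiability is the delicate part. Steady-state levels constrain only
one combination of `k_c` and `K_i` (the production term
`k_c / (1 + (F*/K_i)^n)` is a single number at equilibrium), so separating
them relies entirely on the stress transient. In a high-feedback-gain
regime the combination `k_c * K_i^n` is almost exactly degenerate and no
optimizer can recover both from noisy data. The defaults therefore place
the resting state below the knee of the feedback nonlinearity
(`F*/K_i ≈ 0.55`, Hill coefficient n = 6, the high cooperativity typical
of minimal HPA models) while the canonical stressor (amplitude 10 over the
baseline drive) pushes cortisol past the knee (peak `F/K_i ≈ 1.4`), and
keep the ACTH-equation feedback weak (`F*/K_i2 ≈ 0.5`). Baseline levels
then pin `k_c`, the saturating peak pins `K_i`, and the post-test decay
pins `w_f`. Under this design, differential evolution recovers all three
parameters from noiseless TSST-grid data essentially exactly, and to
within 25% under 10% multiplicative observation noise in the large
majority of noise realizations.

The circadian drive default amplitude is 0.1 around a mesor of 1 (peak at
8 AM, i.e. −540 min in TSST-relative time where the stressor starts at
17:00): large enough to exercise the SCN-drive pathway, small enough that
a steady state computed with the drive frozen at its mesor is an adequate
starting point after the burn-in pre-roll.

## Numerical choices and problem sizes

* Steady states: damped Newton with numerical Jacobian to residual
  1e−10, falling back to a 5000-minute relaxation integration when the
  initial guess is poor; nonnegativity is enforced, failure is explicit.
* Default integrator tolerances `rtol = 1e-6`, `atol = 1e-9`; the cost of
  a converged solution changes by less than 1e−6 under tolerance
  refinement, so the optimizer never chases integrator noise.
* DE ties are broken toward the trial vector (`<=` selection), the
  standard choice that lets the population drift across plateaus;
  population-spread termination is off by default (budget-bound runs).
* Validation seeds derive deterministically from one base seed
  (dataset-major, repeat-minor), so any report is reproducible from its
  manifest; every command writes that manifest (config, seeds, versions,
  file hashes) next to its outputs, and figures are rendered only from
  the tables that are saved.
* The test-suite and acceptance protocols use reduced problem sizes
  chosen as the package's own defaults for a laptop-scale run: the
  seven-dataset protocol runs 35 optimizations at population 10 for six
  generations with a 240-minute burn-in; the recovery study uses
  population 15 with 150 generations (noiseless) and 60 (noisy);
  tolerance oracles run at the defaults. Production runs would raise the
  generation budget and burn-in (one simulated day) without touching the
  protocol shape.

## Known limitations

* The five literature models the original study compared are defined in
  their own publications; here the plugin contract plus three structural
  stand-ins take their place, and real model files can be registered
  through the same contract without touching the framework.
* No stiff solver: a model whose calibration excursions enter stiff
  regimes will report integration failures (as infinite costs) rather
  than integrate slowly.
* The spreadsheet-facing result store is plain CSV (parameters and
  sampled solutions per run) — openable in any spreadsheet program and
  reloadable losslessly, but not a multi-sheet workbook.
* Basal-schema data share the TSST cohort table layout with clock-minute
  times; a dedicated basal schema (evening/morning windows) would be a
  straightforward extension if real basal records are ingested.
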