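---
title: "A personalized model of thyroid hormone regulation and replacement dosing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A personalized model of thyroid hormone regulation and replacement dosing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hptsim)
```

## The problem

Hypothyroid patients are treated with oral levothyroxine (LT4), sometimes
combined with liothyronine (LT3), and the dose is titrated until serum TSH
returns to its reference interval. Titration is slow (weeks per step) and
the common 1.6 µg/kg starting rule systematically overdoses heavier
patients, because the plasma pool into which the drug distributes grows
*sublinearly* with body weight. `hptsim` implements a mechanistic model of
the hypothalamic–pituitary–thyroid (HPT) axis whose distribution volumes and
T3 clearance are personalized from a patient's sex, height and weight, and
builds the clinical applications on top of it: simulated dose titration,
combination-therapy optimization, residual-thyroid-function (RTF) analysis,
and maximum-likelihood quantification of the model itself.

## The compartmental model

The dynamical core is a 19-state compartmental model of the HPT axis in
amount units (µmol; TSH in model units, converted to mU/L on output):

* plasma, fast-tissue (liver/kidney) and slow-tissue pools for T4 and T3,
  exchanging via free-hormone fractions given by cubic binding polynomials
  of plasma T4;
* deiodinase conversion of T4 to T3 in fast (Michaelis–Menten `VmaxD1fast`,
  `KmD1fast`) and slow tissues, and irreversible T3 clearance `k05` from the
  fast pool;
* a lumped "brain T3" signal `T3B` with a first-order lag `T3B_lag`, driven
  by plasma T4 (through the conversion gain `f4`) and plasma T3;
* pituitary TSH with circadian, Hill-saturated secretion (below), and a
  six-stage delay chain through which plasma TSH drives thyroidal T4/T3
  secretion (`S4`, `S3`);
* pill → gut → plasma absorption chains for oral LT4 and LT3
  (bioavailability 0.88), plus an optional constant-rate T3 infusion
  emulating slow-release preparations.

TSH secretion uses saturating Hill kinetics in the lagged brain T3 signal
`x`:

$$SR_{TSH}(t) = \left[B_0 + A_0\, f_{CIRC}(x)\,
  \sin\!\left(\tfrac{\pi}{12}t - \phi\right)\right]
  \frac{K_{SRTSH}^m}{K_{SRTSH}^m + x^m},\qquad
  f_{CIRC}(x) = \frac{x^n}{x^n + K_{circ}^n}.$$

Two properties matter clinically: the rate *saturates* at `B0 = 450` as
brain T3 falls (instead of growing without bound), which caps untreated TSH
at a plateau near 1000 mU/L; and the circadian amplitude vanishes with
brain T3, reproducing the loss of the TSH daily rhythm in severe
hypothyroidism. The brain conversion gain is likewise a Hill function,
`f4 = k3 (1 + 5 K_{f4}^l / (K_{f4}^l + T3B^l))`, falling from `6 k3` to
`k3`. Defaults for every constant are in `hpt_params()`; parameter sets
serialize losslessly to YAML (`write_params()`).

## Personalization

Anthropometry enters through three quantities:

1. **Plasma volume.** An ideal-weight quadratic in height (per sex) gives
   the percent deviation $\Delta_{iBW}$; blood volume is
   $V_B = a\,(100+\Delta_{iBW})^{n_{bv}-1}\,BW$ liters with $a = 1.27$,
   $n_{bv} = 0.373$ (so blood volume *per kg* falls with excess weight),
   and $V_P = V_B(1-HEM)$ with hematocrit defaulting to 0.45 (male) / 0.40
   (female). $V_P$ is rescaled as $V_{Pnew} = 3.2\,V_P/V_{Pref}$, where
   $V_{Pref} \approx 2.77$ L is the average over a reference male
   (BMI 21.8, 1.76 m) and female (BMI 23, 1.67 m), so that reference
   patients keep the base model's 3.2 L.
2. **TSH distribution volume.** $V_{TSHnew} = 5.2 + (V_{Pnew} - 3.2)$:
   the 2 L non-vascular TSH space is held fixed.
3. **T3 clearance.** `k05` scales allometrically,
   $k_{05,new} = [C_M]\,k_{05}\,(BW/BW_{ref})^{3/4}$, with the factor
   $C_M = 1.05$ on the male branch only and sex-specific reference weights
   $BW_{ref} = BMI_{ref} H_{ref}^2$.

**Where the volumes act** is a genuinely open design point, because the
base equations are calibrated at the reference volumes. We place them so
that the *regulatory feedback senses concentrations*: every
concentration-dependent nonlinearity (binding polynomials, brain uptake,
TSH degradation saturation) is evaluated at volume-normalized amounts
$x = q\,V_{ref}/V_{new}$, and TSH secretion scales with $V_{TSHnew}$ so the
regulated TSH *concentration* is volume-invariant (every patient's
untreated plateau is ≈ 914 mU/L). Doses and thyroidal secretion stay in
amount units, so a larger plasma pool genuinely requires a larger dose.
The TSH derivative uses $V_{TSHnew}$ and the T4/T3 plasma conversions use
$V_{Pnew}$. A consequence we report rather than hide: because `k05` varies
as $BW^{3/4}$ while T3 production is nearly size-invariant, untreated
steady-state T3 (and to a lesser degree T4) retains a 15–30% spread across
BMI 18.5–35; the RTF *shape* and the TSH plateau are volume-invariant, but
pointwise overlap of RTF curves across BMI holds only to within a few
percent, not to 1%.

## Numerics

The right-hand side is implemented in C (registered with `deSolve`), with
an R transcription (`hpt_rhs()`) kept for verification; the two integrate
identically to solver precision. Integration uses `lsoda` with
`rtol = 1e-6`, `atol = 1e-9` (TSH spans four orders of magnitude across
scenarios). Oral doses are bit-exact boluses added to the pill compartment
at each administration time via integrator restart events, never smoothed
forcing functions. States are physically non-negative: sub-tolerance
negative excursions are clipped to zero inside the RHS; anything below
−10⁻⁶ aborts with a state dump.

The euthyroid initial condition (`initial_condition()`) is the algebraic
root of the *cycle-averaged* RHS (oscillatory term set to its zero mean),
found by long averaged integration polished with a Broyden root solve.
Starting the circadian system there, day-averaged hormones sit within ~1.5%
of the limit cycle's own means and settle onto them over a few weeks; this
averaging error is measured in the test suite, and steady-state summaries
(`steady_state()`, default 50 days) flag non-convergence when consecutive
daily means differ by more than 0.5% (with small absolute floors — 10 µg/L
T4, 0.2 µg/L T3, 0.1 mU/L TSH — so that hormones decaying to zero after
thyroidectomy are not flagged forever). The slowest mode is the
hypothyroid brain-T3 lag (`fLAG ≈ 0.0034`/h, time constant ~12 days), so a
few heavily dosed scenarios sit marginally above the flag at 50 days; they
are excluded from optimizer argmins per contract.

## Dose optimization

* `optimize_lt4_tsh()`: simulates each candidate dose of the 62.5–325 µg
  grid (12.5-µg tablet steps) for 42 days in a thyroidectomized patient
  (`rtf = 0`) starting from their euthyroid state, and picks the dose whose
  *end-of-course* TSH (a trough for once-daily dosing; the sensitivity to
  this sampling choice is below the 12.5-µg grid resolution in our checks)
  is closest to the 1.8 mU/L target. Ties break to the lower dose.
* `optimize_lt4_t4tsh()`: same sweep, scoring `|T4−a|/60 + |TSH−b|/4`; the
  divisors normalize the scale difference between the two variables, and
  the targets default to range midpoints.
* `optimize_combo()`: 2-D grid search (LT3 0–20 µg in 2.5-µg steps) under
  three schedules — once daily, twice daily (half-doses 12 h apart) and
  LT4 + constant T3 infusion — minimizing the symmetric normalized L1
  distance of the 50-day steady-state final-day means from the
  normal-range midpoints, $\sum_h |h - mid_h|/(width_h/2)$. The half-width
  normalization mirrors the 60/4 convention of the monotherapy objective.

Normal ranges (`normal_ranges()`) are configurable; defaults are TSH
0.5–4.5 mU/L, total T4 45–105 µg/L (upper bound from the model's reference
range; lower bound the standard 4.5 µg/dL assay limit) and total T3
0.8–2.0 µg/L (the standard 80–200 ng/dL interval). The T4 lower bound and
the T3 interval are assumptions, stated here because no printed values fix
them.

The 18 canonical combination scenarios (`combo_scenarios()`) cross sex
(heights fixed at 1.78/1.63 m) with BMI 18.5 / 23 / 27.5 (underweight
boundary, mid-normal, midpoint of the overweight class) and the three
schedule–RTF pairings (daily at RTF 10%, twice daily at 15%, infusion at
25%). Two caveats from running this sweep, reported as findings: (i) the
objective surface is a flat ridge along the LT4↔LT3 trade-off, so the
formal argmin can land at neighboring grid corners whose scores differ by
<5%; (ii) because treated steady-state T3 inherits the allometric clearance
spread, the optimized LT3 spans the full 0–20 µg grid across these
scenarios (center 7.5–10 µg) rather than a narrow band, with the grid floor
selected for underweight women and the ceiling for overweight men. The LT4
optima are tighter: ≤100 µg/day for men, ≤87.5 µg/day for women across all
scenarios. Lower-dose tie-breaking is clinical conservatism.

`dose_accuracy()` scores a predicted dose as correct within 12.5 µg (one
tablet step, boundary inclusive) of the empirical dose, with cohort
summaries in the BMI bins ≤26, 26–32, ≥32 (`cohort_accuracy()`). The
protocol is self-consistent by construction: scoring the optimizer against
itself (zero jitter) yields accuracy 1 in every bin.

## Residual thyroid function

`rtf_curve()` maps RTF (thyroidal secretion scaled by a factor in [0, 1])
to untreated 50-day steady-state hormones on a grid (default 0–0.5, step
0.01; heights 1.78/1.63 m, BMI via weight). Over this range TSH is
strictly decreasing and T4/T3 strictly increasing in RTF, so the curve is
invertible: `estimate_rtf()` uses monotone piecewise-cubic interpolation
(exact at grid nodes) to read an individual's unmeasurable RTF off their
pre-treatment hormone values, with boundary clamping and, for a full
T4/T3/TSH triple, a least-squares-consistent consensus across channels.

## Maximum-likelihood estimation

`fit_parameters()` minimizes the independent-Gaussian negative
log-likelihood with channel-specific standard deviations,

$$\sum_{i \in \{T4, T3, TSH\}} \frac{n_i}{2}\log 2\pi + n_i \log\sigma_i +
\sum_j \frac{w_{ij}(y_{ij} - \mu_{ij})^2}{2\sigma_i^2},$$

over any subset of the 17 estimable parameters. The σ's are profiled out
in closed form at every evaluation (their MLE is the weighted RMS
residual, which is also the stationarity condition of the likelihood), the
simplex search runs on log-parameters to enforce positivity, and a fixed
number of deterministically perturbed restarts guards against stagnation.
`scale_tsh_points()` implements the emphasis of selected TSH observations
(canonically the two highest and two lowest of the initial trajectory,
indices 9/13/24/28, × 100); we treat the scaling as an observation
*weight* by default — value-scaling is available — because weights
preserve unit coherence. `parameter_cvs()` converts the numerical Hessian
at the optimum into %CVs (`100·SE/estimate`), with per-parameter rescaling
for conditioning; flat directions give `NA` with a warning. `calibrate_b0()`
implements the plateau calibration: pick a plausible maximum TSH (300–1000
mU/L; individual data above ~300–500 are censored by assay dilution
ceilings) and adjust `B0` by secant iteration until the simulated
thyroidectomy plateau matches.

Because the original clinical datasets are not redistributable, the
estimation machinery is validated on synthetic data only (below); the
package makes no attempt to reproduce published point estimates.

## Synthetic data, and what passing tests do not show

`synth_blood_volume_data()`, `synth_cohort()` and `synth_timecourses()`
generate, deterministically per seed: per-kg blood-volume scatter on the
two-parameter curve (±3 ml/kg Gaussian noise by default); anthropometric
cohorts (sex Bernoulli(½), heights N(1.76/1.63, 0.07) m, BMI log-normal
with median 26 — invented distributions, chosen as plausible for an adult
surgical population, not estimated from any dataset); and noisy hormone
time courses under protocol designs such as the euthyroid oral-challenge
design (400/450/600 µg LT4 at hour 24 of a 5-day course).

These generators emulate the *structure* of the corresponding clinical
data, not their biology: noise is Gaussian and independent, adherence is
perfect, there are no assay floors/ceilings, no diurnal sampling bias, and
"empirical" cohort doses are the model's own optimum plus tablet jitter.
Parameter-recovery and self-consistency tests therefore demonstrate that
the estimators and scoring protocols are correctly implemented — not that
the model is correct for real patients, which only the withheld clinical
data could show.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full 22-dose monotherapy
sweeps, the complete 18-scenario × 198-dose-pair combination sweep
(~3,600 50-day courses, a few minutes on one CPU thanks to the compiled
RHS), RTF grids at 0.1 steps with three BMIs per sex, and two-parameter
(`S4`, `k05`) noise-free recovery fits on three-arm challenge data.
Finer RTF grids (0.01) and larger fits run in minutes and are exposed
through the same interfaces.

## Known limitations

* The combination-therapy objective formalizes "incremental adjustment to
  near the midpoints" as a global argmin; on its flat ridge the two are
  not equivalent, and the LT3 optima inherit the model's allometric T3
  spread (see above).
* RTF curves are BMI-invariant only to within a few percent (T3 worst);
  the TSH plateau and curve shapes are invariant.
* No meal/fasting absorption effects, adherence modelling, TRH dynamics,
  drug interactions, pediatric or pregnancy anthropometry.
* Free-hormone fractions are reported implicitly through totals; the model
  tracks total T4/T3.
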