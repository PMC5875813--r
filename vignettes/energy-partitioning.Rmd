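---
title: "Energy-system partitioning for low-intensity cycling with blood-flow restriction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-system partitioning for low-intensity cycling with blood-flow restriction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfrenergetics)
```

## The problem

Endurance exercise performed at low intensity (about 40% of maximal oxygen
uptake) with a pneumatic cuff partially occluding leg blood flow (blood-flow
restriction, BFR) elicits cardiorespiratory and metabolic responses that the
same exercise without the cuff does not. To quantify *where* the extra energy
comes from, the session's total energy expenditure is partitioned into three
energy systems, each estimated from a different physiological signal:

* **Aerobic**: the oxygen actually consumed during exercise. It is the area
  under the breath-by-breath V̇O~2~ curve over the exercise bout minus the
  resting baseline times the bout duration.
* **Anaerobic alactic** (phosphocreatine): the oxygen equivalent of the fast
  component of excess post-exercise oxygen consumption (EPOC). Recovery
  V̇O~2~ is fitted with a mono-exponential decay and the fast component's
  volume is the amplitude times the time constant.
* **Anaerobic lactic** (glycolytic): the oxygen equivalent of net blood
  lactate accumulation, at 3 mL O~2~ per kg body mass per mmol·L^-1^.

Total energy expenditure is the exact sum of the three oxygen volumes,
converted to kJ with a caloric equivalent.

## The off-kinetics model

Recovery oxygen uptake is modelled as

$$
\dot{V}O_2(t) = \dot{V}O_{2,\mathrm{baseline}} + A_1\, e^{-(t - t_d)/\tau_1},
\qquad t \ge t_d,
$$

with a plateau at $\dot{V}O_{2,\mathrm{baseline}} + A_1$ for $t < t_d$
(continuity at the delay). Time is measured in minutes from exercise
cessation. Only the fast component is modelled; slow-component EPOC is out
of scope. The anaerobic alactic volume is $A_1 \tau_1$ (L·min^-1^ × min =
L O~2~), which equals $\int_{t_d}^{\infty} (\dot{V}O_2(t) -
\mathrm{baseline})\,dt$.

Some typeset sources render the exponent of this model ambiguously (an
apparent $e^{1-(t-t_d)/\tau_1}$). Read literally, that form makes
$\dot{V}O_2(t_d) = \mathrm{baseline} + e\,A_1$, contradicting the
description of $A_1$ as the amplitude, so the package implements the
standard decay and exposes the literal reading behind
`fit_off_kinetics(..., exponent = "as_printed")` for sensitivity analysis
(both the plateau and the alactic volume then gain a factor of $e$).

### Fitting

`fit_off_kinetics()` minimises the unweighted residual sum of squares on the
raw recovery breaths of the first 10 min after exercise (no pre-smoothing).
For fixed $(\tau_1, t_d)$ the model is linear in
$(\mathrm{baseline}, A_1)$, so those two parameters are profiled out in
closed form (variable projection) and only $(\tau_1, t_d)$ are searched, by
Nelder-Mead from a fixed 3 × 3 multistart grid ($\tau_1 \in \{0.3, 0.75,
1.5\}$ min, $t_d \in \{0, 0.25, 0.5\}$ min) with a relative convergence
tolerance of 10^-14^ on the objective. Bounds — $A_1 \in [0, 10]$ L·min^-1^,
$\tau_1 \in (0.05, 10]$ min, $t_d \in [0, 2]$ min, baseline $\in [0, 2]$
L·min^-1^ — are enforced by rejection in the outer search; in the rare case
the profiled linear solution leaves its box, a bounded four-parameter
L-BFGS-B refit is used. If every start fails, deterministic jittered
restarts derived from the `seed` argument are tried before erroring with
the best attempt attached.

On noiseless data generated by the model itself, the fit recovers all four
parameters to well below 10^-4^ relative error (the residual surface has an
exact zero), and the tests verify this.

### An identifiability caveat

Breaths arrive every ~3 s. If a subject's true $t_d$ is shorter than the
arrival of the first recovery breath, no observation lies on the pre-delay
plateau and $(A_1, t_d)$ are jointly unidentifiable on noiseless data: every
$t_d' \in [0, t_{\text{first}}]$ with $A_1' = A_1 e^{(t_d - t_d')/\tau_1}$
fits exactly, because the curves coincide from the first breath onwards.
The practical consequence is a few-percent ambiguity in $A_1$ (and hence the
alactic volume) for subjects with very short delays. Tests that assert exact
round-trip recovery therefore pin the simulated $t_d$ at 0.1 min, just above
the breath interval; the generator's default $t_d$ distribution keeps the
physiological spread, ambiguity included.

## Gas-exchange conventions

* V̇O~2~ is stored in L·min^-1^ (STPD); readers accept mL·min^-1^ and
  mL·kg^-1^·min^-1^ (with body mass) and convert on ingest.
* Windows are half-open `[start, end)`, in seconds from session start.
  Phase-windowed means (e.g. 5-min heart-rate averages) and the rest
  baseline are arithmetic means of the breaths covered by the window.
* The resting baseline is the mean V̇O~2~ over the **final 120 s of rest**
  (configurable). Early seated rest is discarded as un-steady; the choice of
  window is a convention, since protocols only specify "about 5 min" of
  rest.
* Integrals (the aerobic volume) first interpolate breaths linearly to a
  1-s grid anchored at the exercise-phase start, then use the trapezoidal
  rule; breath-by-breath data are unevenly spaced and this makes the
  integral independent of local breath density.
* Because breath timing is jittered, the last breath of a phase falls up to
  one interval short of the nominal boundary; span preconditions ("exercise
  covers 30 min", "recovery covers 10 min") allow a 10-s slack, and the
  recovery span is measured as coverage since exercise end.
* Missing heart-rate or ventilation breaths are allowed and never imputed.

## Lactate conventions

Net accumulation is the **peak** of the post-exercise samples (0, 3, 5,
7 min) minus the pre-exercise value; the 15-min exercise sample is kept for
reporting but never enters the peak. A negative net accumulation (peak below
pre, possible under measurement noise) is clamped to zero with a warning —
a negative lactic energy has no physical meaning — and the clamp can be
switched off for diagnostic work.

The caloric equivalent defaults to 20.92 kJ·L^-1^ O~2~ (≈5 kcal·L^-1^, the
conventional constant at moderate intensity) and is configurable and
reported in every partition, since published totals rarely state the
constant they used.

## The synthetic crossover generator

`simulate_crossover_trial()` generates the data the analysis assumes: a
cohort of subjects, each completing one session with and one without
restriction. It exists both as a testbed (it carries per-session ground
truth for every pipeline stage) and as the package's statement of the study
conditions it targets.

* **Population** (`make_population()`): independent truncated normals,
  body mass 82.8 ± 12.6 kg, V̇O~2max~ 33.4 ± 4.6 mL·kg^-1^·min^-1^,
  age 24.5 ± 4.0 y — a sedentary young-male cohort — plus resting V̇O~2~
  0.30 ± 0.04 L·min^-1^ (≈3.5 mL·kg^-1^·min^-1^ at the mean mass),
  on-kinetics τ 0.50 ± 0.08 min, off-kinetics A~1~ 0.60 ± 0.10 L·min^-1^,
  τ~1~ 0.75 ± 0.12 min, t~d~ 0.08 ± 0.04 min, resting lactate 1.25 ± 0.45
  mmol·L^-1^, resting heart rate 68 ± 7 beats·min^-1^. Covariances between
  parameters are unknown for this population, so independence is assumed
  and documented.
* **Sessions**: 5 min rest, 30 min constant load, 10 min recovery; breaths
  every 3 ± 0.5 s (uniform jitter). Exercise V̇O~2~ rises
  mono-exponentially to a steady state of 40% of absolute V̇O~2max~ (which
  implies ≈75 W at the mean subject via the 10.8 mL·min^-1^·W^-1^ cycling
  economy constant); recovery decays with the subject's own off-kinetics
  parameters, clocked from the last exercise breath. Heart rate and
  ventilation follow analogous on/off kinetics.
* **Restriction effects** (`condition_effects()`): under BFR the lactate
  rise gains +1.0 mmol·L^-1^ (on a 0.7 mmol·L^-1^ unrestricted rise, so the
  two conditions peak near 2.0 and 2.9 mmol·L^-1^ on a ~1.25 mmol·L^-1^
  resting value), steady-state V̇O~2~ gains +0.05 L·min^-1^, heart rate
  +8 beats·min^-1^, ventilation +4 L·min^-1^; the alactic parameters are
  deliberately untouched, so the expected pattern is higher aerobic, lactic
  and total energy under restriction and no systematic alactic difference.
* **Noise**: Gaussian, per breath 0.03 L·min^-1^ (V̇O~2~), 2 beats·min^-1^
  (HR), 1 L·min^-1^ (V̇E); per lactate sample 0.12 mmol·L^-1^ (consistent
  with a test-retest typical error of ≈0.07 mmol·L^-1^, since
  TE = SD~diff~/√2).
* **Seeding**: one trial seed expands to fixed per-subject / per-channel /
  per-condition substreams. Breath *timing* is seeded per subject only, so
  the two conditions of a subject share breath times; channel *noise* is
  seeded per condition, so measurement error is independent between
  sessions — which is what makes null simulations (all effects zero) reject
  at the nominal α in the paired t.

What the generator does **not** emulate: slow-component EPOC drift,
correlated parameters, lactate kinetics between samples (only the sampled
schedule has meaning), movement artefacts, or device-specific breath
detection. Passing tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to every feature of real
metabolic-cart data.

## Crossover statistics

* `paired_t()` — two-sided paired t on condition differences (B − A),
  delegating to `stats::t.test()`; zero-variance edge cases are handled
  explicitly (identical vectors: t = 0, p = 1; constant non-zero
  difference: flagged degenerate).
* `rm_anova()` — balanced two-way repeated-measures decomposition via
  `stats::aov()` with `Error(subject/(condition*time))`; each effect is
  tested against its own subject-interaction stratum. Sphericity is
  assumed (no Greenhouse–Geisser correction), flagged in the result
  attributes; unbalanced or incomplete layouts error rather than impute.
  A stratum with zero effect *and* zero error variation reports F = 0.
* `bonferroni()` — min(1, p·m) via `stats::p.adjust()`; the intended family
  is the per-time-point between-condition comparisons after a significant
  interaction or main effect, so m = number of time points.
* `typical_error_cv()` — TE = SD(differences)/√2 and CV = 100·TE/grand
  mean; a zero grand mean errors rather than returning an undefined CV.

Normality and variance-homogeneity pre-tests are deliberately not wrapped:
callers can run `shapiro.test()` / `car::leveneTest()` themselves and the
package does not gate its statistics on them.

## Incremental-test utilities

The ramp protocol (50 W + 15 W·min^-1^ to 200 W, then 10 W·min^-1^),
maximality criteria (≥2 of: V̇O~2~ plateau, RER > 1.1, HR ≥ 90% of 220 −
age, RPE > 17 — the RPE cut-off is strictly greater), %V̇O~2max~
arithmetic, and cuff prescription (rounded to integer mmHg) are direct
transcriptions of standard practice. Two operationalisations are worth
noting:

* The **plateau** criterion is quantified as ΔV̇O~2~ < 150 mL·min^-1^
  between the final two stages (`vo2_plateau()`), configurable — published
  protocols state "a plateau" without a number.
* **Threshold detection** (`detect_breakpoint()`) replaces the human raters
  of standard practice with a reproducible surrogate: a continuous
  two-segment piecewise-linear fit over a grid of candidate breakpoints at
  interior predictor values, accepted only if it beats the single line by
  an F-ratio test (2 numerator df, α = 0.05). A perfectly linear input is
  short-circuited to "not found" before the F-ratio, which would otherwise
  be 0/0. For the respiratory compensation point, a falling expired-CO~2~
  fraction after the breakpoint is checked when that channel is supplied,
  and skipped otherwise. This is a surrogate, not a re-implementation of
  rater judgment.

## Problem sizes used by the test-suite

The tests run the noiseless kinetics round trip on a 10-min, 3-s-spaced
trace; noisy parameter recovery on 100 seeded replicates; conservation and
monotonicity on 1000 seeded single-session partitions; the crossover effect
pattern on 20 seeded 12-subject trials; and the paired-t null size on 1000
replicates of 12 pairs. These sizes were chosen to make sampling noise in
the checked proportions small relative to the margins being asserted.

## Known limitations

* Absolute energy totals depend on the caloric equivalent, which published
  work often leaves unstated; comparisons across studies should use the
  reported constant.
* The alactic estimate inherits the t~d~ identifiability ambiguity above
  and, like all fast-EPOC methods, attributes the whole fast component to
  phosphocreatine resynthesis.
* The lactate-to-oxygen equivalence (3 mL·kg^-1^ per mmol·L^-1^) is a
  population constant; per-subject deviations are not modelled.
* The segmented-regression threshold detector assumes a single breakpoint
  on a monotone ramp and is not validated against human raters here.
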