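---
title: "Generative models of systematic reach biases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative models of systematic reach biases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachbias)
```

## The problem

When people make rapid center-out reaches to visual targets without
feedback, their endpoints deviate from the targets in a way that is highly
systematic: plotted against target direction, the angular error traces a
smooth, idiosyncratic but stable "bias function". Competing explanations
locate the error at different processing stages — a distortion of the
perceived target location, a misperception of the hand's starting position
(in endpoint or joint coordinates), a systematic error in translating
visually defined positions into the proprioceptive coordinates used for
motor planning, or a distortion of perceived depth. These accounts are
difficult to separate by goodness of fit alone, but they make qualitatively
different predictions about the *shape* of the bias function — in
particular its number of peaks over the circle — and about how the function
changes across experimental scenarios (start position visible, hidden, or
displaced; reaches with either hand; before and after implicit visuomotor
adaptation). `reachbias` implements the full model family, the scenario
logic, maximum-likelihood fitting with BIC comparison, the post-adaptation
shift analysis, the reliability statistics, and a seeded synthetic cohort
generator so that the complete pipeline can be exercised and validated
without access to behavioral recordings.

Conventions throughout: angles in degrees with 0° at 3 o'clock and
counterclockwise positive; positions in cm in a start-centered frame;
angular bias positive = counterclockwise; radial (extent) bias in cm,
defined as the planned movement length minus the target radius.

## The model family

**Target bias (TG).** The perceived direction of the target is attracted
toward the diagonal axes (45°, 135°, 225°, 315°). With `x' = angle mod 90`,
the bias is piecewise linear: `b·x'/a` for `x' < a`, falling linearly from
`+b` at `x' = a` to `−b` at `x' = 90 − a`, and `−b·(90 − x')/a` beyond.
Parameters: the transition-zone half-width `a` (degrees, 0 < a < 45) and
peak bias `b` (degrees). The function has period 90° and therefore four
peaks over the circle, and it is mirror-symmetric across the vertical
meridian — the two hands should show superimposable functions if this is
the only source of bias.

**Vector-based proprioceptive bias (PV).** The unseen hand is misperceived
by an error vector `(x_e, y_e)` (cm); the motor plan runs from the
perceived start to the target and is executed from the true start. A
constant planning-vector offset produces a single-peaked angular bias
function and a sinusoidal radial bias.

**Joint-based proprioceptive bias (PJ).** Movements are planned as shoulder
and elbow angle changes of a planar two-link arm (segment lengths
`l1 = l2 = 24` cm, shoulder at the origin, hand position
`[l1 cos θ + l2 cos φ, l1 sin θ + l2 sin φ]`, admissible postures
`π > φ > θ > 0`). The initial posture `(θ0, φ0)` is misperceived by
`(θe, φe)`; joint changes are solved (closed-form inverse kinematics, with
the admissibility constraint enforced to 1e-9 rad) such that the *perceived*
hand would land on the target, then executed from the *true* posture.
Veridical perception short-circuits to exactly zero bias. The model
predicts a single-peaked angular function and makes no movement-extent
prediction.

**Transformation bias (TR).** Visually coded positions must be transformed
into proprioceptive coordinates before planning. The transformation error
at position `p` has a fixed direction `(x_e, y_e)` (per cm) and magnitude
proportional to the Euclidean distance `d` from `p` to a body reference
point `(x_r, y_r)` near the shoulder: `T(p) = d·(x_e, y_e)`. The plan is
the vector between the transformed target and the transformed start:
`plan = (target + T(target)) − (start + T(start))`. With a visible start
this predicts a two-peaked angular *and* radial bias function.

**Visual depth bias (TGD).** Viewing the display at an oblique angle
distorts perceived depth: `y ↦ y + k·y + c` (gain `k`, offset `c` in cm),
applied to both the target and the start. Because both positions receive
the same offset `c`, it cancels out of the pure-TGD motor plan, which
therefore depends only on `k`; `c` does matter inside the TR+TGD hybrid,
where it displaces the start position that the transformation stage sees.

**Hybrids.** `PV+TG` and `PJ+TG` *add* their components' angular bias
functions. `TR+TG` and `TR+TGD` *compose*: the perceptual distortion is
applied first (the target rotated by the TG bias; target and start
displaced by the depth rule), and the transformation stage then operates on
the distorted positions. The target-bias distortion is applied to the
target only, not to the visible start: the diagonal attraction is defined
on target direction, and the start sits at the fovea during the hold
period.

### Scenario logic

The layout's `start_visibility` selects how the transformation stage treats
the start position:

* `visible` — both positions transformed (two-peaked function);
* `hidden` — the start is sensed proprioceptively and needs no
  transformation; only the target is transformed (single-peaked function);
* `perturbed` — the displayed start is displaced by a vector Δ from the
  true hand position before being transformed; opposite horizontal
  perturbations produce exact mirror-image bias functions.

A point worth documenting explicitly: in the `visible` scenario the
component of the transformation error shared by the start and the target
cancels out of the plan, so the peak-to-trough amplitude of the angular
bias function is nearly invariant to the workspace's distance from the
reference point (numerically it even grows slightly as the reference point
enters the workspace). The amplitude does collapse with proximity in the
`hidden` pipeline, where the start transformation is absent and the full
(distance-scaled) target transformation drives the bias. The package's
monotonicity test therefore runs the translation sweep in the hidden-start
scenario. An alternative reading of the planning rule — forcing the start
transformation to zero while keeping the start visible — is exposed as
`transformation_bias(..., t_start = "zero")` for auditing; under it,
visible- and hidden-start predictions coincide, which is why it is not the
default. The analogous sign ambiguity in the joint model's planning
equation is exposed as `joint_prop_bias(..., plan_displacement =
"as_printed")`.

### Peak counting

`count_peaks()` operationalizes "number of peaks": strict circular local
maxima on a uniform grid (default 1°, 360 samples) whose prominence —
height above the higher of the two adjacent valleys — is at least a
fraction (default 0.1) of the function's range. The prominence rule
discards floating-point micro-ripples without touching the qualitative
counts that separate the models: TG → 4, PV → 1, PJ → 1, TR with a visible
start → 2 (for angle and extent), TR with a hidden start → 1. These counts
are insensitive to the parameter values over a broad range; the package's
canonical demonstration parameters (`canonical_spec()`: TG `a = 10°,
b = 5°`; PV `(1.5, −1)` cm; PJ `θ0 = 50°, φ0 = 120°, θe = 2°, φe = 0`; TR
`(x_e, y_e) = (−0.05, −0.05)` per cm with reference `(10, −30)` cm; TGD
`k = 0.1, c = 0.5` cm) sit in the middle of that range.

## Fitting and model comparison

Trials are modeled as the model-predicted bias plus Gaussian motor noise.
The noise scale is the maximum-likelihood plug-in estimate — the
root-mean-square residual, floored at 1e-6° to keep degenerate noiseless
fits finite — so the negative log-likelihood reduces to a monotone function
of the mean squared residual. For 2-D (angle-and-extent) designs the radial
residuals (cm) contribute a second independent Gaussian term with its own
scale; angular and radial terms are weighted equally.

Minimization uses a bounded Nelder-Mead simplex: parameters are mapped to
the real line by a sine transform and optimized unconstrained
(`reltol = 1e-10`), from `n_restarts` uniform-in-bounds random starts
(default 20; the heavier simulation suites use 6–10) plus two kinds of
deterministic starts: the canonical parameters, and — for hybrids — the
fitted nested component models with the other component at its neutral
value. The warm starts guarantee in particular that a hybrid never fits
worse than its nested component, so BIC differences between nested models
are never optimizer artifacts. Infeasible parameter regions (unreachable
targets, inadmissible postures, `φ0 ≤ θ0`) are penalized rather than
errored. Fits are bit-deterministic given their seed, and the package never
disturbs the caller's RNG stream.

Default bounds are generous physical ranges (TG `a ∈ (0.5, 44.5)°`,
`b ∈ (−20, 20)°`; PV components `±5` cm; PJ posture angles in `(0, π)` and
perceived errors `±0.35` rad; TR error components `±0.3` per cm and
reference `±60` cm per axis; TGD `k ∈ (−1, 1)`, `c ∈ (−5, 5)` cm), all
overridable per fit.

`bic()` implements `2·negLL + k·ln(n)` with `k` counting only the
generative model's free parameters (TG/PV/TGD: 2, PJ/TR: 4, hybrids: sums).
`compare_models()` fits every candidate per participant, picks the
per-participant BIC minimum (ties broken toward fewer parameters, then
lexically), reports best-model frequencies and summed ΔBIC relative to the
best total, and excludes participants with fewer than `max(k) + 2` trials
rather than fitting them silently. `fit_group()` pools trials and reports
R² of the predicted function against per-target mean biases (flagged
undefined when those means are numerically constant).

Two identifiability facts surface in testing and are worth knowing. On a
15°-spaced target grid with `a < 15°`, the TG parameters are jointly
unidentified: any `(a, b)` with the same ratio `b/(45 − a)` reproduces the
sampled values exactly, so recovery must be assessed in function space (or
on a grid that samples the transition zone, e.g. 5° spacing). And the TR
error vector and reference position are only weakly separable — fits are
evaluated by the RMSE between predicted and generating bias functions, not
by parameter distance.

## Adaptation shift

After implicit adaptation driven by clamped feedback, the aftereffect is
modeled as a displacement of the frozen baseline bias function:
`b(i) = baseline(i + v) + h`, with `v` the shift along the target axis and
`h` the additive offset along the bias axis. A recalibrated sensorimotor
map downstream of the visuo-proprioceptive transformation predicts a pure
vertical displacement (`h ≠ 0`, `v = 0`); a bias tied to the executed
movement direction would move both. `fit_shift()` estimates `(v, h)` by
least squares on per-target mean aftereffect biases (the loss is a package
choice; a likelihood-based loss gives the same optimum under homoscedastic
noise), using a grid of `v` seeds with the conditionally optimal `h`
followed by a bounded simplex over `v, h ∈ (−30, 30)°`. The baseline
parameters stay frozen exactly as fitted. `bootstrap_shift()` resamples
participants with replacement (default 200 resamples), refits `(v, h)` on
each bootstrap group average, and reports percentile 95% intervals.

## Reliability statistics

* `remove_outliers()` — single-pass, per-participant 3-SD filter on angular
  errors (sample SD; a zero-SD participant loses nothing). Re-running the
  filter could remove more trials; it is deliberately not iterated.
* `split_half()` — participants are split into random halves (⌊n/2⌋ /
  ⌈n/2⌉), each half's group-mean function computed, the halves correlated
  (Pearson), and the mean over (default) 2000 splits returned.
* `noise_ceiling()` — `r_max = sqrt(2 / (1 + sqrt(1 / r_half²)))`, the
  maximal correlation attainable against the true underlying function given
  split-half reliability `r_half`.
* `normalized_correlation()` — Pearson correlation of two bias functions
  divided by the smaller of the two conditions' ceilings; may exceed 1
  under sampling noise.
* `mirror_rmse()` — each participant's function is compared (RMSE) against
  the opposite hand's group-mean map, as-is and mirror-reversed; the
  statistic is a pooled-variance two-sample t on original vs mirrored RMSEs
  (df = 2n − 2), computed degenerate-safely. Which construction to use here
  is genuinely open (paired vs pooled, per-participant vs leave-one-out
  maps); the chosen one is simple, symmetric in the hands, and
  seed-reproducible. A body-centered bias source makes the mirrored
  comparison win; a pure target bias makes the two comparisons tie exactly.

## The synthetic cohort generator

`generate_cohort()` emulates the trial structure the analysis assumes: a
generative `model_spec` shared by the cohort; per-participant parameter
jitter (Gaussian, default SD = 20% of each parameter's magnitude, clamped
inside the fitting bounds — a level that produces between-participant
function correlations around 0.5, i.e. stable but clearly idiosyncratic
maps); trial-level Gaussian angular noise (default SD 4°, a typical
no-feedback reach dispersion); multiplicative attenuation of the expressed
bias on feedback blocks (default 0.5 — feedback reduces but does not
abolish the bias); and, for 2-D layouts, endpoints with radial noise
(default SD 0.3 cm). `generate_adaptation()` adds the endpoint consequence
of a clamp block: a per-participant vertical shift of the washout function,
`N(12.5°, 2°)` by default, positive for a clockwise clamp and negated for a
counterclockwise one. Standard layouts mirror common designs: 8 targets ×
5 trials at 8 cm, 24 × 4 at 8 cm, 12 × 30°-spacing at 10 cm, and
baseline/washout blocks of 10 trials/target.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: trial-by-trial adaptation dynamics, movement
trajectories and speed profiles, biomechanical (inertial) anisotropies,
non-Gaussian or target-dependent noise, and session effects. The generator
draws every participant from the same model family that is later fitted, so
recovery results validate the pipeline's correctness, not the models'
empirical adequacy.

## Validation suites and problem sizes

The test suite checks every closed-form prediction against an independent
geometric oracle written in complex arithmetic (with root-finding inverse
kinematics) to 1e-9°; verifies the hand-mirroring symmetry, the
scenario peak-count changes, the perturbed-start antisymmetry, and the
hidden-start amplitude sweep; and runs end-to-end recoveries at the scale
of the emulated designs: a 56-participant, 24-target, 4-trials/target
cohort at 4° noise for function recovery (RMSE < 1°, group R² ≥ 0.9) and
BIC selection (the generating TR+TG hybrid must win in ≥ 80% of
participants against all eight alternatives), and a 16-participant
adaptation cohort for shift recovery (imposed 12.5° ± 2° vertical shift
bracketed by the bootstrap CI, |v| < 1° at the tested seed — the horizontal
shift is weakly constrained by a 12-target design, and its estimate can
exceed a degree at other noise realizations). `scripts/acceptance.R`
recomputes all of these quantities from scratch for any seed.

## Known limitations

* The joint-based model is angular-only; comparisons on 2-D designs
  exclude it by construction.
* The pure TGD model's offset `c` is unidentifiable (it cancels in the
  plan), so its fitted value is arbitrary within bounds; BIC still charges
  the model for it.
* Bias functions are treated as functions of target direction only; radius
  is fixed within a layout.
* The 3-SD outlier filter and the split-half bootstrap follow the simple
  conventions stated above; robust variants (median-based splits,
  iterated filters) are out of scope.
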