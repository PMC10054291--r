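---
title: "Objective Hess Lancaster screen analysis: models and methods"
author: "hessgaze authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective Hess Lancaster screen analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hessgaze)
```

## The measurement problem

The Hess Lancaster screen test (HLST) quantifies heterophoria — the latent
misalignment of the two visual axes revealed when binocular fusion is broken —
across the main gaze positions. The subject sits 1 m from a wall grid of 5 cm
squares wearing red–green filters, so each eye sees only one of two projected
light stripes. The examiner's stripe drives one eye (the *fixating* eye); the
subject places the other stripe with the other eye (the *tested* eye). The gap
between the stripes at each of 17 grid targets is the deviation at that gaze
position, and at 1 m one grid square corresponds to 5 prism diopters (PD):
1 PD deviates a ray 1 cm per metre of travel, $\Delta = 100 \tan\theta$.

Performed manually, the test is read off the grid by eye: the examiner's
template is effectively quantized to the 5 PD square and further blurred by the
subject's hand–eye coordination. An eye tracker between subject and screen
records where each eye actually lands, which removes the subjective reading
step and resolves deviations well below 1 PD. This package implements the
objective pipeline — gaze recording to per-target prismatic deviations to
Hess-chart data to a statistical comparison against the examiner's template —
with a synthetic gaze simulator standing in for the tracker hardware.

## Geometry

The screen is the plane $z = 0$ with $x$ positive to the subject's right and
$y$ positive up, origin at the central target. Target 1 is the centre; ids 2–9
form the inner ring at 4 squares (20 cm) and ids 10–17 the outer ring at
8 squares (40 cm), cardinals on even ids, diagonals on odd, clockwise from
straight up within each ring. The rotation angle needed to fixate a target at
radius $r$ is $\arctan(r/D)$, which with the default geometry reproduces the
canonical ring values (11.31°, 15.79°, 21.80°, 29.50°) and the tracker-coverage
extents (26.57° at 10 squares cardinal, 35.26° at the 50 cm corner). The outer
diagonals sit essentially at the 35° limit of a remote tracker's measurable
range, which is why quantitative analysis restricts to the nine central
targets (`central_nine()`, the `deviation.central_only` default).

Two conventions deserve a note:

* **Prism definition.** We use $\Delta = 100\tan\theta$, not centrads; this is
  forced by the square rule (5 cm at 1 m = 5 PD exactly).
* **Id-to-direction assignment.** The ring membership of each id is standard,
  but which inner-ring id is "up" versus "right" is a chart-layout choice. We
  fix id 2 = up and proceed clockwise; a protocol using a different layout
  supplies a grid CSV (`id,x_cm,y_cm`) and everything downstream follows it.

## From gaze samples to deviations

The recording is segmented into the two examiner-marked events (LE test, then
RE test). Within an event, target assignment keys on the **fixating** eye —
it is locked to the examiner's stripe, while the tested eye floats by the
deviation — so a dwell at target $k$ is a period when the fixating eye sits
within `radius_cm` (default 7.5 cm, 1.5 squares) of target $k$.

Within those periods, fixations are found by dispersion-threshold
identification (I-DT): maximal windows whose $x$-range + $y$-range stays at or
below `dispersion_max_cm` for at least `min_duration_s` (default 300 ms).
Invalid samples (blinks, tracking loss) break windows. Because dispersion is
monotone as a window grows, the maximal extension from a given start is well
defined; windows are taken greedily from the earliest qualifying start, which
is the semantics the exhaustive window-scan oracle in the test suite verifies
case by case.

Qualifying windows must additionally hold at least `min_valid_frac` (default
80%) binocularly valid samples. Per target, the **last** qualifying window is
selected by default: the subject adjusts the flashlight and then confirms, and
the examiner's manual reading records the final placement (`selection =
"longest"` is available). Targets with no qualifying window are reported
missing, never fabricated; if more than `max_missing_frac` of the traversal is
missing the analysis aborts with a quality error advising re-recording.

The per-eye fixation estimate is the coordinate-wise **median** over the
eye's valid samples in the window (mean available), after which the deviation
at the target is the landing-point difference converted to PD:

$$\Delta x = \frac{100}{D}(x_{LE} - x_{RE}), \qquad
  \Delta y = \frac{100}{D}(y_{RE} - y_{LE}).$$

Signs follow the clinical reading: the LE landing temporal-ward of the RE
means divergence, so **exophoria is negative and esophoria positive**; the
vertical axis is anchored to the right eye so that **RE hyperphoria is
positive**. (A single "left eye relative to right eye" reference cannot
satisfy the RE-hyper-positive rule on the vertical axis; where the two
conventions collide, the explicit vertical sign rule wins — that is why
$\Delta y$ subtracts in the opposite order from $\Delta x$.) These definitions
use screen-plane differences, ignoring the ~6 cm inter-ocular offset; at 1 m
and clinical magnitudes that approximation is below 0.2 PD.

A Hess chart is assembled by displacing each expected target position by the
tested eye's landing offset relative to the fixating eye: the LE chart shifts
by $(+\Delta x, -\Delta y) \cdot D/100$ cm and the RE chart by
$(-\Delta x, +\Delta y) \cdot D/100$, so a uniform 4 PD exophoria draws the LE
field 4 cm left and the RE field 4 cm right. Inner and outer ring polygons
connect measured positions in circular id order; missing targets leave
flagged gaps.

## Choice of the I-DT dispersion default

`dispersion_max_cm` must sit **above** the spatial range that the tracker's
own noise produces within a minimum-duration window, or no window can ever
qualify. With isotropic gaze noise of 0.3° radial RMS at 1 m (the simulator's
default, typical of a remote tracker on a compliant subject), the per-axis
standard deviation is $\tan(0.3°) \cdot 100/\sqrt{2} \approx 0.37$ cm, and the
expected $x$-range + $y$-range of 75 independent samples (300 ms at 250 Hz) is
about $2 \times 4.8\sigma \approx 3.6$ cm. The default is therefore **6 cm**:
comfortable headroom over that expectation while remaining far below the 20 cm
inter-target spacing and the excursion of any saccade, so transitions still
break windows immediately. A lower threshold (1–2.5 cm) is appropriate only
for substantially cleaner or smoothed data, and is exposed in the `[dwell]`
config section.

## The synthetic subject

`simulate_subject()` emulates the acquisition: a 250 Hz binocular stream
traversing the 17 targets in order, LE test first, then the RE test after a
1 s gap, 2 s of dwell per target joined by 40 ms linear transitions. The
fixating eye holds each target; the tested eye lands displaced by the
configured deviation with the sign algebra mirroring the analysis definitions
(during the LE test, $x_{LE} = x_t + \Delta x \cdot D/100$ and
$y_{LE} = y_t - \Delta y \cdot D/100$ with the RE on target; during the RE
test, $x_{RE} = x_t - \Delta x \cdot D/100$, $y_{RE} = y_t + \Delta y \cdot
D/100$). Deviations are comitant by default; an `incomitance_map` adds
per-target components. Gaussian noise is applied in angle and projected to
screen centimetres. Blinks (0.2 Hz onsets, 150 ms, both eyes) and per-eye
independent sample loss (0.5%) mark samples invalid; landing points beyond
the tracker's 35° coverage are flagged invalid with a warning, reproducing
the peripheral losses that motivate the central-nine restriction.

Matching examiner templates come from `simulate_subjective()`: recorded value
$= \mathrm{round}((\text{true} + u)/5)\cdot 5$ PD with
$u \sim U(-2.5, +2.5)$, i.e. a reading quantized to the grid square after
half-a-square of imprecision. `simulate_cohort()` draws per-subject comitant
phorias from $U(-6, +6)$ PD horizontally and $U(-2, +2)$ PD vertically —
placeholders spanning clinically common small phorias, since the true
population distribution behind any given clinic sample is unknown — with
per-subject seeds derived reproducibly from one master seed.

**What a green test does and does not establish.** The simulator's world is
piecewise-stationary with white Gaussian noise, instantaneous linear
saccades, and a subject who always fixates where asked. Real recordings add
calibration drift, temporally correlated noise, suppression episodes,
vergence effects and head motion, none of which are modelled. Parameter
recovery on this synthetic world validates the *pipeline algebra and
segmentation logic* — it does not certify accuracy on clinical data, and the
original study's human-cohort correlations (e.g. horizontal subjective-vs-
objective correlations near 0.4–0.5) cannot be reproduced without those
recordings. The acceptance suite therefore tests recovery of known injected
deviations and sign concordance between simulated examiner templates and the
objective output instead.

## Statistics

`compare_methods()` mirrors the four-way method-agreement design: pairs
(subject × central target) are pooled into one cell per tested eye × axis —
13 subjects × 9 points = 117 pairs per cell — and each cell reports a paired
t-test of subjective minus objective, the Pearson correlation between the
methods, and a normality check of the paired differences.

The normality check is the one-sample Kolmogorov–Smirnov statistic against a
normal with the sample's own mean and SD. Since the parameters are estimated,
the classical KS p-value is anti-conservative; the default p uses the
Lilliefors approximation (Dallal & Wilkinson 1986 below p ≈ 0.1, Stephens
1974 polynomials above), with `ks_mode = "standard"` available for
comparability with software that ignores the correction. Calibration is
verified by simulation in the test suite (type-I error at the binomial band
around 5%, power ≈ 100% against uniform data at n = 500).

Degenerate inputs are reported, not patched: zero-variance differences with a
nonzero mean give p = 0 with a `degenerate` flag, all-equal pairs give
t = 0, p = 1, and zero-variance inputs make the correlation *undefined* (an
error object and an explanatory note in the table) rather than silently 0 —
this is exactly what an orthophoric zero-noise end-to-end run produces.

## Numerical and design notes

* Timestamps are normalized to seconds from the first sample at read time;
  readers preserve coordinates to 1e-6 cm and reject non-monotonic time with
  the offending row index.
* Invalid samples carry `NA` coordinates by construction, so no downstream
  computation can accidentally use them.
* `angle_from_prism()`/`prism_from_angle()` round-trip to 1e-9; all geometry
  is closed-form, no iteration anywhere in the pipeline.
* Tie-breaks: with `selection = "last"`, re-fixations of a target override
  earlier visits; two qualifying windows with identical start cannot occur
  (windows are disjoint by construction).
* The classification tolerance for phoria labels is 0.5 PD — half the
  smallest deviation the objective method is claimed to resolve reliably —
  and configurable.
* Configuration files use a deliberately small TOML subset (tables, scalars,
  flat arrays, comments) parsed internally; unknown keys are rejected with
  the list of accepted ones, so typos cannot silently fall back to defaults.

## Known limitations

* Torsional (cyclo-) deviations are out of scope: the screen-difference model
  has no rotational degree of freedom per eye.
* No head-pose compensation or tracker calibration model; inputs are assumed
  already expressed as screen landing points.
* The inter-ocular-axis approximation above (< 0.2 PD at 1 m) grows at
  shorter working distances.
* The I-VT (velocity) family of fixation detectors is intentionally absent;
  dwell extraction only needs to survive transitions, not characterize them.
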