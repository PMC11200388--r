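---
title: "Benchtop pre-validation of pedometer settings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchtop pre-validation of pedometer settings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepbench)
```

## The problem

Commercial wearable activity monitors expose a handful of step-detection
settings -- an acceleration threshold, a debounce step count, and a debounce
time -- whose 7595 combinations cannot all be validated in human trials.
`stepbench` implements the pre-validation strategy of replacing early human
testing with a *mechanical analog*: a continuous stepper that produces
mechanically regular steps at a set cadence, an independent optical channel
that yields a trustworthy ground-truth count, and a model-based search over
the full setting space. The entire rig is simulated here, so every stage is
deterministic, seedable, and testable against known truth; the trial-record
CSV is also the ingestion point for real hardware runs.

The pipeline is: simulate trials over a subsample of the setting space ->
derive converged ground-truth counts -> fit a polynomial error surface ->
recommend settings per cadence range by a weighted composite score.

## The simulated stepper

`generate_impulse_train()` emits one acceleration impulse per step with a
1.1 g peak, the magnitude of foot impact during ordinary walking. Steps are
regular at 60/cadence seconds, the first at one interval (never at t = 0),
so a noise-free train has exactly `floor(duration * cadence / 60)` events.
`generate_optical_trace()` is the ground-truth channel: 100 Hz voltage
samples with rectangular pulses alternating between a left-fin amplitude
(1.5 V) and a right-fin amplitude (2.5 V) on a 0 V baseline.

Defaults worth knowing:

* **Pulse amplitudes (1.5 / 2.5 V).** Chosen self-consistently with the
  quantization cuts below; the real fin amplitude depends on the optical
  hardware and both are configurable.
* **Pulse width (9 samples, 0.09 s).** Comparable to the dwell time of a
  fin in front of the switch. The width matters: the ground-truth
  convergence loop filters at windows of 3, 4, 5, ... samples, and a
  plateau only survives a window it can contain. A 3-sample pulse dies at
  window 4 and would make every clean trace "converge" to zero; 9 samples
  leaves generous margin while staying far below the shortest inter-step
  interval (54.5 samples at 110 steps/min).
* **Pulse alignment.** Each pulse *ends* at its step time. A trial whose
  last step falls exactly at the end of the recording therefore still
  captures the whole pulse; centre-aligned pulses would be truncated, and a
  truncated edge pulse is fragile under the growing filter windows.
* **Noise model** (`noise_spec()`): Poisson single-sample voltage spikes on
  the optical trace (the artifact the filtering stage exists to remove),
  and Gaussian timing/amplitude jitter on the impulses. `bench_noise()`
  fixes the experiment default at 2 spikes/min, 20 ms timing jitter and
  0.05 g amplitude jitter -- mild imperfection for a machine explicitly
  built to be regular. With a 0.05 g jitter about 2% of impacts fall below
  the topmost (996 mg) thresholds, which is what gives the threshold axis
  any signal at all in a rig whose impacts otherwise always exceed it.

What the generator deliberately does **not** emulate: human stride-time
variability (the mechanical analog's defining simplification), non-step
impulses such as weight shifts or fidgeting (during a continuous-stepper
trial any such impulse would land inside an active bout and be counted
under every setting, so it has no discriminating power), and any
speed-dependent attenuation of impact acceleration. A green test suite
therefore establishes correctness of the machinery on mechanically regular
input, not accuracy of any specific setting on human gait.

## The pedometer state machine

`count_steps()` replays the embedded counter. An impulse qualifies if its
peak reaches the threshold (milli-g). Qualifying impulses chain while each
gap is within the debounce time; chains reaching the debounce step count
are *promoted*, crediting all accumulated impulses retroactively, and keep
counting until a longer gap closes the bout.

Three semantic choices are load-bearing:

* **Inclusive gaps.** A gap exactly equal to the window passes (with a
  1 ns slack absorbing floating-point error in event times). This is what
  makes a 2000 ms window sufficient, at exact equality, for the 2 s gaps
  of a 30 steps/min train.
* **Retroactive credit.** A fully connected bout of 12 impulses yields 12
  steps, which is only possible if the debounced impulses are credited on
  promotion. `retroactive = FALSE` provides the alternative reading
  (debounced impulses dropped) for sensitivity checks.
* **A grouping needs two impulses.** With a debounce step count of 1 a
  literal reading would promote every isolated impulse, making the
  debounce time irrelevant at that setting. We instead require at least
  two chained impulses before anything is a step: the setting's purpose is
  to accept *groupings* with a walking rhythm, and detectability should be
  governed by the debounce window at every debounce step count. Under this
  rule a regular train is either fully counted (gap within window, length
  reaching the step count) or entirely rejected, and the minimum
  detectable cadence is the clean inversion
  `min_detectable_cadence(dt) = ceiling(60000 / dt)`:
  1000 ms misses everything below 60 steps/min, and 30 steps/min requires
  at least 2000 ms.

## Ground truth from the optical channel

`converged_count()` implements the adaptive pipeline: quantize, filter,
count peaks, enforce alternation, and grow the filter window until two
successive window sizes agree.

* **Quantization** (`quantize_trace()`): below 0.5 V is baseline; at or
  above 1 V is an impact, classified left (1) below 2 V and right (2) at
  or above it. Voltages in [0.5, 1) V are a dead band that the hardware
  description leaves unspecified; they quantize to 0 here.
* **Moving-mean filter** (`smooth_labels()`): centered mean over the
  window, zero-padded at the edges, with non-whole outputs replaced by 0.
  One refinement: for even windows the arithmetic mean can be a whole
  number without any plateau being present (a window half covered by 2s
  averages to exactly 1), which would fabricate left-impact labels
  flanking every right pulse. A retained output must therefore also equal
  every nonzero sample in its window; for odd windows this is exactly the
  plain non-integer rule.
* **Alternation check** (`enforce_alternation()`): the fins alternate, so
  consecutive equal sides mark a surviving artifact; the later of the two
  is removed (the earlier peak anchors the alternation already
  established; `drop = "earlier"` is available and leaves counts
  unchanged).
* **Convergence**: counts are compared at windows w and w + 1 starting at
  w = 3; agreement defines the ground truth. A cap of 25 samples turns
  pathological non-convergence into a diagnosable error naming the trial
  rather than a silent wrong count.

On noise-free traces the converged count equals the generator's step log
exactly at every cadence in 30--110, and single-sample spikes at up to
10/min never change it: an isolated spike is erased by the window-3 mean,
and a spike landing *inside* a pulse splits it into two same-side peaks
that the alternation check merges back.

## The error model

Signed error is `(sensor - truth) / truth`; negative means missed steps.
All four predictors are min--max scaled to [0, 1] using the *grid*
extremes (threshold 32--996 mg, steps 1--7, time 80--2480 ms, cadence
30--110), not the observed extremes, so the fitted surface is evaluated on
the same scale everywhere in the space it must extrapolate to.

`fit_error_model()` is ordinary least squares on the complete monomial
basis of total degree d (choose(d+4, 4) terms). Rank deficiency is
detected by the rank-revealing QR and *flagged*, never papered over:
notably, the standard experiment subsample takes every other debounce-step
value (1, 3, 5, 7), and with only four distinct values any fourth power of
that predictor is exactly collinear with its lower powers -- degrees 4 and
5 are structurally inadmissible on that design, whatever the data say.

`select_order()` reproduces the published selection logic: R-squared,
in-sample RMSE, 10-fold cross-validated MAE and the 90/10 Fit gap
(test RMSE minus train RMSE; positive suggests overfitting) are tabulated
for degrees 1--5, and the chosen degree is the highest-R-squared one that
is not rank deficient and whose Fit gap stays within `overfit_bound`
(default 0.05). Because R-squared never decreases with degree, a literal
"highest R-squared" rule would always buy noise; improvements smaller than
`r2_tol` (default 0.01) are treated as immaterial and the lower degree
wins. CVMAE is reported in the fractional units of the response, with a
percent column (`cvmae_pct`) alongside, since published values of this
diagnostic are conventionally quoted in percent while RMSE is quoted as a
fraction.

## Recommendation

For a cadence range, `recommend_settings()` predicts the signed error at
every integer cadence for all 7595 combinations and summarizes each as

* AE -- the mean of |error| over the range. The literal composite formula
  uses an average error, but a signed mean would reward settings whose
  positive and negative errors cancel while the stated goal is minimizing
  error *magnitude*; `signed_ae = TRUE` gives the literal form.
* STD -- the sample (n - 1) standard deviation of the signed errors.
* Composite = w * AE + (1 - w) * STD, with w = 0.5 by default. No
  published weighting is stated; equal weighting is the neutral choice and
  w is echoed in every artifact.

Candidates must keep |predicted error| within the tolerance (default
+/-10%) at *every* integer cadence -- the strictest reading of keeping
error within the band "across the range". Survivors are ranked by
composite, with deterministic tie-breaks (STD, AE, then the setting axes),
and the three preset ranges (30--60, 30--90, 30--110 steps/min) cover
disabled low-mobility, disabled high-mobility, and healthy walkers.

## Known limitations

The simulated rig produces a harsher error surface than real hardware: a
combination whose window cannot cover the inter-step gap misses *all*
steps, so the surface contains cliffs from 0 to -100% occupying a large
fraction of the space. Polynomials of the admissible degrees carry ripple
on the order of 0.15 from such cliffs into the flat zero-error region, so
at the default bench scale the +/-10% pointwise filter can reject every
combination: `recommend_settings()` then warns and attaches the
best-ranked out-of-tolerance candidates instead of returning silence.
Those top candidates are structurally sensible -- for the 30--60 range
they sit at a 2240 ms debounce time, which covers the 2 s gap of the
slowest cadence with margin -- but the in-tolerance set itself can be
empty. This is a property of fitting cliff-valued data with low-order
polynomials, not of the search; with real (milder) hardware error data the
same pipeline yields populated recommendation tables.

Seeds: every stochastic stage takes an explicit seed; `run_experiment()`
derives per-trial seeds as `seed + 2i` (optical) and `seed + 2i + 1`
(impulse train) so any single trial can be reproduced alone. The caller's
RNG state is never disturbed.
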