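---
title: "Online deconvolution of task-evoked pupillary responses: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online deconvolution of task-evoked pupillary responses: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupildeconv)
```

## The problem

The pupil dilates transiently when cognitive processing intensifies — the
task-evoked pupillary response (TEPR). In stimulus-locked laboratory
analyses, traces are segmented around known event onsets, baselined, and
averaged. In applied settings there are no known onsets: the interesting
question is whether the *moments of mental engagement* and the *size of the
associated demand* can be recovered from the diameter stream alone.

`pupildeconv` treats the observed diameter $Z[t]$ (mm, 60 Hz) as a static
baseline $b$ plus a superposition of latent **attentional pulses**
$w_i(s_i, t_i)$ — point events with onset $t_i$ and nonnegative scale $s_i$
— convolved with a fixed impulse response:

$$M[t] \;=\; b + \sum_i s_i \, h(t - t_i), \qquad
  h(t) \;=\; t^{\,n} e^{-n t / t_{max}},$$

with shape $n = 10.1$ and peak latency $t_{max} = 0.93$ s, the empirically
established TEPR kernel. The package normalises $h$ to unit peak so that
$s_i$ reads directly as mm of peak dilation; the kernel's free vertical
scale is otherwise unidentifiable (it trades off exactly against the
$s_i$). The kernel's analytic argmax is $t_{max}$ regardless of $n$, which
the test suite uses as a closed-form oracle.

The deconvolver is **online**: it consumes samples strictly in order,
never reading ahead. Each frame it compares the observation with the
current model; when the residual $Z[t] - M[t]$ exceeds a detection
threshold — 0.25% of a reference diameter, the recording's median — and a
refractory period (100 ms) has elapsed since the last insertion, a
candidate pulse is inserted **back-projected by 500 ms** (a dilation
visible now was driven by processing that began about half a second
earlier, given the kernel's slow rise), and the scales of all recent
pulses are refit by nonnegative least squares against the trailing 4 s of
observation. `deconv_step()` exposes exactly this contract; `run_deconv()`
folds it over a recording (internally jumping between threshold crossings,
which is equivalent because the model only changes at insertions — an
equality the tests assert frame by frame).

## Numerical choices in the loop

**Baseline.** The static baseline must sit below the dilation level being
modelled. On real, noisy samples the literal minimum is an outlier
(2–4 noise SDs below the tonic level); anchoring the baseline there leaves
a permanent positive residual that the loop would "explain" with a
steady trickle of spurious pulses. The baseline is therefore estimated on
a 1-s moving average of the diameter: its 1st percentile, clamped from
above by its minimum. On a noiseless trace this reduces to the plain
minimum. A fixed user-supplied baseline is also accepted.

**Windowed refitting and freezing.** Scales are refit only for pulses
whose *onset* still lies inside the trailing 4-s window; older pulses are
frozen and their contribution subtracted. The rise and peak of a pulse are
the data that identify its scale; once they have left the window, a least
squares fit sees only the kernel's negligible tail and would zero out
well-fit history. Freezing by onset keeps the loop $O(\text{frames}
\times \text{window})$ and the history stable. Within a call the windowed
squared error never increases (the previous scales remain feasible), a
property the tests check at every insertion.

**Nonnegativity.** Scales are constrained $s_i \ge 0$ (active-set NNLS).
Attentional pulses drive dilation; transient constrictions are carried by
the gap to the baseline, not by negative pulses. Coincident candidate
onsets would make the design singular; a tiny ridge fallback covers that
case.

**Finalisation.** The refractory rule means one physiological pulse can
spawn several candidates on a 100-ms grid. At the end of a run the
candidate list is consolidated: candidates whose optimised scale falls
below a floor (default: the detection threshold, in mm) are discarded;
surviving candidates separated by less than 0.25 s are merged into one
pulse at their scale-weighted mean onset; each merged pulse is refit
locally against the full trace and the floor is applied once more.
Finally, a pulse whose onset lies within $t_{max}$ of the recording end is
withheld from the report: its peak was never observed, so its scale is
unidentifiable from the few early-rise samples (in simulation such
end-of-stream candidates were the dominant source of false pulses). The
reported modelled trace is always the exact reconvolution of the reported
pulses — the offline-reproduction property the result object guarantees.

On the benchmark conditions (three pulses of 0.2–0.5 mm at least 2 s
apart, 0.01 mm noise, 60 Hz) this recovers over 95% of pulses within ±3
samples with mean scale error around 1%, and reports no pulses on
pulse-free noise at the default threshold; the acceptance tests recompute
these figures from scratch.

## Preprocessing

The preprocessing chain mirrors standard pupillometry practice:

* **Blink detection** (invented plumbing — acquisition software is out of
  scope): maximal runs with sample confidence below 0.6 or inside a
  filled clock gap, merged across gaps under 50 ms and padded by 33 ms —
  roughly two 60-Hz samples of partial lid closure on each side.
* **Blink reconstruction**: a cubic spline through four anchors, two
  consecutive samples per side taken 100 ms outside the padded interval
  so partially occluded samples never steer the spline. Intervals too
  close to the recording edge fall back to a nearest-value hold.
* **Despiking**: a five-point median Hampel filter; a sample is replaced
  by its window median when it deviates by more than
  $3 \times 1.4826 \times \mathrm{MAD}$. When the window MAD is zero the
  rule's limit applies: any deviation from the median is replaced. Edge
  samples use shrunken windows, and all medians are computed on the input
  (non-recursive). Note the filter is exactly idempotent on traces with
  isolated artifacts, but on dense white noise a second pass can re-flag
  the occasional sample — a structural property of scaled-MAD rules, not
  an implementation accident.
* **Trial exclusion**: gaze eccentricity beyond 2.8° at any sample
  between the first stimulus onset and the response, or any blink
  intersecting a 300-ms window around a stimulus onset, read as symmetric
  ±150 ms (the conventional interpretation of "around"). Trials without
  a response are excluded explicitly. Shrinking the gaze limit can only
  remove trials (a monotonicity the tests check).
* **Epoching**: one epoch per kept, correct trial, locked to the nearest
  grid sample of the lock event (at most 8.3 ms of rounding, far below
  effect timescales), minus the mean over the 100-ms pre-onset window —
  the mean rather than the median, six samples at 60 Hz.

## Validation statistics

**Per-sample mixed-model scan.** For every epoch sample, a linear mixed
model `pupil ~ load + (1 + load | participant)` (two factors add the
interaction and per-factor random slopes) is fitted via `lme4`, with
factors deviation-coded (−½, +½) so each coefficient is the high-minus-low
difference. Samples with $|t| > 2$ form maximal runs; runs shorter than
200 ms (12 samples at 60 Hz) are discarded. That duration rule is the only
multiplicity control, and no explicit mixed-model p values are produced.
Boundary (singular) variance estimates are accepted as valid REML
solutions; only genuine non-convergence triggers a flagged fallback to a
random-intercept-only model. Successive samples reuse the first
successful fit via `refit` for speed.

**Features and classification.** Within configured windows the signed
extrema of each baselined epoch and their earliest-sample latencies are
extracted. Per participant, a logistic regression of condition on the
features is evaluated by stratified 5-fold cross-validation under a
recorded seed. Accuracy is the average over test folds. Two AUCs are
reported side by side: `auc_cv`, from pooled out-of-fold probabilities,
and `auc_insample`, from the full in-sample fit. The in-sample AUC of a
fitted classifier is optimistic by construction — with 40 trials and one
feature its expectation under label permutation is about 0.57, and higher
with more features — so `auc_cv`, whose permuted-label distribution is
centred near 0.5 (slightly below, the usual mild pessimism of pooled
cross-validated scores), is the primary measure; the in-sample value is
retained for comparability with conventional reports. A one-sample t-test
of per-participant accuracies against 0.5 accompanies the AUCs, since AUC
is only interpreted when accuracy is above chance.

**Behavioural indices.** Cowan's $K = N(\mathrm{hit} - \mathrm{FA})$,
inverse efficiency $\mathrm{RT}/\mathrm{proportion\ correct}$, and an RT
filter keeping trials in [200, 2500] ms are provided as exact formula
implementations.

**Pulse timing.** `strongest_pulse_offsets()` finds, for each stimulus
event, the largest-scale pulse within ±1 s and averages the signed offset
(negative = pulse precedes onset) per condition.

## The synthetic-data generator

No recordings ship with the package, so every stage is validated against
simulations with known ground truth.

`simulate_recording()` builds a 60-Hz session from the dual-task trial
timeline (fixation 1.1 s → memory array → 2-s retention containing a
search array → memory probe → response), with one attentional pulse per
stimulus event. Condition effects live on pulse scales: working-memory
load adds (by default) 0.15 mm to the memory-array and probe pulses,
search difficulty 0.10 mm to the search-array pulse; base scales are
0.25–0.30 mm with 0.03 mm trial scatter and 0.05 s onset jitter — the
magnitudes of task-evoked dilations in dual-task settings. Tonic levels
are 5.0 mm (dark background) and 3.2 mm (bright). Participants receive
normal random shifts of overall scale (SD 0.05 mm) and of the load effect
(SD 0.03 mm), which is what gives the per-sample mixed models a real
random-effects structure. Blinks (4/min) drop confidence to zero and
collapse the diameter linearly to 60% and back — enough to exercise the
detector's input contract, with no claim to ocular realism. Measurement
noise is white Gaussian, 0.01 mm by default: a clean-recording
assumption matching the deconvolver's benchmark conditions. The default
cohort is 8 participants × 16 trials, a desk-scale stand-in for a full
laboratory session; the classifier benchmarks use 20 participants with
15–20 trials per level, and the behavioural law-of-large-numbers check
runs at $10^4$ trials.

`simulate_epochs()` skips the recording layer and generates baselined
epoch sets directly — a constant offset over a known window, participant
random intercepts and slopes, white noise — for the cases where the true
extent of an effect must be known exactly (significance-scan calibration,
chance-level classification).

What passing these tests does **not** show: robustness to the 1/f drift,
foreshortening error, luminance transients and correlated noise of real
eye-tracking hardware; the generator's noise is white and its tonic level
static within a recording. The pupillary light reflex is likewise only
available as an optional negative-going component and is off by default.

## Known limitations and open choices

* The baseline is static by design; slow luminance changes masquerade as
  sustained attentional pulses. A dynamic baseline is deliberately out of
  scope.
* The denominator of the "0.25% change" detection threshold is a design
  choice (median raw diameter, configurable); so are the refractory
  period, the optimisation window, and the consolidation gap — the loop's
  published description leaves them open, and the defaults were fixed
  against the recovery benchmarks above.
* Whether historical pulses should ever be re-optimised is open; the
  package freezes them once their onset leaves the trailing window.
* Detection compares the baseline-subtracted residual, not the raw
  diameter, with the threshold.
* With two factors, per-participant random slopes are included per factor
  but not for the interaction, keeping the per-sample models estimable at
  desk-scale cohort sizes.
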