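---
title: "Methods: seizure jitter, detection, and dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seizure jitter, detection, and dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(szjitter)
```

This vignette documents the statistical model behind `szjitter`, the
operational definitions used by the detectors, the numerical choices made in
the implementation, and the design of the synthetic ground-truth generator
that validates all of them.

## 1. The jitter statistic

A seizure is represented by its ordered population-spike peak times
$t_1 < t_2 < \dots < t_n$, i.e. by its inter-spike intervals
$I_k = t_{k+1} - t_k$. Two seizures $a$ and $b$ are compared by anchoring
each at one *alignment spike* ($i_a$, $i_b$), indexing every interval by its
signed offset from the anchor, and pairing intervals that share an offset:

$$ J(a, b; i_a, i_b) \;=\; 100 \cdot \operatorname{mean}_k
   \frac{|I^a_k - I^b_{k'}|}{(I^a_k + I^b_{k'})/2} \;[\%] $$

The reported jitter is the minimum over all alignment pairs. Because the set
of paired intervals depends on $(i_a, i_b)$ only through the shift
$d = i_b - i_a$, the search space collapses from $n_a \cdot n_b$ alignments
to $n_a + n_b - 1$ shifts; `jitter()` enumerates the shifts in the order of
their lexicographically smallest realizing pair, so ties resolve to the
smallest $(i_a, i_b)$. The test suite checks this implementation against a
brute-force minimizer over the full alignment grid.

Properties (each verified by a randomized property suite): $J = 0$ for a
train against itself; symmetry in $a, b$; invariance under time shifts of
either train; invariance under a common rescaling of time (the statistic
compares intervals *relatively*). The normalization by the pair mean bounds
each term at 200%, so a single grossly mismatched interval cannot dominate
arbitrarily.

```{r}
a <- spike_train(c(0, 0.100, 0.300, 0.600), refractory_s = 0)
b <- spike_train(c(0, 0.110, 0.300, 0.600), refractory_s = 0)
jitter(a, b)   # intervals 100/200/300 ms vs 110/190/300 ms -> 4.88%
```

## 2. Detection

**Background scale.** `estimate_background()` uses the median absolute
deviation (scaled by 1.4826) of the samples outside any excluded events; it
estimates the noise SD robustly even when paroxysmal activity is present.

**Seizures.** The seizure threshold is the background scale plus a 40 µV
offset (values outside 20–65 µV are accepted with a warning). A
*super-threshold excursion* is a run of $|x| >$ threshold. Two numerical
choices matter here:

* runs shorter than 5 ms are discarded *before* any merging. At 6 kHz a
  Gaussian noise process crosses 3 SD several times per second for a single
  sample; without the duration floor those isolated crossings chain together
  through the merge step and fabricate events.
* surviving runs separated by less than the 100 ms refractory period are
  merged, so the two lobes of one biphasic spike count as a single excursion.

Excursions whose quiescent gaps are at most 2 s are bridged into one
candidate event; candidates are kept when they last at least 10 s with a
within-event excursion rate of at least 2 Hz. Both rejection rules (too
short; too sparse) are exercised directly in the tests.

**Population spikes.** A spike candidate is an excursion of $|x|$ above the
*lower* threshold (0.5 mV) that exceeds the *upper* threshold (1 mV), with a
total span of 5–150 ms; its time is the peak of $|x|$. Candidate peaks closer
than 100 ms are merged iteratively — closest pair first — keeping the larger
peak (ties keep the earlier). Manual curation is supported programmatically
via `apply_spike_overrides()` rather than interactively.

## 3. Preprocessing numerics

All filters are Butterworth designs applied **zero-phase**
(forward–backward). Jitter is a timing statistic; a causal filter's
frequency-dependent group delay would shift sharp spike peaks relative to
slow components and bias it. The price is that the effective magnitude
response is $|H(f)|^2$, which `filter_gain()` reports.

Two implementation details are load-bearing:

* **Second-order sections.** A narrow band-stop (58–62 Hz at 6 kHz) has
  poles at radius ≈ 0.999 packed closely in angle. Expanding the design into
  a single numerator/denominator polynomial is numerically singular — the
  roots of the expanded denominator stray *outside* the unit circle and the
  filter explodes. The design is therefore kept in factored zero/pole/gain
  form and applied as a cascade of biquads; the magnitude response is also
  evaluated from the factored form.
* **Edge handling.** The input is extended by odd reflection long enough for
  the slowest pole's transient to decay (9 time constants), so start-up
  transients land in discarded padding. DC-rejecting filters additionally
  subtract the channel mean first, making the map exactly linear in the
  input and sending constants to exactly zero.

`downsample()` applies an 8th-order low-pass at 0.4× the target rate before
decimation; tests verify > 40 dB alias suppression.

## 4. Jitter dynamics and transition calling

`windowed_jitter()` averages the pairwise jitter over all unique pairs of
seizures whose onsets fall in a sliding window (defaults 1 h / 10 min). A
lazy pair cache ensures each pair is aligned at most once across overlapping
windows.

`detect_transitions()` thresholds a trace at the mean + 2 SD *of its own
values*: a recording that never changes state produces no transitions by
construction, and the threshold adapts to each recording's baseline jitter.
Maximal super-threshold runs become transitions. The point estimate of when
the waveform changed, `change_time_s`, is the centroid of the run's window
centres weighted by the jitter excess above threshold. Rationale: a window
mixing the two waveform states most evenly contains the most cross-state
pairs and therefore the largest excess; weighting by excess pulls the
estimate toward that window. On 20 h synthetic schedules (20 seeds, 3–4
switches each) this estimator located every switch within one 600 s step,
whereas using only the peak window's centre missed the 600 s tolerance on a
small fraction of switches.

`state_vs_transition_jitter()` pools within-segment pairs and pairs seizures
across adjacent segments; `fano()` (variance/mean) summarizes duration and
interval dispersion; `jitter_variability_correlation()` relates the trace to
per-window SDs of durations or onset intervals.

## 5. Calcium fluorescence analysis

The ΔF/F baseline is estimated by asymmetric least squares: minimize
$\sum_i w_i (f_i - z_i)^2 + \lambda \sum (\Delta^2 z)^2$ with $w_i = p$ above
the baseline and $1 - p$ below, iterating the weights. The effective
smoothing kernel width grows like $\lambda^{1/4}$, so **λ must scale with
the fourth power of the transient width (in samples) the baseline should
ignore**. The defaults (λ = 1e5, p = 0.01) suit short spontaneous calcium
events (seconds at 5 Hz). An electrode-insertion transient decaying over
~900 s at 5 Hz is ~4500 samples wide; analyses of that assay use
λ = 1e12, p = 0.001, 20 iterations, for which the tests show the baseline
stays on the programmed drift (RMSE < 5% of the drift range) instead of
sagging into the transient.

`recovery_time()` reads "recovered" on the ΔF/F scale: the first instant
after the post-event peak at which $|\Delta F/F| \le$ 0.02 *sustained for
60 s* (the sustain requirement suppresses spurious noise re-entries). The
closed form for an exponential decay of amplitude $A$ and time constant
$\tau$, $\tau \ln(A/0.02)$, is reproduced by the tests to within a sample.

## 6. The synthetic generator

Validation rests on simulations with exact ground truth, so the generator's
realism and its limits matter.

* **Templates.** Two canonical seizure shapes: `abrupt_onset` (largest spike
  first, intervals lengthening monotonically toward termination) and
  `ramping` (rate ramps up, peaks mid-event, fades out). Defaults — 20 s
  duration, 3 Hz mean spike rate, 1.2 mV spikes — sit inside the detector's
  design envelope (≥ 10 s, ≥ 2 Hz, 0.5/1 mV thresholds) the way real
  seizure-like events do, not at the margins.
* **Waveform.** Each spike contributes a biphasic kernel: a sharpened
  (cubed) half-sine lobe followed by a smaller opposite lobe. The sharp
  first lobe gives the peak a well-defined time so that sub-millisecond
  timing recovery is a meaningful target at 20 µV noise; the second lobe
  exercises the detector's biphasic-merge rule. A flat-topped peak would
  make "the" spike time ill-defined at the noise floor — a generator
  artifact, not a detector failure.
* **Stochastics.** Per-spike iid Gaussian timing noise (default σ = 5 ms,
  the scale at which same-state jitter lands in the few-percent range);
  gamma-distributed inter-seizure intervals (mean 300 s, CV 0.3); Gaussian
  background noise (20 µV SD). Waveform-state changes are scheduled template
  switches. Everything is a pure function of (configuration, seed), and the
  generator restores the caller's RNG state.
* **Limits.** No electrode drift, no amplitude rundown, no correlated
  (1/f) noise, no multi-channel propagation: variability enters only
  through spike timing, so recovered jitter can be compared against an
  interval-level Monte-Carlo oracle. The tests do exactly that and require
  agreement within 15%.

**Problem sizes.** Desk-scale defaults were chosen so the full suite runs in
minutes: waveform-level validation uses 230 s recordings at 6 kHz holding 5
seizures (1.4 M samples — large enough for realistic detection, small enough
to rerun at two sampling rates); hour-scale dynamics use *event-level*
sequences (`simulate_seizure_sequence()`), since a 20 h waveform at 6 kHz
(432 M samples) would add cost but no information to spike-timing analyses;
calcium assays use 1–2 h traces at 5 frames/s. These sizes are this
package's own validation choices, not properties of any particular
experiment.

## 7. End-to-end reproducibility

`run_pipeline()` chains filtering, detection, pairwise jitter, the windowed
trace, transition calling, and a JSON report; identical inputs give
byte-identical outputs. The downsampling-robustness experiment
(`scripts/acceptance.R`) reruns the full detection + jitter pipeline at
6 kHz and 1 kHz over 100 seizure pairs and reports the maximum relative
change in jitter, which stays well below the 10% design bound.
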