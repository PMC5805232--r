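---
title: "Detecting the point of stabilization of the Phase Coordination Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the point of stabilization of the Phase Coordination Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcipos)
```

## The problem

Bilateral coordination of gait is commonly quantified by the Phase
Coordination Index (PCI). Each gait cycle (stride) of one leg spans 360°,
and the heel strike of the other leg ideally falls exactly half-way through
it, at a stepping phase of φ = 180°. From the heel-strike times `t_A` (the
stepping leg) and `t_B` (the striding leg) the phase of cycle *i* is

φᵢ = 360° · (t_{A,i} − t_{B,i}) / (t_{B,i+1} − t_{B,i}),

and the PCI sums a consistency term and an accuracy term:

PCI = 100 · sd(φ)/mean(φ) + 100 · mean(|φ − 180°|)/180°,

in percent, lower meaning better coordination. Because both terms are
statistics over accumulated strides, a PCI estimate only becomes reliable
once enough strides have been collected — but long walking trials fatigue
elderly or impaired participants. The question this package answers is:
*from which stride onward does adding data stop changing the PCI estimate?*
That stride count is the **point of stabilization (POS)**.

The quantity the detector consumes is the *cumulative PCI series*: for a
trial of N strides, position j (j = 1 … N−1) holds the PCI computed from
the first j+1 phases, so position j corresponds to a stride count of j+1.
This off-by-one convention is applied consistently: every user-facing POS,
reference stride, and table is in stride counts (`strides()` exposes the
mapping). Both phase conventions are supported — right step relative to
left stride (RreL) and the converse (LreR) — along with their element-wise
average series.

## The detector

The detector makes a single a-priori assumption: more strides give a more
stable value. Stability of a window of cumulative-PCI values is judged by
its coefficient of variation, CV = sd/mean (sample sd, raw ratio), with a
window declared stable when CV ≤ 0.05. The CV criterion is insensitive to
the absolute PCI level, so the same threshold serves well-coordinated and
poorly-coordinated walkers alike.

**Stage 1 — backward search.** With window size K = 15, a window is slid
from the right end of the series leftward, one position at a time, until
the first *unstable* window is found — the region of interest (RoI). Two
window shapes are searched independently: *consecutive* (positions
S … S+K−1) and *dispersed* (K positions spread evenly from S to the series
end; for a 50-value series and S = 21 the dispersed positions are 21, 23,
25, …, 50). The dispersed option guards against slow uniform drifts whose
local windows look stable while the series is still moving; the remaining
systematic error in such slope edge cases is about ±1–2 strides.

**Stage 2 — localization.** The K RoI values (for a dispersed RoI,
compressed into a contiguous working vector) are refined iteratively: the
sub-window omitting the leftmost element is tested; if stable, instability
must live at the left edge, so the window shrinks from the right; if
unstable, the search zooms into that right sub-window. After exactly K−2
iterations the window has two elements and the right one, mapped back to
original series coordinates, is the stabilization onset. Each of stage 1's
two options yields a candidate POS and the **maximum of the two** is
reported, in strides.

Two boundary rules are decisions of this package, made where the procedure
itself is silent:

* *No RoI anywhere* (every window stable down to S = 1): the option
  contributes the minimal POS of 2 strides. Stability from the first
  window onward means no additional strides would have changed the
  estimate; the result is flagged in the decision trace.
* *Rightmost window already unstable*: the RoI touches the series end, so
  the trial arguably never stabilized. The POS is still localized inside
  that window, but the result carries `stabilized = FALSE` and a warning
  that the trial may be too short.

Ties (window CV exactly at the threshold) count as stable, matching the
"≤" in the criterion. An undefined CV (zero-mean window) counts as
unstable rather than silently passing. In stage 2 the left sub-window is
adopted without being tested as a whole — only the right sub-window's
verdict steers each step, and the brute-force oracle used in the test
suite encodes the same reading independently.

Tunable parameters, with defaults: window size `K = 15` positions,
threshold `cv_threshold = 0.05` (raw CV). Raising the threshold makes the
detector more permissive (earlier POS); the package exposes a
window-size sensitivity sweep (`sweep_block_size()`). The detector applies
unchanged to any cumulative statistic with positive values;
`cumulative_cv_series()` builds the analogous series for, e.g.,
stride-to-stride time CV.

## The simulator

`simulate_cohort()` generates "virtual participants" emulating comfortable
walking in young healthy adults:

* stride times of the striding leg are i.i.d. Normal(1.07 s, 0.02 s) —
  the ±0.02 s is read as *within-participant* stride-to-stride variability,
  consistent with the reference values for steady treadmill walking
  (non-positive draws are redrawn);
* phases are 180° + i.i.d. Gaussian noise with SD 4°, a value chosen so
  that whole-trial PCIs land in the healthy range;
* whole phase vectors are rejection-resampled until the vector mean lies
  within 180 ± 2° (a stand-in for the normative mean band, which is not
  standardized) and the whole-trial PCI lies within [2, 5]% — a band
  spanning reported means from young (≈3.3%) through elderly (≈5.0%)
  healthy walkers. Whole vectors, never single elements, are resampled so
  the accepted noise stays serially unstructured;
* heel-strike times are reconstructed by placing each stepping-leg event
  inside its stride at the fraction the phase prescribes; recomputing
  phases from those events returns the generating phases to below 1e−9°,
  which the test suite asserts.

Each participant contributes 50 phases per convention. Deriving the
complementary (LreR) phases from the same events consumes one extra
stride, so trials internally carry 51 striding-leg strides and both
conventions are truncated to exactly 50 phases; the complementary vector
is also required to meet both normative bands (violations are rare and
trigger a redraw). Cohorts are a pure function of the master seed; each
participant records its own sub-seed for isolated replay.

What the simulator does *not* emulate: serial correlation of stride times
and phases (real gait has long-range dependence), asymmetric or impaired
gait, speed drift, or turning. Passing tests on simulated cohorts
therefore demonstrate correctness of the machinery and realistic behaviour
under idealized noise, not clinical performance.

## Error metrics and evaluation

With a cohort-level reference stride (23 strides, the rounded mean POS of
simulated cohorts), the error committed by truncating a trial is the true
error TE = (PCI_ref − PCI_end)/PCI_end and its magnitude AE = |TE|,
computed against the raw end value of the series. POS-aligned error
profiles instead compare against the mean of the last three values (a
smoother trial-final reference) and pad series by replicating their first
and last values so offsets of ±20 strides around each participant's POS
stay defined. Internally errors are fractions; tables report percent.

On cohorts at the defaults, the mean POS is ≈ 24, 24 and 21 strides for
the RreL, LreR and average series, and the mean AE at stride 23 on the
average series is ≈ 8% — the average series stabilizes earliest because
averaging the two conventions damps fluctuations. Because the generator
treats the two conventions symmetrically, their POS means are
statistically exchangeable here; any ordering between RreL and LreR in a
single 20-participant cohort is a draw of that cohort.

## Numerical choices

* Sample (n−1) standard deviation everywhere — in the PCI, in all
  cumulative CV series and in the window CV.
* Cumulative series recompute every prefix directly rather than updating
  running sums; at CV values of a few percent the cancellation error of
  running-sum updates is visible at the 1e−9 tolerances the package
  promises.
* Dispersed positions round half away from zero, with the rare collision
  after rounding resolved by pushing the later index up by one; the first
  and last positions are pinned to S and N.
* Phases are used raw — no wrapping or folding around 180°, no circular
  statistics — matching how the PCI is defined.
* Writers emit full-precision text so read/write round trips are lossless
  to 1e−12; display formatting is applied only at the console boundary.

## Problem sizes in the test suite

The packaged checks run 500 randomized detector-vs-oracle comparisons on
series of 30–60 values, 200 change-point-recovery replicates, and 5
simulated cohorts of 20 participants × 50 strides; these sizes give
stable cohort means (between-cohort SE of the mean POS ≈ 0.7 strides at 5
cohorts) while keeping the default test run quick.

## Known limitations

* The dispersed option mitigates but does not eliminate slow-drift edge
  cases (systematic ±1–2 strides).
* The detector is offline: it consumes a completed series. Streaming
  operation would need a stopping rule for the backward search.
* Published reference values for healthy cohorts were obtained from
  self-paced treadmill and over-ground protocols; applying the defaults to
  other protocols or impaired gait warrants re-examining the normative
  bands and the CV threshold.
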