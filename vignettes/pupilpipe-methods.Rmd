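---
title: "pupilpipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pupilpipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilpipe)
```

This vignette explains what each stage of the pipeline computes, why the
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the design decisions taken where reasonable people could
disagree. It states no empirical result that the package's tests do not
themselves compute.

## The data model

A recording is a long-format table: one row per gaze sample, with a trial
identifier tuple (one or more columns, e.g. `block` + `trial`), a trial
clock `trialtime` (ms, re-zeroed at each trial's first sample), the recorder
clock `trackertime`, gaze `x`/`y` in screen pixels (origin top-left, y
increasing downward, kept exactly as recorded), and pupil size `pp` in
recorder units (area or diameter — the pipeline is unit-agnostic).

Missing data are a floating `NA`, never 0. Recorders typically write 0 for
a lost pupil; those zeros are preserved on read and only neutralised by
`deblink()`, so the raw column always shows what the tracker actually
reported.

Every pipeline verb reads the *latest* stage column and writes a new one
with a fixed suffix (`_db`, `_ds`, `_us`, `_ar`, `_xy`, `_sm`, `_ip`,
`_bc`), so all intermediate signals survive and any step's effect can be
audited after the fact. Two invariants are enforced and tested: no step
overwrites an existing column, and the cleaning steps never decrease the
per-trial missing count (interpolation never increases it).

All statistics are computed within trials. Processing is therefore
invariant to trial order, and multiple participants can share one processor
as long as the identifier tuple is unique per trial.

## Trial segmentation and the marker grammar

Messages are paired to samples by "most recent message at or before the
sample's timestamp"; a message exactly simultaneous with a sample applies
to it. Only messages that parse under the declared grammar participate —
recorder chatter (calibration lines etc.) is ignored. Samples between a
stop boundary and the next start are discarded. Nested or interleaved
start/start and stop-without-start patterns are rejected with warnings
rather than guessed at; an unmatched start at end of file drops that trial.
Binocular sample rows are reduced to one eye (left by default) since the
pipeline is monocular.

## Blink removal

The recorder's zero/missing runs understate a blink: pupil area is already
distorted while the eyelid closes and reopens. Following the noise-based
blink-detection approach, `deblink()`:

1. finds zero/missing runs and merges runs closer than `merge_gap_ms`
   (default 100 ms — half-blinks separated by a flicker are one blink);
2. smooths the trace with a short moving average (`smooth_window_ms`,
   default 10 ms) to suppress sample noise before slope inspection;
3. extends each run backward while the smoothed signal was still falling
   into the blink (to the nearest preceding non-decreasing→decreasing
   transition) and forward while it is still rising out of it (to the first
   non-increasing sample), bounded by `onset_search_ms` / `offset_search_ms`
   (default 500 ms each).

All four constants are exposed. The smoothing window trades noise
robustness against edge precision: a wider window can push the detected
ramp boundary a few samples into clean data (a conservative error). The
unit tests pin the exact ramp extents with a 1-sample window; the
end-to-end test allows the documented superset.

## Artifact rejection

Two rules, both computed per trial on the same input column; the default
applies their union, which makes the result independent of any ordering.

*Dilation speed.* `d_i` is the larger of the absolute forward and backward
first differences at sample *i*, each divided by its time difference
(endpoints use their single side; differences are taken between consecutive
non-missing samples, so a gap contributes one speed across it). The
threshold is `median(d) + n·MAD(d)` with `n = 16` and the **raw** MAD (no
1.4826 consistency scaling — the convention of the robust-threshold
literature this rule comes from). The comparison is strict (`>`), so
degenerate traces (constant, or perfectly linear, where MAD = 0) reject
nothing. A single pass is applied; iterating to convergence is a known
variant we deliberately do not do.

*Extreme sizes.* Within-trial z-scores beyond 2.5 in absolute value are
rejected — but only when the trace's coefficient of variation (sd/mean)
exceeds 0.1. The guard protects stable traces: in a flat trace the sample
variance is tiny and ordinary noise would otherwise be chipped away. A zero
mean leaves the CV undefined; the trial is flagged and left alone.

## Gaze-position filtering

Pupil foreshortening makes measured pupil area shrink as the eye rotates
away from the camera. Rather than model-based correction (explicitly out of
scope), samples recorded while gaze is outside a declared valid region
(rectangle or simple polygon; boundary points count as inside) have their
pupil value set missing. The `pupil_surface()` grid (sample counts or mean
pupil size per gaze cell, plus the mean gaze position) is the diagnostic
for choosing that region.

## Smoothing

The default is a Hann (raised-cosine) window of **100 samples**, normalised
to unit sum and convolved centred. The window is specified in samples, not
milliseconds — at 1000 Hz, 100 samples spans 100 ms. Descriptions of this
default elsewhere sometimes pair the 100-sample figure with a 10 ms
duration, which cannot both hold at 1000 Hz; here the window is
unambiguously 100 samples, and at other sampling rates you should scale
`window` yourself.

All methods operate strictly within contiguous non-missing runs: weights
that would reach across a gap or a run edge are dropped and the remainder
renormalised, which preserves unit DC gain everywhere and guarantees that
missing samples neither shrink nor bleed. A trial none of whose runs reaches
the window length is blanked and flagged rather than half-smoothed.

The Butterworth option (defaults: order 3, cutoff 4 Hz — the pupil's
task-evoked response lives well below that) is zero-phase
(forward–backward) to avoid lag. Because no IIR-filtering package is
assumed at run time, the design (bilinear transform) and the
`filtfilt`-style application (odd-reflection padding, steady-state initial
conditions, mean-centring for conditioning) are implemented in
`R/filters.R` and covered by DC-gain/attenuation tests.

## Interpolation

Gaps can be bridged linearly (chord between the bounding samples) or with a
natural cubic spline fitted through all non-missing points of the trial.
Interpolation is refused — column copied, trial flagged — when more than
`max_missing` (default 40%) of the trial is missing, because a trace that
is half gap is guesswork whatever the interpolant. Leading and trailing
missing runs are never extrapolated. Linear interpolation is exact on
affine signals and the spline matches an independent tridiagonal
natural-spline solver to 1e-9; both are tested property-style.

## Baseline correction

The baseline `b` is the mean of the last `last_k = 100` samples (by
position) of the baseline window — typically the pre-stimulus fixation
period selected by an event label, alternatively an explicit time range
(global or per-trial). Missing samples inside the window are ignored in the
mean; if fewer than 10% of the `last_k` samples are usable the trial is
flagged instead of silently averaged over next to nothing. Correction is
subtractive (`p − b`) by default; divisive (`p / b`) is available but prone
to producing outlier traces (and a zero baseline flags the trial), which is
why subtractive is the default.

## Outlier diagnostics

Both diagnostics use the same robust band construction, `median ± n·MAD`
with raw MAD and `n = 4` by default, and both are **advisory**: they fill
the trial summary but never modify data. Exclusion happens only through
`validate_trials()`, which writes the `valid` column and is idempotent.

For baselines the band is inclusive, so identical values are never flagged,
and it can be computed per group (e.g. per participant) — whether grouping
should be the default is genuinely open; we default to ungrouped.

For traces, the "grand mean" is read as the time-varying pointwise mean
over trials aligned on the trial clock, with unequal-length trials
contributing where they have data; the band is a constant half-width
`median(D) + n·MAD(D)` around that trace, where `D_j` is trial *j*'s
maximum absolute deviation from it. A scalar-band reading of the same
construction exists in the wild; the report returns the grand-mean trace
and half-width so either view can be derived, but the constant-width moving
band is what the flag uses. A trial with no overlap with the common grid is
reported as unevaluable rather than flagged.

With few trials the MAD band is very tight (with 3 trials, the band
half-width is on the order of the between-trial jitter), which is the
statistically honest behaviour of a robust band — another reason flags are
suggestions, not decisions.

## Fixations and AOIs

AOIs are closed polygons; the JSON format is `{"name": [[x, y], …]}`, or
nested one level by trial key (identifier tuple joined with `"|"`) when
regions move between trials. Polygons must be closed (first vertex repeated
last) and non-self-intersecting; both are validated on construction and
load.

Point-in-polygon uses the even-odd rule with an inclusive boundary: a
fixation exactly on an AOI edge is assigned to it. Overlaps resolve by
declaration order (first wins). Both conventions are package decisions —
deterministic and documented, not attributed to any source. The property
test checks agreement with an independent winding-number oracle on random
off-boundary points.

`compute_aoi_statistics()` reports fixation counts and total durations for
every (trial, AOI) pair including zero rows and an `outside` row, so counts
and durations are conserved by construction (and tested). The density map
is a sum of isotropic Gaussian kernels (duration-weighted when durations
exist) on the pixel grid; the default bandwidth is 2% of the canvas
diagonal — no principled value exists in the literature we follow, so this
is a smoothing choice on the scale of a typical stimulus, made once.

## The synthetic world

The generator exists so that every operation is testable against known
truth without any external download. A trial is `baseline + bump + noise`:

* baseline 1000 recorder units (a typical video-based area value);
* an event-locked dilation bump shaped like the classic gamma-form pupil
  response (shape 10.1, peak latency 930 ms), amplitude 100 units, onset
  1000 ms into the trial;
* Gaussian sample noise, sd 5 units (a few tenths of a percent of
  baseline, typical of a well-calibrated video tracker);
* blinks overwrite the signal with a strictly decreasing closing ramp
  (20 ms), a zero plateau (60 ms), and a strictly increasing reopening ramp
  (20 ms) — round numbers in the physiological range of a blink;
* optional spike impulses model residual transients.

The ASC emitter wraps such trials in boundary/phase messages, integer
millisecond timestamps, track-loss (`.`) fields during plateaus,
EFIX/EBLINK event rows, header chatter and discardable inter-trial samples.

What the generator does **not** emulate: physiologically realistic pupil
dynamics (hippus, tonic drift), autocorrelated measurement noise, partial
occlusions that distort rather than zero the pupil, saccade-locked
foreshortening gradients, or binocular disparity. A green test therefore
establishes that the algorithms implement their stated contracts on signals
with known truth — not that any particular parameter setting is optimal
for a given real dataset.

Generators are pure functions of spec + seed (the global RNG stream is
saved and restored), and the pipeline-recovery test checks that the default
chain removes at least the injected artifact samples and reconstructs the
clean signal within smoothing tolerance.

## Numerical choices

* Raw (unscaled) MAD everywhere; strict `>` threshold comparisons so
  MAD = 0 on degenerate data rejects/flags nothing.
* Sampling rate, when not declared, is 1000 / median inter-sample interval.
* Downsampling requires an integer rate factor and uses plain window means
  (it is documented for use after deblinking on slow signals, where a
  decimation filter would be overkill); an all-missing window stays
  missing; times take the window start.
* Upsampling and smoothing never interpolate across gaps; gap boundaries
  are sacred until `interpolate_pupil()` is asked to fill them.
* Even-length smoothing windows centre at offset `-((w-1) %/% 2)`, i.e.
  the kernel support for `w = 100` is offsets −49…50.
* Natural-spline interpolation delegates to `stats::splinefun(method =
  "natural")`; the test oracle is an independent tridiagonal solve.
* Point-in-polygon boundary tolerance is 1e-9 (scaled by segment length).

## Limitations

* Blink detection constants are exposed but their defaults were chosen for
  1000 Hz video trackers; very low sampling rates need wider smoothing and
  search windows.
* The z-score rule assumes a roughly unimodal within-trial distribution;
  long bimodal trials (e.g. light/dark alternation within one trial) can
  defeat both the CV guard and the threshold.
* Interactive inspection (hover, zoom, per-trial dropdowns) is out of
  scope; the diagnostic computations are exported as static figures and
  tables instead.
* No geometric pupil-foreshortening correction is attempted; position
  filtering only limits exposure to it.
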