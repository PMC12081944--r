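---
title: "Methods: simulating and analysing spatial-oddball ERP studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing spatial-oddball ERP studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oddballerp)
```

This vignette documents the models, parameter choices and numerical
decisions behind `oddballerp`. The package re-implements, as tested code,
the analysis methodology used to validate a virtual auditory environment
against a real room with a spatial-oddball ERP paradigm: constrained
sequence design, synthetic EEG cohorts, FIR preprocessing, P1-anchored
latency alignment, fractional-area component measures, and
jackknife-corrected frequentist plus Bayes-factor inference.

## The experimental world being simulated

One session is 900 noise bursts (500 ms each) at inter-stimulus intervals
of 1300–1700 ms. 684 come from the centre loudspeaker (standards); 216 are
targets at four positions (left, right at ±24° azimuth; near, far on the
median plane), 54 each, with 2–6 standards after every target. Participants
respond to targets with a joystick. Two age groups (22 younger, 22 older)
each complete the paradigm in a real room and in its virtual (headphone)
copy. The room constants — 7.22 × 12 × 3.4 m, T60 ≈ 0.8 s, Schroeder
frequency 2000·√(T60/V) ≈ 104 Hz, speaker elevations
atan((h_LS − h_P)/d) of −18.2°/−9.4°/−4.7° for near/centre/far — are
carried by `room_spec()` and `speaker_layout()`. The critical distance
(≈3.5 m) is stored as a recorded constant: deriving it requires a source
directivity factor that is not modelled, so the package never computes it.

### Sequence generation

`generate_sequence()` tiles the standard budget as a leading run of 2–6
standards plus one run after each target: all 217 runs start at the
minimum gap and the remaining budget is distributed uniformly at random
with the per-run cap, by sampling without replacement from the multiset of
available increments. This makes every admissible gap composition
reachable while holding per-position counts exact. ISIs are uniform on the
1-ms grid — the source design states only the range, so the least
informative distribution on the stated support is used.

## The synthetic EEG generator

Each session is a 64-channel, 1000-Hz continuous recording: component
signal plus 1/f background noise.

**Components as raised-cosine bumps.** Every component is
A·cos²(π(t−L)/W) on |t−L| ≤ W/2, with widths P1 30, N1 60, P2 120, MMN 80,
P3b 300 ms. The bump is the simplest smooth, compactly supported,
symmetric shape; its symmetry makes the 50% fractional-area latency equal
the peak latency, so one latency parameter serves both measure types.
P1/N1/P2 occur on every trial; MMN and P3b only on target trials (with
azimuth- or distance-specific parameters), which is exactly what makes
them appear in target-minus-standard difference waves.

**Amplitude semantics.** A component's table amplitude is defined as what
its designated measure returns on noiseless data. For peak-measured
components that is the bump peak itself. For the FAL-measured MMN/P3b the
20-ms windowed mean of a cos² bump of width W equals the peak times
κ(W) = ½ + W/(40π)·sin(20π/W) (0.9502 for W = 80, 0.9963 for W = 300), so
the generator scales the rendered peak by 1/κ. This keeps the noiseless
round trip exact to < 0.01 µV, which the test suite asserts for all 28
component cells.

**Topographies.** Each component has weight 1 on its measurement grid
(frontocentral for P1/N1/P2, right-frontal/central for the MMN,
centroparietal for P3b) and a uniform negative counterweight on the 41
channels outside every grid, so each topography sums to zero across the
montage and the 64-channel average reference leaves grid measurements
unchanged — the idealisation that average referencing assumes for dipolar
fields. The MMN additionally puts zero weight on the four channels it
shares with the frontocentral grid (up-weighting its other 11 channels by
15/11 so the grid mean still equals the nominal amplitude); this keeps the
early-component peak windows on target trials free of deviance leakage,
an identifiability choice a real scalp does not offer — one of the ways a
green test here is weaker than a real-data validation.

**Background noise** is Gaussian with a 1/f power spectrum (exponent 1)
and broadband SD 10 µV per channel, independent across channels. This
emulates *cleaned* EEG — the artifact regime that ICA handles in practice
is out of scope — so rejection counts in the synthetic world are near
zero, unlike the tens of trials real sessions lose. Channel-independent
noise also understates spatial correlation; grid averages therefore gain
more from averaging than real data would.

**Condition structure.** The per-cell component means are reconstructed
from the reported results of the validating study: marginal means plus
interaction contrasts pin down a full age × environment × dimension cell
table per component, and the reconstruction is checked against every
printed margin (e.g. azimuth MMN cells −1.29/−1.00/−0.96/−0.67 µV average
to −0.98; environment margins −0.80/−0.51; age margins −0.82/−0.49).
Where no interaction was reported the model is additive; the P3b amplitude
table uses the four printed older-group cells directly and solves the
younger cells from the marginal constraints.

**Variability.** Per component, participants get a shared amplitude
intercept (SD: P1 0.79, N1 1.09, P2 1.63, MMN 0.44, P3b 1.00 µV) plus an
independent per-cell jitter (0.50/0.64/0.78/0.52/1.03 µV). These SDs are
back-computed from the reported F statistics of the corresponding
between- and within-subject effects (an F of 4.82 for the 0.75-µV N1 age
difference at n = 22+22 implies a between-subject SD near 1.1 µV, and so
on); where two effects implied different values the smaller was taken.
Realized deviance amplitudes are truncated at zero — participant variation
scales a response but cannot invert its polarity, and a polarity-inverted
MMN would make the rectified-area latency meaningless. True latency
jitter is deliberately small (P1 3, N1 5, P2 8, MMN 6, P3b 15 ms SD):
most of the latency variance behind the reported FAL F values is
attributed to single-subject measurement noise rather than true latency
spread, because cross-participant latency smearing attenuates
group-average amplitudes (a 12-ms SD would already bias the grand MMN by
~18%, contradicting the recovery tolerances this generator is built to
meet). This attribution is a modelling commitment, stated here once.

**Technical onset offsets.** The playback chains of the two environments
delay the physical sound relative to the marker by +4 ms (real) and −5 ms
(virtual) by default — the integer-rounded counterparts of the mean
alignment shifts the validating study observed (−4.10 and +4.60 ms;
shift = −offset). Offsets may also be specified per environment ×
position.

**Behavior.** Target responses are Bernoulli with cell probabilities
0.968/0.948 (real azimuth/distance) and 0.953/0.922 (virtual), derived
from the study's printed per-dimension inclusion counts (e.g. 104.55 of
108 azimuth targets retained in the real room); no numeric accuracy means
are printed. Participants get a logit-scale ability intercept (SD 0.5)
and per-dimension jitter (SD 0.25); standards are "correct" (no response)
with probability 0.99.

## Preprocessing

The chain is fixed and logged: Hamming-windowed sinc FIR filtering
(high-pass 0.25 Hz/6601 taps, low-pass 33.75 Hz/441 taps, applied to the
continuous data as one combined zero-phase-compensated kernel), 64-channel
average reference, [−200, 1000) ms epochs (sample at t is the recording
sample at onset + t; baseline [−200, 0)), correct-trials-only selection,
exclusion of each first post-target standard (216 per full session), and
±100 µV absolute amplitude rejection. The rejection threshold is a
conventional default — the source reports rejection counts but not
criteria — and the two-stage rejection around ICA collapses to one stage
because ICA is out of scope. Counts are conserved: retained plus each
logged removal category equals the input count, asserted in tests.

Filters attenuate narrow bumps: the 30-ms P1 loses ~18% of its peak to the
33.75-Hz low-pass. This is faithful to any real pipeline; the exact
round-trip oracle is therefore defined on unfiltered epochs, while
pipeline-level recovery tolerances (below) absorb the filtering bias of
the wider MMN/P3b bumps (< 2%).

## P1-anchored alignment

The reference is the P1 peak latency (maximum positive deflection,
30–90 ms search window) of the everything-pooled, trial-weighted grand
average on the frontocentral grid. Each environment × age × position cell
is measured the same way and its markers shifted by
round(reference − latency) (integer ms — marker resolution at 1000 Hz;
|shift| ≤ 25 ms sanity bound). The 30–90 ms search window is wider than
the 50–60 ms quantification window to tolerate offsets up to ±20 ms.
Alignment identifies offsets only *relative to the pooled reference*: a
delay common to all cells is absorbed into the reference, exactly as in
the original procedure. The idempotence property (a second pass shifts by
at most 1 ms) fixes the sign convention and is asserted in tests.

## Component measurement

Measures operate on grid-averaged waveforms (grid-average-first; the
alternative per-channel-then-average order is not what the reported
six-electrode averaging suggests). Peaks take the stated-polarity extremum
in the window, ties to the earliest sample; a window without any
stated-polarity sample still returns the extremum but flags it. The FAL
rectifies to the component's polarity (robust to baseline ripple; a
signed-area alternative sits behind `area = "signed"`), integrates by the
trapezoid rule, and inverts the cumulative curve by linear interpolation
— an independent brute-force scan oracle agrees to 1e−9 ms. The windowed
mean integrates the piecewise-linear waveform over the exact (possibly
fractional) 20-ms window, so a linear ramp returns its centre value. The
MMN (100–300 ms) and P3b (250–900 ms) FAL windows are package defaults
chosen to bracket every reported mean latency; the source states no
windows for the difference components. A leave-one-out average with *no*
rectified area in the window (possible for the near-zero
older/virtual/distance MMN cell) is scored at the window midpoint and
flagged, keeping jackknife score vectors complete; the low-level operation
keeps its hard-error contract.

## Jackknife-corrected inference

Scores are measures of leave-one-participant-out averages within each age
group. For linear measures this shrinks within-group deviations by
1/(n−1); the package corrects by exactly inverting that map
(y_i = n·mean(J) − (n−1)·J_i per group) before running conventional
statistics. For equal groups this coincides with the classical
divide-t-by-(n−1), divide-F-by-(n−1)² rule; unlike a fixed divisor it
stays exact for unequal groups, and for the between-subject t the usual
(n₁+n₂−2) divisor would *not* reproduce the conventional statistic under
within-group leave-one-out — the linear-measure equivalence test in the
suite is the arbiter of this choice. The mixed 2×2×2 ANOVA itself is
computed from per-participant contrast scores (exact for this design;
Type-III/unweighted-means behaviour under unbalance; `stats::aov` serves
as the oracle in tests, not as the engine, so the equivalence check keeps
two independent routes). Partial η² is F/(F + df₂); p-values use the
conventional degrees of freedom. Sphericity corrections are unnecessary
for 2-level factors. Post hoc real-vs-virtual t-tests are BH-FDR-adjusted
within each component × measure family. Bayes factors for these contrasts
are JZS (Cauchy(0, √2/2) effect-size prior) computed from the corrected t
— whether the original analysis fed jackknifed or individual scores to its
BF tests is unstated; the corrected-t route keeps frequentist and Bayesian
columns on the same footing. The BF integral is evaluated adaptively on
the normal-inverse-gamma mixture representation and tested at 1e−6
relative against a fine-grid noncentral-t quadrature over the prior.
Behavioral accuracies use the adjusted logit log(p*/(1−p*)) with
p* = (k+0.5)/(n+1), keeping perfect scores finite, and a conventional
(non-jackknifed) mixed ANOVA.

## The fast cohort path and its equivalence guarantees

A full cohort is 88 sessions of 64 × ~1.8 M samples; generating broadband
noise and FIR-filtering it channel by channel in R would take hours. The
cohort runner instead exploits linearity three ways, each covered by an
equivalence test against the literal module chain:

1. **Noise:** 1/f noise is drawn directly in the frequency domain with the
   compensated FIR response folded into the spectrum. Given the same
   spectrum draws this is the *same* realization as generate-then-filter
   (asserted to 1e−8 on small recordings). Spectrum bins where the shaped
   amplitude falls below 1e−4 of its maximum are skipped (< 4e−8 of the
   variance).
2. **Signal:** component bumps are convolved with the combined kernel once
   and placed as templates (filtering commutes with time shifts). With
   noise off, the fast path reproduces the literal
   synthesize→filter→re-reference→epoch chain to machine precision.
3. **Channels:** topographies are zero-sum, so the 41 non-grid channels
   enter only through the average-reference mean; their noise is drawn as
   one aggregate trace with SD·√41 — identical in law.

Re-epoching after alignment reuses margin-extended per-cell averages
(±32 ms) because all trials of a cell share one integer shift and every
stage after epoching is linear; amplitude rejection is applied on the
margin-extended window so the retained set is shift-invariant. The literal
`apply_shifts_and_reepoch()` is retained and tested equal.

For calibration studies needing thousands of cohorts, a waveform-level
emulator (`simulate_measure_cohort()`) draws the per-participant grid
traces directly: the same component parameter model plus smooth residual
noise whose per-trace SDs (0.19/0.10/0.18 µV for target-ERP, MMN- and
P3b-difference traces) were measured from the full generator's
signal-free trace windows at default settings, with a 15-ms interpolation
scale matching the observed autocorrelation. It skips continuous EEG,
filtering and alignment — it emulates their *output*, so it can calibrate
the inference machinery but cannot test the preprocessing itself; the
full-EEG path is exercised by the recovery tests.

## What the tests establish — and what they cannot

The suite asserts: exact design counts (684 standards, 216 flagged
post-target standards, all gaps in 2–6); the geometry/acoustics constants;
offset-injection recovery within ±1 ms across the observed −19..+11 ms
shift range and alignment idempotence; full-scale recovery of the 57-ms P1
reference (±2 ms) and the −0.98 µV grand azimuth MMN (±0.15 µV) on a
default 44-participant cohort; the oracle equivalences (FAL 1e−9; JZS BF
1e−6; BH step-up; jackknife linear-measure 1e−6); corrected-ANOVA type-I
rate 5% ± 2% under the null table (1000 reduced-scale cohorts); and
recovery of the full qualitative effect-sign pattern in ≥ 90% of emulated
22+22 cohorts. With the F-derived between-subject variances the grand-MMN
estimator has an SD near 0.08 µV, so the ±0.15 µV criterion retains
roughly a 7% across-seed failure probability — a property of the stated
world, not of the implementation. None of this validates the generator
against real EEG: channel-independent noise, idealised topographies,
absent artifacts and the small-latency-jitter commitment all mean a green
suite demonstrates the *pipeline's* correctness, not biological realism.

## Reproducibility

A run is fully determined by its configuration and master seed: the seed
expands to per-session substreams (drawn once up front), participant
random effects, and per-session RNG for sequence, behavior, component
jitter and noise, in a fixed documented order. Identical seeds give
bit-identical score tables; the manifest records a configuration hash,
per-stage timings and the per-session trial-count ledger. Configurations
serialize to JSON (`save_config()`/`load_config()`) — no YAML parser is
assumed — and result tables to TSV (`write_study_tsv()`).
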