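---
title: "Multi-scale ripple analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale ripple analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rippletools detects transient 80–120 Hz ripple oscillations simultaneously at
the macro scale (intracranial EEG) and micro scale (microelectrode-array
local field potentials, LFP), and quantifies how those events relate to
single-unit spiking: spike–field phase locking through pairwise phase
consistency (PPC), cross-scale phase alignment, event coincidence against
shift-predictor and circular-shift chance distributions, burstiness of
population spiking, bimodality of activity distributions, and random-effects
pooling of per-participant correlation effects. This vignette explains the
underlying models and the choices the package makes where the methods
literature leaves the details open.

## The detection model

A ripple is defined operationally: the voltage is band-passed in the ripple
band (80–120 Hz by default) with a second-order Butterworth design applied
forward–backward (zero phase), and the instantaneous amplitude is the
magnitude of the analytic signal. Candidate events are intervals where the
envelope exceeds an *extent* threshold, expressed in SD of the envelope;
candidates closer than a join gap are merged; an event is retained if it
lasts at least a minimum duration and its envelope maximum exceeds a second,
higher *maximum-amplitude* threshold. Two presets are provided:

| preset  | extent | maximum | min duration | join gap |
|---------|--------|---------|--------------|----------|
| strict  | 2 SD   | 3 SD    | 25 ms        | 15 ms    |
| relaxed | 1 SD   | 2 SD    | 10 ms        | 15 ms    |

The relaxed preset exists because ripples form a continuum of amplitudes and
durations; events below conventional thresholds still carry physiological
signal, and several analyses in the package are designed to run on that
continuum. No upper duration limit is applied. Every strict event is
contained in some relaxed event on the same signal (the superlevel sets
nest), which the test suite asserts as an invariant.

Choices the detector had to make explicit:

* **Normalization epoch.** Envelope mean and SD are computed per channel
  over the whole session, excluding artifact-masked samples (a per-trial
  alternative is available via `envelope_stats = "trials"`). The original
  description does not state the epoch; session-wide statistics make event
  z-scores comparable across trials.
* **Event extent.** Start and end are the *extent*-threshold crossings, not
  the maximum-threshold crossings: the lower threshold delimits the event,
  the higher one validates it.
* **Join rule.** The gap is measured end-of-previous to start-of-next, and
  merging happens for gaps strictly below 15 ms.
* **Artifact exclusion.** Events overlapping any masked sample (interictal
  discharges, movement transients) are discarded, mirroring the exclusion of
  pathological high-frequency oscillations.
* **Threshold monotonicity is only guaranteed without a mask.** Raising the
  extent threshold shrinks a candidate interval, which can pull it off a
  masked sample and *rescue* an event that the wider interval would have
  lost. The monotonicity invariant is therefore stated (and tested) for
  unmasked detection.

## Preprocessing

Line noise at 60 and 120 Hz is removed by least-squares regression of
sine/cosine pairs in sliding windows (10 s, 50% overlap, Hann-weighted
overlap-add so the fitted component is smooth and the weights sum to one
everywhere). The window length is a package choice; the cited toolbox
approach gives no parameters. Slow fluctuations (≤ 2 Hz) are removed by
subtracting a zero-phase low-pass running fit. Transients are masked where
the z-score of either the signal gradient or the envelope of the > 250 Hz
high-passed signal exceeds 5, dilated ±100 ms; on clean Gaussian background
this flags roughly 0.5–1% of samples (the tails of the high-frequency
envelope are Rayleigh-like, not Gaussian), which is the false-positive floor
of that rule rather than a defect.

Trial rejection sorts a per-trial voltage statistic and excludes trials
above `Q3 + 2.3 (Q3 − Q1)`. The statistic is interpreted as the mean
*absolute* voltage per trial per channel, aggregated across channels by the
maximum: raw signed means cancel around zero and cannot index artifact
severity. This interpretation is configurable (`stat_fun`). The comparison
is a strict inequality with no special case: when all trials are equal the
threshold equals the common value and everything is kept, and a degenerate
quartile spread still excludes genuinely extreme trials.

A common average reference is provided (`common_average_reference`) and is
idempotent. The synthetic pipeline does *not* apply it to the simulated
iEEG: with a handful of synthetic channels that share the true
ensemble-mean signal by construction, subtracting the channel average would
subtract the signal itself. CAR is appropriate when the shared component is
reference contamination spread over many electrodes, which is the clinical
situation but not the simulated one.

## Spectral measures

Time–frequency power and phase come from convolution with complex Morlet
wavelets (200 linearly spaced frequencies between 2 and 200 Hz, 6 cycles by
default), implemented as frequency-domain multiplication with one-sided
Gaussian kernels so each output is an analytic signal. "Wavelet number 6" is
read as 6 cycles. Wavelets are energy-normalized (unit continuous-time L2
norm); the normalization only affects raw power, never the log-transformed
and z-scored values used downstream. Power is squared magnitude,
log-transformed, and z-scored per frequency against the session mean and SD
with a 1000 ms edge buffer excluded from all statistics.

High-frequency activity (HFA) is the mean z-scored power over 70–200 Hz,
smoothed with a sliding 600 ms window at 90% overlap (output step 60 ms).
The ripple-removal control recomputes HFA after deleting the sample indices
of detected ripples from the window averages; on sessions where ripples
drive the high-frequency band this reduces trial-mean HFA, which is the
package's synthetic analogue of the control analysis relating HFA to
discrete events.

## The phase-locking machinery

All phases follow the `x = A cos(φ)` convention, so the oscillation trough
is at φ = π. PPC is the mean pairwise cosine of phase differences,

γ̂ = 2/(N(N−1)) Σ_{j<k} cos(θ_j − θ_k) = (|Σ_j e^{iθ_j}|² − N) / (N(N−1)),

a bias-free concentration estimator whose population value equals the
squared phase-locking value; it lives in [−1/(N−1), 1]. The unit-vector
identity is exact, and the suite checks it against the explicit double loop
to 1e−12, together with the analytic cases (equal phases → 1, an antipodal
pair → −1, four evenly spaced phases → −1/3) and the unbiasedness identity
for von Mises samples (mean PPC ≈ (I₁(κ)/I₀(κ))²). The average pairwise
circular distance (APCD) is reported alongside as a descriptive statistic;
its "mod π" distance is kept separate from the PPC estimator itself. The
Rayleigh p-value uses the standard finite-n approximation
`p = exp(√(1+4n+4(n²−R²)) − (1+2n))`.

Spike–field PPC spectra evaluate the Morlet phase of the unit's channel at
each spike time (60 log-spaced frequencies between 2 and 400 Hz by
default), compute PPC per trial for trials contributing at least 2 spikes,
and average across trials and then units. The z-scored variant builds a
null by re-pairing each trial's spikes with the LFP of a randomly chosen
other trial (same within-trial offsets), 100 shuffles by default. Condition
contrasts (e.g. spikes inside vs outside ripples) pool spikes across trials
because per-trial counts are low, require 10 spikes per condition per unit,
subsample the larger condition to the smaller count 200 times, and use raw
(not z-scored) PPC since the comparison is within participant.

Cross-scale alignment treats every time point inside a macro-scale ripple
as an observation: the across-channel set of micro-scale ripple-band phases
at that sample gets a PPC value, and the event's score is the maximum over
its samples. A variant restricts the channel set, per event, to channels
with a concurrently detected LFP ripple.

## Cluster permutation across frequencies

Per frequency, a one-sample t-test of the per-participant values against
zero; adjacent significant frequencies (two-sided p < .05) with a common
sign form clusters scored by the summed t-statistics. The null distribution
retains the maximum *signed* cluster score under random per-participant
sign flips; all 2^k patterns are enumerated when 2^k does not exceed the
permutation budget. Two consequences worth knowing:

* The test is **directed at positive deviations** — the direction the
  phase-locking questions ask about. Negative clusters are reported with p
  near 1; negate the input to test the other direction. Had the null used
  the maximum *absolute* score instead, every sign pattern would have a
  mirrored twin and the attainable p floor would be 2/2^k — with six
  participants the exact size of the exhaustive test would be 1/32 ≈ .031
  and with five, p < .05 would be unattainable. The signed maximum gives an
  exact size of 3/64 ≈ .047 at k = 6, matching the nominal level.
* p-values can never be zero: the identity pattern always counts against
  itself (with a numerical tolerance so recomputation noise cannot drop
  it), and sampled permutations use the (b+1)/(n+1) convention.

For paired two-condition comparisons, pass per-participant differences:
swapping condition labels within a participant is exactly a sign flip of
the difference.

## Event-level synchrony statistics

Cross-correlograms histogram peak-time differences between events of the
same trial, pooled across trials (1 ms bins, ±200 ms by default; both are
package defaults). The
shift predictor cross-correlates each trial's events in one channel with
the events of every *other* trial in the second channel, averages the n−1
correlograms per trial (unweighted), and sums across trials so that true
and chance correlograms share a scale. The synchronization metric is the
ratio of true to predictor mass in a ±50 ms window; 1 is chance. The
cross-scale coincidence statistic replaces the predictor with the average
correlogram over random per-trial circular shifts of the micro-scale event
train. The population burst metric compares the ±25 ms mass of the
population spiking auto-correlogram inside macro-scale ripples against
random duration-matched windows placed between ripples; five matched
windows are drawn per event and averaged, which keeps the chance estimate
defined when between-ripple spiking is sparse. A session with no in-ripple
spiking returns 0 by definition.

Circular-shift nulls shift each unit's spike indices independently within
each trial by a uniform draw that excludes zero, recompute the target
statistic, and report the exceedance probability with the (b+1)/(n+1)
convention. The same machinery, applied to the ripple-band phase series
within each detected event, serves the alignment-versus-amplitude control.

## Dip test on binned densities

Hartigan's dip — the maximum distance between the empirical distribution
function and the nearest unimodal distribution function — is computed on a
200-bin probability density over the range of the data, and z-scored
against the dips of 10,000 uniform PDFs of the same sample size and
binning. The dip itself is computed exactly for a weighted point
distribution via a convex-envelope characterization: for a modal split
after point k, a convex left fit within a ±t tube around the ECDF exists
iff 2t is at least the largest gap between upper ECDF corners and the lower
convex envelope of the lower corners, the concave right side is symmetric,
and the dip minimizes the larger one-sided requirement over splits. The
test suite verifies this implementation against an independent
linear-programming formulation of the same minimax problem (solved with
`boot::simplex`, enumerating modal intervals) on randomized small samples,
along with the classical facts dip(two points) = 1/4 and affine invariance.
Because the null depends only on sample size and binning, callers may reuse
one null across repeated tests (`null_dips`), which the calibration
simulations do.

## Meta-analysis

Per participant, the observed correlation is z-scored against its own
shuffle-null distribution — the r-equivalent construction — and treated as
an effect with sampling variance 1/(n−3), the Fisher-z large-sample
variance for a correlation built from n samples (the r-equivalent
construction itself does not fix a variance; 1/(n−3) is the standard choice
and is configurable by supplying `vi` directly). Effects are pooled by a
random-effects model fit by restricted maximum likelihood through
`metafor::rma`; the package reports the pooled estimate, its 95% CI, τ²,
and a forest-plot-ready per-participant table.

## What the synthetic generator emulates — and what it does not

`sim_config()`/`build_session()` produce sessions with: 1/f background
(slope 2) plus 60/120 Hz mains components; Hann-windowed sinusoidal ripple
bursts whose carrier frequency is drawn in the band and whose amplitudes
and durations form a continuum (log-normal with median 2.5 envelope-SD and
σ_log 0.4; gamma with shape 3, mean 40 ms, floored at 15 ms); a trial
structure (4 s trials, 35% "correct") with per-channel ripple rates of 0.45
Hz on correct and 0.30 Hz on incorrect trials, giving a session mean near
0.35 Hz; a controllable fraction of events shared — identical time,
frequency, and phase — across the micro-array (default 0.4); iEEG channels
formed as the array ensemble mean plus independent 1/f noise; spike trains
with Poisson baseline (2.5 Hz) plus in-event bursts whose ripple phase is
von Mises around the trough (π) and whose count scales with event
amplitude; stereotyped biphasic interictal-discharge transients (~50 ms, 10
channel-SD) at shared times on both scales; and synthetic 32-sample spike
waveforms. One RNG stream per sub-generator is derived from the master
seed, so identical configurations reproduce bit-identical sessions.

Two unit conventions deserve emphasis because there is no canonical
generative model for such events and the choices are the package's own:

* **Amplitude** is the expected peak of the *filtered* ripple-band envelope
  in session z-score units. Two things follow. First, the events inflate
  the envelope statistics that define their own units, so the generator
  calibrates by injecting a provisional event stream into a probe channel
  and iterating the envelope mean/SD to a fixed point. Second, the
  band-pass attenuates carriers near the band edges, so the injected
  amplitude is compensated by the zero-phase filter gain at the carrier
  frequency — without this, an "amplitude 4" event at 118 Hz would be
  delivered ~30% weak and detector-facing guarantees would silently
  degrade.
* **Duration** is the expected time the envelope spends above the 2-SD
  extent threshold (the Hann window length is solved per event from the
  amplitude, capped for sub-threshold events). Durations are thus specified
  in the units the detector measures.

Features of real recordings that the generator deliberately does not
emulate: biophysical neuron or field models, electrode geometry and volume
conduction, non-stationary background spectra, spike sorting errors and
waveform drift, seizure activity beyond stereotyped IEDs, and behavioural
reaction-time structure. Consequently, passing tests demonstrate that the
*analysis chain* is correct and calibrated under known ground truth — not
that any particular biological claim holds in real data.

## Numerical choices and degenerate inputs

* Analytic signals via FFT; phases wrapped into (−π, π].
* Butterworth designs are order 2, applied forward–backward (effective
  order 4 magnitude, zero phase), so phase-locking measures see no filter
  delay.
* Spike-rate kernels are truncated at ±5σ with reflection at the edges, so
  the rate integrates exactly to the spike count.
* Waveform SNR errors out on identical waveforms (zero noise) instead of
  returning infinity; PPC and the Rayleigh test require at least two
  phases; quartile rejection requires at least four trials; CAR requires at
  least two channels; meta-analysis requires two studies and positive
  variances; the dip requires ten samples with nonzero range.
* The narrowband-episode detector fits the 1/f background by robust
  regression (`MASS::rlm`) of log power on log frequency (falling back to
  ordinary least squares if it fails to converge), defines bands as
  contiguous frequencies above the fit, and estimates instantaneous
  frequency by frequency sliding: the smoothed derivative (10 ms median
  filter, then 10 ms moving average) of the unwrapped Hilbert phase.
  Episode activity is judged on the wavelet power scale on both sides of
  the comparison.
* Very short bursts (≲ 3 cycles) have broadband spectra; the band-pass
  reshapes them and their measured instantaneous phase deviates from the
  carrier model. Phase-locking validation against analytic expectations is
  therefore done on configurations with ≥ 30 ms events and band-centered
  carriers; the default continuum includes shorter events on purpose, and
  their partial phase scrambling is part of what the relaxed detector and
  the z-scored statistics are exercised against.

## Problem sizes used by the tests and the acceptance script

Simulation sizes are the package's own desk-scale choices: reference
sessions for detector validation run 600 s at 1000 Hz (the generator's
default), detection recall is evaluated on a 24–96-channel array (recall
and rate are per-channel properties, so the channel count only sets the
sample size), phase-locking and synchrony effect checks use 35–160 s
sessions with 2–8 channels, calibration simulations use 500 null datasets
for the family-wise error rate of the cluster test and 200 runs for
p-uniformity, and the dip null uses 10,000 uniform PDFs (shared across
repeated calibration runs, which is valid because the null depends only on
sample size and binning).

## Known limitations

* The amplitude unit calibration targets channel-exchangeable backgrounds;
  configurations whose channels differ in variance would need per-channel
  calibration.
* The cluster test corrects across frequencies only; time–frequency
  clustering is out of scope.
* The shift predictor assumes trials of comparable length (relative event
  times are pooled across trials); the trial-shuffle PPC null maps
  within-trial offsets modulo the target trial length.
* `ripple_alignment_ppc` treats time points within an event as
  observations, which are serially dependent; this matches the procedure
  being reproduced, and its chance level is therefore assessed by the
  circular-shift null rather than analytically.
* The r-equivalent's 1/(n−3) variance treats windows/events as independent
  samples; autocorrelation within sessions makes it optimistic, which
  matters for the width of per-participant CIs but not for the pooled
  point estimate recovery that the tests check.
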