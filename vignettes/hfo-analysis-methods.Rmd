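---
title: "Detection and classification of high-frequency oscillations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection and classification of high-frequency oscillations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfokit)
```

High-frequency oscillations (HFOs) — brief oscillatory events above roughly
80 Hz in intracranial EEG — are a candidate biomarker of epileptogenic
tissue. `hfokit` implements the full analysis chain: calibrated reading of
clinical EDF recordings, band-pass isolation of the HFO band, two
complementary automatic detectors, a compact convolutional classifier that
separates artifacts and spike-associated HFOs, concordance evaluation
between detectors, and a synthetic simulator that provides ground truth for
every stage. This vignette explains the models, the parameters that matter,
and the design choices made where the methods literature leaves the design
open.

## Signal reading and calibration

EDF stores 16-bit integers; each channel's header declares a physical range
$[V_{\min}, V_{\max}]$ and a digital range $[D_{\min}, D_{\max}]$. The
physical signal is the affine map

$$V = R\,D_{\mathrm{raw}} + O,\qquad
R = \frac{V_{\max}-V_{\min}}{D_{\max}-D_{\min}},\qquad
O = V_{\min} - R\,D_{\min},$$

exact at both digital endpoints. An offset-free variant ($V = R\,
D_{\mathrm{raw}}$) circulates in older tooling and produces a DC-shifted
trace; `hfokit` always includes the offset, matching mainstream readers.
Units are whatever the header declares (conventionally microvolts); no
conversion is attempted, since the map is dimension-agnostic. Files whose
channels disagree on sampling rate are rejected rather than resampled — the
analysis chain assumes one clock — and EDF+ annotation streams are ignored.
Sample coordinates are 0-based and half-open throughout, with time
$t = i/f_s$; the convention is arbitrary but applied uniformly.

## Band-pass filtering

The HFO band is isolated with a Chebyshev type-II band-pass. The contract
is stated as four numbers: passband edges (default 80–500 Hz), maximum
passband ripple $r_p$ (0.5 dB) and minimum stopband attenuation $r_s$
(93 dB). Type II puts the equiripple behaviour in the stopband, leaving the
passband monotone — appropriate when event amplitudes matter. A 100 dB
request at this geometry drives the design numerically infeasible; 93 dB is
the closest contract a stable realization meets, and the default.

Only the two passband numbers are conventionally quoted, so the stopband
edges default to $0.9 \times$ the low edge and $\min(1.1 \times$ high edge,
$0.95 \times$ Nyquist$)$; all four edges are explicit in `filter_spec()`.
The minimal order comes from the closed-form Chebyshev bound evaluated at
the bilinear-prewarped edges; the design chain is analog prototype →
lowpass-to-bandpass transform → bilinear transform → second-order sections.
Transfer-function polynomials are never formed: at the realized order
(48 for the default contract) their coefficients overflow double precision,
which is precisely the failure mode the SOS factorization avoids. Filtering
is zero-phase by default (forward–backward application with odd extension
and steady-state initial conditions), the common choice in HFO work because
detector thresholds operate on instantaneous energy; a causal single pass
is available behind a flag. The realized response is verified on a dense
grid with 0.1 dB slack for floating-point evaluation.

## The STE detector

The short-time-energy detector computes a centered moving RMS (3 ms window)
of the band-passed signal and declares candidate events where the RMS
exceeds the epoch mean plus 5 SD for at least 6 ms; candidates closer than
10 ms merge, and a candidate is kept only if the rectified signal shows at
least 6 local maxima above its mean plus 3 SD. Statistics are computed per
600 s epoch (a shorter final epoch is processed as-is; recordings shorter
than one epoch form a single epoch, with a warning). All constants are
fields of `ste_params()`.

One genuinely open design point is where an event *ends*. A threshold five
standard deviations into the energy distribution's tail detects reliably
but systematically truncates tapered events: for a Gaussian-envelope burst
the mean+5SD crossings sit near $\pm 1.5\sigma$ while the event's support
extends to $\pm 3\sigma$, so single-threshold boundaries capture roughly
half the event regardless of amplitude. `hfokit` therefore delineates each
supra-threshold run outward to the crossings of a secondary lower threshold
(`boundary_sd`, default mean + 1 SD), a standard dual-threshold
burst-delineation scheme; setting `boundary_sd = rms_threshold_sd`
reproduces plain run boundaries. Local maxima are strict sign changes of
the first difference, with plateaus credited to their leftmost sample, and
merging precedes the peak-count validation.

## The MNI-style detector

The second detector classifies 125 ms segments of the band-passed signal as
*baseline* or not by the wavelet entropy of their autocorrelation spectrum:
the segment's power spectrum is projected onto a bank of Gaussian Gabor
kernels spanning the analysis band (one matrix multiplication over all
scales), and the Shannon entropy of the normalized per-scale energies is
compared with $0.67 \log(n_{\mathrm{scales}})$. Noise-like segments spread
energy across scales and score high; oscillations concentrate it and score
low. The bank's time-bandwidth constant (`entropy_cycles`, default 12) is
chosen so adjacent log-spaced scales are resolvable — a broader bank blurs
oscillations across scales and lets event segments masquerade as baseline,
which in turn contaminates the threshold estimate.

With at least 5 s of cumulative baseline, the detection threshold is the
99.99th percentile of the baseline moving-RMS energy (10 ms window); events
are supra-threshold stretches of at least 10 ms, merged across sub-10 ms
gaps, delineated outward to a secondary 95th-percentile boundary level for
the same truncation reason as STE. Channels with continuous high-frequency
activity lack usable baseline; they fall to an iterative branch that fits a
gamma distribution to the energy samples per 60 s block, thresholds at its
95th-percentile CDF, removes the detected stretches, and refits for up to
10 rounds. The gamma fit subsamples at most 10,000 energy values; that
subsampling is the detector's only source of randomness, drawn from a
generator seeded per channel, which is why identical input and seed give
bitwise-identical output.

## Channel-parallel orchestration

Channels share no state, so `detect()` distributes them across forked
worker processes. Per-channel seeds derive from the master seed plus a
stable hash of the channel name, making results invariant to both `n_jobs`
and channel order. On platforms without fork the work runs serially with
identical results.

## Event features

Each detected event is summarized by two 128×128 images computed from a
window of ±285 ms around the event center: a time-frequency image (Morlet
magnitude scalogram, 6-cycle kernel, 128 linear frequency steps over
10–290 Hz computed directly — no post-hoc resize — with low frequencies at
the bottom) and an amplitude-coding image (the waveform resampled to 128
columns, each column filled outward from the midline over rows proportional
to the normalized absolute amplitude, signed by polarity). Both are
min–max normalized per image with a zero-range guard. The default geometry
gives 2.1875 Hz and 4.4531 ms per pixel; the whole geometry scales
coherently from 32×32 (10–80 Hz, ±72 ms) to 224×224 (10–500 Hz, ±500 ms).
At the small end the low-frequency wavelets outlast the window; the
too-short guard therefore demands only one full cycle of the lowest
frequency, accepting edge effects in exchange for supporting the geometry
sweep. The time-frequency input uses the raw (unfiltered) segment — the
10 Hz floor would be empty on a band-passed one — with the choice exposed
to callers.

Training-time augmentation shifts the window center uniformly within
±50 ms (re-extracting from the recording, so new samples enter the window)
and reverses the segment in time with probability 1/2. Evaluation paths
never augment.

## Classifier and training protocol

Two binary models share one compact architecture: 3×3 convolution + ReLU +
2×2 max-pool blocks (default widths 8-16-32-32) and a small dense head with
softmax. The artifact-rejection model sees the time-frequency image alone;
the spike classifier sees both images as two input channels. The default
network costs about 13 M multiply-accumulates at 128×128 — deliberately far
under the few-hundred-M budget that makes CPU inference practical — and no
claim of compatibility with any externally published weights is made.

Training is Adam (learning rate 3e-4, batch 128) for 30 epochs with
augmentation applied to every training sample in every epoch; the returned
model is the checkpoint with minimum validation loss. Evaluation uses
five-fold cross-validation: the shuffled data divides into five test
groups, and within each fold the remainder splits so train and validation
are 70% and 10% of the whole set. Per-fold metrics (precision, recall,
accuracy, F1, with zero denominators reported as undefined rather than 0)
are summarized as means with normal-theory 95% confidence intervals —
chosen over t-intervals as the convention in the applied literature; the
difference at five folds is a constant factor the reader can apply. Class
imbalance is handled by unweighted loss. A rule-based override labels any
event in the first or last second of a recording as artifact, because
recording edges produce filter and montage transients regardless of what
the models say.

Structured pruning iteratively removes the convolution channel with the
smallest filter L2 norm, propagating the removal to the dependent input
slice of the following layer (or the dense head), and fine-tunes at a fixed
cadence — by default 5000 iterations fine-tuning every 250 by 5 epochs,
with a reduced preset used in the test suite. The criterion is simpler than
gradient-based saliency methods but structurally faithful to
dependency-aware channel pruning, and swappable.

## Concordance evaluation

Two detectors' event sets are compared per channel through the overlap
ratio — interval intersection over union, 1 exactly for identical events —
with "exceeds a threshold" read inclusively so that threshold 1.0 demands
integer-sample equality. Matching is one-to-one and maximizes the number of
matched pairs: candidate pairs come from a linear sweep over the sorted
intervals, and an augmenting-path search (exploring higher-overlap edges
first) guarantees maximum cardinality, verified against an exhaustive
bipartite-matching oracle in the tests. Among equal-cardinality matchings
the higher-overlap preference acts as a tie-break heuristic, not a
certified maximum-weight solution. The discrepancy statistic is the number
of unmatched events from both sets over the reference set's size.

## The synthetic cohort

The simulator emulates the study conditions every property check runs
under: per-channel $1/f$ pink background noise (spectral shaping of seeded
white noise, exponent 1), Gaussian-windowed sinusoidal ripple events
(80–250 Hz, 30–100 ms, truth interval defined as the ±3σ envelope support),
optional biphasic spike transients co-occurring with events, and broadband
raised-cosine artifact bursts. Event amplitude is specified as the RMS of
the injected component over its truth interval in multiples of the
broadband background RMS — an SNR in the usual sense, and the reading under
which the generator's post-hoc SNR matches its configuration. The default
recovery conditions are 4 channels × 60 s with 20 ripples at 6× background
RMS. Everything is reproducible from one seed, with noise drawn before
event parameters so the injected component is recoverable by differencing
against a zero-event run.

What the simulator does *not* model is as important: electrode-dependent
noise floors, cross-channel correlation, physiological rhythms below the
HFO band beyond the $1/f$ slope, and the morphological diversity of real
artifacts. Passing recovery and separability checks on this cohort
demonstrates the pipeline's internal correctness — thresholds, boundaries,
seeding, geometry, protocol — not clinical-grade sensitivity; on clinical
data the detectors should be expected to behave like their well-studied
reference implementations, whose parameters they share.

## Numerical choices and problem sizes

Gamma fitting normalizes by the sample mean before maximum likelihood (the
shape is scale-invariant) with a Newton-on-shape fallback; quantile
percentile 0 returns 0. Filter responses are evaluated in magnitude
directly from the section cascade, never via polynomial expansion. The test
suite runs the classifier protocol on a 252-event synthetic feature set and
the recovery checks on the 4×60 s cohort; these sizes give stable
statistics (binomial noise on the validation split is tamed by averaging
across epochs where a chance-level claim is tested) while keeping the whole
suite practical on a single CPU. The concordance oracle sweep covers 1000
random instances with up to 10 events per side, where exhaustive matching
is tractable.

## Known limitations

Cross-channel artifact reasoning, separate ripple/fast-ripple sub-band
detection, Hilbert/SLL detector families and BrainVision/BioSemi readers
are out of scope. The amplitude-coding construction follows the column-fill
description above; compatibility with any specific published variant should
be verified before exchanging trained weights. XLSX export is not provided
in this environment; the per-channel and per-event tables are written as
CSV (with a JSON metadata header) or RDS, with the same content.
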