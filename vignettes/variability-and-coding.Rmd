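---
title: "Resting-discharge variability and coding strategy in central vestibular neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-discharge variability and coding strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestcoding)
```

## The scientific question

Central vestibular neurons fire spontaneously ("resting discharge") at
30–90 sp/s, and the regularity of that firing differs enormously from
neuron to neuron: the interspike-interval coefficient of variation (ISI CV)
spans roughly 0.1 (clock-like) to 1 (Poisson-like). This package implements
an analysis pipeline for asking what that variability does to a neuron's
coding strategy during naturalistic head motion:

* **Temporal whitening.** A neuron whose response power spectrum is flat
  over the stimulus band (0–20 Hz for natural head movements) spreads its
  power evenly over frequencies — the information-theoretic signature of
  efficient coding when the input signal-to-noise ratio is high. We
  quantify it with a whitening index (WI), the band integral of the
  spectrum divided by bandwidth × maximum in-band power.
* **Faithful encoding.** A neuron that tracks the stimulus waveform allows
  a linear decoder to reconstruct the stimulus from its spike train. We
  quantify it with the coding fraction (CF), the fraction of stimulus
  variance recovered by the optimal linear (Wiener) reconstruction, and
  with the coherence-based mutual-information rate.
* **Downstream use.** For neurons in the vestibulo-ocular reflex (VOR)
  pathway, faithfulness can be judged against a concrete decoder: the
  brainstem neural integrator and oculomotor plant. We feed spike trains
  through that model and score the predicted eye-velocity spectrum against
  the actual one with a matching index.

The pipeline is exercised on a synthetic cohort of model neurons in which
the resting-discharge CV is the experimentally graded variable while firing
rate and stimulus sensitivity are held fixed. On that cohort the package
reproduces, at simulation level, the qualitative signature pattern: WI
rises with CV, while CF, information rate and VOR matching index fall with
CV, and LN-predicted whitening matches measured whitening per neuron.

## Synthetic study conditions

The generator defines the study conditions; its defaults are fixed once and
used throughout the tests and the acceptance script.

* **Stimulus.** Naturalistic head yaw velocity is modelled as filtered
  Gaussian noise: white noise through a causal one-pole low-pass with a
  2 Hz knee, hard band-limited at 20 Hz with a zero-phase cutoff, rescaled
  to SD 20 deg/s. Only the Gaussianity, symmetry about zero and the 0–20 Hz
  band are empirically constrained for natural head motion; the knee and SD
  are free parameters and were chosen once as realistic for vigorous
  natural head movements of a freely moving primate (velocities mostly
  within ±60 deg/s, power concentrated below a few Hz). Because the
  construction is a linear filter of Gaussian noise, the marginal
  distribution is exactly Gaussian and symmetric.
* **Resting discharge.** A gamma-interval renewal process with shape
  k = 1/CV², so the target CV is exact in expectation and the
  renewal-theory anchor holds: spectral power at low frequencies
  approaches rate × CV².
* **Stimulus-driven responses.** A linear–nonlinear (LN) cascade: a linear
  stage (one-pole kernel, corner 30 Hz, gain = "sensitivity" in
  (sp/s)/(deg/s)), an optional static nonlinearity, a rate floor at zero,
  and spike generation by *time-rescaling* the same gamma renewal process
  through the integrated rate. Time-rescaling preserves the resting-segment
  CV while the rate follows the stimulus, which is what lets one CV
  parameter control both conditions.
* **Eye movements.** Slow-phase eye velocity is the VOR cascade output;
  optional quick phases are Poisson-timed 40–80 ms half-sine transients
  whose sign opposes the ongoing slow-phase excursion, with a mask marking
  them for exclusion. During quick phases the LN rate can be suppressed
  (the neurons pause).
* **Cohort.** 24 neurons: CV grid 0.1–0.8 × 3 independent seeds, rate
  50 sp/s, sensitivity 0.5 (sp/s)/(deg/s), 200 s of stimulation and 100 s
  of rest per neuron. Holding rate fixed across the CV grid mirrors the
  control analyses in which firing rates are confined to a narrow range so
  that variability is the only graded factor. All randomness derives from
  one master seed through named substreams, so any module can be
  regenerated independently and the whole cohort is bit-reproducible.

What the generator deliberately does **not** emulate: bursting, adaptation
and rate nonstationarity, eye-movement sensitivity of the neurons
themselves, 3-D rotations, and any attempt to match a specific recorded
stimulus waveform. Passing tests therefore show that the *estimators and
models* behave correctly under known ground truth, not that real central
vestibular neurons satisfy the generator's assumptions.

## Spectral estimation

All spectra come from one estimator: Welch-style averaging of 2.048 s
windows with 50% overlap, four orthonormal **sine tapers** per window, and
per-window mean removal. Sine tapers are a standard multitaper family with
variance reduction equivalent to Slepian tapers at this time–bandwidth
product and a closed construction; the defaults give ~0.49 Hz resolution,
comfortably resolving a 0–20 Hz band. Two normalization conventions are
carried in the estimate objects:

* traces: one-sided PSD (unit²/Hz) whose band integral recovers the
  variance (checked by a Parseval property test);
* spike trains: the binarized train is converted to a zero-mean rate signal
  (binary × 1000) and reported as a point-process spectral density in
  sp²/s, the convention in which a Poisson train is flat at its rate λ and
  a gamma renewal train approaches λ·CV² at low frequencies (both checked
  against renewal theory).

Rate traces (LN predictions, trial averages) use the point-process
convention so they are directly additive with spike spectra. Cross-spectra
use E[conj(X)·Y]/fs, which makes the transfer function from x to y equal
S\_xy/S\_xx and gives a delayed signal the phase slope −2πτ. Windows never
straddle the seams introduced by masking-and-concatenation; the boundary
list travels with the concatenated object. The Poisson surrogate band
simulates (by default) 1000 Poisson trains with the same spike count and
duration and takes per-frequency percentiles with the same estimator
settings.

Known estimator bias worth stating: the whitening index's reference level
is the in-band maximum of the (3-point median smoothed) spectrum, and a
maximum over noisy, positively correlated bins is biased upward. With the
default settings this depresses WI of an ideally white train to ~0.9–0.95
rather than 1. The median smoothing bounds the effect of single-bin
spikes; longer records or more tapers reduce it further, which is why the
Poisson-limit checks use 300 s rests.

## Information and optimality conventions

The mutual-information rate is the Gaussian-channel coherence lower bound,
−∫ log₂(1−C(f)) df over 0–20 Hz. The information estimator behind the
original analyses is not fully specified in print, so this bound is
documented as the package's convention and validated through internal
consistency (closed-form values for constant coherence, the analytic
C = ρ/(1+ρ) channel, and the monotone CV trends). "Optimality" is the
measured rate divided by the maximum possible rate at the same level of
variability: a water-filling Gaussian capacity over the band, with the
measured noise spectrum as channel noise and a total signal-power budget
equal to the measured stimulus-driven response power (response spectrum
minus resting spectrum, floored at zero, integrated over the band). A
flat-allocation bound is exposed behind a flag for sensitivity analysis.
The water-filling solver is checked against an exhaustive allocation
search on a two-band noise profile.

In the cohort run the noise spectrum is the resting-discharge spectrum
rather than a trial-residual spectrum. This is the model's own additivity
assumption — supported by the observation that resting and trial-to-trial
variability spectra are indistinguishable — and it keeps the default
cohort inside a practical runtime; the residual route
(`residual_noise_spectrum()`, `signal_noise_decomposition()`) is
implemented and tested on repeated-trial simulations.

## LN model and the whitening prediction

The linear stage is estimated as H(f) = P\_RS(f)/P\_SS(f); the tuning
function is G = |H| and "sensitivity" is G(1 Hz). The static nonlinearity
is the binned mean of observed firing rate against the linear prediction,
with monotone interpolation and clamped extrapolation. For this fit only,
both the linear prediction and the binarized rate are smoothed with the
same ~100 ms Gaussian kernel (SD 25 ms): using the *same* kernel on both
sides keeps a linear encoder's fitted slope at 1 regardless of the
smoothing bandwidth. Spectra are never computed from smoothed sequences.

The predicted response spectrum is P0(f) + P\_FR(f): the resting spectrum
plus the spectrum of the nonlinearity applied to the (unsmoothed) linear
prediction. The per-neuron agreement between predicted and measured
whitening indices (|ΔWI| ≤ 0.1 for ≥90% of the cohort, mean difference
≈ 0) is the pipeline's self-consistency check. `whitening_vs_cv_curve()`
holds the fitted linear/nonlinear stages fixed and regenerates P0 from
matched renewal trains across a CV grid — the model that isolates
variability as the driver of whitening. Individual points on that curve
jitter with the regenerated resting-spectrum realization; the curve is
increasing overall and exceeds 0.9 at the Poisson endpoint when the rest
record is long (300 s in the tests).

## Wiener reconstruction and coding fraction

Kernels are solved in the frequency domain (K = S\_RS\*/S\_RR for one
neuron; a per-frequency 2×2 cross-spectral solve for pairs), restricted to
0–30 Hz by default, inverse-transformed, truncated to ±300 ms and
cosine-tapered over the outer 10%. Two numerical choices matter:

* the DC bin of the solve is uninformative after per-window demeaning, so
  the kernel's DC response is extrapolated from the first resolved bin
  (the response is continuous there) rather than zeroed;
* spike trains enter as mean-subtracted binary sequences, which makes the
  kernel's DC term well-posed and the reconstruction an estimate of the
  stimulus about its mean.

Ill-conditioned pair solves are regularized by adding a small multiple of
the mean diagonal (the affected bin fraction is reported); identical
trains fall back to the single-neuron kernel with a warning. Samples
within half a kernel window of record edges or concatenation seams are
excluded from scoring.

CF = 1 − RMSE/σ (the root *inside* the normalization), the convention
under which a perfect reconstruction scores 1 and the mean predictor
scores 0. Scoring is on the fitting data by default, for comparability;
the agreement of the frequency-domain kernel with an explicit
least-squares FIR fit, and of CF with the analytic Wiener error on a
constructed Gaussian channel, are both part of the test suite. For those
equivalence checks the spectra are estimated with longer windows (10 s)
than the default: the least-squares oracle imposes no taper-induced
attenuation of long lags, and matching its effective resolution is what
brings the two independent solutions within a few percent of each other.

## VOR model

The head-to-eye cascade is implemented in reconstructed canonical forms
(the printed fractions in the source material are typographically
collapsed):

* afferents: sTc(1+sT1) / ((1+sT2)(1+sTc)) — torsion-pendulum dynamics
  with a lead term;
* VOR neurons: −g(T\_vor/Tc)(1+sTc)/(1+sT\_vor) — the canal time constant
  cancels and velocity storage (T\_vor = 16 s) takes its place;
* neural integrator: (sTe1+1)/s, with its pole at DC;
* plant: s·e^(−sτ)/((sTe1+1)(sTe2+1)), whose zero cancels the integrator
  pole, leaving a delayed first-order low-pass for the motor half.

Time constants: T1 = 0.0175 s, T2 = 0.0027 s, Tc = 5.7 s, T\_vor = 16 s,
Te1 = 1 s, Te2 = 0.016 s, τ = 8 ms, g\_vor = 1. Each cancellation identity
is unit-tested (composite gain insensitive to ±10% changes of Tc; NI ×
plant equals the closed-form low-pass), and the FFT simulation is checked
against the analytic gain and phase at six probe frequencies. Spike-driven
prediction removes the mean rate before the motor filter so the
integrator pole never integrates a DC rate; the composite DC gain is set
to zero (all pathway outputs are zero-mean).

The matching index between predicted and actual eye-velocity spectra is
mi = max(0, 1 − RMS\_f(log P\_pred − log P\_actual)/SD\_f(log P\_actual)),
with zero-power bins floored at 10⁻¹² of the in-band maximum. The printed
formula in the source material is corrupted; this convention is the
package's own, chosen to satisfy the stated properties (range [0,1], 1
exactly for identical spectra, invariance to common rescaling) and
documented as such. VOR gain is the negative slope of the eye-on-head
regression over retained (non-saccadic) samples.

## Numerical choices and degenerate inputs

* Band integrals use the trapezoidal rule on the estimator grid.
* Coherence is clipped to [0,1]; bins with vanishing auto-spectra are
  flagged undefined; coherence at 1 is capped at 1−10⁻⁹ before the
  information integral (and flagged).
* Renewal generation draws interval batches until the duration is covered;
  time-rescaling floors the rate at 10⁻⁹ sp/s so the cumulative intensity
  stays strictly increasing.
* `isi_stats()` refuses fewer than 3 spikes; CV uses the unbiased (n−1)
  SD, recorded in the output. Whether the original analyses used the
  biased or unbiased SD is unstated; for the train lengths involved the
  difference is negligible.
* Masks are half-open [start, end) intervals on a 0-based sample grid (bin
  t covers [t/fs, (t+1)/fs)), which makes concatenation unambiguous and
  lossless in round-trip I/O.
* Empty retained sets, all-zero spectra, zero-variance stimuli, zero
  power budgets and empty spike trains raise errors rather than returning
  silent defaults.

## Problem sizes

The default test and acceptance runs use 60–300 s records: 300 s for the
renewal-theory spectral oracles, 60 s for the Wiener/least-squares
equivalences, 120 s for the constructed Gaussian channel, 200 s of
stimulation per cohort neuron, and 24 neurons in the default cohort. These
sizes were chosen so every oracle comparison has enough averaging to sit
well inside its tolerance while the whole suite stays quick to run on a
single CPU.

## Known limitations

* The information measures are the coherence lower bound and a Gaussian
  capacity — appropriate for this model class, but not direct estimates;
  no bias-corrected or histogram-based information estimators are
  provided.
* The whitening index inherits the upward bias of a maximum over noisy
  bins (see above); comparisons across neurons analysed with identical
  settings are unaffected, absolute values near 1 are conservative.
* Quick-phase detection from raw eye traces is a simple velocity-threshold
  helper, not a clinical saccade detector.
* The oculomotor plant is linear: no motoneuron saturation, no VOR
  adaptation dynamics.
* Matching-index values are comparable within an estimator configuration;
  like the underlying log-spectral RMS they depend on the scored band and
  resolution.
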