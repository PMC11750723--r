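---
title: "Models and methods behind menmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind menmod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menmod)
```

`menmod` covers the computational chain of magnetoelectric-nanodisc (MEND)
neuromodulation: field-to-potential transduction, subthreshold temporal
summation on the membrane, and the fluorescence trace analyses used to read
out neuronal responses in vitro (calcium imaging) and in vivo (fibre
photometry), together with synthetic-data generators that close the loop for
parameter-recovery testing. This vignette explains each model, its
assumptions, the defaults and why they were chosen, and what the passing
tests do and do not establish.

## Transduction

A disc in a near-saturating offset field (OMF) responds to an alternating
field (AMF) with magnetostrictive strain; the piezoelectric shell converts
strain to surface polarization. We treat the chain linearly:

* `single_particle_potential(alpha, h_amf, L)` computes
  `V0 = alpha * h_amf * L` with exact unit conversion (mV mT^-1 cm^-1 x mT x
  m -> uV). The characteristic length defaults to the 250 nm disc diameter:
  with the measured peak coefficient of 150 mV mT^-1 cm^-1 and a 10 mT AMF
  this reproduces the reported ~37.5 uV single-particle potential exactly,
  which is the arithmetic that motivated the choice. Whether the original
  estimate used the diameter or another length is not stated in the source
  text; the length is therefore an explicit argument, not a constant.
* `me_model()` is a separable empirical model
  `alpha(f, H) = alpha_ref (f/f_ref)^p G(H)/G(H_ref)`. The frequency
  dependence is known only to be increasing below resonance, so a power law
  with default exponent 1 is used until `calibrate_freq_exponent()` is run
  on measured `(f, alpha)` pairs (an exact log-log least-squares fit; the
  test suite recovers a planted exponent of 0.5 to within 0.01 from a
  noiseless grid). The offset-field response `G` is a Gaussian bump centred
  at 220 mT — the field at which the measured coefficient peaks — with a free
  width (80 mT default); only the peak location is constrained by data.
* `interparticle_spacing()` converts a deposited surface mass density
  (ug mm^-2) to a particle count density via the disc mass
  `m = pi (D/2)^2 t rho`, with `rho` the volume-weighted composite density of
  the three layers (handbook values 5.17, 5.30 and 6.02 g cm^-3 for
  magnetite, cobalt ferrite and barium titanate; the source gives none). The
  default layer split (150 nm core, two 25 nm shells) is a representative
  geometry consistent with the 250 nm diameter; it enters only through the
  composite density, whose plausible range (5.17-6.02) moves the spacing by
  under 5%. Mean spacing uses the square-lattice convention `n^(-1/2)`; the
  Poisson nearest-neighbour expectation `0.5 n^(-1/2)` is reported alongside
  because deposited particles are closer to random than to a lattice.

## Membrane model

The mechanistic question is how particles generating tens of microvolts
excite neurons that need ~15 mV of depolarization. The model is repetitive
subthreshold summation:

* Both half-cycles of the AMF depolarize (rectified increments). This is
  required for the observed monotone rise of membrane potential over an
  epoch; with signed increments the potential would oscillate and never
  accumulate.
* Spatial summation over a one-dimensional particle lattice with spacing `d`
  (in units of the cell radius `a`) and effective space constant
  `lambda_eff`: `g(d) = 1 + 2 sum_n exp(-n d / lambda_eff)`, the cable-theory
  attenuation summed over both neighbours at every lattice distance. The
  implementation sums the series explicitly, truncating below 1e-12; tests
  verify it against the geometric closed form `1 + 2e^-x/(1-e^-x)`.
* Temporal summation: increments `dV = kappa g(d) V0` arrive at the
  half-period times `(k + 1/2)/(2f)` and accumulate in a lossless integrator
  (`tau_int = Inf`) during an epoch. The lossless default is implied by the
  printed anchor: 24.5 uV per half-cycle times 600 half-cycles is 14.7 mV
  ~ the 15 mV rest-to-threshold gap, i.e. near-perfect summation. A finite
  leak (`tau_int` in seconds) is available but off by default. Between
  epochs, the potential resets to rest (the data show a >= 5 s recovery
  requirement).

`calibrate_to_anchor()` pins the one unconstrained product: with rest -70 mV,
threshold -55 mV, 150 Hz and a 2 s epoch,
`kappa * g(0.25a) = 15000/(600 x 24.5) = 1.0204`. Holding `kappa = 1`
(no attenuation of the local particle potential), the space constant follows
from inverting the closed form, giving `lambda_eff = 0.0544 a`. Resting
potential is -70 mV by default (the value paired with the 2 s anchor);
a -75 mV variant used in some frequency sweeps is available via
`cable_params(v_rest = -75)`.

Numerical choices: events are generated in closed form (the equally spaced
increments admit an exact per-event recursion), so simulations are exact at
event times rather than step-integrated; threshold crossings use a 1e-9 mV
slack so that anchors calibrated to exact equality at the last event are not
lost to floating-point rounding; `threshold_v0()` bisects to 0.05 uV with an
explicit bracket check that reports the bracket on failure.

Two caveats are documented rather than hidden. First, the underlying
supplementary equations were not available; this reconstruction is
calibrated to the printed anchors (24.5 uV, -70/-55 mV, 2 s, 150 Hz) and its
correctness is carried by the property suite (exact linearity of dV in V0,
monotone trajectories, closed-form oracle agreement within one half-cycle,
bisection-vs-closed-form equality). The threshold-potential check is
therefore a calibration-consistency test, not an independent prediction.
Second, the claim that particles below 24.5 uV cannot fire "regardless of
spacing" holds in this model only for spacings at or above the particle
diameter (0.25 a at a 1 um cell radius): the lattice sum `g(d)` diverges as
`d -> 0`, so arbitrarily dense (unphysical, overlapping) lattices would fire
at any V0. The test suite asserts the positive threshold floor over
`d >= 0.25 a`, where the threshold is monotone increasing in `d` with its
minimum 24.5 uV at the anchor spacing. The model deliberately omits
conduction block above 150 Hz, ion-channel kinetics, diffuse-charge effects
and fluctuation summation.

## Calcium-event analysis

All statistics operate on `dF/F0` with `F0` the per-cell mean over the 30 s
immediately before the first stimulation onset. Windows are half-open
`[start, end)`; frame timestamps are `frame/fps`, 0-based; argmax ties
resolve to the earliest frame. Cells with non-positive `F0` or zero baseline
variance are excluded with warnings, never imputed.

* **Peak counting**: local maxima strictly above both neighbouring distinct
  values (plateaus count once, at their first frame) whose height above the
  cell's baseline mean exceeds half the reference SD. "Mean standard
  deviation" is read as the per-cell SD of dF/F0 over the full recording,
  averaged across the cells of the video, applied uniformly; a per-cell
  variant is a config switch.
* **Responsiveness**: a cell responds to an epoch if dF/F0 exceeds
  `3 sigma` at any frame within 15 s of onset, where `sigma` is the baseline
  SD. The scope of `sigma` is ambiguous in the source; the package default is
  the *pooled* (video-level) mean of per-cell baseline SDs, with per-cell as
  an option. The reason is statistical: at 1 fps the baseline window holds
  ~30 frames, and Monte-Carlo measurement shows the noisy per-cell SD
  roughly doubles the rule's false-positive rate on pure noise (~4% vs ~2%
  per cell-epoch window). Either way the rule has an irreducible
  false-positive floor on Gaussian noise — the test suite includes a
  Monte-Carlo oracle for it — so a detected responsive fraction estimates
  `p + (1-p) * FPR`, slightly above the true response probability `p`.
* **Spiking probability**: the population-average dF/F0 trace is thresholded
  at `3 sigma` of its own baseline within each epoch's window; the
  probability is the fraction of epochs that spike.
* **Latency**: time from onset to the dF/F0 argmax within the response
  window, at frame resolution, reported only for responsive (cell, epoch)
  pairs (absent rows, not zeros).

## Photometry analysis

The pipeline order is fixed: 25 Hz second-order Butterworth low-pass applied
forward-backward (zero phase, so peak positions are not lag-shifted; the
source does not specify phase handling), two-term exponential debleaching of
each channel, isosbestic subtraction, per-trial segmentation, classification.

The debleaching fit `a e^{bt} + c e^{dt}` is decay-constrained (`b, d <= 0`;
whether the original fits were constrained is unstated, so the constraint is
applied and documented). Initialisation uses log-linear fits to the first
and last thirds of the trace; non-convergence falls back to a single
exponential and then to the signal mean, each with a warning. Samples within
60 s after each stimulation onset are masked from the trend fit by default so
evoked transients do not bias it; long recordings are fitted on a thinned
grid (20,000 points) because the trend is smooth, and evaluated everywhere.

Because the motion-corrected residual (470 residual minus 405 residual) is
zero-mean, it cannot be segmented directly into `dF/F0` with a positive
per-trial `F0`. The session wrapper `pm_process()` therefore expresses the
residual as a fraction of the fitted 470 nm bleach level at each sample and
restores a constant DC level (the mean fitted intensity) before
segmentation. Per-trial `F0` is then positive, within-segment bleach drift
is absent, and the resulting `dF/F0` equals the fractional transient
amplitude; the elementwise `motion_subtract()` contract itself is unchanged.

Trial classification follows the 2-sigma rule: responsive if dF/F0 reaches
twice the SD of the trial's own pre-window at any sample within 20 s of
onset (`sigma` is per-trial; a pooled option exists). Peak intensity and
position are the post-onset maximum and its time; peak width is the interval
between the `sigma/2` crossings bracketing the maximum, linearly
interpolated between samples, and is reported as censored when the trace
never returns to that level on one side. Segmentation windows are preset A
(30 s pre / 150 s post) or preset B (15/85 s) matching the two fibre
configurations; trials whose windows exceed the recording are dropped with a
warning, and overlapping windows are permitted (logged), since close trial
spacing can overlap a 150 s post-window.

## Synthetic data

The generators plant known structure and return it as ground truth, so every
analysis stage is tested by recovery rather than by re-deriving its own
output.

**Calcium videos** (`gen_calcium_dataset()`): per cell and epoch a Bernoulli
response; responding pairs receive one transient whose fluorescence maximum
lands at `onset + latency`. Three choices matter and are deliberate:

* *Latency distribution*: latencies are drawn from a normal truncated at
  zero whose parameters are solved (`truncnorm_moment_params()`) so that the
  *truncated* distribution has the requested mean and SD (3.9 and 2.9 s for
  the in vitro presets). Reported latency statistics are sample moments of
  necessarily positive values; naively truncating a Normal(3.9, 2.9^2) would
  shift the planted mean to ~4.4 s and no analysis could recover 3.9 s.
* *Frame-grid quantisation*: the planted latency is rounded to the frame
  grid and the kernel peak placed exactly on a frame. At 1 fps, a continuous
  peak time combined with the asymmetric rise/decay kernel makes the sampled
  argmax land on the *later* frame most of the time (~+0.2 s mean offset), a
  pure measurement artifact that real recordings absorb into their reported
  statistics; planting on the grid keeps the ground truth representable in
  the sampled trace.
* *Kernel and noise*: a difference of exponentials with 0.2 s rise and 1.5 s
  decay (typical slow genetically encoded calcium indicator; the source
  specifies no kinetics, so these are labelled non-source defaults), unit
  peak, lognormal amplitude (mean 0.5 dF/F0, CV 0.2), additive white
  Gaussian noise (SD 0.05 dF/F0) on a multiplicative baseline, clipped at a
  small positive floor. Spontaneous activity defaults to zero events/s: real
  cultures do show spontaneous transients, so recovery tests on these data
  characterise the stimulus-locked component only.

Presets: `invitro-0.75/-0.5/-0.25` plant response probabilities
0.741/0.463/0.276 (the responsive fractions measured at those particle
densities); `fast-10fps` plants 857 +/- 69 ms latencies at 10 fps with a
fast kernel (0.05 s rise, 0.4 s decay) and a 3 s response window. The fast
preset's window is shorter than the default 15 s for two reasons: epochs in
the fast-imaging protocol are ~12 s apart, so a 15 s window would bleed into
the next epoch; and over 150 frames the 3-sigma rule's false positives,
whose latencies are uniform over the window, would bias the recovered
sub-second mean by ~+0.1 s.

**Photometry sessions** (`gen_photometry_session()`): each channel is a
two-term exponential bleach curve multiplied by `1 +` (transients +
physiological oscillation + motion + white noise) for 470 nm, and `1 +`
(motion + white noise) for the isosbestic channel. The motion artifact is
one realization shared by both channels (band-limited below 5 Hz, SD 1%);
the bleach curves of the two channels are proportional to within 5%, so the
plain isosbestic subtraction cancels the artifact by more than an order of
magnitude, as the tests verify. Responsive trials (Bernoulli, presets 0.791
for the 100 Hz/5 s protocol and 0.659 for 150 Hz/2 s) receive a fast primary
transient (5% dF/F0, 1 s rise, 8 s decay, peak ~2 s after onset) plus a slow
secondary transient decaying over ~80 s.

The baseline fluctuation on the calcium channel is a *bounded* quasi-periodic
oscillation (random-phase sinusoid at 0.25 Hz, SD 1% dF/F0 — vasomotor-type
activity under anaesthesia) rather than a Gaussian process. This is the one
place where the noise model is load-bearing: a 2-sigma any-sample rule over a
20 s window saturates on Gaussian noise of any correlation time (either the
window holds many effective draws, or the 30 s pre-window SD estimate is too
noisy), classifying essentially every quiet trial as responsive. A bounded
oscillation has maximum sqrt(2) x SD < 2 x SD, which is precisely the regime
in which the rule is informative — and the regime real anaesthetized
recordings occupy. Consequently, recovery tests demonstrate correct pipeline
behaviour for data with bounded, oscillatory baselines plus a small white
floor; they do not certify the 2-sigma rule against heavy-tailed or strongly
non-stationary baselines, where it over-calls by construction.

**Particle layouts** (`gen_particle_layout()`): square-lattice or uniform
(Poisson) placement at a surface density, with nearest-neighbour distances
computed by a bucketed grid search; the Poisson mean nearest-neighbour
distance matches the analytic `0.5 / sqrt(intensity)` within 2% at 10^4
particles in the tests.

## Problem sizes and determinism

Recovery tests and the acceptance script use 10 synthetic replicates per
quantity: 300 cells x 5 epochs at 1 fps for the in vitro loop, 100 cells x 5
epochs at 10 fps for the fast-imaging loop, and 20-trial sessions at 130 Hz
(~3,900 s, ~5 x 10^5 samples per channel) for the photometry loop — sizes at
which the standard errors of the recovered means are a small fraction of the
quantities themselves while the whole suite runs in about a minute on one
CPU. Every generator is bit-deterministic given its `seed`; the acceptance
script derives replicate seeds from its single `--seed` argument.

## Known limitations

* The membrane model is a calibrated reconstruction (lattice sum + lossless
  integration), not a transcription of the original equations; conflicts
  with the original supplement, if obtained, should be resolved in its
  favour.
* The transduction module consumes printed simulation outputs (deformations,
  coefficients) as constants; it does not perform micromagnetic or
  finite-element modelling.
* The analysis starts from per-cell traces and two-channel time series; ROI
  extraction from movies is out of scope.
* Generator kinetics (indicator kernels, transient shapes, bleach constants,
  oscillation frequency) are literature-typical stand-ins, not values from
  the source study; recovery results certify the analysis code under these
  assumptions, not the biology.
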