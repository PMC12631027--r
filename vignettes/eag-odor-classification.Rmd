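---
title: "Classifying odors from electroantennogram waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying odors from electroantennogram waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eagwave)
```

## The problem

An excised insect antenna responds to a puff of odor with a local field
potential (LFP): the summed receptor currents of thousands of olfactory
sensory neurons, recorded between the antenna's base and tip as a slow
voltage wave. Different odorants recruit different neuron populations with
different kinetics, so the *shape* of the wave — amplitude, onset latency,
rise and decay, post-depolarization overshoot — carries information about
odor identity, not just intensity. `eagwave` implements a complete offline
analysis chain for exploiting that information with standard machine
learning, plus a synthetic session generator so that every stage is
testable without access to raw recordings.

## The recording model the generator emulates

A session delivers odors to one antenna at a time. Each *delivery* opens a
valve for 500 ms and is repeated every 30 s, producing three successive
response waves; each odor is delivered twice per antenna (six waves per
odor), and the reference odor (ylang-ylang, the strongest stimulus in the
panel) is additionally recorded at the beginning, middle and end of the
session. Analysis windows cover 250 ms before to 4750 ms after stimulus
onset. The recording rate is configurable; the default of 1 kHz makes the
5 s window exactly 5000 samples, which is also the SVM's feature count.

`simulate_session()` draws waves from the generative model

\[
v(t) = g_a \, d^{\,k} \, j \, A(c) \, s(t - \ell) \; (+\ \text{saturation, noise, artifacts})
\]

* **Template** `s`: each odor has a unit-peak difference-of-exponentials
  shape \(e^{-t/\tau_d} - e^{-t/\tau_r}\) (`tau_decay_s > tau_rise_s`),
  zero before the onset latency \(\ell\), rendered as a downward
  deflection per EAG convention, with an optional slow positive rebound.
  This is the simplest form reproducing "depolarization followed by
  recovery"; the default panel's amplitudes (1.0, 0.8, 0.7, 0.55, 0.3)
  and latencies encode the qualitative ordering of a floral odor panel
  (the reference odor largest, linalool delayed, limonene smallest).
* **Antenna gain** \(g_a\): lognormal (multiplicative, positive), log-sd
  0.3 by default — electrode placement and antenna condition scale whole
  sessions.
* **Responsiveness decay** \(d^k\): geometric per acquisition step
  (default 0.3% per trial), the simplest monotone model of an antenna
  slowly losing sensitivity over a session.
* **Trial-to-trial jitter** \(j\): lognormal per wave (log-sd 0.1),
  ordinary response variability.
* **Concentration** \(A(c)\): `concentration_response()` maps relative
  concentration through \(A \, c(1+K)/(c+K)\) (half-saturation
  \(K = 0.5\)), normalized so \(c = 1\) returns the template amplitude —
  weak at the low end, saturating at the high end.
* **Recording ceiling**: optionally, the clean signal is compressed
  through \(V_{max}\tanh(v/V_{max})\) before noise is added, emulating an
  amplifier driven into saturation at high odor concentration. Disabled
  (`Inf`) by default; it is the mechanism behind the high-concentration
  degradation scenario below.
* **Noise and artifacts**: additive Gaussian noise (sd 0.02), and with
  probability `artifact_rate` a fixed-frequency sinusoid (60 Hz mains,
  amplitude 0.25) whose presence is recorded in the ground-truth
  `artifact` flag.

What the generator does *not* emulate: receptor-level adaptation, plume
dynamics, correlated (non-white) noise, baseline drift, and odor-specific
concentration-response exponents. Tests passing on synthetic sessions
therefore demonstrate that the *pipeline* is correct and leak-free under
the stated statistical structure, not that any particular accuracy will be
attained on real antennae.

## Calibration normalization

Raw wave amplitudes confound odor identity with antenna gain and fatigue.
Every wave is therefore rescaled by the extrema of the *nearest-in-time*
reference-odor response from the same antenna
(`x ↦ (x − v_min)/(v_max − v_min)`; ties between equally distant
calibrations go to the earlier one). Under the generative model the gain
and decay multiply calibration and experimental waves alike, so they cancel
exactly — a property the test suite asserts. Two deliberate choices:

* Calibration extrema are taken from the **mean** of a calibration
  delivery's successive responses (noise reduction); per-wave stats are
  available via `per_wave = TRUE`.
* Normalized values are **not clipped** to [0, 1]: the reference odor
  usually evokes the largest response, but an experimental response
  exceeding the calibration range must remain distinguishable.

## Spectral quality control

Odor-evoked EAG deflections are slow; genuine response energy lives below
about 10 Hz. QC computes each wave's periodogram after mean removal
(so the DC term cannot dominate the in-band power) and rejects waves whose
out-of-band power fraction exceeds a threshold. The band (0, 10] Hz and
threshold 0.2 are configurable; the fraction is scale-invariant, and an
all-zero wave is reported as fraction 1 and failed. QC runs on normalized
waves (matching the processing order collect → normalize → QC → filter),
but nothing in the implementation requires that order.

## GA-tuned Butterworth filtering

Filtering is zero-phase (forward–backward), appropriate for offline
analysis and latency-preserving; the effective two-pass gain is
\(|H(f)|^2\). The band edges and order are chosen by a genetic algorithm
over the three-gene chromosome low cut ∈ (0, 1] Hz, high cut ∈ [1.001, 5]
Hz (the ranges are disjoint, so every chromosome is a valid band-pass),
order ∈ 1..4, with a population of 100. Fitness filters the tuning waves,
refits the PCA (the filter changes the data, so the basis must be refit
per individual), and scores the first five PC scores by Fisher class
separability.

Two definitional points the literature leaves open, resolved here:

* "Difference between interclass and intraclass variance" vs "Fisher's
  discriminant ratio": the **difference** is implemented as the default
  (it matches the operational description); the ratio is available via
  `fitness = "ratio"`.
* The variance terms weight **classes equally** (mean squared distance of
  class means to their grand mean; mean over classes of within-class mean
  squared distance), making the score robust to label imbalance.

Operators are unstated in the source material, so conventional choices are
used and exposed in `ga_config()`: tournament selection (size 3), blend
crossover (α = 0.5), Gaussian mutation (sd = 10% of each gene range,
clipped; order re-rounded), elitism 1, 30 generations, termination by
generation count. Elitism guarantees a monotone best-so-far trajectory,
which is asserted per generation. Half of the antennae (not half of the
waves — the same leakage policy as model evaluation) form the tuning
subset.

## PCA features and class ellipses

PCA is fit with `stats::prcomp` on centered waves. Component signs follow
the convention that each component's largest-magnitude coefficient is
positive, so saved models and score plots are reproducible. In repeated
evaluation the basis is fit on the **training antennae only** and test
waves are projected onto it; fitting on all waves would leak information
across the split. The random forest consumes the first five components,
with `check_variance_floor()` warning (not aborting) if they carry less
than 90% of the variance.

Score plots show 95% confidence ellipses **of the class mean**, not of the
data cloud: eigen-decomposition of (sample covariance)/n with semi-axes
\(\sqrt{\lambda_i \, \chi^2_{2,0.95}}\). They answer "where is this odor's
mean response?", which is the quantity of interest when judging whether
two odors are distinguishable at all.

## Classifiers and evaluation

The SVM (RBF kernel, `e1071`) sees the full time series; the RF
(`randomForest`) sees the five PC scores. Hyperparameter grids are not
dictated by the method, so the defaults span four orders of magnitude in
SVM cost and kernel width and 100–500 trees for the RF; selection runs a
random search over the broad grid followed by an exhaustive search of the
narrowed neighborhood, scored by antenna-grouped 3-fold cross-validated
balanced accuracy inside the training set. `evaluate_repeated()` tunes on
the first split and freezes the hyperparameters by default
(`tune = "once"`); `"per_split"` re-tunes every split at proportional
cost, `"none"` uses fixed defaults.

Splits are 70/30 **by antenna** — every wave of an antenna falls on one
side, so a model is never tested on an antenna it has seen. With n
antennae, round-half-up(0.7 n) go to training: 15 antennae give 11 train /
4 test. The per-split metric is balanced accuracy (mean per-class recall;
chance = 1/k for k classes); confusion matrices are pooled over splits and
row-normalized to percentages (per-split counts are also retained), and
the paired correct/incorrect table pooled over splits feeds
`mcnemar_exact()`: a two-sided exact binomial test on the discordant
counts, `p = min(1, 2 P(X ≤ min(n01, n10)))`, `X ~ Bin(n01+n10, ½)`,
with p = 1 when no discordant pairs exist. The exact test (rather than the
chi-square approximation, available via `method = "chisq"`) is well
defined at the small discordant counts a single test set produces; when
the discordant total is odd and as balanced as possible the lower tail is
exactly one half, and the implementation returns exactly 1 rather than a
floating-point neighbor of it.

## Numerical choices and degenerate inputs

* Window convention: half-open `[onset − pre, onset + post)`; the onset
  sample opens the post-stimulus segment. All times in seconds, all
  indices 0-based.
* CSV wave tables serialize voltages with `%.17g`, and parsing goes
  through `strtod`, so round trips are bit-exact.
* Degenerate cases fail loudly and early: flat calibrations, all-zero
  waves in QC (failed, fraction 1), identical waves in PCA, single-class
  training sets, fewer than three points for an ellipse, fewer than two
  antennae for a split.
* Filter cutoffs must lie below Nyquist; at the test suite's reduced
  sample rates this is checked explicitly.

## Problem sizes

The package's own checks run on deliberately small instances chosen to
keep the full suite quick while preserving the structure under test:
two-to-ten antenna sessions at 200 Hz with 2 s windows for pipeline and
evaluation properties, the full 15-antenna 1 kHz session for the
variance-floor and QC-recall checks, a 16-individual / 8-generation GA
against a 288-point exhaustive grid for the optimizer benchmark, and 100
label-permuted splits for the chance-level bound. The acceptance script
runs the full default session (about 585 waves of 5000 samples).

## Known limitations

* The GA offers no global-optimality guarantee; the test suite benchmarks
  it against an exhaustive coarse grid instead.
* `signal::filtfilt` handles edges by simple forward–backward filtering
  without padding; gain assertions therefore exclude window edges, and
  very low cut frequencies on short windows will show transients.
* Confusion-matrix pooling over splits weights antennae by how often they
  are drawn into test sets; per-split accuracies are retained so either
  summary can be computed.
* The synthetic generator's realism limits are listed above; in
  particular, accuracies obtained on synthetic sessions say nothing
  quantitative about real antennae.
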