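---
title: "Quantifying target boosting and distractor suppression with frequency tagging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying target boosting and distractor suppression with frequency tagging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experiment being modelled

In a rapid-invisible-frequency-tagging (RIFT) visual-search experiment,
yellow and cyan search items flicker sinusoidally at 60 and 67 Hz — too
fast to be perceived, but strong enough to drive a flicker-locked response
in early visual cortex that MEG sensors pick up. Because each colour is
tagged at its own frequency, the neural response to "all items of the
target colour" and "all items of the distractor colour" can be separated
spectrally. Comparing those responses between *guided* search (the target
colour is cued at the start of a block, so the distractor colour is also
known) and *unguided* search (colour unknown, randomized per trial) asks
whether feature guidance boosts the excitability of neurons representing
the target colour and suppresses those representing the distractor colour
— the signature of a priority map operating as early as V1.

`riftsearch` implements the full analysis chain for this design, driven by
a synthetic-data generator with known ground truth so that every stage is
verifiable without access to MEG recordings.

## The synthetic-data generator

`generate_experiment()` emulates the statistical structure the analysis
assumes, not the physics of the recording. Each trial's sensor signal is
the sum of:

* **1/f background noise** (unit sd, exponent `noise_exponent`, default 1)
  plus white sensor noise (`white_noise_sd`, default 0.3). The modelled
  experiment never characterises its noise; a power-law background is the
  standard electrophysiological surrogate.
* **A phase-locked broadband evoked transient** at search-display onset:
  30–80 Hz filtered noise under a 0.15 s raised-cosine envelope, identical
  across trials. Because it is phase-locked to onset (as evoked responses
  are) it produces the broadband coherence ridge just after t = 0 that the
  real data show, which is exactly why the single-trial analysis window
  starts at 0.2 s.
* **Tag carriers** during the search interval only, on the
  `signal_sensors` subset (default 4 of 20 sensors, standing in for the
  occipital candidate set): one sinusoid per stimulus colour, phase-locked
  to the matching reference channel, with amplitude
  `snr × gain`. The gain encodes the planted effect: `boost_gain` (1.6)
  for the guided target colour, `suppress_gain` (0.5) for the guided
  distractor colour, `unguided_gain` (1.0) for either colour in unguided
  blocks. Setting all three equal gives an exact null; `snr = 0` removes
  the flicker-locked component entirely.

The design is blocked exactly like the modelled task: blocks are assigned
round-robin to the guided/unguided × set-size cells, target presence is
50/50 within block, the colour-to-frequency assignment is counterbalanced
within block, guided blocks keep one target colour while unguided blocks
randomise it per trial. Defaults are 24 blocks of 40 trials (960 trials),
1000 Hz sampling, a 1.5 s baseline. The default `search_duration` is 1 s:
trials in the modelled task ran up to 4 s, but every analysis window ends
by 0.5 s, so simulating longer search only costs memory. Reaction times
are shifted-lognormal with location effects `+0.180` (larger set size) and
`−0.138` (guidance) on the log scale — the directions and magnitudes of
the behavioural regression betas of the modelled experiment — and
responses follow an equal-variance signal-detection model whose d′ varies
by `−0.74` (set size) and `+0.56` (guidance) around `dprime_base = 2.8`.

On target-absent unguided trials no true "target colour" exists; the
generator carries the design's randomised colour label so both analysis
conventions can be exercised downstream.

Gaze traces are Ornstein–Uhlenbeck fixational jitter (stationary sd
`gaze_jitter_scale = 0.3°`) with Poisson microsaccades whose amplitudes
are horizontally anisotropic (ratio 2:1, matching the predominantly
horizontal microsaccades of fixation) and Poisson blinks that invalidate
samples. The `colour_bias` parameter maps to an attraction weight
`w = 2·bias − 1` toward a randomly chosen target-colour item: 0.5 gives
gaze that is exactly colour-independent (the null of the control
analysis), 1 with zero jitter pins gaze to a target-colour stimulus.

**What the generator does not emulate:** volume conduction and realistic
sensor covariance, non-stationary or oscillatory (alpha, gamma) background
structure, eye-movement artefacts in the MEG channels, head movement, or
any anatomical forward model (the DICS stage uses synthetic lead fields).
Passing tests therefore demonstrate correctness and calibration of the
*statistical machinery* under the assumed signal model, not robustness to
every physiological confound of real MEG.

## Trial-averaged coherence

The flicker-locked response is quantified by the coherence between each
sensor and a phase-matched reference sinusoid (the offline stand-in for
the photodiode trace). Signals are bandpass filtered at the tag frequency
± 3.5 Hz with a two-pass windowed-sinc (Hamming) FIR filter and converted
to analytic signals; the coherence at sample $t$ over $n$ trials is

$$\mathrm{coh}(t) =
\frac{\left|n^{-1}\sum_k m_{\mathrm{meg}}(t)\, m_{\mathrm{ref}}(t)\,
e^{i\phi(t)}\right|}
{\left(n^{-1}\sum_k |m_{\mathrm{meg}}(t)|\right)
\left(n^{-1}\sum_k |m_{\mathrm{ref}}(t)|\right)}$$

with $m$ the instantaneous amplitudes and $\phi$ the phase difference.
This is a phase-locking-weighted amplitude ratio rather than
magnitude-squared coherence; it is implemented literally (the Welch
estimator used at the single-trial level is kept separate). It is
invariant to positive rescaling of either signal and bounded by 1 whenever
the reference amplitude is constant over trials — with an
amplitude-correlated reference the bound can fail, so the suite asserts it
only under the constant-amplitude condition.

Implementation notes: the two filter passes are applied in the frequency
domain as the squared magnitude response after reflection-padding each
epoch by one filter length (identical to forward–backward filtering,
exactly zero phase), with the analytic signal formed in the same FFT pair;
epochs are zero-padded to 5-smooth FFT lengths. The filter order
(`3.3 fs / halfwidth`, Hamming) puts the −53 dB stopband one transition
width beyond the band edges, comfortably exceeding 40 dB attenuation at
±2 halfwidths. Samples within one filter length of the epoch edges are
contaminated by the padding and are avoided by all windowed statistics.

For time–frequency maps (`coherence_tfr()`, 50–75 Hz in 1 Hz steps by
default) the reference is augmented with white noise of amplitude 0.05,
because a perfect sine has zero off-peak power and the denominator would
vanish away from the tag frequency.

Role-specific series (`condition_coherence()`) honour the
counterbalancing: trials are split by which frequency tags the role's
colour, coherence is computed per split against the matching reference,
and the two series are averaged. For the unguided reference series all
unguided trials are pooled and the series at both tag frequencies are
averaged — i.e. pooling *after* coherence computation, the convention
chosen here where the modelled analysis is ambiguous (computing on
pre-pooled trials is available by calling the splits directly).

## Sensor selection

Sensors with a reliable tagging response are found by comparing the
window-averaged coherence between a search interval (0–0.5 s) and an
equally long pre-search baseline (−0.7 to −0.2 s), z-transformed as

$$Z = \frac{(\tanh^{-1}|\mathrm{coh}_{\mathrm{search}}| - b) -
(\tanh^{-1}|\mathrm{coh}_{\mathrm{bsl}}| - b)}{\sqrt{2b}},
\qquad b = \frac{1}{2n-2}.$$

The bias terms cancel in the numerator, so
$Z = (\tanh^{-1}\mathrm{coh}_s - \tanh^{-1}\mathrm{coh}_b)\sqrt{n-1}$;
the suite asserts this identity to machine precision. The null
distribution permutes the interval labels by swapping the baseline and
search segments within randomly chosen trials — the scheme that preserves
within-trial structure — and a sensor is selected when its empirical Z
*strictly* exceeds the 1 − α quantile of its own per-sensor null (α =
0.01; a pooled null would also be defensible but per-sensor is the
default here). Coherence is averaged per sample across the window before
the z-transform; selection uses the first tag frequency's reference only.

The permutation loop is algebraic: per-trial per-sample cross-products and
amplitudes are precomputed for both windows and each permutation's trial
means follow from one 0/1 swap-matrix multiplication, so 1000 permutations
cost a single BLAS product per sensor. This is what makes the type-I
calibration (500 independent null datasets) run in about a minute.

## Single-trial GLM

Each trial's RIFT response is a Welch magnitude-squared coherence: the
epoch is filtered at 30–80 Hz (two-pass Butterworth, order 4, applied to
the full generously sized epoch so filter edges stay far from the window),
the 0.2–0.5 s interval is cut into 0.1 s Hanning windows stepped by
0.025 s (9 windows), each zero-padded to 512 samples, and coherence is
formed from the averaged cross- and auto-spectra at the FFT bin nearest
the tag frequency. At 1000 Hz the 512-point grid puts 60 and 67 Hz
off-grid; the nearest bins are 60.55 and 66.41 Hz. The estimator is
cross-checked in the suite against an independently coded per-window
CSD/PSD oracle at 1e−10.

The target- and distractor-colour responses of all trials are concatenated
(targets first) and modelled as

$$y = X\beta + \varepsilon, \qquad X = [\,T\;U\;D\;\mathrm{tot}\,],$$

where the indicators mark guided-target, unguided, and guided-distractor
observations (both observations of an unguided trial load on $U$) and
time-on-task is the trial's global index scaled to $[0,1]$, shared by the
trial's two rows. The three indicators sum to the all-ones vector, which
is why no separate intercept exists. The fit is
$\hat\beta = X^{+}y$ (Moore–Penrose); residual variance uses the unbiased
denominator $N - \mathrm{rank}(X)$ (the modelled analysis says only
"variance of the residuals"). Contrasts $C_T = [1, -1, 0, 0]$ (boosting)
and $C_D = [0, -1, 1, 0]$ (suppression) give
$t = C\hat\beta / \sqrt{C (X^\top X)^{-} C^\top \sigma^2}$, with zero
residual variance flagged as undefined rather than returned as ±∞.
Coherence values enter per role frequency (frequency-resolved, then
role-labelled), matching the concatenation description; averaging the two
frequencies first would also be possible but is not the default.

The behaviour-link variant regresses one role's guided-trial responses on
`[1, tot, rt]` and tests the reaction-time column.

## Cluster-based permutation inference

Per-feature dependent-sample t values (over participants or replicates)
are thresholded at the `cluster_alpha = 0.05` quantile of the t
distribution — the conventional default in this framework; the modelled
analysis never states its threshold, so it is exposed as a parameter.
Contiguous suprathreshold features (temporal contiguity over time;
k-nearest-neighbour graphs with k = 4 over sensor layouts) form clusters
scored by the sum of t (maxsum). The null is the distribution of the
maximal cluster mass under random within-unit condition swaps, and
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(n_{\mathrm{perm}} + 1)$,
so p can never be exactly zero and its granularity is
$1/(n_{\mathrm{perm}}+1)$. One-tailed tests take their direction from the
contrast being tested. The unguided reference series for the temporal
test is formed before per-participant differencing.

## DICS source mapping

The cross-spectral density at the tag frequency is estimated from
Hanning-tapered 0–0.5 s segments by evaluating the Fourier coefficient at
exactly the analysis frequency and averaging outer products (reference
channel last). Because rank-reduced data make the CSD inverse unstable,
the sensor block is inverted by truncated-SVD pseudoinverse; the default
cut-off is the numerical-rank convention (machine epsilon × dimension ×
largest singular value), with an explicit rank override. Spatial filters
are $w_g \propto C^{+} L_{:,g}$ normalised to unit norm (unit noise
gain), and the map value is the magnitude-squared coherence
$|w^H c_{\mathrm{ref}}|^2 / ((w^H C w)\, C_{\mathrm{refref}})$, reported
in $[0,1]$. Masking keeps the top `ceiling(percent/100 × n)` grid points,
ties broken stably by grid index.

Lead fields are synthetic: random smooth distance-attenuated gains from a
ring of sensors over a unit lattice (`synthetic_leadfield()`), labelled as
such. Localization tests plant sources with depth-normalised dipole
moments (amplitude scaled by the inverse lead-field column norm) so the
planted sensor-level snr — and hence the claimed recovery property — is
the same at every grid location. Anatomy, coregistration and realistic
head models are out of scope; fixed-orientation scalar dipoles only.

## Behavioural conventions

Trials with reaction times ≤ 200 ms or without a response are excluded
before any statistic (exclusion-first, also before d′). Hit and
false-alarm rates of exactly 0 or 1 are adjusted by the half-count rule
$0 \to 1/(2N)$, $1 \to 1 - 1/(2N)$ before the normal quantiles. Median
splits are rank-based within each condition cell — sorted by rt, the
first $\lceil n/2 \rceil$ labelled fast — so label counts never differ by
more than one and an odd-n median trial goes to the fast half. The
hierarchical mixed-model regression of the modelled behavioural analysis
is not reproduced; only its effect directions parameterise the simulator.

## Problem sizes and runtime

The test suite runs every stage at reduced scale chosen to keep the whole
suite within a few minutes while leaving each statistical check adequately
powered: type-I calibration of sensor selection uses 500 single-sensor
null datasets of 50 trials with 1000 permutations; the cluster-test
calibration uses 200 null replicates of 12 units × 25 features with 500
permutations; GLM sign recovery uses 60 end-to-end replicates; DICS
localization 30 replicates; the full-pipeline check simulates six
participants per snr scenario with 80 trials, 6 sensors and 1.4 s epochs.
`scripts/acceptance.R` recomputes the two headline calibration values
(sensor-selection false-positive percentage; null gaze bias) at exactly
these scales in about a minute.

## Known limitations

* The coherence measure implements the printed amplitude-ratio formula;
  results are not numerically interchangeable with magnitude-squared
  coherence, though both rank conditions identically in the planted-effect
  direction.
* Null coherence scales like $n^{-1/2}$, so comparisons across conditions
  with very different trial counts inherit a bias; the counterbalanced
  averaging keeps splits equal-sized by design.
* The permutation swap scheme assumes baseline and search windows of
  equal length; unequal windows are truncated to the shorter.
* Synthetic sensor layouts use a square grid with k-nearest-neighbour
  adjacency; real sensor-cap neighbourhood definitions are out of scope.
* With few units (e.g. six participants) the permutation null of the
  cluster test has limited granularity; reported p values saturate at
  $1/(n_{\mathrm{perm}}+1)$.
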