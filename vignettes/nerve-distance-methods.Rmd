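---
title: "Methods: impedance-aware probe-to-nerve distance prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: impedance-aware probe-to-nerve distance prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nerveloc)
```

# The problem

Electrical nerve localization during acoustic neuroma surgery works by
eliciting compound muscle action potentials (CMAPs): if a constant-current
pulse delivered through a monopolar probe activates the facial nerve, a CMAP
appears in the facial-muscle EMG some milliseconds later. The binary
presence of a CMAP is unreliable — low-impedance media shunt the stimulus
away from the nerve and high-impedance media make it jump toward it — and a
single CMAP amplitude carries no usable distance information because it is
confounded by muscle volume and by the impedance between probe and nerve.

`nerveloc` treats localization as regression: predict the probe-to-nerve
distance $d$ (mm) from features that are all measurable through the probe
and one EMG channel — the tissue equivalent circuit, the motor threshold,
and a multi-intensity CMAP response profile.

# Tissue equivalent circuit from pulse responses

## Model

The electrode-tissue interface is a series resistance $R_s$ in line with a
parallel pair ($R_p$, $C_p$). Driven by a constant current $i$,

$$V(t) = i R_s + i R_p \left(1 - e^{-t/\tau}\right), \qquad \tau = R_p C_p .$$

The waveform jumps to $V_0 = i R_s$ at the rising edge $t_0$ (an uncharged
capacitor is a short) and saturates at $V_x = i(R_s + R_p)$ by the plateau
time $t_x$, giving the landmark estimators $R_s = V_0/i$ and
$R_p = V_x/i - R_s$. The time constant is fitted over $[t_0, t_x]$ by
least squares on the charging model

$$F(\tau, t) = V_0 + (V_x - V_0)\left(1 - e^{-(t-t_0)/\tau}\right),$$

whose sign and time origin are forced by the boundary conditions
$F(\tau, t_0) = V_0$ and $F(\tau, \infty) = V_x$; then $C_p = \tau / R_p$
(the only dimensionally consistent combination of $\tau$ and $R_p$).
Impedance magnitude at frequency $f$ is
$|Z| = |R_s + R_p / (1 + j\,2\pi f R_p C_p)|$, reported at 500 kHz by
default (`impedance_magnitude(rc, frequency = 5e5)`); this series +
parallel-pair convention reproduces reference mock-material impedances from
their printed RC triples to better than 0.5 %.

## Numerical choices

* **Pulse detection** thresholds the *values* against the pre-pulse
  baseline (median of the leading 4 % of samples) at
  `max(noise_mult * baseline SD, 2 % of the voltage range)` with
  `noise_mult = 10`. Thresholding values rather than sample-to-sample
  differences keeps detection robust for slowly charging responses whose
  per-sample increments sit below the noise floor. Above-threshold runs
  separated by less than 1 % of the record merge into one pulse; two or
  more remaining runs raise an ambiguity error rather than guessing.
* **$V_0$ is read at the first pulse sample** (`v0_method = "edge"`). A
  median over the first few pulse samples — superficially more robust — is
  biased upward by $O((\Delta t/\tau)(V_x - V_0))$ because charging has
  already begun, which at 20 samples per $\tau$ corrupts $R_s$ by several
  percent; the single-sample read is exact on sampled charging curves.
  `v0_method = "median3"` is available for very noisy traces where the
  bias is preferable to the variance.
* **Plateau**: $t_x$ is the first pulse sample where the local slope falls
  below 1 % of the initial charging slope; $V_x$ is the mean of the final
  10 % of the pulse. An ideal square step (zero charging slope) plateaus
  immediately.
* **$\tau$ fit**: with $V_0, V_x$ fixed at their landmark values the fit is
  one-dimensional, so it is solved by a 200-point logarithmic grid over
  [one sample period, pulse duration] followed by golden-section refinement
  of the bracketing cell — deterministic, derivative-free, and within
  0.5 % of a 10,000-point exhaustive grid oracle in the test suite. The
  fit's $R^2$ is reported; it is 1 (to $10^{-9}$) on noiseless input and
  decreases with added noise.
* **Degenerate charging** ($V_x \approx V_0$, relative tolerance $10^{-4}$)
  returns a purely resistive estimate: $R_p = 0$, $C_p$ undefined (`NA`),
  and impedance defined only at DC. Pulses shorter than $5\hat\tau$ trigger
  a warning because $V_x$ (hence $R_p$) is then biased low.

# CMAP features

Per trial the motor threshold $i_{MT}$ is found by increasing the current
from `start` in fixed steps until a CMAP is detected (default step 5 µA;
detection = peak-to-peak of the averaged response exceeding 5× the baseline
noise SD, with a 1 µV absolute floor). Four pulses are then applied at each
of 100/110/120/130 % MT. The EMG is segmented at the trigger instants,
grand-averaged per level, and each average is measured in a 2–50 ms
post-trigger window (the first 2 ms are blanked as stimulus artifact):
peak-to-peak voltage as amplitude, time of the largest-magnitude peak as
latency. Amplitudes are normalized,

$$\mathrm{NCMAP}_i = \frac{\mathrm{CMAP}_i - \mathrm{CMAP}_1}
{\mathrm{CMAP}_4 - \mathrm{CMAP}_1} \times 100,$$

which pins the endpoints at 0 and 100 % and removes subject-dependent scale
(muscle volume, electrode placement). An ordinary least-squares line
through (intensity, NCMAP) gives the transfer parameters $\theta_1$
(%/A) and $\theta_2$ (%), and the trial latency $t_L$ is the mean over the
four grand averages. All of these definitions are configurable where
practice varies (window, detection multiple, which peak defines latency).

# The distance model

## Base and extended forms

Two generative assumptions — amplitude falls as
$\mathrm{CMAP} = \lambda_1 i_{MT} / (d \, Z) + \eta_1$ and latency grows as
$t_L = \lambda_2 (Z d) + \eta_2$ — combine into the base regression

$$d = \lambda_1 \frac{i_{MT}}{\mathrm{CMAP} \cdot Z}
    + \lambda_2 \frac{t_L}{Z} + \eta .$$

The extended variant replaces $\eta$ with structured error functions built
from the remaining measurements:

$$\eta_1 = \sum_{j=0}^{4} b_1(j) X_1(j), \qquad
  \eta_2 = \sum_{j=0}^{3} b_2(j) X_2(j)
         + \sum_{k=0}^{1} \alpha(k) e^{\beta(k) R(k)},$$

with $X_1 = [1, \theta_1, \theta_2, R^2_{lin}, i_{MT}/R_p]$,
$X_2 = [C_p, R^2_\tau, R_s/C_p, t_L]$ and $R = [R_s, R_p]$ — 15 parameters
in total.

Three terms are implemented as ratios by default — $t_L/Z$, $i_{MT}/R_p$,
$R_s/C_p$ — because the latency law inverts to $d \propto t_L/Z$ and the
ratio readings are the dimensionally coherent ones; the product readings
are one switch away (`feature_options()`) so both interpretations can be
compared empirically. Which amplitude enters the base term is likewise
configurable (`cmap_level`); the default is the MT-level grand average,
matching the $i_{MT}$ in the same term.

## Fitting

All predictors are standardized (centered/scaled by training-set SD) before
fitting, and the exponents act on *scaled* resistances: with raw
$R_p \sim 10^4\,\Omega$, $e^{\beta R_p}$ overflows for any useful $\beta$,
and standardization also makes predictions invariant to the raw units of
every feature (asserted in the test suite). Coefficients are therefore
reported in scaled space, with the scaling stored in (and serialized with)
the model; the base variant additionally back-transforms its three
coefficients to raw space, where they are directly interpretable.

The base fit is ordinary least squares. The extended fit exploits the model
structure: for fixed $\beta = (\beta_s, \beta_p)$ every other parameter is
linear, so the profiled sum of squares is computed by exact OLS and only the
two exponents are searched — multi-start L-BFGS-B within
$|\beta| \le 10$, starting from the four sign combinations $(\pm 0.1, \pm
0.1)$ plus four seeded uniform draws in $[-2, 2]^2$. This is deterministic
given the seed (bit-reproducible re-runs are asserted), respects the bounds
exactly, and cannot be destabilized by the linear parameters. Because the
extended design contains the base design's columns, its training SSE can
never exceed the base fit's — a nested-model inequality the acceptance
suite asserts. Exponential terms can be locally linear in the data's range,
so individual extended *coefficients* are not always identifiable;
correctness is therefore defined (and tested) at the level of predictions,
which recover noiseless labels to 0.01 mm.

# Validation

`cross_validate()` shuffles records with a seed, forms $k$ near-equal
disjoint folds (default $k = 10$), fits on each complement and evaluates
two metrics on the held-out fold:

* **accuracy** — Pearson correlation between predictions and held-out
  labels, × 100. This is invariant under any positive-slope affine
  transform of the predictions (asserted as a documented caveat): it
  measures linear association, not calibration.
* **error** — mean absolute error in mm (RMSE via `error_type = "rmse"`).

Fold summaries are mean ± sample SD ($n-1$) across folds, in percentage
points for accuracy. Plain record-level shuffling is the default; because
it lets a subject straddle train and test folds, `group_by = "subject"`
assigns whole subjects to folds for a leakage-free estimate.

# The phantom

## What it emulates

`generate_dataset(phantom_config())` reproduces the bench protocol with no
external data: 12 subjects × 4 mock materials × 5 distances (0–4 mm), and
per trial a grid-based MT search, four pulses per level at 0.5 s ISI,
a 1 MHz pulse waveform and 2 kHz EMG. Features are extracted by the *real*
pipeline running on the synthetic traces — the generator never copies
generative values into the records.

Generative laws and defaults (all configurable, all documented as synthetic
rather than calibrated tissue claims):

* amplitude $\mathrm{amp} = \lambda_1^* i_{MT} / (d_{\mathrm{eff}} Z)$ with
  $\lambda_1^* = 2\times10^4$ V·mm·Ω/A, giving ~0.4–3 mV CMAPs; the
  effective distance $d_{\mathrm{eff}} = d + 0.5$ mm models a finite
  electrode standoff, keeping the law finite at contact;
* recruitment: amplitude grows by `recruit_gain = 1.5` per unit fractional
  current above threshold, making NCMAP exactly linear in current;
* latency $t_L = \lambda_2^* Z d_{\mathrm{eff}} + 7.25$ ms with
  $\lambda_2^* = 10^{-6}$ s/(Ω·mm): ~7.3–12.5 ms over the design, the
  baseline matching a typical threshold-level CMAP latency;
* motor threshold $i_{MT} = a_0 (1 + a_1 d_{\mathrm{eff}})(1 + a_2/Z)$ with
  $a_0 = 20$ µA, $a_1 = 0.8$/mm, $a_2 = 200$ Ω — rising with distance,
  falling with impedance, spanning ~30–150 µA;
* materials: the four reference RC triples, with per-subject log-normal
  jitter (SD 0.1) providing between-subject spread in $R_s, R_p, C_p$;
* noise: waveform 5 mV, EMG baseline 20 µV, per-pulse amplitude 5 %
  (log-normal), per-pulse latency 0.1 ms, threshold 5 % (log-normal), all
  multiplied by `noise_scale` (0 = noiseless phantom);
* the CMAP template is biphasic — a 3 ms positive lobe carrying 60 % of the
  peak-to-peak and a 3 ms negative lobe — with its peak snapped to the EMG
  sample grid, so that at zero noise the sampled extrema equal the designed
  amplitude exactly and extracted features match the generative laws up to
  latency quantization of at most half a sample. The 3 ms lobe width is
  physiological for a twitch CMAP and deliberately wide relative to the
  0.5 ms EMG sampling interval: much narrower lobes make the grand average
  hypersensitive to sub-sample latency jitter.

## What it does not emulate

No volume conduction, axon recruitment statistics, electrode polarization,
stimulus artifact, movement artifact, line noise, or gelatin chemistry; the
law coefficients are chosen for realistic magnitudes, not fitted to animal
data. Passing tests therefore demonstrate that the pipeline is correct and
self-consistent and that the model class can be recovered under controlled
noise — not that the specific published in-vivo accuracies transfer, which
cannot be checked without the original recordings (never deposited).

## Exact-recovery datasets

Two flavors of ground truth are used in testing. *Geometric* labels (the
phantom's actual distances) exercise the whole measurement chain, but carry
irreducible extraction error — e.g. $Z$ is re-estimated from the sampled
waveform — so they are used for the noise-degradation properties.
*Model-consistent* labels, produced by relabeling phantom records with a
known model built by `prediction_model()`, make exact recovery well-defined
and are used for the closed-form checks: base coefficients recovered to
0.1 %, extended out-of-sample predictions to 0.01 mm, noiseless 10-fold CV
accuracy of 100 % (to $10^{-6}$).

## Problem sizes in the test suite

The study-scale checks use the full 240-record noiseless phantom (generated
once and cached). The noise-degradation property uses 3 subjects × 4
materials × 5 distances at a shortened 60 ms ISI across 3 noise scales
(0.5×, 1×, 2×) × 20 seeds, with a Wilcoxon signed-rank test on per-seed
Spearman correlations between noise level and each CV metric — small enough
to keep the whole suite under a minute on one core while still giving the
rank test 20 independent replicates.

# Known limitations

* The correlation-based accuracy metric rewards any monotone-linear
  predictor regardless of scale; always read it together with the error
  metric.
* Extended-model coefficients are reported in standardized space and may be
  non-identifiable when the exponential terms are locally linear; compare
  models by predictions, not coefficients.
* The default ungrouped CV leaks subject effects across folds (kept as the
  protocol's plain k-fold description); use `group_by = "subject"` for a
  conservative estimate.
* $R_s$ estimation inherits the noise of a single sample at the rising
  edge; at very low SNR consider `v0_method = "median3"` and expect a
  known positive bias.
* The phantom's four-level, four-pulse design means $\theta_1, \theta_2$
  are estimated from four points; their sampling error at realistic noise
  is substantial, which is faithful to the protocol rather than a defect of
  the implementation.
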