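---
title: "Reading out task variables from parallel spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading out task variables from parallel spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`popsignal` implements a read-out model of parallel spike trains. A
population of $N$ simultaneously recorded neurons is imagined to project to
a single read-out neuron; each projecting neuron $n$ has a synaptic weight
$\tilde w_n$, and the read-out's input current in trial $j$ is

$$x_j(t_k) \;=\; \sum_{\tau \ge 0} \Big(\sum_{n=1}^{N} \tilde w_n\,
o_{n,j}(t_k - \tau)\Big)\, u(\tau), \qquad u(\tau) = e^{-\lambda \tau},$$

where $o_{n,j}(t_k) \in \{0, 1\}$ is the 1-ms-binned spike train. The
causal exponential kernel models a postsynaptic current: every spike
produces a jump followed by decay with time constant $1/\lambda$ (20 ms by
default). The model separates *learning* from *reconstruction*:

1. **Learning (classification).** On a training half of the trials, spike
   counts in the 400-ms analysis window are z-scored per neuron and a
   soft-margin linear SVM is fit to discriminate the two task conditions
   ("match", label $+1$, vs "non-match", label $-1$). The feature weights,
   L2-normalized, are the decoding weights $\tilde w$. The SVM cost $C$ is
   chosen by stratified 5-fold cross-validation on the training set,
   maximizing balanced accuracy over the grid
   $\{0.0012, 0.0015, 0.002, 0.005, 0.01, 0.05, 0.1, 0.5\}$, with ties
   going to the smallest (most regularized) value.
2. **Reconstruction.** The learned weights are frozen and applied to the
   held-out trials, bin by bin, giving a one-dimensional single-trial
   signal. Signals are centered by subtracting the across-trial mean
   $z(t_k)$, averaged within condition, and summarized by the per-bin
   difference $\Delta x(t_k) = \tilde x^{m}(t_k) - \tilde x^{nm}(t_k)$.

The split into training and validation halves is repeated (Monte-Carlo
cross-validation, 100 runs by default, stratified by condition; with odd
trial counts the training set gets $\lfloor J/2 \rfloor$); reported
weights, accuracies and signal curves are averages across runs. The whole
procedure is what `readout()` fits; `run_full_analysis()` adds the survey
analyses around it.

Significance of $\Delta x$ is assessed nonparametrically: condition labels
are permuted across trials — the same permutation in the learning and in
the reconstruction step — and the full pipeline is re-run `nperm` times
(1000 by default). Per bin we report both the strict "outside the null
min/max" criterion and an add-one empirical p-value
$p = (1 + \#\{|\Delta x^{perm}| \ge |\Delta x|\})/(nperm + 1)$, since the
min/max criterion sharpens indefinitely with `nperm`. No correction across
time bins is applied; the per-bin presentation is the object of interest.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `kernel rate` $\lambda$ | 1/20 | 1/ms | decay of the read-out kernel |
| kernel support | $\lceil 5/\lambda \rceil$ | bins | truncation, $\ge 99.3\%$ of kernel mass |
| `sigma_sq` | 10 | ms$^2$ | variance of the PSTH smoothing kernel (support $\pm 10$ ms) |
| `C` grid | 0.0012 … 0.5 | — | SVM soft-margin cost candidates |
| `n_cv` | 100 | runs | Monte-Carlo cross-validations |
| `nperm` | 1000 | replicates | permutation null size |
| `alpha` | 0.05 | — | per-bin significance level |
| `zscore_scope` | `"train"` | — | trials supplying z-scoring statistics |
| `ddof` | 1 | — | variance convention for z-scoring |

The kernel is unnormalized by default ($u(0) = 1$); `normalized = TRUE`
divides by the kernel area $\sum_t u(t)$, which puts signals computed with
different time constants on a common amplitude scale (they then differ
essentially only in smoothness).

## Subpopulation decompositions

Neurons with positive weight (*plus* pool) and negative weight (*minus*
pool) are reconstructed separately, with off-pool weights zeroed and the
pool weights scaled by $f^{\pm} = N / (2 N^{\pm})$ so that signals are
comparable across pools of different size. Zero weights belong to neither
pool. By linearity the decomposition is exact:
$x = x^{+}/f^{+} + x^{-}/f^{-}$. Cortical layers (supragranular SG,
granular G, infragranular IG) are handled identically with
$f^{r} = N/(3 N^{r})$.

Layer membership comes from the laminar LFP: the current source density is
the second spatial difference of the trial-averaged potential (edge
channels dropped; a depth-linear potential gives exactly zero). The map is
oriented sink-positive — a focal negative potential deflection (an
extracellular sink, the hallmark of the granular input layer) appears as a
positive peak — and normalized to $[-1, 1]$. The strongest sink is located
in the 20–100 ms window after stimulus onset; the spatial covariance
$C = A A^{T}/N_{time}$ (raw Gram form, not mean-subtracted, with a
mean-subtracted option) is taken through the sink channel, and the G-layer
borders are the first zero crossings on either side of the sink peak,
linearly interpolated between channels. Walking outward from the peak
automatically selects the crossing nearest the peak when several exist; a
side with no crossing gets its border at the probe end, with a warning.
Neurons exactly on a border are assigned to G (deterministic tie rule).

## Information-source perturbations

To ask which part of the weights carries the discrimination, the package
re-runs the reconstruction with perturbed weights: fully random (uniform on
the weight range), random signs (true moduli), random moduli (true signs),
and deterministic binary weights $\pm a$ with $a = N^{-1}\sum_n |\tilde
w_n|$; plus a spike-timing permutation that shuffles the order of time bins
within each trial (the same shuffle for all neurons, preserving counts and
zero-lag coincidences). The expected pattern — and what the acceptance
tests check on planted-effect sessions — is that destroying the signs
abolishes the condition difference while destroying the moduli or the
timing does not, and the binary-weight difference curve correlates strongly
with the regular one.

## Cross-correlations and their null

Simultaneous pool (or layer-pair) signals are compared with the normalized
cross-correlation
$\tilde R(\tau) = R^{+-}(\tau)/\sqrt{R^{++}(0) R^{--}(0)}$, computed per
trial and then averaged (per condition or over all trials). The raw lagged
sums are used as printed — no per-overlap normalization — because the
Eq-style zero-lag normalization makes the lag-0 value identical under
either convention; values are bounded by 1 (Cauchy–Schwarz). Trials where
either signal has zero energy are dropped from the average with a count.

Two conventions matter and both are available. Used *as produced*, the
minus-pool signal is non-positive (negative weights), so the plus × minus
lag-0 correlation is structurally negative and its level is dominated by
the stimulus-locked envelope shared by all trials. The random-assignment
null (weights permuted across neurons, pool sizes and weight values
preserved) shares that envelope, so what the comparison actually isolates
is trial-by-trial coupling between the pools: a differential latent input
(opposite rate loadings in the two pools) decorrelates the pools' temporal
shapes and displaces the observed lag-0 value outside the null band. The
`mean_subtract` option removes each trial's temporal mean first; CCFs of
the across-trial-centered signals (`$centered`) remove the deterministic
envelope entirely, and with independent pools their lag-0 values center on
zero — the cleanest calibration, used in the generator's tests.

## The synthetic generator

`generate_session()` emulates the statistical setting the package is meant
for, not its biophysics: ~20 neurons, ~100 trials per condition, 400 1-ms
bins per window, Bernoulli-per-bin spiking (discrete-time Poisson, no
refractoriness), 5 Hz baselines. The *test* epoch carries a planted
condition effect — a 10 Hz rate shift in match trials confined to the late
window (200–400 ms), with a neuron-specific sign (55% plus neurons) —
while the *target* epoch carries none. An optional shared latent (smoothed
Gaussian process, 20-ms scale, opposite loadings in the two pools) adds
trial-wise co-fluctuations. The laminar LFP plants a negative
Gaussian-in-depth deflection (depth SD 1.5 channel spacings, centred
mid-probe, evoked transient at 60 ms) plus white noise at SNR 5; the true
G-layer borders sit one depth-SD either side of the sink, where the second
derivative of a Gaussian changes sign. What passing tests show is that the
algorithms recover planted count-level, sign-level and laminar structure
at realistic sizes; they do not show robustness to refractoriness, bursting,
non-stationary baselines, electrode drift, or correlated noise beyond the
single shared latent.

## Numerical choices

* Counting windows and bins are half-open, `[start, start + K)` ms,
  0-based, so a 400-ms window at 1 ms is exactly `K = 400` bins.
* Convolutions (exponential kernel, per-trial signals) are FFT-based with
  zero history before the window: signals start at 0, like a read-out
  neuron at rest, and the first ~$5/\lambda$ ms are a build-up transient.
* The PSTH kernel is pre-normalized over its finite support; the series is
  zero-padded, accepting slight attenuation in the first/last 10 bins.
* Zero-variance neurons get z-score 0 (with a warning) rather than being
  dropped, keeping the neuron dimension stable; constant-count neurons get
  AUC weight 0.
* The SVM orientation is fixed so that $\mathrm{sign}(w \cdot s + b) = +1$
  predicts "match" regardless of class order in the data; solver
  tolerance is $10^{-6}$ and the fit is deterministic.
* $C$ is selected once per session (on the first training set) and reused
  across CV runs and null replicates, matching a per-session fit while
  keeping permutation nulls affordable; pass a fixed `C` to override.
* z-scoring statistics come from the training trials only by default
  (no leakage into validation); `zscore_scope = "all"` reproduces the
  pooled variant, and the choice is exposed because either reading of the
  method is defensible.
* All randomness (splits, folds, permutations, the generator) is seeded;
  the same seed reproduces splits, ensembles and sessions exactly, and
  `run_full_analysis()` summaries are byte-identical across repeats.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at these scales,
chosen to make sampling bands tight while keeping a full run in minutes:
sign-recovery over 20 sessions of 20 neurons x 200 trials; calibration
(chance-level balanced accuracy and a per-bin flag rate within
[0.02, 0.09] at $\alpha = 0.05$) over 50 zero-effect sessions with
`nperm = 200`; perturbation patterns over 3 sessions with `nperm = 200`;
laminar border recovery over 100 LFP instances at SNR 5. The acceptance
script (`scripts/acceptance.R`) re-runs a compact version of the same
analyses from scratch for any seed.

## Known limitations

* The SVM is linear and unweighted; class imbalance is handled only
  through balanced-accuracy evaluation, as in the method being modeled.
* The univariate (AUC) weights are normalized by the L2 norm of the
  centered AUC vector; they share the reconstruction pipeline but not the
  multivariate interactions.
* The CSD is the plain second-difference estimator on a uniform probe —
  no inverse (iCSD/kernel-CSD) methods, no conductivity model.
* The t-test convenience statistic on time-averaged signals is an
  interpretation (two-sample t-test on per-trial time averages); the
  permutation machinery is the package's primary inference path.
* Spike sorting, unit screening and anything upstream of binary 1-ms
  spike trains are out of scope.
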