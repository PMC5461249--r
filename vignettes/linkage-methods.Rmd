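---
title: "Latent EEG-fMRI linkage discovery and fMRI-informed EEG decoding: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent EEG-fMRI linkage discovery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bcilink` implements a complete simulation-and-analysis chain for a
multimodal brain-computer-interface idea: learn a mapping from EEG to
(deconvolved) fMRI during a simultaneous recording session, then run an
EEG-only P300 speller whose decoder consumes fMRI-like features predicted
from EEG alone. This vignette explains the models behind each stage, the
tunable parameters and their defaults, and the design decisions that were
genuinely open.

## 1. Hemodynamics: the Balloon model

BOLD fMRI is an indirect, temporally smeared readout of neuronal activity.
The package uses the standard four-state hemodynamic ("Balloon") model: a
vasodilatory signal $s$ is driven by neuronal activity $n$ and decays with
rate $\kappa$ while being fed back by flow; flow $f$ integrates $s$; venous
volume $v$ and deoxyhemoglobin $q$ follow with mean transit time $\tau$ and
stiffness exponent $\alpha$:

$$\dot s = \varepsilon n - \kappa s - \gamma (f - 1),\qquad \dot f = s,$$
$$\tau \dot v = f - v^{1/\alpha},\qquad
  \tau \dot q = f\,\frac{E(f, E_0)}{E_0} - v^{1/\alpha}\frac{q}{v},\qquad
  E(f, E_0) = 1 - (1 - E_0)^{1/f}.$$

The observation is the classic nonlinear BOLD equation in $(q, v)$, in
percent signal change: $y = 100\,V_0\,[k_1(1-q) + k_2(1-q/v) + k_3(1-v)]$
with $k_1 = 7E_0$, $k_2 = 2$, $k_3 = 2E_0 - 0.2$. Defaults are the
canonical values $\kappa=0.65\,\mathrm{s^{-1}}$, $\gamma=0.41\,
\mathrm{s^{-1}}$, $\tau=0.98\,\mathrm{s}$, $\alpha=0.32$, $E_0=0.34$,
$V_0=0.04$, $\varepsilon=0.54$. Integration is fixed-step RK4 at the
neuronal sampling interval; the test suite verifies agreement with a
10-fold-refined integration to better than $10^{-3}$ relative RMS, so a
step of 0.1 s (and up to 0.25 s) is adequate for these dynamics. The same
machinery yields per-voxel HRF kernels (`hrf_impulse_response`), which are
always integrated on a grid of at most 0.1 s and then decimated, because
the $v^{1/\alpha}$ term makes the system stiff for short transit times.

## 2. Blind deconvolution: joint cubature Kalman filtering

`blind_deconvolve()` inverts the Balloon model: given only a BOLD series,
it estimates the hidden neuronal drive and a subset of the hemodynamic
parameters. The augmented state is $(n, s, f, v, q, \log\tau,
\operatorname{logit} E_0)$; the parameters follow a small-variance random
walk on their unconstrained scales, which enforces $\tau>0$ and $0<E_0<1$
without constrained filtering. Moments are propagated with the
third-degree spherical-radial cubature rule ($2n$ points); on
linear-Gaussian systems this filter and its Rauch-Tung-Striebel-style
smoother agree with the closed-form Kalman filter/smoother to $10^{-8}$,
which the tests assert on randomly drawn systems. Covariance factorization
uses a Cholesky with a jitter ladder and an eigenvalue-clipping (PSD
projection) fallback; the filter aborts with a step-indexed error only
when the state or covariance becomes non-finite, i.e. on genuine
divergence.

Two estimation regimes differ in how the neuronal state evolves:

* **With an experimental boxcar** (the simultaneous session, where
  highlight times are known), $n$ relaxes exponentially toward the input
  with rate $2\,\mathrm{s^{-1}}$ (time constant 0.5 s). The discretization
  is chosen so a sustained unit boxcar settles exactly at $n = 1$; this
  pins the amplitude scale of $n$ and makes $E_0$ identifiable (with a
  free amplitude, $E_0$ and the neuronal gain trade off against each
  other). The relaxation rate was fixed by forward simulation during
  design: fast rates (4-8/s) re-introduce a timing bias that drags the
  $\tau$ estimate down, slow rates blur the drive; 2/s recovers both
  $\tau$ and $E_0$ with median relative error well under 25% across voxels
  spanning a plausible parameter range and 5-20 dB SNR.
* **Fully blind** (no input), $n$ relaxes at $0.3\,\mathrm{s^{-1}}$ with
  10-fold inflated neuronal process noise. The slower time constant
  matters because, without an input, information about $n$ reaches the
  filter only through the hemodynamic delay; the smoother can only carry
  evidence backwards across that delay if the neuronal state itself has
  enough temporal memory.

Measurement-update steps occur only at observation instants; intermediate
steps on the `upsample_factor`-times finer grid are pure predictions, so
the smoothed neuronal estimate lives at `TR / upsample_factor` (sub-TR
effective resolution). By default the measurement noise variance is
estimated as half the variance of the first-differenced BOLD series (a
high-frequency residual estimate) and the process noise uses fixed scales
($10^{-2}$ neuronal, $10^{-6}$ for the transformed parameters), all
overridable through `noise_spec()`.

## 3. Time-frequency tensors

Both modalities are represented as 4-way tensors over (trials, space,
time, frequency) via the complex Morlet wavelet, power taken as squared
magnitude, log-transformed, and z-scored per (space, time, frequency) bin
across trials; zero-variance bins map to zero so degenerate inputs cannot
produce NaN. The trial axis is the only shared axis: EEG stays at 250 Hz
with a 2-40 Hz, 20-bin log-spaced grid (7-cycle wavelets), the deconvolved
fMRI at its own rate with a 0.03-2 Hz, 8-bin grid (3-cycle wavelets; its
Nyquist at the 0.2 s effective step is 2.5 Hz). Neither modality is
resampled to the other. Epochs are 0-1 s post-highlight for EEG (covering
the 250-400 ms P300 latency range) and 0-8 s for fMRI (the
hemodynamically relevant span). Windows are half-open with 0-based onset
sample indexing. For the lowest fMRI frequency bins the wavelet support
exceeds the epoch; those coefficients are edge-flagged and retained — they
act as smooth local averages rather than genuine oscillatory estimates,
which is acceptable for the regression but should not be interpreted
spectrally. For streaming (single-trial) use, the z-scoring statistics are
frozen from the training data (`tensor_norm_stats` /
`build_tensor_with_ref`), since a single trial has no across-trial
variance of its own.

## 4. Orthogonal Tucker decomposition and the sequential update

`tucker_decompose()` is the non-iterative multilinear SVD: per-mode
singular vectors of the unfoldings, core by orthonormal projection, no
alternating least squares. Sign indeterminacy is removed by making each
factor column's largest-magnitude entry positive; ties in singular values
keep the first column, so results are reproducible. The squared
reconstruction error is bracketed by the discarded mode-wise singular
values — at least the largest single-mode discard, at most the sum across
modes — and the tests assert both bounds (this is the standard multilinear
SVD bound; equality holds at full rank).

The streaming mode (`tucker_stream` / `tucker_update`) maintains, for mode
1, a rank-truncated incremental SVD of the growing unfolding and, for the
remaining modes, running Gram-matrix accumulators whose leading
eigenvectors are the factors. No forgetting factor is applied: the stream
is treated as stationary, which matches the within-session use here.
Updating is $O(\text{slice size})$ per trial and the tests verify that 20
sequential updates land within 10% of the batch reconstruction error and
that appending an in-span slice leaves the factor subspaces unchanged.

## 5. HOPLS: higher-order PLS between the modality tensors

The linkage model couples the EEG tensor $\underline{X}$ and the
deconvolved-fMRI tensor $\underline{Y}$ through shared trial-mode latent
scores. Each component $r$ consists of a unit-norm latent vector $t_r$
(length = trials), orthonormal loading matrices on every non-trial mode
($P_r$ on the X side, $Q_r$ on the Y side), and small core tensors $G_r$,
$D_r$ that absorb all scale — including the diagonal regression weight
linking the two sides, which resolves the scale indeterminacy of the
latent pair. Components are extracted greedily:

1. form the mode-1 cross covariance of the current residuals (a tensor
   over both sides' non-trial modes);
2. take its rank-$(L_2..L_N, K_2..K_M)$ orthogonal approximation by
   multilinear SVD → $P_r, Q_r$;
3. $t_r$ = dominant left singular vector of the X residual projected onto
   $P_r$;
4. cores by projection onto $(t_r, P_r)$ and $(t_r, Q_r)$; deflate both
   residuals by the fitted rank-$(1, L)$ / rank-$(1, K)$ terms.

Deflation subtracts an orthogonal projection, so both residual norms are
non-increasing in $r$ (tested). Prediction for new trials is a forward,
well-posed pass: sequential score extraction through $P_r$ and the
pseudo-inverse of $G_r$'s mode-1 unfolding, then through $D_r$ and $Q_r$.
On training data this reproduces the fitted reconstruction exactly.

`pls_fit()` is the matrix specialization used as the test oracle: per
component, the leading singular pair of the residual cross covariance
gives weights $(w, c)$, the score is $t = Ew/\lVert Ew\rVert$, and both
residuals are deflated by the fitted rank-one terms. This is deliberately
the covariance-maximizing PLS variant with rank-one deflation rather than
classic PLS2 regression deflation ($p = X^\top t$): the two coincide at
the first component but diverge afterwards, and only the rank-one variant
is the exact matrix case of the tensor algorithm (the tensor model with
full per-mode ranks recovers the classic deflation as a special case).

Default ranks are $R = 5$, $L = K = (3,3,3)$; all are configuration
parameters and, for a given dataset, can be chosen by cross-validated grid
search with `hopls_cv_r2()`. If a residual cross covariance degenerates to
(numerical) zero the fit stops early with a warning and returns the
components found.

## 6. Surrogate statistics and the sparse linkage model

Stability and significance are assessed by two resampling layers:

* `split_half_distribution()` refits the model on random halves of the
  trials, recording each fit's core-tensor entries (scaled by
  $1/\sqrt{n_\text{trials}}$ so fits on different trial counts are
  comparable) and its prediction $R^2$ on the complementary half.
  Components are aligned across fits to a reference full-data fit by
  maximal absolute correlation of their all-trial scores, with signs fixed
  accordingly; loading rotations are already pinned by the deterministic
  multilinear-SVD sign convention.
* `null_distribution()` repeats the same statistic on surrogate data. The
  default surrogate permutes the time axis of the X tensor with one random
  permutation per trial (shared across channels and frequencies), which
  preserves the multiset of values in every (trial, channel, frequency)
  fiber exactly while destroying time-locked predictability. Each null
  sample is the median over the same number of split-half fits as the
  observed statistic — this makes observed and null statistics
  exchangeable under the null, which is what makes the empirical p-values
  calibrated; a single full-data fit per surrogate would be mis-scaled
  relative to a median-of-splits observed statistic.

An important limitation, discovered by construction and handled
explicitly: within-trial time shuffling cannot destroy linkage carried by
shuffle-invariant trial aggregates (e.g. total within-epoch power, which
differs between target and non-target trials). For such variance-mediated
linkage the scheme `"across_trial"` additionally permutes the trial
assignment, and the null-chain controls in the decoding pipeline use it.
The default remains the within-trial scheme, which specifically targets
temporally structured linkage.

`sparsify()` computes per-parameter two-sided empirical p-values (with the
+1 finite-sample correction) of the observed median against the null,
applies Benjamini-Hochberg FDR across parameters, and zeroes
non-surviving core entries exactly. Note the resolution limit: with $n$
surrogates the smallest attainable p-value is $2/(n+1)$, so detecting any
parameter after FDR across $m$ parameters requires roughly $n \gtrsim
2m/\alpha$ surrogates unless several parameters are jointly extreme. The
full-scale default of 10,000 surrogates is comfortably past this limit;
reduced counts in the tests use small parameter sets.

## 7. The synthetic P300 speller and its planted linkage

The generator emulates a 6x6 row/column speller: 12 highlights of 500 ms
per displaying cycle (each row and column exactly once, random order),
inter-trial intervals uniform on 2-5 s, 12 cycles per scan, and one spelled
symbol per block. Two latent sources drive both modalities: an early
"visual" source responding to every highlight, and a "P300" source
responding only to target highlights at a latency uniform on 250-400 ms
with lognormal amplitude jitter. EEG is a per-seed random unit-norm mixture
of the two sources at 250 Hz plus 1/f noise; BOLD is the per-voxel Balloon
response (TR 0.2 s, per-voxel parameters jittered ±15%) to the voxel's
region source — voxels are partitioned 30% "P300 region", 30% "visual
region", 40% null — plus white noise. SNR is defined per modality as
evoked-signal variance over noise variance in dB; the generator's defaults
(10 dB both) represent a clean but not unrealistic recording, and the
high-SNR end-to-end demonstrations use 18 dB.

What the generator does *not* emulate: volume-conduction head models, MR
gradient/ballistocardiogram artifacts in EEG, physiological (cardiac or
respiratory) BOLD noise, spatial correlation between voxels, and
non-stationarity across the session. Passing tests therefore show that the
algorithms recover the planted structure under idealized mixing and noise;
they do not certify performance on real simultaneous recordings.

## 8. Decoding, abstention, and the two BCI modes

Trial-level decoding uses a linear SVM (cost 1, features standardized with
training-set statistics) with recursive cluster elimination: features are
grouped by average-linkage clustering of $1-|\text{cor}|$, clusters are
scored by the cross-validated accuracy of an SVM on that cluster alone,
and the lowest-scoring fraction (default 0.2 of 20 clusters) is dropped
per round while overall accuracy does not degrade. Letters are decided by
averaging per-trial scores per highlight index over the first
`n_cycles_used` cycles and taking the row and column argmax (ties to the
lowest index, so an all-constant score stream yields "A").

One decoder design choice deserves emphasis. After training, the decoder
is calibrated by internal 3-fold cross-validation *on the training data*:
if out-of-fold scores do not separate the classes (one-sided t-test,
$\alpha = 0.01$), the decoder marks itself uninformative and abstains at
scoring time, emitting constant scores. The reason is structural: the
dominant variance axis of any EEG-derived feature set is the P300 axis
itself, so even a decoder trained against misaligned labels (as in a
null-linkage control) ends up with a weight vector whose projection onto
that axis is substantial with an arbitrary sign. Without abstention such a
"null" chain decodes letters at roughly 50% per block — the argmax letter
rule converts any consistent score-target correlation, of either sign,
into accuracy. Abstention is applied uniformly to every chain and is what
a deployed speller should do anyway when its calibration run shows no
signal; with it, null-trained chains fall to genuine letter-level chance.
For the same reason, the chance-level control of the post-hoc analysis
permutes the feature rows against the whole trial table (destroying both
label and highlight alignment) rather than only shuffling the SVM's
training labels.

The post-hoc mode decodes a simultaneous session from five feature
families under identical cross-validation folds: measured-fMRI MVPA
(epoch-averaged voxel responses), estimated fMRI (sparse-HOPLS prediction
of the deconvolved-fMRI tensor, collapsed over frequency and re-convolved
with each voxel's estimated HRF), the full non-sparse estimate, latent
subspace features (per-trial Tucker cores of the EEG tensor), and
ERP amplitude/latency features. The EEG-only mode streams trials through
epoch → frozen-normalization TFR → sequential Tucker update → HOPLS
forward prediction → HRF re-convolution → decoder score, logging
per-stage latencies; "real time" here means per-trial streaming with
latency accounting, not a hard deadline.

Generalization across synthetic subjects (`evaluate_generalization`)
trains each subject's chain on the first half of their blocks and decodes
the remaining blocks with chains from: the same subject, all other
subjects (model averaging — the per-subject value is therefore exactly
leave-one-subject-out transfer), and one random other subject. K-fold and
leave-one-out coincide at singleton folds by construction
(`make_folds(n, n)`).

## 9. Numerical choices and problem sizes

Degenerate inputs are handled explicitly everywhere: zero-variance TFR
bins map to zero; an all-zero residual cross covariance stops HOPLS early
with a warning; `alpha = 0` zeroes every linkage parameter and predicts
the zero tensor; an abstaining decoder yields the tie-break letter.
Cubature covariances are symmetrized each step; the filter errors (with
the step index) only on non-finite states.

The test-suite and demonstration problem sizes — sessions of 6-9 blocks x
3 cycles, 8 channels, 12 voxels, 10 EEG / 6 fMRI frequency bins, TFR time
axes decimated to 10 samples per epoch, HOPLS at $R = 3$, $L = K =
(3,3,3)$, 200 surrogates x 20 replicates for calibration — were chosen so
the full suite exercises every claim at statistically meaningful scale
while remaining runnable on a laptop in minutes. The same code paths scale
to full-size sessions (48 cycles, thousands of voxels, 10,000 surrogates)
without modification; only wall-clock time changes.

## 10. Known limitations

* Parameter recovery in blind deconvolution is reliable for $\tau$ and
  $E_0$ with a known input boxcar; in the fully blind regime the neuronal
  correlation remains high but parameter estimates should be treated as
  nuisance quantities.
* The sparse model's significance machinery assumes the surrogate scheme
  matches the linkage actually present (see section 6); aggregate-power
  linkage requires the across-trial scheme.
* The HOPLS rank defaults are sensible for the synthetic sessions; real
  data should use the cross-validated grid search.
* All performance statements in this vignette are properties of the
  synthetic generator and are verified by the package's tests; none are
  claims about real simultaneous EEG-fMRI recordings.
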