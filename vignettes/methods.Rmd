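---
title: "Symmetric source decomposition for fNIRS-EEG fusion: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetric source decomposition for fNIRS-EEG fusion: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Concurrent EEG and functional near-infrared spectroscopy (fNIRS) record two
views of the same neural event on very different terms: EEG sees millisecond
electrical activity, fNIRS sees the hemodynamic response that follows it
seconds later through neurovascular coupling. During a motor task the link is
well characterized: alpha-band (8-12 Hz) power over the contralateral motor
cortex drops (event-related desynchronization, ERD) while oxygenated
hemoglobin (HbO) rises with the shape of a canonical hemodynamic response
function (HRF), delayed by several seconds and with amplitude tied to the
size of the power drop.

`neurofuse` implements the family of *unsupervised, symmetric*
source-decomposition methods that look for this shared structure without
labels: both modalities are modeled as linear mixtures

$$x(t) = A_x s_x(t) + \epsilon_x(t), \qquad y(t) = A_y s_y(t) + \epsilon_y(t),$$

and each method learns backward-model filters $\hat s_x = W_x^\top x$,
$\hat s_y = W_y^\top y$ that expose a coupled source pair. Spatial patterns
are recovered from filters by $\hat A = C W (W^\top C W)^{-1}$, where $C$ is
the data covariance; this is the conversion every method shares
(`estimate_patterns()`), and it is what makes filter weights interpretable
as activation topographies.

## The method family

**CCA** (`fit_cca()`) maximizes $w_x^\top C_{xy} w_y$ under unit source
variance $w_x^\top C_x w_x = w_y^\top C_y w_y = 1$. We solve it as the SVD of
the whitened cross-covariance $C_x^{-1/2} C_{xy} C_y^{-1/2}$, which is
algebraically equivalent to the generalized eigenproblem form and needs no
general eigensolver. On whitened inputs CCA coincides with PLS (the SVD of
$C_{xy}$ itself); the test suite checks this identity and also cross-checks
`fit_cca()` against an exhaustive search over unit-norm filter angles on
2-channel problems and against `stats::cancor`.

**Regularized CCA** (`fit_regularized_cca()`) adds l1 (sparsity), l2
(ridge), and GraphNet ($w^\top L w$, with $L = D - B$ a channel-graph
Laplacian; `build_channel_graph()`) penalties in Lagrangian form. Design
choices that matter:

* *Identity substitution.* Once an l1 or graph penalty is active, the
  variance constraints are replaced by unit-norm constraints
  ($\|w\|_2 = 1$), the standard move in penalized-CCA implementations. Pure
  ridge keeps covariance constraints and is solved in closed form (SVD on
  ridge-shrunk whitened covariances). The mode is always recorded in the
  model.
* *Standardized penalty scale.* Penalty weights are defined on
  unit-variance features: the solver standardizes channels internally and
  maps filters back to raw units. Without this, a fixed numeric penalty
  (such as the benchmark's 0.2/0.8) would mean something different for
  every data scale. CCA itself is invariant to per-channel scaling, so all
  zero-penalty reductions are unaffected.
* *Solver.* Alternating penalized power iterations: each side's update
  soft-thresholds the cross-covariance image of the other side's filter and
  applies the normalization matrix $(1 + \lambda_2) I + \lambda_g L$,
  initialized from the leading SVD pair of $C_{xy}$, tolerance $10^{-6}$ on
  the objective, at most 500 iterations. Iterates are accepted only while
  the penalized objective does not decrease, so the recorded objective
  history is monotone and the best iterate is kept if the heuristic stalls.
* *A consequence worth knowing:* under unit-norm constraints a scalar ridge
  term is absorbed by the per-step normalization, so ElasticNet and pure-l1
  configurations coincide in this solver family. Both are kept as named
  benchmark methods for protocol fidelity, but their fits are identical by
  construction.
* *Deflation.* Rank-one deflation of the cross-covariance for two-set fits;
  components are re-ordered by achieved correlation.

**Temporally embedded CCA** (`fit_tcca()`) concatenates time-shifted copies
of the EEG-bandpower series along the feature dimension
($\tilde X \in \mathbb{R}^{PN_x \times T}$) before fitting, so the
instantaneous CCA machinery can capture the hemodynamic delay. We embed the
EEG-bandpower side (the fNIRS series is the delayed modality's counterpart);
lags default to 1-4 s in 1-s steps. Padding is zero-fill on mean-centered
data (edge-replication available); the boundary bias is $O(\text{lag}/T)$.
The x-side filter is reported both flat ($PN_x$) and reshaped
($N_x \times P$); for channel-space pattern comparisons the lag block with
the largest pattern norm is used, a choice documented here because the
embedded pattern has no unique channel-space reduction.

**Kernel CCA** (`fit_kcca()`) replaces channel filters with dual
coefficients over training samples, using centered linear, polynomial, or
gaussian kernels. Defaults are ridge 0.1 and the median-pairwise-distance
bandwidth heuristic; kCCA is ill-posed without ridge for flexible kernels,
so a positive ridge is enforced. The implementation eigendecomposes the
centered Gram matrices into implicit feature coordinates and runs the
closed-form ridge CCA there; reported correlations are therefore the
ridge-constrained objective values, which shrink to zero as the ridge grows
(a useful sanity direction) and approach the raw canonical correlations as
the ridge vanishes.

**Multiset CCA** (`fit_mcca()`) maximizes the summed pairwise covariance
(SUMCOR) or its squared version (SSQCOR) across $D \ge 2$ datasets under
per-dataset unit-variance constraints. Each alternating update is the exact
maximizer given the other filters, so the objective ascends monotonically;
with $D = 2$ and SUMCOR the fixed point is standard CCA's leading pair.
Additional components impose plain filter orthogonality
($w_{i,l} \perp w_{i,1..l-1}$), implemented by solving in the orthogonal
complement. **ssmCCA** (`fit_ssmcca()`) is the structured-sparse variant:
it maximizes $\sum_{i \ne j} |w_i^\top C_{ij} w_j|$ under $\|w_i\|_2 = 1$
with l1 and GraphNet penalties per dataset (identity-substituted
constraints, standardized penalty scale, same accept-while-ascending rule).

**mSPoC** (`fit_mspoc()`) avoids computing bandpower at channel level: it
couples the *source-level* bandpower
$\Phi(\hat s_x)(e) = w_x^\top C_x(e) w_x$ (within-window covariances
$C_x(e)$, `epoch_covariances()`) through an FIR lag filter
$h(\Phi)(e) = \sum_i w_{\tau,i} \Phi(e - \tau_i)$ to the latent fNIRS
source, maximizing $\mathrm{Cov}(h(\Phi), \hat s_y)$ under
$w_x^\top C_x w_x = w_y^\top C_y w_y = w_\tau^\top w_\tau = 1$. The
alternation makes each step optimal given the others: $w_\tau$ is the
normalized covariance of the lagged bandpower with $\hat s_y$; $w_x$ solves
a generalized eigenproblem on the $s_y$-weighted, lag-combined covariance
stack (ridge $\lambda_2 I$ added to the constraint matrix, default 0.8);
$w_y = C_y^{-1}\mathrm{cov}(y, h(\Phi))$ in closed form. Ten random restarts
plus one spectral initialization are run and the best objective kept;
within a restart the objective is non-decreasing or the restart is cut at
its best iterate. A PCA preprojection keeping 0.99 of the EEG variance is
on by default; both it and the ridge can be disabled to recover the bare
formulation. Lags are non-negative epoch offsets $\{0..N_\tau-1\}$
(bandpower precedes hemodynamics); the default $N_\tau = 8$ at the 2 Hz
epoch rate covers 0-3.5 s of delay, a range that brackets typical
neurovascular latencies.

**jICA** (`fit_jica()`) operates on group-level subject-by-feature matrices
concatenated across modalities, $D = (D_x, D_y) = G V^\top$, treating the
multimodal feature profiles $v_i$ as independent directions; each component
has a single subject-loading vector shared by both modality blocks. The ICA
core is a seeded fixed-point iteration with tanh contrast and symmetric
decorrelation after PCA-whitening to $k$ components (tolerance $10^{-7}$,
1000 iterations). Features are z-scored by default so neither modality
dominates by scale. Recovery is always assessed up to sign and permutation
(`match_components()`).

## The simulator

`simulate_session()` generates a semi-synthetic high-density fNIRS-EEG
motor-task session with full ground truth:

* **Montage** (`make_montage()`): 32 EEG electrodes on a spherical 10-20
  layout (87.5 mm radius) and two planar triangular-lattice fNIRS patches
  (19 mm spacing) tangent to the scalp at C3 and C4. Each patch carries 7
  sources and 16 detectors on 23 frozen lattice sites; taking all pairs in
  the 19 plus/minus 2 or 33 plus/minus 2 mm separation bands yields exactly 100
  channels (56 short at 19.0 mm, 44 long at 32.9 mm) from 14 sources and 32
  detectors. The site-role assignment was found once by exhaustive search
  under those printed constraints and is shipped as a package constant; the
  true layout behind those counts is not public, so this is a surrogate
  constrained to reproduce them.
* **Spatial patterns** (`make_spatial_patterns()`): the common source sits
  at the C3 landmark. EEG gets a signed "Mexican hat" topography
  (positive peak at the nearest electrode, negative surround, scale 30 mm) as
  a parametric surrogate for a dipolar leadfield; fNIRS gets a non-negative
  gaussian activity mask (15 mm scale) over channel midpoints. Full FEM
  head modelling and photon transport are deliberately out of scope; the
  surrogates keep the two patterns co-localized, smooth, and unit-norm,
  which is what the evaluated methods are sensitive to.
* **Sources** (`simulate_sources()`): the EEG source is unit-variance
  8-12 Hz noise whose envelope drops by a per-trial ERD depth (uniform
  0.4-0.8) during the 10-s stimulus, with 1-s raised-cosine ramps; trials
  are followed by uniform 8-16 s recoveries (`make_trial_schedule()`, 12
  trials). The fNIRS source is a sum of double-gamma HRF kernels (peak 6 s,
  undershoot 16 s, ratio 1/6, support 32 s) locked to each ERD onset plus a
  1-s hemodynamic delay, with amplitude equal to the trial's realized
  bandpower decrease (so amplitude and bandpower decrease correlate exactly
  by construction, and zero-depth trials produce exactly zero response).
  Because the ERD is a 10-s block and the HRF peaks at 6 s, the
  cross-correlation between negative bandpower and the HbO source peaks
  between the onset delay and the delay plus time-to-peak - not at the
  delay itself - and the tests check that mechanism-correct window.
* **Background** (`simulate_background()`): a synthetic stand-in for a real
  resting-state recording (none is available to ship). EEG: spatially
  smoothed 1/f noise plus a few spatially weighted alpha generators.
  fNIRS: smoothed 1/f noise plus global systemic oscillations - cardiac
  (~1.1 Hz), respiration (~0.25 Hz), and Mayer waves (~0.1 Hz, narrowband) -
  mixed across channels through distance-kernel weights, so nearby channels
  co-fluctuate the way shared physiology makes them. Channel variances stay
  within a factor of ~1.8. What it does *not* contain: real physiological
  nonstationarity, motion or ocular artifacts, ipsilateral ERD, or the
  post-movement beta rebound. Passing tests on this background demonstrate
  method behaviour under controlled, physiologically *shaped* noise, not
  performance on real recordings.
* **Mixing** (`assemble_dataset()`): channel-space signals are normalized to
  unit mean power over channels and scaled by an analytically computed
  gamma so the realized total-power SNR equals the request exactly (both
  modalities at the same nominal SNR; a per-channel variant of the
  normalization is a documented alternative, not the default). The
  benchmark grid spans -25 to 10 dB in 20 levels. Sessions embed a manifest
  of all seeds and parameters and reproduce bit-exactly from it.

## The benchmark protocol

`run_benchmark()` mirrors the evaluation loop end to end: simulate,
preprocess (fNIRS: 0.01-0.6 Hz zero-phase band-pass with odd-reflection
padding, linear detrend, resample to 2 Hz; EEG: 8-12 Hz zero-phase
band-pass, plus per-0.5-s-window variance giving a 2 Hz bandpower series),
epoch into 8 + 10 + 8 s trials, split 80/20 (round-half-up with a minimum
of one test trial, reproducing the 10/2 split of 12 trials), fit each
method on the concatenated training trials, and score held-out trials by
the absolute Pearson correlation of reconstructed vs. true sources and
estimated vs. true patterns. Sign-invariant (absolute) correlations are
used throughout because filters carry an inherent sign ambiguity.

Two comparator choices are deliberate and documented: CCA-family methods
consume bandpower, so their reconstructed EEG source is compared against
the true source's bandpower envelope, while mSPoC's is compared against the
band-passed source itself; and geometry, spatial patterns, and background
are held fixed across simulations while source time courses vary.
Aggregation is Fisher-z: correlations are averaged in z-space and
back-transformed; the error bar is the back-transformed standard error of
the mean in z-space. Per-cell failures are logged and isolated, never
fatal to the sweep.

Default method settings are the protocol's: l1 = 0.2, l2 = 0.8 (on the
standardized scale), lags 1-4 s, graph distance thresholds 60 mm (EEG) /
25 mm (fNIRS), mSPoC ridge 0.8 with 0.99-variance PCA. The constraint
constants of the structured-sparse formulations are exposed as Lagrangian
weights; the correspondence to constraint-form constants is
implementation-defined and noted here rather than hidden.

The shipped tests and the acceptance script run a reduced sweep - 5
simulations at three SNRs (-25, 0, +10 dB) across all seven methods - which
is enough to exhibit the qualitative structure: every method recovers
better at +10 than at -25 dB on both source metrics; standard CCA trails
tCCA on fNIRS-side recovery (temporal embedding is what buys the delay);
regularized tCCA variants reach fNIRS-side correlations around 0.9 at high
SNR; and mSPoC dominates EEG-side source and pattern recovery, which is
expected since it is the one method whose bandpower model matches the
generative forward model. tCCA's EEG-side source correlation is low by
construction - its reconstruction is a lag-mixture of bandpower - which is
the same trade-off the protocol it follows reports.

## Numerical conventions and edge cases

* Covariances use the 1/T estimator; default shrinkage is
  $10^{-9} \cdot \mathrm{tr}(C)/N$ on the diagonal - enough to guarantee
  invertibility, too small to bias any test quantity.
* Filter signs follow one convention everywhere: the largest-magnitude
  pattern coefficient is made positive; metrics are sign-invariant anyway.
* Embedding lags must land on the sampling grid within $10^{-6}$ samples;
  anything else errors rather than silently rounding.
* Bandpower windows remove the per-window mean (a `demean = "global"`
  option exists); non-overlapping windows only; the trailing partial
  window is dropped.
* Degenerate inputs error early and specifically: mismatched sample
  counts, rank-deficient whitening (with the rank reported), k beyond the
  smallest dataset, windows shorter than two samples, more FIR lags than
  epochs.
* Non-convergence never fails silently: models return
  `converged = FALSE` with a warning and the best iterate.

## Interchange formats

Models serialize to schema-versioned JSON at full (17-digit) precision, so
filters round-trip bit-exactly. Sessions export as plain CSV matrices plus
a JSON manifest (schedule, patterns, per-trial amplitudes, every seed, and
a content hash); the manifest alone regenerates the session bit-exactly.
Run configuration files are YAML validated against a fixed schema (unknown
keys are rejected before any compute). A thin command-line wrapper
(`inst/cli/neurofuse`) exposes `simulate`, `fit`, `benchmark`, and `report`
subcommands over these functions.

## Known limitations

* The fNIRS montage is a constrained reconstruction, not the exact layout
  behind the published counts.
* The background is synthetic; results quantify robustness to shaped,
  spatially correlated noise, not to real single-subject physiology.
* Multi-component mSPoC deflation beyond the first component is provided
  but not validated against any reference; the benchmark uses a single
  filter pair per method.
* kCCA hyperparameters (ridge, bandwidth) have sensible defaults but no
  tuned values; cross-validated penalty selection is intentionally left to
  the user (a coarse grid is trivial to write over `penalty_config()`).
* The recovered mSPoC FIR filter is reported but its resemblance to the
  generating HRF is not analyzed.
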