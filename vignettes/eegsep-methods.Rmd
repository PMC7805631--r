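---
title: "Methods: multi-method EEG decomposition and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-method EEG decomposition and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The signal model

All sixteen decompositions in `eegsep` estimate the same linear model
`X = A Ξ + N`: channels × samples EEG `X`, mixing matrix `A` whose columns
are topographic maps, component activities `Ξ`, optional noise `N`. We keep
as many components as channels and assume a full-rank channel covariance,
so `W = A⁻¹` exists. Blind methods operate on the whitened signal
`Z = V X` with `V = cov(X)^(-1/2)` (the symmetric inverse square root,
which makes `V` unique and runs reproducible); under unit component
variance the whitened mixing factor `U` is orthogonal and `A = V⁻¹U`.
Component activity scale and sign are not identifiable; we fix unit
activity variance for the blind methods and flip signs so each map's
largest-magnitude entry is positive, which stabilizes matching and
clustering downstream.

## The methods and their numerical choices

* **PCA** diagonalizes the signal covariance; components are ordered by
  variance and scaled to unit variance.
* **KURT, FastICAT, FastICAG** use a deflationary fixed-point search
  (tolerance 1e-6, at most 1000 iterations, up to 3 random restarts per
  component; non-converged components are flagged). KURT's contrast is the
  absolute excess kurtosis (the cubic nonlinearity); FastICA uses `tanh`
  or `x·exp(−x²/2)`.
* **CUMUL** maximizes the summed lagged fourth-order cross-cumulant
  `E[x²(t)x²(t−τ)] − E[x²]E[x²_τ] − 2E[x(t)x(t−τ)]²` at τ = 100 ms over
  orthogonal unmixing matrices, by projected gradient ascent with QR
  re-orthonormalization and step halving. The contrast is positive for
  sources whose *amplitude envelope* is positively correlated at the lag;
  iid signals make it vanish (the run is then flagged degenerate).
* **RunICA** (extended infomax) runs batch natural-gradient updates
  `ΔB ∝ (I − K tanh(u)uᵀ − uuᵀ)B` with per-component switching between a
  super-Gaussian and a sub-Gaussian branch by the sign of the component's
  excess kurtosis. Individual natural-gradient steps are not monotone in
  the likelihood, so the learning rate is annealed at checkpoints: every
  10 passes the log-likelihood implied by the current switch assignment is
  evaluated and the rate halved on a clear decrease.
* **AMICA** models each source as a mixture (2 by default) of generalized
  Gaussians `q(ξ; ρ, μ, β) ∝ exp(−|ξ−μ|^ρ/β^ρ)` and optionally two
  whole-signal models with per-sample responsibilities. The EM loop
  updates mixture weights and scales in closed form, searches the shape ρ
  by a bounded 1-D likelihood search (on a subsample for speed), and
  updates each unmixing matrix by a responsibility-normalized natural
  gradient. An iteration-level guard rejects any iteration that would
  decrease the observed-data log-likelihood (and halves the rate), so the
  reported likelihood trace is non-decreasing by construction. With two
  models the first iterations train each model on its own contiguous
  temporal chunk: the symmetric state in which both models fit the pooled
  data is a fixed point of plain EM, and the warm-up breaks it. Variants:
  AMICA (2 models, free ρ and μ), AMICA1 (2 models, Gaussian ρ=2, μ=0),
  AMICA2 (1 model, Gaussian, μ=0). For multi-model fits the dominant model
  (largest total responsibility) is reported as the decomposition.
  Segmentation accuracy is bounded by the per-sample Bayes rate of the
  true models; the tests verify the EM attains that bound rather than an
  absolute number.
* **PWCICA** forms `z = x + i·dx/dt` (central difference scaled by the
  sampling rate), whitens it in the complex domain and runs deflationary
  complex FastICA. Because `z = A(s + i·ds/dt)`, the true complex mixing
  matrix equals the real `A` up to one phase per column; we therefore
  rotate each estimated column onto the real axis (half the argument of
  the column's pseudo-norm `Σ_k a_k²`) and take the real part. We chose
  this extraction over a least-squares regression of `x` on `Re ξ` after
  observing that the regression leaves residual mixing when the complex
  separation is imperfect, whereas phase alignment is exact whenever the
  complex estimate is.
* **SOBI** symmetrizes lagged covariances (lags 1..min(50, fs/2) samples
  by default) and jointly diagonalizes them. The joint diagonalizer used
  everywhere (SOBI and MCSP) is orthogonal Jacobi rotation sweeps, each
  pair rotation solving a closed-form 2×2 eigenproblem; the off-diagonal
  norm never increases and sweeps stop below a relative tolerance. Since
  both call sites work in a whitened space, an orthogonal transform incurs
  no loss of generality, and its rows are unit-norm by construction.
* **CSP** (relax/left, relax/right, left/right, relax/both) has the
  closed-form solution via whitening of the pooled two-class covariance;
  the identities `W C₁ Wᵀ = D₁`, `W(C₁+C₂)Wᵀ = I` hold to 1e-8 on every
  input. **MCSP** whitens by the summed three-class covariance and
  approximately jointly diagonalizes the whitened class covariances; exact
  simultaneous diagonality is not guaranteed for three classes and the
  residual off-diagonal norm is reported. All covariances are zero-mean
  sample covariances with divisor T (filtered EEG is zero-mean; epochs are
  not re-centered).

## Classification and specificity

The Bayesian covariance classifier scores a window by
`ln P(i) − tr(cov(X)C_i⁻¹) − ln det C_i`; priors are proportional to total
cue time, ties break to the earliest class, and a class covariance whose
condition number exceeds 1e10 receives a relative ridge of 1e-6 (logged).
Cross-validation fits on 7 of 10 blocks and classifies whole test epochs
from their covariance, over all 120 splits. The sliding window (1 s, 100 ms
shift) is reserved for the offline replay of online feedback: for each
block after the first, the classifier is fitted on all earlier blocks and
every window in the block is classified — the package's stand-in for the
online protocol in which the classifier was updated after each block.
Greedy task-specific selection considers only dipolar components, starts
from the best singleton or pair, adds one component per step, and reports
the set at the global kappa maximum; candidate sets are capped at the 24
most dipolar components and the search stops early once kappa has clearly
peaked (both caps configurable).

## Entropy, MIR and its sign

The entropy estimator is a 512-bin histogram over the sample range:
discrete entropy plus `log₂(bin width)`, with the Miller–Madow correction
`(K−1)/(2N ln 2)` for `K` occupied bins. MIR is computed as
`Σ H(x_i) − Σ H(ξ_i) − log₂|det A|`. The sign of the determinant term
follows from substituting `H(X) = H(Ξ) + log₂|det A|` into the difference
of the channel- and component-wise mutual informations; it is also the
choice under which MIR is the (nonnegative) mutual information of a
correlated Gaussian pair after decorrelation, which the tests verify
against the closed form `−½log₂(1−ρ²)`. The rate normalization to
bits/(s·channel) is `per-sample MIR × fs / n_channels`; this convention is
ours and is stated wherever the rate is reported.

## Head model and dipolarity

The forward model is a three-shell concentric spherical conductor (radii
0.087/0.092/0.100 m; conductivities 0.33/0.0042/0.33 S/m) with electrodes
at idealized 10–10 angular positions projected onto the outer sphere
(constructed from the layout rules by great-circle interpolation, not
tabulated). The potential is expanded in spherical harmonics; the radial
coefficients per degree solve a 5×5 boundary-condition system numerically,
which keeps the model exact up to series truncation (tolerance-controlled;
the homogeneous limit reproduces the classical per-degree gain (2n+1)/n).
Dipole fitting minimizes residual variance with the moment solved linearly
at each position, a 1 cm coarse grid (orthonormalized lead-field bases
precomputed and cached, so the grid scan is a single matrix product) and
Nelder–Mead refinement with a boundary penalty — fully deterministic.
A component is dipolar when the residual variance is at most 10%
(inclusive).

Two notes on what dipolarity can and cannot separate in a spherical model:
a pair of *opposite-signed* bilateral sources is genuinely well
approximated by one central tangential dipole, and a source outside the
electrode-covered cap contributes too little signal to reject a
single-dipole fit. The two-dipole non-dipolarity checks therefore use
same-polarity superficial radial pairs under the cap, at least 8 cm apart
— the canonical "two synchronous sources" pattern.

## Shared components, similarity, rank

Two components are the same when |map cosine| ≥ 0.9 *and* |activity
correlation| ≥ 0.8 (absolute values make sign alignment irrelevant);
candidate pairs are made one-to-one greedily by descending |cos|·|r|.
Method similarity is `n_s/(n_i+n_j−n_s)`, optionally counting only dipolar
components; the matrix is embedded in 2-D by classical (Torgerson) MDS on
`1 − similarity` with a sign convention fixing each axis. Component groups
across methods are the transitive closure (union–find) of the pairwise
matches; the rank is the number of distinct methods in a group minus one.
Transitive closure can in principle chain A~B~C without a direct A~C
match; we accept this (and test it) as the natural reading of "found by k
methods". Pairwise method comparisons use paired Wilcoxon signed-rank
tests with Benjamini–Hochberg correction over all pairs.

## Clustering across sessions

Components from different sessions are compared by unit-norm maps and
per-task Welch PSDs (2 s Hann windows, 50% overlap, 5–30 Hz, unit total
power per task; the three task PSDs are concatenated before correlating —
per-task correlation then averaging is the other defensible reading).
Similarity is the mean of |map cosine| and the PSD correlation clamped to
[0, 1]. The per-task PSDs share one normalization across the three task
rows rather than being normalized per task: a per-task normalization
removes precisely the between-task amplitude differences (rhythm
suppression) that distinguish, say, a left from a right sensorimotor mu
component, and with it much of the feature's discriminative value. ANNIA
grows clusters from the unclustered feature with the largest summed
similarity (a deterministic seed choice, making the result
order-invariant), repeatedly adding the feature with maximal mean
similarity to the set while the mean intra-set similarity stays at or
above the threshold (minimum accepted size 3). Because the stopping rule
averages over all pairs, a large homogeneous cluster can absorb members
of a neighboring family long before its mean similarity decays: with
within-family similarity near 0.97 and cross-family similarity near 0.5,
a threshold of 0.75 admits roughly as many foreign members as the cluster
already holds. The default threshold is therefore 0.9, between the
within- and cross-family similarity ranges the forward model produces;
on recordings with more topographic variability a lower value is
appropriate, and the parameter is exposed.

## The synthetic-data generator

`simulate_session()` emulates the block protocol: 10 blocks, 2 cues per
hand per block in random order, 10 s cues, 2 s preparation, a relaxation
cue before each imagery cue. Eight default sources model the families such
experiments produce: left/right sensorimotor mu (10.5 Hz, contralateral
suppression to gain 0.3 during imagery), occipital and precuneus alpha
(10 Hz, gain 0.7/0.6 during imagery), SMA and premotor beta (19–20 Hz),
and two ocular surrogates (6–6.5 Hz, frontal). Because the pipeline
band-passes at 5–30 Hz, true sub-5 Hz blink energy would vanish; the blink
surrogate is therefore band-limited to survive filtering. Source
waveforms are Laplacian innovations band-passed to the source's band,
multiplied by a slow log-normal burst envelope (narrow-band filtering
Gaussianizes, bursts restore the excess kurtosis > 0.5 that real rhythms
show and that kurtosis-based methods need) and by the task envelope with
0.5 s cosine ramps. Forward maps come from the head model above and are
normalized to unit sensor RMS; sensor noise is white Gaussian (default SD
0.2 of the unit source scale). Every random draw descends from one seed.

What the generator does *not* emulate: realistic cortical geometry and
volume conduction from MRI, eye-tracking-faithful EOG waveforms,
nonstationarity of electrode impedance, inter-subject variability. Tests
passing on these sessions show the estimators are correct and the
pipeline's decisions coherent — not that the same effect sizes would be
measured on real recordings.

## Problem sizes used in the study-level tests

The separation-oracle checks use 8 sources × 8 channels at 10⁵ samples
(5 seeds). The scaled-down replications of the method-comparison and
specificity studies use five sessions on a 16-channel montage at 72 Hz
with 3 s cues and 1 s preparation — the full block structure at a desk
scale — with 20 AMICA EM iterations, 500 infomax passes, 300 complex-ICA
iterations per component, and dipole refinement restricted to the
deciding residual band (0.05–0.4; a grid residual outside it already
settles the 10% dipolarity decision). The cluster-recovery corpus uses
ten six-block sessions with the six well-separated source families
(precuneus and premotor are by design spatially entangled with their
neighbors and are evaluated qualitatively, not as recovery oracles) and
three decomposition methods. These sizes are the package's defaults for
its own validation studies; all are configurable.

## Known limitations

* The spherical head model places dipoles and electrodes on idealized
  geometry; residual-variance values on real heads differ, though the 10%
  decision rule is model-agnostic.
* AMICA's shape search is bounded to ρ ∈ [0.6, 4]; extremely heavy-tailed
  sources hit the boundary.
* CUMUL's contrast can be negative for phase-coherent oscillations
  (deterministic sinusoids), where maximization is not separation; it is
  intended for envelope-modulated rhythms.
* The EDF interchange format is not read or written; sessions live in the
  package's plain-text container (`write_recording()`/`read_recording()`).
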