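# eegsep

Multi-method EEG source separation and component evaluation for
motor-imagery brain–computer interface (BCI) experiments.

## The problem

A motor-imagery BCI records multichannel EEG while the operator relaxes or
imagines moving the left or right hand, and decodes the task from the
signal. The scalp signal is a linear superposition of a modest number of
cortical and artifactual generators,

    X = A Ξ + N,

where the columns `a_i` of the mixing matrix `A` are the generators'
topographic maps and the rows `ξ_i` of `Ξ` their activities. Many linear
decompositions estimate `A` (equivalently the unmixing matrix `W = A⁻¹`),
and they disagree: different independence or variance criteria find
different components. `eegsep` implements sixteen of these methods behind
one interface and, more importantly, the machinery for judging and
combining what they find:

* **Decompositions** — PCA; kurtosis-contrast ICA (KURT); a
  nonstationarity contrast built on the lagged fourth-order cumulant
  (CUMUL); FastICA with `tanh` and Gaussian nonlinearities (FastICAT,
  FastICAG); extended infomax (RunICA); adaptive-mixture ICA with
  generalized-Gaussian mixture source densities and one or two whole-signal
  models (AMICA, AMICA1, AMICA2); complex-domain ICA on the signal plus its
  derivative (PWCICA); second-order blind identification via joint
  diagonalization of lagged covariances (SOBI); and the supervised
  common-spatial-pattern family (CSP12/CSP13/CSP23/CSP1X and a multi-class
  MCSP solved by approximate joint diagonalization).
* **Classification** — a Bayesian classifier on zero-mean covariances,
  `argmax_i [ln P(i) − tr(cov(X) C_i⁻¹) − ln det C_i]`, with sliding-window
  replay of online feedback, block-wise cross-validation (all C(10,3) = 120
  splits of a 10-block session) and Cohen's kappa
  `κ = (g₀ Σ g_ii − Σ g_j²) / (g₀² − Σ g_j²)`.
* **Component quality** — mutual-information reduction
  `MIR = Σ H(x_i) − Σ H(ξ_i) − log₂|det A|` with a bias-corrected histogram
  entropy estimator; single-dipole fits in an analytic three-shell
  spherical head model (a component is *dipolar* when the residual variance
  of its best fit is ≤ 10%); shared components across methods
  (map cosine ≥ 0.9 and activity correlation ≥ 0.8), the method similarity
  `sim_ij = n_s / (n_i + n_j − n_s)` with multidimensional scaling, and a
  component *rank* (number of methods that found it, minus one).
* **Task specificity** — greedy selection of the dipolar components that
  maximize cross-validated kappa.
* **Clustering** — attractor-network clustering (ANNIA) of components
  across sessions by combined topography and per-task power-spectral
  similarity, with occurrence/dipolarity/rank/specificity statistics per
  cluster.
* **Synthetic sessions** — a generator of full motor-imagery sessions
  (10 blocks, 2 cues per hand per block, 10 s cues, 2 s preparation,
  relaxation before each imagery cue) from dipolar sources with
  task-modulated band-limited rhythms, so every stage above can be
  validated against known ground truth (e.g. with the Amari separation
  index).

## Worked example

```r
library(eegsep)

## a synthetic session: 32-channel 10-10 montage, 8 sources, 10 blocks
sess <- simulate_session(seed = 3)
rec  <- bandpass_notch(sess$recording)      # 5-30 Hz + 50 Hz notch
ep   <- epoch_by_task(rec)                  # 20 left, 20 right, 40 relax

## decompose and check recovery of the planted left-mu topographic map
decs <- decompose_all(rec, ep, methods = c("FastICAT", "CSP23"), seed = 1)
U <- apply(decs$FastICAT$A, 2, function(a) a / sqrt(sum(a^2)))
truth <- sess$ground_truth$A_true[, "mu_left_SI"]
best <- which.max(abs(crossprod(U, truth / sqrt(sum(truth^2)))))
max(abs(crossprod(U, truth / sqrt(sum(truth^2)))))
#> [1] 0.9990458

## classify tasks from the raw channels: all 120 block splits
cm <- cross_validate(ep)
cohen_kappa(cm)
#> [1] 0.98

## dipolarity of the recovered component's map
f <- fit_dipole(decs$FastICAT$A[, best], montage_1010())
f
#> dipole fit: rv = 0.04% at (-44.9, -11.0, 62.0) mm
is_dipolar(f)
#> [1] TRUE
```

The map cosine of 0.999 says FastICA recovered the planted left-mu
topography almost exactly; kappa = 0.98 says the three tasks are nearly
perfectly separable from whole-epoch covariances at this noise level; the
dipole fit (residual variance 0.04%, position within 2 mm of the planted
generator at (-45, -10, 60) mm) marks the component as dipolar, hence
physiologically plausible.

`run_pipeline(pipeline_config(...))` chains all stages over several
sessions and returns the per-method summary table (% dipolar components,
MIR, kappa of the selected components), the method-similarity matrix with
its 2-D embedding, and the cross-session component clusters.

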