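test_that("every BSS method satisfies W A = I and unit activity variance", {
  S <- bursty_sources(4, 2e4, seed = 10)
  set.seed(10)
  A0 <- matrix(rnorm(16), 4)
  X <- A0 %*% S
  wh <- whiten(X)
  decs <- list(
    pca_decompose(X),
    kurt_ica(wh, X, seed = 1),
    fastica(wh, "tanh", X, seed = 1),
    fastica(wh, "gauss", X, seed = 1),
    runica_extended(wh, X, seed = 1),
    cumul_ica(wh, X, fs = 128, seed = 1),
    sobi(wh, X, fs = 128),
    pwcica(X, fs = 128, seed = 1))
  T_ <- ncol(X)
  for (d in decs) {
    expect_equal(d$W %*% d$A, diag(4), tolerance = 1e-6,
                 label = paste(d$method, "W A"))
    v <- apply(d$activities, 1, function(x) mean(x^2) - mean(x)^2)
    expect_equal(v, rep(1, 4), tolerance = 1e-2,
                 label = paste(d$method, "activity variance"))
    ## reconstruction within numerical accuracy (noiseless data)
    expect_equal(d$A %*% d$activities, X, tolerance = 1e-6,
                 label = paste(d$method, "reconstruction"))
  }
})

test_that("ICA methods separate bursty band-limited sources; PCA does not", {
  S <- bursty_sources(4, 2e4, seed = 20)
  set.seed(20)
  A0 <- matrix(rnorm(16), 4)   # deliberately non-orthogonal
  X <- A0 %*% S
  wh <- whiten(X)
  expect_lt(amari_index(fastica(wh, "tanh", X, seed = 2)$W, A0), 0.1)
  expect_lt(amari_index(kurt_ica(wh, X, seed = 2)$W, A0), 0.1)
  expect_lt(amari_index(sobi(wh, X, fs = 128)$W, A0), 0.1)
  expect_gt(amari_index(pca_decompose(X)$W, A0), 0.2)
})

test_that("kurtosis contrast matches a grid-search oracle in two dimensions", {
  set.seed(30)
  T_ <- 4e4
  S <- rbind(rexp(T_) - rexp(T_), rexp(T_) - rexp(T_))
  S <- S / apply(S, 1, sd)
  phi <- 0.6
  A0 <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  X <- A0 %*% S
  wh <- whiten(X)
  ## oracle: rotation angle maximizing summed |excess kurtosis|
  angles <- seq(0, pi / 2, length.out = 400)
  obj <- vapply(angles, function(a) {
    U <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    sum(abs(apply(t(U) %*% wh$Z, 1, eegsep:::excess_kurtosis)))
  }, 0)
  a_star <- angles[which.max(obj)]
  U_star <- matrix(c(cos(a_star), sin(a_star), -sin(a_star), cos(a_star)), 2)
  W_star <- t(U_star) %*% wh$V
  d <- kurt_ica(wh, X, seed = 3)
  expect_lt(amari_index(d$W, A0), 0.05)
  expect_lt(amari_index(W_star, A0), 0.05)   # oracle agrees
  ## Gaussian-only input cannot be separated and is flagged
  set.seed(31)
  G <- matrix(rnorm(2 * 2e4), 2)
  dg <- kurt_ica(whiten(G), G, seed = 3)
  expect_true(isTRUE(dg$flags$unreliable))
})

test_that("already-separated input returns a signed permutation", {
  tm <- toy_mixture(3, 2e4, seed = 40)
  d <- fastica(whiten(tm$S), "tanh", tm$S, seed = 1)
  expect_lt(amari_index(d$W, diag(3)), 0.05)
  S <- bursty_sources(3, 2e4, seed = 40)
  dp <- pwcica(S, fs = 128, seed = 1)
  expect_lt(amari_index(dp$W, diag(3)), 0.1)
})

test_that("the lagged cumulant at lag zero reduces to excess kurtosis", {
  set.seed(50)
  Z <- whiten(matrix(rexp(2 * 2e4) - rexp(2 * 2e4), 2))$Z
  U <- diag(2)
  og <- eegsep:::.cum4_obj_grad(U, cbind(Z, Z[, 1]), 0)
  k <- apply(Z, 1, eegsep:::excess_kurtosis)
  ## cum4 at tau = 0 is E[x^4] - 3 E[x^2]^2 per component
  expect_equal(og$obj, sum(k), tolerance = 0.01)
})

test_that("nonstationarity contrast recovers an amplitude-modulated source", {
  set.seed(60)
  fs <- 128; T_ <- 3e4
  x <- signal::filtfilt(signal::butter(2, c(8, 12) / (fs / 2)), rnorm(T_))
  env <- 1 + 0.9 * sin(2 * pi * seq_len(T_) / (10 * fs))
  s1 <- x * env; s1 <- s1 / sd(s1)
  s2 <- rnorm(T_)
  phi <- 0.8
  A0 <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  X <- A0 %*% rbind(s1, s2)
  wh <- whiten(X)
  d <- cumul_ica(wh, X, fs = fs, seed = 4)
  expect_lt(amari_index(d$W, A0), 0.1)
  ## oracle: brute-force rotation search on the same objective
  lag <- max(1L, round(0.1 * fs))
  angles <- seq(0, pi / 2, length.out = 300)
  obj <- vapply(angles, function(a) {
    U <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    eegsep:::.cum4_obj_grad(U, wh$Z, lag)$obj
  }, 0)
  U_star <- with(list(a = angles[which.max(obj)]),
                 matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2))
  expect_lt(amari_index(t(U_star) %*% wh$V, A0), 0.1)
  ## iid Gaussian input is flagged degenerate
  G <- matrix(rnorm(2 * 2e4), 2)
  dg <- cumul_ica(whiten(G), G, fs = fs, seed = 4)
  expect_true(isTRUE(dg$flags$degenerate))
})

test_that("extended infomax handles mixed sub- and super-Gaussian sources", {
  set.seed(70)
  T_ <- 3e4
  S <- rbind(rexp(T_) - rexp(T_),
             rexp(T_) - rexp(T_),
             runif(T_, -1, 1) * sqrt(12),
             runif(T_, -1, 1) * sqrt(12))
  S <- S / apply(S, 1, sd)
  A0 <- matrix(rnorm(16), 4)
  X <- A0 %*% S
  d <- runica_extended(whiten(X), X, seed = 5)
  expect_lt(amari_index(d$W, A0), 0.1)
  expect_equal(sum(d$subgaussian), 2)
  ## super-Gaussian-only input: the super-Gaussian branch is chosen
  S2 <- S[1:2, ]
  X2 <- A0[1:2, 1:2] %*% S2
  d2 <- runica_extended(whiten(X2), X2, seed = 5)
  expect_false(any(d2$subgaussian))
})

test_that("AMICA recovers sources and mixture scales from Gaussian scale mixtures", {
  set.seed(80)
  n <- 3; T_ <- 2e4
  sig <- c(0.6, 2.2)
  S <- matrix(0, n, T_)
  for (i in 1:n) {
    z <- rbinom(T_, 1, 0.3)
    S[i, ] <- rnorm(T_, 0, ifelse(z, sig[2], sig[1]))
  }
  sc <- apply(S, 1, sd)
  S <- S / sc
  A0 <- matrix(rnorm(n * n), n)
  X <- A0 %*% S
  r <- amica(whiten(X), X, n_models = 1, fix_gaussian = TRUE,
             fix_zero_mean = TRUE, seed = 6, n_em_iter = 60)
  expect_lt(amari_index(r$decomposition$W, A0), 0.1)
  ## log-likelihood is non-decreasing
  ll <- r$mixture$loglik
  expect_true(all(diff(ll) > -1e-8 * abs(ll[1])))
  ## recovered generalized-Gaussian scales: beta = sigma * sqrt(2)
  beta_true <- sort(sig / mean(sc)) * sqrt(2)
  for (i in 1:n) {
    bhat <- sort(r$mixture$models[[1]]$beta[i, ])
    expect_equal(bhat, beta_true, tolerance = 0.2)
  }
})

test_that("two-model AMICA segments concatenated mixing regimes", {
  set.seed(90)
  n <- 6; T_ <- 6000
  S1 <- matrix(rexp(n * T_) - rexp(n * T_), n)
  S2 <- matrix(rexp(n * T_) - rexp(n * T_), n)
  S1 <- S1 / apply(S1, 1, sd); S2 <- S2 / apply(S2, 1, sd)
  A1 <- matrix(rnorm(n * n), n)
  A2 <- matrix(rnorm(n * n), n)
  X <- cbind(A1 %*% S1, A2 %*% S2)
  truth <- rep(c(1, 2), each = T_)
  ## Bayes reference: per-sample assignment from the true models bounds
  ## what any estimator can achieve (~0.94 on this fixture)
  llm <- function(A) {
    W <- solve(A); s <- W %*% X
    colSums(-abs(s) * sqrt(2)) + determinant(W)$modulus
  }
  oracle <- mean(ifelse(llm(A1) >= llm(A2), 1, 2) == truth)
  expect_gt(oracle, 0.9)
  r <- amica(whiten(X), X, n_models = 2, seed = 7, n_em_iter = 80)
  pred <- apply(r$mixture$responsibilities, 1, which.max)
  maj1 <- as.integer(names(which.max(table(pred[seq_len(T_)]))))
  acc <- mean(ifelse(pred == maj1, 1, 2) == truth)
  expect_gt(acc, 0.9)
})

test_that("a single forced Gaussian mixture component gives the closed-form likelihood", {
  set.seed(95)
  n <- 2; T_ <- 5000
  X <- matrix(rnorm(n * T_), n)
  wh <- whiten(X)
  r <- amica(wh, X, n_models = 1, n_mix = 1, fix_gaussian = TRUE,
             fix_zero_mean = TRUE, seed = 8, n_em_iter = 3)
  ## evaluate the model likelihood at its fitted parameters and compare to
  ## the closed-form Gaussian log-likelihood with sigma = beta / sqrt(2)
  B <- r$decomposition$W %*% solve(wh$V)
  par <- r$mixture$models[[1]]
  ll_model <- sum(eegsep:::.amica_model_ll(B, par, wh$Z))
  s <- B %*% wh$Z
  sigma <- par$beta / sqrt(2)
  ll_gauss <- ncol(s) * as.numeric(determinant(B)$modulus)
  for (i in 1:n)
    ll_gauss <- ll_gauss +
      sum(dnorm(s[i, ], 0, sigma[i, 1], log = TRUE))
  expect_equal(ll_model, ll_gauss, tolerance = 1e-6 * abs(ll_gauss))
})

test_that("SOBI separates colored sources and flags white input", {
  set.seed(100)
  T_ <- 2e4
  s1 <- as.numeric(arima.sim(list(ar = c(1.6, -0.9)), T_))
  s2 <- as.numeric(arima.sim(list(ar = c(0.2, 0.5)), T_))
  S <- rbind(s1 / sd(s1), s2 / sd(s2))
  A0 <- matrix(rnorm(4), 2)
  X <- A0 %*% S
  d <- sobi(whiten(X), X, lags = 1:20)
  expect_lt(amari_index(d$W, A0), 0.05)
  ## already jointly diagonal: identity recovered up to permutation/sign
  dd <- sobi(whiten(S), S, lags = 1:20)
  expect_lt(amari_index(dd$W, diag(2)), 0.05)
  ## iid white input is non-identifiable
  G <- matrix(rnorm(2 * 2e4), 2)
  dw <- sobi(whiten(G), G, lags = 1:20)
  expect_true(isTRUE(dw$flags$nonidentifiable))
})

test_that("joint diagonalization handles exact and approximate cases", {
  ## already diagonal: identity up to row signs/permutation, zero off-norm
  Ds <- list(diag(c(3, 1, 0.5)), diag(c(1, 2, 4)))
  jd <- joint_diagonalize(Ds)
  expect_lt(jd$off_norm, 1e-10)
  expect_equal(abs(jd$M[order(apply(abs(jd$M), 1, which.max)), ]),
               diag(3), tolerance = 1e-8)
  ## constructed exactly diagonalizable pair: R recovered
  set.seed(110)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  Cs <- list(R %*% diag(c(3, 1, 0.2)) %*% t(R),
             R %*% diag(c(1, 4, 2)) %*% t(R))
  jd2 <- joint_diagonalize(Cs)
  expect_lt(jd2$off_norm, 1e-8)
  P <- jd2$M %*% R   # must be a signed permutation
  expect_equal(apply(abs(P), 1, max), rep(1, 3), tolerance = 1e-6)
  ## non-commuting pair: off-norm strictly reduced from identity
  C1 <- crossprod(matrix(rnorm(9), 3)); C2 <- crossprod(matrix(rnorm(9), 3))
  off0 <- eegsep:::offdiag_norm2(C1) + eegsep:::offdiag_norm2(C2)
  jd3 <- joint_diagonalize(list(C1, C2))
  expect_lt(jd3$off_norm^2, off0)
  ## rows are unit norm
  expect_equal(rowSums(jd3$M^2), rep(1, 3), tolerance = 1e-10)
})

test_that("CSP solves the two-class variance problem in closed form", {
  ## hand-solved case
  d <- csp_pair(diag(c(2, 1)), diag(c(1, 2)), method = "CSP23")
  expect_equal(abs(d$W), diag(2) / sqrt(3), tolerance = 1e-10)
  expect_equal(d$D1, c(2 / 3, 1 / 3), tolerance = 1e-10)
  ## identical classes: no discriminative component
  ds <- csp_pair(diag(2), diag(2))
  expect_equal(ds$D1, c(0.5, 0.5), tolerance = 1e-10)
  ## CSP identities on random epoch covariances
  set.seed(120)
  C1 <- crossprod(matrix(rnorm(25), 5)) / 5
  C2 <- crossprod(matrix(rnorm(25), 5)) / 5
  d2 <- csp_pair(C1, C2)
  WC1W <- d2$W %*% C1 %*% t(d2$W)
  expect_lt(eegsep:::offdiag_norm2(WC1W), 1e-16)
  expect_equal(d2$W %*% (C1 + C2) %*% t(d2$W), diag(5), tolerance = 1e-8)
})

test_that("CSP recovers a class-modulated source map from epochs", {
  el <- small_montage()
  specs <- default_source_specs(el)[c(1, 3, 4)]
  sess <- simulate_session(specs, el, noise_sd = 0.05, fs = 128, seed = 7,
                           protocol = list(task_duration_s = 5,
                                           preparation_s = 1))
  rec <- bandpass_notch(sess$recording)
  ep <- epoch_by_task(rec, 5)
  cls <- eegsep:::split_epochs(ep)
  ## the left-SI mu source is suppressed during right-hand imagery: CSP of
  ## relax vs right_MI puts it first
  d <- csp_pair(cls$relax, cls$right_MI, rec$data, method = "CSP13")
  a <- d$A[, 1]
  truth <- sess$ground_truth$A_true[, 1]
  cosab <- abs(sum(a * truth)) / sqrt(sum(a^2) * sum(truth^2))
  expect_gt(cosab, 0.95)
})

test_that("MCSP jointly diagonalizes three class covariances", {
  ## mutually diagonal class covariances: exact solution
  d <- mcsp(list(diag(c(3, 1, 1)), diag(c(1, 3, 1)), diag(c(1, 1, 3))))
  expect_lt(d$off_norm, 1e-10)
  ## commuting (shared eigenvectors) case stays exact
  set.seed(130)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  mk <- function(v) R %*% diag(v) %*% t(R)
  d2 <- mcsp(list(mk(c(3, 1, 1)), mk(c(1, 3, 1)), mk(c(1, 1, 3))))
  expect_lt(d2$off_norm, 1e-8)
  ## the defining identity: W (C1+C2+C3) W' = I
  Cs <- list(crossprod(matrix(rnorm(16), 4)) / 4,
             crossprod(matrix(rnorm(16), 4)) / 4,
             crossprod(matrix(rnorm(16), 4)) / 4)
  d3 <- mcsp(Cs)
  expect_equal(d3$W %*% Reduce(`+`, Cs) %*% t(d3$W), diag(4),
               tolerance = 1e-8)
  ## a component with high variance in one class has lower variance in the
  ## others (per-class variances sum to 1 by construction)
  cv <- d3$class_variances
  expect_equal(rowSums(cv), rep(1, 4), tolerance = 1e-8)
})

test_that("decompose_all runs the battery with shared whitening and seeds", {
  el <- montage_1010(c("F3", "F4", "C3", "Cz", "C4", "P3", "P4", "Oz"))
  specs <- default_source_specs(el)[c(1, 2, 3, 5)]
  sess <- simulate_session(specs, el, noise_sd = 0.2, fs = 72, seed = 9,
                           protocol = list(n_blocks = 4,
                                           task_duration_s = 3,
                                           preparation_s = 1))
  rec <- bandpass_notch(sess$recording)
  ep <- epoch_by_task(rec, 3)
  decs <- decompose_all(rec, ep, seed = 2, amica_iter = 10)
  expect_named(decs, DECOMP_METHODS)
  for (m in DECOMP_METHODS) {
    expect_false(inherits(decs[[m]], "try-error"), label = m)
    expect_equal(ncol(decs[[m]]$A), 8, label = m)
  }
  ## single-method subset and determinism of stochastic methods
  one <- decompose_all(rec, methods = "PCA", seed = 2)
  expect_named(one, "PCA")
  again <- decompose_all(rec, ep, methods = c("KURT", "RunICA"), seed = 2)
  expect_identical(decs$KURT$A, again$KURT$A)
  expect_identical(decs$RunICA$A, again$RunICA$A)
  expect_error(decompose_all(rec, ep, methods = "NOPE"), "unknown method")
  expect_error(decompose_all(rec, methods = "CSP12"), "require task epochs")
})
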