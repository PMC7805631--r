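## Sixteen linear source-separation methods.
##
## Every method returns the same structure: a mixing matrix A (channels x n,
## columns = topographic maps), the unmixing matrix W = A^-1, and component
## activities W X.  Blind methods search for an orthogonal factor U in the
## whitened space (Z = V X, A = V^-1 U); supervised CSP-family methods solve
## generalized eigenvalue problems on class covariances instead.

#' The sixteen decomposition method names
#' @export
DECOMP_METHODS <- c("PCA", "KURT", "CUMUL", "FastICAT", "FastICAG",
                    "RunICA", "AMICA", "AMICA1", "AMICA2", "PWCICA",
                    "SOBI", "CSP12", "CSP13", "CSP23", "CSP1X", "MCSP")

new_decomposition <- function(method, A, W, activities = NULL, U = NULL,
                              flags = list(), extra = list()) {
  fixed <- fix_map_signs(A, W, activities)
  structure(c(list(method = method, A = fixed$A, W = fixed$W,
                   activities = fixed$activities, U = U, flags = flags),
              extra),
            class = "eeg_decomposition")
}

#' @export
print.eeg_decomposition <- function(x, ...) {
  cat(sprintf("decomposition [%s]: %d components", x$method, ncol(x$A)))
  if (!is.null(x$activities))
    cat(sprintf(", activities %d samples", ncol(x$activities)))
  if (length(x$flags)) cat("  flags:", paste(names(x$flags), collapse = ", "))
  cat("\n")
  invisible(x)
}

## assemble a decomposition from an orthogonal factor U in whitened space
.from_whitened <- function(method, U, wh, X, flags = list(), extra = list()) {
  W <- t(U) %*% wh$V
  A <- solve(wh$V) %*% U
  act <- W %*% X
  rownames(A) <- rownames(X)
  new_decomposition(method, A, W, act, U = U, flags = flags, extra = extra)
}

## ---------------------------------------------------------------------------
## PCA

#' Principal component analysis decomposition
#'
#' Diagonalizes the zero-mean signal covariance; all components are kept,
#' ordered by decreasing variance, and their activities are scaled to unit
#' variance (so the unmixing matrix is not orthonormal).
#'
#' @param X channels x samples matrix (or \code{eeg_recording}).
#' @return \code{eeg_decomposition}.
#' @export
pca_decompose <- function(X) {
  if (inherits(X, "eeg_recording")) X <- X$data
  C <- cov0(X)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) <= 1e-12 * max(e$values))
    stop("rank-deficient covariance")
  A <- e$vectors %*% diag(sqrt(e$values), length(e$values))
  W <- diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
  rownames(A) <- rownames(X)
  new_decomposition("PCA", A, W, W %*% X)
}

## ---------------------------------------------------------------------------
## deflationary fixed-point ICA core (KURT, FastICAT, FastICAG)

.fastica_nonlin <- function(name) {
  switch(name,
    cube = list(g = function(u) u^3, dg = function(u) 3 * u^2),
    tanh = list(g = function(u) tanh(u), dg = function(u) 1 - tanh(u)^2),
    gauss = list(g = function(u) u * exp(-u^2 / 2),
                 dg = function(u) (1 - u^2) * exp(-u^2 / 2)),
    stop("unknown nonlinearity ", name))
}

.deflation_ica <- function(Z, nonlin, seed = NULL, tol = 1e-6,
                           max_iter = 1000, restarts = 3) {
  n <- nrow(Z); T_ <- ncol(Z)
  nl <- .fastica_nonlin(nonlin)
  with_seed(seed, {
    U <- matrix(0, n, n)
    converged <- rep(FALSE, n)
    for (i in seq_len(n)) {
      best_w <- NULL
      for (r in seq_len(restarts)) {
        w <- stats::rnorm(n)
        if (i > 1) {
          Ui <- U[, seq_len(i - 1), drop = FALSE]
          w <- w - Ui %*% crossprod(Ui, w)
        }
        w <- w / sqrt(sum(w^2))
        ok <- FALSE
        for (it in seq_len(max_iter)) {
          u <- as.numeric(crossprod(w, Z))
          w_new <- Z %*% nl$g(u) / T_ - mean(nl$dg(u)) * w
          if (i > 1) {
            Ui <- U[, seq_len(i - 1), drop = FALSE]
            w_new <- w_new - Ui %*% crossprod(Ui, w_new)
          }
          nw <- sqrt(sum(w_new^2))
          if (nw < 1e-12) break
          w_new <- as.numeric(w_new) / nw
          if (abs(abs(sum(w_new * w))) > 1 - tol) {
            w <- w_new; ok <- TRUE; break
          }
          w <- w_new
        }
        best_w <- w
        if (ok) break
      }
      U[, i] <- best_w
      converged[i] <- ok
    }
    flags <- list()
    if (!all(converged)) flags$nonconverged <- which(!converged)
    list(U = U, flags = flags)
  })
}

#' Kurtosis-contrast ICA
#'
#' Sequential (deflationary) extraction of components maximizing the
#' absolute excess kurtosis of \code{t(w) Z} under orthogonality of the
#' unmixing columns.  Components whose extracted kurtosis is near zero are
#' flagged unreliable (the contrast cannot identify Gaussian sources).
#'
#' @param Z whitened signal (channels x samples) or \code{whitened_signal}.
#' @param X original signal for activity computation; defaults to the
#'   whitened input interpreted as the signal itself.
#' @param seed,tol,max_iter,restarts optimizer controls.
#' @return \code{eeg_decomposition}.
#' @export
kurt_ica <- function(Z, X = NULL, seed = NULL, tol = 1e-6,
                     max_iter = 1000, restarts = 3) {
  prep <- .as_whitened(Z, X)
  res <- .deflation_ica(prep$wh$Z, "cube", seed, tol, max_iter, restarts)
  k <- apply(crossprod(res$U, prep$wh$Z), 1, excess_kurtosis)
  if (all(abs(k) < 0.1)) res$flags$unreliable <- TRUE
  .from_whitened("KURT", res$U, prep$wh, prep$X, flags = res$flags,
                 extra = list(kurtosis = k))
}

#' FastICA with negentropy-proxy nonlinearities
#'
#' Deflationary fixed-point search with either the \code{tanh} or the
#' Gaussian (\code{x exp(-x^2/2)}) nonlinearity.
#'
#' @inheritParams kurt_ica
#' @param nonlinearity \code{"tanh"} or \code{"gauss"}.
#' @return \code{eeg_decomposition} with method \code{FastICAT} or
#'   \code{FastICAG}.
#' @export
fastica <- function(Z, nonlinearity = c("tanh", "gauss"), X = NULL,
                    seed = NULL, tol = 1e-6, max_iter = 1000, restarts = 3) {
  nonlinearity <- match.arg(nonlinearity)
  prep <- .as_whitened(Z, X)
  if (nrow(prep$wh$Z) == 1) {
    return(new_decomposition(
      if (nonlinearity == "tanh") "FastICAT" else "FastICAG",
      matrix(stats::sd(prep$X), 1, 1), matrix(1 / stats::sd(prep$X), 1, 1),
      matrix(prep$X / stats::sd(prep$X), 1)))
  }
  res <- .deflation_ica(prep$wh$Z, nonlinearity, seed, tol, max_iter,
                        restarts)
  .from_whitened(if (nonlinearity == "tanh") "FastICAT" else "FastICAG",
                 res$U, prep$wh, prep$X, flags = res$flags)
}

## accept either a whitened_signal (+ the original X) or a raw matrix
.as_whitened <- function(Z, X = NULL) {
  if (inherits(Z, "whitened_signal")) {
    if (is.null(X)) X <- solve(Z$V) %*% Z$Z
    list(wh = Z, X = as.matrix(X))
  } else {
    if (inherits(Z, "eeg_recording")) Z <- Z$data
    X <- as.matrix(Z)
    list(wh = whiten(X), X = X)
  }
}

## ---------------------------------------------------------------------------
## CUMUL: nonstationarity contrast via the lagged fourth-order cumulant

.cum4_obj_grad <- function(U, Z, lag) {
  T_ <- ncol(Z)
  za <- Z[, (lag + 1):T_, drop = FALSE]
  zb <- Z[, 1:(T_ - lag), drop = FALSE]
  Aact <- crossprod(U, za)   # components, current samples
  Bact <- crossprod(U, zb)   # lagged samples
  m <- ncol(za)
  obj <- 0
  G <- matrix(0, nrow(U), ncol(U))
  for (i in seq_len(ncol(U))) {
    a <- Aact[i, ]; b <- Bact[i, ]
    ma2 <- mean(a^2); mb2 <- mean(b^2); mab <- mean(a * b)
    obj <- obj + mean(a^2 * b^2) - ma2 * mb2 - 2 * mab^2
    G[, i] <- (za %*% (2 * a * b^2) + zb %*% (2 * a^2 * b)) / m -
      (2 * mb2 / m) * (za %*% a) - (2 * ma2 / m) * (zb %*% b) -
      (4 * mab / m) * (za %*% b + zb %*% a)
  }
  list(obj = obj, G = G)
}

#' Nonstationarity-contrast ICA (lagged fourth-order cumulant)
#'
#' Maximizes the sum over components of the cross-cumulant
#' \code{E[x^2(t) x^2(t-tau)] - E[x^2]E[x^2_tau] - 2 E[x(t)x(t-tau)]^2}
#' under an orthogonal unmixing matrix in the whitened space, by projected
#' gradient ascent with re-orthonormalization and step halving.
#'
#' @inheritParams kurt_ica
#' @param lag_ms cumulant lag in milliseconds (converted with \code{fs}).
#' @param fs sampling rate in Hz, needed to convert \code{lag_ms}.
#' @param max_iter,tol optimizer controls.
#' @return \code{eeg_decomposition}.
#' @export
cumul_ica <- function(Z, X = NULL, fs = NULL, lag_ms = 100, seed = NULL,
                      tol = 1e-8, max_iter = 300) {
  prep <- .as_whitened(Z, X)
  Zw <- prep$wh$Z
  lag <- if (is.null(fs)) as.integer(lag_ms) else
    max(1L, as.integer(round(lag_ms / 1000 * fs)))
  if (lag >= ncol(Zw)) stop("cumulant lag exceeds the sample count")
  n <- nrow(Zw)
  with_seed(seed, {
    U <- orthonormalize(diag(n) + 0.05 * matrix(stats::rnorm(n * n), n))
    step <- 0.5
    og <- .cum4_obj_grad(U, Zw, lag)
    for (it in seq_len(max_iter)) {
      improved <- FALSE
      while (step > 1e-8) {
        U_new <- orthonormalize(U + step * og$G)
        og_new <- .cum4_obj_grad(U_new, Zw, lag)
        if (og_new$obj > og$obj) {
          rel <- (og_new$obj - og$obj) / max(abs(og$obj), 1e-12)
          U <- U_new; og <- og_new; improved <- TRUE
          step <- step * 1.5
          if (rel < tol) improved <- FALSE
          break
        }
        step <- step / 2
      }
      if (!improved) break
    }
    flags <- list()
    ## flat objective: nothing beyond the sampling noise of the cumulant
    if (abs(og$obj) < 0.01 * n) flags$degenerate <- TRUE
    .from_whitened("CUMUL", U, prep$wh, prep$X, flags = flags,
                   extra = list(objective = og$obj, lag = lag))
  })
}

## ---------------------------------------------------------------------------
## RunICA: extended infomax (batch natural gradient, sub/super switching)

#' Extended infomax ICA
#'
#' Batch natural-gradient infomax with per-component switching between a
#' super-Gaussian and a sub-Gaussian nonlinearity according to the sign of a
#' running kurtosis estimate.  The learning rate is annealed; it is halved
#' whenever the data log-likelihood decreases.
#'
#' @inheritParams kurt_ica
#' @param lrate initial learning rate.
#' @param max_iter maximum number of passes.
#' @param tol stop when the relative weight change falls below this.
#' @return \code{eeg_decomposition}; \code{$subgaussian} records the final
#'   switch signs (TRUE = sub-Gaussian nonlinearity chosen).
#' @export
runica_extended <- function(Z, X = NULL, seed = NULL, lrate = 0.5,
                            max_iter = 1000, tol = 1e-5) {
  prep <- .as_whitened(Z, X)
  Zw <- prep$wh$Z
  n <- nrow(Zw); T_ <- ncol(Zw)
  ## log-densities implied by the extended-infomax score K tanh(u) + u:
  ## super-Gaussian -log cosh(u) - u^2/2, sub-Gaussian log cosh(u) - u^2/2
  loglik <- function(B, sub) {
    u <- B %*% Zw
    K <- ifelse(sub, 1, -1)
    sum(-K * log(cosh(u)) - u^2 / 2) + T_ * determinant(B)$modulus
  }
  with_seed(seed, {
    B <- orthonormalize(diag(n) + 0.05 * matrix(stats::rnorm(n * n), n))
    sub <- rep(FALSE, n)
    ll_ckpt <- -Inf
    sub_ckpt <- sub
    ## kurtosis switching runs on a subsample: the sign of the excess
    ## kurtosis is stable long before its value is
    ksub <- if (T_ > 2e4) round(seq(1L, T_, length.out = 2e4)) else
      seq_len(T_)
    for (it in seq_len(max_iter)) {
      u <- B %*% Zw
      sub <- apply(u[, ksub, drop = FALSE], 1, excess_kurtosis) < 0
      K <- ifelse(sub, -1, 1)
      th <- tanh(u)
      grad <- diag(n) - (K * th) %*% t(u) / T_ - u %*% t(u) / T_
      B_new <- B + lrate * grad %*% B
      if (!all(is.finite(B_new)) || max(abs(B_new)) > 1e8) {
        lrate <- lrate / 2
        if (lrate < 1e-12) stop("extended infomax diverged")
        next
      }
      B <- B_new
      ## annealing checkpoint: individual natural-gradient steps are not
      ## monotone, so the likelihood is monitored every 10 passes (under a
      ## fixed switch assignment) and the rate halved on a clear decrease
      if (it %% 10 == 0) {
        ll <- loglik(B, sub)
        if (identical(sub, sub_ckpt) && is.finite(ll_ckpt) &&
            ll < ll_ckpt - 1e-4 * abs(ll_ckpt)) {
          lrate <- lrate / 2
          if (lrate < 1e-8) break
        }
        ll_ckpt <- ll
        sub_ckpt <- sub
      }
      if (max(abs(lrate * grad)) < tol) break
    }
    ## normalize rows to unit component variance
    act <- B %*% Zw
    B <- B / apply(act, 1, stats::sd)
    W <- B %*% prep$wh$V
    A <- solve(W)
    flags <- list()
    if (all(abs(apply(B %*% Zw, 1, excess_kurtosis)) < 0.1))
      flags$unreliable <- TRUE
    new_decomposition("RunICA", A, W, W %*% prep$X, flags = flags,
                      extra = list(subgaussian = sub))
  })
}

## ---------------------------------------------------------------------------
## AMICA: adaptive-mixture ICA (generalized Gaussian mixtures, 1-2 models)

.row_max <- function(M) do.call(pmax, lapply(seq_len(ncol(M)), function(j) M[, j]))

.gg_logq <- function(s, rho, mu, beta) {
  d <- (s - mu) / beta
  pen <- if (rho == 2) d * d else if (rho == 1) abs(d) else abs(d)^rho
  log(rho) - log(2 * beta) - lgamma(1 / rho) - pen
}

## per-model observed-data log-likelihood terms for every sample
.amica_model_ll <- function(B, par, Zw) {
  s <- B %*% Zw
  n <- nrow(s)
  ll <- rep(as.numeric(determinant(B)$modulus), ncol(s))
  for (i in seq_len(n)) {
    lq <- vapply(seq_along(par$alpha[i, ]), function(j)
      .gg_logq(s[i, ], par$rho[i, j], par$mu[i, j], par$beta[i, j]),
      numeric(ncol(s)))
    m <- .row_max(lq)
    ll <- ll + m + log(rowSums(exp(lq - m) *
                                 rep(par$alpha[i, ], each = nrow(lq))))
  }
  ll
}

#' Adaptive-mixture ICA
#'
#' Expectation-maximization over generalized-Gaussian mixture source
#' densities, the unmixing matrices and (optionally) two whole-signal
#' models with per-sample responsibilities.  Parameter updates are guarded:
#' any update that would decrease the observed-data log-likelihood is
#' rejected (step-halved for the unmixing update), so the likelihood is
#' non-decreasing by construction.
#'
#' Variants: \code{AMICA} = 2 models, free shape and location;
#' \code{AMICA1} = 2 models, Gaussian (shape 2) with zero means;
#' \code{AMICA2} = 1 model, Gaussian with zero means.
#'
#' @inheritParams kurt_ica
#' @param n_models 1 or 2 signal models.
#' @param n_mix mixture components per source density.
#' @param fix_gaussian fix all shapes to 2 (Gaussian mixtures).
#' @param fix_zero_mean fix all mixture means to zero.
#' @param n_em_iter EM iterations.
#' @param lrate initial unmixing learning rate.
#' @return list with \code{decomposition} (from the dominant model) and
#'   \code{mixture} (per-model \code{alpha}, \code{rho}, \code{mu},
#'   \code{beta}, model priors and per-sample model responsibilities, and
#'   the log-likelihood trace).
#' @export
amica <- function(Z, X = NULL, n_models = 2, n_mix = 2,
                  fix_gaussian = FALSE, fix_zero_mean = FALSE,
                  seed = NULL, n_em_iter = 200, lrate = 0.5) {
  stopifnot(n_models %in% c(1, 2), n_em_iter >= 1)
  prep <- .as_whitened(Z, X)
  Zw <- prep$wh$Z
  n <- nrow(Zw); T_ <- ncol(Zw)
  method <- if (n_models == 2 && !fix_gaussian) "AMICA"
            else if (n_models == 2) "AMICA1" else "AMICA2"
  with_seed(seed, {
    models <- lapply(seq_len(n_models), function(m) {
      list(B = orthonormalize(diag(n) +
                                0.05 * matrix(stats::rnorm(n * n), n)),
           par = list(alpha = matrix(1 / n_mix, n, n_mix),
                      rho = matrix(2, n, n_mix),
                      mu = matrix(0, n, n_mix),
                      beta = matrix(rep(seq(0.6, 1.6, length.out = n_mix),
                                        each = n), n, n_mix)))
    })
    gamma <- rep(1 / n_models, n_models)

    model_lls <- function(mods, gam) {
      vapply(seq_along(mods), function(m)
        .amica_model_ll(mods[[m]]$B, mods[[m]]$par, Zw) + log(gam[m]),
        numeric(T_))
    }
    sum_lls <- function(lls) {
      if (ncol(lls) == 1) return(sum(lls))
      mx <- .row_max(lls)
      sum(mx + log(rowSums(exp(lls - mx))))
    }
    total_ll <- function(mods, gam) sum_lls(model_lls(mods, gam))
    ## lls_cache always holds the per-sample terms of the CURRENT models,
    ## so the guard's evaluation doubles as the next iteration's E-step
    lls_cache <- model_lls(models, gamma)
    ll <- sum_lls(lls_cache)
    trace_ll <- numeric(0)
    collapsed <- FALSE

    ## multi-model symmetry breaking: during the first iterations each
    ## model is trained on its own contiguous temporal chunk (hard
    ## responsibilities); afterwards responsibilities are free
    init_iters <- if (n_models > 1) 5L else 0L
    chunk <- ceiling(seq_len(T_) / (T_ / n_models))
    chunk[chunk > n_models] <- n_models

    for (iter in seq_len(n_em_iter)) {
      snapshot <- list(models = models, gamma = gamma)
      if (iter <= init_iters) {
        R <- vapply(seq_len(n_models), function(m)
          as.numeric(chunk == m), numeric(T_))
      } else {
        ## E-step: model responsibilities from the cached per-sample terms
        lls <- lls_cache
        mx <- .row_max(lls)
        R <- exp(lls - mx)
        R <- R / rowSums(R)         # T x n_models
      }

      for (m in seq_along(models)) {
        B <- models[[m]]$B
        par <- models[[m]]$par
        r <- R[, m]
        rsum <- sum(r)
        if (rsum < 1e-8 * T_) next
        s <- B %*% Zw
        phi <- matrix(0, n, T_)
        for (i in seq_len(n)) {
          lq <- vapply(seq_len(n_mix), function(j)
            .gg_logq(s[i, ], par$rho[i, j], par$mu[i, j], par$beta[i, j]) +
              log(par$alpha[i, j]), numeric(T_))
          mj <- .row_max(lq)
          u <- exp(lq - mj)
          u <- u / rowSums(u)       # T x n_mix mixture responsibilities
          wgt <- u * r              # model-weighted
          wsum <- colSums(wgt)
          if (any(wsum / rsum < 1e-6)) {
            ## collapsed mixture weight: reinitialize this component once
            if (!collapsed) {
              par$beta[i, ] <- seq(0.6, 1.6, length.out = n_mix)
              par$alpha[i, ] <- 1 / n_mix
              collapsed <- TRUE
              next
            }
          }
          par$alpha[i, ] <- wsum / rsum
          for (j in seq_len(n_mix)) {
            w <- wgt[, j] / max(wsum[j], 1e-12)
            if (!fix_zero_mean)
              par$mu[i, j] <- sum(w * s[i, ])
            dev <- abs(s[i, ] - par$mu[i, j])
            rho <- par$rho[i, j]
            par$beta[i, j] <-
              max(1e-4, (rho * sum(w * dev^rho))^(1 / rho))
            if (!fix_gaussian && iter %% 5 == 0) {
              ## 1-D likelihood search for the shape parameter on a
              ## subsample (the iteration-level guard keeps the full
              ## likelihood monotone regardless)
              sub <- if (T_ > 2e4) seq(1L, T_, length.out = 2e4) else
                seq_len(T_)
              ws <- w[sub]; devs <- dev[sub]; ss <- s[i, sub]
              f <- function(p) {
                b <- max(1e-4, (p * sum(ws * devs^p) / sum(ws))^(1 / p))
                sum(ws * .gg_logq(ss, p, par$mu[i, j], b))
              }
              opt <- stats::optimize(f, c(0.6, 4), maximum = TRUE,
                                     tol = 0.02)
              rho <- opt$maximum
              par$rho[i, j] <- rho
              par$beta[i, j] <-
                max(1e-4, (rho * sum(w * dev^rho))^(1 / rho))
            }
            ## mixture score for the unmixing update
            phi[i, ] <- phi[i, ] + u[, j] * rho *
              sign(s[i, ] - par$mu[i, j]) *
              (dev / par$beta[i, j])^(rho - 1) / par$beta[i, j]
          }
        }
        models[[m]]$par <- par
        ## natural-gradient unmixing step, normalized by the model's
        ## responsibility mass so minority models learn at full speed
        sw <- s * rep(r, each = n)
        grad <- diag(n) - (phi %*% t(sw)) / rsum
        models[[m]]$B <- B + lrate * grad %*% B
      }
      if (n_models > 1) {
        gamma <- pmax(colMeans(R), 1e-8)
        gamma <- gamma / sum(gamma)
      }
      ## iteration-level monotonicity guard: reject the whole iteration and
      ## anneal the unmixing rate if the observed likelihood decreased
      ## (not enforced during the forced-responsibility warm-up)
      lls_new <- try(model_lls(models, gamma), silent = TRUE)
      ll_new <- if (inherits(lls_new, "try-error")) lls_new else
        sum_lls(lls_new)
      if (iter <= init_iters) {
        if (!inherits(ll_new, "try-error") && is.finite(ll_new)) {
          ll <- ll_new
          lls_cache <- lls_new
          if (iter == init_iters) trace_ll <- numeric(0)
        } else {
          models <- snapshot$models; gamma <- snapshot$gamma
        }
        next
      }
      if (inherits(ll_new, "try-error") || !is.finite(ll_new) ||
          ll_new < ll - 1e-8 * abs(ll)) {
        models <- snapshot$models
        gamma <- snapshot$gamma
        lrate <- lrate / 2
        if (lrate < 1e-6) break
        next
      }
      ll <- ll_new
      lls_cache <- lls_new
      trace_ll <- c(trace_ll, ll)
      if (length(trace_ll) > 10 &&
          abs(diff(utils::tail(trace_ll, 2))) < 1e-9 * abs(ll)) break
    }

    ## report the dominant model as the decomposition
    lls <- lls_cache
    mx <- .row_max(lls)
    R <- exp(lls - mx); R <- R / rowSums(R)
    dominant <- which.max(colSums(R))
    B <- models[[dominant]]$B
    act <- B %*% Zw
    B <- B / apply(act, 1, stats::sd)
    W <- B %*% prep$wh$V
    A <- solve(W)
    dec <- new_decomposition(method, A, W, W %*% prep$X,
                             flags = if (collapsed)
                               list(mixture_reinit = TRUE) else list(),
                             extra = list(loglik = trace_ll,
                                          dominant_model = dominant))
    list(decomposition = dec,
         mixture = list(models = lapply(models, `[[`, "par"),
                        priors = gamma, responsibilities = R,
                        loglik = trace_ll))
  })
}

## ---------------------------------------------------------------------------
## PWCICA: complex-domain ICA on signal + i * derivative

.complex_fastica <- function(Zc, seed = NULL, tol = 1e-6, max_iter = 1000,
                             restarts = 3) {
  n <- nrow(Zc); T_ <- ncol(Zc)
  g <- function(u) 1 / (2 * sqrt(0.1 + u))
  dg <- function(u) -1 / (4 * (0.1 + u)^1.5)
  with_seed(seed, {
    U <- matrix(0 + 0i, n, n)
    converged <- rep(FALSE, n)
    for (i in seq_len(n)) {
      for (r in seq_len(restarts)) {
        w <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
        w <- w / sqrt(Re(sum(Conj(w) * w)))
        ok <- FALSE
        for (it in seq_len(max_iter)) {
          y <- as.vector(Conj(t(w)) %*% Zc)
          ay2 <- Re(y * Conj(y))
          w_new <- Zc %*% (Conj(y) * g(ay2)) / T_ -
            mean(g(ay2) + ay2 * dg(ay2)) * w
          if (i > 1) {
            Ui <- U[, seq_len(i - 1), drop = FALSE]
            w_new <- w_new - Ui %*% (Conj(t(Ui)) %*% w_new)
          }
          nw <- sqrt(Re(sum(Conj(w_new) * w_new)))
          if (nw < 1e-12) break
          w_new <- as.vector(w_new) / nw
          if (abs(Mod(sum(Conj(w_new) * w))) > 1 - tol) {
            w <- w_new; ok <- TRUE; break
          }
          w <- w_new
        }
        if (ok) break
      }
      U[, i] <- w
      converged[i] <- ok
    }
    list(U = U, converged = converged)
  })
}

#' Pair-wise complex ICA on the signal and its derivative
#'
#' Maps the real signal into the complex domain as \code{x + i dx/dt}
#' (central first difference scaled by the sampling rate), whitens it and
#' separates with complex FastICA.  Because \code{x + i dx/dt = A (s + i
#' ds/dt)}, the true complex mixing matrix is the real mixing matrix up to
#' a per-column complex phase; the real mixing is therefore recovered by
#' rotating each estimated column onto the real axis (phase of the column's
#' pseudo-norm) and taking the real part.
#'
#' @param X channels x samples real matrix (or \code{eeg_recording}).
#' @param fs sampling rate, Hz.
#' @param seed RNG seed.
#' @return \code{eeg_decomposition}.
#' @export
pwcica <- function(X, fs = NULL, seed = NULL, max_iter = 1000) {
  if (inherits(X, "eeg_recording")) { fs <- X$fs; X <- X$data }
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 samples")
  if (is.null(fs)) fs <- 1
  T_ <- ncol(X)
  ## central first difference, one-sided at the edges
  D <- cbind(X[, 2] - X[, 1],
             (X[, 3:T_, drop = FALSE] - X[, 1:(T_ - 2), drop = FALSE]) / 2,
             X[, T_] - X[, T_ - 1]) * fs
  Zc <- X + 1i * D
  Cc <- Zc %*% Conj(t(Zc)) / T_
  e <- eigen(Cc, symmetric = TRUE)
  vals <- Re(e$values)
  if (min(vals) <= 1e-12 * max(vals)) stop("rank-deficient covariance")
  Vc <- e$vectors %*% (Conj(t(e$vectors)) / sqrt(vals))
  Zcw <- Vc %*% Zc
  res <- .complex_fastica(Zcw, seed = seed, max_iter = max_iter)
  Ac <- solve(Vc) %*% res$U        # complex mixing of Zc
  theta <- Arg(colSums(Ac^2)) / 2  # per-column phase to the real axis
  A <- Re(Ac * rep(exp(-1i * theta), each = nrow(Ac)))
  W <- solve(A)
  ## rescale so the real activities have unit variance
  act <- W %*% X
  sdv <- apply(act, 1, stats::sd)
  W <- W / sdv
  A <- A * rep(sdv, each = nrow(A))
  flags <- if (all(res$converged)) list() else
    list(nonconverged = which(!res$converged))
  rownames(A) <- rownames(X)
  new_decomposition("PWCICA", A, W, W %*% X, flags = flags)
}

## ---------------------------------------------------------------------------
## SOBI

#' Second-order blind identification
#'
#' Estimates symmetrized lagged covariance matrices of the whitened signal
#' and jointly diagonalizes them with an orthogonal transform.
#'
#' @inheritParams kurt_ica
#' @param lags sample lags; default \code{1:min(50, floor(fs/2))} when
#'   \code{fs} is known, else \code{1:50}.
#' @param fs sampling rate (only used for the default lag set).
#' @return \code{eeg_decomposition}.
#' @export
sobi <- function(Z, X = NULL, lags = NULL, fs = NULL) {
  prep <- .as_whitened(Z, X)
  Zw <- prep$wh$Z
  T_ <- ncol(Zw)
  if (is.null(lags))
    lags <- seq_len(min(50L, if (is.null(fs)) 50L else floor(fs / 2)))
  if (max(lags) >= T_) stop("largest lag exceeds the sample count")
  Ck <- lapply(lags, function(k) {
    C <- Zw[, (k + 1):T_, drop = FALSE] %*%
      t(Zw[, 1:(T_ - k), drop = FALSE]) / (T_ - k)
    (C + t(C)) / 2
  })
  total <- sum(vapply(Ck, function(C) sum(C^2), numeric(1)))
  flags <- list()
  ## white input: every entry of a lagged covariance is O(1/sqrt(T)), so
  ## the total energy stays near its sampling-noise expectation
  noise_floor <- nrow(Zw)^2 * length(Ck) / T_
  if (total < 5 * noise_floor) flags$nonidentifiable <- TRUE
  jd <- joint_diagonalize(Ck)
  U <- t(jd$M)
  .from_whitened("SOBI", U, prep$wh, prep$X, flags = flags,
                 extra = list(off_norm = jd$off_norm, lags = lags))
}

## ---------------------------------------------------------------------------
## joint diagonalization (Jacobi rotations over pairs)

#' Approximate joint diagonalization of symmetric matrices
#'
#' Orthogonal simultaneous diagonalization by Jacobi rotation sweeps: for
#' every index pair the rotation angle minimizing the summed off-diagonal
#' energy of all matrices is applied; sweeps repeat until the relative
#' improvement of the off-diagonal norm drops below \code{tol}.  The
#' returned transform has unit-norm rows and never increases the
#' off-diagonal norm.
#'
#' @param matrices list of (>= 2) symmetric matrices of a common dimension.
#' @param tol relative improvement threshold.
#' @param max_iter maximum number of sweeps.
#' @return list with \code{M} (the transform; rows unit norm),
#'   \code{off_norm} (final summed off-diagonal Frobenius norm),
#'   \code{iterations}, and \code{converged}.
#' @export
joint_diagonalize <- function(matrices, tol = 1e-10, max_iter = 100) {
  stopifnot(length(matrices) >= 2)
  n <- nrow(matrices[[1]])
  Cs <- lapply(matrices, function(C) {
    stopifnot(nrow(C) == n, ncol(C) == n)
    (C + t(C)) / 2
  })
  M <- diag(n)
  offn <- function() sum(vapply(Cs, offdiag_norm2, numeric(1)))
  off_old <- offn()
  it <- 0
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1
    for (p in seq_len(n - 1)) for (q in (p + 1):n) {
      ## Jacobi angle maximizing the diagonal energy of all matrices
      G <- matrix(0, 2, 2)
      for (C in Cs) {
        h <- c(C[p, p] - C[q, q], C[p, q] + C[q, p])
        G <- G + tcrossprod(h)
      }
      e <- eigen(G, symmetric = TRUE)
      v <- e$vectors[, 1]
      if (v[1] < 0) v <- -v
      theta <- 0.5 * atan2(v[2], v[1])
      c_ <- cos(theta); s_ <- sin(theta)
      if (abs(s_) < 1e-14) next
      R <- diag(n); R[p, p] <- c_; R[q, q] <- c_
      R[p, q] <- -s_; R[q, p] <- s_
      Cs <- lapply(Cs, function(C) t(R) %*% C %*% R)
      M <- t(R) %*% M
    }
    off_new <- offn()
    if (off_old - off_new < tol * max(off_old, 1e-300)) {
      converged <- TRUE
      off_old <- off_new
      break
    }
    off_old <- off_new
  }
  if (!converged)
    warning("joint diagonalization: max_iter reached, returning best so far")
  list(M = M, off_norm = sqrt(off_old), iterations = it,
       converged = converged)
}

## ---------------------------------------------------------------------------
## CSP family

## pooled zero-mean class covariance from an epoch set
.class_cov <- function(epochs) {
  tot <- 0
  S <- 0
  for (e in epochs) {
    S <- S + tcrossprod(e$X)
    tot <- tot + ncol(e$X)
  }
  if (tot == 0) stop("empty epoch class")
  S / tot
}

#' Two-class common spatial patterns
#'
#' Solves \code{W C1 W' = D1}, \code{W (C1 + C2) W' = I} in closed form via
#' whitening of the pooled covariance followed by an eigendecomposition.
#' Components are ordered by decreasing class-1 variance fraction.
#'
#' @param epochs_class1,epochs_class2 epoch sets (lists with \code{$X}) of
#'   the two classes, or covariance matrices.
#' @param X optional continuous signal for component activities.
#' @param method label stored on the result (\code{CSP12}, \code{CSP13},
#'   \code{CSP23}, \code{CSP1X}).
#' @return \code{eeg_decomposition} with extra fields \code{D1} (class-1
#'   variance fractions).
#' @export
csp_pair <- function(epochs_class1, epochs_class2, X = NULL,
                     method = "CSP") {
  C1 <- if (is.matrix(epochs_class1)) epochs_class1
        else .class_cov(epochs_class1)
  C2 <- if (is.matrix(epochs_class2)) epochs_class2
        else .class_cov(epochs_class2)
  P <- sym_inv_sqrt(C1 + C2)
  S <- P %*% C1 %*% P
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  W <- t(e$vectors) %*% P
  A <- solve(W)
  act <- if (!is.null(X)) W %*% as.matrix(X) else NULL
  new_decomposition(method, A, W, act,
                    extra = list(D1 = e$values))
}

#' Multi-class common spatial patterns
#'
#' Whitens by the summed class covariance and approximately jointly
#' diagonalizes the whitened class covariances with an orthogonal factor;
#' exact simultaneous diagonality is not guaranteed for three or more
#' classes, so the residual off-diagonal norm is reported.
#'
#' @param epochs_by_class list of three epoch sets (or covariance
#'   matrices), one per task.
#' @param X optional continuous signal for component activities.
#' @return \code{eeg_decomposition} with \code{class_variances} (n x 3) and
#'   \code{off_norm}.
#' @export
mcsp <- function(epochs_by_class, X = NULL) {
  stopifnot(length(epochs_by_class) == 3)
  Cs <- lapply(epochs_by_class, function(e)
    if (is.matrix(e)) e else .class_cov(e))
  P <- sym_inv_sqrt(Reduce(`+`, Cs))
  Cw <- lapply(Cs[1:2], function(C) P %*% C %*% P)
  jd <- joint_diagonalize(Cw)
  W <- jd$M %*% P
  A <- solve(W)
  cv <- vapply(Cs, function(C) diag(W %*% C %*% t(W)), numeric(nrow(W)))
  ## order by class discriminability (spread of per-class variances)
  ord <- order(apply(cv, 1, stats::var), decreasing = TRUE)
  W <- W[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  cv <- cv[ord, , drop = FALSE]
  act <- if (!is.null(X)) W %*% as.matrix(X) else NULL
  new_decomposition("MCSP", A, W, act,
                    extra = list(class_variances = cv,
                                 off_norm = jd$off_norm))
}

## ---------------------------------------------------------------------------
## batch driver

#' Run a set of decomposition methods on one session
#'
#' Blind methods work on the continuous (filtered) signal with a shared
#' whitening; CSP-family methods additionally receive the task epochs.
#' Every stochastic method gets a seed derived deterministically from
#' \code{seed} and its position in the method list.  A failing method is
#' recorded and the remaining methods still run.
#'
#' @param recording filtered \code{eeg_recording}.
#' @param epochs epoch set from [epoch_by_task()]; required for the CSP
#'   family.
#' @param methods character vector of method names (see
#'   \code{DECOMP_METHODS}); default all 16.
#' @param seed master seed.
#' @param amica_iter EM iterations for the AMICA variants.
#' @param runica_iter maximum extended-infomax passes.
#' @param pwcica_iter maximum complex FastICA iterations per component.
#' @return named list of \code{eeg_decomposition} (failed methods carry a
#'   \code{try-error}).
#' @export
decompose_all <- function(recording, epochs = NULL,
                          methods = DECOMP_METHODS, seed = 1,
                          amica_iter = 60, runica_iter = 1000,
                          pwcica_iter = 1000) {
  bad <- setdiff(methods, DECOMP_METHODS)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  X <- recording$data
  fs <- recording$fs
  wh <- whiten(X)
  byclass <- if (!is.null(epochs)) split_epochs(epochs) else NULL
  need_ep <- c("CSP12", "CSP13", "CSP23", "CSP1X", "MCSP")
  if (any(methods %in% need_ep) && is.null(byclass))
    stop("CSP-family methods require task epochs")
  out <- list()
  for (m in methods) {
    ## seed depends on the method's canonical index so that running a
    ## subset reproduces the full battery's results
    sd_k <- (seed * 131L + match(m, DECOMP_METHODS)) %%
      .Machine$integer.max
    out[[m]] <- try(switch(
      m,
      PCA = pca_decompose(X),
      KURT = kurt_ica(wh, X, seed = sd_k),
      CUMUL = cumul_ica(wh, X, fs = fs, seed = sd_k),
      FastICAT = fastica(wh, "tanh", X, seed = sd_k),
      FastICAG = fastica(wh, "gauss", X, seed = sd_k),
      RunICA = runica_extended(wh, X, seed = sd_k,
                               max_iter = runica_iter),
      AMICA = amica(wh, X, n_models = 2, seed = sd_k,
                    n_em_iter = amica_iter)$decomposition,
      AMICA1 = amica(wh, X, n_models = 2, fix_gaussian = TRUE,
                     fix_zero_mean = TRUE, seed = sd_k,
                     n_em_iter = amica_iter)$decomposition,
      AMICA2 = amica(wh, X, n_models = 1, fix_gaussian = TRUE,
                     fix_zero_mean = TRUE, seed = sd_k,
                     n_em_iter = amica_iter)$decomposition,
      PWCICA = pwcica(X, fs = fs, seed = sd_k, max_iter = pwcica_iter),
      SOBI = sobi(wh, X, fs = fs),
      CSP12 = csp_pair(byclass$relax, byclass$left_MI, X, "CSP12"),
      CSP13 = csp_pair(byclass$relax, byclass$right_MI, X, "CSP13"),
      CSP23 = csp_pair(byclass$left_MI, byclass$right_MI, X, "CSP23"),
      CSP1X = csp_pair(byclass$relax,
                       structure(c(unclass(byclass$left_MI),
                                   unclass(byclass$right_MI)),
                                 class = "epoch_set"),
                       X, "CSP1X"),
      MCSP = mcsp(byclass, X)), silent = TRUE)
    if (inherits(out[[m]], "try-error"))
      warning("method ", m, " failed: ",
              attr(out[[m]], "condition")$message)
  }
  out
}
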