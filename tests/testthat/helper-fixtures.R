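## Shared fixtures.  Everything is generated in code at test time; heavy
## objects (multi-session corpora with full decompositions) are cached in a
## package-local environment so several test files can share them.

.fixture_env <- new.env(parent = emptyenv())

## 16-channel montage used for the scaled-down session studies
small_montage <- function() {
  montage_1010(c("Fp1", "Fp2", "F3", "Fz", "F4", "FC5", "FC6", "T7",
                 "C3", "Cz", "C4", "T8", "P3", "Pz", "P4", "Oz"))
}

## iid super-Gaussian toy mixture for quick ICA checks
toy_mixture <- function(n = 4, T_ = 2e4, seed = 1, orthogonal = FALSE) {
  set.seed(seed)
  S <- matrix(stats::rexp(n * T_) - stats::rexp(n * T_), n)
  S <- S / apply(S, 1, stats::sd)
  A <- matrix(stats::rnorm(n * n), n)
  if (orthogonal) A <- qr.Q(qr(A))
  list(S = S, A = A, X = A %*% S)
}

## bursty band-limited sources (the structure every method family can see)
bursty_sources <- function(n = 4, T_ = 2e4, fs = 128, seed = 1) {
  set.seed(seed)
  fcs <- seq(7, 23, length.out = n)
  S <- t(vapply(fcs, function(fc) {
    x <- signal::filtfilt(signal::butter(2, c(fc - 1.5, fc + 1.5) / (fs / 2)),
                          stats::rexp(T_) - stats::rexp(T_))
    e <- 1 + 0.8 * sin(2 * pi * seq_len(T_) / (20 * fs) +
                         stats::runif(1, 0, 2 * pi))
    x <- x * e
    x / stats::sd(x)
  }, numeric(T_)))
  S
}

## independent implementation of the Amari separation error (test oracle)
amari_reference <- function(W, A) {
  P <- abs(W %*% A)
  n <- nrow(P)
  s <- 0
  for (i in seq_len(n)) s <- s + sum(P[i, ]) / max(P[i, ]) - 1
  for (j in seq_len(n)) s <- s + sum(P[, j]) / max(P[, j]) - 1
  s / (2 * n * (n - 1))
}

## scaled-down study sessions (10 blocks, short cues, 16 channels) with the
## full 16-method battery and per-component dipole fits; built once
study_corpus <- function(n_sessions = 5) {
  key <- paste0("corpus", n_sessions)
  hit <- .fixture_env[[key]]
  if (!is.null(hit)) return(hit)
  el <- small_montage()
  specs <- default_source_specs(el)
  fs <- 72
  out <- lapply(seq_len(n_sessions), function(s) {
    sess <- simulate_session(
      specs, el,
      protocol = list(task_duration_s = 3, preparation_s = 1),
      noise_sd = 0.2, fs = fs, seed = 100 + s)
    rec <- bandpass_notch(sess$recording)
    epochs <- epoch_by_task(rec, task_duration_s = 3)
    decs <- decompose_all(rec, epochs, seed = 100 + s, amica_iter = 20,
                          runica_iter = 500, pwcica_iter = 300)
    ok <- !vapply(decs, inherits, TRUE, "try-error")
    dip <- list(); rv <- list()
    for (m in names(decs)[ok]) {
      fits <- lapply(seq_len(ncol(decs[[m]]$A)), function(j)
        fit_dipole(decs[[m]]$A[, j], el, refine_range = c(0.05, 0.4)))
      rv[[m]] <- vapply(fits, `[[`, 0, "residual_variance")
      d <- rv[[m]] <= 0.10
      attr(d, "rv") <- rv[[m]]
      dip[[m]] <- d
    }
    list(session = sess, rec = rec, epochs = epochs, decs = decs,
         dipolar = dip, rv = rv, electrodes = el, fs = fs)
  })
  .fixture_env[[key]] <- out
  out
}
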