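## Synthetic motor-imagery sessions with known ground truth.
##
## Sources are dipolar cortical generators with band-limited rhythms whose
## amplitude is modulated by the experimental task (relaxation, left-hand
## motor imagery, right-hand motor imagery), plus ocular artifacts and
## sensor noise.  Because the mixing matrix and the per-task envelopes are
## known exactly, every downstream stage (decomposition, classification,
## dipole fitting, clustering) can be validated against ground truth.

#' The three experimental task labels
#' @export
TASKS <- c("relax", "left_MI", "right_MI")

#' Specification of one synthetic EEG source
#'
#' @param kind one of \code{"mu_left_SI"}, \code{"mu_right_SI"},
#'   \code{"occipital_alpha"}, \code{"precuneus_alpha"},
#'   \code{"sma_alpha_beta"}, \code{"premotor"}, \code{"blink"},
#'   \code{"eye_movement"}, \code{"noise"}.
#' @param position dipole position (3-vector, meters, inside the inner
#'   shell).
#' @param moment dipole moment direction (3-vector; normalized internally).
#' @param center_freq rhythm center frequency, Hz.
#' @param bandwidth rhythm bandwidth, Hz (> 0).
#' @param modulation named numeric vector of per-task amplitude gains
#'   \code{c(relax=, left_MI=, right_MI=)}, all > 0.
#' @param distribution innovation distribution, \code{"laplacian_envelope"}
#'   (super-Gaussian, the default) or \code{"gaussian"}.
#' @return object of class \code{source_spec}.
#' @export
source_spec <- function(kind, position, moment, center_freq, bandwidth,
                        modulation = c(relax = 1, left_MI = 1, right_MI = 1),
                        distribution = c("laplacian_envelope", "gaussian")) {
  distribution <- match.arg(distribution)
  kinds <- c("mu_left_SI", "mu_right_SI", "occipital_alpha",
             "precuneus_alpha", "sma_alpha_beta", "premotor",
             "blink", "eye_movement", "noise")
  kind <- match.arg(kind, kinds)
  position <- as.numeric(position)
  moment <- as.numeric(moment)
  stopifnot(length(position) == 3, length(moment) == 3)
  if (any(moment != 0)) moment <- moment / sqrt(sum(moment^2))
  modulation <- modulation[TASKS]
  if (anyNA(modulation) || any(modulation <= 0))
    stop("modulation must supply positive gains for relax, left_MI, right_MI")
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  structure(list(kind = kind, position = position, moment = moment,
                 center_freq = center_freq, bandwidth = bandwidth,
                 modulation = modulation, distribution = distribution),
            class = "source_spec")
}

#' Default synthetic source families
#'
#' Eight sources emulating the component families recurrently found in
#' motor-imagery BCI sessions: left and right sensorimotor mu generators
#' with contralateral suppression during imagery, occipital and precuneus
#' alpha, supplementary-motor-area beta, a left premotor source, a frontal
#' blink surrogate band-limited to 5-8 Hz (a session band-passed at
#' 5-30 Hz retains no true sub-5 Hz blink energy), and a lateral
#' eye-movement source.
#'
#' @param electrodes electrode matrix; used only to scale depths to the
#'   head model.  Unused at present but kept for signature stability.
#' @return list of [source_spec()] objects.
#' @export
default_source_specs <- function(electrodes = montage_1010()) {
  g <- function(r, l, ri) c(relax = r, left_MI = l, right_MI = ri)
  list(
    ## left SI mu: suppressed by right-hand imagery (contralateral ERD)
    source_spec("mu_left_SI", c(-0.045, -0.01, 0.060), c(-0.4, 0.2, 1),
                center_freq = 10.5, bandwidth = 3, modulation = g(1, 1, 0.3)),
    ## right SI mu: suppressed by left-hand imagery
    source_spec("mu_right_SI", c(0.045, -0.01, 0.060), c(0.4, 0.2, 1),
                center_freq = 10.5, bandwidth = 3, modulation = g(1, 0.3, 1)),
    ## occipital alpha: mildly suppressed by both imagery tasks
    source_spec("occipital_alpha", c(0.015, -0.065, 0.030), c(0.2, -1, 0.3),
                center_freq = 10, bandwidth = 2.5, modulation = g(1, 0.7, 0.7)),
    source_spec("precuneus_alpha", c(0, -0.045, 0.060), c(0, -0.5, 1),
                center_freq = 10, bandwidth = 2.5, modulation = g(1, 0.6, 0.6)),
    ## SMA: beta that desynchronizes during imagery
    source_spec("sma_alpha_beta", c(0, 0.015, 0.070), c(0, 0.3, 1),
                center_freq = 20, bandwidth = 5, modulation = g(1, 0.6, 0.6)),
    ## left premotor: slightly enhanced by imagery
    source_spec("premotor", c(-0.040, 0.035, 0.050), c(-0.5, 0.5, 1),
                center_freq = 19, bandwidth = 5, modulation = g(0.8, 1.2, 1.2)),
    ## blink surrogate: frontal radial, 5-8 Hz, more frequent at rest
    source_spec("blink", c(0, 0.060, 0.030), c(0, 0.8, 0.6),
                center_freq = 6.5, bandwidth = 3, modulation = g(1.3, 0.8, 0.8)),
    source_spec("eye_movement", c(0.025, 0.062, 0.015), c(1, 0.2, 0),
                center_freq = 6, bandwidth = 2, modulation = g(1.2, 0.9, 0.9))
  )
}

## ---------------------------------------------------------------------------
## protocol events

#' Cue events for the block-design motor-imagery protocol
#'
#' Ten blocks, each holding two cues per hand in random order; every imagery
#' cue is preceded by a relaxation cue and a short preparation gap.
#'
#' @param n_blocks number of blocks.
#' @param cues_per_hand_per_block imagery cues per hand in each block.
#' @param task_duration_s cue length, seconds (applies to relaxation and
#'   imagery cues alike).
#' @param preparation_s preparation gap between the relaxation cue and the
#'   imagery cue, seconds.
#' @param fs sampling rate, Hz.
#' @param seed RNG seed controlling within-block cue order.
#' @return data.frame with columns \code{onset} (sample index, 1-based),
#'   \code{task}, \code{block}.
#' @export
protocol_events <- function(n_blocks = 10, cues_per_hand_per_block = 2,
                            task_duration_s = 10, preparation_s = 2,
                            fs = 128, seed = NULL) {
  task_n <- round(task_duration_s * fs)
  prep_n <- round(preparation_s * fs)
  with_seed(seed, {
    onset <- 1L
    rows <- list()
    for (b in seq_len(n_blocks)) {
      cues <- sample(rep(c("left_MI", "right_MI"), cues_per_hand_per_block))
      for (task in cues) {
        rows[[length(rows) + 1L]] <-
          data.frame(onset = onset, task = "relax", block = b)
        onset <- onset + task_n + prep_n
        rows[[length(rows) + 1L]] <-
          data.frame(onset = onset, task = task, block = b)
        onset <- onset + task_n + prep_n
      }
    }
    ev <- do.call(rbind, rows)
    ev$task <- factor(ev$task, levels = TASKS)
    attr(ev, "n_samples") <- onset - 1L  # last cue + trailing preparation
    attr(ev, "task_samples") <- task_n
    ev
  })
}

## per-sample task gain timeline with raised-cosine ramps
.task_envelope <- function(gains, events, n_samples, fs, task_samples,
                           ramp_s = 0.5) {
  ## without events the source is stationary with unit envelope
  if (is.null(events) || nrow(events) == 0) return(rep(1, n_samples))
  g <- rep(gains["relax"], n_samples)
  if (!is.null(events) && nrow(events) > 0) {
    for (k in seq_len(nrow(events))) {
      i0 <- events$onset[k]
      i1 <- min(n_samples, i0 + task_samples - 1L)
      if (i0 <= n_samples) g[i0:i1] <- gains[as.character(events$task[k])]
    }
  }
  nr <- max(1L, round(ramp_s * fs))
  if (nr > 1 && length(g) > 2 * nr) {
    h <- 0.5 - 0.5 * cos(pi * seq_len(nr) / (nr + 1))  # 0..1 cosine ramp
    h <- h / sum(h)
    g <- stats::filter(c(rep(g[1], nr), g, rep(g[length(g)], nr)), h,
                       sides = 2)
    g <- as.numeric(g[(nr + 1):(nr + n_samples)])
    g[is.na(g)] <- gains["relax"]
  }
  g
}

#' Simulate source activities
#'
#' Each source is a band-limited oscillation: white innovations (Laplacian
#' by default, hence super-Gaussian) are band-pass filtered to
#' \code{center_freq +/- bandwidth/2}, scaled to unit variance, then
#' multiplied by the per-task amplitude envelope of the source.
#'
#' @param specs list of [source_spec()].
#' @param events protocol events (may be NULL for stationary sources).
#' @param fs sampling rate, Hz; must satisfy
#'   \code{fs >= 2.5 * max(center_freq + bandwidth / 2)}.
#' @param n_samples number of samples to generate.
#' @param seed RNG seed.
#' @param task_samples samples per cue (defaults to the events attribute).
#' @return list with \code{activities} (sources x samples) and
#'   \code{envelopes} (sources x samples).
#' @export
simulate_sources <- function(specs, events, fs, n_samples, seed = NULL,
                             task_samples = attr(events, "task_samples")) {
  hi <- max(vapply(specs, function(s) s$center_freq + s$bandwidth / 2,
                   numeric(1)))
  if (fs < 2.5 * hi)
    stop(sprintf("fs = %g Hz cannot carry a band reaching %g Hz (need >= %g)",
                 fs, hi, 2.5 * hi))
  if (is.null(task_samples)) task_samples <- round(10 * fs)
  with_seed(seed, {
    S <- matrix(0, length(specs), n_samples)
    E <- matrix(0, length(specs), n_samples)
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      innov <- if (sp$distribution == "laplacian_envelope") {
        ## standard Laplace: difference of exponentials
        stats::rexp(n_samples) - stats::rexp(n_samples)
      } else stats::rnorm(n_samples)
      band <- c(sp$center_freq - sp$bandwidth / 2,
                sp$center_freq + sp$bandwidth / 2) / (fs / 2)
      band[1] <- max(band[1], 1e-3)
      bf <- signal::butter(2, band, type = "pass")
      x <- signal::filtfilt(bf, innov)
      if (sp$distribution == "laplacian_envelope") {
        ## rhythms come in bursts: a slow log-normal amplitude envelope
        ## keeps the source super-Gaussian after the (Gaussianizing)
        ## band-pass filter
        g <- stats::rnorm(n_samples)
        span <- max(3L, round(fs))   # ~1 s smoothing
        g <- stats::filter(g, rep(1 / span, span), sides = 2,
                           circular = TRUE)
        g <- as.numeric(g) / stats::sd(g)
        x <- x * exp(0.5 * g)
      }
      x <- x / stats::sd(x)
      env <- .task_envelope(sp$modulation, events, n_samples, fs,
                            task_samples)
      S[i, ] <- x * env
      E[i, ] <- env
    }
    rownames(S) <- rownames(E) <- vapply(specs, `[[`, "", "kind")
    list(activities = S, envelopes = E)
  })
}

## ---------------------------------------------------------------------------
## full session

#' Simulate a complete motor-imagery session
#'
#' Generates a multichannel recording \code{data = A_true sources + noise}
#' where the forward maps \code{A_true} come from the three-shell spherical
#' head model and the sources follow the block-design protocol.
#'
#' @param specs list of [source_spec()]; at most as many as channels.
#' @param electrodes electrode position matrix, e.g. [montage_1010()].
#' @param protocol list of protocol parameters passed to
#'   [protocol_events()] (\code{n_blocks}, \code{cues_per_hand_per_block},
#'   \code{task_duration_s}, \code{preparation_s}).
#' @param noise_sd sensor noise standard deviation relative to the unit
#'   source scale (>= 0).
#' @param fs sampling rate, Hz.
#' @param seed RNG seed; the cue order, the source innovations and the
#'   sensor noise all derive from it.
#' @param model head model for the forward maps.
#' @return list with elements \code{recording} (class \code{eeg_recording}:
#'   \code{data} channels x samples, \code{fs}, \code{channel_names},
#'   \code{channel_positions}, \code{events}) and \code{ground_truth}
#'   (\code{A_true}, \code{specs}, \code{envelopes}, \code{sources}).
#' @export
simulate_session <- function(specs = default_source_specs(),
                             electrodes = montage_1010(),
                             protocol = list(), noise_sd = 0.2,
                             fs = 128, seed = 1, model = head_model()) {
  if (length(specs) > nrow(electrodes))
    stop("more sources (", length(specs), ") than channels (",
         nrow(electrodes), ")")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  pargs <- utils::modifyList(
    list(n_blocks = 10, cues_per_hand_per_block = 2,
         task_duration_s = 10, preparation_s = 2, fs = fs),
    protocol)
  with_seed(seed, {
    ev <- protocol_events(pargs$n_blocks, pargs$cues_per_hand_per_block,
                          pargs$task_duration_s, pargs$preparation_s,
                          fs = fs, seed = NULL)
    n_samples <- attr(ev, "n_samples")
    src <- simulate_sources(specs, ev, fs, n_samples, seed = NULL,
                            task_samples = attr(ev, "task_samples"))
    A <- vapply(specs,
                function(sp) forward_map(sp$position, sp$moment,
                                         electrodes, model),
                numeric(nrow(electrodes)))
    ## scale maps to comparable sensor-level strength (unit RMS per map)
    A <- apply(A, 2, function(a) a / sqrt(mean(a^2)))
    colnames(A) <- vapply(specs, `[[`, "", "kind")
    X <- A %*% src$activities
    if (noise_sd > 0)
      X <- X + matrix(stats::rnorm(length(X), sd = noise_sd), nrow(X))
    rownames(X) <- rownames(electrodes)
    rec <- structure(list(data = X, fs = fs,
                          channel_names = rownames(electrodes),
                          channel_positions = electrodes,
                          events = ev), class = "eeg_recording")
    list(recording = rec,
         ground_truth = list(A_true = A, specs = specs,
                             envelopes = src$envelopes,
                             sources = src$activities))
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.null(x$events))
    cat("  events:", paste(sprintf("%s=%d", levels(x$events$task),
                                   table(x$events$task)), collapse = ", "),
        "\n")
  invisible(x)
}

#' Amari separation index
#'
#' Permutation- and scale-invariant distance between an estimated unmixing
#' matrix and the true mixing matrix.  Zero exactly when \code{W A_true} is
#' a scaled permutation matrix; normalized to lie in \[0, 1\].
#'
#' @param W estimated unmixing matrix (n x channels).
#' @param A_true true mixing matrix (channels x n).
#' @return nonnegative scalar.
#' @examples
#' A <- matrix(rnorm(16), 4)
#' amari_index(solve(A), A)  # 0
#' @export
amari_index <- function(W, A_true) {
  P <- abs(W %*% A_true)
  if (nrow(P) != ncol(P)) stop("W %*% A_true must be square")
  n <- nrow(P)
  if (any(apply(P, 1, max) == 0) || any(apply(P, 2, max) == 0))
    stop("W %*% A_true is singular")
  rows <- sum(rowSums(P / apply(P, 1, max)) - 1)
  cols <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (rows + cols) / (2 * n * (n - 1))
}
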