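## Pipeline front end: zero-phase band-pass + notch filtering, whitening by
## the symmetric inverse square root of the covariance, and task epoching.

#' Band-pass and notch filter a recording
#'
#' Fourth-order Butterworth band-pass plus a second-order IIR notch, both
#' applied forward-backward (zero phase).
#'
#' @param recording \code{eeg_recording} (or a bare channels x samples
#'   matrix).
#' @param band band edges in Hz, default \code{c(5, 30)}.
#' @param notch notch (power-line) frequency in Hz, or NULL to skip;
#'   default 50.
#' @param order Butterworth order (applied once per direction).
#' @param notch_q notch quality factor (center frequency / -3 dB width).
#' @return filtered recording of the same shape/class.
#' @export
bandpass_notch <- function(recording, band = c(5, 30), notch = 50,
                           order = 4, notch_q = 35) {
  X <- if (inherits(recording, "eeg_recording")) recording$data
       else as.matrix(recording)
  fs <- if (inherits(recording, "eeg_recording")) recording$fs
        else attr(recording, "fs")
  if (is.null(fs)) stop("sampling rate unknown; pass an eeg_recording")
  if (fs <= 2 * band[2])
    stop(sprintf("band upper edge %g Hz infeasible at fs = %g Hz",
                 band[2], fs))
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  Y <- t(apply(X, 1, function(x) signal::filtfilt(bf, x)))
  if (!is.null(notch) && notch < fs / 2) {
    ## RBJ biquad notch at notch/fs with quality factor notch_q
    w0 <- 2 * pi * notch / fs
    alpha <- sin(w0) / (2 * notch_q)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    flt <- signal::Arma(b = b / a[1], a = a / a[1])
    Y <- t(apply(Y, 1, function(x) signal::filtfilt(flt, x)))
  }
  dimnames(Y) <- dimnames(X)
  if (inherits(recording, "eeg_recording")) {
    recording$data <- Y
    recording
  } else Y
}

#' Whiten a multichannel signal
#'
#' Computes the symmetric whitening matrix \code{V = C^(-1/2)} of the
#' zero-mean signal covariance, so that \code{cov(V X) = I}.  The symmetric
#' square root makes V unique, hence runs reproducible.
#'
#' @param X channels x samples matrix (or \code{eeg_recording}).
#' @return list of class \code{whitened_signal} with \code{Z} (whitened
#'   channels x samples) and \code{V} (whitening matrix).
#' @export
whiten <- function(X) {
  if (inherits(X, "eeg_recording")) X <- X$data
  X <- as.matrix(X)
  C <- cov0(X)
  V <- sym_inv_sqrt(C)
  structure(list(Z = V %*% X, V = V), class = "whitened_signal")
}

#' Cut a recording into task epochs
#'
#' One epoch per cue; the preparation interval after relaxation cues is not
#' part of any epoch because cues are stamped at task onset.  Epochs that
#' would run past the end of the recording are dropped with a warning.
#'
#' @param recording \code{eeg_recording} with an \code{events} data.frame.
#' @param task_duration_s epoch length in seconds.
#' @param data optional alternative signal (rows x samples) to epoch with
#'   the recording's events, e.g. component activities.
#' @return list of class \code{epoch_set}; each element has \code{X}
#'   (channels x samples), \code{task}, \code{block}.
#' @export
epoch_by_task <- function(recording, task_duration_s = 10, data = NULL) {
  if (task_duration_s <= 0) stop("task_duration_s must be > 0")
  ev <- recording$events
  X <- if (is.null(data)) recording$data else as.matrix(data)
  if (is.null(ev) || nrow(ev) == 0) {
    warning("recording has no events; returning an empty epoch set")
    return(structure(list(), class = "epoch_set"))
  }
  n <- round(task_duration_s * recording$fs)
  out <- list()
  dropped <- 0L
  for (k in seq_len(nrow(ev))) {
    i0 <- ev$onset[k]
    i1 <- i0 + n - 1L
    if (i1 > ncol(X)) { dropped <- dropped + 1L; next }
    out[[length(out) + 1L]] <- list(X = X[, i0:i1, drop = FALSE],
                                    task = as.character(ev$task[k]),
                                    block = ev$block[k])
  }
  if (dropped > 0)
    warning(sprintf("%d epoch(s) dropped: insufficient samples", dropped))
  structure(out, class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  if (!length(x)) { cat("empty epoch set\n"); return(invisible(x)) }
  tasks <- vapply(x, `[[`, "", "task")
  cat(sprintf("epoch set: %d epochs (%s), %d channels x %d samples each\n",
              length(x),
              paste(sprintf("%s=%d", names(table(tasks)), table(tasks)),
                    collapse = ", "),
              nrow(x[[1]]$X), ncol(x[[1]]$X)))
  invisible(x)
}

## split an epoch_set by task label
split_epochs <- function(epochs, tasks = TASKS) {
  lab <- vapply(epochs, `[[`, "", "task")
  stats::setNames(lapply(tasks, function(t) {
    structure(unclass(epochs)[lab == t], class = "epoch_set")
  }), tasks)
}
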