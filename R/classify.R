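## Bayesian covariance classifier for task discrimination.
##
## The signal is modeled per task as zero-mean multivariate Gaussian with a
## task-specific covariance C_i; an epoch X is assigned to the class
## maximizing ln P(i) - trace(cov(X) C_i^-1) - ln det C_i.  Accuracy is
## summarized by Cohen's kappa over a block-wise cross-validation.

#' Fit the Bayesian covariance classifier
#'
#' Class covariances are pooled zero-mean covariances over each class's
#' epochs; class priors are proportional to the total cue time per class.
#'
#' @param epochs an \code{epoch_set} (or plain list of \code{list(X, task,
#'   block)}).
#' @param ridge relative ridge added to a class covariance whose condition
#'   number exceeds \code{cond_max}.
#' @param cond_max condition-number threshold triggering regularization.
#' @return object of class \code{bayes_model}: \code{C} (list of class
#'   covariances), \code{priors}, \code{classes}.
#' @export
fit_bayes <- function(epochs, ridge = 1e-6, cond_max = 1e10) {
  lab <- vapply(epochs, `[[`, "", "task")
  classes <- intersect(TASKS, unique(lab))
  if (!length(classes)) stop("no labeled epochs")
  C <- list(); nsamp <- numeric(0)
  for (cl in classes) {
    idx <- which(lab == cl)
    if (!length(idx)) stop("empty class: ", cl)
    S <- 0; tot <- 0
    for (k in idx) { S <- S + tcrossprod(epochs[[k]]$X); tot <- tot + ncol(epochs[[k]]$X) }
    Ci <- S / tot
    ev <- eigen(Ci, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || max(ev) / max(min(ev), 1e-300) > cond_max) {
      eps <- ridge * sum(diag(Ci)) / nrow(Ci)
      Ci <- Ci + diag(eps, nrow(Ci))
      message(sprintf("fit_bayes: ridge %g added to class '%s'", eps, cl))
    }
    C[[cl]] <- Ci
    nsamp[cl] <- tot
  }
  if (any(vapply(C, nrow, 0L) != nrow(C[[1]])))
    stop("inconsistent epoch dimensions")
  if (length(unique(lab[lab %in% classes])) &&
      min(table(lab)[classes]) == 1)
    warning("a class has a single epoch; covariance estimate is weak")
  structure(list(C = C, priors = nsamp / sum(nsamp), classes = classes),
            class = "bayes_model")
}

#' Classify a signal window
#'
#' Evaluates the Bayesian covariance score \code{ln P(i) - trace(cov(X)
#' C_i^-1) - ln det C_i} for every class and returns the argmax (ties break
#' to the earliest class).
#'
#' @param X window, channels x samples (or a precomputed covariance matrix
#'   with attribute \code{is_cov = TRUE}).
#' @param model a \code{bayes_model}.
#' @return list with \code{class} (label), \code{index}, \code{scores}.
#' @export
classify_window <- function(X, model) {
  Cx <- if (isTRUE(attr(X, "is_cov"))) unclass(X) else cov0(X)
  if (nrow(Cx) != nrow(model$C[[1]]))
    stop("window dimension does not match the model")
  scores <- vapply(model$classes, function(cl) {
    Ci <- model$C[[cl]]
    log(model$priors[[cl]]) - sum(diag(solve(Ci, Cx))) -
      determinant(Ci)$modulus
  }, numeric(1))
  i <- which.max(scores)   # which.max takes the first maximum: tie -> lowest
  list(class = model$classes[i], index = i, scores = scores)
}

#' Sliding-window classification
#'
#' Offline replay of the online feedback decision stream: a window of
#' \code{window_s} seconds slides in steps of \code{shift_s} seconds and
#' each position is classified.
#'
#' @param X channels x samples signal (e.g. component activities), or
#'   \code{eeg_recording}.
#' @param model \code{bayes_model}.
#' @param fs sampling rate (taken from the recording when available).
#' @param window_s window length, seconds.
#' @param shift_s window shift, seconds.
#' @return data.frame with \code{onset} (sample of window start),
#'   \code{label}.
#' @export
sliding_window_classify <- function(X, model, fs = NULL, window_s = 1,
                                    shift_s = 0.1) {
  if (inherits(X, "eeg_recording")) { fs <- X$fs; X <- X$data }
  if (is.null(fs)) stop("sampling rate required")
  n <- round(window_s * fs)
  step <- shift_s * fs  # may be fractional; onsets are floored per window
  if (ncol(X) < n) stop("signal shorter than one window")
  starts <- seq(0, ncol(X) - n, by = step)
  onsets <- floor(starts) + 1L
  lab <- vapply(onsets, function(i0)
    classify_window(X[, i0:(i0 + n - 1L), drop = FALSE], model)$class, "")
  data.frame(onset = onsets, label = lab)
}

#' Block-wise cross-validation of epoch classification
#'
#' Iterates every choice of \code{n_test_blocks} test blocks (all
#' \code{C(n_blocks, n_test_blocks)} splits; 120 for the standard 10-block
#' session), fits the Bayesian model on the remaining blocks and classifies
#' each test epoch from its whole-epoch covariance, accumulating a
#' confusion matrix of classified class x cued class.
#'
#' @param epochs \code{epoch_set} with block indices.
#' @param n_test_blocks test blocks per split.
#' @return object of class \code{confusion_matrix}: integer matrix
#'   (classified x cued) with attribute \code{n_folds}.
#' @export
cross_validate <- function(epochs, n_test_blocks = 3) {
  lab <- vapply(epochs, `[[`, "", "task")
  blocks <- vapply(epochs, function(e) as.integer(e$block), 0L)
  ub <- sort(unique(blocks))
  if (length(ub) <= n_test_blocks)
    stop("need more blocks than test blocks")
  splits <- utils::combn(ub, n_test_blocks)
  classes <- intersect(TASKS, unique(lab))
  G <- matrix(0L, length(classes), length(classes),
              dimnames = list(classified = classes, cued = classes))
  ## precompute epoch covariances once
  covs <- lapply(epochs, function(e) tcrossprod(e$X) / ncol(e$X))
  n_folds <- 0L
  skipped <- 0L
  for (s in seq_len(ncol(splits))) {
    test_b <- splits[, s]
    tr <- which(!(blocks %in% test_b))
    te <- which(blocks %in% test_b)
    if (length(unique(lab[tr])) < length(classes)) { skipped <- skipped + 1L; next }
    model <- suppressMessages(
      fit_bayes(structure(unclass(epochs)[tr], class = "epoch_set")))
    for (k in te) {
      Ck <- covs[[k]]
      attr(Ck, "is_cov") <- TRUE
      pred <- classify_window(Ck, model)$class
      G[pred, lab[k]] <- G[pred, lab[k]] + 1L
    }
    n_folds <- n_folds + 1L
  }
  if (skipped > 0)
    warning(sprintf("%d split(s) skipped: class missing from training set",
                    skipped))
  structure(G, n_folds = n_folds, class = c("confusion_matrix", "matrix"))
}

#' Offline replay of the online block-wise feedback protocol
#'
#' Mimics online operation: for each block after the first, the classifier
#' is fitted on all earlier blocks' epochs and every sliding window inside
#' the block's cues is classified; window decisions accumulate into a
#' confusion matrix (classified x cued).
#'
#' @param epochs \code{epoch_set} with block indices.
#' @param fs sampling rate of the epochs.
#' @param window_s,shift_s sliding-window parameters.
#' @return \code{confusion_matrix} of window decisions.
#' @export
online_replay <- function(epochs, fs, window_s = 1, shift_s = 0.1) {
  lab <- vapply(epochs, `[[`, "", "task")
  blocks <- vapply(epochs, function(e) as.integer(e$block), 0L)
  classes <- intersect(TASKS, unique(lab))
  G <- matrix(0L, length(classes), length(classes),
              dimnames = list(classified = classes, cued = classes))
  for (b in sort(unique(blocks))[-1]) {
    tr <- which(blocks < b)
    if (length(unique(lab[tr])) < length(classes)) next
    model <- suppressMessages(
      fit_bayes(structure(unclass(epochs)[tr], class = "epoch_set")))
    for (k in which(blocks == b)) {
      dec <- sliding_window_classify(epochs[[k]]$X, model, fs = fs,
                                     window_s = window_s,
                                     shift_s = shift_s)
      for (lb in dec$label) G[lb, lab[k]] <- G[lb, lab[k]] + 1L
    }
  }
  structure(G, class = c("confusion_matrix", "matrix"))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement
#' \code{(g0 sum(g_ii) - sum(g_j^2)) / (g0^2 - sum(g_j^2))} where \code{g0}
#' is the total count and \code{g_j} are the cued-class column totals.
#' Equals 1 for perfect classification, 0 for random assignment.
#'
#' @param confusion square count matrix, classified class x cued class.
#' @return scalar in \[-1, 1\].
#' @examples
#' cohen_kappa(diag(c(10, 10, 10)))           # 1
#' cohen_kappa(matrix(5, 3, 3))               # 0
#' @export
cohen_kappa <- function(confusion) {
  G <- unclass(as.matrix(confusion))
  if (any(G < 0)) stop("confusion matrix entries must be >= 0")
  g0 <- sum(G)
  if (g0 <= 0) stop("empty confusion matrix")
  gj <- colSums(G)
  den <- g0^2 - sum(gj^2)
  if (den == 0) stop("kappa undefined: all mass in one cued class")
  (g0 * sum(diag(G)) - sum(gj^2)) / den
}
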