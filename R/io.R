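## Plain-text session container.
##
## A recording is stored as a directory: meta.json (fs, channel names,
## electrode positions, cue events), data.csv (samples x channels, full
## double precision) and optionally ground_truth.json (mixing matrix and
## source specifications).  Everything is text, diffable and
## machine-readable without binary dependencies.

#' Write a recording (and optional ground truth) to a directory
#'
#' @param recording \code{eeg_recording}.
#' @param path target directory (created if needed).
#' @param ground_truth optional ground-truth list from [simulate_session()].
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(recording, path, ground_truth = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(fs = recording$fs,
               channel_names = recording$channel_names,
               channel_positions = unname(as.matrix(recording$channel_positions)),
               events = recording$events[, c("onset", "task", "block")])
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(
    matrix(sprintf("%.17g", t(recording$data)), ncol = nrow(recording$data),
           dimnames = list(NULL, recording$channel_names)),
    file.path(path, "data.csv"), sep = ",", row.names = FALSE,
    quote = FALSE)
  if (!is.null(ground_truth)) {
    gt <- list(A_true = unname(ground_truth$A_true),
               specs = lapply(ground_truth$specs, unclass))
    jsonlite::write_json(gt, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path directory path.
#' @return \code{eeg_recording}; ground truth (when present) is attached as
#'   attribute \code{ground_truth}.
#' @export
read_recording <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("not a recording directory: ", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  dat <- utils::read.csv(file.path(path, "data.csv"),
                         colClasses = "numeric", check.names = FALSE)
  X <- t(as.matrix(dat))
  pos <- matrix(as.numeric(meta$channel_positions), ncol = 3)
  rownames(pos) <- meta$channel_names
  colnames(pos) <- c("x", "y", "z")
  ev <- as.data.frame(meta$events)
  ev$task <- factor(ev$task, levels = TASKS)
  ev$onset <- as.integer(ev$onset)
  ev$block <- as.integer(ev$block)
  rownames(X) <- meta$channel_names
  rec <- structure(list(data = X, fs = meta$fs,
                        channel_names = meta$channel_names,
                        channel_positions = pos, events = ev),
                   class = "eeg_recording")
  gf <- file.path(path, "ground_truth.json")
  if (file.exists(gf)) {
    gt <- jsonlite::read_json(gf, simplifyVector = TRUE)
    gt$A_true <- matrix(as.numeric(gt$A_true), nrow = nrow(X))
    attr(rec, "ground_truth") <- gt
  }
  rec
}
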