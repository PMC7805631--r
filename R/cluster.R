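## Cross-session component clustering.
##
## Components from different sessions cannot be compared by activity
## correlation, so each component is summarized by its topographic map and
## its per-task activity power spectral densities; similarity is the mean
## of the absolute map cosine and the (clamped) correlation of the
## concatenated per-task PSDs.  Clusters are grown with an attractor-style
## procedure: from a seed component the active set adds the component with
## the highest mean similarity to the set until the mean intra-set
## similarity would fall below a threshold.

#' Welch power spectral density
#'
#' Hann-windowed Welch periodogram averaged over 50%-overlapping segments.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param seg_s segment length in seconds (frequency resolution
#'   \code{1/seg_s}).
#' @return list with \code{freq} and \code{psd}.
#' @export
welch_psd <- function(x, fs, seg_s = 2) {
  nper <- round(seg_s * fs)
  nper <- min(nper, length(x))
  step <- max(1L, floor(nper / 2))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  scale <- sum(w^2) * fs
  nf <- floor(nper / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)] * w
    sp <- abs(stats::fft(seg))^2 / scale
    acc <- acc + sp[seq_len(nf)]
  }
  psd <- acc / length(starts)
  psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]  # one-sided
  list(freq = (seq_len(nf) - 1L) * fs / nper, psd = psd)
}

#' Per-task power spectral densities of one component activity
#'
#' Welch PSDs over the concatenated epochs of each task, restricted to the
#' analysis band.  The three task rows share one normalization (unit total
#' power summed over tasks): a per-task normalization would erase the
#' between-task amplitude modulation that makes rhythm suppression visible
#' in the spectra.
#'
#' @param activity component activity (numeric vector over the session).
#' @param recording session recording providing events and fs.
#' @param band frequency band to keep, Hz.
#' @param task_duration_s epoch length.
#' @param seg_s Welch segment length, seconds.
#' @return matrix tasks x frequencies (rownames relax/left_MI/right_MI,
#'   attribute \code{freq}); a missing task yields a NaN row and a flag.
#' @export
per_task_psd <- function(activity, recording, band = c(5, 30),
                         task_duration_s = 10, seg_s = 2) {
  epochs <- epoch_by_task(recording, task_duration_s,
                          data = matrix(activity, 1))
  lab <- vapply(epochs, `[[`, "", "task")
  fs <- recording$fs
  out <- NULL; freq <- NULL
  missing <- character(0)
  for (task in TASKS) {
    idx <- which(lab == task)
    if (!length(idx)) {
      missing <- c(missing, task)
      row <- rep(NaN, if (is.null(freq)) 1 else length(freq))
    } else {
      x <- unlist(lapply(epochs[idx], function(e) e$X[1, ]))
      w <- welch_psd(x, fs, seg_s)
      keep <- w$freq >= band[1] & w$freq <= band[2]
      freq <- w$freq[keep]
      row <- w$psd[keep]
    }
    out <- rbind(out, row)
  }
  rownames(out) <- TASKS
  tot <- sum(out[is.finite(out)])
  if (tot > 0) out <- out / tot
  if (length(missing)) {
    out <- out[, seq_along(freq), drop = FALSE]
    attr(out, "missing_tasks") <- missing
  }
  attr(out, "freq") <- freq
  out
}

#' Feature summary of one component for clustering
#'
#' @param map topographic map (mixing column); stored unit-norm.
#' @param psd per-task PSD matrix from [per_task_psd()].
#' @param session,method,index component origin.
#' @param rv dipole-fit residual variance.
#' @param rank component rank across methods.
#' @param specific was the component in the best task-specific set?
#' @return object of class \code{component_feature}.
#' @export
component_feature <- function(map, psd, session, method, index,
                              rv = NA_real_, rank = NA_integer_,
                              specific = NA) {
  map <- as.numeric(map)
  map <- map / sqrt(sum(map^2))
  structure(list(map = map, psd = psd, session = session, method = method,
                 index = index, rv = rv, rank = rank, specific = specific),
            class = "component_feature")
}

#' Similarity between two component features
#'
#' Mean of (a) the absolute cosine between maps and (b) the Pearson
#' correlation between concatenated per-task PSDs, clamped to \[0, 1\].
#'
#' @param f1,f2 \code{component_feature}.
#' @return scalar in \[0, 1\].
#' @export
component_similarity <- function(f1, f2) {
  if (length(f1$map) != length(f2$map)) stop("different channel spaces")
  mc <- abs(sum(f1$map * f2$map))
  p1 <- as.numeric(t(f1$psd)); p2 <- as.numeric(t(f2$psd))
  if (length(p1) != length(p2)) stop("different frequency grids")
  ok <- is.finite(p1) & is.finite(p2)
  pc <- if (sum(ok) > 2) stats::cor(p1[ok], p2[ok]) else 0
  if (is.na(pc)) pc <- 0
  pc <- max(0, pc)
  (mc + pc) / 2
}

#' Attractor-network clustering of component features
#'
#' Iterative set growing: the unclustered feature with the largest summed
#' similarity seeds a cluster; the feature with maximal mean similarity to
#' the current set is added while the mean intra-set similarity stays at or
#' above \code{similarity_threshold}; the set is accepted when it reaches
#' \code{min_cluster_size}, its members are removed, and the procedure
#' repeats until no acceptable cluster remains.  Clusters are sorted by
#' occurrence (fraction of sessions represented), descending.
#'
#' @param features list of \code{component_feature}.
#' @param similarity_threshold minimal average intra-cluster similarity.
#'   The default 0.9 sits between the within-family (~0.95+) and
#'   cross-family (~0.5) similarity ranges that forward-model component
#'   features produce; a markedly lower value lets a large homogeneous
#'   cluster absorb members of a neighboring family before its mean
#'   similarity drops below threshold.
#' @param min_cluster_size minimal accepted cluster size.
#' @param n_sessions total number of sessions (for occurrence; defaults to
#'   the number of distinct sessions among features).
#' @return list of clusters (class \code{component_cluster}): each has
#'   \code{members} (feature indices), \code{features}, \code{mean_map},
#'   \code{mean_psd}, \code{occurrence}.
#' @export
annia_cluster <- function(features, similarity_threshold = 0.9,
                          min_cluster_size = 3, n_sessions = NULL) {
  n <- length(features)
  if (n < 2) stop("need at least 2 features")
  if (similarity_threshold >= 1)
    warning("similarity threshold >= 1: only exact duplicates will cluster")
  if (is.null(n_sessions))
    n_sessions <- length(unique(vapply(features, `[[`, "", "session")))
  ## vectorized pairwise similarity: one crossproduct for the maps, one
  ## correlation matrix for the concatenated per-task PSDs
  M <- vapply(features, `[[`, numeric(length(features[[1]]$map)), "map")
  P <- vapply(features, function(f) as.numeric(t(f$psd)),
              numeric(length(features[[1]]$psd)))
  P[!is.finite(P)] <- NA
  S <- (abs(crossprod(M)) +
          pmax(0, stats::cor(P, use = "pairwise.complete.obs"))) / 2
  S[is.na(S)] <- 0
  diag(S) <- 1
  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining) >= min_cluster_size) {
    ## deterministic seed: largest summed similarity among the remaining
    tot <- rowSums(S[remaining, remaining, drop = FALSE]) - 1
    set <- remaining[which.max(tot)]
    pool <- setdiff(remaining, set)
    while (length(pool)) {
      msim <- vapply(pool, function(j) mean(S[j, set]), numeric(1))
      j <- pool[which.max(msim)]
      cand <- c(set, j)
      intra <- S[cand, cand][upper.tri(matrix(0, length(cand),
                                              length(cand)))]
      if (mean(intra) < similarity_threshold) break
      set <- cand
      pool <- setdiff(pool, j)
    }
    if (length(set) < min_cluster_size) {
      ## seed cannot form a cluster; discard it and continue
      remaining <- setdiff(remaining, set[1])
      next
    }
    fl <- features[set]
    maps <- vapply(fl, `[[`, numeric(length(fl[[1]]$map)), "map")
    ## align member map signs to the seed before averaging
    signs <- sign(as.numeric(crossprod(maps, maps[, 1])))
    signs[signs == 0] <- 1
    mean_map <- rowMeans(maps * rep(signs, each = nrow(maps)))
    psds <- lapply(fl, `[[`, "psd")
    mean_psd <- Reduce(`+`, psds) / length(psds)
    occ <- length(unique(vapply(fl, `[[`, "", "session"))) / n_sessions
    clusters[[length(clusters) + 1]] <-
      structure(list(members = set, features = fl, mean_map = mean_map,
                     mean_psd = mean_psd, occurrence = 100 * occ),
                class = "component_cluster")
    remaining <- setdiff(remaining, set)
  }
  ord <- order(vapply(clusters, `[[`, 0, "occurrence"), decreasing = TRUE)
  clusters[ord]
}

#' Cluster summary statistics
#'
#' Per cluster: occurrence (percentage of sessions with at least one
#' member), mean dipolarity (residual variance, %), mean rank, and
#' specificity (percentage of members that were part of the best
#' task-specific component set).
#'
#' @param clusters list from [annia_cluster()].
#' @param n_sessions total session count.
#' @return data.frame with one row per cluster.
#' @export
cluster_stats <- function(clusters, n_sessions) {
  if (!length(clusters)) stop("no clusters")
  if (n_sessions <= 0) stop("n_sessions must be positive")
  do.call(rbind, lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    fl <- cl$features
    rv <- vapply(fl, `[[`, 0, "rv")
    rk <- vapply(fl, function(f) as.numeric(f$rank), 0)
    sp <- vapply(fl, function(f) as.logical(f$specific), NA)
    data.frame(
      cluster = k,
      size = length(fl),
      occurrence = 100 *
        length(unique(vapply(fl, `[[`, "", "session"))) / n_sessions,
      dipolarity = 100 * mean(rv, na.rm = TRUE),
      rank = mean(rk, na.rm = TRUE),
      specificity = 100 * mean(sp, na.rm = TRUE))
  }))
}
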