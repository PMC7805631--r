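## End-to-end pipeline driver: simulate (or load) sessions, filter, run the
## decomposition battery, score components (dipolarity, MIR, shared
## components, task-specific selection), classify, and cluster components
## across sessions.

#' Default pipeline configuration
#'
#' @param ... overrides of the defaults.
#' @return configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_sessions = 3,
    channels = NULL,            # NULL = full 32-channel montage
    fs = 128,
    protocol = list(n_blocks = 10, cues_per_hand_per_block = 2,
                    task_duration_s = 10, preparation_s = 2),
    noise_sd = 0.2,
    filter = list(band = c(5, 30), notch = 50, order = 4),
    methods = DECOMP_METHODS,
    seed = 1,
    dipolarity_threshold = 0.10,
    map_thresh = 0.9,
    act_thresh = 0.8,
    cluster = list(similarity_threshold = 0.9, min_cluster_size = 3),
    amica_iter = 60,
    greedy = list(max_candidates = 24, max_set_size = 6)
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full multi-method evaluation pipeline
#'
#' For each session: simulate (or read), band-pass + notch filter, epoch,
#' decompose with every requested method, fit dipoles to all maps, compute
#' MIR, match components between methods, and run greedy task-specific
#' selection per method.  Across sessions: average the method similarity
#' matrix, embed it with MDS, cluster all components, and tabulate cluster
#' statistics.
#'
#' @param config list from [pipeline_config()].
#' @param sessions optional list of precomputed sessions (as returned by
#'   [simulate_session()]); otherwise simulated per config.
#' @return report list (see details in the package vignette).
#' @export
run_pipeline <- function(config = pipeline_config(), sessions = NULL) {
  electrodes <- montage_1010(config$channels)
  specs <- default_source_specs(electrodes)
  n_sessions <- if (!is.null(sessions)) length(sessions) else
    config$n_sessions
  per_session <- list()
  features <- list()
  sim_sum <- NULL; sim_cnt <- NULL
  for (s in seq_len(n_sessions)) {
    sess <- if (!is.null(sessions)) sessions[[s]] else
      simulate_session(specs, electrodes, protocol = config$protocol,
                       noise_sd = config$noise_sd, fs = config$fs,
                       seed = config$seed + 1000L * s)
    rec <- bandpass_notch(sess$recording, band = config$filter$band,
                          notch = config$filter$notch,
                          order = config$filter$order)
    epochs <- epoch_by_task(rec, config$protocol$task_duration_s)
    decs <- decompose_all(rec, epochs, methods = config$methods,
                          seed = config$seed + s,
                          amica_iter = config$amica_iter)
    ok <- !vapply(decs, inherits, TRUE, "try-error")
    ## per-method component scoring
    mstats <- list()
    dipolar_flags <- list()
    for (m in names(decs)[ok]) {
      d <- decs[[m]]
      fits <- lapply(seq_len(ncol(d$A)), function(j)
        fit_dipole(d$A[, j], electrodes))
      rv <- vapply(fits, `[[`, 0, "residual_variance")
      dip <- rv <= config$dipolarity_threshold
      attr(dip, "rv") <- rv
      dipolar_flags[[m]] <- dip
      mir <- mutual_info_reduction(rec$data, d, fs = rec$fs)
      sel <- greedy_select(d, rec, dip,
                           task_duration_s = config$protocol$task_duration_s,
                           max_candidates = config$greedy$max_candidates,
                           max_set_size = config$greedy$max_set_size)
      mstats[[m]] <- list(rv = rv, dipolar = dip,
                          pct_dipolar = 100 * mean(dip),
                          mir = mir$rate, mir_per_sample = mir$per_sample,
                          selected = sel$selected, kappa = sel$kappa,
                          fits = fits)
    }
    ranks <- component_rank(decs[ok], config$map_thresh, config$act_thresh)
    sim <- method_similarity(decs[ok], map_thresh = config$map_thresh,
                             act_thresh = config$act_thresh)
    if (is.null(sim_sum)) {
      sim_sum <- matrix(0, nrow(sim), ncol(sim), dimnames = dimnames(sim))
      sim_cnt <- sim_sum
    }
    upd <- !is.na(sim)
    sim_sum[upd] <- sim_sum[upd] + sim[upd]
    sim_cnt[upd] <- sim_cnt[upd] + 1
    ## cluster features for all components of all methods
    for (m in names(decs)[ok]) {
      d <- decs[[m]]
      st <- mstats[[m]]
      for (j in seq_len(ncol(d$A))) {
        rk <- ranks$rank[ranks$method == m & ranks$comp == j]
        features[[length(features) + 1]] <- component_feature(
          map = d$A[, j],
          psd = per_task_psd(d$activities[j, ], rec,
                             band = config$filter$band,
                             task_duration_s =
                               config$protocol$task_duration_s),
          session = sprintf("s%02d", s), method = m, index = j,
          rv = st$rv[j], rank = if (length(rk)) rk else NA_integer_,
          specific = j %in% st$selected)
      }
    }
    per_session[[s]] <- list(methods = mstats, similarity = sim,
                             ranks = ranks)
  }
  sim_avg <- sim_sum / pmax(sim_cnt, 1)
  sim_avg[sim_cnt == 0] <- NA
  clusters <- annia_cluster(
    features,
    similarity_threshold = config$cluster$similarity_threshold,
    min_cluster_size = config$cluster$min_cluster_size,
    n_sessions = n_sessions)
  list(
    config = config,
    sessions = per_session,
    method_table = .method_table(per_session),
    similarity = structure(sim_avg,
                           class = c("method_similarity", "matrix")),
    mds = mds_embed(structure(sim_avg,
                              class = c("method_similarity", "matrix"))),
    features = features,
    clusters = clusters,
    cluster_table = if (length(clusters))
      cluster_stats(clusters, n_sessions) else NULL)
}

## summarize per-method metrics across sessions (medians)
.method_table <- function(per_session) {
  methods <- names(per_session[[1]]$methods)
  do.call(rbind, lapply(methods, function(m) {
    pct <- vapply(per_session, function(s) s$methods[[m]]$pct_dipolar, 0)
    mir <- vapply(per_session, function(s) s$methods[[m]]$mir, 0)
    kap <- vapply(per_session, function(s) s$methods[[m]]$kappa, 0)
    data.frame(method = m,
               pct_dipolar = stats::median(pct),
               mir = stats::median(mir),
               kappa = stats::median(kap, na.rm = TRUE))
  }))
}

#' Write a pipeline report to disk
#'
#' Emits the per-method summary and cluster statistics as CSV, and the
#' similarity matrix, MDS coordinates and configuration as JSON.
#'
#' @param report list from [run_pipeline()].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$method_table,
                   file.path(dir, "method_summary.csv"), row.names = FALSE)
  if (!is.null(report$cluster_table))
    utils::write.csv(report$cluster_table,
                     file.path(dir, "cluster_stats.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(similarity = as.data.frame(unclass(report$similarity)),
         mds = as.data.frame(report$mds),
         config = report$config[setdiff(names(report$config), "methods")],
         methods = report$config$methods),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
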