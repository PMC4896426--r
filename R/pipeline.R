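#' Pipeline run configuration
#'
#' Bundles every stage's parameters with their standard defaults: discard
#' the first 20 frames, high-pass at 0.008 Hz, 40 s windows stepping by one
#' frame with theta a third of the window, 100 community-detection
#' initializations, 4 CV folds, 10,000 permutations.
#'
#' @param sim either a [sim_spec()] (signals will be simulated) or NULL
#'   when signals are supplied to [run_pipeline()] directly.
#' @param dt seconds per frame (taken from `sim` when given).
#' @param discard_frames initial frames to drop.
#' @param highpass_hz high-pass cutoff (Hz).
#' @param window_s window length (seconds).
#' @param step_frames window step (frames).
#' @param theta_fraction theta as a fraction of the window length.
#' @param n_init community-detection initializations per matrix.
#' @param n_subjects,sessions cohort size when simulating.
#' @param cca_folds cross-validation folds.
#' @param n_perm permutations for the CCA test.
#' @param seed master seed, fanned out to every stage by named counters.
#' @param output_dir optional directory; when set, artifacts and a manifest
#'   are written there.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim = NULL, dt = if (!is.null(sim)) sim$dt else 0.72,
                       discard_frames = 20L, highpass_hz = 0.008,
                       window_s = 40, step_frames = 1L,
                       theta_fraction = 1 / 3, n_init = 100L,
                       n_subjects = 20L, sessions = 1L,
                       cca_folds = 4L, n_perm = 10000L,
                       seed = 1L, output_dir = NULL) {
  cfg <- list(sim = sim, dt = dt, discard_frames = as.integer(discard_frames),
              highpass_hz = highpass_hz, window_s = window_s,
              step_frames = as.integer(step_frames),
              theta_fraction = theta_fraction, n_init = as.integer(n_init),
              n_subjects = as.integer(n_subjects),
              sessions = as.integer(sessions),
              cca_folds = as.integer(cca_folds), n_perm = as.integer(n_perm),
              seed = as.integer(seed), output_dir = output_dir)
  if (cfg$theta_fraction <= 0) stopf("theta_fraction must be > 0")
  class(cfg) <- "run_config"
  cfg
}

config_manifest <- function(config) {
  cfg <- config
  cfg$output_dir <- NULL
  if (!is.null(cfg$sim)) cfg$sim <- unclass(cfg$sim)
  txt <- yaml::as.yaml(unclass(cfg))
  list(config = unclass(cfg), config_hash = fnv_hash(txt),
       seed = config$seed,
       stage_versions = list(netdyn = as.character(packageVersion("netdyn"))))
}

#' Run the full dynamic-network pipeline on one session
#'
#' Stages, in order: preprocess (frame discard, high-pass), static group
#' connectivity and reference partition, per-subject sliding-window
#' connectivity and windowed community detection, temporal co-occurrence,
#' node-level metrics, network aggregation, high-flexibility cluster.
#' Reruns with the same config produce identical numeric outputs.
#'
#' @param config a [run_config()].
#' @param signals optional [signal_set()] (otherwise simulated from
#'   `config$sim`).
#' @param atlas optional atlas data.frame (simulated alongside signals
#'   when absent and `config$sim` is given).
#' @param session session index used for seed derivation and file naming.
#' @return list with `signals` (preprocessed), `static`, `reference`,
#'   `cooc` (per-subject [co_occurrence()]), `node_table`,
#'   `network_summary`, `cluster`, `config`, `manifest`.
#' @export
run_pipeline <- function(config, signals = NULL, atlas = NULL, session = 1L) {
  stopifnot(inherits(config, "run_config"))
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(signals)) {
      if (is.null(config$sim)) stopf("no signals and no sim spec in config")
      signals <- simulate_cohort(config$sim, config$n_subjects,
                                 sessions = session)[[session]]
    }
    if (is.null(atlas) && !is.null(config$sim))
      atlas <- simulate_atlas(config$sim)

    stage <- "preprocess"
    s <- discard_initial_frames(signals, config$discard_frames)
    s <- highpass(s, config$highpass_hz)

    stage <- "static connectivity"
    static <- static_connectivity(s)
    reference <- reference_partition(static, n_init = config$n_init,
                                     seed = derive_seed(config$seed,
                                                        "reference", session))

    stage <- "windowed communities"
    wspec <- window_spec(config$window_s, dt = s$dt,
                         step_frames = config$step_frames)
    wspec$theta_frames <- wspec$length_frames * config$theta_fraction
    cooc <- vector("list", length(s$subjects))
    names(cooc) <- s$subjects
    for (i in seq_along(s$subjects)) {
      subj <- s$subjects[i]
      zarr <- sliding_windows(s$data[[subj]], wspec)
      cooc[[subj]] <- subject_co_occurrence(
        zarr, n_init = config$n_init,
        seed = derive_seed(config$seed, "community", session, subj),
        subject = subj)
    }

    stage <- "node metrics"
    node_table <- do.call(rbind, lapply(s$subjects, function(subj) {
      node_dynamics(cooc[[subj]], reference, static_W = static)
    }))

    stage <- "aggregation"
    network_summary <- if (!is.null(atlas))
      aggregate_by_network(node_table, atlas) else NULL
    cluster <- high_flex_cluster(node_table,
                                 seed = derive_seed(config$seed, "cluster",
                                                    session))
    list(signals = s, atlas = atlas, static = static, reference = reference,
         cooc = cooc, node_table = node_table,
         network_summary = network_summary, cluster = cluster,
         config = config, manifest = config_manifest(config))
  }, error = function(e) {
    stopf("pipeline failed at stage '%s' (session %d): %s",
          stage, session, conditionMessage(e))
  })
  if (!is.null(config$output_dir)) write_run(res, config$output_dir, session)
  res
}

write_run <- function(res, dir, session) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tag <- sprintf("session%d", session)
  write_matrix_txt(res$static, file.path(dir, paste0(tag, "_static.tsv")))
  write_partition(res$reference,
                  file.path(dir, paste0(tag, "_reference_partition.tsv")))
  for (subj in names(res$cooc))
    write_matrix_txt(res$cooc[[subj]],
                     file.path(dir, sprintf("%s_cooc_%s.tsv", tag, subj)))
  write_node_dynamics(res$node_table,
                      file.path(dir, paste0(tag, "_node_dynamics.tsv")))
  if (!is.null(res$atlas))
    write_atlas(res$atlas, file.path(dir, paste0(tag, "_atlas.tsv")))
  yaml::write_yaml(res$manifest, file.path(dir, paste0(tag, "_manifest.yaml")))
  invisible(dir)
}

#' Compare two sessions of the same cohort
#'
#' Per subject, the Pearson correlation between the vectorized upper
#' triangles of the two sessions' co-occurrence matrices; reported with the
#' across-subject mean and a one-sample t-test of the Fisher-z similarities
#' against zero, plus the bidirectional overlap of the high-flexibility
#' clusters.
#'
#' @param runA,runB results of [run_pipeline()] for the two sessions.
#' @return list: `similarity` (per-subject r), `mean_similarity`,
#'   `p_vs_zero`, `overlap` (from [session_overlap()]).
#' @export
compare_sessions <- function(runA, runB) {
  subjects <- intersect(names(runA$cooc), names(runB$cooc))
  if (!length(subjects)) stopf("sessions share no subjects")
  sim <- vapply(subjects, function(subj) {
    cor(upper_tri_vec(runA$cooc[[subj]]$C), upper_tri_vec(runB$cooc[[subj]]$C))
  }, numeric(1))
  p <- if (length(sim) >= 2 && sd(sim) > 0)
    t.test(atanh(pmin(pmax(sim, -1 + 1e-12), 1 - 1e-12)))$p.value
  else NA_real_
  list(similarity = sim, mean_similarity = mean(sim), p_vs_zero = p,
       overlap = session_overlap(runA$cluster$nodes, runB$cluster$nodes))
}
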