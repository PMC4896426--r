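#' Specify a synthetic cohort with planted community structure
#'
#' The generator draws each subject's node time series from a zero-mean
#' multivariate normal whose correlation matrix is block-structured:
#' `within_corr` inside each planted community, `between_corr` elsewhere.
#' Time is cut into non-overlapping epochs of `switch_period` frames; in each
#' epoch every *flexible* node is reassigned round-robin (seeded starting
#' offset) to one of the other communities, so flexible nodes have a known
#' uniform target for their cross-community interactions while all other
#' nodes stay put. White noise of sd `noise_sd` is added on top.
#'
#' Defaults describe the study conditions used throughout the package's own
#' validation: 40 nodes in 4 equal communities, 1,200 frames at 0.72 s,
#' within/between correlations 0.5/0.05, 4 flexible nodes (one per
#' community, so planted flexibility is not confounded with community
#' size), a 100-frame switching period.
#'
#' @param n_nodes number of nodes.
#' @param n_communities number of planted communities.
#' @param community_sizes integer vector summing to `n_nodes`.
#' @param n_frames frames per subject.
#' @param dt sampling interval in seconds per frame.
#' @param within_corr target correlation within a community, in \[0, 1).
#' @param between_corr target correlation between communities,
#'   `0 <= between_corr < within_corr`.
#' @param flexible_nodes integer ids of nodes that switch community each epoch.
#' @param switch_period frames per epoch (>= 2).
#' @param noise_sd sd of additive white noise.
#' @param seed master seed for the cohort.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(n_nodes = 40L, n_communities = 4L,
                     community_sizes = rep(n_nodes %/% n_communities, n_communities),
                     n_frames = 1200L, dt = 0.72,
                     within_corr = 0.5, between_corr = 0.05,
                     flexible_nodes = c(1L, 11L, 21L, 31L),
                     switch_period = 100L,
                     noise_sd = 0.25, seed = 1L) {
  spec <- list(n_nodes = as.integer(n_nodes),
               n_communities = as.integer(n_communities),
               community_sizes = as.integer(community_sizes),
               n_frames = as.integer(n_frames), dt = dt,
               within_corr = within_corr, between_corr = between_corr,
               flexible_nodes = as.integer(flexible_nodes),
               switch_period = as.integer(switch_period),
               noise_sd = noise_sd, seed = as.integer(seed))
  if (sum(spec$community_sizes) != spec$n_nodes)
    stopf("community_sizes must sum to n_nodes (%d != %d)",
          sum(spec$community_sizes), spec$n_nodes)
  if (!(spec$within_corr > spec$between_corr && spec$between_corr >= 0))
    stopf("need within_corr > between_corr >= 0 (got %.3f, %.3f)",
          spec$within_corr, spec$between_corr)
  if (spec$within_corr >= 1) stopf("within_corr must be < 1")
  if (length(spec$flexible_nodes) &&
      !all(spec$flexible_nodes %in% seq_len(spec$n_nodes)))
    stopf("flexible_nodes outside 1..n_nodes")
  if (spec$switch_period < 2) stopf("switch_period must be >= 2")
  if (spec$noise_sd < 0) stopf("noise_sd must be >= 0")
  class(spec) <- "sim_spec"
  spec
}

# Planted static assignment: community of each node ignoring switching.
planted_assignment <- function(spec) {
  rep(seq_len(spec$n_communities), spec$community_sizes)
}

# Block correlation matrix for one epoch's assignment, projected to the
# nearest positive-definite matrix (eigenvalue floor 1e-6) and rescaled to
# unit diagonal. Materially indefinite targets are rejected.
epoch_correlation <- function(assign, within, between) {
  same <- outer(assign, assign, `==`)
  R <- ifelse(same, within, between)
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -0.01)
    stopf(paste0("target correlation matrix is not positive definite ",
                 "(min eigenvalue %.3f) for within_corr=%.3f, between_corr=%.3f"),
          min(ev$values), within, between)
  if (min(ev$values) < 1e-6) {
    vals <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
  }
  R
}

# Epoch-by-epoch community assignment for every node (nodes x epochs).
epoch_assignments <- function(spec, rotation_start) {
  base <- planted_assignment(spec)
  n_epochs <- ceiling(spec$n_frames / spec$switch_period)
  A <- matrix(rep(base, n_epochs), nrow = spec$n_nodes)
  m <- spec$n_communities
  for (idx in seq_along(spec$flexible_nodes)) {
    i <- spec$flexible_nodes[idx]
    others <- setdiff(seq_len(m), base[i])
    for (e in seq_len(n_epochs)) {
      A[i, e] <- others[((rotation_start[idx] + e - 1L) %% length(others)) + 1L]
    }
  }
  A
}

#' Simulate one subject's node-by-time signal matrix
#'
#' @param spec a [sim_spec()].
#' @param subject_seed seed controlling the subject's flexible-node rotation
#'   schedule (shared across sessions of the same subject).
#' @param draw_seed seed for the stochastic signal draw (differs across
#'   sessions); defaults to `subject_seed`.
#' @return numeric matrix, `n_nodes` rows by `n_frames` columns.
#' @export
simulate_subject <- function(spec, subject_seed, draw_seed = subject_seed) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- spec$n_nodes
  set.seed(subject_seed)
  rotation_start <- if (length(spec$flexible_nodes))
    sample.int(max(1L, spec$n_communities - 1L),
               length(spec$flexible_nodes), replace = TRUE) else integer(0)
  A <- epoch_assignments(spec, rotation_start)
  n_epochs <- ncol(A)
  X <- matrix(0, n, spec$n_frames)
  set.seed(draw_seed)
  for (e in seq_len(n_epochs)) {
    f0 <- (e - 1L) * spec$switch_period + 1L
    f1 <- min(e * spec$switch_period, spec$n_frames)
    len <- f1 - f0 + 1L
    R <- epoch_correlation(A[, e], spec$within_corr, spec$between_corr)
    L <- chol(R)
    Z <- matrix(rnorm(n * len), n, len)
    X[, f0:f1] <- crossprod(L, Z)
  }
  if (spec$noise_sd > 0)
    X <- X + matrix(rnorm(n * spec$n_frames, sd = spec$noise_sd),
                    n, spec$n_frames)
  rownames(X) <- node_names(n)
  X
}

node_names <- function(n) sprintf("n%03d", seq_len(n))

network_names <- function(m) {
  base <- c("SN-like", "FPN-like", "DMN-like", "Visual-like",
            "Motor-like", "Auditory-like")
  if (m <= length(base)) base[seq_len(m)] else sprintf("net%02d", seq_len(m))
}

#' Atlas table for a simulated cohort
#'
#' Node metadata in the shape of a node atlas: id, coordinates (arbitrary
#' units, seeded), and the static network label, which for simulated data is
#' the planted community of each node.
#'
#' @param spec a [sim_spec()].
#' @return data.frame with columns `node_id`, `x`, `y`, `z`, `network_label`.
#' @export
simulate_atlas <- function(spec) {
  set.seed(derive_seed(spec$seed, "atlas"))
  base <- planted_assignment(spec)
  data.frame(node_id = node_names(spec$n_nodes),
             x = round(runif(spec$n_nodes, -70, 70), 1),
             y = round(runif(spec$n_nodes, -100, 70), 1),
             z = round(runif(spec$n_nodes, -50, 80), 1),
             network_label = network_names(spec$n_communities)[base],
             stringsAsFactors = FALSE)
}

#' Simulate a cohort, optionally with twin sessions
#'
#' Subject-level seeds are derived deterministically from `spec$seed`.
#' Sessions share each subject's flexible-node rotation schedule but use
#' independent signal draws, emulating a test-retest design.
#'
#' @param spec a [sim_spec()].
#' @param n_subjects number of subjects (>= 2).
#' @param sessions number of sessions (>= 1).
#' @return list of [signal_set()] objects, one per session.
#' @export
simulate_cohort <- function(spec, n_subjects, sessions = 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  if (n_subjects < 2) stopf("n_subjects must be >= 2")
  if (sessions < 1) stopf("sessions must be >= 1")
  subjects <- sprintf("sub%03d", seq_len(n_subjects))
  lapply(seq_len(sessions), function(s) {
    data <- lapply(seq_len(n_subjects), function(i) {
      simulate_subject(spec,
                       subject_seed = derive_seed(spec$seed, "subject", i),
                       draw_seed = derive_seed(spec$seed, "subject", i,
                                               "session", s))
    })
    names(data) <- subjects
    signal_set(data, dt = spec$dt)
  })
}

#' Specify synthetic behavioral scores with planted brain coupling
#'
#' Emulates a small battery of cognitive scores (defaults: processing speed,
#' card sort, flanker). The composite `Y %*% true_weights` correlates with
#' the supplied per-subject brain score at `coupling_r` in expectation.
#'
#' @param n_measures number of behavioral measures.
#' @param true_weights length-`n_measures` composite weights (not all zero).
#' @param coupling_r target Pearson correlation in \[-1, 1\] between the
#'   composite and the brain score.
#' @param seed integer seed.
#' @return an object of class `behavior_spec`.
#' @export
behavior_spec <- function(n_measures = 3L, true_weights = c(0.4, 0.8, 0.4),
                          coupling_r = 0.45, seed = 1L) {
  if (length(true_weights) != n_measures)
    stopf("true_weights must have length n_measures")
  if (all(true_weights == 0)) stopf("true_weights must not all be zero")
  if (abs(coupling_r) > 1) stopf("coupling_r must be in [-1, 1]")
  if (abs(sum(true_weights)) < 1e-12)
    stopf("true_weights must not sum to zero (composite coupling undefined)")
  structure(list(n_measures = as.integer(n_measures),
                 true_weights = true_weights,
                 coupling_r = coupling_r, seed = as.integer(seed)),
            class = "behavior_spec")
}

#' Simulate behavioral scores coupled to a brain score
#'
#' Each measure loads on the standardized brain score with a common loading
#' chosen in closed form so that the `true_weights` composite attains the
#' target coupling; the residual is independent standard normal. Columns are
#' standardized to mean 0, sd 1.
#'
#' @param bspec a [behavior_spec()].
#' @param flex_scores per-subject brain scalar (e.g., mean flexibility).
#' @return data.frame: `subject` plus one standardized column per measure.
#' @export
simulate_behavior <- function(bspec, flex_scores) {
  stopifnot(inherits(bspec, "behavior_spec"))
  n <- length(flex_scores)
  if (n < 3) stopf("need at least 3 subjects")
  if (n < bspec$n_measures) stopf("fewer subjects than measures")
  if (sd(flex_scores) == 0) stopf("flex_scores are constant")
  w <- bspec$true_weights
  rho <- abs(bspec$coupling_r)
  s1 <- sum(w); s2 <- sum(w^2)
  lam2 <- if (rho >= 1) 1 else rho^2 * s2 / (s1^2 * (1 - rho^2) + rho^2 * s2)
  lam <- sqrt(lam2) * sign(s1)
  g <- as.numeric(scale(flex_scores)) * sign(bspec$coupling_r)
  if (bspec$coupling_r == 0) g <- g * 0   # fully decoupled
  set.seed(bspec$seed)
  E <- matrix(rnorm(n * bspec$n_measures), n, bspec$n_measures)
  Y <- outer(g, rep(lam, bspec$n_measures)) + sqrt(1 - lam2) * E
  Y <- scale(Y)
  attr(Y, "scaled:center") <- attr(Y, "scaled:scale") <- NULL
  measure_names <- if (bspec$n_measures == 3)
    c("processing_speed", "card_sort", "flanker")
  else sprintf("measure%02d", seq_len(bspec$n_measures))
  out <- data.frame(subject = sprintf("sub%03d", seq_len(n)), Y,
                    stringsAsFactors = FALSE)
  names(out) <- c("subject", measure_names)
  out
}
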