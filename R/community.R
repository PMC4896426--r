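#' Signed modularity matrix (asymmetric weighting)
#'
#' Builds the modularity matrix for the asymmetric signed quality Q*:
#' positive weights are rewarded within communities relative to their
#' configuration-model expectation, while intramodular negative weights are
#' penalized, down-weighted by the total negative strength relative to the
#' total strength:
#' `B = (W+ - s+ s+' / v+) / v+  -  (W- - s- s-' / v-) / (v+ + v-)`.
#' The diagonal is zeroed; it never contributes to quality.
#'
#' @param W symmetric signed weighted matrix (diagonal ignored).
#' @return symmetric modularity matrix with zero diagonal.
#' @export
modularity_matrix <- function(W) {
  if (!isSymmetric(unname(W), tol = 1e-8)) stopf("matrix must be symmetric")
  W <- (W + t(W)) / 2
  diag(W) <- 0
  Wp <- pmax(W, 0)
  Wn <- -pmin(W, 0)
  vp <- sum(Wp)
  vn <- sum(Wn)
  B <- matrix(0, nrow(W), ncol(W))
  if (vp > 0) {
    sp <- rowSums(Wp)
    B <- B + (Wp - outer(sp, sp) / vp) / vp
  }
  if (vn > 0) {
    sn <- rowSums(Wn)
    B <- B - (Wn - outer(sn, sn) / vn) / (vp + vn)
  }
  diag(B) <- 0
  dimnames(B) <- dimnames(W)
  B
}

#' Evaluate the signed quality Q* of a candidate partition
#'
#' Direct summation of the modularity matrix over within-community pairs
#' (`i != j`); independent of the optimizer, usable as an oracle.
#'
#' @param W symmetric signed weighted matrix.
#' @param assignment integer community labels, one per node.
#' @return the Q* value.
#' @export
qstar <- function(W, assignment) {
  B <- modularity_matrix(W)
  same <- outer(assignment, assignment, `==`)
  diag(same) <- FALSE
  sum(B[same])
}

#' Detect communities by signed-weighted Louvain optimization
#'
#' Runs a Louvain-style greedy optimization of the asymmetric signed
#' quality Q* on the complete unthresholded weighted matrix, `n_init` times
#' with seeded random node orders, and returns the run with maximal Q*.
#' The number of communities is determined automatically.
#'
#' @param W symmetric signed weighted matrix (e.g., Fisher-z connectivity).
#' @param n_init number of random initializations (default 100).
#' @param seed integer seed.
#' @return an object of class `partition`: list with `assignment` (named
#'   integer vector, labels contiguous from 1), `quality` (Q* of the best
#'   run), `n_communities`, and `q_runs` (Q* of every initialization).
#' @export
detect_communities <- function(W, n_init = 100L, seed = 1L) {
  if (n_init < 1) stopf("n_init must be >= 1")
  if (anyNA(W) || any(!is.finite(W)))
    stopf("connectivity matrix has non-finite entries")
  nodes <- rownames(W)
  if (is.null(nodes)) nodes <- node_names(nrow(W))
  Wd <- W
  diag(Wd) <- 0
  if (all(Wd == 0)) {
    assignment <- setNames(rep(1L, nrow(W)), nodes)
    return(structure(list(assignment = assignment, quality = 0,
                          n_communities = 1L, q_runs = rep(0, n_init)),
                     class = "partition"))
  }
  B <- modularity_matrix(W)
  res <- louvain_best_cpp(B, as.integer(n_init), as.double(seed))
  assignment <- setNames(as.integer(res$assignment), nodes)
  structure(list(assignment = assignment, quality = res$quality,
                 n_communities = max(assignment), q_runs = res$q_runs),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes in %d communities, Q* = %.4f\n",
              length(x$assignment), x$n_communities, x$quality))
  invisible(x)
}

#' Reference (static) community partition
#'
#' Community detection applied to the group-averaged static connectivity
#' matrix; the result serves as the native community of every node for the
#' node-level dynamics metrics.
#'
#' @param group_static symmetric group-mean Fisher-z matrix
#'   (see [static_connectivity()]).
#' @inheritParams detect_communities
#' @return a `partition`.
#' @export
reference_partition <- function(group_static, n_init = 100L, seed = 1L) {
  detect_communities(group_static, n_init = n_init, seed = seed)
}

#' Per-window allegiance matrix
#'
#' Binary symmetric matrix with `A_ij = 1` when nodes i and j share a
#' community in the given partition; diagonal fixed at 1.
#'
#' @param partition a `partition` or a bare assignment vector.
#' @return binary matrix.
#' @export
window_allegiance <- function(partition) {
  a <- if (inherits(partition, "partition")) partition$assignment else partition
  A <- outer(a, a, `==`) * 1
  diag(A) <- 1
  A
}

#' Temporal co-occurrence matrix
#'
#' Element-wise temporal mean of per-window allegiance matrices: `C_ij` is
#' the proportion of windows in which nodes i and j are in the same
#' community (module allegiance). The diagonal is 1 by construction and is
#' excluded from every downstream strength sum.
#'
#' @param allegiances list of binary allegiance matrices, or a 3-d array
#'   nodes x nodes x windows.
#' @param subject optional subject id to record.
#' @return object of class `co_occurrence`: list with `C`, `subject`,
#'   `n_windows`.
#' @export
co_occurrence <- function(allegiances, subject = NA_character_) {
  if (is.array(allegiances) && length(dim(allegiances)) == 3) {
    nw <- dim(allegiances)[3]
    C <- apply(allegiances, c(1, 2), mean)
  } else {
    nw <- length(allegiances)
    if (!nw) stopf("no allegiance matrices given")
    C <- Reduce(`+`, allegiances) / nw
  }
  diag(C) <- 1
  structure(list(C = C, subject = subject, n_windows = nw),
            class = "co_occurrence")
}

#' @export
print.co_occurrence <- function(x, ...) {
  cat(sprintf("<co_occurrence> %d nodes over %d windows (subject %s)\n",
              nrow(x$C), x$n_windows, x$subject))
  invisible(x)
}

#' Windowed community detection and co-occurrence for one subject
#'
#' Detects communities independently in every window of a sliding-window
#' connectivity array (no temporal coupling across adjacent windows is
#' imposed) and accumulates the temporal co-occurrence matrix. Per-window
#' seeds are derived by counter from `seed`, so results do not depend on
#' processing order.
#'
#' @param zarr nodes x nodes x windows array from [sliding_windows()].
#' @param n_init initializations per window.
#' @param seed integer seed.
#' @param subject optional subject id.
#' @param keep_partitions if TRUE, also return the per-window assignments
#'   (windows x nodes integer matrix).
#' @return a [co_occurrence()] (with `partitions` attached when requested).
#' @export
subject_co_occurrence <- function(zarr, n_init = 100L, seed = 1L,
                                  subject = NA_character_,
                                  keep_partitions = FALSE) {
  nw <- dim(zarr)[3]
  n <- dim(zarr)[1]
  acc <- matrix(0, n, n)
  parts <- if (keep_partitions) matrix(NA_integer_, nw, n) else NULL
  for (k in seq_len(nw)) {
    p <- detect_communities(zarr[, , k], n_init = n_init,
                            seed = derive_seed(seed, "window", k))
    acc <- acc + window_allegiance(p)
    if (keep_partitions) parts[k, ] <- p$assignment
  }
  C <- acc / nw
  diag(C) <- 1
  dimnames(C) <- dimnames(zarr)[1:2]
  out <- structure(list(C = C, subject = subject, n_windows = nw),
                   class = "co_occurrence")
  if (keep_partitions) attr(out, "partitions") <- parts
  out
}

#' Export a partition / square matrix as delimited text
#'
#' Partitions are written as two-column tab-separated text
#' (`node_id`, `community`); co-occurrence and connectivity matrices as
#' square tab-separated matrices with node ids as header and first column.
#'
#' @param p a `partition`.
#' @param path output path.
#' @export
write_partition <- function(p, path) {
  data.table::fwrite(data.frame(node_id = names(p$assignment),
                                community = as.integer(p$assignment)),
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_partition
#' @param m square numeric matrix (or `co_occurrence`).
#' @export
write_matrix_txt <- function(m, path) {
  if (inherits(m, "co_occurrence")) m <- m$C
  ids <- rownames(m)
  if (is.null(ids)) ids <- node_names(nrow(m))
  out <- data.table::data.table(node_id = ids)
  vals <- data.table::as.data.table(m)
  data.table::setnames(vals, ids)
  data.table::fwrite(cbind(out, vals), path, sep = "\t")
  invisible(path)
}
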