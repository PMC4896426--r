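cooc_matrix <- function(C) {
  if (inherits(C, "co_occurrence")) C <- C$C
  C
}

ref_assignment <- function(ref) {
  if (inherits(ref, "partition")) ref$assignment else ref
}

# Off-diagonal co-occurrence with per-community strength sums.
strength_by_community <- function(C, assign) {
  Cd <- cooc_matrix(C)
  diag(Cd) <- 0
  m <- max(assign)
  S <- vapply(seq_len(m), function(u) rowSums(Cd[, assign == u, drop = FALSE]),
              numeric(nrow(Cd)))
  # own-community sums above still include nothing for j == i (diag zeroed)
  list(S = matrix(S, nrow = nrow(Cd)), total = rowSums(Cd))
}

#' Temporal flexibility
#'
#' Fraction of a node's temporal co-occurrence mass spent outside its
#' native (reference) community:
#' `f_i = sum_{j not in u_i} C_ij / sum_{j != i} C_ij`.
#' Nodes with zero total co-occurrence get `NA`.
#'
#' @param C a [co_occurrence()] or its matrix.
#' @param ref reference `partition` (or assignment vector) defining each
#'   node's native community.
#' @return named numeric vector in \[0, 1\].
#' @export
temporal_flexibility <- function(C, ref) {
  assign <- ref_assignment(ref)
  sb <- strength_by_community(C, assign)
  own <- sb$S[cbind(seq_along(assign), assign)]
  f <- (sb$total - own) / sb$total
  f[sb$total <= 0] <- NA_real_
  setNames(f, names(assign))
}

#' Spatiotemporal diversity
#'
#' Normalized entropy of a node's co-occurrence strength across reference
#' communities (the node's own community included):
#' `h_i = -(1/log m) * sum_u p_i(u) log p_i(u)` with
#' `p_i(u) = s_i(u) / s_i`. Zero-probability terms contribute 0; nodes with
#' zero total strength get `NA`.
#'
#' @inheritParams temporal_flexibility
#' @return named numeric vector in \[0, 1\].
#' @export
spatiotemporal_diversity <- function(C, ref) {
  assign <- ref_assignment(ref)
  m <- max(assign)
  if (m < 2) stopf("diversity undefined with fewer than 2 communities")
  sb <- strength_by_community(C, assign)
  P <- sb$S / sb$total
  H <- -rowSums(ifelse(P > 0, P * log(P), 0)) / log(m)
  H[sb$total <= 0] <- NA_real_
  setNames(H, names(assign))
}

#' Within-community normalized centrality
#'
#' z-score of a node's co-occurrence strength within its own reference
#' community: `z_i = (s_i(m_i) - mean(s(m_i))) / sd(s(m_i))`, mean and
#' sample sd taken over the community's nodes. Singleton communities or
#' zero spread yield 0 and are flagged.
#'
#' @inheritParams temporal_flexibility
#' @return named numeric vector; attribute `flagged` marks degenerate nodes.
#' @export
within_community_centrality <- function(C, ref) {
  assign <- ref_assignment(ref)
  Cd <- cooc_matrix(C)
  diag(Cd) <- 0
  z <- numeric(length(assign))
  flagged <- logical(length(assign))
  for (u in seq_len(max(assign))) {
    idx <- which(assign == u)
    if (length(idx) < 2) {
      z[idx] <- 0
      flagged[idx] <- TRUE
      next
    }
    s_own <- rowSums(Cd[idx, idx, drop = FALSE])
    sdev <- sd(s_own)
    if (sdev == 0) {
      z[idx] <- 0
      flagged[idx] <- TRUE
    } else {
      z[idx] <- (s_own - mean(s_own)) / sdev
    }
  }
  structure(setNames(z, names(assign)), flagged = flagged)
}

#' Static node strength and participation coefficient
#'
#' On the static connectivity matrix (positive weights only): strength is
#' the off-diagonal positive-part row sum; the participation coefficient is
#' `1 - sum_u (s_i(u)/s_i)^2` over reference communities. Nodes with zero
#' positive strength get strength 0 and participation `NA`.
#'
#' @param W static connectivity matrix (Fisher-z).
#' @param ref reference `partition` or assignment vector.
#' @return data.frame with `node_id`, `strength`, `participation`.
#' @export
static_node_metrics <- function(W, ref) {
  assign <- ref_assignment(ref)
  Wp <- pmax(W, 0)
  diag(Wp) <- 0
  s <- rowSums(Wp)
  S <- vapply(seq_len(max(assign)),
              function(u) rowSums(Wp[, assign == u, drop = FALSE]),
              numeric(nrow(Wp)))
  p <- 1 - rowSums((S / s)^2)
  p[s <= 0] <- NA_real_
  data.frame(node_id = names(assign), strength = s, participation = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Node dynamics table for one subject
#'
#' @param C a [co_occurrence()].
#' @param ref reference `partition`.
#' @param static_W optional static matrix for strength/participation.
#' @return tidy data.frame, one row per node: subject, node_id,
#'   flexibility, diversity, centrality (+ static columns when given).
#' @export
node_dynamics <- function(C, ref, static_W = NULL) {
  assign <- ref_assignment(ref)
  z <- within_community_centrality(C, ref)
  out <- data.frame(subject = if (inherits(C, "co_occurrence")) C$subject
                              else NA_character_,
                    node_id = names(assign),
                    community = as.integer(assign),
                    flexibility = as.numeric(temporal_flexibility(C, ref)),
                    diversity = as.numeric(spatiotemporal_diversity(C, ref)),
                    centrality = as.numeric(z),
                    centrality_flagged = attr(z, "flagged"),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(static_W)) {
    st <- static_node_metrics(static_W, ref)
    out$static_strength <- st$strength
    out$static_participation <- st$participation
  }
  out
}

#' Aggregate node dynamics by atlas network
#'
#' Per subject, the mean of a metric over each network's nodes; plus
#' cross-network contrasts of the top-ranked network against every other
#' (paired two-sided Wilcoxon signed-rank across subjects, Holm-corrected).
#' Networks with no nodes in the table are dropped with a warning.
#'
#' @param nd node dynamics table (rows: subject x node).
#' @param atlas atlas data.frame with `node_id`, `network_label`.
#' @param metric column of `nd` to aggregate (default "flexibility").
#' @return list with `means` (subject x network table) and `contrasts`.
#' @export
aggregate_by_network <- function(nd, atlas, metric = "flexibility") {
  if (!metric %in% names(nd)) stopf("no column '%s' in node table", metric)
  nd$network <- atlas$network_label[match(nd$node_id, atlas$node_id)]
  if (anyNA(nd$network)) stopf("nodes missing from atlas")
  empty <- setdiff(unique(atlas$network_label), unique(nd$network))
  if (length(empty))
    warning(sprintf("networks with no nodes excluded: %s",
                    paste(empty, collapse = ", ")))
  means <- aggregate(nd[[metric]],
                     by = list(subject = nd$subject, network = nd$network),
                     FUN = mean, na.rm = TRUE)
  names(means)[3] <- "value"
  wide <- as.data.frame(tapply(means$value,
                               list(means$subject, means$network), identity))
  net_means <- colMeans(as.matrix(wide), na.rm = TRUE)
  top <- names(which.max(net_means))
  others <- setdiff(names(net_means), top)
  contrasts <- NULL
  if (length(others) && nrow(wide) >= 2) {
    p_raw <- vapply(others, function(o) {
      wilcox.test(wide[[top]], wide[[o]], paired = TRUE, exact = FALSE)$p.value
    }, numeric(1))
    contrasts <- data.frame(network_a = top, network_b = others,
                            p_raw = p_raw,
                            p_holm = p.adjust(p_raw, "holm"),
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  list(means = means, top_network = top, contrasts = contrasts)
}

#' High-flexibility node cluster
#'
#' On the group-mean (flexibility, diversity) plane, both axes are
#' standardized and a 2-component k-means (50 seeded restarts) is run; the
#' component with higher mean flexibility is returned. A percentile
#' threshold variant (default: top 15 percent flexibility) is always
#' reported alongside; if clustering degenerates, the threshold rule is the
#' fallback (with a warning).
#'
#' @param nd node dynamics table (any number of subjects; node means are
#'   taken internally), or a data.frame with `node_id`, `flexibility`,
#'   `diversity` already at node level.
#' @param method "kmeans" or "threshold".
#' @param prob flexibility quantile for the threshold variant (default 0.85).
#' @param seed integer seed for the k-means restarts.
#' @return list with `nodes` (selected node ids), `method` actually used,
#'   `threshold_nodes`, and the node-level summary table.
#' @export
high_flex_cluster <- function(nd, method = c("kmeans", "threshold"),
                              prob = 0.85, seed = 1L) {
  method <- match.arg(method)
  summ <- aggregate(cbind(flexibility, diversity) ~ node_id, nd, mean,
                    na.action = stats::na.omit)
  summ <- summ[match(unique(nd$node_id), summ$node_id), ]
  thr <- quantile(summ$flexibility, prob, na.rm = TRUE)
  threshold_nodes <- summ$node_id[summ$flexibility >= thr]
  used <- method
  nodes <- threshold_nodes
  if (method == "kmeans") {
    fs <- sd(summ$flexibility)
    ds <- sd(summ$diversity)
    if (is.na(fs) || fs == 0 || is.na(ds) || ds == 0) {
      warning("degenerate flexibility-diversity plane; falling back to threshold rule")
      used <- "threshold"
    } else {
      XY <- cbind(scale(summ$flexibility), scale(summ$diversity))
      set.seed(seed)
      km <- kmeans(XY, centers = 2, nstart = 50)
      means_f <- tapply(summ$flexibility, km$cluster, mean)
      pick <- as.integer(names(which.max(means_f)))
      sel <- km$cluster == pick
      if (!any(sel) || all(sel)) {
        warning("degenerate clustering; falling back to threshold rule")
        used <- "threshold"
      } else {
        nodes <- summ$node_id[sel]
      }
    }
  }
  list(nodes = nodes, method = used, threshold_nodes = threshold_nodes,
       node_means = summ)
}

#' Overlap of two node sets, both directions
#'
#' @param clusterA,clusterB character vectors of node ids.
#' @return list with `a_in_b` and `b_in_a`, percentages.
#' @export
session_overlap <- function(clusterA, clusterB) {
  inter <- length(intersect(clusterA, clusterB))
  list(a_in_b = if (length(clusterA)) 100 * inter / length(clusterA) else NA_real_,
       b_in_a = if (length(clusterB)) 100 * inter / length(clusterB) else NA_real_)
}

#' Write a node dynamics table as delimited text
#'
#' @param nd node dynamics table.
#' @param path output path.
#' @export
write_node_dynamics <- function(nd, path) {
  data.table::fwrite(nd, path, sep = "\t")
  invisible(path)
}
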