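# Shared fixtures and independent oracles for the test suite.

# All set partitions of n items as restricted-growth strings (e.g. n = 6
# gives the 203 partitions of the Bell number B6). Independent oracle for
# exhaustive modularity optimization.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(rgs, maxv) {
    k <- length(rgs)
    if (k == n) {
      out[[length(out) + 1]] <<- rgs
      return()
    }
    for (v in seq_len(maxv + 1)) {
      recurse(c(rgs, v), max(maxv, v))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Brute-force optimum of the signed quality over every partition.
brute_force_qstar <- function(W) {
  parts <- all_partitions(nrow(W))
  qs <- vapply(parts, function(p) qstar(W, p), numeric(1))
  list(q = max(qs), assignment = parts[[which.max(qs)]], all_q = qs)
}

# Two positive cliques of size n1 and n2 with given between-weight.
two_clique_matrix <- function(n1 = 4, n2 = 4, within = 1, between = 0) {
  n <- n1 + n2
  W <- matrix(between, n, n)
  W[seq_len(n1), seq_len(n1)] <- within
  W[(n1 + 1):n, (n1 + 1):n] <- within
  diag(W) <- 0
  W
}

# Random symmetric signed matrix for small-scale optimizer trials.
random_signed_matrix <- function(n, seed) {
  set.seed(seed)
  W <- matrix(rnorm(n * n), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# Small cohort settings used by the faster property tests (scaled down from
# the full study conditions for runtime).
small_spec <- function(seed = 11, ...) {
  sim_spec(n_nodes = 20L, n_communities = 4L, community_sizes = rep(5L, 4),
           n_frames = 400L, flexible_nodes = c(1L, 6L, 11L, 16L),
           switch_period = 50L, seed = seed, ...)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
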