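#' Phase-randomized surrogate time series
#'
#' Per node independently: forward Fourier transform, add an i.i.d.
#' uniform\[0, 2*pi) phase at every non-DC frequency (conjugate-symmetric so
#' the output is real; the Nyquist bin of even-length series is kept), then
#' inverse transform. The amplitude spectrum of every node is preserved
#' exactly, so per-node mean, variance and power spectrum survive while all
#' cross-correlations between nodes are destroyed.
#'
#' @param s a [signal_set()].
#' @param n_surrogates number of surrogate datasets (>= 1).
#' @param seed integer seed.
#' @return list of `n_surrogates` [signal_set()] objects.
#' @export
phase_randomize <- function(s, n_surrogates = 1L, seed = 1L) {
  stopifnot(inherits(s, "signal_set"))
  if (n_surrogates < 1) stopf("n_surrogates must be >= 1")
  nf <- n_frames(s)
  half <- floor((nf - 1) / 2)           # freely randomizable bins
  lapply(seq_len(n_surrogates), function(r) {
    sur <- s
    for (subj in s$subjects) {
      set.seed(derive_seed(seed, "surrogate", r, subj))
      m <- s$data[[subj]]
      out <- m
      for (i in seq_len(nrow(m))) {
        sp <- fft(m[i, ])
        if (half >= 1) {
          ph <- runif(half, 0, 2 * pi)
          idx <- 2:(half + 1)
          sp[idx] <- Mod(sp[idx]) * exp(1i * ph)
          sp[nf + 2 - idx] <- Conj(sp[idx])
        }
        out[i, ] <- Re(fft(sp, inverse = TRUE)) / nf
      }
      sur$data[[subj]] <- out
    }
    sur
  })
}

edge_list <- function(mask) {
  idx <- which(mask & upper.tri(mask), arr.ind = TRUE)
  matrix(as.integer(idx), ncol = 2)
}

# Rewire one sign's subnetwork (degree-preserving swaps that avoid node
# pairs occupied by either sign), then reassign that sign's weight multiset
# by residual strength rank-matching.
rewire_sign_part <- function(Wpart, occupied, n_swap_per_edge, seed) {
  n <- nrow(Wpart)
  el <- edge_list(Wpart > 0)
  if (nrow(el) == 0) return(list(mat = matrix(0, n, n), edges = el))
  el_new <- rewire_edgelist_cpp(n, el, occupied,
                                as.integer(n_swap_per_edge * nrow(el)),
                                as.double(seed))
  strengths <- rowSums(Wpart)
  wvals <- Wpart[upper.tri(Wpart)]
  w_desc <- sort(wvals[wvals > 0], decreasing = TRUE)
  w_new <- assign_null_weights_cpp(el_new[, 1], el_new[, 2],
                                   strengths, w_desc,
                                   as.double(derive_seed(seed, "weights")))
  out <- matrix(0, n, n)
  out[el_new] <- w_new
  out[el_new[, 2:1, drop = FALSE]] <- w_new
  list(mat = out, edges = el_new)
}

#' Degree/strength/weight-preserving random graphs
#'
#' For each null: the binary topology of each sign's subnetwork is rewired
#' by degree-preserving edge swaps (default 10 swaps per edge), then the
#' original weight multiset of that sign is reassigned to the rewired edges
#' by rank-matching against residual node strengths. Weight multiset and
#' degree sequence are preserved exactly; the strength sequence is
#' approximated. Positive and negative weights are handled separately and
#' merged.
#'
#' @param W symmetric signed weighted matrix (diagonal ignored).
#' @param n_graphs number of null matrices.
#' @param seed integer seed.
#' @param n_swap_per_edge binary swaps per edge (default 10).
#' @return list of `n_graphs` matrices with zero diagonal.
#' @export
random_graph_null <- function(W, n_graphs, seed = 1L, n_swap_per_edge = 10L) {
  if (!isSymmetric(unname(W), tol = 1e-8)) stopf("matrix must be symmetric")
  W <- (W + t(W)) / 2
  diag(W) <- 0
  Wp <- pmax(W, 0)
  Wn <- -pmin(W, 0)
  n_edges <- sum(W[upper.tri(W)] != 0)
  if (n_edges < 2) stopf("matrix too sparse to rewire (%d edges)", n_edges)
  occ0 <- edge_list(W != 0)
  lapply(seq_len(n_graphs), function(g) {
    pos <- rewire_sign_part(Wp, occ0, n_swap_per_edge,
                            derive_seed(seed, "null", g, "pos"))
    occ1 <- rbind(pos$edges, edge_list(Wn > 0))
    neg <- rewire_sign_part(Wn, occ1, n_swap_per_edge,
                            derive_seed(seed, "null", g, "neg"))
    null <- pos$mat - neg$mat
    dimnames(null) <- dimnames(W)
    null
  })
}

# Variance fraction of the first principal component of a column-centered
# matrix.
pc1_fraction <- function(M) {
  ev <- prcomp(M, center = TRUE, scale. = FALSE)$sdev^2
  ev[1] / sum(ev)
}

#' First-principal-component structure test against random graphs
#'
#' Tests whether a temporal co-occurrence matrix has more low-rank
#' structure than random graphs with the same weight, degree and strength
#' distributions: the observed statistic is the variance fraction of the
#' first principal component of the column-centered matrix, the null
#' distribution comes from [random_graph_null()] draws (off-diagonal
#' entries rewired, unit diagonal restored), and
#' `p = (1 + #\{null >= observed\}) / (1 + n_graphs)`.
#'
#' @param C a [co_occurrence()] or square matrix.
#' @param n_graphs number of null graphs (>= 19).
#' @param seed integer seed.
#' @return list: `observed`, `null` (vector), `p`.
#' @export
pc1_structure_test <- function(C, n_graphs = 1000L, seed = 1L) {
  C <- cooc_matrix(C)
  if (n_graphs < 19) stopf("n_graphs must be >= 19 for usable p resolution")
  obs <- pc1_fraction(C)
  d <- diag(C)
  nulls <- vapply(random_graph_null(C, n_graphs, seed = seed), function(N) {
    diag(N) <- d
    pc1_fraction(N)
  }, numeric(1))
  list(observed = obs, null = nulls,
       p = (1 + sum(nulls >= obs)) / (1 + n_graphs))
}
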