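test_that("phase surrogates preserve each node's spectrum, mean, variance", {
  spec <- small_spec()
  s <- simulate_cohort(spec, 2)[[1]]
  sur <- phase_randomize(s, n_surrogates = 2, seed = 7)
  expect_length(sur, 2)
  for (subj in s$subjects) {
    m <- s$data[[subj]]
    m2 <- sur[[1]]$data[[subj]]
    expect_false(identical(m, m2))
    for (i in c(1, 10, 20)) {
      expect_equal(Mod(fft(m2[i, ])), Mod(fft(m[i, ])), tolerance = 1e-10)
      expect_equal(mean(m2[i, ]), mean(m[i, ]), tolerance = 1e-10)
      expect_equal(var(m2[i, ]), var(m[i, ]), tolerance = 1e-10)
    }
  }
  # reproducibility and independence across surrogate index
  sur_b <- phase_randomize(s, n_surrogates = 2, seed = 7)
  expect_equal(sur[[1]]$data, sur_b[[1]]$data, tolerance = 1e-14)
  expect_false(identical(sur[[1]]$data[[1]], sur[[2]]$data[[1]]))
})

test_that("phase surrogates destroy cross-node correlation", {
  # two strongly correlated noise channels
  set.seed(5)
  base <- rnorm(800)
  m <- rbind(n001 = base + rnorm(800, 0, 0.3),
             n002 = base + rnorm(800, 0, 0.3))
  s <- signal_set(list(a = m), dt = 0.72)
  r_orig <- cor(m[1, ], m[2, ])
  expect_gt(r_orig, 0.8)
  rs <- vapply(phase_randomize(s, n_surrogates = 50, seed = 3),
               function(x) cor(x$data$a[1, ], x$data$a[2, ]), numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
  expect_lt(max(abs(rs)), 0.5)
})

test_that("rewired null graphs preserve weights, degrees, approximate strengths", {
  # heterogeneous community sizes so strengths genuinely vary across nodes
  spec <- sim_spec(n_nodes = 50, n_communities = 4,
                   community_sizes = c(20L, 15L, 10L, 5L), n_frames = 800,
                   flexible_nodes = integer(0), seed = 12)
  s <- simulate_cohort(spec, 3)[[1]]
  W <- static_connectivity(s)
  nulls <- random_graph_null(W, 3, seed = 4)
  deg_p <- rowSums(W > 0); deg_n <- rowSums(W < 0)
  for (N in nulls) {
    expect_equal(N, t(N), tolerance = 1e-12)
    expect_equal(unname(diag(N)), rep(0, 50))
    # weight multisets exact per sign
    wo <- W[upper.tri(W)]; wn <- N[upper.tri(N)]
    expect_equal(sort(wn[wn > 0]), sort(wo[wo > 0]), tolerance = 1e-12)
    expect_equal(sort(wn[wn < 0]), sort(wo[wo < 0]), tolerance = 1e-12)
    # degree sequences exact per sign
    expect_equal(rowSums(N > 0), deg_p)
    expect_equal(rowSums(N < 0), deg_n)
    # strength sequence approximately preserved
    sp_o <- rowSums(pmax(W, 0)); sp_n <- rowSums(pmax(N, 0))
    expect_gt(cor(sp_o, sp_n), 0.8)
    # weights actually moved (the matrix is dense, so the randomness comes
    # from the strength-conditioned weight reassignment, not edge swaps)
    expect_gt(sum(N != W), 0)
  }
  # determinism and across-draw variety
  nulls2 <- random_graph_null(W, 3, seed = 4)
  expect_equal(nulls[[1]], nulls2[[1]], tolerance = 1e-14)
  expect_false(identical(nulls[[1]], nulls[[2]]))
  expect_error(random_graph_null(matrix(0, 4, 4), 1), "too sparse")
})

test_that("sparse graphs are genuinely rewired with degrees intact", {
  spec <- sim_spec(n_nodes = 50, n_communities = 4,
                   community_sizes = c(20L, 15L, 10L, 5L), n_frames = 800,
                   flexible_nodes = integer(0), seed = 12)
  s <- simulate_cohort(spec, 3)[[1]]
  W <- static_connectivity(s)
  thr <- quantile(abs(W[upper.tri(W)]), 0.7)
  W[abs(W) < thr] <- 0   # keep the strongest 30 percent of edges
  N <- random_graph_null(W, 1, seed = 8)[[1]]
  expect_gt(sum((W != 0) != (N != 0)), 0)          # topology moved
  expect_equal(rowSums(N > 0), rowSums(W > 0))     # per-sign degrees intact
  expect_equal(rowSums(N < 0), rowSums(W < 0))
  expect_equal(sort(N[upper.tri(N)]), sort(W[upper.tri(W)]),
               tolerance = 1e-12)
  # no node pair carries both a positive and a negative weight
  expect_true(all((N > 0) + (N < 0) <= 1))
})

test_that("block-structured co-occurrence beats its rewired nulls on PC1", {
  set.seed(9)
  C <- matrix(0.1, 40, 40)
  for (u in 0:3) {
    idx <- u * 10 + 1:10
    C[idx, idx] <- 0.85
  }
  C <- C + matrix(rnorm(1600, 0, 0.01), 40, 40)
  C <- (C + t(C)) / 2
  C <- pmin(pmax(C, 0), 1)
  diag(C) <- 1
  res <- pc1_structure_test(C, n_graphs = 99, seed = 6)
  expect_equal(res$p, 1 / 100, tolerance = 1e-12)
  expect_gt(res$observed, max(res$null))
  expect_length(res$null, 99)
  expect_error(pc1_structure_test(C, n_graphs = 5), "n_graphs")
})

test_that("an unstructured matrix is not declared significant", {
  set.seed(13)
  M <- matrix(runif(900, 0.2, 0.8), 30, 30)
  C <- (M + t(M)) / 2
  diag(C) <- 1
  res <- pc1_structure_test(C, n_graphs = 99, seed = 2)
  expect_gt(res$p, 0.05)
})
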