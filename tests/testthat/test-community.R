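# Hand-computable oracle: two positive 2-cliques (weight 1), no
# between-edges. v+ = 4, s+ = (1,1,1,1); within pair (1,2):
# B_12 = (1 - 1/4)/4 = 3/16, across pairs B = (0 - 1/4)/4 = -1/16.
# Q* for the 2-clique split = 4 * 3/16 = 3/4... with n1 = n2 = 2:
test_that("modularity matrix and Q* match closed-form values", {
  W <- two_clique_matrix(2, 2, within = 1, between = 0)
  B <- modularity_matrix(W)
  expect_equal(B[1, 2], (1 - 1 / 4) / 4, tolerance = 1e-14)
  expect_equal(B[1, 3], (0 - 1 / 4) / 4, tolerance = 1e-14)
  expect_equal(qstar(W, c(1, 1, 2, 2)), 2 * 2 * 3 / 16, tolerance = 1e-14)
  expect_equal(qstar(W, c(1, 1, 1, 1)),
               2 * 2 * 3 / 16 + 2 * 4 * (-1 / 16), tolerance = 1e-14)
  # purely negative graph: the negative part is scaled by 1/(v+ + v-)
  Wn <- -W
  Bn <- modularity_matrix(Wn)
  expect_equal(Bn[1, 2], -(1 - 1 / 4) / 4, tolerance = 1e-14)
  expect_error(modularity_matrix(matrix(1:9, 3, 3)), "symmetric")
})

test_that("Q* is invariant to community relabeling", {
  W <- random_signed_matrix(7, 21)
  a <- c(1, 2, 1, 3, 2, 3, 1)
  for (perm in list(c(2, 3, 1), c(3, 1, 2), c(2, 1, 3)))
    expect_equal(qstar(W, perm[a]), qstar(W, a), tolerance = 1e-12)
})

test_that("the optimizer recovers the exhaustive optimum on small graphs", {
  # modest version of the acceptance-scale enumeration check
  for (s in 1:10) {
    W <- random_signed_matrix(6, 100 + s)
    bf <- brute_force_qstar(W)
    p <- detect_communities(W, n_init = 30, seed = s)
    expect_equal(p$quality, bf$q, tolerance = 1e-10)
    expect_equal(qstar(W, p$assignment), p$quality, tolerance = 1e-10)
  }
})

test_that("detected partitions are contiguous, named, deterministic", {
  W <- random_signed_matrix(12, 5)
  rownames(W) <- colnames(W) <- sprintf("n%03d", 1:12)
  p1 <- detect_communities(W, n_init = 20, seed = 9)
  p2 <- detect_communities(W, n_init = 20, seed = 9)
  expect_identical(p1$assignment, p2$assignment)
  expect_identical(sort(unique(unname(p1$assignment))),
                   seq_len(p1$n_communities))
  expect_identical(names(p1$assignment), rownames(W))
  expect_length(p1$q_runs, 20)
  expect_equal(max(p1$q_runs), p1$quality, tolerance = 1e-12)
  # all-zero matrix: single community, Q* = 0
  p0 <- detect_communities(matrix(0, 5, 5), n_init = 3, seed = 1)
  expect_equal(unname(p0$assignment), rep(1L, 5))
  expect_equal(p0$quality, 0)
  expect_error(detect_communities(matrix(NA_real_, 2, 2)), "non-finite")
})

test_that("two-clique split with weak coupling is found exactly", {
  W <- two_clique_matrix(4, 4, within = 1, between = 0.1)
  p <- detect_communities(W, n_init = 20, seed = 2)
  expect_equal(p$n_communities, 2L)
  expect_equal(adjusted_rand(p$assignment, rep(1:2, each = 4)), 1)
  bf <- brute_force_qstar(W)
  expect_equal(p$quality, bf$q, tolerance = 1e-12)
})

test_that("allegiance and co-occurrence count shared-community windows", {
  a1 <- c(1, 1, 2, 2)
  a2 <- c(1, 2, 2, 1)
  A1 <- window_allegiance(a1)
  expect_equal(A1, rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                         c(0, 0, 1, 1), c(0, 0, 1, 1)))
  co <- co_occurrence(list(A1, window_allegiance(a2)))
  expect_equal(co$C[1, 2], 0.5)   # together in 1 of 2 windows
  expect_equal(co$C[3, 4], 0.5)
  expect_equal(co$C[2, 3], 0.5)
  expect_equal(unname(diag(co$C)), rep(1, 4))
  expect_equal(co$n_windows, 2L)
  arr <- array(c(A1, window_allegiance(a2)), c(4, 4, 2))
  expect_equal(co_occurrence(arr)$C, co$C)
  expect_error(co_occurrence(list()), "no allegiance")
})

test_that("subject co-occurrence is order-independent and in [0, 1]", {
  spec <- small_spec()
  X <- simulate_subject(spec, 17)
  ws <- window_spec(length_s = 40, dt = spec$dt, step_frames = 20)
  zarr <- sliding_windows(X, ws)
  co <- subject_co_occurrence(zarr, n_init = 10, seed = 33, subject = "s1",
                              keep_partitions = TRUE)
  expect_true(all(co$C >= 0 & co$C <= 1))
  expect_equal(co$C, t(co$C), tolerance = 1e-12)
  parts <- attr(co, "partitions")
  expect_equal(dim(parts), c(dim(zarr)[3], nrow(X)))
  # per-window derived seeds: window k alone reproduces row k
  k <- 5
  pk <- detect_communities(zarr[, , k], n_init = 10,
                           seed = derive_seed(33, "window", k))
  expect_equal(unname(parts[k, ]), unname(pk$assignment))
  # co-occurrence equals the mean of the recorded allegiances
  manual <- Reduce(`+`, lapply(seq_len(nrow(parts)), function(k)
    window_allegiance(parts[k, ]))) / nrow(parts)
  expect_equal(unname(co$C), unname(manual), tolerance = 1e-12)
})

test_that("partition and matrix text exports round-trip", {
  W <- random_signed_matrix(6, 3)
  rownames(W) <- colnames(W) <- sprintf("n%03d", 1:6)
  p <- detect_communities(W, n_init = 10, seed = 1)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "part.tsv")
  write_partition(p, f1)
  tab <- read.delim(f1)
  expect_identical(tab$node_id, names(p$assignment))
  expect_identical(tab$community, unname(as.integer(p$assignment)))
  f2 <- file.path(dir, "mat.tsv")
  write_matrix_txt(W, f2)
  m2 <- as.matrix(read.delim(f2, row.names = 1, check.names = FALSE))
  expect_equal(m2, W, tolerance = 1e-12)
})
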