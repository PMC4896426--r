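as_behavior_matrix <- function(behavior) {
  if (is.data.frame(behavior)) {
    num <- vapply(behavior, is.numeric, logical(1))
    behavior <- as.matrix(behavior[, num, drop = FALSE])
  }
  if (anyNA(behavior)) stopf("behavior table has missing values")
  behavior
}

# One full cross-validated CCA pass; x scalar brain measure per subject,
# Y raw behavior matrix. Returns pooled held-out Spearman rho and per-fold
# canonical weights. Kept lean: it is the inner loop of the permutation test.
cv_cca_core <- function(x, Y, k, seed) {
  n <- length(x)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  pooled_brain <- numeric(n)
  pooled_beh <- numeric(n)
  weights <- vector("list", k)
  for (f in seq_len(k)) {
    te <- fold == f
    tr <- !te
    Ytr <- Y[tr, , drop = FALSE]
    ntr <- nrow(Ytr)
    mu <- colMeans(Ytr)
    Yc <- Ytr - rep(mu, each = ntr)
    sdv <- sqrt(colSums(Yc^2) / (ntr - 1))
    if (any(sdv == 0)) stopf("constant behavioral measure in training fold")
    Ys <- Yc * rep(1 / sdv, each = ntr)
    xtr <- x[tr] - mean(x[tr])
    b <- tryCatch(solve(crossprod(Ys), crossprod(Ys, xtr)),
                  error = function(e) {
                    # collinear measures: least-squares basic solution
                    cf <- qr.coef(qr(Ys), xtr)
                    cf[is.na(cf)] <- 0
                    cbind(cf)
                  })
    if (sum((Ys %*% b) * xtr) < 0) b <- -b
    b <- b / sqrt(sum(b^2))
    weights[[f]] <- as.numeric(b)
    nte <- sum(te)
    Yte <- (Y[te, , drop = FALSE] - rep(mu, each = nte)) *
      rep(1 / sdv, each = nte)
    pooled_beh[te] <- Yte %*% b
    pooled_brain[te] <- x[te]
  }
  list(rho = cor(pooled_brain, pooled_beh, method = "spearman"),
       weights = weights, fold = fold)
}

#' Cross-validated canonical correlation between brain and behavior
#'
#' Subjects are randomly split into `k` folds (seeded shuffle). Per fold,
#' behavioral measures are standardized on the training subjects only and
#' canonical weights maximizing the training correlation between the
#' behavioral composite and the brain measure are fitted (for a scalar
#' brain measure these coincide, up to scale, with least-squares regression
#' weights of brain on behavior); the sign is fixed so the training
#' correlation is nonnegative. Weights are applied to the held-out
#' subjects, all held-out pairs are pooled, and a single Spearman
#' correlation is reported.
#'
#' @param brain per-subject scalar brain measure (e.g., mean temporal
#'   flexibility of a node set).
#' @param behavior data.frame or matrix of behavioral scores (numeric
#'   columns are used; complete cases required).
#' @param k number of folds (default 4); requires `n >= 2k`.
#' @param seed integer seed for the fold shuffle.
#' @return object of class `cca_result`: `rho`, per-fold `weights`,
#'   `fold`, `k`, `seed` (`p` is added by [permutation_p()]).
#' @export
cv_cca <- function(brain, behavior, k = 4L, seed = 1L) {
  Y <- as_behavior_matrix(behavior)
  n <- length(brain)
  if (nrow(Y) != n) stopf("brain and behavior disagree on subjects")
  if (n < 2 * k) stopf("need at least %d subjects for %d folds", 2 * k, k)
  if (sd(brain) == 0) stopf("brain measure is constant")
  res <- cv_cca_core(brain, Y, k, seed)
  structure(list(rho = res$rho, weights = res$weights, fold = res$fold,
                 k = k, seed = seed, p = NA_real_, n_permutations = 0L),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> held-out Spearman rho = %.3f", x$rho))
  if (!is.na(x$p))
    cat(sprintf(", permutation p = %.4g (%d permutations)",
                x$p, x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Permutation test for the cross-validated canonical correlation
#'
#' The brain measure is randomized across subjects `n_perm` times; the full
#' cross-validation analysis (fold scheme regenerated per permutation from
#' a derived seed) is repeated on each null dataset, and the one-sided
#' empirical p-value is `(1 + #\{null rho >= observed rho\}) / (1 + n_perm)`.
#'
#' @inheritParams cv_cca
#' @param n_perm number of permutations (>= 99; default 10000).
#' @return a `cca_result` with `p`, `null` distribution and observed `rho`.
#' @export
permutation_p <- function(brain, behavior, k = 4L, n_perm = 10000L,
                          seed = 1L) {
  if (n_perm < 99) stopf("n_perm must be >= 99")
  Y <- as_behavior_matrix(behavior)
  obs <- cv_cca(brain, behavior, k = k, seed = derive_seed(seed, "folds", 0))
  null_rho <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    set.seed(derive_seed(seed, "shuffle", p))
    xb <- sample(brain)
    null_rho[p] <- cv_cca_core(xb, Y, k,
                               seed = derive_seed(seed, "folds", p))$rho
  }
  obs$p <- (1 + sum(null_rho >= obs$rho)) / (1 + n_perm)
  obs$n_permutations <- as.integer(n_perm)
  obs$null <- null_rho
  obs
}
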