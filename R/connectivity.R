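#' Sliding-window specification
#'
#' Windows are indexed by start frame and cover `[start, start + T)`
#' half-open; the window length in frames is `round(length_s / dt)`. The
#' decay constant theta defaults to a third of the window length.
#'
#' @param length_s window length in seconds (default 40).
#' @param dt seconds per frame.
#' @param step_frames frames between window starts (default 1).
#' @param theta_frames exponential decay constant in frames
#'   (default `length_frames / 3`).
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(length_s = 40, dt = 0.72, step_frames = 1L,
                        theta_frames = NULL) {
  length_frames <- as.integer(round(length_s / dt))
  if (length_frames < 3) stopf("window of %.1f s is under 3 frames", length_s)
  if (step_frames < 1) stopf("step_frames must be >= 1")
  if (is.null(theta_frames)) theta_frames <- length_frames / 3
  if (theta_frames <= 0) stopf("theta_frames must be > 0")
  structure(list(length_s = length_s, dt = dt,
                 length_frames = length_frames,
                 step_frames = as.integer(step_frames),
                 theta_frames = theta_frames),
            class = "window_spec")
}

#' Exponentially decaying window weights
#'
#' `w_t = w0 * exp((t - T) / theta)` for `t = 1..T`, with
#' `w0 = (1 - exp(-1/theta)) / (1 - exp(-T/theta))`, so the weights sum to
#' one and increase toward the most recent frame.
#'
#' @param T window length in frames (>= 2).
#' @param theta decay constant in frames (> 0).
#' @return numeric weight vector of length `T`.
#' @export
exp_weights <- function(T, theta) {
  if (T < 2) stopf("T must be >= 2")
  if (theta <= 0) stopf("theta must be > 0")
  w0 <- (1 - exp(-1 / theta)) / (1 - exp(-T / theta))
  w0 * exp((seq_len(T) - T) / theta)
}

#' Weighted Pearson correlation
#'
#' Correlation of two series under nonnegative observation weights, using
#' weighted means and weighted central moments. Invariant to positive
#' rescaling of the weight vector. If either series has zero weighted
#' variance the correlation is undefined and `NA` is returned.
#'
#' @param x,y numeric series of equal length.
#' @param w nonnegative weights with positive sum.
#' @return correlation in \[-1, 1\], or `NA` if undefined.
#' @export
weighted_pearson <- function(x, y, w) {
  if (length(x) != length(y) || length(x) != length(w))
    stopf("x, y, w must have equal length")
  if (any(w < 0) || sum(w) <= 0) stopf("weights must be >= 0 with positive sum")
  w <- w / sum(w)
  dx <- x - sum(w * x)
  dy <- y - sum(w * y)
  vx <- sum(w * dx^2)
  vy <- sum(w * dy^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  r <- sum(w * dx * dy) / sqrt(vx * vy)
  min(max(r, -1), 1)
}

# All-pairs weighted correlation of the rows of a nodes x frames matrix.
weighted_corr_matrix <- function(X, w) {
  w <- w / sum(w)
  mu <- as.numeric(X %*% w)
  Xc <- X - mu
  Cw <- (Xc * rep(w, each = nrow(X))) %*% t(Xc)
  v <- diag(Cw)
  R <- Cw / sqrt(outer(v, v))
  R[v <= 0, ] <- NA_real_
  R[, v <= 0] <- NA_real_
  diag(R) <- 1
  pmin(pmax(R, -1), 1)
}

#' Sliding-window connectivity for one subject matrix
#'
#' Each window's all-pairs weighted Pearson correlation matrix is Fisher
#' z-transformed (|r| clipped at 1 - 1e-7). The number of windows is
#' `floor((n_frames - length_frames) / step_frames) + 1`.
#'
#' @param X nodes x frames numeric matrix.
#' @param wspec a [window_spec()].
#' @return 3-d array nodes x nodes x windows of Fisher-z values; attribute
#'   `starts` gives window start frames.
#' @export
sliding_windows <- function(X, wspec) {
  stopifnot(inherits(wspec, "window_spec"))
  Tn <- wspec$length_frames
  if (ncol(X) < Tn)
    stopf("series of %d frames shorter than window of %d", ncol(X), Tn)
  w <- exp_weights(Tn, wspec$theta_frames)
  starts <- seq(1L, ncol(X) - Tn + 1L, by = wspec$step_frames)
  n <- nrow(X)
  out <- array(NA_real_, c(n, n, length(starts)),
               dimnames = list(rownames(X), rownames(X), NULL))
  for (k in seq_along(starts)) {
    R <- weighted_corr_matrix(X[, starts[k]:(starts[k] + Tn - 1L),
                                drop = FALSE], w)
    Z <- fisher_z(R)
    diag(Z) <- 0
    out[, , k] <- Z
  }
  attr(out, "starts") <- starts
  out
}

#' Sliding-window connectivity for every subject of a signal set
#'
#' @param s a [signal_set()].
#' @param wspec a [window_spec()].
#' @return named list (per subject) of arrays from [sliding_windows()].
#' @export
sliding_connectivity <- function(s, wspec) {
  stopifnot(inherits(s, "signal_set"))
  lapply(s$data, sliding_windows, wspec = wspec)
}

#' Group-averaged static connectivity matrix
#'
#' Per subject, full-series Pearson correlation of all node pairs, Fisher
#' z-transformed, then averaged element-wise across subjects.
#'
#' @param s a [signal_set()].
#' @return symmetric nodes x nodes matrix of mean Fisher-z values
#'   (diagonal set to 0).
#' @export
static_connectivity <- function(s) {
  stopifnot(inherits(s, "signal_set"))
  zs <- lapply(s$data, function(m) {
    Z <- fisher_z(cor(t(m)))
    diag(Z) <- 0
    Z
  })
  Reduce(`+`, zs) / length(zs)
}
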