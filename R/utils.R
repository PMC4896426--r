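#' Derive a reproducible sub-seed from a master seed and a label path
#'
#' One master seed is fanned out to named stages/subjects/windows through a
#' small deterministic hash, so partial reruns of any stage see the same
#' stream regardless of execution order. The result is always a positive
#' 32-bit integer, suitable for `set.seed()`.
#'
#' @param seed integer master seed.
#' @param ... further labels (strings or integers) identifying the consumer,
#'   e.g. `derive_seed(1, "community", subject, window)`.
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, unlist(list(...))), collapse = "/")
  h <- 97531
  for (b in utf8ToInt(key)) h <- (h * 69069 + b) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

# FNV-1a style hash of a character scalar, hex string out (manifest hashes).
fnv_hash <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Clip correlations away from +/-1 so the Fisher transform stays finite.
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

upper_tri_vec <- function(m) m[upper.tri(m)]

stopf <- function(...) stop(sprintf(...), call. = FALSE)
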