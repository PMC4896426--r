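#' Construct a validated signal set
#'
#' A signal set holds one node-by-time matrix per subject, a shared node
#' order, and the sampling interval `dt` (seconds per frame). All subjects
#' must agree on node count and node order; missing values fail loudly.
#'
#' @param data named list of numeric matrices (nodes x frames), rows named
#'   by node id (node names are taken from the first subject if absent).
#' @param dt seconds per frame (> 0).
#' @return an object of class `signal_set`.
#' @export
signal_set <- function(data, dt) {
  if (!length(data)) stopf("signal set needs at least one subject")
  if (is.null(names(data))) names(data) <- sprintf("sub%03d", seq_along(data))
  if (!is.numeric(dt) || dt <= 0) stopf("dt must be > 0")
  ref_ids <- rownames(data[[1]])
  if (is.null(ref_ids)) ref_ids <- node_names(nrow(data[[1]]))
  for (s in names(data)) {
    m <- data[[s]]
    if (!is.matrix(m) || !is.numeric(m))
      stopf("subject '%s': data must be a numeric matrix", s)
    if (nrow(m) != length(ref_ids))
      stopf("subject '%s': %d nodes, expected %d", s, nrow(m), length(ref_ids))
    ids <- rownames(m)
    if (!is.null(ids) && !identical(ids, ref_ids))
      stopf("subject '%s': node order differs from first subject", s)
    if (anyNA(m) || any(!is.finite(m))) {
      bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
      stopf("subject '%s': non-finite value at node row %d, frame %d",
            s, bad[1], bad[2])
    }
    rownames(data[[s]]) <- ref_ids
  }
  structure(list(subjects = names(data), data = data,
                 node_ids = ref_ids, dt = dt),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("<signal_set> %d subjects, %d nodes, %d frames, dt = %g s\n",
              length(x$subjects), length(x$node_ids),
              ncol(x$data[[1]]), x$dt))
  invisible(x)
}

n_frames <- function(s) ncol(s$data[[1]])

#' Write signal matrices as delimited text
#'
#' One tab-separated file per subject: first column `node_id`, then one
#' column per frame (header `f1`, `f2`, ...).
#'
#' @param s a [signal_set()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_signals <- function(s, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(s$subjects, ".tsv"))
  for (i in seq_along(s$subjects)) {
    m <- s$data[[i]]
    dt_out <- data.table::data.table(node_id = s$node_ids)
    frames <- data.table::as.data.table(m)
    data.table::setnames(frames, sprintf("f%d", seq_len(ncol(m))))
    data.table::fwrite(cbind(dt_out, frames), paths[i], sep = "\t")
  }
  invisible(paths)
}

#' Load signal matrices from delimited text
#'
#' Files must be rectangular and numeric (comma or tab separated,
#' auto-detected); the node order of the first file is enforced on all.
#'
#' @param paths character vector of file paths, one per subject.
#' @param dt seconds per frame.
#' @param subjects subject ids (default: file base names).
#' @return a [signal_set()].
#' @export
load_signals <- function(paths, dt, subjects = NULL) {
  if (!length(paths)) stopf("no files given")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stopf("file not found: %s", missing[1])
  if (is.null(subjects))
    subjects <- sub("\\.[^.]*$", "", basename(paths))
  data <- vector("list", length(paths))
  names(data) <- subjects
  ref_ids <- NULL
  for (i in seq_along(paths)) {
    tab <- tryCatch(
      data.table::fread(paths[i], header = TRUE, sep = "auto"),
      error = function(e) stopf("file '%s': %s", paths[i], conditionMessage(e)))
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m))
      stopf("file '%s': non-numeric cells in signal block", paths[i])
    if (anyNA(m) || any(!is.finite(m))) {
      bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
      stopf("file '%s': non-finite value at row %d, frame column %d",
            paths[i], bad[1], bad[2])
    }
    rownames(m) <- ids
    if (is.null(ref_ids)) {
      ref_ids <- ids
    } else if (!identical(ids, ref_ids)) {
      first_bad <- which(ids != ref_ids)[1]
      stopf("file '%s': node order mismatch at row %d ('%s' vs '%s')",
            paths[i], first_bad, ids[first_bad], ref_ids[first_bad])
    }
    data[[i]] <- m
  }
  signal_set(data, dt = dt)
}

#' Write / load an atlas table
#'
#' Columns: `node_id`, `x`, `y`, `z`, `network_label`.
#' @param atlas data.frame with the columns above.
#' @param path file path.
#' @return `load_atlas` returns the validated data.frame.
#' @export
write_atlas <- function(atlas, path) {
  data.table::fwrite(atlas, path, sep = "\t")
  invisible(path)
}

#' @rdname write_atlas
#' @export
load_atlas <- function(path) {
  atlas <- as.data.frame(data.table::fread(path, sep = "auto"))
  need <- c("node_id", "x", "y", "z", "network_label")
  if (!all(need %in% names(atlas)))
    stopf("atlas missing columns: %s",
          paste(setdiff(need, names(atlas)), collapse = ", "))
  if (anyDuplicated(atlas$node_id)) stopf("atlas node_ids are not unique")
  atlas$node_id <- as.character(atlas$node_id)
  atlas
}

#' Discard initial frames
#'
#' Removes the first `n` frames of every subject, the usual guard against
#' non-equilibrium effects at scan start.
#'
#' @param s a [signal_set()].
#' @param n frames to drop (default 20).
#' @return a [signal_set()] with `n` fewer frames.
#' @export
discard_initial_frames <- function(s, n = 20L) {
  stopifnot(inherits(s, "signal_set"))
  if (n < 0) stopf("n must be >= 0")
  if (n >= n_frames(s))
    stopf("cannot discard %d of %d frames", n, n_frames(s))
  if (n == 0) return(s)
  s$data <- lapply(s$data, function(m) m[, -seq_len(n), drop = FALSE])
  s
}

# Discrete-cosine high-pass basis: intercept plus cosines with frequency
# k / (2 * N * dt) below the cutoff.
dct_lowfreq_basis <- function(n, dt, cutoff_hz) {
  k_max <- floor(2 * n * dt * cutoff_hz)
  t_idx <- seq_len(n) - 0.5
  B <- matrix(1 / sqrt(n), n, 1)
  if (k_max >= 1) {
    cosines <- vapply(seq_len(k_max),
                      function(k) cos(pi * k * t_idx / n), numeric(n))
    B <- cbind(B, cosines)
  }
  qr.Q(qr(B))
}

#' Temporal high-pass filter (discrete cosine basis regression)
#'
#' Removes the intercept and all discrete-cosine components with frequency
#' below `cutoff_hz` from every node's series. The filter is a linear
#' zero-phase projection, exact on the finite window; output series have
#' mean zero.
#'
#' @param s a [signal_set()].
#' @param cutoff_hz high-pass cutoff in Hz (default 0.008); must be below
#'   the Nyquist frequency `1 / (2 * dt)`.
#' @return a filtered [signal_set()].
#' @export
highpass <- function(s, cutoff_hz = 0.008) {
  stopifnot(inherits(s, "signal_set"))
  nyquist <- 1 / (2 * s$dt)
  if (cutoff_hz >= nyquist)
    stopf("cutoff %.4f Hz is not below Nyquist %.4f Hz", cutoff_hz, nyquist)
  if (cutoff_hz < 0) stopf("cutoff must be >= 0")
  Q <- dct_lowfreq_basis(n_frames(s), s$dt, cutoff_hz)
  s$data <- lapply(s$data, function(m) m - (m %*% Q) %*% t(Q))
  s
}
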