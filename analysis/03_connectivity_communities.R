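#!/usr/bin/env Rscript
# Static connectivity, the reference partition, sliding-window community
# detection and per-subject temporal co-occurrence matrices for session 1.
# This is the expensive stage (~1 min per subject at n_init = 20).

library(netdyn)

session <- 1
in_dir <- file.path("results", "preprocessed", sprintf("session%d", session))
paths <- list.files(in_dir, pattern = "^sub.*\\.tsv$", full.names = TRUE)
signals <- load_signals(paths, dt = 0.72)

static <- static_connectivity(signals)
reference <- reference_partition(static, n_init = 100,
                                 seed = derive_seed(41, "reference", session))
print(reference)

out_dir <- file.path("results", "communities", sprintf("session%d", session))
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
write_matrix_txt(static, file.path(out_dir, "static.tsv"))
write_partition(reference, file.path(out_dir, "reference_partition.tsv"))

wspec <- window_spec(length_s = 40, dt = signals$dt, step_frames = 1)
for (subj in signals$subjects) {
  zarr <- sliding_windows(signals$data[[subj]], wspec)
  co <- subject_co_occurrence(
    zarr, n_init = 20,
    seed = derive_seed(41, "community", session, subj), subject = subj)
  write_matrix_txt(co, file.path(out_dir, sprintf("cooc_%s.tsv", subj)))
  cat(sprintf("%s: %d windows\n", subj, co$n_windows))
}
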