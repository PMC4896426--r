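#!/usr/bin/env Rscript
# Preprocess both sessions: discard the first 20 frames and high-pass at
# 0.008 Hz. Writes filtered signals under results/preprocessed/.

library(netdyn)

for (s in 1:2) {
  in_dir <- file.path("results", "signals", sprintf("session%d", s))
  paths <- list.files(in_dir, pattern = "^sub.*\\.tsv$", full.names = TRUE)
  signals <- load_signals(paths, dt = 0.72)
  signals <- discard_initial_frames(signals, 20)
  signals <- highpass(signals, 0.008)
  out_dir <- file.path("results", "preprocessed", sprintf("session%d", s))
  write_signals(signals, out_dir)
  cat(sprintf("session %d: %d frames after preprocessing\n",
              s, ncol(signals$data[[1]])))
}
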