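#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 20 subjects, two sessions, 40 nodes
# in 4 planted communities with one flexible node per community, plus the
# node atlas. Writes per-subject signal tables under results/signals/.

library(netdyn)

spec <- sim_spec(seed = 41)
sessions <- simulate_cohort(spec, n_subjects = 20, sessions = 2)
atlas <- simulate_atlas(spec)

for (s in seq_along(sessions)) {
  dir <- file.path("results", "signals", sprintf("session%d", s))
  write_signals(sessions[[s]], dir)
  cat(sprintf("session %d: %d subjects written to %s\n",
              s, length(sessions[[s]]$subjects), dir))
}
write_atlas(atlas, file.path("results", "signals", "atlas.tsv"))
print(sessions[[1]])
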