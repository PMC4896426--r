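#!/usr/bin/env Rscript
# Test-retest replication: run the pipeline on the twin session and compare
# per-subject co-occurrence matrices and the high-flexibility clusters.

library(netdyn)

spec <- sim_spec(seed = 41)
cfg <- run_config(sim = spec, n_subjects = 20, n_init = 20, seed = 41)
run1 <- run_pipeline(cfg, session = 1)
run2 <- run_pipeline(cfg, session = 2)

cmp <- compare_sessions(run1, run2)
cat(sprintf("mean co-occurrence similarity: %.3f (t-test vs 0: p = %.2e)\n",
            cmp$mean_similarity, cmp$p_vs_zero))
cat(sprintf("cluster overlap: %.1f%% of session 1 in session 2, %.1f%% back\n",
            cmp$overlap$a_in_b, cmp$overlap$b_in_a))

dir.create("results/retest", recursive = TRUE, showWarnings = FALSE)
write.table(data.frame(subject = names(cmp$similarity),
                       similarity = cmp$similarity),
            "results/retest/session_similarity.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
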