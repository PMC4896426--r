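#!/usr/bin/env Rscript
# Node-level dynamics metrics (flexibility, diversity, centrality) plus
# static strength/participation, network-level aggregation, and the
# high-flexibility node cluster for session 1.

library(netdyn)

session <- 1
com_dir <- file.path("results", "communities", sprintf("session%d", session))
static <- as.matrix(read.delim(file.path(com_dir, "static.tsv"),
                               row.names = 1, check.names = FALSE))
ref_tab <- read.delim(file.path(com_dir, "reference_partition.tsv"))
reference <- setNames(as.integer(ref_tab$community), ref_tab$node_id)
atlas <- load_atlas(file.path("results", "signals", "atlas.tsv"))

cooc_paths <- list.files(com_dir, pattern = "^cooc_.*\\.tsv$",
                         full.names = TRUE)
node_table <- do.call(rbind, lapply(cooc_paths, function(p) {
  subj <- sub("^cooc_(.*)\\.tsv$", "\\1", basename(p))
  C <- as.matrix(read.delim(p, row.names = 1, check.names = FALSE))
  co <- structure(list(C = C, subject = subj, n_windows = NA_integer_),
                  class = "co_occurrence")
  node_dynamics(co, reference, static_W = static)
}))

out_dir <- file.path("results", "metrics", sprintf("session%d", session))
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
write_node_dynamics(node_table, file.path(out_dir, "node_dynamics.tsv"))

agg <- aggregate_by_network(node_table, atlas)
cat(sprintf("top network by mean flexibility: %s\n", agg$top_network))
print(agg$contrasts)
write.table(agg$means, file.path(out_dir, "network_means.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

cluster <- high_flex_cluster(node_table, seed = derive_seed(41, "cluster",
                                                            session))
cat(sprintf("high-flexibility cluster (%s): %s\n", cluster$method,
            paste(cluster$nodes, collapse = ", ")))
writeLines(cluster$nodes, file.path(out_dir, "high_flex_cluster.txt"))
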