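#!/usr/bin/env Rscript
# Step 4 — internal consistency of the reported network summaries.
#
# The study's per-condition degree centralities imply integer in/out degree
# sequences (centrality x 7 counterpart nodes). This step realizes each
# sequence as a simple digraph and recomputes density and the extreme
# centralities with the package's graph metrics, confirming that the
# reported densities (0.46 / 0.48 / 0.23) and the extreme degree values
# follow from the degree tables alone. Writes
# results/reported_consistency.tsv.

library(phosnet)

prof <- diet_centrality_profiles()
rows <- list()
for (cond in c("regular", "low", "high")) {
  p <- prof[prof$condition == cond, ]
  net <- realize_degree_sequence(round(p$out_degree * 7), round(p$in_degree * 7),
                                 nodes = p$variable)
  rep_ <- centrality_report(net)
  deg <- rep_$table
  rows[[cond]] <- data.frame(
    condition = cond,
    edges = rep_$edge_count,
    density = round_half_up(rep_$density, 2),
    max_indegree = round_half_up(max(deg$indegree_centrality), 2),
    max_indegree_node = deg$node[which.max(deg$indegree_centrality)],
    max_outdegree = round_half_up(max(deg$outdegree_centrality), 2),
    max_outdegree_node = deg$node[which.max(deg$outdegree_centrality)])
  cat(sprintf("%-8s: %2d edges, density %.2f; most regulated: %s (%.2f in), strongest regulator: %s (%.2f out)\n",
              cond, rep_$edge_count, rows[[cond]]$density,
              rows[[cond]]$max_indegree_node, rows[[cond]]$max_indegree,
              rows[[cond]]$max_outdegree_node, rows[[cond]]$max_outdegree))
}
dir.create("results", showWarnings = FALSE)
write.table(do.call(rbind, rows), "results/reported_consistency.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/reported_consistency.tsv\n")
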