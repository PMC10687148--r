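#!/usr/bin/env Rscript
# Hydrogen-bond network statistics along the synthetic cooling series:
# bonds per molecule n_H, mean largest cluster size, cluster-size
# distribution and modularity Q of the cluster partition. With planted
# chains lengthening upon cooling, n_H approaches its single-hydroxyl
# saturation value 1 and the mean largest cluster grows, while Q stays in
# the strong-community regime (clusters with sharp boundaries).
# Run analysis/01_simulate.R first.

suppressMessages(library(fluctnet))

idx <- read.delim("results/synthetic/index.tsv")
rows <- NULL
dists <- NULL

for (i in seq_len(nrow(idx))) {
  tmp <- idx$temperature[i]
  traj <- read_trajectory(idx$chains[i], "gro", temperature = tmp)
  spec <- read_synthetic_spec(sub("\\.gro$", ".json", idx$chains[i]))
  rpt <- analyze_hbond_network(traj)
  stopifnot(isTRUE(all.equal(rpt$Q, spec$truth$Q)))  # ground-truth check
  rows <- rbind(rows, data.frame(
    temperature = tmp, n_H = rpt$n_H,
    mean_largest = rpt$clusters$mean_largest,
    Q = rpt$Q, regime = rpt$regime,
    mean_degree_bonded = rpt$mean_degree_bonded))
  d <- rpt$clusters$size_distribution
  d$temperature <- tmp
  dists <- rbind(dists, d)
}

write.table(rows, "results/hbond_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(dists, "results/hbond_size_distribution.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("hydrogen-bond network statistics along the cooling series:\n")
print(rows, digits = 4)
cat("n_H rises toward saturation and the largest cluster grows on cooling;\n")
cat(sprintf("all partitions sit in the community regime (min Q = %.3f)\n",
            min(rows$Q)))
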