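#!/usr/bin/env Rscript
# Stage 1 -- simulate the study inputs with known ground truth.
#
# Builds a synthetic middle-adulthood cohort (156 adults, 13 standardized
# behavioural features with two planted latent subgroups), regional time
# series with block covariance over an 8-network partition, and a
# connectome stack carrying a planted group-difference component. Writes
# everything under results/sim/ as plain-text tables, plus the settings
# actually used, so later stages (and a reader) can re-trace the run.

suppressMessages(library(connstrat))

seed <- 20240901
out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## behavioural cohort: planted subgroup separation d = 1 on 10/13 features
spec <- cohort_spec(seed = seed)
coh <- gen_cohort(spec)
write.table(cbind(coh$metadata, subgroup_true = coh$subgroup),
            file.path(out_dir, "metadata.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(data.frame(subject_id = coh$metadata$subject_id, coh$features),
            file.path(out_dir, "features.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

## node-to-network partition (8 intrinsic networks over 60 nodes)
n_nodes <- 60
partition <- gen_partition(n_nodes, 8, seed = seed + 1)
write_partition_tsv(partition, file.path(out_dir, "partition.tsv"))

## regional time series for a handful of subjects (connectome-stage input)
ts <- gen_timeseries(8, n_nodes, n_timepoints = 256, tr_seconds = 2,
                     partition = partition, seed = seed + 2)
for (s in seq_along(ts))
  write_matrix_tsv(ts[[s]], file.path(out_dir, sprintf("timeseries_%02d.tsv", s)))

## connectome stack with a planted VPT-vs-FT component
pspec <- planted_component_spec(n_nodes = n_nodes, n_edges_planted = 80,
                                delta = 0.3, seed = seed + 3)
stk <- gen_connectome_stack(coh$metadata, pspec)
# the stack itself is regenerated by later stages from the recorded seed
write.table(data.frame(i = stk$true_edges[, 1], j = stk$true_edges[, 2]),
            file.path(out_dir, "true_edges.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

writeLines(c(
  sprintf("seed\t%d", seed),
  sprintf("n_subjects\t%d", spec$n_subjects),
  sprintf("n_features\t%d", spec$n_features),
  sprintf("subgroup_fraction\t%.4f", spec$subgroup_fraction),
  sprintf("n_nodes\t%d", n_nodes),
  sprintf("n_edges_planted\t%d", pspec$n_edges_planted),
  sprintf("delta\t%.2f", pspec$delta)
), file.path(out_dir, "settings.tsv"))

cat("Simulated cohort: ", spec$n_subjects, " subjects, ",
    sum(coh$subgroup == 2), " in the planted at-risk subgroup; ",
    "planted component: ", pspec$n_edges_planted, " edges over ",
    length(unique(as.vector(stk$true_edges))), " nodes.\n", sep = "")
cat("Outputs in ", out_dir, "\n", sep = "")
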