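#!/usr/bin/env Rscript
# Monosynaptic-connection inference from CCGs with the convolution null:
# recovery of injected synapses, spike-transmission probabilities, the
# STP-versus-distance correlation, and connection motifs.
#
# Reads results/session and results/03_unit_table.tsv; writes
# results/05_edges.tsv and results/05_connectivity.json

suppressMessages(library(optoephys))
ses <- read_session("results/session")
cls <- utils::read.table("results/03_unit_table.tsv", header = TRUE,
                         sep = "\t")

edges <- detect_monosynaptic(ses, classes = cls)
gt <- ses$ground_truth$synapses
key <- paste(edges$pre, edges$post)
gt$recovered <- paste(gt$pre, gt$post) %in% key
gt$stp_hat <- edges$stp[match(paste(gt$pre, gt$post), key)]

dd <- tryCatch(
  distance_decay(edges, cls, n_perm = 10000, seed = 51),
  error = function(e) list(r = NA, p_value = NA, n_edges = nrow(edges)))
ms <- motif_summary(edges)

utils::write.table(edges, "results/05_edges.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
summ <- list(n_pairs_tested = attr(edges, "n_pairs"),
             n_edges = nrow(edges),
             n_true = nrow(gt),
             n_true_recovered = sum(gt$recovered),
             stp_mae = mean(abs(gt$stp_hat - gt$p), na.rm = TRUE),
             distance_r = dd$r, distance_p = dd$p_value,
             n_divergence_motifs = nrow(ms$divergence),
             n_convergence_motifs = nrow(ms$convergence))
jsonlite::write_json(summ, "results/05_connectivity.json",
                     auto_unbox = TRUE, digits = NA)
cat(sprintf(
  "connectivity: %d/%d injected synapses recovered among %d significant edges\n  (%d pairs tested); STP mean abs error %.3f; STP~distance r=%.3f (p=%.3g);\n  %d divergence / %d convergence motifs\n",
  summ$n_true_recovered, summ$n_true, summ$n_edges, summ$n_pairs_tested,
  summ$stp_mae, summ$distance_r, summ$distance_p,
  summ$n_divergence_motifs, summ$n_convergence_motifs))
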