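#!/usr/bin/env Rscript
# Waveform/autocorrelogram features, the three-way cell-type classification
# and soma localization, compared against the generator's ground truth.
#
# Reads results/session; writes results/03_unit_table.tsv and
# results/03_classification.json

suppressMessages(library(optoephys))
ses <- read_session("results/session")

cls <- classify_units(ses)
truth <- ses$units$cell_type[match(cls$unit_id, ses$units$unit_id)]
conf <- table(truth = truth, assigned = cls$label)
loc_err <- sqrt((cls$x_um - ses$units$x_um[match(cls$unit_id,
                                                 ses$units$unit_id)])^2 +
                (cls$y_um - ses$units$y_um[match(cls$unit_id,
                                                 ses$units$unit_id)])^2)

utils::write.table(cls, "results/03_unit_table.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(
  n_classified = nrow(cls),
  accuracy = mean(cls$label == truth),
  confusion = as.data.frame(conf),
  soma_error_median_um = stats::median(loc_err, na.rm = TRUE)),
  "results/03_classification.json", auto_unbox = TRUE)
cat(sprintf(
  "cell types: %d units classified, %.0f%% agreement with ground truth;\n  median soma localization error %.1f um\n",
  nrow(cls), 100 * mean(cls$label == truth),
  stats::median(loc_err, na.rm = TRUE)))
print(conf)
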