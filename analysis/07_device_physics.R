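#!/usr/bin/env Rscript
# Reduced device-physics simulations: light-fluence profile around one
# micro-LED (with the illumination-volume radius), steady-state tissue
# heating at the maximum safe drive, and the interconnect insertion-loss /
# crosstalk sweep.
#
# Writes results/07_fluence_profile.tsv, results/07_tnetwork.tsv and
# results/07_device_physics.json

suppressMessages(library(optoephys))
dir.create("results", showWarnings = FALSE)

fl <- light_fluence(geometry = "half")
prof <- data.frame(r_um = fl$r_um, phi_mw_mm2 = fl$phi[, 1])
utils::write.table(prof, "results/07_fluence_profile.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
r01 <- illumination_radius()

bh <- bioheat_steady()

tn <- tnetwork_response()
utils::write.table(tn, "results/07_tnetwork.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

summ <- list(illumination_radius_um = r01,
             fluence_at_50um = fluence_point_source(50),
             fluence_at_300um = fluence_point_source(300),
             max_tissue_dT_C = bh$max_tissue_dT,
             bioheat_cells = bh$n_cells,
             il_worst_db = max(abs(tn$il_db)),
             fext_worst_db = max(tn$fext_db))
jsonlite::write_json(summ, "results/07_device_physics.json",
                     auto_unbox = TRUE, digits = NA)
cat(sprintf(
  "device physics: 0.1 mW/mm2 fluence contour at %.0f um (0.027 mW/mm2 at a\n  neighboring shank); max tissue dT %.3f C at 300 uW; interconnect loss\n  %.2f dB worst-case, crosstalk %.1f dB\n",
  r01, bh$max_tissue_dT, max(abs(tn$il_db)), max(tn$fext_db)))
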