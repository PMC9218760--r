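#!/usr/bin/env Rscript
# Build the reference synthetic session used by the downstream analysis
# scripts: 100 units (70 pyramidal / 20 narrow / 10 wide) over 600 s on the
# 4-shank layout, ~20 log-normal monosynaptic connections, multi-site
# waveforms, a single-LED tagging protocol (50 ms pulses every 100 ms), and
# an LFP channel bank with 50 injected 6-SD ripples.
#
# Writes: results/session/ (the bundle) and results/01_summary.json

suppressMessages(library(optoephys))
seed <- 20260929L
dir.create("results", showWarnings = FALSE)

ses <- generate_units(duration_s = 600, seed = seed)
# local, distance-decaying connectivity: candidate pairs within 400 um,
# strength scaled by exp(-d / 300 um)
syn <- make_synapses(ses, n_synapses = 40, seed = seed + 1,
                     distance_lambda_um = 300, max_distance_um = 400)
ses <- inject_monosynaptic(ses, syn, seed = seed + 2)
ses <- generate_waveforms(ses, seed = seed + 3)

# tagging protocol on the LED nearest an opsin+ unit
op <- which(ses$units$opsin_positive)[1]
led <- which.min((ses$layout$leds$x_um - ses$units$x_um[op])^2 +
                 (ses$layout$leds$y_um - ses$units$y_um[op])^2)
prot <- make_pulse_protocol(led, n_pulses = 400, start_s = 5)
ses <- apply_stimulation(ses, prot, seed = seed + 4)

ses <- generate_lfp(ses, seed = seed + 5,
                    ripples = list(n = 50, amp_sd = 6,
                                   dur_range_ms = c(30, 100),
                                   freq_range_hz = c(110, 200),
                                   channels = 1L))

write_session(ses, "results/session")
summ <- list(seed = seed, n_units = nrow(ses$units),
             n_spikes = sum(lengths(ses$spikes)),
             n_synapses = nrow(syn),
             n_inserted = nrow(ses$ground_truth$inserted_spikes),
             tag_led = led,
             n_evoked = nrow(ses$ground_truth$evoked_spikes),
             n_ripples_injected = nrow(ses$ground_truth$ripples))
jsonlite::write_json(summ, "results/01_summary.json", auto_unbox = TRUE)
cat(sprintf(
  "session: %d units, %d spikes, %d synapses (%d inserted spikes),\n  tagging LED %d (%d evoked spikes), %d injected ripples -> results/session\n",
  summ$n_units, summ$n_spikes, summ$n_synapses, summ$n_inserted,
  summ$tag_led, summ$n_evoked, summ$n_ripples_injected))
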