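test_that("renewal trains hit their target rate and refractory ISI mix", {
  set.seed(11)
  st <- sample_renewal_train(5, 1000)
  expect_true(abs(length(st) / 1000 - 5) < 3 * sqrt(5 / 1000) * 5) # ~3 SD
  # with a constant post-refractory hazard, P(ISI < 9 ms) =
  # 1 - exp(-r_h * 7.5 ms); r_h solves the rate calibration
  isi <- diff(st)
  rh <- 1 / (1 / 5 - 0.0015)
  expected <- 1 - exp(-rh * 0.0075)
  expect_lt(abs(mean(isi < 0.009) - expected), 0.012)
  # close to (though below) the no-refractory Poisson expectation
  expect_lt(abs(mean(isi < 0.009) - (1 - exp(-5 * 0.009))), 0.015)
  expect_true(all(isi >= 0.0015 - 1e-12))
})

test_that("unit generation is reproducible and validates inputs", {
  a <- generate_units(duration_s = 20, seed = 5,
                      n_per_type = c(pyramidal = 3, narrow_int = 2,
                                     wide_int = 1))
  b <- generate_units(duration_s = 20, seed = 5,
                      n_per_type = c(pyramidal = 3, narrow_int = 2,
                                     wide_int = 1))
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$units, b$units)
  expect_error(generate_units(n_per_type = c(pyramidal = 0, narrow_int = 0,
                                             wide_int = 0)), "counts")
  expect_error(generate_units(duration_s = -1), "duration")
})

test_that("spike count of a 5 Hz unit over 100 s is within 3 SD of 500", {
  set.seed(21)
  st <- sample_renewal_train(5, 100)
  expect_lt(abs(length(st) - 500), 3 * sqrt(500))
})

test_that("monosynaptic injection matches its construction", {
  set.seed(31)
  ses <- generate_units(duration_s = 200, seed = 31,
                        n_per_type = c(pyramidal = 2, narrow_int = 2,
                                       wide_int = 1))
  pre_n <- length(ses$spikes[["1"]])
  # p = 1, no jitter, 2 ms latency: all mass lands in the +2 ms CCG bin
  syn <- data.frame(pre = 1L, post = 3L, p = 1, latency_ms = 2, jitter_ms = 0)
  s2 <- inject_monosynaptic(ses, syn)
  cc <- compute_ccg(s2$spikes[["1"]], s2$spikes[["3"]])
  ins <- nrow(s2$ground_truth$inserted_spikes)
  expect_gte(cc$count[cc$lag_ms == 2], ins)
  expect_gt(ins, 0.95 * pre_n) # a few lost to refractory collisions

  # binomial count at p = 0.2
  ses2 <- generate_units(duration_s = 2000, seed = 32,
                         n_per_type = c(pyramidal = 1, narrow_int = 1,
                                        wide_int = 1),
                         rate_median_hz = c(pyramidal = 5, narrow_int = 5,
                                            wide_int = 5))
  n_pre <- length(ses2$spikes[["1"]])
  syn2 <- data.frame(pre = 1L, post = 2L, p = 0.2, latency_ms = 2,
                     jitter_ms = 0.2)
  s3 <- inject_monosynaptic(ses2, syn2, seed = 33)
  ins2 <- nrow(s3$ground_truth$inserted_spikes)
  expect_lt(abs(ins2 - 0.2 * n_pre), 3.5 * sqrt(n_pre * 0.2 * 0.8))

  # p = 0 leaves the session unchanged; invalid p errors
  s4 <- inject_monosynaptic(ses, data.frame(pre = 1L, post = 3L, p = 0,
                                            latency_ms = 2, jitter_ms = 0))
  expect_identical(s4$spikes, ses$spikes)
  expect_error(inject_monosynaptic(ses, data.frame(pre = 1L, post = 3L,
                                                   p = 1.5, latency_ms = 2,
                                                   jitter_ms = 0)), "prob")
  expect_error(inject_monosynaptic(ses, data.frame(pre = 3L, post = 1L,
                                                   p = 0.5, latency_ms = 2,
                                                   jitter_ms = 0)),
               "pyramidal")
})

test_that("stimulation drives only nearby opsin-positive units", {
  ts <- tag_session()
  ses <- ts$session
  gt <- ses$ground_truth$evoked_spikes
  expect_gt(nrow(gt), 0)
  expect_true(all(gt$unit == ts$tagged_unit))
  # PSTH of the driven unit peaks inside the 5-8 ms latency window
  r <- optotag_test(ses$spikes[[as.character(ts$tagged_unit)]],
                    ts$protocol$onset_s, seed = 1)
  pk <- r$psth$t_ms[which.max(r$psth$rate_hz)]
  expect_gte(pk, 5); expect_lte(pk, 8)
  expect_error(apply_stimulation(ses, make_pulse_protocol(999, 10)),
               "unknown LED")
  expect_error(apply_stimulation(
    ses, make_pulse_protocol(3, 10, amp_uA = 80)), "75")
})

test_that("waveform amplitudes follow the distance model", {
  ses <- default_session()
  lay <- ses$layout
  # soma midway between the two site columns: both columns carry > 25% of
  # the peak amplitude
  ses2 <- ses
  ses2$units$x_um[1] <- lay$sites$x_um[1] + 13.5
  ses2$units$y_um[1] <- lay$sites$y_um[1] + 10
  ses2 <- generate_waveforms(ses2, seed = 1)
  wf <- ses2$waveforms[["1"]]
  amp <- apply(wf$mean_uv, 1, function(w) max(w) - min(w))
  cols <- lay$sites$column[wf$sites]
  expect_gte(sum(cols == 0 & amp > 0.25 * max(amp)), 2)
  expect_gte(sum(cols == 1 & amp > 0.25 * max(amp)), 2)
  # soma 100 um off the shank: out of recording range
  ses2$units$x_um[2] <- lay$sites$x_um[1] - 100
  ses2$units$y_um[2] <- lay$sites$y_um[1]
  ses2 <- generate_waveforms(ses2, seed = 2)
  expect_equal(length(ses2$waveforms[["2"]]$sites), 0L)
  # narrow-interneuron trough-to-peak measures below the 0.425 ms rule
  cls <- classify_units(ses)
  truth <- ses$units$cell_type[match(cls$unit_id, ses$units$unit_id)]
  expect_true(all(cls$tp_ms[truth == "narrow_int"] < 0.425))
})

test_that("LFP generation is reproducible and validates ripple amplitude", {
  ses <- generate_units(duration_s = 20, seed = 61,
                        n_per_type = c(pyramidal = 2, narrow_int = 1,
                                       wide_int = 1))
  a <- generate_lfp(ses, channel_sites = 1:2, seed = 62,
                    ripples = list(n = 3, amp_sd = 6,
                                   dur_range_ms = c(30, 100),
                                   freq_range_hz = c(110, 200),
                                   channels = 1L))
  b <- generate_lfp(ses, channel_sites = 1:2, seed = 62,
                    ripples = list(n = 3, amp_sd = 6,
                                   dur_range_ms = c(30, 100),
                                   freq_range_hz = c(110, 200),
                                   channels = 1L))
  expect_identical(a$lfp$samples, b$lfp$samples)
  expect_error(generate_lfp(ses, channel_sites = 1:2,
                            ripples = list(n = 3, amp_sd = -1,
                                           dur_range_ms = c(30, 100),
                                           freq_range_hz = c(110, 200),
                                           channels = 1L)),
               "amplitude")
})

test_that("sequence protocols interleave forward and reverse events", {
  lay <- build_layout()
  leds <- c(1L, 33L, 65L, 97L)
  p <- make_sequence_protocol(lay, leds, n_events = 240, seed = 1)
  wins <- event_windows(p)
  expect_equal(as.integer(table(wins$condition)[c("forward", "reverse")]),
               c(120L, 120L))
  fwd <- p[p$event == which(wins$condition == "forward")[1L], ]
  rev_ <- p[p$event == which(wins$condition == "reverse")[1L], ]
  expect_equal(rev_$led[order(rev_$onset_s)],
               rev(fwd$led[order(fwd$onset_s)]))
  expect_warning(p2 <- make_sequence_protocol(lay, leds, n_events = 5),
                 "odd")
  expect_equal(length(unique(p2$event)), 4L)
  # zero stagger: simultaneous pulses are degenerate but legal
  p3 <- make_sequence_protocol(lay, leds, n_events = 2, stagger_ms = 0)
  expect_equal(length(unique(p3$onset_s[p3$event == 1])), 1L)
})
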