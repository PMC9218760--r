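test_that("ripple detector recovers injected events on a quiet background", {
  ses <- generate_units(duration_s = 120, seed = 71,
                        n_per_type = c(pyramidal = 2, narrow_int = 1,
                                       wide_int = 1))
  ses <- generate_lfp(ses, channel_sites = 1:2, seed = 72,
                      ripples = list(n = 20, amp_sd = 6,
                                     dur_range_ms = c(40, 80),
                                     freq_range_hz = c(120, 180),
                                     channels = 1L))
  ev <- detect_ripples(ses$lfp, 1L)
  gt <- ses$ground_truth$ripples
  mid <- (ev$start_s + ev$stop_s) / 2
  hit <- vapply(seq_len(nrow(gt)), function(k)
    any(mid >= gt$start_s[k] & mid <= gt$stop_s[k]), logical(1))
  expect_gte(mean(hit), 0.9)
  expect_true(all(ev$stop_s - ev$start_s >= 0.015))
  expect_true(all(diff(ev$start_s) > 0))
  # events detected on an untouched channel come from noise only
  ev2 <- detect_ripples(ses$lfp, 2L)
  expect_lt(nrow(ev2) / 120, 0.1)
})

test_that("ripple detector rejects invalid bands and respects monotonicity", {
  ses <- generate_units(duration_s = 60, seed = 73,
                        n_per_type = c(pyramidal = 1, narrow_int = 1,
                                       wide_int = 1))
  ses <- generate_lfp(ses, channel_sites = 1L, seed = 74,
                      ripples = list(n = 8, amp_sd = 5,
                                     dur_range_ms = c(40, 80),
                                     freq_range_hz = c(120, 180),
                                     channels = 1L))
  expect_error(detect_ripples(ses$lfp, 1L, band = c(80, 700)), "Nyquist")
  n4 <- nrow(detect_ripples(ses$lfp, 1L, detect_sd = 4))
  n6 <- nrow(detect_ripples(ses$lfp, 1L, detect_sd = 6))
  expect_lte(n6, n4) # raising the threshold never adds events
})

test_that("ripple detection is translation-equivariant", {
  ses <- generate_units(duration_s = 60, seed = 75,
                        n_per_type = c(pyramidal = 1, narrow_int = 1,
                                       wide_int = 1))
  ses <- generate_lfp(ses, channel_sites = 1L, seed = 76,
                      ripples = list(n = 6, amp_sd = 6,
                                     dur_range_ms = c(40, 80),
                                     freq_range_hz = c(120, 180),
                                     channels = 1L))
  lfp <- ses$lfp
  shift_n <- round(2 * lfp$rate_hz) # 2 s circular shift
  lfp2 <- lfp
  lfp2$samples <- lfp$samples[, c((shift_n + 1):ncol(lfp$samples),
                                  1:shift_n), drop = FALSE]
  ev1 <- detect_ripples(lfp, 1L)
  ev2 <- detect_ripples(lfp2, 1L)
  # compare events away from the wrap point
  s1 <- ev1$start_s[ev1$start_s > 2.1 & ev1$start_s < 59.9]
  s2 <- ev2$start_s + 2
  for (s in s1) expect_lt(min(abs(s2 - s)), 0.004)
})

test_that("Morlet spectrogram localizes tones and scales quadratically", {
  rate <- 1250
  tgrid <- seq(0, 20, by = 1 / rate)
  x <- sin(2 * pi * 100 * tgrid)
  lfp <- list(samples = matrix(x, 1), rate_hz = rate)
  events <- c(5, 10, 15)
  sp <- morlet_spectrogram(lfp, events, band = c(50, 150), step_hz = 2)
  expect_equal(length(sp$freq_hz), 51L)
  expect_equal(sp$freq_hz[which.max(rowMeans(sp$power))], 100)
  expect_true(all(sp$power >= 0))
  lfp2 <- list(samples = matrix(2 * x, 1), rate_hz = rate)
  sp2 <- morlet_spectrogram(lfp2, events, band = c(50, 150), step_hz = 2)
  expect_equal(sp2$power, 4 * sp$power, tolerance = 1e-10)
  expect_warning(morlet_spectrogram(lfp, c(5, 19.99)), "skipped")
  expect_error(morlet_spectrogram(lfp, numeric(0)), "event")
})

test_that("CSD annihilates linear profiles and localizes a bump", {
  depth <- seq_len(9)
  prof <- outer(2 * depth + 1, rep(1, 5)) # linear in depth
  expect_equal(max(abs(csd(prof, 20))), 0)
  bump <- matrix(exp(-0.5 * ((depth - 5) / 1)^2), 9, 1)
  cs <- csd(bump, 20)
  expect_equal(which.max(cs[, 1]), 4L) # sink at the bump center (row 5)
  expect_lt(cs[1, 1], 0); expect_lt(cs[7, 1], 0) # flanking sources
  # second difference telescopes to ~0 against interior mass
  expect_lt(abs(sum(cs[, 1])), abs(min(cs[, 1])))
  expect_equal(nrow(csd(prof[1:3, ], 20)), 1L)
  expect_error(csd(prof[1:2, ], 20), "3")
  expect_error(csd(prof, 0), "positive")
})

test_that("evoked band power falls off with shank distance as constructed", {
  lay <- build_layout()
  ses <- generate_units(lay, duration_s = 40, seed = 81,
                        n_per_type = c(pyramidal = 2, narrow_int = 1,
                                       wide_int = 1))
  led <- which(lay$leds$shank == 0L)[20L]
  prot <- make_pulse_protocol(led, n_pulses = 20, dur_ms = 100,
                              period_ms = 1000, start_s = 2, label = "single")
  ses$protocol <- prot
  chans <- vapply(0:3, function(sh)
    which(lay$sites$shank == sh)[30L], integer(1))
  # spreading oscillation (CA3-like drive): power reaches all shanks
  spread <- generate_lfp(ses, channel_sites = chans, seed = 82,
                         ripples = NULL,
                         evoked = list(freq_hz = 140,
                                       amp_sd_by_distance = c(8, 6, 5, 4)))
  # local-only oscillation (CA1-like drive)
  loc <- generate_lfp(ses, channel_sites = chans, seed = 82,
                      ripples = NULL,
                      evoked = list(freq_hz = 140,
                                    amp_sd_by_distance = c(8, 0, 0, 0)))
  ps <- band_power_vs_distance(spread$lfp, prot, lay)
  pl <- band_power_vs_distance(loc$lfp, prot, lay)
  expect_equal(ps$shank_distance, 0:3)
  # remote power under spreading drive exceeds the local-only case
  expect_true(all(ps$power_uv2[2:4] > pl$power_uv2[2:4]))
  # local-only: on-shank power dwarfs the farthest shank
  expect_gt(pl$power_uv2[1], 10 * pl$power_uv2[4])
  empty <- band_power_vs_distance(loc$lfp, prot[0, ], lay)
  expect_equal(nrow(empty), 0L)
})
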