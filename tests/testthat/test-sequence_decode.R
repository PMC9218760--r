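seq_fixture <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- simulate_sequence_session(seed = 61, n_events = 80,
                                         driven_per_shank = 3)
    memo
  }
})

test_that("center-of-mass sequences follow their construction", {
  # one spike at the window midpoint -> COM 0.5; two at 0.2/0.8 -> 0.5
  lay <- build_layout()
  prot <- make_sequence_protocol(lay, c(1L, 33L, 65L, 97L), n_events = 2,
                                 stagger_ms = 0, pulse_ms = 100,
                                 start_s = 1)
  ses <- generate_units(lay, duration_s = 5, seed = 62,
                        n_per_type = c(pyramidal = 2, narrow_int = 1,
                                       wide_int = 1))
  ses$spikes[["1"]] <- c(1.05, 2.02, 2.08)
  ses$spikes[["2"]] <- c(1.02, 2.03)
  sq <- build_sequences(ses, prot, units = 1:2)
  expect_equal(sq$com[sq$event == 1 & sq$unit == 1], 0.5)
  expect_equal(sq$com[sq$event == 2 & sq$unit == 1], 0.5)
  # events with < 2 active units are skipped and logged
  ses$spikes[["2"]] <- numeric(0)
  sq1 <- build_sequences(ses, prot, units = 1:2)
  expect_equal(nrow(sq1), 0L)
  expect_equal(attr(sq1, "skipped"), c(1L, 2L))

  # generator forward events: COM order matches shank order
  fx <- seq_fixture()
  seqs <- build_sequences(fx$session, fx$protocol, units = fx$driven_units)
  e1 <- seqs[seqs$event == seqs$event[seqs$condition == "forward"][1L], ]
  sh <- (e1$unit - 1L) %% 4L # driven unit k sits on shank (k-1) mod 4
  expect_gt(stats::cor(e1$com, sh, method = "spearman"), 0.8)
})

test_that("rank correlation honors its boundary cases", {
  a <- data.frame(unit = 1:5, com = c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_equal(rank_correlation(a, a), 1)
  b <- a; b$com <- rev(a$com)
  expect_equal(rank_correlation(a, b), -1)
  expect_true(is.na(rank_correlation(a[1:2, ], a[1:2, ])))
  # random independent orders average to ~0
  set.seed(63)
  rs <- replicate(2000, {
    x <- data.frame(unit = 1:6, com = runif(6))
    y <- data.frame(unit = 1:6, com = runif(6))
    rank_correlation(x, y)
  })
  expect_lt(abs(mean(rs)), 0.02)
  expect_true(all(abs(rs) <= 1 + 1e-12))
})

test_that("within-condition correlations beat between-condition ones", {
  fx <- seq_fixture()
  seqs <- build_sequences(fx$session, fx$protocol, units = fx$driven_units)
  sht <- sequence_shuffle_test(seqs, n_shuffle = 200, seed = 64)
  expect_gt(mean(sht$r_within), mean(sht$r_between))
  expect_lt(sht$p_ranksum, 0.001)
  expect_lt(sht$p_shuffle, 0.01)
  # randomized condition labels: effect disappears
  seqs2 <- seqs
  set.seed(65)
  ev <- unique(seqs2$event)
  newlab <- sample(c("forward", "reverse"), length(ev), replace = TRUE)
  seqs2$condition <- newlab[match(seqs2$event, ev)]
  sht2 <- sequence_shuffle_test(seqs2, n_shuffle = 100, seed = 66)
  expect_lt(abs(sht2$diff_obs), 0.2)
  expect_gt(sht2$p_ranksum, 0.001)
  expect_error(sequence_shuffle_test(seqs[seqs$condition == "forward", ]),
               "both conditions")
})

test_that("sequence separation shrinks monotonically with spike jitter", {
  fx <- seq_fixture()
  diffs <- vapply(c(0, 0.03, 0.09), function(jit) {
    ses <- fx$session
    if (jit > 0) {
      set.seed(67)
      ses$spikes <- lapply(ses$spikes, function(st)
        sort(st + rnorm(length(st), 0, jit)))
    }
    seqs <- build_sequences(ses, fx$protocol, units = fx$driven_units)
    sht <- sequence_shuffle_test(seqs, n_shuffle = 0, seed = 68)
    sht$diff_obs
  }, numeric(1))
  expect_true(all(diff(diffs) < 0))
})

test_that("the decoder separates conditions and is calibrated at chance", {
  fx <- seq_fixture()
  dec <- svm_decode(fx$session, fx$protocol, units = fx$driven_units,
                    window_ms = 120, n_label_shuffles = 300, seed = 69)
  expect_gte(dec$accuracy, 0.95)
  expect_lte(dec$p_value, 1 / 300)
  expect_lt(abs(mean(dec$shuffle_acc) - 0.5), 0.05) # chance under shuffles
  expect_equal(dec$n_train + dec$n_test, 80L)
  # features: 12 bins of 10 ms per unit over the 120 ms window
  expect_equal(dec$n_features, length(fx$driven_units) * 12L)
})

test_that("decoding accuracy is non-decreasing in the stagger", {
  accs <- vapply(c(6, 30), function(stg) {
    fx <- simulate_sequence_session(seed = 70, n_events = 60,
                                    driven_per_shank = 2, stagger_ms = stg)
    svm_decode(fx$session, fx$protocol, units = fx$driven_units,
               window_ms = 120, n_label_shuffles = 0, seed = 71)$accuracy
  }, numeric(1))
  expect_gte(accs[2], accs[1])
})
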