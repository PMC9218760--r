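test_that("CCG counts are exact on constructed trains", {
  set.seed(41)
  a <- sort(runif(500, 0, 100))
  b <- a + 0.002
  cc <- compute_ccg(a, b)
  expect_equal(length(cc$count), 11L)
  expect_gte(cc$count[cc$lag_ms == 2], 500) # all mass in the +2 ms bin
  expect_equal(sum(cc$count[cc$lag_ms != 2]),
               sum(cc$count) - cc$count[cc$lag_ms == 2])
  # time-reversal symmetry holds exactly
  cc2 <- compute_ccg(b, a)
  expect_identical(cc$count, rev(cc2$count))
  expect_warning(ccw <- compute_ccg(numeric(0), a), "empty")
  expect_equal(sum(ccw$count), 0)
})

test_that("independent Poisson trains give flat CCGs at the product rate", {
  set.seed(42)
  a <- poisson_train(10, 600); b <- poisson_train(10, 600)
  cc <- compute_ccg(a, b)
  lam <- length(a) * length(b) / 600 * 0.001
  expect_true(all(abs(cc$count - lam) < 4 * sqrt(lam)))
})

test_that("convolution null brackets flat CCGs and flags injected peaks", {
  counts <- rep(100, 101)
  nul <- convolution_null(counts)
  expect_equal(nul$expected, rep(100, 101), tolerance = 1e-10)
  expect_true(all(counts <= nul$upper))
  expect_error(convolution_null(rep(10, 5), kernel_sd_ms = 50), "wider")
  # injected synapse at 2 ms
  set.seed(43)
  pre <- poisson_train(5, 600); post <- poisson_train(10, 600)
  hit <- runif(length(pre)) < 0.2
  post2 <- sort(c(post, pre[hit] + 0.002 + rnorm(sum(hit), 0, 2e-4)))
  tst <- ccg_pair_test(pre, post2)
  expect_true(tst$significant)
  expect_equal(tst$peak_ms, 2)
  expect_lt(abs(tst$stp - 0.2), 0.05)
})

test_that("type-I error of the pair test matches alpha", {
  set.seed(44)
  fp <- vapply(seq_len(500), function(i) {
    ccg_pair_test(poisson_train(5, 600),
                  poisson_train(10, 600))$significant
  }, logical(1))
  # alpha = 0.001: P(X >= 4 | n = 500) < 1e-4 even without Poisson
  # discreteness, which only makes the test more conservative
  expect_lte(sum(fp), 3)
})

test_that("STP recovery is unbiased within +/-0.05 for p in {0.05,0.1,0.2}", {
  set.seed(45)
  for (p in c(0.05, 0.1, 0.2)) {
    stps <- replicate(4, {
      pre <- poisson_train(5, 600); post <- poisson_train(10, 600)
      hit <- runif(length(pre)) < p
      post2 <- sort(c(post, pre[hit] + 0.0015 + rnorm(sum(hit), 0, 2e-4)))
      tst <- ccg_pair_test(pre, post2)
      expect_true(tst$significant)
      tst$stp
    })
    expect_lt(abs(mean(stps) - p), 0.05)
  }
})

test_that("session-level detection recovers injected synapses", {
  set.seed(46)
  ses <- generate_units(duration_s = 600, seed = 46,
                        n_per_type = c(pyramidal = 4, narrow_int = 3,
                                       wide_int = 1),
                        rate_median_hz = c(pyramidal = 5, narrow_int = 10,
                                           wide_int = 6))
  syn <- data.frame(pre = c(1L, 2L), post = c(5L, 6L), p = c(0.15, 0.2),
                    latency_ms = c(1.5, 2.2), jitter_ms = 0.2)
  ses <- inject_monosynaptic(ses, syn, seed = 47)
  ed <- detect_monosynaptic(ses)
  key <- paste(ed$pre, ed$post)
  expect_true(all(paste(syn$pre, syn$post) %in% key))
  stp_rec <- ed$stp[match(paste(syn$pre, syn$post), key)]
  expect_true(all(abs(stp_rec - syn$p) < 0.05))
  expect_true(all(ed$peak_ms >= 0.5 & ed$peak_ms <= 3.5))
})

test_that("distance decay recovers a constructed exponential fall-off", {
  set.seed(48)
  n <- 60
  d <- runif(n, 20, 400)
  stp <- 0.3 * exp(-d / 150) * exp(rnorm(n, 0, 0.2))
  pos <- data.frame(unit_id = seq_len(2 * n),
                    x_um = c(rep(0, n), d), y_um = 0)
  edges <- data.frame(pre = seq_len(n), post = n + seq_len(n), stp = stp)
  dd <- distance_decay(edges, pos, n_perm = 2000, seed = 49)
  expect_lt(dd$r, 0)
  expect_lt(dd$p_value, 0.01)
  # distance-independent STP: r near zero
  edges2 <- edges; edges2$stp <- sample(stp)
  dd2 <- distance_decay(edges2, pos, n_perm = 500, seed = 50)
  expect_lt(abs(dd2$r), 0.35)
  expect_error(distance_decay(edges[1:2, ], pos), "10 edges")
})

test_that("motif summary counts stars and per-class means", {
  star <- data.frame(pre = rep(1L, 5), post = 2:6)
  ms <- motif_summary(star)
  expect_equal(nrow(ms$divergence), 1L)
  expect_equal(ms$divergence$size, 5L)
  expect_equal(nrow(ms$convergence), 0L)
  empty <- motif_summary(star[0, ])
  expect_equal(nrow(empty$per_cell), 0L)
  # per-class means recovered within one connection
  set.seed(51)
  cls <- data.frame(unit_id = 1:40,
                    class = rep(c("PV", "SOM"), each = 20))
  edges <- do.call(rbind, lapply(1:40, function(u) {
    k <- rpois(1, if (u <= 20) 3.5 else 2)
    if (k == 0) return(NULL)
    data.frame(pre = 100L + seq_len(k) + u * 50L, post = u)
  }))
  ms2 <- motif_summary(edges, cls)
  pv <- ms2$per_class[ms2$per_class$class == "PV", ]
  som <- ms2$per_class[ms2$per_class$class == "SOM", ]
  expect_lt(abs(pv$mean - 3.5), 1)
  expect_lt(abs(som$mean - 2), 1)
})
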