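test_that("trough-to-peak latency is read off the peak-site waveform", {
  rate <- 20000
  tt <- seq(-1.6e-3, 2.4e-3, by = 1 / rate)
  w <- -exp(-0.5 * (tt / 1e-4)^2) +
    0.4 * exp(-0.5 * ((tt - 3e-4) / 1.2e-4)^2)
  wf <- list(sites = 1L, mean_uv = matrix(200 * w, 1), peak_site = 1L,
             t_ms = tt * 1000)
  set.seed(1)
  f <- extract_features(wf, sort(runif(200, 0, 60)), rate)
  expect_equal(f$tp_ms, 0.3, tolerance = 0.051) # one-sample quantization
  expect_error(extract_features(wf, runif(10, 0, 60), rate), "few spikes")
})

test_that("burst index of a Poisson train matches the closed form", {
  set.seed(2)
  st <- poisson_train(5, 2000)
  bi <- mean(diff(st) < 0.009)
  expect_equal(bi, 1 - exp(-5 * 0.009), tolerance = 0.15)
})

test_that("ACG fit recovers a known rise constant within 20%", {
  # lag range long enough to contain the slow-rise plateau
  t <- seq(0.25, 99.75, by = 0.5)
  for (tr_true in c(2, 8, 15)) {
    set.seed(tr_true)
    y <- 5 + 3 * exp(-t / 40) - 8 * exp(-t / tr_true) +
      rnorm(length(t), 0, 0.05)
    fit <- fit_acg(data.frame(lag_ms = t, rate_hz = pmax(y, 0)))
    expect_true(fit$converged)
    expect_lt(abs(fit$tau_rise_ms - tr_true) / tr_true, 0.2)
  }
})

test_that("classification rules are applied verbatim", {
  expect_equal(classify_cell(0.30, 2), "narrow_int")
  expect_equal(classify_cell(0.60, 8), "wide_int")
  expect_equal(classify_cell(0.60, 3), "pyramidal")
  expect_equal(classify_cell(0.425, 8), "pyramidal") # boundary -> pyramidal
  expect_equal(classify_cell(0.60, NA), "pyramidal") # failed fit fallback
  # exactly one label each
  labs <- classify_cell(c(0.3, 0.5, 0.7), c(1, 10, 2))
  expect_equal(length(labs), 3L)
  expect_true(all(labs %in% c("narrow_int", "wide_int", "pyramidal")))
})

test_that("default synthetic sessions classify with >= 90% agreement", {
  ses <- default_session()
  cls <- classify_units(ses)
  truth <- ses$units$cell_type[match(cls$unit_id, ses$units$unit_id)]
  expect_gte(mean(cls$label == truth), 0.9)
  expect_gte(nrow(cls), 90) # almost all units pass the spike floor
})

test_that("soma localization matches its oracle cases and ground truth", {
  lay <- build_layout()
  wf1 <- list(sites = c(1L, 2L),
              mean_uv = rbind(c(-100, 50), c(0, 0)), peak_site = 1L)
  expect_error(localize_soma(list(sites = integer(),
                                  mean_uv = matrix(0, 0, 0)), lay),
               "undefined")
  loc <- localize_soma(list(sites = 1L, mean_uv = matrix(c(-100, 50), 1),
                            peak_site = 1L), lay)
  expect_equal(loc, c(lay$sites$x_um[1], lay$sites$y_um[1]))
  # equal amplitudes on two sites: midpoint
  wf2 <- list(sites = c(1L, 3L),
              mean_uv = rbind(c(-100, 50), c(-100, 50)), peak_site = 1L)
  loc2 <- localize_soma(wf2, lay)
  expect_equal(loc2[1], mean(lay$sites$x_um[c(1, 3)]))
  expect_equal(loc2[2], mean(lay$sites$y_um[c(1, 3)]))
  # generator ground truth: median error below 20 um over >= 50 units
  ses <- default_session()
  errs <- vapply(seq_len(nrow(ses$units)), function(i) {
    wf <- ses$waveforms[[as.character(i)]]
    if (!length(wf$sites)) return(NA_real_)
    p <- localize_soma(wf, ses$layout)
    sqrt((p[1] - ses$units$x_um[i])^2 + (p[2] - ses$units$y_um[i])^2)
  }, numeric(1))
  expect_gte(sum(!is.na(errs)), 50)
  expect_lt(median(errs, na.rm = TRUE), 20)
})
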