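test_that("fluence solver matches the point-source Green function to 5%", {
  fl <- light_fluence(geometry = "infinite")
  dist <- sqrt(outer(fl$r_um^2, fl$z_um^2, "+"))
  sel <- which(dist >= 20 & dist <= 200, arr.ind = TRUE)
  ana <- fluence_point_source(dist[sel], reflective = FALSE)
  expect_lt(max(abs(fl$phi[sel] / ana - 1)), 0.05)
})

test_that("fluence field is linear in power and non-negative", {
  f1 <- light_fluence(P_uW = 7.03, extent_um = 500)
  f2 <- light_fluence(P_uW = 14.06, extent_um = 500)
  expect_equal(f2$phi, 2 * f1$phi, tolerance = 1e-12)
  expect_true(all(f1$phi >= 0))
  expect_warning(light_fluence(h0_um = 12, extent_um = 400), "coarser")
})

test_that("illumination volume stays far inside a shank pitch", {
  r <- illumination_radius() # 0.1 mW/mm^2 threshold at 7.03 uW
  expect_lt(r, 200)
  expect_gt(r, 40)
  # neighboring-shank fluence is an order below threshold
  expect_lt(fluence_point_source(300), 0.05)
  fh <- light_fluence(geometry = "half", extent_um = 800)
  dist <- sqrt(outer(fh$r_um^2, fh$z_um^2, "+"))
  expect_true(all(dist[fh$phi > 0.1] < 200))
})

test_that("fluence solution converges under grid refinement", {
  co <- light_fluence(extent_um = 600, h0_um = 3, growth = 1.2)
  fi <- light_fluence(extent_um = 600, h0_um = 1.5, growth = 1.1)
  # compare at matched probe-scale points via the interpolating accessor
  pts <- cbind(r = c(30, 60, 120), z = c(10, 25, 40))
  v1 <- co$at(pts[, 1], pts[, 2]); v2 <- fi$at(pts[, 1], pts[, 2])
  expect_lt(max(abs(v1 / v2 - 1)), 0.02)
})

test_that("bioheat solution obeys the conduction oracle and positivity", {
  p <- bioheat_params(domain_um = 3000, z_source_um = 2500,
                      shank_length_um = 2600,
                      width_profile_um = cbind(z = c(0, 2500, 2600),
                                               w = c(140, 50, 20)))
  # no shank, no perfusion: pure conduction against P/(4 pi k r)
  bo <- bioheat_steady(p, include_shank = FALSE, perfusion = FALSE)
  ix <- which.min(abs(bo$x_um)); iz <- which.min(abs(bo$z_um - 2500))
  iy <- which(bo$y_um > 35 & bo$y_um < 400)
  r <- (bo$y_um[iy] - 30.25) * 1e-6
  ana <- p$q_source_W / (4 * pi * p$k_tissue * r)
  num <- bo$temperature[ix, iy, iz]
  # mid-range: far enough from the source cell, well short of the
  # isothermal boundary whose image term grows linearly in r
  sel <- r > 30e-6 & r < 100e-6
  expect_lt(max(abs(num[sel] / ana[sel] - 1)), 0.1)
  expect_true(all(bo$temperature >= -1e-12))
  # zero power: identically zero
  p0 <- p; p0$q_source_W <- 0
  b0 <- bioheat_steady(p0, include_shank = FALSE, perfusion = FALSE)
  expect_equal(max(abs(b0$temperature)), 0)
  # linearity in power
  p2 <- p; p2$q_source_W <- 2 * p$q_source_W
  b1 <- bioheat_steady(p)
  b2 <- bioheat_steady(p2)
  expect_equal(b2$temperature, 2 * b1$temperature, tolerance = 1e-10)
})

test_that("bioheat solution converges under grid refinement", {
  p <- bioheat_params(domain_um = 1500, z_source_um = 1200,
                      shank_length_um = 1300,
                      width_profile_um = cbind(z = c(0, 1200, 1300),
                                               w = c(140, 50, 20)))
  c1 <- bioheat_steady(p, refine = 1)
  c2 <- bioheat_steady(p, refine = 1.6)
  expect_lt(abs(c1$max_tissue_dT / c2$max_tissue_dT - 1), 0.02)
})

test_that("maximum tissue heating at 300 uW stays within the safe bound", {
  bh <- bioheat_steady()
  expect_gt(bh$max_tissue_dT, 0)
  expect_lte(bh$max_tissue_dT, 0.6)
  # the hottest tissue sits next to the source
  idx <- which(bh$temperature == bh$max_dT, arr.ind = TRUE)[1, ]
  expect_lt(abs(bh$z_um[idx[3]] - bh$params$z_source_um), 50)
})

test_that("bioheat parameter validation rejects unphysical inputs", {
  expect_error(bioheat_params(k_tissue = -1), "non-negative")
  expect_error(bioheat_params(source_dims_um = c(0, 17, 0.5)), "positive")
  expect_error(bioheat_params(z_source_um = 8000), "inside")
})

test_that("T-network meets the signal-integrity bounds with defaults", {
  tn <- tnetwork_response()
  expect_lt(max(abs(tn$il_db)), 1)    # insertion loss below 1 dB
  expect_lt(max(tn$fext_db), -88)     # crosstalk below -88 dB
  # capacitive coupling blocks DC: crosstalk falls as f -> 0
  expect_lt(tn$fext_db[1], tn$fext_db[nrow(tn)])
  # zero coupling: reported at the floor
  tn0 <- tnetwork_response(tnetwork_params(C_coupling_total = 0))
  expect_true(all(tn0$fext_db == -300))
  expect_error(tnetwork_params(n_cells = 0), "at least one")
})

test_that("crosstalk is monotone in the coupling capacitance", {
  fe <- vapply(c(0.1, 0.35, 1) * 1e-15, function(cc) {
    tn <- tnetwork_response(tnetwork_params(C_coupling_total = cc),
                            freqs_hz = 1000)
    tn$fext_db
  }, numeric(1))
  expect_true(all(diff(fe) > 0))
})
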