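# Reduced device-physics models: photon diffusion in tissue (fluence),
# steady-state Pennes bioheat with an implanted silicon shank, and a lumped
# T-network ladder for interconnect insertion loss and crosstalk.

#' Optical tissue parameters
#'
#' Absorption and reduced scattering coefficients of grey matter at the
#' micro-LED emission wavelength (~470 nm), plus the derived diffusion
#' constant `D = 1/(3 (mu_a + mu_s'))` and effective attenuation
#' `mu_eff = sqrt(3 mu_a (mu_a + mu_s'))`.
#'
#' @param mu_a_cm absorption coefficient (cm^-1, default 4.47).
#' @param mu_sp_cm reduced scattering coefficient (cm^-1, default 50.5).
#' @return list with `mu_a`, `mu_sp`, `mu_eff` (m^-1) and `D` (m).
#' @export
optical_params <- function(mu_a_cm = 4.47, mu_sp_cm = 50.5) {
  if (mu_a_cm <= 0 || mu_sp_cm <= 0)
    stop("optical coefficients must be positive")
  mu_a <- mu_a_cm * 100
  mu_sp <- mu_sp_cm * 100
  list(mu_a = mu_a, mu_sp = mu_sp,
       D = 1 / (3 * (mu_a + mu_sp)),
       mu_eff = sqrt(3 * mu_a * (mu_a + mu_sp)))
}

#' Closed-form fluence rate of a point source in turbid tissue
#'
#' Diffusion-approximation Green's function
#' `Phi(r) = P exp(-mu_eff r) / (4 pi D r)`, doubled when the source sits on
#' the reflective probe surface (method of images). This is the light model
#' used by the synthetic-session generator and the analytic oracle for the
#' grid solver.
#'
#' @param r_um distance from the source (µm); values below 0.5 µm are clamped.
#' @param P_uW source radiant flux (µW; default 7.03, the output of a
#'   micro-LED driven at its 75 µA safe maximum).
#' @param params see [optical_params()].
#' @param reflective logical; source mounted on an ideal reflector (default
#'   TRUE).
#' @return fluence rate in mW mm^-2.
#' @export
fluence_point_source <- function(r_um, P_uW = 7.03,
                                 params = optical_params(),
                                 reflective = TRUE) {
  r <- pmax(r_um, 0.5) * 1e-6
  P <- P_uW * 1e-6
  fac <- if (reflective) 2 else 1
  (fac * P * exp(-params$mu_eff * r) / (4 * pi * params$D * r)) / 1000
}

#' Radius of the effective illumination volume
#'
#' Distance at which the closed-form fluence falls to `threshold`
#' (0.1 mW mm^-2 by default, the effective channelrhodopsin activation
#' threshold used for illumination-volume bounds).
#'
#' @inheritParams fluence_point_source
#' @param threshold fluence threshold (mW mm^-2).
#' @return radius in µm.
#' @export
illumination_radius <- function(P_uW = 7.03, params = optical_params(),
                                threshold = 0.1, reflective = TRUE) {
  f <- function(r) fluence_point_source(r, P_uW, params, reflective) - threshold
  if (f(1) < 0) return(0)
  stats::uniroot(f, c(1, 5000), tol = 1e-6)$root
}

#' Steady-state light fluence field (diffusion approximation)
#'
#' Solves `-div(D grad Phi) + mu_a Phi = S` on an axisymmetric (r, z) grid
#' with a point-like source on the axis. Geometry modes: `"half"` places the
#' source on an ideal reflective plane (the probe surface; zero-flux at
#' z = 0) with absorbing far boundaries, `"infinite"` embeds it in a full
#' medium with absorbing boundaries all round (the configuration matched by
#' the analytic Green's function).
#'
#' @param params see [optical_params()].
#' @param P_uW source radiant flux (µW).
#' @param geometry `"half"` or `"infinite"`.
#' @param extent_um domain extent (µm): radial and axial half-size.
#' @param h0_um finest cell width near the source (µm); a warning is issued
#'   above 10 µm.
#' @param growth geometric grid growth factor.
#' @param hmax_um largest allowed cell width (µm).
#' @return list with class `fluence_field`: `phi` (nr x nz, mW mm^-2),
#'   `r_um`, `z_um` cell centers (z measured from the source plane), and an
#'   interpolating `at(r_um, z_um)` accessor.
#' @export
light_fluence <- function(params = optical_params(), P_uW = 7.03,
                          geometry = c("half", "infinite"),
                          extent_um = 1200, h0_um = 1.5,
                          growth = 1.15, hmax_um = 40) {
  geometry <- match.arg(geometry)
  if (h0_um > 10)
    warning("grid coarser than 10 um near the source; fluence will be inaccurate")
  um <- 1e-6
  wfine <- rep(h0_um, 20)
  wr <- c(wfine, grow_widths(extent_um - sum(wfine), h0_um * growth,
                             growth, hmax_um))
  re <- c(0, cumsum(wr)) * um
  wz <- c(rev(wfine), grow_widths(extent_um - sum(wfine),
                                  h0_um * growth, growth, hmax_um))
  if (geometry == "half") {
    ze <- c(0, cumsum(c(wfine, grow_widths(extent_um - sum(wfine),
                                           h0_um * growth, growth,
                                           hmax_um)))) * um
    z0 <- 0
    neumann <- "zlo"
  } else {
    ze <- c(-rev(cumsum(wz)), 0,
            cumsum(c(wfine, grow_widths(extent_um - sum(wfine),
                                        h0_um * growth, growth,
                                        hmax_um)))) * um
    z0 <- 0
    neumann <- character(0)
  }
  nr <- length(re) - 1L; nz <- length(ze) - 1L
  q <- array(0, dim = c(nr, nz))
  iz0 <- findInterval(z0, ze, rightmost.closed = TRUE)
  if (geometry == "half") iz0 <- 1L
  q[1L, iz0] <- P_uW * 1e-6
  phi <- fv_solve_axisym(re, ze, params$D, params$mu_a, q, neumann = neumann)
  rc <- (re[-1L] + re[-length(re)]) / 2 / um
  zc <- (ze[-1L] + ze[-length(ze)]) / 2 / um
  zsrc <- (ze[iz0] + ze[iz0 + 1L]) / 2 / um
  phi_mw <- phi / 1000
  at <- function(r_um, z_um) {
    # bilinear interpolation on cell centers, clamped at the grid edge
    interp1 <- function(q, centers) {
      i0 <- pmax(1L, pmin(length(centers) - 1L, findInterval(q, centers)))
      w <- (q - centers[i0]) / (centers[i0 + 1L] - centers[i0])
      list(i = i0, w = pmax(0, pmin(1, w)))
    }
    gr <- interp1(r_um, rc)
    gz <- interp1(z_um + zsrc, zc)
    phi_mw[cbind(gr$i, gz$i)] * (1 - gr$w) * (1 - gz$w) +
      phi_mw[cbind(gr$i + 1L, gz$i)] * gr$w * (1 - gz$w) +
      phi_mw[cbind(gr$i, gz$i + 1L)] * (1 - gr$w) * gz$w +
      phi_mw[cbind(gr$i + 1L, gz$i + 1L)] * gr$w * gz$w
  }
  structure(list(phi = phi_mw, r_um = rc, z_um = zc - zsrc,
                 P_uW = P_uW, geometry = geometry, at = at),
            class = "fluence_field")
}

#' Bioheat model parameters
#'
#' Literature thermal properties of perfused brain tissue, silicon and the
#' oxide passivation, the source power and geometry, and the shank width
#' taper. Defaults: 300 µW dissipated in an 8 x 17 x 0.5 µm volume at the
#' lowermost LED of a 6-mm, 30-µm-thick silicon shank inside a 7-mm tissue
#' cube.
#'
#' @param k_tissue,k_si,k_oxide thermal conductivities (W m^-1 K^-1).
#' @param perf_coeff volumetric perfusion coefficient
#'   `omega rho_blood c_blood` (W m^-3 K^-1; default 0.008 s^-1 x
#'   1050 kg m^-3 x 3600 J kg^-1 K^-1).
#' @param q_source_W dissipated power (W).
#' @param source_dims_um source box (width x length x height, µm).
#' @param z_source_um depth of the lowermost LED below the brain surface (µm).
#' @param shank_thickness_um,shank_length_um shank cross-section and length.
#' @param oxide_thickness_um oxide cap on the shank top surface (µm).
#' @param width_profile_um 2-column matrix (depth µm, width µm) describing
#'   the shank width taper; linearly interpolated.
#' @param domain_um tissue cube edge length (µm).
#' @return list of parameters for [bioheat_steady()].
#' @export
bioheat_params <- function(k_tissue = 0.51, k_si = 150, k_oxide = 1.4,
                           perf_coeff = 0.008 * 1050 * 3600,
                           q_source_W = 300e-6,
                           source_dims_um = c(8, 17, 0.5),
                           z_source_um = 5850,
                           shank_thickness_um = 30,
                           shank_length_um = 6000,
                           oxide_thickness_um = 1,
                           width_profile_um = cbind(
                             z = c(0, 4610, 5850, 6000),
                             w = c(250, 140, 50, 20)
                           ),
                           domain_um = 7000) {
  p <- as.list(environment())
  if (any(unlist(p[c("k_tissue", "k_si", "k_oxide", "q_source_W")]) < 0) ||
      p$perf_coeff < 0)
    stop("physical parameters must be non-negative")
  if (any(source_dims_um <= 0)) stop("source volume must be positive")
  if (z_source_um > domain_um || z_source_um > shank_length_um)
    stop("source must lie on the implanted shank inside the domain")
  p
}

#' Steady-state Pennes bioheat solution
#'
#' Finite-volume solution of
#' `-div(k grad T) + omega rho_b c_b T = q` for the temperature rise above
#' baseline in a tissue cube containing the implanted silicon shank. The
#' heat source is embedded at the silicon top surface (the LED stack has
#' silicon-like conductivity); the oxide cap elsewhere on the top surface is
#' an extra series face resistance. The tissue top surface (z = 0, where the
#' shank enters) is insulating, all other outer faces are isothermal at the
#' baseline temperature.
#'
#' @param params see [bioheat_params()].
#' @param include_shank include the silicon inclusion (FALSE gives a
#'   homogeneous-tissue conduction problem, used against the `P/(4 pi k r)`
#'   closed form).
#' @param perfusion include the blood-perfusion sink term.
#' @param refine grid refinement factor (>1 shrinks all cell widths).
#' @return list of class `bioheat_field`: `max_tissue_dT` (deg C, maximum
#'   over tissue cells), `max_dT` (deg C, global), `temperature`
#'   (nx x ny x nz array, deg C), cell centers `x_um`, `y_um`, `z_um`
#'   (x lateral, y normal to the shank plane with the shank at y in
#'   [0, thickness], z depth), and `tissue_mask`.
#' @export
bioheat_steady <- function(params = bioheat_params(),
                           include_shank = TRUE, perfusion = TRUE,
                           refine = 1) {
  um <- 1e-6
  p <- params
  half <- p$domain_um / 2
  g <- 1.4^(1 / refine)
  h_src <- c(2, 0.5, 4) / refine       # finest widths in x, y, z
  hmax <- 350 / refine

  sx <- p$source_dims_um[1L] / 2
  xfine <- rep(h_src[1L], ceiling(sx / h_src[1L]) + 2L)
  wx <- c(xfine, grow_widths(half - sum(xfine), h_src[1L] * g, g, hmax))
  xe <- c(-rev(cumsum(wx)), 0, cumsum(wx)) * um

  th <- p$shank_thickness_um
  # y: tissue below shank | shank (thin subsurface cell at the top) |
  #    source layer | tissue above
  y_below <- grow_widths(half, 6 / refine, g, hmax)
  y_shank <- rev(grow_widths(th, 1 / refine, 1.8^(1 / refine), 12 / refine))
  y_src <- rep(p$source_dims_um[3L],
               max(1L, round(refine)))
  y_src <- rep(p$source_dims_um[3L] / length(y_src), length(y_src))
  y_above <- grow_widths(half - th - p$source_dims_um[3L],
                         1 / refine, 1.5^(1 / refine), hmax)
  ye <- c(-rev(cumsum(y_below)), 0, cumsum(c(y_shank, y_src, y_above))) * um

  zl <- p$z_source_um; sz <- p$source_dims_um[2L] / 2
  zfine <- rep(h_src[3L], 2L * ceiling((sz + 4) / h_src[3L]))
  z0fine <- zl - sum(zfine) / 2
  z_up <- rev(grow_widths(z0fine, h_src[3L] * g, g, hmax))
  z_mid <- grow_widths(p$shank_length_um - (z0fine + sum(zfine)),
                       h_src[3L] * g, g, hmax)
  z_dn <- grow_widths(p$domain_um - p$shank_length_um, 15 / refine, g, hmax)
  ze <- c(0, cumsum(c(z_up, zfine, z_mid, z_dn))) * um

  nx <- length(xe) - 1L; ny <- length(ye) - 1L; nz <- length(ze) - 1L
  xc <- (xe[-1L] + xe[-length(xe)]) / 2 / um
  yc <- (ye[-1L] + ye[-length(ye)]) / 2 / um
  zc <- (ze[-1L] + ze[-length(ze)]) / 2 / um

  karr <- array(p$k_tissue, dim = c(nx, ny, nz))
  width_at <- stats::approxfun(p$width_profile_um[, 1L],
                               p$width_profile_um[, 2L], rule = 2)
  if (include_shank) {
    in_y <- yc >= 0 & yc <= th
    in_z <- zc >= 0 & zc <= p$shank_length_um
    for (iz in which(in_z)) {
      wz <- width_at(zc[iz]) / 2
      in_x <- abs(xc) <= wz
      karr[in_x, in_y, iz] <- p$k_si
    }
  }

  # source box: overlap-weighted deposition just above the silicon surface
  ox <- edge_overlap(xe / um, -sx, sx)
  oy <- edge_overlap(ye / um, th, th + p$source_dims_um[3L])
  oz <- edge_overlap(ze / um, zl - sz, zl + sz)
  wsrc <- outer(ox, outer(oy, oz))
  qarr <- array(p$q_source_W * wsrc / sum(wsrc), dim = c(nx, ny, nz))
  src_mask <- wsrc > 0
  if (include_shank) karr[src_mask] <- p$k_si # LED stack ~ silicon

  carr <- array(if (perfusion) p$perf_coeff else 0, dim = c(nx, ny, nz))
  if (include_shank) carr[karr == p$k_si] <- 0

  face_res_y <- NULL
  if (include_shank && p$oxide_thickness_um > 0) {
    face_res_y <- array(0, dim = c(nx, ny - 1L, nz))
    iy_top <- max(which(yc <= th))       # topmost shank cell layer
    if (iy_top < ny) {
      si_below <- karr[, iy_top, ] == p$k_si
      src_above <- src_mask[, iy_top + 1L, ]
      face_res_y[, iy_top, ][si_below & !src_above] <-
        p$oxide_thickness_um * um / p$k_oxide
    }
  }

  temp <- fv_solve_3d(xe, ye, ze, karr, carr, qarr,
                      neumann = "zlo", face_res_y = face_res_y)
  tissue <- karr == p$k_tissue & !src_mask
  structure(list(
    temperature = temp,
    x_um = xc, y_um = yc, z_um = zc,
    tissue_mask = tissue,
    max_tissue_dT = max(temp[tissue]),
    max_dT = max(temp),
    n_cells = nx * ny * nz,
    params = p
  ), class = "bioheat_field")
}

#' @export
print.bioheat_field <- function(x, ...) {
  cat(sprintf(
    "bioheat_field: %d cells, max tissue dT = %.3f C (global %.3f C)\n",
    x$n_cells, x$max_tissue_dT, x$max_dT
  ))
  invisible(x)
}

#' Interconnect T-network parameters
#'
#' Lumped element values for the two-line RC ladder used to estimate
#' insertion loss and far-end crosstalk of the recording interconnects.
#' Series resistance follows from the 0.7 µm x 100 nm gold trace
#' cross-section over 6 mm; the source impedance is the median 1-kHz
#' electrode impedance; shunt and line-to-line coupling capacitances are
#' placeholder estimates pending measured values, chosen to be consistent
#' with sub-dB loss and below -88 dB crosstalk.
#'
#' @param n_cells ladder unit cells.
#' @param R_series_total total trace resistance (Ohm).
#' @param R_electrode electrode (source) impedance (Ohm).
#' @param C_shunt_total total trace-to-tissue capacitance (F).
#' @param C_coupling_total total line-to-line coupling capacitance (F).
#' @param R_in,C_in recording-chain input resistance (Ohm) and capacitance
#'   (F).
#' @return parameter list for [tnetwork_response()].
#' @export
tnetwork_params <- function(n_cells = 32L,
                            R_series_total = 0.35e6,
                            R_electrode = 1.4e6,
                            C_shunt_total = 0.15e-12,
                            C_coupling_total = 0.35e-15,
                            R_in = 1.3e9, C_in = 0.5e-12) {
  if (n_cells < 1L) stop("ladder must have at least one cell")
  if (R_series_total < 0 || R_electrode < 0 || R_in <= 0)
    stop("resistances must be non-negative")
  if (C_shunt_total < 0 || C_coupling_total < 0 || C_in < 0)
    stop("capacitances must be non-negative")
  as.list(environment())
}

#' Frequency response of the two-line recording interconnect ladder
#'
#' Nodal analysis of two coupled RC ladders: line 1 is driven by a unit
#' source behind the electrode impedance, line 2's electrode end is
#' grounded through its own electrode impedance. Insertion loss is
#' `20 log10 |Vo1|` and far-end crosstalk `20 log10 |Vo2|` at the
#' recording-chain input nodes.
#'
#' @param params see [tnetwork_params()].
#' @param freqs_hz frequencies (Hz); default log-spaced 0.1 Hz to 10 kHz.
#' @param floor_db value reported when the coupled voltage underflows
#'   (e.g. zero coupling capacitance).
#' @return data frame with `freq_hz`, `il_db`, `fext_db`.
#' @export
tnetwork_response <- function(params = tnetwork_params(),
                              freqs_hz = 10^seq(-1, 4, length.out = 61),
                              floor_db = -300) {
  p <- params
  n <- as.integer(p$n_cells)
  Rc <- p$R_series_total / n
  Cs <- p$C_shunt_total / n
  Cc <- p$C_coupling_total / n
  out <- data.frame(freq_hz = freqs_hz, il_db = NA_real_, fext_db = NA_real_)
  for (fi in seq_along(freqs_hz)) {
    w <- 2 * pi * freqs_hz[fi]
    yL <- 1 / p$R_in + 1i * w * p$C_in
    ys <- 1i * w * Cs
    yc <- 1i * w * Cc
    ye <- 1 / p$R_electrode
    N <- 2L * n
    Y <- matrix(0 + 0i, N, N)
    node <- function(line, j) (line - 1L) * n + j
    for (line in 1:2) {
      for (j in seq_len(n)) {
        a <- node(line, j)
        Y[a, a] <- Y[a, a] + ys + yc
        b <- node(3L - line, j)
        Y[a, b] <- Y[a, b] - yc
        if (j < n) {
          nb <- node(line, j + 1L)
          Y[a, a] <- Y[a, a] + 1 / Rc
          Y[nb, nb] <- Y[nb, nb] + 1 / Rc
          Y[a, nb] <- Y[a, nb] - 1 / Rc
          Y[nb, a] <- Y[nb, a] - 1 / Rc
        }
      }
      Y[node(line, 1L), node(line, 1L)] <-
        Y[node(line, 1L), node(line, 1L)] + ye
      Y[node(line, n), node(line, n)] <-
        Y[node(line, n), node(line, n)] + yL
    }
    b <- rep(0 + 0i, N)
    b[node(1L, 1L)] <- ye # Vi1 = 1 V behind the electrode impedance
    v <- solve(Y, b)
    vo1 <- Mod(v[node(1L, n)])
    vo2 <- Mod(v[node(2L, n)])
    out$il_db[fi] <- 20 * log10(max(vo1, 10^(floor_db / 20)))
    out$fext_db[fi] <- 20 * log10(max(vo2, 10^(floor_db / 20)))
  }
  out
}
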