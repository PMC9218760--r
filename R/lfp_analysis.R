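# Continuous-trace analyses: ripple detection, Morlet spectrograms,
# current-source density, and evoked band power versus shank distance.

# zero-lag Gaussian low-pass FIR; cutoff at -3 dB, kernel truncated at 4 sigma
gauss_lp_kernel <- function(rate_hz, cutoff_hz) {
  sigma_s <- sqrt(log(sqrt(2))) / (pi * sqrt(2)) / cutoff_hz # |H(fc)| = 2^-1/2
  sigma <- max(sigma_s * rate_hz, 0.3)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k / sum(k)
}

# symmetric FIR filtering via FFT with edge padding (zero phase by kernel
# symmetry)
fir_filter <- function(x, kernel) {
  half <- (length(kernel) - 1L) / 2L
  n <- length(x)
  xp <- c(rep(x[1L], half), x, rep(x[n], half))
  m <- length(xp) + length(kernel) - 1L
  nf <- stats::nextn(m, 2)
  X <- stats::fft(c(xp, rep(0, nf - length(xp))))
  K <- stats::fft(c(kernel, rep(0, nf - length(kernel))))
  y <- Re(stats::fft(X * K, inverse = TRUE)) / nf
  y[(2L * half + 1L):(2L * half + n)]
}

#' Difference-of-Gaussians band-pass filter
#'
#' Zero-lag linear-phase FIR band-pass realized as the difference of two
#' Gaussian low-pass kernels with -3 dB cutoffs at the band edges.
#'
#' @param x signal vector.
#' @param rate_hz sampling rate.
#' @param band `c(low, high)` cutoffs (Hz).
#' @return filtered signal, same length as `x`.
#' @export
dog_filter <- function(x, rate_hz, band = c(80, 250)) {
  if (band[2L] >= rate_hz / 2)
    stop("band upper edge must be below the Nyquist frequency")
  if (band[1L] <= 0 || band[1L] >= band[2L]) stop("invalid band")
  fir_filter(x, gauss_lp_kernel(rate_hz, band[2L])) -
    fir_filter(x, gauss_lp_kernel(rate_hz, band[1L]))
}

#' Ripple power low-pass cutoff
#'
#' Cutoff of the rectified-power smoother: `mean(band) / p_cycles` Hz
#' (55 Hz for the default 80-250 Hz band at 3 cycles).
#'
#' @param band band-pass edges (Hz).
#' @param p_cycles smoothing cycles.
#' @return cutoff frequency (Hz).
#' @export
ripple_lowpass_cutoff <- function(band = c(80, 250), p_cycles = 3) {
  mean(band) / p_cycles
}

#' Detect sharp-wave ripples on one LFP channel
#'
#' Pipeline: difference-of-Gaussians band-pass (zero lag), clip at
#' `clip_sd` SDs, rectify and low-pass at `mean(band)/p_cycles` Hz (55 Hz
#' for the default 80-250 Hz band) to form the instantaneous power; the
#' mean/SD of the clipped power standardize the non-clipped power, events
#' are detected where that exceeds `detect_sd`, expanded until it falls
#' below `edge_sd` (overlapping expansions merge), and events shorter than
#' `min_dur_ms` are discarded.
#'
#' @param lfp lfp object (list with `samples` channels x time and
#'   `rate_hz`), e.g. `session$lfp`.
#' @param channel channel row index (a pyramidal-layer channel).
#' @param band band-pass edges (Hz).
#' @param clip_sd,detect_sd,edge_sd thresholds in SD units.
#' @param min_dur_ms minimum event duration (ms).
#' @param p_cycles smoothing cycles defining the power low-pass cutoff.
#' @param exclude optional 2-column matrix of time intervals (s) excluded
#'   from the mean/SD estimation (e.g. stimulation windows).
#' @return data frame of events: `start_s`, `stop_s`, `peak_s`, `peak_sd`,
#'   `channel`, sorted and non-overlapping.
#' @export
detect_ripples <- function(lfp, channel = 1L, band = c(80, 250),
                           clip_sd = 4, detect_sd = 4, edge_sd = 1,
                           min_dur_ms = 15, p_cycles = 3,
                           exclude = NULL) {
  rate <- lfp$rate_hz
  x <- lfp$samples[channel, ]
  bp <- dog_filter(x, rate, band)
  tgrid <- (seq_along(x) - 1L) / rate
  mask <- rep(TRUE, length(x))
  if (!is.null(exclude) && nrow(exclude))
    for (k in seq_len(nrow(exclude)))
      mask[tgrid >= exclude[k, 1L] & tgrid <= exclude[k, 2L]] <- FALSE
  sd_bp <- stats::sd(bp[mask])
  clipped <- pmax(pmin(bp, clip_sd * sd_bp), -clip_sd * sd_bp)
  lp_cut <- ripple_lowpass_cutoff(band, p_cycles)
  klp <- gauss_lp_kernel(rate, lp_cut)
  pow_clip <- fir_filter(abs(clipped), klp)
  pow_raw <- fir_filter(abs(bp), klp)
  mu <- mean(pow_clip[mask]); s <- stats::sd(pow_clip[mask])
  z <- (pow_raw - mu) / s

  above_edge <- z >= edge_sd
  r <- rle(above_edge)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- NULL
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    zmax <- max(z[i0:i1])
    if (zmax < detect_sd) next
    dur <- (i1 - i0) / rate
    if (dur * 1000 < min_dur_ms) next
    ipk <- i0 - 1L + which.max(z[i0:i1])
    ev <- rbind(ev, data.frame(start_s = tgrid[i0], stop_s = tgrid[i1],
                               peak_s = tgrid[ipk], peak_sd = zmax,
                               channel = channel))
  }
  if (is.null(ev))
    ev <- data.frame(start_s = numeric(), stop_s = numeric(),
                     peak_s = numeric(), peak_sd = numeric(),
                     channel = integer())
  ev
}

#' Event-averaged Morlet spectrogram
#'
#' Complex Morlet wavelet power in `band` at `step_hz` spacing, averaged
#' across event-centered windows on one channel.
#'
#' @param lfp lfp object.
#' @param event_times_s event centers (s), e.g. ripple peaks or pulse
#'   onsets; events whose window exceeds the recording are skipped with a
#'   warning.
#' @param channel channel index.
#' @param band frequency range (Hz); default 50-150.
#' @param step_hz frequency step (default 2 Hz -> 51 rows for the default
#'   band).
#' @param window_ms half window around each event (default 150 ms).
#' @param n_cycles Morlet width parameter (default 7 cycles).
#' @return list: `freq_hz`, `time_ms`, `power` (freq x time, averaged over
#'   events), `n_events`.
#' @export
morlet_spectrogram <- function(lfp, event_times_s, channel = 1L,
                               band = c(50, 150), step_hz = 2,
                               window_ms = 150, n_cycles = 7) {
  if (!length(event_times_s)) stop("need at least one event")
  rate <- lfp$rate_hz
  x <- lfp$samples[channel, ]
  freqs <- seq(band[1L], band[2L], by = step_hz)
  hw <- round(window_ms / 1000 * rate)
  pad <- ceiling(n_cycles / band[1L] * rate / 2) + 1L
  n <- length(x)
  centers <- round(event_times_s * rate) + 1L
  ok <- centers - hw - pad >= 1L & centers + hw + pad <= n
  if (!all(ok)) warning(sum(!ok), " event(s) outside the recording; skipped")
  centers <- centers[ok]
  if (!length(centers)) stop("no usable events")
  pow <- matrix(0, length(freqs), 2L * hw + 1L)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sig <- n_cycles / (2 * pi * f)
    hk <- ceiling(3 * sig * rate)
    tt <- (-hk:hk) / rate
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sig^2))
    w <- w / sum(Mod(w)) # L1 norm: unit passband gain at every frequency
    for (ce in centers) {
      seg <- x[(ce - hw - hk):(ce + hw + hk)]
      m <- length(seg) + length(w) - 1L
      nf <- stats::nextn(m, 2)
      conv <- stats::fft(stats::fft(c(seg, rep(0, nf - length(seg)))) *
                         stats::fft(c(w, rep(0, nf - length(w)))),
                         inverse = TRUE) / nf
      cen <- conv[(2L * hk + 1L):(2L * hk + 2L * hw + 1L)]
      pow[fi, ] <- pow[fi, ] + Mod(cen)^2
    }
  }
  list(freq_hz = freqs, time_ms = (-hw:hw) / rate * 1000,
       power = pow / length(centers), n_events = length(centers))
}

#' Current-source density of a laminar voltage profile
#'
#' Second spatial difference `-(V[i-1] - 2 V[i] + V[i+1]) / dz^2` along
#' equally spaced channels ordered by depth; edge channels are dropped.
#'
#' @param profile channels x time matrix (µV), ordered by depth.
#' @param spacing_um inter-channel spacing (µm).
#' @return (channels - 2) x time CSD matrix (µV µm^-2; sinks positive).
#' @export
csd <- function(profile, spacing_um) {
  profile <- as.matrix(profile)
  n <- nrow(profile)
  if (n < 3L) stop("CSD needs at least 3 equally spaced channels")
  if (spacing_um <= 0) stop("spacing must be positive")
  i <- 2L:(n - 1L)
  -(profile[i - 1L, , drop = FALSE] - 2 * profile[i, , drop = FALSE] +
      profile[i + 1L, , drop = FALSE]) / spacing_um^2
}

#' Evoked band power versus horizontal shank distance
#'
#' Mean band power inside stimulation-event windows, grouped by the number
#' of shanks between each channel and the active LED's shank.
#'
#' @param lfp lfp object (with `channel_sites`).
#' @param protocol stimulation data frame (`led`, `onset_s`, `dur_ms`).
#' @param layout probe layout.
#' @param band band edges (Hz; default 80-200).
#' @return data frame `shank_distance`, `power_uv2` (mean over channels and
#'   events); zero rows if the protocol is empty.
#' @export
band_power_vs_distance <- function(lfp, protocol, layout,
                                   band = c(80, 200)) {
  if (is.null(protocol) || !nrow(protocol))
    return(data.frame(shank_distance = integer(), power_uv2 = numeric()))
  rate <- lfp$rate_hz
  ch_shank <- layout$sites$shank[lfp$channel_sites]
  acc <- list()
  filt <- lapply(seq_len(nrow(lfp$samples)), function(ch)
    dog_filter(lfp$samples[ch, ], rate, band))
  for (k in seq_len(nrow(protocol))) {
    p <- protocol[k, ]
    led_shank <- layout$leds$shank[p$led]
    i0 <- max(1L, round(p$onset_s * rate) + 1L)
    i1 <- min(ncol(lfp$samples), round((p$onset_s + p$dur_ms / 1000) * rate))
    if (i1 <= i0) next
    for (ch in seq_along(filt)) {
      acc[[length(acc) + 1L]] <- data.frame(
        shank_distance = abs(ch_shank[ch] - led_shank),
        power_uv2 = mean(filt[[ch]][i0:i1]^2)
      )
    }
  }
  if (!length(acc))
    return(data.frame(shank_distance = integer(), power_uv2 = numeric()))
  d <- do.call(rbind, acc)
  out <- stats::aggregate(power_uv2 ~ shank_distance, d, mean)
  out[order(out$shank_distance), ]
}
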