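# Ground-truthed synthetic opto-electrophysiology sessions.
#
# The generator emulates what the downstream analyses assume about real
# multi-shank recordings: bursty pyramidal cells and two interneuron classes
# with distinct waveform widths and autocorrelogram recovery, excitatory
# monosynaptic connections with millisecond latency, opsin-positive units
# responding within 5-8 ms to nearby micro-LED pulses (with distance fall-off
# given by the tissue fluence model), and LFP with a 1/f background plus
# injected ripple bursts. Every inserted spike, evoked spike and ripple
# interval is recorded in the session's ground truth.

REFRACTORY_S <- 0.0015 # absolute refractory period enforced on all trains

#' Sample a renewal spike train with refractory recovery
#'
#' Interspike intervals follow a hazard that is zero during an absolute
#' refractory period and then recovers as `r_h (1 - exp(-t/tau_rec))`
#' (constant `r_h` when `tau_rec = 0`). The underlying hazard rate is
#' calibrated so the mean firing rate equals `rate_hz`. With
#' `tau_rec = 0` and `t_ref = 0` this is a homogeneous Poisson process.
#'
#' @param rate_hz target mean rate (Hz).
#' @param duration_s train length (s).
#' @param tau_rec_s recovery time constant (s); shapes the autocorrelogram
#'   rise.
#' @param t_ref_s absolute refractory period (s).
#' @return sorted spike times in (0, duration_s).
#' @export
sample_renewal_train <- function(rate_hz, duration_s,
                                 tau_rec_s = 0, t_ref_s = REFRACTORY_S) {
  stopifnot(rate_hz > 0, duration_s > 0)
  tmax <- t_ref_s + 30 / rate_hz
  tgrid <- seq(0, tmax - t_ref_s, length.out = 4000L)
  H1 <- function(rh) { # integrated hazard on tgrid (beyond refractory)
    if (tau_rec_s > 0) rh * (tgrid - tau_rec_s * (1 - exp(-tgrid / tau_rec_s)))
    else rh * tgrid
  }
  mean_isi <- function(rh) {
    S <- exp(-H1(rh))
    t_ref_s + sum((S[-1L] + S[-length(S)]) / 2) * diff(tgrid[1:2])
  }
  target <- 1 / rate_hz
  if (mean_isi(50 * rate_hz) > target)
    stop("rate_hz unattainable with this refractory period")
  rh <- stats::uniroot(function(r) mean_isi(r) - target,
                       c(rate_hz / 2, 50 * rate_hz))$root
  Fg <- 1 - exp(-H1(rh))
  qf <- stats::approxfun(Fg, tgrid, rule = 2, ties = "ordered")
  n <- ceiling(duration_s * rate_hz + 6 * sqrt(duration_s * rate_hz) + 20)
  isi <- t_ref_s + qf(stats::runif(n))
  st <- cumsum(isi)
  while (st[length(st)] < duration_s) { # top up in the (rare) short case
    extra <- t_ref_s + qf(stats::runif(n))
    st <- c(st, st[length(st)] + cumsum(extra))
  }
  st[st < duration_s]
}

# drop spikes violating the absolute refractory period (keep earlier spike)
enforce_refractory <- function(st, t_ref_s = REFRACTORY_S) {
  st <- sort(st)
  if (length(st) < 2L) return(st)
  keep <- logical(length(st)); keep[1L] <- TRUE
  last <- st[1L]
  for (i in 2L:length(st)) {
    if (st[i] - last >= t_ref_s) { keep[i] <- TRUE; last <- st[i] }
  }
  st[keep]
}

#' Generate a unit population with baseline spike trains
#'
#' Creates pyramidal cells, narrow and wide interneurons with per-type
#' waveform widths, firing-rate distributions and autocorrelogram recovery
#' constants, places somata near recording sites, and samples baseline
#' trains: interneurons as refractory-recovery renewal processes (slow
#' recovery for wide, fast for narrow) and pyramidal cells as renewal trains
#' with appended burst spikes (a fraction `burst_propensity` of spikes is
#' followed by an extra spike 3-8 ms later).
#'
#' @param layout a [build_layout()] probe layout.
#' @param n_per_type named counts for `pyramidal`, `narrow_int`, `wide_int`
#'   (defaults 70/20/10).
#' @param duration_s session duration (default 600 s).
#' @param seed RNG seed (optional).
#' @param opsin_fraction fraction of units expressing the opsin.
#' @param region_breaks_um depth boundaries (µm) between CTX, CA1 and CA3
#'   bands used to label units by soma depth.
#' @param rate_median_hz,burst_propensity,tp_range_ms,tau_rec_ms per-type
#'   generator knobs (named lists; see defaults).
#' @return a `spike_session` with `units`, `spikes`, `layout`,
#'   `duration_s` and an empty ground truth.
#' @export
generate_units <- function(layout = build_layout(),
                           n_per_type = c(pyramidal = 70, narrow_int = 20,
                                          wide_int = 10),
                           duration_s = 600, seed = NULL,
                           opsin_fraction = 0.3,
                           region_breaks_um = c(400, 800),
                           rate_median_hz = c(pyramidal = 2, narrow_int = 12,
                                              wide_int = 6),
                           burst_propensity = 0.2,
                           tp_range_ms = list(pyramidal = c(0.55, 0.9),
                                              narrow_int = c(0.15, 0.35),
                                              wide_int = c(0.5, 0.8)),
                           tau_rec_ms = c(pyramidal = 0, narrow_int = 3,
                                          wide_int = 18)) {
  if (!is.null(seed)) set.seed(seed)
  if (any(n_per_type < 0) || sum(n_per_type) == 0)
    stop("unit counts must be non-negative and not all zero")
  if (duration_s <= 0) stop("duration_s must be positive")
  types <- rep(names(n_per_type), n_per_type)
  n <- length(types)
  site_idx <- sample.int(nrow(layout$sites), n, replace = TRUE)
  x <- layout$sites$x_um[site_idx] + stats::runif(n, -20, 20)
  y <- layout$sites$y_um[site_idx] + stats::runif(n, -20, 20)
  region <- cut(y, c(-Inf, region_breaks_um, Inf),
                labels = c("CTX", "CA1", "CA3"))
  rates <- stats::rlnorm(n, log(rate_median_hz[types]), 0.4)
  bp <- ifelse(types == "pyramidal",
               pmin(1, pmax(0, stats::rnorm(n, burst_propensity, 0.05))), 0)
  tp <- vapply(seq_len(n), function(i) {
    rg <- tp_range_ms[[types[i]]]; stats::runif(1, rg[1L], rg[2L])
  }, numeric(1))
  units <- data.frame(
    unit_id = seq_len(n),
    cell_type = types,
    x_um = x, y_um = y,
    region = as.character(region),
    baseline_rate_hz = rates,
    burst_propensity = bp,
    tp_ms = tp,
    opsin_positive = stats::runif(n) < opsin_fraction,
    opsin_latency_ms = stats::runif(n, 5, 8),
    stringsAsFactors = FALSE
  )
  spikes <- vector("list", n)
  for (i in seq_len(n)) {
    tau <- tau_rec_ms[types[i]] / 1000
    if (types[i] == "pyramidal") {
      base_rate <- rates[i] / (1 + bp[i])
      st <- sample_renewal_train(base_rate, duration_s, tau_rec_s = tau)
      if (bp[i] > 0 && length(st)) {
        burst_sel <- stats::runif(length(st)) < bp[i]
        extra <- st[burst_sel] + stats::runif(sum(burst_sel), 0.0025, 0.006)
        st <- enforce_refractory(c(st, extra[extra < duration_s]))
      }
    } else {
      st <- sample_renewal_train(rates[i], duration_s, tau_rec_s = tau)
    }
    spikes[[i]] <- st
  }
  names(spikes) <- as.character(units$unit_id)
  structure(list(
    layout = layout,
    duration_s = duration_s,
    rate_hz = 20000,
    units = units,
    spikes = spikes,
    waveforms = NULL,
    lfp = NULL,
    protocol = NULL,
    ground_truth = list(synapses = NULL, inserted_spikes = NULL,
                        ripples = NULL, evoked_spikes = NULL),
    seed = seed
  ), class = "spike_session")
}

#' @export
print.spike_session <- function(x, ...) {
  cat(sprintf("spike_session: %d units, %.0f s, %d spikes\n",
              nrow(x$units), x$duration_s,
              sum(lengths(x$spikes))))
  if (!is.null(x$protocol))
    cat(sprintf("  stimulation: %d pulses (%s)\n", nrow(x$protocol),
                paste(unique(x$protocol$label), collapse = "/")))
  if (!is.null(x$lfp))
    cat(sprintf("  lfp: %d channels at %g Hz\n", nrow(x$lfp$samples),
                x$lfp$rate_hz))
  invisible(x)
}

#' Build a monosynaptic connection table
#'
#' Draws excitatory pyramidal-to-interneuron connections with log-normally
#' distributed transmission probabilities, uniform latencies in the
#' monosynaptic 0.5-3 ms window and sub-millisecond jitter.
#'
#' @param session a `spike_session`.
#' @param n_synapses number of connections.
#' @param p_median,p_sdlog log-normal parameters of the transmission
#'   probability (capped at 1).
#' @param latency_range_ms,jitter_ms latency window and Gaussian jitter SD.
#' @param seed RNG seed (optional).
#' @param distance_lambda_um if finite, transmission probabilities are
#'   scaled by `exp(-d / lambda)` of the soma distance (distance-decaying
#'   connectivity); `Inf` disables the decay.
#' @param max_distance_um only pairs with soma distance below this are
#'   eligible (connectivity is local; default `Inf`).
#' @return data frame of synapse specs (`pre`, `post`, `p`, `latency_ms`,
#'   `jitter_ms`).
#' @export
make_synapses <- function(session, n_synapses = 20,
                          p_median = 0.1, p_sdlog = 0.5,
                          latency_range_ms = c(0.5, 3), jitter_ms = 0.3,
                          seed = NULL, distance_lambda_um = Inf,
                          max_distance_um = Inf) {
  if (!is.null(seed)) set.seed(seed)
  u <- session$units
  pre_pool <- u$unit_id[u$cell_type == "pyramidal"]
  post_pool <- u$unit_id[u$cell_type != "pyramidal"]
  if (!length(pre_pool) || !length(post_pool))
    stop("need at least one pyramidal and one interneuron unit")
  pairs <- expand.grid(pre = pre_pool, post = post_pool)
  if (is.finite(max_distance_um)) {
    dp <- sqrt((u$x_um[pairs$pre] - u$x_um[pairs$post])^2 +
               (u$y_um[pairs$pre] - u$y_um[pairs$post])^2)
    pairs <- pairs[dp <= max_distance_um, ]
    if (!nrow(pairs)) stop("no candidate pairs within max_distance_um")
  }
  pairs <- pairs[sample.int(nrow(pairs), min(n_synapses, nrow(pairs))), ]
  p <- pmin(1, stats::rlnorm(nrow(pairs), log(p_median), p_sdlog))
  if (is.finite(distance_lambda_um)) {
    d <- sqrt((u$x_um[pairs$pre] - u$x_um[pairs$post])^2 +
              (u$y_um[pairs$pre] - u$y_um[pairs$post])^2)
    p <- pmin(1, p * exp(-d / distance_lambda_um))
  }
  data.frame(pre = pairs$pre, post = pairs$post, p = p,
             latency_ms = stats::runif(nrow(pairs), latency_range_ms[1L],
                                       latency_range_ms[2L]),
             jitter_ms = jitter_ms)
}

#' Inject monosynaptic spikes
#'
#' For every presynaptic spike, inserts a postsynaptic spike with the
#' synapse's transmission probability at `latency + N(0, jitter)`; inserted
#' spikes respect the postsynaptic refractory period and are recorded in the
#' ground truth.
#'
#' @param session a `spike_session`.
#' @param synapses data frame as returned by [make_synapses()].
#' @param seed RNG seed (optional).
#' @return the session with updated trains and ground truth.
#' @export
inject_monosynaptic <- function(session, synapses, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("pre", "post", "p", "latency_ms") %in% names(synapses)))
  if (any(synapses$p < 0 | synapses$p > 1))
    stop("transmission probabilities must lie in [0, 1]")
  synapses_all <- synapses
  synapses <- synapses[synapses$p > 0, ] # p = 0: inert connection
  if (!all(synapses$pre %in% session$units$unit_id) ||
      !all(synapses$post %in% session$units$unit_id))
    stop("synapse endpoints must be existing units")
  pre_types <- session$units$cell_type[match(synapses$pre,
                                             session$units$unit_id)]
  if (any(pre_types != "pyramidal"))
    stop("excitatory connections only: presynaptic units must be pyramidal")
  inserted <- list()
  for (k in seq_len(nrow(synapses))) {
    s <- synapses[k, ]
    pre_t <- session$spikes[[as.character(s$pre)]]
    if (!length(pre_t)) next
    hit <- stats::runif(length(pre_t)) < s$p
    if (!any(hit)) next
    new_t <- pre_t[hit] + s$latency_ms / 1000 +
      stats::rnorm(sum(hit), 0, s$jitter_ms / 1000)
    new_t <- new_t[new_t > 0 & new_t < session$duration_s]
    post_key <- as.character(s$post)
    merged <- enforce_refractory(c(session$spikes[[post_key]], new_t))
    kept <- new_t[new_t %in% merged]
    session$spikes[[post_key]] <- merged
    if (length(kept))
      inserted[[length(inserted) + 1L]] <-
        data.frame(pre = s$pre, post = s$post, time_s = kept)
  }
  session$ground_truth$synapses <- synapses_all
  session$ground_truth$inserted_spikes <-
    if (length(inserted)) do.call(rbind, inserted) else
      data.frame(pre = integer(), post = integer(), time_s = numeric())
  session
}

#' Saturating evoked-rate gain versus fluence
#'
#' Hill-type gain used by [apply_stimulation()]: zero below the activation
#' threshold, then `gain_max phi^2 / (phi^2 + phi50^2)`.
#'
#' @param phi fluence rate (mW mm^-2).
#' @param gain_max_hz peak sustained evoked rate (Hz).
#' @param phi50 half-saturation fluence (mW mm^-2).
#' @param threshold activation threshold (mW mm^-2, default 0.1).
#' @return evoked rate (Hz).
#' @export
evoked_gain <- function(phi, gain_max_hz = 100, phi50 = 0.3, threshold = 0.1) {
  ifelse(phi < threshold, 0, gain_max_hz * phi^2 / (phi^2 + phi50^2))
}

#' Apply optical stimulation to opsin-positive units
#'
#' For every pulse and every opsin-positive unit, computes the fluence at
#' the soma from the diffusion closed form ([fluence_point_source()]) at the
#' soma-LED distance. Above the activation threshold the unit fires a
#' short-latency first spike (drawn in its 5-8 ms latency window, with
#' per-pulse reliability saturating in fluence) followed by sustained
#' Poisson firing at the Hill gain for the remainder of the pulse.
#' Opsin-negative units, and units on other shanks (negligible fluence at
#' >= 300 µm), are unaffected. Evoked spikes are recorded in the ground
#' truth.
#'
#' @param session a `spike_session`.
#' @param protocol stimulation data frame (`led`, `onset_s`, `dur_ms`,
#'   `amp_uA`, `label`), e.g. from [make_pulse_protocol()].
#' @param light list with `P_uW` and `params` ([optical_params()]) for the
#'   fluence model.
#' @param gain list with `gain_max_hz`, `phi50`, `threshold`, and maximum
#'   first-spike reliability `rel_max`.
#' @param first_spike_sd_ms jitter of the first evoked spike around the
#'   unit's opsin latency.
#' @param seed RNG seed (optional).
#' @return the session with evoked spikes merged in and `protocol` attached.
#' @export
apply_stimulation <- function(session, protocol,
                              light = list(P_uW = 7.03,
                                           params = optical_params()),
                              gain = list(gain_max_hz = 100, phi50 = 0.3,
                                          threshold = 0.1, rel_max = 0.8),
                              first_spike_sd_ms = 0.5,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_protocol(protocol, session$layout)
  u <- session$units
  leds <- session$layout$leds
  evoked <- list()
  for (i in which(u$opsin_positive)) {
    d_led <- sqrt((leds$x_um - u$x_um[i])^2 + (leds$y_um - u$y_um[i])^2)
    phi_led <- fluence_point_source(d_led, P_uW = light$P_uW,
                                    params = light$params)
    new_t <- numeric(0)
    for (led in unique(protocol$led)) {
      phi <- phi_led[led]
      if (phi < gain$threshold) next
      rate <- evoked_gain(phi, gain$gain_max_hz, gain$phi50, gain$threshold)
      rel <- gain$rel_max * phi^2 / (phi^2 + gain$phi50^2)
      pl <- protocol[protocol$led == led, ]
      for (k in seq_len(nrow(pl))) {
        t0 <- pl$onset_s[k]; dur <- pl$dur_ms[k] / 1000
        if (stats::runif(1) < rel) {
          lat <- u$opsin_latency_ms[i] / 1000 +
            stats::rnorm(1, 0, first_spike_sd_ms / 1000)
          lat <- min(max(lat, 0.004), 0.009)
          new_t <- c(new_t, t0 + lat)
        }
        t_sus <- 0.009 # sustained firing after the first-spike window
        if (dur > t_sus && rate > 0) {
          nn <- stats::rpois(1, rate * (dur - t_sus))
          if (nn > 0)
            new_t <- c(new_t, t0 + t_sus + sort(stats::runif(nn, 0, dur - t_sus)))
        }
      }
    }
    if (length(new_t)) {
      new_t <- new_t[new_t > 0 & new_t < session$duration_s]
      key <- as.character(u$unit_id[i])
      merged <- enforce_refractory(c(session$spikes[[key]], new_t))
      kept <- new_t[new_t %in% merged]
      session$spikes[[key]] <- merged
      if (length(kept))
        evoked[[length(evoked) + 1L]] <-
          data.frame(unit = u$unit_id[i], time_s = kept)
    }
  }
  session$ground_truth$evoked_spikes <-
    if (length(evoked)) do.call(rbind, evoked) else
      data.frame(unit = integer(), time_s = numeric())
  session$protocol <- if (is.null(session$protocol)) protocol else
    rbind(session$protocol, protocol)
  session$protocol <- session$protocol[order(session$protocol$onset_s), ]
  session
}

validate_protocol <- function(protocol, layout) {
  stopifnot(all(c("led", "onset_s", "dur_ms", "amp_uA", "label") %in%
                names(protocol)))
  if (any(protocol$led < 1L | protocol$led > nrow(layout$leds)))
    stop("unknown LED index in protocol")
  if (any(protocol$amp_uA > 75))
    stop("pulse amplitude exceeds the 75 uA safe-operation maximum")
  for (led in unique(protocol$led)) {
    p <- protocol[protocol$led == led, ]
    p <- p[order(p$onset_s), ]
    if (nrow(p) > 1L &&
        any(p$onset_s[-1L] < p$onset_s[-nrow(p)] + p$dur_ms[-nrow(p)] / 1000))
      stop("overlapping pulses on LED ", led)
  }
  invisible(TRUE)
}

#' Single-LED pulse-train protocol
#'
#' Regular pulse train on one LED: the optotagging default is 50 ms pulses
#' every 100 ms; the single-LED mapping protocol in cortex/hippocampus used
#' 100 ms pulses every 5 s.
#'
#' @param led 1-based LED index.
#' @param n_pulses number of pulses.
#' @param dur_ms,period_ms pulse duration and period.
#' @param start_s onset of the first pulse.
#' @param amp_uA drive current (µA, <= 75).
#' @param label event label.
#' @return stimulation data frame.
#' @export
make_pulse_protocol <- function(led, n_pulses = 400, dur_ms = 50,
                                period_ms = 100, start_s = 1,
                                amp_uA = 50, label = "tag") {
  stopifnot(n_pulses >= 1, dur_ms > 0, period_ms >= dur_ms)
  data.frame(led = led,
             onset_s = start_s + (seq_len(n_pulses) - 1L) * period_ms / 1000,
             dur_ms = dur_ms, amp_uA = amp_uA, label = label,
             event = seq_len(n_pulses))
}

#' Forward/reverse sequential stimulation protocol
#'
#' Interleaved forward and reverse events: within an event the chosen LED of
#' each shank fires a 120 ms pulse with a fixed stagger, in shank order
#' (forward) or reversed (reverse).
#'
#' @param layout probe layout.
#' @param leds_per_shank 1-based LED indices, one per shank (e.g. the LED in
#'   the pyramidal layer of each shank).
#' @param n_events total event count (floored to even with a warning).
#' @param pulse_ms pulse duration (default 120 ms).
#' @param stagger_ms onset stagger between consecutive LEDs (default 30 ms;
#'   0 gives simultaneous pulses).
#' @param period_s event period.
#' @param start_s first event onset.
#' @param amp_uA drive current.
#' @param seed seed controlling the forward/reverse interleaving.
#' @return stimulation data frame with one row per pulse and an `event`
#'   column; `label` is `"forward"` or `"reverse"`.
#' @export
make_sequence_protocol <- function(layout, leds_per_shank,
                                   n_events = 240, pulse_ms = 120,
                                   stagger_ms = 30, period_s = 1,
                                   start_s = 1, amp_uA = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(leds_per_shank) != layout$n_shanks)
    stop("need one LED per shank")
  if (n_events %% 2L == 1L) {
    warning("n_events is odd; flooring to even")
    n_events <- n_events - 1L
  }
  labels <- rep(c("forward", "reverse"), n_events / 2L)
  rows <- list()
  for (ev in seq_len(n_events)) {
    order_leds <- if (labels[ev] == "forward") leds_per_shank else
      rev(leds_per_shank)
    t0 <- start_s + (ev - 1L) * period_s
    rows[[ev]] <- data.frame(
      led = order_leds,
      onset_s = t0 + (seq_along(order_leds) - 1L) * stagger_ms / 1000,
      dur_ms = pulse_ms, amp_uA = amp_uA, label = labels[ev], event = ev
    )
  }
  do.call(rbind, rows)
}

#' Generate per-unit, per-site mean waveform snippets
#'
#' Biphasic templates with the unit's trough-to-peak latency, amplitude
#' decaying exponentially with soma-site distance (length constant
#' `lambda_um`, zero beyond `cutoff_um`), sampled at the session rate in a
#' 1.6 ms pre / 2.4 ms post window around the trough.
#'
#' @param session a `spike_session`.
#' @param seed RNG seed (optional).
#' @param lambda_um amplitude decay length constant (µm).
#' @param cutoff_um recording radius beyond which amplitude is zero (µm).
#' @param peak_uv_median median trough amplitude at the soma (µV).
#' @param min_peak_uv if non-NULL, units are rescaled so the nearest-site
#'   amplitude is at least this (µV).
#' @param noise_uv additive Gaussian noise SD on the mean waveform (µV).
#' @return the session with `waveforms`: per unit a list with `sites`,
#'   `mean_uv` (site x sample matrix), `peak_site`, `t_ms`.
#' @export
generate_waveforms <- function(session, seed = NULL, lambda_um = 28,
                               cutoff_um = 60, peak_uv_median = 300,
                               min_peak_uv = 200, noise_uv = 2) {
  if (!is.null(seed)) set.seed(seed)
  lay <- session$layout
  rate <- session$rate_hz
  t_pre <- 1.6e-3; t_post <- 2.4e-3
  tt <- seq(-t_pre, t_post, by = 1 / rate)
  u <- session$units
  wf <- vector("list", nrow(u))
  for (i in seq_len(nrow(u))) {
    d <- sqrt((lay$sites$x_um - u$x_um[i])^2 + (lay$sites$y_um - u$y_um[i])^2)
    sites <- which(d <= cutoff_um)
    a0 <- stats::rlnorm(1, log(peak_uv_median), 0.3)
    if (length(sites)) {
      amp <- a0 * exp(-d[sites] / lambda_um)
      if (!is.null(min_peak_uv) && max(amp) < min_peak_uv)
        amp <- amp * min_peak_uv / max(amp)
    } else amp <- numeric(0)
    shape <- spike_template(tt, u$tp_ms[i] / 1000)
    m <- outer(amp, shape) # sites x samples, trough-normalized
    if (length(m)) m <- m + stats::rnorm(length(m), 0, noise_uv)
    wf[[i]] <- list(
      sites = sites,
      mean_uv = m,
      peak_site = if (length(sites)) sites[which.max(amp)] else NA_integer_,
      t_ms = tt * 1000
    )
  }
  names(wf) <- as.character(u$unit_id)
  session$waveforms <- wf
  session
}

# biphasic extracellular template: unit-amplitude trough at t = 0 and a
# slower positive after-peak at t = tp (trough-to-peak latency, s)
spike_template <- function(t, tp_s) {
  trough <- -exp(-0.5 * (t / 1e-4)^2)
  peak <- 0.35 * exp(-0.5 * ((t - tp_s) / (0.35 * tp_s + 8e-5))^2)
  trough + peak
}

#' Generate a multi-channel LFP recording with injected ripples
#'
#' Per-channel 1/f ("pink") background noise plus Gaussian-enveloped
#' ripple-band oscillations on designated pyramidal-layer channels, and
#' optional stimulation-evoked oscillatory transients whose amplitude
#' depends on the shank distance to the active LED. Injected ripple
#' intervals are stored in the ground truth.
#'
#' @param session a `spike_session`.
#' @param channel_sites site indices (rows of `layout$sites`) mapped to LFP
#'   channels.
#' @param rate_hz LFP sampling rate (default 1250 Hz; the raw acquisition
#'   runs at 20 kS/s but ripple-band analyses operate on the downsampled
#'   trace).
#' @param noise_sd_uv background noise SD (µV).
#' @param ripples list: `n` events, `amp_sd` amplitude in SDs of the
#'   ripple-band-filtered background, `dur_range_ms`, `freq_range_hz`,
#'   `channels` (indices into `channel_sites` forming the pyramidal layer).
#' @param evoked optional list for stimulation-evoked transients:
#'   `freq_hz`, `amp_sd_by_distance` (amplitude per |shank - LED shank| =
#'   0,1,2,3, in the same SD units), plus the session protocol is used for
#'   pulse times.
#' @param seed RNG seed (optional).
#' @return the session with `lfp` set: list(`samples` channels x time
#'   matrix (µV), `rate_hz`, `channel_sites`).
#' @export
generate_lfp <- function(session,
                         channel_sites = NULL,
                         rate_hz = 1250,
                         noise_sd_uv = 50,
                         ripples = list(n = 50, amp_sd = 6,
                                        dur_range_ms = c(30, 100),
                                        freq_range_hz = c(110, 200),
                                        channels = 1L),
                         evoked = NULL,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lay <- session$layout
  if (is.null(channel_sites))
    channel_sites <- which(lay$sites$column == 0L & lay$sites$shank == 0L)
  nch <- length(channel_sites)
  ns <- round(session$duration_s * rate_hz)
  if (!is.null(ripples) && ripples$n > 0 && ripples$amp_sd < 0)
    stop("ripple amplitude must be non-negative")
  x <- matrix(0, nch, ns)
  for (ch in seq_len(nch)) x[ch, ] <- pink_noise(ns, rate_hz) * noise_sd_uv
  tgrid <- (seq_len(ns) - 1L) / rate_hz
  # ripple-band SD of the background noise, per channel: the unit in which
  # injected amplitudes are expressed
  band_ref <- c(80, 250)
  sd_band_ch <- vapply(seq_len(nch), function(ch)
    stats::sd(dog_filter(x[ch, ], rate_hz, band_ref)), numeric(1))

  gt_rip <- NULL
  if (!is.null(ripples) && ripples$n > 0) {
    for (ch in ripples$channels) {
      sd_band <- sd_band_ch[ch]
      k <- ripples$n
      # non-overlapping onsets on a margin-protected grid
      slots <- seq(1, session$duration_s - 1, by = 0.25)
      if (length(slots) < k) stop("session too short for requested ripples")
      t0 <- sort(sample(slots, k)) + stats::runif(k, 0, 0.05)
      dur <- stats::runif(k, ripples$dur_range_ms[1L],
                          ripples$dur_range_ms[2L]) / 1000
      f <- stats::runif(k, ripples$freq_range_hz[1L],
                        ripples$freq_range_hz[2L])
      for (j in seq_len(k)) {
        sel <- which(tgrid >= t0[j] & tgrid <= t0[j] + dur[j])
        tc <- t0[j] + dur[j] / 2
        env <- exp(-0.5 * ((tgrid[sel] - tc) / (dur[j] / 6))^2)
        x[ch, sel] <- x[ch, sel] + ripples$amp_sd * sd_band * env *
          sin(2 * pi * f[j] * (tgrid[sel] - t0[j]))
      }
      gt_rip <- rbind(gt_rip, data.frame(channel = ch, start_s = t0,
                                         stop_s = t0 + dur, freq_hz = f))
    }
  }

  if (!is.null(evoked)) {
    if (is.null(session$protocol))
      stop("evoked transients require a stimulation protocol")
    ch_shank <- lay$sites$shank[channel_sites]
    for (k in seq_len(nrow(session$protocol))) {
      p <- session$protocol[k, ]
      led_shank <- lay$leds$shank[p$led]
      for (ch in seq_len(nch)) {
        dist_sh <- abs(ch_shank[ch] - led_shank) + 1L
        amp <- evoked$amp_sd_by_distance[min(dist_sh,
                                             length(evoked$amp_sd_by_distance))]
        if (amp <= 0) next
        sd_band <- sd_band_ch[ch]
        sel <- which(tgrid >= p$onset_s & tgrid <= p$onset_s + p$dur_ms / 1000)
        if (!length(sel)) next
        tr <- tgrid[sel] - p$onset_s
        env <- pmin(1, tr / 0.01) * pmin(1, (p$dur_ms / 1000 - tr) / 0.01)
        x[ch, sel] <- x[ch, sel] + amp * sd_band * env *
          sin(2 * pi * evoked$freq_hz * tr)
      }
    }
  }

  session$lfp <- list(samples = x, rate_hz = rate_hz,
                      channel_sites = channel_sites)
  session$ground_truth$ripples <- gt_rip
  session
}

# 1/f-amplitude-shaped Gaussian noise, unit variance
pink_noise <- function(n, rate_hz, f_floor = 1) {
  nf <- stats::nextn(n, 2)
  f <- c(0, seq_len(nf / 2), seq(nf / 2 - 1, 1)) * rate_hz / nf
  shape <- 1 / sqrt(pmax(f, f_floor))
  z <- stats::fft(stats::rnorm(nf))
  x <- Re(stats::fft(z * shape, inverse = TRUE))[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}

#' Synthetic forward/reverse sequence experiment
#'
#' Builds a session emulating the sequential-stimulation experiment: one
#' deep-layer LED per shank, a population of opsin-positive pyramidal cells
#' clustered within recording range of those LEDs (the same cells are
#' active in both conditions; only their activation order differs), plus
#' background units, and an interleaved forward/reverse protocol.
#'
#' @param seed RNG seed.
#' @param n_events total events (half forward, half reverse).
#' @param driven_per_shank opsin+ pyramidal cells placed near each shank's
#'   LED.
#' @param stagger_ms onset stagger between consecutive shanks.
#' @param pulse_ms pulse duration.
#' @param led_depth_um target depth of the stimulated layer.
#' @param n_background extra unstimulated pyramidal units.
#' @param period_s event period.
#' @return list: `session`, `protocol`, `driven_units`, `leds`.
#' @export
simulate_sequence_session <- function(seed = 1, n_events = 240,
                                      driven_per_shank = 4,
                                      stagger_ms = 30, pulse_ms = 120,
                                      led_depth_um = 900,
                                      n_background = 10,
                                      period_s = 1) {
  set.seed(seed)
  lay <- build_layout()
  n_driven <- driven_per_shank * lay$n_shanks
  ses <- generate_units(lay,
                        n_per_type = c(pyramidal = n_driven + n_background,
                                       narrow_int = 4, wide_int = 2),
                        duration_s = n_events * period_s + 2,
                        opsin_fraction = 0)
  leds <- vapply(seq_len(lay$n_shanks) - 1L, function(sh) {
    cand <- which(lay$leds$shank == sh)
    cand[which.min(abs(lay$leds$y_um[cand] - led_depth_um))]
  }, integer(1))
  driven <- seq_len(n_driven)
  for (k in seq_along(driven)) {
    led <- leds[((k - 1L) %% lay$n_shanks) + 1L]
    ses$units$x_um[driven[k]] <- lay$leds$x_um[led] + stats::runif(1, -15, 15)
    ses$units$y_um[driven[k]] <- lay$leds$y_um[led] + stats::runif(1, -15, 15)
    ses$units$opsin_positive[driven[k]] <- TRUE
  }
  ses$units$region[driven] <- "CA3"
  prot <- make_sequence_protocol(lay, leds, n_events = n_events,
                                 pulse_ms = pulse_ms,
                                 stagger_ms = stagger_ms,
                                 period_s = period_s, start_s = 1)
  ses <- apply_stimulation(ses, prot, seed = seed + 1)
  list(session = ses, protocol = prot, driven_units = driven, leds = leds)
}

#' Convenience full synthetic session
#'
#' Units + synapses + waveforms in one call; LFP and stimulation are added
#' separately because their protocols depend on the experiment being
#' emulated.
#'
#' @param seed RNG seed (drives every stage).
#' @param ... passed to [generate_units()].
#' @param n_synapses number of injected connections.
#' @return a `spike_session`.
#' @export
simulate_session <- function(seed = 1, n_synapses = 20, ...) {
  ses <- generate_units(seed = seed, ...)
  syn <- make_synapses(ses, n_synapses = n_synapses)
  ses <- inject_monosynaptic(ses, syn)
  generate_waveforms(ses)
}
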