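# Waveform/autocorrelogram feature extraction, cell-type classification and
# soma localization.

#' Autocorrelation histogram
#'
#' Forward-lag spike-pair counts in (0, `max_lag_ms`] at `bin_ms` bins.
#'
#' @param st sorted spike times (s).
#' @param bin_ms bin width (default 0.5 ms).
#' @param max_lag_ms maximum lag (default 50 ms).
#' @return data frame `lag_ms` (bin centers), `count`, `rate_hz` (pair rate
#'   per reference spike per second).
#' @export
compute_acg <- function(st, bin_ms = 0.5, max_lag_ms = 50) {
  edges <- seq(0, max_lag_ms, by = bin_ms) / 1000
  st <- sort(st)
  # cumulative forward-pair counts at each edge via binary search
  cum <- vapply(edges, function(e) sum(findInterval(st + e, st)),
                numeric(1)) - length(st) * 1 # remove self-pairs (lag 0)
  counts <- diff(cum)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2 * 1000
  data.frame(lag_ms = centers, count = counts,
             rate_hz = counts / length(st) / (bin_ms / 1000))
}

#' Fit the autocorrelogram with a double-exponential rise/decay family
#'
#' Fits `a + b exp(-t / tau_decay) - c exp(-t / tau_rise)` to the ACG rate
#' by bounded least squares with three restarts from different rise-time
#' starting values; `tau_rise` is the reported autocorrelogram rise time.
#'
#' @param acg data frame from [compute_acg()].
#' @return list with `tau_rise_ms`, `tau_decay_ms`, `a`, `b`, `c`,
#'   `converged`; `tau_rise_ms` is `NA` when no restart converges.
#' @export
fit_acg <- function(acg) {
  t <- acg$lag_ms; y <- acg$rate_hz
  a0 <- max(mean(y[t > 30]), 0.1)
  ymax <- max(y); tpk <- t[which.max(y)]
  best <- NULL
  for (tr0 in c(0.7, 3, 12)) {
    for (td0 in c(3, 12, 40)) {
      b0 <- min(max((ymax - a0) * exp(tpk / td0), 0.1), 1e4)
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ a + b * exp(-t / td) - cc * exp(-t / tr),
          start = list(a = a0, b = b0, td = td0, cc = a0 + b0, tr = tr0),
          lower = c(a = 0, b = 0, td = 0.5, cc = 0, tr = 0.1),
          upper = c(a = Inf, b = Inf, td = 500, cc = Inf, tr = 50),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ), error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best))
    return(list(tau_rise_ms = NA_real_, tau_decay_ms = NA_real_,
                a = NA_real_, b = NA_real_, c = NA_real_, converged = FALSE))
  cf <- stats::coef(best$fit)
  list(tau_rise_ms = unname(cf["tr"]), tau_decay_ms = unname(cf["td"]),
       a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["cc"]),
       converged = TRUE)
}

#' Extract waveform and spike-train features for one unit
#'
#' Trough-to-peak latency from the peak-site mean waveform (trough to the
#' subsequent positive peak), burst index (fraction of interspike intervals
#' below 9 ms) and the fitted autocorrelogram rise time.
#'
#' @param wf per-unit waveform entry (list with `mean_uv`, `sites`,
#'   `peak_site`, `t_ms`), e.g. `session$waveforms[[i]]`.
#' @param st the unit's spike times (s).
#' @param rate_hz waveform sampling rate.
#' @param min_spikes minimum spike count (default 50); below it an error is
#'   raised.
#' @return list: `tp_ms`, `burst_index`, `acg_rise_ms` (NA when the fit
#'   fails), `n_spikes`, `peak_site`.
#' @export
extract_features <- function(wf, st, rate_hz = 20000, min_spikes = 50) {
  if (length(st) < min_spikes)
    stop("too few spikes for feature extraction (", length(st), ")")
  if (!length(wf$sites)) stop("unit has no recorded waveform")
  k <- match(wf$peak_site, wf$sites)
  w <- wf$mean_uv[k, ]
  itr <- which.min(w)
  after <- w[itr:length(w)]
  ipk <- itr - 1L + which.max(after)
  tp_ms <- (ipk - itr) / rate_hz * 1000
  isi <- diff(sort(st))
  burst_index <- if (length(isi)) mean(isi < 0.009) else 0
  acg <- compute_acg(st)
  fit <- fit_acg(acg)
  list(tp_ms = tp_ms, burst_index = burst_index,
       acg_rise_ms = fit$tau_rise_ms, n_spikes = length(st),
       peak_site = wf$peak_site)
}

#' Classify a unit into putative cell types
#'
#' Deterministic rule: narrow interneuron when the trough-to-peak latency
#' is < 0.425 ms; wide interneuron when it is > 0.425 ms and the
#' autocorrelogram rise time is > 6 ms; otherwise pyramidal. A latency of
#' exactly 0.425 ms and a missing rise time both fall through to the
#' pyramidal branch.
#'
#' @param tp_ms trough-to-peak latency (ms); vectorized.
#' @param acg_rise_ms autocorrelogram rise time (ms); NA allowed.
#' @return character vector in `{"narrow_int", "wide_int", "pyramidal"}`.
#' @export
classify_cell <- function(tp_ms, acg_rise_ms) {
  ifelse(tp_ms < 0.425, "narrow_int",
         ifelse(tp_ms > 0.425 & !is.na(acg_rise_ms) & acg_rise_ms > 6,
                "wide_int", "pyramidal"))
}

#' Feature table and classification for all units of a session
#'
#' @param session a `spike_session` with waveforms.
#' @param min_spikes units with fewer spikes are skipped.
#' @return data frame: `unit_id`, `tp_ms`, `burst_index`, `acg_rise_ms`,
#'   `label`, `x_um`, `y_um` (localized soma; NA when localization is
#'   undefined).
#' @export
classify_units <- function(session, min_spikes = 50) {
  stopifnot(!is.null(session$waveforms))
  rows <- list()
  for (i in seq_len(nrow(session$units))) {
    uid <- session$units$unit_id[i]
    st <- session$spikes[[as.character(uid)]]
    wf <- session$waveforms[[as.character(uid)]]
    if (length(st) < min_spikes || !length(wf$sites)) next
    f <- extract_features(wf, st, session$rate_hz, min_spikes)
    loc <- tryCatch(localize_soma(wf, session$layout),
                    error = function(e) c(NA_real_, NA_real_))
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = uid, tp_ms = f$tp_ms, burst_index = f$burst_index,
      acg_rise_ms = f$acg_rise_ms,
      label = classify_cell(f$tp_ms, f$acg_rise_ms),
      x_um = loc[1L], y_um = loc[2L]
    )
  }
  do.call(rbind, rows)
}

#' Localize a unit's soma from multi-site amplitudes
#'
#' Amplitude-weighted centroid of the site coordinates, using each site's
#' peak-to-trough amplitude as weight.
#'
#' @param wf per-unit waveform entry.
#' @param layout probe layout.
#' @return `c(x_um, y_um)`.
#' @export
localize_soma <- function(wf, layout) {
  if (!length(wf$sites)) stop("soma localization undefined: no sites")
  amp <- apply(wf$mean_uv, 1L, function(w) max(w) - min(w))
  if (all(amp <= 0)) stop("soma localization undefined: zero amplitudes")
  x <- layout$sites$x_um[wf$sites]; y <- layout$sites$y_um[wf$sites]
  c(sum(amp * x) / sum(amp), sum(amp * y) / sum(amp))
}
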