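# Shared fixtures, built once per test run.

# small full session: units + synapses + waveforms (120 s keeps it fast)
small_session <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- simulate_session(
        seed = 301, duration_s = 120,
        n_per_type = c(pyramidal = 10, narrow_int = 5, wide_int = 3),
        n_synapses = 4)
    }
    memo
  }
})

# default-condition session (600 s, 100 units) for the classification and
# localization checks
default_session <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      s <- generate_units(duration_s = 600, seed = 401)
      memo <<- generate_waveforms(s, seed = 402)
    }
    memo
  }
})

# single-shank session with one opsin+ unit 10 um from LED 10, stimulated
# with the 50 ms / 100 ms tagging protocol
tag_session <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      lay <- build_layout(n_shanks = 1)
      ses <- generate_units(lay,
                            n_per_type = c(pyramidal = 4, narrow_int = 3,
                                           wide_int = 1),
                            duration_s = 42, seed = 501, opsin_fraction = 1)
      ses$units$x_um[5] <- lay$leds$x_um[10] + 10
      ses$units$y_um[5] <- lay$leds$y_um[10]
      ses$units$opsin_positive[1:4] <- FALSE # keep distant pyramidals dark
      prot <- make_pulse_protocol(10, n_pulses = 400, start_s = 1)
      ses <- apply_stimulation(ses, prot, seed = 502)
      memo <<- list(session = ses, protocol = prot, tagged_unit = 5L)
    }
    memo
  }
})

# homogeneous Poisson train on [0, dur]
poisson_train <- function(rate_hz, dur_s) {
  sort(stats::runif(stats::rpois(1, rate_hz * dur_s), 0, dur_s))
}
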