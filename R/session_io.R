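# Session bundle I/O and the end-to-end pipeline driver.
#
# A session directory holds: layout.json, session.json (scalar metadata),
# units.tsv, spikes.tsv, stim.tsv, waveforms.tsv, lfp.bin (flat
# little-endian int16) + lfp.json sidecar, ground_truth.json. All times are
# seconds, positions µm, voltages µV. Tables are TSV (header row, UTF-8,
# '.' decimal); numbers are written with full precision so table round-trips
# are exact.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15,
                sprintf("%.0f", x), sprintf("%.17g", x)))
}

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = colClasses, stringsAsFactors = FALSE)
}

#' Write a session bundle to a directory
#'
#' @param session a `spike_session`.
#' @param path directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_layout(session$layout, file.path(path, "layout.json"))
  jsonlite::write_json(list(duration_s = session$duration_s,
                            rate_hz = session$rate_hz,
                            seed = session$seed),
                       file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_tsv(session$units, file.path(path, "units.tsv"))
  sp <- data.frame(
    unit_id = rep(as.integer(names(session$spikes)),
                  lengths(session$spikes)),
    time_s = unlist(session$spikes, use.names = FALSE))
  sp <- sp[order(sp$time_s, sp$unit_id), ]
  write_tsv(sp, file.path(path, "spikes.tsv"))
  if (!is.null(session$protocol))
    write_tsv(session$protocol, file.path(path, "stim.tsv"))
  if (!is.null(session$waveforms)) {
    wrows <- list()
    for (uid in names(session$waveforms)) {
      wf <- session$waveforms[[uid]]
      if (!length(wf$sites)) next
      wrows[[uid]] <- data.frame(
        unit_id = as.integer(uid),
        site = rep(wf$sites, each = ncol(wf$mean_uv)),
        sample = rep(seq_len(ncol(wf$mean_uv)), length(wf$sites)),
        uv = as.vector(t(wf$mean_uv)))
    }
    write_tsv(do.call(rbind, wrows), file.path(path, "waveforms.tsv"))
  }
  if (!is.null(session$lfp)) {
    x <- session$lfp$samples
    uvb <- session$lfp$uv_per_bit # reuse quantization step on re-write
    if (is.null(uvb)) uvb <- max(abs(x), 1e-12) / 32000
    q <- as.integer(round(t(x) / uvb)) # one channel block after another
    con <- file(file.path(path, "lfp.bin"), "wb")
    writeBin(q, con, size = 2L, endian = "little")
    close(con)
    jsonlite::write_json(list(n_channels = nrow(x), n_samples = ncol(x),
                              rate_hz = session$lfp$rate_hz,
                              uv_per_bit = uvb,
                              channel_sites = session$lfp$channel_sites,
                              order = "channel_major"),
                         file.path(path, "lfp.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  gt <- session$ground_truth
  jsonlite::write_json(gt, file.path(path, "ground_truth.json"),
                       digits = NA, null = "null", dataframe = "columns")
  invisible(path)
}

#' Read a session bundle from a directory
#'
#' Ground truth is optional (real-data mode); binary shape mismatches raise
#' a format error naming the offending field.
#'
#' @param path session directory.
#' @return a `spike_session`.
#' @export
read_session <- function(path) {
  layout <- read_layout(file.path(path, "layout.json"))
  meta <- jsonlite::read_json(file.path(path, "session.json"),
                              simplifyVector = TRUE)
  units <- read_tsv(file.path(path, "units.tsv"))
  sp <- read_tsv(file.path(path, "spikes.tsv"),
                 colClasses = c("integer", "numeric"))
  spikes <- lapply(split(sp$time_s, factor(sp$unit_id,
                                           levels = units$unit_id)), sort)
  names(spikes) <- as.character(units$unit_id)
  protocol <- NULL
  if (file.exists(file.path(path, "stim.tsv")))
    protocol <- read_tsv(file.path(path, "stim.tsv"))
  waveforms <- NULL
  if (file.exists(file.path(path, "waveforms.tsv"))) {
    wl <- read_tsv(file.path(path, "waveforms.tsv"),
                   colClasses = c("integer", "integer", "integer", "numeric"))
    waveforms <- lapply(split(wl, wl$unit_id), function(d) {
      sites <- sort(unique(d$site))
      ns <- max(d$sample)
      m <- matrix(NA_real_, length(sites), ns)
      m[cbind(match(d$site, sites), d$sample)] <- d$uv
      amp <- apply(m, 1L, function(w) max(w) - min(w))
      list(sites = sites, mean_uv = m,
           peak_site = sites[which.max(amp)],
           t_ms = (seq_len(ns) - 1L) / meta$rate_hz * 1000 - 1.6)
    })
    names(waveforms) <- as.character(sort(unique(wl$unit_id)))
    # preserve unit order and include waveform-less units
    waveforms <- waveforms[as.character(units$unit_id)]
    names(waveforms) <- as.character(units$unit_id)
  }
  lfp <- NULL
  if (file.exists(file.path(path, "lfp.json"))) {
    side <- jsonlite::read_json(file.path(path, "lfp.json"),
                                simplifyVector = TRUE)
    fsize <- file.info(file.path(path, "lfp.bin"))$size
    expect <- side$n_channels * side$n_samples * 2
    if (is.na(fsize) || fsize != expect)
      stop(sprintf(
        "lfp.bin size %s does not match sidecar n_channels x n_samples (%d)",
        fsize, expect))
    con <- file(file.path(path, "lfp.bin"), "rb")
    q <- readBin(con, "integer", n = side$n_channels * side$n_samples,
                 size = 2L, signed = TRUE, endian = "little")
    close(con)
    lfp <- list(samples = matrix(q * side$uv_per_bit,
                                 nrow = side$n_channels, byrow = TRUE),
                rate_hz = side$rate_hz,
                channel_sites = side$channel_sites,
                uv_per_bit = side$uv_per_bit)
  }
  gt <- list(synapses = NULL, inserted_spikes = NULL, ripples = NULL,
             evoked_spikes = NULL)
  gt_templates <- list(
    synapses = data.frame(pre = integer(), post = integer(), p = numeric(),
                          latency_ms = numeric(), jitter_ms = numeric()),
    inserted_spikes = data.frame(pre = integer(), post = integer(),
                                 time_s = numeric()),
    ripples = data.frame(channel = integer(), start_s = numeric(),
                         stop_s = numeric(), freq_hz = numeric()),
    evoked_spikes = data.frame(unit = integer(), time_s = numeric()))
  if (file.exists(file.path(path, "ground_truth.json"))) {
    g <- jsonlite::read_json(file.path(path, "ground_truth.json"),
                             simplifyVector = TRUE)
    for (f in names(gt)) {
      if (is.null(g[[f]])) next
      df <- as.data.frame(g[[f]])
      gt[[f]] <- if (nrow(df) && ncol(df)) df else gt_templates[[f]]
    }
  }
  structure(list(layout = layout, duration_s = meta$duration_s,
                 rate_hz = meta$rate_hz, units = units, spikes = spikes,
                 waveforms = waveforms, lfp = lfp, protocol = protocol,
                 ground_truth = gt, seed = meta$seed),
            class = "spike_session")
}

#' Run the full synthetic pipeline
#'
#' Simulate a session, then chain the analysis stages: ripple detection,
#' cell-type classification, optotagging, monosynaptic inference and
#' forward/reverse sequence decoding. A failed stage marks dependent stages
#' skipped; everything is deterministic under the configured seed.
#'
#' @param config list; recognized fields (with defaults): `seed` (1),
#'   `duration_s` (300), `n_per_type` (c(20, 8, 4)), `n_synapses` (8),
#'   `stages` (character vector of stages to run), `n_boot` (500),
#'   `n_label_shuffles` (200), `n_sequence_events` (80), `out` (optional
#'   directory: the session bundle and a JSON report are written there).
#' @return report list: per-stage `status` plus stage summaries.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    seed = 1, duration_s = 300,
    n_per_type = c(pyramidal = 20, narrow_int = 8, wide_int = 4),
    n_synapses = 8,
    stages = c("simulate", "ripples", "classify", "optotag",
               "connectivity", "decode"),
    n_boot = 500, n_label_shuffles = 200, n_sequence_events = 80,
    out = NULL), config)
  report <- list(config = cfg[setdiff(names(cfg), "out")])
  stage_ok <- function(s) s %in% cfg$stages
  failed <- character(0)

  run_stage <- function(name, deps, fun) {
    if (!stage_ok(name)) {
      report$stages[[name]] <<- list(status = "disabled")
      return(invisible(NULL))
    }
    if (length(intersect(deps, failed))) {
      report$stages[[name]] <<- list(
        status = "skipped", reason = paste("failed dependency:",
                                           paste(intersect(deps, failed),
                                                 collapse = ",")))
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      msg <- conditionMessage(res)
      if (startsWith(msg, "skip:")) {
        report$stages[[name]] <<- list(status = "skipped",
                                       reason = trimws(sub("^skip:", "", msg)))
        return(invisible(NULL))
      }
      failed <<- c(failed, name)
      report$stages[[name]] <<- list(status = "failed",
                                     error = msg)
    } else {
      report$stages[[name]] <<- c(list(status = "ok"), res)
    }
    invisible(NULL)
  }

  ses <- NULL
  run_stage("simulate", character(0), function() {
    set.seed(cfg$seed)
    s <- generate_units(n_per_type = cfg$n_per_type,
                        duration_s = cfg$duration_s)
    syn <- make_synapses(s, n_synapses = cfg$n_synapses)
    s <- inject_monosynaptic(s, syn)
    s <- generate_waveforms(s)
    # optotagging pulse train on the LED nearest the median opsin+ unit
    op <- which(s$units$opsin_positive)
    led <- if (length(op)) {
      d2 <- (s$layout$leds$x_um - s$units$x_um[op[1L]])^2 +
        (s$layout$leds$y_um - s$units$y_um[op[1L]])^2
      which.min(d2)
    } else 1L
    prot <- make_pulse_protocol(led, n_pulses = 200, start_s = 5)
    s <- apply_stimulation(s, prot)
    # forward/reverse sequence protocol on one LED per shank
    leds <- vapply(seq_len(s$layout$n_shanks) - 1L, function(sh) {
      cand <- which(s$layout$leds$shank == sh)
      cand[which.min(abs(s$layout$leds$y_um[cand] - 900))]
    }, integer(1))
    if (cfg$n_sequence_events >= 2) {
      t_seq0 <- max(prot$onset_s) + 1
      sprot <- make_sequence_protocol(
        s$layout, leds, n_events = cfg$n_sequence_events,
        start_s = t_seq0, period_s = 0.6)
      sprot <- sprot[sprot$onset_s + sprot$dur_ms / 1000 < s$duration_s, ]
      s <- apply_stimulation(s, sprot)
    }
    s <- generate_lfp(s, seed = cfg$seed + 1)
    ses <<- s
    list(n_units = nrow(s$units), n_spikes = sum(lengths(s$spikes)),
         tag_led = led)
  })

  run_stage("ripples", "simulate", function() {
    stim_iv <- if (!is.null(ses$protocol))
      cbind(ses$protocol$onset_s,
            ses$protocol$onset_s + ses$protocol$dur_ms / 1000) else NULL
    ev <- detect_ripples(ses$lfp, channel = 1L, exclude = stim_iv)
    gt <- ses$ground_truth$ripples
    hit <- 0L
    if (!is.null(gt) && nrow(ev)) {
      mid <- (ev$start_s + ev$stop_s) / 2
      hit <- sum(vapply(seq_len(nrow(gt)), function(k)
        any(mid >= gt$start_s[k] & mid <= gt$stop_s[k]), logical(1)))
    }
    list(n_detected = nrow(ev),
         n_injected = if (is.null(gt)) 0L else nrow(gt),
         n_recovered = hit)
  })

  cls <- NULL
  run_stage("classify", "simulate", function() {
    cls <<- classify_units(ses)
    truth <- ses$units$cell_type[match(cls$unit_id, ses$units$unit_id)]
    list(n_classified = nrow(cls),
         accuracy = mean(cls$label == truth))
  })

  run_stage("optotag", "simulate", function() {
    prot <- ses$protocol[ses$protocol$label == "tag", ]
    tm <- tag_matrix(ses, prot, n_boot = cfg$n_boot, seed = cfg$seed + 2)
    truth <- ses$units$opsin_positive[match(tm$unit_id, ses$units$unit_id)]
    list(n_tagged = sum(tm$tagged),
         n_tagged_opsin_neg = sum(tm$tagged & !truth))
  })

  run_stage("connectivity", c("simulate", "classify"), function() {
    ed <- detect_monosynaptic(ses, classes = data.frame(
      unit_id = cls$unit_id, label = cls$label))
    gt <- ses$ground_truth$synapses
    tp <- if (!is.null(gt))
      sum(paste(ed$pre, ed$post) %in% paste(gt$pre, gt$post)) else 0L
    list(n_edges = nrow(ed), n_pairs = attr(ed, "n_pairs"),
         n_true_recovered = tp)
  })

  run_stage("decode", "simulate", function() {
    sprot <- ses$protocol[ses$protocol$label %in% c("forward", "reverse"), ]
    if (!nrow(sprot)) stop("skip: no sequence protocol present")
    units <- ses$units$unit_id[ses$units$cell_type == "pyramidal" &
                               ses$units$opsin_positive]
    if (length(units) < 3L)
      units <- ses$units$unit_id[ses$units$cell_type == "pyramidal"][1:5]
    dec <- svm_decode(ses, sprot, units = units,
                      n_label_shuffles = cfg$n_label_shuffles,
                      seed = cfg$seed + 3)
    list(accuracy = dec$accuracy, p_value = dec$p_value)
  })

  if (!is.null(cfg$out)) {
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(ses)) write_session(ses, file.path(cfg$out, "session"))
    jsonlite::write_json(report, file.path(cfg$out, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  report
}
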