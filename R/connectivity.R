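# Cross-correlogram computation, convolution-null significance testing,
# spike-transmission probability, and connectivity summaries.

# exact pair counts of (target - ref) lags per bin; edges in seconds
ccg_counts <- function(ref, target, edges_s) {
  ref <- sort(ref); target <- sort(target)
  cum <- vapply(edges_s, function(e) sum(findInterval(ref + e, target)),
                numeric(1))
  diff(cum)
}

#' Cross-correlogram of two spike trains
#'
#' Counts of target spikes in each lag bin relative to every reference
#' spike; bins are centered on integer multiples of `bin_ms` (the default
#' +/-5 ms window at 1 ms bins gives 11 bins, the bin centered on +2 ms
#' covering lags in (1.5, 2.5] ms). Exact and order-independent within
#' bins; `ccg(a, b)` at lag t equals `ccg(b, a)` at -t.
#'
#' @param ref,target spike times (s).
#' @param window_ms half-window (default 5 ms).
#' @param bin_ms bin width (default 1 ms).
#' @return list of class `ccg`: `lag_ms` (bin centers), `count`, `n_ref`,
#'   `n_target`, `bin_ms`. Empty trains give zero counts with a warning.
#' @export
compute_ccg <- function(ref, target, window_ms = 5, bin_ms = 1) {
  nb <- 2L * round(window_ms / bin_ms) + 1L
  lags <- (seq_len(nb) - (nb + 1L) / 2) * bin_ms
  if (!length(ref) || !length(target)) {
    warning("empty spike train; returning empty CCG")
    return(structure(list(lag_ms = lags, count = rep(0, nb),
                          n_ref = length(ref), n_target = length(target),
                          bin_ms = bin_ms), class = "ccg"))
  }
  edges <- (c(lags - bin_ms / 2, lags[nb] + bin_ms / 2)) / 1000
  structure(list(lag_ms = lags, count = ccg_counts(ref, target, edges),
                 n_ref = length(ref), n_target = length(target),
                 bin_ms = bin_ms), class = "ccg")
}

#' Convolution null for a cross-correlogram
#'
#' Expected bin counts under a slowly varying baseline: the CCG is convolved
#' with a partially hollow Gaussian kernel (the central bin's weight scaled
#' by `1 - hollow_fraction`, kernel renormalized, edges handled by
#' renormalizing over the valid support). Per-bin acceptance bounds are
#' Poisson tails at level `alpha`, Bonferroni-corrected over the detection
#' bins.
#'
#' @param counts CCG bin counts (vector over the wide baseline window).
#' @param bin_ms bin width (ms).
#' @param kernel_sd_ms Gaussian kernel SD (default 10 ms).
#' @param hollow_fraction down-weighting of the central bin (default 0.6).
#' @param alpha family-wise level (default 0.001).
#' @param n_detect_bins number of detection bins Bonferroni-corrected for
#'   (default 3).
#' @return data frame: `expected`, `upper`, `lower` per bin.
#' @export
convolution_null <- function(counts, bin_ms = 1, kernel_sd_ms = 10,
                             hollow_fraction = 0.6, alpha = 0.001,
                             n_detect_bins = 3L) {
  nb <- length(counts)
  sd_bins <- kernel_sd_ms / bin_ms
  half <- ceiling(3 * sd_bins)
  if (2L * half + 1L > 2L * nb)
    stop("kernel wider than the CCG support")
  kk <- exp(-0.5 * ((-half:half) / sd_bins)^2)
  kk[half + 1L] <- kk[half + 1L] * (1 - hollow_fraction)
  expected <- numeric(nb)
  for (i in seq_len(nb)) {
    j <- (i - half):(i + half)
    ok <- j >= 1L & j <= nb
    w <- kk[ok]
    expected[i] <- sum(counts[j[ok]] * w) / sum(w)
  }
  a <- alpha / n_detect_bins
  data.frame(expected = expected,
             upper = stats::qpois(1 - a, expected),
             lower = stats::qpois(a, expected))
}

#' Test one ordered pair for an excitatory monosynaptic connection
#'
#' Computes the CCG over a wide (+/-50 ms) baseline window, forms the
#' convolution-null expectation, and flags the pair when any bin inside the
#' 0.5-3 ms detection window exceeds the Poisson upper bound. The spike
#' transmission probability is the summed excess over the detection window
#' per reference spike.
#'
#' @param ref,target spike times (s) of the putative pre/postsynaptic unit.
#' @param alpha significance level (default 0.001).
#' @param detect_window_ms detection lag window (default `c(0.5, 3)`).
#' @param baseline_window_ms half-width of the baseline CCG (default 50).
#' @param bin_ms bin width (default 1 ms).
#' @param kernel_sd_ms,hollow_fraction convolution-null parameters.
#' @return list: `significant`, `stp`, `peak_ms` (most extreme detection
#'   bin), `ccg` (wide-window counts), `null` (bounds), `detect_idx`.
#' @export
ccg_pair_test <- function(ref, target, alpha = 0.001,
                          detect_window_ms = c(0.5, 3),
                          baseline_window_ms = 50, bin_ms = 1,
                          kernel_sd_ms = 10, hollow_fraction = 0.6) {
  cc <- compute_ccg(ref, target, baseline_window_ms, bin_ms)
  didx <- which(cc$lag_ms - bin_ms / 2 >= detect_window_ms[1L] - 1e-9 &
                cc$lag_ms - bin_ms / 2 < detect_window_ms[2L])
  nul <- convolution_null(cc$count, bin_ms, kernel_sd_ms, hollow_fraction,
                          alpha, length(didx))
  sig <- cc$count[didx] > nul$upper[didx]
  stp <- sum(cc$count[didx] - nul$expected[didx]) / max(cc$n_ref, 1L)
  peak <- cc$lag_ms[didx][which.max(cc$count[didx] - nul$expected[didx])]
  list(significant = any(sig), stp = stp, peak_ms = peak,
       ccg = cc, null = nul, detect_idx = didx)
}

#' Detect monosynaptic pyramidal-to-interneuron edges in a session
#'
#' Enumerates ordered pairs with a classified pyramidal reference and a
#' non-pyramidal target, applies [ccg_pair_test()] to each, and returns the
#' significant edges. Spikes inside stimulation pulses are excluded by
#' default so light-driven common input cannot masquerade as connectivity.
#'
#' @param session a `spike_session`.
#' @param classes data frame with `unit_id`, `label` (e.g. from
#'   [classify_units()]); defaults to ground-truth cell types when absent.
#' @param alpha family-wise significance level per pair (default 0.001).
#' @param exclude_stim drop spikes during stimulation pulses (default TRUE).
#' @param min_spikes skip units with fewer spikes (default 100).
#' @param ... passed to [ccg_pair_test()].
#' @return data frame of significant edges: `pre`, `post`, `peak_ms`,
#'   `stp`; attribute `n_pairs` gives the number of pairs tested.
#' @export
detect_monosynaptic <- function(session, classes = NULL, alpha = 0.001,
                                exclude_stim = TRUE, min_spikes = 100,
                                ...) {
  if (is.null(classes))
    classes <- data.frame(unit_id = session$units$unit_id,
                          label = session$units$cell_type)
  spikes <- session$spikes
  if (exclude_stim && !is.null(session$protocol) &&
      nrow(session$protocol)) {
    iv <- cbind(session$protocol$onset_s,
                session$protocol$onset_s + session$protocol$dur_ms / 1000)
    spikes <- lapply(spikes, drop_in_intervals, iv)
  }
  pre_ids <- classes$unit_id[classes$label == "pyramidal"]
  post_ids <- classes$unit_id[classes$label != "pyramidal"]
  edges <- list(); n_pairs <- 0L
  for (a in pre_ids) {
    ra <- spikes[[as.character(a)]]
    if (length(ra) < min_spikes) next
    for (b in post_ids) {
      if (a == b) next
      rb <- spikes[[as.character(b)]]
      if (length(rb) < min_spikes) next
      n_pairs <- n_pairs + 1L
      tst <- ccg_pair_test(ra, rb, alpha = alpha, ...)
      if (tst$significant)
        edges[[length(edges) + 1L]] <- data.frame(
          pre = a, post = b, peak_ms = tst$peak_ms, stp = tst$stp)
    }
  }
  out <- if (length(edges)) do.call(rbind, edges) else
    data.frame(pre = integer(), post = integer(),
               peak_ms = numeric(), stp = numeric())
  attr(out, "n_pairs") <- n_pairs
  out
}

# remove spike times falling inside any [start, stop] interval
drop_in_intervals <- function(st, intervals) {
  if (!length(st) || is.null(intervals) || !nrow(intervals)) return(st)
  o <- order(intervals[, 1L])
  starts <- intervals[o, 1L]; stops <- intervals[o, 2L]
  idx <- findInterval(st, starts)
  inside <- idx >= 1L & st <= stops[pmax(idx, 1L)]
  st[!inside]
}

#' Distance decay of spike-transmission probability
#'
#' Pearson correlation between edge STP and the Euclidean distance between
#' the connected somata, with a permutation p-value from shuffling the
#' distance labels.
#'
#' @param edges edge data frame (`pre`, `post`, `stp`).
#' @param positions data frame with `unit_id`, `x_um`, `y_um`.
#' @param n_perm label permutations (default 10000).
#' @param seed RNG seed (optional).
#' @return list: `r`, `p_value` (two-sided permutation), `n_edges`.
#' @export
distance_decay <- function(edges, positions, n_perm = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(edges) < 10L)
    stop("need at least 10 edges with localized somata")
  i <- match(edges$pre, positions$unit_id)
  j <- match(edges$post, positions$unit_id)
  d <- sqrt((positions$x_um[i] - positions$x_um[j])^2 +
            (positions$y_um[i] - positions$y_um[j])^2)
  ok <- is.finite(d) & is.finite(edges$stp)
  d <- d[ok]; s <- edges$stp[ok]
  if (stats::sd(d) == 0 || stats::sd(s) == 0)
    stop("degenerate variance; correlation undefined")
  r <- stats::cor(s, d)
  null_r <- vapply(seq_len(n_perm),
                   function(k) stats::cor(s, sample(d)), numeric(1))
  list(r = r, p_value = mean(abs(null_r) >= abs(r)), n_edges = length(d))
}

#' Connection-count and motif summary
#'
#' Per-cell connection counts, divergence motifs (one presynaptic cell onto
#' several targets), convergence motifs (several presynaptic cells onto one
#' target), and optional per-class summaries of connections per cell.
#'
#' @param edges edge data frame (`pre`, `post`).
#' @param classes optional data frame `unit_id`, `class` (e.g. optotag
#'   labels) for the per-class summary.
#' @return list: `per_cell` (unit, out_degree, in_degree, total),
#'   `divergence` (pre, size), `convergence` (post, size), `per_class`
#'   (class, mean, sd, n) or NULL.
#' @export
motif_summary <- function(edges, classes = NULL) {
  if (!nrow(edges)) {
    per_cell <- data.frame(unit = integer(), out_degree = integer(),
                           in_degree = integer(), total = integer())
    return(list(per_cell = per_cell,
                divergence = data.frame(pre = integer(), size = integer()),
                convergence = data.frame(post = integer(), size = integer()),
                per_class = NULL))
  }
  units <- sort(unique(c(edges$pre, edges$post)))
  outd <- as.integer(table(factor(edges$pre, levels = units)))
  ind <- as.integer(table(factor(edges$post, levels = units)))
  per_cell <- data.frame(unit = units, out_degree = outd, in_degree = ind,
                         total = outd + ind)
  dv <- per_cell[per_cell$out_degree >= 2L, c("unit", "out_degree")]
  cv <- per_cell[per_cell$in_degree >= 2L, c("unit", "in_degree")]
  names(dv) <- c("pre", "size"); names(cv) <- c("post", "size")
  per_class <- NULL
  if (!is.null(classes)) {
    m <- merge(per_cell, classes, by.x = "unit", by.y = "unit_id")
    if (nrow(m)) {
      agg <- stats::aggregate(total ~ class, m,
                              function(v) c(mean = mean(v), sd = stats::sd(v),
                                            n = length(v)))
      per_class <- data.frame(class = agg$class,
                              mean = agg$total[, "mean"],
                              sd = agg$total[, "sd"],
                              n = agg$total[, "n"])
    }
  }
  list(per_cell = per_cell, divergence = dv, convergence = cv,
       per_class = per_class)
}
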