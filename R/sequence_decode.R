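# Rank-order readout of forward vs reverse upstream stimulation, and
# linear decoding of the input pattern from downstream population activity.

#' Event windows of a sequential stimulation protocol
#'
#' @param protocol stimulation data frame with an `event` column.
#' @return data frame: `event`, `condition`, `t0`, `t1` (first pulse onset
#'   to last pulse offset).
#' @export
event_windows <- function(protocol) {
  stopifnot(all(c("event", "label", "onset_s", "dur_ms") %in% names(protocol)))
  ev <- split(protocol, protocol$event)
  out <- do.call(rbind, lapply(ev, function(p) data.frame(
    event = p$event[1L], condition = p$label[1L],
    t0 = min(p$onset_s), t1 = max(p$onset_s + p$dur_ms / 1000))))
  out[order(out$t0), ]
}

#' Per-event normalized firing sequences
#'
#' For each stimulation event, the center of mass (COM) of each
#' participating unit's spikes inside the event window, min-max normalized
#' to [0, 1] within the window. Units silent in an event are excluded from
#' it; events with fewer than 2 active units are skipped (logged as an
#' attribute).
#'
#' @param session a `spike_session`.
#' @param protocol sequential protocol (defaults to the session's).
#' @param units unit ids to include (typically downstream pyramidal cells);
#'   default: units classified pyramidal in the ground truth and located in
#'   the `region` band.
#' @param region region label used for the default unit selection
#'   (default "CA1").
#' @return long data frame: `event`, `condition`, `unit`, `com` in [0, 1];
#'   attribute `skipped` lists events with < 2 active units.
#' @export
build_sequences <- function(session, protocol = session$protocol,
                            units = NULL, region = "CA1") {
  if (is.null(protocol)) stop("no stimulation protocol")
  if (is.null(units)) {
    u <- session$units
    units <- u$unit_id[u$cell_type == "pyramidal" & u$region == region]
  }
  wins <- event_windows(protocol)
  rows <- list(); skipped <- integer(0)
  for (k in seq_len(nrow(wins))) {
    w <- wins[k, ]
    ev_rows <- list()
    for (uid in units) {
      st <- session$spikes[[as.character(uid)]]
      sel <- st[st >= w$t0 & st <= w$t1]
      if (!length(sel)) next
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        event = w$event, condition = w$condition, unit = uid,
        com = (mean(sel) - w$t0) / (w$t1 - w$t0))
    }
    if (length(ev_rows) < 2L) skipped <- c(skipped, w$event)
    else rows <- c(rows, ev_rows)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event = integer(), condition = character(),
               unit = integer(), com = numeric())
  attr(out, "skipped") <- skipped
  out
}

#' Rank-order correlation between two event sequences
#'
#' Pearson correlation of the firing-order ranks of the units shared by the
#' two events (Spearman-type); undefined below 3 shared units.
#'
#' @param seq_a,seq_b data frames with `unit` and `com` (one event each).
#' @return correlation in [-1, 1], or `NA` with fewer than 3 shared units
#'   or degenerate ranks.
#' @export
rank_correlation <- function(seq_a, seq_b) {
  shared <- intersect(seq_a$unit, seq_b$unit)
  if (length(shared) < 3L) return(NA_real_)
  ra <- rank(seq_a$com[match(shared, seq_a$unit)])
  rb <- rank(seq_b$com[match(shared, seq_b$unit)])
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) return(NA_real_)
  stats::cor(ra, rb)
}

# COM matrix (units x events) from a long sequence table
com_matrix <- function(sequences) {
  units <- sort(unique(sequences$unit))
  evs <- unique(sequences$event)
  m <- matrix(NA_real_, length(units), length(evs),
              dimnames = list(units, evs))
  m[cbind(match(sequences$unit, units), match(sequences$event, evs))] <-
    sequences$com
  m
}

# pairwise rank correlations from a COM matrix: columns are ranked within
# event, correlations use pairwise-complete shared units (>= min_shared)
pairwise_rank_cor <- function(m, min_shared = 3L) {
  rk <- apply(m, 2L, function(v) { v[!is.na(v)] <- rank(v[!is.na(v)]); v })
  suppressWarnings(cm <- stats::cor(rk, use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(m))
  cm[shared < min_shared] <- NA
  diag(cm) <- NA
  cm
}

#' Within- versus between-condition sequence correlation test
#'
#' Pairwise rank-order correlations of all event pairs, split into
#' within-condition (forward-forward plus reverse-reverse) and
#' between-condition sets; reports a rank-sum test of within > between and
#' a shuffle null in which unit identities are permuted within each event.
#'
#' @param sequences long data frame from [build_sequences()].
#' @param n_shuffle unit-identity shuffles (default 1000).
#' @param seed RNG seed (optional).
#' @return list: `r_within`, `r_between` (vectors), `p_ranksum`
#'   (one-sided within > between), `diff_obs` (mean within - mean between),
#'   `diff_null` (shuffle distribution), `p_shuffle`.
#' @export
sequence_shuffle_test <- function(sequences, n_shuffle = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conds <- unique(sequences$condition)
  if (length(conds) < 2L)
    stop("both conditions required for the between-condition comparison")
  m <- com_matrix(sequences)
  ev_cond <- sequences$condition[match(colnames(m), sequences$event)]
  split_rs <- function(cm) {
    same <- outer(ev_cond, ev_cond, "==")
    ut <- upper.tri(cm)
    list(within = cm[ut & same][!is.na(cm[ut & same])],
         between = cm[ut & !same][!is.na(cm[ut & !same])])
  }
  rs <- split_rs(pairwise_rank_cor(m))
  p_rank <- stats::wilcox.test(rs$within, rs$between,
                               alternative = "greater", exact = FALSE)$p.value
  diff_obs <- mean(rs$within) - mean(rs$between)
  diff_null <- vapply(seq_len(n_shuffle), function(k) {
    ms <- apply(m, 2L, function(v) {
      ok <- !is.na(v); v[ok] <- v[ok][sample.int(sum(ok))]; v
    })
    r0 <- split_rs(pairwise_rank_cor(ms))
    mean(r0$within) - mean(r0$between)
  }, numeric(1))
  list(r_within = rs$within, r_between = rs$between,
       p_ranksum = p_rank, diff_obs = diff_obs, diff_null = diff_null,
       p_shuffle = mean(diff_null >= diff_obs))
}

#' Linear decoding of the stimulation pattern from population spike trains
#'
#' Features are concatenated per-unit binned spike counts over each event
#' window; a linear max-margin classifier (SVM, cost `cost`) is trained on
#' a stratified half of the events and evaluated on the held-out half.
#' Significance is the fraction of label-shuffled re-fits whose held-out
#' accuracy reaches the observed one.
#'
#' @param session a `spike_session`.
#' @param protocol sequential protocol (defaults to the session's).
#' @param units unit ids used as features (default: same selection as
#'   [build_sequences()]).
#' @param region region label for the default unit selection.
#' @param bin_ms feature bin width (default 10 ms).
#' @param window_ms feature window from each event's first pulse onset
#'   (e.g. 120 ms, the stimulation-pulse duration); `NULL` (default) uses
#'   the full first-onset-to-last-offset event span.
#' @param train_fraction training fraction (default 0.5, stratified).
#' @param n_label_shuffles shuffles for the null (default 10000).
#' @param cost SVM regularization (default 1).
#' @param seed RNG seed (optional).
#' @return list: `accuracy`, `p_value`, `n_features`, `n_train`, `n_test`,
#'   `shuffle_acc` (null accuracies).
#' @export
svm_decode <- function(session, protocol = session$protocol, units = NULL,
                       region = "CA1", bin_ms = 10, window_ms = NULL,
                       train_fraction = 0.5,
                       n_label_shuffles = 10000, cost = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(protocol)) stop("no stimulation protocol")
  if (is.null(units)) {
    u <- session$units
    units <- u$unit_id[u$cell_type == "pyramidal" & u$region == region]
  }
  wins <- event_windows(protocol)
  if (min(table(wins$condition)) < 20L)
    stop("need at least 20 events per condition")
  wlen <- if (is.null(window_ms)) max(wins$t1 - wins$t0) else window_ms / 1000
  nb <- ceiling(wlen * 1000 / bin_ms)
  feats <- matrix(0, nrow(wins), length(units) * nb)
  for (k in seq_len(nrow(wins))) {
    w <- wins[k, ]
    for (ui in seq_along(units)) {
      st <- session$spikes[[as.character(units[ui])]]
      sel <- st[st >= w$t0 & st < w$t0 + nb * bin_ms / 1000]
      if (length(sel)) {
        b <- floor((sel - w$t0) * 1000 / bin_ms) + 1L
        tb <- tabulate(b, nbins = nb)
        feats[k, ((ui - 1L) * nb + 1L):(ui * nb)] <- tb
      }
    }
  }
  y <- factor(wins$condition)
  train <- unlist(lapply(levels(y), function(lv) {
    idx <- which(y == lv)
    sample(idx, round(length(idx) * train_fraction))
  }))
  test <- setdiff(seq_along(y), train)
  fit_acc <- function(labels) {
    fit <- e1071::svm(feats[train, , drop = FALSE], labels[train],
                      type = "C-classification", kernel = "linear",
                      cost = cost, scale = FALSE)
    mean(stats::predict(fit, feats[test, , drop = FALSE]) == y[test])
  }
  acc <- fit_acc(y)
  shuffle_acc <- vapply(seq_len(n_label_shuffles),
                        function(k) fit_acc(sample(y)), numeric(1))
  list(accuracy = acc, p_value = mean(shuffle_acc >= acc),
       n_features = ncol(feats), n_train = length(train),
       n_test = length(test), shuffle_acc = shuffle_acc)
}
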