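# Measurement layer: spike and complex-spike detection, segmentation of
# the spike train into tonic / burst / quiescent / cf_pause modes, toggle
# statistics and tonic-rate computation.
#
# The detection constants (spike threshold -20 mV, refractory 2 ms,
# quiescence gap 500 ms, burst-association window 50 ms, complex-spike
# onset/extent windows 5/15 ms, cf-pause ceiling 100 ms) are analysis
# choices fixed from the scale of the model's waveforms; all are
# overridable arguments.

#' Detect somatic spikes in a sampled voltage trace
#'
#' Upward crossings of the threshold with a refractory window, aligned to
#' the local maximum following each crossing.
#'
#' @param trace a `purksim_trace`, or a list with `t` (ms) and a voltage
#'   matrix `v`.
#' @param compartment column of `v` to use (name or index).
#' @param threshold crossing threshold, mV.
#' @param refractory minimum spike separation, ms.
#' @return vector of peak-aligned spike times, ms.
#' @export
detect_spikes <- function(trace, compartment = "soma", threshold = -20,
                          refractory = 2) {
  if (is.null(trace$v) || is.null(trace$t)) stop("analysis error: trace lacks t/v")
  v <- trace$v[, compartment]
  t <- trace$t
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (!length(up)) return(numeric(0))
  dtm <- stats::median(diff(t))
  peaks <- vapply(up, function(i) {
    j <- i:min(length(v), i + max(1, ceiling(refractory / dtm)))
    t[j[which.max(v[j])]]
  }, numeric(1))
  keep <- c(TRUE, diff(peaks) > refractory)
  peaks[keep]
}

#' Detect CF-evoked complex spikes
#'
#' A complex spike is a somatic multi-spike event (at least `min_spikes`
#' somatic spikes within `extent` ms) whose first spike falls within
#' `onset` ms after a CF event, coincident with a dendritic Ca2+ spike
#' (a smooth-compartment crossing within `ca_window` ms of the CF event).
#' Burst events without a CF input are excluded by construction.
#'
#' @param spikes somatic spike times, ms.
#' @param dend_spikes dendritic Ca-spike times, ms.
#' @param cf_events CF event times, ms.
#' @param onset,extent,ca_window detection windows, ms.
#' @param min_spikes spikelet count required (default 1: the model's
#'   complex spike expresses a single large somatic spikelet).
#' @return times of detected complex-spike onsets, ms.
#' @export
detect_complex_spikes <- function(spikes, dend_spikes, cf_events,
                                  onset = 5, extent = 15, ca_window = 10,
                                  min_spikes = 1) {
  if (!length(cf_events)) return(numeric(0))
  out <- vapply(cf_events, function(e) {
    first <- spikes[spikes >= e & spikes <= e + onset]
    if (!length(first)) return(NA_real_)
    s0 <- first[1]
    if (sum(spikes >= s0 & spikes <= s0 + extent) < min_spikes)
      return(NA_real_)
    if (!any(dend_spikes >= e & dend_spikes <= e + ca_window))
      return(NA_real_)
    s0
  }, numeric(1))
  out[!is.na(out)]
}

#' Segment a spike train into firing modes
#'
#' Tiles the analysis window with labelled intervals:
#' \itemize{
#'   \item quiescent: inter-spike gap above `quiescent_gap` (500 ms);
#'   \item cf_pause: a complex spike and its evoked after-pause (gap to
#'     the next spike at most `cf_pause_max` ms);
#'   \item burst: firing accompanied by dendritic Ca2+ spikes (a Ca spike
#'     within `burst_window` ms of the somatic spike);
#'   \item tonic: all remaining firing.
#' }
#' Contiguous same-label intervals are merged. Boundaries between runs of
#' differently-labelled spikes are placed midway between the bounding
#' spikes.
#'
#' @param spikes somatic spike times, ms (sorted).
#' @param ca_spikes dendritic Ca-spike times, ms.
#' @param window `c(start, end)` of the analysis window, ms.
#' @param complex_spikes complex-spike onset times (from
#'   [detect_complex_spikes()]).
#' @param quiescent_gap,burst_window,cf_pause_max,complex_extent windows, ms.
#' @return data frame with `start`, `end`, `label`, `n_spikes`,
#'   `rate_hz`; intervals tile the window without overlap.
#' @export
segment_modes <- function(spikes, ca_spikes, window,
                          complex_spikes = numeric(0),
                          quiescent_gap = 500, burst_window = 50,
                          cf_pause_max = 100, complex_extent = 15) {
  w0 <- window[1]; w1 <- window[2]
  s <- sort(spikes[spikes >= w0 & spikes <= w1])
  if (!length(s))
    return(data.frame(start = w0, end = w1, label = "quiescent",
                      n_spikes = 0L, rate_hz = 0))

  # per-spike labels
  lab <- rep("tonic", length(s))
  if (length(ca_spikes))
    lab[vapply(s, function(x) any(abs(ca_spikes - x) <= burst_window),
               logical(1))] <- "burst"
  if (length(complex_spikes))
    lab[vapply(s, function(x)
      any(x >= complex_spikes & x <= complex_spikes + complex_extent),
      logical(1))] <- "cf_pause"

  segs <- list()
  add <- function(start, end, label, n) {
    if (end > start)
      segs[[length(segs) + 1L]] <<- data.frame(
        start = start, end = end, label = label, n_spikes = n)
  }

  # leading / trailing quiescence
  lead_q <- (s[1] - w0) > quiescent_gap
  trail_q <- (w1 - s[length(s)]) > quiescent_gap
  if (lead_q) add(w0, s[1], "quiescent", 0L)

  # split into firing epochs at large gaps
  gap_after <- c(diff(s) > quiescent_gap, FALSE)
  epoch_id <- cumsum(c(0, head(gap_after, -1)))
  start_prev <- if (lead_q) s[1] else w0
  for (ep in unique(epoch_id)) {
    idx <- which(epoch_id == ep)
    ss <- s[idx]; ll <- lab[idx]
    ep_start <- if (ep == epoch_id[1]) start_prev else ss[1]
    ep_end <- if (idx[length(idx)] == length(s) && !trail_q) w1
              else ss[length(ss)]
    # run-length encode labels inside the epoch
    runs <- rle(ll)
    pos <- ep_start
    cume <- cumsum(runs$lengths)
    for (ri in seq_along(runs$values)) {
      last_i <- cume[ri]
      run_end <- if (ri == length(runs$values)) ep_end
                 else (ss[last_i] + ss[last_i + 1]) / 2
      label <- runs$values[ri]
      if (label == "cf_pause") {
        # extend through the evoked after-pause (gap to next spike)
        nxt <- s[s > ss[last_i]]
        pe <- ss[last_i] + if (length(nxt)) min(nxt[1] - ss[last_i],
                                                cf_pause_max) else cf_pause_max
        run_end <- max(run_end, min(pe, ep_end))
      }
      add(pos, run_end, label, runs$lengths[ri])
      pos <- run_end
    }
    # quiescent gap to the next epoch
    nxt_idx <- which(epoch_id == ep + 1)
    if (length(nxt_idx)) add(ss[length(ss)], s[nxt_idx[1]], "quiescent", 0L)
  }
  if (trail_q) add(s[length(s)], w1, "quiescent", 0L)

  out <- do.call(rbind, segs)
  # merge contiguous same-label intervals
  keep <- c(TRUE, out$label[-1] != out$label[-nrow(out)])
  grp <- cumsum(keep)
  out <- do.call(rbind, lapply(split(out, grp), function(d)
    data.frame(start = d$start[1], end = d$end[nrow(d)], label = d$label[1],
               n_spikes = sum(d$n_spikes))))
  rownames(out) <- NULL
  out$rate_hz <- ifelse(out$end > out$start,
                        1000 * out$n_spikes / (out$end - out$start), 0)
  out
}

#' Pooled tonic-mode firing frequency
#'
#' Total spike count over total duration of the tonic intervals (Hz);
#' complex spikes and their pauses sit in their own intervals and are
#' therefore excluded.
#'
#' @param seg segmentation data frame from [segment_modes()].
#' @return pooled tonic rate, Hz; `NA` (with a warning) if no tonic
#'   interval exists.
#' @export
tonic_frequency <- function(seg) {
  tn <- seg[seg$label == "tonic", , drop = FALSE]
  if (!nrow(tn)) { warning("no tonic interval in segmentation"); return(NA_real_) }
  1000 * sum(tn$n_spikes) / sum(tn$end - tn$start)
}

#' Trimodal repeat and firing lengths
#'
#' Repeat length: time between successive quiescent-to-firing transitions
#' (averaged when more than one full repeat is present). Firing length:
#' duration of the contiguous tonic+burst span between quiescent periods.
#' Only quiescent intervals longer than `min_quiescent` count as the
#' trimodal quiescent mode.
#'
#' @param seg segmentation data frame.
#' @param min_quiescent minimum quiescent-mode duration, ms.
#' @return list with `repeat_length` and `firing_length`, ms (NA when the
#'   window contains fewer than two transitions / no complete firing span).
#' @export
trimodal_repeat_length <- function(seg, min_quiescent = 1000) {
  q <- seg$label == "quiescent" & (seg$end - seg$start) > min_quiescent
  trans <- numeric(0)  # quiescent -> firing transition times
  for (i in which(q))
    if (i < nrow(seg) && seg$label[i + 1] %in% c("tonic", "burst"))
      trans <- c(trans, seg$end[i])
  rep_len <- if (length(trans) >= 2) mean(diff(trans)) else NA_real_
  # firing spans: between a quiescent end and the next quiescent start
  qi <- which(q)
  fl <- NA_real_
  if (length(qi) >= 2) {
    spans <- vapply(seq_len(length(qi) - 1), function(k)
      seg$start[qi[k + 1]] - seg$end[qi[k]], numeric(1))
    fl <- mean(spans)
  }
  list(repeat_length = rep_len, firing_length = fl)
}

#' Toggle statistics of a CF-driven spike train
#'
#' Classifies each inter-CF interval (excluding the `exclude` ms that
#' contain the complex spike itself) as up (mean rate above `up_rate` Hz)
#' or down, merges consecutive same-state intervals into runs, and
#' reports: the fraction of CF events that flip the state, duration lists
#' of up and down runs, and pump silences (down runs spanning more than
#' `silence_span` consecutive CF events, which are excluded from the
#' median down duration).
#'
#' @param spikes somatic spike times, ms.
#' @param cf_events CF event times, ms.
#' @param exclude post-CF exclusion window, ms.
#' @param up_rate rate threshold, Hz.
#' @param silence_span CF events a down run must span to count as a pump
#'   silence.
#' @return list with `states`, `flip_fraction`, `up_durations`,
#'   `down_durations`, `median_up`, `median_down`, `pump_silences`.
#' @export
toggle_statistics <- function(spikes, cf_events, exclude = 100,
                              up_rate = 20, silence_span = 3) {
  cf <- sort(cf_events)
  if (length(cf) < 2) stop("analysis error: need at least two CF events")
  n <- length(cf) - 1
  state <- character(n); dur <- numeric(n)
  for (k in seq_len(n)) {
    a <- cf[k] + exclude; b <- cf[k + 1]
    rate <- if (b > a) 1000 * sum(spikes > a & spikes <= b) / (b - a) else 0
    state[k] <- if (rate > up_rate) "up" else "down"
    dur[k] <- cf[k + 1] - cf[k]
  }
  flips <- state[-1] != state[-n]
  runs <- rle(state)
  ends <- cumsum(runs$lengths); starts <- c(1, head(ends, -1) + 1)
  run_df <- data.frame(
    state = runs$values,
    start = cf[starts], end = cf[ends + 1],
    n_cf = runs$lengths)
  run_df$duration <- run_df$end - run_df$start
  silences <- run_df[run_df$state == "down" & run_df$n_cf > silence_span, ,
                     drop = FALSE]
  down_reg <- run_df[run_df$state == "down" & run_df$n_cf <= silence_span, ]
  up_runs <- run_df[run_df$state == "up", ]
  list(states = state,
       flip_fraction = if (length(flips)) mean(flips) else NA_real_,
       up_durations = up_runs$duration,
       down_durations = down_reg$duration,
       median_up = if (nrow(up_runs)) stats::median(up_runs$duration) else NA_real_,
       median_down = if (nrow(down_reg)) stats::median(down_reg$duration) else NA_real_,
       pump_silences = silences, runs = run_df)
}

#' Post-complex-spike pause lengths
#'
#' For each complex spike, the gap between its last spikelet and the next
#' simple spike.
#'
#' @param spikes somatic spike times, ms.
#' @param complex_spikes complex-spike onsets, ms.
#' @param extent spikelet window after the onset, ms.
#' @param median return the median (default) or the vector of gaps.
#' @return pause length(s), ms.
#' @export
cf_pause_lengths <- function(spikes, complex_spikes, extent = 15,
                             median = TRUE) {
  gaps <- vapply(complex_spikes, function(c0) {
    inb <- spikes[spikes >= c0 & spikes <= c0 + extent]
    last <- if (length(inb)) max(inb) else c0
    nxt <- spikes[spikes > last]
    if (length(nxt)) nxt[1] - last else NA_real_
  }, numeric(1))
  gaps <- gaps[!is.na(gaps)]
  if (median) stats::median(gaps) else gaps
}
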