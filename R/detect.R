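#' Spike detection parameters
#'
#' @param threshold_mult detection threshold in multiples of the robust noise
#'   estimate (median absolute deviation / 0.6745).
#' @param refractory_ms minimum separation between detected events, ms.
#' @param waveform_window_ms length-2 `(pre, post)` waveform window around the
#'   trough, ms.
#' @param cs_spikelet_window_ms window after a complex-spike trough whose
#'   energy identifies complex spikes and within which trailing detections are
#'   absorbed into the complex spike, ms.
#' @return a `detection_params` list.
#' @export
detection_params <- function(threshold_mult = 4.5, refractory_ms = 1.0,
                             waveform_window_ms = c(1.0, 3.0),
                             cs_spikelet_window_ms = 6.0) {
  if (threshold_mult <= 0 || refractory_ms <= 0 ||
      any(waveform_window_ms <= 0) || cs_spikelet_window_ms <= 0)
    stop_invalid("detection parameters must be positive")
  structure(list(threshold_mult = threshold_mult,
                 refractory_ms = refractory_ms,
                 waveform_window_ms = waveform_window_ms,
                 cs_spikelet_window_ms = cs_spikelet_window_ms),
            class = "detection_params")
}

#' Detect threshold-crossing events in a band-passed trace
#'
#' Estimates the noise scale as `mad(x)` (median absolute deviation scaled by
#' 1/0.6745), thresholds negative-going excursions at
#' `-threshold_mult * sigma`, aligns each event on its trough, and merges
#' events closer than the refractory period (keeping the deeper trough).
#'
#' @param trace a [voltage_trace()] (band-passed).
#' @param params a [detection_params()].
#' @return numeric vector of event times (s, trough-aligned), with the noise
#'   `sigma` and `threshold` as attributes.
#' @export
detect_events <- function(trace, params = detection_params()) {
  fs <- sampling_rate(trace)
  v <- as.numeric(trace)
  win_n <- sum(round(params$waveform_window_ms * fs / 1000))
  if (length(v) < win_n) {
    warning("trace shorter than one waveform window; no events detected")
    return(structure(numeric(0), sigma = NA_real_, threshold = NA_real_))
  }
  # (near-)noiseless traces: mad picks up only filter ringing (<<1% of the
  # spike amplitude); floor the scale so the threshold stays meaningful
  sigma <- mad(v)
  if (sigma < max(abs(v)) * 5e-3) sigma <- max(abs(v)) / 10
  thr <- -params$threshold_mult * sigma
  below <- v < thr
  if (!any(below)) return(structure(numeric(0), sigma = sigma, threshold = thr))
  # contiguous sub-threshold runs -> one candidate per run, trough aligned
  d <- diff(c(FALSE, below, FALSE))
  starts <- which(d == 1L); ends <- which(d == -1L) - 1L
  troughs <- mapply(function(s, e) s - 1L + which.min(v[s:e]), starts, ends)
  amps <- v[troughs]
  # enforce refractory separation, keeping the deeper trough
  ref_n <- params$refractory_ms * fs / 1000
  res_t <- integer(0); res_a <- numeric(0)
  for (i in seq_along(troughs)) {
    last <- length(res_t)
    if (last > 0L && troughs[i] - res_t[last] < ref_n) {
      if (amps[i] < res_a[last]) {  # deeper trough wins
        res_t[last] <- troughs[i]; res_a[last] <- amps[i]
      }
    } else {
      res_t <- c(res_t, troughs[i]); res_a <- c(res_a, amps[i])
    }
  }
  structure((res_t - 1L) / fs, sigma = sigma, threshold = thr)
}

#' Extract trough-aligned waveform snippets
#'
#' @param trace a [voltage_trace()].
#' @param times event times (s, trough-aligned).
#' @param window_ms length-2 `(pre, post)` window, ms.
#' @return matrix with one row per retained event (`pre+post` samples); events
#'   whose window is clipped by the trace edges are dropped and counted in the
#'   `n_dropped` attribute; the retained times are in the `times` attribute.
#' @export
extract_waveforms <- function(trace, times,
                              window_ms = c(1.0, 3.0)) {
  fs <- sampling_rate(trace)
  pre_n <- round(window_ms[1] * fs / 1000)
  post_n <- round(window_ms[2] * fs / 1000)
  if (length(times) == 0) {
    out <- matrix(numeric(0), 0, pre_n + post_n)
    return(structure(out, n_dropped = 0L, times = numeric(0)))
  }
  idx <- round(as.numeric(times) * fs) + 1L
  ok <- idx - pre_n >= 1L & idx + post_n - 1L <= length(trace)
  rows <- t(vapply(idx[ok], function(i)
    as.numeric(trace)[(i - pre_n):(i + post_n - 1L)], numeric(pre_n + post_n)))
  if (sum(ok) == 1) rows <- matrix(rows, 1)
  structure(rows, n_dropped = sum(!ok), times = as.numeric(times)[ok])
}

#' Classify detected events as simple or complex spikes
#'
#' Complex spikes carry spikelets, hence extra energy after the trough. The
#' classifier is an unsupervised two-stage split of the post-trough energies:
#'
#' 1. *Energy outliers.* Each event's waveform is smoothed with a ~0.3 ms
#'    moving average (white-noise power drops ~k-fold; spikelets, correlated
#'    over ~1 ms, survive) and the log mean-square energy in
#'    `(refractory, cs_spikelet_window]` ms is computed, truncating the
#'    window at the next detected event so a simple spike closely followed by
#'    another full-amplitude spike sees only noise. Events more than 3 robust
#'    standard deviations (MAD) above the median energy become candidates.
#' 2. *Spikelet verification.* A candidate is labelled complex only if its
#'    window holds at least two local minima deeper than the spikelet
#'    threshold (3 x smoothed noise SD, floored at 15% of the trough depth),
#'    and no minimum approaching full spike depth (>65% of the trough, which
#'    marks a merged spike pair rather than spikelets).
#'
#' The feature window should extend to `cs_spikelet_window_ms`, so pass
#' waveforms extracted with a post-window at least that long. If no event
#' passes both stages, or the high-energy class is not a clear minority, all
#' events are labelled simple and the `no_complex` flag is set.
#'
#' @param waveforms waveform matrix from [extract_waveforms()] (trough at
#'   column `pre` + 1).
#' @param times event times matching the rows of `waveforms`.
#' @param params a [detection_params()].
#' @param fs_hz sampling rate of the waveforms, Hz.
#' @param window_ms the `(pre, post)` window used at extraction, ms.
#' @return character vector of labels (`"simple"`/`"complex"`) with attribute
#'   `no_complex` (logical).
#' @export
classify_events <- function(waveforms, times, params = detection_params(),
                            fs_hz, window_ms = c(1.0, 3.0)) {
  n_ev <- nrow(waveforms)
  if (n_ev == 0) return(structure(character(0), no_complex = TRUE))
  pre_n <- round(window_ms[1] * fs_hz / 1000)
  from <- pre_n + 1L + round(params$refractory_ms * fs_hz / 1000)
  to <- min(ncol(waveforms),
            pre_n + round(params$cs_spikelet_window_ms * fs_hz / 1000))
  times <- as.numeric(times)
  # ~0.3 ms moving average: white-noise power drops ~k-fold, spikelet power
  # (correlated over ~1 ms) survives
  k <- max(3L, round(0.3 * fs_hz / 1000))
  if (k %% 2L == 0L) k <- k + 1L
  sm <- t(apply(waveforms, 1, function(r)
    as.numeric(stats::filter(r, rep(1 / k, k), sides = 2, circular = TRUE))))
  gap_to_next <- c(diff(times), Inf)
  min_cols <- round(2e-3 * fs_hz)  # need >= 2 ms of usable post-trough window
  usable_hi <- vapply(seq_len(n_ev), function(i)
    min(to, pre_n + floor((gap_to_next[i] - 0.5e-3) * fs_hz)), numeric(1))
  feat <- vapply(seq_len(n_ev), function(i) {
    if (usable_hi[i] - from + 1 < min_cols) return(NA_real_)
    log10(mean(sm[i, from:usable_hi[i]]^2) + 1e-12)
  }, numeric(1))
  ok <- !is.na(feat)
  labels <- rep("simple", n_ev)
  degenerate <- TRUE
  if (sum(ok) >= 4) {
    med <- median(feat[ok]); spread <- mad(feat[ok])
    cand <- which(ok & feat > med + 3 * spread)
    if (length(cand)) {
      # verify candidates by their spikelets: >= 2 local minima below
      # -3 * (smoothed noise sd) in the post-trough window
      front_n <- max(2L, round(0.3e-3 * fs_hz))
      sigma_sm <- mad(as.numeric(sm[ok, seq_len(front_n)]))
      # floor for (near-)noiseless traces so filter ringing (a few % of the
      # trough) never counts as a spikelet, which sits at ~25% of the trough
      med_depth <- median(-sm[ok, pre_n + 1L])
      v_thr <- -max(3 * sigma_sm, 0.15 * med_depth)
      verified <- vapply(cand, function(i) {
        seg <- sm[i, from:usable_hi[i]]
        n <- length(seg)
        if (n < 3) return(FALSE)
        mid <- 2:(n - 1)
        n_spikelets <- sum(seg[mid] < seg[mid - 1] & seg[mid] <= seg[mid + 1] &
                             seg[mid] < v_thr)
        # spikelets are much shallower than a full spike: a near-full-depth
        # trough in the window is a merged spike pair, not a complex spike
        depth <- -sm[i, pre_n + 1L]
        n_spikelets >= 2 && min(seg) > -0.65 * depth
      }, logical(1))
      hit <- cand[verified]
      if (length(hit) && length(hit) < 0.4 * n_ev) {
        labels[hit] <- "complex"
        degenerate <- FALSE
      }
    }
  }
  structure(labels, no_complex = degenerate)
}

#' Verify the post-complex-spike pause
#'
#' Fraction of complex spikes whose next simple spike occurs more than
#' `min_pause_ms` later; a sanity check on sorting, expected near 1 for
#' genuine Purkinje cells. Complex spikes with no subsequent simple spike are
#' excluded from the denominator.
#'
#' @param ss_times,cs_times sorted, disjoint spike time vectors (s).
#' @param min_pause_ms minimum pause, ms.
#' @return fraction in `[0, 1]`, or `NA` (flagged) when `cs_times` is empty.
#' @examples
#' verify_cs_pause(c(0.050), c(0.020))  # 1: gap 30 ms
#' verify_cs_pause(c(0.025), c(0.020))  # 0: gap 5 ms
#' @export
verify_cs_pause <- function(ss_times, cs_times, min_pause_ms = 20) {
  cs_times <- as.numeric(cs_times); ss_times <- as.numeric(ss_times)
  if (length(cs_times) == 0) {
    warning("no complex spikes; pause fraction undefined")
    return(NA_real_)
  }
  nxt <- vapply(cs_times, function(t) {
    after <- ss_times[ss_times > t]
    if (length(after)) after[1] else NA_real_
  }, numeric(1))
  ok <- !is.na(nxt)
  if (!any(ok)) return(NA_real_)
  mean((nxt[ok] - cs_times[ok]) > min_pause_ms / 1000)
}

#' Detect and sort simple vs complex spikes in one trace
#'
#' Full sorting chain: [detect_events()], [extract_waveforms()],
#' [classify_events()], absorption of trailing detections within the spikelet
#' window of each complex spike, and [verify_cs_pause()].
#'
#' @param trace a band-passed [voltage_trace()].
#' @param params a [detection_params()].
#' @return a `sorted_train` list: `ss`/`cs` [spike_train()]s, mean waveforms,
#'   `pause_verified_fraction`, `no_complex` flag and detection metadata.
#' @export
sort_spikes <- function(trace, params = detection_params()) {
  fs <- sampling_rate(trace)
  dur <- length(trace) / fs
  ev <- detect_events(trace, params)
  # absorb sub-events (spikelets riding a larger spike) before classification:
  # an event much shallower than its predecessor within the spikelet window is
  # part of that spike, not an independent one
  if (length(ev) > 1) {
    v <- as.numeric(trace)
    amp <- -v[round(as.numeric(ev) * fs) + 1L]
    keep <- rep(TRUE, length(ev))
    last <- 1L
    for (i in 2L:length(ev)) {
      if (ev[i] - ev[last] <= params$cs_spikelet_window_ms / 1000 &&
          amp[i] < 0.75 * amp[last]) {
        keep[i] <- FALSE
      } else last <- i
    }
    ev <- structure(as.numeric(ev)[keep], sigma = attr(ev, "sigma"),
                    threshold = attr(ev, "threshold"))
  }
  wf <- extract_waveforms(trace, ev, params$waveform_window_ms)
  times <- attr(wf, "times")
  # feature window long enough to cover the spikelet energy window
  feat_win <- c(params$waveform_window_ms[1],
                max(params$waveform_window_ms[2],
                    params$cs_spikelet_window_ms + 0.5))
  wf_feat <- extract_waveforms(trace, times, feat_win)
  labels <- classify_events(wf_feat, attr(wf_feat, "times"), params, fs, feat_win)
  # events near the trace end lack the long feature window; label them simple
  if (nrow(wf_feat) < length(times)) {
    lab_all <- rep("simple", length(times))
    lab_all[times %in% attr(wf_feat, "times")] <- as.character(labels)
    labels <- structure(lab_all, no_complex = attr(labels, "no_complex"))
  }
  cs_t <- times[labels == "complex"]
  ss_t <- times[labels == "simple"]
  # absorb trailing sub-events (spikelets) into their complex spike
  if (length(cs_t)) {
    w <- params$cs_spikelet_window_ms / 1000
    j <- findInterval(ss_t, cs_t)
    absorbed <- j > 0 & ss_t > cs_t[pmax(j, 1)] & ss_t <= cs_t[pmax(j, 1)] + w
    ss_t <- ss_t[!absorbed]
  }
  mean_wf <- function(lab) {
    m <- wf[labels == lab, , drop = FALSE]
    if (nrow(m)) colMeans(m) else NULL
  }
  pv <- if (length(cs_t)) verify_cs_pause(ss_t, cs_t) else NA_real_
  structure(list(
    ss = spike_train(ss_t, dur),
    cs = spike_train(cs_t, dur),
    mean_ss_waveform = mean_wf("simple"),
    mean_cs_waveform = mean_wf("complex"),
    pause_verified_fraction = pv,
    no_complex = attr(labels, "no_complex"),
    sigma = attr(ev, "sigma"), threshold = attr(ev, "threshold"),
    n_dropped = attr(wf, "n_dropped")), class = "sorted_train")
}

#' @export
print.sorted_train <- function(x, ...) {
  cat(sprintf("<sorted_train> %d simple, %d complex spikes; pause fraction %s\n",
              length(x$ss), length(x$cs),
              ifelse(is.na(x$pause_verified_fraction), "NA",
                     sprintf("%.2f", x$pause_verified_fraction))))
  invisible(x)
}
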