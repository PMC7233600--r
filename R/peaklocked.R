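#' Detect oscillation peaks or troughs in a narrowband reference
#'
#' Local extrema of the real part of the narrowband series, gated by an
#' amplitude-envelope percentile and a minimum separation of one cycle, and
#' ranked by envelope amplitude.
#'
#' @param nb a `narrowband` reference series
#' @param polarity "peak" or "trough"
#' @param env_percentile envelope gate (default 75: only extrema whose
#'   envelope exceeds the 75th percentile qualify)
#' @param top_n keep only the largest `top_n` events (default all)
#' @return integer vector of event positions, as indices into `nb$values`
#' @export
detect_events <- function(nb, polarity = c("peak", "trough"),
                          env_percentile = 75, top_n = Inf) {
  polarity <- match.arg(polarity)
  x <- Re(nb$values)
  if (polarity == "trough") x <- -x
  n <- length(x)
  is_ext <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
                x[2:(n - 1)] >= x[3:n], FALSE)
  env <- Mod(nb$values)
  # gate on the envelope distribution of the extrema themselves
  pool <- is_ext & nb$valid
  stop_if_not(any(pool), "no qualifying events")
  gate <- quantile(env[pool], env_percentile / 100)
  cand <- which(pool & env >= gate)
  stop_if_not(length(cand) > 0, "no qualifying events")
  # enforce near-one-cycle separation, strongest first (slightly below a
  # full cycle so period jitter cannot drop alternate extrema)
  min_sep <- 0.8 * nb$srate / nb$f0
  keep <- integer(0)
  for (i in cand[order(env[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
    if (length(keep) >= top_n) break
  }
  sort(keep)
}

#' Event-locked epoch averages
#'
#' Averages equal-length segments of the broadband channels (and optionally
#' narrowband series) time-locked to the events. Events whose segment leaves
#' the recording (or, for narrowband input, touches invalid samples) are
#' dropped. Phase-locked components survive averaging; components not locked
#' to the events shrink as 1/sqrt(n).
#'
#' @param rec a [bb_recording]
#' @param events event positions in original samples
#' @param segment_ms segment length in ms, centered on the event
#'   (default 1000)
#' @return an object of class `epoch_set`: list(avg_broadband
#'   (channels x time), time_ms, n_events, events)
#' @export
epoch_average <- function(rec, events, segment_ms = 1000) {
  half <- round(segment_ms / 1000 * rec$srate / 2)
  n <- ncol(rec$samples)
  ok <- events - half >= 1 & events + half <= n
  events <- events[ok]
  stop_if_not(length(events) >= 10, "fewer than 10 usable events")
  len <- 2L * half + 1L
  avg <- matrix(0, nrow(rec$samples), len)
  for (ev in events) {
    avg <- avg + rec$samples[, (ev - half):(ev + half), drop = FALSE]
  }
  avg <- avg / length(events)
  rownames(avg) <- rec$meta$label
  structure(list(avg_broadband = avg,
                 time_ms = ((-half):half) / rec$srate * 1000,
                 n_events = length(events), events = events,
                 srate = rec$srate),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d events, %d channels, %.0f ms segments\n",
              x$n_events, nrow(x$avg_broadband),
              diff(range(x$time_ms))))
  invisible(x)
}

#' Time-frequency z-score map of an event-locked average
#'
#' Morlet-filters the averaged broadband signal over a frequency range and
#' z-scores each frequency row against its mean and SD over two baseline
#' windows: `z = (A - A_BL_mean) / A_BL_SD`. Frequency rows with degenerate
#' baseline SD are masked (NA).
#'
#' @param ep an `epoch_set`
#' @param channel channel label or index
#' @param freqs analysis frequencies in Hz (default 4:48)
#' @param baselines list of two `c(lo, hi)` windows in ms relative to the
#'   event (default -500..-200 and 200..500)
#' @param m Morlet width (default 5)
#' @return an object of class `tfz_map`: list(z (freq x time), amplitude,
#'   freqs, time_ms, baselines)
#' @export
tf_zscore <- function(ep, channel = 1, freqs = 4:48,
                      baselines = list(c(-500, -200), c(200, 500)), m = 5) {
  if (is.character(channel)) {
    channel <- match(channel, rownames(ep$avg_broadband))
  }
  x <- ep$avg_broadband[channel, ]
  bl <- ep$time_ms >= baselines[[1]][1] & ep$time_ms <= baselines[[1]][2] |
        ep$time_ms >= baselines[[2]][1] & ep$time_ms <= baselines[[2]][2]
  stop_if_not(any(bl), "baseline windows outside the segment")
  amp <- matrix(NA_real_, length(freqs), length(x))
  z <- matrix(NA_real_, length(freqs), length(x))
  for (k in seq_along(freqs)) {
    w <- morlet_kernel(freqs[k], ep$srate, m)
    a <- Mod(conv_same(x, w))
    amp[k, ] <- a
    mu <- mean(a[bl])
    s <- sd(a[bl])
    if (s > 0) z[k, ] <- (a - mu) / s
  }
  structure(list(z = z, amplitude = amp, freqs = freqs,
                 time_ms = ep$time_ms, baselines = baselines),
            class = "tfz_map")
}

#' Event-locked amplitude time-frequency map
#'
#' For each analysis frequency, filters the broadband channel, takes the
#' amplitude envelope per event segment, and averages envelopes across
#' segments. Phase-amplitude coupling appears as LF-periodic amplitude
#' stripes in the modulated HF rows.
#'
#' @param rec a [bb_recording]
#' @param channel channel label or index
#' @param events event positions (original samples)
#' @param freqs analysis frequencies in Hz (default `seq(20, 200, by = 5)`)
#' @param segment_ms segment length in ms (default 1000)
#' @param m Morlet width (default 5)
#' @return list(amplitude (freq x time), freqs, time_ms, n_events)
#' @export
amplitude_tf <- function(rec, channel = 1, events,
                         freqs = seq(20, 200, by = 5), segment_ms = 1000,
                         m = 5) {
  if (is.character(channel)) channel <- match(channel, rec$meta$label)
  half <- round(segment_ms / 1000 * rec$srate / 2)
  n <- ncol(rec$samples)
  events <- events[events - half >= 1 & events + half <= n]
  stop_if_not(length(events) >= 10, "fewer than 10 usable events")
  x <- rec$samples[channel, ]
  len <- 2L * half + 1L
  amp <- matrix(0, length(freqs), len)
  for (k in seq_along(freqs)) {
    w <- morlet_kernel(freqs[k], rec$srate, m)
    a <- Mod(conv_same(x, w))
    for (ev in events) amp[k, ] <- amp[k, ] + a[(ev - half):(ev + half)]
  }
  list(amplitude = amp / length(events), freqs = freqs,
       time_ms = ((-half):half) / rec$srate * 1000,
       n_events = length(events))
}

#' Time-resolved event-locked cross-frequency coupling
#'
#' Sliding-window coupling between a low-frequency series and a
#' high-frequency (or envelope-band) series, with phase differences
#' concatenated across event-locked segments within each window position.
#' The null is built from the same analysis run on randomly placed segments;
#' a window is significant when its PLV exceeds 2.42x the null mean.
#'
#' @param lf,hf `narrowband` series on a common time base (equal rate and
#'   sample positions); for PAC pass the envelope-band series as `hf` with
#'   `m = 1`
#' @param events event positions, as indices into the series
#' @param m integer frequency ratio (1 for PAC/envelope input)
#' @param window_ms sliding-window length in ms (default 200)
#' @param segment_ms segment length in ms (default 1000)
#' @param n_null random-placement null draws (default 100)
#' @return data.frame: `time_ms`, `plv`, `null_mean`, `significant`
#' @export
sliding_cfc <- function(lf, hf, events, m = 1, window_ms = 200,
                        segment_ms = 1000, n_null = 100L) {
  stop_if_not(isTRUE(all.equal(lf$srate, hf$srate)),
              "series rates differ; resample first")
  half <- round(segment_ms / 1000 * lf$srate / 2)
  L <- length(lf$values)
  events <- events[events - half >= 1 & events + half <= L]
  stop_if_not(length(events) >= 10, "fewer than 10 usable events")
  wlen <- max(2L, round(window_ms / 1000 * lf$srate))
  stop_if_not(wlen <= 2L * half + 1L, "window larger than segment")
  dphi <- wrap_phase(m * Arg(lf$values) - Arg(hf$values))
  seg_plv <- function(evs) {
    # offsets of window starts within the segment
    starts <- seq.int(-half, half - wlen + 1L)
    vapply(starts, function(s) {
      idx <- as.vector(outer(s:(s + wlen - 1L), evs, "+"))
      Mod(mean(exp(1i * dphi[idx])))
    }, 0)
  }
  obs <- seg_plv(events)
  # null: same number of randomly placed segments, pooled over draws
  null_vals <- vapply(seq_len(n_null), function(i) {
    ev <- sample(seq.int(half + 1L, L - half), length(events),
                 replace = TRUE)
    mean(seg_plv(ev))
  }, 0)
  null_mean <- mean(null_vals)
  starts <- seq.int(-half, half - wlen + 1L)
  data.frame(time_ms = (starts + (wlen - 1) / 2) / lf$srate * 1000,
             plv = obs, null_mean = null_mean,
             significant = obs > 2.42 * null_mean)
}
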