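#' Remove power-line noise and its harmonics
#'
#' Band-stop (notch) filters the recording at the line frequency and every
#' harmonic below the Nyquist frequency, using a zero-phase Butterworth
#' band-stop cascade.
#'
#' @param rec a [bb_recording]
#' @param base line frequency in Hz (default 50)
#' @param halfwidth half-width of each stop band in Hz (default 2)
#' @param order Butterworth order per stop band (default 4)
#' @return a filtered [bb_recording] of the same shape
#' @export
remove_line_noise <- function(rec, base = 50, halfwidth = 2, order = 4) {
  nyq <- rec$srate / 2
  stop_if_not(base > 0 && base < nyq, "line frequency must be below Nyquist")
  harmonics <- seq(base, nyq - halfwidth, by = base)
  x <- rec$samples
  for (f in harmonics) {
    bf <- signal::butter(order, c(f - halfwidth, f + halfwidth) / nyq,
                         type = "stop")
    for (ch in seq_len(nrow(x))) {
      x[ch, ] <- signal::filtfilt(bf, x[ch, ])
    }
  }
  bb_recording(x, rec$srate, rec$meta)
}

# complex Morlet kernel, width m cycles, zero-mean (DC-free) correction;
# normalized so a unit-amplitude sinusoid at f0 yields unit envelope
morlet_kernel <- function(f0, srate, m = 5) {
  sigma_t <- m / (2 * pi * f0)
  half <- ceiling(3 * sigma_t * srate)
  t <- (-half:half) / srate
  carrier <- exp(1i * 2 * pi * f0 * t) - exp(-(2 * pi * f0 * sigma_t)^2 / 2)
  w <- carrier * exp(-t^2 / (2 * sigma_t^2))
  w * 2 / (sigma_t * sqrt(2 * pi) * srate)
}

# 'same'-mode FFT convolution of a real signal with a complex kernel
conv_same <- function(x, w) {
  nx <- length(x)
  nw <- length(w)
  n <- stats::nextn(nx + nw - 1L, 2)
  y <- fft(fft(c(x, rep(0, n - nx))) * fft(c(w, rep(0, n - nw))),
           inverse = TRUE) / n
  half <- (nw - 1L) %/% 2L
  y[(half + 1L):(half + nx)]
}

new_narrowband <- function(values, f0, srate, label, valid, idx, m) {
  structure(list(values = values, f0 = f0, srate = srate, label = label,
                 valid = valid, idx = idx, m = m),
            class = "narrowband")
}

#' @export
print.narrowband <- function(x, ...) {
  cat(sprintf(
    "<narrowband> '%s' @ %g Hz center, %d samples @ %.4g Hz (%d valid)\n",
    x$label, x$f0, length(x$values), x$srate, sum(x$valid)))
  invisible(x)
}

#' Morlet filterbank decomposition
#'
#' Convolves every channel with a complex Morlet wavelet at each grid
#' frequency, yielding complex analytic narrowband series. Samples within one
#' wavelet half-support (3 sigma_t) of the segment edges -- and, optionally,
#' of rejected artifact windows -- are marked invalid; coupling estimators
#' skip invalid samples.
#'
#' @param rec a [bb_recording]
#' @param grid a [frequency_grid]; all center frequencies must be below
#'   Nyquist
#' @param decimate decimate each series to its grid target (default TRUE)
#' @param bad_windows optional logical vector over original samples marking
#'   artifact samples to invalidate (see [detect_artifact_windows()])
#' @return a narrowband store: list (per channel label) of lists (per grid
#'   frequency) of `narrowband` objects, with the grid attached as an
#'   attribute
#' @export
morlet_decompose <- function(rec, grid, decimate = TRUE, bad_windows = NULL) {
  nyq <- rec$srate / 2
  stop_if_not(max(grid$f0) < nyq, "grid frequency at or above Nyquist")
  m <- attr(grid, "wavelet_width")
  n <- ncol(rec$samples)
  if (!is.null(bad_windows)) {
    stop_if_not(length(bad_windows) == n,
                "bad_windows must have one entry per original sample")
  }
  store <- vector("list", nrow(rec$samples))
  names(store) <- rec$meta$label
  for (ch in seq_len(nrow(rec$samples))) {
    per_f <- vector("list", nrow(grid))
    for (k in seq_len(nrow(grid))) {
      f0 <- grid$f0[k]
      w <- morlet_kernel(f0, rec$srate, m)
      z <- conv_same(rec$samples[ch, ], w)
      half <- (length(w) - 1L) %/% 2L
      valid <- rep(TRUE, n)
      edge <- min(half, n)
      valid[seq_len(edge)] <- FALSE
      valid[seq.int(n - edge + 1L, n)] <- FALSE
      if (!is.null(bad_windows)) {
        bad <- which(bad_windows)
        if (length(bad)) {
          lo <- pmax(1L, bad - half)
          hi <- pmin(n, bad + half)
          for (b in seq_along(bad)) valid[lo[b]:hi[b]] <- FALSE
        }
      }
      nb <- new_narrowband(z, f0, rec$srate, rec$meta$label[ch], valid,
                           seq_len(n), m)
      if (decimate) nb <- decimate_narrowband(nb)
      per_f[[k]] <- nb
    }
    store[[ch]] <- per_f
  }
  attr(store, "grid") <- grid
  attr(store, "orig_srate") <- rec$srate
  attr(store, "meta") <- rec$meta
  class(store) <- "nb_store"
  store
}

#' @export
print.nb_store <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<nb_store> %d channels x %d frequencies (%.3g-%.3g Hz)\n",
              length(x), nrow(g), min(g$f0), max(g$f0)))
  invisible(x)
}

#' Decimate a narrowband series
#'
#' Subsamples so the retained rate is approximately `decim_mult` (default 5)
#' times the center frequency: integer factor `floor(rate / (5 f0))`, clamped
#' at 1. The narrowband filter already bounds the bandwidth, so plain
#' subsampling needs no extra anti-alias stage. Original-sample indices are
#' kept so series at different rates can be realigned.
#'
#' @param nb a `narrowband` object
#' @param decim_mult samples-per-cycle multiple, default 5
#' @return the decimated `narrowband`
#' @export
decimate_narrowband <- function(nb, decim_mult = 5) {
  factor <- max(1L, floor(nb$srate / (decim_mult * nb$f0)))
  if (factor == 1L) return(nb)
  keep <- seq.int(1L, length(nb$values), by = factor)
  new_narrowband(nb$values[keep], nb$f0, nb$srate / factor, nb$label,
                 nb$valid[keep], nb$idx[keep], nb$m)
}

#' Detect artifact (e.g., interictal-event) windows
#'
#' Divides the recording into non-overlapping windows and flags, per channel
#' and per frequency band, windows whose mean amplitude envelope exceeds the
#' channel's mean by more than `sd_thresh` standard deviations. A window is
#' globally rejected when at least `channel_frac` of the channels are flagged
#' in more than `band_frac` of the bands.
#'
#' @param env list of per-band envelope matrices (channels x time, all at the
#'   same rate and length)
#' @param srate sampling rate of the envelopes, Hz
#' @param window_ms window length in ms (default 500)
#' @param sd_thresh envelope threshold in channel SDs (default 5)
#' @param channel_frac fraction of channels required (default 0.10)
#' @param band_frac fraction of bands required (default 0.5)
#' @return list with `window_rejected` (logical per window),
#'   `sample_rejected` (logical per sample), `n_windows`, `window_samples`
#' @export
detect_artifact_windows <- function(env, srate, window_ms = 500,
                                    sd_thresh = 5, channel_frac = 0.10,
                                    band_frac = 0.5) {
  stop_if_not(window_ms > 0, "window_ms must be positive")
  stop_if_not(channel_frac > 0 && channel_frac <= 1 &&
                band_frac > 0 && band_frac <= 1,
              "fractions must be in (0, 1]")
  if (is.matrix(env)) env <- list(env)
  n <- unique(vapply(env, ncol, 0L))
  stop_if_not(length(n) == 1L, "envelope lengths inconsistent across bands")
  n_ch <- unique(vapply(env, nrow, 0L))
  stop_if_not(length(n_ch) == 1L, "channel counts inconsistent across bands")
  wlen <- max(1L, round(window_ms / 1000 * srate))
  n_win <- ceiling(n / wlen)
  win_of <- rep(seq_len(n_win), each = wlen, length.out = n)
  # flagged[win, ch, band]
  flagged <- array(FALSE, c(n_win, n_ch, length(env)))
  for (b in seq_along(env)) {
    mu <- rowMeans(env[[b]])
    s <- apply(env[[b]], 1, sd)
    for (ch in seq_len(n_ch)) {
      wmax <- tapply(env[[b]][ch, ], win_of, max)
      flagged[, ch, b] <- wmax > mu[ch] + sd_thresh * s[ch]
    }
  }
  # per window: channel is "artifactual" if flagged in > band_frac of bands
  n_band <- length(env)
  ch_art <- apply(flagged, c(1, 2), sum) > band_frac * n_band
  window_rejected <- rowSums(ch_art) >= channel_frac * n_ch
  list(window_rejected = window_rejected,
       sample_rejected = window_rejected[win_of],
       n_windows = n_win, window_samples = wlen)
}

#' Default artifact-detection bands
#'
#' Picks the grid frequencies at or below 100 Hz closest to `n` log-spaced
#' targets; used as the envelope bands for [detect_artifact_windows()].
#'
#' @param grid a [frequency_grid]
#' @param n number of bands (default 18)
#' @return integer vector of grid indices
#' @export
iie_bands <- function(grid, n = 18) {
  cand <- which(grid$f0 <= 100)
  stop_if_not(length(cand) >= 1, "no grid frequencies at or below 100 Hz")
  targets <- exp(seq(log(min(grid$f0[cand])), log(max(grid$f0[cand])),
                     length.out = n))
  idx <- vapply(targets, function(tt) cand[which.min(abs(grid$f0[cand] - tt))],
                0L)
  unique(idx)
}

#' Low-frequency band of a high-frequency amplitude envelope
#'
#' Takes the amplitude envelope (modulus) of a high-frequency narrowband
#' series, removes its mean over valid samples, filters it with a Morlet
#' wavelet at the low-frequency center, and resamples the result at the
#' low-frequency series' sample positions. The phase of the output is the
#' envelope phase used by phase-amplitude and amplitude-amplitude coupling.
#'
#' @param hf a `narrowband` object (high-frequency series)
#' @param lf_center low-frequency center in Hz, must be below the HF series'
#'   Nyquist
#' @param lf_idx original-sample indices of the target low-frequency series
#'   (`lf$idx`); if NULL the envelope band stays at the HF rate
#' @param lf_srate sampling rate matching `lf_idx`
#' @return a `narrowband` at the LF rate holding the complex LF-band envelope
#' @export
envelope_band <- function(hf, lf_center, lf_idx = NULL, lf_srate = NULL) {
  stop_if_not(lf_center < hf$srate / 2,
              "lf_center at or above envelope Nyquist")
  env <- Mod(hf$values)
  env <- env - mean(env[hf$valid])
  w <- morlet_kernel(lf_center, hf$srate, hf$m)
  z <- conv_same(env, w)
  half <- (length(w) - 1L) %/% 2L
  valid <- hf$valid
  n <- length(valid)
  edge <- min(half, n)
  valid[seq_len(edge)] <- FALSE
  valid[seq.int(n - edge + 1L, n)] <- FALSE
  out <- new_narrowband(z, lf_center, hf$srate, hf$label, valid, hf$idx,
                        hf$m)
  if (!is.null(lf_idx)) {
    vals <- interp_complex(out$values, out$idx, lf_idx)
    vmask <- interp_valid(out$valid, out$idx, lf_idx) & !is.na(vals)
    vals[is.na(vals)] <- 0 + 0i
    out <- new_narrowband(vals, lf_center,
                          if (is.null(lf_srate)) out$srate else lf_srate,
                          hf$label, vmask, lf_idx, hf$m)
  }
  out
}
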