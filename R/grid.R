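#' Logarithmically spaced Morlet filterbank definition
#'
#' Builds a geometric grid of wavelet center frequencies with a common Morlet
#' width parameter and per-frequency decimation targets. The default analysis
#' grid for 1 kHz intracranial recordings uses 49 center frequencies from
#' 1.2 to 315 Hz; a 53-frequency 1.1--315 Hz variant suits source-level MEG.
#' Decimation targets are 5x the center frequency, so every narrowband series
#' retains roughly five samples per cycle.
#'
#' @param f_min,f_max lowest and highest center frequency, Hz
#' @param n number of center frequencies (>= 2)
#' @param wavelet_width Morlet width parameter m (cycles), default 5
#' @param decim_mult decimation-target multiple of the center frequency,
#'   default 5 (targets must be >= 4.5x the center frequency)
#' @return an object of class `frequency_grid`: data.frame with columns
#'   `f0` (Hz) and `decim_target` (Hz), attribute `wavelet_width`
#' @export
#' @examples
#' g <- frequency_grid(1.2, 315, 49)
#' head(g)
frequency_grid <- function(f_min, f_max, n, wavelet_width = 5,
                           decim_mult = 5) {
  stop_if_not(is.numeric(f_min) && is.numeric(f_max) && f_min > 0 &&
                f_max > f_min, "need 0 < f_min < f_max")
  stop_if_not(n >= 2, "need at least 2 grid frequencies")
  stop_if_not(decim_mult >= 4.5, "decimation target must be >= 4.5 x f0")
  f0 <- exp(seq(log(f_min), log(f_max), length.out = n))
  g <- data.frame(f0 = f0, decim_target = decim_mult * f0)
  attr(g, "wavelet_width") <- wavelet_width
  attr(g, "decim_mult") <- decim_mult
  class(g) <- c("frequency_grid", "data.frame")
  g
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf(
    "<frequency_grid> %d center frequencies %.3g-%.3g Hz (m = %g)\n",
    nrow(x), min(x$f0), max(x$f0), attr(x, "wavelet_width")))
  invisible(x)
}

#' Match low/high frequency pairs at an integer ratio
#'
#' Finds all grid pairs whose center-frequency ratio lies within a tolerance
#' of an integer 1:m ratio (cross-frequency analysis pairs). When several
#' high-frequency candidates match the same low frequency at the same m, the
#' minimum-deviation one is kept (ties broken toward the lower HF index).
#'
#' @param grid a [frequency_grid]
#' @param m integer ratio >= 2 (or a vector of ratios)
#' @param tol maximum fractional deviation `|f_HF/(m * f_LF) - 1|`,
#'   default 0.05
#' @return data.frame with columns `lf_index`, `hf_index`, `ratio_m`,
#'   `lf_hz`, `hf_hz`, `deviation`
#' @export
match_ratio_pairs <- function(grid, m, tol = 0.05) {
  stop_if_not(all(m >= 2) && all(m == round(m)), "m must be integers >= 2")
  out <- list()
  for (mm in as.integer(m)) {
    for (i in seq_len(nrow(grid))) {
      dev <- abs(grid$f0 / (mm * grid$f0[i]) - 1)
      ok <- which(dev <= tol)
      if (!length(ok)) next
      j <- ok[order(dev[ok], ok)][1]
      out[[length(out) + 1L]] <- data.frame(
        lf_index = i, hf_index = j, ratio_m = mm,
        lf_hz = grid$f0[i], hf_hz = grid$f0[j], deviation = dev[j])
    }
  }
  if (!length(out)) {
    return(data.frame(lf_index = integer(), hf_index = integer(),
                      ratio_m = integer(), lf_hz = numeric(),
                      hf_hz = numeric(), deviation = numeric()))
  }
  do.call(rbind, out)
}
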