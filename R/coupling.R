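as_complex_series <- function(x) {
  if (inherits(x, "narrowband")) {
    list(values = x$values, valid = x$valid, idx = x$idx, srate = x$srate)
  } else {
    list(values = as.complex(x), valid = rep(TRUE, length(x)),
         idx = seq_along(x), srate = NA_real_)
  }
}

joint_valid <- function(a, b) {
  stop_if_not(length(a$values) == length(b$values),
              "series lengths differ; realign before coupling estimation")
  a$valid & b$valid
}

#' Complex phase-locking value
#'
#' Mean unit phasor of the phase difference over jointly valid samples:
#' `cPLV = mean(exp(i (theta_a - theta_b)))`. Its modulus is the PLV, its
#' argument the mean phase lag.
#'
#' @param za,zb complex series (`narrowband` objects or plain complex
#'   vectors) of equal length on a common time base
#' @return a complex scalar with modulus <= 1
#' @export
cplv <- function(za, zb) {
  a <- as_complex_series(za)
  b <- as_complex_series(zb)
  v <- joint_valid(a, b)
  stop_if_not(sum(v) >= 2, "fewer than 2 jointly valid samples")
  pa <- a$values[v] / Mod(a$values[v])
  pb <- b$values[v] / Mod(b$values[v])
  mean(pa * Conj(pb))
}

#' Phase-locking value
#'
#' Modulus of the complex phase-locking value ([cplv()]); in `[0, 1]`.
#'
#' @inheritParams cplv
#' @return a number in `[0, 1]`
#' @export
plv <- function(za, zb) Mod(cplv(za, zb))

#' Weighted phase-lag index
#'
#' `wPLI = |mean(Im X_ab)| / mean(|Im X_ab|)` where `X_ab = Z_a conj(Z_b)` is
#' the per-sample cross spectrum of the narrowband series. Insensitive to
#' zero-lag (linear-mixing) interactions. When the imaginary cross spectrum is
#' identically zero the index is defined as 0 (no evidence of lagged
#' coupling).
#'
#' @inheritParams cplv
#' @return a number in `[0, 1]`
#' @export
wpli <- function(za, zb) {
  a <- as_complex_series(za)
  b <- as_complex_series(zb)
  v <- joint_valid(a, b)
  stop_if_not(sum(v) >= 2, "fewer than 2 jointly valid samples")
  imx <- Im(a$values[v] * Conj(b$values[v]))
  denom <- mean(abs(imx))
  if (denom == 0) return(0)
  abs(mean(imx)) / denom
}

# LF phase resampled at the HF series' sample positions
lf_phase_at_hf <- function(lf, hf) {
  theta <- interp_phase(Arg(lf$values), lf$idx, hf$idx)
  valid <- interp_valid(lf$valid, lf$idx, hf$idx) & !is.na(theta)
  theta[is.na(theta)] <- 0
  list(theta = theta, valid = valid)
}

#' n:m cross-frequency phase synchrony (CFS)
#'
#' Phase-locking between a low-frequency series at channel a and a
#' high-frequency series at channel b whose center frequencies are in an
#' integer 1:m ratio: `|mean(exp(i (m theta_a,LF - theta_b,HF)))|`. The LF
#' phase is unwrapped, linearly interpolated at the HF sample positions,
#' rewrapped, and accelerated by multiplication with m. Local CFS is the
#' case a = b.
#'
#' @param lf `narrowband` at the low frequency (channel a)
#' @param hf `narrowband` at the high frequency (channel b)
#' @param m integer frequency ratio (m = 1 reduces to [plv()])
#' @return a number in `[0, 1]`
#' @export
cfs_plv <- function(lf, hf, m) {
  stop_if_not(m >= 1 && m == round(m), "m must be a positive integer")
  lf <- as_complex_series(lf)
  hf <- as_complex_series(hf)
  up <- lf_phase_at_hf(lf, hf)
  v <- up$valid & hf$valid
  stop_if_not(sum(v) >= 2, "fewer than 2 jointly valid samples")
  Mod(mean(exp(1i * (m * up$theta[v] - Arg(hf$values[v])))))
}

#' Phase-amplitude coupling (PAC)
#'
#' Phase-locking between the low-frequency phase at channel a and the phase
#' of the low-frequency-filtered amplitude envelope of the high-frequency
#' series at channel b (see [envelope_band()]):
#' `|mean(exp(i (theta_a,LF - theta_b,HF,LFenv)))|`. Local PAC is a = b.
#'
#' @param lf `narrowband` at the low frequency (channel a)
#' @param env LF-band envelope series of the HF channel, already resampled to
#'   the LF time base ([envelope_band()] with `lf_idx`)
#' @return a number in `[0, 1]`
#' @export
pac_plv <- function(lf, env) {
  a <- as_complex_series(lf)
  b <- as_complex_series(env)
  if (!is.na(a$srate) && !is.na(b$srate)) {
    stop_if_not(isTRUE(all.equal(a$srate, b$srate)),
                "LF and envelope-band rates differ; resample first")
  }
  plv(lf, env)
}

#' Amplitude-amplitude coupling (AC)
#'
#' Phase synchrony (PLV) of the LF-band amplitude envelopes of two
#' high-frequency series; symmetric in its arguments. Used as the
#' envelope-correlation leg of the PAC pruning motif.
#'
#' @param enva,envb envelope-band series at the same LF center and rate
#' @return a number in `[0, 1]`
#' @export
ac_plv <- function(enva, envb) plv(enva, envb)
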