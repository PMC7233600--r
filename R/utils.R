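#' @useDynLib cfcnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif sd quantile median approx cor.test
#'   wilcox.test p.adjust pnorm complete.cases
#' @importFrom utils head read.delim write.table
NULL

wrap_phase <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Phase of a complex series
#'
#' Argument of a complex vector, in (-pi, pi].
#'
#' @param z complex vector
#' @return numeric vector of phases
#' @export
phase_of <- function(z) Arg(z)

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# linear interpolation of a complex series sampled at positions `at`
# (positions expressed on the same axis as `pos`); NA outside the range
interp_complex <- function(values, pos, at) {
  re <- approx(pos, Re(values), xout = at, rule = 1)$y
  im <- approx(pos, Im(values), xout = at, rule = 1)$y
  complex(real = re, imaginary = im)
}

# interpolate a phase series (unwrap -> interp -> rewrap)
interp_phase <- function(theta, pos, at) {
  un <- unwrap_phase(theta)
  wrap_phase(approx(pos, un, xout = at, rule = 1)$y)
}

unwrap_phase <- function(theta) {
  d <- diff(theta)
  jumps <- cumsum(c(0, round(d / (2 * pi))))
  theta - 2 * pi * jumps
}

# boolean mask interpolation: TRUE only where both bracketing samples valid
interp_valid <- function(valid, pos, at) {
  v <- approx(pos, as.numeric(valid), xout = at, rule = 1)$y
  !is.na(v) & v >= 1 - 1e-9
}
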