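# Brute-force reference implementations (naive per-sample loops), kept
# deliberately independent of the package's vectorized estimators.

cplv_naive <- function(za, zb) {
  s <- 0 + 0i
  n <- 0L
  for (t in seq_along(za)) {
    s <- s + exp(1i * (Arg(za[t]) - Arg(zb[t])))
    n <- n + 1L
  }
  s / n
}

plv_naive <- function(za, zb) Mod(cplv_naive(za, zb))

wpli_naive <- function(za, zb) {
  num <- 0
  den <- 0
  for (t in seq_along(za)) {
    ims <- Im(za[t] * Conj(zb[t]))
    num <- num + ims
    den <- den + abs(ims)
  }
  if (den == 0) return(0)
  abs(num) / den
}

cfs_naive <- function(theta_lf, theta_hf, m) {
  s <- 0 + 0i
  for (t in seq_along(theta_lf)) {
    s <- s + exp(1i * (m * theta_lf[t] - theta_hf[t]))
  }
  Mod(s / length(theta_lf))
}

# wrap a complex vector as a narrowband object on a shared time base
as_nb <- function(values, f0 = 10, srate = 100, label = "x",
                  valid = rep(TRUE, length(values))) {
  structure(list(values = values, f0 = f0, srate = srate, label = label,
                 valid = valid, idx = seq_along(values), m = 5),
            class = "narrowband")
}

rand_phases <- function(n) runif(n, -pi, pi)

rayleigh_mean <- function(n) sqrt(pi / (4 * n))
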