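#' 1/f ("pink") noise
#'
#' Gaussian noise with a power spectrum proportional to `1/f^exponent`,
#' generated by spectral shaping of white noise; unit variance.
#'
#' @param n number of samples
#' @param exponent spectral exponent (default 1)
#' @return numeric vector
#' @export
one_over_f_noise <- function(n, exponent = 1) {
  white <- rnorm(n)
  sp <- fft(white)
  f <- c(1, seq_len(n - 1))              # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)                # symmetric (two-sided) frequencies
  sp <- sp / f^(exponent / 2)
  x <- Re(fft(sp, inverse = TRUE)) / n
  as.vector(scale(x))
}

#' Channel process specification
#'
#' One oscillatory process for the synthetic-recording generator.
#' `sinusoid` is a stochastic narrowband oscillator (filtered noise);
#' `harmonic_rich` adds phase-locked harmonics (2nd, 3rd, ...), the
#' nonsinusoidal waveform whose filtered harmonics mimic local
#' cross-frequency synchrony; `nonzero_mean_am` is a non-zero-mean carrier
#' at `f0` amplitude-modulated at `f0/2` (modulator phase-locked to the
#' carrier), which leaks a low-frequency component and mimics local
#' cross-frequency coupling of both kinds.
#'
#' @param f0 base frequency, Hz (carrier frequency for `nonzero_mean_am`)
#' @param waveform one of "sinusoid", "harmonic_rich", "nonzero_mean_am"
#' @param amplitude amplitude, a.u.
#' @param snr_db band signal-to-noise ratio of additive 1/f noise in dB
#'   (Inf = noiseless), measured in the process' lowest oscillation band
#' @param noise_exp 1/f exponent of the additive noise (default 1)
#' @param jitter optional extra phase-drift random walk, SD in rad per
#'   sample on top of the intrinsic filtered-noise phase diffusion
#'   (default 0)
#' @param harmonics relative amplitudes of harmonics 2, 3, ...
#'   (default `c(0.5, 0.25)`)
#' @param mean_offset carrier mean for `nonzero_mean_am` (default 0.6)
#' @param mod_depth modulation depth for `nonzero_mean_am` (default 0.6)
#' @return a `channel_spec` list
#' @export
channel_spec <- function(f0, waveform = c("sinusoid", "harmonic_rich",
                                          "nonzero_mean_am"),
                         amplitude = 1, snr_db = Inf, noise_exp = 1,
                         jitter = 0, harmonics = c(0.5, 0.25),
                         mean_offset = 0.6, mod_depth = 0.6) {
  waveform <- match.arg(waveform)
  structure(list(f0 = f0, waveform = waveform, amplitude = amplitude,
                 snr_db = snr_db, noise_exp = noise_exp, jitter = jitter,
                 harmonics = harmonics, mean_offset = mean_offset,
                 mod_depth = mod_depth),
            class = "channel_spec")
}

#' Scenario specification for the synthetic generator
#'
#' @param channels list of [channel_spec()]s
#' @param edges data.frame of planted couplings with columns `type` ("PS",
#'   "CFS", "PAC"), `a`, `b` (channel indices; `a` drives `b`), `ratio`
#'   (integer; 1 for PS), `strength` in `[0, 1]`, `lag` (radians); may be
#'   NULL
#' @param duration recording length in s
#' @param rate sampling rate in Hz
#' @return a `scenario_spec` list
#' @export
scenario_spec <- function(channels, edges = NULL, duration = 10,
                          rate = 1000) {
  if (is.null(edges)) {
    edges <- data.frame(type = character(), a = integer(), b = integer(),
                        ratio = integer(), strength = numeric(),
                        lag = numeric())
  }
  stop_if_not(all(edges$strength >= 0 & edges$strength <= 1),
              "edge strengths must be in [0, 1]")
  stop_if_not(all(c(edges$a, edges$b) %in% seq_along(channels)),
              "edge references a missing channel")
  structure(list(channels = channels, edges = edges, duration = duration,
                 rate = rate),
            class = "scenario_spec")
}

#' Generate a synthetic multichannel recording with labelled ground truth
#'
#' Realizes a [scenario_spec()]: each channel's base oscillator is
#' Morlet-filtered white noise at its center frequency -- a stochastic
#' narrowband process with Rayleigh-fading amplitude and diffusive phase
#' whose memory is filter-limited (about m/f0 seconds), as in resting-state
#' rhythms. Planted phase-synchrony edges overwrite the target's base phase
#' with the argument of the strength-weighted sum of the lagged driver
#' phasor and the target's own phasor (linear mixing at the phase level);
#' planted cross-frequency-synchrony edges inject a
#' phase-locked component at `ratio x` the driver's phase into the target's
#' waveform (two separable processes, mixed `strength : (1 - strength)` with
#' the target's own band content); planted phase-amplitude edges modulate
#' the target's amplitude by the driver's phase with depth `strength`.
#' Additive 1/f noise is scaled per channel to the requested band SNR.
#'
#' @param spec a [scenario_spec()]
#' @return list with `rec` (a [bb_recording]) and `truth` (list: `edges`,
#'   the planted edge table; `local_cfc`, logical per channel marking
#'   processes whose waveform mimics local cross-frequency coupling)
#' @export
gen_recording <- function(spec) {
  n <- round(spec$duration * spec$rate)
  t_idx <- seq_len(n)
  nch <- length(spec$channels)
  # base oscillators: Morlet-filtered white noise at f0 -- a stochastic
  # narrowband process whose phase diffuses with filter-limited memory
  # (~m/f0), like resting-state rhythms; amplitude is Rayleigh-fading.
  # theta holds the unwrapped phase, amp the envelope (unit RMS)
  theta <- amp <- matrix(0, nch, n)
  for (i in seq_len(nch)) {
    ch <- spec$channels[[i]]
    z <- conv_same(rnorm(n), morlet_kernel(ch$f0, spec$rate, 5))
    z <- z / sqrt(mean(Mod(z)^2))
    ramp <- 2 * pi * ch$f0 * t_idx / spec$rate
    th <- unwrap_phase(Arg(z))
    # align the unwrapped branch with the nominal ramp
    th <- th + 2 * pi * round((ramp[1] - th[1]) / (2 * pi))
    if (ch$jitter > 0) th <- th + cumsum(rnorm(n, 0, ch$jitter))
    theta[i, ] <- th
    amp[i, ] <- Mod(z)
  }
  # PS edges rewrite the target's base phase (harmonics then follow it) by
  # phasor mixing: strength-weighted sum of the lagged driver phasor and
  # the target's own phasor, so the residual deviation stays bounded
  ps <- spec$edges[spec$edges$type == "PS", , drop = FALSE]
  for (e in seq_len(nrow(ps))) {
    a <- ps$a[e]; b <- ps$b[e]; s <- ps$strength[e]
    mixed <- s * exp(1i * (theta[a, ] + ps$lag[e])) +
      (1 - s) * exp(1i * theta[b, ])
    theta[b, ] <- unwrap_phase(Arg(mixed))
  }
  # waveform synthesis
  x <- matrix(0, nch, n)
  # a CFS injection landing in the target's own band displaces the target's
  # own content (strength : 1 - strength mixture); injections into a band
  # the target does not occupy are purely additive
  own_scale <- rep(1, nch)
  cfs <- spec$edges[spec$edges$type == "CFS", , drop = FALSE]
  for (e in seq_len(nrow(cfs))) {
    f_inj <- cfs$ratio[e] * spec$channels[[cfs$a[e]]]$f0
    f_own <- spec$channels[[cfs$b[e]]]$f0
    if (abs(f_inj / f_own - 1) < 0.05) {
      own_scale[cfs$b[e]] <- 1 - cfs$strength[e]
    }
  }
  for (i in seq_len(nch)) {
    ch <- spec$channels[[i]]
    th <- theta[i, ]
    a_i <- amp[i, ]
    sig <- switch(ch$waveform,
      sinusoid = a_i * cos(th),
      harmonic_rich = {
        s <- a_i * cos(th)
        for (h in seq_along(ch$harmonics)) {
          s <- s + ch$harmonics[h] * a_i * cos((h + 1) * th)
        }
        s
      },
      nonzero_mean_am = {
        (ch$mean_offset + a_i * cos(th)) *
          (1 + ch$mod_depth * cos(th / 2))
      })
    x[i, ] <- ch$amplitude * own_scale[i] * sig
  }
  # CFS edges: inject a phase-locked component at ratio x driver phase
  for (e in seq_len(nrow(cfs))) {
    a <- cfs$a[e]; b <- cfs$b[e]
    x[b, ] <- x[b, ] + spec$channels[[b]]$amplitude * cfs$strength[e] *
      amp[b, ] * cos(cfs$ratio[e] * theta[a, ] + cfs$lag[e])
  }
  # PAC edges: modulate the target's amplitude by the driver's phase
  pac <- spec$edges[spec$edges$type == "PAC", , drop = FALSE]
  for (e in seq_len(nrow(pac))) {
    a <- pac$a[e]; b <- pac$b[e]; s <- pac$strength[e]
    x[b, ] <- x[b, ] * (1 + s * cos(theta[a, ] - pac$lag[e])) / (1 + s)
  }
  # additive 1/f noise at the requested band SNR
  for (i in seq_len(nch)) {
    ch <- spec$channels[[i]]
    if (!is.finite(ch$snr_db)) next
    noise <- one_over_f_noise(n, ch$noise_exp)
    f_band <- if (ch$waveform == "nonzero_mean_am") ch$f0 / 2 else ch$f0
    w <- morlet_kernel(f_band, spec$rate, 5)
    p_sig <- mean(Mod(conv_same(x[i, ], w))^2)
    p_noise <- mean(Mod(conv_same(noise, w))^2)
    scale <- sqrt(p_sig / p_noise / 10^(ch$snr_db / 10))
    x[i, ] <- x[i, ] + scale * noise
  }
  local_cfc <- vapply(spec$channels,
                      function(ch) ch$waveform != "sinusoid", TRUE)
  list(rec = bb_recording(x, spec$rate),
       truth = list(edges = spec$edges, local_cfc = local_cfc))
}

#' Triangle-motif scenario generator
#'
#' Two-channel recordings realizing the canonical constellations that the
#' pruning step must handle: (d) a sinusoidal LF process phase-coupled to a
#' nonsinusoidal (harmonic-rich) one -- the interareal cross-frequency
#' synchrony observable from A's LF band to B's HF band is spurious and
#' removable via the HF-side motif; (e) a non-zero-mean amplitude-modulated
#' process HF-coupled to a sinusoid -- spurious, removable via the LF-side
#' motif; (f) genuine interareal CFS between two separable processes with no
#' complete motif -- kept; (g) genuine interareal CFS embedded in a full
#' motif -- removed by design (the conservative case); (h) nonsinusoidal
#' processes at both ends with LF phase synchrony -- spurious, removable.
#'
#' @param panel one of "d", "e", "f", "g", "h"
#' @param f_lf,f_hf low and high frequencies (Hz), `f_hf = 2 f_lf`
#' @param duration,rate recording length (s) and sampling rate (Hz)
#' @param strength planted coupling strength (default 0.9)
#' @param snr_db additive-noise band SNR (default 20)
#' @return as [gen_recording()], plus `truth$panel`,
#'   `truth$spurious_edges` and `truth$genuine_edges` (each a data.frame
#'   with `lf_channel`, `hf_channel`, `expect` in "removed"/"kept")
#' @export
gen_triangle_scenarios <- function(panel = c("d", "e", "f", "g", "h"),
                                   f_lf = 5, f_hf = 2 * f_lf,
                                   duration = 20, rate = 200,
                                   strength = 0.9, snr_db = 20) {
  panel <- match.arg(panel)
  stop_if_not(isTRUE(all.equal(f_hf, 2 * f_lf)),
              "scenarios are built at a 1:2 ratio")
  sinu <- function(f) channel_spec(f, "sinusoid", snr_db = snr_db)
  harm <- function(f) channel_spec(f, "harmonic_rich", snr_db = snr_db,
                                   harmonics = 0.6)
  am <- function(f) channel_spec(f, "nonzero_mean_am", snr_db = snr_db)
  ed <- function(type, a, b, ratio, s = strength, lag = pi / 3) {
    data.frame(type = type, a = a, b = b, ratio = ratio, strength = s,
               lag = lag)
  }
  mark <- function(lf_ch, hf_ch, expect) {
    data.frame(lf_channel = lf_ch, hf_channel = hf_ch, expect = expect,
               stringsAsFactors = FALSE)
  }
  none <- mark(character(), character(), character())
  sp <- switch(panel,
    d = list(channels = list(sinu(f_lf), harm(f_lf)),
             edges = ed("PS", 1, 2, 1L),
             spurious = mark("ch1", "ch2", "removed"), genuine = none),
    e = list(channels = list(am(f_hf), sinu(f_hf)),
             edges = ed("PS", 1, 2, 1L),
             spurious = mark("ch1", "ch2", "removed"), genuine = none),
    f = list(channels = list(sinu(f_lf), sinu(f_hf)),
             edges = ed("CFS", 1, 2, 2L),
             spurious = none, genuine = mark("ch1", "ch2", "kept")),
    g = list(channels = list(sinu(f_lf), harm(f_lf)),
             # full phase lock: the canonical complete-motif constellation
             edges = rbind(ed("PS", 1, 2, 1L, s = 1),
                           ed("CFS", 1, 2, 2L)),
             spurious = none, genuine = mark("ch1", "ch2", "removed")),
    h = list(channels = list(harm(f_lf), harm(f_lf)),
             edges = ed("PS", 1, 2, 1L),
             spurious = rbind(mark("ch1", "ch2", "removed"),
                              mark("ch2", "ch1", "removed")),
             genuine = none))
  out <- gen_recording(scenario_spec(sp$channels, sp$edges, duration, rate))
  out$truth$panel <- panel
  out$truth$spurious_edges <- sp$spurious
  out$truth$genuine_edges <- sp$genuine
  out$f_lf <- f_lf
  out$f_hf <- f_hf
  out
}

#' Synthetic cohort generator
#'
#' Independent seeded realizations of a scenario mix with subject-level
#' variation of planted strengths; feeds the group-level statistics and
#' topology test suites.
#'
#' @param n_subjects number of subjects (>= 2)
#' @param base_spec a [scenario_spec()]
#' @param strength_sd SD of the per-subject perturbation of planted edge
#'   strengths (truncated to `[0, 1]`; default 0.05)
#' @return list of per-subject [gen_recording()] results
#' @export
gen_cohort <- function(n_subjects, base_spec, strength_sd = 0.05) {
  stop_if_not(n_subjects >= 2, "need at least 2 subjects")
  lapply(seq_len(n_subjects), function(s) {
    sp <- base_spec
    if (nrow(sp$edges)) {
      sp$edges$strength <- pmin(1, pmax(0,
        sp$edges$strength + rnorm(nrow(sp$edges), 0, strength_sd)))
    }
    gen_recording(sp)
  })
}
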