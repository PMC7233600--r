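test_that("frequency grids are geometric with exact endpoints", {
  g <- frequency_grid(1.2, 315, 49)
  expect_equal(nrow(g), 49)
  expect_equal(g$f0[1], 1.2)
  expect_equal(g$f0[49], 315)
  ratios <- g$f0[-1] / g$f0[-49]
  expect_equal(ratios, rep((315 / 1.2)^(1 / 48), 48), tolerance = 1e-12)

  g53 <- frequency_grid(1.1, 315, 53)
  expect_equal(nrow(g53), 53)
  expect_equal(range(g53$f0), c(1.1, 315))

  expect_error(frequency_grid(10, 10, 1), "f_min < f_max")
  expect_error(frequency_grid(-1, 10, 5), "f_min")
})

test_that("ratio-pair matching enforces the 5% deviation bound", {
  # hand-built grid around one LF with two m = 2 candidates
  g <- data.frame(f0 = c(10, 19.4, 21.2))
  rp <- match_ratio_pairs(g, 2)
  hit <- rp[rp$lf_hz == 10, ]
  expect_equal(hit$hf_hz, 19.4)          # 3% deviation beats 6%
  expect_false(21.2 %in% rp$hf_hz[rp$lf_hz == 10])

  g2 <- data.frame(f0 = c(10, 20))
  rp2 <- match_ratio_pairs(g2, 2)
  expect_equal(rp2$deviation[rp2$lf_hz == 10], 0)

  # full analysis grid, ratios 2..7: every returned pair within bound
  g49 <- frequency_grid(1.2, 315, 49)
  rp_all <- match_ratio_pairs(g49, 2:7)
  expect_true(all(rp_all$deviation <= 0.05))
  expect_true(all(rp_all$hf_hz > rp_all$lf_hz))

  # tightening the tolerance can only remove pairs
  rp_tight <- match_ratio_pairs(g49, 2:7, tol = 0.02)
  key <- function(x) paste(x$lf_index, x$hf_index, x$ratio_m)
  expect_true(all(key(rp_tight) %in% key(rp_all)))
})

test_that("line-noise removal notches the base and all harmonics", {
  srate <- 1000
  t <- seq_len(4000) / srate
  # projection on the tone itself (exact-bin amplitude, interior samples)
  tone_amp <- function(x, f) {
    Mod(mean((x * exp(-2i * pi * f * t))[1001:3000]))
  }
  set.seed(1)
  x <- sin(2 * pi * 50 * t) + 0.5 * sin(2 * pi * 100 * t) +
    0.5 * sin(2 * pi * 150 * t) + rnorm(4000, 0, 0.1)
  rec <- bb_recording(matrix(x, 1), srate)
  out <- remove_line_noise(rec, 50)
  for (f in c(50, 100, 150)) {
    atten <- 20 * log10(tone_amp(out$samples[1, ], f) /
                          tone_amp(rec$samples[1, ], f))
    expect_lt(atten, -40)
  }
  # pass band: a 30 Hz tone is preserved away from the stop bands
  x2 <- sin(2 * pi * 30 * t)
  out2 <- remove_line_noise(bb_recording(matrix(x2, 1), srate), 50)
  expect_equal(out2$samples[1, 1500:2500], x2[1500:2500], tolerance = 1e-2)
  expect_error(remove_line_noise(rec, 600), "Nyquist")
})

test_that("Morlet decomposition recovers sinusoid envelope and phase ramp", {
  srate <- 1000
  t <- seq_len(4000) / srate
  rec <- bb_recording(matrix(cos(2 * pi * 10 * t), 1), srate)
  g <- data.frame(f0 = c(10, 40))
  attr(g, "wavelet_width") <- 5
  store <- morlet_decompose(rec, g, decimate = FALSE)
  nb <- store[[1]][[1]]
  mid <- which(nb$valid)
  expect_equal(mean(Mod(nb$values[mid])), 1, tolerance = 5e-3)
  expect_lt(sd(Mod(nb$values[mid])), 1e-3)
  # phase advances 2 pi f0 / rate per sample in the valid region
  dphi <- diff(Arg(nb$values[mid]))
  dphi <- dphi[abs(dphi) < pi]
  expect_equal(mean(dphi), 2 * pi * 10 / srate, tolerance = 1e-4)
  # analyzing the 10 Hz tone at 40 Hz center: >= 20 dB down
  nb40 <- store[[1]][[2]]
  ratio <- mean(Mod(nb40$values[nb40$valid])) / mean(Mod(nb$values[mid]))
  expect_lt(20 * log10(ratio), -20)
  expect_error(morlet_decompose(rec, frequency_grid(10, 600, 3)), "Nyquist")
})

test_that("filterbank is linear", {
  set.seed(2)
  srate <- 500
  x <- rnorm(2000)
  y <- rnorm(2000)
  g <- data.frame(f0 = 12)
  attr(g, "wavelet_width") <- 5
  dec <- function(v) {
    morlet_decompose(bb_recording(matrix(v, 1), srate), g,
                     decimate = FALSE)[[1]][[1]]$values
  }
  expect_equal(dec(2 * x - 3 * y), 2 * dec(x) - 3 * dec(y),
               tolerance = 1e-10)
})

test_that("decimation follows the 5x-center-frequency rule and keeps phase", {
  mk <- function(f0, srate, n = 8000) {
    tt <- seq_len(n) / srate
    as_nb(exp(1i * 2 * pi * f0 * tt), f0 = f0, srate = srate)
  }
  d1 <- decimate_narrowband(mk(10, 1000))
  expect_equal(d1$srate, 50)           # factor 20
  d2 <- decimate_narrowband(mk(300, 1000))
  expect_equal(d2$srate, 1000)         # factor clamps at 1
  d3 <- decimate_narrowband(mk(1.2, 1000))
  expect_equal(1000 / d3$srate, 166)   # floor(1000 / 6)
  expect_equal(d3$srate, 1000 / 166, tolerance = 1e-12)

  # decimate-then-upsample introduces no phase bias
  set.seed(3)
  srate <- 500
  z <- cfcnet:::conv_same(rnorm(6000), cfcnet:::morlet_kernel(8, srate, 5))
  nb <- as_nb(z, f0 = 8, srate = srate)
  nb$valid[c(1:300, 5701:6000)] <- FALSE
  dec <- decimate_narrowband(nb)
  back <- cfcnet:::interp_complex(dec$values, dec$idx, nb$idx)
  ok <- nb$valid & !is.na(back)
  expect_gte(Mod(mean(exp(1i * (Arg(nb$values[ok]) - Arg(back[ok]))))),
             0.99)
})

test_that("artifact-window rejection applies the channel/band fractions", {
  set.seed(4)
  srate <- 200
  n <- 4000                             # 20 s, 40 windows of 500 ms
  n_ch <- 20
  quiet <- lapply(1:3, function(b) {
    matrix(abs(rnorm(n_ch * n, 1, 0.1)), n_ch, n)
  })
  res <- detect_artifact_windows(quiet, srate)
  expect_false(any(res$window_rejected))

  burst <- function(frac) {
    env <- lapply(1:3, function(b) matrix(abs(rnorm(n_ch * n, 1, 0.1)),
                                          n_ch, n))
    hit <- seq_len(round(frac * n_ch))
    for (b in 1:3) env[[b]][hit, 2001:2100] <- 10   # window 21
    env
  }
  res20 <- detect_artifact_windows(burst(0.20), srate)
  expect_true(res20$window_rejected[21])
  expect_equal(sum(res20$window_rejected), 1)
  res05 <- detect_artifact_windows(burst(0.05), srate)
  expect_false(res05$window_rejected[21])

  bad <- list(matrix(1, 2, 100), matrix(1, 2, 90))
  expect_error(detect_artifact_windows(bad, srate), "inconsistent")
})

test_that("envelope band tracks amplitude-modulation phase", {
  srate <- 1000
  t <- seq_len(20000) / srate
  f_hf <- 80
  f_mod <- 10
  x <- (1 + 0.5 * cos(2 * pi * f_mod * t)) * cos(2 * pi * f_hf * t)
  g <- data.frame(f0 = c(f_mod, f_hf))
  attr(g, "wavelet_width") <- 5
  store <- morlet_decompose(bb_recording(matrix(x, 1), srate), g)
  hf <- store[[1]][[2]]
  lf <- store[[1]][[1]]
  env <- envelope_band(hf, f_mod, lf$idx, lf$srate)
  expect_equal(env$srate, lf$srate)
  expect_equal(length(env$values), length(lf$values))
  # envelope phase tracks the modulation phase
  ok <- env$valid
  target <- 2 * pi * f_mod * env$idx[ok] / srate
  expect_gte(Mod(mean(exp(1i * (Arg(env$values[ok]) - target)))), 0.98)

  # constant envelope maps to (near) zero after mean removal
  y <- cos(2 * pi * f_hf * t)
  store2 <- morlet_decompose(bb_recording(matrix(y, 1), srate), g)
  env2 <- envelope_band(store2[[1]][[2]], f_mod)
  expect_lt(mean(Mod(env2$values[env2$valid])),
            0.01 * mean(Mod(store2[[1]][[2]]$values)))
})

test_that("default artifact bands stay at or below 100 Hz", {
  g <- frequency_grid(1.2, 315, 49)
  idx <- iie_bands(g)
  expect_true(all(g$f0[idx] <= 100))
  expect_lte(length(idx), 18)
})
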