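#' Configuration of the four-population Kuramoto validation model
#'
#' Two "areas" (A, B), each with a low-frequency and a high-frequency
#' population of phase oscillators (f_HF = 2 f_LF, i.e. a 1:2 ratio).
#' Oscillators within a population are all-to-all coupled with constant weak
#' internal coupling; populations are coupled through their mean signals
#' (order parameter M and mean-field phase psi) by 1:1 phase synchrony (the
#' LF pair and the HF pair), local 1:2 cross-frequency synchrony (within each
#' area), and interareal 1:2 cross-frequency synchrony. Each external
#' coupling is kappa = c * eps, with a shared coupling factor c scaling all
#' eps jointly.
#'
#' The per-iteration phase increment omega is drawn uniformly from
#' `[pi/(15 m'), pi/m']`, m' = 1 for HF and 2 for LF populations (the
#' nominal reference increment is pi/10, i.e. 5,000 HF cycles per 100,000
#' iterations). This wide heterogeneity keeps the populations partially
#' incoherent, so the mean fields fluctuate ("intermittent synchronization")
#' and coupling strengthens phase correlations gradually rather than
#' snapping the whole system into a periodic locked state; narrower spreads
#' fully synchronize each population and are available via `omega_range`.
#'
#' @param n_per_pop oscillators per population (default 500)
#' @param kappa_internal internal coupling (default 0.12)
#' @param eps named list of coupling susceptibilities: `lf_ps`, `hf_ps`,
#'   `local_cfs`, `interareal_cfs`
#' @param c_factor shared coupling factor c (default 0.3)
#' @param n_iter iterations of the discrete map (default 100000)
#' @param omega_range function(m_prime) returning c(lo, hi) of the uniform
#'   omega distribution; default `c(pi/(15 m'), pi/m')`
#' @return an object of class `kuramoto_config`
#' @export
kuramoto_config <- function(n_per_pop = 500L, kappa_internal = 0.12,
                            eps = list(lf_ps = 0.5, hf_ps = 0.5,
                                       local_cfs = 0.3,
                                       interareal_cfs = 0),
                            c_factor = 0.3, n_iter = 100000L,
                            omega_range = function(m_prime)
                              c(pi / (15 * m_prime), pi / m_prime)) {
  stop_if_not(n_per_pop >= 2, "need at least 2 oscillators per population")
  stop_if_not(kappa_internal >= 0 && c_factor >= 0 &&
                all(unlist(eps) >= 0), "couplings must be >= 0")
  stop_if_not(all(c("lf_ps", "hf_ps", "local_cfs", "interareal_cfs") %in%
                    names(eps)), "eps must name all four couplings")
  structure(list(n_per_pop = as.integer(n_per_pop),
                 kappa_internal = kappa_internal, eps = eps,
                 c_factor = c_factor, n_iter = as.integer(n_iter),
                 omega_range = omega_range),
            class = "kuramoto_config")
}

#' @export
print.kuramoto_config <- function(x, ...) {
  cat(sprintf(
    "<kuramoto_config> 4 x %d oscillators, kappa_int %g, c %g, %d iterations\n",
    x$n_per_pop, x$kappa_internal, x$c_factor, x$n_iter))
  cat(sprintf("  eps: lf_ps %g, hf_ps %g, local_cfs %g, interareal_cfs %g\n",
              x$eps$lf_ps, x$eps$hf_ps, x$eps$local_cfs,
              x$eps$interareal_cfs))
  invisible(x)
}

# population order: 1 = A_LF, 2 = A_HF, 3 = B_LF, 4 = B_HF
# edge rows: src, tgt (0-based), n (multiplier of source mean phase),
# m (multiplier of target phase), kappa
kuramoto_edges <- function(cfg) {
  k <- function(e) cfg$c_factor * e
  e <- cfg$eps
  # symmetric (bidirectional) coupling for each link; 1:2 links multiply the
  # LF phase by 2
  rbind(
    c(2, 0, 1, 1, k(e$lf_ps)), c(0, 2, 1, 1, k(e$lf_ps)),       # A_LF<->B_LF
    c(3, 1, 1, 1, k(e$hf_ps)), c(1, 3, 1, 1, k(e$hf_ps)),       # A_HF<->B_HF
    c(0, 1, 2, 1, k(e$local_cfs)), c(1, 0, 1, 2, k(e$local_cfs)), # A local
    c(2, 3, 2, 1, k(e$local_cfs)), c(3, 2, 1, 2, k(e$local_cfs)), # B local
    c(0, 3, 2, 1, k(e$interareal_cfs)), c(3, 0, 1, 2, k(e$interareal_cfs)),
    c(2, 1, 2, 1, k(e$interareal_cfs)), c(1, 2, 1, 2, k(e$interareal_cfs)))
}

#' Simulate the four-population Kuramoto model
#'
#' Discrete unit-step map: at every iteration each oscillator's phase
#' advances by its intrinsic increment omega plus the internal mean-field
#' term `kappa_int R_k sin(psi_k - theta)` plus, for each external link into
#' its population, `kappa M_src sin(n psi_src - m theta)` (n:m generalization
#' of the 1:1 mean-signal coupling; n = m = 1 for phase synchrony links).
#' Initial phases are uniform on (-pi, pi]. Randomness is taken from the R
#' random-number stream; identical seeds give identical trajectories.
#'
#' @param cfg a [kuramoto_config]
#' @param save_phases keep full phase trajectories (memory-heavy; for small
#'   models and oracle checks)
#' @return an object of class `kuramoto_sim`: list with `M` and `psi`
#'   (4 x n_iter order-parameter modulus and mean-field phase), `omega`,
#'   `cfg`, and optionally `phases`
#' @export
kuramoto_simulate <- function(cfg, save_phases = FALSE) {
  n <- cfg$n_per_pop
  pop <- rep(0:3, each = n)
  m_prime <- c(2, 1, 2, 1)[pop + 1L]   # LF populations advance half as fast
  omega <- numeric(length(pop))
  for (mp in unique(m_prime)) {
    r <- cfg$omega_range(mp)
    sel <- m_prime == mp
    omega[sel] <- runif(sum(sel), r[1], r[2])
  }
  theta0 <- runif(length(pop), -pi, pi)
  res <- kuramoto_core(theta0, omega, pop, 4L, cfg$kappa_internal,
                       kuramoto_edges(cfg), cfg$n_iter, save_phases)
  out <- list(M = res$M, psi = res$psi, omega = omega, cfg = cfg)
  if (save_phases) out$phases <- res$phases
  rownames(out$M) <- rownames(out$psi) <- c("A_LF", "A_HF", "B_LF", "B_HF")
  class(out) <- "kuramoto_sim"
  out
}

#' @export
print.kuramoto_sim <- function(x, ...) {
  cat(sprintf("<kuramoto_sim> %d iterations; mean order parameters:\n",
              ncol(x$M)))
  print(round(rowMeans(x$M), 3))
  invisible(x)
}

# reference implementation with explicit O(N^2) pairwise internal coupling;
# used as an independent oracle for the mean-field core
kuramoto_naive <- function(theta0, omega, pop, kappa_int, edges, n_iter) {
  theta <- theta0
  npop <- max(pop) + 1L
  M <- psi <- matrix(0, npop, n_iter)
  phases <- matrix(0, length(theta0), n_iter)
  for (t in seq_len(n_iter)) {
    op <- vapply(seq_len(npop) - 1L,
                 function(k) mean(exp(1i * theta[pop == k])), 0i)
    M[, t] <- Mod(op)
    psi[, t] <- Arg(op)
    phases[, t] <- theta
    new_theta <- theta
    for (i in seq_along(theta)) {
      k <- pop[i]
      same <- which(pop == k)
      d <- omega[i] +
        kappa_int / length(same) * sum(sin(theta[same] - theta[i]))
      for (e in seq_len(nrow(edges))) {
        if (edges[e, 2] != k) next
        src <- edges[e, 1]
        d <- d + edges[e, 5] * M[src + 1L, t] *
          sin(edges[e, 3] * psi[src + 1L, t] - edges[e, 4] * theta[i])
      }
      new_theta[i] <- theta[i] + d
    }
    theta <- new_theta
  }
  list(M = M, psi = psi, phases = phases)
}

# |cPLV| between two phase series at every circular shift of the second,
# via FFT cross-correlation; returns the vector over shifts 0..L-1
plv_all_shifts <- function(theta_a, theta_b) {
  u <- exp(1i * theta_a)
  v <- exp(1i * theta_b)
  L <- length(u)
  # c(s) = (1/L) sum_t u_t * Conj(v_{t+s}) = (1/L) IFFT(Conj(FFT(u)) * FFT(v))
  Mod(fft(Conj(fft(u)) * fft(v), inverse = TRUE)) / L^2
}

# rotation-surrogate null mean for a phase pair: mean |cPLV| over n_surr
# shifts drawn uniformly from [0.1 L, 0.9 L]
rotation_null_mean <- function(theta_a, theta_b, n_surr = 200L) {
  all_shifts <- plv_all_shifts(theta_a, theta_b)
  L <- length(theta_a)
  s <- sample(ceiling(0.1 * L):floor(0.9 * L), n_surr, replace = TRUE)
  mean(all_shifts[s + 1L])
}

#' Measure population-level phase correlations in a simulation
#'
#' Computes the PLV between population mean-field phase series for 1:1 phase
#' synchrony (the LF pair and the HF pair), local 1:2 cross-frequency
#' synchrony within each area, and interareal 1:2 cross-frequency synchrony
#' (both orientations). Each observation is tested at nominal p < 0.01 by
#' thresholding at 2.42x the mean PLV of rotation surrogates of the
#' second series (surrogates rather than the closed-form Rayleigh mean,
#' because mean-field phases are autocorrelated).
#'
#' @param sim a `kuramoto_sim`
#' @param n_surrogates rotation surrogates per observation (default 200)
#' @param transient initial iterations to discard (default 0)
#' @return an object of class `kuramoto_measures`: data.frame with columns
#'   `coupling`, `plv`, `null_mean`, `significant`
#' @export
kuramoto_measure <- function(sim, n_surrogates = 200L, transient = 0L) {
  keep <- (transient + 1L):ncol(sim$psi)
  p <- sim$psi[, keep, drop = FALSE]
  # (a, b, na, nb): PLV of (na * psi_a - nb * psi_b)
  defs <- list(
    ps_lf           = c(1, 3, 1, 1),
    ps_hf           = c(2, 4, 1, 1),
    local_cfs_A     = c(1, 2, 2, 1),
    local_cfs_B     = c(3, 4, 2, 1),
    interareal_cfs_AB = c(1, 4, 2, 1),
    interareal_cfs_BA = c(3, 2, 2, 1))
  rows <- lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    ta <- d[3] * p[d[1], ]
    tb <- d[4] * p[d[2], ]
    v <- Mod(mean(exp(1i * (ta - tb))))
    nm0 <- rotation_null_mean(ta, tb, n_surrogates)
    data.frame(coupling = nm, plv = v, null_mean = nm0,
               significant = v > 2.42 * nm0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("kuramoto_measures", "data.frame")
  out
}

#' Validation sweep: spurious interareal CFS and post-pruning false positives
#'
#' Runs one simulation per value of the shared coupling factor c (fresh
#' random initial phases and omega draws each time), with zero genuine
#' interareal cross-frequency coupling. Every significant interareal CFS
#' observation is therefore spurious. An observation counts as a surviving
#' false positive when it is significant but NOT excluded by the triangle
#' motif, i.e. not accompanied by both significant local CFS (at either
#' area for the AB/BA orientations) and significant 1:1 phase synchrony.
#' The false-positive rate of a sweep is the fraction of surviving false
#' positives over all interareal observations; with `reps > 1` the mean and
#' SD across repetitions of the whole sweep are reported.
#'
#' @param cfg_base a [kuramoto_config]; its `c_factor` is replaced by each
#'   grid value (defaults follow the validation setting:
#'   eps interareal = 0, local = 0.3, PS = 0.5)
#' @param c_grid coupling factors to sweep (default 64 values in [0, 0.3])
#' @param reps repetitions of the sweep (default 1)
#' @param n_surrogates surrogates per observation (default 200)
#' @return an object of class `kuramoto_validation`: list with `detail`
#'   (per rep x c x coupling data.frame), `fpr` (per-rep rates),
#'   `fpr_mean`, `fpr_sd`, `fpr_unpruned_mean`
#' @export
kuramoto_validation <- function(cfg_base = kuramoto_config(
                                  eps = list(lf_ps = 0.5, hf_ps = 0.5,
                                             local_cfs = 0.3,
                                             interareal_cfs = 0)),
                                c_grid = seq(0, 0.3, length.out = 64),
                                reps = 1L, n_surrogates = 200L) {
  detail <- list()
  fpr <- fpr_unpruned <- numeric(reps)
  for (r in seq_len(reps)) {
    n_fp <- n_sig <- n_obs <- 0L
    for (cc in c_grid) {
      cfg <- cfg_base
      cfg$c_factor <- cc
      sim <- kuramoto_simulate(cfg)
      meas <- kuramoto_measure(sim, n_surrogates)
      sig <- setNames(meas$significant, meas$coupling)
      # triangle-motif exclusion in the model: interareal CFS between the
      # LF population of one area and the HF population of the other is
      # excluded when local CFS (either area of the motif) plus the
      # corresponding 1:1 PS are both significant
      excl_AB <- (sig["local_cfs_A"] && sig["ps_hf"]) ||
                 (sig["local_cfs_B"] && sig["ps_lf"])
      excl_BA <- (sig["local_cfs_B"] && sig["ps_hf"]) ||
                 (sig["local_cfs_A"] && sig["ps_lf"])
      fp_AB <- sig["interareal_cfs_AB"] && !excl_AB
      fp_BA <- sig["interareal_cfs_BA"] && !excl_BA
      n_obs <- n_obs + 2L
      n_sig <- n_sig + sum(sig[c("interareal_cfs_AB", "interareal_cfs_BA")])
      n_fp <- n_fp + sum(c(fp_AB, fp_BA))
      detail[[length(detail) + 1L]] <-
        cbind(rep = r, c = cc, meas,
              fp = c(NA, NA, NA, NA, fp_AB, fp_BA))
    }
    fpr[r] <- n_fp / n_obs
    fpr_unpruned[r] <- n_sig / n_obs
  }
  structure(list(detail = do.call(rbind, detail), fpr = fpr,
                 fpr_mean = mean(fpr), fpr_sd = if (reps > 1) sd(fpr) else NA,
                 fpr_unpruned_mean = mean(fpr_unpruned),
                 c_grid = c_grid, reps = reps),
            class = "kuramoto_validation")
}

#' @export
print.kuramoto_validation <- function(x, ...) {
  cat(sprintf(
    "<kuramoto_validation> %d reps x %d coupling values\n", x$reps,
    length(x$c_grid)))
  cat(sprintf("  post-pruning FPR: %.4g (SD %.4g); unpruned: %.4g\n",
              x$fpr_mean, x$fpr_sd, x$fpr_unpruned_mean))
  invisible(x)
}

#' @export
summary.kuramoto_validation <- function(object, ...) {
  d <- object$detail
  agg <- stats::aggregate(cbind(plv, significant) ~ coupling + c, data = d,
                          FUN = mean)
  names(agg)[3:4] <- c("mean_plv", "frac_significant")
  agg
}
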