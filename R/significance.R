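#' Circular-rotation surrogate
#'
#' Circularly shifts a series by a random integer drawn uniformly from
#' 10%--90% of its length. Rotation preserves the autocorrelation structure
#' (avoiding underestimation of null-hypothesis coupling) while destroying
#' cross-signal alignment; the outer 10% of shifts is excluded to avoid
#' near-identity surrogates.
#'
#' @param z a `narrowband` object or complex vector (length >= 10)
#' @return a surrogate of the same type; uses the R random-number stream
#' @export
rotation_surrogate <- function(z) {
  vals <- if (inherits(z, "narrowband")) z$values else z
  L <- length(vals)
  stop_if_not(L >= 10, "series too short to rotate (L < 10)")
  lo <- ceiling(0.1 * L)
  hi <- floor(0.9 * L)
  s <- sample(lo:hi, 1L)
  rot <- c(vals[(s + 1L):L], vals[seq_len(s)])
  if (inherits(z, "narrowband")) {
    # the valid mask is not rotated: surrogates stand in for the same
    # retained samples
    z$values <- rot
    z
  } else rot
}

#' Pooled surrogate null for a coupling metric
#'
#' One (or more) rotation-surrogate coupling value per channel pair, with the
#' second series rotated, pooled across pairs into a null mean (and SD, used
#' by the wPLI z-rule). Nulls are built separately per subject, per metric
#' and per frequency(-pair).
#'
#' @param pairs list of pair specs; each element a list/pair of the two
#'   series exactly as passed to the estimator (for CFS/PAC the second
#'   element is the HF-side or envelope-band series, which is the one
#'   rotated)
#' @param fun the coupling estimator taking (first, second, ...)
#' @param ... extra arguments to `fun` (e.g. `m` for [cfs_plv()])
#' @param n_surrogates surrogates per pair (default 1, pooled)
#' @return an object of class `surrogate_null`: list(mean, sd, n_pairs,
#'   values)
#' @export
build_null <- function(pairs, fun, ..., n_surrogates = 1L) {
  stop_if_not(length(pairs) >= 1, "no admissible pairs for the null")
  vals <- numeric(0)
  for (p in pairs) {
    for (s in seq_len(n_surrogates)) {
      vals <- c(vals, fun(p[[1]], rotation_surrogate(p[[2]]), ...))
    }
  }
  structure(list(mean = mean(vals),
                 sd = if (length(vals) > 1) sd(vals) else 0,
                 n_pairs = length(pairs), values = vals),
            class = "surrogate_null")
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat(sprintf("<surrogate_null> mean %.4g, sd %.4g over %d pairs\n",
              x$mean, x$sd, x$n_pairs))
  invisible(x)
}

#' Per-edge significance mask
#'
#' PLV-family metrics (PLV, CFS, PAC, AC): an edge is significant when its
#' value strictly exceeds 2.42x the surrogate-null mean. The PLV of
#' uncorrelated phases is Rayleigh distributed, and a Rayleigh distribution
#' reaches its 99th percentile at 2.42x its mean, so this is a nominal
#' p < 0.01 test. wPLI: significant when the z-score
#' `(value - null mean)/null SD` strictly exceeds 2 (nominal alpha = 0.02).
#'
#' @param cm a `coupling_matrix`
#' @param null a `surrogate_null` for the same metric/frequency
#' @param rule "rayleigh_2.42" or "zscore_2"; default chosen by metric
#' @return an object of class `significance_result`: list(mask, rule,
#'   threshold, n_possible, n_significant)
#' @export
significance_mask <- function(cm, null,
                              rule = if (cm$metric == "wPLI") "zscore_2"
                                     else "rayleigh_2.42") {
  rule <- match.arg(rule, c("rayleigh_2.42", "zscore_2"))
  if (rule == "zscore_2") {
    stop_if_not(null$sd > 0, "degenerate null: SD is zero")
    mask <- (cm$values - null$mean) / null$sd > 2
    threshold <- null$mean + 2 * null$sd
    alpha <- 0.02
  } else {
    threshold <- 2.42 * null$mean
    mask <- cm$values > threshold
    alpha <- 0.01
  }
  mask[is.na(cm$values)] <- FALSE
  if (cm$metric %in% c("PLV", "wPLI", "AC")) diag(mask) <- FALSE
  n_possible <- sum(!is.na(cm$values) & (row(mask) != col(mask)))
  structure(list(mask = mask, rule = rule, alpha_nominal = alpha,
                 threshold = threshold, n_possible = n_possible,
                 n_significant = sum(mask & (row(mask) != col(mask)))),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("<significance_result> %d / %d edges significant (%s)\n",
              x$n_significant, x$n_possible, x$rule))
  invisible(x)
}

#' Baseline-adjusted connection density
#'
#' `K = n_significant / n_possible - baseline`. At a nominal p < 0.01, 1% of
#' edges are expected to be false positives under the null, so 1% (the
#' default baseline) is subtracted; K is not clamped and may be slightly
#' negative.
#'
#' @param sig a `significance_result` (or a list with `n_significant`,
#'   `n_possible`)
#' @param baseline expected false-positive fraction (default 0.01)
#' @return a fraction (possibly slightly negative)
#' @export
connection_density <- function(sig, baseline = 0.01) {
  stop_if_not(sig$n_possible > 0, "no possible connections")
  sig$n_significant / sig$n_possible - baseline
}

#' Graph strength
#'
#' Mean coupling strength over admissible (non-masked, interareal) edges.
#'
#' @param cm a `coupling_matrix`
#' @param sig optional `significance_result`; when given, the mean is over
#'   significant edges only
#' @return mean strength, unitless
#' @export
graph_strength <- function(cm, sig = NULL) {
  off <- row(cm$values) != col(cm$values)
  sel <- !is.na(cm$values) & off
  if (!is.null(sig)) sel <- sel & sig$mask
  stop_if_not(any(sel), "no admissible edges")
  mean(cm$values[sel])
}

#' Group-level bootstrap of subject statistics
#'
#' Resamples subjects with replacement and reports the 2.5th/97.5th
#' percentiles of the weighted group mean. For intracranial cohorts the
#' weights are the per-subject contact counts (equivalent to pooling contacts
#' across subjects); equal weights give the ordinary bootstrap.
#'
#' @param values per-subject statistic (e.g. K or GS)
#' @param weights per-subject weights (default equal)
#' @param n_resamples number of bootstrap resamples (default 1000)
#' @return an object of class `graph_summary`: list(mean, ci_low, ci_high,
#'   n_subjects, n_resamples)
#' @export
group_bootstrap <- function(values, weights = rep(1, length(values)),
                            n_resamples = 1000L) {
  n <- length(values)
  stop_if_not(n >= 2, "need at least 2 subjects")
  stop_if_not(length(weights) == n, "one weight per subject")
  wmean <- function(idx) sum(values[idx] * weights[idx]) / sum(weights[idx])
  boots <- vapply(seq_len(n_resamples),
                  function(i) wmean(sample.int(n, n, replace = TRUE)), 0)
  qs <- quantile(boots, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(mean = wmean(seq_len(n)), ci_low = qs[1], ci_high = qs[2],
                 n_subjects = n, n_resamples = n_resamples,
                 resamples = boots),
            class = "graph_summary")
}

#' @export
print.graph_summary <- function(x, ...) {
  cat(sprintf("<graph_summary> mean %.4g [%.4g, %.4g] (%d subjects, %d resamples)\n",
              x$mean, x$ci_low, x$ci_high, x$n_subjects, x$n_resamples))
  invisible(x)
}
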