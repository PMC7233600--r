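#' End-to-end genuine-CFC analysis for one frequency pair
#'
#' Convenience driver tying the modules together for a single (LF, HF, 1:m)
#' combination: computes the directed cross-frequency coupling matrix (CFS
#' or PAC, local coupling on the diagonal), the within-frequency phase
#' synchrony at the LF and HF grid frequencies, and -- for PAC -- the HF
#' envelope correlation; builds pooled rotation-surrogate nulls per metric;
#' thresholds edges; and applies triangle-motif pruning.
#'
#' @param store an `nb_store` from [morlet_decompose()]
#' @param lf_index,hf_index grid indices of the frequency pair
#' @param m integer frequency ratio
#' @param cfc_metric "CFS" or "PAC"
#' @param ps_metric within-frequency metric used for the motif legs
#'   ("PLV" or "wPLI")
#' @param n_surrogates surrogates per pair pooled into each null
#'   (default 20)
#' @param rules a [pair_rules]
#' @return list: `cfc` (coupling_matrix), `sig_cfc`, `sig_ps_lf`,
#'   `sig_ps_hf`, `sig_ac` (PAC only), `multiplex`, `report`
#'   (pruning_report)
#' @export
analyze_frequency_pair <- function(store, lf_index, hf_index, m,
                                   cfc_metric = c("CFS", "PAC"),
                                   ps_metric = c("PLV", "wPLI"),
                                   n_surrogates = 20L,
                                   rules = pair_rules(min_distance = 0)) {
  cfc_metric <- match.arg(cfc_metric)
  ps_metric <- match.arg(ps_metric)
  grid <- attr(store, "grid")
  rp <- data.frame(lf_index = lf_index, hf_index = hf_index, ratio_m = m,
                   lf_hz = grid$f0[lf_index], hf_hz = grid$f0[hf_index],
                   deviation = abs(grid$f0[hf_index] /
                                     (m * grid$f0[lf_index]) - 1))
  stop_if_not(rp$deviation <= 0.05, "frequency pair not within 5% of 1:m")
  n <- length(store)
  adm <- admissible_pairs(attr(store, "meta"), rules)

  cfc <- connectome(store, cfc_metric, ratio_pairs = rp, rules = rules)[[1]]
  ps <- connectome(store, ps_metric, freq_indices = c(lf_index, hf_index),
                   rules = rules)

  ordered_pairs <- function(build) {
    out <- list()
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (!adm[i, j]) next
        out[[length(out) + 1L]] <- build(i, j)
      }
    }
    out
  }
  unordered_pairs <- function(build) {
    out <- list()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (adm[i, j]) out[[length(out) + 1L]] <- build(i, j)
      }
    }
    out
  }

  ps_fun <- if (ps_metric == "PLV") plv else wpli
  sig_of_ps <- function(cm, k) {
    pairs <- unordered_pairs(function(i, j)
      list(nb_at(store, i, k), nb_at(store, j, k)))
    null <- build_null(pairs, ps_fun, n_surrogates = n_surrogates)
    significance_mask(cm, null)
  }
  sig_ps_lf <- sig_of_ps(ps[[1]], lf_index)
  sig_ps_hf <- sig_of_ps(ps[[2]], hf_index)

  if (cfc_metric == "CFS") {
    pairs <- ordered_pairs(function(i, j)
      list(nb_at(store, i, lf_index), nb_at(store, j, hf_index)))
    null_cfc <- build_null(pairs, cfs_plv, m = m,
                           n_surrogates = n_surrogates)
    sig_cfc <- significance_mask(cfc, null_cfc)
    mx <- multiplex_connectome(
      sig_cfc$mask, ps_lf_mask = sig_ps_lf$mask,
      ps_hf_mask = sig_ps_hf$mask, cfc_metric = "CFS",
      lf_hz = rp$lf_hz, hf_hz = rp$hf_hz, ratio_m = m)
    report <- prune_cfs(mx)
    sig_ac <- NULL
  } else {
    ref_lf <- nb_at(store, 1, lf_index)
    envs <- lapply(seq_len(n), function(j)
      envelope_band(nb_at(store, j, hf_index), grid$f0[lf_index],
                    ref_lf$idx, ref_lf$srate))
    pairs <- ordered_pairs(function(i, j)
      list(nb_at(store, i, lf_index), envs[[j]]))
    null_cfc <- build_null(pairs, pac_plv, n_surrogates = n_surrogates)
    sig_cfc <- significance_mask(cfc, null_cfc)
    ac <- connectome(store, "AC", ratio_pairs = rp, rules = rules)[[1]]
    ac_pairs <- unordered_pairs(function(i, j) list(envs[[i]], envs[[j]]))
    null_ac <- build_null(ac_pairs, ac_plv, n_surrogates = n_surrogates)
    sig_ac <- significance_mask(ac, null_ac)
    mx <- multiplex_connectome(
      sig_cfc$mask, ps_lf_mask = sig_ps_lf$mask,
      ps_hf_mask = sig_ps_hf$mask, ac_hf_mask = sig_ac$mask,
      cfc_metric = "PAC", lf_hz = rp$lf_hz, hf_hz = rp$hf_hz, ratio_m = m)
    report <- prune_pac(mx)
  }
  list(cfc = cfc, sig_cfc = sig_cfc, sig_ps_lf = sig_ps_lf,
       sig_ps_hf = sig_ps_hf, sig_ac = sig_ac, multiplex = mx,
       report = report)
}

#' Analyze a triangle-motif scenario recording
#'
#' Decomposes a [gen_triangle_scenarios()] recording at its two frequencies
#' and runs [analyze_frequency_pair()] at the 1:2 ratio.
#'
#' @param scen output of [gen_triangle_scenarios()]
#' @param cfc_metric "CFS" or "PAC"
#' @param n_surrogates surrogates per pair for the nulls (default 20)
#' @return as [analyze_frequency_pair()]
#' @export
analyze_triangle_scenario <- function(scen, cfc_metric = "CFS",
                                      n_surrogates = 20L) {
  grid <- frequency_grid(scen$f_lf, scen$f_hf, 2)
  store <- morlet_decompose(scen$rec, grid)
  analyze_frequency_pair(store, 1L, 2L, 2L, cfc_metric = cfc_metric,
                         n_surrogates = n_surrogates)
}
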