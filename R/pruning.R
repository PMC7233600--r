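#' Multiplex connectome of aligned significance masks
#'
#' Bundles, on a common channel set, the directed cross-frequency
#' significance mask with the within-frequency and local masks that the
#' triangle-motif pruning rules consume.
#'
#' @param cfc_mask directed logical matrix of significant cross-frequency
#'   edges; rows index the LF channel, columns the HF channel
#' @param local_cfc logical per channel: significant local CFC (the
#'   `cfc_mask` diagonal is used when NULL)
#' @param ps_lf_mask,ps_hf_mask symmetric logical matrices of significant
#'   within-frequency phase synchrony at the LF and HF grid frequencies
#' @param ac_hf_mask symmetric logical matrix of significant HF
#'   envelope correlation (required for PAC pruning)
#' @param cfc_metric "CFS" or "PAC"
#' @param lf_hz,hf_hz,ratio_m frequency-pair bookkeeping
#' @return an object of class `multiplex_connectome`
#' @export
multiplex_connectome <- function(cfc_mask, local_cfc = NULL,
                                 ps_lf_mask = NULL, ps_hf_mask = NULL,
                                 ac_hf_mask = NULL,
                                 cfc_metric = c("CFS", "PAC"),
                                 lf_hz = NA_real_, hf_hz = NA_real_,
                                 ratio_m = NA_integer_) {
  cfc_metric <- match.arg(cfc_metric)
  n <- nrow(cfc_mask)
  stop_if_not(ncol(cfc_mask) == n, "cfc_mask must be square")
  if (is.null(local_cfc)) local_cfc <- diag(cfc_mask)
  stop_if_not(length(local_cfc) == n, "one local-CFC flag per channel")
  chk_sym <- function(m, nm) {
    if (is.null(m)) return(invisible())
    stop_if_not(all(dim(m) == n), paste(nm, "dimension mismatch"))
    stop_if_not(isTRUE(all(m == t(m))), paste(nm, "must be symmetric"))
  }
  chk_sym(ps_lf_mask, "ps_lf_mask")
  chk_sym(ps_hf_mask, "ps_hf_mask")
  chk_sym(ac_hf_mask, "ac_hf_mask")
  structure(list(cfc_mask = cfc_mask, local_cfc = as.logical(local_cfc),
                 ps_lf_mask = ps_lf_mask, ps_hf_mask = ps_hf_mask,
                 ac_hf_mask = ac_hf_mask, cfc_metric = cfc_metric,
                 lf_hz = lf_hz, hf_hz = hf_hz, ratio_m = ratio_m,
                 labels = rownames(cfc_mask)),
            class = "multiplex_connectome")
}

prune_edges <- function(mx, lf_side, hf_side) {
  n <- nrow(mx$cfc_mask)
  labels <- if (is.null(mx$labels)) as.character(seq_len(n)) else mx$labels
  edges <- which(mx$cfc_mask & (row(mx$cfc_mask) != col(mx$cfc_mask)),
                 arr.ind = TRUE)
  kept <- removed <- list()
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]  # LF node
    b <- edges[e, 2]  # HF node
    lf_motif <- lf_side(a, b)
    hf_motif <- hf_side(a, b)
    reason <- if (lf_motif && hf_motif) "both"
      else if (lf_motif) "lf_side_motif"
      else if (hf_motif) "hf_side_motif"
      else NA_character_
    row <- data.frame(lf_channel = labels[a], hf_channel = labels[b],
                      reason = reason, stringsAsFactors = FALSE)
    if (is.na(reason)) kept[[length(kept) + 1L]] <- row
    else removed[[length(removed) + 1L]] <- row
  }
  empty <- data.frame(lf_channel = character(), hf_channel = character(),
                      reason = character(), stringsAsFactors = FALSE)
  structure(list(
    kept = if (length(kept)) do.call(rbind, kept)[, 1:2] else empty[, 1:2],
    removed = if (length(removed)) do.call(rbind, removed) else empty,
    n_significant = nrow(edges), cfc_metric = mx$cfc_metric,
    lf_hz = mx$lf_hz, hf_hz = mx$hf_hz, ratio_m = mx$ratio_m),
    class = "pruning_report")
}

#' @export
print.pruning_report <- function(x, ...) {
  cat(sprintf(
    "<pruning_report> %s: %d significant edges, %d kept, %d removed\n",
    x$cfc_metric, x$n_significant, nrow(x$kept), nrow(x$removed)))
  if (nrow(x$removed)) print(table(x$removed$reason))
  invisible(x)
}

#' Triangle-motif pruning of interareal cross-frequency phase synchrony
#'
#' A genuine cross-frequency interaction connects two separable oscillatory
#' processes, whereas a single nonsinusoidal process projects signal
#' components into several frequency bands and can mimic interareal
#' cross-frequency synchrony via within-frequency synchrony. A significant
#' interareal CFS edge a -> b (a the LF node, b the HF node) is therefore
#' discarded when it closes a triangle motif: significant local CFS at the LF
#' location together with significant interareal HF phase synchrony, or
#' significant local CFS at the HF location together with significant
#' interareal LF phase synchrony. Edges outside any motif cannot stem from a
#' single source and are kept as genuine. The test is conservative (genuine
#' edges inside full motifs are also removed), yielding a lower bound on
#' genuine CFS.
#'
#' @param mx a [multiplex_connectome] with `cfc_metric = "CFS"` and both PS
#'   masks present
#' @return a `pruning_report` with kept/removed edge sets and per-edge
#'   removal reasons (`lf_side_motif`, `hf_side_motif`, `both`)
#' @export
prune_cfs <- function(mx) {
  stop_if_not(mx$cfc_metric == "CFS", "multiplex connectome is not CFS")
  stop_if_not(!is.null(mx$ps_lf_mask) && !is.null(mx$ps_hf_mask),
              "both PS masks are required for CFS pruning")
  prune_edges(mx,
              lf_side = function(a, b) mx$local_cfc[a] && mx$ps_hf_mask[a, b],
              hf_side = function(a, b) mx$local_cfc[b] && mx$ps_lf_mask[a, b])
}

#' Triangle-motif pruning of interareal phase-amplitude coupling
#'
#' PAC analogue of [prune_cfs()]: a significant interareal PAC edge a -> b is
#' discarded when there is significant local PAC at the HF location together
#' with significant interareal LF phase synchrony, or significant local PAC
#' at the LF location together with significant interareal HF
#' amplitude-envelope correlation.
#'
#' @param mx a [multiplex_connectome] with `cfc_metric = "PAC"`, the LF PS
#'   mask and the HF envelope-correlation (AC) mask present
#' @return a `pruning_report`
#' @export
prune_pac <- function(mx) {
  stop_if_not(mx$cfc_metric == "PAC", "multiplex connectome is not PAC")
  stop_if_not(!is.null(mx$ps_lf_mask), "LF PS mask required for PAC pruning")
  stop_if_not(!is.null(mx$ac_hf_mask), "HF AC mask required for PAC pruning")
  prune_edges(mx,
              lf_side = function(a, b) mx$local_cfc[a] && mx$ac_hf_mask[a, b],
              hf_side = function(a, b) mx$local_cfc[b] && mx$ps_lf_mask[a, b])
}

#' Corrected connection density after pruning
#'
#' `K_corr = kept / (n_possible - removed) - baseline`: the fraction of
#' remaining significant connections over the possible connections left after
#' removing putatively spurious ones, with the same baseline subtraction as
#' [connection_density()]. `fixed_denominator = TRUE` keeps the full
#' `n_possible` denominator instead (sensitivity alternative).
#'
#' @param rep a `pruning_report`
#' @param n_possible number of possible (admissible) directed connections
#' @param baseline expected false-positive fraction (default 0.01)
#' @param fixed_denominator do not exclude pruned edges from the denominator
#' @return a fraction (possibly slightly negative)
#' @export
corrected_density <- function(rep, n_possible, baseline = 0.01,
                              fixed_denominator = FALSE) {
  n_removed <- nrow(rep$removed)
  denom <- if (fixed_denominator) n_possible else n_possible - n_removed
  stop_if_not(denom > 0, "denominator is not positive")
  nrow(rep$kept) / denom - baseline
}

#' Write a pruning report as TSV
#'
#' @param rep a `pruning_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pruning_report <- function(rep, path) {
  k <- rep$kept
  r <- rep$removed
  df <- rbind(
    if (nrow(k)) cbind(k, status = "kept", reason = NA_character_),
    if (nrow(r)) cbind(r[, 1:2], status = "removed", reason = r$reason))
  if (is.null(df)) {
    df <- data.frame(lf_channel = character(), hf_channel = character(),
                     status = character(), reason = character())
  }
  df <- cbind(lf_hz = rep$lf_hz, hf_hz = rep$hf_hz, ratio = rep$ratio_m, df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
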