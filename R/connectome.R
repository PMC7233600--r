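#' Channel-pair exclusion rules
#'
#' Pairs closer than `min_distance` (volume conduction), pairs sharing a
#' reference contact, and explicitly listed channels or pairs are excluded
#' from connectivity analysis.
#'
#' @param min_distance minimum contact-to-contact Euclidean distance in mm
#'   (default 20)
#' @param exclude_shared_reference exclude pairs with the same
#'   `reference_label` (default TRUE)
#' @param exclusion_list character vector of channel labels, or "a|b" pair
#'   labels, to exclude
#' @return an object of class `pair_rules`
#' @export
pair_rules <- function(min_distance = 20, exclude_shared_reference = TRUE,
                       exclusion_list = character()) {
  stop_if_not(min_distance >= 0, "min_distance must be >= 0")
  structure(list(min_distance = min_distance,
                 exclude_shared_reference = exclude_shared_reference,
                 exclusion_list = exclusion_list),
            class = "pair_rules")
}

#' Admissible-pair mask from metadata and exclusion rules
#'
#' @param meta channel metadata data.frame (columns `label`, optionally
#'   `x_mm`/`y_mm`/`z_mm` and `reference_label`)
#' @param rules a [pair_rules]
#' @return logical channels x channels matrix, TRUE where the (unordered)
#'   pair is admissible; diagonal TRUE (local coupling is always admissible)
#' @export
admissible_pairs <- function(meta, rules = pair_rules()) {
  n <- nrow(meta)
  ok <- matrix(TRUE, n, n, dimnames = list(meta$label, meta$label))
  pos_cols <- c("x_mm", "y_mm", "z_mm")
  if (all(pos_cols %in% names(meta)) && rules$min_distance > 0) {
    pos <- as.matrix(meta[, pos_cols])
    if (!anyNA(pos)) {
      d <- as.matrix(stats::dist(pos))
      ok[d < rules$min_distance] <- FALSE
    }
  }
  if (rules$exclude_shared_reference && "reference_label" %in% names(meta)) {
    ref <- meta$reference_label
    same <- outer(ref, ref, "==") & !is.na(outer(ref, ref, paste))
    same[is.na(same)] <- FALSE
    ok[same] <- FALSE
  }
  if (length(rules$exclusion_list)) {
    chans <- rules$exclusion_list[!grepl("\\|", rules$exclusion_list)]
    pairs <- rules$exclusion_list[grepl("\\|", rules$exclusion_list)]
    ok[meta$label %in% chans, ] <- FALSE
    ok[, meta$label %in% chans] <- FALSE
    for (p in pairs) {
      ab <- strsplit(p, "\\|")[[1]]
      if (all(ab %in% meta$label)) {
        ok[ab[1], ab[2]] <- FALSE
        ok[ab[2], ab[1]] <- FALSE
      }
    }
  }
  diag(ok) <- TRUE
  ok
}

new_coupling_matrix <- function(values, metric, lf_hz, hf_hz, ratio_m,
                                admissible) {
  structure(list(values = values, metric = metric, lf_hz = lf_hz,
                 hf_hz = hf_hz, ratio_m = ratio_m, admissible = admissible),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("<coupling_matrix> %s, LF %.3g Hz / HF %.3g Hz (1:%d), %d ch\n",
              x$metric, x$lf_hz, x$hf_hz, x$ratio_m, nrow(x$values)))
  invisible(x)
}

# fetch the narrowband series of channel ch at grid index k
nb_at <- function(store, ch, k) store[[ch]][[k]]

#' All-pairs coupling matrices over a narrowband store
#'
#' Driver computing one coupling metric for every admissible channel pair.
#' Phase synchrony (`PLV`, `wPLI`) and amplitude coupling (`AC`) are
#' symmetric and computed per grid frequency (for AC, per ratio pair's HF
#' frequency with the LF center defining the envelope band). Cross-frequency
#' metrics (`CFS`, `PAC`) are directional -- rows index the LF channel,
#' columns the HF channel -- and computed per ratio pair, with local coupling
#' on the diagonal.
#'
#' @param store an `nb_store` from [morlet_decompose()]
#' @param metric one of "PLV", "wPLI", "CFS", "PAC", "AC"
#' @param freq_indices grid indices for PS metrics
#' @param ratio_pairs data.frame from [match_ratio_pairs()] for CFS/PAC/AC
#' @param rules a [pair_rules]
#' @return list of `coupling_matrix` objects
#' @export
connectome <- function(store, metric = c("PLV", "wPLI", "CFS", "PAC", "AC"),
                       freq_indices = NULL, ratio_pairs = NULL,
                       rules = pair_rules()) {
  metric <- match.arg(metric)
  meta <- attr(store, "meta")
  grid <- attr(store, "grid")
  adm <- admissible_pairs(meta, rules)
  n <- length(store)
  labels <- names(store)
  out <- list()
  if (metric %in% c("PLV", "wPLI")) {
    stop_if_not(!is.null(freq_indices), "freq_indices required for PS")
    fun <- if (metric == "PLV") plv else wpli
    for (k in freq_indices) {
      stop_if_not(k <= nrow(grid), "frequency index outside grid")
      vals <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (!adm[i, j]) next
          vals[i, j] <- vals[j, i] <- fun(nb_at(store, i, k),
                                          nb_at(store, j, k))
        }
      }
      out[[length(out) + 1L]] <-
        new_coupling_matrix(vals, metric, grid$f0[k], grid$f0[k], 1L, adm)
    }
    return(out)
  }
  stop_if_not(!is.null(ratio_pairs) && nrow(ratio_pairs) > 0,
              "ratio_pairs required for cross-frequency metrics")
  for (r in seq_len(nrow(ratio_pairs))) {
    kl <- ratio_pairs$lf_index[r]
    kh <- ratio_pairs$hf_index[r]
    mm <- ratio_pairs$ratio_m[r]
    vals <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
    if (metric == "CFS") {
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (!adm[i, j]) next
          vals[i, j] <- cfs_plv(nb_at(store, i, kl), nb_at(store, j, kh), mm)
        }
      }
    } else {
      # envelope bands of each channel's HF series at the LF center,
      # resampled to the LF time base
      ref_lf <- nb_at(store, 1, kl)
      envs <- lapply(seq_len(n), function(j) {
        envelope_band(nb_at(store, j, kh), grid$f0[kl], ref_lf$idx,
                      ref_lf$srate)
      })
      if (metric == "PAC") {
        for (i in seq_len(n)) {
          for (j in seq_len(n)) {
            if (!adm[i, j]) next
            vals[i, j] <- pac_plv(nb_at(store, i, kl), envs[[j]])
          }
        }
      } else { # AC
        for (i in seq_len(n - 1)) {
          for (j in (i + 1):n) {
            if (!adm[i, j]) next
            vals[i, j] <- vals[j, i] <- ac_plv(envs[[i]], envs[[j]])
          }
        }
      }
    }
    out[[length(out) + 1L]] <- new_coupling_matrix(
      vals, metric, ratio_pairs$lf_hz[r], ratio_pairs$hf_hz[r], mm, adm)
  }
  out
}

#' Write coupling matrices as a long-format edge list
#'
#' @param cms list of `coupling_matrix` objects
#' @param path output TSV path (columns: metric, lf_hz, hf_hz, ratio,
#'   lf_channel, hf_channel, value)
#' @return `path`, invisibly
#' @export
write_edge_list <- function(cms, path) {
  rows <- lapply(cms, function(cm) {
    idx <- which(!is.na(cm$values), arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(metric = cm$metric, lf_hz = cm$lf_hz, hf_hz = cm$hf_hz,
               ratio = cm$ratio_m,
               lf_channel = rownames(cm$values)[idx[, 1]],
               hf_channel = colnames(cm$values)[idx[, 2]],
               value = cm$values[idx])
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
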