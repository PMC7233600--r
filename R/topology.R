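#' Collapse a channel-level directed connectome to parcels
#'
#' Sums significant-edge counts and strengths over ordered parcel pairs and
#' accumulates the possible-connection counts N_C,pot. For multi-subject
#' intracranial data, call once per subject and combine with
#' [combine_parcel_edges()] (possible counts sum over subjects); for
#' parcel-level MEG data a single call with `n_subjects` multiplies the
#' admissible pair count.
#'
#' @param sig a `significance_result` (directed CFC mask, rows = LF channel)
#' @param cm the matching `coupling_matrix` (for strengths)
#' @param parcel_of named character vector mapping channel label -> parcel;
#'   channels mapped to NA are dropped
#' @param drop_unmapped silently drop channels missing from `parcel_of`
#'   (default FALSE: error)
#' @return an object of class `parcel_edges`: list with `edges` (one row per
#'   ordered parcel pair: `lf_parcel`, `hf_parcel`, `n_sig`, `strength`
#'   (summed), `n_pot`) and `connections` (one row per significant
#'   channel-level connection with its individual strength)
#' @export
collapse_to_atlas <- function(sig, cm, parcel_of, drop_unmapped = FALSE) {
  labels <- rownames(sig$mask)
  unmapped <- setdiff(labels, names(parcel_of))
  if (length(unmapped) && !drop_unmapped) {
    stop("unmapped channels: ", paste(unmapped, collapse = ", "),
         " (set drop_unmapped = TRUE to drop)", call. = FALSE)
  }
  keep <- labels %in% names(parcel_of) & !is.na(parcel_of[labels])
  rows <- list()
  admiss <- !is.na(cm$values)
  for (i in which(keep)) {
    for (j in which(keep)) {
      if (i == j || !admiss[i, j]) next
      rows[[length(rows) + 1L]] <- data.frame(
        lf_parcel = unname(parcel_of[labels[i]]),
        hf_parcel = unname(parcel_of[labels[j]]),
        n_sig = as.integer(sig$mask[i, j]),
        strength = if (sig$mask[i, j]) cm$values[i, j] else 0,
        n_pot = 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    df <- data.frame(lf_parcel = character(), hf_parcel = character(),
                     n_sig = integer(), strength = numeric(),
                     n_pot = integer())
    return(structure(list(edges = df, connections = df[, 1:2]),
                     class = "parcel_edges"))
  }
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(n_sig, strength, n_pot) ~
                            lf_parcel + hf_parcel, data = df, FUN = sum)
  conn <- df[df$n_sig > 0, c("lf_parcel", "hf_parcel", "strength")]
  structure(list(edges = agg, connections = conn), class = "parcel_edges")
}

#' Combine per-subject parcel edge tables
#'
#' @param ... `parcel_edges` objects from [collapse_to_atlas()]
#' @return a combined `parcel_edges` with counts and strengths summed and
#'   connections pooled
#' @export
combine_parcel_edges <- function(...) {
  xs <- list(...)
  df <- do.call(rbind, lapply(xs, function(x) x$edges))
  agg <- stats::aggregate(cbind(n_sig, strength, n_pot) ~
                            lf_parcel + hf_parcel, data = df, FUN = sum)
  conn <- do.call(rbind, lapply(xs, function(x) x$connections))
  structure(list(edges = agg, connections = conn), class = "parcel_edges")
}

#' Construct a parcel edge set directly
#'
#' @param edges aggregated table (`lf_parcel`, `hf_parcel`, `n_sig`,
#'   `strength`, `n_pot`)
#' @param connections per-connection table (`lf_parcel`, `hf_parcel`,
#'   `strength`), one row per significant connection; derived from `edges`
#'   by mean-strength replication when omitted
#' @return a `parcel_edges` object
#' @export
parcel_edges <- function(edges, connections = NULL) {
  as_parcel_edges(edges, connections)
}

as_parcel_edges <- function(x, connections = NULL) {
  if (inherits(x, "parcel_edges")) return(x)
  if (is.null(connections)) {
    # fall back to replicating each orientation's mean strength
    conn <- x[x$n_sig > 0, ]
    connections <- do.call(rbind, lapply(seq_len(nrow(conn)), function(r) {
      data.frame(lf_parcel = conn$lf_parcel[r],
                 hf_parcel = conn$hf_parcel[r],
                 strength = conn$strength[r] / conn$n_sig[r])[
                   rep(1, conn$n_sig[r]), ]
    }))
    if (is.null(connections)) {
      connections <- x[0, c("lf_parcel", "hf_parcel", "strength")]
    }
  }
  structure(list(edges = x, connections = connections),
            class = "parcel_edges")
}

#' Relative directed degree per parcel
#'
#' For each parcel, the relative in-degree is the fraction of its possible
#' connections in which it is the HF node of a significant cross-frequency
#' edge; the relative out-degree the fraction in which it is the LF node.
#' The relative directed degree is in-degree minus out-degree: positive
#' values mark predominantly HF hubs, negative predominantly LF hubs.
#'
#' @param edges a `parcel_edges` object from [collapse_to_atlas()], or its
#'   aggregated `edges` data.frame
#' @return data.frame: `parcel`, `in_degree`, `out_degree`, `value` in
#'   `[-1, 1]`
#' @export
relative_directed_degree <- function(edges) {
  if (inherits(edges, "parcel_edges")) edges <- edges$edges
  parcels <- sort(unique(c(edges$lf_parcel, edges$hf_parcel)))
  out <- lapply(parcels, function(p) {
    as_lf <- edges[edges$lf_parcel == p, ]
    as_hf <- edges[edges$hf_parcel == p, ]
    n_pot <- sum(as_lf$n_pot) + sum(as_hf$n_pot)
    if (n_pot == 0) {
      return(data.frame(parcel = p, in_degree = NA_real_,
                        out_degree = NA_real_, value = NA_real_))
    }
    indeg <- sum(as_hf$n_sig) / n_pot
    outdeg <- sum(as_lf$n_sig) / n_pot
    data.frame(parcel = p, in_degree = indeg, out_degree = outdeg,
               value = indeg - outdeg)
  })
  do.call(rbind, out)
}

#' Permutation-tested parcel directionality
#'
#' For each unordered parcel pair (p1, p2) the directionality statistic is
#' the summed strength of significant edges in which p1 is the HF node minus
#' the summed strength of those in which p1 is the LF node, divided by the
#' number of possible connections N between the parcels. Pairs with fewer
#' than `min_connections` significant connections are forced to 0.
#' Significance is assessed one-sidedly on the observed sign by pooling the
#' two orientations' strengths and randomly reassigning them (`n_perm`
#' permutations): the observed statistic must exceed the permuted one in 95%
#' of permutations. The per-parcel directionality is then (number of
#' significantly positive pairs - significantly negative pairs) / possible
#' connections.
#'
#' @param edges a `parcel_edges` object from [collapse_to_atlas()] (the
#'   per-connection strengths drive the permutations; an aggregated
#'   data.frame is accepted, replicating mean strengths)
#' @param n_perm permutations (default 1000)
#' @param min_connections minimum significant connections per pair before
#'   forcing the statistic to 0 (default 8, intracranial convention; use 0
#'   to disable)
#' @return list with `pairs` (per-pair `dir_lh`, `n_connections`,
#'   `significant`) and `parcels` (per-parcel `value` in `[-1, 1]`)
#' @export
parcel_directionality <- function(edges, n_perm = 1000L,
                                  min_connections = 8L) {
  stop_if_not(n_perm >= 100, "use at least 100 permutations")
  x <- as_parcel_edges(edges)
  agg <- x$edges
  conn <- x$connections
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  agg$pair <- key(agg$lf_parcel, agg$hf_parcel)
  conn$pair <- key(conn$lf_parcel, conn$hf_parcel)
  pair_rows <- list()
  for (pk in unique(agg$pair)) {
    sub <- agg[agg$pair == pk, ]
    csub <- conn[conn$pair == pk, , drop = FALSE]
    p1 <- sort(c(sub$lf_parcel[1], sub$hf_parcel[1]))[1]
    p2 <- sort(c(sub$lf_parcel[1], sub$hf_parcel[1]))[2]
    str1 <- csub$strength[csub$hf_parcel == p1]   # p1 is the HF node
    str2 <- csub$strength[csub$hf_parcel == p2]
    n_pot <- sum(sub$n_pot)
    n_con <- length(str1) + length(str2)
    dir_lh <- if (n_pot > 0) (sum(str1) - sum(str2)) / n_pot else 0
    if (n_con < min_connections) dir_lh <- 0
    significant <- FALSE
    if (dir_lh != 0 && n_con >= 2) {
      pooled <- c(str1, str2)
      n1 <- length(str1)
      perm <- vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n_con, n1)
        (sum(pooled[idx]) - sum(pooled[-idx])) / n_pot
      }, 0)
      # the observed magnitude must beat 95% of permuted magnitudes;
      # comparing on the observed sign alone would double the nominal
      # rate under an orientation-symmetric null
      significant <- mean(abs(dir_lh) > abs(perm)) >= 0.95
    }
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      p1 = p1, p2 = p2, dir_lh = dir_lh, n_connections = n_con,
      n_pot = n_pot, significant = significant, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pair_rows)
  parcels <- sort(unique(c(pairs$p1, pairs$p2)))
  parcel_rows <- lapply(parcels, function(p) {
    # dir_lh > 0 means p1 is the HF-dominant node of the pair
    plus <- sum((pairs$p1 == p & pairs$significant & pairs$dir_lh > 0) |
                  (pairs$p2 == p & pairs$significant & pairs$dir_lh < 0))
    minus <- sum((pairs$p1 == p & pairs$significant & pairs$dir_lh < 0) |
                   (pairs$p2 == p & pairs$significant & pairs$dir_lh > 0))
    n_pot <- sum(pairs$n_pot[pairs$p1 == p | pairs$p2 == p])
    data.frame(parcel = p,
               value = if (n_pot > 0) (plus - minus) / n_pot else NA_real_)
  })
  list(pairs = pairs, parcels = do.call(rbind, parcel_rows))
}

#' Equal-count distance bins for channel pairs
#'
#' Assigns each admissible channel pair to one of `n_bins` Euclidean-distance
#' bins holding equal numbers of pairs (ties broken by a stable sort on the
#' pair order).
#'
#' @param meta channel metadata with `x_mm`, `y_mm`, `z_mm`
#' @param pairs two-column matrix/data.frame of channel indices (or labels)
#' @param n_bins number of bins (default 3)
#' @return data.frame: pair columns, `distance_mm`, `bin` (integer)
#' @export
distance_bins <- function(meta, pairs, n_bins = 3L) {
  stop_if_not(all(c("x_mm", "y_mm", "z_mm") %in% names(meta)),
              "positions (x_mm, y_mm, z_mm) required")
  pos <- as.matrix(meta[, c("x_mm", "y_mm", "z_mm")])
  stop_if_not(!anyNA(pos), "positions missing for some channels")
  pairs <- as.data.frame(pairs)
  idx <- function(x) if (is.numeric(x)) x else match(x, meta$label)
  i <- idx(pairs[[1]])
  j <- idx(pairs[[2]])
  d <- sqrt(rowSums((pos[i, , drop = FALSE] - pos[j, , drop = FALSE])^2))
  ord <- order(d, seq_along(d))   # stable
  bin <- integer(length(d))
  bin[ord] <- ceiling(seq_along(d) / (length(d) / n_bins))
  bin <- pmin(bin, n_bins)
  data.frame(a = pairs[[1]], b = pairs[[2]], distance_mm = d, bin = bin)
}

#' Laminar-depth group of each directed channel pair
#'
#' Contacts with gray-matter proximity index in (0.5, 1.2) are superficial,
#' in (-0.3, 0) deep; others are unassigned and their edges dropped. The
#' label orders the LF channel first: "s-s", "d-d", "s-d" (LF superficial,
#' HF deep), "d-s".
#'
#' @param meta channel metadata with a `gmpi` column
#' @param pairs two-column structure of (LF, HF) channel indices or labels
#' @return data.frame: `lf`, `hf`, `group` (NA when either end unassigned)
#' @export
depth_groups <- function(meta, pairs) {
  stop_if_not("gmpi" %in% names(meta), "gmpi column required")
  cls <- function(g) {
    ifelse(!is.na(g) & g > 0.5 & g < 1.2, "s",
           ifelse(!is.na(g) & g > -0.3 & g < 0, "d", NA))
  }
  depth <- cls(meta$gmpi)
  pairs <- as.data.frame(pairs)
  idx <- function(x) if (is.numeric(x)) x else match(x, meta$label)
  i <- idx(pairs[[1]])
  j <- idx(pairs[[2]])
  grp <- ifelse(is.na(depth[i]) | is.na(depth[j]), NA,
                paste(depth[i], depth[j], sep = "-"))
  data.frame(lf = pairs[[1]], hf = pairs[[2]], group = grp,
             stringsAsFactors = FALSE)
}

#' Paired group comparisons with multiplicity correction
#'
#' Wilcoxon signed-rank tests between all group pairs of a per-subject
#' statistic (e.g. connection density per distance bin or laminar-depth
#' group), Benjamini-Hochberg corrected across all tests supplied (typically
#' frequencies x group combinations) at the given q.
#'
#' @param values matrix of the statistic, subjects x groups (or a data.frame)
#' @param q FDR level (default 0.05)
#' @return data.frame: `group1`, `group2`, `p`, `p_adj`, `significant`
#' @export
compare_groups <- function(values, q = 0.05) {
  values <- as.matrix(values)
  stop_if_not(ncol(values) >= 2, "need at least 2 groups")
  if (nrow(values) < 6) {
    warning("fewer than 6 paired subjects: low power", call. = FALSE)
  }
  gs <- colnames(values)
  if (is.null(gs)) gs <- paste0("g", seq_len(ncol(values)))
  combs <- utils::combn(ncol(values), 2)
  res <- apply(combs, 2, function(ij) {
    d <- values[, ij[1]] - values[, ij[2]]
    p <- if (all(d == 0)) 1 else
      suppressWarnings(wilcox.test(values[, ij[1]], values[, ij[2]],
                                   paired = TRUE)$p.value)
    c(ij, p)
  })
  out <- data.frame(group1 = gs[res[1, ]], group2 = gs[res[2, ]],
                    p = res[3, ])
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < q
  out
}

#' Rank-correlate two parcel maps
#'
#' Spearman rank correlation over the common (non-missing) parcel support.
#'
#' @param map1,map2 named numeric vectors (names = parcels) or data.frames
#'   with `parcel` and `value` columns
#' @return list: `rho`, `p`, `n`
#' @export
correlate_parcel_maps <- function(map1, map2) {
  as_named <- function(m) {
    if (is.data.frame(m)) setNames(m$value, m$parcel) else m
  }
  m1 <- as_named(map1)
  m2 <- as_named(map2)
  common <- intersect(names(m1), names(m2))
  x <- m1[common]
  y <- m2[common]
  ok <- !is.na(x) & !is.na(y)
  stop_if_not(sum(ok) >= 5, "fewer than 5 common parcels")
  stop_if_not(sd(x[ok]) > 0 && sd(y[ok]) > 0,
              "constant map: correlation undefined")
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Compare two independent correlations (Fisher z)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`; |z| > 1.96 is
#' significant at the two-sided 5% level.
#'
#' @param r1,r2 correlation coefficients
#' @param n1,n2 sample sizes (> 3)
#' @return the z statistic
#' @export
fisher_z <- function(r1, n1, r2, n2) {
  stop_if_not(n1 > 3 && n2 > 3, "need n > 3 in both samples")
  (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
}
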