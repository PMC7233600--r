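mask2 <- function(a12 = FALSE, a21 = FALSE, d1 = FALSE, d2 = FALSE) {
  m <- matrix(c(d1, a21, a12, d2), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  m
}
sym2 <- function(on = FALSE) {
  matrix(c(FALSE, on, on, FALSE), 2, 2,
         dimnames = list(c("A", "B"), c("A", "B")))
}

test_that("CFS pruning removes exactly the triangle-motif edges", {
  # local CFS at the HF end + LF phase synchrony -> removed (hf side)
  mx <- multiplex_connectome(mask2(a12 = TRUE, d2 = TRUE),
                             ps_lf_mask = sym2(TRUE),
                             ps_hf_mask = sym2(FALSE), cfc_metric = "CFS")
  rep <- prune_cfs(mx)
  expect_equal(nrow(rep$kept), 0)
  expect_equal(rep$removed$reason, "hf_side_motif")

  # local CFS at the LF end + HF phase synchrony -> removed (lf side)
  mx2 <- multiplex_connectome(mask2(a12 = TRUE, d1 = TRUE),
                              ps_lf_mask = sym2(FALSE),
                              ps_hf_mask = sym2(TRUE), cfc_metric = "CFS")
  expect_equal(prune_cfs(mx2)$removed$reason, "lf_side_motif")

  # both sides complete -> tagged once as "both"
  mx3 <- multiplex_connectome(mask2(a12 = TRUE, d1 = TRUE, d2 = TRUE),
                              ps_lf_mask = sym2(TRUE),
                              ps_hf_mask = sym2(TRUE), cfc_metric = "CFS")
  rep3 <- prune_cfs(mx3)
  expect_equal(nrow(rep3$removed), 1)
  expect_equal(rep3$removed$reason, "both")

  # incomplete motifs keep the edge: PS without local CFC, or local CFC
  # without the matching PS leg
  mx4 <- multiplex_connectome(mask2(a12 = TRUE),
                              ps_lf_mask = sym2(TRUE),
                              ps_hf_mask = sym2(TRUE), cfc_metric = "CFS")
  expect_equal(nrow(prune_cfs(mx4)$removed), 0)
  mx5 <- multiplex_connectome(mask2(a12 = TRUE, d2 = TRUE),
                              ps_lf_mask = sym2(FALSE),
                              ps_hf_mask = sym2(TRUE), cfc_metric = "CFS")
  expect_equal(nrow(prune_cfs(mx5)$removed), 0)

  # empty PS masks keep every edge
  mx6 <- multiplex_connectome(mask2(a12 = TRUE, a21 = TRUE, d1 = TRUE,
                                    d2 = TRUE),
                              ps_lf_mask = sym2(FALSE),
                              ps_hf_mask = sym2(FALSE), cfc_metric = "CFS")
  expect_equal(nrow(prune_cfs(mx6)$kept), 2)
  expect_error(prune_cfs(multiplex_connectome(mask2(a12 = TRUE),
                                              cfc_metric = "CFS")),
               "PS masks")
})

test_that("PAC pruning uses the LF-PS and HF-envelope-correlation legs", {
  # local PAC at the HF end + LF PS -> removed
  mx <- multiplex_connectome(mask2(a12 = TRUE, d2 = TRUE),
                             ps_lf_mask = sym2(TRUE),
                             ac_hf_mask = sym2(FALSE), cfc_metric = "PAC")
  expect_equal(prune_pac(mx)$removed$reason, "hf_side_motif")
  # local PAC at the LF end + HF envelope correlation -> removed
  mx2 <- multiplex_connectome(mask2(a12 = TRUE, d1 = TRUE),
                              ps_lf_mask = sym2(FALSE),
                              ac_hf_mask = sym2(TRUE), cfc_metric = "PAC")
  expect_equal(prune_pac(mx2)$removed$reason, "lf_side_motif")
  # local PAC at the LF end alone (no AC, no LF-PS) -> kept
  mx3 <- multiplex_connectome(mask2(a12 = TRUE, d1 = TRUE),
                              ps_lf_mask = sym2(FALSE),
                              ac_hf_mask = sym2(FALSE), cfc_metric = "PAC")
  expect_equal(nrow(prune_pac(mx3)$removed), 0)
  expect_error(prune_pac(multiplex_connectome(mask2(a12 = TRUE),
                                              ps_lf_mask = sym2(TRUE),
                                              cfc_metric = "PAC")),
               "AC mask")
})

test_that("corrected density excludes pruned edges from the denominator", {
  rep <- list(kept = data.frame(lf_channel = letters[1:5],
                                hf_channel = LETTERS[1:5]),
              removed = data.frame(lf_channel = letters[6:10],
                                   hf_channel = LETTERS[6:10],
                                   reason = "both"))
  class(rep) <- "pruning_report"
  expect_equal(corrected_density(rep, 400), 5 / 395 - 0.01)
  expect_equal(corrected_density(rep, 400, fixed_denominator = TRUE),
               5 / 400 - 0.01)
  rep0 <- rep
  rep0$removed <- rep0$removed[0, ]
  expect_equal(corrected_density(rep0, 400),
               connection_density(list(n_significant = 5,
                                       n_possible = 400)))
  rep_all <- rep
  rep_all$kept <- rep_all$kept[0, ]
  expect_equal(corrected_density(rep_all, 400), -0.01)
})

test_that("adding coupling evidence can only shrink the kept set", {
  set.seed(8)
  for (i in 1:30) {
    n <- 6
    cfc <- matrix(runif(n * n) < 0.4, n, n,
                  dimnames = list(letters[1:n], letters[1:n]))
    ps1 <- matrix(FALSE, n, n)
    on <- which(upper.tri(ps1) & runif(n * n) < 0.3)
    ps1[on] <- TRUE
    ps1 <- ps1 | t(ps1)
    ps2 <- matrix(FALSE, n, n)
    dimnames(ps1) <- dimnames(ps2) <- dimnames(cfc)
    mk <- function(lf, hf) {
      multiplex_connectome(cfc, ps_lf_mask = lf, ps_hf_mask = hf,
                           cfc_metric = "CFS")
    }
    base_kept <- prune_cfs(mk(ps2, ps2))$kept
    more_kept <- prune_cfs(mk(ps1, ps1))$kept
    key <- function(df) paste(df$lf_channel, df$hf_channel)
    expect_true(all(key(more_kept) %in% key(base_kept)))
    # adding local CFC likewise
    cfc2 <- cfc
    diag(cfc2) <- TRUE
    less_kept <- prune_cfs(multiplex_connectome(cfc2, ps_lf_mask = ps1,
                                                ps_hf_mask = ps1,
                                                cfc_metric = "CFS"))$kept
    expect_true(all(key(less_kept) %in% key(more_kept)))
  }
})

test_that("pruning reports round-trip to TSV", {
  mx <- multiplex_connectome(mask2(a12 = TRUE, a21 = TRUE, d2 = TRUE),
                             ps_lf_mask = sym2(TRUE),
                             ps_hf_mask = sym2(FALSE), cfc_metric = "CFS",
                             lf_hz = 5, hf_hz = 10, ratio_m = 2L)
  rep <- prune_cfs(mx)
  path <- tempfile(fileext = ".tsv")
  write_pruning_report(rep, path)
  df <- read.delim(path)
  expect_equal(sum(df$status == "removed"), nrow(rep$removed))
  expect_equal(sum(df$status == "kept"), nrow(rep$kept))
  expect_equal(unique(df$ratio), 2)
})
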