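sig_from_mask <- function(mask, values = NULL) {
  if (is.null(values)) values <- matrix(0.5, nrow(mask), ncol(mask),
                                        dimnames = dimnames(mask))
  values[row(values) == col(values)] <- NA
  list(sig = structure(list(mask = mask), class = "significance_result"),
       cm = structure(list(values = values, metric = "CFS"),
                      class = "coupling_matrix"))
}

test_that("atlas collapse sums edges and possible counts", {
  labs <- c("c1", "c2", "c3")
  mask <- matrix(FALSE, 3, 3, dimnames = list(labs, labs))
  mask["c1", "c3"] <- TRUE
  mask["c2", "c3"] <- TRUE
  x <- sig_from_mask(mask)
  # one channel per parcel: identity collapse
  p1 <- setNames(c("P1", "P2", "P3"), labs)
  res <- collapse_to_atlas(x$sig, x$cm, p1)
  df <- res$edges
  expect_equal(df$n_sig[df$lf_parcel == "P1" & df$hf_parcel == "P3"], 1)
  expect_equal(sum(df$n_pot), 6)
  expect_equal(nrow(res$connections), 2)
  # two channels in one parcel: counts sum, connections stay individual
  p2 <- setNames(c("P1", "P1", "P3"), labs)
  df2 <- collapse_to_atlas(x$sig, x$cm, p2)$edges
  expect_equal(df2$n_sig[df2$lf_parcel == "P1" & df2$hf_parcel == "P3"], 2)
  expect_equal(df2$strength[df2$lf_parcel == "P1" & df2$hf_parcel == "P3"],
               1.0)
  # excluded pairs do not enter the possible counts
  vals <- matrix(0.5, 3, 3, dimnames = list(labs, labs))
  vals["c1", "c3"] <- NA
  vals["c3", "c1"] <- NA
  mask2 <- mask
  mask2["c1", "c3"] <- FALSE
  x2 <- sig_from_mask(mask2, vals)
  df3 <- collapse_to_atlas(x2$sig, x2$cm, p1)$edges
  expect_equal(sum(df3$n_pot), 4)
  expect_error(collapse_to_atlas(x$sig, x$cm, p1[1:2]), "unmapped")
})

test_that("relative directed degree recovers hand-counted toys", {
  # 3 parcels, p1 the LF node of 2 significant edges of 4 possible each way
  edges <- data.frame(
    lf_parcel = c("p1", "p1", "p2", "p3"),
    hf_parcel = c("p2", "p3", "p1", "p1"),
    n_sig = c(1, 1, 0, 0), strength = c(0.5, 0.5, 0, 0),
    n_pot = c(2, 2, 2, 2))
  m <- relative_directed_degree(edges)
  expect_equal(m$value[m$parcel == "p1"], 0 - 2 / 8)
  # sign convention: pure HF hub is positive
  e2 <- data.frame(lf_parcel = "p2", hf_parcel = "p1", n_sig = 1,
                   strength = 0.6, n_pot = 4)
  m2 <- relative_directed_degree(e2)
  expect_gt(m2$value[m2$parcel == "p1"], 0)
  expect_lt(m2$value[m2$parcel == "p2"], 0)
  # balanced in/out cancels
  e3 <- data.frame(lf_parcel = c("p1", "p2"), hf_parcel = c("p2", "p1"),
                   n_sig = 1, strength = 0.5, n_pot = 4)
  m3 <- relative_directed_degree(e3)
  expect_equal(m3$value, c(0, 0))
})

test_that("in/out degree counts balance over any directed connectome", {
  set.seed(30)
  for (i in 1:20) {
    np <- sample(3:8, 1)
    parcels <- paste0("p", seq_len(np))
    combs <- expand.grid(lf_parcel = parcels, hf_parcel = parcels,
                         stringsAsFactors = FALSE)
    combs <- combs[combs$lf_parcel != combs$hf_parcel, ]
    combs$n_sig <- rbinom(nrow(combs), 3, 0.3)
    combs$strength <- combs$n_sig * 0.4
    combs$n_pot <- 3
    m <- relative_directed_degree(combs)
    net <- sum((m$in_degree - m$out_degree) *
                 vapply(m$parcel, function(p) {
                   sum(combs$n_pot[combs$lf_parcel == p |
                                     combs$hf_parcel == p])
                 }, 0))
    expect_equal(net, 0)
  }
})

test_that("parcel directionality matches the exhaustive permutation oracle", {
  # orientation p2 -> p1 (p1 HF node) strengths {0.6, 0.6};
  # p1 -> p2 strengths {0.1, 0.1}; N = 4 possible
  edges <- data.frame(lf_parcel = c("p2", "p1"), hf_parcel = c("p1", "p2"),
                      n_sig = c(2, 2), strength = c(1.2, 0.2), n_pot = c(2, 2))
  set.seed(31)
  res <- parcel_directionality(edges, n_perm = 2000, min_connections = 0)
  expect_equal(res$pairs$dir_lh, (1.2 - 0.2) / 4)
  # exhaustive oracle: choose(4, 2) = 6 assignments of {.6,.6,.1,.1}
  pool <- c(0.6, 0.6, 0.1, 0.1)
  combs <- combn(4, 2)
  perms <- apply(combs, 2, function(ix) (sum(pool[ix]) - sum(pool[-ix])) / 4)
  frac_below <- mean(0.25 > perms)  # 4/6 strictly below
  expect_equal(res$pairs$significant, frac_below >= 0.95)
  # symmetric strengths are never directional
  edges_sym <- data.frame(lf_parcel = c("p2", "p1"),
                          hf_parcel = c("p1", "p2"),
                          n_sig = c(2, 2), strength = c(0.8, 0.8),
                          n_pot = c(2, 2))
  res_sym <- parcel_directionality(edges_sym, n_perm = 500,
                                   min_connections = 0)
  expect_equal(res_sym$pairs$dir_lh, 0)
  expect_false(res_sym$pairs$significant)
  # sparse pairs are forced to zero
  edges_few <- data.frame(lf_parcel = "p2", hf_parcel = "p1", n_sig = 7,
                          strength = 3.5, n_pot = 20)
  res_few <- parcel_directionality(edges_few, n_perm = 200)
  expect_equal(res_few$pairs$dir_lh, 0)
})

test_that("orientation-symmetric fixtures yield ~5% directional calls", {
  set.seed(32)
  hits <- 0
  trials <- 200
  for (i in seq_len(trials)) {
    s1 <- runif(4, 0.2, 0.8)   # exchangeable individual strengths
    s2 <- runif(4, 0.2, 0.8)
    pe <- parcel_edges(
      data.frame(lf_parcel = c("p2", "p1"), hf_parcel = c("p1", "p2"),
                 n_sig = c(4, 4), strength = c(sum(s1), sum(s2)),
                 n_pot = c(4, 4)),
      data.frame(lf_parcel = rep(c("p2", "p1"), each = 4),
                 hf_parcel = rep(c("p1", "p2"), each = 4),
                 strength = c(s1, s2)))
    r <- parcel_directionality(pe, n_perm = 200, min_connections = 0)
    hits <- hits + r$pairs$significant
  }
  rate <- hits / trials
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / trials) + 0.02)
})

test_that("hubness statistics agree on strongly directed fixtures", {
  set.seed(33)
  np <- 10
  parcels <- paste0("p", seq_len(np))
  hub_sign <- rep(c(1, -1), length.out = np)  # alternating HF/LF hubs
  rows <- list()
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      # the higher-hub-sign parcel is the HF node of most edges
      hf_first <- hub_sign[i] > hub_sign[j]
      n_forward <- 10
      n_back <- 2
      rows[[length(rows) + 1L]] <- data.frame(
        lf_parcel = parcels[if (hf_first) j else i],
        hf_parcel = parcels[if (hf_first) i else j],
        n_sig = n_forward, strength = n_forward * 0.6, n_pot = 15)
      rows[[length(rows) + 1L]] <- data.frame(
        lf_parcel = parcels[if (hf_first) i else j],
        hf_parcel = parcels[if (hf_first) j else i],
        n_sig = n_back, strength = n_back * 0.3, n_pot = 15)
    }
  }
  edges <- do.call(rbind, rows)
  rdd <- relative_directed_degree(edges)
  dir <- parcel_directionality(edges, n_perm = 300)
  merged <- merge(rdd, dir$parcels, by = "parcel",
                  suffixes = c("_rdd", "_dir"))
  nonzero <- merged$value_dir != 0
  agree <- sign(merged$value_rdd) == sign(merged$value_dir)
  expect_gte(mean(agree[nonzero]), 0.9)
  # and both recover the planted hub signs
  planted <- hub_sign[match(merged$parcel, parcels)]
  expect_gte(mean(sign(merged$value_rdd) == planted), 0.9)
})

test_that("distance bins hold equal pair counts with stable ties", {
  meta <- data.frame(label = paste0("c", 1:9),
                     x_mm = c(0, 10, 25, 40, 60, 85, 110, 140, 170),
                     y_mm = 0, z_mm = 0)
  pairs <- t(combn(9, 2))[1:9, ]
  db <- distance_bins(meta, pairs, 3)
  expect_equal(as.vector(table(db$bin)), c(3L, 3L, 3L))
  expect_true(all(db$distance_mm[db$bin == 1] <=
                    min(db$distance_mm[db$bin == 3])))
  # all-equal distances: deterministic stable assignment
  meta2 <- data.frame(label = c("a", "b", "c", "d"),
                      x_mm = c(0, 1, 0, 1), y_mm = c(0, 0, 1, 1), z_mm = 0)
  pairs2 <- rbind(c(1, 2), c(3, 4), c(1, 3), c(2, 4))
  db2 <- distance_bins(meta2, pairs2, 2)
  expect_equal(db2$bin, c(1L, 1L, 2L, 2L))
  expect_error(distance_bins(data.frame(label = "a"), rbind(c(1, 1))),
               "positions")
})

test_that("laminar depth groups follow the proximity-index windows", {
  meta <- data.frame(label = c("s", "d", "u", "s2"),
                     gmpi = c(0.7, -0.1, 0.3, 1.1))
  dg <- depth_groups(meta, rbind(c(1, 2), c(2, 1), c(1, 4), c(3, 1)))
  expect_equal(dg$group, c("s-d", "d-s", "s-s", NA))
})

test_that("group comparisons reject shifted groups and respect BH", {
  set.seed(34)
  same <- matrix(rnorm(40, 0.2, 0.05), 20, 2)
  res_same <- compare_groups(same)
  expect_false(any(res_same$significant & res_same$p_adj < 0.001))
  hits <- vapply(1:40, function(i) {
    a <- rnorm(20, 0, 1)
    b <- a + 2   # 2-SD shift, paired
    compare_groups(cbind(a = a, b = b))$significant
  }, TRUE)
  expect_gte(mean(hits), 0.8)
  expect_warning(compare_groups(matrix(rnorm(8), 4, 2)), "low power")
  # BH monotonicity: adding a smaller p never un-rejects
  p <- c(0.001, 0.012, 0.03, 0.2)
  rej1 <- p.adjust(p, "BH") < 0.05
  rej2 <- p.adjust(c(p, 1e-5), "BH")[seq_along(p)] < 0.05
  expect_true(all(rej2[rej1]))
})

test_that("parcel-map correlation and Fisher z follow the closed forms", {
  m1 <- setNames(runif(20), paste0("p", 1:20))
  expect_equal(correlate_parcel_maps(m1, m1)$rho, 1)
  expect_equal(correlate_parcel_maps(m1, -m1)$rho, -1)
  expect_error(correlate_parcel_maps(m1, setNames(rep(1, 20), names(m1))),
               "constant")
  # two-sample Fisher z, frozen from the closed form
  z <- fisher_z(0.5, 100, 0.1, 100)
  expect_equal(z, (atanh(0.5) - atanh(0.1)) / sqrt(2 / 97))
  expect_equal(z, 3.1266, tolerance = 1e-4)
  expect_equal(fisher_z(0.3, 50, 0.3, 80), 0)
  expect_error(fisher_z(0.5, 3, 0.1, 100), "n > 3")
})
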