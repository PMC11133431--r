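test_that("Pearson correlation matches hand-computed values and guards input", {
  parc <- dkt_parc()
  m <- make_autocorrelated_map(parc, 0.5, 1)
  expect_equal(pearson_corr(m, m), 1)
  flipped <- parcel_map(parc, -m$value)
  expect_equal(pearson_corr(m, flipped), -1)
  expect_equal(pearson_corr(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(pearson_corr(c(1, 2), c(3, 4)), "fewer than 3")
  expect_error(pearson_corr(c(1, 1, 1, 1), c(2, 1, 4, 3)), "zero variance")
  lh <- subset_hemisphere(parc, "left")
  expect_error(pearson_corr(m, make_autocorrelated_map(lh, 0.5, 1)),
               "different parcellations|length")
})

test_that("missing parcels are dropped pairwise, not imputed", {
  parc <- dkt_parc()
  a <- make_autocorrelated_map(parc, 0.5, 3)$value
  b <- make_autocorrelated_map(parc, 0.5, 4)$value
  a[1:5] <- NA
  b[4:8] <- NA
  ok <- !is.na(a) & !is.na(b)
  expect_equal(pearson_corr(parcel_map(parc, a), parcel_map(parc, b)),
               cor(a[ok], b[ok]))
})

test_that("degenerate identity ensemble gives p = 1", {
  parc <- dkt_parc()
  a <- make_autocorrelated_map(parc, 0.5, 5)
  b <- make_autocorrelated_map(parc, 0.5, 6)
  p <- spin_pvalue(a, b, identity_ensemble(parc, 10L))
  expect_equal(as.numeric(p), 1)
})

test_that("the empirical p formula counts exceedances with a +1 correction", {
  # hand-built ensemble of 99 members: 4 identity assignments (null |r|
  # equal to |r_obs|) and 95 assignments onto a constant-ish rearrangement
  # with strictly smaller |r|
  parc <- make_sphere_parcellation(8, seed = 2, hemisphere = "left")
  a <- c(1, 2, 3, 4, 5, 6, 7, 100)
  b <- c(1, 2, 3, 4, 5, 6, 7, 100)
  weak <- c(8L, 7L, 2L, 1L, 4L, 3L, 6L, 5L)   # scrambles the outlier
  stopifnot(abs(cor(a[weak], b)) < 1)
  assign <- rbind(matrix(rep(1:8, each = 4), 4),
                  matrix(rep(weak, each = 95), 95))
  ens <- structure(list(n_perm = 99L, assignment = assign,
                        parcellation = parc, seed = 0L),
                   class = "spin_ensemble")
  p <- spin_pvalue(parcel_map(parc, a), parcel_map(parc, b), ens)
  expect_equal(as.numeric(p), (1 + 4) / (99 + 1))
})

test_that("spin p-values respect their attainable range", {
  parc <- dkt_parc()
  ens <- spin_ensemble(parc, 99, seed = 8)
  for (s in 1:5) {
    a <- make_autocorrelated_map(parc, 0.5, 100 + s)
    b <- make_autocorrelated_map(parc, 0.5, 200 + s)
    p <- as.numeric(spin_pvalue(a, b, ens))
    expect_gte(p, 1 / 100)
    expect_lte(p, 1)
  }
  lh <- subset_hemisphere(parc, "left")
  expect_error(
    spin_pvalue(make_autocorrelated_map(lh, 0.5, 1),
                make_autocorrelated_map(lh, 0.5, 2), ens),
    "parcellation")
})

test_that("battery correlation returns one FDR-adjusted row per map", {
  parc <- dkt_parc()
  ens <- spin_ensemble(parc, 99, seed = 10)
  target <- make_autocorrelated_map(parc, 0.5, 50)
  battery <- lapply(1:19, function(i) make_autocorrelated_map(parc, 0.5, 300 + i))
  names(battery) <- sprintf("receptor%02d", 1:19)
  res <- correlate_battery(target, battery, ens)
  expect_equal(nrow(res), 19L)
  expect_true(all(res$q >= res$p_spin))
  expect_true(all(res$n_parcels_used == 62L))
  expect_true(!is.unsorted(res$q))

  # battery of one: BH with m = 1 leaves p untouched
  res1 <- correlate_battery(target, battery[1], ens)
  expect_equal(res1$q, res1$p_spin)

  # duplicated target dominates
  battery$self <- target
  res2 <- correlate_battery(target, battery, ens)
  self_row <- res2[res2$map_id == "self", ]
  expect_equal(self_row$r, 1)
  expect_equal(self_row$p_spin, min(res2$p_spin))
  expect_error(correlate_battery(target, list(), ens), "empty battery")
})

test_that("battery order does not change adjusted q-values", {
  parc <- dkt_parc()
  ens <- spin_ensemble(parc, 99, seed = 14)
  target <- make_autocorrelated_map(parc, 0.5, 60)
  battery <- lapply(1:7, function(i) make_autocorrelated_map(parc, 0.5, 400 + i))
  names(battery) <- paste0("m", 1:7)
  r1 <- correlate_battery(target, battery, ens)
  r2 <- correlate_battery(target, rev(battery), ens)
  expect_equal(r1[order(r1$map_id), ], r2[order(r2$map_id), ],
               ignore_attr = TRUE)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  set.seed(9)
  for (rep in 1:20) {
    p <- runif(sample(1:30, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(-0.1)), "\\[0, 1\\]")
})

test_that("spin null is exchangeable under map relabeling", {
  # spinning a vs spinning b yields p distributions with similar spread
  # on isotropic synthetic maps (small simulation scale)
  parc <- dkt_parc()
  ens <- spin_ensemble(parc, 199, seed = 16)
  pa <- pb <- numeric(40)
  for (i in 1:40) {
    a <- make_autocorrelated_map(parc, 0.5, 700 + i)
    b <- make_autocorrelated_map(parc, 0.5, 900 + i)
    pa[i] <- spin_pvalue(a, b, ens)
    pb[i] <- spin_pvalue(b, a, ens)
  }
  expect_lt(abs(mean(pa) - mean(pb)), 0.15)
  expect_gt(suppressWarnings(ks.test(pa, pb)$p.value), 0.01)
})
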