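test_that("the bundled centroid fixture loads as a 62-parcel parcellation", {
  parc <- load_parcellation(dkt_path())
  expect_s3_class(parc, "spherical_parcellation")
  expect_length(parc$parcel_id, 62L)
  expect_equal(as.vector(table(parc$hemisphere)), c(31L, 31L))
  expect_equal(rowSums(parc$centroids^2), rep(1, 62),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("centroids are normalized and bad tables are rejected", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("parcel_id\themisphere\tx\ty\tz",
               "lh.a\tleft\t0\t0\t2",
               "rh.a\tRight\t0\t0\t-2"), tf)
  parc <- load_parcellation(tf)
  expect_equal(unname(parc$centroids[1, ]), c(0, 0, 1))
  expect_equal(unname(parc$centroids[2, ]), c(0, 0, -1))

  writeLines(c("parcel_id\themisphere\tx\ty\tz",
               "lh.insula\tleft\t1\t0\t0",
               "lh.insula\tleft\t0\t1\t0"), tf)
  expect_error(load_parcellation(tf), "lh.insula")

  writeLines(c("parcel_id\themisphere\tx\ty\tz",
               "lh.a\tleft\t0\t0\t0",
               "lh.b\tleft\t0\t1\t0"), tf)
  expect_error(load_parcellation(tf), "zero-length")

  writeLines(c("parcel_id\themisphere\tx\ty\tz",
               "lh.a\tmiddle\t1\t0\t0",
               "lh.b\tleft\t0\t1\t0"), tf)
  expect_error(load_parcellation(tf), "hemisphere")
})

test_that("sampled rotations are proper, uniform and seed-deterministic", {
  rs <- sample_rotations(200, seed = 7)
  for (i in c(1, 50, 200)) {
    R <- rs$rotations[, , i]
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-8)
    expect_equal(det(R), 1, tolerance = 1e-8)
    expect_equal(sqrt(sum((R %*% c(0, 0, 1))^2)), 1, tolerance = 1e-12)
  }
  expect_identical(sample_rotations(50, seed = 3)$rotations,
                   sample_rotations(50, seed = 3)$rotations)
  expect_error(sample_rotations(0, seed = 1), "n_perm")

  # Monte-Carlo uniformity: the mean of many uniformly rotated copies of a
  # fixed direction collapses toward the origin
  rs <- sample_rotations(10000, seed = 11)
  v <- c(0, 0, 1)
  rotated <- apply(rs$rotations, 3, function(R) R %*% v)
  expect_lt(sqrt(sum(rowMeans(rotated)^2)), 0.05)
})

test_that("identity rotation yields the identity assignment", {
  parc <- dkt_parc()
  ens <- build_spin_ensemble(parc, identity_rotations())
  expect_identical(unname(ens$assignment[1, ]), seq_len(62L))
  m <- make_autocorrelated_map(parc, 0.5, 1)
  expect_identical(permute_map(m, ens, 1), unname(m$value))
})

test_that("a 180-degree rotation swaps antipodal parcels (hand oracle)", {
  # two left-hemisphere parcels at the poles; rotation by pi about the
  # y axis maps each pole onto the other: geodesic distance after
  # rotation is 0 to the opposite parcel, pi to itself
  parc <- spherical_parcellation(c("lh.n", "lh.s"), c("left", "left"),
                                 rbind(c(0, 0, 1), c(0, 0, -1)))
  Ry <- matrix(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), 3, 3)
  rs <- structure(list(n_perm = 1L, rotations = array(Ry, c(3, 3, 1)),
                       seed = 0L), class = "rotation_set")
  ens <- build_spin_ensemble(parc, rs)
  expect_identical(unname(ens$assignment[1, ]), c(2L, 1L))
})

test_that("assignments stay within hemisphere and draw only original values", {
  parc <- dkt_parc()
  ens <- spin_ensemble(parc, 50, seed = 5)
  hemi <- as.integer(parc$hemisphere)
  for (i in seq_len(50)) {
    expect_identical(hemi[ens$assignment[i, ]], hemi)
  }
  # permuted values are always a sub-multiset of the original values;
  # counts are preserved iff the assignment is a bijection
  m <- make_autocorrelated_map(parc, 0.3, 2)
  n_bij <- 0L
  for (i in seq_len(50)) {
    pv <- permute_map(m, ens, i)
    expect_true(all(pv %in% m$value))
    if (length(unique(ens$assignment[i, ])) == 62L) {
      n_bij <- n_bij + 1L
      expect_identical(sort(pv), sort(unname(m$value)))
    } else {
      expect_true(any(duplicated(pv)))
    }
  }
  # nearest-neighbour reassignment produces duplicates for generic rotations
  expect_lt(n_bij, 50L)
})

test_that("ensembles are byte-identical under the same seed", {
  parc <- dkt_parc()
  e1 <- spin_ensemble(parc, 20, seed = 9)
  e2 <- spin_ensemble(parc, 20, seed = 9)
  expect_identical(serialize(e1, NULL), serialize(e2, NULL))
})
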