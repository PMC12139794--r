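# Superposition, water aggregation, single-linkage clustering, first-shell
# filtering and consensus classification.

test_that("superposition recovers identity, translations and random rotations", {
  ref <- tiny_solute()
  tf <- superpose(ref, ref)
  expect_equal(tf$rmsd, 0, tolerance = 1e-10)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-10)

  shifted <- solute_structure(sweep(ref$xyz, 2, c(1, 2, 3), "+"),
                              elety = ref$elety, resid = ref$resid,
                              resno = ref$resno, chain = ref$chain)
  tf <- superpose(shifted, ref)
  expect_equal(tf$translation, c(-1, -2, -3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(tf$rmsd, 0, tolerance = 1e-10)

  set.seed(41)
  for (rep in 1:5) {
    R <- random_rotation()
    t0 <- stats::rnorm(3)
    mobile <- solute_structure(sweep(ref$xyz %*% R, 2, t0, "+"),
                               elety = ref$elety, resid = ref$resid,
                               resno = ref$resno, chain = ref$chain)
    tf <- superpose(mobile, ref)
    expect_equal(tf$rmsd, 0, tolerance = 1e-8)
    # recovered rotation inverts the applied one (angle < 1e-6 rad)
    resid_rot <- tf$rotation %*% R
    angle <- acos(pmin(1, (sum(diag(resid_rot)) - 1) / 2))
    expect_lt(angle, 1e-6)
    waters_back <- apply_transform(sweep(matrix(c(4.3, 0, 0), 1, 3) %*% R, 2, t0, "+"), tf)
    expect_equal(drop(waters_back), c(4.3, 0, 0), tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("superposition RMSD is invariant under rigid motion of the mobile set", {
  set.seed(99)
  ref <- solute_structure(random_points(10), elety = "CA", resno = 1:10)
  mob_xyz <- ref$xyz + matrix(stats::rnorm(30, sd = 0.3), 10, 3)
  mobile <- solute_structure(mob_xyz, elety = "CA", resno = 1:10)
  base_rmsd <- superpose(mobile, ref)$rmsd
  for (rep in 1:3) {
    R <- random_rotation()
    moved <- solute_structure(sweep(mob_xyz %*% R, 2, stats::rnorm(3), "+"),
                              elety = "CA", resno = 1:10)
    expect_equal(superpose(moved, ref)$rmsd, base_rmsd, tolerance = 1e-8)
  }
})

test_that("superposition cross-checks against an established implementation", {
  set.seed(7)
  ref <- solute_structure(random_points(12), elety = "CA", resno = 1:12)
  mobile_xyz <- sweep(ref$xyz %*% random_rotation(), 2, c(2, -1, 0.5), "+") +
    matrix(stats::rnorm(36, sd = 0.1), 12, 3)
  mobile <- solute_structure(mobile_xyz, elety = "CA", resno = 1:12)
  tf <- superpose(mobile, ref)
  moved <- bio3d::fit.xyz(fixed = as.vector(t(ref$xyz)),
                          mobile = as.vector(t(mobile_xyz)),
                          fixed.inds = 1:36, mobile.inds = 1:36)
  expect_equal(apply_transform(mobile_xyz, tf),
               matrix(moved, ncol = 3, byrow = TRUE),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("degenerate or undersized atom selections are rejected", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)),
               class = "watsite_validation_error")
  line <- cbind(1:5, 0, 0)  # collinear
  expect_error(kabsch(line, line + 1), "degenerate")
})

test_that("aggregation keeps waters by shell distance with provenance", {
  sol <- tiny_solute()
  # waters at 3.9 and 4.1 A from the nearest atom (atom at (1.5, 0, 0))
  near <- c(1.5 + 3.9, 0, 0)
  far <- c(1.5 + 4.1, 0, 0)
  recs <- list(
    structure_record("A", sol, rbind(near, far)),
    structure_record("B", sol, matrix(numeric(0), 0, 3))
  )
  agg <- aggregate_waters(recs, recs[[1]], shell = 4.0)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$structure, "A")
  expect_equal(unlist(agg[1, c("x", "y", "z")]), near,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("single-linkage clustering uses strict distance and spans chains", {
  # chain of 3 waters 0.8 A apart from 3 structures -> one cluster
  w <- data.frame(structure = c("S1", "S2", "S3"),
                  x = c(0, 0.8, 1.6), y = 0, z = 0)
  cl <- cluster_waters(w, link_cutoff = 1.0)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$n_structures, 3L)
  expect_equal(unlist(cl$clusters[1, c("x", "y", "z")]), c(0.8, 0, 0),
               tolerance = 1e-12, ignore_attr = TRUE)

  # 1.2 A apart -> two clusters; exactly 1.0 A apart -> still two (strict <)
  w2 <- data.frame(structure = c("S1", "S2"), x = c(0, 1.2), y = 0, z = 0)
  expect_equal(nrow(cluster_waters(w2, 1.0)$clusters), 2)
  w3 <- data.frame(structure = c("S1", "S2"), x = c(0, 1.0), y = 0, z = 0)
  expect_equal(nrow(cluster_waters(w3, 1.0)$clusters), 2)

  # one structure contributing two nearby waters still counts once
  w4 <- data.frame(structure = c("S1", "S1", "S2"),
                   x = c(0, 0.5, 0.9), y = 0, z = 0)
  cl4 <- cluster_waters(w4, 1.0)
  expect_equal(cl4$clusters$n_structures, 1L + 1L)
  expect_equal(cl4$clusters$n_members, 3L)
})

test_that("clustering matches a brute-force union-find oracle on random points", {
  set.seed(17)
  for (rep in 1:4) {
    n <- sample(50:200, 1)
    pts <- random_points(n, -4, 4)
    w <- data.frame(structure = paste0("S", sample(1:9, n, replace = TRUE)),
                    x = pts[, 1], y = pts[, 2], z = pts[, 3])
    cl <- cluster_waters(w, link_cutoff = 1.0)
    truth <- oracle_components(pts, 1.0)
    # same partition: compare co-membership matrices
    impl <- integer(n)
    for (r in seq_len(nrow(cl$members))) {
      # members keep coordinates; map back by matching positions
      hit <- which(abs(pts[, 1] - cl$members$x[r]) < 1e-12 &
                   abs(pts[, 2] - cl$members$y[r]) < 1e-12)
      impl[hit] <- cl$members$cluster[r]
    }
    expect_equal(outer(impl, impl, "=="), outer(truth, truth, "=="))
    # partition property: every water in exactly one cluster
    expect_equal(nrow(cl$members), n)
    expect_equal(sum(cl$clusters$n_members), n)
  }
})

test_that("cluster means are invariant to input ordering", {
  set.seed(23)
  pts <- random_points(60, -3, 3)
  w <- data.frame(structure = paste0("S", rep(1:6, 10)),
                  x = pts[, 1], y = pts[, 2], z = pts[, 3])
  cl1 <- cluster_waters(w, 1.0)
  perm <- sample(nrow(w))
  cl2 <- cluster_waters(w[perm, ], 1.0)
  m1 <- cl1$clusters[order(cl1$clusters$x, cl1$clusters$y), c("x", "y", "z", "n_structures")]
  m2 <- cl2$clusters[order(cl2$clusters$x, cl2$clusters$y), c("x", "y", "z", "n_structures")]
  expect_equal(m1, m2, ignore_attr = TRUE)
})

test_that("first-shell filter keeps means at <= 3.25 A and needs a solute", {
  sol <- tiny_solute()
  # singleton clusters at 3.20 A (from atom (1.5,0,0)) and 3.30 A (from (0,1.5,0))
  w <- data.frame(structure = c("S1", "S2"),
                  x = c(1.5 + 3.20, 0), y = c(0, 1.5 + 3.30), z = c(0, 0))
  cl <- cluster_waters(w, 1.0)
  expect_equal(nrow(cl$clusters), 2)
  filt <- filter_first_shell(cl, sol, cutoff = 3.25)
  expect_equal(nrow(filt$clusters), 1)
  kept <- filt$clusters
  expect_equal(kept$x, 1.5 + 3.20)
  expect_equal(nrow(filter_first_shell(cluster_waters(w[0, ], 1.0), sol)$clusters), 0)
})

test_that("consensus classes split at the high threshold and counts add up", {
  sol <- tiny_solute()
  mk <- function(ns, x) data.frame(structure = paste0("S", seq_len(ns)),
                                   x = x, y = 4.0, z = 0)
  w <- rbind(mk(9, 0), mk(5, 3), mk(4, 6), mk(1, 9))
  cl <- classify_consensus(cluster_waters(w, 1.0), high_threshold = 5)
  cls <- cl$clusters[order(cl$clusters$x), ]
  expect_equal(cls$consensus_class, c("high", "high", "lower", "lower"))
  expect_equal(sum(cls$consensus_class == "high") +
               sum(cls$consensus_class == "lower"), nrow(cls))
})

test_that("the full consensus pipeline recovers planted sites exactly", {
  truth <- rbind(c(4.3, 0, 0), c(0, 4.3, 0), c(0, -4.3, 0), c(-4.3, 0, 0))
  recs <- generate_pseudo_structures(truth, n_structures = 9,
                                     jitter_sigma = 0, detect_prob = 1, seed = 3)
  cw <- consensus_waters(recs)
  expect_equal(nrow(cw$clusters), nrow(truth))
  expect_true(all(cw$clusters$n_structures == 9L))
  expect_true(all(cw$clusters$consensus_class == "high"))
  expect_equal(cw$n_aggregated, 9L * nrow(truth))

  # detect_prob = 0 -> waterless structures -> no clusters
  empty <- generate_pseudo_structures(truth, n_structures = 3,
                                      jitter_sigma = 0, detect_prob = 0, seed = 3)
  expect_equal(nrow(consensus_waters(empty)$clusters), 0)

  # a single structure: everything is lower consensus
  one <- consensus_waters(recs[1])
  expect_true(all(one$clusters$n_structures == 1L))
  expect_true(all(one$clusters$consensus_class == "lower"))
})
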