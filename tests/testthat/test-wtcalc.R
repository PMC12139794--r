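# Fine-grid binning and the Boltzmann-averaged excess chemical potential.

test_that("the default fine grid has 200^3 voxels and conserves counts", {
  traj <- water_trajectory(list(matrix(c(0, 0, 0), 1, 3)))
  g <- bin_fine_grid(traj, c(0, 0, 0))
  expect_equal(g$dims, c(200L, 200L, 200L))
  expect_equal(g$n_voxels, 8e6)

  # seven points placed in the cube -> counts sum to 7
  set.seed(2)
  pts <- matrix(stats::runif(21, -0.49, 0.49), 7, 3)
  g7 <- bin_fine_grid(water_trajectory(list(pts)), c(0, 0, 0))
  expect_equal(sum(g7$count), 7)
  expect_equal(g7$n_binned, 7)

  # nothing in the cube -> empty occupancy, WT undefined
  g_empty <- bin_fine_grid(traj, c(30, 30, 30))
  expect_equal(length(g_empty$count), 0)
  expect_error(boltzmann_wt(g_empty), class = "watsite_validation_error")
  expect_error(bin_fine_grid(traj, c(0, 0, 0), half_extent = -1),
               class = "watsite_validation_error")
})

test_that("per-voxel WT follows the density-ratio formula with an Inf sentinel", {
  th <- make_thermo(300)
  dV <- 0.005^3
  # density exactly at bulk -> 0 (use rho = rho_bulk: count = rho_bulk * n * dV)
  nf <- 1 / (th$rho_bulk * dV)  # frames making one count equal bulk density
  expect_equal(voxel_wt(1, nf, dV, th), 0, tolerance = 1e-9)
  # one observation in 100,000 frames: rho/rho_bulk = 1/(1e5 * dV * 0.033)
  expect_equal(voxel_wt(1, 1e5, 1.25e-7, th),
               -th$kT * log(1 / (1e5 * 1.25e-7 * 0.033)), tolerance = 1e-9)
  expect_identical(voxel_wt(0, 100, dV, th), Inf)
})

test_that("the selection keeps round(top_fraction * n_voxels) voxels", {
  traj <- water_trajectory(list(matrix(c(0, 0, 0), 1, 3)))
  g <- bin_fine_grid(traj, c(0, 0, 0))
  res <- boltzmann_wt(g)
  expect_equal(res$n_selected_voxels, 80000)
  expect_equal(res$total_selected_count, 1)
})

test_that("uniform bulk-density occupancy scores WT = 0", {
  # craft a grid whose every selected voxel sits exactly at bulk density
  th <- make_thermo(300)
  dims1 <- 20L
  nvox <- as.numeric(dims1)^3
  n <- round(0.01 * nvox)  # 80 voxels
  dV <- 0.05^3
  nf <- 1000L
  count_bulk <- th$rho_bulk * nf * dV  # not integer; scale frames to make it 1
  nf <- as.integer(round(1 / (th$rho_bulk * dV)))
  g <- structure(
    list(reference = c(0, 0, 0), half_extent = 0.5, voxel_edge = 0.05,
         dims = rep(dims1, 3L), n_voxels = nvox,
         voxel_index = seq_len(n) - 1, count = rep(1L, n),
         n_binned = n, n_frames = nf),
    class = "fine_grid")
  expect_equal(boltzmann_wt(g, th)$wt, 0, tolerance = 2e-3)
})

test_that("boltzmann_wt equals the enumerate-sort-sum oracle on sparse grids", {
  th <- make_thermo(300)
  set.seed(53)
  for (rep in 1:20) {
    g <- random_fine_grid(n_occupied = sample(c(10L, 500L, 5000L, 100000L), 1),
                          n_frames = sample(c(100L, 1000L), 1))
    res <- boltzmann_wt(g, th)
    expect_equal(res$wt,
                 oracle_boltzmann_wt(g$voxel_index, g$count, g$n_voxels,
                                     g$n_frames, g$voxel_edge^3, th),
                 tolerance = 1e-9)
    # algebraic identity: -kT log(S / (n nf dV rho)) with S the selected count
    expect_equal(res$wt,
                 -th$kT * log(res$total_selected_count /
                              (res$n_selected_voxels * g$n_frames *
                               g$voxel_edge^3 * th$rho_bulk)),
                 tolerance = 1e-12)
    expect_equal(res$density_ratio, exp(-res$wt / th$kT), tolerance = 1e-12)
  }
})

test_that("equal-count ties at the selection boundary do not change WT", {
  th <- make_thermo(300)
  g <- random_fine_grid(100000L, n_frames = 200L, max_count = 1L)
  set.seed(71)
  g2 <- g
  perm <- sample(length(g2$voxel_index))
  g2$voxel_index <- g2$voxel_index[perm][order(g2$voxel_index[perm])]
  # all counts equal 1 so any 80,000 of them give the same sum
  expect_equal(boltzmann_wt(g, th)$wt, boltzmann_wt(g2, th)$wt, tolerance = 1e-12)
})

test_that("adding an observation to a selected voxel strictly lowers WT", {
  th <- make_thermo(300)
  set.seed(61)
  g <- random_fine_grid(2000L, n_frames = 500L)
  base <- boltzmann_wt(g, th)
  g$count[1] <- g$count[1] + 1L
  expect_lt(boltzmann_wt(g, th)$wt, base$wt)
})

test_that("WT is invariant in expectation to doubling the frame count", {
  th <- make_thermo(300)
  mk <- function(nf, seed) {
    spec <- synthetic_spec(
      data.frame(x = 0, y = 0, z = 0, occupancy = 0.9, sigma = 0.15),
      box = rbind(c(-2, -2, -2), c(2, 2, 2)), bulk_density = 0.033,
      n_frames = nf, seed = seed)
    boltzmann_wt(bin_fine_grid(generate_trajectory(spec), c(0, 0, 0)), th)$wt
  }
  w1 <- mk(4000, 101)
  w2 <- mk(8000, 102)
  expect_equal(w1, w2, tolerance = 0.05)  # Monte-Carlo tolerance
})

test_that("sparse uniform bulk approaches -kT log(V_cube/(n dV))", {
  th <- make_thermo(300)
  spec <- synthetic_spec(
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               occupancy = numeric(0), sigma = numeric(0)),
    box = rbind(c(-3, -3, -3), c(3, 3, 3)), bulk_density = 0.033,
    n_frames = 20000, seed = 77)
  traj <- generate_trajectory(spec)
  g <- bin_fine_grid(traj, c(0, 0, 0))
  res <- boltzmann_wt(g, th)
  baseline <- -th$kT * log(1 / (80000 * 0.005^3))  # = -kT log(100)
  expect_equal(res$wt, baseline, tolerance = 0.1)
  # the optional baseline correction recentres bulk at ~0
  expect_equal(boltzmann_wt(g, th, baseline_correction = TRUE)$wt, 0,
               tolerance = 0.1)
})

test_that("score_sites ranks stronger sources first and is deterministic", {
  sol <- tiny_solute()
  spec <- synthetic_spec(
    data.frame(x = c(4.3, 0), y = c(0, 4.3), z = c(0, 0),
               occupancy = c(1.0, 0.5), sigma = c(0.15, 0.15)),
    box = rbind(c(-6, -6, -6), c(6, 6, 6)), bulk_density = 0.02,
    n_frames = 2000, seed = 19, solute = sol)
  traj <- generate_trajectory(spec)
  sites <- data.frame(cx = c(0.05, 4.25), cy = c(4.25, 0.05), cz = c(0.05, 0.05),
                      window_count = c(1L, 1L))
  scored <- score_sites(traj, sites)
  expect_equal(nrow(scored), 2)
  expect_equal(scored$rank, c(1L, 2L))
  # the occupancy-1.0 source (near x = 4.3) must rank first
  expect_lt(abs(scored$cx[1] - 4.25), 1e-9)
  expect_true(all(diff(scored$wt) >= 0))
  # identical duplicate inputs give identical WT
  dup <- score_sites(traj, sites[c(1, 1), ])
  expect_equal(dup$wt[1], dup$wt[2], tolerance = 1e-12)
  # empty cube is dropped with a warning
  sites_bad <- rbind(sites, data.frame(cx = 50, cy = 50, cz = 50, window_count = 1L))
  expect_warning(scored_bad <- score_sites(traj, sites_bad), "empty fine cube")
  expect_equal(nrow(scored_bad), 2)
})
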