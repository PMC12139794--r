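# Coarse-grid accumulation, sliding-cube window sums, greedy site selection
# and site mean positions.

one_frame_traj <- function(points) water_trajectory(list(as.matrix(points)))

min_dist_to_solute <- function(points, solute) {
  vapply(seq_len(nrow(points)), function(i) {
    min(rowSums(sweep(solute$xyz, 2, points[i, ])^2))
  }, numeric(1))
}

test_that("coarse binning conserves in-shell observations and honours the shell", {
  sol <- tiny_solute()
  near <- c(1.5 + 3.0, 0, 0)       # 3.0 A from nearest atom -> counted
  boundary_out <- c(1.5 + 3.30, 0, 0)  # 3.30 A -> beyond 3.25, not counted
  traj <- one_frame_traj(rbind(near, boundary_out))
  grid <- accumulate_coarse_grid(traj, sol)
  expect_equal(grid$n_binned, 1)
  expect_equal(sum(grid$counts), 1)
  expect_equal(sum(grid$counts > 0), 1)

  # identical position over 10 frames accumulates in one voxel
  traj10 <- water_trajectory(rep(list(matrix(near, 1, 3)), 10))
  grid10 <- accumulate_coarse_grid(traj10, sol)
  expect_equal(max(grid10$counts), 10)
  expect_equal(sum(grid10$counts), 10)
})

test_that("window sums equal the brute-force triple-loop convolution", {
  # trivial fields
  sol <- tiny_solute()
  g0 <- list(origin = c(0, 0, 0), voxel_edge = 0.1, dims = c(12L, 12L, 12L),
             counts = integer(12^3), n_binned = 0L, n_frames = 1L, shell = 3.25)
  class(g0) <- "coarse_grid"
  f0 <- window_sums(g0, 10)
  expect_true(all(f0$sums == 0))
  g1 <- g0
  g1$counts <- rep(1L, 12^3)
  expect_true(all(window_sums(g1, 10)$sums == 1000))

  # random grids against the oracle, exactly
  set.seed(31)
  for (rep in 1:3) {
    dims <- c(20L, 20L, 20L)
    counts <- rpois(prod(dims), 0.3)
    g <- g0
    g$dims <- dims
    g$counts <- counts
    for (w in c(3L, 10L)) {
      expect_identical(window_sums(g, w)$sums,
                       oracle_window_sums(counts, dims, w))
    }
  }
  expect_error(window_sums(g0, 13), class = "watsite_validation_error")
})

# A window field with exactly the given nonzero window sums, for testing the
# greedy suppression logic without binning ambiguity.
crafted_field <- function(entries, dims = c(40L, 40L, 40L),
                          origin = c(10, 10, 10), voxel_edge = 0.1,
                          window = 10L) {
  W <- array(0, dims)
  for (e in entries) W[e$i[1], e$i[2], e$i[3]] <- e$count
  structure(list(sums = W, window = window, origin = origin,
                 voxel_edge = voxel_edge, grid_dims = dims + window - 1L,
                 dims = dims),
            class = "window_field")
}

# lowest-corner index (5,5,5) -> center origin + (4 + window/2) * 0.1
win_center <- function(i, origin = c(10, 10, 10)) origin + (i - 1 + 5) * 0.1

test_that("greedy selection suppresses close peaks and solute-adjacent cubes", {
  far_solute <- solute_structure(matrix(c(0, 0, 0), 1, 3))
  w1 <- list(i = c(5L, 5L, 5L), count = 50)          # center (10.9, 10.9, 10.9)
  w2 <- list(i = c(25L, 5L, 5L), count = 30)         # 2.0 A away in x

  # one isolated occupied window -> exactly that site
  s1 <- select_sites(crafted_field(list(w1)), far_solute)
  expect_equal(nrow(s1), 1)
  expect_equal(unlist(s1[1, c("cx", "cy", "cz")]), win_center(w1$i),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(s1$window_count, 50)

  # two peaks 2.0 A apart (< 2.25): only the higher-count peak survives
  s2 <- select_sites(crafted_field(list(w1, w2)), far_solute)
  expect_equal(nrow(s2), 1)
  expect_equal(s2$window_count, 50)

  # at 2.3 A separation both survive, stronger first
  w3 <- list(i = c(28L, 5L, 5L), count = 30)
  s3 <- select_sites(crafted_field(list(w1, w3)), far_solute)
  expect_equal(s3$window_count, c(50, 30))

  # a peak whose center is 2.0 A from a solute atom is rejected
  near_solute <- solute_structure(matrix(win_center(w1$i) + c(0, 0, 2.0), 1, 3))
  s4 <- select_sites(crafted_field(list(w1)), near_solute)
  expect_equal(nrow(s4), 0)
  # ... and the 2.83-A-away second peak is then the only site kept
  s5 <- select_sites(crafted_field(list(w1, w2)), near_solute)
  expect_equal(nrow(s5), 1)
  expect_equal(s5$window_count, 30)

  # equal counts break ties toward the lexicographically lowest corner
  w_tie <- list(i = c(5L, 25L, 5L), count = 50)
  s6 <- select_sites(crafted_field(list(w_tie, w1)), far_solute, max_sites = 1)
  expect_equal(unlist(s6[1, c("cx", "cy", "cz")]), win_center(w1$i),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("selected sites satisfy the separation constraints by construction", {
  spec <- default_synthetic_spec(n_frames = 500, seed = 9)
  traj <- generate_trajectory(spec)
  grid <- accumulate_coarse_grid(traj, spec$solute)
  sites <- select_sites(window_sums(grid), spec$solute, max_sites = 20)
  expect_gt(nrow(sites), 1)
  centers <- as.matrix(sites[, c("cx", "cy", "cz")])
  d <- as.matrix(dist(centers))
  diag(d) <- Inf
  expect_true(all(d >= 2.25))
  expect_true(all(sqrt(min_dist_to_solute(centers, spec$solute)) >= 2.25))
})

test_that("selection is deterministic including its tie-breaks", {
  spec <- default_synthetic_spec(n_frames = 300, seed = 13)
  traj <- generate_trajectory(spec)
  grid <- accumulate_coarse_grid(traj, spec$solute)
  f <- window_sums(grid)
  s1 <- select_sites(f, spec$solute, max_sites = 10)
  s2 <- select_sites(f, spec$solute, max_sites = 10)
  expect_identical(s1, s2)
})

test_that("two planted sites 4 A apart are recovered within half a cube", {
  sol <- tiny_solute()
  sites_df <- data.frame(x = c(4.3, 0.3), y = c(0, 0), z = c(0, 0),
                         occupancy = c(1, 0.8), sigma = c(0.15, 0.15))
  # second site must be in shell: (0.3, 0, 0) is inside the solute - move it
  sites_df$x[2] <- 0
  sites_df$y[2] <- 4.3
  spec <- synthetic_spec(sites_df, box = rbind(c(-6, -6, -6), c(6, 6, 6)),
                         bulk_density = 0.033, n_frames = 2000, seed = 21,
                         solute = sol)
  traj <- generate_trajectory(spec)
  grid <- accumulate_coarse_grid(traj, sol)
  top2 <- select_sites(window_sums(grid), sol, max_sites = 2)
  found <- as.matrix(top2[, c("cx", "cy", "cz")])
  truth <- as.matrix(sites_df[, c("x", "y", "z")])
  for (i in 1:2) {
    expect_lt(min(sqrt(rowSums(sweep(found, 2, truth[i, ])^2))), 0.5)
  }
})

test_that("site mean positions average member waters inside the cube", {
  center <- c(4.25, 0.05, 0.05)
  # two waters symmetric about the center -> the center itself
  traj <- one_frame_traj(rbind(center + c(0.2, 0, 0), center - c(0.2, 0, 0)))
  expect_equal(site_mean_position(traj, center), center,
               tolerance = 1e-12, ignore_attr = TRUE)
  # a single water -> that water
  w <- center + c(0.1, -0.2, 0.3)
  expect_equal(site_mean_position(one_frame_traj(matrix(w, 1, 3)), center), w,
               tolerance = 1e-12, ignore_attr = TRUE)
  # empty cube errors
  expect_error(site_mean_position(traj, c(20, 20, 20)),
               class = "watsite_validation_error")
})

test_that("the mean position of a planted Gaussian matches its sample mean", {
  mu <- c(4.3, 0, 0)
  spec <- synthetic_spec(
    data.frame(x = mu[1], y = mu[2], z = mu[3], occupancy = 1, sigma = 0.15),
    box = rbind(c(-6, -6, -6), c(6, 6, 6)), bulk_density = 0,
    n_frames = 5000, seed = 37, solute = tiny_solute())
  traj <- generate_trajectory(spec)
  m <- site_mean_position(traj, mu)
  expect_lt(sqrt(sum((m - mu)^2)), 0.02)
  # and it equals the direct sample mean of the generated in-cube points
  p <- traj$coords
  h <- 0.5
  inside <- p[, 1] >= mu[1] - h & p[, 1] < mu[1] + h &
            p[, 2] >= mu[2] - h & p[, 2] < mu[2] + h &
            p[, 3] >= mu[3] - h & p[, 3] < mu[3] + h
  expect_equal(m, colMeans(p[inside, , drop = FALSE]), tolerance = 1e-12)
})
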