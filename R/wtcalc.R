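# Excess chemical potential (WT) of a hydration site from fine-grid occupancy.
#
# Around each reference position a cube extending 0.5 A in x, y and z is
# divided into fine voxels of edge a = 0.005 A (200^3 = 8 million voxels,
# dV = a^3).  Each voxel's local density over the trajectory gives a per-voxel
# WT(dV) = -kT log(rho/rho_bulk); the site-level WT is the Boltzmann average
# over the densest top 1% of voxels (n = 80,000 by default):
#
#   WT(V) = -kT log( sum_selected exp(-WT(dV)/kT) / n )
#         = -kT log( S / (n * n_frames * dV * rho_bulk) )
#
# where S is the total count in the selected voxels.  The two forms are
# algebraically identical; the count form is used for numerical robustness.

#' Bin water observations into a fine voxel grid around a reference position
#'
#' Collects every water-oxygen observation inside the half-open cube
#' `[reference - half_extent, reference + half_extent)` and bins it into
#' half-open cubic voxels of edge `voxel_edge`.  Only occupied voxels are
#' stored; with the defaults the full grid has 200^3 = 8,000,000 voxels.
#'
#' @param traj A [water_trajectory()].
#' @param reference Length-3 numeric: the reference position (a site's cube
#'   center).
#' @param half_extent Half edge of the sampling cube in Angstrom.
#' @param voxel_edge Fine voxel edge in Angstrom.
#' @return An object of class `fine_grid`: `reference`, `dims`, `n_voxels`
#'   (total, as a double), sorted `voxel_index`/`count` for occupied voxels,
#'   `n_binned`, `n_frames`, and the geometry parameters.
#' @export
bin_fine_grid <- function(traj, reference, half_extent = 0.5, voxel_edge = 0.005) {
  stopifnot(inherits(traj, "water_trajectory"))
  reference <- as.numeric(reference)
  if (length(reference) != 3L || any(!is.finite(reference))) {
    stop_validation("`reference` must be a finite length-3 vector")
  }
  if (!is.numeric(half_extent) || half_extent <= 0) {
    stop_validation("`half_extent` must be positive")
  }
  if (!is.numeric(voxel_edge) || voxel_edge <= 0) {
    stop_validation("`voxel_edge` must be positive")
  }
  d1 <- as.integer(round(2 * half_extent / voxel_edge))
  if (d1 < 1L) stop_validation("`voxel_edge` larger than the sampling cube")
  lo <- reference - half_extent
  hi <- reference + half_extent
  p <- traj$coords
  inb <- p[, 1L] >= lo[1L] & p[, 1L] < hi[1L] &
         p[, 2L] >= lo[2L] & p[, 2L] < hi[2L] &
         p[, 3L] >= lo[3L] & p[, 3L] < hi[3L]
  q <- p[inb, , drop = FALSE]
  if (nrow(q)) {
    ijk <- floor(sweep(q, 2L, lo) / voxel_edge)
    ijk[ijk < 0] <- 0           # guard floating-point underflow at the lower faces
    ijk[ijk > d1 - 1L] <- d1 - 1L
    lin <- ijk[, 1L] + d1 * (ijk[, 2L] + d1 * ijk[, 3L])
    r <- rle(sort(lin))
    voxel_index <- r$values
    count <- r$lengths
  } else {
    voxel_index <- numeric(0)
    count <- integer(0)
  }
  structure(
    list(reference = reference, half_extent = half_extent, voxel_edge = voxel_edge,
         dims = rep(d1, 3L), n_voxels = as.numeric(d1)^3,
         voxel_index = voxel_index, count = count,
         n_binned = nrow(q), n_frames = traj$n_frames),
    class = "fine_grid"
  )
}

#' @export
print.fine_grid <- function(x, ...) {
  cat(sprintf(
    "Fine grid at (%.2f, %.2f, %.2f): %d^3 voxels of %g A, %d observations in %d occupied voxels\n",
    x$reference[1], x$reference[2], x$reference[3], x$dims[1], x$voxel_edge,
    x$n_binned, length(x$count)))
  invisible(x)
}

#' Per-voxel excess chemical potential
#'
#' Applies `WT(dV) = -kT log(rho / rho_bulk)` with the local density
#' `rho = count / (n_frames * dV)`.  A zero count gives `+Inf` (an unoccupied
#' voxel contributes nothing to Boltzmann sums).
#'
#' @param count Observation count(s) in the voxel (vectorised).
#' @param n_frames Number of trajectory frames.
#' @param dV Voxel volume in cubic Angstrom.
#' @param thermo A [make_thermo()] object.
#' @return WT(dV) in kcal/mol.
#' @export
voxel_wt <- function(count, n_frames, dV, thermo = make_thermo()) {
  stopifnot(inherits(thermo, "thermo_params"))
  if (n_frames < 1L) stop_validation("`n_frames` must be at least 1")
  if (dV <= 0) stop_validation("`dV` must be positive")
  rho <- count / (n_frames * dV)
  out <- rep(Inf, length(count))
  nz <- count > 0
  out[nz] <- -thermo$kT * log(rho[nz] / thermo$rho_bulk)
  out
}

#' Boltzmann-averaged excess chemical potential of a fine grid
#'
#' Selects the `round(top_fraction * n_voxels)` voxels with the highest counts
#' (ties broken by voxel index; zero-count voxels fill the selection when
#' fewer are occupied, contributing nothing to the sum) and returns
#' `WT(V) = -kT log( S / (n * n_frames * dV * rho_bulk) )` where `S` is the
#' total count in the selection.  This equals the Boltzmann average of the
#' per-voxel WT values over the selected sub-volume.
#'
#' @param grid A `fine_grid` from [bin_fine_grid()]; must have at least one
#'   occupied voxel.
#' @param thermo A [make_thermo()] object.
#' @param top_fraction Fraction of all voxels to select (default 0.01, i.e.
#'   80,000 of 8,000,000 with default grid geometry).
#' @param baseline_correction If `TRUE`, subtracts the sparse-bulk baseline
#'   `-kT log(V_cube / (n * dV))` so that uniform bulk scores approximately 0.
#'   The default (`FALSE`) reports the raw estimator.
#' @return An object of class `wt_result` with `wt` (kcal/mol),
#'   `density_ratio` (`= exp(-wt/kT)`), `n_selected_voxels`,
#'   `total_selected_count`, `reference` and `n_frames`.
#' @export
boltzmann_wt <- function(grid, thermo = make_thermo(), top_fraction = 0.01,
                         baseline_correction = FALSE) {
  stopifnot(inherits(grid, "fine_grid"), inherits(thermo, "thermo_params"))
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1) {
    stop_validation("`top_fraction` must be in (0, 1]")
  }
  if (length(grid$count) == 0L || sum(grid$count) == 0L) {
    stop_validation("all-zero fine grid: WT is undefined for an unvisited cube")
  }
  n <- round(top_fraction * grid$n_voxels)
  if (n < 1) stop_validation("`top_fraction` selects no voxels")
  if (length(grid$count) > n) {
    ord <- order(-grid$count, grid$voxel_index)
    S <- sum(grid$count[ord[seq_len(n)]])
  } else {
    S <- sum(grid$count)
  }
  dV <- grid$voxel_edge^3
  ratio <- S / (n * grid$n_frames * dV * thermo$rho_bulk)
  wt <- -thermo$kT * log(ratio)
  if (baseline_correction) {
    v_cube <- (2 * grid$half_extent)^3
    wt <- wt + thermo$kT * log(v_cube / (n * dV))
  }
  structure(
    list(reference = grid$reference, wt = wt,
         density_ratio = exp(-wt / thermo$kT),
         n_selected_voxels = n, total_selected_count = S,
         n_frames = grid$n_frames, baseline_correction = baseline_correction),
    class = "wt_result"
  )
}

#' @export
print.wt_result <- function(x, ...) {
  cat(sprintf(
    "WT = %.3f kcal/mol (density ratio %.3g; %d observations in top-%d voxel selection)\n",
    x$wt, x$density_ratio, x$total_selected_count, x$n_selected_voxels))
  invisible(x)
}

#' Score predicted sites by excess chemical potential
#'
#' For each site, bins the trajectory into the fine grid at the site's cube
#' center (the reference position) and computes the Boltzmann-averaged WT.
#' Sites whose fine cube received no observations are dropped with a warning.
#' The result is sorted ascending by WT (most favourable first) and ranked.
#'
#' @param traj A [water_trajectory()].
#' @param sites A `predicted_sites` data frame from [select_sites()] (columns
#'   `cx, cy, cz`, `window_count`).
#' @param thermo A [make_thermo()] object.
#' @param half_extent,fine_voxel,top_fraction Fine-grid parameters, see
#'   [bin_fine_grid()] and [boltzmann_wt()].
#' @param baseline_correction Passed to [boltzmann_wt()].
#' @return The sites data frame with `wt`, `density_ratio` and `rank` added,
#'   sorted ascending by `wt`.
#' @export
score_sites <- function(traj, sites, thermo = make_thermo(), half_extent = 0.5,
                        fine_voxel = 0.005, top_fraction = 0.01,
                        baseline_correction = FALSE) {
  stopifnot(inherits(traj, "water_trajectory"), is.data.frame(sites))
  n <- nrow(sites)
  if (n == 0L) {
    sites$wt <- numeric(0)
    sites$density_ratio <- numeric(0)
    sites$rank <- integer(0)
    return(sites)
  }
  wt <- rep(NA_real_, n)
  ratio <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- bin_fine_grid(traj, c(sites$cx[i], sites$cy[i], sites$cz[i]),
                       half_extent = half_extent, voxel_edge = fine_voxel)
    res <- tryCatch(
      boltzmann_wt(g, thermo, top_fraction = top_fraction,
                   baseline_correction = baseline_correction),
      watsite_validation_error = function(e) NULL
    )
    if (is.null(res)) {
      warning(sprintf("site %d at (%.2f, %.2f, %.2f) has an empty fine cube; dropped",
                      i, sites$cx[i], sites$cy[i], sites$cz[i]))
      next
    }
    wt[i] <- res$wt
    ratio[i] <- res$density_ratio
  }
  keep <- !is.na(wt)
  sites <- sites[keep, , drop = FALSE]
  sites$wt <- wt[keep]
  sites$density_ratio <- ratio[keep]
  ord <- order(sites$wt)   # stable: equal WT keeps selection order
  sites <- sites[ord, , drop = FALSE]
  sites$rank <- seq_len(nrow(sites))
  rownames(sites) <- NULL
  sites
}
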