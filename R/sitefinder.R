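# Candidate hydration sites from a coarse occupancy grid: bin first-shell
# water-oxygen observations into 0.1 A voxels, convolve with a 10x10x10
# sliding cube (1 A edge), and greedily pick the densest non-overlapping
# cubes away from the solute.

#' Accumulate first-shell water observations on a coarse voxel grid
#'
#' Bins every water-oxygen observation whose minimum distance to the solute is
#' at most `shell` into half-open cubic voxels `[origin + i*a, origin +
#' (i+1)*a)`.  The grid spans the solute bounding box plus `padding` on every
#' side, so all first-shell observations fall inside it.
#'
#' @param traj A [water_trajectory()].
#' @param solute A [solute_structure()] or [structure_record()].
#' @param shell First-hydration-shell cutoff in Angstrom (inclusive).
#' @param voxel_edge Coarse voxel edge length in Angstrom.
#' @param padding Margin beyond the solute bounding box; default `shell + 1`.
#' @return An object of class `coarse_grid`: origin, voxel edge, dims, a dense
#'   integer `counts` vector in column-major voxel order, and bookkeeping.
#' @export
accumulate_coarse_grid <- function(traj, solute, shell = 3.25, voxel_edge = 0.1,
                                   padding = shell + 1) {
  stopifnot(inherits(traj, "water_trajectory"))
  solute <- as_solute(solute)
  if (nrow(traj$coords) == 0L) stop_validation("trajectory contains no waters")
  if (voxel_edge <= 0) stop_validation("`voxel_edge` must be positive")
  if (padding < shell) stop_validation("`padding` must be at least `shell`")
  origin <- apply(solute$xyz, 2L, min) - padding
  upper <- apply(solute$xyz, 2L, max) + padding
  dims <- as.integer(ceiling((upper - origin) / voxel_edge))
  nvox <- prod(as.numeric(dims))
  if (nvox > .Machine$integer.max) {
    stop_validation(sprintf(
      "coarse grid would need %.0f voxels; reduce the padding or coarsen the grid", nvox))
  }
  pts <- traj$coords
  keep <- min_sq_dist(pts, solute$xyz) <= shell^2
  pts <- pts[keep, , drop = FALSE]
  counts <- integer(nvox)
  if (nrow(pts)) {
    ijk <- floor(sweep(pts, 2L, origin) / voxel_edge)
    if (any(ijk < 0) || any(ijk[, 1L] >= dims[1L]) ||
        any(ijk[, 2L] >= dims[2L]) || any(ijk[, 3L] >= dims[3L])) {
      stop("internal error: in-shell water outside the padded grid (padding too small)")
    }
    lin <- ijk[, 1L] + dims[1L] * (ijk[, 2L] + dims[2L] * ijk[, 3L]) + 1
    counts <- tabulate(lin, nbins = nvox)
  }
  structure(
    list(origin = origin, voxel_edge = voxel_edge, dims = dims, counts = counts,
         n_binned = nrow(pts), n_frames = traj$n_frames, shell = shell),
    class = "coarse_grid"
  )
}

#' @export
print.coarse_grid <- function(x, ...) {
  cat(sprintf("Coarse grid: %d x %d x %d voxels of %.3g A, %d binned observations\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_edge, x$n_binned))
  invisible(x)
}

# 3-D summed-area table (cumulative sums along each axis).
summed_area_3d <- function(A) {
  S <- apply(A, c(2L, 3L), cumsum)
  S <- aperm(apply(S, c(1L, 3L), cumsum), c(2L, 1L, 3L))
  aperm(apply(S, c(1L, 2L), cumsum), c(2L, 3L, 1L))
}

#' Sliding-cube window sums over a coarse grid
#'
#' For every voxel that can anchor the lowest-index corner of a
#' `window^3`-voxel cube, computes the exact sum of counts in that cube
#' (stride 1 in all axes).  With the default 0.1 A voxels and `window = 10`
#' each cube has a 1 A edge.  Implemented with a 3-D summed-area table; counts
#' are integers well below 2^53, so the sums are exact.
#'
#' @param grid A `coarse_grid` from [accumulate_coarse_grid()].
#' @param window Cube side in voxels; must not exceed any grid dimension.
#' @return An object of class `window_field`: the 3-D array `sums` with
#'   dimension `dims - window + 1`, plus grid geometry.
#' @export
window_sums <- function(grid, window = 10L) {
  stopifnot(inherits(grid, "coarse_grid"))
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop_validation("`window` must be a positive integer")
  d <- grid$dims
  if (any(window > d)) {
    stop_validation(sprintf("window (%d) exceeds grid dimensions (%s)",
                            window, paste(d, collapse = "x")))
  }
  A <- array(as.numeric(grid$counts), dim = d)
  S <- summed_area_3d(A)
  P <- array(0, d + 1L)
  P[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- S
  n_out <- d - window + 1L
  lo1 <- seq_len(n_out[1L]); hi1 <- lo1 + window
  lo2 <- seq_len(n_out[2L]); hi2 <- lo2 + window
  lo3 <- seq_len(n_out[3L]); hi3 <- lo3 + window
  W <- P[hi1, hi2, hi3, drop = FALSE] -
       P[lo1, hi2, hi3, drop = FALSE] -
       P[hi1, lo2, hi3, drop = FALSE] -
       P[hi1, hi2, lo3, drop = FALSE] +
       P[lo1, lo2, hi3, drop = FALSE] +
       P[lo1, hi2, lo3, drop = FALSE] +
       P[hi1, lo2, lo3, drop = FALSE] -
       P[lo1, lo2, lo3, drop = FALSE]
  structure(
    list(sums = W, window = window, origin = grid$origin,
         voxel_edge = grid$voxel_edge, grid_dims = d, dims = dim(W)),
    class = "window_field"
  )
}

#' @export
print.window_field <- function(x, ...) {
  cat(sprintf("Window-sum field: %s windows of %d^3 voxels (%.2f A cubes)\n",
              paste(x$dims, collapse = " x "), x$window,
              x$window * x$voxel_edge))
  invisible(x)
}

#' Select candidate hydration sites by greedy non-maximum suppression
#'
#' Iterates over occupied windows in descending window count (ties broken by
#' lexicographic lowest-corner index) and accepts a window if its geometric
#' center is at least `min_separation` from every previously accepted center
#' and at least `min_solute_dist` from every solute atom.
#'
#' @param field A `window_field` from [window_sums()].
#' @param solute A [solute_structure()] or [structure_record()].
#' @param min_separation Minimum center-to-center distance between accepted
#'   cubes (Angstrom).
#' @param min_solute_dist Minimum center-to-solute-atom distance (Angstrom).
#' @param max_sites Stop after accepting this many sites (default unlimited).
#' @return A data frame of class `predicted_sites` with columns `cx, cy, cz`
#'   (cube center), `window_count`; attributes record the cube edge and
#'   selection parameters.  May have zero rows.
#' @export
select_sites <- function(field, solute, min_separation = 2.25,
                         min_solute_dist = 2.25, max_sites = Inf) {
  stopifnot(inherits(field, "window_field"))
  solute <- as_solute(solute)
  W <- field$sums
  pos <- which(W > 0)
  empty <- data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
                      window_count = numeric(0))
  if (length(pos) == 0L) {
    return(as_predicted_sites(empty, field, min_separation, min_solute_dist))
  }
  counts <- W[pos]
  ai <- arrayInd(pos, dim(W))
  # geometric center of the window whose lowest corner is voxel (i,j,k):
  # origin + (i - 1 + window/2) * voxel_edge
  centers <- sweep((ai - 1 + field$window / 2) * field$voxel_edge, 2L,
                   field$origin, "+")
  ord <- order(-counts, ai[, 1L], ai[, 2L], ai[, 3L])
  far_enough <- min_sq_dist(centers, solute$xyz) >= min_solute_dist^2
  acc <- integer(0)
  min_sep2 <- min_separation^2
  for (idx in ord) {
    if (!far_enough[idx]) next
    if (length(acc)) {
      d2 <- (centers[acc, 1L] - centers[idx, 1L])^2 +
            (centers[acc, 2L] - centers[idx, 2L])^2 +
            (centers[acc, 3L] - centers[idx, 3L])^2
      if (any(d2 < min_sep2)) next
    }
    acc <- c(acc, idx)
    if (length(acc) >= max_sites) break
  }
  if (length(acc) == 0L) {
    return(as_predicted_sites(empty, field, min_separation, min_solute_dist))
  }
  df <- data.frame(cx = centers[acc, 1L], cy = centers[acc, 2L],
                   cz = centers[acc, 3L], window_count = counts[acc])
  as_predicted_sites(df, field, min_separation, min_solute_dist)
}

as_predicted_sites <- function(df, field, min_separation, min_solute_dist) {
  attr(df, "cube_edge") <- field$window * field$voxel_edge
  attr(df, "min_separation") <- min_separation
  attr(df, "min_solute_dist") <- min_solute_dist
  class(df) <- c("predicted_sites", "data.frame")
  df
}

#' Mean water position within a site's cube
#'
#' Averages all water-oxygen observations (over all frames) that fall in the
#' axis-aligned cube of edge `cube_edge` centered on `center` (half-open
#' bounds, matching the voxel convention).  When a solute is supplied, only
#' observations within `shell` of it are included, consistent with the
#' first-shell counts the site was selected from.
#'
#' @param traj A [water_trajectory()].
#' @param center Cube center, length-3 numeric.
#' @param cube_edge Cube edge length in Angstrom (default 1).
#' @param solute Optional [solute_structure()] for the shell filter.
#' @param shell Shell cutoff used with `solute`.
#' @return Length-3 numeric: the mean position.
#' @export
site_mean_position <- function(traj, center, cube_edge = 1.0, solute = NULL,
                               shell = 3.25) {
  stopifnot(inherits(traj, "water_trajectory"))
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center))) {
    stop_validation("`center` must be a finite length-3 vector")
  }
  h <- cube_edge / 2
  p <- traj$coords
  inside <- p[, 1L] >= center[1L] - h & p[, 1L] < center[1L] + h &
            p[, 2L] >= center[2L] - h & p[, 2L] < center[2L] + h &
            p[, 3L] >= center[3L] - h & p[, 3L] < center[3L] + h
  if (!is.null(solute)) {
    solute <- as_solute(solute)
    inside[inside] <- min_sq_dist(p[inside, , drop = FALSE], solute$xyz) <= shell^2
  }
  if (!any(inside)) {
    stop_validation("no water observations inside the site cube")
  }
  colMeans(p[inside, , drop = FALSE])
}
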