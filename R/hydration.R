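# The main model fit: from a water-oxygen trajectory around a fixed solute to
# a ranked table of predicted hydration sites with excess chemical potentials.

#' Fit hydration sites to a water trajectory
#'
#' Runs the full prediction pipeline: accumulate first-shell water occupancy
#' on a coarse voxel grid, convolve with a 1 Angstrom sliding cube, greedily
#' select the densest non-overlapping cubes away from the solute, compute the
#' mean water position inside each cube, and score every site's excess
#' chemical potential (WT) by fine-grid Boltzmann averaging at the cube
#' center.
#'
#' @param traj A [water_trajectory()] in the solute-fixed frame.
#' @param solute A [solute_structure()] or [structure_record()].
#' @param config A configuration list from [default_config()]; individual
#'   entries may be overridden through `...` (e.g. `max_sites = 10`).
#' @param verbose Log stage-by-stage counts via `message()`.
#' @param ... Named configuration overrides.
#' @return An object of class `hydration_sites`: a list with
#'   \describe{
#'     \item{sites}{data frame, one row per site sorted by ascending WT:
#'       `rank`, predicted water position `x, y, z` (mean of member waters),
#'       cube center `cx, cy, cz`, `window_count`, `wt` (kcal/mol),
#'       `density_ratio`.}
#'     \item{n_frames, n_binned, grid_dims}{fit bookkeeping.}
#'     \item{config, thermo, call}{what produced the fit.}
#'   }
#'   Methods: `print`, `summary`, `coef` (WT vector), `predict` (top-n
#'   positions), `plot` (WT vs rank), `as.data.frame`.
#' @examples
#' spec <- synthetic_spec(
#'   sites = data.frame(x = 4.3, y = 0, z = 0, occupancy = 0.9, sigma = 0.15),
#'   box = rbind(c(-6, -6, -6), c(6, 6, 6)),
#'   bulk_density = 0.02, n_frames = 400, seed = 42,
#'   solute = synthetic_solute())
#' traj <- generate_trajectory(spec)
#' fit <- hydration_sites(traj, spec$solute, max_sites = 3)
#' fit
#' coef(fit)
#' @export
hydration_sites <- function(traj, solute, config = default_config(),
                            verbose = FALSE, ...) {
  config <- merge_config(config, list(...))
  solute <- as_solute(solute)
  thermo <- make_thermo(config$temperature, config$rho_bulk)
  if (config$stride > 1L) traj <- subsample_trajectory(traj, config$stride)

  grid <- accumulate_coarse_grid(traj, solute, shell = config$shell_predict,
                                 voxel_edge = config$coarse_voxel)
  if (verbose) {
    message(sprintf("coarse grid %s: %d first-shell observations over %d frames",
                    paste(grid$dims, collapse = "x"), grid$n_binned, traj$n_frames))
  }
  field <- window_sums(grid, window = config$window)
  sites <- select_sites(field, solute,
                        min_separation = config$min_separation,
                        min_solute_dist = config$min_solute_dist,
                        max_sites = config$max_sites)
  if (verbose) message(sprintf("%d candidate sites selected", nrow(sites)))

  if (nrow(sites)) {
    mp <- t(vapply(seq_len(nrow(sites)), function(i) {
      site_mean_position(traj, c(sites$cx[i], sites$cy[i], sites$cz[i]),
                         cube_edge = config$window * config$coarse_voxel,
                         solute = solute, shell = config$shell_predict)
    }, numeric(3)))
    sites$x <- mp[, 1L]; sites$y <- mp[, 2L]; sites$z <- mp[, 3L]
  } else {
    sites$x <- sites$y <- sites$z <- numeric(0)
  }

  sites <- score_sites(traj, sites, thermo,
                       half_extent = config$half_extent,
                       fine_voxel = config$fine_voxel,
                       top_fraction = config$top_fraction)
  if (verbose && nrow(sites)) {
    message(sprintf("scored %d sites; WT range [%.2f, %.2f] kcal/mol",
                    nrow(sites), min(sites$wt), max(sites$wt)))
  }
  cols <- c("rank", "x", "y", "z", "cx", "cy", "cz", "window_count",
            "wt", "density_ratio")
  sites <- as.data.frame(sites)[, cols]
  structure(
    list(sites = sites, n_frames = traj$n_frames, n_binned = grid$n_binned,
         grid_dims = grid$dims, config = config, thermo = thermo,
         call = match.call()),
    class = "hydration_sites"
  )
}

#' @export
print.hydration_sites <- function(x, n = 6L, ...) {
  cat(sprintf("Hydration-site fit: %d site(s) from %d frames (%d first-shell observations)\n",
              nrow(x$sites), x$n_frames, x$n_binned))
  if (nrow(x$sites)) {
    cat(sprintf("WT range: [%.3f, %.3f] kcal/mol at T = %g K\n",
                min(x$sites$wt), max(x$sites$wt), x$thermo$temperature))
    cat(sprintf("Top %d sites:\n", min(n, nrow(x$sites))))
    print(utils::head(format_sites_table(x$sites), n))
  }
  invisible(x)
}

format_sites_table <- function(sites) {
  data.frame(
    rank = sites$rank,
    x = round(sites$x, 3), y = round(sites$y, 3), z = round(sites$z, 3),
    window_count = sites$window_count,
    wt = round(sites$wt, 3),
    density_ratio = signif(sites$density_ratio, 4)
  )
}

#' @export
summary.hydration_sites <- function(object, ...) {
  s <- object$sites
  out <- list(
    n_sites = nrow(s),
    n_frames = object$n_frames,
    n_binned = object$n_binned,
    wt_summary = if (nrow(s)) summary(s$wt) else NULL,
    count_summary = if (nrow(s)) summary(s$window_count) else NULL,
    thermo = object$thermo,
    config = object$config
  )
  class(out) <- "summary.hydration_sites"
  out
}

#' @export
print.summary.hydration_sites <- function(x, ...) {
  cat(sprintf("Hydration-site fit: %d sites, %d frames, %d first-shell observations\n",
              x$n_sites, x$n_frames, x$n_binned))
  print(x$thermo)
  if (!is.null(x$wt_summary)) {
    cat("WT (kcal/mol):\n"); print(x$wt_summary)
    cat("Window counts:\n"); print(x$count_summary)
  }
  invisible(x)
}

#' @export
coef.hydration_sites <- function(object, ...) {
  stats::setNames(object$sites$wt, paste0("site", object$sites$rank))
}

#' Predicted water positions from a hydration-site fit
#'
#' @param object A `hydration_sites` fit.
#' @param n Number of top-ranked sites to return (default all).
#' @param what `"position"` for the mean water position (the predicted water
#'   coordinates) or `"center"` for the reference cube centers.
#' @param ... Unused.
#' @return An n x 3 coordinate matrix, best-ranked first.
#' @export
predict.hydration_sites <- function(object, n = NULL, what = c("position", "center"), ...) {
  what <- match.arg(what)
  s <- object$sites
  if (is.null(n)) n <- nrow(s)
  n <- min(n, nrow(s))
  s <- s[seq_len(n), , drop = FALSE]
  m <- if (what == "position") cbind(x = s$x, y = s$y, z = s$z)
       else cbind(x = s$cx, y = s$cy, z = s$cz)
  m
}

#' @export
as.data.frame.hydration_sites <- function(x, ...) x$sites

#' @export
plot.hydration_sites <- function(x, ...) {
  s <- x$sites
  if (nrow(s) == 0L) stop_validation("no sites to plot")
  graphics::plot(s$rank, s$wt, type = "b", pch = 19,
                 xlab = "site rank", ylab = "WT (kcal/mol)",
                 main = "Excess chemical potential by site rank", ...)
  graphics::abline(h = 0, lty = 3, col = "grey50")
  invisible(x)
}
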