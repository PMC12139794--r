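# Synthetic data with known ground truth: localized Gaussian hydration sites
# over uniform Poisson bulk, a small rigid pseudo-solute, and jittered
# pseudo-experimental structures.  Every stochastic quantity is reproducible
# from the spec's seed, and expected_wt() provides the analytic expectation of
# the WT estimator for parameter-recovery tests.

#' A small synthetic solute
#'
#' Six pseudo-atoms at the vertices of an octahedron (C-alpha names, residue
#' numbers 1-6, chain A) so that superposition, shell filters, and site
#' selection all operate as they would on a protein.
#'
#' @param scale Half-distance between opposite vertices, Angstrom.
#' @return A [solute_structure()].
#' @export
synthetic_solute <- function(scale = 1.5) {
  xyz <- rbind(
    c( scale, 0, 0), c(-scale, 0, 0),
    c(0,  scale, 0), c(0, -scale, 0),
    c(0, 0,  scale), c(0, 0, -scale)
  )
  solute_structure(xyz, elety = "CA", resid = "ALA", resno = 1:6, chain = "A")
}

#' Specify a synthetic water system
#'
#' Each site emits, per frame and independently, one water oxygen with
#' probability `occupancy`, displaced from its center by an isotropic
#' Gaussian of width `sigma`; on top of this a uniform bulk contributes
#' `Poisson(bulk_density * box volume)` oxygens per frame.
#'
#' @param sites Data frame with columns `x, y, z, occupancy, sigma` (may have
#'   zero rows).
#' @param box 2 x 3 matrix `rbind(lower, upper)` of box bounds, Angstrom.
#' @param bulk_density Bulk water number density, A^-3 (default 0.033, the
#'   number density of liquid water).
#' @param n_frames Number of frames to generate.
#' @param seed Integer seed; part of the specification so that every
#'   downstream quantity is reproducible.
#' @param solute Optional [solute_structure()] fixed in the box.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(sites, box, bulk_density = 0.033, n_frames, seed = 1L,
                           solute = NULL) {
  if (is.null(sites)) {
    sites <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        occupancy = numeric(0), sigma = numeric(0))
  }
  stopifnot(is.data.frame(sites))
  need <- c("x", "y", "z", "occupancy", "sigma")
  if (!all(need %in% names(sites))) {
    stop_validation("`sites` needs columns x, y, z, occupancy, sigma")
  }
  box <- matrix(as.numeric(box), 2L, 3L)
  if (any(box[2L, ] <= box[1L, ])) stop_validation("box upper bounds must exceed lower bounds")
  if (nrow(sites)) {
    if (any(sites$occupancy <= 0 | sites$occupancy > 1)) {
      stop_validation("site occupancies must lie in (0, 1]")
    }
    if (any(sites$sigma < 0)) stop_validation("site sigmas must be non-negative")
    inside <- sites$x >= box[1, 1] & sites$x <= box[2, 1] &
              sites$y >= box[1, 2] & sites$y <= box[2, 2] &
              sites$z >= box[1, 3] & sites$z <= box[2, 3]
    if (!all(inside)) stop_validation("all sites must lie inside the box")
  }
  if (!is.numeric(bulk_density) || bulk_density < 0) {
    stop_validation("`bulk_density` must be non-negative")
  }
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L) stop_validation("`n_frames` must be at least 1")
  if (!is.null(solute)) solute <- as_solute(solute)
  structure(
    list(sites = sites, box = box, bulk_density = bulk_density,
         n_frames = n_frames, seed = as.integer(seed), solute = solute),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("Synthetic spec: %d site(s), bulk %.3g A^-3, %d frames, seed %d\n",
              nrow(x$sites), x$bulk_density, x$n_frames, x$seed))
  invisible(x)
}

#' Default synthetic study conditions
#'
#' Five Gaussian hydration sites in the 2.25-3.25 Angstrom shell of the
#' synthetic solute (occupancies 1.0 down to 0.8, widths 0.12 up to 0.20
#' Angstrom, pairwise separations over 4 Angstrom), over uniform bulk at the
#' liquid-water density 0.033 in a 12 Angstrom box, sampled for 20,000
#' frames.  These are the reference conditions used by the package's
#' parameter-recovery validation.
#'
#' @param n_frames Number of frames (default 20,000).
#' @param seed Integer seed.
#' @return A [synthetic_spec()].
#' @export
default_synthetic_spec <- function(n_frames = 20000L, seed = 1L) {
  solute <- synthetic_solute()
  # site centers 2.8 A from the nearest pseudo-atom, >= 4 A apart
  sites <- data.frame(
    x = c(4.3, -4.3, 0.0, 0.0, 0.0),
    y = c(0.0, 0.0, 4.3, -4.3, 0.0),
    z = c(0.0, 0.0, 0.0, 0.0, 4.3),
    occupancy = c(1.00, 0.95, 0.90, 0.85, 0.80),
    sigma = c(0.12, 0.14, 0.16, 0.18, 0.20)
  )
  synthetic_spec(sites, box = rbind(c(-6, -6, -6), c(6, 6, 6)),
                 bulk_density = 0.033, n_frames = n_frames, seed = seed,
                 solute = solute)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate a synthetic water trajectory
#'
#' Per frame, each site emits a Gaussian-displaced water oxygen with its
#' occupancy probability, and the bulk contributes Poisson-distributed
#' uniform points.  Identical specs (including seed) yield identical
#' trajectories.
#'
#' @param spec A [synthetic_spec()].
#' @return A [water_trajectory()].
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nf <- spec$n_frames
  with_seed(spec$seed, {
    coords_list <- list()
    frame_list <- list()
    for (i in seq_len(nrow(spec$sites))) {
      present <- which(stats::runif(nf) < spec$sites$occupancy[i])
      k <- length(present)
      if (k == 0L) next
      pts <- matrix(stats::rnorm(3L * k, sd = spec$sites$sigma[i]), k, 3L)
      pts <- sweep(pts, 2L, c(spec$sites$x[i], spec$sites$y[i], spec$sites$z[i]), "+")
      coords_list[[length(coords_list) + 1L]] <- pts
      frame_list[[length(frame_list) + 1L]] <- present
    }
    vol <- prod(spec$box[2L, ] - spec$box[1L, ])
    lambda <- spec$bulk_density * vol
    if (lambda > 0) {
      nb <- stats::rpois(nf, lambda)
      total <- sum(nb)
      if (total > 0L) {
        pts <- cbind(
          stats::runif(total, spec$box[1, 1], spec$box[2, 1]),
          stats::runif(total, spec$box[1, 2], spec$box[2, 2]),
          stats::runif(total, spec$box[1, 3], spec$box[2, 3])
        )
        coords_list[[length(coords_list) + 1L]] <- pts
        frame_list[[length(frame_list) + 1L]] <- rep.int(seq_len(nf), nb)
      }
    }
    if (length(coords_list) == 0L) {
      return(new_water_trajectory(matrix(numeric(0), 0, 3), integer(0), nf))
    }
    coords <- do.call(rbind, coords_list)
    frame <- unlist(frame_list, use.names = FALSE)
    ord <- order(frame)
    new_water_trajectory(coords[ord, , drop = FALSE], frame[ord], nf)
  })
}

#' Expected WT of a synthetic site under the Boltzmann estimator
#'
#' Analytic/numerical expectation of the fine-grid WT estimator for a
#' Gaussian site of known occupancy and width over uniform bulk, with the
#' fine cube centered on the site.  In the sparse regime (expected in-cube
#' observations well below the number of selected voxels, the case for
#' desk-scale frame counts) every observation lands in its own selected
#' voxel, so the expected selected count is the expected total in-cube count
#'
#'   M = n_frames * (occupancy * f_cube + bulk_density * V_cube),
#'
#' with `f_cube` the Gaussian mass inside the cube, and the expectation is
#' `-kT log( M / (n * n_frames * dV * rho_bulk) )`.  Outside the sparse
#' regime the expected per-voxel counts are enumerated on the fine grid and
#' the top-n selection is applied to them (an approximation that ignores
#' count fluctuations around the selection boundary).
#'
#' @param site A one-row data frame or list with `occupancy` and `sigma`
#'   (the site is taken as centered in the cube); use `occupancy = 0` for
#'   pure bulk.
#' @param thermo A [make_thermo()] object (supplies the estimator's
#'   `rho_bulk` reference).
#' @param n_frames Number of frames of the trajectory to be scored.
#' @param half_extent,voxel_edge,top_fraction Fine-grid parameters matching
#'   [bin_fine_grid()] / [boltzmann_wt()].
#' @param bulk_density Bulk density of the *generated* trajectory (defaults
#'   to the estimator reference `thermo$rho_bulk`).
#' @return Expected WT in kcal/mol.
#' @export
expected_wt <- function(site, thermo = make_thermo(), n_frames,
                        half_extent = 0.5, voxel_edge = 0.005,
                        top_fraction = 0.01, bulk_density = thermo$rho_bulk) {
  occupancy <- site$occupancy %||% 0
  sigma <- site$sigma %||% 0
  d1 <- as.integer(round(2 * half_extent / voxel_edge))
  n <- round(top_fraction * as.numeric(d1)^3)
  dV <- voxel_edge^3
  v_cube <- (2 * half_extent)^3
  f_cube <- if (occupancy > 0) {
    if (sigma > 0) {
      (stats::pnorm(half_extent, 0, sigma) - stats::pnorm(-half_extent, 0, sigma))^3
    } else 1
  } else 0
  M <- n_frames * (occupancy * f_cube + bulk_density * v_cube)
  if (M <= 0) stop_validation("expected in-cube count is zero; WT undefined")
  if (M <= 0.5 * n) {
    S <- M
  } else {
    # dense regime: enumerate expected per-voxel counts and select the top n
    g <- diff(stats::pnorm(seq(-half_extent, half_extent, length.out = d1 + 1L), 0, sigma))
    lam2 <- as.vector(outer(g, g))
    lam <- occupancy * n_frames * as.vector(outer(lam2, g)) +
      n_frames * bulk_density * dV
    S <- sum(sort(lam, decreasing = TRUE)[seq_len(n)])
  }
  -thermo$kT * log(S / (n * n_frames * dV * thermo$rho_bulk))
}

#' Generate pseudo-experimental structures from true site positions
#'
#' Emulates a set of independently determined structures: each structure
#' contains each true site with probability `detect_prob`, displaced by an
#' isotropic Gaussian of width `jitter_sigma`, and shares the same synthetic
#' solute (so superposition is exercised with a known identity answer).
#'
#' @param true_sites n x 3 matrix or data frame of true water positions.
#' @param n_structures Number of pseudo-structures.
#' @param jitter_sigma Coordinate jitter per detection, Angstrom.
#' @param detect_prob Detection probability per site per structure, in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @param solute Shared [solute_structure()] (default [synthetic_solute()]).
#' @param resolution Nominal resolution recorded on each record.
#' @return A list of [structure_record()] objects with ids `SYN01`, `SYN02`,
#'   ...
#' @export
generate_pseudo_structures <- function(true_sites, n_structures = 9L,
                                       jitter_sigma = 0.1, detect_prob = 1,
                                       seed = 1L, solute = synthetic_solute(),
                                       resolution = 1.2) {
  true_sites <- extract_xyz(true_sites, "true sites")
  if (!is.numeric(detect_prob) || detect_prob < 0 || detect_prob > 1) {
    stop_validation("`detect_prob` must be in [0, 1]")
  }
  if (jitter_sigma < 0) stop_validation("`jitter_sigma` must be non-negative")
  n_structures <- as.integer(n_structures)
  if (is.na(n_structures) || n_structures < 1L) {
    stop_validation("`n_structures` must be at least 1")
  }
  solute <- as_solute(solute)
  ns <- nrow(true_sites)
  with_seed(seed, {
    lapply(seq_len(n_structures), function(s) {
      detected <- which(stats::runif(ns) < detect_prob)
      waters <- true_sites[detected, , drop = FALSE]
      if (nrow(waters) && jitter_sigma > 0) {
        waters <- waters + matrix(stats::rnorm(3L * nrow(waters), sd = jitter_sigma),
                                  nrow(waters), 3L)
      }
      structure_record(sprintf("SYN%02d", s), solute, waters, resolution = resolution)
    })
  })
}
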