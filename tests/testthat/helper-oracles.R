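# Shared fixtures and independent brute-force oracles.  The oracles
# deliberately use naive algorithms (triple loops, pairwise enumeration,
# union-find) so they share no code path with the implementation they check.

tiny_solute <- function() synthetic_solute()

# Random points in a box, reproducibly.
random_points <- function(n, lo = -5, hi = 5) {
  matrix(stats::runif(3 * n, lo, hi), n, 3)
}

# --- window-sum oracle: direct triple-loop convolution ---------------------
oracle_window_sums <- function(counts, dims, window) {
  A <- array(counts, dim = dims)
  n_out <- dims - window + 1L
  W <- array(0, n_out)
  for (i in seq_len(n_out[1])) {
    for (j in seq_len(n_out[2])) {
      for (k in seq_len(n_out[3])) {
        W[i, j, k] <- sum(A[i:(i + window - 1L),
                            j:(j + window - 1L),
                            k:(k + window - 1L)])
      }
    }
  }
  W
}

# --- Boltzmann WT oracle: enumerate voxels, sort, sum exponentials ---------
# Works from a sparse (index, count) fine grid exactly as the estimator is
# defined: per-voxel WT(dV) = -kT log(rho/rho_bulk), select the top-n voxels
# by count (ties by index, zero-count voxels pad the selection), then
# WT(V) = -kT log( mean of exp(-WT(dV)/kT) over the selection ).
oracle_boltzmann_wt <- function(voxel_index, count, n_voxels, n_frames, dV,
                                thermo, top_fraction = 0.01) {
  n <- round(top_fraction * n_voxels)
  ord <- order(-count, voxel_index)
  sel_counts <- if (length(count) >= n) count[ord][seq_len(n)] else count
  wt_dv <- -thermo$kT * log((sel_counts / (n_frames * dV)) / thermo$rho_bulk)
  terms <- exp(-wt_dv / thermo$kT)
  # zero-count voxels inside the selection contribute 0
  s <- sum(terms) + 0 * max(0, n - length(sel_counts))
  -thermo$kT * log(s / n)
}

# --- single-linkage components oracle: union-find over all pairs -----------
oracle_components <- function(points, cutoff) {
  n <- nrow(points)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- sqrt(sum((points[i, ] - points[j, ])^2))
      if (d < cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# --- greedy matching oracle: explicit pair enumeration ---------------------
oracle_match <- function(predicted, experimental, cutoff) {
  pairs <- NULL
  for (i in seq_len(nrow(predicted))) {
    for (j in seq_len(nrow(experimental))) {
      d <- sqrt(sum((predicted[i, ] - experimental[j, ])^2))
      if (d <= cutoff) pairs <- rbind(pairs, c(i, j, d))
    }
  }
  tp <- 0L
  assignments <- NULL
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs[, 3], pairs[, 1], pairs[, 2]), , drop = FALSE]
    used_p <- logical(nrow(predicted))
    used_e <- logical(nrow(experimental))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (used_p[i] || used_e[j]) next
      used_p[i] <- TRUE; used_e[j] <- TRUE
      tp <- tp + 1L
      assignments <- rbind(assignments, pairs[r, ])
    }
  }
  list(tp = tp, fp = nrow(predicted) - tp, fn = nrow(experimental) - tp,
       assignments = assignments)
}

# A sparse random fine grid (as if from bin_fine_grid) for estimator checks.
random_fine_grid <- function(n_occupied, n_frames = 1000L, dims1 = 200L,
                             half_extent = 0.5, voxel_edge = 0.005,
                             max_count = 5L) {
  nvox <- as.numeric(dims1)^3
  idx <- sort(sample.int(nvox, n_occupied))
  counts <- sample.int(max_count, n_occupied, replace = TRUE)
  structure(
    list(reference = c(0, 0, 0), half_extent = half_extent,
         voxel_edge = voxel_edge, dims = rep(dims1, 3L), n_voxels = nvox,
         voxel_index = idx - 1, count = counts,
         n_binned = sum(counts), n_frames = n_frames),
    class = "fine_grid"
  )
}

# Random rigid rotation via QR of a Gaussian matrix (det +1).
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
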