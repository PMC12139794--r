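# In-memory containers: solute structures, experimental structure records, and
# water-oxygen trajectories.  Waters are represented solely by their oxygen
# atom throughout.

#' Construct a solute structure
#'
#' A minimal atom-level representation of the fixed solute: coordinates plus
#' the identifiers needed for chain selection and C-alpha pairing.
#'
#' @param xyz n x 3 numeric matrix of atom coordinates (Angstrom).
#' @param elety Atom names (e.g. "CA", "N"); recycled default "C".
#' @param resid Residue names; default "UNK".
#' @param resno Residue numbers; default `seq_len(n)`.
#' @param chain Chain identifiers; default "A".
#' @return An object of class `solute_structure`.
#' @export
solute_structure <- function(xyz, elety = NULL, resid = NULL, resno = NULL,
                             chain = NULL) {
  xyz <- as_points(xyz, "solute coordinates")
  n <- nrow(xyz)
  recycle <- function(v, default) {
    if (is.null(v)) v <- default
    if (length(v) == 1L) v <- rep(v, n)
    if (length(v) != n) stop_validation("atom annotation length does not match coordinates")
    v
  }
  structure(
    list(
      xyz = xyz,
      elety = recycle(elety, "C"),
      resid = recycle(resid, "UNK"),
      resno = recycle(resno, seq_len(n)),
      chain = recycle(chain, "A"),
      natoms = n
    ),
    class = "solute_structure"
  )
}

#' @export
print.solute_structure <- function(x, ...) {
  cat(sprintf("Solute structure: %d atoms, %d chain(s) [%s]\n",
              x$natoms, length(unique(x$chain)),
              paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

# Accept either a solute_structure or a structure_record where a solute is
# needed.
as_solute <- function(x) {
  if (inherits(x, "structure_record")) x <- x$solute
  if (!inherits(x, "solute_structure")) {
    stop_validation("expected a `solute_structure` or `structure_record`")
  }
  if (x$natoms == 0L) stop_validation("solute structure has no atoms")
  x
}

#' Construct an experimental structure record
#'
#' Couples a solute structure with the water-oxygen positions modelled in the
#' same deposition, for consensus analysis across structures.
#'
#' @param id Structure identifier (e.g. a PDB accession); non-empty.
#' @param solute A [solute_structure()].
#' @param waters m x 3 matrix of water-oxygen coordinates (may have 0 rows).
#' @param resolution Reported resolution in Angstrom, or `NA`.
#' @return An object of class `structure_record`.
#' @export
structure_record <- function(id, solute, waters = matrix(numeric(0), 0, 3),
                             resolution = NA_real_) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop_validation("`id` must be a non-empty string")
  }
  waters <- as_points(waters, "water coordinates")
  structure(
    list(id = id, resolution = as.numeric(resolution),
         solute = as_solute(solute), waters = waters),
    class = "structure_record"
  )
}

#' @export
print.structure_record <- function(x, ...) {
  cat(sprintf("Structure %s: %d solute atoms, %d waters%s\n",
              x$id, x$solute$natoms, nrow(x$waters),
              if (is.na(x$resolution)) "" else sprintf(", %.2f A", x$resolution)))
  invisible(x)
}

#' Construct a water-oxygen trajectory
#'
#' Frames of water-oxygen positions expressed in a common, solute-fixed
#' coordinate frame.  Internally the trajectory is stored as one coordinate
#' matrix plus a frame index, which keeps grid accumulation over millions of
#' observations vectorised.
#'
#' @param frames A list of k x 3 coordinate matrices, one per frame (frames
#'   may be empty).
#' @return An object of class `water_trajectory` with elements `coords`
#'   (N x 3), `frame` (integer N), and `n_frames`.
#' @export
water_trajectory <- function(frames) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop_validation("`frames` must be a non-empty list of coordinate matrices")
  }
  frames <- lapply(frames, as_points, what = "frame coordinates")
  counts <- vapply(frames, nrow, integer(1))
  coords <- do.call(rbind, frames)
  if (is.null(coords)) coords <- matrix(numeric(0), 0, 3)
  new_water_trajectory(coords, rep.int(seq_along(frames), counts), length(frames))
}

# Fast internal constructor; inputs assumed consistent.
new_water_trajectory <- function(coords, frame, n_frames) {
  colnames(coords) <- c("x", "y", "z")
  structure(
    list(coords = coords, frame = as.integer(frame), n_frames = as.integer(n_frames)),
    class = "water_trajectory"
  )
}

#' Split a trajectory back into per-frame coordinate matrices
#'
#' @param traj A [water_trajectory()].
#' @return A list of length `n_frames` of k x 3 matrices.
#' @export
trajectory_frames <- function(traj) {
  stopifnot(inherits(traj, "water_trajectory"))
  out <- rep(list(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z")))),
             traj$n_frames)
  if (nrow(traj$coords)) {
    split_idx <- split(seq_len(nrow(traj$coords)), traj$frame)
    for (nm in names(split_idx)) {
      out[[as.integer(nm)]] <- traj$coords[split_idx[[nm]], , drop = FALSE]
    }
  }
  out
}

#' Subsample a trajectory by frame stride
#'
#' @param traj A [water_trajectory()].
#' @param stride Keep every `stride`-th frame starting from the first.
#' @return A [water_trajectory()] with `ceiling(n_frames / stride)` frames.
#' @export
subsample_trajectory <- function(traj, stride = 1L) {
  stopifnot(inherits(traj, "water_trajectory"))
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop_validation("`stride` must be a positive integer")
  if (stride == 1L) return(traj)
  keep <- seq.int(1L, traj$n_frames, by = stride)
  sel <- traj$frame %in% keep
  new_frame <- match(traj$frame[sel], keep)
  new_water_trajectory(traj$coords[sel, , drop = FALSE], new_frame, length(keep))
}

#' @export
print.water_trajectory <- function(x, ...) {
  cat(sprintf("Water trajectory: %d frames, %d water-oxygen observations (mean %.1f/frame)\n",
              x$n_frames, nrow(x$coords), nrow(x$coords) / x$n_frames))
  invisible(x)
}
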