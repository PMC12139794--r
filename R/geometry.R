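# Low-level geometry: point-set distances, rigid (Kabsch) superposition.

# Coerce to an n x 3 numeric matrix with columns x, y, z.
as_points <- function(x, what = "points") {
  if ((is.data.frame(x) || is.matrix(x)) && nrow(x) == 0L) {
    return(matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("x", "y", "z"))))
  }
  if (is.data.frame(x)) {
    cols <- intersect(c("x", "y", "z"), names(x))
    if (length(cols) == 3L) x <- as.matrix(x[, c("x", "y", "z")]) else x <- as.matrix(x)
  }
  if (is.null(dim(x))) {
    if (length(x) == 3L) x <- matrix(as.numeric(x), 1L, 3L)
  }
  if (!is.matrix(x) || ncol(x) != 3L || !is.numeric(x)) {
    stop_validation(sprintf("%s must be an n x 3 numeric matrix", what))
  }
  if (nrow(x) > 0L && any(!is.finite(x))) {
    stop_validation(sprintf("%s contain non-finite coordinates", what))
  }
  colnames(x) <- c("x", "y", "z")
  x
}

# Squared minimum distance from each row of `points` to the point set `ref`.
# Loops over the (smaller) reference set so the work is vectorised over points.
min_sq_dist <- function(points, ref) {
  points <- as_points(points)
  ref <- as_points(ref, "reference atoms")
  if (nrow(ref) == 0L) stop_validation("reference atom set is empty")
  if (nrow(points) == 0L) return(numeric(0))
  best <- rep(Inf, nrow(points))
  for (k in seq_len(nrow(ref))) {
    d2 <- (points[, 1L] - ref[k, 1L])^2 +
          (points[, 2L] - ref[k, 2L])^2 +
          (points[, 3L] - ref[k, 3L])^2
    best <- pmin(best, d2)
  }
  best
}

#' Least-squares rigid superposition of two paired point sets
#'
#' Computes the rotation and translation minimising the RMSD between paired
#' coordinates (the Kabsch algorithm, via singular value decomposition), with
#' the reflection branch excluded so the result is a proper rotation.
#'
#' @param mobile,reference n x 3 coordinate matrices with rows paired
#'   (`mobile[i, ]` corresponds to `reference[i, ]`); n >= 3.
#' @return A `rigid_transform`: list with `rotation` (3 x 3, applied to row
#'   vectors as `x %*% rotation`), `translation` (length 3), `rmsd` of the fit
#'   and `n_atoms`. Apply with [apply_transform()].
#' @seealso [superpose()] for structure-aware atom selection and pairing.
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as_points(mobile, "mobile coordinates")
  reference <- as_points(reference, "reference coordinates")
  if (nrow(mobile) != nrow(reference)) {
    stop_validation("mobile and reference must have the same number of paired atoms")
  }
  if (nrow(mobile) < 3L) {
    stop_validation("superposition needs at least 3 paired atoms")
  }
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(reference, 2L, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  # rank < 2 (collinear or coincident selection) leaves the rotation undefined
  if (sv$d[2L] <= 1e-8 * max(sv$d[1L], 1)) {
    stop("degenerate (collinear) atom selection: superposition is numerically undefined")
  }
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tvec <- cr - drop(cm %*% R)
  rmsd <- sqrt(mean(rowSums((P %*% R - Q)^2)))
  structure(
    list(rotation = R, translation = tvec, rmsd = rmsd, n_atoms = nrow(mobile)),
    class = "rigid_transform"
  )
}

#' Apply a rigid transform to coordinates
#'
#' @param points n x 3 coordinate matrix (rows are points).
#' @param transform A `rigid_transform` from [kabsch()] or [superpose()].
#' @return The transformed n x 3 matrix.
#' @export
apply_transform <- function(points, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  points <- as_points(points)
  if (nrow(points) == 0L) return(points)
  sweep(points %*% transform$rotation, 2L, transform$translation, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("Rigid transform fitted on %d atom pairs, RMSD = %.4f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}
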