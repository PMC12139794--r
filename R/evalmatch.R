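# Predicted-vs-experimental water matching and precision/recall.
#
# Matching is globally greedy: all predicted-experimental pairs within the
# cutoff are sorted by ascending distance and accepted one at a time, each
# water participating in at most one match.  This realises "each predicted
# water is assigned to its closest experimental water, one prediction per
# experimental water" deterministically and independent of input order.

extract_xyz <- function(x, what) {
  if (inherits(x, "hydration_sites")) x <- x$sites
  if (is.data.frame(x)) {
    if (!all(c("x", "y", "z") %in% names(x))) {
      stop_validation(sprintf("%s data frame needs x,y,z columns", what))
    }
    return(cbind(x = x$x, y = x$y, z = x$z))
  }
  as_points(x, what)
}

#' Match predicted waters to experimental waters
#'
#' One-to-one greedy matching by ascending oxygen-oxygen distance within
#' `cutoff` (inclusive: a pair at exactly the cutoff counts).  A true positive
#' is a matched prediction; unmatched predictions are false positives and
#' unmatched experimental waters false negatives, giving
#' `precision = TP/(TP+FP)` and `recall = TP/(TP+FN)`.
#'
#' @param predicted,experimental n x 3 coordinate matrices, data frames with
#'   `x,y,z` columns, or a `hydration_sites` fit.
#' @param cutoff Match distance in Angstrom (default 2.2).
#' @return An object of class `water_match`: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `cutoff`, and `assignments` (data frame `predicted,
#'   experimental, distance`).  Rates are 0 (with a warning) when their
#'   denominator is 0.
#' @examples
#' p <- rbind(c(0, 0, 0), c(0.5, 0, 0))
#' e <- rbind(c(0.2, 0, 0))
#' match_waters(p, e)   # one TP, one FP: one prediction per experimental water
#' @export
match_waters <- function(predicted, experimental, cutoff = 2.2) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop_validation("`cutoff` must be positive")
  p <- extract_xyz(predicted, "predicted")
  e <- extract_xyz(experimental, "experimental")
  np <- nrow(p)
  ne <- nrow(e)
  assignments <- data.frame(predicted = integer(0), experimental = integer(0),
                            distance = numeric(0))
  if (np > 0L && ne > 0L) {
    d2 <- outer(p[, 1L], e[, 1L], "-")^2 +
          outer(p[, 2L], e[, 2L], "-")^2 +
          outer(p[, 3L], e[, 3L], "-")^2
    idx <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(idx)) {
      d <- sqrt(d2[idx])
      ord <- order(d, idx[, 1L], idx[, 2L])
      used_p <- logical(np)
      used_e <- logical(ne)
      keep <- integer(0)
      for (k in ord) {
        i <- idx[k, 1L]; j <- idx[k, 2L]
        if (used_p[i] || used_e[j]) next
        used_p[i] <- TRUE
        used_e[j] <- TRUE
        keep <- c(keep, k)
      }
      assignments <- data.frame(predicted = idx[keep, 1L],
                                experimental = idx[keep, 2L],
                                distance = d[keep])
    }
  }
  tp <- nrow(assignments)
  fp <- np - tp
  fn <- ne - tp
  precision <- if (np > 0L) tp / np else { warning("no predictions: precision set to 0"); 0 }
  recall <- if (ne > 0L) tp / ne else { warning("no experimental waters: recall set to 0"); 0 }
  structure(
    list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
         cutoff = cutoff, n_predicted = np, n_experimental = ne,
         assignments = assignments),
    class = "water_match"
  )
}

#' @export
print.water_match <- function(x, ...) {
  cat(sprintf("Water matching at %.2f A: TP = %d, FP = %d, FN = %d\n",
              x$cutoff, x$tp, x$fp, x$fn))
  cat(sprintf("  precision = %.3f, recall = %.3f\n", x$precision, x$recall))
  invisible(x)
}

#' Precision/recall across WT thresholds or top-k cuts
#'
#' Evaluates [match_waters()] for nested subsets of a ranked site list:
#' either the sites with `wt <= threshold` for each threshold, or the top-k
#' sites for each k.  The site list must be ranked ascending by WT (most
#' favourable first), as produced by [hydration_sites()] or [score_sites()].
#'
#' @param sites A `hydration_sites` fit or data frame with `x,y,z,wt` sorted
#'   ascending by `wt`.
#' @param experimental Experimental water coordinates (matrix or data frame).
#' @param cutoff Match distance in Angstrom.
#' @param thresholds Numeric vector of WT thresholds (kcal/mol); or
#' @param top_k Integer vector of prediction-list depths.  If neither is
#'   given, every depth `1..n` is evaluated.
#' @return A data frame with one row per evaluation: `threshold` or `k`,
#'   `n_predicted`, `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
precision_recall_curve <- function(sites, experimental, cutoff = 2.2,
                                   thresholds = NULL, top_k = NULL) {
  if (inherits(sites, "hydration_sites")) sites <- sites$sites
  if (!is.data.frame(sites) || !all(c("x", "y", "z", "wt") %in% names(sites))) {
    stop_validation("`sites` must be a data frame with x,y,z,wt columns")
  }
  if (is.unsorted(sites$wt)) {
    stop_validation("`sites` must be ranked ascending by wt (most favourable first)")
  }
  e <- extract_xyz(experimental, "experimental")
  n <- nrow(sites)
  if (!is.null(thresholds) && !is.null(top_k)) {
    stop_validation("give either `thresholds` or `top_k`, not both")
  }
  by_threshold <- !is.null(thresholds)
  if (is.null(thresholds) && is.null(top_k)) top_k <- seq_len(n)
  cuts <- if (by_threshold) sort(thresholds) else sort(unique(as.integer(top_k)))
  rows <- lapply(cuts, function(v) {
    k <- if (by_threshold) sum(sites$wt <= v) else min(v, n)
    sub <- sites[seq_len(k), , drop = FALSE]
    m <- suppressWarnings(match_waters(sub, e, cutoff = cutoff))
    data.frame(threshold = if (by_threshold) v else NA_real_,
               k = if (by_threshold) NA_integer_ else v,
               n_predicted = k, tp = m$tp, fp = m$fp, fn = m$fn,
               precision = m$precision, recall = m$recall)
  })
  do.call(rbind, rows)
}
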