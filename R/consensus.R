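# Consensus analysis of experimentally modelled waters across structures:
# superpose each structure onto a reference, pool all waters near a chosen
# protomer, single-linkage cluster them, keep first-shell clusters, and
# classify each cluster as high- or lower-consensus by how many distinct
# structures contributed to it.

#' Superpose one structure onto another
#'
#' Selects paired atoms (by default the C-alpha atoms of one chain, paired by
#' residue number) and computes the least-squares rigid transform mapping the
#' mobile structure onto the reference frame.
#'
#' @param mobile,reference [solute_structure()] or [structure_record()]
#'   objects.
#' @param selection `"calpha"` (default) or `"all"` (pairs atoms by position
#'   in the chain-filtered atom list; requires equal atom counts).
#' @param mobile_chain,reference_chain Chain IDs used for the selection;
#'   default the first chain of each structure.
#' @return A `rigid_transform` (see [kabsch()]) carrying the fit RMSD.
#'   Apply it to the mobile structure's waters with [apply_transform()] to
#'   express them in the reference frame.
#' @export
superpose <- function(mobile, reference, selection = c("calpha", "all"),
                      mobile_chain = NULL, reference_chain = NULL) {
  selection <- match.arg(selection)
  mobile <- as_solute(mobile)
  reference <- as_solute(reference)
  if (is.null(mobile_chain)) mobile_chain <- mobile$chain[1L]
  if (is.null(reference_chain)) reference_chain <- reference$chain[1L]
  mi <- which(mobile$chain == mobile_chain)
  ri <- which(reference$chain == reference_chain)
  if (selection == "calpha") {
    mi <- mi[mobile$elety[mi] == "CA"]
    ri <- ri[reference$elety[ri] == "CA"]
    common <- intersect(mobile$resno[mi], reference$resno[ri])
    mi <- mi[match(common, mobile$resno[mi])]
    ri <- ri[match(common, reference$resno[ri])]
  } else {
    if (length(mi) != length(ri)) {
      stop_validation("selection \"all\" requires equal atom counts in both chains")
    }
  }
  if (length(mi) < 3L) {
    stop_validation(sprintf("only %d paired atoms after selection; need at least 3", length(mi)))
  }
  kabsch(mobile$xyz[mi, , drop = FALSE], reference$xyz[ri, , drop = FALSE])
}

#' Pool waters from several structures around a reference protomer
#'
#' Superposes every record onto the reference, maps its waters into the
#' reference frame, and keeps those whose minimum distance to any atom of the
#' reference protomer is at most `shell` (default 4 Angstrom).  Provenance
#' (source structure id) is retained for consensus counting.
#'
#' @param records List of [structure_record()] objects.
#' @param reference A [structure_record()] defining the target frame.
#' @param shell Aggregation shell around the reference protomer, Angstrom.
#' @param selection,reference_chain Passed to [superpose()]; the reference
#'   protomer is the `reference_chain` (default: first chain) of `reference`.
#' @return A data frame with columns `structure, x, y, z`, one row per
#'   retained water.
#' @export
aggregate_waters <- function(records, reference, shell = 4.0,
                             selection = "calpha", reference_chain = NULL) {
  if (inherits(records, "structure_record")) records <- list(records)
  stopifnot(inherits(reference, "structure_record"))
  ref_sol <- reference$solute
  if (is.null(reference_chain)) reference_chain <- ref_sol$chain[1L]
  prot_idx <- which(ref_sol$chain == reference_chain)
  if (length(prot_idx) == 0L) {
    stop_validation(sprintf("reference has no atoms in chain %s", reference_chain))
  }
  prot_xyz <- ref_sol$xyz[prot_idx, , drop = FALSE]
  out <- lapply(records, function(rec) {
    stopifnot(inherits(rec, "structure_record"))
    if (nrow(rec$waters) == 0L) return(NULL)
    tf <- superpose(rec$solute, ref_sol, selection = selection,
                    reference_chain = reference_chain)
    w <- apply_transform(rec$waters, tf)
    keep <- min_sq_dist(w, prot_xyz) <= shell^2
    if (!any(keep)) return(NULL)
    data.frame(structure = rec$id, x = w[keep, 1L], y = w[keep, 2L], z = w[keep, 3L])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(structure = character(0), x = numeric(0),
                      y = numeric(0), z = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Single-linkage clustering of pooled water positions
#'
#' Connects every pair of waters strictly less than `link_cutoff` apart
#' (default 1 Angstrom) and takes the connected components as clusters.  Each
#' cluster records its arithmetic mean position and the number of distinct
#' source structures contributing to it (which, not the raw member count, is
#' the consensus size: one structure can contribute two nearby waters).
#'
#' @param waters Data frame with columns `structure, x, y, z` (from
#'   [aggregate_waters()]), or an n x 3 matrix (all waters then count as one
#'   structure).
#' @param link_cutoff Linkage distance in Angstrom; pairs at exactly
#'   `link_cutoff` are *not* connected.
#' @return An object of class `consensus_clusters`: list with `clusters`
#'   (data frame `cluster, x, y, z, n_structures, n_members,
#'   consensus_class`), `members` (data frame `cluster, structure, x, y, z`)
#'   and the parameters used.
#' @export
cluster_waters <- function(waters, link_cutoff = 1.0) {
  if (is.matrix(waters)) {
    waters <- data.frame(structure = "S1", x = waters[, 1L],
                         y = waters[, 2L], z = waters[, 3L])
  }
  stopifnot(is.data.frame(waters), all(c("structure", "x", "y", "z") %in% names(waters)))
  if (!is.numeric(link_cutoff) || link_cutoff <= 0) {
    stop_validation("`link_cutoff` must be positive")
  }
  n <- nrow(waters)
  if (n == 0L) {
    return(new_consensus_clusters(
      clusters = data.frame(cluster = integer(0), x = numeric(0), y = numeric(0),
                            z = numeric(0), n_structures = integer(0),
                            n_members = integer(0), consensus_class = character(0)),
      members = data.frame(cluster = integer(0), structure = character(0),
                           x = numeric(0), y = numeric(0), z = numeric(0)),
      link_cutoff = link_cutoff
    ))
  }
  m <- as.matrix(waters[, c("x", "y", "z")])
  if (any(!is.finite(m))) stop_validation("water coordinates must be finite")
  adj <- as.matrix(stats::dist(m)) < link_cutoff   # strict "<"
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  membership <- igraph::components(g)$membership
  # renumber components in order of first appearance for determinism
  membership <- match(membership, unique(membership))

  sums <- rowsum(m, membership)
  sizes <- as.vector(table(membership))
  means <- sums / sizes
  nstruct <- vapply(split(as.character(waters$structure), membership),
                    function(s) length(unique(s)), integer(1))
  clusters <- data.frame(
    cluster = seq_len(nrow(means)),
    x = means[, 1L], y = means[, 2L], z = means[, 3L],
    n_structures = as.integer(nstruct),
    n_members = as.integer(sizes),
    consensus_class = NA_character_
  )
  members <- data.frame(cluster = membership, structure = as.character(waters$structure),
                        x = m[, 1L], y = m[, 2L], z = m[, 3L])
  members <- members[order(members$cluster), , drop = FALSE]
  rownames(members) <- NULL
  new_consensus_clusters(clusters, members, link_cutoff)
}

new_consensus_clusters <- function(clusters, members, link_cutoff,
                                   first_shell = NULL, high_threshold = NULL,
                                   n_aggregated = NULL) {
  structure(
    list(clusters = clusters, members = members, link_cutoff = link_cutoff,
         first_shell = first_shell, high_threshold = high_threshold,
         n_aggregated = n_aggregated),
    class = "consensus_clusters"
  )
}

#' Keep clusters whose mean position lies in the first hydration shell
#'
#' Discards clusters whose mean position is more than `cutoff` (default 3.25
#' Angstrom, the first hydration shell) from every solute atom; a mean at
#' exactly the cutoff is kept.
#'
#' @param clusters A `consensus_clusters` object.
#' @param solute A [solute_structure()] or [structure_record()].
#' @param cutoff First-shell distance in Angstrom.
#' @return The filtered `consensus_clusters` object.
#' @export
filter_first_shell <- function(clusters, solute, cutoff = 3.25) {
  stopifnot(inherits(clusters, "consensus_clusters"))
  solute <- as_solute(solute)
  cl <- clusters$clusters
  if (nrow(cl) > 0L) {
    d2 <- min_sq_dist(as.matrix(cl[, c("x", "y", "z")]), solute$xyz)
    keep <- d2 <= cutoff^2
    kept_ids <- cl$cluster[keep]
    cl <- cl[keep, , drop = FALSE]
    clusters$members <- clusters$members[clusters$members$cluster %in% kept_ids, , drop = FALSE]
    # renumber 1..k preserving order
    remap <- stats::setNames(seq_along(kept_ids), kept_ids)
    cl$cluster <- as.integer(remap[as.character(cl$cluster)])
    clusters$members$cluster <- as.integer(remap[as.character(clusters$members$cluster)])
    rownames(cl) <- NULL
    rownames(clusters$members) <- NULL
  }
  clusters$clusters <- cl
  clusters$first_shell <- cutoff
  clusters
}

#' Classify clusters as high- or lower-consensus
#'
#' A cluster observed in `high_threshold` or more distinct structures
#' (default 5) is high-consensus; clusters seen in fewer structures are
#' lower-consensus.
#'
#' @param clusters A `consensus_clusters` object.
#' @param high_threshold Minimum number of distinct structures for the
#'   high-consensus class; at least 1.
#' @return The `consensus_clusters` object with `consensus_class` filled in.
#' @export
classify_consensus <- function(clusters, high_threshold = 5L) {
  stopifnot(inherits(clusters, "consensus_clusters"))
  high_threshold <- as.integer(high_threshold)
  if (is.na(high_threshold) || high_threshold < 1L) {
    stop_validation("`high_threshold` must be a positive integer")
  }
  cl <- clusters$clusters
  cl$consensus_class <- ifelse(cl$n_structures >= high_threshold, "high", "lower")
  clusters$clusters <- cl
  clusters$high_threshold <- high_threshold
  clusters
}

#' Consensus water analysis across superposed structures
#'
#' End-to-end wrapper: superpose every record onto the reference, pool waters
#' within `shell` of the reference protomer, single-linkage cluster at
#' `link_cutoff`, keep clusters whose mean lies within `first_shell` of the
#' solute, and classify high/lower consensus at `high_threshold` structures.
#'
#' @param records List of [structure_record()] objects.
#' @param reference Reference [structure_record()]; default the first record.
#' @param shell Aggregation shell (Angstrom).
#' @param link_cutoff Single-linkage cutoff (strict, Angstrom).
#' @param first_shell First-hydration-shell cutoff (inclusive, Angstrom).
#' @param high_threshold Structures needed for the high-consensus class.
#' @param selection,reference_chain Superposition atom selection, see
#'   [superpose()].
#' @param verbose Log stage counts via `message()`.
#' @return A classified `consensus_clusters` object.
#' @examples
#' recs <- generate_pseudo_structures(
#'   true_sites = rbind(c(4.3, 0, 0), c(0, 4.3, 0)),
#'   n_structures = 9, jitter_sigma = 0.1, detect_prob = 1, seed = 7)
#' cw <- consensus_waters(recs)
#' cw$clusters
#' @export
consensus_waters <- function(records, reference = records[[1L]], shell = 4.0,
                             link_cutoff = 1.0, first_shell = 3.25,
                             high_threshold = 5L, selection = "calpha",
                             reference_chain = NULL, verbose = FALSE) {
  if (length(records) == 0L) stop_validation("need at least one structure record")
  pooled <- aggregate_waters(records, reference, shell = shell,
                             selection = selection, reference_chain = reference_chain)
  if (verbose) message(sprintf("aggregated %d waters from %d structures within %.2f A",
                               nrow(pooled), length(records), shell))
  cl <- cluster_waters(pooled, link_cutoff = link_cutoff)
  if (verbose) message(sprintf("%d clusters at %.2f A single linkage", nrow(cl$clusters), link_cutoff))
  ref_sol <- as_solute(reference)
  if (is.null(reference_chain)) reference_chain <- ref_sol$chain[1L]
  prot <- which(ref_sol$chain == reference_chain)
  prot_struct <- solute_structure(ref_sol$xyz[prot, , drop = FALSE],
                                  elety = ref_sol$elety[prot], resid = ref_sol$resid[prot],
                                  resno = ref_sol$resno[prot], chain = ref_sol$chain[prot])
  cl <- filter_first_shell(cl, prot_struct, cutoff = first_shell)
  if (verbose) message(sprintf("%d clusters within the %.2f A first shell",
                               nrow(cl$clusters), first_shell))
  cl <- classify_consensus(cl, high_threshold = high_threshold)
  cl$n_aggregated <- nrow(pooled)
  cl$n_structures_in <- length(records)
  cl
}

#' @export
print.consensus_clusters <- function(x, ...) {
  cl <- x$clusters
  cat(sprintf("Consensus water clusters: %d cluster(s)", nrow(cl)))
  if (!is.null(x$n_aggregated)) cat(sprintf(" from %d pooled waters", x$n_aggregated))
  cat("\n")
  if (nrow(cl) && !all(is.na(cl$consensus_class))) {
    n_high <- sum(cl$consensus_class == "high", na.rm = TRUE)
    n_lower <- sum(cl$consensus_class == "lower", na.rm = TRUE)
    cat(sprintf("  high-consensus: %d, lower-consensus: %d (threshold: >= %s structures)\n",
                n_high, n_lower, x$high_threshold %||% "?"))
  }
  invisible(x)
}

#' @export
summary.consensus_clusters <- function(object, ...) {
  cl <- object$clusters
  out <- list(
    n_clusters = nrow(cl),
    size_distribution = table(factor(cl$n_structures)),
    class_counts = table(cl$consensus_class, useNA = "ifany"),
    n_aggregated = object$n_aggregated
  )
  class(out) <- "summary.consensus_clusters"
  out
}

#' @export
print.summary.consensus_clusters <- function(x, ...) {
  cat(sprintf("Consensus clustering of %s pooled waters -> %d clusters\n",
              x$n_aggregated %||% "?", x$n_clusters))
  cat("Cluster sizes (distinct structures):\n")
  print(x$size_distribution)
  cat("Classes:\n")
  print(x$class_counts)
  invisible(x)
}

#' @export
as.data.frame.consensus_clusters <- function(x, ...) x$clusters

#' @export
plot.consensus_clusters <- function(x, ...) {
  cl <- x$clusters
  if (nrow(cl) == 0L) {
    stop_validation("no clusters to plot")
  }
  tab <- table(factor(cl$n_structures, levels = seq_len(max(cl$n_structures))))
  cols <- if (!is.null(x$high_threshold)) {
    ifelse(as.integer(names(tab)) >= x$high_threshold, "firebrick", "steelblue")
  } else "grey"
  graphics::barplot(tab, col = cols,
                    xlab = "structures per cluster",
                    ylab = "number of clusters",
                    main = "Consensus water cluster sizes", ...)
  invisible(x)
}

#' Write consensus clusters to CSV and/or a PDB of cluster means
#'
#' The CSV carries mean position, structure count and class per cluster (plus
#' a member table alongside); the PDB writes one oxygen per cluster mean with
#' the number of contributing structures in the occupancy column.
#'
#' @param clusters A `consensus_clusters` object.
#' @param csv,pdb Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_clusters <- function(clusters, csv = NULL, pdb = NULL) {
  stopifnot(inherits(clusters, "consensus_clusters"))
  cl <- clusters$clusters
  written <- character(0)
  if (!is.null(csv)) {
    utils::write.csv(cl, csv, row.names = FALSE)
    member_path <- sub("\\.csv$", "_members.csv", csv, ignore.case = TRUE)
    utils::write.csv(clusters$members, member_path, row.names = FALSE)
    written <- c(written, csv, member_path)
  }
  if (!is.null(pdb)) {
    out <- tryCatch(file(pdb, "w"), error = function(e) stop_io(conditionMessage(e)))
    if (nrow(cl)) {
      lines <- vapply(seq_len(nrow(cl)), function(i) {
        format_pdb_atom("HETATM", i, "O", "HOH", "A", i,
                        c(cl$x[i], cl$y[i], cl$z[i]),
                        occ = cl$n_structures[i], b = 0, element = "O")
      }, character(1))
      writeLines(lines, out)
    }
    writeLines("END", out)
    close(out)
    written <- c(written, pdb)
  }
  invisible(written)
}
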