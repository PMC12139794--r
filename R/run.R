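# File-in / file-out orchestration used by the command-line interface.
# Each run_* function reads standard formats, calls the corresponding
# in-memory pipeline, writes its primary outputs to files, and logs progress
# via message() (stderr) so stdout stays clean.

#' Run the consensus-water pipeline on structure files
#'
#' @param structure_paths Character vector of PDB/mmCIF paths.
#' @param reference_path Path of the reference structure (defaults to the
#'   first of `structure_paths`).
#' @param out_prefix Output prefix; writes `<prefix>_clusters.csv`,
#'   `<prefix>_clusters_members.csv` and `<prefix>_clusters.pdb`.
#' @param config Configuration list, see [default_config()].
#' @return The classified `consensus_clusters` object, invisibly.
#' @export
run_consensus <- function(structure_paths, reference_path = structure_paths[1L],
                          out_prefix = "consensus", config = default_config()) {
  config <- validate_config(config)
  if (length(structure_paths) < 1L) stop_validation("need at least one structure file")
  records <- lapply(structure_paths, read_structure)
  reference <- if (reference_path %in% structure_paths) {
    records[[match(reference_path, structure_paths)]]
  } else {
    read_structure(reference_path)
  }
  cw <- consensus_waters(records, reference,
                         shell = config$shell_aggregate,
                         link_cutoff = config$link_cutoff,
                         first_shell = config$first_shell,
                         high_threshold = config$high_threshold,
                         verbose = TRUE)
  write_clusters(cw, csv = paste0(out_prefix, "_clusters.csv"),
                 pdb = paste0(out_prefix, "_clusters.pdb"))
  message(sprintf("wrote %s_clusters.{csv,pdb}", out_prefix))
  invisible(cw)
}

#' Run hydration-site prediction on a trajectory and solute file
#'
#' @param trajectory_path Multi-model PDB or XYZ water trajectory.
#' @param solute_path PDB/mmCIF of the fixed solute.
#' @param out_prefix Output prefix; writes `<prefix>_sites.csv`,
#'   `<prefix>_sites.pdb` (WT in the B-factor column) and
#'   `<prefix>_runlog.json`.
#' @param config Configuration list, see [default_config()].
#' @return The `hydration_sites` fit, invisibly.
#' @export
run_predict <- function(trajectory_path, solute_path, out_prefix = "predicted",
                        config = default_config()) {
  config <- validate_config(config)
  record <- read_structure(solute_path)
  traj <- read_trajectory(trajectory_path, stride = config$stride)
  if (nrow(traj$coords) == 0L) stop_validation("trajectory contains no waters")
  fit <- hydration_sites(traj, record, config = merge_config(config, list(stride = 1L)),
                         verbose = TRUE)
  write_sites(fit, paste0(out_prefix, "_sites.csv"), format = "csv")
  write_sites(fit, paste0(out_prefix, "_sites.pdb"), format = "pdb")
  log <- list(
    tool = "watsite", version = as.character(utils::packageVersion("watsite")),
    trajectory = trajectory_path, solute = solute_path,
    n_frames = fit$n_frames, n_first_shell_observations = fit$n_binned,
    n_sites = nrow(fit$sites),
    config = config[setdiff(names(config), character(0))]
  )
  jsonlite::write_json(log, paste0(out_prefix, "_runlog.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("wrote %s_sites.{csv,pdb} and %s_runlog.json", out_prefix, out_prefix))
  invisible(fit)
}

#' Evaluate predicted sites against experimental waters
#'
#' @param predicted_path Predicted-site table (CSV from [write_sites()]) or a
#'   PDB of predicted waters.
#' @param experimental_path PDB (waters as HOH oxygens) or CSV of
#'   experimental positions.
#' @param out_prefix Output prefix; writes `<prefix>_match.csv`,
#'   `<prefix>_assignments.csv` and, when WT values are present,
#'   `<prefix>_curve.csv` (precision/recall versus list depth).
#' @param config Configuration list, see [default_config()].
#' @return The `water_match` report, invisibly.
#' @export
run_evaluate <- function(predicted_path, experimental_path, out_prefix = "evaluation",
                         config = default_config()) {
  config <- validate_config(config)
  predicted <- read_sites(predicted_path)
  experimental <- read_sites(experimental_path)
  m <- match_waters(predicted, experimental, cutoff = config$match_cutoff)
  message(sprintf("matched %d/%d predictions to %d experimental waters (precision %.3f, recall %.3f)",
                  m$tp, m$n_predicted, m$n_experimental, m$precision, m$recall))
  utils::write.csv(
    data.frame(tp = m$tp, fp = m$fp, fn = m$fn, precision = m$precision,
               recall = m$recall, cutoff = m$cutoff,
               n_predicted = m$n_predicted, n_experimental = m$n_experimental),
    paste0(out_prefix, "_match.csv"), row.names = FALSE)
  utils::write.csv(m$assignments, paste0(out_prefix, "_assignments.csv"),
                   row.names = FALSE)
  if ("wt" %in% names(predicted) && nrow(predicted) > 1L &&
      !any(is.na(predicted$wt))) {
    predicted <- predicted[order(predicted$wt), , drop = FALSE]
    curve <- precision_recall_curve(predicted, experimental,
                                    cutoff = config$match_cutoff)
    utils::write.csv(curve, paste0(out_prefix, "_curve.csv"), row.names = FALSE)
  }
  invisible(m)
}

#' Generate synthetic inputs from a specification file
#'
#' Reads a YAML synthetic specification (keys `sites` - a list of
#' `x,y,z,occupancy,sigma` maps -, `box` as `[xmin, ymin, zmin, xmax, ymax,
#' zmax]`, `bulk_density`, `n_frames`, `seed`, and optionally `pseudo` with
#' `n_structures`, `jitter_sigma`, `detect_prob`), writes the trajectory and
#' any pseudo-structures, and prints the ground-truth site table.
#'
#' @param spec A [synthetic_spec()], or the path to a YAML spec file.
#' @param out_dir Output directory (created if missing).
#' @param pseudo Optional list with `n_structures`, `jitter_sigma`,
#'   `detect_prob` (overrides the file's `pseudo` block).
#' @return Invisibly, a list of the files written.
#' @export
run_simulate <- function(spec, out_dir = ".", pseudo = NULL) {
  if (is.character(spec)) {
    parsed <- read_synthetic_spec(spec)
    spec <- parsed$spec
    if (is.null(pseudo)) pseudo <- parsed$pseudo
  }
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  traj <- generate_trajectory(spec)
  traj_path <- file.path(out_dir, "trajectory.xyz")
  write_trajectory(traj, traj_path)
  truth_path <- file.path(out_dir, "truth.csv")
  utils::write.csv(spec$sites, truth_path, row.names = FALSE)
  files <- c(traj_path, truth_path)
  if (!is.null(spec$solute)) {
    solute_path <- file.path(out_dir, "solute.pdb")
    write_structure(structure_record("SOLUTE", spec$solute), solute_path)
    files <- c(files, solute_path)
  }
  if (!is.null(pseudo)) {
    recs <- generate_pseudo_structures(
      spec$sites, n_structures = pseudo$n_structures %||% 9L,
      jitter_sigma = pseudo$jitter_sigma %||% 0.1,
      detect_prob = pseudo$detect_prob %||% 1,
      seed = spec$seed + 1L,
      solute = spec$solute %||% synthetic_solute())
    for (r in recs) {
      p <- file.path(out_dir, paste0(tolower(r$id), ".pdb"))
      write_structure(r, p)
      files <- c(files, p)
    }
  }
  message(sprintf("simulated %d frames (%d water observations) -> %s",
                  traj$n_frames, nrow(traj$coords), traj_path))
  cat("Ground-truth sites:\n")
  print(spec$sites)
  invisible(files)
}

read_synthetic_spec <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("spec file not found: %s", path))
  vals <- tryCatch(yaml::read_yaml(path),
                   error = function(e) stop_format(sprintf("cannot parse spec %s: %s",
                                                           path, conditionMessage(e))))
  sites <- if (length(vals$sites)) {
    do.call(rbind, lapply(vals$sites, function(s) {
      # YAML 1.1 parses a bare `y` key as boolean TRUE; map it back
      names(s)[names(s) == "TRUE"] <- "y"
      missing <- setdiff(c("x", "y", "z", "occupancy", "sigma"), names(s))
      if (length(missing)) {
        stop_format(sprintf("site entry lacks key(s): %s", paste(missing, collapse = ", ")))
      }
      as.data.frame(s[c("x", "y", "z", "occupancy", "sigma")])
    }))
  } else NULL
  box <- as.numeric(vals$box)
  if (length(box) != 6L) stop_format("spec `box` must be [xmin, ymin, zmin, xmax, ymax, zmax]")
  spec <- synthetic_spec(
    sites, box = rbind(box[1:3], box[4:6]),
    bulk_density = vals$bulk_density %||% 0.033,
    n_frames = vals$n_frames %||% stop_format("spec needs `n_frames`"),
    seed = vals$seed %||% 1L,
    solute = if (isTRUE(vals$solute)) synthetic_solute() else NULL
  )
  list(spec = spec, pseudo = vals$pseudo)
}
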