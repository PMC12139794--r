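# Run configuration: every tunable of the pipeline with its standard default.

#' Default pipeline configuration
#'
#' Returns the full set of tunables with their standard defaults:
#' \describe{
#'   \item{shell_predict}{3.25 A - first-hydration-shell cutoff for coarse-grid
#'     accumulation and site membership.}
#'   \item{shell_aggregate}{4.0 A - shell for pooling experimental waters
#'     around the reference protomer.}
#'   \item{coarse_voxel}{0.1 A - coarse voxel edge.}
#'   \item{window}{10 - sliding-cube side in coarse voxels (1 A cube).}
#'   \item{min_separation}{2.25 A - minimum distance between accepted cubes.}
#'   \item{min_solute_dist}{2.25 A - minimum cube-center-to-solute distance.}
#'   \item{fine_voxel}{0.005 A - fine voxel edge.}
#'   \item{half_extent}{0.5 A - fine-grid half extent (1 A cube, 8e6 voxels).}
#'   \item{top_fraction}{0.01 - fraction of fine voxels in the Boltzmann
#'     average (80,000 voxels).}
#'   \item{link_cutoff}{1.0 A - single-linkage cutoff (strict) for consensus
#'     clustering.}
#'   \item{first_shell}{3.25 A - cluster-mean first-shell filter.}
#'   \item{high_threshold}{5 - structures needed for high consensus.}
#'   \item{match_cutoff}{2.2 A - predicted/experimental match distance.}
#'   \item{temperature}{300 K.}
#'   \item{rho_bulk}{0.033 A^-3 - bulk water number density.}
#'   \item{stride}{1 - trajectory frame stride.}
#'   \item{seed}{1 - RNG seed for synthetic generation.}
#'   \item{max_sites}{Inf - cap on the number of reported sites.}
#' }
#'
#' @return A named list of class `watsite_config`.
#' @export
default_config <- function() {
  structure(
    list(
      shell_predict = 3.25,
      shell_aggregate = 4.0,
      coarse_voxel = 0.1,
      window = 10L,
      min_separation = 2.25,
      min_solute_dist = 2.25,
      fine_voxel = 0.005,
      half_extent = 0.5,
      top_fraction = 0.01,
      link_cutoff = 1.0,
      first_shell = 3.25,
      high_threshold = 5L,
      match_cutoff = 2.2,
      temperature = 300,
      rho_bulk = 0.033,
      stride = 1L,
      seed = 1L,
      max_sites = Inf
    ),
    class = "watsite_config"
  )
}

validate_config <- function(config) {
  numeric_keys <- setdiff(names(default_config()), character(0))
  for (key in numeric_keys) {
    v <- config[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop_validation(sprintf("config entry `%s` must be a single positive number", key))
    }
  }
  if (config$top_fraction > 1) stop_validation("config entry `top_fraction` must be <= 1")
  config
}

#' Merge configuration overrides
#'
#' @param config A configuration list from [default_config()] or
#'   [read_config()].
#' @param overrides Named list of entries to replace; unknown names are an
#'   error.
#' @return The merged, validated configuration.
#' @export
merge_config <- function(config, overrides = list()) {
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(default_config()))
    if (length(unknown)) {
      stop_validation(sprintf("unknown config entr%s: %s",
                              if (length(unknown) > 1) "ies" else "y",
                              paste(unknown, collapse = ", ")))
    }
    for (nm in names(overrides)) {
      v <- overrides[[nm]]
      if (nm %in% c("window", "high_threshold", "stride", "seed")) v <- as.integer(v)
      config[[nm]] <- v
    }
  }
  validate_config(config)
}

#' Read a configuration file
#'
#' A flat YAML mapping of configuration keys (see [default_config()]) to
#' values; unspecified keys keep their defaults.
#'
#' @param path Path to the YAML file.
#' @param defaults Base configuration to override.
#' @return The merged configuration list.
#' @export
read_config <- function(path, defaults = default_config()) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
  vals <- tryCatch(yaml::read_yaml(path),
                   error = function(e) stop_format(sprintf("cannot parse config %s: %s",
                                                           path, conditionMessage(e))))
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop_format(sprintf("config %s is not a flat key/value mapping", path))
  merge_config(defaults, vals)
}
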