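# File formats: PDB / mmCIF structures (via bio3d), multi-model PDB and XYZ
# water trajectories, and CSV/PDB site tables.  Coordinates are Angstrom
# throughout; PDB is the canonical interchange format.

# Residue names treated as water, and as monoatomic/common ions (excluded from
# both solute and waters).
.default_water_resnames <- c("HOH", "WAT", "SOL", "TIP3")
.ion_resnames <- c(
  "NA", "CL", "K", "MG", "ZN", "CA", "MN", "FE", "CU", "NI", "CO", "CD",
  "IOD", "BR", "F", "LI", "RB", "CS", "SR", "BA", "NA+", "CL-", "SO4", "PO4"
)

is_hydrogen <- function(elety, elesy = NULL) {
  if (!is.null(elesy) && any(nzchar(elesy), na.rm = TRUE)) {
    h <- !is.na(elesy) & toupper(trimws(elesy)) == "H"
    # fall through to name-based detection where the element column is blank
    blank <- is.na(elesy) | !nzchar(trimws(elesy))
    h[blank] <- grepl("^[0-9]*H", trimws(elety[blank]))
    return(h)
  }
  grepl("^[0-9]*H", trimws(elety))
}

parse_pdb_resolution <- function(path) {
  head_lines <- tryCatch(readLines(path, n = 500L, warn = FALSE), error = function(e) character(0))
  hit <- grep("^REMARK   2 RESOLUTION\\.", head_lines, value = TRUE)
  if (length(hit)) {
    val <- suppressWarnings(as.numeric(sub(".*RESOLUTION\\.\\s*([0-9.]+).*", "\\1", hit[1])))
    if (is.finite(val)) return(val)
  }
  NA_real_
}

#' Read a structure file into a structure record
#'
#' Parses a PDB or mmCIF file, splitting atoms into the solute (all non-water,
#' non-ion heavy atoms of the selected chains) and the water-oxygen positions.
#' Alternate locations other than blank or 'A' are dropped, so each atom
#' appears once.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param water_residue_names Residue names recognised as water.
#' @param chain_filter Optional character vector of chain IDs to keep.
#' @param id Record identifier; defaults to the file name without extension.
#' @return A [structure_record()].
#' @export
read_structure <- function(path, water_residue_names = .default_water_resnames,
                           chain_filter = NULL, id = NULL) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop_format(sprintf("cannot parse %s: %s", path, conditionMessage(e))),
    warning = function(w) stop_format(sprintf("cannot parse %s: %s", path, conditionMessage(w)))
  )
  atoms <- pdb$atom
  if (is.null(atoms) || nrow(atoms) == 0L) stop_format(sprintf("no atoms parsed from %s", path))

  alt <- atoms$alt
  keep_alt <- is.na(alt) | alt %in% c("", "A")
  atoms <- atoms[keep_alt, , drop = FALSE]
  if (!is.null(chain_filter)) {
    atoms <- atoms[atoms$chain %in% chain_filter, , drop = FALSE]
  }

  resid <- toupper(trimws(atoms$resid))
  elety <- trimws(atoms$elety)
  is_water <- resid %in% toupper(water_residue_names)
  is_ion <- resid %in% .ion_resnames
  is_h <- is_hydrogen(elety, atoms$elesy)

  wat <- atoms[is_water & !is_h & grepl("^O", elety), , drop = FALSE]
  waters <- as.matrix(wat[, c("x", "y", "z")])

  sol <- atoms[!is_water & !is_ion & !is_h, , drop = FALSE]
  if (nrow(sol) == 0L) {
    stop_validation(sprintf("no solute atoms left in %s after filtering", path))
  }
  solute <- solute_structure(
    as.matrix(sol[, c("x", "y", "z")]),
    elety = trimws(sol$elety), resid = trimws(sol$resid),
    resno = sol$resno, chain = sol$chain
  )
  if (is.null(id)) id <- sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  structure_record(id, solute, waters,
                   resolution = if (is_cif) NA_real_ else parse_pdb_resolution(path))
}

#' Read a water-oxygen trajectory
#'
#' Supports multi-model PDB (one frame per MODEL; water-oxygen atoms selected
#' by residue name) and XYZ (one frame per block; only oxygen entries are
#' kept).  Frame order is preserved; `stride` keeps every `stride`-th frame
#' starting from the first.
#'
#' @param path Path to the trajectory file.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @param stride Frame subsampling stride (default 1 = all frames).
#' @param water_residue_names Residue names recognised as water (PDB only).
#' @return A [water_trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz"), stride = 1L,
                            water_residue_names = .default_water_resnames) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  traj <- if (format == "pdb") read_trajectory_pdb(path, water_residue_names)
          else read_trajectory_xyz(path)
  subsample_trajectory(traj, stride)
}

read_trajectory_pdb <- function(path, water_residue_names) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop_format(sprintf("cannot parse %s: %s", path, conditionMessage(e))),
    warning = function(w) stop_format(sprintf("cannot parse %s: %s", path, conditionMessage(w)))
  )
  atoms <- pdb$atom
  resid <- toupper(trimws(atoms$resid))
  elety <- trimws(atoms$elety)
  sel <- which(resid %in% toupper(water_residue_names) & grepl("^O", elety) &
               !is_hydrogen(elety, atoms$elesy))
  if (length(sel) == 0L) stop_format(sprintf("no water-oxygen atoms in %s", path))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  cols <- as.vector(rbind(3L * (sel - 1L) + 1L, 3L * (sel - 1L) + 2L, 3L * sel))
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, cols], ncol = 3L, byrow = TRUE)
  })
  water_trajectory(frames)
}

read_trajectory_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 0L) {
      stop_format(sprintf("malformed XYZ frame header at line %d of %s", i, path))
    }
    if (i + 1L + n > length(lines)) {
      stop_format(sprintf("truncated XYZ frame at line %d of %s", i, path))
    }
    block <- lines[seq.int(i + 2L, length.out = n)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- vapply(toks, length, integer(1)) < 4L
    if (any(bad)) stop_format(sprintf("malformed XYZ atom line in %s", path))
    el <- toupper(vapply(toks, `[[`, "", 1L))
    coords <- matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))), ncol = 3L, byrow = TRUE)
    if (any(!is.finite(coords))) stop_format(sprintf("non-numeric XYZ coordinates in %s", path))
    keep <- el %in% c("O", "OW", "OH2")
    frames[[length(frames) + 1L]] <- coords[keep, , drop = FALSE]
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop_format(sprintf("no frames parsed from %s", path))
  water_trajectory(frames)
}

# Fixed-column PDB ATOM/HETATM line.
format_pdb_atom <- function(type, serial, elety, resid, chain, resno, xyz,
                            occ = 1, b = 0, element = "") {
  name <- if (nchar(elety) < 4L) sprintf(" %-3s", elety) else substr(elety, 1, 4)
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial %% 100000L, name, substr(resid, 1, 3), substr(chain, 1, 1),
          resno %% 10000L, xyz[1], xyz[2], xyz[3], occ, b, element)
}

#' Write predicted hydration sites to PDB or CSV
#'
#' PDB output writes one water-oxygen HETATM per site at the predicted water
#' position (occupancy 1.00, B-factor = WT in kcal/mol); CSV output has
#' columns `id,x,y,z,wt,density_ratio,window_count`.
#'
#' @param sites A data frame of predicted sites (from [hydration_sites()] or
#'   [select_sites()]), with columns `x,y,z` and optionally `wt`,
#'   `density_ratio`, `window_count`.
#' @param path Output file path.
#' @param format `"pdb"` or `"csv"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path, format = c("auto", "pdb", "csv")) {
  format <- match.arg(format)
  if (inherits(sites, "hydration_sites")) sites <- sites$sites
  sites <- as.data.frame(sites)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "csv"
  }
  n <- nrow(sites)
  wt <- if ("wt" %in% names(sites)) sites$wt else rep(0, n)
  out <- tryCatch(file(path, "w"), error = function(e) stop_io(conditionMessage(e)))
  on.exit(close(out))
  if (format == "pdb") {
    if (n > 0L) {
      lines <- vapply(seq_len(n), function(i) {
        format_pdb_atom("HETATM", i, "O", "HOH", "A", i,
                        c(sites$x[i], sites$y[i], sites$z[i]),
                        occ = 1, b = wt[i], element = "O")
      }, character(1))
      writeLines(lines, out)
    }
    writeLines("END", out)
  } else {
    df <- data.frame(
      id = if (n) seq_len(n) else integer(0),
      x = sites$x, y = sites$y, z = sites$z,
      wt = wt,
      density_ratio = if ("density_ratio" %in% names(sites)) sites$density_ratio else NA_real_,
      window_count = if ("window_count" %in% names(sites)) sites$window_count else NA_integer_
    )
    utils::write.csv(df, out, row.names = FALSE)
  }
  invisible(path)
}

#' Read a predicted-site table (CSV) or water positions (PDB)
#'
#' @param path A CSV written by [write_sites()], or any PDB whose water
#'   HETATM records should be read as positions (B-factor column is returned
#'   as `wt`).
#' @return A data frame with columns `x,y,z` and, when available, `wt`,
#'   `density_ratio`, `window_count`.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- tryCatch(utils::read.csv(path), error = function(e) stop_format(conditionMessage(e)))
    if (!all(c("x", "y", "z") %in% names(df))) {
      stop_format(sprintf("site table %s lacks x,y,z columns", path))
    }
    return(df)
  }
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop_format(conditionMessage(e)),
                  warning = function(w) stop_format(conditionMessage(w)))
  atoms <- pdb$atom
  resid <- toupper(trimws(atoms$resid))
  sel <- resid %in% .default_water_resnames & grepl("^O", trimws(atoms$elety))
  if (!any(sel)) stop_format(sprintf("no water-oxygen records in %s", path))
  data.frame(x = atoms$x[sel], y = atoms$y[sel], z = atoms$z[sel], wt = atoms$b[sel])
}

#' Write a structure record as a PDB file
#'
#' Solute atoms are written as ATOM records with their original identifiers;
#' waters as HOH oxygen HETATMs.
#'
#' @param record A [structure_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(record, path) {
  stopifnot(inherits(record, "structure_record"))
  s <- record$solute
  out <- tryCatch(file(path, "w"), error = function(e) stop_io(conditionMessage(e)))
  on.exit(close(out))
  lines <- vapply(seq_len(s$natoms), function(i) {
    format_pdb_atom("ATOM", i, s$elety[i], s$resid[i], s$chain[i], s$resno[i],
                    s$xyz[i, ], element = substr(s$elety[i], 1, 1))
  }, character(1))
  writeLines(lines, out)
  nw <- nrow(record$waters)
  if (nw > 0L) {
    wl <- vapply(seq_len(nw), function(i) {
      format_pdb_atom("HETATM", s$natoms + i, "O", "HOH", "W", i,
                      record$waters[i, ], element = "O")
    }, character(1))
    writeLines(wl, out)
  }
  writeLines("END", out)
  invisible(path)
}

#' Write a water trajectory as a multi-model PDB or XYZ file
#'
#' With a `.pdb` path each frame becomes one MODEL/ENDMDL block of HOH oxygen
#' HETATMs; this requires every frame to hold the same number of waters (PDB
#' models share an atom table).  With a `.xyz` path each frame becomes an XYZ
#' block of `O` entries, which also accommodates fluctuating water counts.
#' Both forms round-trip through [read_trajectory()].
#'
#' @param traj A [water_trajectory()].
#' @param path Output path ending in `.pdb` or `.xyz`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "water_trajectory"))
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    return(write_trajectory_xyz(traj, path))
  }
  frames <- trajectory_frames(traj)
  counts <- vapply(frames, nrow, integer(1))
  if (max(counts) == 0L) stop_validation("cannot write a trajectory with no waters in any frame")
  if (length(unique(counts)) > 1L) {
    stop_validation("PDB models must have equal water counts per frame; write to a .xyz path instead")
  }
  out <- tryCatch(file(path, "w"), error = function(e) stop_io(conditionMessage(e)))
  on.exit(close(out))
  for (f in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", f), out)
    m <- frames[[f]]
    lines <- vapply(seq_len(nrow(m)), function(i) {
      format_pdb_atom("HETATM", i, "O", "HOH", "W", i, m[i, ], element = "O")
    }, character(1))
    writeLines(lines, out)
    writeLines("ENDMDL", out)
  }
  writeLines("END", out)
  invisible(path)
}

# XYZ fallback for trajectories whose per-frame water count varies (the usual
# case for a grand-canonical-like synthetic bulk).
write_trajectory_xyz <- function(traj, path) {
  frames <- trajectory_frames(traj)
  out <- tryCatch(file(path, "w"), error = function(e) stop_io(conditionMessage(e)))
  on.exit(close(out))
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    writeLines(as.character(nrow(m)), out)
    writeLines(sprintf("frame %d", f), out)
    if (nrow(m)) {
      writeLines(sprintf("O %12.6f %12.6f %12.6f", m[, 1], m[, 2], m[, 3]), out)
    }
  }
  invisible(path)
}
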