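#' Molecule map: atom-to-molecule assignment
#'
#' Assigns every atom of a frame to a molecule, records its element symbol and
#' whether it belongs to a solute molecule (solvent, co-solvent and ions are
#' retained in the coordinates but masked out of clustering).
#'
#' @param mol_id Integer vector, 1-based molecule id per atom. Solute ids must
#'   be contiguous `1..n_solute_molecules`.
#' @param element Character vector of element symbols per atom.
#' @param is_solute Logical vector per atom; defaults to all `TRUE`.
#' @return Object of class `molecule_map`.
#' @export
molecule_map <- function(mol_id, element, is_solute = NULL) {
  n <- length(mol_id)
  if (is.null(is_solute)) is_solute <- rep(TRUE, n)
  stopifnot(length(element) == n, length(is_solute) == n)
  mol_id <- as.integer(mol_id)
  sol_ids <- sort(unique(mol_id[is_solute]))
  if (length(sol_ids) < 1)
    stop("selection error: molecule map contains no solute molecules")
  if (!identical(sol_ids, seq_along(sol_ids)))
    stop("solute molecule ids must be contiguous starting at 1")
  structure(list(mol_id = mol_id, element = as.character(element),
                 is_solute = as.logical(is_solute),
                 n_solute = length(sol_ids)),
            class = "molecule_map")
}

#' @export
print.molecule_map <- function(x, ...) {
  cat(sprintf("<molecule_map> %d atoms; %d solute molecules (%d solute atoms)\n",
              length(x$mol_id), x$n_solute, sum(x$is_solute)))
  invisible(x)
}

#' Trajectory container
#'
#' Time-ordered coordinate frames sharing one molecule map and one periodic
#' cell. Coordinates are stored as a list of `n_atoms x 3` matrices (Angstrom).
#'
#' @param coords List of `n_atoms x 3` coordinate matrices, one per frame.
#' @param times Numeric vector of frame times, picoseconds; strictly
#'   increasing. Defaults to `0, 1, 2, ...`.
#' @param box A [box_spec] shared by all frames.
#' @param map A [molecule_map].
#' @param provenance Named list of free-form metadata (source file,
#'   selection, parameters).
#' @return Object of class `md_trajectory`.
#' @export
trajectory <- function(coords, box, map, times = NULL, provenance = list()) {
  stopifnot(is.list(coords), length(coords) >= 1)
  nat <- length(map$mol_id)
  for (i in seq_along(coords)) {
    ci <- coords[[i]]
    if (!is.matrix(ci) || ncol(ci) != 3 || nrow(ci) != nat)
      stop(sprintf("frame %d: coordinates must be a %d x 3 matrix", i, nat))
  }
  if (is.null(times)) times <- as.numeric(seq_along(coords) - 1)
  if (length(times) != length(coords) || any(diff(times) <= 0))
    stop("frame times must be strictly increasing, one per frame")
  box_volume(box)  # validates
  structure(list(coords = coords, times = times, box = box, map = map,
                 provenance = provenance),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(
    "<md_trajectory> %d frames; %d atoms; %d solute molecules; t = %g..%g ps\n",
    n_frames(x), length(x$map$mol_id), x$map$n_solute,
    min(x$times), max(x$times)))
  invisible(x)
}

#' @rdname trajectory
#' @param traj An `md_trajectory`.
#' @export
n_frames <- function(traj) length(traj$coords)

#' @rdname trajectory
#' @export
n_molecules <- function(traj) traj$map$n_solute

solvent_residues <- c("WAT", "HOH", "TIP3", "SPC", "SOL", "DMS", "DMSO",
                      "NA+", "CL-", "NA", "CL", "K+", "MG", "SOD", "CLA")

#' Read a trajectory from disk
#'
#' Supported formats: extended XYZ (multi-frame, optional `Lattice="..."` and
#' `Time=` fields on the comment line) with a plain-text molecule-map sidecar;
#' multi-MODEL PDB (molecules from residue records, box from CRYST1); and
#' DCD with a PDB topology (both read via the bio3d reader).
#'
#' @param coord_path Coordinate file (`.xyz`, `.pdb` or `.dcd`).
#' @param topology For XYZ: the molecule-map sidecar (defaults to
#'   `<coord_path>.molmap.csv`). For DCD: a PDB topology file. Ignored for PDB.
#' @param solute_selection For PDB topologies, a character vector of residue
#'   names to treat as solute; default: every residue not a common solvent,
#'   co-solvent or ion name.
#' @param box A [box_spec] overriding (or supplying, when the file has none)
#'   the periodic cell.
#' @param save_interval_ps Frame spacing used when the format stores no time
#'   information (XYZ without `Time=`, DCD).
#' @return An [trajectory()] object.
#' @export
read_trajectory <- function(coord_path, topology = NULL,
                            solute_selection = NULL, box = NULL,
                            save_interval_ps = 1) {
  if (!file.exists(coord_path))
    stop(sprintf("I/O error: file '%s' does not exist", coord_path))
  ext <- tolower(tools::file_ext(coord_path))
  switch(ext,
    xyz = read_xyz_trajectory(coord_path, topology, box, save_interval_ps),
    pdb = read_pdb_trajectory(coord_path, solute_selection, box,
                              save_interval_ps),
    dcd = read_dcd_trajectory(coord_path, topology, solute_selection, box,
                              save_interval_ps),
    stop(sprintf("unsupported trajectory format '.%s' (use .xyz, .pdb or .dcd)",
                 ext)))
}

read_xyz_trajectory <- function(path, map_path, box, save_interval_ps) {
  if (is.null(map_path)) map_path <- paste0(path, ".molmap.csv")
  lines <- readLines(path, warn = FALSE)
  coords <- list(); times <- numeric(); lat_box <- NULL
  i <- 1L; frame <- 0L
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1)
      stop(sprintf("I/O error: frame %d has a malformed atom-count line", frame))
    if (i + 1L + nat > length(lines))
      stop(sprintf("I/O error: frame %d is truncated", frame))
    comment <- lines[i + 1L]
    lt <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(lt) == 2) {
      v <- as.numeric(strsplit(trimws(lt[2]), "\\s+")[[1]])
      if (length(v) != 9 || anyNA(v))
        stop(sprintf("I/O error: frame %d has a malformed Lattice field", frame))
      lat_box <- matrix(v, 3, 3, byrow = TRUE)
    }
    tm <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2])
               else (frame - 1) * save_interval_ps)
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(lengths(parts) < 4)
    if (length(bad))
      stop(sprintf("I/O error: frame %d is truncated at atom %d", frame, bad[1]))
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
    if (anyNA(xyz))
      stop(sprintf("I/O error: frame %d contains unparsable coordinates", frame))
    coords[[frame]] <- xyz
    i <- i + 2L + nat
  }
  if (frame == 0L) stop("I/O error: empty trajectory file")
  if (is.null(box)) {
    if (is.null(lat_box))
      stop("no Lattice field in XYZ file; supply `box`")
    box <- new_box_spec("triclinic", lat_box,
                        sqrt(rowSums(lat_box^2)), c(NA, NA, NA))
  }
  map <- read_molecule_map(map_path)
  trajectory(coords, box, map, times = times,
             provenance = list(source = path, format = "xyz",
                               molecule_map = map_path))
}

read_pdb_trajectory <- function(path, solute_selection, box,
                                save_interval_ps) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (is.null(box)) {
    cl <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
    if (length(cl)) {
      f <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                        substr(cl[1], 25, 33), substr(cl[1], 34, 40),
                        substr(cl[1], 41, 47), substr(cl[1], 48, 54)))
      box <- triclinic_box(f[1:3], f[4:6])
    } else {
      stop("PDB has no CRYST1 record; supply `box`")
    }
  }
  resid <- at$resid
  if (is.null(solute_selection))
    solute_selection <- setdiff(unique(resid), solvent_residues)
  is_sol <- resid %in% solute_selection
  if (!any(is_sol))
    stop("selection error: no atoms match the solute selection")
  mol_key <- paste(at$chain, at$resno, at$insert)
  sol_keys <- unique(mol_key[is_sol])
  mol_id <- integer(nrow(at))
  mol_id[is_sol] <- match(mol_key[is_sol], sol_keys)
  nonsol_keys <- unique(mol_key[!is_sol])
  mol_id[!is_sol] <- length(sol_keys) + match(mol_key[!is_sol], nonsol_keys)
  elem <- at$elesy
  if (is.null(elem) || all(!nzchar(trimws(elem))))
    elem <- toupper(substr(trimws(at$elety), 1, 1))
  map <- molecule_map(mol_id, trimws(elem), is_sol)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  coords <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  trajectory(coords, box, map,
             times = (seq_along(coords) - 1) * save_interval_ps,
             provenance = list(source = path, format = "pdb",
                               selection = solute_selection))
}

read_dcd_trajectory <- function(path, topology, solute_selection, box,
                                save_interval_ps) {
  if (is.null(topology))
    stop("DCD trajectories require a PDB `topology`")
  top <- read_pdb_trajectory(topology, solute_selection, box, save_interval_ps)
  dcd <- bio3d::read.dcd(path, verbose = FALSE)
  coords <- lapply(seq_len(nrow(dcd)), function(i)
    matrix(dcd[i, ], ncol = 3, byrow = TRUE))
  if (ncol(dcd) != length(top$map$mol_id) * 3)
    stop("I/O error: DCD atom count does not match topology")
  trajectory(coords, top$box, top$map,
             times = (seq_along(coords) - 1) * save_interval_ps,
             provenance = list(source = path, format = "dcd",
                               topology = topology))
}

#' Read/write a plain-text molecule map
#'
#' Sidecar CSV with columns `atom_index`, `molecule_id`, `element`,
#' `is_solute` (0/1). Indices are 1-based.
#'
#' @param path File path.
#' @return `read_molecule_map`: a [molecule_map].
#' @export
read_molecule_map <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: molecule map '%s' does not exist", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("atom_index", "molecule_id", "element", "is_solute")
  if (!all(need %in% names(df)))
    stop(sprintf("molecule map must have columns: %s",
                 paste(need, collapse = ", ")))
  df <- df[order(df$atom_index), ]
  molecule_map(df$molecule_id, df$element, as.logical(df$is_solute))
}

#' @rdname read_molecule_map
#' @param map A [molecule_map].
#' @export
write_molecule_map <- function(map, path) {
  df <- data.frame(atom_index = seq_along(map$mol_id),
                   molecule_id = map$mol_id, element = map$element,
                   is_solute = as.integer(map$is_solute))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trajectory as extended XYZ (+ molecule-map sidecar)
#'
#' Emits multi-frame extended XYZ with `Lattice="..."` and `Time=` fields on
#' the comment line (coordinates to 1e-4 Angstrom) and the molecule map as
#' `<path>.molmap.csv`, a pairing [read_trajectory()] reads back.
#'
#' @param traj An [trajectory()] object.
#' @param path Output `.xyz` path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  m <- as_box_matrix(traj$box)
  lat <- paste(sprintf("%.6f", as.vector(t(m))), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  nat <- length(traj$map$mol_id)
  for (i in seq_len(n_frames(traj))) {
    writeLines(as.character(nat), con)
    writeLines(sprintf(
      'Lattice="%s" Properties=species:S:1:pos:R:3 Time=%.6f', lat,
      traj$times[i]), con)
    xyz <- traj$coords[[i]]
    writeLines(sprintf("%-3s %12.4f %12.4f %12.4f", traj$map$element,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  write_molecule_map(traj$map, paste0(path, ".molmap.csv"))
  invisible(path)
}

#' Indices of n equispaced frames
#'
#' 1-based indices `floor(i * (F - 1) / (n - 1)) + 1` for `i = 0..n-1`; always
#' includes the first and last frame when `n >= 2`. When `F < n` all frames
#' are returned.
#'
#' @param n_total Total number of frames F.
#' @param n Number of frames requested.
#' @return Integer vector of frame indices.
#' @export
equispaced_indices <- function(n_total, n) {
  stopifnot(n_total >= 1, n >= 1)
  if (n == 1) return(1L)
  if (n_total <= n) return(seq_len(n_total))
  as.integer(floor((0:(n - 1)) * (n_total - 1) / (n - 1))) + 1L
}

#' Select equispaced analysis frames
#'
#' Subsets a trajectory to `n` equispaced frames (first and last always
#' included). If the trajectory holds fewer than `n` frames, all frames are
#' kept and the shortfall is recorded in the provenance.
#'
#' @inheritParams write_xyz_trajectory
#' @param n Number of frames to keep (analysis convention: 5000).
#' @return A subset `md_trajectory`.
#' @export
select_equispaced_frames <- function(traj, n) {
  if (n_frames(traj) < 1) stop("empty trajectory")
  stopifnot(n >= 1)
  idx <- equispaced_indices(n_frames(traj), n)
  prov <- traj$provenance
  prov$n_frames_requested <- n
  if (n_frames(traj) < n)
    prov$note <- sprintf("only %d frames available of %d requested",
                         n_frames(traj), n)
  trajectory(traj$coords[idx], traj$box, traj$map, times = traj$times[idx],
             provenance = prov)
}

#' Write an N_c time series as CSV
#'
#' Columns: `frame_index`, `time_ps`, `n_clusters`, `largest_cluster_size`.
#'
#' @param series An `nc_series` data frame from [cluster_trajectory()].
#' @param path Output path.
#' @export
write_nc_series <- function(series, path) {
  write.csv(series[, c("frame_index", "time_ps", "n_clusters",
                       "largest_cluster_size")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
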