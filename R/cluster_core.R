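#' Detect intermolecular contacts in one frame
#'
#' Two solute molecules are in contact when any atom of one lies within
#' `cutoff` of any atom of the other under the minimum-image convention
#' ("heavy or hydrogen" -- all atoms by default; the comparison is inclusive,
#' `<= cutoff`). A single qualifying atom pair suffices unless `min_contacts`
#' is raised. Non-solute atoms are excluded via the molecule map's solute
#' mask.
#'
#' `method = "cell_list"` bins atoms into fractional-space cells and only
#' examines neighbouring cells; it requires the cutoff to fit at least three
#' cells across every perpendicular box width and returns a graph identical
#' to the exhaustive `"brute"` search (explicit 27-image enumeration over all
#' atom pairs). `"auto"` picks the cell list when feasible.
#'
#' @param coords `n_atoms x 3` coordinate matrix, Angstrom (one frame), or an
#'   [trajectory()] object plus `frame`.
#' @param map A [molecule_map()]; taken from the trajectory if one is given.
#' @param box A [box_spec]; taken from the trajectory if one is given.
#' @param cutoff Contact distance cutoff, Angstrom. Default 3.0, the minimum
#'   that captures nearest-neighbour solute contacts in atomistic MD.
#' @param method `"auto"`, `"cell_list"` or `"brute"`.
#' @param contact_atoms `"all"` (heavy and hydrogen, default) or `"heavy"`
#'   (hydrogens ignored).
#' @param min_contacts Number of qualifying atom pairs needed for an edge
#'   (default 1).
#' @param frame Frame index when `coords` is a trajectory.
#' @return Object of class `contact_graph`: list with `edges` (m x 2 integer
#'   matrix of 1-based molecule ids, i < j), `n_molecules`, `cutoff`,
#'   `frame_index`.
#' @export
find_contacts <- function(coords, map = NULL, box = NULL, cutoff = 3.0,
                          method = c("auto", "cell_list", "brute"),
                          contact_atoms = c("all", "heavy"),
                          min_contacts = 1L, frame = 1L) {
  method <- match.arg(method)
  contact_atoms <- match.arg(contact_atoms)
  if (inherits(coords, "md_trajectory")) {
    map <- coords$map; box <- coords$box
    coords <- coords$coords[[frame]]
  }
  stopifnot(cutoff > 0, min_contacts >= 1)
  keep <- map$is_solute
  if (contact_atoms == "heavy") keep <- keep & toupper(map$element) != "H"
  xyz <- coords[keep, , drop = FALSE]
  mol <- map$mol_id[keep]
  nmol <- map$n_solute
  m <- as_box_matrix(box)
  storage.mode(xyz) <- "double"
  feasible <- all(floor(box_widths(m) / cutoff) >= 3)
  if (method == "auto") method <- if (feasible) "cell_list" else "brute"
  edges <- if (method == "cell_list") {
    contact_edges_cell_cpp(xyz, as.integer(mol), m, cutoff, nmol,
                           as.integer(min_contacts))
  } else {
    contact_edges_brute_cpp(xyz, as.integer(mol), m, cutoff, nmol,
                            as.integer(min_contacts))
  }
  structure(list(edges = edges, n_molecules = nmol, cutoff = cutoff,
                 frame_index = frame, method = method),
            class = "contact_graph")
}

#' Connected components of a contact graph (cluster labels)
#'
#' Union-find over the contact edges; isolated molecules form singleton
#' clusters, so a fully dispersed frame has `n_clusters` equal to the number
#' of solute molecules.
#'
#' @param graph A `contact_graph` from [find_contacts()], or an m x 2 integer
#'   edge matrix.
#' @param n_molecules Number of solute molecules (taken from the graph when
#'   one is given).
#' @return Object of class `cluster_labels`: list with `labels` (component
#'   id per molecule, numbered 1.. in order of first appearance),
#'   `n_clusters` and `sizes` (decreasing).
#' @export
connected_components <- function(graph, n_molecules = NULL) {
  if (inherits(graph, "contact_graph")) {
    edges <- graph$edges
    if (is.null(n_molecules)) n_molecules <- graph$n_molecules
  } else {
    edges <- graph
  }
  stopifnot(!is.null(n_molecules), n_molecules >= 1)
  if (length(edges) && max(edges) > n_molecules)
    stop("edge refers to a molecule id beyond n_molecules")
  parent <- seq_len(n_molecules)
  if (length(edges)) storage.mode(edges) <- "integer"
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n_molecules), find, integer(1))
  labels <- match(roots, unique(roots))
  sizes <- sort(tabulate(labels), decreasing = TRUE)
  structure(list(labels = labels, n_clusters = max(labels), sizes = sizes),
            class = "cluster_labels")
}

#' Cluster a trajectory into the N_c time series
#'
#' Selects `n_frames` equispaced frames, detects intermolecular contacts in
#' each and counts connected components, yielding the cluster-count series
#' N_c (1 = one aggregate ... N_mol = fully dispersed). The analysis
#' convention is 5000 equispaced frames at a 3.0 Angstrom all-atom cutoff.
#'
#' @inheritParams find_contacts
#' @param traj An [trajectory()] object.
#' @param n_frames Number of equispaced analysis frames (default 5000; all
#'   frames are used when fewer are available).
#' @return An `nc_series` data frame with columns `frame_index` (index into
#'   the source trajectory's frame order), `time_ps`, `n_clusters`,
#'   `largest_cluster_size`; attributes `n_mol`, `cutoff`, `contact_atoms`.
#' @export
cluster_trajectory <- function(traj, cutoff = 3.0, n_frames = 5000,
                               method = c("auto", "cell_list", "brute"),
                               contact_atoms = c("all", "heavy"),
                               min_contacts = 1L) {
  method <- match.arg(method)
  contact_atoms <- match.arg(contact_atoms)
  idx <- equispaced_indices(length(traj$coords), n_frames)
  nmol <- traj$map$n_solute
  nc <- integer(length(idx)); big <- integer(length(idx))
  for (i in seq_along(idx)) {
    g <- find_contacts(traj$coords[[idx[i]]], traj$map, traj$box,
                       cutoff = cutoff, method = method,
                       contact_atoms = contact_atoms,
                       min_contacts = min_contacts, frame = idx[i])
    cl <- connected_components(g)
    nc[i] <- cl$n_clusters
    big[i] <- cl$sizes[1]
  }
  out <- data.frame(frame_index = idx, time_ps = traj$times[idx],
                    n_clusters = nc, largest_cluster_size = big)
  attr(out, "n_mol") <- nmol
  attr(out, "cutoff") <- cutoff
  attr(out, "contact_atoms") <- contact_atoms
  class(out) <- c("nc_series", "data.frame")
  out
}
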