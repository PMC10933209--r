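# Fixture builders and independent oracles used across the suite.

# Random frame: n_mol compact molecules (atoms scattered ~spread A around a
# uniformly placed centre), wrapped into the primary cell.
make_random_frame <- function(n_mol, max_atoms = 6, box = cubic_box(30),
                              spread = 1.5) {
  m <- scamscreen:::as_box_matrix(box)
  n_atoms <- sample.int(max_atoms, n_mol, replace = TRUE)
  coords <- NULL; mol <- integer(0); elem <- character(0)
  for (i in seq_len(n_mol)) {
    center <- as.numeric(stats::runif(3) %*% m)
    at <- sweep(matrix(stats::rnorm(n_atoms[i] * 3, sd = spread), ncol = 3),
                2, center, `+`)
    coords <- rbind(coords, at)
    mol <- c(mol, rep(i, n_atoms[i]))
    elem <- c(elem, sample(c("C", "N", "O", "H"), n_atoms[i], replace = TRUE))
  }
  # wrap into the primary cell so a 27-image enumeration is exhaustive
  f <- coords %*% solve(m)
  f <- f - floor(f)
  list(coords = f %*% m, map = molecule_map(mol, elem), box = box)
}

# Pure-R oracle: all-pairs contact graph by explicit minimisation over the
# 27 periodic images (coords must be wrapped), no cell list, no rounding.
oracle_contact_edges <- function(coords, mol, box, cutoff,
                                 elements = NULL, heavy_only = FALSE) {
  m <- scamscreen:::as_box_matrix(box)
  if (heavy_only) {
    keep <- toupper(elements) != "H"
    coords <- coords[keep, , drop = FALSE]
    mol <- mol[keep]
  }
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*% m
  nmol <- max(mol)
  adj <- matrix(FALSE, nmol, nmol)
  nat <- nrow(coords)
  for (i in seq_len(nat - 1)) {
    for (j in seq((i + 1), nat)) {
      if (mol[i] == mol[j]) next
      d <- coords[j, ] - coords[i, ]
      d2 <- min(rowSums(sweep(shifts, 2, d, `+`)^2))
      if (d2 <= cutoff^2) adj[mol[i], mol[j]] <- adj[mol[j], mol[i]] <- TRUE
    }
  }
  which(adj & upper.tri(adj), arr.ind = TRUE)[, c(1, 2), drop = FALSE]
}

# DFS component-count oracle via igraph
oracle_n_components <- function(edges, n_mol) {
  g <- igraph::make_empty_graph(n = n_mol, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$no
}

# canonical edge ordering for graph comparisons
sort_edges <- function(e) {
  if (!length(e)) return(matrix(integer(0), 0, 2))
  e <- t(apply(matrix(e, ncol = 2), 1, sort))
  unname(e[order(e[, 1], e[, 2]), , drop = FALSE])
}

# nc_series data frame from a bare vector of N_c values
make_series <- function(nc, n_mol) {
  out <- data.frame(frame_index = seq_along(nc), time_ps = seq_along(nc) - 1,
                    n_clusters = as.integer(nc),
                    largest_cluster_size = rep(NA_integer_, length(nc)))
  attr(out, "n_mol") <- n_mol
  attr(out, "cutoff") <- 3.0
  class(out) <- c("nc_series", "data.frame")
  out
}

# tiny deterministic trajectory: n_mol single-atom molecules at given coords
make_point_trajectory <- function(frames_coords, box = cubic_box(50)) {
  n <- nrow(frames_coords[[1]])
  trajectory(frames_coords, box, molecule_map(seq_len(n), rep("C", n)))
}
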