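#' Sticky-sphere simulation configuration
#'
#' Parameters for the overdamped-Langevin surrogate of a solvated MD run:
#' N single-bead (or rigid three-bead) molecules diffusing in a periodic box
#' with a fixed repulsive core and a tunable short-range attraction of depth
#' `epsilon` (in kT). `epsilon` plays the role solute hydrophobicity plays in
#' explicit solvent: 0 produces a dispersed, non-aggregating system, ~4 kT a
#' strongly aggregating one. Internally the dynamics run in reduced units
#' (sigma = 1, kT = 1, time in tau = sigma^2 * gamma / kT); coordinates are
#' scaled to Angstrom by `sigma` on output.
#'
#' @param n_molecules Number of solute molecules (default 12, the scale used
#'   for solvated screens of 11-12 solute copies).
#' @param beads_per_molecule 1 (default) or 3 (rigid linear trimer with
#'   elements C-C-H, so heavy-atom-only contact filtering is exercisable).
#' @param sigma Bead diameter in Angstrom (default 5, a small-drug-sized
#'   bead).
#' @param epsilon Attraction well depth, kT (default 0).
#' @param box A [box_spec]; must be cubic/orthorhombic (default 60 Angstrom
#'   cubic, a dilute ~12 sigma cell).
#' @param temperature Nominal temperature, K (metadata only; the reduced
#'   dynamics are at kT = 1).
#' @param dt Timestep in reduced time tau (default 5e-4, small enough that
#'   core forces never move a bead more than a fraction of sigma per step).
#' @param n_steps Number of integration steps (default 2e5, i.e. 100 tau).
#' @param save_interval Save a frame every this many steps (default 100).
#' @param gamma Bead friction coefficient, reduced units (default 1).
#' @param seed RNG seed; `simulate()` is bitwise reproducible given a seed.
#' @param min_separation Minimum intermolecular distance at placement,
#'   Angstrom (default 1.5 * sigma).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_molecules = 12, beads_per_molecule = 1, sigma = 5,
                       epsilon = 0, box = cubic_box(60), temperature = 300,
                       dt = 5e-4, n_steps = 2e5, save_interval = 100,
                       gamma = 1, seed = NULL,
                       min_separation = 1.5 * sigma) {
  stopifnot(n_molecules >= 1, beads_per_molecule %in% c(1, 3), sigma > 0,
            epsilon >= 0, dt > 0, n_steps >= 1, save_interval >= 1,
            gamma > 0, min_separation > 0)
  m <- as_box_matrix(box)
  if (any(abs(m[upper.tri(m) | lower.tri(m)]) > 1e-9))
    stop("the simulator supports cubic/orthorhombic boxes only")
  if (n_molecules * sigma^3 > 0.25 * box_volume(box))
    stop("density error: n * sigma^3 exceeds a quarter of the box volume")
  structure(list(n_molecules = as.integer(n_molecules),
                 beads_per_molecule = as.integer(beads_per_molecule),
                 sigma = sigma, epsilon = epsilon, box = box,
                 temperature = temperature, dt = dt,
                 n_steps = as.integer(n_steps),
                 save_interval = as.integer(save_interval), gamma = gamma,
                 seed = seed, min_separation = min_separation),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d x %d-bead molecules; sigma %g A; ",
                     "epsilon %g kT; box %s A; %d steps x dt %g tau\n"),
              x$n_molecules, x$beads_per_molecule, x$sigma, x$epsilon,
              paste(signif(x$box$lengths, 4), collapse = "x"),
              x$n_steps, x$dt))
  invisible(x)
}

#' Contact cutoff matched to the bead diameter
#'
#' Beads are coarse particles: two beads "touch" near the Lennard-Jones
#' minimum at 1.12 sigma, so the atomistic 3.0 Angstrom cutoff does not
#' transfer. The recommended criterion is 1.3 sigma -- just beyond touching,
#' the same notion the 3.0 Angstrom value encodes for atoms.
#'
#' @param config A [sim_config()].
#' @return Cutoff in Angstrom.
#' @export
contact_cutoff <- function(config) 1.3 * config$sigma

#' Place molecules with a minimum mutual separation
#'
#' Rejection-samples positions uniformly in the box until all pairwise
#' minimum-image distances are at least `min_sep`; deterministic for a given
#' seed. Replicates by construction the dispersed starting state that a
#' high-temperature pre-equilibration phase produces in solvated MD.
#'
#' @param n Number of molecules.
#' @param box A [box_spec].
#' @param min_sep Minimum pairwise minimum-image distance, Angstrom.
#' @param seed Optional RNG seed.
#' @return `n x 3` matrix of positions, Angstrom.
#' @export
place_molecules <- function(n, box, min_sep, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- as_box_matrix(box)
  pos <- matrix(NA_real_, n, 3)
  rejects <- 0L
  i <- 1L
  while (i <= n) {
    f <- stats::runif(3)
    p <- as.numeric(f %*% m)
    ok <- i == 1L ||
      all(mi_dist_to_set_cpp(m, p, pos[seq_len(i - 1L), , drop = FALSE])
          >= min_sep)
    if (ok) {
      pos[i, ] <- p
      i <- i + 1L
      rejects <- 0L
    } else {
      rejects <- rejects + 1L
      if (rejects >= 10000L)
        stop("density error: could not place molecules at the requested ",
             "minimum separation (10000 consecutive rejections)")
    }
  }
  pos
}

#' Run the sticky-sphere Langevin simulation
#'
#' Overdamped Langevin propagation `x <- x + (F/gamma) dt + N(0,
#' sqrt(2 kT dt / gamma))` with the pair interaction described in
#' [sim_config()] (fixed 1 kT repulsive core + attractive well of depth
#' `epsilon`, cutoff 2.5 sigma), minimum-image wrapped. Frames (including the
#' initial configuration) are emitted every `save_interval` steps with all
#' coordinates wrapped into the primary cell. Bitwise reproducible for a
#' given `seed`.
#'
#' @param object A [sim_config()].
#' @param nsim,seed Standard [stats::simulate()] arguments; `seed` overrides
#'   the config seed.
#' @param ... Unused.
#' @return An [trajectory()] object (coordinates in Angstrom; frame times in
#'   reduced tau reported as ps).
#' @exportS3Method stats::simulate
#' @export simulate.sim_config
simulate.sim_config <- function(object, nsim = 1, seed = NULL, ...) {
  cfg <- object
  if (is.null(seed)) seed <- cfg$seed
  if (!is.null(seed)) set.seed(seed)
  sig <- cfg$sigma
  centers <- place_molecules(cfg$n_molecules, cfg$box, cfg$min_separation)
  orient <- matrix(stats::rnorm(cfg$n_molecules * 3), ncol = 3)
  orient <- orient / sqrt(rowSums(orient^2))
  res <- simulate_langevin_cpp(centers / sig, orient, cfg$beads_per_molecule,
                               cfg$box$lengths / sig, cfg$epsilon, 1.0,
                               cfg$dt, cfg$n_steps, cfg$save_interval,
                               cfg$gamma)
  if (isTRUE(res$unstable))
    stop(sprintf(paste0("instability error: a molecule moved %.2f sigma in ",
                        "one step (> sigma/2); use a smaller dt"),
                 res$max_step_displacement))
  nbead <- cfg$n_molecules * cfg$beads_per_molecule
  nfr <- res$n_frames_saved
  coords <- lapply(seq_len(nfr), function(i)
    matrix(res$coords[, , i], ncol = 3) * sig)
  elem <- if (cfg$beads_per_molecule == 1) rep("C", nbead)
          else rep(c("C", "C", "H"), cfg$n_molecules)
  map <- molecule_map(rep(seq_len(cfg$n_molecules),
                          each = cfg$beads_per_molecule), elem)
  trajectory(coords, cfg$box, map,
             times = res$steps_saved[seq_len(nfr)] * cfg$dt,
             provenance = list(generator = "scamscreen sticky-sphere",
                               epsilon_kT = cfg$epsilon, sigma_A = sig,
                               seed = seed, n_steps = cfg$n_steps,
                               dt_tau = cfg$dt,
                               time_unit = "reduced tau reported as ps"))
}

#' Drop the equilibration burn-in from an N_c series
#'
#' Simulator trajectories start from an artificially dispersed placement;
#' metrics over them conventionally discard the first fifth of the frames.
#' Analyses of externally produced trajectories should not drop frames
#' silently -- this helper is explicit and opt-in.
#'
#' @param series An `nc_series`.
#' @param fraction Leading fraction of frames to drop (default 0.2).
#' @return The truncated `nc_series` (attributes preserved).
#' @export
drop_burnin <- function(series, fraction = 0.2) {
  stopifnot(fraction >= 0, fraction < 1)
  n <- nrow(series)
  keep <- seq.int(floor(n * fraction) + 1L, n)
  out <- series[keep, , drop = FALSE]
  attributes(out)[c("n_mol", "cutoff", "contact_atoms")] <-
    attributes(series)[c("n_mol", "cutoff", "contact_atoms")]
  class(out) <- class(series)
  out
}

#' Read/write simulator configuration as YAML or JSON
#'
#' All [sim_config()] fields are supported; omitted keys take the defaults.
#' `box` is encoded as `{shape, lengths}` (cubic/orthorhombic only).
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return `read_sim_config`: a [sim_config()].
#' @export
read_sim_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be .yaml/.yml or .json")
  if (!is.null(raw$box)) {
    l <- raw$box$lengths
    raw$box <- if (length(l) == 1) cubic_box(l)
               else orthorhombic_box(l[1], l[2], l[3])
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config A [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$box <- list(shape = config$box$shape,
                lengths = as.numeric(config$box$lengths))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(x, path)
  else if (ext == "json")
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  else stop("config must be .yaml/.yml or .json")
  invisible(path)
}
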