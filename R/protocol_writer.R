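#' The reference solvated-MD protocol
#'
#' Five chained stages encoding the standard screen protocol: energy
#' minimisation; two 20 ps NVT phases (heating 0 -> 500 K to disperse the
#' solutes, then cooling 500 -> 300 K); 2 ns of NPT equilibration at 300 K
#' and 1 atm; and 1 microsecond of production at 300 K with structures saved
#' every 20 ps. All dynamic stages use a 2 fs timestep with bond constraints
#' on hydrogens (SHAKE), a 10 Angstrom nonbonded cutoff and a Langevin
#' thermostat with friction 1.0 / ps. Minimisation settings are not dictated
#' by the protocol source and are emitted as implementation defaults.
#'
#' @return Object of class `protocol_spec`: list of stages, each a list with
#'   `name`, `ensemble` (`"minimisation"`, `"NVT"`, `"NPT"`),
#'   `temp_initial_K`, `temp_final_K`, `pressure_atm`, `duration_ps`,
#'   `timestep_fs`, `cutoff_A`, `gamma_ps`, `shake`, `save_interval_ps`,
#'   `min_cycles` (minimisation only).
#' @examples
#' p <- default_protocol()
#' stage_steps(p[[5]])  # 5e8 production steps (1 us at 2 fs)
#' @export
default_protocol <- function() {
  dyn <- function(name, ensemble, ti, tf, dur, pres = NA_real_,
                  save = NA_real_) {
    list(name = name, ensemble = ensemble, temp_initial_K = ti,
         temp_final_K = tf, pressure_atm = pres, duration_ps = dur,
         timestep_fs = 2, cutoff_A = 10, gamma_ps = 1.0, shake = TRUE,
         save_interval_ps = save)
  }
  p <- list(
    c(list(name = "minimise", ensemble = "minimisation",
           temp_initial_K = NA_real_, temp_final_K = NA_real_,
           pressure_atm = NA_real_, duration_ps = NA_real_,
           timestep_fs = NA_real_, cutoff_A = 10, gamma_ps = NA_real_,
           shake = FALSE, save_interval_ps = NA_real_),
      list(min_cycles = 5000)),
    dyn("heat",       "NVT", 0,   500, 20),
    dyn("cool",       "NVT", 500, 300, 20),
    dyn("equilibrate", "NPT", 300, 300, 2000, pres = 1),
    dyn("production",  "NVT", 300, 300, 1e6, save = 20)
  )
  structure(p, class = "protocol_spec")
}

#' @rdname default_protocol
#' @param stage One stage of a `protocol_spec`.
#' @return `stage_steps`: the exact integer step count
#'   `duration_ps * 1000 / timestep_fs` (minimisation: `min_cycles`).
#' @export
stage_steps <- function(stage) {
  if (stage$ensemble == "minimisation") return(stage$min_cycles)
  steps <- stage$duration_ps * 1000 / stage$timestep_fs
  if (abs(steps - round(steps)) > 1e-9)
    stop("stage duration is not an integer number of timesteps")
  round(steps)
}

#' @rdname default_protocol
#' @return `stage_save_stride`: steps between saved structures.
#' @export
stage_save_stride <- function(stage) {
  if (is.na(stage$save_interval_ps)) return(NA_real_)
  round(stage$save_interval_ps * 1000 / stage$timestep_fs)
}

validate_protocol <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec") || is.list(spec))
  for (s in spec) {
    if (s$ensemble != "minimisation" &&
        (!is.finite(s$duration_ps) || s$duration_ps <= 0))
      stop(sprintf("validation error: stage '%s' has non-positive duration",
                   s$name))
    if (s$ensemble == "minimisation" && s$min_cycles <= 0)
      stop("validation error: minimisation needs a positive cycle count")
  }
  prod <- spec[[length(spec)]]
  if (prod$ensemble != "minimisation" &&
      !is.na(prod$save_interval_ps) && prod$save_interval_ps <= 0)
    stop("validation error: production stage must save at a positive interval")
  invisible(spec)
}

fmt_val <- function(x) {
  if (is.logical(x)) return(if (x) "1" else "0")
  if (is.numeric(x) && abs(x - round(x)) < 1e-9)
    return(sprintf("%d", as.integer(round(x))))
  sprintf("%.6g", x)
}

#' Emit protocol stages as AMBER-style mdin input files
#'
#' One text file per stage (`NN_name.mdin`), a title line plus a sorted
#' `&cntrl` namelist with fixed number formatting, so re-emission is
#' byte-identical. Successive stages chain restarts (`irest`/`ntx`). No MD is
#' executed. [parse_mdin()] reads a stage file back into its stage list;
#' emission and parsing round-trip exactly.
#'
#' @param spec A `protocol_spec` from [default_protocol()].
#' @param out_dir Output directory (created if needed).
#' @param dialect Only `"amber_mdin"` is implemented.
#' @return Character vector of the emitted file paths.
#' @export
emit_input_files <- function(spec, out_dir, dialect = "amber_mdin") {
  if (!identical(dialect, "amber_mdin"))
    stop(sprintf("unknown dialect '%s'; supported dialects: amber_mdin",
                 dialect))
  validate_protocol(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(spec))
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    first_dyn <- i == 2  # stage after minimisation starts from coordinates
    keys <- list()
    if (s$ensemble == "minimisation") {
      keys$imin <- 1
      keys$maxcyc <- s$min_cycles
      keys$ncyc <- min(s$min_cycles, 500)
      keys$cut <- s$cutoff_A
      title <- sprintf("%s (minimisation settings unspecified-in-source; %s)",
                       s$name, "implementation defaults")
    } else {
      keys$imin <- 0
      keys$nstlim <- stage_steps(s)
      keys$dt <- s$timestep_fs / 1000  # ps, AMBER convention
      keys$cut <- s$cutoff_A
      keys$ntt <- 3
      keys$gamma_ln <- s$gamma_ps
      keys$tempi <- s$temp_initial_K
      keys$temp0 <- s$temp_final_K
      keys$ntc <- if (s$shake) 2 else 1
      keys$ntf <- if (s$shake) 2 else 1
      keys$irest <- if (first_dyn) 0 else 1
      keys$ntx <- if (first_dyn) 1 else 5
      if (s$ensemble == "NPT") {
        keys$ntb <- 2
        keys$ntp <- 1  # pressure-coupling scheme: implementation-default
        keys$pres0 <- s$pressure_atm
      } else {
        keys$ntb <- 1
        keys$ntp <- 0
      }
      keys$ntwx <- if (is.na(s$save_interval_ps)) 0 else stage_save_stride(s)
      title <- s$name
    }
    keys <- keys[order(names(keys))]
    lines <- c(title, "&cntrl",
               sprintf("  %s = %s,", names(keys),
                       vapply(keys, fmt_val, character(1))),
               "/", "")
    paths[i] <- file.path(out_dir, sprintf("%02d_%s.mdin", i, s$name))
    writeLines(lines, paths[i])
  }
  paths
}

#' @rdname emit_input_files
#' @param path One emitted `.mdin` file.
#' @return `parse_mdin`: the stage list reconstructed from the file.
#' @export
parse_mdin <- function(path) {
  lines <- readLines(path, warn = FALSE)
  title <- lines[1]
  kv <- grep("^  \\w+ = .*,$", lines, value = TRUE)
  keys <- sub("^  (\\w+) = .*$", "\\1", kv)
  vals <- as.numeric(sub("^  \\w+ = (.*),$", "\\1", kv))
  k <- setNames(as.list(vals), keys)
  name <- sub(" \\(.*\\)$", "", title)
  if (k$imin == 1) {
    return(list(name = name, ensemble = "minimisation",
                temp_initial_K = NA_real_, temp_final_K = NA_real_,
                pressure_atm = NA_real_, duration_ps = NA_real_,
                timestep_fs = NA_real_, cutoff_A = k$cut,
                gamma_ps = NA_real_, shake = FALSE,
                save_interval_ps = NA_real_, min_cycles = k$maxcyc))
  }
  ts_fs <- k$dt * 1000
  list(name = name,
       ensemble = if (k$ntp > 0) "NPT" else "NVT",
       temp_initial_K = k$tempi, temp_final_K = k$temp0,
       pressure_atm = if (k$ntp > 0) k$pres0 else NA_real_,
       duration_ps = k$nstlim * ts_fs / 1000,
       timestep_fs = ts_fs, cutoff_A = k$cut, gamma_ps = k$gamma_ln,
       shake = k$ntc == 2,
       save_interval_ps = if (k$ntwx > 0) k$ntwx * ts_fs / 1000 else NA_real_)
}

#' Box composition arithmetic
#'
#' Derived counts for a solvated screen box: solute molarity from the cell
#' volume, NaCl ion pairs from the salt concentration, and the DMSO molecule
#' count matching a volume fraction (via a stated DMSO molar volume --
#' a named parameter, default 71.3 cm^3/mol at room temperature). Counts use
#' round-half-even. For 11 solutes in a 180 Angstrom truncated-octahedron
#' cell the solute concentration is ~4 mM, i.e. millimolar -- well above
#' typical micromolar critical aggregation concentrations.
#'
#' @param box A [box_spec].
#' @param n_solute Number of solute molecules (default 11).
#' @param dmso_volume_fraction DMSO v/v fraction (default 0.05).
#' @param nacl_mM NaCl concentration in mmol/L (default 50).
#' @param dmso_molar_volume_cm3 DMSO molar volume, cm^3/mol (default 71.3).
#' @return Object of class `composition`: list with `box_volume_A3`,
#'   `solute_molarity_mM`, `ion_pairs`, `dmso_count` and the inputs.
#' @export
composition <- function(box, n_solute = 11, dmso_volume_fraction = 0.05,
                        nacl_mM = 50, dmso_molar_volume_cm3 = 71.3) {
  stopifnot(n_solute >= 1, dmso_volume_fraction >= 0,
            dmso_volume_fraction <= 1, nacl_mM >= 0,
            dmso_molar_volume_cm3 > 0)
  avogadro <- 6.02214076e23
  vol_A3 <- box_volume(box)
  vol_L <- vol_A3 * 1e-27
  molarity_mM <- 1000 * n_solute / (avogadro * vol_L)
  ion_pairs <- round(nacl_mM * 1e-3 * avogadro * vol_L)
  v_dmso_A3 <- dmso_molar_volume_cm3 * 1e24 / avogadro  # per molecule
  dmso_count <- round(dmso_volume_fraction * vol_A3 / v_dmso_A3)
  structure(list(box_volume_A3 = vol_A3, n_solute = n_solute,
                 solute_molarity_mM = molarity_mM, nacl_mM = nacl_mM,
                 ion_pairs = ion_pairs,
                 dmso_volume_fraction = dmso_volume_fraction,
                 dmso_molar_volume_cm3 = dmso_molar_volume_cm3,
                 dmso_count = dmso_count),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf(paste0("<composition> V = %.4g A^3; %d solutes -> %.2f mM; ",
                     "%d NaCl pairs (%g mM); %d DMSO (%.0f%% v/v)\n"),
              x$box_volume_A3, x$n_solute, x$solute_molarity_mM, x$ion_pairs,
              x$nacl_mM, x$dmso_count, 100 * x$dmso_volume_fraction))
  invisible(x)
}

#' Write a composition report as JSON or CSV
#'
#' @param comp A [composition()].
#' @param path Output path (`.json` or `.csv`).
#' @export
write_composition <- function(comp, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(comp), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext == "csv") {
    write.csv(as.data.frame(unclass(comp)), path, row.names = FALSE,
              quote = FALSE)
  } else stop("composition report must be .json or .csv")
  invisible(path)
}
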