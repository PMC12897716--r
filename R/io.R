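# Run configuration and trajectory file I/O.

.config_defaults <- list(
  engine = "dpd",
  temperature = 298.15,
  seed = 1L,
  box_side = 22.5,
  rho_reduced = 3,
  gamma = 4.5,
  dt = 0.01,
  pre_thermalization_steps = 1e6,
  thermalization_steps = 1e6,
  production_steps = 5e6,
  snapshot_interval = 1000,
  log_interval = 10000,
  water_count = NULL,
  site_spacing = 2.2,
  chain_length = 8L,
  lattice_extent = 2L,
  pruning_radius = 0.91,
  pruning_center = c(0.135, 0.135, 0.135),
  Nm = 5L,
  monomer_molar_mass = 113.16,
  monomer_mass_density = 1100,
  fh_A = 35.2,
  fh_theta = 308.3,
  bond_K = 0.4,
  bond_r0_A = 6.5,
  output = "trajectory.xyz"
)

#' Read and validate a run configuration
#'
#' Plain-text `key: value` (YAML) configuration with the packaged
#' full-scale defaults filled in for missing keys. Unknown keys are
#' rejected by name, so typos fail loudly rather than silently running
#' with a default.
#'
#' @param path Path to the YAML config file.
#' @return An object of class `run_config` (a validated named list).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("config error: file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(.config_defaults))
  if (length(unknown)) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(.config_defaults, raw)
  if (!cfg$engine %in% c("dpd", "langevin")) {
    stop("config error: engine must be 'dpd' or 'langevin' (key: engine)",
         call. = FALSE)
  }
  if (!is.numeric(cfg$temperature) || cfg$temperature <= 0) {
    stop("config error: temperature must be positive kelvin ",
         "(key: temperature)", call. = FALSE)
  }
  for (key in c("box_side", "rho_reduced", "dt", "site_spacing",
                "bond_K", "bond_r0_A")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0) {
      stop("config error: ", key, " must be positive (key: ", key, ")",
           call. = FALSE)
    }
  }
  for (key in c("pre_thermalization_steps", "thermalization_steps",
                "production_steps")) {
    if (cfg[[key]] < 0) {
      stop("config error: ", key, " must be non-negative (key: ", key, ")",
           call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Run a full workflow from a configuration
#'
#' Builds the force field, topology and initial configuration described by
#' a [read_config()] object and runs the simulation.
#'
#' @param cfg A `run_config`.
#' @return A `trajectory`.
#' @export
run_from_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  beads <- bead_spec(Nm = cfg$Nm, monomer_molar_mass = cfg$monomer_molar_mass,
                     monomer_mass_density = cfg$monomer_mass_density)
  fh <- fh_model(A = cfg$fh_A, theta = cfg$fh_theta)
  gel <- build_nanogel(cfg$chain_length, cfg$lattice_extent,
                       cfg$pruning_radius, cfg$pruning_center)
  bp <- bond_params(cfg$bond_K, cfg$bond_r0_A)
  proto <- protocol(dt = cfg$dt,
                    pre_thermalization_steps = cfg$pre_thermalization_steps,
                    thermalization_steps = cfg$thermalization_steps,
                    production_steps = cfg$production_steps,
                    snapshot_interval = cfg$snapshot_interval,
                    log_interval = cfg$log_interval,
                    seed = cfg$seed)
  if (cfg$engine == "dpd") {
    ff <- build_forcefield(cfg$temperature, beads, fh, gamma = cfg$gamma,
                           rho_reduced = cfg$rho_reduced)
    init <- initial_configuration(gel, cfg$box_side, ff$units,
                                  rho_reduced = cfg$rho_reduced, bond = bp,
                                  seed = cfg$seed,
                                  water_count = cfg$water_count,
                                  site_spacing = cfg$site_spacing)
  } else {
    ff <- langevin_forcefield(cfg$temperature, beads)
    init <- polymer_configuration(gel, cfg$box_side, ff$units, bond = bp,
                                  seed = cfg$seed,
                                  site_spacing = cfg$site_spacing)
  }
  run_simulation(init, ff, proto)
}

#' Write a trajectory in XYZ format
#'
#' One frame per snapshot: an atom-count line, a comment line carrying
#' `step`, `box`, `temperature`, `engine` and `seed`, then one record per
#' bead (`W` water, `M` monomer) with unwrapped coordinates.
#'
#' @param traj A `trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  lab <- ifelse(traj$types == "water", "W", "M")
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in traj$frames) {
    writeLines(as.character(nrow(fr$xyz)), con)
    writeLines(sprintf(
      "step=%d box=%.10g temperature=%.6g engine=%s seed=%d",
      fr$step, fr$box_side, traj$temperature, traj$engine, traj$seed), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", lab, fr$xyz[, 1], fr$xyz[, 2],
                       fr$xyz[, 3]), con)
  }
  invisible(path)
}

.parse_kv <- function(comment, key, line_no) {
  m <- regmatches(comment, regexpr(paste0(key, "=[^ ]+"), comment))
  if (!length(m)) {
    stop("parse error at line ", line_no, ": missing '", key,
         "' in frame header", call. = FALSE)
  }
  sub(paste0(key, "="), "", m)
}

#' Read an XYZ trajectory
#'
#' Inverse of [write_trajectory()]; `read_trajectory(write_trajectory(x))`
#' reproduces the frames to the printed precision. Malformed input raises
#' a parse error carrying the offending line number.
#'
#' @param path XYZ file path.
#' @return A `trajectory` (without velocities or a unit system).
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list()
  types <- NULL
  temperature <- NA_real_
  engine <- NA_character_
  seed <- NA_integer_
  box <- NA_real_
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i])) {
      stop("parse error at line ", i, ": expected atom count", call. = FALSE)
    }
    n <- as.integer(lines[i])
    if (i + 1L + n > length(lines)) {
      stop("parse error at line ", length(lines),
           ": truncated frame (expected ", n, " atom records)",
           call. = FALSE)
    }
    comment <- lines[i + 1L]
    step <- as.integer(.parse_kv(comment, "step", i + 1L))
    box <- as.numeric(.parse_kv(comment, "box", i + 1L))
    temperature <- as.numeric(.parse_kv(comment, "temperature", i + 1L))
    engine <- .parse_kv(comment, "engine", i + 1L)
    seed <- as.integer(.parse_kv(comment, "seed", i + 1L))
    rec <- strsplit(lines[i + 1L + seq_len(n)], "\\s+")
    bad <- which(lengths(rec) != 4L)
    if (length(bad)) {
      stop("parse error at line ", i + 1L + bad[1],
           ": expected 'TYPE x y z'", call. = FALSE)
    }
    rec <- do.call(rbind, rec)
    xyz <- suppressWarnings(matrix(as.numeric(rec[, 2:4]), n, 3))
    if (anyNA(xyz)) {
      stop("parse error near line ", i + 2L, ": non-numeric coordinate",
           call. = FALSE)
    }
    ft <- ifelse(rec[, 1] == "W", "water", "monomer")
    if (is.null(types)) types <- ft
    frames[[length(frames) + 1]] <- list(step = step, box_side = box,
                                         xyz = xyz)
    i <- i + 2L + n
  }
  structure(list(
    frames = frames,
    types = if (is.null(types)) character(0) else types,
    polymer_indices = which(types == "monomer"),
    bonds = matrix(integer(0), 0, 2),
    box_side = box,
    temperature = temperature,
    engine = engine,
    seed = seed,
    units = NULL,
    temp_log = NULL
  ), class = "trajectory")
}

#' Published full-scale mean radii of gyration
#'
#' Reference mean Rg values (with block-binned SEMs) of the 439-bead
#' PNIPAM nanogel from full-scale production runs of both engines over
#' 280-330 K, shipped as a plain-text table. Used as input for
#' transition-bracket and swelling-ratio analyses and as the comparison
#' point for scaled-down runs.
#'
#' @return data.frame with `temperature_K`, `rg_langevin_A`,
#'   `sem_langevin_A`, `rg_dpd_A`, `sem_dpd_A`.
#' @export
reference_rg <- function() {
  read.csv(system.file("extdata", "reference_rg.csv", package = "dpdgel"))
}
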