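# R-level force primitives (reference implementations used in tests and
# documentation) and the simulation driver around the compiled core.

#' DPD conservative force
#'
#' Linear soft repulsion \eqn{F(r) = F^{max} (1 - r/r_c)} for \eqn{r < r_c},
#' zero beyond: the exact negative gradient of the quadratic soft-sphere
#' potential. Continuous at the cutoff and maximal at contact.
#'
#' @param r Pair distance (reduced, >= 0).
#' @param fmax Maximum repulsion parameter (reduced).
#' @param rc Cutoff (1 in reduced units).
#' @return Scalar force along the unit separation vector (non-negative).
#' @export
conservative_force <- function(r, fmax, rc = 1) {
  stopifnot(all(r >= 0))
  ifelse(r < rc, fmax * (1 - r / rc), 0)
}

#' DPD dissipative force
#'
#' \eqn{-\gamma (\hat r \cdot v_{rel}) \hat r} inside the cutoff with the
#' constant weight function, zero beyond. Antisymmetric under particle
#' exchange, so each pair conserves momentum exactly.
#'
#' @param r Pair distance (> 0).
#' @param rhat Unit separation vector.
#' @param v_rel Relative velocity vector.
#' @param gamma Friction coefficient (reduced).
#' @param rc Cutoff.
#' @return Force vector on particle i.
#' @export
dissipative_force <- function(r, rhat, v_rel, gamma, rc = 1) {
  if (r == 0) stop("undefined direction: coincident particles", call. = FALSE)
  if (r >= rc) return(c(0, 0, 0))
  -gamma * sum(rhat * v_rel) * rhat
}

#' DPD random force
#'
#' \eqn{\sigma \theta_{ij} \hat r / \sqrt{\Delta t}} inside the cutoff,
#' with \eqn{\theta_{ij}} a zero-mean unit-variance white-noise variable
#' drawn from the uniform distribution on \eqn{[-\sqrt 3, \sqrt 3]}. One
#' draw is shared by each pair (equal and opposite on the partner), which
#' is what makes the DPD thermostat momentum-conserving. The
#' \eqn{1/\sqrt{\Delta t}} scaling keeps the sampled temperature
#' independent of the time step.
#'
#' @param r Pair distance (> 0).
#' @param rhat Unit separation vector.
#' @param sigma Noise strength (reduced).
#' @param dt Time step (reduced).
#' @param theta Optional noise value; drawn from the uniform distribution
#'   if missing (uses R's RNG).
#' @param rc Cutoff.
#' @return Force vector on particle i.
#' @export
random_force <- function(r, rhat, sigma, dt, theta = NULL, rc = 1) {
  if (r == 0) stop("undefined direction: coincident particles", call. = FALSE)
  if (r >= rc) return(c(0, 0, 0))
  if (is.null(theta)) theta <- sqrt(3) * (2 * runif(1) - 1)
  sigma * theta * rhat / sqrt(dt)
}

#' Harmonic bond force
#'
#' \eqn{F(r) = -K (r - r_0)} along the bond (restoring).
#'
#' @param r Bond length (reduced).
#' @param params List with reduced `K` and `r0` (see [reduce_bond()]).
#' @return Scalar force along the unit separation vector.
#' @export
bond_force <- function(r, params) {
  stopifnot(all(r >= 0))
  -params$K * (r - params$r0)
}

#' Minimum-image neighbour search
#'
#' All unordered pairs with minimum-image distance below the cutoff,
#' computed with the same linked-cell structure as the engine.
#'
#' @param positions N x 3 matrix (reduced units; may be unwrapped).
#' @param box_side Periodic cube side.
#' @param cutoff Search radius; must not exceed half the box.
#' @return Two-column integer matrix of 1-based pair indices (i < j).
#' @export
neighbor_search <- function(positions, box_side, cutoff) {
  stopifnot(is.matrix(positions), ncol(positions) == 3)
  if (cutoff > box_side / 2) {
    stop("geometry error: cutoff exceeds half the box side", call. = FALSE)
  }
  if (nrow(positions) == 0L) return(matrix(integer(0), 0L, 2L))
  p <- .cpp_neighbor_pairs(positions, box_side, cutoff)
  p[order(p[, 1], p[, 2]), , drop = FALSE]
}

#' Instantaneous kinetic temperature
#'
#' \eqn{2 E_{kin} / (3 (N - 1))} in reduced units, with the centre-of-mass
#' motion removed (it carries no thermal energy and DPD conserves it).
#'
#' @param velocities N x 3 matrix of reduced velocities.
#' @param mass Per-bead reduced masses (recycled).
#' @return Reduced temperature.
#' @export
instantaneous_temperature <- function(velocities, mass = 1) {
  stopifnot(is.matrix(velocities), ncol(velocities) == 3,
            nrow(velocities) >= 2)
  n <- nrow(velocities)
  mass <- rep_len(mass, n)
  vcom <- colSums(velocities * mass) / sum(mass)
  v <- sweep(velocities, 2, vcom)
  ke <- 0.5 * sum(mass * rowSums(v^2))
  2 * ke / (3 * (n - 1))
}

#' Simulation protocol
#'
#' Step counts and bookkeeping of a run. The full-scale defaults mirror
#' the published protocol: a Langevin pre-thermalization (1e6 steps), a DPD
#' thermalization (1e6 steps) and a 5e6-step production run at
#' `dt = 0.01` reduced time. Scale the step counts down for desk-size
#' experiments.
#'
#' @param dt Reduced time step.
#' @param pre_thermalization_steps Langevin-thermostatted warm-up steps
#'   (DPD engine only).
#' @param thermalization_steps Equilibration steps with the production
#'   thermostat; no snapshots are recorded.
#' @param production_steps Steps of the sampled production run.
#' @param snapshot_interval Steps between recorded frames.
#' @param log_interval Steps between kinetic-temperature log entries.
#' @param seed Integer seed; every stochastic element of the run derives
#'   from it.
#' @return An object of class `protocol`.
#' @export
protocol <- function(dt = 0.01, pre_thermalization_steps = 1e6,
                     thermalization_steps = 1e6, production_steps = 5e6,
                     snapshot_interval = 1000, log_interval = 10000,
                     seed = 1L) {
  stopifnot(dt > 0, pre_thermalization_steps >= 0,
            thermalization_steps >= 0, production_steps >= 0,
            snapshot_interval > 0, log_interval > 0)
  structure(list(dt = dt,
                 pre_thermalization_steps = as.integer(pre_thermalization_steps),
                 thermalization_steps = as.integer(thermalization_steps),
                 production_steps = as.integer(production_steps),
                 snapshot_interval = as.integer(snapshot_interval),
                 log_interval = as.integer(log_interval),
                 seed = as.integer(seed)),
            class = "protocol")
}

.engine_params <- function(ff, init, mode) {
  if (inherits(ff, "dpd_forcefield")) {
    amat <- matrix(c(ff$fmax_ww, ff$fmax_wm, ff$fmax_wm, ff$fmax_mm), 2, 2)
    list(mode = mode, amat = amat, gamma = ff$gamma, sigma = ff$sigma,
         gamma_lang = ff$gamma, wca_eps = 0, wca_sigma = 1,
         hydro_depth = 0, hydro_r1 = 0, hydro_r2 = 0, force_cap = 1e4,
         cutoff = ff$cutoff, bond_K = init$bond$K, bond_r0 = init$bond$r0)
  } else if (inherits(ff, "langevin_forcefield")) {
    list(mode = 2L, amat = matrix(0, 2, 2), gamma = 0, sigma = 0,
         gamma_lang = ff$damping, wca_eps = ff$wca_epsilon,
         wca_sigma = ff$wca_sigma, hydro_depth = ff$hydro_depth,
         hydro_r1 = ff$hydro_r1, hydro_r2 = ff$hydro_r2,
         force_cap = ff$force_cap, cutoff = ff$cutoff,
         bond_K = init$bond$K, bond_r0 = init$bond$r0)
  } else {
    stop("unknown force-field class", call. = FALSE)
  }
}

.maxwell_velocities <- function(n, mass, seed) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n), n, 3) / sqrt(mass)
  vcom <- colSums(v * mass) / sum(mass)
  sweep(v, 2, vcom)
}

#' Run a simulation
#'
#' Drives the compiled velocity-Verlet core through the protocol stages.
#' For a DPD force field: Langevin-thermostatted pre-thermalization, DPD
#' thermalization, DPD production. For a Langevin (implicit-solvent) force
#' field: thermalization and production under the per-bead Langevin
#' thermostat, with the pre-thermalization stage folded into
#' thermalization. Snapshots (unwrapped positions of every bead) are
#' recorded during production only; an extra frame of the final
#' thermalized state is always included, so a zero-length production still
#' yields one frame.
#'
#' The run is bit-reproducible: all randomness (initial velocities, pair
#' noise, thermostat noise) derives from `protocol$seed`.
#'
#' @param init An [initial_configuration()] (or
#'   [polymer_configuration()]).
#' @param ff A [build_forcefield()] or [langevin_forcefield()] object.
#' @param proto A [protocol()].
#' @return A `trajectory` object: `frames` (list of `step`, `box_side`,
#'   `xyz` unwrapped N x 3 matrices), `types`, `polymer_indices`, `bonds`,
#'   `temperature` (K), `engine`, `seed`, and `temp_log` (data.frame of
#'   kinetic temperature vs step).
#' @export
run_simulation <- function(init, ff, proto = protocol()) {
  stopifnot(inherits(init, "initial_configuration"),
            inherits(proto, "protocol"))
  is_dpd <- inherits(ff, "dpd_forcefield")
  n <- nrow(init$positions)
  type <- ifelse(init$bead_types == "water", 0L, 1L)
  mass <- ifelse(type == 0L, 1, ff$units$monomer_mass_reduced)
  if (!is_dpd) mass <- rep(1, n)  # implicit solvent: monomer mass unit

  pos <- init$positions
  vel <- .maxwell_velocities(n, mass, proto$seed)
  bonds <- init$bonds
  storage.mode(bonds) <- "integer"

  stages <- if (is_dpd) {
    list(list(mode = 1L, steps = proto$pre_thermalization_steps, snap = 0L),
         list(mode = 0L, steps = proto$thermalization_steps, snap = 0L),
         list(mode = 0L, steps = proto$production_steps,
              snap = proto$snapshot_interval))
  } else {
    list(list(mode = 2L,
              steps = proto$pre_thermalization_steps + proto$thermalization_steps,
              snap = 0L),
         list(mode = 2L, steps = proto$production_steps,
              snap = proto$snapshot_interval))
  }

  frames <- list()
  temp_log <- list()
  step_offset <- 0L
  for (si in seq_along(stages)) {
    st <- stages[[si]]
    if (st$steps == 0L) next
    params <- .engine_params(ff, init, st$mode)
    out <- .cpp_run(pos, vel, mass, type, init$box_side, proto$dt,
                    st$steps, params, bonds,
                    seed = (proto$seed * 1000003 + si * 7919) %% 2^31,
                    snapshot_every = st$snap,
                    log_every = proto$log_interval,
                    step_offset = step_offset)
    pos <- out$positions
    vel <- out$velocities
    if (out$n_snapshots > 0) {
      for (k in seq_len(out$n_snapshots)) {
        xyz <- matrix(out$snapshots[((k - 1) * n * 3 + 1):(k * n * 3)], n, 3)
        frames[[length(frames) + 1]] <-
          list(step = out$snapshot_steps[k], box_side = init$box_side,
               xyz = xyz)
      }
    }
    if (out$n_logs > 0) {
      temp_log[[length(temp_log) + 1]] <-
        data.frame(step = out$temperature_steps[seq_len(out$n_logs)],
                   T_kin = out$temperatures[seq_len(out$n_logs)])
    }
    step_offset <- step_offset + st$steps
  }
  if (length(frames) == 0L) {
    frames[[1]] <- list(step = step_offset, box_side = init$box_side,
                        xyz = pos)
  }

  structure(list(
    frames = frames,
    types = init$bead_types,
    polymer_indices = init$polymer_indices,
    bonds = init$bonds,
    box_side = init$box_side,
    temperature = ff$temperature,
    engine = if (is_dpd) "dpd" else "langevin",
    seed = proto$seed,
    units = ff$units,
    temp_log = if (length(temp_log)) do.call(rbind, temp_log) else NULL,
    final_state = list(positions = pos, velocities = vel)
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory (%s engine, %.5g K): %d beads, %d frames, box %.4g rc\n",
    x$engine, x$temperature, length(x$types), length(x$frames),
    x$box_side))
  invisible(x)
}

#' Deterministic pairwise forces of a configuration
#'
#' Conservative, dissipative and bond forces evaluated by the compiled
#' cell-list core (random contributions excluded), mainly for validation
#' against brute-force references.
#'
#' @param positions,velocities N x 3 matrices (reduced).
#' @param types Character vector, "water"/"monomer".
#' @param box_side Cube side.
#' @param ff Force field object.
#' @param bonds Two-column bond matrix (may have zero rows).
#' @param bond Reduced bond parameters (list `K`, `r0`).
#' @param dt Time step (enters only the excluded random term).
#' @return N x 3 matrix of forces.
#' @export
compute_forces <- function(positions, velocities, types, box_side, ff,
                           bonds = matrix(integer(0), 0, 2),
                           bond = list(K = 0, r0 = 1), dt = 0.01) {
  type <- ifelse(types == "water", 0L, 1L)
  mass <- rep(1, nrow(positions))
  storage.mode(bonds) <- "integer"
  params <- .engine_params(ff, list(bond = bond), mode = 0L)
  .cpp_compute_forces(positions, velocities, mass, type, box_side, dt,
                      params, bonds)
}
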