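# Shared helpers: tiny systems built in code.

# a pure-water DPD box at reduced density 3 (no polymer)
water_box <- function(n_beads, temperature = 298.15, seed = 1) {
  ff <- build_forcefield(temperature)
  box <- (n_beads / 3)^(1 / 3)
  set.seed(seed)
  pos <- matrix(runif(3 * n_beads, 0, box), n_beads, 3)
  init <- structure(list(
    positions = pos,
    bead_types = rep("water", n_beads),
    polymer_indices = integer(0),
    bonds = matrix(integer(0), 0, 2),
    bead_roles = character(0),
    box_side = box,
    rho_reduced = 3,
    counts = c(polymer = 0L, water = n_beads),
    bond = list(K = 0, r0 = 1),
    bond_physical = bond_params(),
    units = ff$units,
    seed = as.integer(seed)
  ), class = "initial_configuration")
  list(init = init, ff = ff, box = box)
}

# a free-bead (non-interacting) configuration for Langevin thermostat tests
free_beads <- function(n_beads, temperature = 298.15, box = 30, seed = 1) {
  ff <- langevin_forcefield(temperature, wca_epsilon = 0, hydro_slope = 0)
  set.seed(seed)
  pos <- matrix(runif(3 * n_beads, 0, box), n_beads, 3)
  init <- structure(list(
    positions = pos,
    bead_types = rep("monomer", n_beads),
    polymer_indices = seq_len(n_beads),
    bonds = matrix(integer(0), 0, 2),
    bead_roles = rep("monomer", n_beads),
    box_side = box,
    rho_reduced = NA_real_,
    counts = c(polymer = n_beads, water = 0L),
    bond = list(K = 0, r0 = 1),
    bond_physical = bond_params(),
    units = ff$units,
    seed = as.integer(seed)
  ), class = "initial_configuration")
  list(init = init, ff = ff)
}

# wrap a list of coordinate matrices into a trajectory object
make_traj <- function(frames_xyz, types, box, temperature = 298.15,
                      engine = "dpd", bonds = matrix(integer(0), 0, 2)) {
  frames <- lapply(seq_along(frames_xyz), function(i) {
    list(step = i, box_side = box, xyz = frames_xyz[[i]])
  })
  structure(list(
    frames = frames,
    types = types,
    polymer_indices = which(types == "monomer"),
    bonds = bonds,
    box_side = box,
    temperature = temperature,
    engine = engine,
    seed = 1L,
    units = NULL,
    temp_log = NULL
  ), class = "trajectory")
}

# brute-force reference forces: conservative + dissipative + harmonic bonds,
# all pairs, minimum image (independent of the cell-list machinery)
brute_forces <- function(pos, vel, types, box, ff, bonds = NULL,
                         bond = list(K = 0, r0 = 1)) {
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  amat <- matrix(c(ff$fmax_ww, ff$fmax_wm, ff$fmax_wm, ff$fmax_mm), 2, 2)
  ti <- ifelse(types == "water", 1L, 2L)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      d <- d - box * round(d / box)
      r <- sqrt(sum(d^2))
      if (r < ff$cutoff && r > 0) {
        rhat <- d / r
        fc <- amat[ti[i], ti[j]] * (1 - r / ff$cutoff)
        fd <- -ff$gamma * sum(rhat * (vel[i, ] - vel[j, ]))
        fv <- (fc + fd) * rhat
        f[i, ] <- f[i, ] + fv
        f[j, ] <- f[j, ] - fv
      }
    }
  }
  if (!is.null(bonds) && nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      d <- pos[i, ] - pos[j, ]
      d <- d - box * round(d / box)
      r <- sqrt(sum(d^2))
      fv <- -bond$K * (r - bond$r0) * d / r
      f[i, ] <- f[i, ] + fv
      f[j, ] <- f[j, ] - fv
    }
  }
  f
}
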