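# Initial configuration: geometric embedding of the network plus solvent
# fill, all in reduced (rc = 1) units.

#' Harmonic bond parameters
#'
#' Defaults are the elastic constant 0.4 N/m and equilibrium length 6.5 A
#' shared by the coarse-grained PNIPAM bead-spring models this package
#' follows; the same bonded interaction is used by both engines.
#'
#' @param K Elastic constant (N/m).
#' @param r0_A Equilibrium bond length (angstrom).
#' @return An object of class `bond_params`.
#' @export
bond_params <- function(K = 0.4, r0_A = 6.5) {
  stopifnot(K > 0, r0_A > 0)
  structure(list(K = K, r0_A = r0_A), class = "bond_params")
}

#' Convert bond parameters to reduced units
#'
#' @param bond A [bond_params()].
#' @param units A [reduced_units()] system.
#' @return List with `K` (energy/length^2, reduced) and `r0` (reduced).
#' @export
reduce_bond <- function(bond, units) {
  stopifnot(inherits(bond, "bond_params"), inherits(units, "reduced_units"))
  list(K = bond$K * units$rc^2 / units$energy_unit,
       r0 = bond$r0_A * 1e-10 / units$rc)
}

# Chain beads are laid on a circular arc between their two endpoint
# crosslinkers so that all bonds share one length >= half the equilibrium
# length even when the end-to-end distance is much shorter than the chain
# contour. Returns an (n_interior x 3) matrix.
.arc_chain <- function(p0, p1, n_interior, bond_target) {
  s <- sqrt(sum((p1 - p0)^2))
  nseg <- n_interior + 1
  if (bond_target * nseg <= s * 1.0001) {
    # chain is (almost) taut: straight placement
    frac <- seq_len(n_interior) / nseg
    return(p0[rep(1, n_interior)] + outer(frac, p1 - p0))
  }
  u <- (p1 - p0) / s
  # deterministic perpendicular: least-aligned coordinate axis
  ax <- diag(3)[, which.min(abs(u))]
  perp <- ax - sum(ax * u) * u
  perp <- perp / sqrt(sum(perp^2))
  # central angle phi with nseg equal chords of length bond_target:
  #   s = 2 R sin(phi/2), bond_target = 2 R sin(phi/(2 nseg))
  f <- function(phi) sin(phi / 2) / (nseg * sin(phi / (2 * nseg))) -
    s / (nseg * bond_target)
  phi <- stats::uniroot(f, c(1e-8, 1.99 * pi), tol = 1e-12)$root
  R <- s / (2 * sin(phi / 2))
  centre <- p0 + u * (s / 2) - perp * (R * cos(phi / 2))
  th0 <- atan2(R * cos(phi / 2), -s / 2)
  th1 <- th0 - phi
  th <- th0 - seq_len(n_interior) * (th0 - th1) / nseg
  lx <- R * cos(th)
  ly <- R * sin(th)
  t(vapply(seq_len(n_interior),
           function(k) centre + u * lx[k] + perp * ly[k], numeric(3)))
}

#' Build an initial simulation configuration
#'
#' Embeds the nanogel in the centre of a periodic cube and fills the rest
#' with water beads. Crosslinker sites keep their diamond-lattice geometry
#' scaled to `site_spacing`; the monomer chains joining them are bent onto
#' circular arcs so every initial bond length lies in
#' `[0.5 r0, 2 r0]`. Water beads are inserted uniformly at random,
#' rejecting positions closer than `water_min_dist` to any polymer bead
#' (soft DPD potentials tolerate the remaining mild overlaps, which the
#' thermalization stages relax), then trimmed to the target count.
#'
#' @param topology A `nanogel_topology`.
#' @param box_side Cube side in reduced (rc) units.
#' @param units A [reduced_units()] system (sets the reduced bond length).
#' @param rho_reduced Target total reduced density (beads per rc^3).
#' @param bond A [bond_params()].
#' @param seed Integer seed; the fill is deterministic given the seed.
#' @param water_count Optional override of the water bead count. The
#'   default derives it from the density target,
#'   `round(rho_reduced * box_side^3) - n_polymer`.
#' @param site_spacing Distance between bonded crosslinker sites in the
#'   embedding (rc units).
#' @param water_min_dist Minimum insertion distance from polymer beads.
#' @return An object of class `initial_configuration`: `positions`
#'   (N x 3, polymer beads first), `bead_types`, `polymer_indices`,
#'   `bonds`, `box_side`, `counts`, plus the reduced bond parameters.
#' @export
initial_configuration <- function(topology, box_side, units,
                                  rho_reduced = 3, bond = bond_params(),
                                  seed = 1L, water_count = NULL,
                                  site_spacing = 2.2,
                                  water_min_dist = 0.3) {
  stopifnot(inherits(topology, "nanogel_topology"),
            inherits(units, "reduced_units"), box_side > 0)
  rb <- reduce_bond(bond, units)
  np <- length(topology$bead_ids)
  scale <- site_spacing / (sqrt(3) / 4)

  xyz <- topology$lattice_xyz * scale
  centre <- colMeans(xyz)
  xyz <- sweep(xyz, 2, centre)

  # rebuild chain-bead positions on arcs
  is_x <- topology$bead_roles == "crosslinker"
  adj <- vector("list", np)
  b <- topology$bonds
  for (e in seq_len(nrow(b))) {
    adj[[b[e, 1]]] <- c(adj[[b[e, 1]]], b[e, 2])
    adj[[b[e, 2]]] <- c(adj[[b[e, 2]]], b[e, 1])
  }
  bond_target <- 0.65 * rb$r0
  visited <- logical(np)
  for (x in which(is_x)) {
    for (nb in adj[[x]]) {
      if (is_x[nb] || visited[nb]) next
      chain <- integer(0)
      prev <- x; cur <- nb
      repeat {
        chain <- c(chain, cur)
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) == 0L || is_x[nxt[1]]) {
          endpt <- if (length(nxt)) nxt[1] else NA_integer_
          break
        }
        prev <- cur; cur <- nxt[1]
      }
      visited[chain] <- TRUE
      if (is.na(endpt)) {
        # dangling chain: zigzag along its lattice direction, so it stays
        # inside the pruning sphere while keeping uniform bond lengths
        dirv <- xyz[chain[length(chain)], ] - xyz[x, ]
        nd <- sqrt(sum(dirv^2))
        dirv <- if (nd > 1e-12) dirv / nd else c(1, 0, 0)
        ax <- diag(3)[, which.min(abs(dirv))]
        perp <- ax - sum(ax * dirv) * dirv
        perp <- perp / sqrt(sum(perp^2))
        d <- nd / length(chain)
        h <- if (d >= bond_target) 0 else sqrt(bond_target^2 - d^2)
        for (k in seq_along(chain)) {
          xyz[chain[k], ] <- xyz[x, ] + dirv * d * k +
            perp * h * (k %% 2)
        }
      } else {
        xyz[chain, ] <- .arc_chain(xyz[x, ], xyz[endpt, ], length(chain),
                                   bond_target)
      }
    }
  }

  radius <- max(sqrt(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
  if (2 * radius + 1 > box_side) {
    stop("geometry error: embedded network diameter ",
         signif(2 * radius, 4), " rc does not fit in box of side ",
         box_side, " rc", call. = FALSE)
  }
  poly <- sweep(xyz, 2, colMeans(xyz))
  poly <- poly + box_side / 2

  blen <- sqrt(rowSums((poly[b[, 1], , drop = FALSE] -
                          poly[b[, 2], , drop = FALSE])^2))
  if (any(blen < 0.5 * rb$r0 - 1e-9) || any(blen > 2 * rb$r0 + 1e-9)) {
    stop("geometry error: initial bond lengths outside [0.5 r0, 2 r0]",
         call. = FALSE)
  }

  n_total <- round(rho_reduced * box_side^3)
  n_water <- if (is.null(water_count)) n_total - np else as.integer(water_count)
  if (n_water < 0) stop("geometry error: box too small for the polymer ",
                        "at the requested density", call. = FALSE)

  set.seed(seed)
  water <- matrix(NA_real_, 0L, 3L)
  tries <- 0L
  while (nrow(water) < n_water && tries < 50L) {
    m <- max(1000L, ceiling(1.4 * (n_water - nrow(water))))
    cand <- matrix(runif(3L * m, 0, box_side), ncol = 3L)
    dmin <- .cpp_min_dist_to_set(cand, poly, box_side)
    water <- rbind(water, cand[dmin >= water_min_dist, , drop = FALSE])
    tries <- tries + 1L
  }
  if (nrow(water) < n_water) {
    stop("geometry error: could not place ", n_water, " water beads with ",
         "minimum distance ", water_min_dist, call. = FALSE)
  }
  water <- water[seq_len(n_water), , drop = FALSE]

  structure(list(
    positions = rbind(poly, water),
    bead_types = c(rep("monomer", np), rep("water", n_water)),
    polymer_indices = seq_len(np),
    bonds = topology$bonds,
    bead_roles = topology$bead_roles,
    box_side = box_side,
    rho_reduced = rho_reduced,
    counts = c(polymer = np, water = n_water),
    bond = rb,
    bond_physical = bond,
    units = units,
    seed = as.integer(seed)
  ), class = "initial_configuration")
}

#' @export
print.initial_configuration <- function(x, ...) {
  cat(sprintf(
    "Initial configuration: box %.4g rc, %d polymer + %d water beads (density %.3f)\n",
    x$box_side, x$counts["polymer"], x$counts["water"],
    nrow(x$positions) / x$box_side^3))
  invisible(x)
}

#' Polymer-only initial configuration for the implicit-solvent engine
#'
#' Same geometric embedding as [initial_configuration()] but with no
#' solvent fill; used with `engine = "langevin"`.
#'
#' @inheritParams initial_configuration
#' @return An `initial_configuration` with zero water beads.
#' @export
polymer_configuration <- function(topology, box_side, units,
                                  bond = bond_params(), seed = 1L,
                                  site_spacing = 2.2) {
  cfg <- initial_configuration(topology, box_side, units,
                               rho_reduced = 3, bond = bond, seed = seed,
                               water_count = 0L,
                               site_spacing = site_spacing)
  cfg$rho_reduced <- NA_real_
  cfg
}
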