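# Implicit-solvent comparison mode: Langevin dynamics of the polymer only,
# with WCA excluded volume, the shared harmonic bonds, and a
# temperature-dependent hydrophobic attraction standing in for the solvent.

#' WCA (purely repulsive Lennard-Jones) force
#'
#' The 12-6 interaction truncated at its minimum \eqn{2^{1/6}\sigma} and
#' shifted, leaving only the repulsive core: the standard excluded-volume
#' interaction of hard-sphere-like bead-spring models.
#'
#' @param r Distance (> 0).
#' @param eps Energy scale (reduced kBT).
#' @param sigma Effective bead diameter (reduced length).
#' @param force_cap Cap on the returned force; guards the \eqn{r \to 0}
#'   overflow at initialization.
#' @return Scalar force along the separation vector (>= 0, repulsive).
#' @export
wca_force <- function(r, eps = 1, sigma = 1, force_cap = 1e4) {
  stopifnot(all(r > 0))
  sr6 <- (sigma / r)^6
  f <- ifelse(r < 2^(1 / 6) * sigma, 24 * eps * (2 * sr6^2 - sr6) / r, 0)
  pmin(f, force_cap)
}

#' Temperature-dependent hydrophobic attraction
#'
#' A cosine-smoothed square well between monomer beads standing in for the
#' solvent-mediated hydrophobic effect of the implicit-solvent model:
#' \deqn{U(r) = -\epsilon_h(T) \cos^2\!\big(\tfrac{\pi}{2}
#'   \tfrac{r - r_1}{r_2 - r_1}\big), \quad r_1 < r < r_2,}
#' flat at depth \eqn{-\epsilon_h(T)} for \eqn{r \le r_1} and zero beyond
#' \eqn{r_2} (smooth at both ends). The depth grows linearly with
#' temperature above an onset, \eqn{\epsilon_h(T) = s (T - T_{on})_+}
#' in kBT units, so heating deepens the attraction and collapses the gel.
#'
#' @param r Distance (> 0).
#' @param temperature Temperature (K).
#' @param params List with `r1`, `r2` (reduced lengths), `slope`
#'   (kBT per K) and `T_onset` (K); see [langevin_forcefield()] defaults.
#' @return Scalar force along the separation vector (negative =
#'   attractive); zero outside `(0, r2)`.
#' @export
hydrophobic_force <- function(r, temperature, params) {
  stopifnot(all(r > 0))
  depth <- hydro_depth(temperature, params$slope, params$T_onset)
  w <- params$r2 - params$r1
  u <- (r - params$r1) / w
  ifelse(r >= params$r2 | r <= params$r1, 0,
         -depth * (pi / (2 * w)) * sin(pi * u))
}

#' Hydrophobic well depth at a temperature
#'
#' @param temperature Temperature (K).
#' @param slope Depth increase per kelvin (kBT units).
#' @param T_onset Temperature (K) below which the attraction vanishes.
#' @return Depth in kBT units (non-negative, non-decreasing in T).
#' @export
hydro_depth <- function(temperature, slope = 0.026, T_onset = 270) {
  pmax(0, slope * (temperature - T_onset))
}

#' Implicit-solvent (Langevin) force field
#'
#' Bundles the WCA excluded volume, the temperature-dependent hydrophobic
#' attraction and the per-bead Langevin thermostat for the polymer-only
#' comparison mode. Lengths are reduced by the DPD cutoff at the same
#' temperature so both engines share one unit system and the analysis is
#' engine-agnostic. The defaults put the bead diameter at the bond length
#' scale (6.5 A) and let the attraction reach ~1.6 kBT at 330 K, deep
#' enough to collapse the network above the transition while leaving it
#' swollen at 280 K.
#'
#' @param temperature Temperature (K).
#' @param beads A [bead_spec()] (sets the unit system).
#' @param wca_epsilon WCA energy scale (kBT).
#' @param wca_sigma_A Bead diameter (angstrom).
#' @param hydro_slope Attraction depth slope (kBT per K).
#' @param hydro_onset Onset temperature (K).
#' @param hydro_range_factor Outer cutoff of the attraction as a multiple
#'   of `wca_sigma`.
#' @param damping Reduced friction constant of the thermostat.
#' @param force_cap Repulsive force cap (guards overlapping initial
#'   placements).
#' @return An object of class `langevin_forcefield`.
#' @export
langevin_forcefield <- function(temperature, beads = bead_spec(),
                                wca_epsilon = 1, wca_sigma_A = 6.5,
                                hydro_slope = 0.026, hydro_onset = 270,
                                hydro_range_factor = 2,
                                damping = 1, force_cap = 1e4) {
  units <- reduced_units(temperature, beads)
  sig <- wca_sigma_A * 1e-10 / units$rc
  r1 <- 2^(1 / 6) * sig
  r2 <- hydro_range_factor * sig
  stopifnot(r2 > r1)
  structure(list(
    temperature = temperature,
    wca_epsilon = wca_epsilon,
    wca_sigma = sig,
    hydro_depth = hydro_depth(temperature, hydro_slope, hydro_onset),
    hydro_slope = hydro_slope,
    hydro_onset = hydro_onset,
    hydro_r1 = r1,
    hydro_r2 = r2,
    damping = damping,
    force_cap = force_cap,
    cutoff = max(r1, r2),
    units = units
  ), class = "langevin_forcefield")
}

#' @export
print.langevin_forcefield <- function(x, ...) {
  cat(sprintf("Langevin (implicit-solvent) force field at %.5g K:\n",
              x$temperature))
  cat(sprintf("  WCA: eps = %.3g, sigma = %.3g rc (%.3g A)\n",
              x$wca_epsilon, x$wca_sigma, x$wca_sigma * x$units$rc * 1e10))
  cat(sprintf("  hydrophobic well: depth = %.3g kBT over (%.3g, %.3g) rc\n",
              x$hydro_depth, x$hydro_r1, x$hydro_r2))
  cat(sprintf("  damping = %.3g (reduced)\n", x$damping))
  invisible(x)
}
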