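# Temperature-dependent DPD force-field parameterization.
#
# The chain of quantities, all in reduced units (kBT = 1, rc = 1, water-bead
# mass = 1) unless stated otherwise:
#   chi(T)            Flory-Huggins water-monomer parameter (fitted law)
#   rc(T)             cutoff, fixed by the reduced density and water density
#   k_inv(T)          dimensionless inverse isothermal compressibility
#   fmax_ww(T)        water-water repulsion (Groot-Warren compressibility
#                     matching, generalized by the coarse-graining number)
#   p(T)              matching pressure, from inverting the equation of state
#                     at the water self-repulsion
#   fmax_mm(T)        monomer-monomer repulsion from the same pressure
#   fmax_wm(T)        cross repulsion: geometric-mean baseline plus a
#                     chi-linear excess (unequal-volume generalization)

#' Flory-Huggins temperature model
#'
#' The fitted temperature law \eqn{\chi(T) = 0.5 + A (1 - \Theta/T)}.
#' At the theta temperature the polymer-solvent interaction is exactly the
#' athermal value 0.5; above it water turns into a poor solvent and the gel
#' collapses. The defaults are the values fitted to PNIPAM microgel swelling
#' data.
#'
#' @param A Dimensionless fit amplitude.
#' @param theta Theta temperature in kelvin.
#' @return An object of class `fh_model`.
#' @export
fh_model <- function(A = 35.2, theta = 308.3) {
  stopifnot(is.numeric(A), is.numeric(theta))
  if (theta <= 0) stop("theta temperature must be positive", call. = FALSE)
  structure(list(A = A, theta = theta), class = "fh_model")
}

#' @export
print.fh_model <- function(x, ...) {
  cat(sprintf("Flory-Huggins model: chi(T) = 0.5 + %.3g (1 - %.4g/T)\n",
              x$A, x$theta))
  invisible(x)
}

#' Flory-Huggins interaction parameter at a temperature
#'
#' @param temperature Temperature in kelvin (positive).
#' @param model A [fh_model()].
#' @return The dimensionless \eqn{\chi} value; strictly increasing in
#'   temperature, equal to 0.5 at the theta temperature.
#' @examples
#' chi_of_temperature(308.3)  # exactly 0.5
#' chi_of_temperature(330)    # poor solvent, ~2.8
#' @export
chi_of_temperature <- function(temperature, model = fh_model()) {
  stopifnot(inherits(model, "fh_model"))
  if (any(temperature <= 0)) {
    stop("temperature must be positive (kelvin)", call. = FALSE)
  }
  0.5 + model$A * (1 - model$theta / temperature)
}

#' Bead specification for the coarse-grained model
#'
#' One water bead lumps `Nm` water molecules; one monomer bead is one NIPAM
#' monomer. The default pure monomer number density follows from bulk PNIPAM
#' (1.1 g/cm^3) and the monomer molar mass, which makes the monomer bead
#' volume (~171 A^3) close to the 5-water bead (~150 A^3) so that the two
#' bead types have similar volumes.
#'
#' @param Nm Water molecules per water bead (integer, >= 1).
#' @param water_molar_mass Molar mass of water (g/mol).
#' @param monomer_molar_mass Molar mass of the monomer (g/mol).
#' @param monomer_mass_density Pure (bulk) mass density of the polymer
#'   (kg/m^3).
#' @return An object of class `bead_spec` with the derived
#'   `rho_pure_monomer` (beads/m^3) and `water_molecule_mass` (kg).
#' @export
bead_spec <- function(Nm = 5L, water_molar_mass = .M_WATER,
                      monomer_molar_mass = 113.16,
                      monomer_mass_density = 1100) {
  Nm <- as.integer(Nm)
  if (Nm < 1L) stop("Nm must be a positive integer", call. = FALSE)
  if (monomer_molar_mass <= 0 || monomer_mass_density <= 0 ||
      water_molar_mass <= 0) {
    stop("masses and densities must be strictly positive", call. = FALSE)
  }
  structure(list(
    Nm = Nm,
    water_molar_mass = water_molar_mass,
    monomer_molar_mass = monomer_molar_mass,
    monomer_mass_density = monomer_mass_density,
    water_molecule_mass = water_molar_mass * 1e-3 / .NA,
    rho_pure_monomer = monomer_mass_density /
      (monomer_molar_mass * 1e-3 / .NA)
  ), class = "bead_spec")
}

#' @export
print.bead_spec <- function(x, ...) {
  cat(sprintf(
    "Bead spec: Nm = %d water molecules/bead; monomer %.5g g/mol at %.4g kg/m^3\n",
    x$Nm, x$monomer_molar_mass, x$monomer_mass_density))
  invisible(x)
}

#' Interaction cutoff radius
#'
#' The cutoff is fixed by imposing the reduced number density
#' \eqn{\tilde\rho}: \eqn{r_c = (\tilde\rho N_m m_w / \rho_w)^{1/3}}, so one
#' cutoff-cube holds \eqn{\tilde\rho} water beads at the experimental water
#' density. Because the water density depends on temperature, so does the
#' cutoff, which serves as the length conversion factor.
#'
#' @param temperature Temperature (K); used to look up the water density
#'   unless `rho_water` is given.
#' @param Nm Water molecules per bead.
#' @param rho_reduced Target reduced density (3 for all packaged defaults).
#' @param rho_water Optional water mass density override (kg/m^3).
#' @param water_molecule_mass Mass of one water molecule (kg).
#' @return Cutoff radius in metres.
#' @export
cutoff_radius <- function(temperature, Nm = 5L, rho_reduced = 3,
                          rho_water = NULL,
                          water_molecule_mass = .M_WATER * 1e-3 / .NA) {
  if (is.null(rho_water)) rho_water <- water_properties(temperature)$density
  stopifnot(Nm > 0, rho_reduced > 0, rho_water > 0, water_molecule_mass > 0)
  (rho_reduced * Nm * water_molecule_mass / rho_water)^(1 / 3)
}

#' Dimensionless inverse isothermal compressibility
#'
#' \eqn{\tilde\kappa^{-1} = 1 / (\rho_w k_B T \kappa_T)} with
#' \eqn{\rho_w} the number density of water molecules. For ambient water this
#' is about 16, the value underpinning the classic repulsion
#' \eqn{a \approx 25} at reduced density 3.
#'
#' @param temperature Temperature (K).
#' @param rho_number_water Number density of water molecules (1/m^3).
#' @param kappa_T Isothermal compressibility (1/Pa).
#' @return Dimensionless inverse compressibility.
#' @export
inverse_compressibility <- function(temperature, rho_number_water, kappa_T) {
  stopifnot(temperature > 0, rho_number_water > 0, kappa_T > 0)
  1 / (rho_number_water * .kB * temperature * kappa_T)
}

#' Water-water maximum repulsion
#'
#' Compressibility matching in reduced units:
#' \eqn{F^{max}_{ww} = (N_m \tilde\kappa^{-1} - 1) / (2 \alpha \tilde\rho)}.
#' With \eqn{N_m = 1}, \eqn{\tilde\kappa^{-1} = 16} and
#' \eqn{\tilde\rho = 3} this recovers the classic repulsion parameter
#' \eqn{a \approx 25}.
#'
#' @param Nm Water molecules per bead.
#' @param k_inv Dimensionless inverse compressibility
#'   ([inverse_compressibility()]).
#' @param rho_reduced Reduced density.
#' @param alpha Excess-pressure scaling constant of the DPD equation of
#'   state (0.101).
#' @return Reduced maximum repulsion between water beads.
#' @export
fmax_water <- function(Nm, k_inv, rho_reduced = 3, alpha = 0.101) {
  stopifnot(Nm >= 1, k_inv > 0, rho_reduced > 0, alpha > 0)
  if (Nm * k_inv <= 1) {
    stop("invalid parameterization: Nm * k_inv must exceed 1 ",
         "(ideal-gas limit)", call. = FALSE)
  }
  (Nm * k_inv - 1) / (2 * alpha * rho_reduced)
}

#' Matching pressure of the DPD equation of state
#'
#' Inverts the equation of state \eqn{p = \tilde\rho + \alpha F^{max}
#' \tilde\rho^2} at the water self-repulsion. This "applied pressure" is a
#' bookkeeping quantity of the unequal-volume parameterization, not the
#' physical pressure of the simulated system; every bead type's
#' self-repulsion is then derived from the same p.
#'
#' @param fmax_ww Water-water repulsion (reduced).
#' @param rho_reduced Reduced water density.
#' @param alpha Equation-of-state constant.
#' @return Reduced matching pressure.
#' @export
matching_pressure <- function(fmax_ww, rho_reduced = 3, alpha = 0.101) {
  stopifnot(fmax_ww >= 0, rho_reduced > 0, alpha > 0)
  rho_reduced + alpha * fmax_ww * rho_reduced^2
}

#' Self-repulsion of a bead type from the matching pressure
#'
#' \eqn{F^{max}_{ii} = (p - \tilde\rho_{i,pure}) / (\alpha
#' \tilde\rho_{i,pure}^2)} in reduced units: each pure component, at its own
#' pure reduced number density, is required to sit at the common matching
#' pressure. Applied to water this is the exact inverse of
#' [matching_pressure()].
#'
#' @param p Matching pressure (reduced).
#' @param rho_pure Pure reduced number density of the bead type.
#' @param alpha Equation-of-state constant.
#' @return Reduced self-repulsion (non-negative).
#' @export
fmax_self <- function(p, rho_pure, alpha = 0.101) {
  stopifnot(rho_pure > 0, alpha > 0)
  if (p < rho_pure) {
    stop("invalid parameterization: matching pressure ", signif(p, 6),
         " below ideal-gas pressure of density ", signif(rho_pure, 6),
         " (would give negative repulsion)", call. = FALSE)
  }
  (p - rho_pure) / (alpha * rho_pure^2)
}

#' Cross-interaction repulsion between two bead types
#'
#' Geometric-mean baseline plus a chi-linear excess,
#' \deqn{F^{max}_{ij} = \sqrt{F^{max}_{ii} F^{max}_{jj}} +
#'   \frac{\chi\, p}{0.0454\,(F^{max}_{ii}\rho_{i} + F^{max}_{jj}\rho_{j})}}
#' (reduced units; \eqn{\rho} are the pure reduced densities). At
#' \eqn{\chi = 0} two unlike beads repel exactly at the geometric mean of
#' their self terms; a positive \eqn{\chi} (poor solvent) adds excess
#' repulsion linear in \eqn{\chi}. For two identical classic water beads
#' (repulsion 25 at reduced density 3) the excess slope is ~3.8 per unit
#' \eqn{\chi}, of the same order as the Groot-Warren proportionality
#' \eqn{\Delta a \approx 3.27 \chi}.
#'
#' The full excess expression, including its 0.0454 constant, is isolated
#' here so callers are untouched if the functional form is revised.
#'
#' @param fmax_ii,fmax_jj Self-repulsions (reduced, non-negative).
#' @param chi Flory-Huggins parameter between the two types.
#' @param p Matching pressure (reduced).
#' @param rho_i,rho_j Pure reduced number densities of the two types.
#' @return Reduced cross repulsion.
#' @export
fmax_cross <- function(fmax_ii, fmax_jj, chi, p, rho_i, rho_j) {
  stopifnot(fmax_ii >= 0, fmax_jj >= 0, rho_i > 0, rho_j > 0)
  baseline <- sqrt(fmax_ii * fmax_jj)
  if (chi == 0) return(baseline)
  denom <- 0.0454 * (fmax_ii * rho_i + fmax_jj * rho_j)
  if (denom <= 0) {
    stop("cross-term density weighting is degenerate (zero self-repulsion)",
         call. = FALSE)
  }
  baseline + chi * p / denom
}

#' Reduced-unit system at a temperature
#'
#' Base quantities: length = interaction cutoff \eqn{r_c(T)}, mass = one
#' water bead (\eqn{N_m m_w}), energy = \eqn{k_B T}. The derived time unit
#' is \eqn{\tilde t = r_c \sqrt{m / k_B T}}.
#'
#' @param temperature Temperature (K).
#' @param beads A [bead_spec()].
#' @param rho_reduced Target reduced density.
#' @return An object of class `reduced_units` with fields `rc` (m),
#'   `mass_unit` (kg), `energy_unit` (J), `time_unit` (s), `rho_reduced`,
#'   and the derived reduced monomer pure density `rho_monomer_reduced` and
#'   reduced monomer bead mass `monomer_mass_reduced`.
#' @export
reduced_units <- function(temperature, beads = bead_spec(), rho_reduced = 3) {
  stopifnot(inherits(beads, "bead_spec"))
  rc <- cutoff_radius(temperature, beads$Nm, rho_reduced,
                      water_molecule_mass = beads$water_molecule_mass)
  mass_unit <- beads$Nm * beads$water_molecule_mass
  energy_unit <- .kB * temperature
  structure(list(
    temperature = temperature,
    rc = rc,
    mass_unit = mass_unit,
    energy_unit = energy_unit,
    time_unit = rc * sqrt(mass_unit / energy_unit),
    force_unit = energy_unit / rc,
    rho_reduced = rho_reduced,
    rho_monomer_reduced = beads$rho_pure_monomer * rc^3,
    monomer_mass_reduced = beads$monomer_molar_mass /
      (beads$Nm * beads$water_molar_mass)
  ), class = "reduced_units")
}

#' @export
print.reduced_units <- function(x, ...) {
  cat(sprintf("Reduced units at %.5g K:\n", x$temperature))
  cat(sprintf("  rc     = %.4g A\n", x$rc * 1e10))
  cat(sprintf("  mass   = %.4g kg (one water bead)\n", x$mass_unit))
  cat(sprintf("  energy = %.4g J (kBT)\n", x$energy_unit))
  cat(sprintf("  time   = %.4g ps\n", x$time_unit * 1e12))
  invisible(x)
}

#' Build the complete DPD force field at a temperature
#'
#' Composes the full parameterization chain: water properties at T set the
#' cutoff and the water self-repulsion (compressibility matching); the
#' matching pressure transfers that repulsion scale to the monomer bead at
#' its own pure density; the fitted \eqn{\chi(T)} sets the water-monomer
#' cross repulsion. Friction is global (`gamma` = 4.5 reduced) and the noise
#' strength follows from the fluctuation-dissipation theorem,
#' \eqn{\sigma^2 = 2\gamma} with \eqn{k_B T = 1}.
#'
#' @param temperature Temperature (K), within the packaged water table.
#' @param beads A [bead_spec()].
#' @param fh A [fh_model()].
#' @param gamma Reduced friction coefficient (global for all pairs).
#' @param rho_reduced Target reduced density.
#' @param alpha Equation-of-state constant.
#' @return An object of class `dpd_forcefield` with the three maximum
#'   repulsions (`fmax_ww`, `fmax_mm`, `fmax_wm`), `gamma`, `sigma`, `chi`,
#'   `p_match`, `k_inv`, `kappa_T`, `cutoff` (1 in reduced units) and the
#'   `units` ([reduced_units()]) used for SI conversion.
#' @examples
#' ff <- build_forcefield(298.15)
#' ff$sigma  # 3, from sqrt(2 * 4.5)
#' @export
build_forcefield <- function(temperature, beads = bead_spec(),
                             fh = fh_model(), gamma = 4.5, rho_reduced = 3,
                             alpha = 0.101) {
  wp <- water_properties(temperature)
  units <- reduced_units(temperature, beads, rho_reduced)
  rho_number_water <- wp$density / beads$water_molecule_mass
  k_inv <- inverse_compressibility(temperature, rho_number_water, wp$kappa_T)
  fww <- fmax_water(beads$Nm, k_inv, rho_reduced, alpha)
  p <- matching_pressure(fww, rho_reduced, alpha)
  rho_m <- units$rho_monomer_reduced
  fmm <- fmax_self(p, rho_m, alpha)
  chi <- chi_of_temperature(temperature, fh)
  fwm <- fmax_cross(fww, fmm, chi, p, rho_reduced, rho_m)
  structure(list(
    temperature = temperature,
    fmax_ww = fww, fmax_mm = fmm, fmax_wm = fwm,
    gamma = gamma, sigma = sqrt(2 * gamma),
    alpha = alpha, p_match = p, k_inv = k_inv, kappa_T = wp$kappa_T,
    chi = chi, cutoff = 1, rho_reduced = rho_reduced,
    beads = beads, units = units
  ), class = "dpd_forcefield")
}

#' @export
print.dpd_forcefield <- function(x, ...) {
  cat(sprintf("DPD force field at %.5g K (reduced units, rc = %.3g A):\n",
              x$temperature, x$units$rc * 1e10))
  cat(sprintf("  chi      = %8.3f\n", x$chi))
  cat(sprintf("  fmax_ww  = %8.2f\n", x$fmax_ww))
  cat(sprintf("  fmax_mm  = %8.2f\n", x$fmax_mm))
  cat(sprintf("  fmax_wm  = %8.2f\n", x$fmax_wm))
  cat(sprintf("  gamma    = %8.2f   sigma = %.3f\n", x$gamma, x$sigma))
  invisible(x)
}

#' Force-field parameters over a temperature range
#'
#' Convenience tabulation used by the `parameterize` CLI verb.
#'
#' @param temperatures Vector of temperatures (K).
#' @param ... Passed to [build_forcefield()].
#' @return A data.frame with one row per temperature: `T_K`, `rc_A`,
#'   `fmax_ww`, `fmax_mm`, `fmax_wm` (reduced), `gamma`, `sigma`, `chi`,
#'   and `fmax_wm_pN` (piconewton). Reduced forces at different
#'   temperatures live in different unit systems (the force unit kBT/rc
#'   itself grows with T), so cross-temperature trends should be read from
#'   the physical-unit column.
#' @export
forcefield_table <- function(temperatures, ...) {
  rows <- lapply(temperatures, function(tt) {
    ff <- build_forcefield(tt, ...)
    data.frame(T_K = tt, rc_A = ff$units$rc * 1e10,
               fmax_ww = ff$fmax_ww, fmax_mm = ff$fmax_mm,
               fmax_wm = ff$fmax_wm, gamma = ff$gamma, sigma = ff$sigma,
               chi = ff$chi,
               fmax_wm_pN = ff$fmax_wm * ff$units$force_unit * 1e12)
  })
  do.call(rbind, rows)
}
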