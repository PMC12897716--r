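# Reference properties of liquid water at 1 atm.
#
# Density after Kell (1975); isothermal compressibility after Kell / Fine &
# Millero. Tabulated every 5 C (plus 4 C so the density anomaly maximum is a
# table point) and interpolated piecewise-cubically in between.

.water_table <- data.frame(
  t_C = c(0, 4, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60,
          65, 70, 75, 80, 85, 90, 95, 100),
  density = c(999.843, 999.972, 999.967, 999.702, 999.103, 998.207,
              997.048, 995.650, 994.033, 992.215, 990.213, 988.037,
              985.696, 983.200, 980.555, 977.765, 974.840, 971.785,
              968.606, 965.305, 961.888, 958.345),              # kg/m^3
  kappa_T = 1e-10 * c(5.089, 4.948, 4.913, 4.781, 4.669, 4.589,
                      4.524, 4.476, 4.443, 4.422, 4.411, 4.408,
                      4.413, 4.425, 4.443, 4.467, 4.497, 4.532,
                      4.572, 4.617, 4.666, 4.720)               # 1/Pa
)

.water_density_fun <- stats::splinefun(.water_table$t_C, .water_table$density,
                                       method = "fmm")
.water_kappa_fun <- stats::splinefun(.water_table$t_C, .water_table$kappa_T,
                                     method = "fmm")

#' Density and isothermal compressibility of water
#'
#' Interpolates a packaged standard-reference table of liquid water at 1 atm
#' (density after Kell; compressibility after Kell and Fine--Millero). These
#' are the experimental inputs of the DPD parameterization: the density sets
#' the interaction cutoff and the compressibility sets the water--water
#' repulsion.
#'
#' @param temperature Temperature in kelvin, within 273.15--373.15 K.
#' @return A list with `density` (kg/m^3) and `kappa_T` (1/Pa).
#' @examples
#' water_properties(298.15)$density  # ~997 kg/m^3
#' @export
water_properties <- function(temperature) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  if (temperature < 273.15 || temperature > 373.15) {
    stop("temperature ", temperature,
         " K is outside the packaged water table (273.15-373.15 K)",
         call. = FALSE)
  }
  t_C <- temperature - 273.15
  list(density = .water_density_fun(t_C), kappa_T = .water_kappa_fun(t_C))
}
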