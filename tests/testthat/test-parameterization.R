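# Force-field parameterization: the chi(T) law, compressibility matching,
# pressure matching and the cross-interaction rule.

test_that("chi(T) follows the fitted law and is monotone", {
  expect_identical(chi_of_temperature(308.3), 0.5)
  expect_equal(chi_of_temperature(330), 0.5 + 35.2 * (1 - 308.3 / 330))
  expect_equal(chi_of_temperature(330), 2.814667, tolerance = 1e-6)
  expect_equal(chi_of_temperature(280), -3.057714, tolerance = 1e-6)
  temps <- seq(250, 400, by = 1)
  expect_true(all(diff(chi_of_temperature(temps)) > 0))
  expect_error(chi_of_temperature(-1), "positive")
  expect_error(chi_of_temperature(0), "positive")
})

test_that("custom Flory-Huggins models keep chi(theta) = 0.5", {
  for (theta in c(250, 300, 350)) {
    m <- fh_model(A = 12, theta = theta)
    expect_identical(chi_of_temperature(theta, m), 0.5)
  }
  expect_error(fh_model(theta = -5), "positive")
})

test_that("cutoff radius satisfies its defining identity at every table T", {
  m_w <- 18.01528e-3 / 6.02214076e23
  for (T in seq(275, 370, by = 5)) {
    rho_w <- water_properties(T)$density
    rc <- cutoff_radius(T, Nm = 5, rho_reduced = 3)
    expect_equal(rc^3 * rho_w, 3 * 5 * m_w, tolerance = 1e-12)
  }
  # reference numbers at ambient density
  expect_equal(cutoff_radius(298.15, 5, 3, rho_water = 997) * 1e10,
               7.6635, tolerance = 1e-3)
  expect_equal(cutoff_radius(298.15, 1, 1, rho_water = 997) * 1e10,
               3.1066, tolerance = 1e-3)
  # doubling Nm scales rc by 2^(1/3)
  expect_equal(cutoff_radius(298.15, 10, 3, rho_water = 997) /
                 cutoff_radius(298.15, 5, 3, rho_water = 997),
               2^(1 / 3), tolerance = 1e-12)
})

test_that("inverse compressibility reproduces the ambient-water value", {
  k <- inverse_compressibility(298.15, 3.33e28, 4.52e-10)
  expect_equal(k, 16.1398, tolerance = 1e-3)
  # inverse proportionality in kappa_T and the defining identity
  expect_equal(inverse_compressibility(298.15, 3.33e28, 2 * 4.52e-10),
               k / 2, tolerance = 1e-12)
  expect_equal(k * (3.33e28 * 1.380649e-23 * 298.15 * 4.52e-10), 1,
               tolerance = 1e-12)
})

test_that("water-water repulsion recovers the classic value at Nm = 1", {
  expect_equal(fmax_water(1, 16, 3), (16 - 1) / (2 * 0.101 * 3),
               tolerance = 1e-12)
  expect_equal(fmax_water(1, 16, 3), 24.752, tolerance = 1e-3)
  expect_equal(fmax_water(5, 16.1, 3), (5 * 16.1 - 1) / 0.606,
               tolerance = 1e-12)
  # linear growth in Nm * k_inv
  f1 <- fmax_water(5, 16, 3)
  f2 <- fmax_water(5, 20, 3)
  f3 <- fmax_water(5, 24, 3)
  expect_equal(f3 - f2, f2 - f1, tolerance = 1e-9)
  expect_error(fmax_water(1, 0.5, 3), "invalid parameterization")
})

test_that("pressure matching round-trips through the equation of state", {
  expect_identical(matching_pressure(0, 3), 3)
  expect_equal(matching_pressure(131.4, 3), 3 + 0.101 * 131.4 * 9,
               tolerance = 1e-12)
  for (x in c(0, 1, 25, 131.4, 500)) {
    expect_equal(fmax_self(matching_pressure(x, 3), 3), x,
                 tolerance = 1e-12)
  }
  expect_identical(fmax_self(3, 3), 0)
  expect_error(fmax_self(2, 3), "invalid parameterization")
})

test_that("cross repulsion is the geometric mean at chi = 0 and linear in chi", {
  expect_identical(fmax_cross(100, 25, 0, 122, 3, 2.6), 50)
  expect_identical(fmax_cross(80, 80, 0, 122, 3, 3), 80)
  # linearity of the excess
  p <- 122.4
  f0 <- fmax_cross(131, 170, 0, p, 3, 2.63)
  f1 <- fmax_cross(131, 170, 1, p, 3, 2.63)
  f2 <- fmax_cross(131, 170, 2, p, 3, 2.63)
  f3 <- fmax_cross(131, 170, 3.5, p, 3, 2.63)
  expect_equal(f2 - f1, f1 - f0, tolerance = 1e-9)
  expect_equal((f3 - f0) / 3.5, f1 - f0, tolerance = 1e-9)
  # negative chi reduces the repulsion below the neutral baseline
  expect_lt(fmax_cross(131, 170, -3, p, 3, 2.63), sqrt(131 * 170))
})

test_that("build_forcefield composes a consistent force field", {
  ff <- build_forcefield(298.15)
  expect_s3_class(ff, "dpd_forcefield")
  expect_identical(ff$sigma, 3)  # sqrt(2 * 4.5)
  expect_equal(ff$sigma^2 / (2 * ff$gamma), 1, tolerance = 1e-15)
  expect_equal(ff$chi, chi_of_temperature(298.15))
  # water self-repulsion reproduced through the matching pressure
  expect_equal(fmax_self(ff$p_match, 3), ff$fmax_ww, tolerance = 1e-10)
  # cross term above the geometric mean iff chi > 0
  ff_hot <- build_forcefield(320)
  expect_gt(ff_hot$fmax_wm, sqrt(ff_hot$fmax_ww * ff_hot$fmax_mm))
  expect_lt(ff$fmax_wm, sqrt(ff$fmax_ww * ff$fmax_mm))  # chi < 0 at 298 K
  # the excess changes sign where chi does
  ff_theta <- build_forcefield(308.3)
  expect_gt(ff_theta$fmax_wm, sqrt(ff_theta$fmax_ww * ff_theta$fmax_mm))
})

test_that("reduced unit system is internally consistent", {
  u <- reduced_units(298.15)
  expect_equal(u$time_unit, u$rc * sqrt(u$mass_unit / u$energy_unit),
               tolerance = 1e-15)
  expect_equal(u$energy_unit, 1.380649e-23 * 298.15, tolerance = 1e-12)
  expect_equal(u$mass_unit, 5 * 18.01528e-3 / 6.02214076e23,
               tolerance = 1e-12)
  expect_identical(u$rho_reduced, 3)
  # monomer bead: similar volume to the 5-water bead by construction
  v_mono <- 1 / (bead_spec()$rho_pure_monomer) * 1e30  # A^3
  expect_gt(v_mono, 120)
  expect_lt(v_mono, 220)
})

test_that("fluctuation-dissipation holds for any gamma", {
  for (g in c(1, 4.5, 10)) {
    ff <- build_forcefield(300, gamma = g)
    expect_equal(ff$sigma^2, 2 * g, tolerance = 1e-12)
  }
})
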