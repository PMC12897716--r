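# DPD engine: force primitives, neighbour search, integrator properties.

test_that("conservative force is linear, maximal at contact, zero at rc", {
  expect_identical(conservative_force(1, 131.4), 0)
  expect_identical(conservative_force(0, 131.4), 131.4)
  expect_equal(conservative_force(0.5, 131.4), 131.4 / 2)
  expect_identical(conservative_force(1.7, 131.4), 0)
  # continuity at the cutoff
  expect_lt(conservative_force(1 - 1e-9, 131.4), 1e-6)
})

test_that("dissipative force projects the relative velocity", {
  rhat <- c(1, 0, 0)
  expect_equal(dissipative_force(0.5, rhat, c(0, 2, -1), 4.5), c(0, 0, 0))
  expect_equal(dissipative_force(0.5, rhat, 3 * rhat, 4.5), -4.5 * 3 * rhat)
  expect_equal(dissipative_force(1.2, rhat, 3 * rhat, 4.5), c(0, 0, 0))
  expect_error(dissipative_force(0, rhat, rhat, 4.5), "undefined direction")
})

test_that("random force noise has zero mean, unit variance, pair antisymmetry", {
  set.seed(42)
  th <- sqrt(3) * (2 * runif(1e5) - 1)
  expect_lt(abs(mean(th)), 3 / sqrt(1e5))
  expect_equal(var(th), 1, tolerance = 0.02)
  rhat <- c(0, 1, 0)
  f_i <- random_force(0.4, rhat, sigma = 3, dt = 0.01, theta = 0.7)
  f_j <- random_force(0.4, -rhat, sigma = 3, dt = 0.01, theta = 0.7)
  expect_equal(f_i + f_j, c(0, 0, 0))
  expect_equal(f_i, 3 * 0.7 * rhat / sqrt(0.01))
  expect_equal(random_force(1.1, rhat, 3, 0.01, theta = 1), c(0, 0, 0))
})

test_that("bond force is harmonic and symmetric about r0", {
  rb <- list(K = 57, r0 = 0.85)
  expect_identical(bond_force(rb$r0, rb), 0)
  expect_equal(bond_force(rb$r0 + 0.1, rb), -57 * 0.1)
  expect_equal(bond_force(rb$r0 - 0.1, rb), 57 * 0.1)
  # equal energy at symmetric displacements: F integrates to K d^2 / 2
  expect_equal(abs(bond_force(rb$r0 + 0.2, rb)),
               abs(bond_force(rb$r0 - 0.2, rb)))
})

test_that("neighbour search equals a brute-force oracle with minimum image", {
  set.seed(7)
  box <- 6
  pos <- matrix(runif(600, 0, box), 200, 3)
  got <- neighbor_search(pos, box, 1.0)
  # brute force oracle
  want <- NULL
  for (i in 1:199) {
    for (j in (i + 1):200) {
      d <- pos[i, ] - pos[j, ]
      d <- d - box * round(d / box)
      if (sum(d^2) < 1) want <- rbind(want, c(i, j))
    }
  }
  want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(want))
})

test_that("neighbour search handles boundary-straddling pairs and edge cases", {
  box <- 10
  pos <- rbind(c(0.2, 5, 5), c(9.7, 5, 5))  # 0.5 apart through the face
  got <- neighbor_search(pos, box, 1.0)
  expect_identical(nrow(got), 1L)
  expect_identical(as.integer(got[1, ]), c(1L, 2L))
  expect_identical(nrow(neighbor_search(matrix(numeric(0), 0, 3), box, 1)),
                   0L)
  expect_error(neighbor_search(pos, box, 6), "half the box")
})

test_that("cell-list forces equal brute-force all-pairs forces", {
  set.seed(11)
  box <- (300 / 3)^(1 / 3) * 1.2
  pos <- matrix(runif(900, 0, box), 300, 3)
  vel <- matrix(rnorm(900, sd = 0.5), 300, 3)
  types <- rep(c("water", "monomer"), length.out = 300)
  ff <- build_forcefield(298.15)
  bonds <- cbind(1:10, 21:30)
  rb <- list(K = 40, r0 = 0.85)
  got <- compute_forces(pos, vel, types, box, ff, bonds = bonds, bond = rb)
  want <- brute_forces(pos, vel, types, box, ff, bonds = bonds, bond = rb)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("two isolated resting beads beyond rc do not move", {
  ff <- build_forcefield(298.15)
  init <- water_box(2)$init
  init$positions <- rbind(c(1, 1, 1), c(4, 4, 4))
  init$box_side <- 10
  # gamma = 0 removes the thermostat so the system is strictly deterministic
  ff0 <- ff
  ff0$gamma <- 0
  ff0$sigma <- 0
  proto <- protocol(pre_thermalization_steps = 0, thermalization_steps = 0,
                    production_steps = 50, snapshot_interval = 50, seed = 3)
  # zero velocities: override the Maxwell-Boltzmann draw via zero temperature
  # by integrating by hand through the exported force check instead
  f <- compute_forces(init$positions, matrix(0, 2, 3), init$bead_types,
                      init$box_side, ff0)
  expect_equal(f, matrix(0, 2, 3))
})

test_that("same seed gives bit-identical trajectories", {
  wb <- water_box(120, seed = 5)
  proto <- protocol(pre_thermalization_steps = 50, thermalization_steps = 50,
                    production_steps = 200, snapshot_interval = 50,
                    log_interval = 100, seed = 99)
  t1 <- run_simulation(wb$init, wb$ff, proto)
  t2 <- run_simulation(wb$init, wb$ff, proto)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$final_state, t2$final_state)
  t3 <- run_simulation(wb$init, wb$ff,
                       protocol(pre_thermalization_steps = 50,
                                thermalization_steps = 50,
                                production_steps = 200,
                                snapshot_interval = 50,
                                log_interval = 100, seed = 100))
  expect_false(identical(t1$final_state$positions,
                         t3$final_state$positions))
})

test_that("momentum is conserved by the DPD thermostat", {
  wb <- water_box(200, seed = 2)
  proto <- protocol(pre_thermalization_steps = 0, thermalization_steps = 0,
                    production_steps = 2000, snapshot_interval = 2000,
                    log_interval = 2000, seed = 17)
  traj <- run_simulation(wb$init, wb$ff, proto)
  p_final <- colSums(traj$final_state$velocities)  # water mass = 1
  expect_lt(max(abs(p_final)) / 200, 1e-8)
})

test_that("zero production steps still yields the final state frame", {
  wb <- water_box(60)
  proto <- protocol(pre_thermalization_steps = 0, thermalization_steps = 100,
                    production_steps = 0, snapshot_interval = 10, seed = 1)
  traj <- run_simulation(wb$init, wb$ff, proto)
  expect_identical(length(traj$frames), 1L)
  expect_identical(traj$frames[[1]]$step, 100L)
})

test_that("instantaneous temperature: equipartition and COM invariance", {
  expect_identical(instantaneous_temperature(matrix(0, 5, 3)), 0)
  set.seed(123)
  v <- matrix(rnorm(3e4), 1e4, 3)
  expect_equal(instantaneous_temperature(v), 1, tolerance = 0.02)
  v_shift <- sweep(v, 2, c(3, -2, 0.5), "+")
  expect_equal(instantaneous_temperature(v_shift),
               instantaneous_temperature(v), tolerance = 1e-12)
  # mass-weighted: heavier beads with same speeds mean higher temperature
  expect_equal(instantaneous_temperature(v, mass = 2),
               2 * instantaneous_temperature(v), tolerance = 1e-12)
})

test_that("kinetic temperature relaxes to 1 under the DPD thermostat", {
  wb <- water_box(250, seed = 8)
  proto <- protocol(pre_thermalization_steps = 0, thermalization_steps = 1000,
                    production_steps = 4000, snapshot_interval = 4000,
                    log_interval = 500, seed = 21)
  traj <- run_simulation(wb$init, wb$ff, proto)
  expect_equal(mean(traj$temp_log$T_kin), 1, tolerance = 0.05)
})

test_that("initial configurations are deterministic and dense enough", {
  gel <- nanogel_fixture()
  ff <- build_forcefield(298.15)
  i1 <- initial_configuration(gel, 12, ff$units, seed = 4)
  i2 <- initial_configuration(gel, 12, ff$units, seed = 4)
  expect_identical(i1$positions, i2$positions)
  # density within 0.5% of the target
  expect_equal(nrow(i1$positions) / 12^3, 3, tolerance = 0.005)
  # all bond lengths within [0.5 r0, 2 r0]
  bl <- sqrt(rowSums((i1$positions[i1$bonds[, 1], ] -
                        i1$positions[i1$bonds[, 2], ])^2))
  expect_true(all(bl >= 0.5 * i1$bond$r0 & bl <= 2 * i1$bond$r0))
  # explicit water-count override is honoured
  i3 <- initial_configuration(gel, 12, ff$units, seed = 4,
                              water_count = 4000)
  expect_identical(unname(i3$counts["water"]), 4000L)
  expect_error(initial_configuration(gel, 5, ff$units, seed = 1),
               "geometry error")
})
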