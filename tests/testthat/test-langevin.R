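# Implicit-solvent (Langevin) comparison mode.

test_that("WCA force is purely repulsive and vanishes at its minimum", {
  sig <- 0.85
  rc <- 2^(1 / 6) * sig
  expect_equal(wca_force(rc, 1, sig), 0, tolerance = 1e-12)
  expect_identical(wca_force(rc + 0.3, 1, sig), 0)
  r <- seq(0.5 * sig, rc - 1e-9, length.out = 50)
  expect_true(all(wca_force(r, 1, sig) > 0))
  # monotone decreasing toward the cutoff (below the contact force cap)
  r2 <- seq(0.8 * sig, rc - 1e-9, length.out = 50)
  expect_true(all(diff(wca_force(r2, 1, sig)) < 0))
  # the r -> 0 overflow is capped
  expect_identical(wca_force(1e-6, 1, sig, force_cap = 1e4), 1e4)
})

test_that("hydrophobic well: range, temperature trend, depth consistency", {
  ff <- langevin_forcefield(320)
  params <- list(r1 = ff$hydro_r1, r2 = ff$hydro_r2,
                 slope = ff$hydro_slope, T_onset = ff$hydro_onset)
  expect_identical(hydrophobic_force(ff$hydro_r2, 320, params), 0)
  expect_identical(hydrophobic_force(ff$hydro_r2 + 1, 320, params), 0)
  # attractive (negative) inside the smoothing window
  rs <- seq(params$r1 + 1e-6, params$r2 - 1e-6, length.out = 30)
  expect_true(all(hydrophobic_force(rs, 320, params) < 0))
  # deeper at higher temperature
  expect_lt(hydrophobic_force(mean(rs), 330, params),
            hydrophobic_force(mean(rs), 280, params))
  expect_true(all(diff(hydro_depth(seq(280, 330, 5))) >= 0))
  # integral of the force from contact to cutoff equals minus the depth
  depth <- hydro_depth(320)
  integral <- integrate(function(r) hydrophobic_force(r, 320, params),
                        params$r1, params$r2)$value
  expect_equal(integral, -depth, tolerance = 1e-6)
})

test_that("free-bead ensemble thermostats to reduced T = 1", {
  fb <- free_beads(400, seed = 3)
  proto <- protocol(pre_thermalization_steps = 0, thermalization_steps = 500,
                    production_steps = 3000, snapshot_interval = 3000,
                    log_interval = 250, seed = 31)
  traj <- run_simulation(fb$init, fb$ff, proto)
  expect_equal(mean(traj$temp_log$T_kin), 1, tolerance = 0.05)
})

test_that("free-bead diffusion follows the Einstein relation", {
  fb <- free_beads(600, seed = 5)
  fb$ff$damping <- 2  # D = kBT / gamma = 0.5
  proto <- protocol(pre_thermalization_steps = 0,
                    thermalization_steps = 1000,
                    production_steps = 4000, snapshot_interval = 200,
                    log_interval = 4000, seed = 13)
  traj <- run_simulation(fb$init, fb$ff, proto)
  xyz0 <- traj$frames[[1]]$xyz
  times <- vapply(traj$frames, function(f) f$step, integer(1)) * proto$dt
  msd <- vapply(traj$frames, function(f) mean(rowSums((f$xyz - xyz0)^2)),
                numeric(1))
  # slope of MSD vs time in the diffusive regime (t >> m / gamma = 0.5)
  fit <- coef(lm(msd ~ I(times - times[1])))[2]
  expect_equal(unname(fit), 6 * 0.5, tolerance = 0.2)
})

test_that("Langevin dynamics does not conserve momentum (DPD contrast)", {
  fb <- free_beads(300, seed = 9)
  proto <- protocol(pre_thermalization_steps = 0, thermalization_steps = 0,
                    production_steps = 1000, snapshot_interval = 1000,
                    log_interval = 1000, seed = 41)
  traj <- run_simulation(fb$init, fb$ff, proto)
  p_final <- colSums(traj$final_state$velocities)
  # friction against the implicit background randomizes total momentum
  expect_gt(max(abs(p_final)) / 300, 1e-6)
})

test_that("langevin force field is engine-compatible and documented in rc units", {
  ff <- langevin_forcefield(300)
  expect_s3_class(ff, "langevin_forcefield")
  expect_equal(ff$wca_sigma * ff$units$rc * 1e10, 6.5, tolerance = 1e-9)
  expect_gt(ff$hydro_r2, ff$hydro_r1)
  expect_identical(ff$cutoff, ff$hydro_r2)
  # depth non-decreasing over the studied range
  d <- vapply(seq(280, 330, 10),
              function(T) langevin_forcefield(T)$hydro_depth, numeric(1))
  expect_true(all(diff(d) >= 0))
})
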