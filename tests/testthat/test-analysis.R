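# Observables: Rg, block averaging, RDFs, swelling, transition bracket.

test_that("radius of gyration matches closed forms", {
  # two beads at distance d -> d/2
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(4, 0, 0))), 2)
  # 8 beads at the corners of a cube of side a -> a * sqrt(3) / 2
  a <- 2.5
  cube <- as.matrix(expand.grid(c(0, a), c(0, a), c(0, a)))
  expect_equal(radius_of_gyration(cube), a * sqrt(3) / 2, tolerance = 1e-12)
  # translation and rotation invariance
  expect_equal(radius_of_gyration(sweep(cube, 2, c(7, -3, 11), "+")),
               radius_of_gyration(cube), tolerance = 1e-12)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(radius_of_gyration(cube %*% R), radius_of_gyration(cube),
               tolerance = 1e-12)
})

test_that("squared Rg decomposes additively about the centroid", {
  set.seed(1)
  pts <- matrix(rnorm(60), 20, 3)
  rg2 <- radius_of_gyration(pts)^2
  centred <- sweep(pts, 2, colMeans(pts))
  expect_equal(rg2, sum(centred^2) / 20, tolerance = 1e-12)
})

test_that("wrapped coordinates are detected through stretched bonds", {
  pos <- rbind(c(0.1, 5, 5), c(9.9, 5, 5))
  bonds <- matrix(c(1L, 2L), 1, 2)
  expect_error(radius_of_gyration(pos, bonds = bonds, box_side = 10),
               "wrapped")
  expect_silent(radius_of_gyration(rbind(c(0.1, 5, 5), c(1.0, 5, 5)),
                                   bonds = bonds, box_side = 10))
  expect_error(radius_of_gyration(matrix(1, 1, 3)), "two beads")
})

test_that("block SEM recovers sigma/sqrt(N) for iid data", {
  set.seed(42)
  x <- rnorm(1024)
  bs <- block_sem(x)
  expect_equal(bs$mean, mean(x), tolerance = 1e-12)
  expect_equal(bs$sem, 1 / 32, tolerance = 0.25)
  expect_identical(nrow(bs$sem_by_blocks), 14L)  # 12..25 block window
})

test_that("block SEM is zero for constant data and errors when too short", {
  bs <- block_sem(rep(3.2, 100))
  expect_identical(bs$sem, 0)
  expect_error(block_sem(rnorm(30)), "insufficient data")
})

test_that("block SEM exceeds the naive estimate for AR(1) data", {
  set.seed(7)
  phi <- 0.9
  n <- 20000
  x <- as.numeric(arima.sim(list(ar = phi), n))
  bs <- block_sem(x)
  naive <- sd(x) / sqrt(n)
  # blocking-theory oracle: SEM ~ sd * sqrt((1 + phi) / ((1 - phi) n))
  oracle <- sd(x) * sqrt((1 + phi) / ((1 - phi) * n))
  expect_gt(bs$sem, 2 * naive)
  expect_equal(bs$sem, oracle, tolerance = 0.35)
})

test_that("RDF of an ideal-gas configuration is 1 in every bin", {
  set.seed(3)
  box <- 12
  frames <- lapply(1:4, function(i) matrix(runif(3 * 5000, 0, box), 5000, 3))
  traj <- make_traj(frames, rep("water", 5000), box)
  g <- rdf_pair(traj, "water", "water", bin_width = 0.25, r_max = 5)
  expect_true(all(abs(g$g[g$r > 0.3] - 1) < 0.05))
  # closure: the integral of rho g(r) 4 pi r^2 dr counts the neighbours
  rho <- 5000 / box^3
  shells <- 4 / 3 * pi * diff(seq(0, 5, by = 0.25)^3)
  n_in_5 <- sum(rho * g$g * shells)
  expect_equal(n_in_5, 4999 / box^3 * 4 / 3 * pi * 5^3, tolerance = 0.01)
})

test_that("two fixed beads give a single occupied RDF bin at their distance", {
  box <- 10
  pos <- rbind(c(2, 5, 5), c(5.7, 5, 5))  # distance 3.7
  traj <- make_traj(list(pos), rep("monomer", 2), box)
  g <- rdf_pair(traj, "monomer", "monomer", bin_width = 0.1, r_max = 5)
  occupied <- which(g$g > 0)
  expect_identical(length(occupied), 1L)
  expect_equal(g$r[occupied], 3.75, tolerance = 0.051)
})

test_that("point-reference RDF sees homogeneity and an exclusion hole", {
  set.seed(5)
  box <- 12
  n <- 8000
  pts <- matrix(runif(3 * n * 2, 0, box), 2 * n, 3)
  # carve a cavity of radius 2 around the centre
  centre <- rep(box / 2, 3)
  d <- sqrt(rowSums(sweep(pts, 2, centre)^2))
  hollow <- pts[d > 2, , drop = FALSE][seq_len(n), ]
  traj <- make_traj(list(hollow), rep("water", n), box,
                    engine = "dpd")
  g <- rdf_from_point(traj, "water", bin_width = 0.25, r_max = 5,
                      point_fun = function(fr, tr) centre)
  expect_true(all(g$g[g$r < 1.8] < 1e-12))
  expect_true(all(abs(g$g[g$r > 2.3] - mean(g$g[g$r > 2.3])) < 0.15))
  # homogeneous control: g = 1 within counting noise once shells hold
  # enough beads (inner shells of a single-site reference are tiny)
  frames2 <- lapply(1:4, function(i) matrix(runif(3 * n, 0, box), n, 3))
  traj2 <- make_traj(frames2, rep("water", n), box)
  g2 <- rdf_from_point(traj2, "water", bin_width = 0.5, r_max = 5,
                       point_fun = function(fr, tr) c(1, 7, 3))
  expect_true(all(abs(g2$g[g2$r > 2] - 1) < 0.15))
})

test_that("RDF rejects invalid binning and ranges", {
  traj <- make_traj(list(matrix(runif(30), 10, 3)), rep("water", 10), 5)
  expect_error(rdf_pair(traj, "water", "water", bin_width = 0),
               "bin_width")
  expect_error(rdf_pair(traj, "water", "water", r_max = 4), "half the box")
})

test_that("swelling ratio is 1 at the reference and tracks published values", {
  ref <- reference_rg()
  rg <- setNames(ref$rg_dpd_A, ref$temperature_K)
  sw <- swelling_ratio(rg)
  expect_equal(sw$swelling[sw$temperature == 280], 1)
  expect_equal(sw$swelling[sw$temperature == 330], 19.98 / 44.00,
               tolerance = 1e-12)
  expect_true(all(diff(sw$swelling) < 0))
  expect_error(swelling_ratio(rg, T_ref = 299), "not present")
})

test_that("first-peak position is found by parabolic interpolation", {
  r <- seq(0.05, 15, by = 0.1)
  g <- 1 + 2.5 * exp(-(r - 6.5)^2 / 0.8)
  expect_equal(first_peak_position(data.frame(r = r, g = g)), 6.5,
               tolerance = 0.05)
  # peak centred exactly on a bin edge is recovered within half a bin
  g2 <- 1 + 2 * exp(-(r - 6.4)^2 / 0.5)
  expect_equal(first_peak_position(data.frame(r = r, g = g2)), 6.4,
               tolerance = 0.05)
  # monotone decreasing curve: no-peak sentinel
  expect_identical(first_peak_position(data.frame(r = r, g = exp(-r))),
                   NA_real_)
})

test_that("maximum diameter comes from the g(r) tail threshold", {
  r <- seq(0.1, 10, by = 0.1)
  g <- ifelse(r < 4, 2, ifelse(r < 6, 0.01, 0))
  expect_equal(max_diameter(data.frame(r = r, g = g)), 5.9,
               tolerance = 0.11)
  expect_identical(max_diameter(data.frame(r = r, g = rep(0, 100))),
                   NA_real_)
})

test_that("transition bracket: published table reproduces 305-310 K", {
  ref <- reference_rg()
  dpd <- setNames(ref$rg_dpd_A, ref$temperature_K)
  lan <- setNames(ref$rg_langevin_A, ref$temperature_K)
  expect_identical(as.numeric(transition_temperature(dpd)), c(305, 310))
  expect_identical(as.numeric(transition_temperature(lan)), c(305, 310))
  # monotone increasing Rg: no transition
  flat <- setNames(1:6, seq(280, 330, 10))
  expect_true(all(is.na(transition_temperature(flat))))
  # linear decrease: degenerate bracket is flagged
  lin <- setNames(seq(50, 20, length.out = 6), seq(280, 330, 10))
  out <- transition_temperature(lin)
  expect_true(isTRUE(attr(out, "degenerate")))
  expect_error(transition_temperature(lin[1:3]), "at least 4")
})
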