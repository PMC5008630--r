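single_bead_topology <- function(z0 = 0, tether_k = NA_real_) {
  geom <- list(box = c(50, 50, 50), wall_z = 1e6, wall_k = 0, eps_r = 1,
               cutoff = 5)
  atoms <- tibble::tibble(
    name = "B", resname = "BDS", resnum = 1L, chain = "SOLVENT",
    role = "probe", charge = 0, sigma = 1, epsilon = 0,
    x = 0, y = 0, z = z0,
    anchor_x = 0, anchor_y = 0, anchor_z = 0,
    tether_k = tether_k, tether_r0 = 0, mobile = TRUE)
  sfpore:::new_sf_topology(atoms, geom$box, "t", geom, nbfix = NULL)
}

test_that("identical seed gives bit-identical trajectories", {
  top <- toy_topology(10, seed = 4)
  pr <- bd_protocol(n_steps = 500, save_interval = 10, seed = 42)
  t1 <- simulate_trajectory(top, pr)
  t2 <- simulate_trajectory(top, pr)
  expect_identical(t1$coords, t2$coords)
  pr$seed <- 43L
  t3 <- simulate_trajectory(top, pr)
  expect_false(identical(t1$coords, t3$coords))
})

test_that("a force-free bead at zero temperature is stationary", {
  top <- single_bead_topology(z0 = 1.7)
  top$anchor_x <- NA_real_  # no tether
  top$tether_k <- NA_real_
  pr <- bd_protocol(temperature = 0, n_steps = 200, save_interval = 20,
                    seed = 1)
  tr <- simulate_trajectory(top, pr)
  expect_true(all(tr$coords[1, 3, ] == 1.7))
  expect_true(all(tr$coords[1, 1, ] == 0))
})

test_that("double-well occupancy ratio matches the Boltzmann factor", {
  top <- single_bead_topology(z0 = 1)
  top$tether_k <- NA_real_; top$anchor_x <- NA_real_
  dU <- 1.232; k <- 2.5; z0 <- 1.0
  kT <- kT_at(310)
  expect_equal(kT, 0.616032, tolerance = 1e-6)
  dw <- list(k = k, z1 = z0, z2 = -z0, dU = dU, atoms = 0L)
  tr <- simulate_trajectory(top, bd_protocol(n_steps = 2e6,
                                             save_interval = 10, seed = 11),
                            double_well = dw)
  z <- tr$coords[1, 3, ]
  zstar <- -dU / (2 * k * z0)        # branch crossing point
  in2 <- z < zstar
  ntrans <- sum(diff(in2) != 0)
  ratio <- mean(in2) / mean(!in2)
  se_log <- sqrt(2 / ntrans)         # transition-limited error on log ratio
  expect_gt(ntrans, 100)
  expect_lt(abs(log(ratio) + dU / kT), 3 * se_log)
})

test_that("overlapping cores trigger the instability guard", {
  top <- toy_topology(2, seed = 1)
  top$x <- c(0, 0); top$y <- c(0, 0); top$z <- c(0, 0)
  top$epsilon <- 0.2
  expect_error(
    simulate_trajectory(top, bd_protocol(n_steps = 2000, save_interval = 100,
                                         seed = 1)),
    "unstable|timestep")
})

test_that("restraints referencing missing atoms are rejected", {
  top <- toy_topology(3, seed = 2)
  bad <- tibble::tibble(atom = 9L, x = 0, y = 0, z = 0, radius = 1, k = 5)
  expect_error(simulate_trajectory(top, bd_protocol(n_steps = 10, seed = 1),
                                   restraints = bad), "outside")
})

test_that("planted state fixture recovers its open fraction and geometry", {
  open <- list(mean = c(6, 5), cov = diag(c(0.25, 0.25)))
  closed <- list(mean = c(2, 1), cov = diag(c(0.25, 0.25)))
  pl <- plant_labeled_states(open, closed, n_frames = 10000, seed = 5,
                             open_fraction = 0.3)
  expect_equal(mean(pl$labels == "open"), 0.3, tolerance = 0.02)
  # reporter (R, Z) series reproduces the planted populations
  rz <- rz_series(pl$trajectory, pl$topology, 5L)
  mo <- colMeans(rz[pl$labels == "open", c("R", "Z")])
  se <- 0.5 / sqrt(sum(pl$labels == "open"))
  expect_lt(abs(mo[["R"]] - 6), 3 * se)
  expect_lt(abs(mo[["Z"]] - 5), 3 * se)
})

test_that("degenerate planted covariances are rejected", {
  bad <- list(mean = c(0, 0), cov = matrix(c(1, 2, 2, 1), 2))
  ok <- list(mean = c(0, 0), cov = diag(2))
  expect_error(plant_labeled_states(bad, ok, 10, 1), "positive-definite")
})
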