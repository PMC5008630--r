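hb_fixture <- function(dists) {
  # donor N at varying distance along x from a chain-A acceptor, plus a
  # second acceptor on chain D at fixed 3.0 A along y
  nf <- length(dists)
  atoms <- tibble::tibble(
    name = c("NZ", "OE1", "OE2"),
    resname = c("LYS", "GLU", "GLU"), resnum = c(180L, 183L, 183L),
    chain = c("C", "A", "D"),
    role = c("sidechain-N", "carboxylate-O", "carboxylate-O"),
    charge = 0, sigma = 3, epsilon = 0,
    x = c(0, 1, 0), y = c(0, 0, 3), z = 0,
    anchor_x = NA_real_, anchor_y = NA_real_, anchor_z = NA_real_,
    tether_k = NA_real_, tether_r0 = NA_real_, mobile = TRUE)
  geom <- list(box = c(30, 30, 30), wall_z = 1e6, wall_k = 0, eps_r = 1,
               cutoff = 5)
  top <- sfpore:::new_sf_topology(atoms, geom$box, "hb", geom, nbfix = NULL)
  coords <- array(0, c(3, 3, nf))
  for (f in seq_len(nf)) {
    coords[1, , f] <- c(0, 0, 0)
    coords[2, , f] <- c(dists[f], 0, 0)
    coords[3, , f] <- c(0, 3.0, 0)
  }
  list(top = top, traj = sf_trajectory(coords, box = geom$box))
}

test_that("hydrogen-bond occupancy follows the distance criterion", {
  fx <- hb_fixture(rep(3.0, 8))
  hb <- hbond_occupancy(fx$traj, fx$top, "name NZ", "chain A and name OE1")
  expect_equal(hb$occupancy, 1)
  fx2 <- hb_fixture(rep(4.0, 8))
  hb2 <- hbond_occupancy(fx2$traj, fx2$top, "name NZ",
                         "chain A and name OE1")
  expect_equal(hb2$occupancy, 0)
  fx3 <- hb_fixture(rep(c(3.0, 4.0), 10))
  hb3 <- hbond_occupancy(fx3$traj, fx3$top, "name NZ",
                         "chain A and name OE1")
  expect_equal(hb3$occupancy, 0.5)
})

test_that("occupancy is monotone in the distance cutoff", {
  set.seed(31)
  fx <- hb_fixture(runif(60, 2.5, 5))
  cuts <- c(2.8, 3.2, 3.6, 4.2, 5.0)
  occs <- vapply(cuts, function(cc)
    hbond_occupancy(fx$traj, fx$top, "name NZ", "role carboxylate-O",
                    hbond_criteria(cc))$occupancy, numeric(1))
  expect_true(all(diff(occs) >= 0))
})

test_that("bifurcate flag requires acceptors from two residues at once", {
  fx <- hb_fixture(rep(3.0, 4))  # donor bonds chain A (3.0-ish) and chain D (3.0)
  hb <- hbond_occupancy(fx$traj, fx$top, "name NZ", "role carboxylate-O")
  expect_equal(hb$bifurcate_occupancy, 1)
  fx2 <- hb_fixture(rep(4.2, 4)) # only the chain-D acceptor in range
  hb2 <- hbond_occupancy(fx2$traj, fx2$top, "name NZ", "role carboxylate-O")
  expect_equal(hb2$occupancy, 1)
  expect_equal(hb2$bifurcate_occupancy, 0)
  expect_error(hbond_occupancy(fx$traj, fx$top, "name XX", "role ion") |>
                 suppressWarnings(), "non-empty")
})

coord_fixture <- function(ion_species, o_dists, role = "water-O") {
  n <- length(o_dists)
  ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  atoms <- dplyr::bind_rows(
    tibble::tibble(
      name = ion_species, resname = ion_species, resnum = 2001L,
      chain = "SOLVENT", role = "ion", charge = 1, sigma = 2.4,
      epsilon = 0.05, x = 0, y = 0, z = 0,
      anchor_x = NA_real_, anchor_y = NA_real_, anchor_z = NA_real_,
      tether_k = NA_real_, tether_r0 = NA_real_, mobile = TRUE),
    tibble::tibble(
      name = if (role == "water-O") "OW" else "OD1",
      resname = if (role == "water-O") "HOH" else "ASP",
      resnum = 1000L + seq_len(n),
      chain = if (role == "water-O") "SOLVENT" else "A", role = role,
      charge = 0, sigma = 2.85,
      epsilon = 0.15, x = o_dists * cos(ang), y = o_dists * sin(ang), z = 0,
      anchor_x = NA_real_, anchor_y = NA_real_, anchor_z = NA_real_,
      tether_k = NA_real_, tether_r0 = NA_real_, mobile = TRUE))
  geom <- list(box = c(30, 30, 30), wall_z = 1e6, wall_k = 0, eps_r = 10,
               cutoff = 10)
  sfpore:::new_sf_topology(atoms, geom$box, "co", geom)
}

test_that("coordination counting applies the species cutoffs geometrically", {
  top <- coord_fixture("NA", c(2.50, 3.00))
  X <- as.matrix(top[, c("x", "y", "z")])
  cc <- coordination_count(X, top, 1L)
  expect_equal(cc[["water_O"]], 1L)   # 2.50 in, 3.00 out for Na+
  topk <- coord_fixture("K", c(2.50, 3.00))
  cck <- coordination_count(as.matrix(topk[, c("x", "y", "z")]), topk, 1L)
  expect_equal(cck[["water_O"]], 2L)  # both inside the K+ 3.22 A cutoff
  # counting is geometric: 8 oxygens at 2.0 A all count for Na+
  top8 <- coord_fixture("NA", rep(2.0, 8))
  cc8 <- coordination_count(as.matrix(top8[, c("x", "y", "z")]), top8, 1L)
  expect_equal(cc8[["total"]], 8L)
  expect_error(coordination_count(X, top, 1L, spec = ion_spec("K")),
               "does not match")
})

test_that("coordination equals a brute-force distance filter on random frames", {
  top <- build_model_topology("DEKA", geometry_config(n_water = 30L),
                              seed = 2)
  ion <- top$id[top$role == "ion"][1]
  set.seed(32)
  for (rep in 1:10) {
    X <- as.matrix(top[, c("x", "y", "z")])
    X <- X + matrix(rnorm(length(X), 0, 1.5), ncol = 3)
    cc <- coordination_count(X, top, ion)
    expect_identical(cc[["total"]],
                     brute_coordination(X, top, ion, 2.69))
  }
})

test_that("mode coordination summary applies round-half-up at the 2.5 tie", {
  top <- coord_fixture("NA", rep(2.0, 4), role = "carboxylate-O")
  X4 <- as.matrix(top[, c("x", "y", "z")])
  X1 <- X4
  X1[3:5, 1] <- 9   # move three oxygens away: 1 coordinating
  # alternate 4- and 1-coordinating frames: mean 2.5 -> rounds up to 3
  coords <- array(c(X4, X1, X4, X1), c(5, 3, 4))
  tr <- sf_trajectory(coords, box = attr(top, "box"))
  mode <- tibble::tibble(rank = 1L)
  s <- classify_mode_coordination(mode, 1:4, tr, top, ion_spec("NA"), 1L)
  expect_equal(s$mean_carboxylate_O, 2.5)
  expect_true(s$tight_coordination)
  s4 <- classify_mode_coordination(mode, c(1L, 3L), tr, top, ion_spec("NA"), 1L)
  expect_true(s4$tight_coordination)       # 4 every frame
  s1 <- classify_mode_coordination(mode, c(2L, 4L), tr, top, ion_spec("NA"), 1L)
  expect_false(s1$tight_coordination)      # 1 every frame
})

test_that("group-cation distances and exceedance fractions are exact on fixtures", {
  mk <- function(ds) {
    atoms <- tibble::tibble(
      name = c("NZ", "NA"), resname = c("LYS", "NA"),
      resnum = c(180L, 2001L), chain = c("C", "SOLVENT"),
      role = c("sidechain-N", "ion"), charge = c(1, 1), sigma = 3,
      epsilon = 0, x = 0, y = 0, z = 0,
      anchor_x = NA_real_, anchor_y = NA_real_, anchor_z = NA_real_,
      tether_k = NA_real_, tether_r0 = NA_real_, mobile = TRUE)
    geom <- list(box = c(40, 40, 40), wall_z = 1e6, wall_k = 0, eps_r = 1,
                 cutoff = 5)
    top <- sfpore:::new_sf_topology(atoms, geom$box, "gd", geom, nbfix = NULL)
    coords <- array(0, c(2, 3, length(ds)))
    for (f in seq_along(ds)) coords[2, 1, f] <- ds[f]
    list(top = top, traj = sf_trajectory(coords, box = geom$box))
  }
  fx <- mk(rep(6, 5))
  gd <- group_cation_distance(fx$traj, fx$top, "name NZ", 2L)
  expect_equal(gd$exceedance$fraction[gd$exceedance$threshold == 5.5], 1)
  fx2 <- mk(rep(4, 5))
  gd2 <- group_cation_distance(fx2$traj, fx2$top, "name NZ", 2L)
  expect_equal(gd2$exceedance$fraction[gd2$exceedance$threshold == 5.0], 0)
  fx3 <- mk(rep(c(4.5, 6.0), 4))
  gd3 <- group_cation_distance(fx3$traj, fx3$top, "name NZ", 2L)
  expect_equal(gd3$exceedance$fraction[gd3$exceedance$threshold == 5.0], 0.5)
})

test_that("the repulsion profile reduces to the exact screened Coulomb law", {
  grid <- c(4, 6, 8, 10, 12)
  pr <- repulsion_profile("LYS", "NA", distances = grid,
                          protocol = bd_protocol(temperature = 0,
                                                 n_steps = 10, seed = 1),
                          eps_r = 1)
  expect_equal(pr$mean_elec, 332.06 / grid, tolerance = 1e-6)
  expect_equal(pr$mean_elec[grid == 10], 33.206, tolerance = 1e-6)
  # monotone decreasing for like charges
  expect_true(all(diff(pr$mean_elec) < 0))
  expect_error(repulsion_profile("LYS", "NA", distances = c(1, 5)),
               "contact")
})

test_that("a dense point charge repels more than a spread planar triad at 4 A", {
  pr_l <- repulsion_profile("LYS", "NA", distances = 4,
                            protocol = bd_protocol(n_steps = 60000,
                                                   save_interval = 20,
                                                   seed = 33))
  pr_r <- repulsion_profile("ARG", "NA", distances = 4,
                            protocol = bd_protocol(n_steps = 60000,
                                                   save_interval = 20,
                                                   seed = 33))
  expect_gt(pr_l$mean_elec, pr_r$mean_elec)
})
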