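ion_fixture <- function(zs, rs = 0, box = c(20, 20, 30)) {
  # four fixed reference atoms defining the center plus one ion following
  # the given (Z, R) path
  nf <- length(zs)
  rs <- rep(rs, length.out = nf)
  atoms <- tibble::tibble(
    name = c(rep("CA", 4), "NA"),
    resname = c(rep("GLY", 4), "NA"), resnum = c(rep(180L, 4), 2001L),
    chain = c("A", "B", "C", "D", "SOLVENT"),
    role = c(rep("backbone", 4), "ion"), charge = c(rep(0, 4), 1),
    sigma = 3, epsilon = 0, x = c(1, -1, 1, -1, 0),
    y = c(1, 1, -1, -1, 0), z = 0,
    anchor_x = NA_real_, anchor_y = NA_real_, anchor_z = NA_real_,
    tether_k = NA_real_, tether_r0 = NA_real_,
    mobile = c(rep(FALSE, 4), TRUE))
  geom <- list(box = box, wall_z = 1e6, wall_k = 0, eps_r = 1, cutoff = 5)
  top <- sfpore:::new_sf_topology(atoms, box, "fix", geom, nbfix = NULL)
  coords <- array(0, c(5, 3, nf))
  for (f in seq_len(nf)) {
    coords[1:4, , f] <- as.matrix(atoms[1:4, c("x", "y", "z")])
    coords[5, , f] <- c(rs[f], 0, zs[f])
  }
  list(top = top, traj = sf_trajectory(coords, box = box))
}

test_that("site occupancy is 1 inside a site and 0 outside all sites", {
  fx <- ion_fixture(zs = rep(0.5, 10))
  occ <- site_occupancy(fx$traj, fx$top, 5L)
  fr <- occ$fractions
  expect_equal(fr$fraction[fr$site == "Site_OC"], 1)
  expect_true(all(fr$fraction[fr$site != "Site_OC"] == 0))
  fx2 <- ion_fixture(zs = rep(14, 10))
  fr2 <- site_occupancy(fx2$traj, fx2$top, 5L)$fractions
  expect_equal(fr2$fraction[fr2$site == "unbound"], 1)
})

test_that("overlapping site definitions are rejected with the overlap named", {
  bad <- tibble::tibble(site = c("A", "B"), z_lo = c(0, 1), z_hi = c(2, 3),
                        r_max = 4)
  fx <- ion_fixture(zs = 0)
  expect_error(site_occupancy(fx$traj, fx$top, 5L, sites = bad),
               "overlapping")
})

test_that("uniform sampling splits evenly between two equal sites", {
  set.seed(21)
  zs <- runif(4000, -2, 2)
  fx <- ion_fixture(zs = zs)
  sites <- tibble::tibble(site = c("lower", "upper"), z_lo = c(-2, 0),
                          z_hi = c(0, 2), r_max = 4)
  fr <- site_occupancy(fx$traj, fx$top, 5L, sites = sites)$fractions
  p <- fr$fraction[fr$site == "lower"]
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("free-energy map normalisation and caps behave per definition", {
  rz <- tibble::tibble(R = rep(1.1, 50), Z = rep(0.2, 50))
  fm <- free_energy_map(rz, bin_width = 0.5, cap = 6)
  expect_equal(min(fm$G), 0)
  expect_true(all(fm$G[fm$counts == 0] == 6))
  expect_equal(sum(fm$counts), 50)
  # doubling every count leaves G unchanged
  rz2 <- dplyr::bind_rows(rz, rz)
  fm2 <- free_energy_map(rz2, bin_width = 0.5, cap = 6)
  expect_equal(fm2$G, fm$G)
  expect_error(free_energy_map(rz, kT = -1), "kT")
})

test_that("Boltzmann inversion recovers a planted harmonic well", {
  set.seed(22)
  kT <- kT_at(310)
  kR <- 1.2; kZ <- 0.8
  n <- 2e5
  rz <- tibble::tibble(R = rnorm(n, 5, sqrt(kT / kR)),
                       Z = rnorm(n, 0, sqrt(kT / kZ)))
  fm <- free_energy_map(rz, bin_width = 0.25, kT = kT, cap = 10)
  df <- as_tibble(fm)
  df$U <- 0.5 * kR * (df$R - 5)^2 + 0.5 * kZ * (df$Z - 0)^2
  df$U <- df$U - min(df$U[df$count > 0])
  well <- df[df$count >= 100, ]
  rms <- sqrt(mean((well$G - well$U)^2))
  expect_lt(rms, 0.2)
})

test_that("permeation events honour direction and debounce", {
  # monotone descent through z = 0
  fx <- ion_fixture(zs = seq(5, -5, length.out = 40))
  ev <- detect_permeation_events(rz_series(fx$traj, fx$top, 5L), 0, dwell = 3)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, -1L)
  # rapid oscillation never dwells
  fx2 <- ion_fixture(zs = rep(c(0.5, -0.5), 20))
  ev2 <- detect_permeation_events(rz_series(fx2$traj, fx2$top, 5L), 0,
                                  dwell = 3)
  expect_equal(nrow(ev2), 0)
  # three planted crossings with adequate dwell
  zs <- c(rep(2, 6), rep(-2, 6), rep(2, 6), rep(-2, 6))
  fx3 <- ion_fixture(zs = zs)
  ev3 <- detect_permeation_events(rz_series(fx3$traj, fx3$top, 5L), 0,
                                  dwell = 3)
  expect_equal(nrow(ev3), 3)
  expect_equal(ev3$frame, c(7L, 13L, 19L))
  expect_equal(ev3$direction, c(-1L, 1L, -1L))
})

test_that("identical bound frames collapse to one full-occupancy mode", {
  fx <- cluster_fixture(c(5), list(c(0, 0, 0)), jitter = 0)
  m <- cluster_binding_modes(fx$traj, fx$top, 5L, 1:5, n_analyzed = 5)
  expect_equal(nrow(m), 1)
  expect_equal(m$occupancy, 1)
})

test_that("two planted geometries at 60/40 are recovered exactly", {
  fx <- cluster_fixture(c(60, 40), list(c(0, 0, 0), c(0, 0, 4)))
  m <- cluster_binding_modes(fx$traj, fx$top, 5L, 1:100, n_analyzed = 100)
  expect_equal(nrow(m), 2)
  expect_equal(m$occupancy, c(0.6, 0.4))
  members <- attr(m, "members")
  expect_setequal(members[[1]], which(fx$assign == 1))
  expect_setequal(members[[2]], which(fx$assign == 2))
})

test_that("three planted geometries yield exactly two main modes", {
  fx <- cluster_fixture(c(50, 30, 20),
                        list(c(0, 0, 0), c(0, 0, 4), c(1.5, 0, -4)))
  m <- cluster_binding_modes(fx$traj, fx$top, 5L, 1:100, n_analyzed = 100)
  expect_equal(nrow(m), 3)
  expect_equal(m$main, c(TRUE, TRUE, FALSE))
  expect_equal(sum(m$main), 2)
})

test_that("clustering is invariant to frame order", {
  fx <- cluster_fixture(c(30, 20), list(c(0, 0, 0), c(0, 0, 4)))
  m1 <- cluster_binding_modes(fx$traj, fx$top, 5L, 1:50, n_analyzed = 50)
  perm <- c(seq(2, 50, 2), seq(1, 49, 2))
  m2 <- cluster_binding_modes(fx$traj, fx$top, 5L, perm, n_analyzed = 50)
  expect_equal(m1$occupancy, m2$occupancy)
  expect_setequal(attr(m1, "members")[[1]], attr(m2, "members")[[1]])
})

test_that("empty bound set is a 'no binding' error", {
  fx <- cluster_fixture(c(3), list(c(0, 0, 0)))
  expect_error(cluster_binding_modes(fx$traj, fx$top, 5L, integer(0)),
               "no binding")
})
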