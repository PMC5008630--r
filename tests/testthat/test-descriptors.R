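ref_topology <- function(extra = NULL, box = c(20, 20, 30)) {
  atoms <- tibble::tibble(
    name = "CA", resname = "GLY", resnum = 180L,
    chain = c("A", "B", "C", "D"), role = "backbone", charge = 0,
    sigma = 3, epsilon = 0, x = c(1, -1, 1, -1), y = c(1, 1, -1, -1),
    z = 0, anchor_x = NA_real_, anchor_y = NA_real_, anchor_z = NA_real_,
    tether_k = NA_real_, tether_r0 = NA_real_, mobile = FALSE)
  if (!is.null(extra)) atoms <- dplyr::bind_rows(atoms, extra)
  geom <- list(box = box, wall_z = 1e6, wall_k = 0, eps_r = 1, cutoff = 5)
  sfpore:::new_sf_topology(atoms, box, "ref", geom, nbfix = NULL)
}

test_that("SF center is the mean of the defining atoms", {
  top <- ref_topology()
  X <- as.matrix(top[, c("x", "y", "z")])
  expect_equal(sf_center(X, top), c(x = 0, y = 0, z = 0),
               ignore_attr = TRUE)
  one <- sf_center(X, top, sf_center_def("chain A and name CA"))
  expect_equal(one, c(1, 1, 0), ignore_attr = TRUE)
  expect_error(sf_center(X, top, sf_center_def("resnum 999")) |>
                 suppressWarnings(), "no atoms")
})

test_that("center of atoms straddling the periodic boundary uses unwrapped images", {
  top <- ref_topology(box = c(20, 20, 30))
  X <- as.matrix(top[, c("x", "y", "z")])
  X[, 1] <- c(9.5, -9.5, 9.5, -9.5)   # straddle x boundary
  ctr <- sf_center(X, top)
  # brute force: enumerate image shifts of each atom, pick the compact set
  shifts <- c(-20, 0, 20)
  best <- Inf; best_mean <- NA
  for (s2 in shifts) for (s3 in shifts) for (s4 in shifts) {
    xs <- X[, 1] + c(0, s2, s3, s4)
    if (diff(range(xs)) < best) { best <- diff(range(xs)); best_mean <- mean(xs) }
  }
  expect_equal(sfpore:::min_image(ctr[1] - best_mean, 20), 0,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Z and R follow the 3-4-5 geometry and the minimum image", {
  box <- c(20, 20, 30)
  expect_equal(compute_Z(c(3, 4, 5), c(0, 0, 0)), 5)
  expect_equal(compute_R(c(3, 4, 5), c(0, 0, 0)), 5)
  expect_equal(compute_Z(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(compute_R(c(0, 0, 0), c(0, 0, 0)), 0)
  # dx = 0.6 Lx wraps to dx - Lx
  dx <- 0.6 * box[1]
  r <- compute_R(c(dx, 0, 0), c(0, 0, 0), box)
  imgs <- dx + c(-1, 0, 1) * box[1]
  expect_equal(r, min(abs(imgs)))
})

test_that("R is invariant under rotation about the z axis", {
  set.seed(13)
  for (i in 1:20) {
    p <- runif(3, -5, 5); ctr <- runif(3, -2, 2)
    th <- runif(1, 0, 2 * pi)
    Rm <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                 byrow = TRUE)
    expect_equal(compute_R(drop(Rm %*% p), drop(Rm %*% ctr)),
                 compute_R(p, ctr), tolerance = 1e-12)
  }
})

test_that("rz_series equals frame-by-frame scalar calls", {
  probe <- tibble::tibble(
    name = "NZ", resname = "LYS", resnum = 180L, chain = "C",
    role = "sidechain-N", charge = 0, sigma = 3, epsilon = 0,
    x = 0, y = 0, z = 0, anchor_x = NA_real_, anchor_y = NA_real_,
    anchor_z = NA_real_, tether_k = NA_real_, tether_r0 = NA_real_,
    mobile = TRUE)
  top <- ref_topology(probe)
  set.seed(14)
  nf <- 7
  coords <- array(0, c(5, 3, nf))
  for (f in seq_len(nf)) {
    coords[1:4, , f] <- as.matrix(top[1:4, c("x", "y", "z")])
    coords[5, , f] <- runif(3, -4, 4)
  }
  tr <- sf_trajectory(coords, box = attr(top, "box"))
  rz <- rz_series(tr, top, 5L)
  expect_equal(nrow(rz), nf)
  for (f in seq_len(nf)) {
    ctr <- sf_center(coords[, , f], top)
    expect_identical(rz$Z[f], compute_Z(coords[5, , f], ctr))
    expect_identical(rz$R[f],
                     compute_R(coords[5, , f], ctr, attr(top, "box")))
  }
  # stationary probe: constant series; single frame: length-1
  tr1 <- sf_trajectory(coords[, , 1, drop = FALSE], box = attr(top, "box"))
  expect_equal(nrow(rz_series(tr1, top, 5L)), 1)
  expect_error(rz_series(tr, top, 99L), "outside atom count|out of range")
})
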