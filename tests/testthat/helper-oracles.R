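# Independent oracles and small fixture builders shared across tests.

# Rejection-sample positions keeping every (minimum-image) pair distance
# above min_d, so LJ cores stay finite and kernel-vs-oracle agreement is
# meaningful at absolute tolerance.
spread_positions <- function(n, box, min_d = 2.0) {
  X <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    repeat {
      p <- c(runif(1, -box[1] / 2, box[1] / 2),
             runif(1, -box[2] / 2, box[2] / 2), runif(1, -8, 8))
      if (i == 1) { X[i, ] <- p; break }
      dx <- X[seq_len(i - 1), 1] - p[1]
      dx <- dx - box[1] * round(dx / box[1])
      dy <- X[seq_len(i - 1), 2] - p[2]
      dy <- dy - box[2] * round(dy / box[2])
      if (min(dx^2 + dy^2 + (X[seq_len(i - 1), 3] - p[3])^2) >= min_d^2) {
        X[i, ] <- p; break
      }
    }
  }
  X
}

# Bare bead topology with random charges/LJ in a periodic (x, y) box.
toy_topology <- function(n, seed, box = c(18, 18, 40), eps_r = 10,
                         cutoff = 8, charged = TRUE, wall_z = 1e6,
                         wall_k = 0) {
  set.seed(seed)
  X <- spread_positions(n, box)
  atoms <- tibble::tibble(
    name = sprintf("B%d", seq_len(n)), resname = "BDS",
    resnum = seq_len(n), chain = "SOLVENT", role = "probe",
    charge = if (charged) runif(n, -1, 1) else rep(0, n),
    sigma = runif(n, 2, 4), epsilon = runif(n, 0, 0.3),
    x = X[, 1], y = X[, 2], z = X[, 3],
    anchor_x = NA_real_, anchor_y = NA_real_, anchor_z = NA_real_,
    tether_k = NA_real_, tether_r0 = NA_real_, mobile = TRUE)
  geom <- list(box = box, wall_z = wall_z, wall_k = wall_k, eps_r = eps_r,
               cutoff = cutoff)
  sfpore:::new_sf_topology(atoms, box, "toy", geom, nbfix = NULL)
}

# Brute-force double-loop pair sum (Coulomb + LJ, minimum image in x/y,
# truncation at the cutoff) -- independent of the compiled kernel.
brute_pair_energy <- function(topology, X = NULL) {
  if (is.null(X)) X <- as.matrix(topology[, c("x", "y", "z")])
  box <- attr(topology, "box")
  rc <- attr(topology, "cutoff")
  er <- attr(topology, "eps_r")
  n <- nrow(X)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- X[i, ] - X[j, ]
    d[1] <- d[1] - box[1] * round(d[1] / box[1])
    d[2] <- d[2] - box[2] * round(d[2] / box[2])
    r <- sqrt(sum(d^2))
    if (r >= rc) next
    e <- e + 332.06 * topology$charge[i] * topology$charge[j] / (er * r)
    s <- (topology$sigma[i] + topology$sigma[j]) / 2
    ep <- sqrt(topology$epsilon[i] * topology$epsilon[j])
    if (ep > 0) e <- e + 4 * ep * ((s / r)^12 - (s / r)^6)
  }
  e
}

# Brute-force coordination filter: plain distance threshold over all
# candidate oxygens with minimum image in x/y.
brute_coordination <- function(frame, topology, ion, cutoff) {
  box <- attr(topology, "box")
  cand <- which(topology$role %in% c("carboxylate-O", "water-O") |
                  (topology$role == "placeholder" &
                     grepl("^O", topology$name)))
  p <- frame[ion, ]
  cnt <- 0L
  for (j in cand) {
    d <- frame[j, ] - p
    d[1] <- d[1] - box[1] * round(d[1] / box[1])
    d[2] <- d[2] - box[2] * round(d[2] / box[2])
    if (sqrt(sum(d^2)) <= cutoff) cnt <- cnt + 1L
  }
  cnt
}

# Exhaustive max-margin linear separator for small separable 2-D point
# sets: grid over orientations, analytic best offset per orientation.
oracle_max_margin <- function(P, labels) {
  P <- as.matrix(P)
  y <- ifelse(labels == "open", 1, -1)
  best <- list(margin = -Inf)
  for (theta in seq(0, pi, length.out = 3601)[-3601]) {
    w <- c(cos(theta), sin(theta))
    pr <- drop(P %*% w)
    for (sgn in c(1, -1)) {
      lo <- min(pr[y * sgn > 0]); hi <- max(pr[y * sgn < 0])
      margin <- (lo - hi) / 2
      if (margin > best$margin)
        best <- list(margin = margin, w = sgn * w,
                     b = -sgn * (lo + hi) / 2)
    }
  }
  best
}

# Minimal single-frame trajectory around a topology's coordinates.
traj_of <- function(topology, frames = 1L) {
  X <- as.matrix(topology[, c("x", "y", "z")])
  sf_trajectory(array(rep(X, frames), c(nrow(X), 3, frames)),
                box = attr(topology, "box"))
}

cluster_fixture <- function(weights, centers, seed = 23, jitter = 0.05) {
  # ion positions drawn around planted centers; features are ion-to-oxygen
  # distances so distinct positions give distinct feature vectors
  set.seed(seed)
  n <- sum(weights)
  assign <- rep(seq_along(weights), weights)
  atoms <- tibble::tibble(
    name = c("OD1", "OD2", "OE1", "OE2", "NA"),
    resname = c("ASP", "ASP", "GLU", "GLU", "NA"),
    resnum = c(180L, 180L, 180L, 180L, 2001L),
    chain = c("A", "A", "B", "B", "SOLVENT"),
    role = c(rep("carboxylate-O", 4), "ion"),
    charge = 0, sigma = 3, epsilon = 0,
    x = c(2.5, 2.5, -2.5, -2.5, 0), y = c(0.8, -0.8, 0.8, -0.8, 0), z = 0,
    anchor_x = NA_real_, anchor_y = NA_real_, anchor_z = NA_real_,
    tether_k = NA_real_, tether_r0 = NA_real_,
    mobile = c(rep(FALSE, 4), TRUE))
  geom <- list(box = c(20, 20, 30), wall_z = 1e6, wall_k = 0, eps_r = 1,
               cutoff = 5)
  top <- sfpore:::new_sf_topology(atoms, geom$box, "cl", geom, nbfix = NULL)
  coords <- array(0, c(5, 3, n))
  for (f in seq_len(n)) {
    coords[1:4, , f] <- as.matrix(atoms[1:4, c("x", "y", "z")])
    coords[5, , f] <- centers[[assign[f]]] + rnorm(3, 0, jitter)
  }
  list(top = top, traj = sf_trajectory(coords, box = geom$box),
       assign = assign)
}

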