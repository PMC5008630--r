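#' Trajectory container
#'
#' Frames of bead coordinates from a simulation or a file. Coordinates are
#' stored as an `n_atoms x 3 x n_frames` array in Angstrom (float64); frame
#' times are in ps and the orthorhombic box is per-frame.
#'
#' @param coords n_atoms x 3 x n_frames array.
#' @param times Frame times, ps.
#' @param box Length-3 box vector or n_frames x 3 matrix.
#' @return An `sf_trajectory` object.
#' @export
sf_trajectory <- function(coords, times = NULL, box = c(0, 0, 0)) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  nf <- dim(coords)[3]
  if (is.null(times)) times <- seq_len(nf) - 1
  if (is.null(dim(box))) box <- matrix(box, nrow = max(nf, 1), ncol = 3,
                                       byrow = TRUE)
  stopifnot(length(times) == nf)
  structure(list(coords = coords, times = as.numeric(times), box = box),
            class = "sf_trajectory")
}

#' @export
print.sf_trajectory <- function(x, ...) {
  cat(sprintf("<sf_trajectory> %d frames x %d atoms, t = %.4g..%.4g ps\n",
              n_frames(x), dim(x$coords)[1],
              if (n_frames(x)) min(x$times) else NA,
              if (n_frames(x)) max(x$times) else NA))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory An [sf_trajectory()].
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Extract one frame as a coordinate matrix
#' @param trajectory An [sf_trajectory()].
#' @param i Frame index.
#' @export
frame_coords <- function(trajectory, i) {
  stopifnot(i >= 1, i <= n_frames(trajectory))
  trajectory$coords[, , i, drop = TRUE]
}

#' @export
as_tibble.sf_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  na <- dim(x$coords)[1]
  tibble::tibble(
    frame = rep(seq_len(nf), each = na),
    time = rep(x$times, each = na),
    atom = rep(seq_len(na), nf),
    x = as.numeric(x$coords[, 1, ]),
    y = as.numeric(x$coords[, 2, ]),
    z = as.numeric(x$coords[, 3, ]))
}

#' Run a Brownian-dynamics simulation
#'
#' Integrates the toy Hamiltonian with overdamped Langevin (Euler-Maruyama)
#' steps. With a fixed seed the trajectory is bit-reproducible; at zero
#' temperature and zero net force the configuration is stationary; long runs
#' sample the Boltzmann distribution of [potential_energy()].
#'
#' @param topology An [sf_topology].
#' @param protocol A [bd_protocol()].
#' @param restraints Optional flat-bottom sphere restraints (tibble with
#'   `atom`, `x`, `y`, `z`, `radius`, `k`); atoms must exist.
#' @param start Optional starting coordinates (defaults to the topology's).
#' @param double_well Optional 1-D validation field on z:
#'   `list(k, z1, z2, dU, atoms)` selects the lower branch of two offset
#'   parabolas (well at `z1` has energy 0, well at `z2` has energy `dU`).
#' @return An [sf_trajectory()] with attributes `final` (last configuration)
#'   and `protocol`.
#' @export
simulate_trajectory <- function(topology, protocol, restraints = NULL,
                                start = NULL, double_well = NULL) {
  stopifnot(inherits(protocol, "bd_protocol"))
  if (!is.null(restraints) &&
      any(restraints$atom < 1 | restraints$atom > nrow(topology)))
    abort("restraints reference atoms outside the topology")
  par <- pair_params(topology, restraints, double_well)
  X0 <- if (is.null(start)) coords_of(topology) else as.matrix(start)
  if (nrow(X0) != nrow(topology)) abort("start coordinates do not match topology")
  set.seed(protocol$seed)
  res <- bd_run_cpp(X0, par, protocol$n_steps, protocol$timestep,
                    KB * protocol$temperature,
                    protocol$friction, protocol$save_interval,
                    topology$mobile, protocol$dims, 0)
  traj <- sf_trajectory(res$frames, res$times, attr(topology, "box"))
  attr(traj, "final") <- res$final
  attr(traj, "protocol") <- protocol
  traj
}

#' Plant labelled open/closed reporter states
#'
#' Generates a minimal fixture trajectory whose reporter atom's (R, Z)
#' coordinates are drawn from two 2-D Gaussian populations with known labels
#' -- the training bed for the open/closed state classifier. Four fixed
#' reference atoms at (+-1, +-1, 0) define the filter center at the origin.
#'
#' @param open_params,closed_params Lists with `mean` (length-2: R, Z) and
#'   `cov` (2 x 2 positive-definite covariance).
#' @param n_frames Total frames.
#' @param seed RNG seed.
#' @param open_fraction Fraction of frames drawn from the open population.
#' @return List with `trajectory`, `topology`, `labels` (factor
#'   closed/open), and `rz` (tibble of the planted values).
#' @export
plant_labeled_states <- function(open_params, closed_params, n_frames = 1000L,
                                 seed = 1L, open_fraction = 0.5) {
  check_cov <- function(p, who) {
    cv <- p$cov
    if (!all(dim(cv) == c(2, 2)) || any(eigen(cv, symmetric = TRUE,
                                              only.values = TRUE)$values <= 0))
      abort(paste0(who, " covariance is not positive-definite"))
  }
  check_cov(open_params, "open"); check_cov(closed_params, "closed")
  set.seed(seed)
  lab <- factor(ifelse(runif(n_frames) < open_fraction, "open", "closed"),
                levels = c("closed", "open"))
  draw <- function(p, m) {
    L <- chol(p$cov)
    matrix(rnorm(2 * m), ncol = 2) %*% L +
      matrix(p$mean, m, 2, byrow = TRUE)
  }
  rz <- matrix(NA_real_, n_frames, 2)
  rz[lab == "open", ] <- draw(open_params, sum(lab == "open"))
  rz[lab == "closed", ] <- draw(closed_params, sum(lab == "closed"))
  ref <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1), 0)
  atoms <- tibble::tibble(
    name = c(rep("CA", 4), "NZ"),
    resname = c(rep("GLY", 4), "LYS"),
    resnum = c(rep(180L, 4), 180L),
    chain = c("A", "B", "C", "D", "C"),
    role = c(rep("backbone", 4), "sidechain-N"),
    charge = 0, sigma = 3, epsilon = 0,
    x = c(ref[, 1], 0), y = c(ref[, 2], 0), z = 0,
    anchor_x = NA_real_, anchor_y = NA_real_, anchor_z = NA_real_,
    tether_k = NA_real_, tether_r0 = NA_real_,
    mobile = c(rep(FALSE, 4), TRUE))
  geom <- list(box = c(100, 100, 100), wall_z = 50, wall_k = 0, eps_r = 1,
               cutoff = 3)
  top <- new_sf_topology(atoms, geom$box, "planted", geom)
  coords <- array(0, c(5, 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[1:4, , f] <- ref
    coords[5, , f] <- c(rz[f, 1], 0, rz[f, 2])  # reporter at (R, 0, Z)
  }
  list(trajectory = sf_trajectory(coords, box = geom$box), topology = top,
       labels = lab,
       rz = tibble::tibble(frame = seq_len(n_frames), R = rz[, 1],
                           Z = rz[, 2], label = lab))
}
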