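#' @title Interaction-level analyses
#' @description Hydrogen-bond occupancy between side-chain groups,
#' coordination-shell counting with ion-specific cutoffs, cation--charged-
#' group distance statistics, and the electrostatic repulsion-versus-
#' distance profile contrasting a Lys-like point charge with an Arg-like
#' distributed planar charge.
#' @name interaction_analysis
NULL

#' Hydrogen-bond criteria
#'
#' The coarse model has no hydrogens, so the criterion is a heavy-atom
#' donor--acceptor distance only; an angle term exists in the API but is off
#' by default.
#' @param max_distance Donor--acceptor heavy-atom cutoff (A, default 3.5).
#' @param use_angle Ignored placeholder for an angle criterion.
#' @export
hbond_criteria <- function(max_distance = 3.5, use_angle = FALSE) {
  if (max_distance <= 0) abort("hbond distance cutoff must be positive")
  list(max_distance = max_distance, use_angle = use_angle)
}

pair_dists <- function(X, idx_a, idx_b, box) {
  dx <- outer(X[idx_a, 1], X[idx_b, 1], `-`)
  dy <- outer(X[idx_a, 2], X[idx_b, 2], `-`)
  dz <- outer(X[idx_a, 3], X[idx_b, 3], `-`)
  dx <- min_image(dx, box[1]); dy <- min_image(dy, box[2])
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' A frame counts when at least one donor--acceptor pair satisfies the
#' distance criterion; the per-frame `bifurcate` flag is set when the donor
#' group simultaneously bonds acceptors from two or more distinct residues.
#'
#' @param trajectory,topology Trajectory and topology.
#' @param donor_selection,acceptor_selection Selections (non-empty).
#' @param criteria An [hbond_criteria()].
#' @return List: `occupancy` (fraction of frames bonded),
#'   `bifurcate_occupancy`, and `flags` (tibble frame, bonded, bifurcate).
#' @export
hbond_occupancy <- function(trajectory, topology, donor_selection,
                            acceptor_selection, criteria = hbond_criteria()) {
  don <- resolve_selection(topology, donor_selection)
  acc <- resolve_selection(topology, acceptor_selection)
  if (length(don) == 0 || length(acc) == 0)
    abort("donor and acceptor selections must be non-empty")
  box <- attr(topology, "box")
  acc_res <- paste(topology$chain[acc], topology$resnum[acc])
  nf <- n_frames(trajectory)
  bonded <- logical(nf); bifur <- logical(nf)
  for (f in seq_len(nf)) {
    D <- pair_dists(frame_coords(trajectory, f), don, acc, box)
    hit <- D <= criteria$max_distance
    bonded[f] <- any(hit)
    bifur[f] <- length(unique(acc_res[apply(hit, 2, any)])) >= 2
  }
  list(occupancy = mean(bonded), bifurcate_occupancy = mean(bifur),
       flags = tibble::tibble(frame = seq_len(nf), bonded = bonded,
                              bifurcate = bifur))
}

#' Coordination count of an ion in one frame
#'
#' Counts oxygen (and other candidate) atoms within the species-specific
#' coordinating cutoff (2.69 A for Na+, 3.22 A for K+), reported by role.
#' Counting is purely geometric; the species' chemical maximum (6 / 8) is a
#' property of [ion_spec()], not a truncation.
#'
#' @param frame n_atoms x 3 coordinates.
#' @param topology An [sf_topology].
#' @param ion Atom id of the ion.
#' @param spec An [ion_spec()] row matching the ion.
#' @param oxygen_selection Candidate atoms (default: all carboxylate-O,
#'   water-O and placeholder/hydroxyl oxygens).
#' @return Named integer vector: `carboxylate_O`, `other_protein_O`,
#'   `water_O`, `total`.
#' @export
coordination_count <- function(frame, topology, ion, spec = NULL,
                               oxygen_selection = NULL) {
  ion <- resolve_selection(topology, ion)
  stopifnot(length(ion) == 1)
  if (is.null(spec)) spec <- ion_spec(topology$name[ion])
  if (spec$species != topology$name[ion])
    abort(sprintf("ion-spec species (%s) does not match ion atom (%s)",
                  spec$species, topology$name[ion]))
  if (is.null(oxygen_selection)) {
    cand <- which(topology$role %in% c("carboxylate-O", "water-O") |
                    (topology$role == "placeholder" & grepl("^O", topology$name)))
  } else cand <- resolve_selection(topology, oxygen_selection)
  box <- attr(topology, "box")
  p <- frame[ion, ]
  dx <- min_image(frame[cand, 1] - p[1], box[1])
  dy <- min_image(frame[cand, 2] - p[2], box[2])
  dz <- frame[cand, 3] - p[3]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  inshell <- d <= spec$coord_cutoff
  role <- topology$role[cand]
  c(carboxylate_O = sum(inshell & role == "carboxylate-O"),
    other_protein_O = sum(inshell & !role %in% c("carboxylate-O", "water-O")),
    water_O = sum(inshell & role == "water-O"),
    total = sum(inshell))
}

#' Per-mode coordination summary
#'
#' Averages the carboxylate-oxygen coordination count over a binding mode's
#' member frames; the tight-coordination flag is set when the mean count,
#' rounded half-up to the nearest integer, is at least 3 -- the geometry
#' that favours the small, low-coordination Na+ ion.
#'
#' @param mode One row of a [cluster_binding_modes()] result (with the
#'   `members` attribute available on the full table).
#' @param members Integer member-frame indices for the mode.
#' @param trajectory,topology Trajectory and topology.
#' @param spec [ion_spec()] of the bound ion.
#' @param ion Ion atom id.
#' @return Tibble: mean counts by category, `tight_coordination` flag.
#' @export
classify_mode_coordination <- function(mode, members, trajectory, topology,
                                       spec, ion) {
  if (length(members) == 0) abort("mode has no member frames")
  counts <- t(vapply(members, function(f)
    coordination_count(frame_coords(trajectory, f), topology, ion, spec),
    numeric(4)))
  mc <- colMeans(counts)
  round_half_up <- function(x) floor(x + 0.5)
  tibble::tibble(
    rank = mode$rank,
    mean_carboxylate_O = mc[["carboxylate_O"]],
    mean_other_protein_O = mc[["other_protein_O"]],
    mean_water_O = mc[["water_O"]],
    mean_total = mc[["total"]],
    tight_coordination = round_half_up(mc[["carboxylate_O"]]) >= 3)
}

#' Cation distance to a charged side-chain group
#'
#' Per-frame minimum-image distance between the unweighted centroid of the
#' group's charge-bearing sites and the ion, with exceedance fractions at
#' the given thresholds (defaults 5.0 and 5.5 A, the distances beyond which
#' the side chain's electrostatic repulsion on the bound cation is weak).
#'
#' @param trajectory,topology Trajectory and topology.
#' @param group_selection Selection of the group's charge-bearing sites.
#' @param ion Ion atom id (or selection).
#' @param thresholds Distances (A) to report exceedance fractions for.
#' @return List: `distances` (tibble frame, time, distance), `exceedance`
#'   (tibble threshold, fraction).
#' @export
group_cation_distance <- function(trajectory, topology, group_selection, ion,
                                  thresholds = c(5.0, 5.5)) {
  grp <- resolve_selection(topology, group_selection)
  if (length(grp) == 0) abort("charged-group selection must be non-empty")
  ion <- resolve_selection(topology, ion)
  stopifnot(length(ion) == 1)
  box <- attr(topology, "box")
  nf <- n_frames(trajectory)
  d <- numeric(nf)
  for (f in seq_len(nf)) {
    X <- frame_coords(trajectory, f)
    ref <- X[grp[1], ]
    G <- X[grp, , drop = FALSE]
    G[, 1] <- ref[1] + min_image(G[, 1] - ref[1], box[1])
    G[, 2] <- ref[2] + min_image(G[, 2] - ref[2], box[2])
    ctr <- colMeans(G)
    d[f] <- sqrt(min_image(X[ion, 1] - ctr[1], box[1])^2 +
                   min_image(X[ion, 2] - ctr[2], box[2])^2 +
                   (X[ion, 3] - ctr[3])^2)
  }
  list(distances = tibble::tibble(frame = seq_len(nf),
                                  time = trajectory$times, distance = d),
       exceedance = tibble::tibble(
         threshold = thresholds,
         fraction = vapply(thresholds, function(th) mean(d > th), numeric(1))))
}

# Minimal isolated side-chain-analog systems for the repulsion profile.
analog_topology <- function(analog = c("LYS", "ARG"), ion_species = c("NA", "K"),
                            n_water = 0L, box = c(30, 30, 30), eps_r = 10,
                            seed = 1L) {
  analog <- match.arg(analog)
  ion_species <- match.arg(ion_species)
  geom <- list(box = box, wall_z = box[3] / 2 - 1, wall_k = 2.0,
               eps_r = eps_r, cutoff = min(box[1:2]) / 2 - 0.5,
               swing_arm = 0.0)
  bp <- bead_params()
  row <- function(name, key, pos, q, role, k = 50, r0 = 0) {
    p <- bp[bp$key == key, ]
    tibble::tibble(name = name, resname = analog, resnum = 1L, chain = "A",
                   role = role, charge = q, sigma = p$sigma,
                   epsilon = p$epsilon, x = pos[1], y = pos[2], z = pos[3],
                   anchor_x = pos[1], anchor_y = pos[2], anchor_z = pos[3],
                   tether_k = k, tether_r0 = r0, mobile = TRUE)
  }
  if (analog == "LYS") {
    grp <- row("NZ", "amine-N", c(0, 0, 0), 1.0, "sidechain-N")
    bonds <- NULL
  } else {
    grp <- dplyr::bind_rows(
      row("CZ", "guanidine-C", c(0, 0, 0), 0.10, "sidechain-C"),
      # NH beads ride on the CZ pivot through stiff bonds; their own tether
      # is a loose leash so the planar triad can reorient thermally
      row("NH1", "guanidine-N", c(1.5, 0, 0.3), 0.45, "sidechain-N",
          k = 1, r0 = 3.0),
      row("NH2", "guanidine-N", c(-1.5, 0, 0.3), 0.45, "sidechain-N",
          k = 1, r0 = 3.0))
    bonds <- tibble::tibble(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                            k = c(100, 100, 100), r0 = c(1.5, 1.5, 3.0))
  }
  is <- ion_spec(ion_species)
  ion <- tibble::tibble(
    name = ion_species, resname = ion_species, resnum = 2001L,
    chain = "SOLVENT", role = "ion", charge = is$charge, sigma = is$sigma,
    epsilon = is$epsilon, x = 10, y = 0, z = 0,
    anchor_x = NA_real_, anchor_y = NA_real_, anchor_z = NA_real_,
    tether_k = NA_real_, tether_r0 = NA_real_, mobile = FALSE)
  atoms <- dplyr::bind_rows(grp, ion)
  if (n_water > 0) {
    set.seed(seed)
    wat <- place_solvent(n_water, list(box = box, wall_z = geom$wall_z),
                         avoid = atoms[, c("x", "y", "z")])
    pw <- bp[bp$key == "water-O", ]
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      name = "OW", resname = "HOH", resnum = 1000L + seq_len(n_water),
      chain = "SOLVENT", role = "water-O", charge = 0, sigma = pw$sigma,
      epsilon = pw$epsilon, x = wat[, 1], y = wat[, 2], z = wat[, 3],
      anchor_x = NA_real_, anchor_y = NA_real_, anchor_z = NA_real_,
      tether_k = NA_real_, tether_r0 = NA_real_, mobile = TRUE))
  }
  top <- new_sf_topology(atoms, box, paste0(analog, "-analog"), geom,
                         bonds = bonds)
  attr(top, "total_charge") <- sum(top$charge)
  top
}

#' Electrostatic repulsion versus distance for a side-chain analog
#'
#' Places an isolated Lys-like (+1 point) or Arg-like (planar triad, +1/3
#' per site) charged group at the origin with the ion fixed at each grid
#' distance along x, samples the group's thermal motion with seeded
#' Brownian dynamics, and reports the mean group--ion electrostatic energy
#' at every grid distance. With a single-site group, no solvent and no
#' thermal motion this reduces to the exact screened Coulomb repulsion
#' `332.06 / (eps_r r)`.
#'
#' @param analog `"LYS"` or `"ARG"`.
#' @param ion_species `"NA"` or `"K"` (the charge is +1 either way; LJ only
#'   matters if solvent is present).
#' @param distances Grid of centroid separations (A).
#' @param protocol A [bd_protocol()]; `n_steps` of sampling per distance.
#' @param n_water Solvent beads (0 = vacuum).
#' @param eps_r Uniform dielectric (default 10; set 1 for bare Coulomb).
#' @param equil_fraction Leading fraction of frames discarded.
#' @return Tibble: `distance`, `mean_elec` (kcal/mol).
#' @export
repulsion_profile <- function(analog = c("LYS", "ARG"),
                              ion_species = c("NA", "K"),
                              distances = seq(3, 12, by = 1),
                              protocol = bd_protocol(n_steps = 20000L,
                                                     save_interval = 20L),
                              n_water = 0L, eps_r = 10,
                              equil_fraction = 0.2) {
  analog <- match.arg(analog)
  ion_species <- match.arg(ion_species)
  top0 <- analog_topology(analog, ion_species, n_water = n_water,
                          eps_r = eps_r, seed = protocol$seed)
  contact <- 2.0
  if (any(distances <= contact))
    abort("grid distances must exceed the LJ contact distance")
  grp <- which(top0$role %in% c("sidechain-N", "sidechain-C"))
  ion <- which(top0$role == "ion")
  ke <- KCOUL / eps_r
  box <- attr(top0, "box")
  out <- purrr::map(distances, function(d0) {
    top <- top0
    top$x[ion] <- d0
    if (protocol$temperature == 0 || all(!top$mobile[grp])) {
      X <- coords_of(top)
      frames <- array(X, c(nrow(top), 3, 1))
    } else {
      traj <- simulate_trajectory(top, protocol)
      nf <- n_frames(traj)
      keep <- seq(max(1, floor(nf * equil_fraction) + 1), nf)
      frames <- traj$coords[, , keep, drop = FALSE]
    }
    e <- vapply(seq_len(dim(frames)[3]), function(f) {
      X <- frames[, , f]
      dx <- min_image(X[grp, 1] - X[ion, 1], box[1])
      dy <- min_image(X[grp, 2] - X[ion, 2], box[2])
      dz <- X[grp, 3] - X[ion, 3]
      sum(ke * top$charge[grp] * top$charge[ion] /
            sqrt(dx^2 + dy^2 + dz^2))
    }, numeric(1))
    tibble::tibble(distance = d0, mean_elec = mean(e))
  })
  dplyr::bind_rows(out)
}
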