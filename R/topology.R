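#' Coarse-grained bead models of the Na_v selectivity filter
#'
#' A topology is a tibble with one row per bead (atom) plus attributes holding
#' the simulation box, dielectric, non-bonded overrides and intra-group bonds.
#' Four chains (A--D) carry the constriction-site (inner-ring, residue 180)
#' motif -- DEKA, DERA, DEAA, wild-type Ser, or charge-modified variants --
#' and an outer-ring (residue 183) acidic residue each. Neutral water-oxygen
#' beads and one or two permeant cations complete the system.
#'
#' Columns: `id`, `name`, `resname`, `resnum`, `chain`, `role`, `charge` (e),
#' `sigma` (A), `epsilon` (kcal/mol), `x`/`y`/`z` (initial coordinates, A),
#' `anchor_x`/`anchor_y`/`anchor_z` (tether anchor or NA), `tether_k`
#' (kcal/mol/A^2), `tether_r0` (flat-bottom tether radius, A), `mobile`.
#'
#' @name sf_topology
NULL

#' Recognised model variants
#' @export
sf_variants <- c("WT", "DEAA", "DEKA", "DERA", "DEKA-0.5e", "DEKA-0.05e",
                 "DERA-estar", "DERA-E183D", "DERA-E183A")

# Bead non-bonded parameter book (sigma A, epsilon kcal/mol, charge e).
bead_params <- function() {
  tibble::tribble(
    ~key,            ~sigma, ~epsilon, ~charge,
    "carboxylate-O",  2.90,   0.12,    -0.5,
    "amine-N",        3.00,   0.10,     1.0,
    "guanidine-N",    3.00,   0.10,     NA,   # per-variant charge split
    "guanidine-C",    3.20,   0.10,     NA,
    "neutral-C",      3.50,   0.10,     0.0,
    "hydroxyl-O",     3.00,   0.12,     0.0,
    "backbone",       3.50,   0.10,     0.0,
    "water-O",        2.85,   0.15,     0.0,
    "NA",             2.42,   0.0469,   1.0,
    "K",              3.14,   0.0870,   1.0
  )
}

#' Ion species parameters
#'
#' Lennard-Jones parameters, first-shell coordination cutoff and the maximal
#' (chemical) coordination number for the two permeant cations. The cutoffs
#' are the means of QM/MM ion--oxygen coordinating-distance ranges
#' (2.39--2.99 A for Na+, 2.80--3.65 A for K+); the maximal coordination
#' numbers are 6 (Na+) and 8 (K+).
#'
#' @param species `"NA"` or `"K"`.
#' @return A one-row tibble with `species`, `charge`, `sigma`, `epsilon`,
#'   `coord_cutoff`, `max_coordination`.
#' @export
ion_spec <- function(species = c("NA", "K")) {
  species <- match.arg(species)
  bp <- bead_params()
  p <- bp[bp$key == species, ]
  tibble::tibble(
    species = species,
    charge = 1.0,
    sigma = p$sigma,
    epsilon = p$epsilon,
    coord_cutoff = if (species == "NA") 2.69 else 3.22,
    max_coordination = if (species == "NA") 6L else 8L
  )
}

#' Brownian-dynamics protocol
#'
#' @param temperature Kelvin; 310 K default.
#' @param friction Friction coefficient gamma in kcal*ps/(mol*A^2); the
#'   diffusion constant is kT/gamma (~0.2 A^2/ps at defaults).
#' @param timestep Integration step, ps.
#' @param n_steps Number of steps.
#' @param save_interval Save a frame every this many steps.
#' @param seed Integer RNG seed.
#' @param dims Logical length-3 vector of integrated Cartesian axes (used to
#'   construct reduced-dimensional validation systems).
#' @return A `bd_protocol` list.
#' @export
bd_protocol <- function(temperature = 310, friction = 3.0, timestep = 0.01,
                        n_steps = 10000L, save_interval = 10L, seed = 1L,
                        dims = c(TRUE, TRUE, TRUE)) {
  stopifnot(temperature >= 0, friction > 0, timestep > 0, n_steps >= 1,
            save_interval >= 1, length(dims) == 3)
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, n_steps = as.integer(n_steps),
                 save_interval = as.integer(save_interval),
                 seed = as.integer(seed), dims = as.logical(dims)),
            class = "bd_protocol")
}

#' Pore geometry configuration
#'
#' Positions are cylindrical: each chain sits at a fixed azimuth (A 0, B 180,
#' C 90, D 270 degrees) so that the Asp and Glu carboxylates of the inner
#' ring face each other across the pore and the cationic side chain (chain C)
#' is flanked by both.
#'
#' @param box Orthorhombic box (A); periodic in x and y only.
#' @param pore_radius Radius of the inner-ring backbone circle (A).
#' @param inner_tip_radius Radial position of inner-ring carboxylate tips (A).
#' @param outer_z Height of the outer ring above the inner ring (A).
#' @param outer_radius Backbone radius of the outer ring (A).
#' @param outer_tip_radius Radial position of outer-ring carboxylate tips (A).
#' @param swing_arm Flat-bottom tether radius of the cationic side-chain
#'   terminal group (A); the group swings freely within this arm length.
#' @param wall_z Soft-wall half-height confining solvent in z (A).
#' @param wall_k Wall stiffness (kcal/mol/A^2).
#' @param eps_r Uniform relative dielectric of the toy Hamiltonian.
#' @param cutoff Non-bonded cutoff (A); must not exceed half the box.
#' @param n_water Number of neutral water-oxygen beads.
#' @param n_ions Number of permeant cations (1 or 2).
#' @export
geometry_config <- function(box = c(20, 20, 30), pore_radius = 4.5,
                            inner_tip_radius = 2.45, outer_z = 6.0,
                            outer_radius = 6.0, outer_tip_radius = 4.6,
                            swing_arm = 5.5, wall_z = 13.0, wall_k = 2.0,
                            eps_r = 10.0, cutoff = 9.0, n_water = 150L,
                            n_ions = 2L) {
  if (pore_radius <= 0) abort("geometry error: pore_radius must be positive")
  stopifnot(length(box) == 3, all(box > 0), cutoff <= min(box[1:2]) / 2,
            n_ions %in% 1:2)
  list(box = box, pore_radius = pore_radius,
       inner_tip_radius = inner_tip_radius, outer_z = outer_z,
       outer_radius = outer_radius, outer_tip_radius = outer_tip_radius,
       swing_arm = swing_arm, wall_z = wall_z, wall_k = wall_k,
       eps_r = eps_r, cutoff = cutoff, n_water = as.integer(n_water),
       n_ions = as.integer(n_ions))
}

chain_angles <- c(A = 0, B = 180, C = 90, D = 270)

cyl <- function(radius, angle_deg, z) {
  a <- angle_deg * pi / 180
  c(radius * cos(a), radius * sin(a), z)
}

# One residue's beads as a tibble; tangential pair offset for carboxylates.
residue_beads <- function(resname, resnum, chain, geom, ring = c("inner", "outer"),
                          charges = NULL) {
  ring <- match.arg(ring)
  ang <- chain_angles[[chain]]
  z <- if (ring == "inner") 0 else geom$outer_z
  bb_r <- if (ring == "inner") geom$pore_radius else geom$outer_radius
  tip_r <- if (ring == "inner") geom$inner_tip_radius else geom$outer_tip_radius
  bp <- bead_params()
  par_of <- function(key) bp[bp$key == key, ]
  tang <- cyl(1, ang + 90, 0)  # unit tangential direction
  rows <- list()
  add <- function(name, key, pos, anchor, k, r0, charge = NULL, role) {
    p <- par_of(key)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      name = name, resname = resname, resnum = resnum, chain = chain,
      role = role, charge = charge %||% p$charge, sigma = p$sigma,
      epsilon = p$epsilon, x = pos[1], y = pos[2], z = pos[3],
      anchor_x = anchor[1], anchor_y = anchor[2], anchor_z = anchor[3],
      tether_k = k, tether_r0 = r0, mobile = TRUE)
  }
  bb <- cyl(bb_r, ang, z)
  p <- par_of("backbone")
  rows[[1]] <- tibble::tibble(
    name = "CA", resname = resname, resnum = resnum, chain = chain,
    role = "backbone", charge = 0, sigma = p$sigma, epsilon = p$epsilon,
    x = bb[1], y = bb[2], z = bb[3], anchor_x = NA_real_, anchor_y = NA_real_,
    anchor_z = NA_real_, tether_k = NA_real_, tether_r0 = NA_real_,
    mobile = FALSE)
  tip <- cyl(tip_r, ang, z)
  if (resname %in% c("ASP", "GLU")) {
    nm <- if (resname == "ASP") c("OD1", "OD2") else c("OE1", "OE2")
    off <- 0.8
    # inner-ring oxygens are held snugly: the sandwich sub-site is
    # size-selective only if its geometry cannot relax around a larger ion
    k <- if (ring == "inner") 10 else 5
    r0 <- if (ring == "inner") 0.2 else 1.0
    for (i in 1:2) {
      pos <- tip + (if (i == 1) off else -off) * tang
      add(nm[i], "carboxylate-O", pos, pos, k, r0, role = "carboxylate-O")
    }
  } else if (resname == "LYS") {
    # start in the protruding pose -- the ammonium group near the pore
    # axis, the posture the dense flexible side chain favours
    pos <- cyl(2.0, ang, z + 1.0)
    q <- if (is.null(charges)) 1.0 else charges
    add("NZ", "amine-N", pos, bb, 5, geom$swing_arm, charge = q,
        role = "sidechain-N")
  } else if (resname == "ARG") {
    # planar guanidine triad: CZ pivot, NH1/NH2 flanking at 1.5 A; the
    # positive charge sits mostly on the two NH sites (evenly spread),
    # unlike the single dense Lys amino site
    q <- charges %||% c(NH1 = 0.45, NH2 = 0.45, CZ = 0.10)
    # guanidine starts wall-ward (outer-ring capture pose)
    ctr <- cyl(3.8, ang, z + 3.0)
    add("CZ", "guanidine-C", ctr, bb, 5, geom$swing_arm - 0.5,
        charge = unname(q["CZ"]), role = "sidechain-C")
    add("NH1", "guanidine-N", ctr + 1.5 * tang + c(0, 0, 0.3),
        bb, 5, geom$swing_arm, charge = unname(q["NH1"]), role = "sidechain-N")
    add("NH2", "guanidine-N", ctr - 1.5 * tang + c(0, 0, 0.3),
        bb, 5, geom$swing_arm, charge = unname(q["NH2"]), role = "sidechain-N")
  } else if (resname == "ALA") {
    pos <- cyl(if (ring == "inner") 3.8 else 5.5, ang, z)
    add("CB", "neutral-C", pos, pos, 10, 0.5, role = "placeholder")
  } else if (resname == "SER") {
    pos <- cyl(if (ring == "inner") 3.4 else 5.0, ang, z)
    add("OG", "hydroxyl-O", pos, pos, 10, 0.5, role = "placeholder")
  } else {
    abort(paste0("unknown residue name: ", resname))
  }
  dplyr::bind_rows(rows)
}

inner_ring_motif <- function(variant) {
  switch(variant,
    "WT"         = list(res = c("SER", "SER", "SER", "SER"), charges = NULL),
    "DEAA"       = list(res = c("ASP", "GLU", "ALA", "ALA"), charges = NULL),
    "DEKA"       = list(res = c("ASP", "GLU", "LYS", "ALA"), charges = NULL),
    "DEKA-0.5e"  = list(res = c("ASP", "GLU", "LYS", "ALA"), charges = 0.5),
    "DEKA-0.05e" = list(res = c("ASP", "GLU", "LYS", "ALA"), charges = 0.05),
    "DERA"       = list(res = c("ASP", "GLU", "ARG", "ALA"), charges = NULL),
    "DERA-estar" = list(res = c("ASP", "GLU", "ARG", "ALA"),
                        charges = c(NH1 = 0.8, NH2 = 0.1, CZ = 0.1)),
    "DERA-E183D" = list(res = c("ASP", "GLU", "ARG", "ALA"), charges = NULL),
    "DERA-E183A" = list(res = c("ASP", "GLU", "ARG", "ALA"), charges = NULL)
  )
}

default_nbfix <- function() {
  # ion--oxygen overrides standing in for hydration/carboxylate contact
  # chemistry: first-shell minima sit inside each species' coordination
  # cutoff, and the ion-water well is deep enough that a bulk ion keeps a
  # first shell of >= 4 water oxygens.
  tibble::tribble(
    ~species, ~role,           ~sigma, ~epsilon,
    "NA",     "water-O",        2.05,   3.50,
    "K",      "water-O",        2.50,   2.80,
    "NA",     "carboxylate-O",  2.20,   0.30,
    "K",      "carboxylate-O",  2.65,   0.30
  )
}

new_sf_topology <- function(atoms, box, variant, geom, bonds = NULL,
                            nbfix = default_nbfix()) {
  atoms$id <- seq_len(nrow(atoms))
  atoms <- dplyr::relocate(atoms, "id")
  for (cl in names(atoms)) atoms[[cl]] <- unname(atoms[[cl]])
  stopifnot(all(atoms$sigma > 0), all(atoms$epsilon >= 0))
  stopifnot(all(atoms$chain %in% c("A", "B", "C", "D", "SOLVENT")))
  structure(
    tibble::new_tibble(atoms, nrow = nrow(atoms),
                       class = c("sf_topology", "tbl_df", "tbl")),
    box = box, variant = variant,
    eps_r = geom$eps_r, cutoff = geom$cutoff,
    wall_z = geom$wall_z, wall_k = geom$wall_k,
    bonds = bonds %||% tibble::tibble(i = integer(), j = integer(),
                                      k = numeric(), r0 = numeric()),
    nbfix = nbfix)
}

#' Build a coarse-grained pore model topology
#'
#' Constructs the four-chain selectivity-filter bead model for one of the
#' recognised variants: inner-ring (residue 180) motif per chain, an
#' outer-ring (residue 183) acidic residue per chain, neutral water-oxygen
#' beads placed randomly in the box, and the permeant cation(s).
#'
#' @param variant One of [sf_variants]. `DEKA-0.5e` / `DEKA-0.05e` scale the
#'   Lys amino-group charge to +0.5 / +0.05 e; `DERA-estar` keeps the +1 e
#'   guanidine total but concentrates 0.8 e on one site; `DERA-E183D` /
#'   `DERA-E183A` mutate the chain-D outer-ring Glu to Asp / Ala.
#' @param geometry A [geometry_config()] list.
#' @param seed RNG seed for solvent placement.
#' @param ion_species `"NA"` or `"K"` for the permeant cation(s).
#' @return An [sf_topology] tibble; the total system charge is stored in the
#'   `total_charge` attribute.
#' @export
build_model_topology <- function(variant, geometry = geometry_config(),
                                 seed = 1L, ion_species = c("NA", "K")) {
  if (!variant %in% sf_variants)
    abort(paste0("unknown variant '", variant, "'; allowed: ",
                 paste(sf_variants, collapse = ", ")))
  ion_species <- match.arg(ion_species)
  geom <- geometry
  motif <- inner_ring_motif(variant)
  chains <- c("A", "B", "C", "D")
  inner <- purrr::map2(motif$res, chains, function(rn, ch) {
    ch_charges <- if (ch == "C") {
      if (rn == "LYS" && is.numeric(motif$charges)) motif$charges
      else if (rn == "ARG") motif$charges
      else NULL
    } else NULL
    residue_beads(rn, 180L, ch, geom, "inner", charges = ch_charges)
  })
  outer_res <- c(A = "GLU", B = "GLU", C = "GLU",
                 D = switch(variant, "DERA-E183D" = "ASP",
                            "DERA-E183A" = "ALA", "GLU"))
  outer <- purrr::map(chains, function(ch)
    residue_beads(outer_res[[ch]], 183L, ch, geom, "outer"))
  protein <- dplyr::bind_rows(c(inner, outer))

  bp <- bead_params()
  ion_z <- c(-5.5, 1.5)[seq_len(geom$n_ions)]
  set.seed(seed)
  wat <- place_solvent(geom$n_water, geom,
                       avoid = rbind(as.matrix(protein[, c("x", "y", "z")]),
                                     cbind(0, 0, ion_z)))
  pw <- bp[bp$key == "water-O", ]
  water <- tibble::tibble(
    name = "OW", resname = "HOH",
    resnum = 1000L + seq_len(geom$n_water), chain = "SOLVENT",
    role = "water-O", charge = 0, sigma = pw$sigma, epsilon = pw$epsilon,
    x = wat[, 1], y = wat[, 2], z = wat[, 3],
    anchor_x = NA_real_, anchor_y = NA_real_, anchor_z = NA_real_,
    tether_k = NA_real_, tether_r0 = NA_real_, mobile = TRUE)

  is <- ion_spec(ion_species)
  ions <- tibble::tibble(
    name = ion_species, resname = ion_species,
    resnum = 2000L + seq_len(geom$n_ions), chain = "SOLVENT", role = "ion",
    charge = is$charge, sigma = is$sigma, epsilon = is$epsilon,
    x = 0, y = 0, z = ion_z,
    anchor_x = NA_real_, anchor_y = NA_real_, anchor_z = NA_real_,
    tether_k = NA_real_, tether_r0 = NA_real_, mobile = TRUE)

  atoms <- dplyr::bind_rows(protein, water, ions)
  top <- new_sf_topology(atoms, geom$box, variant, geom)
  # stiff planar bonds holding the guanidine triad together
  if (any(top$name == "CZ")) {
    cz <- top$id[top$name == "CZ"]
    nh1 <- top$id[top$name == "NH1"]
    nh2 <- top$id[top$name == "NH2"]
    attr(top, "bonds") <- tibble::tibble(
      i = c(cz, cz, nh1), j = c(nh1, nh2, nh2),
      k = c(100, 100, 100), r0 = c(1.5, 1.5, 3.0))
  }
  attr(top, "total_charge") <- sum(top$charge)
  top
}

# Rejection-sampled solvent placement (uniform; min contact 2.6 A).
place_solvent <- function(n, geom, avoid) {
  hx <- geom$box[1] / 2 - 0.1
  hz <- geom$wall_z - 0.5
  placed <- matrix(numeric(0), ncol = 3)
  occ <- as.matrix(avoid)
  tries <- 0L
  while (nrow(placed) < n) {
    tries <- tries + 1L
    if (tries > 200L * n) abort("geometry error: cannot place solvent; box too small")
    p <- c(runif(1, -hx, hx), runif(1, -hx, hx), runif(1, -hz, hz))
    all_pts <- rbind(occ, placed)
    if (nrow(all_pts) > 0) {
      dx <- all_pts[, 1] - p[1]; dx <- dx - geom$box[1] * round(dx / geom$box[1])
      dy <- all_pts[, 2] - p[2]; dy <- dy - geom$box[2] * round(dy / geom$box[2])
      d2 <- dx^2 + dy^2 + (all_pts[, 3] - p[3])^2
      if (min(d2) < 2.6^2) next
    }
    placed <- rbind(placed, p)
  }
  placed
}

#' Build a bulk solvent box containing a single cation
#'
#' A periodic (x, y) slab of water-oxygen beads with one permeant cation at
#' the origin: the reference system for the bulk leg of the thermodynamic
#' cycle and for solvated-ion validation runs.
#'
#' @param ion_species `"NA"` or `"K"`.
#' @param n_water Number of water beads.
#' @param box Box vector (A).
#' @param wall_z Soft-wall half-height (A).
#' @param eps_r,cutoff As in [geometry_config()].
#' @param seed Solvent-placement seed.
#' @export
build_bulk_box <- function(ion_species = c("NA", "K"), n_water = 60L,
                           box = c(16, 16, 20), wall_z = 8, eps_r = 10,
                           cutoff = 7.5, seed = 1L) {
  ion_species <- match.arg(ion_species)
  geom <- list(box = box, wall_z = wall_z, wall_k = 2.0, eps_r = eps_r,
               cutoff = cutoff)
  bp <- bead_params()
  is <- ion_spec(ion_species)
  ion <- tibble::tibble(
    name = ion_species, resname = ion_species, resnum = 2001L,
    chain = "SOLVENT", role = "ion", charge = is$charge, sigma = is$sigma,
    epsilon = is$epsilon, x = 0, y = 0, z = 0,
    anchor_x = NA_real_, anchor_y = NA_real_, anchor_z = NA_real_,
    tether_k = NA_real_, tether_r0 = NA_real_, mobile = TRUE)
  set.seed(seed)
  wat <- place_solvent(n_water,
                       list(box = box, wall_z = wall_z),
                       avoid = ion[, c("x", "y", "z")])
  pw <- bp[bp$key == "water-O", ]
  water <- tibble::tibble(
    name = "OW", resname = "HOH", resnum = 1000L + seq_len(n_water),
    chain = "SOLVENT", role = "water-O", charge = 0, sigma = pw$sigma,
    epsilon = pw$epsilon, x = wat[, 1], y = wat[, 2], z = wat[, 3],
    anchor_x = NA_real_, anchor_y = NA_real_, anchor_z = NA_real_,
    tether_k = NA_real_, tether_r0 = NA_real_, mobile = TRUE)
  top <- new_sf_topology(dplyr::bind_rows(ion, water), box, "bulk", geom)
  attr(top, "total_charge") <- sum(top$charge)
  top
}

#' Total charge of a charged side-chain group
#'
#' @param topology An [sf_topology].
#' @param resnum Residue number (180 for the inner ring).
#' @param chain Chain identifier (the cationic side chain sits on chain C).
#' @return Summed partial charge (e) of the residue's side-chain beads.
#' @export
group_charge <- function(topology, resnum = 180L, chain = "C") {
  sub <- topology[topology$resnum == resnum & topology$chain == chain &
                    topology$role != "backbone", ]
  sum(sub$charge)
}

#' @export
print.sf_topology <- function(x, ...) {
  cat(sprintf("<sf_topology> variant %s: %d beads, box %s A, total charge %+.2f e\n",
              attr(x, "variant"), nrow(x),
              paste(attr(x, "box"), collapse = " x "),
              sum(x$charge)))
  NextMethod()
}

#' Pin the cationic side chain in its characteristic pose
#'
#' Replaces the free swing-arm tether of the residue-180 cationic group
#' with a short leash at the pose each chemistry favours: the dense
#' ammonium site near the pore axis just above the carboxylate plane
#' (Lys-like), or the guanidine triad at the pore wall where its bifurcate
#' outer-ring contacts hold it (Arg-like and the e* variant). Used by the
#' paired selectivity comparison so that the energetic consequence of the
#' charge geometry can be probed without the slow side-chain/cation
#' exchange dynamics.
#'
#' @param topology An [sf_topology] carrying a cationic side chain.
#' @param leash_k,leash_r0 Tether stiffness (kcal/mol/A^2) and flat radius
#'   (A) of the pinned pose.
#' @return The topology with updated anchors and starting positions; a
#'   topology without a cationic group is returned unchanged.
#' @export
pin_side_chain_pose <- function(topology, leash_k = 10, leash_r0 = 0.5) {
  ang <- chain_angles[["C"]]
  set_pose <- function(top, name, anchor) {
    i <- which(top$resnum == 180 & top$chain == "C" & top$name == name)
    if (length(i) != 1) return(top)
    top$anchor_x[i] <- anchor[1]; top$anchor_y[i] <- anchor[2]
    top$anchor_z[i] <- anchor[3]
    top$tether_k[i] <- leash_k; top$tether_r0[i] <- leash_r0
    top$x[i] <- anchor[1]; top$y[i] <- anchor[2]; top$z[i] <- anchor[3]
    top
  }
  if (any(topology$name == "NZ" & topology$resnum == 180)) {
    topology <- set_pose(topology, "NZ", cyl(1.5, ang, 1.2))
  } else if (any(topology$name == "CZ" & topology$resnum == 180)) {
    ctr <- cyl(3.6, ang, 2.2)
    tang <- cyl(1, ang + 90, 0)
    topology <- set_pose(topology, "CZ", ctr)
    topology <- set_pose(topology, "NH1", ctr + 1.5 * tang + c(0, 0, 0.3))
    topology <- set_pose(topology, "NH2", ctr - 1.5 * tang + c(0, 0, 0.3))
  }
  topology
}
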