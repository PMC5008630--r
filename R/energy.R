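#' @title Toy Hamiltonian
#' @description
#' The potential energy of a configuration is a sum of: screened Coulomb
#' interactions `332.06 q_i q_j / (eps_r r_ij)` with the minimum-image
#' convention in x and y; Lennard-Jones terms with Lorentz-Berthelot mixing
#' (plus per-pair ion--oxygen overrides); flat-bottom radial tethers holding
#' side-chain beads to their backbone anchors; stiff harmonic bonds inside
#' multi-bead groups; soft harmonic z-walls confining the solvent slab; and
#' any flat-bottom sphere restraints supplied at run time.
#' @name toy_hamiltonian
NULL

# Assemble the C++ parameter pack from a topology. `restraints` is a tibble
# (atom, x, y, z, radius, k); `override` optionally replaces per-atom
# sigma/epsilon/nbfix for the alchemical path.
pair_params <- function(topology, restraints = NULL, double_well = NULL) {
  n <- nrow(topology)
  sig <- outer(topology$sigma, topology$sigma, `+`) / 2
  eps <- sqrt(outer(topology$epsilon, topology$epsilon))
  nb <- attr(topology, "nbfix")
  if (!is.null(nb) && nrow(nb) > 0) {
    for (r in seq_len(nrow(nb))) {
      ai <- which(topology$role == "ion" & topology$name == nb$species[r])
      aj <- which(topology$role == nb$role[r])
      if (length(ai) && length(aj)) {
        sig[ai, aj] <- nb$sigma[r];  sig[aj, ai] <- nb$sigma[r]
        eps[ai, aj] <- nb$epsilon[r]; eps[aj, ai] <- nb$epsilon[r]
      }
    }
  }
  kq <- KCOUL * outer(topology$charge, topology$charge) / attr(topology, "eps_r")
  # non-bonded exclusions: atoms of the same residue group, and bonded pairs
  grp <- paste(topology$chain, topology$resnum)
  same <- outer(grp, grp, `==`)
  bonds <- attr(topology, "bonds")
  excl <- same
  if (nrow(bonds) > 0)
    for (b in seq_len(nrow(bonds))) {
      excl[bonds$i[b], bonds$j[b]] <- TRUE
      excl[bonds$j[b], bonds$i[b]] <- TRUE
    }
  diag(excl) <- TRUE
  kq[excl] <- 0
  eps[excl] <- 0
  teth <- which(!is.na(topology$tether_k) & topology$mobile)
  wall_atoms <- which(topology$mobile & is.na(topology$tether_k))
  if (is.null(restraints))
    restraints <- tibble::tibble(atom = integer(), x = numeric(),
                                 y = numeric(), z = numeric(),
                                 radius = numeric(), k = numeric())
  list(
    n = n, sig = as.numeric(sig), eps = as.numeric(eps), kq = as.numeric(kq),
    box = attr(topology, "box"), cutoff = attr(topology, "cutoff"),
    teth_atom = teth - 1L,
    teth_x = topology$anchor_x[teth], teth_y = topology$anchor_y[teth],
    teth_z = topology$anchor_z[teth],
    teth_k = topology$tether_k[teth], teth_r0 = topology$tether_r0[teth],
    bond_i = bonds$i - 1L, bond_j = bonds$j - 1L,
    bond_k = bonds$k, bond_r0 = bonds$r0,
    wall_k = attr(topology, "wall_k") %||% 0,
    wall_z = attr(topology, "wall_z") %||% 1e6,
    wall_atom = wall_atoms - 1L,
    restr_atom = as.integer(restraints$atom) - 1L,
    restr_x = restraints$x, restr_y = restraints$y, restr_z = restraints$z,
    restr_r = restraints$radius, restr_k = restraints$k,
    double_well = double_well %||% list()
  )
}

coords_of <- function(topology) {
  as.matrix(topology[, c("x", "y", "z")])
}

#' Potential energy of a configuration
#'
#' @param topology An [sf_topology].
#' @param coordinates n_atoms x 3 matrix (A); defaults to the topology's
#'   initial coordinates.
#' @param restraints Optional flat-bottom sphere restraints: a tibble with
#'   columns `atom`, `x`, `y`, `z`, `radius`, `k`.
#' @param components If `TRUE`, return the named energy breakdown instead of
#'   the total.
#' @return Total energy in kcal/mol (or a named vector of components).
#' @export
potential_energy <- function(topology, coordinates = coords_of(topology),
                             restraints = NULL, components = FALSE) {
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) != nrow(topology) || ncol(coordinates) != 3)
    abort(sprintf("coordinates (%d x %d) do not match topology (%d atoms x 3)",
                  nrow(coordinates), ncol(coordinates), nrow(topology)))
  e <- energy_components_cpp(coordinates, pair_params(topology, restraints))
  if (components) e else unname(e["total"])
}

#' Forces on every atom
#'
#' Analytic negative gradient of [potential_energy()].
#' @inheritParams potential_energy
#' @return n_atoms x 3 matrix, kcal/mol/A.
#' @export
forces <- function(topology, coordinates = coords_of(topology),
                   restraints = NULL) {
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) != nrow(topology))
    abort("coordinate/topology length mismatch")
  forces_cpp(coordinates, pair_params(topology, restraints))
}
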