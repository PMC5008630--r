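#' @title Cation binding analysis
#' @description Binding-site occupancy in (Z, R) space, 2D free-energy maps
#' by Boltzmann inversion of the sampled probability density, permeation
#' event detection, and hierarchical clustering of the binding modes at the
#' outer constriction site (Site_OC).
#' @name binding_analysis
NULL

#' Default binding-site definitions
#'
#' Z intervals are relative to the SF geometric center (positive =
#' extracellular), measured on the bundled model geometry; the sites are
#' pairwise disjoint in z. Site_OC sits at the inner-ring carboxylate
#' midpoint (|Z| <= 2 A, R <= 4 A).
#'
#' @return Tibble with `site`, `z_lo`, `z_hi` (A), `r_max` (A).
#' @export
default_sites <- function() {
  tibble::tribble(
    ~site,       ~z_lo, ~z_hi, ~r_max,
    "Ion_EX",      7.0,  11.0,   6.0,
    "Site_HFS",    2.0,   7.0,   4.0,
    "Site_OC",    -2.0,   2.0,   4.0,
    "Site_CEN",   -4.5,  -2.0,   4.0,
    "Site_INT",   -7.0,  -4.5,   4.0,
    "Site_IN",   -10.0,  -7.0,   4.0
  )
}

check_sites <- function(sites) {
  stopifnot(all(c("site", "z_lo", "z_hi", "r_max") %in% names(sites)))
  if (any(sites$z_lo >= sites$z_hi)) abort("site z intervals must have z_lo < z_hi")
  if (any(sites$r_max <= 0)) abort("site r_max must be positive")
  if (anyDuplicated(sites$site)) abort("site names must be unique")
  n <- nrow(sites)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (sites$z_lo[i] < sites$z_hi[j] && sites$z_lo[j] < sites$z_hi[i])
        abort(sprintf("overlapping site z intervals: %s [%g, %g] and %s [%g, %g]",
                      sites$site[i], sites$z_lo[i], sites$z_hi[i],
                      sites$site[j], sites$z_lo[j], sites$z_hi[j]))
    }
  }
  invisible(sites)
}

label_site <- function(Z, R, sites) {
  lab <- rep("unbound", length(Z))
  for (s in seq_len(nrow(sites))) {
    hit <- Z >= sites$z_lo[s] & Z < sites$z_hi[s] & R <= sites$r_max[s]
    lab[hit] <- sites$site[s]
  }
  lab
}

#' Binding-site occupancy of the permeant ion(s)
#'
#' A frame counts toward a site when the ion's (Z, R) reporter falls inside
#' the site's z interval and radial bound; sites must be pairwise disjoint
#' in z, so per-ion fractions over sites plus "unbound" sum to 1.
#'
#' @param trajectory,topology Trajectory and matching topology.
#' @param ion_selection Selection resolving to one or more ions.
#' @param sites Site definition tibble (see [default_sites()]).
#' @param definition SF-center definition.
#' @return List: `fractions` (tibble ion x site), `labels` (tibble frame x
#'   ion with per-frame site labels).
#' @export
site_occupancy <- function(trajectory, topology, ion_selection = "role ion",
                           sites = default_sites(),
                           definition = sf_center_def()) {
  check_sites(sites)
  ions <- resolve_selection(topology, ion_selection)
  if (length(ions) == 0) abort("ion selection matched no atoms")
  labs <- purrr::map(ions, function(a) {
    rz <- rz_series(trajectory, topology, a, definition)
    tibble::tibble(frame = rz$frame, ion = a,
                   site = label_site(rz$Z, rz$R, sites))
  })
  labels <- dplyr::bind_rows(labs)
  lv <- c(sites$site, "unbound")
  fractions <- labels |>
    dplyr::mutate(site = factor(.data$site, levels = lv)) |>
    dplyr::count(.data$ion, .data$site, .drop = FALSE) |>
    dplyr::group_by(.data$ion) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("ion", "site", "fraction")
  list(fractions = fractions, labels = labels)
}

#' 2D free-energy map by Boltzmann inversion
#'
#' Histograms an (R, Z) series and converts counts to free energy,
#' `G = -kT ln(count / count_max)`, so the most populated bin sits at zero;
#' empty bins carry the cap value.
#'
#' @param rz An [rz_series()] (or data frame with `R`, `Z`).
#' @param bin_width Bin width in A (default 0.5).
#' @param kT Thermal energy (kcal/mol); default 310 K.
#' @param cap Free energy assigned to empty bins (kcal/mol, default 6).
#' @return An `sf_femap`: list with `r_edges`, `z_edges`, `counts`, `G`,
#'   `kT`, `cap`.
#' @export
free_energy_map <- function(rz, bin_width = 0.5, kT = kT_at(310), cap = 6) {
  if (kT <= 0) abort("kT must be positive")
  if (bin_width <= 0) abort("bin width must be positive")
  df <- as.data.frame(rz)
  if (nrow(df) == 0) abort("empty (R, Z) series")
  edges <- function(v) {
    lo <- floor(min(v) / bin_width) * bin_width
    hi <- ceiling(max(v) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    seq(lo, hi, by = bin_width)
  }
  re <- edges(df$R); ze <- edges(df$Z)
  ri <- findInterval(df$R, re, rightmost.closed = TRUE)
  zi <- findInterval(df$Z, ze, rightmost.closed = TRUE)
  counts <- matrix(0L, length(re) - 1, length(ze) - 1)
  for (k in seq_len(nrow(df))) counts[ri[k], zi[k]] <- counts[ri[k], zi[k]] + 1L
  G <- matrix(cap, nrow(counts), ncol(counts))
  nz <- counts > 0
  G[nz] <- -kT * log(counts[nz] / max(counts))
  structure(list(r_edges = re, z_edges = ze, counts = counts, G = G,
                 kT = kT, cap = cap), class = "sf_femap")
}

#' @export
as_tibble.sf_femap <- function(x, ...) {
  rc <- (head(x$r_edges, -1) + tail(x$r_edges, -1)) / 2
  zc <- (head(x$z_edges, -1) + tail(x$z_edges, -1)) / 2
  tibble::tibble(R = rep(rc, times = length(zc)),
                 Z = rep(zc, each = length(rc)),
                 count = as.integer(x$counts),
                 G = as.numeric(x$G))
}

#' @export
print.sf_femap <- function(x, ...) {
  cat(sprintf("<sf_femap> %d x %d bins, kT = %.4f kcal/mol, cap = %g\n",
              nrow(x$G), ncol(x$G), x$kT, x$cap))
  invisible(x)
}

#' Detect permeation events across an axial threshold
#'
#' An event is a signed crossing of the z threshold that subsequently dwells
#' at least `dwell` frames on the far side (debounce); events come back
#' time-ordered. Direction `-1` is inward (extracellular to intracellular,
#' decreasing Z), `+1` outward.
#'
#' @param rz An [rz_series()] for one ion.
#' @param z_threshold Axial threshold (A), inside the trajectory's z range.
#' @param dwell Debounce dwell, frames (default 5).
#' @return Tibble with `frame`, `time`, `direction`.
#' @export
detect_permeation_events <- function(rz, z_threshold, dwell = 5L) {
  z <- rz$Z
  if (z_threshold < min(z) || z_threshold > max(z))
    abort("threshold outside the trajectory's z range")
  side <- ifelse(z >= z_threshold, 1L, -1L)
  events <- list()
  i <- 2
  while (i <= length(z)) {
    if (side[i] != side[i - 1]) {
      far <- side[i]
      run_end <- i
      while (run_end < length(z) && side[run_end + 1] == far) run_end <- run_end + 1
      if (run_end - i + 1 >= dwell)
        events[[length(events) + 1]] <- tibble::tibble(
          frame = rz$frame[i], time = rz$time[i],
          direction = ifelse(far < 0, -1L, 1L))
      i <- run_end + 1
    } else i <- i + 1
  }
  if (length(events) == 0)
    return(tibble::tibble(frame = integer(), time = numeric(),
                          direction = integer()))
  dplyr::arrange(dplyr::bind_rows(events), .data$frame)
}

#' Default clustering feature atoms
#'
#' Side-chain oxygen/nitrogen beads of the inner-ring (residue 180) motif,
#' in fixed id order.
#' @param topology An [sf_topology].
#' @export
mode_feature_atoms <- function(topology) {
  sort(topology$id[topology$resnum == 180 &
                     topology$role %in% c("carboxylate-O", "sidechain-N")])
}

#' Cluster the cation binding modes at a site
#'
#' Each bound frame is described by the vector of distances from the ion to
#' the inner-ring side-chain O/N beads (fixed atom order). Average-linkage
#' hierarchical clustering with a merge cutoff partitions the frames;
#' clusters are ranked by size (ties broken by first occurrence), the top
#' `top_n` reported, the top `main_n` flagged "main", and modes below the
#' occupancy floor are marked ineligible for free-energy evaluation.
#'
#' @param trajectory,topology Trajectory and topology.
#' @param ion Atom id (or selection) of the bound ion.
#' @param bound_frames Integer frame indices counted as bound.
#' @param n_analyzed Denominator for occupancy fractions (default: the
#'   trajectory's frame count).
#' @param feature_atoms Atom ids of the feature distances (default
#'   [mode_feature_atoms()]).
#' @param cutoff Merge cutoff c in feature space (A, default 1.5).
#' @param top_n,main_n Clusters reported / flagged main (3 / 2).
#' @param occupancy_floor Minimum occupancy for FEP eligibility (0.05).
#' @return A `binding_modes` tibble: `rank`, `n_members`, `occupancy`,
#'   `main`, `fep_eligible`, `representative_frame`, restraint center
#'   `cx`/`cy`/`cz` and centroid feature columns `d_<atomname>`; member
#'   frame indices ride along in the `members` attribute (a list).
#' @export
cluster_binding_modes <- function(trajectory, topology, ion, bound_frames,
                                  n_analyzed = n_frames(trajectory),
                                  feature_atoms = mode_feature_atoms(topology),
                                  cutoff = 1.5, top_n = 3L, main_n = 2L,
                                  occupancy_floor = 0.05) {
  if (length(bound_frames) == 0) abort("no binding detected: empty bound-frame set")
  ion <- resolve_selection(topology, ion)
  stopifnot(length(ion) == 1)
  box <- attr(topology, "box")
  feat <- matrix(NA_real_, length(bound_frames), length(feature_atoms))
  pos <- matrix(NA_real_, length(bound_frames), 3)
  for (k in seq_along(bound_frames)) {
    X <- frame_coords(trajectory, bound_frames[k])
    p <- X[ion, ]
    pos[k, ] <- p
    dx <- min_image(X[feature_atoms, 1] - p[1], box[1])
    dy <- min_image(X[feature_atoms, 2] - p[2], box[2])
    dz <- X[feature_atoms, 3] - p[3]
    feat[k, ] <- sqrt(dx^2 + dy^2 + dz^2)
  }
  colnames(feat) <- paste0("d_", topology$name[feature_atoms], "_",
                           topology$chain[feature_atoms])
  if (nrow(feat) == 1) {
    cl <- 1L
  } else {
    hc <- hclust(dist(feat), method = "average")
    cl <- cutree(hc, h = cutoff)
  }
  sizes <- table(cl)
  first_seen <- vapply(names(sizes), function(g) min(which(cl == as.integer(g))),
                       integer(1))
  ord <- order(-as.integer(sizes), first_seen)
  keep <- head(ord, top_n)
  modes <- purrr::imap(keep, function(g, rank) {
    members <- which(cl == as.integer(names(sizes)[g]))
    ctr <- colMeans(feat[members, , drop = FALSE])
    rep_idx <- members[which.min(rowSums(
      sweep(feat[members, , drop = FALSE], 2, ctr)^2))]
    occ <- length(members) / n_analyzed
    row <- tibble::tibble(
      rank = rank, n_members = length(members), occupancy = occ,
      main = rank <= main_n, fep_eligible = occ >= occupancy_floor,
      representative_frame = bound_frames[rep_idx],
      cx = mean(pos[members, 1]), cy = mean(pos[members, 2]),
      cz = mean(pos[members, 3]))
    dplyr::bind_cols(row, tibble::as_tibble(as.list(ctr)))
  })
  out <- dplyr::bind_rows(modes)
  attr(out, "members") <- purrr::map(keep, function(g)
    bound_frames[cl == as.integer(names(sizes)[g])])
  attr(out, "ion") <- ion
  class(out) <- c("binding_modes", class(out))
  out
}
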