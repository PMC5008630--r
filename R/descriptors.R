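#' @title Geometric descriptors of the selectivity filter
#' @description The analyses track two reporter coordinates relative to the
#' geometric center of the selectivity filter (SF): the signed axial distance
#' Z (positive toward the extracellular side, the direction ions enter from)
#' and the in-plane radial distance R projected onto the membrane (xy)
#' plane. Both use the minimum-image convention in x and y.
#' @name descriptors
NULL

#' Definition of the SF geometric center
#'
#' Defaults to the geometric center of the four inner-ring (residue 180)
#' backbone sites, recomputed per frame so protein drift cannot masquerade as
#' ion motion.
#'
#' @param selection Selection expression for the defining atoms.
#' @param per_frame Recompute the center per frame (`TRUE`) or once from the
#'   first frame (`FALSE`).
#' @export
sf_center_def <- function(selection = "resnum 180 and name CA",
                          per_frame = TRUE) {
  list(selection = selection, per_frame = per_frame)
}

min_image <- function(d, L) {
  if (L > 0) d - L * round(d / L) else d
}

#' Geometric center of the SF in one frame
#'
#' Arithmetic mean of the selected atoms' coordinates, computed on images
#' unwrapped relative to the first selected atom so that a selection
#' straddling a periodic boundary still averages correctly.
#'
#' @param frame n_atoms x 3 coordinate matrix.
#' @param topology An [sf_topology].
#' @param definition An [sf_center_def()].
#' @return Length-3 center (A).
#' @export
sf_center <- function(frame, topology, definition = sf_center_def()) {
  idx <- resolve_selection(topology, definition$selection)
  if (length(idx) == 0) abort("SF center selection resolved to no atoms")
  box <- attr(topology, "box")
  X <- frame[idx, , drop = FALSE]
  ref <- X[1, ]
  X[, 1] <- ref[1] + min_image(X[, 1] - ref[1], box[1])
  X[, 2] <- ref[2] + min_image(X[, 2] - ref[2], box[2])
  colMeans(X)
}

#' Axial (Z) and radial (R) coordinates relative to a center
#'
#' `compute_Z` is the signed z offset (no periodicity in z); `compute_R` is
#' the in-plane distance with the minimum image taken in x and y.
#'
#' @param position Length-3 position (A).
#' @param center Length-3 center (A).
#' @param box Length-3 box for the xy minimum image (0 disables).
#' @return Scalar Angstrom value.
#' @export
compute_Z <- function(position, center, box = c(0, 0, 0)) {
  unname(position[3] - center[3])
}

#' @rdname compute_Z
#' @export
compute_R <- function(position, center, box = c(0, 0, 0)) {
  dx <- min_image(position[1] - center[1], box[1])
  dy <- min_image(position[2] - center[2], box[2])
  sqrt(dx^2 + dy^2)
}

#' (Z, R) reporter series for a tracked atom
#'
#' @param trajectory An [sf_trajectory()].
#' @param topology An [sf_topology].
#' @param tracked_atom Atom id (or single-atom selection) to track.
#' @param definition An [sf_center_def()].
#' @return An `rz_series` tibble: `frame`, `time` (ps), `Z` (A), `R` (A),
#'   with the tracked atom id as an attribute.
#' @export
rz_series <- function(trajectory, topology, tracked_atom,
                      definition = sf_center_def()) {
  idx <- resolve_selection(topology, tracked_atom)
  if (length(idx) != 1)
    abort("tracked_atom must resolve to exactly one atom")
  if (idx > dim(trajectory$coords)[1]) abort("atom id out of range")
  box <- attr(topology, "box")
  nf <- n_frames(trajectory)
  Z <- R <- numeric(nf)
  ctr <- NULL
  for (f in seq_len(nf)) {
    X <- frame_coords(trajectory, f)
    if (is.null(ctr) || definition$per_frame)
      ctr <- sf_center(X, topology, definition)
    p <- X[idx, ]
    Z[f] <- compute_Z(p, ctr, box)
    R[f] <- compute_R(p, ctr, box)
  }
  out <- tibble::new_tibble(
    tibble::tibble(frame = seq_len(nf), time = trajectory$times, Z = Z, R = R),
    nrow = nf, class = c("rz_series", "tbl_df", "tbl"))
  attr(out, "tracked_atom") <- idx
  out
}
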