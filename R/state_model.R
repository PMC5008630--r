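#' @title Open/closed state model in (R, Z) space
#' @description The side-chain reporter atom's (R, Z) distribution separates
#' closed from open filter conformations. A soft-margin linear SVM supplies
#' the best linear separation; per-class confidence offsets then bound the
#' 95% regions: each class's offset line is the separator shifted in
#' parallel, starting deep inside the class and moving toward the other
#' class just far enough that at least `ceil(level * n_class)` of the
#' class's training points lie on the class side of the line. Frames between
#' the two offset lines are "unassigned". Features are used raw, in
#' Angstrom, so the offsets keep physical units.
#' @name state_model
NULL

new_state_boundary <- function(w, b, offset_closed = NA_real_,
                               offset_open = NA_real_, level = 0.95) {
  w <- unname(w); b <- unname(b)
  nrm <- sqrt(sum(w^2))
  structure(list(w = w / nrm, b = b / nrm, offset_closed = offset_closed,
                 offset_open = offset_open, level = level),
            class = "sf_state_boundary")
}

#' Decision value of (R, Z) points under a boundary
#'
#' `d(p) = w . (R, Z) + b`; open states lie on the `d > 0` side.
#' @param boundary An `sf_state_boundary`.
#' @param points Two-column matrix or data frame with `R`, `Z`.
#' @export
decision_values <- function(boundary, points) {
  P <- as.matrix(as.data.frame(points)[, c("R", "Z")])
  as.numeric(P %*% boundary$w + boundary$b)
}

#' Fit the best linear open/closed separator
#'
#' Maximum-margin (soft, penalty `C`) linear discriminant on (R, Z) points,
#' normalised so that `||w|| = 1` and open lies on the positive side.
#'
#' @param points Data frame or matrix with columns `R` and `Z`.
#' @param labels Factor or character vector with values `closed` / `open`.
#' @param C Soft-margin penalty (default 10).
#' @return An `sf_state_boundary` (confidence offsets unset; see
#'   [confidence_regions()]).
#' @export
fit_separator <- function(points, labels, C = 10) {
  P <- as.data.frame(points)[, c("R", "Z")]
  labels <- factor(as.character(labels), levels = c("closed", "open"))
  if (length(unique(labels[!is.na(labels)])) < 2)
    abort("both classes (closed, open) must be present")
  fit <- e1071::svm(x = as.matrix(P), y = labels, kernel = "linear",
                    cost = C, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  bnd <- new_state_boundary(w, b)
  # orient: open side must have positive decision values
  mu_open <- colMeans(P[labels == "open", , drop = FALSE])
  if (sum(bnd$w * mu_open) + bnd$b < 0) {
    bnd$w <- -bnd$w
    bnd$b <- -bnd$b
  }
  bnd
}

#' Fill per-class confidence offsets of a fitted boundary
#'
#' @param boundary A fitted `sf_state_boundary`.
#' @param points,labels Training points and labels (as in
#'   [fit_separator()]).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return The boundary with `offset_open` / `offset_closed` filled. The
#'   open region is `d >= offset_open`, the closed region
#'   `d <= -offset_closed`; offsets are clamped at zero so neither region
#'   crosses the separator.
#' @export
confidence_regions <- function(boundary, points, labels, level = 0.95) {
  if (!inherits(boundary, "sf_state_boundary")) abort("boundary must be fitted")
  if (level <= 0 || level >= 1) abort("level must be inside (0, 1)")
  d <- decision_values(boundary, points)
  labels <- factor(as.character(labels), levels = c("closed", "open"))
  need <- function(n) ceiling(level * n)
  d_open <- sort(d[labels == "open"], decreasing = TRUE)
  d_closed <- sort(-d[labels == "closed"], decreasing = TRUE)
  boundary$offset_open <- max(0, d_open[need(length(d_open))])
  boundary$offset_closed <- max(0, d_closed[need(length(d_closed))])
  boundary$level <- level
  boundary
}

#' Classify frames against the state regions
#'
#' @param rz An [rz_series()] tibble (or any data frame with `R`, `Z`).
#' @param boundary A boundary with confidence offsets filled.
#' @return The input with a `state` column (`closed` / `open` /
#'   `unassigned`) plus an `occupancy` attribute: the named fractions
#'   (summing to 1). Points exactly on a region line assign to the open
#'   side.
#' @export
classify_frames <- function(rz, boundary) {
  if (is.na(boundary$offset_open) || is.na(boundary$offset_closed))
    abort("boundary has no confidence offsets; call confidence_regions() first")
  d <- decision_values(boundary, rz)
  state <- ifelse(d >= boundary$offset_open, "open",
                  ifelse(d < -boundary$offset_closed, "closed", "unassigned"))
  out <- tibble::as_tibble(rz)
  out$state <- factor(state, levels = c("closed", "open", "unassigned"))
  occ <- table(out$state) / nrow(out)
  attr(out, "occupancy") <- setNames(as.numeric(occ), names(occ))
  out
}

#' State-region occupancy fractions
#' @param classified Output of [classify_frames()].
#' @return Tibble with `state` and `fraction`.
#' @export
state_occupancy <- function(classified) {
  occ <- attr(classified, "occupancy")
  tibble::tibble(state = names(occ), fraction = occ)
}

#' @export
print.sf_state_boundary <- function(x, ...) {
  cat(sprintf(
    "<sf_state_boundary> d = %.4f R + %.4f Z + %.4f; offsets closed %.3f / open %.3f (level %.2f)\n",
    x$w[1], x$w[2], x$b, x$offset_closed, x$offset_open, x$level))
  invisible(x)
}

#' Serialise a state boundary as a 6-number text record
#' @param boundary An `sf_state_boundary`.
#' @param path File path.
#' @export
write_boundary <- function(boundary, path) {
  writeLines(paste(format(c(boundary$w, boundary$b, boundary$offset_closed,
                            boundary$offset_open, boundary$level),
                          digits = 17), collapse = "\t"), path)
  invisible(path)
}

#' @rdname write_boundary
#' @export
read_boundary <- function(path) {
  v <- as.numeric(strsplit(readLines(path, n = 1), "\t")[[1]])
  new_state_boundary(v[1:2], v[3], v[4], v[5], v[6])
}
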