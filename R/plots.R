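#' Plot a 2D free-energy map
#'
#' Raster of the Boltzmann-inverted free energy in (R, Z) space, low free
#' energy dark.
#' @param object An `sf_femap`.
#' @param ... Unused.
#' @export
autoplot.sf_femap <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$R, y = .data$Z,
                                   fill = .data$G)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(direction = -1,
                                  name = "G (kcal/mol)") +
    ggplot2::labs(x = "R (Å)", y = "Z (Å)") +
    ggplot2::theme_minimal()
}

#' Plot an (R, Z) reporter series
#' @param object An [rz_series()].
#' @param ... Unused.
#' @export
autoplot.rz_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$R, y = .data$Z)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = "R (Å)", y = "Z (Å)") +
    ggplot2::theme_minimal()
}

#' Plot (R, Z) points with the state separator and confidence offsets
#'
#' @param rz Data frame with `R`, `Z` (and optionally `state`).
#' @param boundary A fitted `sf_state_boundary`.
#' @export
plot_state_space <- function(rz, boundary) {
  df <- tibble::as_tibble(rz)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$R, y = .data$Z))
  p <- if ("state" %in% names(df))
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$state),
                            alpha = 0.4, size = 0.7)
  else p + ggplot2::geom_point(alpha = 0.4, size = 0.7)
  # line w_R R + w_Z Z + b = d  =>  Z = (d - b - w_R R) / w_Z
  add_line <- function(p, d, lt) {
    if (abs(boundary$w[2]) < 1e-9) return(p)
    p + ggplot2::geom_abline(
      slope = -boundary$w[1] / boundary$w[2],
      intercept = (d - boundary$b) / boundary$w[2], linetype = lt)
  }
  p <- add_line(p, 0, "solid")
  if (!is.na(boundary$offset_open))
    p <- add_line(p, boundary$offset_open, "dashed")
  if (!is.na(boundary$offset_closed))
    p <- add_line(p, -boundary$offset_closed, "dashed")
  p + ggplot2::labs(x = "R (Å)", y = "Z (Å)") +
    ggplot2::theme_minimal()
}

#' Plot per-window FEP free energies
#' @param object An `sf_fep`.
#' @param ... Unused.
#' @export
autoplot.sf_fep <- function(object, ...) {
  ggplot2::ggplot(object$windows,
                  ggplot2::aes(x = (.data$lambda_from + .data$lambda_to) / 2,
                               y = .data$dG)) +
    ggplot2::geom_col(width = 0.8 * min(diff(object$protocol$lambdas))) +
    ggplot2::labs(x = expression(lambda), y = "window dG (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Plot a repulsion-versus-distance profile
#' @param profile Output of [repulsion_profile()] (optionally several,
#'   row-bound with a `group` column).
#' @export
plot_repulsion_profile <- function(profile) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$distance,
                                             y = .data$mean_elec))
  p <- if ("group" %in% names(profile))
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$group)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  else p + ggplot2::geom_line() + ggplot2::geom_point()
  p + ggplot2::labs(x = "centroid separation (Å)",
                    y = "mean electrostatic energy (kcal/mol)") +
    ggplot2::theme_minimal()
}
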