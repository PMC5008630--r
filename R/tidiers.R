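#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an FEP leg into its per-window table
#' @param x An `sf_fep`.
#' @param ... Unused.
#' @export
tidy.sf_fep <- function(x, ...) x$windows

#' One-row summary of an FEP leg
#' @param x An `sf_fep`.
#' @param ... Unused.
#' @export
glance.sf_fep <- function(x, ...) {
  tibble::tibble(leg = x$leg, estimator = x$estimator, dG = x$dG, se = x$se,
                 n_windows = nrow(x$windows), kT = x$kT,
                 n_convergence_warnings = length(x$warnings))
}

#' Tidy FEP repeats
#' @param x An `sf_fep_summary`.
#' @param ... Unused.
#' @export
tidy.sf_fep_summary <- function(x, ...) tibble::as_tibble(x)

#' Mean and SD over FEP repeats
#' @param x An `sf_fep_summary`.
#' @param ... Unused.
#' @export
glance.sf_fep_summary <- function(x, ...) {
  tibble::tibble(mean = attr(x, "mean"), sd = attr(x, "sd"),
                 n_repeats = nrow(x))
}

#' Tidy a state boundary
#' @param x An `sf_state_boundary`.
#' @param ... Unused.
#' @export
tidy.sf_state_boundary <- function(x, ...) {
  tibble::tibble(term = c("w_R", "w_Z", "b", "offset_closed", "offset_open",
                          "level"),
                 estimate = c(x$w, x$b, x$offset_closed, x$offset_open,
                              x$level))
}
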