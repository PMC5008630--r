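#' @title Free-energy perturbation engine
#' @description Alchemical Na+ -> K+ transformation of a permeant cation in
#' the toy system. The charge stays +1 throughout; only the ion's
#' Lennard-Jones parameters (including its ion--oxygen pair overrides)
#' interpolate linearly in lambda, so no soft core is needed. Each leg
#' (bound or bulk) restrains the ion with a flat-bottom sphere so that the
#' restraint contribution cancels in the thermodynamic cycle; the relative
#' binding affinity is `ddG(Na->K) = dG_bound - dG_bulk`, positive for a
#' Na+-selective site.
#' @name fep_engine
NULL

#' FEP protocol
#'
#' @param lambdas Strictly increasing schedule from 0 to 1 (>= 2 values);
#'   21 equally spaced windows by default.
#' @param steps_equil,steps_prod Equilibration / production BD steps per
#'   window.
#' @param sample_every Steps between work samples.
#' @param estimator `"BAR"` (default), `"EXP-forward"` or `"EXP-backward"`.
#' @param restraint_radius Flat-bottom radius (A, default 1.5).
#' @param restraint_k Wall stiffness outside the flat bottom
#'   (kcal/mol/A^2, default 10).
#' @param temperature Kelvin (310 default).
#' @param friction,timestep BD parameters (see [bd_protocol()]).
#' @param seed Base seed; per-window seeds derive deterministically.
#' @param from,to Species at lambda = 0 / 1.
#' @param ess_floor Effective-sample-size floor below which a convergence
#'   warning is attached.
#' @param dims Integrated axes (validation hook).
#' @export
fep_protocol <- function(lambdas = seq(0, 1, length.out = 21),
                         steps_equil = 1000L, steps_prod = 5000L,
                         sample_every = 10L,
                         estimator = c("BAR", "EXP-forward", "EXP-backward"),
                         restraint_radius = 1.5, restraint_k = 10,
                         temperature = 310, friction = 3.0, timestep = 0.01,
                         seed = 1L, from = "NA", to = "K", ess_floor = 50,
                         dims = c(TRUE, TRUE, TRUE)) {
  if (length(lambdas) < 2 || any(diff(lambdas) <= 0) ||
      abs(lambdas[1]) > 1e-12 || abs(lambdas[length(lambdas)] - 1) > 1e-12)
    abort("lambdas must increase strictly from 0 to 1 with >= 2 values")
  if (restraint_radius <= 0) abort("flat-bottom radius must be positive")
  structure(list(lambdas = lambdas, steps_equil = as.integer(steps_equil),
                 steps_prod = as.integer(steps_prod),
                 sample_every = as.integer(sample_every),
                 estimator = match.arg(estimator),
                 restraint_radius = restraint_radius,
                 restraint_k = restraint_k, temperature = temperature,
                 friction = friction, timestep = timestep,
                 seed = as.integer(seed), from = from, to = to,
                 ess_floor = ess_floor, dims = dims),
            class = "fep_protocol")
}

#' Alchemically interpolated topology
#'
#' Returns the topology with the chosen ion's LJ parameters (and its
#' ion--oxygen pair overrides) interpolated between the `from` and `to`
#' species: `sigma(lambda) = (1 - lambda) sigma_from + lambda sigma_to`,
#' likewise epsilon. Endpoints reproduce the unperturbed Hamiltonians
#' exactly; the charge is constant.
#'
#' @param topology An [sf_topology].
#' @param ion Ion atom id.
#' @param lambda Coupling parameter in `[0, 1]`.
#' @param from,to Species labels (`"NA"`, `"K"`).
#' @export
alchemical_topology <- function(topology, ion, lambda, from = "NA", to = "K") {
  if (lambda < 0 || lambda > 1) abort("lambda must lie in [0, 1]")
  ion <- resolve_selection(topology, ion)
  stopifnot(length(ion) == 1, topology$role[ion] == "ion")
  sf <- ion_spec(from); st <- ion_spec(to)
  mix <- function(a, b) (1 - lambda) * a + lambda * b
  topology$sigma[ion] <- mix(sf$sigma, st$sigma)
  topology$epsilon[ion] <- mix(sf$epsilon, st$epsilon)
  nb <- attr(topology, "nbfix")
  if (!is.null(nb) && nrow(nb) > 0) {
    ion_name <- topology$name[ion]
    for (r in which(nb$species == ion_name)) {
      role <- nb$role[r]
      row_f <- nb[nb$species == from & nb$role == role, ]
      row_t <- nb[nb$species == to & nb$role == role, ]
      if (nrow(row_f) == 1 && nrow(row_t) == 1) {
        nb$sigma[r] <- mix(row_f$sigma, row_t$sigma)
        nb$epsilon[r] <- mix(row_f$epsilon, row_t$epsilon)
      }
    }
    attr(topology, "nbfix") <- nb
  }
  topology
}

fermi <- function(x) 1 / (1 + exp(x))

# BAR between two neighbouring states from reduced works (units of kT).
bar_solve <- function(wF, wR, tol = 1e-10, max_iter = 200) {
  nF <- length(wF); nR <- length(wR)
  M <- log(nF / nR)
  lse <- function(x) {  # log-sum-exp mean
    m <- max(x)
    m + log(mean(exp(x - m)))
  }
  dg <- -lse(-wF)       # EXP-forward initialisation
  for (it in seq_len(max_iter)) {
    C <- dg + M
    new <- C + lse(log(fermi(wR + C))) - lse(log(fermi(wF - C)))
    if (abs(new - dg) < tol) { dg <- new; break }
    dg <- new
  }
  C <- dg + M
  fF <- fermi(wF - C); fR <- fermi(wR + C)
  se2 <- (mean(fF^2) / mean(fF)^2 - 1) / nF +
    (mean(fR^2) / mean(fR)^2 - 1) / nR
  list(dg = dg, se = sqrt(max(se2, 0)))
}

exp_estimate <- function(w) {
  m <- min(w)
  dg <- m - log(mean(exp(-(w - m))))
  wt <- exp(-(w - m))
  list(dg = dg, ess = sum(wt)^2 / sum(wt^2))
}

# Core window machinery: `top_at(lambda)` builds the lambda topology;
# `restraints` is fixed across windows. Returns an sf_fep.
fep_run <- function(top_at, protocol, restraints = NULL, leg = "generic",
                    start = NULL) {
  kT <- kT_at(protocol$temperature)
  lam <- protocol$lambdas
  nw <- length(lam) - 1
  tops <- purrr::map(lam, top_at)
  pars <- purrr::map(tops, pair_params, restraints = restraints)
  n_equil_frames <- ceiling(protocol$steps_equil / protocol$sample_every)
  samples <- vector("list", length(lam))
  X <- start %||% coords_of(tops[[1]])
  for (i in seq_along(lam)) {
    bd <- bd_protocol(temperature = protocol$temperature,
                      friction = protocol$friction,
                      timestep = protocol$timestep,
                      n_steps = protocol$steps_equil + protocol$steps_prod,
                      save_interval = protocol$sample_every,
                      seed = protocol$seed + 131L * i,
                      dims = protocol$dims)
    traj <- simulate_trajectory(tops[[i]], bd, restraints = restraints,
                                start = X)
    X <- attr(traj, "final")
    keep <- seq(n_equil_frames + 1, n_frames(traj))
    frames <- traj$coords[, , keep, drop = FALSE]
    U_self <- energy_frames_cpp(frames, pars[[i]])
    samples[[i]] <- list(
      frames = frames, U_self = U_self,
      U_next = if (i < length(lam)) energy_frames_cpp(frames, pars[[i + 1]]),
      U_prev = if (i > 1) energy_frames_cpp(frames, pars[[i - 1]]))
  }
  warnings <- character(0)
  windows <- purrr::map(seq_len(nw), function(i) {
    wF <- (samples[[i]]$U_next - samples[[i]]$U_self) / kT
    wR <- (samples[[i + 1]]$U_prev - samples[[i + 1]]$U_self) / kT
    ef <- exp_estimate(wF)
    eb <- exp_estimate(wR)
    est <- switch(protocol$estimator,
      "EXP-forward" = list(dg = ef$dg, se = NA_real_),
      "EXP-backward" = list(dg = -eb$dg, se = NA_real_),
      "BAR" = bar_solve(wF, wR))
    if (min(ef$ess, eb$ess) < protocol$ess_floor)
      warnings <<- c(warnings, sprintf(
        "window %d (lambda %.3f -> %.3f): effective sample size %.1f below floor %g",
        i, lam[i], lam[i + 1], min(ef$ess, eb$ess), protocol$ess_floor))
    tibble::tibble(window = i, lambda_from = lam[i], lambda_to = lam[i + 1],
                   dG = est$dg * kT, se = est$se * kT,
                   n_forward = length(wF), n_reverse = length(wR),
                   ess_forward = ef$ess, ess_reverse = eb$ess)
  })
  windows <- dplyr::bind_rows(windows)
  res <- structure(list(
    windows = windows, dG = sum(windows$dG),
    se = sqrt(sum(windows$se^2, na.rm = TRUE)),
    leg = leg, estimator = protocol$estimator, kT = kT,
    protocol = protocol, warnings = warnings), class = "sf_fep")
  # production frames of the first window (the lambda = 0 reference
  # ensemble), kept for coordination diagnostics of the restrained state
  attr(res, "frames_lambda0") <- samples[[1]]$frames
  if (length(warnings)) warn(paste(warnings, collapse = "\n"))
  res
}

#' @export
print.sf_fep <- function(x, ...) {
  cat(sprintf("<sf_fep> %s leg (%s): dG = %.4f +/- %.4f kcal/mol over %d windows\n",
              x$leg, x$estimator, x$dG, x$se, nrow(x$windows)))
  if (length(x$warnings)) cat(" convergence warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Run one FEP leg (bound or bulk)
#'
#' Transforms the ion `from -> to` over the protocol's lambda schedule with
#' a flat-bottom positional restraint, identical in geometry for both legs
#' so the restraint contribution cancels in the cycle. The bound leg takes
#' its restraint center from a binding mode; the bulk leg centers the ion
#' in the solvent region (at least 10 A from any pore bead by default).
#'
#' @param topology An [sf_topology].
#' @param ion Ion atom id (or selection).
#' @param protocol An [fep_protocol()].
#' @param leg `"bound"` or `"bulk"`.
#' @param center Restraint center (length 3); required for the bound leg.
#'   For the bulk leg defaults to `c(0, 0, -10)` relative to the SF center.
#' @return An `sf_fep` with per-window free energies; `dG` is their sum.
#' @export
run_fep_leg <- function(topology, ion, protocol, leg = c("bound", "bulk"),
                        center = NULL) {
  leg <- match.arg(leg)
  ion <- resolve_selection(topology, ion)
  stopifnot(length(ion) == 1)
  if (leg == "bound" && is.null(center))
    abort("bound leg requires a restraint center (use a binding mode)")
  if (is.null(center)) center <- c(0, 0, -10)
  restr <- tibble::tibble(atom = ion, x = center[1], y = center[2],
                          z = center[3], radius = protocol$restraint_radius,
                          k = protocol$restraint_k)
  start <- coords_of(topology)
  start[ion, ] <- center
  fep_run(function(l) alchemical_topology(topology, ion, l,
                                          from = protocol$from,
                                          to = protocol$to),
          protocol, restraints = restr, leg = leg, start = start)
}

#' Relative binding affinity from the thermodynamic cycle
#'
#' `ddG = dG_bound - dG_bulk`; with the Na -> K direction, positive values
#' mean the site prefers Na+.
#'
#' @param bound,bulk `sf_fep` legs run under the same protocol.
#' @return ddG in kcal/mol (with `se` attribute combining both legs).
#' @export
ddG <- function(bound, bulk) {
  same <- isTRUE(all.equal(bound$protocol$lambdas, bulk$protocol$lambdas)) &&
    bound$protocol$temperature == bulk$protocol$temperature &&
    bound$estimator == bulk$estimator
  if (!same) abort("bound and bulk legs must share lambda schedule, temperature and estimator")
  structure(bound$dG - bulk$dG, se = sqrt(bound$se^2 + bulk$se^2))
}

#' Repeat a free-energy calculation and aggregate mean and SD
#'
#' @param run_fn Function of a single seed returning a numeric free energy
#'   (e.g. a ddG) or an `sf_fep` (its `dG` is taken).
#' @param seeds Distinct integer seeds, one per repeat (>= 2 for an SD).
#' @return An `sf_fep_summary`: tibble of repeats plus `mean`/`sd`
#'   attributes.
#' @export
repeat_and_aggregate <- function(run_fn, seeds) {
  if (anyDuplicated(seeds)) abort("seeds must be distinct across repeats")
  vals <- purrr::map_dbl(seeds, function(s) {
    r <- run_fn(s)
    if (inherits(r, "sf_fep")) r$dG else as.numeric(r)
  })
  out <- tibble::new_tibble(
    tibble::tibble(repeat_ = seq_along(seeds), seed = as.integer(seeds),
                   value = vals),
    nrow = length(seeds), class = c("sf_fep_summary", "tbl_df", "tbl"))
  attr(out, "mean") <- mean(vals)
  attr(out, "sd") <- if (length(vals) >= 2) sd(vals) else NA_real_
  out
}

#' @export
print.sf_fep_summary <- function(x, ...) {
  cat(sprintf("<sf_fep_summary> %d repeats: %.3f +/- %.3f kcal/mol\n",
              nrow(x), attr(x, "mean"), attr(x, "sd")))
  NextMethod()
}

#' Analytic-oracle FEP system: harmonic spring-constant transform
#'
#' A single bead on a one-dimensional harmonic tether whose spring constant
#' interpolates `k1 -> k2`; the exact free-energy difference is
#' `(kT/2) ln(k2/k1)`, which validates the window machinery and estimators.
#'
#' @param k1,k2 Spring constants (kcal/mol/A^2).
#' @param protocol An [fep_protocol()]; its `dims` is forced to z-only.
#' @return An `sf_fep`.
#' @export
run_fep_harmonic <- function(k1, k2, protocol = fep_protocol()) {
  protocol$dims <- c(FALSE, FALSE, TRUE)
  geom <- list(box = c(50, 50, 50), wall_z = 1e6, wall_k = 0, eps_r = 1,
               cutoff = 5)
  atoms <- tibble::tibble(
    name = "BD", resname = "BDW", resnum = 1L, chain = "SOLVENT",
    role = "probe", charge = 0, sigma = 3, epsilon = 0,
    x = 0, y = 0, z = 0, anchor_x = 0, anchor_y = 0, anchor_z = 0,
    tether_k = k1, tether_r0 = 0, mobile = TRUE)
  base <- new_sf_topology(atoms, geom$box, "harmonic-demo", geom,
                          nbfix = NULL)
  fep_run(function(l) {
    top <- base
    top$tether_k <- (1 - l) * k1 + l * k2
    top
  }, protocol, leg = "harmonic")
}

#' Thermodynamic-integration reference for an FEP leg
#'
#' Independent estimator used to cross-check the FEP estimates: simulates a
#' dense lambda grid and integrates `<dU/dlambda>` (central finite
#' difference of the lambda-Hamiltonian on each sampled frame) with the
#' trapezoid rule.
#'
#' @inheritParams run_fep_leg
#' @param n_lambda Grid size (default 64).
#' @param delta Finite-difference half-step in lambda.
#' @return List with `dG` (kcal/mol) and the per-point `profile` tibble.
#' @export
fep_ti_reference <- function(topology, ion, protocol, leg = c("bound", "bulk"),
                             center = NULL, n_lambda = 64, delta = 1e-3) {
  leg <- match.arg(leg)
  ion <- resolve_selection(topology, ion)
  if (leg == "bound" && is.null(center))
    abort("bound leg requires a restraint center")
  if (is.null(center)) center <- c(0, 0, -10)
  restr <- tibble::tibble(atom = ion, x = center[1], y = center[2],
                          z = center[3], radius = protocol$restraint_radius,
                          k = protocol$restraint_k)
  lam <- seq(0, 1, length.out = n_lambda)
  top_at <- function(l) alchemical_topology(topology, ion, l,
                                            from = protocol$from,
                                            to = protocol$to)
  X <- coords_of(topology)
  X[ion, ] <- center
  n_equil_frames <- ceiling(protocol$steps_equil / protocol$sample_every)
  dudl <- numeric(n_lambda)
  for (i in seq_along(lam)) {
    bd <- bd_protocol(temperature = protocol$temperature,
                      friction = protocol$friction,
                      timestep = protocol$timestep,
                      n_steps = protocol$steps_equil + protocol$steps_prod,
                      save_interval = protocol$sample_every,
                      seed = protocol$seed + 977L * i, dims = protocol$dims)
    traj <- simulate_trajectory(top_at(lam[i]), bd, restraints = restr,
                                start = X)
    X <- attr(traj, "final")
    keep <- seq(n_equil_frames + 1, n_frames(traj))
    frames <- traj$coords[, , keep, drop = FALSE]
    lp <- max(0, lam[i] - delta); lm <- min(1, lam[i] + delta)
    Up <- energy_frames_cpp(frames, pair_params(top_at(lm), restr))
    Um <- energy_frames_cpp(frames, pair_params(top_at(lp), restr))
    dudl[i] <- mean((Up - Um) / (lm - lp))
  }
  dG <- sum(diff(lam) * (head(dudl, -1) + tail(dudl, -1)) / 2)
  list(dG = dG, profile = tibble::tibble(lambda = lam, dudl = dudl))
}
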