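#' @title Experiment pipeline
#' @description One seeded, configured run: build the variant topology,
#' simulate, compute reporter series, classify filter states, measure site
#' occupancy, hydrogen bonds, binding-mode clusters and coordination, and
#' (optionally) the relative Na+/K+ binding affinity -- emitting one TSV
#' table per analysis plus a manifest.
#' @name pipeline
NULL

#' Round half to even at a fixed number of decimals
#'
#' Decimal-aware banker's rounding that is robust to binary floating-point
#' representation of exact decimal ties (e.g. 3.225 at two decimals gives
#' 3.22).
#' @param x Numeric.
#' @param digits Decimal places.
#' @export
round_half_even <- function(x, digits = 2) {
  s <- 10^digits
  y <- x * s
  fl <- floor(y)
  frac <- y - fl
  tie <- abs(frac - 0.5) < 1e-9
  out <- ifelse(tie, ifelse(fl %% 2 == 0, fl, fl + 1), round(y))
  out / s
}

#' Derive coordination cutoffs from coordinating-distance ranges
#'
#' The cutoff for each species is the mean of the lower and upper limits of
#' its ion--oxygen coordinating-distance range, reported at two decimals
#' (round half to even). The QM/MM ranges 2.39--2.99 A (Na+) and
#' 2.80--3.65 A (K+) give 2.69 A and 3.22 A.
#'
#' @param ranges Tibble/data frame with columns `species`, `lower`, `upper`
#'   (A).
#' @return Tibble with `species` and `cutoff` (A, two decimals).
#' @export
derive_coordination_cutoffs <- function(ranges = tibble::tibble(
  species = c("NA", "K"), lower = c(2.39, 2.80), upper = c(2.99, 3.65))) {
  if (any(ranges$lower >= ranges$upper))
    abort("each coordinating-distance range needs lower < upper")
  tibble::tibble(species = ranges$species,
                 cutoff = round_half_even((ranges$lower + ranges$upper) / 2, 2))
}

#' Run configuration
#'
#' Collects every tunable of the pipeline; round-trips through YAML
#' unchanged. Stage seeds derive deterministically from the global seed via
#' a counter scheme, so adding a stage never perturbs earlier stages.
#'
#' @param variant One of [sf_variants].
#' @param ion_species `"NA"` or `"K"`.
#' @param seed Global seed.
#' @param n_steps,save_interval,temperature,friction,timestep BD protocol.
#' @param geometry Overrides for [geometry_config()] (named list).
#' @param sites Site-definition tibble (default [default_sites()]).
#' @param equilibration_fraction Leading fraction of frames excluded from
#'   binding analyses (0.25: the final 75% is analysed).
#' @param cluster_cutoff,occupancy_floor Clustering parameters.
#' @param hbond_max_distance H-bond heavy-atom cutoff (A).
#' @param fep Logical: run the FEP stage.
#' @param fep_windows,fep_steps_equil,fep_steps_prod,fep_repeats FEP stage
#'   parameters.
#' @param classifier Training-set parameters for the state model (means /
#'   sds of the planted populations, or `NULL` to skip).
#' @param output_dir Where [run_experiment()] writes its bundle.
#' @export
run_config <- function(variant = "DEKA", ion_species = "NA", seed = 1L,
                       n_steps = 50000L, save_interval = 50L,
                       temperature = 310, friction = 3.0, timestep = 0.01,
                       geometry = list(), sites = default_sites(),
                       equilibration_fraction = 0.25,
                       cluster_cutoff = 1.5, occupancy_floor = 0.05,
                       hbond_max_distance = 3.5,
                       fep = FALSE, fep_windows = 11L,
                       fep_steps_equil = 500L, fep_steps_prod = 2500L,
                       fep_repeats = 3L,
                       classifier = NULL, output_dir = tempfile("sfpore_run_")) {
  cfg <- list(variant = variant, ion_species = ion_species,
              seed = as.integer(seed), n_steps = as.integer(n_steps),
              save_interval = as.integer(save_interval),
              temperature = temperature, friction = friction,
              timestep = timestep, geometry = geometry,
              sites = as.data.frame(sites),
              equilibration_fraction = equilibration_fraction,
              cluster_cutoff = cluster_cutoff,
              occupancy_floor = occupancy_floor,
              hbond_max_distance = hbond_max_distance,
              fep = fep, fep_windows = as.integer(fep_windows),
              fep_steps_equil = as.integer(fep_steps_equil),
              fep_steps_prod = as.integer(fep_steps_prod),
              fep_repeats = as.integer(fep_repeats),
              classifier = classifier, output_dir = output_dir)
  structure(cfg, class = "run_config")
}

#' Derive a stage seed from the global seed
#'
#' Counter-based splitting: `(seed * 48271 + 1000003 * stage) mod (2^31-1)`.
#' @param seed Global seed.
#' @param stage Stage counter (integer).
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * as.numeric(stage)) %%
               2147483647)
}

#' Write / read a run configuration (YAML)
#' @param config A [run_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$sites <- tibble::as_tibble(as.data.frame(
    lapply(as.data.frame(do.call(rbind, lapply(seq_along(cfg$sites[[1]]),
      function(i) lapply(cfg$sites, `[[`, i)))), unlist)))
  do.call(run_config, cfg[setdiff(names(cfg), character(0))])
}

fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 4294967296
  sprintf("%08x", h)
}

#' Run a configured experiment end to end
#'
#' Stages: topology build, BD simulation, reporter (Z, R) series, state
#' classification (if a classifier training spec is given), site occupancy,
#' hydrogen bonds, binding-mode clustering with per-mode coordination, and
#' optionally the FEP relative-affinity estimate for the top binding mode.
#' All tables land in `config$output_dir` as TSV, with a `manifest.yaml`
#' recording the config, its hash and stage seeds. Identical config + seed
#' reproduce identical tables.
#'
#' @param config A [run_config()].
#' @return Invisible list of the in-memory results.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
  }
  geom <- do.call(geometry_config, config$geometry)
  top <- stage("topology", build_model_topology(
    config$variant, geom, seed = stage_seed(config$seed, 1),
    ion_species = config$ion_species))
  out$topology <- top
  write_topology_table(top, file.path(config$output_dir, "topology.tsv"))

  proto <- bd_protocol(temperature = config$temperature,
                       friction = config$friction,
                       timestep = config$timestep, n_steps = config$n_steps,
                       save_interval = config$save_interval,
                       seed = stage_seed(config$seed, 2))
  traj <- stage("simulate", simulate_trajectory(top, proto))
  out$trajectory <- traj
  write_dcd(traj, top, file.path(config$output_dir, "trajectory.dcd"))

  # reporter series: cationic side-chain terminal site (if any) and ions
  rep_sel <- top$id[top$resnum == 180 & top$role == "sidechain-N"]
  ions <- top$id[top$role == "ion"]
  cdef <- sf_center_def()
  if (length(rep_sel)) {
    rz_rep <- stage("descriptors", rz_series(traj, top, rep_sel[1], cdef))
    out$reporter_rz <- rz_rep
    write_tables(rz_rep, file.path(config$output_dir, "reporter_rz.tsv"))
  }
  rz_ions <- purrr::map(ions, function(a) rz_series(traj, top, a, cdef))
  out$ion_rz <- rz_ions

  if (!is.null(config$classifier) && length(rep_sel)) {
    cl <- config$classifier
    planted <- stage("classifier", plant_labeled_states(
      open_params = list(mean = unlist(cl$open_mean),
                         cov = diag(unlist(cl$open_sd)^2)),
      closed_params = list(mean = unlist(cl$closed_mean),
                           cov = diag(unlist(cl$closed_sd)^2)),
      n_frames = cl$n_frames %||% 2000L,
      seed = stage_seed(config$seed, 3),
      open_fraction = cl$open_fraction %||% 0.5))
    bnd <- fit_separator(planted$rz, planted$labels)
    bnd <- confidence_regions(bnd, planted$rz, planted$labels)
    classified <- classify_frames(out$reporter_rz, bnd)
    out$boundary <- bnd
    out$state_table <- state_occupancy(classified)
    write_boundary(bnd, file.path(config$output_dir, "boundary.txt"))
    write_tables(out$state_table,
                 file.path(config$output_dir, "state_occupancy.tsv"))
    write_tables(classified,
                 file.path(config$output_dir, "classified_frames.tsv"))
  }

  occ <- stage("site_occupancy",
               site_occupancy(traj, top, ions, config$sites, cdef))
  out$site_table <- occ$fractions
  write_tables(occ$fractions, file.path(config$output_dir,
                                        "site_occupancy.tsv"))

  if (length(rep_sel)) {
    hb <- stage("hbonds", hbond_occupancy(
      traj, top, rep_sel, "role carboxylate-O",
      hbond_criteria(config$hbond_max_distance)))
    out$hbond <- hb
    write_tables(tibble::tibble(
      donor = "sidechain-N", acceptor = "carboxylate-O",
      occupancy = hb$occupancy,
      bifurcate_occupancy = hb$bifurcate_occupancy),
      file.path(config$output_dir, "hbond_occupancy.tsv"))
  }

  # binding modes of the outer-constriction-bound ion (final frames only)
  nf <- n_frames(traj)
  first_kept <- floor(nf * config$equilibration_fraction) + 1
  analyzed <- seq(first_kept, nf)
  modes <- NULL
  bound_ion <- NULL
  for (k in rev(seq_along(ions))) {  # prefer the outer (second) ion
    lab <- occ$labels[occ$labels$ion == ions[k], ]
    bound <- intersect(lab$frame[lab$site == "Site_OC"], analyzed)
    if (length(bound) >= 2) {
      bound_ion <- ions[k]
      modes <- stage("clustering", cluster_binding_modes(
        traj, top, bound_ion, bound, n_analyzed = length(analyzed),
        cutoff = config$cluster_cutoff,
        occupancy_floor = config$occupancy_floor))
      break
    }
  }
  if (!is.null(modes)) {
    out$modes <- modes
    write_tables(tibble::as_tibble(modes),
                 file.path(config$output_dir, "binding_modes.tsv"))
    spec <- ion_spec(config$ion_species)
    members <- attr(modes, "members")
    coord <- purrr::map(seq_len(nrow(modes)), function(i)
      classify_mode_coordination(modes[i, ], members[[i]], traj, top, spec,
                                 bound_ion))
    out$coordination <- dplyr::bind_rows(coord)
    write_tables(out$coordination,
                 file.path(config$output_dir, "coordination.tsv"))
  }

  if (isTRUE(config$fep) && !is.null(modes)) {
    # weak binders: when no cluster clears the occupancy floor, fall back to
    # the top binding mode alone
    mode1 <- if (any(modes$fep_eligible))
      modes[which(modes$fep_eligible)[1], ] else modes[1, ]
    fp_base <- fep_protocol(
      lambdas = seq(0, 1, length.out = config$fep_windows),
      steps_equil = config$fep_steps_equil,
      steps_prod = config$fep_steps_prod,
      temperature = config$temperature, friction = config$friction,
      timestep = config$timestep)
    reps <- stage("fep", repeat_and_aggregate(function(s) {
      fp <- fp_base; fp$seed <- s
      b <- run_fep_leg(top, bound_ion, fp, "bound",
                       center = c(mode1$cx, mode1$cy, mode1$cz))
      u <- run_fep_leg(top, bound_ion, fp, "bulk")
      ddG(b, u)
    }, seeds = stage_seed(config$seed, 4) + seq_len(config$fep_repeats)))
    out$ddG <- reps
    write_tables(tibble::tibble(
      system = config$variant, ion = config$ion_species, mode = mode1$rank,
      ddG_mean = attr(reps, "mean"), ddG_sd = attr(reps, "sd"),
      n_repeats = nrow(reps)),
      file.path(config$output_dir, "ddG_summary.tsv"))
  }

  cfg_yaml <- yaml::as.yaml(unclass(config))
  manifest <- list(
    package = "sfpore",
    version = as.character(utils::packageVersion("sfpore")),
    config_hash = fnv1a(cfg_yaml),
    global_seed = config$seed,
    stage_seeds = list(topology = stage_seed(config$seed, 1),
                       simulate = stage_seed(config$seed, 2),
                       classifier = stage_seed(config$seed, 3),
                       fep = stage_seed(config$seed, 4)),
    timestamp = format(Sys.time(), tz = "UTC"))
  yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  write_config(config, file.path(config$output_dir, "config.yaml"))
  invisible(out)
}

#' Characteristic Site_OC probe centers
#'
#' Two sub-sites of the outer constriction site characterise the competing
#' binding situations: the "tight" carboxylate-midpoint center, where the
#' cation is sandwiched by the Asp/Glu pairs, and the "loose" periphery on
#' the far (Ala) side of the pore, where the cation trades carboxylate
#' contacts for water coordination. The dense central ammonium charge
#' admits only the tight mode; the distributed, wall-captured guanidine
#' leaves the loose mode accessible.
#'
#' @return Tibble with `mode`, `x`, `y`, `z` (A, SF-centered frame) and the
#'   probe's flat-bottom `radius` (A), matched to the mode's spatial
#'   extent: sub-angstrom for the tight sandwich basin, wider for the
#'   diffuse loose mode.
#' @export
oc_probe_centers <- function() {
  tibble::tribble(
    ~mode,   ~x, ~y,   ~z,  ~radius,
    "tight",  0,  0,    0,  0.5,
    "loose",  0, -2.5,  1.0, 1.5
  )
}

#' Paired selectivity comparison across variants
#'
#' Runs the full chain for each variant with matched protocols: an
#' equilibrium BD run (free side chains) for the conformational statistics
#' -- side-chain reporter position, hydrogen bonds, site occupancy and
#' binding-mode clustering -- followed by a flat-bottom-restrained FEP
#' estimate of ddG(Na->K) at the variant's characteristic Site_OC
#' sub-site (see [oc_probe_centers()]): the tight carboxylate sandwich for
#' a dense amine side chain, the loose water-coordinated periphery for the
#' distributed guanidine variants. Coordination is measured on the
#' restrained lambda = 0 probe ensemble, so the reported tight-coordination
#' flag describes exactly the state whose ddG is estimated.
#'
#' @param variants Character vector of [sf_variants].
#' @param seed Global seed.
#' @param n_steps Equilibrium BD steps per variant.
#' @param fep_windows,fep_steps_equil,fep_steps_prod,fep_sample_every FEP
#'   sampling parameters per window.
#' @param n_repeats FEP repeats per variant (>= 2 gives an SD).
#' @param geometry A [geometry_config()].
#' @param ion_species Permeant cation species.
#' @param retention Weak flat-bottom sphere (list with `radius` A and `k`
#'   kcal/mol/A^2, or `NULL` to disable) keeping the tracked cation in the
#'   constriction-site neighbourhood during the mode-sampling run -- the
#'   desk-scale analogue of a pre-equilibration retention constraint. The
#'   sphere is flat over the whole Site_OC region, so the bound ensemble
#'   inside it is unbiased.
#' @param restraint_radius Flat-bottom radius of the FEP positional
#'   restraint (A); `NULL` (default) takes each probe's own radius from
#'   [oc_probe_centers()].
#' @return Tibble: one row per variant with the probe mode, equilibrium
#'   side-chain radial position, mode occupancy, probe-ensemble mean
#'   carboxylate coordination, the tight-coordination flag, and
#'   `ddG_mean` / `ddG_sd` (kcal/mol).
#' @export
compare_variants <- function(variants = c("DEKA", "DERA"), seed = 1L,
                             n_steps = 100000L, fep_windows = 11L,
                             fep_steps_equil = 1000L,
                             fep_steps_prod = 8000L,
                             fep_sample_every = 40L, n_repeats = 2L,
                             geometry = geometry_config(),
                             ion_species = "NA",
                             retention = list(radius = 3, k = 5),
                             restraint_radius = NULL) {
  probes <- oc_probe_centers()
  rows <- purrr::map(variants, function(v) {
    top <- build_model_topology(v, geometry, seed = stage_seed(seed, 1),
                                ion_species = ion_species)
    ions <- top$id[top$role == "ion"]
    tracked <- ions[length(ions)]   # the outer (second) cation
    restr <- if (!is.null(retention))
      tibble::tibble(atom = tracked, x = 0, y = 0, z = 0,
                     radius = retention$radius, k = retention$k)
    tr <- simulate_trajectory(top, bd_protocol(
      n_steps = n_steps, save_interval = 100L,
      seed = stage_seed(seed, 2)), restraints = restr)
    occ <- site_occupancy(tr, top, ions)
    nf <- n_frames(tr)
    analyzed <- seq(floor(nf * 0.25) + 1, nf)
    lab <- occ$labels[occ$labels$ion == tracked, ]
    bound <- intersect(lab$frame[lab$site == "Site_OC"], analyzed)
    mode_occ <- NA_real_
    if (length(bound) >= 2) {
      modes <- cluster_binding_modes(tr, top, tracked, bound,
                                     n_analyzed = length(analyzed))
      mode_occ <- modes$occupancy[1]
    }
    sc <- top$id[top$resnum == 180 & top$role == "sidechain-N"]
    sc_R <- if (length(sc)) {
      rzs <- rz_series(tr, top, sc[1])
      mean(rzs$R[analyzed])
    } else NA_real_
    # probe sub-site: tight sandwich for a dense amine, loose periphery
    # for the distributed guanidine (and for variants with no repeller)
    dense <- any(top$name == "NZ" & top$resnum == 180)
    probe <- probes[probes$mode == (if (dense) "tight" else "loose"), ]
    center <- c(probe$x, probe$y, probe$z)
    fp0 <- fep_protocol(lambdas = seq(0, 1, length.out = fep_windows),
                        steps_equil = fep_steps_equil,
                        steps_prod = fep_steps_prod,
                        sample_every = fep_sample_every,
                        restraint_radius = restraint_radius %||% probe$radius)
    spec <- ion_spec(ion_species)
    carb <- NA_real_
    reps <- repeat_and_aggregate(function(s) {
      fp <- fp0; fp$seed <- s
      b <- run_fep_leg(top, tracked, fp, "bound", center = center)
      if (is.na(carb)) {
        frames <- attr(b, "frames_lambda0")
        cc <- vapply(seq_len(dim(frames)[3]), function(f)
          coordination_count(frames[, , f], top, tracked,
                             spec)[["carboxylate_O"]], numeric(1))
        carb <<- mean(cc)
      }
      u <- run_fep_leg(top, tracked, fp, "bulk")
      ddG(b, u)
    }, seeds = stage_seed(seed, 4) %% 100000000L + seq_len(n_repeats))
    tibble::tibble(
      variant = v, ion = ion_species, probe_mode = probe$mode,
      sidechain_R = sc_R, mode_occupancy = mode_occ,
      n_bound = length(bound),
      mean_carboxylate_O = carb,
      tight_coordination = floor(carb + 0.5) >= 3,
      ddG_mean = attr(reps, "mean"), ddG_sd = attr(reps, "sd"))
  })
  dplyr::bind_rows(rows)
}
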