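test_that("lambda endpoints reproduce the unperturbed Hamiltonians exactly", {
  top <- build_bulk_box("NA", n_water = 20, seed = 3)
  ion <- 1L
  t0 <- alchemical_topology(top, ion, 0)
  t1 <- alchemical_topology(top, ion, 1)
  tk <- build_bulk_box("K", n_water = 20, seed = 3)
  set.seed(41)
  for (i in 1:10) {
    X <- as.matrix(top[, c("x", "y", "z")]) + matrix(rnorm(63, 0, 0.5),
                                                     ncol = 3)
    expect_equal(potential_energy(t0, X), potential_energy(top, X),
                 tolerance = 1e-12)
    # the K endpoint equals a K-built system up to the ion's label
    expect_equal(potential_energy(t1, X), potential_energy(tk, X),
                 tolerance = 1e-12)
  }
  # midpoint sigma is the arithmetic mean of the species sigmas
  th <- alchemical_topology(top, ion, 0.5)
  expect_equal(th$sigma[ion],
               (ion_spec("NA")$sigma + ion_spec("K")$sigma) / 2)
  expect_error(alchemical_topology(top, ion, 1.2), "lambda")
})

test_that("the identity transformation has zero free energy", {
  top <- build_bulk_box("NA", n_water = 30, seed = 4)
  fp <- fep_protocol(lambdas = seq(0, 1, length.out = 6),
                     steps_equil = 300, steps_prod = 1500,
                     sample_every = 25, seed = 5, to = "NA")
  leg <- run_fep_leg(top, 1L, fp, "bulk", center = c(0, 0, 0))
  expect_lt(abs(leg$dG), 0.02)
})

test_that("harmonic spring transform matches the analytic free energy", {
  kT <- kT_at(310)
  fp <- fep_protocol(lambdas = seq(0, 1, length.out = 11),
                     steps_equil = 2000, steps_prod = 20000,
                     sample_every = 50, seed = 6)
  reps <- repeat_and_aggregate(function(s) {
    p <- fp; p$seed <- s
    run_fep_harmonic(1, 4, p)
  }, seeds = c(101, 202, 303))
  analytic <- kT / 2 * log(4)
  expect_equal(analytic, 0.4270, tolerance = 1e-4)
  se <- attr(reps, "sd") / sqrt(3)
  expect_lt(abs(attr(reps, "mean") - analytic), 3 * se + 0.02)
})

test_that("reversing the transform negates the free energy within noise", {
  fp <- fep_protocol(lambdas = seq(0, 1, length.out = 11),
                     steps_equil = 2000, steps_prod = 20000,
                     sample_every = 50, seed = 7)
  f <- run_fep_harmonic(1, 4, fp)
  b <- run_fep_harmonic(4, 1, fp)
  expect_lt(abs(f$dG + b$dG), 3 * sqrt(f$se^2 + b$se^2) + 0.02)
})

test_that("refining the lambda schedule leaves the leg free energy unchanged", {
  mk <- function(nl, seed) {
    fp <- fep_protocol(lambdas = seq(0, 1, length.out = nl),
                       steps_equil = 2000, steps_prod = 15000,
                       sample_every = 50, seed = seed)
    run_fep_harmonic(1, 4, fp)$dG
  }
  coarse <- mk(6, 8)
  fine <- mk(21, 9)
  expect_lt(abs(coarse - fine), 0.05)
})

test_that("ddG follows the cycle arithmetic and checks protocols", {
  mkfep <- function(dG, lambdas = seq(0, 1, length.out = 6), temp = 310) {
    structure(list(dG = dG, se = 0.01, leg = "bound", estimator = "BAR",
                   windows = tibble::tibble(dG = dG),
                   protocol = list(lambdas = lambdas, temperature = temp),
                   warnings = character(0)), class = "sf_fep")
  }
  expect_equal(as.numeric(ddG(mkfep(3.5), mkfep(1.0))), 2.5)
  expect_equal(as.numeric(ddG(mkfep(2.2), mkfep(2.2))), 0)
  expect_error(ddG(mkfep(1, temp = 310), mkfep(1, temp = 300)), "share")
  expect_error(ddG(mkfep(1), mkfep(1, lambdas = c(0, 0.5, 1))), "share")
})

test_that("repeat aggregation needs distinct seeds and reports mean/SD", {
  expect_error(repeat_and_aggregate(function(s) s, seeds = c(1, 1, 2)),
               "distinct")
  out <- repeat_and_aggregate(function(s) s * 1.0, seeds = c(1, 2, 3))
  expect_equal(attr(out, "mean"), 2)
  expect_equal(attr(out, "sd"), 1)
  g <- glance(out)
  expect_equal(g$n_repeats, 3)
})

test_that("underscored sampling attaches convergence warnings", {
  fp <- fep_protocol(lambdas = c(0, 0.5, 1), steps_equil = 50,
                     steps_prod = 200, sample_every = 50, seed = 10,
                     ess_floor = 1e6)
  expect_warning(leg <- run_fep_harmonic(1, 4, fp), "effective sample size")
  expect_gt(length(leg$warnings), 0)
})

test_that("tidy and glance expose the window table and leg summary", {
  fp <- fep_protocol(lambdas = c(0, 0.5, 1), steps_equil = 200,
                     steps_prod = 1000, sample_every = 20, seed = 11)
  leg <- suppressWarnings(run_fep_harmonic(1, 2, fp))
  td <- tidy(leg)
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$dG), leg$dG)
  gl <- glance(leg)
  expect_equal(gl$n_windows, 2)
  expect_equal(gl$dG, leg$dG)
})
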