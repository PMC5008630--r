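gaussian_points <- function(n, mean, sd, seed) {
  set.seed(seed)
  tibble::tibble(R = rnorm(n, mean[1], sd), Z = rnorm(n, mean[2], sd))
}

two_clouds <- function(sep_sigma = 10, n = 60, seed = 1, sd = 0.3) {
  open <- gaussian_points(n, c(3 + sep_sigma * sd, 2 + sep_sigma * sd), sd,
                          seed)
  closed <- gaussian_points(n, c(3, 2), sd, seed + 1)
  list(points = dplyr::bind_rows(closed, open),
       labels = factor(rep(c("closed", "open"), each = n),
                       levels = c("closed", "open")))
}

test_that("well-separated clouds are classified perfectly", {
  d <- two_clouds(10)
  bnd <- fit_separator(d$points, d$labels)
  expect_equal(sqrt(sum(bnd$w^2)), 1, tolerance = 1e-9)
  dv <- decision_values(bnd, d$points)
  expect_true(all((dv > 0) == (d$labels == "open")))
})

test_that("mirroring the labels negates the boundary", {
  d <- two_clouds(8, seed = 3)
  b1 <- fit_separator(d$points, d$labels)
  flipped <- factor(ifelse(d$labels == "open", "closed", "open"),
                    levels = c("closed", "open"))
  b2 <- fit_separator(d$points, flipped)
  expect_equal(b2$w, -b1$w, tolerance = 1e-6)
  expect_equal(b2$b, -b1$b, tolerance = 1e-6)
})

test_that("single-class input and bad levels are rejected", {
  d <- two_clouds(5)
  expect_error(fit_separator(d$points, rep("open", nrow(d$points))), "both")
  bnd <- fit_separator(d$points, d$labels)
  expect_error(confidence_regions(bnd, d$points, d$labels, level = 1.2),
               "level")
})

test_that("decision signs agree with an exhaustive max-margin oracle", {
  for (s in c(2, 5, 9)) {
    set.seed(s)
    n <- 10
    pts <- tibble::tibble(R = c(rnorm(n, 2, 0.5), rnorm(n, 6, 0.5)),
                          Z = c(rnorm(n, 1, 0.5), rnorm(n, 4, 0.5)))
    labels <- factor(rep(c("closed", "open"), each = n),
                     levels = c("closed", "open"))
    bnd <- fit_separator(pts, labels, C = 1000)
    orc <- oracle_max_margin(pts, labels)
    d_svm <- decision_values(bnd, pts)
    d_orc <- as.matrix(pts) %*% orc$w + orc$b
    expect_identical(sign(d_svm), sign(drop(d_orc)),
                     label = sprintf("seed %d", s))
  }
})

test_that("confidence offsets keep the required fraction of each class", {
  d <- two_clouds(4, n = 100, seed = 7, sd = 0.5)
  bnd <- fit_separator(d$points, d$labels)
  bnd <- confidence_regions(bnd, d$points, d$labels, level = 0.95)
  dv <- decision_values(bnd, d$points)
  open_in <- sum(dv[d$labels == "open"] >= bnd$offset_open)
  closed_in <- sum(dv[d$labels == "closed"] <= -bnd$offset_closed)
  expect_gte(open_in, ceiling(0.95 * 100))
  expect_gte(closed_in, ceiling(0.95 * 100))
  expect_gte(bnd$offset_open, 0)
  expect_gte(bnd$offset_closed, 0)
})

test_that("at level ~1 on separable data the unassigned band is the margin band", {
  d <- two_clouds(10, n = 50, seed = 8)
  bnd <- fit_separator(d$points, d$labels)
  bnd <- confidence_regions(bnd, d$points, d$labels, level = 0.999)
  dv <- decision_values(bnd, d$points)
  # no training point strictly inside the band between the offset lines
  expect_false(any(dv > -bnd$offset_closed & dv < bnd$offset_open))
  expect_gt(bnd$offset_open, 0)
  expect_gt(bnd$offset_closed, 0)
})

test_that("classification fractions are exhaustive and tie-break to open", {
  d <- two_clouds(6, seed = 10)
  bnd <- confidence_regions(fit_separator(d$points, d$labels), d$points,
                            d$labels)
  cl <- classify_frames(d$points, bnd)
  occ <- attr(cl, "occupancy")
  expect_equal(sum(occ), 1)
  # all frames at the closed centroid
  centroid <- colMeans(d$points[d$labels == "closed", ])
  cl2 <- classify_frames(tibble::tibble(R = rep(centroid[["R"]], 5),
                                        Z = rep(centroid[["Z"]], 5)), bnd)
  expect_equal(unname(attr(cl2, "occupancy")["closed"]), 1)
  # points exactly on the separator with zero offsets label open
  bnd0 <- bnd; bnd0$offset_open <- 0; bnd0$offset_closed <- 0
  on_line <- tibble::tibble(R = 0, Z = -bnd$b / bnd$w[2])
  cl3 <- classify_frames(on_line, bnd0)
  expect_equal(as.character(cl3$state), "open")
})

test_that("classification is invariant under a common affine rescaling", {
  d <- two_clouds(6, n = 40, seed = 12, sd = 0.5)
  bnd <- confidence_regions(fit_separator(d$points, d$labels), d$points,
                            d$labels)
  lab1 <- classify_frames(d$points, bnd)$state
  resc <- function(p) tibble::tibble(R = 2 * p$R + 5, Z = 0.5 * p$Z - 1)
  d2 <- resc(d$points)
  bnd2 <- confidence_regions(fit_separator(d2, d$labels), d2, d$labels)
  lab2 <- classify_frames(resc(d$points), bnd2)$state
  expect_gt(mean(lab1 == lab2), 0.97)
})

test_that("the open region sits at larger R and Z on planted data", {
  open <- list(mean = c(6, 5), cov = diag(c(0.3, 0.3)))
  closed <- list(mean = c(2, 1), cov = diag(c(0.3, 0.3)))
  pl <- plant_labeled_states(open, closed, n_frames = 800, seed = 15,
                             open_fraction = 0.5)
  bnd <- confidence_regions(fit_separator(pl$rz, pl$labels), pl$rz,
                            pl$labels)
  cl <- classify_frames(pl$rz, bnd)
  mo <- dplyr::summarise(dplyr::group_by(cl, .data$state),
                         R = mean(R), Z = mean(Z))
  expect_gt(mo$R[mo$state == "open"], mo$R[mo$state == "closed"])
  expect_gt(mo$Z[mo$state == "open"], mo$Z[mo$state == "closed"])
})

test_that("boundary text record round-trips", {
  d <- two_clouds(7, seed = 20)
  bnd <- confidence_regions(fit_separator(d$points, d$labels), d$points,
                            d$labels)
  f <- tempfile(fileext = ".txt")
  write_boundary(bnd, f)
  rd <- read_boundary(f)
  expect_equal(rd$w, bnd$w)
  expect_equal(rd$b, bnd$b)
  expect_equal(rd$offset_open, bnd$offset_open)
  expect_equal(rd$offset_closed, bnd$offset_closed)
})
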