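test_that("edge-area score handles the exact textbook profiles", {
  flat <- line_profile(seq(0, 1, length.out = 21), rep(2, 21))
  expect_equal(junctional_actin_score(flat), 0.2)

  # all mass strictly inside the edge bands (support ends inside x = 0.1/0.9)
  x <- seq(0, 1, length.out = 101)
  edges <- as.numeric(x <= 0.09 | x >= 0.91)
  edge_only <- line_profile(x, edges)
  expect_equal(junctional_actin_score(edge_only), 1.0)
})

test_that("edge-area score agrees with quadrature on a Gaussian bump", {
  x <- seq(0, 1, length.out = 4001)
  y <- exp(-(x - 0.5)^2 / (2 * 0.1^2))
  # oracle: independent numerical quadrature of the same density
  f <- function(z) exp(-(z - 0.5)^2 / (2 * 0.1^2))
  tail_mass <- stats::integrate(f, 0, 0.10)$value +
    stats::integrate(f, 0.90, 1)$value
  total <- stats::integrate(f, 0, 1)$value
  expect_equal(junctional_actin_score(line_profile(x, y)),
               tail_mass / total, tolerance = 1e-3)
})

test_that("edge-area score is invariant to scaling and reversal", {
  set.seed(42)
  for (i in 1:1000) {
    p <- random_profile()
    s1 <- junctional_actin_score(line_profile(p$position, p$intensity))
    k <- runif(1, 0.01, 100)
    s2 <- junctional_actin_score(line_profile(p$position, k * p$intensity))
    rev_x <- rev(1 - p$position); rev_y <- rev(p$intensity)
    s3 <- junctional_actin_score(line_profile(rev_x, rev_y))
    expect_equal(s2, s1, tolerance = 1e-12)
    expect_equal(s3, s1, tolerance = 1e-12)
  }
})

test_that("profile constructor enforces its invariants", {
  expect_error(line_profile(c(seq(0, 0.5, length.out = 10), 0.5), rep(1, 11)),
               "increasing")
  expect_error(line_profile(seq(0, 1, length.out = 5), rep(1, 5)), "10 samples")
  expect_error(line_profile(seq(0, 1, length.out = 11), rep(0, 11)),
               "positive")
})

test_that("Golgi polarity angle matches its defining geometry", {
  n <- c(10, 10)
  expect_equal(golgi_polarity_angle(n, n + c(0, -5), c(0, -1))$angle, 0)
  expect_equal(golgi_polarity_angle(n, n + c(5, 0), c(0, -1))$angle, 90)
  expect_equal(golgi_polarity_angle(n, n + c(0, 5), c(0, -1))$angle, 180)
  expect_error(golgi_polarity_angle(n, n, c(0, 1)), "coincide")
  expect_error(golgi_polarity_angle(n, n + c(1, 0), c(0, 0)), "non-zero")
})

test_that("Golgi polarity angle is invariant under rigid rotations", {
  set.seed(7)
  for (i in 1:100) {
    nuc <- runif(2, -50, 50)
    gol <- nuc + runif(2, -10, 10)
    if (sqrt(sum((gol - nuc)^2)) < 1e-6) gol <- nuc + c(3, 1)
    ap <- runif(2, -1, 1); if (all(ap == 0)) ap <- c(1, 0)
    base <- golgi_polarity_angle(nuc, gol, ap)$angle
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    rot <- golgi_polarity_angle(R %*% nuc, R %*% gol, R %*% ap)$angle
    expect_equal(rot, base, tolerance = 1e-9)
  }
})

test_that("Ki67 fraction is exact on clean renders and errors on no nuclei", {
  g <- generate_morphology_image(synthetic_morphology_spec(
    n_cells = 50, ki67_fraction = 0.1, seed = 21, image_size = 1400))
  kf <- ki67_fraction(g$stack)
  expect_identical(kf$positive, 5L)
  expect_identical(kf$total, 50L)
  expect_equal(kf$fraction, 0.10)

  g0 <- generate_morphology_image(synthetic_morphology_spec(
    n_cells = 10, ki67_fraction = 0, seed = 22, image_size = 800))
  expect_equal(ki67_fraction(g0$stack)$positive, 0L)

  blank <- matrix(0, 64, 64)
  expect_error(ki67_fraction(blank, blank), "no nuclei")
})

test_that("Ki67 recovery under noise stays within 0.05 median error", {
  errs <- vapply(1:10, function(s) {
    g <- generate_morphology_image(synthetic_morphology_spec(
      n_cells = 40, ki67_fraction = 0.3, noise_sd = 0.1, seed = s,
      image_size = 1200))
    abs(ki67_fraction(g$stack)$fraction - g$truth$params$true_ki67_fraction)
  }, numeric(1))
  expect_lte(stats::median(errs), 0.05)
})

test_that("Ki67 positivity is monotone in rendered marker intensity", {
  g <- generate_morphology_image(synthetic_morphology_spec(
    n_cells = 30, ki67_fraction = 0.4, seed = 13, image_size = 1000))
  dapi <- get_plane(g$stack, "dapi"); ki <- get_plane(g$stack, "ki67")
  fr <- vapply(c(0.2, 0.6, 1), function(gain)
    ki67_fraction(dapi, ki * gain,
                  config = list(ki67_threshold = 0.5))$fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("vessel diameter follows the station-mean definition", {
  m <- band_mask(width_px = 80)
  geom <- vessel_geometry(m, band_axis(m), diameter_um = 160,
                          window = m, pixel_size = 2)
  res <- measure_vessel_diameter(geom)
  expect_equal(res$diameter_um, 160, tolerance = 2)
  res1 <- measure_vessel_diameter(geom, n_locations = 1L)
  expect_equal(res1$diameter_um, res$diameter_um, tolerance = 1e-9)

  # linear taper 50 -> 110 px: mean of three stations = the mid-station width
  nrow_ <- 160; ncol_ <- 200
  taper <- matrix(FALSE, nrow_, ncol_)
  for (j in seq_len(ncol_)) {
    w <- 50 + (110 - 50) * (j - 1) / (ncol_ - 1)
    taper[abs(seq_len(nrow_) - nrow_ / 2) <= w / 2 - 0.5, j] <- TRUE
  }
  gt <- vessel_geometry(taper, list(center = c(ncol_ / 2, nrow_ / 2),
                                    direction = c(1, 0)),
                        diameter_um = 80, window = taper, pixel_size = 1)
  rt <- measure_vessel_diameter(gt, n_locations = 3L)
  expect_equal(rt$diameter_um, rt$stations[2], tolerance = 2)
})

test_that("line profiles are sampled, normalized and symmetric", {
  const <- matrix(4, 60, 60)
  pr <- extract_line_profile(const, list(c(5, 30), c(50, 30)))
  expect_true(all(pr$intensity == 1))
  expect_error(extract_line_profile(const, list(c(5, 5), c(5, 5))), "zero-length")

  g <- generate_morphology_image(synthetic_morphology_spec(
    n_cells = 5, junctional_fraction = 1, seed = 6, image_size = 700))
  cells <- g$truth$params$cells
  for (i in seq_len(min(3, nrow(cells)))) {
    e1 <- c(cells$profile_x1[i], cells$profile_y1[i])
    e2 <- c(cells$profile_x2[i], cells$profile_y2[i])
    a <- junctional_actin_score(extract_line_profile(
      g$stack, list(e1, e2), channel = "actin"))
    b <- junctional_actin_score(extract_line_profile(
      g$stack, list(e2, e1), channel = "actin"))
    expect_gte(a, 0.9)                     # cortical construction
    expect_equal(b, a, tolerance = 1e-9)   # reversal symmetry
  }
})

test_that("integrated density matches direct arithmetic", {
  img <- matrix(0, 80, 80)
  img[20:39, 30:49] <- 5                   # 400 px at intensity 5
  res <- vecadherin_integrated_density(img,
    config = list(background = "constant", background_value = 0))
  expect_equal(res$integrated_density, 400 * 5)
  expect_equal(res$mask_area_px, 400L)

  # constant offset removed by background subtraction
  res2 <- vecadherin_integrated_density(img + 3,
    config = list(background = "constant"))
  expect_equal(res2$integrated_density, res$integrated_density)

  expect_warning(res0 <- vecadherin_integrated_density(matrix(1, 50, 50)),
                 "blank")
  expect_equal(res0$integrated_density, 0)
})

test_that("sprout counting tallies per vessel, by side, with dedup", {
  ax <- list(v1 = list(center = c(50, 20), direction = c(1, 0)))
  empty <- data.frame(x = numeric(), y = numeric(), vessel = character())
  expect_equal(count_sprouts(empty, ax)$counts$n, 0L)

  ann <- data.frame(x = c(10, 40, 60, 90), y = c(10, 10, 30, 30),
                    vessel = "v1")
  res <- count_sprouts(ann, ax)
  expect_equal(res$counts$n, 4L)
  expect_equal(c(res$counts$left, res$counts$right), c(2L, 2L))

  # duplicates inside the merge radius collapse; brute-force pairwise oracle
  ann2 <- data.frame(x = c(10, 11, 10.5), y = c(10, 10, 11), vessel = "v1")
  res2 <- count_sprouts(ann2, ax, merge_radius = 3)
  d <- as.matrix(stats::dist(ann2[, c("x", "y")]))
  expect_true(all(d[upper.tri(d)] < 3))    # oracle: all mutually mergeable
  expect_equal(res2$counts$n, 1L)

  orphan <- data.frame(x = 1, y = 1, vessel = "ghost")
  res3 <- count_sprouts(rbind(ann, orphan), ax)
  expect_equal(nrow(res3$orphans), 1L)
  expect_equal(res3$counts$n, 4L)
})
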