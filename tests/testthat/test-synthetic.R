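test_that("invalid vessel specs are rejected with the offending field named", {
  expect_error(synthetic_vessel_spec(vessel_diameter = -1), "vessel_diameter")
  expect_error(synthetic_vessel_spec(duration = 15, frame_interval = 10),
               "duration")
  expect_error(synthetic_vessel_spec(noise_sd = -0.1), "noise_sd")
})

test_that("zero-permeability time-lapse keeps the gel at background", {
  spec <- synthetic_vessel_spec(true_PD = 0, noise_sd = 0, margin = 120,
                                axial_extent = 40, duration = 60)
  g <- generate_vessel_timelapse(spec)
  arr <- g$stack$data
  # rows more than a couple px outside the vessel band edge
  ny <- dim(arr)[1]
  y <- (seq_len(ny) - (ny + 1) / 2) * spec$pixel_size
  gel <- abs(y) > spec$vessel_diameter / 2 + 2 * spec$pixel_size
  expect_equal(max(abs(arr[gel, , ] - spec$background_intensity)), 0)
})

test_that("vessel time-lapse generation is bit-identical under one seed", {
  spec <- synthetic_vessel_spec(true_PD = 1e-6, noise_sd = 5, seed = 11,
                                duration = 60, axial_extent = 40, margin = 100)
  g1 <- generate_vessel_timelapse(spec)
  g2 <- generate_vessel_timelapse(spec)
  expect_identical(g1$stack$data, g2$stack$data)
  expect_identical(g1$truth$params, g2$truth$params)
})

test_that("forward simulation books gel mass gain as wall flux times area", {
  # discrete mass bookkeeping: per-step gel mass gain integrates
  # P_D (c_lumen - c_wall) * wall area
  dom <- transport_domain(grid_spacing = 2, extent = 500, D = 4e-7,
                          vascular = list(center = c(0, 0), diameter = 160))
  es <- simulate_radial_efflux(dom, P_D = 1e-6, c_lumen = 1, duration = 300)
  expect_lt(mass_conservation_error(es), 1e-4)
})

test_that("morphology rendering honours Ki67 and Golgi construction", {
  g0 <- generate_morphology_image(synthetic_morphology_spec(
    n_cells = 8, ki67_fraction = 0, seed = 3, image_size = 700))
  expect_identical(sum(g0$truth$params$cells$ki67_positive), 0L)
  expect_equal(max(get_plane(g0$stack, "ki67")), 0)

  ga <- generate_morphology_image(synthetic_morphology_spec(
    n_cells = 6, golgi_angles = 0, seed = 4, image_size = 700))
  cells <- ga$truth$params$cells
  for (i in seq_len(nrow(cells))) {
    v <- c(cells$gm130_x[i] - cells$x[i], cells$gm130_y[i] - cells$y[i])
    a <- c(cells$apical_x[i], cells$apical_y[i])
    cosang <- sum(v * a) / sqrt(sum(v^2) * sum(a^2))
    expect_equal(cosang, 1, tolerance = 1e-9)
  }
})

test_that("overfull morphology placement fails with guidance", {
  expect_error(generate_morphology_image(
    synthetic_morphology_spec(n_cells = 60, image_size = 300)),
    "larger")
})

test_that("rendered cortical profile realizes the expected edge-area score", {
  # analytic oracle: trapezoid integration of the generating profile itself
  for (f in c(0, 0.2, 0.7, 1)) {
    expect_equal(junctional_actin_score(cortical_profile(f)),
                 0.2 + 0.8 * f, tolerance = 2e-3)
  }
  # and the rasterized render reproduces it up to render blur
  g <- generate_morphology_image(synthetic_morphology_spec(
    n_cells = 10, junctional_fraction = 0.2, seed = 5, image_size = 800))
  cells <- g$truth$params$cells
  sc <- vapply(seq_len(nrow(cells)), function(i) {
    pr <- extract_line_profile(
      g$stack, list(c(cells$profile_x1[i], cells$profile_y1[i]),
                    c(cells$profile_x2[i], cells$profile_y2[i])),
      channel = "actin")
    junctional_actin_score(pr)
  }, numeric(1))
  expect_equal(mean(sc), 0.36, tolerance = 0.05)
})

test_that("cytokine membranes realize requested folds and reject bad layouts", {
  lay <- cytokine_array_layout()
  g1 <- generate_cytokine_array(lay, fold_changes = numeric(), seed = 2)
  ev <- quantify_array(g1$stack, lay, channel = "ev")
  mut <- quantify_array(g1$stack, lay, channel = "mutant")
  expect_equal(as.numeric(normalize_to_ev(mut, ev)),
               rep(1, length(ev$means)), tolerance = 1e-9)

  g3 <- generate_cytokine_array(lay, fold_changes = c(CK3 = 3), seed = 2)
  rel <- normalize_to_ev(quantify_array(g3$stack, lay, channel = "mutant"),
                         quantify_array(g3$stack, lay, channel = "ev"))
  expect_equal(unname(rel["CK3"]), 3, tolerance = 1e-9)

  bad <- lay
  bad$grid_row[2] <- bad$grid_row[1]; bad$grid_col[2] <- bad$grid_col[1]
  expect_error(generate_cytokine_array(bad, seed = 1), "duplicate")
  expect_error(generate_cytokine_array(lay, fold_changes = c(NOPE = 2)),
               "NOPE")
})

test_that("noisy membranes still recover folds via regeneration oracle", {
  lay <- cytokine_array_layout()
  folds <- c(CK1 = 0.5, CK4 = 2, CK9 = 3.5)
  g <- generate_cytokine_array(lay, fold_changes = folds, seed = 8,
                               noise_sd = 0.01)
  rel <- normalize_to_ev(quantify_array(g$stack, lay, channel = "mutant"),
                         quantify_array(g$stack, lay, channel = "ev"))
  # oracle: the noiseless regeneration of the same spec
  g0 <- generate_cytokine_array(lay, fold_changes = folds, seed = 8)
  rel0 <- normalize_to_ev(quantify_array(g0$stack, lay, channel = "mutant"),
                          quantify_array(g0$stack, lay, channel = "ev"))
  expect_equal(rel, rel0, tolerance = 0.05)
})

test_that("indentation generator matches the Hertz law and validates input", {
  g <- generate_indentation_curve(E = 500, seed = 1)
  expect_identical(g$curve$force[1], 0)          # delta = 0 -> F = 0
  g2 <- generate_indentation_curve(E = 1000, seed = 1)
  expect_equal(g2$curve$force, 2 * g$curve$force)  # linear in E
  expect_error(generate_indentation_curve(E = -5), "E")
  expect_error(generate_indentation_curve(E = 100, depth_max = 0), "depth_max")
  expect_error(generate_indentation_curve(E = 100, poisson = 0.7), "poisson")
})

test_that("all generators are deterministic under a fixed seed", {
  lay <- cytokine_array_layout()
  a <- generate_cytokine_array(lay, c(CK2 = 2), seed = 5, noise_sd = 0.02)
  b <- generate_cytokine_array(lay, c(CK2 = 2), seed = 5, noise_sd = 0.02)
  expect_identical(a$stack$data, b$stack$data)
  m1 <- generate_morphology_image(synthetic_morphology_spec(
    n_cells = 6, noise_sd = 0.05, seed = 9, image_size = 600))
  m2 <- generate_morphology_image(synthetic_morphology_spec(
    n_cells = 6, noise_sd = 0.05, seed = 9, image_size = 600))
  expect_identical(m1$stack$data, m2$stack$data)
  i1 <- generate_indentation_curve(130, noise_sd = 1e-9, seed = 4)
  i2 <- generate_indentation_curve(130, noise_sd = 1e-9, seed = 4)
  expect_identical(i1$curve$force, i2$curve$force)
})

test_that("estimator error grows with generator noise on average", {
  errs <- vapply(c(0, 5e-9, 5e-8), function(ns) {
    mean(vapply(1:20, function(s) {
      g <- generate_indentation_curve(130, noise_sd = ns, seed = s)
      abs(fit_hertz(g$curve)$E - 130) / 130
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) >= 0))
})

test_that("image stacks and ground truth survive a TIFF/JSON round trip", {
  spec <- synthetic_vessel_spec(true_PD = 1e-6, duration = 30, seed = 2,
                                axial_extent = 30, margin = 80)
  g <- generate_vessel_timelapse(spec)
  tf <- tempfile(fileext = ".tif"); jf <- tempfile(fileext = ".json")
  write_stack_tiff(g$stack, tf)
  back <- read_stack_tiff(tf)
  expect_equal(back$data, g$stack$data, tolerance = 1e-6)
  expect_equal(back$pixel_size, g$stack$pixel_size)
  expect_equal(back$frame_interval, g$stack$frame_interval)
  write_ground_truth(g$truth, jf)
  js <- jsonlite::fromJSON(jf)
  expect_equal(js$params$true_PD, 1e-6)
  expect_equal(frame_times(g$stack),
               (seq_len(n_planes(g$stack)) - 1) * 10)
})
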