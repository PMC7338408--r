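#' Specification for a synthetic dextran time-lapse
#'
#' Parameters of a rendered mid-plane permeability movie: a perfused vessel
#' of known diameter whose wall carries a known diffusive permeability, in
#' the imaging protocol of the assay (one frame every 10 s for 5 min by
#' default). Intensities are arbitrary units: the rendered signal is a
#' depth-integrated (widefield-style) projection of the tracer concentration
#' so that window-summed intensity is proportional to tracer mass per unit
#' vessel length, which is what the mass-conservation estimator assumes.
#'
#' @param vessel_diameter vessel diameter, um (default 160, the needle
#'   template used in the device).
#' @param pixel_size um/px (default 2).
#' @param frame_interval s between frames (default 10).
#' @param duration length of the post-filling time-lapse, s (default 300).
#' @param true_PD ground-truth diffusive permeability, cm/s.
#' @param diffusivity_ECM tracer diffusivity in the gel, cm^2/s.
#' @param vessel_intensity intensity of the vessel-center pixel at filling,
#'   a.u.
#' @param background_intensity camera background, a.u.
#' @param noise_sd additive Gaussian noise sd per pixel, a.u.
#' @param seed integer RNG seed.
#' @param n_prefill background frames acquired before the tracer arrives.
#' @param margin perivascular gel margin rendered on each side, um.
#' @param axial_extent rendered axial length of the vessel, um.
#' @return object of class \code{synthetic_vessel_spec}.
#' @export
synthetic_vessel_spec <- function(vessel_diameter = 160, pixel_size = 2,
                                  frame_interval = 10, duration = 300,
                                  true_PD = 1e-6, diffusivity_ECM = 4e-7,
                                  vessel_intensity = 100,
                                  background_intensity = 10,
                                  noise_sd = 0, seed = 1L,
                                  n_prefill = 2L, margin = 200,
                                  axial_extent = 200) {
  fail_field(vessel_diameter <= 0, "vessel_diameter", "must be > 0 um")
  fail_field(pixel_size <= 0, "pixel_size", "must be > 0 um/px")
  fail_field(frame_interval <= 0, "frame_interval", "must be > 0 s")
  fail_field(duration / frame_interval < 3, "duration",
             "must cover at least 3 frames at `frame_interval`")
  fail_field(true_PD < 0, "true_PD", "must be >= 0 cm/s")
  fail_field(diffusivity_ECM <= 0, "diffusivity_ECM", "must be > 0 cm^2/s")
  fail_field(noise_sd < 0, "noise_sd", "must be >= 0")
  fail_field(margin <= 0, "margin", "must be > 0 um")
  structure(list(vessel_diameter = vessel_diameter, pixel_size = pixel_size,
                 frame_interval = frame_interval, duration = duration,
                 true_PD = true_PD, diffusivity_ECM = diffusivity_ECM,
                 vessel_intensity = vessel_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 n_prefill = as.integer(n_prefill), margin = margin,
                 axial_extent = axial_extent),
            class = "synthetic_vessel_spec")
}

#' Render a synthetic mid-plane dextran time-lapse
#'
#' Runs the radial efflux physics (\code{\link{simulate_radial_efflux}}) at
#' the spec's true permeability and renders each frame as a depth-integrated
#' projection: a pixel at in-plane offset y from the vessel axis integrates
#' the concentration along the optical axis z, so vessel pixels show the
#' familiar bright-band chord profile and perivascular pixels accumulate
#' tracer as it crosses the wall. The first \code{n_prefill} frames precede
#' tracer arrival (background only); filling is instantaneous at the next
#' frame. Additive Gaussian noise is applied per pixel.
#'
#' @param spec a \code{\link{synthetic_vessel_spec}}.
#' @return list with \code{stack} (an \code{\link{image_stack}}, planes =
#'   time) and \code{truth} (a \code{\link{ground_truth}} recording every
#'   generating parameter, including \code{fill_frame}).
#' @export
generate_vessel_timelapse <- function(spec) {
  stopifnot(inherits(spec, "synthetic_vessel_spec"))
  px <- spec$pixel_size
  rw <- spec$vessel_diameter / 2
  rout <- rw + spec$margin + 150          # gel simulated past the rendered margin
  sim_h <- min(2, px)
  dom <- transport_domain(
    grid_spacing = min(sim_h, spec$vessel_diameter / 8), extent = rout,
    D = spec$diffusivity_ECM,
    vascular = list(center = c(0, 0), diameter = spec$vessel_diameter),
    duct = list(center = c(1e6, 0), diameter = spec$vessel_diameter))
  times <- seq(0, spec$duration, by = spec$frame_interval)
  sim <- simulate_radial_efflux(dom, P_D = spec$true_PD, c_lumen = 1,
                                duration = spec$duration, output_times = times)
  k <- spec$vessel_intensity / spec$vessel_diameter   # a.u. per (conc * um depth)

  half_w <- rw + spec$margin
  y <- seq(-half_w, half_w, by = px)                  # cross-vessel (rows)
  nx <- max(3L, round(spec$axial_extent / px))        # axial (cols)
  zmax <- rout
  z <- seq(0, zmax, by = sim_h)
  profile_at <- function(field) {
    ci <- radial_interpolator(field)
    rho <- sqrt(outer(y^2, z^2, "+"))
    vals <- matrix(ci(as.vector(rho)), nrow = length(y))
    2 * k * (rowSums(vals) - (vals[, 1L] + vals[, ncol(vals)]) / 2) * sim_h
  }
  nframes <- spec$n_prefill + length(times)
  arr <- array(spec$background_intensity, dim = c(length(y), nx, nframes))
  for (i in seq_along(times)) {
    pr <- profile_at(sim$fields[[i]])
    arr[, , spec$n_prefill + i] <- spec$background_intensity +
      matrix(pr, nrow = length(y), ncol = nx)
  }
  if (spec$noise_sd > 0)
    arr <- with_seed(spec$seed,
                     arr + stats::rnorm(length(arr), sd = spec$noise_sd))
  truth <- ground_truth(
    c(unclass(spec),
      list(fill_frame = spec$n_prefill + 1L, c_lumen = 1,
           intensity_per_conc_um = k)),
    seed = spec$seed, generator = "generate_vessel_timelapse")
  stack <- image_stack(arr, pixel_size = px,
                       frame_interval = spec$frame_interval,
                       plane_type = "time",
                       metadata = list(generator = "generate_vessel_timelapse",
                                       seed = spec$seed))
  list(stack = stack, truth = truth)
}

#' Specification for a synthetic morphology snapshot
#'
#' Parameters of a rendered multichannel image of schematic epithelial or
#' endothelial cells: elliptical cells with DAPI nuclei, a known fraction of
#' Ki67-positive nuclei, a GM130 (Golgi) blob at a known angle from each
#' nucleus relative to a recorded apical axis, and a cortical actin channel
#' placing a known fraction of each cell's actin mass in the outer 10% of
#' its short axis.
#'
#' @param n_cells number of cells to place.
#' @param ki67_fraction fraction of Ki67-positive cells, in [0, 1];
#'   \code{round(ki67_fraction * n_cells)} cells are rendered positive.
#' @param golgi_angles Golgi polarity angles in degrees [0, 180], recycled
#'   to \code{n_cells}; 0 = apical (toward the recorded apical axis),
#'   180 = basal.
#' @param junctional_fraction fraction of per-cell actin mass placed in the
#'   outer 10% at each end of the short axis (edge band), in [0, 1]; the
#'   remainder is uniform, so the expected edge-area score is
#'   \code{0.2 + 0.8 * junctional_fraction}.
#' @param image_size image side, px.
#' @param pixel_size um/px.
#' @param noise_sd additive Gaussian noise sd per channel, a.u. (signal is
#'   order 1).
#' @param seed integer RNG seed.
#' @param cell_axes semi-axes (long, short) of the cell ellipse, um.
#' @param nucleus_axes semi-axes of the nucleus ellipse, um.
#' @return object of class \code{synthetic_morphology_spec}.
#' @export
synthetic_morphology_spec <- function(n_cells = 30, ki67_fraction = 0.1,
                                      golgi_angles = 0,
                                      junctional_fraction = 0.5,
                                      image_size = 1024, pixel_size = 0.5,
                                      noise_sd = 0, seed = 1L,
                                      cell_axes = c(25, 14),
                                      nucleus_axes = c(7, 5)) {
  fail_field(n_cells < 1, "n_cells", "must be >= 1")
  fail_field(ki67_fraction < 0 || ki67_fraction > 1, "ki67_fraction",
             "must be in [0, 1]")
  fail_field(any(golgi_angles < 0 | golgi_angles > 180), "golgi_angles",
             "all angles must be in [0, 180] degrees")
  fail_field(junctional_fraction < 0 || junctional_fraction > 1,
             "junctional_fraction", "must be in [0, 1]")
  fail_field(image_size < 32, "image_size", "must be >= 32 px")
  fail_field(noise_sd < 0, "noise_sd", "must be >= 0")
  structure(list(n_cells = as.integer(n_cells),
                 ki67_fraction = ki67_fraction,
                 golgi_angles = rep(golgi_angles, length.out = n_cells),
                 junctional_fraction = junctional_fraction,
                 image_size = as.integer(image_size),
                 pixel_size = pixel_size, noise_sd = noise_sd,
                 seed = as.integer(seed), cell_axes = cell_axes,
                 nucleus_axes = nucleus_axes),
            class = "synthetic_morphology_spec")
}

#' Render a synthetic multichannel morphology image
#'
#' Places non-overlapping elliptical cells (schematic renders: indicator
#' ellipses and blobs, not photorealistic texture) and renders four named
#' channels: \code{dapi} (nuclei), \code{ki67} (positive nuclei only),
#' \code{gm130} (one Golgi blob per cell at its specified polarity angle
#' from the recorded apical axis), and \code{actin} (cortical profile along
#' the cell's short axis with the specified edge-band mass fraction).
#' Ground truth records the per-cell geometry, apical axes, Golgi centroids,
#' Ki67 labels, short-axis profile endpoints, and the expected edge-area
#' score. All coordinates in the truth table are 0-based pixel indices
#' (x = column, y = row, origin top-left).
#'
#' @param spec a \code{\link{synthetic_morphology_spec}}.
#' @return list with \code{stack} (channel \code{image_stack}) and
#'   \code{truth} (\code{ground_truth}; \code{$params$cells} is the per-cell
#'   table).
#' @export
generate_morphology_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_morphology_spec"))
  n <- spec$n_cells
  sz <- spec$image_size
  px <- spec$pixel_size
  a <- spec$cell_axes[1] / px; b <- spec$cell_axes[2] / px
  an <- spec$nucleus_axes[1] / px; bn <- spec$nucleus_axes[2] / px
  pad <- a + 2
  min_sep <- 2 * a + 2

  with_seed(spec$seed, {
    centers <- matrix(NA_real_, nrow = n, ncol = 2)
    placed <- 0L; tries <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > 400L * n)
        stop(sprintf(
          "could not place %d non-overlapping cells in a %d px image; use a larger `image_size`",
          n, sz))
      cand <- stats::runif(2, min = pad + 1, max = sz - pad)
      if (placed > 0L) {
        d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
              (centers[seq_len(placed), 2] - cand[2])^2
        if (min(d2) < min_sep^2) next
      }
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
    theta <- stats::runif(n, 0, pi)              # cell long-axis orientation
    apical_sign <- sample(c(-1, 1), n, replace = TRUE)
    golgi_side <- sample(c(-1, 1), n, replace = TRUE)
    n_pos <- round(spec$ki67_fraction * n)
    pos <- rep(FALSE, n); pos[sample.int(n, n_pos)] <- TRUE
  })

  ch <- c("dapi", "ki67", "gm130", "actin")
  arr <- array(0, dim = c(sz, sz, length(ch)), dimnames = list(NULL, NULL, ch))
  f <- spec$junctional_fraction
  r_g <- 7 / px; r_blob <- 2.5 / px
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    cx <- centers[i, 1]; cy <- centers[i, 2]    # (col, row) in 1-based px
    ct <- cos(theta[i]); st <- sin(theta[i])
    # short-axis unit vector, apical side chosen by apical_sign
    sv <- c(-st, ct) * apical_sign[i]
    r0 <- max(1L, floor(cy - pad)); r1 <- min(sz, ceiling(cy + pad))
    c0 <- max(1L, floor(cx - pad)); c1 <- min(sz, ceiling(cx + pad))
    rows <- r0:r1; cols <- c0:c1
    X <- matrix(rep(cols, each = length(rows)), nrow = length(rows))
    Y <- matrix(rep(rows, times = length(cols)), nrow = length(rows))
    u <- ct * (X - cx) + st * (Y - cy)
    v <- -st * (X - cx) + ct * (Y - cy)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    in_nuc <- (u / an)^2 + (v / bn)^2 <= 1
    # cortical actin: normalized position across the local short-axis chord
    halfw <- b * sqrt(pmax(1 - (u / a)^2, 0))
    xn <- ifelse(halfw > 0, (v / halfw + 1) / 2, 0.5)
    edge <- inside & (xn <= 0.10 | xn >= 0.90)
    actin <- inside * (1 - f) + edge * (5 * f)
    arr[rows, cols, "actin"] <- arr[rows, cols, "actin"] + actin
    arr[rows, cols, "dapi"] <- arr[rows, cols, "dapi"] + in_nuc
    if (pos[i])
      arr[rows, cols, "ki67"] <- arr[rows, cols, "ki67"] + in_nuc
    # GM130 blob: rotate the apical direction by the polarity angle
    ang <- spec$golgi_angles[i] * pi / 180 * golgi_side[i]
    gdir <- c(cos(ang) * sv[1] - sin(ang) * sv[2],
              sin(ang) * sv[1] + cos(ang) * sv[2])
    gx <- cx + r_g * gdir[1]; gy <- cy + r_g * gdir[2]
    arr[, , "gm130"] <- paint_disk(arr[, , "gm130"], gy, gx, r_blob, 1)
    cells[[i]] <- data.frame(
      cell = i, x = cx - 1, y = cy - 1, theta = theta[i],
      semi_long_px = a, semi_short_px = b,
      apical_x = sv[1], apical_y = sv[2],
      golgi_angle = spec$golgi_angles[i],
      gm130_x = gx - 1, gm130_y = gy - 1,
      ki67_positive = pos[i],
      profile_x1 = cx - 1 + b * sv[1], profile_y1 = cy - 1 + b * sv[2],
      profile_x2 = cx - 1 - b * sv[1], profile_y2 = cy - 1 - b * sv[2])
  }
  if (spec$noise_sd > 0)
    arr <- with_seed(spec$seed + 1L,
                     arr + stats::rnorm(length(arr), sd = spec$noise_sd))
  truth <- ground_truth(
    list(n_cells = n, ki67_fraction = spec$ki67_fraction,
         n_ki67_positive = sum(pos),
         true_ki67_fraction = sum(pos) / n,
         junctional_fraction = f,
         expected_junctional_score = 0.2 + 0.8 * f,
         pixel_size = px, noise_sd = spec$noise_sd,
         cells = do.call(rbind, cells)),
    seed = spec$seed, generator = "generate_morphology_image")
  stack <- image_stack(arr, pixel_size = px, plane_type = "channel",
                       plane_names = ch,
                       metadata = list(generator = "generate_morphology_image",
                                       seed = spec$seed))
  list(stack = stack, truth = truth)
}

#' Default duplicate-spot cytokine array layout
#'
#' Builds a membrane layout in the style of sandwich antibody arrays:
#' each analyte printed as a horizontal duplicate spot pair, plus duplicate
#' positive-control "reference" spots (the loading/protein-content
#' reference) in the top corners and duplicate negative-control spots in
#' the bottom-right corner.
#'
#' @param cytokines character vector of analyte names.
#' @param n_cols spot-grid columns (default 10).
#' @param pitch spot pitch, px.
#' @param origin grid origin (x, y), px, 0-based.
#' @param spot_radius spot radius, px.
#' @return object of class \code{array_layout}: data.frame of spots
#'   (\code{name}, \code{grid_row}, \code{grid_col}, \code{type}) plus grid
#'   geometry attributes.
#' @export
cytokine_array_layout <- function(cytokines = paste0("CK", 1:12),
                                  n_cols = 10, pitch = 24,
                                  origin = c(30, 30), spot_radius = 7) {
  n <- length(cytokines)
  spots <- data.frame(
    name = rep(cytokines, each = 2L),
    type = "analyte",
    dup = rep(1:2, times = n))
  # duplicate pairs packed left-to-right, two grid columns per analyte
  pair <- rep(seq_len(n), each = 2L) - 1L
  ncol_pairs <- max(1L, n_cols %/% 2L)
  spots$grid_row <- pair %/% ncol_pairs + 2L      # row 1 reserved for controls
  spots$grid_col <- (pair %% ncol_pairs) * 2L + spots$dup
  ctrl <- data.frame(
    name = c("REF", "REF", "NEG", "NEG"),
    type = c("reference", "reference", "negative", "negative"),
    dup = c(1L, 2L, 1L, 2L),
    grid_row = 1L,
    grid_col = c(1L, 2L, n_cols - 1L, n_cols))
  layout <- rbind(spots, ctrl)
  key <- paste(layout$grid_row, layout$grid_col)
  if (anyDuplicated(key))
    stop("layout has duplicate grid coordinates")
  structure(layout, pitch = pitch, origin = origin,
            spot_radius = spot_radius, class = c("array_layout", "data.frame"))
}

# Spot centers in 0-based px (x = col, y = row) for a layout.
layout_centers <- function(layout) {
  o <- attr(layout, "origin"); p <- attr(layout, "pitch")
  data.frame(x = o[1] + (layout$grid_col - 1L) * p,
             y = o[2] + (layout$grid_row - 1L) * p)
}

#' Render a synthetic duplicate-membrane cytokine array experiment
#'
#' Renders two membranes from one layout: a control membrane (EV, the
#' empty-vector secretion baseline) and a test membrane whose
#' background-subtracted analyte densities realize the requested fold
#' changes. Reference spots carry the same underlying density on both
#' membranes; per-membrane exposure factors multiply everything on a
#' membrane (spots and background alike), which the cross-membrane
#' normalization must cancel.
#'
#' @param layout an \code{\link{cytokine_array_layout}}.
#' @param fold_changes named numeric vector, analyte name -> fold change of
#'   the test membrane relative to control; analytes not named get fold 1.
#' @param seed integer RNG seed (used for per-analyte baseline densities and
#'   noise).
#' @param noise_sd additive Gaussian pixel noise sd, a.u.
#' @param base_density mean baseline analyte density above background, a.u.
#' @param background_level membrane background, a.u.
#' @param reference_density reference-spot density above background, a.u.
#' @param exposure length-2 numeric, exposure multipliers of the (control,
#'   test) membranes.
#' @param image_size image side, px.
#' @return list with \code{stack} (2-plane channel stack, planes "ev" and
#'   "mutant") and \code{truth} (per-analyte densities and the expected
#'   normalized secretion, which equals the requested fold).
#' @export
generate_cytokine_array <- function(layout, fold_changes = numeric(),
                                    seed = 1L, noise_sd = 0,
                                    base_density = 0.6,
                                    background_level = 0.08,
                                    reference_density = 1,
                                    exposure = c(1, 1),
                                    image_size = 280) {
  stopifnot(inherits(layout, "array_layout"))
  if (anyDuplicated(paste(layout$grid_row, layout$grid_col)))
    stop("layout has duplicate grid coordinates")
  analytes <- unique(layout$name[layout$type == "analyte"])
  if (length(analytes) < 1L) stop("layout defines no analyte spots")
  if (length(fold_changes) && is.null(names(fold_changes)))
    stop("`fold_changes` must be named by analyte")
  unknown <- setdiff(names(fold_changes), analytes)
  if (length(unknown))
    stop("fold_changes name(s) not in layout: ", paste(unknown, collapse = ", "))
  folds <- stats::setNames(rep(1, length(analytes)), analytes)
  folds[names(fold_changes)] <- fold_changes
  base <- with_seed(seed, stats::setNames(
    base_density * stats::runif(length(analytes), 0.6, 1.4), analytes))
  ctr <- layout_centers(layout)
  rs <- attr(layout, "spot_radius")

  render <- function(dens_map, expo) {
    img <- matrix(background_level * expo, image_size, image_size)
    for (j in seq_len(nrow(layout))) {
      dens <- switch(layout$type[j],
                     analyte = dens_map[[layout$name[j]]],
                     reference = reference_density,
                     negative = 0)
      img <- paint_disk(img, ctr$y[j] + 1, ctr$x[j] + 1, rs, dens * expo)
    }
    img
  }
  ev_img <- render(as.list(base), exposure[1])
  mut_img <- render(as.list(base * folds), exposure[2])
  arr <- array(c(ev_img, mut_img), dim = c(image_size, image_size, 2L),
               dimnames = list(NULL, NULL, c("ev", "mutant")))
  if (noise_sd > 0)
    arr <- with_seed(seed + 1L,
                     arr + stats::rnorm(length(arr), sd = noise_sd))
  truth <- ground_truth(
    list(analytes = analytes, folds = as.list(folds),
         ev_density = as.list(base),
         mutant_density = as.list(base * folds),
         expected_normalized = as.list(folds),
         background_level = background_level,
         reference_density = reference_density,
         exposure = exposure, noise_sd = noise_sd),
    seed = seed, generator = "generate_cytokine_array")
  stack <- image_stack(arr, pixel_size = 1, plane_type = "channel",
                       plane_names = c("ev", "mutant"),
                       metadata = list(generator = "generate_cytokine_array",
                                       seed = seed))
  list(stack = stack, truth = truth)
}

#' Generate a synthetic Hertzian indentation curve
#'
#' Samples the spherical-indenter Hertz force law at a known Young's modulus
#' on an even depth grid, optionally adding Gaussian force noise — the
#' forward model whose inversion is \code{\link{fit_hertz}}.
#'
#' @param E true Young's modulus, Pa (> 0).
#' @param probe_radius probe radius, um (default 50).
#' @param poisson Poisson ratio in [0, 0.5]; default 0.5 (incompressible).
#' @param depth_max maximum indentation depth, um (default 10).
#' @param n_samples samples on the loading branch.
#' @param noise_sd Gaussian force noise sd, N.
#' @param seed integer RNG seed.
#' @return list with \code{curve} (an \code{\link{indentation_curve}}) and
#'   \code{truth} (a \code{\link{ground_truth}}).
#' @export
generate_indentation_curve <- function(E, probe_radius = 50, poisson = 0.5,
                                       depth_max = 10, n_samples = 100L,
                                       noise_sd = 0, seed = 1L) {
  fail_field(E <= 0, "E", "must be > 0 Pa")
  fail_field(depth_max <= 0, "depth_max", "must be > 0 um")
  fail_field(poisson < 0 || poisson > 0.5, "poisson", "must be in [0, 0.5]")
  fail_field(noise_sd < 0, "noise_sd", "must be >= 0")
  depth <- seq(0, depth_max, length.out = n_samples)
  force <- hertz_prefactor(E, probe_radius, poisson) * (depth * 1e-6)^1.5
  if (noise_sd > 0)
    force <- with_seed(seed, force + stats::rnorm(n_samples, sd = noise_sd))
  curve <- indentation_curve(depth, force, probe_radius, poisson,
                             metadata = list(speed_um_s = 5,
                                             instrument = "synthetic"))
  truth <- ground_truth(
    list(E = E, probe_radius = probe_radius, poisson = poisson,
         depth_max = depth_max, n_samples = n_samples, noise_sd = noise_sd),
    seed = seed, generator = "generate_indentation_curve")
  list(curve = curve, truth = truth)
}
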