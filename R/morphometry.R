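#' Normalized line profile through a cell
#'
#' Intensity samples along a line drawn through the short axis of a cell
#' (through the nucleus), with position and intensity each normalized to
#' their own maxima — the input of the junctional (cortical) localization
#' score.
#'
#' @param position sample positions; normalized internally to [0, 1] by the
#'   maximum.
#' @param intensity intensities; normalized internally to a maximum of 1.
#' @param length_um raw profile length, um (optional bookkeeping).
#' @param id cell/vessel identifier (optional).
#' @return object of class \code{line_profile}.
#' @export
line_profile <- function(position, intensity, length_um = NA_real_,
                         id = NA_character_) {
  if (length(position) != length(intensity))
    stop("`position` and `intensity` must have the same length")
  if (length(position) < 10L) stop("a line profile needs >= 10 samples")
  if (any(diff(position) <= 0)) stop("`position` must be strictly increasing")
  if (max(intensity) <= 0) stop("profile has no positive intensity")
  pos <- (position - min(position))
  pos <- pos / max(pos)
  structure(list(position = pos, intensity = intensity / max(intensity),
                 length_um = length_um, id = id),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples, length %.4g um\n",
              length(x$position), x$length_um))
  invisible(x)
}

#' Junctional (cortical) actin localization score
#'
#' The edge-area fraction of a normalized short-axis intensity profile:
#' \deqn{\mathrm{score} = \frac{A_{0-10\%} + A_{90-100\%}}{A_{Total}}}
#' with areas computed by trapezoidal integration on the normalized axes and
#' the edge regions taken inclusively as x <= 0.10 and x >= 0.90. A uniform
#' profile scores 0.2 (the edges hold 20% of the support); a profile with
#' all mass at the cell borders scores 1. The score is invariant to positive
#' scaling of the intensities and to reversing the profile.
#'
#' @param profile a \code{\link{line_profile}}.
#' @return score in [0, 1].
#' @export
junctional_actin_score <- function(profile) {
  stopifnot(inherits(profile, "line_profile"))
  pr <- insert_breaks(profile$position, profile$intensity, c(0.10, 0.90))
  x <- pr$x; y <- pr$y
  total <- trapz_int(x, y)
  if (total <= 0) stop("zero total area under the profile")
  left <- x <= 0.10; right <- x >= 0.90
  (trapz_int(x[left], y[left]) + trapz_int(x[right], y[right])) / total
}

#' Golgi polarity angle of one cell
#'
#' Angle between the nucleus-to-Golgi vector and the cell's apical
#' direction, in degrees: 0 means the Golgi sits apically (toward the
#' lumen), 180 basally. Computed as the arccosine of the normalized dot
#' product, so it is unsigned and always in [0, 180], and invariant to
#' rigid rotations of all inputs.
#'
#' @param nucleus_centroid numeric (x, y), px.
#' @param gm130_centroid numeric (x, y), px; must differ from the nucleus
#'   centroid.
#' @param apical_direction numeric (x, y), non-zero vector toward the
#'   apical (lumen) side.
#' @return list with \code{angle} (degrees), the two centroids and the
#'   normalized apical direction, of class \code{polarity_record}.
#' @export
golgi_polarity_angle <- function(nucleus_centroid, gm130_centroid,
                                 apical_direction) {
  v <- as.numeric(gm130_centroid) - as.numeric(nucleus_centroid)
  if (sqrt(sum(v^2)) < 1e-12)
    stop("undefined angle: nucleus and GM130 centroids coincide")
  a <- as.numeric(apical_direction)
  if (sqrt(sum(a^2)) < 1e-12) stop("`apical_direction` must be non-zero")
  cosang <- sum(v * a) / (sqrt(sum(v^2)) * sqrt(sum(a^2)))
  angle <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  structure(list(nucleus_centroid = as.numeric(nucleus_centroid),
                 gm130_centroid = as.numeric(gm130_centroid),
                 apical_direction = a / sqrt(sum(a^2)),
                 angle = angle),
            class = "polarity_record")
}

#' @export
print.polarity_record <- function(x, ...) {
  cat(sprintf("<polarity_record> %.2f deg\n", x$angle))
  invisible(x)
}

#' Fraction of Ki67-positive nuclei
#'
#' DAPI channel is thresholded (Otsu by default), connected components above
#' a minimum area are nuclei (optionally excluding border-touching ones),
#' and a nucleus is Ki67-positive when its mean Ki67 intensity exceeds the
#' positivity threshold. The default threshold is data-driven: halfway from
#' the Ki67 channel's median to its 99.9th percentile, which lands between
#' the negative and positive nuclear populations without assuming absolute
#' units.
#'
#' @param dapi DAPI channel: matrix, or a channel \code{image_stack} (the
#'   \code{"dapi"} plane is used).
#' @param ki67 Ki67 channel: matrix, or taken from the same stack.
#' @param config list: \code{min_area} (px, default 20),
#'   \code{exclude_border} (default TRUE), \code{dapi_threshold} (NULL =
#'   Otsu), \code{ki67_threshold} (NULL = the data-driven rule),
#'   \code{criterion} — \code{"nuclear_mean"} (default) or
#'   \code{"pixel_overlap"} (positive when >50\% of nuclear pixels exceed
#'   the threshold).
#' @return list with \code{positive}, \code{total}, \code{fraction}, the
#'   per-nucleus table, and the thresholds used.
#' @export
ki67_fraction <- function(dapi, ki67 = NULL, config = list()) {
  if (inherits(dapi, "image_stack")) {
    st <- dapi
    dapi <- get_plane(st, "dapi")
    if (is.null(ki67)) ki67 <- get_plane(st, "ki67")
  }
  stopifnot(is.matrix(dapi), is.matrix(ki67),
            all(dim(dapi) == dim(ki67)))
  cfg <- utils::modifyList(
    list(min_area = 20L, exclude_border = TRUE, dapi_threshold = NULL,
         ki67_threshold = NULL, criterion = "nuclear_mean"), config)
  rng <- range(dapi)
  thr <- cfg$dapi_threshold
  if (is.null(thr)) {
    norm <- if (diff(rng) > 0) (dapi - rng[1]) / diff(rng) else dapi * 0
    thr <- rng[1] + EBImage::otsu(EBImage::Image(norm)) * diff(rng)
  }
  lab <- EBImage::bwlabel(EBImage::Image((dapi > thr) * 1))
  labm <- matrix(as.integer(lab), nrow(dapi))
  nlab <- max(labm)
  if (nlab < 1L) stop("no nuclei detected in the DAPI channel")
  areas <- tabulate(labm[labm > 0L], nbins = nlab)
  keep <- areas >= cfg$min_area
  if (cfg$exclude_border) {
    border_ids <- unique(c(labm[1L, ], labm[nrow(labm), ],
                           labm[, 1L], labm[, ncol(labm)]))
    keep[setdiff(border_ids, 0L)] <- FALSE
  }
  ids <- which(keep)
  if (!length(ids)) stop("no nuclei passed the area/border filters")
  kthr <- cfg$ki67_threshold
  if (is.null(kthr)) {
    med <- stats::median(ki67)
    kthr <- med + 0.5 * (stats::quantile(ki67, 0.999, names = FALSE) - med)
  }
  per <- lapply(ids, function(id) {
    sel <- labm == id
    mu <- mean(ki67[sel])
    ov <- mean(ki67[sel] > kthr)
    data.frame(nucleus = id, area_px = sum(sel), ki67_mean = mu,
               ki67_overlap = ov,
               positive = switch(cfg$criterion,
                                 nuclear_mean = mu > kthr,
                                 pixel_overlap = ov > 0.5,
                                 stop("unknown `criterion`")))
  })
  tab <- do.call(rbind, per)
  list(positive = sum(tab$positive), total = nrow(tab),
       fraction = mean(tab$positive), nuclei = tab,
       dapi_threshold = thr, ki67_threshold = kthr)
}

#' Mean vessel diameter from a segmented frame
#'
#' Width of the vessel mask perpendicular to its axis at \code{n_locations}
#' evenly spaced stations; the mean of the station widths is reported as the
#' diameter, as in manual width measurements at distinct locations along a
#' vessel.
#'
#' @param image a frame matrix, \code{image_stack}, or a
#'   \code{\link{vessel_geometry}} (skips segmentation).
#' @param n_locations number of measurement stations (default 3).
#' @param pixel_size um/px, for bare matrices.
#' @param ... passed to \code{\link{segment_vessel}}.
#' @return list with \code{diameter_um} (mean) and \code{stations} (per-
#'   station widths, um).
#' @export
measure_vessel_diameter <- function(image, n_locations = 3L,
                                    pixel_size = NULL, ...) {
  geom <- if (inherits(image, "vessel_geometry")) image
          else segment_vessel(image, pixel_size = pixel_size,
                              n_stations = n_locations, ...)
  w <- mask_width_stations(geom$mask, geom$axis, geom$pixel_size, n_locations)
  list(diameter_um = mean(w), stations = w)
}

#' Extract a normalized line profile from an image
#'
#' Samples intensity along a segment (bilinear interpolation), averaging
#' across \code{width_px} parallel offsets perpendicular to the segment,
#' then normalizes position and intensity to their maxima.
#'
#' @param image matrix or \code{image_stack} (with \code{channel}).
#' @param endpoints list or 2x2 matrix of the segment endpoints, 0-based px
#'   \code{(x, y)} rows.
#' @param width_px odd number of parallel sampling lines (default 1).
#' @param channel channel name/index when \code{image} is a stack.
#' @param id identifier stored on the profile.
#' @return a \code{\link{line_profile}}.
#' @export
extract_line_profile <- function(image, endpoints, width_px = 1L,
                                 channel = NULL, id = NA_character_) {
  if (inherits(image, "image_stack"))
    image <- get_plane(image, if (is.null(channel)) 1L else channel)
  ep <- if (is.list(endpoints)) rbind(endpoints[[1]], endpoints[[2]])
        else as.matrix(endpoints)
  stopifnot(all(dim(ep) == c(2L, 2L)))
  p1 <- ep[1L, ]; p2 <- ep[2L, ]
  len <- sqrt(sum((p2 - p1)^2))
  if (len < 1e-9) stop("zero-length profile segment")
  n <- max(10L, ceiling(len) + 1L)
  tt <- seq(0, 1, length.out = n)
  dirv <- (p2 - p1) / len
  perp <- c(-dirv[2], dirv[1])
  offs <- seq_len(width_px) - (width_px + 1) / 2
  acc <- numeric(n)
  for (o in offs) {
    xs <- p1[1] + tt * len * dirv[1] + o * perp[1]
    ys <- p1[2] + tt * len * dirv[2] + o * perp[2]
    acc <- acc + bilinear_sample(image, xs, ys)
  }
  line_profile(tt * len, acc / length(offs), length_um = len, id = id)
}

# Bilinear sampling of matrix `img` at 0-based (x = col, y = row) points;
# clamped to the image border.
bilinear_sample <- function(img, x, y) {
  x <- pmin(pmax(x, 0), ncol(img) - 1L)
  y <- pmin(pmax(y, 0), nrow(img) - 1L)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, ncol(img) - 1L); y1 <- pmin(y0 + 1, nrow(img) - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]; i01 <- img[cbind(y0 + 1, x1 + 1)]
  i10 <- img[cbind(y1 + 1, x0 + 1)]; i11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Integrated density of a junctional marker channel
#'
#' Background subtraction, Otsu binarization, and integrated pixel density:
#' the sum of background-subtracted intensities inside the binary mask (the
#' mask pixel count is also reported). Used for junctional VE-cadherin
#' quantification.
#'
#' @param image matrix or \code{image_stack} (with \code{channel}).
#' @param config list: \code{background} — \code{"rolling_ball"} (default;
#'   morphological-opening background with \code{ball_radius} px, the
#'   grayscale analogue of a rolling ball) or \code{"constant"} (subtract
#'   \code{background_value}, default the image minimum).
#' @param channel channel selector for stacks.
#' @return list with \code{integrated_density}, \code{mask_area_px},
#'   \code{threshold}, and \code{degenerate} (TRUE for a blank image, which
#'   returns zero density with a warning).
#' @export
vecadherin_integrated_density <- function(image, config = list(),
                                          channel = NULL) {
  if (inherits(image, "image_stack"))
    image <- get_plane(image, if (is.null(channel)) 1L else channel)
  cfg <- utils::modifyList(
    list(background = "rolling_ball", ball_radius = 25L,
         background_value = NULL), config)
  bgsub <- switch(cfg$background,
    rolling_ball = {
      rng <- range(image)
      sc <- if (diff(rng) > 0) diff(rng) else 1
      norm <- (image - rng[1]) / sc
      br <- EBImage::makeBrush(2L * cfg$ball_radius + 1L, shape = "disc")
      bg <- EBImage::opening(EBImage::Image(norm), br)
      (norm - as.matrix(bg)) * sc
    },
    constant = {
      bv <- if (is.null(cfg$background_value)) min(image) else cfg$background_value
      image - bv
    },
    stop("config$background must be 'rolling_ball' or 'constant'"))
  bgsub[bgsub < 0] <- 0
  rng <- range(bgsub)
  if (diff(rng) <= 0) {
    warning("blank image: Otsu threshold degenerate, returning zero density")
    return(list(integrated_density = 0, mask_area_px = 0L,
                threshold = NA_real_, degenerate = TRUE))
  }
  thr <- rng[1] + EBImage::otsu(EBImage::Image((bgsub - rng[1]) / diff(rng))) *
    diff(rng)
  mask <- bgsub > thr
  list(integrated_density = sum(bgsub[mask]), mask_area_px = sum(mask),
       threshold = thr, degenerate = FALSE)
}

#' Count manually annotated sprouts per vessel
#'
#' Tallies sprout point annotations by vessel, splitting counts by side of
#' the vessel axis (sign of the cross product with the axis direction).
#' Points within \code{merge_radius} of each other (single-linkage) can be
#' merged into one sprout to absorb duplicate clicks.
#'
#' @param annotations data.frame with columns \code{x}, \code{y} (0-based
#'   px) and \code{vessel} (ID).
#' @param axes named list, vessel ID -> \code{list(center, direction)} axis
#'   (as in \code{\link{vessel_geometry}}).
#' @param merge_radius px; 0 (default) disables deduplication.
#' @return list with \code{counts} (data.frame: vessel, n, left, right) and
#'   \code{orphans} (rows whose vessel ID has no axis).
#' @export
count_sprouts <- function(annotations, axes, merge_radius = 0) {
  stopifnot(all(c("x", "y", "vessel") %in% names(annotations)))
  known <- annotations$vessel %in% names(axes)
  orphans <- annotations[!known, , drop = FALSE]
  ann <- annotations[known, , drop = FALSE]
  res <- lapply(names(axes), function(vid) {
    pts <- ann[ann$vessel == vid, c("x", "y"), drop = FALSE]
    if (nrow(pts) > 1L && merge_radius > 0) {
      dl <- stats::hclust(stats::dist(pts), method = "single")
      cl <- stats::cutree(dl, h = merge_radius)
      pts <- do.call(rbind, lapply(split(pts, cl), colMeans))
      pts <- as.data.frame(pts)
    }
    if (!nrow(pts))
      return(data.frame(vessel = vid, n = 0L, left = 0L, right = 0L))
    ax <- axes[[vid]]
    rel_x <- pts$x - ax$center[1]; rel_y <- pts$y - ax$center[2]
    cross <- ax$direction[1] * rel_y - ax$direction[2] * rel_x
    data.frame(vessel = vid, n = nrow(pts),
               left = sum(cross < 0), right = sum(cross >= 0))
  })
  list(counts = do.call(rbind, res), orphans = orphans)
}
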