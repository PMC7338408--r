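#' Calibrated image stack
#'
#' Lightweight container for calibrated intensity data. The pixel data live in
#' a 3D array indexed \code{[row, col, plane]}; planes are either time points
#' (a time-lapse of one channel) or named channels (a multichannel snapshot).
#' Spatial calibration is carried as micrometres per pixel and, for
#' time-lapses, the frame interval in seconds.
#'
#' @param data numeric matrix or 3D array, \code{[row, col, plane]}.
#' @param pixel_size pixel size in micrometres per pixel (> 0).
#' @param frame_interval frame interval in seconds for time-lapse stacks, or
#'   \code{NA} for snapshots.
#' @param plane_type \code{"time"} or \code{"channel"}.
#' @param plane_names optional character vector naming the planes (channel
#'   names, required when \code{plane_type = "channel"}).
#' @param metadata optional named list of extra metadata (seeds, generator
#'   parameters); stored verbatim.
#' @return An object of class \code{image_stack}.
#' @export
image_stack <- function(data, pixel_size, frame_interval = NA_real_,
                        plane_type = c("time", "channel"),
                        plane_names = NULL, metadata = list()) {
  plane_type <- match.arg(plane_type)
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L)
    stop("`data` must be a matrix or a 3D array [row, col, plane]")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/px)")
  if (plane_type == "channel" && is.null(plane_names))
    stop("channel stacks need `plane_names`")
  if (!is.null(plane_names) && length(plane_names) != dim(data)[3L])
    stop("`plane_names` length must match the number of planes")
  structure(
    list(data = data, pixel_size = pixel_size,
         frame_interval = frame_interval, plane_type = plane_type,
         plane_names = plane_names, metadata = metadata),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d px, %d %s plane(s)\n",
              d[1], d[2], d[3], x$plane_type))
  cat(sprintf("  pixel size %.4g um/px", x$pixel_size))
  if (!is.na(x$frame_interval))
    cat(sprintf(", frame interval %.4g s", x$frame_interval))
  cat("\n")
  if (!is.null(x$plane_names))
    cat("  planes:", paste(x$plane_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Number of planes in a stack
#' @param x an \code{image_stack}.
#' @return integer plane count.
#' @export
n_planes <- function(x) dim(x$data)[3L]

#' Extract one plane of a stack
#'
#' @param x an \code{image_stack}.
#' @param i plane index or (for channel stacks) channel name.
#' @return numeric matrix.
#' @export
get_plane <- function(x, i) {
  stopifnot(inherits(x, "image_stack"))
  if (is.character(i)) {
    if (is.null(x$plane_names)) stop("stack has no named planes")
    j <- match(i, x$plane_names)
    if (is.na(j)) stop("no plane named '", i, "'")
    i <- j
  }
  x$data[, , i]
}

#' Times (s) of the frames of a time-lapse stack
#' @param x an \code{image_stack} with \code{plane_type = "time"}.
#' @return numeric vector of acquisition times, starting at 0.
#' @export
frame_times <- function(x) {
  stopifnot(inherits(x, "image_stack"), x$plane_type == "time")
  (seq_len(n_planes(x)) - 1L) * x$frame_interval
}

#' Write an image stack to a multi-page TIFF
#'
#' Pixel data are scaled to \code{[0, 1]} by \code{scale_max} (32-bit float
#' pages, so fractional intensities survive a round trip); calibration and
#' metadata travel in a JSON side-car at \code{<path>.meta.json}.
#'
#' @param x an \code{image_stack}.
#' @param path output file path.
#' @param scale_max intensities are divided by this before writing; defaults
#'   to the stack maximum (or 1 for a non-positive maximum).
#' @return \code{path}, invisibly.
#' @export
write_stack_tiff <- function(x, path, scale_max = NULL) {
  stopifnot(inherits(x, "image_stack"))
  if (is.null(scale_max)) scale_max <- max(x$data, 1e-12)
  jsonlite::write_json(
    list(pixel_size = x$pixel_size, frame_interval = x$frame_interval,
         plane_type = x$plane_type, plane_names = x$plane_names,
         scale_max = scale_max, metadata = x$metadata),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA,
    null = "null", force = TRUE)
  pages <- lapply(seq_len(n_planes(x)), function(i) x$data[, , i] / scale_max)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read an image stack written by \code{write_stack_tiff}
#'
#' @param path TIFF file path.
#' @return An \code{image_stack}; calibration is recovered from the JSON
#'   side-car when present, otherwise \code{pixel_size = 1}.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  if (file.exists(paste0(path, ".meta.json")))
    meta <- tryCatch(jsonlite::fromJSON(paste0(path, ".meta.json")),
                     error = function(e) NULL)
  scale_max <- if (!is.null(meta$scale_max)) meta$scale_max else 1
  arr <- array(0, dim = c(dim(pages[[1L]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]   # collapse accidental RGB
    arr[, , i] <- p * scale_max
  }
  image_stack(
    arr,
    pixel_size = if (!is.null(meta$pixel_size)) meta$pixel_size else 1,
    frame_interval = if (!is.null(meta$frame_interval) &&
                         length(meta$frame_interval))
      meta$frame_interval else NA_real_,
    plane_type = if (!is.null(meta$plane_type)) meta$plane_type else "time",
    plane_names = meta$plane_names,
    metadata = if (!is.null(meta$metadata)) meta$metadata else list())
}

#' Ground-truth record for a synthetic dataset
#'
#' Every synthetic generator returns one of these alongside its rendered
#' data: a named list of every generating parameter, the seed, and a
#' generator version tag, so estimator-recovery tests can compare against
#' construction.
#'
#' @param params named list of true generating parameters.
#' @param seed integer seed used for the render.
#' @param generator name of the generating function.
#' @return An object of class \code{ground_truth}.
#' @export
ground_truth <- function(params, seed, generator) {
  stopifnot(is.list(params), !is.null(names(params)))
  structure(list(params = params, seed = seed, generator = generator,
                 version = "ductflux-synth-1"),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s (seed %s)\n", x$generator,
              format(x$seed)))
  scal <- vapply(x$params, function(p)
    is.atomic(p) && length(p) == 1L, logical(1))
  for (nm in names(x$params)[scal])
    cat(sprintf("  %s = %s\n", nm, format(x$params[[nm]])))
  if (any(!scal))
    cat("  [+", paste(names(x$params)[!scal], collapse = ", "), "]\n")
  invisible(x)
}

#' Write a ground-truth record as a JSON side-car
#' @param truth a \code{ground_truth}.
#' @param path output path (.json).
#' @return \code{path}, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", force = TRUE)
  invisible(path)
}
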