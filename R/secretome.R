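#' Densitometry of one cytokine-array membrane
#'
#' Per-spot density is the mean intensity inside a fixed-radius disk at each
#' layout position (mean, not sum, so spot-size jitter is tolerated);
#' duplicate spots are averaged per analyte. The membrane background is the
#' mean of the negative-control spots and the protein-content reference the
#' mean of the reference spots. Registration refines the nominal grid by the
#' mean centroid displacement of the reference spots; a membrane scanned
#' upside down is handled by the \code{rotated_180} layout flag.
#'
#' @param image matrix or \code{image_stack} (with \code{channel} selecting
#'   the membrane plane).
#' @param layout an \code{\link{cytokine_array_layout}}.
#' @param channel channel selector for stacks.
#' @param rotated_180 logical; flip the image before quantification.
#' @param refine_registration logical; centroid-refine the grid from the
#'   reference spots (default TRUE).
#' @param search_radius px, centroid search window for registration.
#' @return object of class \code{cytokine_array}: \code{densities} (named
#'   list, analyte -> duplicate spot densities), \code{means} (named vector
#'   of duplicate-averaged densities), \code{background},
#'   \code{reference}, and provenance fields.
#' @export
quantify_array <- function(image, layout, channel = NULL,
                           rotated_180 = FALSE, refine_registration = TRUE,
                           search_radius = 10) {
  if (inherits(image, "image_stack"))
    image <- get_plane(image, if (is.null(channel)) 1L else channel)
  stopifnot(inherits(layout, "array_layout"))
  if (rotated_180)
    image <- image[rev(seq_len(nrow(image))), rev(seq_len(ncol(image)))]
  ctr <- layout_centers(layout)
  rs <- attr(layout, "spot_radius")
  shift <- c(0, 0)
  if (refine_registration) {
    ref <- which(layout$type == "reference")
    if (!length(ref)) stop("registration error: layout has no reference spots")
    disp <- vapply(ref, function(j) {
      spot_centroid(image, ctr$x[j], ctr$y[j], search_radius)
    }, numeric(2))
    if (anyNA(disp))
      stop("registration error: reference spots not detected near their nominal positions")
    shift <- rowMeans(disp) - c(mean(ctr$x[ref]), mean(ctr$y[ref]))
  }
  dens <- vapply(seq_len(nrow(layout)), function(j)
    disk_mean(image, ctr$x[j] + shift[1], ctr$y[j] + shift[2], rs),
    numeric(1))
  analytes <- unique(layout$name[layout$type == "analyte"])
  dlist <- lapply(analytes, function(a)
    dens[layout$name == a & layout$type == "analyte"])
  names(dlist) <- analytes
  structure(list(
    densities = dlist,
    means = vapply(dlist, mean, numeric(1)),
    background = mean(dens[layout$type == "negative"]),
    reference = mean(dens[layout$type == "reference"]),
    shift = shift, layout_spots = nrow(layout)),
    class = "cytokine_array")
}

#' @export
print.cytokine_array <- function(x, ...) {
  cat(sprintf("<cytokine_array> %d analytes; background %.4g, reference %.4g\n",
              length(x$means), x$background, x$reference))
  invisible(x)
}

# Mean intensity in a disk around 0-based (x, y).
disk_mean <- function(img, x, y, radius) {
  row <- y + 1; col <- x + 1
  r0 <- max(1L, floor(row - radius)); r1 <- min(nrow(img), ceiling(row + radius))
  c0 <- max(1L, floor(col - radius)); c1 <- min(ncol(img), ceiling(col + radius))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, "+")
  sel <- d2 <= radius^2
  mean(img[rr, cc][sel])
}

# Intensity-weighted centroid in a search window; NA when the window has no
# contrast above its median (spot absent).
spot_centroid <- function(img, x, y, radius) {
  row <- y + 1; col <- x + 1
  r0 <- max(1L, floor(row - radius)); r1 <- min(nrow(img), ceiling(row + radius))
  c0 <- max(1L, floor(col - radius)); c1 <- min(ncol(img), ceiling(col + radius))
  rr <- r0:r1; cc <- c0:c1
  w <- img[rr, cc] - stats::median(img[rr, cc])
  w[w < 0] <- 0
  if (sum(w) <= 0) return(c(NA_real_, NA_real_))
  c(sum(t(w) * cc) / sum(w) - 1, sum(w * rr) / sum(w) - 1)
}

#' Cross-membrane normalization of cytokine secretion
#'
#' Normalizes a test membrane against the empty-vector (EV) control
#' membrane: for each analyte i,
#' \deqn{\frac{i_{test} - Bg_{test}}{i_{EV} - Bg_{EV}} \times
#'       \frac{Ref_{EV}}{Ref_{test}}}
#' where Bg is each membrane's negative-control background and Ref its
#' protein-content reference, so exposure differences between membranes
#' cancel. Analytes whose EV signal does not exceed background are flagged
#' \code{NA} (undefined) rather than fabricated.
#'
#' @param mutant \code{cytokine_array} of the test (e.g. mutant-duct)
#'   membrane.
#' @param ev \code{cytokine_array} of the EV control membrane; must share
#'   the layout.
#' @return named numeric vector of relative secretion per analyte (NA where
#'   undefined), with attribute \code{"undefined"} listing flagged analytes.
#' @export
normalize_to_ev <- function(mutant, ev) {
  stopifnot(inherits(mutant, "cytokine_array"), inherits(ev, "cytokine_array"))
  if (!identical(names(mutant$means), names(ev$means)))
    stop("membranes were quantified with different layouts")
  denom <- ev$means - ev$background
  num <- mutant$means - mutant$background
  out <- (num / denom) * (ev$reference / mutant$reference)
  bad <- denom <= 0
  out[bad] <- NA_real_
  if (any(bad))
    warning("EV signal at or below background for: ",
            paste(names(out)[bad], collapse = ", "))
  attr(out, "undefined") <- names(out)[bad]
  out
}

#' Write raw and normalized array densities as tidy CSV
#'
#' @param mutant,ev quantified membranes (\code{cytokine_array}).
#' @param path output CSV path.
#' @return the tidy data.frame, invisibly.
#' @export
write_array_csv <- function(mutant, ev, path) {
  rel <- normalize_to_ev(mutant, ev)
  df <- data.frame(cytokine = names(ev$means),
                   ev_density = unname(ev$means),
                   mutant_density = unname(mutant$means),
                   ev_background = ev$background,
                   mutant_background = mutant$background,
                   ev_reference = ev$reference,
                   mutant_reference = mutant$reference,
                   relative_secretion = as.numeric(rel))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
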