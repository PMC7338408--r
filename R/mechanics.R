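#' Nanoindentation force-depth curve
#'
#' Loading-branch samples of a spherical nanoindentation measurement, as
#' produced by ferrule-top or AFM indenters on soft hydrogels. Depths are in
#' micrometres, forces in newtons; the probe radius and the assumed Poisson
#' ratio travel with the curve because the Hertz fit needs them.
#'
#' @param depth indentation depths, um; non-negative and non-decreasing on
#'   the loading branch.
#' @param force forces, N; same length as \code{depth}.
#' @param probe_radius spherical probe radius, um (default 50, i.e. a
#'   ~100 um diameter probe).
#' @param poisson Poisson ratio; 0.5 treats the gel as incompressible.
#' @param metadata optional list (displacement speed, instrument, ...).
#' @return An object of class \code{indentation_curve}.
#' @export
indentation_curve <- function(depth, force, probe_radius = 50, poisson = 0.5,
                              metadata = list()) {
  if (length(depth) != length(force))
    stop("`depth` and `force` must have the same length")
  if (any(depth < 0)) stop("`depth` must be non-negative")
  if (is.unsorted(depth)) stop("`depth` must be non-decreasing (loading branch)")
  if (probe_radius <= 0) stop("`probe_radius` must be > 0 (um)")
  if (poisson < 0 || poisson > 0.5) stop("`poisson` must be in [0, 0.5]")
  structure(list(depth = depth, force = force, probe_radius = probe_radius,
                 poisson = poisson, metadata = metadata),
            class = "indentation_curve")
}

#' @export
print.indentation_curve <- function(x, ...) {
  cat(sprintf(
    "<indentation_curve> %d samples, depth [0, %.3g] um, R = %.3g um, nu = %.3g\n",
    length(x$depth), max(x$depth), x$probe_radius, x$poisson))
  invisible(x)
}

# Hertz prefactor mapping E (Pa) to F = k * delta^{3/2} with delta in metres.
hertz_prefactor <- function(E, probe_radius_um, poisson) {
  (4 / 3) * (E / (1 - poisson^2)) * sqrt(probe_radius_um * 1e-6)
}

#' Fit the Hertzian contact model to an indentation curve
#'
#' Least-squares fit of the spherical-indenter Hertz relation
#' \deqn{F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}}
#' over the loading branch, returning the Young's modulus E. With
#' \code{fit_contact_point = FALSE} (the default) the model is linear in the
#' prefactor and solved in closed form; with co-fitting enabled, a
#' Levenberg-Marquardt fit of \code{(E, delta0)} handles exported curves
#' whose contact point is uncertain, replacing depth with
#' \code{pmax(depth - delta0, 0)}.
#'
#' @param curve an \code{indentation_curve}.
#' @param fit_contact_point logical; co-fit a contact-point offset.
#' @return list with \code{E} (Pa), \code{contact_offset} (um),
#'   \code{residual_norm} (N), \code{r_squared}, \code{n} samples used, and
#'   the fitted forces.
#' @export
fit_hertz <- function(curve, fit_contact_point = FALSE) {
  stopifnot(inherits(curve, "indentation_curve"))
  keep <- curve$depth >= 0
  d <- curve$depth[keep]; f <- curve$force[keep]
  if (length(d) < 10L) stop("need >= 10 loading samples to fit")
  x <- (d * 1e-6)^1.5
  if (!fit_contact_point) {
    k <- sum(x * f) / sum(x * x)                 # closed-form slope, no intercept
    offset <- 0
    fitted <- k * x
  } else {
    k0 <- sum(x * f) / sum(x * x)
    fit <- minpack.lm::nlsLM(
      f ~ k * (pmax(d - d0, 0) * 1e-6)^1.5,
      start = list(k = k0, d0 = 0),
      lower = c(0, -max(d) / 2), upper = c(Inf, max(d) / 2),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    k <- stats::coef(fit)[["k"]]; offset <- stats::coef(fit)[["d0"]]
    fitted <- stats::predict(fit)
  }
  E <- k / hertz_prefactor(1, curve$probe_radius, curve$poisson)
  if (!is.finite(E) || E <= 0)
    stop(sprintf("non-physical Hertz fit (E = %.4g Pa); residual norm %.4g N",
                 E, sqrt(sum((f - fitted)^2))))
  ss_res <- sum((f - fitted)^2)
  ss_tot <- sum((f - mean(f))^2)
  list(E = E, contact_offset = offset,
       residual_norm = sqrt(ss_res),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       n = length(d), fitted = fitted)
}

#' Summarize a set of Young's modulus fits
#'
#' @param E numeric vector of fitted moduli (Pa), one per measurement;
#'   at least two values.
#' @return list with \code{mean}, \code{sd} (sample standard deviation),
#'   \code{sem}, and \code{n}.
#' @export
summarize_stiffness <- function(E) {
  if (length(E) < 2L) stop("need >= 2 modulus fits to summarize")
  list(mean = mean(E), sd = stats::sd(E),
       sem = stats::sd(E) / sqrt(length(E)), n = length(E))
}

#' Read an indentation curve from CSV
#'
#' Expects columns \code{depth_um} and \code{force_n} (header required);
#' probe radius and Poisson ratio come from the arguments.
#'
#' @param path CSV path.
#' @inheritParams indentation_curve
#' @return an \code{indentation_curve}.
#' @export
read_indentation_csv <- function(path, probe_radius = 50, poisson = 0.5) {
  df <- utils::read.csv(path)
  need <- c("depth_um", "force_n")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  indentation_curve(df$depth_um, df$force_n, probe_radius, poisson)
}
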