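#' Transport domain for the two-channel device
#'
#' Describes the diffusion problem geometry for the microfluidic device: a
#' perfused vascular channel and a dead-ended duct channel (both cylindrical,
#' 160 um diameter by default) embedded in a collagen hydrogel, with the duct
#' channel a default 500 um from the vessel. All lengths are micrometres;
#' diffusivity is given in cm^2/s as is conventional for solutes.
#'
#' @param grid_spacing grid spacing h in um. Must resolve the smallest
#'   channel with at least 8 cells across its diameter.
#' @param extent domain extent in um. For the radial efflux solver this is
#'   the outer radius of the gel annulus; for the Cartesian gradient solver
#'   it is recycled to \code{c(width, height)} of the rectangle.
#' @param D solute diffusivity in the gel, cm^2/s. Default 4e-7 cm^2/s, an
#'   order-of-magnitude literature value for 70 kDa dextran in collagen
#'   (configurable; see the methods vignette).
#' @param vascular,duct lists \code{list(center = c(x, y), diameter)} in um
#'   placing the two channels in the cross-sectional plane. The default duct
#'   center is 500 um from the vascular center.
#' @param bc named list of boundary conditions. Recognized entries:
#'   \code{outer} (\code{"closed"} zero-flux or \code{"open"} fixed at 0) and
#'   \code{duct} (\code{"sink"} fixed at 0 or \code{"noflux"} inert).
#' @return An object of class \code{transport_domain}.
#' @export
transport_domain <- function(grid_spacing = 20, extent = 600,
                             D = 4e-7,
                             vascular = list(center = c(0, 0), diameter = 160),
                             duct = list(center = c(500, 0), diameter = 160),
                             bc = list(outer = "closed", duct = "sink")) {
  if (!is.numeric(D) || D <= 0) stop("`D` must be > 0 (cm^2/s)")
  if (grid_spacing <= 0) stop("`grid_spacing` must be > 0")
  dmin <- min(vascular$diameter, duct$diameter)
  if (grid_spacing > dmin / 8)
    stop(sprintf(
      "grid_spacing %.3g um too coarse: smallest channel (%.3g um) needs >= 8 cells across (max %.3g um)",
      grid_spacing, dmin, dmin / 8))
  sep <- sqrt(sum((vascular$center - duct$center)^2))
  if (sep < (vascular$diameter + duct$diameter) / 2)
    stop("channel geometry invalid: vascular and duct channels overlap")
  structure(list(grid_spacing = grid_spacing, extent = extent, D = D,
                 vascular = vascular, duct = duct, bc = bc),
            class = "transport_domain")
}

#' @export
print.transport_domain <- function(x, ...) {
  cat(sprintf(
    "<transport_domain> h = %.3g um, extent %s um, D = %.3g cm^2/s\n",
    x$grid_spacing, paste(format(x$extent), collapse = " x "), x$D))
  cat(sprintf("  vascular: d = %.3g um at (%.4g, %.4g); duct: d = %.3g um at (%.4g, %.4g)\n",
              x$vascular$diameter, x$vascular$center[1], x$vascular$center[2],
              x$duct$diameter, x$duct$center[1], x$duct$center[2]))
  invisible(x)
}

CM2_PER_UM2 <- 1e-8   # 1 um^2 in cm^2; D[um^2/s] = D[cm^2/s] * 1e8
UM_PER_CM <- 1e4

#' Concentration field snapshot
#'
#' One time point of a transport simulation. Radial (axisymmetric) fields
#' store the profile c(r); Cartesian fields store the full grid. Either way,
#' \code{as.matrix()} returns the 2D cross-sectional concentration array.
#'
#' @param values concentration values (vector for radial, matrix for
#'   Cartesian), arbitrary units.
#' @param coords list of coordinates: \code{r} (um, cell centers) for radial;
#'   \code{x}, \code{y} (um) for Cartesian.
#' @param time timestamp, s.
#' @param domain the parent \code{transport_domain}.
#' @param geometry \code{"radial"} or \code{"cartesian"}.
#' @param lumen_value concentration inside the source channel (radial only).
#' @return An object of class \code{concentration_field}.
#' @export
concentration_field <- function(values, coords, time, domain,
                                geometry = c("radial", "cartesian"),
                                lumen_value = NA_real_) {
  geometry <- match.arg(geometry)
  if (any(values < -1e-9))
    warning("concentration field has negative values")
  structure(list(values = values, coords = coords, time = time,
                 domain = domain, geometry = geometry,
                 lumen_value = lumen_value),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf("<concentration_field> %s, t = %.4g s, range [%.4g, %.4g]\n",
              x$geometry, x$time, min(x$values), max(x$values)))
  invisible(x)
}

#' Rasterize a concentration field to a 2D array
#'
#' @param x a \code{concentration_field}.
#' @param grid_spacing raster spacing in um (defaults to the domain's).
#' @param ... unused.
#' @return numeric matrix over the cross-sectional plane; for radial fields
#'   the lumen region is filled with \code{lumen_value}.
#' @export
as.matrix.concentration_field <- function(x, grid_spacing = NULL, ...) {
  if (x$geometry == "cartesian") return(x$values)
  h <- if (is.null(grid_spacing)) x$domain$grid_spacing else grid_spacing
  rout <- max(x$coords$r)
  g <- seq(-rout, rout, by = h)
  rho <- sqrt(outer(g^2, g^2, "+"))
  rw <- x$domain$vascular$diameter / 2
  val <- stats::approx(x$coords$r, x$values, xout = pmin(rho, rout),
                       rule = 2)$y
  val[rho < rw] <- x$lumen_value
  matrix(val, nrow = length(g), ncol = length(g))
}

# Interpolator for a radial field: c(rho) with the lumen held at lumen_value.
radial_interpolator <- function(field) {
  r <- field$coords$r; v <- field$values
  rw <- field$domain$vascular$diameter / 2
  lum <- field$lumen_value
  rout <- max(r)
  function(rho) {
    out <- stats::approx(r, v, xout = pmin(rho, rout), rule = 2)$y
    out[rho < rw] <- lum
    out
  }
}

#' Simulate radial dextran efflux across a permeable vessel wall
#'
#' Conservative finite-volume solution of the diffusion equation in the gel
#' annulus around a perfused cylindrical vessel, in cylindrical-radial
#' coordinates (the efflux is radially symmetric in the cross-sectional
#' plane). The lumen is held at a fixed concentration (perfusion replenishes
#' the tracer) and the wall is a permeable (Robin) boundary carrying the
#' flux \code{J = P_D * (c_lumen - c_wall)}; the wall concentration is
#' obtained by matching this flux to the diffusive flux into the first gel
#' cell. The outer boundary is closed (zero flux) or open (fixed 0) per the
#' domain's \code{bc$outer}.
#'
#' @param domain a \code{transport_domain}.
#' @param P_D diffusive permeability of the wall, cm/s.
#' @param c_lumen lumen concentration (arbitrary units).
#' @param duration simulated time, s.
#' @param dt explicit time step, s; \code{NULL} picks half the stable bound.
#'   A user-supplied unstable step is rejected with the stable bound in the
#'   message.
#' @param output_times times (s) at which fields are returned; defaults to
#'   ten evenly spaced times plus t = 0.
#' @return An object of class \code{efflux_series}: list with \code{fields}
#'   (list of \code{concentration_field}), \code{bookkeeping} (data.frame of
#'   time, instantaneous wall flux per unit vessel length, cumulative wall
#'   influx, and gel mass per unit length, all in concentration-um^2 units),
#'   and the inputs.
#' @export
simulate_radial_efflux <- function(domain, P_D, c_lumen = 1, duration = 300,
                                   dt = NULL, output_times = NULL) {
  stopifnot(inherits(domain, "transport_domain"))
  if (P_D < 0) stop("`P_D` must be >= 0 (cm/s)")
  Dum <- domain$D / CM2_PER_UM2        # um^2/s
  Pum <- P_D * UM_PER_CM               # um/s
  h <- domain$grid_spacing
  rw <- domain$vascular$diameter / 2
  rout <- if (length(domain$extent) > 1) max(domain$extent) else domain$extent
  if (rout <= rw + 2 * h) stop("domain extent must exceed the vessel radius")
  n <- floor((rout - rw) / h)
  r <- rw + (seq_len(n) - 0.5) * h      # cell centers
  rf <- rw + (0:n) * h                  # cell faces
  stable <- h^2 / (2 * Dum)
  if (is.null(dt)) dt <- 0.5 * stable
  if (dt > stable)
    stop(sprintf("explicit step dt = %.4g s unstable; stable bound is %.4g s",
                 dt, stable))
  if (is.null(output_times))
    output_times <- seq(0, duration, length.out = 11L)
  output_times <- sort(unique(pmin(pmax(output_times, 0), duration)))

  cc <- numeric(n)                      # gel concentration, t = 0
  open_outer <- identical(domain$bc$outer, "open")
  wall_coef <- 1 / (1 / Pum + h / (2 * Dum))  # flux = coef*(c_lumen - c1)

  nstep <- ceiling(duration / dt)
  dt <- duration / nstep
  out_idx <- round(output_times / dt)
  fields <- vector("list", length(output_times))
  book_t <- numeric(nstep + 1L); book_flux <- numeric(nstep + 1L)
  book_cum <- numeric(nstep + 1L); book_mass <- numeric(nstep + 1L)
  cellvol <- 2 * pi * r * h             # per unit axial length
  wall_area <- 2 * pi * rw              # per unit axial length

  snap <- function(k, cc, t) {
    concentration_field(cc, list(r = r), t, domain, "radial", c_lumen)
  }
  oi <- 1L
  cum <- 0
  for (k in 0:nstep) {
    qw <- wall_coef * (c_lumen - cc[1L])          # um/s * conc
    book_t[k + 1L] <- k * dt
    book_flux[k + 1L] <- qw * wall_area
    book_cum[k + 1L] <- cum
    book_mass[k + 1L] <- sum(cc * cellvol)
    while (oi <= length(out_idx) && out_idx[oi] == k) {
      fields[[oi]] <- snap(oi, cc, k * dt)
      oi <- oi + 1L
    }
    if (k == nstep) break
    # face fluxes (positive outward): F_j at rf[j+1], j = 1..n-1
    Ff <- -Dum * diff(cc) / h                      # interior faces
    Fout <- if (open_outer) -Dum * (0 - cc[n]) / (h / 2) else 0
    div <- (c(rf[2:n] * Ff, rf[n + 1L] * Fout) -
            c(rf[1L] * qw, rf[2:n] * Ff)) / (r * h)
    cc <- cc - dt * div
    cum <- cum + qw * wall_area * dt
  }
  structure(list(fields = fields,
                 bookkeeping = data.frame(time = book_t, wall_flux = book_flux,
                                          cumulative_influx = book_cum,
                                          gel_mass = book_mass),
                 domain = domain, P_D = P_D, c_lumen = c_lumen, dt = dt),
            class = "efflux_series")
}

#' @export
print.efflux_series <- function(x, ...) {
  bk <- x$bookkeeping
  cat(sprintf(
    "<efflux_series> P_D = %.3g cm/s, %d fields over %.4g s\n",
    x$P_D, length(x$fields), max(bk$time)))
  cat(sprintf("  final gel mass %.4g, integrated wall influx %.4g (per um axis)\n",
              bk$gel_mass[nrow(bk)], bk$cumulative_influx[nrow(bk)]))
  invisible(x)
}

#' Mass-conservation error of an efflux simulation
#'
#' With a closed outer boundary, the gel mass gain must equal the
#' time-integrated wall influx; this returns the relative mismatch.
#'
#' @param series an \code{efflux_series}.
#' @return relative error (dimensionless).
#' @export
mass_conservation_error <- function(series) {
  bk <- series$bookkeeping
  # trapezoidal correction: cumulative influx above is left-rectangle
  infl <- bk$cumulative_influx[nrow(bk)] +
    series$dt * (bk$wall_flux[nrow(bk)] - bk$wall_flux[1L]) / 2
  gain <- bk$gel_mass[nrow(bk)] - bk$gel_mass[1L]
  if (infl == 0) return(abs(gain))
  abs(gain - infl) / infl
}

# ---- device gradient solver -------------------------------------------------

theta_step_matrices <- function(L, dirichlet, dir_val, dt, theta) {
  n <- nrow(L)
  I <- Matrix::Diagonal(n)
  A <- I - theta * dt * L
  B <- I + (1 - theta) * dt * L
  if (any(dirichlet)) {
    idx <- which(dirichlet)
    A[idx, ] <- 0
    A[cbind(idx, idx)] <- 1
    B[idx, ] <- 0
  }
  list(A = A, B = B, fix = function(rhs) {
    rhs[dirichlet] <- dir_val[dirichlet]; rhs
  })
}

#' Simulate morphogen gradient formation between the two channels
#'
#' Implicit (theta-scheme) finite-difference solution of diffusion from the
#' vascular channel (held at \code{source_conc}, modelling perfusion of the
#' growth factor) into the gel, with the duct channel acting as a sink or an
#' inert region per the domain's \code{bc$duct}. A 1D reduction along the
#' inter-channel axis is available for analytic comparisons and fast
#' estimates of gradient formation time.
#'
#' @param domain a \code{transport_domain}. In 1D mode, \code{extent[1]} is
#'   the axis length; the source boundary sits at x = 0 and the far boundary
#'   at x = extent is fixed at 0 (\code{bc$duct = "sink"}) or closed
#'   (\code{"noflux"}).
#' @param source_conc source concentration (arbitrary units).
#' @param duration simulated time, s.
#' @param dt implicit time step, s; default \code{duration / 600}.
#' @param output_times times at which fields are kept (default 25, evenly
#'   spaced); the monitor trace is recorded every step regardless.
#' @param dimension \code{"2d"} (channels as disks in the cross-sectional
#'   plane) or \code{"1d"}.
#' @param theta implicitness (1 backward Euler, 0.5 Crank-Nicolson);
#'   default 1 for a monotone start from the step initial condition.
#' @param monitor 1D: positions (um) to track; 2D: list of \code{c(x, y)}.
#'   Default: the midpoint between the channels.
#' @return An object of class \code{gradient_series}: fields at
#'   \code{output_times}, the per-step monitor trace, the steady-state
#'   solution, and \code{time_to_fraction} for 50\% of steady state at each
#'   monitor point (linear interpolation of the trace; NA if not reached).
#' @export
simulate_device_gradient <- function(domain, source_conc = 1, duration,
                                     dt = NULL, output_times = NULL,
                                     dimension = c("2d", "1d"),
                                     theta = 1, monitor = NULL) {
  stopifnot(inherits(domain, "transport_domain"))
  dimension <- match.arg(dimension)
  Dum <- domain$D / CM2_PER_UM2
  h <- domain$grid_spacing
  if (is.null(dt)) dt <- duration / 600
  if (is.null(output_times))
    output_times <- seq(0, duration, length.out = 25L)
  output_times <- sort(unique(pmin(pmax(output_times, 0), duration)))
  nstep <- ceiling(duration / dt)
  dt <- duration / nstep
  sink_duct <- !identical(domain$bc$duct, "noflux")

  if (dimension == "1d") {
    L <- if (length(domain$extent) > 1) domain$extent[1] else domain$extent
    x <- seq(0, L, by = h)
    n <- length(x)
    k0 <- Dum / h^2
    lower <- rep(k0, n - 1L)
    upper <- rep(k0, n - 1L)
    if (!sink_duct) lower[n - 1L] <- 2 * k0  # reflecting far end: ghost mirror
    Lap <- Matrix::bandSparse(n, k = c(-1L, 0L, 1L),
                              diagonals = list(lower, rep(-2 * k0, n), upper))
    dirichlet <- logical(n); dir_val <- numeric(n)
    dirichlet[1L] <- TRUE; dir_val[1L] <- source_conc
    if (sink_duct) { dirichlet[n] <- TRUE; dir_val[n] <- 0 }
    cc <- numeric(n); cc[1L] <- source_conc
    if (is.null(monitor)) monitor <- L / 2
    mon_idx <- vapply(monitor, function(m) which.min(abs(x - m)), integer(1))
    steady <- steady_state_pinned(Lap, dirichlet, dir_val)
    mk_field <- function(v, t) concentration_field(
      matrix(v, nrow = 1L), list(x = x, y = 0), t, domain, "cartesian")
  } else {
    ext <- rep(domain$extent, length.out = 2L)
    ctrs <- rbind(domain$vascular$center, domain$duct$center)
    x0 <- min(ctrs[, 1]) - ext[1] / 2; x1 <- max(ctrs[, 1]) + ext[1] / 2
    y0 <- min(ctrs[, 2]) - ext[2] / 2; y1 <- max(ctrs[, 2]) + ext[2] / 2
    x <- seq(x0, x1, by = h); y <- seq(y0, y1, by = h)
    nx <- length(x); ny <- length(y); n <- nx * ny
    idx <- function(i, j) (j - 1L) * nx + i
    rho_v <- sqrt(outer((x - domain$vascular$center[1])^2,
                        (y - domain$vascular$center[2])^2, "+"))
    rho_d <- sqrt(outer((x - domain$duct$center[1])^2,
                        (y - domain$duct$center[2])^2, "+"))
    in_v <- rho_v <= domain$vascular$diameter / 2
    in_d <- rho_d <= domain$duct$diameter / 2
    dirichlet <- as.vector(in_v) | (sink_duct & as.vector(in_d))
    dir_val <- numeric(n); dir_val[as.vector(in_v)] <- source_conc
    # 5-point Laplacian with reflecting outer boundary
    ii <- integer(0); jj <- integer(0); vv <- numeric(0)
    gi <- rep(seq_len(nx), ny); gj <- rep(seq_len(ny), each = nx)
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      ni <- gi + d[1]; nj <- gj + d[2]
      inside <- ni >= 1L & ni <= nx & nj >= 1L & nj <= ny
      k <- which(inside)
      ii <- c(ii, k); jj <- c(jj, idx(ni[inside], nj[inside]))
      vv <- c(vv, rep(Dum / h^2, length(k)))
      # reflecting: out-of-domain neighbour mirrors the cell itself
      k2 <- which(!inside)
      ii <- c(ii, k2); jj <- c(jj, k2); vv <- c(vv, rep(Dum / h^2, length(k2)))
    }
    Lap <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n)) -
      Matrix::Diagonal(n, 4 * Dum / h^2)
    cc <- numeric(n); cc[dirichlet] <- dir_val[dirichlet]
    if (is.null(monitor))
      monitor <- list((domain$vascular$center + domain$duct$center) / 2)
    if (!is.list(monitor)) monitor <- list(monitor)
    mon_idx <- vapply(monitor, function(m)
      idx(which.min(abs(x - m[1])), which.min(abs(y - m[2]))), integer(1))
    steady <- steady_state_pinned(Lap, dirichlet, dir_val)
    mk_field <- function(v, t) concentration_field(
      matrix(v, nrow = nx, ncol = ny), list(x = x, y = y), t, domain,
      "cartesian")
  }

  St <- theta_step_matrices(Lap, dirichlet, dir_val, dt, theta)
  Af <- Matrix::lu(St$A)
  out_idx <- round(output_times / dt)
  fields <- vector("list", length(output_times))
  trace <- matrix(NA_real_, nrow = nstep + 1L, ncol = length(mon_idx))
  times <- (0:nstep) * dt
  oi <- 1L
  for (k in 0:nstep) {
    trace[k + 1L, ] <- cc[mon_idx]
    while (oi <= length(out_idx) && out_idx[oi] == k) {
      fields[[oi]] <- mk_field(cc, k * dt); oi <- oi + 1L
    }
    if (k == nstep) break
    rhs <- St$fix(as.numeric(St$B %*% cc))
    cc <- as.numeric(Matrix::solve(Af, rhs))
  }
  steady_mon <- steady[mon_idx]
  t_frac <- vapply(seq_along(mon_idx), function(m) {
    target <- 0.5 * steady_mon[m]
    if (steady_mon[m] <= 0) return(NA_real_)
    i <- which(trace[, m] >= target)[1L]
    if (is.na(i) || i == 1L) return(if (is.na(i)) NA_real_ else 0)
    t0 <- times[i - 1L]; t1 <- times[i]
    v0 <- trace[i - 1L, m]; v1 <- trace[i, m]
    t0 + (target - v0) / (v1 - v0) * (t1 - t0)
  }, numeric(1))
  structure(list(fields = fields, times = output_times,
                 monitor = monitor, monitor_trace = trace,
                 trace_times = times, steady_state = mk_field(steady, Inf),
                 steady_monitor = steady_mon, time_to_half = t_frac,
                 domain = domain, source_conc = source_conc,
                 dimension = dimension, dt = dt),
            class = "gradient_series")
}

# Steady state of Lap c = 0 with Dirichlet rows pinned.
steady_state_pinned <- function(Lap, dirichlet, dir_val) {
  n <- nrow(Lap)
  A <- Lap
  idxd <- which(dirichlet)
  A[idxd, ] <- 0
  A[cbind(idxd, idxd)] <- 1
  b <- numeric(n); b[idxd] <- dir_val[idxd]
  as.numeric(Matrix::solve(A, b))
}

#' @export
print.gradient_series <- function(x, ...) {
  cat(sprintf("<gradient_series> %s, %d fields, source %.3g\n",
              x$dimension, length(x$fields), x$source_conc))
  for (m in seq_along(x$time_to_half))
    cat(sprintf("  monitor %d: steady %.4g, t(50%% steady) = %.4g s\n",
                m, x$steady_monitor[m], x$time_to_half[m]))
  invisible(x)
}

#' Steady-state profile along the inter-channel axis
#'
#' @param series a \code{gradient_series}.
#' @return data.frame of position (um, from the source-channel center along
#'   the axis toward the duct) and steady concentration.
#' @export
steady_profile <- function(series) {
  f <- series$steady_state
  if (series$dimension == "1d")
    return(data.frame(position = f$coords$x, conc = as.numeric(f$values)))
  dom <- series$domain
  dir <- dom$duct$center - dom$vascular$center
  dir <- dir / sqrt(sum(dir^2))
  s <- seq(0, sqrt(sum((dom$duct$center - dom$vascular$center)^2)),
           by = dom$grid_spacing)
  px <- dom$vascular$center[1] + s * dir[1]
  py <- dom$vascular$center[2] + s * dir[2]
  ix <- vapply(px, function(v) which.min(abs(f$coords$x - v)), integer(1))
  iy <- vapply(py, function(v) which.min(abs(f$coords$y - v)), integer(1))
  data.frame(position = s, conc = f$values[cbind(ix, iy)])
}
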