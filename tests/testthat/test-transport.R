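dom160 <- function(h = 2, extent = 500, D = 4e-7)
  transport_domain(grid_spacing = h, extent = extent, D = D,
                   vascular = list(center = c(0, 0), diameter = 160))

test_that("domain validation rejects coarse grids and overlapping channels", {
  expect_error(transport_domain(grid_spacing = 30), "8 cells")
  expect_error(transport_domain(
    grid_spacing = 10,
    vascular = list(center = c(0, 0), diameter = 160),
    duct = list(center = c(100, 0), diameter = 160)), "overlap")
  expect_error(transport_domain(grid_spacing = 10, D = 0), "D")
})

test_that("impermeable wall keeps the gel empty", {
  es <- simulate_radial_efflux(dom160(), P_D = 0, duration = 100)
  expect_true(all(vapply(es$fields, function(f) max(abs(f$values)),
                         numeric(1)) == 0))
})

test_that("non-limiting wall drives wall concentration to the lumen value", {
  es <- simulate_radial_efflux(dom160(h = 1, extent = 400), P_D = 1e-2,
                               c_lumen = 2, duration = 300,
                               output_times = c(0, 300))
  near_wall <- es$fields[[2]]$values[1L]
  expect_gt(near_wall / 2, 0.97)
})

test_that("unstable explicit steps are rejected with the stable bound", {
  expect_error(simulate_radial_efflux(dom160(), P_D = 1e-6, duration = 100,
                                      dt = 10),
               "stable bound")
})

test_that("wall-flux bookkeeping conserves mass with a closed outer boundary", {
  for (pd in c(1e-7, 1e-5)) {
    es <- simulate_radial_efflux(dom160(), P_D = pd, duration = 300)
    expect_lt(mass_conservation_error(es), 0.01)
  }
})

test_that("early-time efflux matches the analytic half-space Robin solution", {
  # oracle: C&J constant-transfer-coefficient half-space solution
  # c/c0 = erfc(eta) - exp(hx + h^2 Dt) erfc(eta + h sqrt(Dt)), h = P/D
  D <- 4e-7; P <- 1e-4; t <- 25
  dom <- transport_domain(grid_spacing = 1, extent = 2300, D = D,
                          vascular = list(center = c(0, 0), diameter = 4000),
                          duct = list(center = c(9e4, 0), diameter = 4000))
  es <- simulate_radial_efflux(dom, P_D = P, duration = t,
                               output_times = c(0, t))
  f <- es$fields[[2]]
  xs <- seq(2, 50, by = 4)
  num <- stats::approx(f$coords$r - 2000, f$values, xout = xs)$y
  Dum <- D * 1e8; Pum <- P * 1e4; hh <- Pum / Dum
  eta <- xs / (2 * sqrt(Dum * t))
  ana <- erfc_(eta) - exp(-eta^2) * pracma::erfcx(eta + hh * sqrt(Dum * t))
  expect_lt(max(abs(num - ana) / ana), 0.02)
})

test_that("halving the grid changes integrated wall flux by under 2%", {
  f1 <- simulate_radial_efflux(dom160(h = 2), P_D = 1e-6, duration = 300)
  f2 <- simulate_radial_efflux(dom160(h = 1), P_D = 1e-6, duration = 300)
  m1 <- utils::tail(f1$bookkeeping$cumulative_influx, 1)
  m2 <- utils::tail(f2$bookkeeping$cumulative_influx, 1)
  expect_lt(abs(m1 - m2) / m2, 0.02)
})

test_that("1D gradient steady state is linear between fixed boundaries", {
  dom <- transport_domain(grid_spacing = 5, extent = 500, D = 1e-6)
  g <- simulate_device_gradient(dom, source_conc = 1, duration = 3000,
                                dimension = "1d")
  sp <- steady_profile(g)
  expect_equal(stats::approx(sp$position, sp$conc, 250)$y, 0.5,
               tolerance = 0.005)
  # linearity everywhere, not just the midpoint
  pred <- 1 - sp$position / 500
  expect_lt(max(abs(sp$conc - pred)), 1e-9)
})

test_that("all-closed domain relaxes to a uniform steady state", {
  dom <- transport_domain(grid_spacing = 5, extent = 400, D = 1e-6,
                          bc = list(outer = "closed", duct = "noflux"))
  g <- simulate_device_gradient(dom, source_conc = 3, duration = 100,
                                dimension = "1d")
  expect_equal(as.numeric(g$steady_state$values),
               rep(3, length(g$steady_state$coords$x)), tolerance = 1e-9)
})

test_that("time to half steady state matches the erfc half-space oracle", {
  dom <- transport_domain(grid_spacing = 5, extent = 2000, D = 1e-6,
                          bc = list(outer = "closed", duct = "noflux"))
  g <- simulate_device_gradient(dom, source_conc = 1, duration = 2000,
                                dt = 2, dimension = "1d", monitor = 250)
  # oracle: c/c0 = erfc(x / (2 sqrt(D t))) = 1/2 at x = 250 um
  eta_half <- uniroot(function(z) erfc_(z) - 0.5, c(0.3, 0.7),
                      tol = 1e-12)$root
  t_ana <- (250e-4 / (2 * eta_half))^2 / 1e-6
  expect_lt(abs(g$time_to_half - t_ana) / t_ana, 0.05)
})

test_that("2D device gradient is monotone from vessel to duct", {
  dom <- transport_domain(grid_spacing = 20, extent = 700, D = 1e-6)
  g <- simulate_device_gradient(dom, source_conc = 1, duration = 86400,
                                dt = 900)
  sp <- steady_profile(g)
  outside <- sp$position > 90 & sp$position < 410   # between the two walls
  expect_true(all(diff(sp$conc[outside]) <= 1e-9))
  expect_equal(max(sp$conc), 1, tolerance = 1e-6)
  # duct held at 0 by the sink condition
  expect_equal(sp$conc[length(sp$conc)], 0, tolerance = 1e-9)
})

test_that("radial fields rasterize to symmetric 2D cross-sections", {
  es <- simulate_radial_efflux(dom160(h = 4, extent = 400), P_D = 1e-5,
                               duration = 100, output_times = c(0, 100))
  m <- as.matrix(es$fields[[2]])
  expect_equal(m, m[rev(seq_len(nrow(m))), ], tolerance = 1e-12)
  expect_equal(m, t(m), tolerance = 1e-12)
  ctr <- (nrow(m) + 1) / 2
  expect_equal(m[ctr, ctr], es$c_lumen)
})
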