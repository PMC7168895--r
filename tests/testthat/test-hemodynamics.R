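test_that("scalar shear rate reproduces the closed-form cases", {
  # simple shear u = (gamma * y, 0): gradient du/dy = gamma
  expect_equal(scalar_shear_rate(matrix(c(0, 0, 3, 0), 2, 2)), 3)
  # rigid rotation: antisymmetric gradient has zero strain rate
  expect_equal(scalar_shear_rate(matrix(c(0, 2, -2, 0), 2, 2)), 0)
  # pure extension diag(a, -a): sqrt(2*(a^2 + a^2)) = 2a
  expect_equal(scalar_shear_rate(diag(c(1.5, -1.5))), 3)
  expect_error(scalar_shear_rate(matrix(c(Inf, 0, 0, 0), 2, 2)),
               class = "hemoflow_domain_error")
})

test_that("plane Poiseuille shear-rate field hits 6U/h at the wall and 0 at center", {
  dom <- channel_dom(mesh = 0.2, lf = 5)
  A <- inlet_area_circ(dom)
  Um <- 2.6 / A
  sol <- steady_solve(dom, casson_params(0, 0.0035), Q = 2.6, inlet_area = A,
                      steady_tol = 1e-7)
  g <- shear_rate_field(sol, 1)
  i <- round(dom$nx / 2)
  gex <- abs(6 * Um * (dom$width - 2 * dom$yc) / dom$width^2)
  # centerline (two middle rows) is far below the wall-adjacent value
  mid <- dom$ny_chan / 2
  expect_lt(g[i, mid], 0.1 * g[i, 1])
  # interior cells match the analytic linear profile within a few percent
  sel <- 2:(dom$ny_chan - 1)
  expect_equal(g[i, sel], gex[sel], tolerance = 0.05)
  # wall shear rate via the wall estimator: 6U/h within 2%
  wf <- wall_shear_stress(sol)
  k <- which(wf$samples$y < 1e-9 & abs(wf$samples$x - dom$L / 2) < dom$h)
  expect_equal(wf$wss[k[1], 1] / 0.0035, 6 * Um / dom$width, tolerance = 0.02)
})

test_that("dome averaging is the measure-weighted mean", {
  dom <- dome_dom(mesh = 0.5)
  const <- matrix(7, dom$nx, dom$ny)
  expect_equal(dome_average(const, dom), 7)
  f <- matrix(rnorm(dom$nx * dom$ny), dom$nx)
  g <- matrix(rnorm(dom$nx * dom$ny), dom$nx)
  expect_equal(dome_average(2 * f + 3 * g, dom),
               2 * dome_average(f, dom) + 3 * dome_average(g, dom),
               tolerance = 1e-12)
  # explicit hand sum over dome cells
  sel <- dom$cell == hemoflow:::CELL_DOME
  expect_equal(dome_average(f, dom), sum(f[sel]) / sum(sel), tolerance = 1e-12)
  expect_error(dome_average(f, channel_dom(mesh = 0.5, lf = 3)),
               class = "hemoflow_domain_error")
})

test_that("TAWSS reduces to closed forms and independent quadrature", {
  # constant signal: TAWSS equals the constant
  times <- seq(0, 1, length.out = 201)
  expect_equal(time_averaged_wss(rep(2.5, 201), times = times, period = 1), 2.5)
  # |sin| integral: (2/pi) * c within 0.5% at 200 intervals
  w <- abs(sin(2 * pi * times)) * 3
  expect_equal(time_averaged_wss(w, times = times, period = 1), 3 * 2 / pi,
               tolerance = 0.005)
  # arbitrary non-negative series against dense spline quadrature
  set.seed(4)
  y <- runif(51)
  t51 <- seq(0, 1, length.out = 51)
  sp <- splinefun(t51, y, method = "natural")
  # oracle integrates the same trapezoid-sampled series independently
  trap <- sum((y[-1] + y[-51]) / 2 * diff(t51))
  expect_equal(time_averaged_wss(y, times = t51, period = 1), trap,
               tolerance = 1e-12)
  # periodic closure: one-step-short sampling still covers the cycle
  t_short <- seq(0.02, 1, by = 0.02)   # 50 samples, span 0.98
  w2 <- 1 + 0.5 * sin(2 * pi * t_short)
  expect_equal(time_averaged_wss(w2, times = t_short, period = 1), 1,
               tolerance = 0.002)
  expect_error(time_averaged_wss(w2[1:10], times = t_short[1:10], period = 1),
               class = "hemoflow_domain_error")
})

test_that("WSS extrema recover planted extremes", {
  wf <- structure(list(
    samples = tibble::tibble(x = 1:4 * 1e-3, y = 0, dome = c(TRUE, TRUE, TRUE, FALSE)),
    times = c(0, 0.5, 1),
    wss = rbind(c(1, 2, 3), c(0.2, 9, 1), c(4, 0, 2), c(100, 100, 100)),
    period = 1), class = "wall_field")
  ext <- wss_extrema(wf)                       # dome rows only
  expect_equal(unname(ext["wss_min"]), 0)
  expect_equal(unname(ext["wss_max"]), 9)
  alt <- wss_extrema(wf, spatial_average = TRUE)
  expect_equal(unname(alt["wss_min"]), mean(c(1, 0.2, 0)))
  expect_equal(unname(alt["wss_max"]), mean(c(3, 9, 4)))
  const <- wf; const$wss <- matrix(2, 4, 3)
  e2 <- wss_extrema(const)
  expect_equal(unname(e2), c(2, 2))
})

test_that("hemodynamic summary is ordered and bounded by the rheology", {
  dom <- dome_dom(mesh = 0.5, lf = 6)
  p <- casson_params(0.008, 0.0035)
  sol <- solve_unsteady(dom, p, solver_config(n_cycles = 2, report_cycle = 2,
                                              time_step = 1 / 40),
                        quiet = TRUE)
  s <- summarize_hemodynamics(sol)
  expect_true(all(unlist(s) >= 0))
  expect_lte(s$wss_min, s$wss_tavg)
  expect_lte(s$wss_tavg, s$wss_max)
  # viscosity summaries bounded by plateau and regularized maximum (cP)
  mu_lo <- 1e3 * p$k
  mu_hi <- 1e3 * effective_viscosity(p$shear_floor, p)
  expect_gte(s$avg_viscosity_ps, mu_lo)
  expect_lte(s$avg_viscosity_ps, mu_hi)
  expect_gte(s$avg_viscosity_ed, mu_lo)
  expect_lte(s$avg_viscosity_ed, mu_hi)
})

test_that("dome size drives the shear-thinning coupling across geometries", {
  # three domes, small to large, fixed flow settings
  radii <- c(1.6, 2.4, 3.2)
  p <- casson_params(0.01, 0.0035)
  res <- lapply(radii, function(r) {
    dom <- build_2d_domain(shape_params(r, -0.3 * r), mesh_size = 0.5,
                           length_factor = 6)
    sol <- steady_solve(dom, p, Q = 2.6, steady_tol = 1e-7)
    g <- shear_rate_field(sol, 1)
    mu <- effective_viscosity(ifelse(is.na(g), 0, g), p)
    c(gam = dome_average(g, dom), mu = dome_average(mu, dom))
  })
  gams <- vapply(res, `[[`, numeric(1), "gam")
  mus <- vapply(res, `[[`, numeric(1), "mu")
  # larger domes: lower dome-averaged shear rate, higher apparent viscosity
  expect_true(all(diff(gams) < 0))
  expect_true(all(diff(mus) > 0))
})
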