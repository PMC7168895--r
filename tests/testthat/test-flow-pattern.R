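test_that("stream function reproduces uniform flow and the Poiseuille cubic", {
  dom <- channel_dom(mesh = 0.25, lf = 4)
  cx <- corner_xy(dom)
  # uniform flow (U0, 0): psi = U0 * y + const
  U0 <- 0.3
  U <- matrix(U0, dom$nx + 1, dom$ny)
  V <- matrix(0, dom$nx, dom$ny + 1)
  psi <- stream_function(dom, U, V)
  expect_equal(psi[5, ] - psi[5, 1], U0 * cx$y, tolerance = 1e-12)
  # solver Poiseuille snapshot: psi cubic in y, matches closed form
  A <- inlet_area_circ(dom)
  Um <- 2.6 / A
  sol <- steady_solve(dom, casson_params(0, 0.0035), Q = 2.6, inlet_area = A,
                      steady_tol = 1e-7)
  psi2 <- solution_stream_function(sol, 1)
  d <- dom$width
  psi_ex <- 6 * Um * (cx$y^2 / 2 - cx$y^3 / (3 * d)) / d   # int of parabola
  i <- round(dom$nx / 2)
  expect_lt(max(abs(psi2[i, ] - psi2[i, 1] - psi_ex)) / max(psi_ex), 0.01)
  # strongly non-solenoidal input is rejected
  Ubad <- U; Ubad[10, ] <- 10 * U0
  expect_error(stream_function(dom, Ubad, V), class = "hemoflow_domain_error")
})

test_that("rigid vortex stream function has concentric circular level sets", {
  dom <- dome_dom(mesh = 0.4)
  cx <- corner_xy(dom)
  ctr <- c(dom$circ$x0, dom$circ$y0)
  psi0 <- outer(cx$x, cx$y, function(x, y)
    -0.5 * ((x - ctr[1])^2 + (y - ctr[2])^2))   # u = (-w(y-yc), w(x-xc))
  f <- fields_from_psi(dom, psi0)
  psi1 <- stream_function(dom, f$U, f$V)
  # reconstructed psi differs from the source by a constant
  dev <- psi1 - psi0
  expect_lt(max(dev) - min(dev), 1e-9 * diff(range(psi0)))
})

test_that("planted vortices are counted 0 / 1 / 2", {
  dom <- dome_dom(radius = 2.6, offset = -0.8, mesh = 0.25, lf = 6)
  ctr <- c(dom$circ$x0, dom$circ$y0 + 0.3 * dom$circ$R)
  base <- psi_with_vortices(dom)                      # pure through-flow
  f0 <- fields_from_psi(dom, base)
  expect_identical(count_recirculation_zones(dom, stream_function(dom, f0$U, f0$V)), 0L)
  one <- psi_with_vortices(dom, centers = matrix(ctr, 1),
                           amplitudes = 5e-7, sigma = 0.4 * dom$circ$R)
  f1 <- fields_from_psi(dom, one)
  expect_identical(count_recirculation_zones(dom, stream_function(dom, f1$U, f1$V)), 1L)
  two_c <- rbind(ctr + c(-0.45 * dom$circ$R, 0), ctr + c(0.45 * dom$circ$R, 0))
  two <- psi_with_vortices(dom, centers = two_c,
                           amplitudes = c(5e-7, -5e-7), sigma = 0.22 * dom$circ$R)
  f2 <- fields_from_psi(dom, two)
  expect_identical(count_recirculation_zones(dom, stream_function(dom, f2$U, f2$V)), 2L)
})

test_that("counting is threshold-monotone and invariant to the psi constant", {
  dom <- dome_dom(radius = 2.6, offset = -0.8, mesh = 0.25, lf = 6)
  ctr <- c(dom$circ$x0, dom$circ$y0 + 0.3 * dom$circ$R)
  two_c <- rbind(ctr + c(-0.45 * dom$circ$R, 0), ctr + c(0.45 * dom$circ$R, 0))
  psi <- psi_with_vortices(dom, centers = two_c,
                           amplitudes = c(5e-7, -1e-7), sigma = 0.22 * dom$circ$R)
  f <- fields_from_psi(dom, psi)
  psi_r <- stream_function(dom, f$U, f$V)
  counts <- vapply(c(0.001, 0.01, 0.1, 0.5),
                   function(th) count_recirculation_zones(dom, psi_r, th),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(count_recirculation_zones(dom, psi_r + 42),
                   count_recirculation_zones(dom, psi_r))
})

test_that("complexity classification follows the recirculation count", {
  expect_identical(classify_complexity(1), "simple")
  expect_identical(classify_complexity(2), "complex")
  expect_identical(classify_complexity(0), "simple")
  expect_identical(classify_complexity(c(0, 1, 2, 5)),
                   c("simple", "simple", "complex", "complex"))
  expect_error(classify_complexity(-1), class = "hemoflow_domain_error")
})

test_that("inflow jet classification separates tip-directed from wall-following flow", {
  dom <- dome_dom(radius = 2.4, offset = -0.6, mesh = 0.25, lf = 6)
  nxp <- dom$nx + 1; nyp <- dom$ny + 1
  cfg <- solver_config()
  mk_sol <- function(U, V) {
    structure(list(domain = dom, params = casson_params(0, 0.0035),
                   config = cfg, times = 0.25, U = list(U), V = list(V),
                   P = list(matrix(0, dom$nx, dom$ny)), Q_t = 2.6,
                   peak_systole_index = 1L, end_diastole_index = 1L,
                   convergence = data.frame()), class = "flow_solution")
  }
  # straight jet: uniform upward velocity in a narrow column through the
  # ostium center, aimed at the dome tip
  U <- matrix(0, nxp, dom$ny); V <- matrix(0, dom$nx, nyp)
  icol <- round(dom$circ$x0 / dom$h) + (-1:1)
  V[icol, ] <- 0.3
  jet <- classify_inflow_jet(mk_sol(U, V))
  expect_identical(jet$jet, "concentrated")
  expect_lt(jet$median_impingement_deg, 30)
  # wall-following: ring vortex about the dome center; streamlines circle
  # back out through the neck without impinging near the tip
  cx <- corner_xy(dom)
  ctr <- c(dom$circ$x0, dom$circ$y0)
  psi <- outer(cx$x, cx$y, function(x, y)
    1e-6 * exp(-((x - ctr[1])^2 + (y - ctr[2])^2) / (2 * (0.8 * dom$circ$R)^2)))
  f <- fields_from_psi(dom, psi)
  expect_identical(classify_inflow_jet(mk_sol(f$U, f$V))$jet, "diffused")
  # zero flow: no-inflow error
  expect_error(classify_inflow_jet(mk_sol(U * 0, V * 0)),
               class = "hemoflow_domain_error")
})
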