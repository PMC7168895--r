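# Independent analytic/numeric oracles used across the suite. These never
# call the solver or the package's own formulas for the quantity they check.

# Casson shear rate at stress tau (inverse constitutive law)
casson_gamma_of_tau <- function(tau, tau_y, k) {
  ifelse(tau > tau_y, (sqrt(tau) - sqrt(tau_y))^2 / k, 0)
}

# 2D flux per unit depth of fully developed plane-Casson flow in a channel
# of half-gap a under pressure gradient G, by direct quadrature of the
# two-zone profile (u(y) = int_y^a gamma dy', flux = 2 int_0^a u dy)
plane_casson_flux <- function(G, a, tau_y, k) {
  gam <- function(y) casson_gamma_of_tau(G * y, tau_y, k)
  u <- function(y) vapply(y, function(yy)
    integrate(gam, yy, a, rel.tol = 1e-10)$value, numeric(1))
  2 * integrate(u, 0, a, rel.tol = 1e-8)$value
}

# pressure gradient that drives a given 2D flux, and the wall stress G * a
plane_casson_G <- function(flux, a, tau_y, k) {
  uniroot(function(g) plane_casson_flux(g, a, tau_y, k) - flux,
          c(1e-3, 1e7), tol = 1e-12)$root
}

# velocity profile of plane-Casson flow at cross-channel positions y
# (measured from the bottom wall, channel gap 2a)
plane_casson_profile <- function(y, G, a, tau_y, k) {
  gam <- function(z) casson_gamma_of_tau(G * abs(z), tau_y, k)
  vapply(y, function(yy)
    integrate(gam, abs(yy - a), a, rel.tol = 1e-10)$value, numeric(1))
}

# staggered fields from a corner stream function (exactly divergence-free
# by construction): U[i, j] = (psi[i, j+1] - psi[i, j]) / h, etc.
fields_from_psi <- function(dom, psi) {
  nx <- dom$nx; ny <- dom$ny; h <- dom$h
  U <- (psi[, -1, drop = FALSE] - psi[, -(ny + 1L), drop = FALSE]) / h
  V <- -(psi[-1, , drop = FALSE] - psi[-(nx + 1L), , drop = FALSE]) / h
  list(U = U, V = V)
}

# corner-grid coordinates of a domain
corner_xy <- function(dom) {
  list(x = (seq_len(dom$nx + 1L) - 1L) * dom$h,
       y = (seq_len(dom$ny + 1L) - 1L) * dom$h)
}

# a channel+dome stream function: through-flow in the channel (cubic
# profile of a parabola), constant on/above the channel top except for
# optional Gaussian vortex bumps planted inside the dome
psi_with_vortices <- function(dom, centers = NULL, amplitudes = NULL,
                              sigma = NULL, Q2d = 1e-6) {
  cx <- corner_xy(dom)
  d <- dom$width
  profile <- function(y) {
    yy <- pmin(pmax(y, 0), d)
    Q2d * (3 * (yy / d)^2 - 2 * (yy / d)^3)   # int of parabola, 0 -> Q2d
  }
  psi <- outer(rep(1, dom$nx + 1L), profile(cx$y))
  if (!is.null(centers)) {
    for (m in seq_len(nrow(centers))) {
      r2 <- outer(cx$x, cx$y, function(x, y)
        (x - centers[m, 1])^2 + (y - centers[m, 2])^2)
      psi <- psi + amplitudes[m] * exp(-r2 / (2 * sigma^2))
    }
  }
  psi
}

# coarse shared fixtures (built once per test run)
channel_dom <- function(mesh = 0.2, lf = 6)
  build_2d_domain(NULL, mesh_size = mesh, length_factor = lf,
                  parent_diameter = 4)

dome_dom <- function(radius = 2.4, offset = -0.9, mesh = 0.4, lf = 8)
  build_2d_domain(shape_params(radius, offset), mesh_size = mesh,
                  length_factor = lf)

inlet_area_circ <- function(dom) (pi / 4) * (dom$width * 1e3)^2
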