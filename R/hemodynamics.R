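#' Scalar shear rate from a velocity gradient
#'
#' The standard generalized-Newtonian scalar invariant
#' \eqn{\dot\gamma = \sqrt{2 D : D}} with
#' \eqn{D = (\nabla u + \nabla u^T)/2}. For simple shear
#' \eqn{u = (\gamma y, 0)} this returns \eqn{\gamma}; for rigid rotation it
#' returns 0.
#'
#' @param grad 2x2 (or 3x3) velocity-gradient matrix, \eqn{\partial u_i /
#'   \partial x_j} in row i, column j; units 1/s.
#' @return Scalar shear rate, 1/s.
#' @examples
#' scalar_shear_rate(matrix(c(0, 0, 2, 0), 2, 2))   # simple shear, gamma = 2
#' @export
scalar_shear_rate <- function(grad) {
  grad <- as.matrix(grad)
  if (nrow(grad) != ncol(grad) || any(!is.finite(grad)))
    stop_domain("`grad` must be a finite square matrix.")
  D <- (grad + t(grad)) / 2
  sqrt(2 * sum(D * D))
}

#' Shear-rate field of a stored snapshot
#'
#' @param solution A `flow_solution`.
#' @param time_index Snapshot index (default peak systole).
#' @return Matrix (nx x ny) of scalar shear rate at cell centers, 1/s; NA in
#'   solid cells.
#' @export
shear_rate_field <- function(solution, time_index = solution$peak_systole_index) {
  shear_rate_centers(solution$domain, solution$U[[time_index]],
                     solution$V[[time_index]])
}

#' Measure-weighted average of a cell field over the aneurysm dome
#'
#' On the uniform grid all cells have equal measure, so this is the
#' arithmetic mean over dome-tagged cells (the 2D analog of averaging over
#' the dome volume).
#'
#' @param field nx x ny matrix of cell-centered values.
#' @param domain A `sim_domain`.
#' @return Scalar average.
#' @export
dome_average <- function(field, domain) {
  stopifnot(inherits(domain, "sim_domain"))
  sel <- domain$cell == CELL_DOME
  if (!any(sel)) stop_domain("domain has no dome region.")
  w <- rep(domain$h^2, sum(sel))
  sum(field[sel] * w) / sum(w)
}

# near-wall tangential shear rate for one wall face. The ghost-consistent
# two-point estimate gamma_w = 2|u1|/h (u1 the tangential cell-centered
# velocity at h/2 from the wall) is exact for the scheme's discrete
# fully developed channel profile: the mirror-ghost wall treatment shifts
# the resolved parabola by G h^2/(8 mu), and that offset cancels here.
wall_shear_rates <- function(dom, U, V) {
  w <- dom$walls
  h <- dom$h
  n <- nrow(w)
  g <- numeric(n)
  for (k in seq_len(n)) {
    i <- w$i[k]; j <- w$j[k]
    if (w$dy[k] != 0L) {                       # horizontal wall: tangential u
      u1 <- (U[i, j] + U[i + 1L, j]) / 2
      g[k] <- 2 * abs(u1) / h
    } else {                                   # vertical wall: tangential v
      v1 <- (V[i, j] + V[i, j + 1L]) / 2
      g[k] <- 2 * abs(v1) / h
    }
  }
  g
}

#' Wall shear stress along the domain walls
#'
#' For each wall face and stored time, the instantaneous wall shear stress
#' magnitude \eqn{WSS_i = \mu(\dot\gamma_w)\,\dot\gamma_w}: the tangential
#' viscous traction of the generalized-Newtonian stress, with
#' \eqn{\dot\gamma_w} the near-wall tangential shear rate.
#'
#' @param solution A `flow_solution`.
#' @param params Casson parameters (default: the solve's).
#' @return An object of class `wall_field`: list with `samples` (tibble of
#'   wall-face midpoints and dome flag), `times` (s), and `wss` (samples x
#'   times matrix, Pa).
#' @export
wall_shear_stress <- function(solution, params = solution$params) {
  dom <- solution$domain
  if (is.null(dom$walls) || nrow(dom$walls) == 0L)
    stop_domain("domain has no wall faces.")
  nt <- length(solution$times)
  wss <- matrix(0, nrow(dom$walls), nt)
  for (it in seq_len(nt)) {
    g <- wall_shear_rates(dom, solution$U[[it]], solution$V[[it]])
    wss[, it] <- effective_viscosity(g, params) * g
  }
  structure(list(samples = as_tibble(dom$walls[, c("x", "y", "dome")]),
                 times = solution$times, wss = wss,
                 period = solution$config$cycle_period),
            class = "wall_field")
}

#' @export
print.wall_field <- function(x, ...) {
  cat(sprintf("wall_field: %d wall samples (%d on the dome), %d times\n",
              nrow(x$samples), sum(x$samples$dome), length(x$times)))
  invisible(x)
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' Per-sample trapezoidal approximation of
#' \eqn{\mathrm{TAWSS} = \frac{1}{T}\int_0^T |WSS_i|\,dt} over one cardiac
#' cycle. Accepts either a `wall_field` or a plain matrix/vector of WSS
#' samples with a `times` vector. The samples must span one full cycle:
#' either endpoints a full period apart, or one time step short of it (the
#' usual one-cycle storage), in which case the integral is closed
#' periodically.
#'
#' @param wall_field A `wall_field`, or a numeric matrix (samples x times) /
#'   vector of instantaneous WSS.
#' @param times Sample times, s (taken from the `wall_field` if given).
#' @param period Cycle duration T, s (from the `wall_field` config if given).
#' @return Per-sample TAWSS, Pa (vector).
#' @export
time_averaged_wss <- function(wall_field, times = NULL, period = NULL) {
  if (inherits(wall_field, "wall_field")) {
    times <- wall_field$times
    if (is.null(period)) period <- wall_field$period
    w <- wall_field$wss
  } else {
    w <- wall_field
    if (is.vector(w)) w <- matrix(w, nrow = 1)
  }
  if (is.null(times) || length(times) < 2L)
    stop_domain("need at least 2 time samples.")
  if (is.null(period)) period <- diff(range(times))
  span <- diff(range(times))
  dt_med <- median(diff(times))
  w <- abs(w)
  if (abs(span - period) < 1e-9 * period) {
    wt <- diff(times)
    integral <- (w[, -ncol(w), drop = FALSE] + w[, -1, drop = FALSE]) %*% wt / 2
  } else if (abs(span + dt_med - period) < 0.05 * period) {
    # periodic closure: last sample wraps to the first
    wt <- diff(times)
    integral <- (w[, -ncol(w), drop = FALSE] + w[, -1, drop = FALSE]) %*% wt / 2 +
      (w[, ncol(w)] + w[, 1]) * (period - span) / 2
  } else {
    stop_domain("time samples do not span one full cycle.")
  }
  as.numeric(integral) / period
}

#' Extremes of the instantaneous WSS over the dome surface and cycle
#'
#' Default: the global minimum and maximum of \eqn{WSS_i} over dome wall
#' samples and all stored cycle times. With `spatial_average = TRUE` the
#' alternative reading is returned: the dome-surface average of each
#' sample's temporal extremum.
#'
#' @param wall_field A `wall_field`.
#' @param dome_only Restrict to dome wall samples (default TRUE).
#' @param spatial_average Average per-sample temporal extrema over the dome
#'   instead of taking the global extrema.
#' @return Named numeric: `wss_min`, `wss_max` (Pa).
#' @export
wss_extrema <- function(wall_field, dome_only = TRUE, spatial_average = FALSE) {
  stopifnot(inherits(wall_field, "wall_field"))
  sel <- if (dome_only) wall_field$samples$dome else rep(TRUE, nrow(wall_field$samples))
  if (!any(sel)) stop_domain("no dome wall samples.")
  w <- wall_field$wss[sel, , drop = FALSE]
  if (spatial_average) {
    c(wss_min = mean(apply(w, 1, min)), wss_max = mean(apply(w, 1, max)))
  } else {
    c(wss_min = min(w), wss_max = max(w))
  }
}

#' Per-patient hemodynamic summary
#'
#' The dome-resolved scalars reported per patient: dome-averaged shear rate
#' and apparent viscosity at peak systole and end diastole, and the minimal,
#' time-averaged and maximal wall shear stress on the dome surface over the
#' reported cycle. TAWSS is the dome-surface (area-weighted) average of the
#' per-sample time integral; the extrema are global over dome samples and
#' times.
#'
#' @param solution A `flow_solution` with PS/ED indices flagged.
#' @param params Casson parameters (default: the solve's).
#' @param spatial_average_extrema Use the spatial-average-of-temporal-extrema
#'   alternative for `wss_min`/`wss_max`.
#' @return One-row tibble: `avg_shear_rate_ps`, `avg_shear_rate_ed` (1/s),
#'   `avg_viscosity_ps`, `avg_viscosity_ed` (cP), `wss_min`, `wss_tavg`,
#'   `wss_max` (Pa).
#' @export
summarize_hemodynamics <- function(solution, params = solution$params,
                                   spatial_average_extrema = FALSE) {
  dom <- solution$domain
  avg_at <- function(idx) {
    g <- shear_rate_centers(dom, solution$U[[idx]], solution$V[[idx]])
    mu <- effective_viscosity(ifelse(is.na(g), 0, g), params)
    c(gam = dome_average(g, dom), mu = dome_average(mu, dom))
  }
  ps <- avg_at(solution$peak_systole_index)
  ed <- avg_at(solution$end_diastole_index)
  wf <- wall_shear_stress(solution, params)
  dome_sel <- wf$samples$dome
  if (!any(dome_sel)) stop_domain("domain has no dome wall samples.")
  tawss <- time_averaged_wss(wf)
  ext <- wss_extrema(wf, dome_only = TRUE, spatial_average = spatial_average_extrema)
  tibble(avg_shear_rate_ps = ps[["gam"]], avg_shear_rate_ed = ed[["gam"]],
         avg_viscosity_ps = pa_s_to_cp(ps[["mu"]]),
         avg_viscosity_ed = pa_s_to_cp(ed[["mu"]]),
         wss_min = ext[["wss_min"]], wss_tavg = mean(tawss[dome_sel]),
         wss_max = ext[["wss_max"]])
}
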