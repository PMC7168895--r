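#' Stream function of a divergence-free snapshot
#'
#' Integrates the staggered velocities to the stream function \eqn{\psi} at
#' grid corners (\eqn{u = \partial\psi/\partial y},
#' \eqn{v = -\partial\psi/\partial x}), anchored at \eqn{\psi = 0} on the
#' bottom-left corner. Because the stored fields are discretely
#' divergence-free the line integration is path-independent; strongly
#' non-solenoidal input is rejected.
#'
#' @param domain A `sim_domain`.
#' @param U,V Staggered velocity fields ((nx+1) x ny and nx x (ny+1), m/s).
#' @param div_tol Maximum allowed relative divergence.
#' @return Matrix of \eqn{\psi} at corners, (nx+1) x (ny+1), m^2/s.
#' @export
stream_function <- function(domain, U, V, div_tol = 1e-6) {
  stopifnot(inherits(domain, "sim_domain"))
  nx <- domain$nx; ny <- domain$ny; h <- domain$h
  ps <- domain$p_str
  div <- (U[cbind(ps$i + 1L, ps$j)] - U[cbind(ps$i, ps$j)]) / h +
    (V[cbind(ps$i, ps$j + 1L)] - V[cbind(ps$i, ps$j)]) / h
  uscale <- max(abs(U), abs(V), 1e-300)
  if (max(abs(div)) * h / uscale > div_tol)
    stop_domain("velocity snapshot is not divergence-free within tolerance.")
  psi <- matrix(0, nx + 1L, ny + 1L)
  # up the left edge with u, then across each row with v
  psi[1, ] <- c(0, cumsum(U[1, ] * h))
  for (j in seq_len(ny + 1L)) {
    jv <- min(j, ny + 1L)
    psi[-1, j] <- psi[1, j] - cumsum(V[, jv] * h)
  }
  psi
}

#' Stream function of a stored solution snapshot
#'
#' @param solution A `flow_solution`.
#' @param time_index Snapshot index (default peak systole).
#' @inheritParams stream_function
#' @return Corner stream-function matrix.
#' @export
solution_stream_function <- function(solution,
                                     time_index = solution$peak_systole_index,
                                     div_tol = 1e-6) {
  stream_function(solution$domain, solution$U[[time_index]],
                  solution$V[[time_index]], div_tol)
}

# corners whose 4 surrounding cells are all dome cells
dome_interior_corners <- function(dom) {
  nx <- dom$nx; ny <- dom$ny
  dome <- dom$cell == CELL_DOME
  pad <- matrix(FALSE, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- dome
  sub <- function(di, dj) pad[(1:(nx + 1L)) + di, (1:(ny + 1L)) + dj]
  sub(0, 0) & sub(1, 0) & sub(0, 1) & sub(1, 1)
}

#' Count recirculation zones inside the aneurysm dome
#'
#' A recirculation zone is a closed-streamline region: an interior local
#' extremum of the stream function inside the dome. Numerical micro-eddies
#' are suppressed by a circulation threshold: an extremum counts only if its
#' \eqn{\psi} deviation from the dome wall streamline exceeds
#' `circulation_threshold` times the dome's maximum deviation. The count is
#' deterministic given the snapshot and never increases when the threshold
#' is raised.
#'
#' @param domain A `sim_domain` with a dome.
#' @param psi Corner stream-function matrix from [stream_function()].
#' @param circulation_threshold Fraction of the dome's |psi| deviation range
#'   (default 0.01).
#' @return Integer count of recirculation zones.
#' @export
count_recirculation_zones <- function(domain, psi,
                                      circulation_threshold = 0.01) {
  stopifnot(inherits(domain, "sim_domain"))
  interior <- dome_interior_corners(domain)
  if (!any(domain$cell == CELL_DOME)) stop_domain("domain has no dome region.")
  if (!any(interior)) return(0L)
  nx <- domain$nx; ny <- domain$ny
  # wall streamline value: psi is constant along the connected upper wall,
  # which carries the dome boundary; take it at the channel-top corner at
  # the inlet end
  psi_wall <- psi[1, domain$ny_chan + 1L]
  dev <- abs(psi - psi_wall)
  scale <- max(dev[interior])
  if (scale == 0) return(0L)
  count <- 0L
  idx <- which(interior, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    nb <- psi[cbind(pmin(pmax(rep(i + c(-1L, 0L, 1L), 3L), 1L), nx + 1L),
                    pmin(pmax(rep(j + c(-1L, 0L, 1L), each = 3L), 1L), ny + 1L))]
    ctr <- psi[i, j]
    others <- nb[-5L]
    is_max <- all(ctr > others)
    is_min <- all(ctr < others)
    if ((is_max || is_min) && abs(ctr - psi_wall) > circulation_threshold * scale)
      count <- count + 1L
  }
  count
}

#' Classify flow complexity from the recirculation-zone count
#'
#' Simple flow has at most one recirculation zone; complex flow has two or
#' more. A zero count (no closed streamline resolved) maps to simple.
#'
#' @param n_recirculation Non-negative integer count.
#' @return `"simple"` or `"complex"`. Vectorized.
#' @examples
#' classify_complexity(0:3)
#' @export
classify_complexity <- function(n_recirculation) {
  if (any(n_recirculation < 0) || any(n_recirculation != round(n_recirculation)))
    stop_domain("`n_recirculation` must be a non-negative integer.")
  ifelse(n_recirculation >= 2, "complex", "simple")
}

# bilinear interpolation of the staggered velocity at point (x, y) in m
interp_velocity <- function(dom, U, V, x, y) {
  h <- dom$h; nx <- dom$nx; ny <- dom$ny
  # u component: nodes at x = (i-1)h, y = (j-1/2)h
  fx <- x / h + 1; fy <- y / h + 0.5
  i0 <- floor(fx); j0 <- floor(fy)
  ax <- fx - i0; ay <- fy - j0
  gu <- function(i, j) {
    i <- pmin(pmax(i, 1L), nx + 1L); j <- pmin(pmax(j, 1L), ny)
    U[cbind(i, j)]
  }
  u <- (1 - ax) * (1 - ay) * gu(i0, j0) + ax * (1 - ay) * gu(i0 + 1L, j0) +
    (1 - ax) * ay * gu(i0, j0 + 1L) + ax * ay * gu(i0 + 1L, j0 + 1L)
  # v component: nodes at x = (i-1/2)h, y = (j-1)h
  fx <- x / h + 0.5; fy <- y / h + 1
  i0 <- floor(fx); j0 <- floor(fy)
  ax <- fx - i0; ay <- fy - j0
  gv <- function(i, j) {
    i <- pmin(pmax(i, 1L), nx); j <- pmin(pmax(j, 1L), ny + 1L)
    V[cbind(i, j)]
  }
  v <- (1 - ax) * (1 - ay) * gv(i0, j0) + ax * (1 - ay) * gv(i0 + 1L, j0) +
    (1 - ax) * ay * gv(i0, j0 + 1L) + ax * ay * gv(i0 + 1L, j0 + 1L)
  c(u, v)
}

point_in_fluid <- function(dom, x, y) {
  i <- floor(x / dom$h) + 1L; j <- floor(y / dom$h) + 1L
  if (i < 1L || i > dom$nx || j < 1L || j > dom$ny) return(FALSE)
  dom$fluid[i, j]
}

#' Classify the inflow jet as diffused or concentrated
#'
#' Operationalizes the visual definition: a concentrated inflow jet aims at
#' the dome tip, a diffused inflow follows the dome wall. Streamlines are
#' seeded on the fastest-inflow portion of the ostium (top decile of inward
#' speeds), traced through the dome to their first wall impingement, and the
#' jet is called concentrated when the median impingement point lies within
#' `delta_deg` of the tip direction (the neck normal through the dome apex),
#' measured as the polar angle about the dome circle center.
#'
#' @param solution A `flow_solution` on a domed domain.
#' @param time_index Snapshot index (default peak systole).
#' @param delta_deg Angular window about the tip, degrees (default 30).
#' @return List with `jet` ("diffused"/"concentrated"),
#'   `median_impingement_deg`, and `n_traced`.
#' @export
classify_inflow_jet <- function(solution,
                                time_index = solution$peak_systole_index,
                                delta_deg = 30) {
  dom <- solution$domain
  if (is.null(dom$circ)) stop_domain("domain has no dome.")
  U <- solution$U[[time_index]]; V <- solution$V[[time_index]]
  io <- dom$ostium$i; jo <- dom$ostium$j
  vin <- V[cbind(io, jo)]
  flux_in <- sum(pmax(vin, 0)) * dom$h
  if (flux_in <= 1e-12 * max(abs(U), abs(V), 1e-300) * dom$h)
    stop_domain("no inflow through the ostium segment.")
  pos <- which(vin > 0)
  thr <- quantile(vin[pos], 0.9)
  seeds <- io[pos[vin[pos] >= thr]]
  y_seed <- (jo - 1) * dom$h + 1e-3 * dom$h
  ctr <- c(dom$circ$x0, dom$circ$y0)
  ang <- c()
  step <- dom$h / 2
  for (i_s in seeds) {
    x <- (i_s - 0.5) * dom$h; y <- y_seed
    last_in <- c(x, y)
    for (it in seq_len(5000L)) {
      vel <- interp_velocity(dom, U, V, x, y)
      sp <- sqrt(sum(vel^2))
      if (sp < 1e-12) break
      # RK2 midpoint step along the streamline
      xm <- x + 0.5 * step * vel[1] / sp
      ym <- y + 0.5 * step * vel[2] / sp
      vel2 <- interp_velocity(dom, U, V, xm, ym)
      sp2 <- sqrt(sum(vel2^2))
      if (sp2 < 1e-12) break
      x <- x + step * vel2[1] / sp2
      y <- y + step * vel2[2] / sp2
      if (y < (jo - 1) * dom$h) break            # left the dome via the neck
      if (!point_in_fluid(dom, x, y)) {          # impinged on the dome wall
        d <- last_in - ctr
        ang <- c(ang, atan2(d[1], d[2]) * 180 / pi)
        break
      }
      last_in <- c(x, y)
    }
  }
  if (!length(ang)) {
    # every traced streamline recirculated back out through the neck:
    # wall-following flow
    return(list(jet = "diffused", median_impingement_deg = NA_real_,
                n_traced = 0L))
  }
  med <- median(abs(ang))
  list(jet = if (med <= delta_deg) "concentrated" else "diffused",
       median_impingement_deg = med, n_traced = length(ang))
}

#' Flow-pattern labels for a solution
#'
#' Combines the recirculation-zone count, the simple/complex call and the
#' inflow-jet call at peak systole into the per-patient label set.
#'
#' @param solution A `flow_solution` on a domed domain.
#' @param time_index Snapshot index (default peak systole).
#' @param circulation_threshold Passed to [count_recirculation_zones()].
#' @param delta_deg Passed to [classify_inflow_jet()].
#' @return One-row tibble: `n_recirculation`, `complexity`, `jet`.
#' @export
classify_flow_pattern <- function(solution,
                                  time_index = solution$peak_systole_index,
                                  circulation_threshold = 0.01,
                                  delta_deg = 30) {
  psi <- solution_stream_function(solution, time_index, div_tol = 1e-4)
  n <- count_recirculation_zones(solution$domain, psi, circulation_threshold)
  jet <- tryCatch(classify_inflow_jet(solution, time_index, delta_deg)$jet,
                  hemoflow_domain_error = function(e) NA_character_)
  tibble(n_recirculation = n, complexity = classify_complexity(n), jet = jet)
}
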