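#' Solver configuration
#'
#' Settings for the unsteady generalized-Newtonian solve. Defaults follow
#' the study protocol: blood density 1060 kg/m^3, 1 s cardiac period, 4
#' cycles simulated with data taken from the second, nonlinear iteration
#' stopped at relative tolerance 0.01 or 50 iterations, mean inlet flow rate
#' 2.6 mL/s. The inlet waveform is a single-harmonic sinusoid about that
#' mean with relative amplitude `waveform_amplitude`.
#'
#' @param density Blood density, kg/m^3.
#' @param cycle_period Cardiac period T, s.
#' @param n_cycles Number of cycles to simulate.
#' @param report_cycle Which cycle's fields are stored (1-based).
#' @param time_step Time step, s; default `cycle_period / 200`.
#' @param relative_tolerance Picard stopping tolerance on the relative
#'   velocity increment.
#' @param max_nonlinear_iterations Picard iteration cap per step.
#' @param mean_flow_rate Cycle-mean inlet flow rate, mL/s.
#' @param waveform_amplitude Relative waveform amplitude A in [0, 1).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(density = 1060, cycle_period = 1, n_cycles = 4,
                          report_cycle = 2, time_step = NULL,
                          relative_tolerance = 0.01,
                          max_nonlinear_iterations = 50,
                          mean_flow_rate = 2.6, waveform_amplitude = 0.5) {
  if (is.null(time_step)) time_step <- cycle_period / 200
  if (density <= 0 || cycle_period <= 0 || time_step <= 0)
    stop_domain("density, cycle_period and time_step must be positive.")
  if (report_cycle < 1 || report_cycle > n_cycles)
    stop_domain("`report_cycle` must lie in 1..n_cycles.")
  if (waveform_amplitude < 0 || waveform_amplitude >= 1)
    stop_domain("`waveform_amplitude` must lie in [0, 1).")
  if (relative_tolerance <= 0 || relative_tolerance >= 1)
    stop_domain("`relative_tolerance` must lie in (0, 1).")
  structure(list(density = density, cycle_period = cycle_period,
                 n_cycles = n_cycles, report_cycle = report_cycle,
                 time_step = time_step,
                 relative_tolerance = relative_tolerance,
                 max_nonlinear_iterations = max_nonlinear_iterations,
                 mean_flow_rate = mean_flow_rate,
                 waveform_amplitude = waveform_amplitude),
            class = "solver_config")
}

#' Pulsatile inlet flow-rate waveform
#'
#' \eqn{Q(t) = \bar Q (1 + A \sin(2\pi t / T))}: cycle mean \eqn{\bar Q},
#' peak systole at \eqn{t = T/4} and end diastole at \eqn{t = 3T/4} (mod T).
#'
#' @param t Time(s), s (>= 0). Vectorized.
#' @param config A [solver_config()].
#' @return Flow rate(s), mL/s.
#' @export
inlet_waveform <- function(t, config) {
  stopifnot(inherits(config, "solver_config"))
  if (any(t < 0)) stop_domain("`t` must be non-negative.")
  config$mean_flow_rate *
    (1 + config$waveform_amplitude * sin(2 * pi * t / config$cycle_period))
}

#' Parabolic inlet velocity profile
#'
#' Fully developed profile across the inlet, scaled so the area-mean speed
#' equals `Q / inlet_area` (the patient's inlet area carries the 2D channel
#' to physiologic speeds): \eqn{u(y) = 6 U y (w - y) / w^2} with mean
#' \eqn{U} and maximum \eqn{1.5 U}.
#'
#' @param Q Flow rate, mL/s (>= 0).
#' @param inlet_area Inlet cross-sectional area, mm^2 (> 0).
#' @param y Cross-channel sample positions, m, in [0, width].
#' @param width Channel width, m.
#' @return Velocities, m/s, at `y`.
#' @export
inlet_profile <- function(Q, inlet_area, y, width) {
  if (Q < 0) stop_domain("`Q` must be non-negative.")
  if (inlet_area <= 0 || width <= 0) stop_domain("inlet extent must be positive.")
  U <- Q / inlet_area                     # (mL/s) / mm^2 = m/s exactly
  6 * U * y * (width - y) / width^2
}

# --- fields on the staggered grid ------------------------------------------

# scalar shear rate sqrt(2 D:D) at cell centers (NA in solid cells)
shear_rate_centers <- function(dom, U, V) {
  nx <- dom$nx; ny <- dom$ny; h <- dom$h
  # face-defined masks: a face value is meaningful if any adjacent cell fluid
  fl <- dom$fluid
  u_def <- rbind(fl[1, , drop = FALSE], fl[-nx, ] | fl[-1, ], fl[nx, , drop = FALSE])
  v_def <- cbind(fl[, 1, drop = FALSE], fl[, -ny] | fl[, -1], fl[, ny, drop = FALSE])
  Uv <- ifelse(u_def, U, 0)
  Vv <- ifelse(v_def, V, 0)
  dudx <- (Uv[-1, , drop = FALSE] - Uv[-(nx + 1L), , drop = FALSE]) / h
  dvdy <- (Vv[, -1, drop = FALSE] - Vv[, -(ny + 1L), drop = FALSE]) / h
  # corner (i, j), i in 1..nx+1, j in 1..ny+1: du/dy with wall ghosts
  u_top <- matrix(0, nx + 1L, ny + 1L); u_bot <- matrix(0, nx + 1L, ny + 1L)
  top_def <- cbind(matrix(FALSE, nx + 1L, 1L), u_def)[, -1, drop = FALSE]
  # u_top(i,j) = U(i,j) for j<=ny else undefined; u_bot(i,j) = U(i,j-1), j>=2
  Ut <- cbind(Uv, 0); Td <- cbind(u_def, FALSE)        # (nx+1) x (ny+1)
  Ub <- cbind(0, Uv); Bd <- cbind(FALSE, u_def)
  both <- Td & Bd; only_t <- Td & !Bd; only_b <- Bd & !Td
  dudy_c <- matrix(0, nx + 1L, ny + 1L)
  dudy_c[both] <- (Ut[both] - Ub[both]) / h
  dudy_c[only_b] <- (-2 * Ub[only_b]) / h              # wall above: ghost -u
  dudy_c[only_t] <- (2 * Ut[only_t]) / h               # wall below: ghost -u
  Vr <- rbind(Vv, 0); Rd <- rbind(v_def, FALSE)        # (nx+1) x (ny+1)
  Vl <- rbind(0, Vv); Ld <- rbind(FALSE, v_def)
  both <- Rd & Ld; only_r <- Rd & !Ld; only_l <- Ld & !Rd
  dvdx_c <- matrix(0, nx + 1L, ny + 1L)
  dvdx_c[both] <- (Vr[both] - Vl[both]) / h
  dvdx_c[only_r] <- (2 * Vr[only_r]) / h               # x = 0 line: v = 0
  dvdx_c[only_l] <- 0                                  # outlet: zero gradient
  shear_c <- dudy_c + dvdx_c
  # average the 4 corners of each cell
  sc <- (shear_c[-(nx + 1L), -(ny + 1L)] + shear_c[-1, -(ny + 1L)] +
           shear_c[-(nx + 1L), -1] + shear_c[-1, -1]) / 4
  g <- sqrt(2 * dudx^2 + 2 * dvdy^2 + sc^2)
  g[!fl] <- NA_real_
  g
}

# viscosity at cell centers and at corners (fluid-neighbor average)
viscosity_fields <- function(dom, U, V, params) {
  g <- shear_rate_centers(dom, U, V)
  mu_c <- matrix(params$k, dom$nx, dom$ny)
  mu_c[dom$fluid] <- effective_viscosity(g[dom$fluid], params)
  mu_pad <- matrix(NA_real_, dom$nx + 2L, dom$ny + 2L)
  mu_pad[2:(dom$nx + 1L), 2:(dom$ny + 1L)] <- ifelse(dom$fluid, mu_c, NA_real_)
  # corner (i, j): cells (i-1, j-1), (i, j-1), (i-1, j), (i, j) -> padded
  sub <- function(di, dj) mu_pad[(1:(dom$nx + 1L)) + di, (1:(dom$ny + 1L)) + dj]
  stack <- array(c(sub(0, 0), sub(1, 0), sub(0, 1), sub(1, 1)),
                 dim = c(dom$nx + 1L, dom$ny + 1L, 4L))
  mu_k <- apply(stack, c(1, 2), function(z) {
    z <- z[!is.na(z)]
    if (length(z)) mean(z) else NA_real_
  })
  list(mu_c = mu_c, mu_corner = mu_k, gamma = g)
}

# one implicit momentum solve (u or v component) given frozen fields;
# P is the current pressure (incremental pressure-correction form)
solve_momentum <- function(dom, comp, mu_c, mu_k, Uk, Vk, old_vec, rho, idt,
                           u_in, P) {
  s <- if (comp == "u") dom$u_str else dom$v_str
  h <- dom$h; n <- s$n
  i <- s$i; j <- s$j
  if (comp == "u") {
    dE <- mu_c[cbind(i, j)] / h^2
    dW <- mu_c[cbind(i - 1L, j)] / h^2
    dN <- mu_k[cbind(i, j + 1L)] / h^2
    dS <- mu_k[cbind(i, j)] / h^2
    abar <- Uk[cbind(i, j)]
    vbar <- (Vk[cbind(i - 1L, j)] + Vk[cbind(i, j)] +
               Vk[cbind(i - 1L, j + 1L)] + Vk[cbind(i, j + 1L)]) / 4
  } else {
    dN <- mu_c[cbind(i, j)] / h^2
    dS <- mu_c[cbind(i, j - 1L)] / h^2
    dE <- mu_k[cbind(i + 1L, j)] / h^2
    dW <- mu_k[cbind(i, j)] / h^2
    abar <- (Uk[cbind(i, j - 1L)] + Uk[cbind(i + 1L, j - 1L)] +
               Uk[cbind(i, j)] + Uk[cbind(i + 1L, j)]) / 4
    vbar <- Vk[cbind(i, j)]
  }
  dN[is.na(dN)] <- 0; dS[is.na(dS)] <- 0; dE[is.na(dE)] <- 0; dW[is.na(dW)] <- 0
  aE <- dE + rho * pmax(-abar, 0) / h
  aW <- dW + rho * pmax(abar, 0) / h
  aN <- dN + rho * pmax(-vbar, 0) / h
  aS <- dS + rho * pmax(vbar, 0) / h
  diag <- rho * idt + aE + aW + aN + aS
  gradP <- if (comp == "u") {
    (P[cbind(i, j)] - P[cbind(i - 1L, j)]) / h
  } else {
    (P[cbind(i, j)] - P[cbind(i, j - 1L)]) / h
  }
  rhs <- rho * idt * old_vec - gradP
  ii <- vector("list", 5L); jj <- vector("list", 5L); xx <- vector("list", 5L)
  m <- 1L
  for (dname in c("E", "W", "N", "S")) {
    code <- s[[dname]]
    a <- switch(dname, E = aE, W = aW, N = aN, S = aS)
    unk <- code > 0L
    ii[[m]] <- which(unk); jj[[m]] <- code[unk]; xx[[m]] <- -a[unk]
    m <- m + 1L
    gh <- code == NB_GHOST
    diag[gh] <- diag[gh] + a[gh]
    out <- code == NB_OUTLET
    diag[out] <- diag[out] - a[out]
    if (comp == "u") {
      din <- code == NB_INLET
      rhs[din] <- rhs[din] + a[din] * u_in[j[din]]
    }
  }
  ii[[5L]] <- seq_len(n); jj[[5L]] <- seq_len(n); xx[[5L]] <- diag
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  as.numeric(Matrix::solve(A, rhs))
}

# Chorin projection: make (U, V) discretely divergence-free; returns the
# corrected fields and the pressure phi
project_fields <- function(dom, U, V, rho, idt) {
  h <- dom$h; nx <- dom$nx; ny <- dom$ny
  ps <- dom$p_str
  # outlet faces copy the last interior face before the divergence is formed
  out_rows <- which(dom$fluid[nx, ])
  U[nx + 1L, out_rows] <- U[nx, out_rows]
  ci <- ps$i; cj <- ps$j
  div <- (U[cbind(ci + 1L, cj)] - U[cbind(ci, cj)]) / h +
    (V[cbind(ci, cj + 1L)] - V[cbind(ci, cj)]) / h
  rhs <- -rho * idt * div
  phi_v <- as.numeric(Matrix::solve(dom$p_chol, rhs))
  Phi <- matrix(0, nx, ny)
  Phi[cbind(ci, cj)] <- phi_v
  us <- dom$u_str
  U[cbind(us$i, us$j)] <- U[cbind(us$i, us$j)] -
    (1 / (rho * idt)) * (Phi[cbind(us$i, us$j)] - Phi[cbind(us$i - 1L, us$j)]) / h
  vs <- dom$v_str
  V[cbind(vs$i, vs$j)] <- V[cbind(vs$i, vs$j)] -
    (1 / (rho * idt)) * (Phi[cbind(vs$i, vs$j)] - Phi[cbind(vs$i, vs$j - 1L)]) / h
  U[nx + 1L, out_rows] <- U[nx + 1L, out_rows] +
    (1 / (rho * idt)) * 2 * Phi[nx, out_rows] / h
  list(U = U, V = V, Phi = Phi)
}

# advance one time step: Picard iteration over viscosity + advection with
# incremental pressure-correction projection inside the loop; returns fields
# + iteration diagnostics
advance_step <- function(dom, params, config, U, V, P, u_in, idt) {
  rho <- config$density
  U_old <- U; V_old <- V
  U_old[1, seq_len(dom$ny_chan)] <- u_in           # Dirichlet inlet
  Uk <- U_old; Vk <- V_old; Pk <- P
  iters <- 0L; err <- Inf
  repeat {
    iters <- iters + 1L
    vf <- viscosity_fields(dom, Uk, Vk, params)
    ustar <- solve_momentum(dom, "u", vf$mu_c, vf$mu_corner, Uk, Vk,
                            U_old[cbind(dom$u_str$i, dom$u_str$j)], rho, idt,
                            u_in, Pk)
    vstar <- solve_momentum(dom, "v", vf$mu_c, vf$mu_corner, Uk, Vk,
                            V_old[cbind(dom$v_str$i, dom$v_str$j)], rho, idt,
                            u_in, Pk)
    Un <- Uk; Vn <- Vk
    Un[cbind(dom$u_str$i, dom$u_str$j)] <- ustar
    Un[1, seq_len(dom$ny_chan)] <- u_in
    Vn[cbind(dom$v_str$i, dom$v_str$j)] <- vstar
    pr <- project_fields(dom, Un, Vn, rho, idt)
    Un <- pr$U; Vn <- pr$V
    Pk <- Pk + pr$Phi                              # pressure increment
    num <- sum((Un - Uk)^2) + sum((Vn - Vk)^2)
    den <- sum(Un^2) + sum(Vn^2)
    err <- sqrt(num / max(den, 1e-300))
    Uk <- Un; Vk <- Vn
    if (err < config$relative_tolerance || iters >= config$max_nonlinear_iterations)
      break
  }
  if (!all(is.finite(Uk)) || max(abs(Uk)) > 1e3)
    abort("solver failure: velocity norm diverged.", class = "hemoflow_solver_error")
  list(U = Uk, V = Vk, P = Pk, iters = iters, err = err)
}

new_flow_solution <- function(dom, params, config, times, U_list, V_list,
                              P_list, Q_t, log) {
  ps <- which.max(Q_t); ed <- which.min(Q_t)
  structure(list(domain = dom, params = params, config = config,
                 times = times, U = U_list, V = V_list, P = P_list,
                 Q_t = Q_t, peak_systole_index = ps, end_diastole_index = ed,
                 convergence = log),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "flow_solution: %d stored snapshots (t in [%.3g, %.3g] s), PS at t = %.3g s, ED at t = %.3g s\n",
    length(x$times), min(x$times), max(x$times),
    x$times[x$peak_systole_index], x$times[x$end_diastole_index]))
  if (any(!x$convergence$converged))
    cat(sprintf("  %d/%d steps hit the nonlinear iteration cap\n",
                sum(!x$convergence$converged), nrow(x$convergence)))
  invisible(x)
}

#' Solve the unsteady generalized-Newtonian flow problem
#'
#' Advances the incompressible momentum equation
#' \eqn{\rho(\partial u/\partial t + u\cdot\nabla u) = -\nabla p +
#' \nabla\cdot(\mu(\dot\gamma)\nabla u)} with \eqn{\nabla\cdot u = 0} and
#' Casson apparent viscosity over `n_cycles` cardiac cycles on the staggered
#' grid, using semi-implicit (implicit upwind advection + implicit
#' variable-viscosity diffusion) stepping with Chorin projection. Within
#' each step the viscosity/advection nonlinearity is Picard-iterated until
#' the relative velocity increment drops below `relative_tolerance` or
#' `max_nonlinear_iterations` is hit (a warning flags steps that hit the
#' cap). Walls are rigid and no-slip; the inlet carries the pulsatile
#' parabolic profile; the outlet is traction-free (zero normal stress).
#' Fields are stored for `report_cycle` only.
#'
#' @param domain A [build_2d_domain()] result.
#' @param params A [casson_params()] object.
#' @param config A [solver_config()].
#' @param inlet_area Patient inlet area, mm^2; default the circular-lumen
#'   area \eqn{(\pi/4) d^2} of the parent vessel.
#' @param quiet Suppress the iteration-cap warning.
#' @return A `flow_solution`: stored times (s), velocity/pressure fields,
#'   waveform samples and PS/ED snapshot indices.
#' @export
solve_unsteady <- function(domain, params, config = solver_config(),
                           inlet_area = NULL, quiet = FALSE) {
  stopifnot(inherits(domain, "sim_domain"), inherits(params, "casson_params"),
            inherits(config, "solver_config"))
  if (is.null(inlet_area)) inlet_area <- (pi / 4) * (domain$width * 1e3)^2
  dt <- config$time_step
  n_steps <- ceiling(config$n_cycles * config$cycle_period / dt)
  rep_lo <- (config$report_cycle - 1) * config$cycle_period
  rep_hi <- config$report_cycle * config$cycle_period
  y_in <- (seq_len(domain$ny_chan) - 0.5) * domain$h
  U <- matrix(0, domain$nx + 1L, domain$ny)
  V <- matrix(0, domain$nx, domain$ny + 1L)
  P <- matrix(0, domain$nx, domain$ny)
  times <- c(); U_list <- list(); V_list <- list(); P_list <- list(); Q_t <- c()
  log <- data.frame(step = integer(), t = numeric(), iters = integer(),
                    err = numeric(), converged = logical())
  for (n in seq_len(n_steps)) {
    t_new <- n * dt
    Q <- inlet_waveform(t_new, config)
    u_in <- inlet_profile(Q, inlet_area, y_in, domain$width)
    st <- advance_step(domain, params, config, U, V, P, u_in, 1 / dt)
    U <- st$U; V <- st$V; P <- st$P
    log <- rbind(log, data.frame(step = n, t = t_new, iters = st$iters,
                                 err = st$err,
                                 converged = st$err < config$relative_tolerance))
    if (t_new > rep_lo + 1e-12 && t_new <= rep_hi + 1e-12) {
      times <- c(times, t_new)
      U_list[[length(U_list) + 1L]] <- U
      V_list[[length(V_list) + 1L]] <- V
      P_list[[length(P_list) + 1L]] <- st$P
      Q_t <- c(Q_t, Q)
    }
  }
  if (!quiet && any(!log$converged))
    warn(sprintf("%d/%d steps stopped at the nonlinear iteration cap (worst residual %.3g).",
                 sum(!log$converged), nrow(log), max(log$err)))
  new_flow_solution(domain, params, config, times, U_list, V_list, P_list,
                    Q_t, log)
}

#' Steady-state solve at a fixed flow rate
#'
#' Pseudo-time marches the same discretization with a constant inflow until
#' the step-to-step relative change falls below `steady_tol`. Used for
#' validation against analytic channel solutions and as the quasi-steady
#' oracle for slow pulsatile runs.
#'
#' @param domain A [build_2d_domain()] result.
#' @param params A [casson_params()] object.
#' @param Q Inlet flow rate, mL/s.
#' @param config A [solver_config()] (its density/tolerances are reused).
#' @param inlet_area Inlet area, mm^2 (default as in [solve_unsteady()]).
#' @param steady_tol Relative step-to-step change declaring steady state.
#' @param max_steps Pseudo-time step cap (default 800).
#' @return A single-snapshot `flow_solution`.
#' @export
steady_solve <- function(domain, params, Q, config = solver_config(),
                         inlet_area = NULL, steady_tol = 1e-6,
                         max_steps = 800) {
  stopifnot(inherits(domain, "sim_domain"), inherits(params, "casson_params"))
  if (is.null(inlet_area)) inlet_area <- (pi / 4) * (domain$width * 1e3)^2
  y_in <- (seq_len(domain$ny_chan) - 0.5) * domain$h
  u_in <- inlet_profile(Q, inlet_area, y_in, domain$width)
  U <- matrix(0, domain$nx + 1L, domain$ny)
  V <- matrix(0, domain$nx, domain$ny + 1L)
  P <- matrix(0, domain$nx, domain$ny)
  # pseudo step: advective scale, capped at the cell viscous time (the
  # pressure increment per projection scales with 1/dt, so an unbounded dt
  # stalls the pressure build-up at low flow rates)
  dt <- min(0.25 * domain$L / max(max(u_in), 1e-9),
            config$density * domain$h^2 / params$k)
  change <- Inf; st <- NULL
  for (n in seq_len(max_steps)) {
    st <- advance_step(domain, params, config, U, V, P, u_in, 1 / dt)
    num <- sum((st$U - U)^2) + sum((st$V - V)^2)
    den <- max(sum(st$U^2) + sum(st$V^2), 1e-300)
    change <- sqrt(num / den)
    U <- st$U; V <- st$V; P <- st$P
    if (change < steady_tol) break
  }
  if (change >= steady_tol)
    warn(sprintf("steady_solve stopped at max_steps with relative change %.3g.", change))
  log <- data.frame(step = 1L, t = 0, iters = n, err = change,
                    converged = change < steady_tol)
  new_flow_solution(domain, params, config, times = 0, U_list = list(U),
                    V_list = list(V), P_list = list(P), Q_t = Q, log)
}

#' Extract cell-centered fields at a stored time as a tibble
#'
#' @param solution A `flow_solution`.
#' @param time_index Index into `solution$times` (default peak systole).
#' @return Tibble with cell centers (m), region, velocity components and
#'   speed (m/s), shear rate (1/s), viscosity (Pa s) and pressure (Pa).
#' @export
solution_fields <- function(solution, time_index = solution$peak_systole_index) {
  dom <- solution$domain
  U <- solution$U[[time_index]]; V <- solution$V[[time_index]]
  P <- solution$P[[time_index]]
  g <- shear_rate_centers(dom, U, V)
  fl <- dom$fluid
  idx <- which(fl, arr.ind = TRUE)
  uc <- (U[cbind(idx[, 1], idx[, 2])] + U[cbind(idx[, 1] + 1L, idx[, 2])]) / 2
  vc <- (V[cbind(idx[, 1], idx[, 2])] + V[cbind(idx[, 1], idx[, 2] + 1L)]) / 2
  tibble(x = dom$xc[idx[, 1]], y = dom$yc[idx[, 2]],
         region = ifelse(dom$cell[idx] == CELL_DOME, "dome", "parent"),
         u = uc, v = vc, speed = sqrt(uc^2 + vc^2),
         shear_rate = g[idx],
         viscosity = effective_viscosity(g[idx], solution$params),
         pressure = P[idx])
}

#' @export
autoplot.flow_solution <- function(object,
                                   time_index = object$peak_systole_index,
                                   field = "speed", ...) {
  d <- solution_fields(object, time_index)
  ggplot(d, aes(x = .data$x * 1e3, y = .data$y * 1e3,
                fill = .data[[field]])) +
    geom_raster() +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = "x (mm)", y = "y (mm)", fill = field,
         title = sprintf("%s at t = %.3g s", field, object$times[time_index])) +
    theme_minimal()
}
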