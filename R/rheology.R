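#' Casson model parameters
#'
#' The Casson constitutive law for whole blood,
#' \eqn{\sqrt{\tau} = \sqrt{\tau_y} + \sqrt{k \dot\gamma}} for
#' \eqn{\tau > \tau_y} (and \eqn{\dot\gamma = 0} below the yield stress),
#' rearranges to an apparent viscosity
#' \eqn{\mu(\dot\gamma) = (\sqrt{\tau_y/\dot\gamma} + \sqrt{k})^2}:
#' shear-thinning from a low-shear maximum toward the plateau \eqn{k} at
#' high shear. Because the apparent viscosity diverges as
#' \eqn{\dot\gamma \to 0}, evaluation clamps the shear rate at
#' `shear_floor` (default 1 s^-1, the lowest shear rate a capillary
#' viscometer typically calibrates).
#'
#' @param tau_y Yield stress, Pa (>= 0).
#' @param k Casson plateau viscosity, Pa s (> 0). Chosen in Pa s so that
#'   \eqn{\mu \to k} at high shear, matching the measured high-shear plateau.
#' @param shear_floor Regularization floor for the shear rate, s^-1 (> 0).
#' @return An object of class `casson_params`.
#' @examples
#' casson_params(tau_y = 0.005, k = 0.0035)
#' @export
casson_params <- function(tau_y, k, shear_floor = 1) {
  if (!is.numeric(tau_y) || length(tau_y) != 1L || is.na(tau_y) || tau_y < 0)
    stop_domain("`tau_y` must be a single non-negative number (Pa).")
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0)
    stop_domain("`k` must be a single positive number (Pa s).")
  if (!is.numeric(shear_floor) || length(shear_floor) != 1L || shear_floor <= 0)
    stop_domain("`shear_floor` must be a single positive number (1/s).")
  structure(list(tau_y = as.numeric(tau_y), k = as.numeric(k),
                 shear_floor = as.numeric(shear_floor)),
            class = "casson_params")
}

#' @export
print.casson_params <- function(x, ...) {
  cat(sprintf(
    "Casson parameters: tau_y = %.4g Pa, k = %.4g Pa s (%.3g cP plateau), shear floor %.3g 1/s\n",
    x$tau_y, x$k, pa_s_to_cp(x$k), x$shear_floor))
  invisible(x)
}

#' Apparent (effective) viscosity of the Casson model
#'
#' Evaluates \eqn{\mu(\dot\gamma) = (\sqrt{\tau_y/\dot\gamma} + \sqrt{k})^2}
#' with the shear rate clamped below at `params$shear_floor`. Vectorized over
#' `gamma_dot`.
#'
#' @param gamma_dot Shear rate(s), s^-1 (>= 0).
#' @param params A [casson_params()] object.
#' @return Apparent viscosity in Pa s, same length as `gamma_dot`.
#' @examples
#' p <- casson_params(0.005, 0.0035)
#' effective_viscosity(c(1, 10, 100, 1000), p)
#' @export
effective_viscosity <- function(gamma_dot, params) {
  stopifnot(inherits(params, "casson_params"))
  if (any(!is.finite(gamma_dot)) || any(gamma_dot < 0))
    stop_domain("`gamma_dot` must be finite and non-negative.")
  if (params$tau_y == 0)                 # exact Newtonian collapse
    return(rep(params$k, length(gamma_dot)))
  g <- pmax(gamma_dot, params$shear_floor)
  (sqrt(params$tau_y / g) + sqrt(params$k))^2
}

#' Viscosity curve container
#'
#' A per-patient whole-blood viscosity profile: apparent viscosity (cP)
#' measured at an increasing series of shear rates (s^-1). Returned as a
#' tibble of class `viscosity_curve` with columns `shear_rate_per_s` and
#' `viscosity_cP` plus a `patient_id` attribute.
#'
#' @param shear_rates Strictly increasing positive shear rates, s^-1.
#' @param viscosities Positive apparent viscosities, cP.
#' @param patient_id Identifier carried through the pipeline.
#' @return A `viscosity_curve` tibble.
#' @export
viscosity_curve <- function(shear_rates, viscosities, patient_id = NA_character_) {
  if (length(shear_rates) != length(viscosities))
    stop_domain("`shear_rates` and `viscosities` must have equal length.")
  if (any(shear_rates <= 0) || any(diff(shear_rates) <= 0))
    stop_domain("`shear_rates` must be positive and strictly increasing.")
  if (any(viscosities <= 0))
    stop_domain("`viscosities` must be positive (cP).")
  out <- tibble(shear_rate_per_s = as.numeric(shear_rates),
                viscosity_cP = as.numeric(viscosities))
  attr(out, "patient_id") <- patient_id
  class(out) <- c("viscosity_curve", class(out))
  out
}

#' Read / write a viscosity curve CSV
#'
#' File format: CSV with header `shear_rate_per_s,viscosity_cP`, one row per
#' measurement.
#'
#' @param path File path.
#' @param patient_id Identifier attached to the curve on read.
#' @return `read_viscosity_curve()` returns a [viscosity_curve()];
#'   `write_viscosity_curve()` returns `path` invisibly.
#' @export
read_viscosity_curve <- function(path, patient_id = NA_character_) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("shear_rate_per_s", "viscosity_cP")
  if (!all(need %in% names(d)))
    stop_domain("viscosity curve CSV must have columns shear_rate_per_s, viscosity_cP")
  viscosity_curve(d$shear_rate_per_s, d$viscosity_cP, patient_id)
}

#' @rdname read_viscosity_curve
#' @param curve A [viscosity_curve()].
#' @export
write_viscosity_curve <- function(curve, path) {
  write.csv(as.data.frame(curve)[, c("shear_rate_per_s", "viscosity_cP")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit the Casson model to a measured viscosity curve
#'
#' Converts each measurement to a shear stress
#' \eqn{\tau_i = \mu_i \dot\gamma_i} (SI units) and fits the Casson law in
#' its exactly linear form, regressing \eqn{\sqrt{\tau}} on
#' \eqn{\sqrt{\dot\gamma}}: the squared slope is \eqn{k} and the squared
#' intercept is \eqn{\tau_y}. Because viscometer noise is multiplicative,
#' \eqn{\mathrm{Var}(\sqrt{\tau_i}) \propto \tau_i}, so the regression is
#' weighted by \eqn{1/\tau_i}; on noiseless data the fit is exact either
#' way. A negative intercept (super-Newtonian noise) is clamped:
#' \eqn{\tau_y = 0} and \eqn{k} refit through the origin. The
#' transformed-space fit is deterministic and needs no initialization.
#'
#' @param curve A [viscosity_curve()] (>= 3 points).
#' @param shear_floor Regularization floor passed to the returned
#'   [casson_params()].
#' @return An object of class `casson_fit`: list with `params`
#'   ([casson_params()]), `residual` (root-mean-square residual in sqrt(Pa)),
#'   `n`, `clamped` (logical), and the fitted curve.
#' @examples
#' cur <- synth_viscosity_curve(casson_params(0.004, 0.0032), 50, 0, seed = 1)
#' fit_casson(cur)
#' @export
fit_casson <- function(curve, shear_floor = 1) {
  stopifnot(inherits(curve, "viscosity_curve") || is.data.frame(curve))
  g <- curve$shear_rate_per_s
  mu <- curve$viscosity_cP
  if (length(g) < 3L)
    stop_domain("Casson fit needs at least 3 measurements.")
  if (any(mu <= 0)) stop_domain("viscosities must be positive.")
  tau <- cp_to_pa_s(mu) * g
  x <- sqrt(g)
  y <- sqrt(tau)
  wts <- 1 / tau
  fit <- lm(y ~ x, weights = wts)
  icpt <- coef(fit)[[1]]
  slope <- coef(fit)[[2]]
  clamped <- FALSE
  if (icpt < 0) {
    clamped <- TRUE
    slope <- sum(wts * x * y) / sum(wts * x * x)  # refit through the origin
    icpt <- 0
  }
  if (slope <= 0) stop_domain("Casson fit failed: non-positive slope (data not shear-thinning?).")
  resid <- sqrt(mean((y - (icpt + slope * x))^2))
  structure(list(
    params = casson_params(tau_y = icpt^2, k = slope^2, shear_floor = shear_floor),
    residual = resid, n = length(g), clamped = clamped,
    curve = curve), class = "casson_fit")
}

#' @export
print.casson_fit <- function(x, ...) {
  cat(sprintf("Casson fit (n = %d points): tau_y = %.4g Pa, k = %.4g Pa s, RMS residual %.3g sqrt(Pa)%s\n",
              x$n, x$params$tau_y, x$params$k, x$residual,
              if (x$clamped) " [yield stress clamped at 0]" else ""))
  invisible(x)
}

#' @export
tidy.casson_fit <- function(x, ...) {
  tibble(term = c("tau_y", "k"),
         estimate = c(x$params$tau_y, x$params$k),
         unit = c("Pa", "Pa.s"))
}

#' @export
glance.casson_fit <- function(x, ...) {
  tibble(tau_y = x$params$tau_y, k = x$params$k,
         residual = x$residual, n = x$n, clamped = x$clamped)
}

#' Analytic Casson flow rate in a circular tube
#'
#' Closed-form volumetric flow rate for steady, fully developed Casson flow
#' in a tube of radius `radius` under pressure gradient `pressure_gradient`,
#' with an unyielded plug core of radius \eqn{\tau_y / (G/2)}. With
#' \eqn{\tau_w = G R / 2} and \eqn{\xi = \tau_y / \tau_w}:
#' \deqn{Q = \frac{\pi G R^4}{8 k}\left(1 - \frac{16}{7}\xi^{1/2} +
#'   \frac{4}{3}\xi - \frac{1}{21}\xi^4\right), \quad \xi < 1,}
#' and \eqn{Q = 0} when the wall stress does not exceed the yield stress.
#' At \eqn{\tau_y = 0} this is the Poiseuille law \eqn{\pi G R^4 / (8k)}.
#' Serves as the analytic oracle for solver validation.
#'
#' @param radius Tube radius, m (> 0).
#' @param pressure_gradient Driving pressure gradient G = -dp/dx, Pa/m (>= 0).
#' @param params A [casson_params()] object.
#' @return Volumetric flow rate, m^3/s.
#' @export
casson_tube_flow_rate <- function(radius, pressure_gradient, params) {
  stopifnot(inherits(params, "casson_params"))
  if (radius <= 0) stop_domain("`radius` must be positive.")
  if (pressure_gradient < 0) stop_domain("`pressure_gradient` must be non-negative.")
  if (pressure_gradient == 0) return(0)
  tau_w <- pressure_gradient * radius / 2
  xi <- params$tau_y / tau_w
  if (xi >= 1) return(0)
  (pi * pressure_gradient * radius^4 / (8 * params$k)) *
    (1 - (16 / 7) * sqrt(xi) + (4 / 3) * xi - (1 / 21) * xi^4)
}

#' Synthesize a viscosity curve from Casson parameters
#'
#' Emulates a capillary-viscometer measurement: log-spaced shear rates on
#' [1, 1000] s^-1 and apparent viscosities from [effective_viscosity()]
#' perturbed by multiplicative Gaussian noise.
#'
#' @param params A [casson_params()] object.
#' @param n_points Number of measurements (>= 3).
#' @param noise_sd Relative (multiplicative) noise SD, e.g. 0.02 for 2%.
#' @param seed Integer seed; the draw is reproducible and leaves the global
#'   RNG state untouched.
#' @param patient_id Identifier attached to the curve.
#' @return A [viscosity_curve()].
#' @export
synth_viscosity_curve <- function(params, n_points = 30, noise_sd = 0.02,
                                  seed = 1L, patient_id = NA_character_) {
  stopifnot(inherits(params, "casson_params"))
  if (n_points < 3) stop_domain("`n_points` must be >= 3.")
  if (noise_sd < 0) stop_domain("`noise_sd` must be >= 0.")
  g <- 10^seq(0, 3, length.out = n_points)
  mu <- pa_s_to_cp(effective_viscosity(g, params))
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, rnorm(n_points, 0, noise_sd))
    mu <- mu * (1 + noise)
    if (any(mu <= 0)) stop_domain("noise drew a non-positive viscosity; reduce `noise_sd`.")
  }
  viscosity_curve(g, mu, patient_id)
}

#' @export
autoplot.viscosity_curve <- function(object, fit = NULL, ...) {
  p <- ggplot(object, aes(x = .data$shear_rate_per_s, y = .data$viscosity_cP)) +
    geom_point(size = 1) +
    scale_x_log10() +
    labs(x = "shear rate (1/s)", y = "apparent viscosity (cP)",
         title = "Whole-blood viscosity profile") +
    theme_minimal()
  if (!is.null(fit)) {
    g <- 10^seq(0, 3, length.out = 200)
    d <- tibble(shear_rate_per_s = g,
                viscosity_cP = pa_s_to_cp(effective_viscosity(g, fit$params)))
    p <- p + geom_line(data = d, colour = "firebrick")
  }
  p
}
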