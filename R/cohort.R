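#' Cohort generator configuration
#'
#' Defaults reproduce the study conditions: 16 small (height <= 5 mm) and 5
#' large (> 5 mm) virtual patients with per-group morphology distributions
#' centered on the reported group means and SDs (height 3.4 +/- 0.8 vs
#' 6.2 +/- 2.4 mm; width 4.5 +/- 1.5 vs 7.4 +/- 2.5 mm; ostium 4.5 +/- 0.8
#' vs 5.9 +/- 1.1 mm), a parent artery of 4 mm nominal diameter, and Casson
#' rheology drawn uniformly from tau_y in [0.002, 0.02] Pa and k in
#' [0.003, 0.005] Pa s with a 2% viscometer noise model. Only morphology is
#' calibrated to the reported tables; hemodynamics must emerge from the
#' solver.
#'
#' @param n_small,n_large Group sizes.
#' @param height_mean,height_sd,width_mean,width_sd,ostium_mean,ostium_sd
#'   Length-2 numeric vectors `(small, large)`, mm.
#' @param cutoff Size cutoff, mm.
#' @param parent_diameter_mean,parent_diameter_sd Parent artery diameter
#'   distribution, mm.
#' @param tau_y_range,k_range Uniform ranges for the Casson draws (Pa, Pa s).
#' @param noise_sd Relative viscometer noise.
#' @param n_curve_points Measurements per synthetic viscosity curve.
#' @param seed Master seed; every draw derives from it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_small = 16, n_large = 5,
                          height_mean = c(3.4, 6.2), height_sd = c(0.8, 2.4),
                          width_mean = c(4.5, 7.4), width_sd = c(1.5, 2.5),
                          ostium_mean = c(4.5, 5.9), ostium_sd = c(0.8, 1.1),
                          cutoff = 5,
                          parent_diameter_mean = 4, parent_diameter_sd = 0.3,
                          tau_y_range = c(0.002, 0.02),
                          k_range = c(0.003, 0.005),
                          noise_sd = 0.02, n_curve_points = 50,
                          seed = 1L) {
  if (n_small < 0 || n_large < 0) stop_domain("group sizes must be >= 0.")
  if (any(c(height_sd, width_sd, ostium_sd, parent_diameter_sd) < 0))
    stop_domain("SDs must be >= 0.")
  if (height_mean[1] > cutoff + 3 * height_sd[1])
    stop_domain("infeasible: small-group height mean more than 3 SD above the cutoff.")
  if (height_mean[2] + 3 * height_sd[2] < cutoff)
    stop_domain("infeasible: large-group heights cannot exceed the cutoff.")
  structure(list(n_small = n_small, n_large = n_large,
                 height_mean = height_mean, height_sd = height_sd,
                 width_mean = width_mean, width_sd = width_sd,
                 ostium_mean = ostium_mean, ostium_sd = ostium_sd,
                 cutoff = cutoff,
                 parent_diameter_mean = parent_diameter_mean,
                 parent_diameter_sd = parent_diameter_sd,
                 tau_y_range = tau_y_range, k_range = k_range,
                 noise_sd = noise_sd, n_curve_points = n_curve_points,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# truncated-normal draw by redraw (bounds are never far in the configured
# regimes, so rejection is cheap)
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf,
                        max_tries = 10000L) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (t in seq_len(max_tries)) {
      v <- rnorm(1, mean, sd)
      if (v > lower && v <= upper) { out[i] <- v; break }
      if (t == max_tries) stop_domain("truncated-normal rejection failed; bounds infeasible.")
    }
  }
  out
}

#' Generate a virtual patient cohort
#'
#' For each patient: draw height from the group's truncated normal
#' (positive, and respecting the 5 mm group cutoff), width and ostium
#' conditionally (redrawn until positive and W >= O), fit the closest
#' spherical cap through (height, width, ostium) with extra weight on
#' height (redrawing if the fitted cap's height crosses the group cutoff),
#' draw the parent diameter and Casson parameters, synthesize a noisy
#' viscosity curve, and refit it with [fit_casson()] so every patient
#' exercises the rheology pipeline end to end. Fully deterministic given
#' `config$seed` (per-patient seeds are derived from it); the global RNG
#' state is left untouched.
#'
#' @param config A [cohort_config()].
#' @return Tibble of class `virtual_cohort`: one row per patient with
#'   identifiers, group, target and cap-fitted morphology, inlet area,
#'   generating and refitted Casson parameters, and list-columns `shape`
#'   ([shape_params()]), `curve` ([viscosity_curve()]), `casson`
#'   (refitted [casson_params()]).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n_tot <- config$n_small + config$n_large
  groups <- rep(c("small", "large"), c(config$n_small, config$n_large))
  rows <- withr::with_seed(config$seed, {
    patient_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
    lapply(seq_len(n_tot), function(i) {
      g <- if (groups[i] == "small") 1L else 2L
      withr::with_seed(patient_seeds[i], {
        lo <- if (g == 1L) 0 else config$cutoff
        hi <- if (g == 1L) config$cutoff else Inf
        shape <- NULL
        for (try in 1:200) {
          H <- rtrunc_norm(1, config$height_mean[g], config$height_sd[g], lo, hi)
          repeat {
            W <- rnorm(1, config$width_mean[g], config$width_sd[g])
            O <- rnorm(1, config$ostium_mean[g], config$ostium_sd[g])
            if (W > 0.5 && O > 0.5 && W >= O) break
          }
          d_par <- rtrunc_norm(1, config$parent_diameter_mean,
                               config$parent_diameter_sd, lower = 2)
          cand <- cap_from_morphometrics(H, W, O, parent_diameter = d_par,
                                         height_weight = 4)
          Hfit <- cap_closed_form(cand)$height
          ok <- if (g == 1L) Hfit <= config$cutoff else Hfit > config$cutoff
          if (ok) { shape <- cand; break }
        }
        if (is.null(shape))
          stop_domain("could not generate a cap respecting the group cutoff.")
        tau_y <- runif(1, config$tau_y_range[1], config$tau_y_range[2])
        k <- runif(1, config$k_range[1], config$k_range[2])
        curve_seed <- sample.int(.Machine$integer.max - 1L, 1)
        pid <- sprintf("P%02d", i)
        curve <- synth_viscosity_curve(casson_params(tau_y, k),
                                       n_points = config$n_curve_points,
                                       noise_sd = config$noise_sd,
                                       seed = curve_seed, patient_id = pid)
        fit <- fit_casson(curve)
        cf <- cap_closed_form(shape)
        tibble(patient_id = pid, group = groups[i],
               target_height_mm = H, target_width_mm = W, target_ostium_mm = O,
               height_mm = cf$height, width_mm = cf$width,
               ostium_mm = 2 * cf$neck_radius,
               dome_radius_mm = shape$dome_radius,
               neck_offset_mm = shape$neck_offset,
               parent_diameter_mm = shape$parent_diameter,
               inlet_area_mm2 = (pi / 4) * shape$parent_diameter^2,
               tau_y_true = tau_y, k_true = k,
               tau_y_fit = fit$params$tau_y, k_fit = fit$params$k,
               shape = list(shape), curve = list(curve),
               casson = list(fit$params))
      })
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("virtual_cohort", class(out))
  out
}

#' Run the full synthetic study
#'
#' For every patient in the cohort: triangulate the dome and measure its
#' morphometrics, build the 2D simulation domain, run the pulsatile
#' generalized-Newtonian solve with the patient's refitted Casson
#' parameters and inlet area, summarize the dome hemodynamics, and classify
#' the flow pattern at peak systole. Patients whose solve fails are flagged
#' and excluded from the group tables; the run continues. Results and the
#' four group tables can be written to `out_dir` (CSV + JSON + manifest).
#'
#' @param cohort A [generate_cohort()] result.
#' @param solver_config A [solver_config()].
#' @param mesh_size 2D grid spacing, mm.
#' @param mesh_resolution 3D dome-mesh edge length for morphometry, mm.
#' @param alpha Significance level for the group tables.
#' @param cutoff Size cutoff for classification, mm.
#' @param out_dir Optional output directory for [write_results()].
#' @param quiet Suppress per-patient progress messages.
#' @return Object of class `study_result`: list with `patients` (per-patient
#'   tibble), `tables` (list of four tibbles), `failures` (tibble), and the
#'   configs used.
#' @export
run_study <- function(cohort, solver_config = solver_config(),
                      mesh_size = 0.25, mesh_resolution = 0.2, alpha = 0.05,
                      cutoff = 5, out_dir = NULL, quiet = FALSE) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    res <- tryCatch({
      shape <- cohort$shape[[i]]
      dm <- make_dome_mesh(shape, resolution = mesh_resolution)
      morph <- measure_morphometrics(dm$mesh, dm$neck, cutoff = cutoff)
      dom <- build_2d_domain(shape, mesh_size = mesh_size)
      sol <- solve_unsteady(dom, cohort$casson[[i]], solver_config,
                            inlet_area = cohort$inlet_area_mm2[i],
                            quiet = TRUE)
      hemo <- summarize_hemodynamics(sol)
      pat <- classify_flow_pattern(sol)
      iters <- sol$convergence
      if (!quiet)
        message(sprintf(
          "%s (%s): %d steps, median %d nonlinear iters, worst residual %.3g",
          pid, cohort$group[i], nrow(iters), median(iters$iters),
          max(iters$err)))
      dplyr::bind_cols(
        tibble(patient_id = pid, group = cohort$group[i]),
        morph, hemo, pat)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- tibble(patient_id = pid,
                                            reason = conditionMessage(res))
      if (!quiet) message(sprintf("%s FAILED: %s", pid, conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  patients <- dplyr::bind_rows(rows)
  failures <- if (length(fails)) dplyr::bind_rows(fails) else
    tibble(patient_id = character(), reason = character())
  tables <- if (nrow(patients)) make_group_tables(patients, alpha = alpha) else NULL
  out <- structure(list(patients = patients, tables = tables,
                        failures = failures, solver_config = solver_config,
                        mesh_size = mesh_size, alpha = alpha,
                        seed = attr(cohort, "seed")),
                   class = "study_result")
  if (!is.null(out_dir)) write_results(out, out_dir)
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result: %d patients analyzed (%d failed)\n",
              nrow(x$patients), nrow(x$failures)))
  if (!is.null(x$tables)) {
    for (nm in names(x$tables)) {
      cat("\n--", nm, "--\n")
      print(as.data.frame(x$tables[[nm]][, c("variable", "small_mean",
                                             "large_mean", "p", "significant")]),
            digits = 3, row.names = FALSE)
    }
  }
  invisible(x)
}
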