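#' Mean and standard deviation of one group
#'
#' Sample mean and SD (n - 1 denominator). A single observation reports
#' SD = 0 with `degenerate = TRUE`.
#'
#' @param x Numeric values (n >= 1).
#' @return One-row tibble: `n`, `mean`, `sd`, `degenerate`.
#' @examples
#' group_summary(c(2, 4, 6))   # 4 +/- 2
#' @export
group_summary <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 1L) stop_domain("empty group.")
  tibble(n = length(x), mean = mean(x),
         sd = if (length(x) > 1L) sd(x) else 0,
         degenerate = length(x) == 1L)
}

# Exact two-sided Mann-Whitney p by complete enumeration of group
# assignments (midranks, so ties are handled exactly). The permutation
# distribution of the rank sum is symmetric about m(N+1)/2, so the
# two-sided p is P(|W - E W| >= |W_obs - E W|).
mann_whitney_exact <- function(x, y) {
  m <- length(x); N <- m + length(y)
  r <- rank(c(x, y))
  W_obs <- sum(r[seq_len(m)])
  EW <- m * (N + 1) / 2
  sets <- combn(N, m)
  W_all <- colSums(matrix(r[sets], nrow = m))
  mean(abs(W_all - EW) >= abs(W_obs - EW) - 1e-9)
}

# Normal approximation with tie correction (no continuity correction)
mann_whitney_approx <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  EW <- m * (N + 1) / 2
  ties <- table(r)
  corr <- sum(ties^3 - ties) / (N * (N - 1))
  varW <- m * n / 12 * ((N + 1) - corr)
  if (varW <= 0) return(1)
  2 * pnorm(-abs(W - EW) / sqrt(varW))
}

#' Two-sample comparison with a normality gate
#'
#' The two-group testing protocol for small versus large aneurysms:
#' Shapiro-Wilk normality on each group at the 0.05 level; when both groups
#' pass, a two-sided pooled-variance (Student) t test; otherwise a
#' two-sided Mann-Whitney rank-sum test, computed by exhaustive permutation
#' enumeration for pooled n <= 20 (exact even with ties) and by the
#' tie-corrected normal approximation above that. Welch's t is available
#' behind `var_equal = FALSE`. If the pooled data are all identical the
#' comparison is degenerate and p = 1 is reported with a flag.
#'
#' @param small,large Numeric samples (each n >= 3 for the normality gate).
#' @param alpha Significance level (default 0.05).
#' @param variable Label carried into the result.
#' @param var_equal Pooled-variance t (default TRUE); FALSE gives Welch.
#' @return Object of class `group_comparison` (also a one-row tibble):
#'   group means/SDs/sizes, `test_used`, `p_value`, `significant`,
#'   `degenerate`.
#' @examples
#' compare_groups(rnorm(16, 3.4, 0.8), rnorm(5, 6.2, 2.4))
#' @export
compare_groups <- function(small, large, alpha = 0.05, variable = NA_character_,
                           var_equal = TRUE) {
  small <- small[!is.na(small)]; large <- large[!is.na(large)]
  if (length(small) < 3L || length(large) < 3L)
    stop_domain("each group needs n >= 3 for the normality gate.")
  gs <- group_summary(small); gl <- group_summary(large)
  degenerate <- length(unique(c(small, large))) == 1L
  if (degenerate) {
    test_used <- "degenerate"; p <- 1
  } else {
    sw_ok <- function(v) {
      if (length(unique(v)) == 1L) return(FALSE)   # zero variance: not normal
      shapiro.test(v)$p.value > 0.05
    }
    if (sw_ok(small) && sw_ok(large)) {
      test_used <- "t_test"
      p <- t.test(small, large, var.equal = var_equal)$p.value
    } else {
      test_used <- "mann_whitney"
      p <- if (length(small) + length(large) <= 20L) {
        mann_whitney_exact(small, large)
      } else {
        mann_whitney_approx(small, large)
      }
    }
  }
  out <- tibble(variable = variable,
                small_mean = gs$mean, small_sd = gs$sd, n_small = gs$n,
                large_mean = gl$mean, large_sd = gl$sd, n_large = gl$n,
                test_used = test_used, p_value = p,
                significant = p < alpha, degenerate = degenerate)
  class(out) <- c("group_comparison", class(out))
  out
}

#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(variable = x$variable,
         estimate = x$large_mean - x$small_mean,
         statistic = NA_real_, p.value = x$p_value,
         method = x$test_used)
}

#' Percent increase of one value over a baseline
#'
#' \eqn{100 (other - base) / base}, truncated (not rounded) to one decimal
#' to match the reporting convention used for the printed viscosity
#' contrast: e.g. `percent_increase(3.8, 6.2)` is 63.157...%, reported as
#' 63.1.
#'
#' @param base Baseline value (> 0).
#' @param other Comparison value.
#' @return Percent, truncated to 1 decimal.
#' @examples
#' percent_increase(3.8, 6.2)   # 63.1
#' @export
percent_increase <- function(base, other) {
  if (!is.numeric(base) || any(base <= 0)) stop_domain("`base` must be positive.")
  pct <- 100 * (other - base) / base
  trunc(round(pct * 10, 6)) / 10
}

#' Fold change between two positive values
#'
#' `numerator / denominator`, rounded half-up to `decimals` decimals (the
#' convention of printed "x times greater" statements: 9.90 / 2.90 at one
#' decimal is 3.4; 339 / 112 at zero decimals is 3).
#'
#' @param numerator,denominator Positive values.
#' @param decimals Decimal places (default 1).
#' @return Rounded ratio.
#' @examples
#' fold_change(9.90, 2.90)      # 3.4
#' fold_change(339, 112, 0)     # 3
#' @export
fold_change <- function(numerator, denominator, decimals = 1) {
  if (any(numerator <= 0) || any(denominator <= 0))
    stop_domain("fold_change needs positive inputs.")
  x <- numerator / denominator
  floor(x * 10^decimals + 0.5 + 1e-12) / 10^decimals
}

#' Format a p value for reporting
#'
#' Three decimals, with values below 0.001 printed as `<0.001`.
#'
#' @param p Numeric p value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

#' Build the four per-study group tables
#'
#' From a per-patient results table (one row per patient with morphometrics
#' and hemodynamic summaries plus a `group` column), emits the four
#' standard tables: morphology; dome-averaged shear rate at PS/ED;
#' dome-averaged viscosity at PS/ED; and minimal / time-averaged / maximal
#' wall shear stress. Each row carries small and large group mean +/- SD,
#' the gated test's p value, its formatted form and a significance star.
#' With a single-group cohort the comparison columns are NA and a warning
#' is raised.
#'
#' @param patients Tibble with columns `group` ("small"/"large") and the
#'   variables below.
#' @param alpha Significance level.
#' @return Named list of four tibbles: `morphology`, `shear_rate`,
#'   `viscosity`, `wss`.
#' @export
make_group_tables <- function(patients, alpha = 0.05) {
  stopifnot(is.data.frame(patients), "group" %in% names(patients))
  vars <- list(
    morphology = c(height_mm = "Height (mm)", width_mm = "Width (mm)",
                   ostium_diameter_mm = "Ostium diameter (mm)",
                   ostium_area_mm2 = "Cross-sectional area of ostium (mm2)",
                   surface_area_mm2 = "Surface area of aneurysm (mm2)"),
    shear_rate = c(avg_shear_rate_ps = "Average shear rate at PS (1/s)",
                   avg_shear_rate_ed = "Average shear rate at ED (1/s)"),
    viscosity = c(avg_viscosity_ps = "Average viscosity at PS (cP)",
                  avg_viscosity_ed = "Average viscosity at ED (cP)"),
    wss = c(wss_min = "Minimal wall shear stress (Pa)",
            wss_tavg = "Time-averaged wall shear stress (Pa)",
            wss_max = "Maximal wall shear stress (Pa)"))
  all_vars <- unlist(lapply(vars, names))
  present <- all_vars %in% names(patients)
  if (!all(present))
    stop_domain(paste0("missing variables: ",
                       paste(all_vars[!present], collapse = ", ")))
  for (v in all_vars) {
    bad <- is.na(patients[[v]])
    if (any(bad))
      stop_domain(paste0("variable ", v, " missing for patients: ",
                         paste(patients$patient_id[bad], collapse = ", ")))
  }
  sm <- patients[patients$group == "small", , drop = FALSE]
  lg <- patients[patients$group == "large", , drop = FALSE]
  two_groups <- nrow(sm) >= 3L && nrow(lg) >= 3L
  if (!two_groups)
    warn("fewer than 3 patients in a group: comparison columns left empty.")
  one_table <- function(v_map) {
    rows <- lapply(names(v_map), function(v) {
      if (two_groups) {
        cmp <- compare_groups(sm[[v]], lg[[v]], alpha = alpha, variable = v)
        tibble(variable = v_map[[v]],
               small_mean = cmp$small_mean, small_sd = cmp$small_sd,
               n_small = cmp$n_small,
               large_mean = cmp$large_mean, large_sd = cmp$large_sd,
               n_large = cmp$n_large,
               test_used = cmp$test_used, p_value = cmp$p_value,
               p = format_p(cmp$p_value),
               significant = ifelse(cmp$significant, "*", ""))
      } else {
        gs <- if (nrow(sm)) group_summary(sm[[v]]) else tibble(n = 0L, mean = NA_real_, sd = NA_real_)
        gl <- if (nrow(lg)) group_summary(lg[[v]]) else tibble(n = 0L, mean = NA_real_, sd = NA_real_)
        tibble(variable = v_map[[v]],
               small_mean = gs$mean, small_sd = gs$sd, n_small = gs$n,
               large_mean = gl$mean, large_sd = gl$sd, n_large = gl$n,
               test_used = NA_character_, p_value = NA_real_,
               p = NA_character_, significant = NA_character_)
      }
    })
    dplyr::bind_rows(rows)
  }
  lapply(vars, one_table)
}

#' Boxplots of per-patient metrics by size group
#'
#' @param patients Per-patient results tibble with a `group` column.
#' @param metrics Column names to plot (default the hemodynamic summaries).
#' @return A ggplot object (facetted boxplots).
#' @export
plot_group_metrics <- function(patients,
                               metrics = c("avg_shear_rate_ps",
                                           "avg_viscosity_ps", "wss_tavg")) {
  stopifnot(all(metrics %in% names(patients)))
  d <- tidyr::pivot_longer(patients[, c("group", metrics)],
                           dplyr::all_of(metrics),
                           names_to = "metric", values_to = "value")
  ggplot(d, aes(x = .data$group, y = .data$value, fill = .data$group)) +
    geom_boxplot(outlier.size = 0.8, show.legend = FALSE) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = NULL,
         title = "Dome hemodynamics by aneurysm size group") +
    theme_minimal()
}
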