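test_that("effective viscosity matches direct evaluation of the rearranged law", {
  p <- casson_params(0.005, 0.0035)
  # independent scalar evaluation: mu = (sqrt(tau_y/g) + sqrt(k))^2
  for (g in c(1, 10, 100, 1000)) {
    expect_equal(effective_viscosity(g, p),
                 (sqrt(0.005 / g) + sqrt(0.0035))^2, tolerance = 1e-12)
  }
  # Newtonian limit: yield term vanishes for any shear rate
  pn <- casson_params(0, 0.0035)
  expect_identical(effective_viscosity(c(1, 50, 1000), pn), rep(0.0035, 3))
})

test_that("effective viscosity is positive, bounded and shear-thinning", {
  p <- casson_params(0.012, 0.004)
  g <- 10^seq(0, 3, length.out = 200)
  mu <- effective_viscosity(g, p)
  expect_true(all(mu > 0))
  expect_true(all(diff(mu) <= 1e-15))          # non-increasing
  expect_true(effective_viscosity(10, p) > effective_viscosity(100, p))
  expect_true(effective_viscosity(100, p) > effective_viscosity(1000, p))
  # below the floor the clamp freezes the value
  expect_equal(effective_viscosity(0, p), effective_viscosity(1, p))
  expect_error(effective_viscosity(-1, p), class = "hemoflow_domain_error")
})

test_that("cP <-> Pa s conversion round-trips to representation precision", {
  x <- c(3.5, 0.001, 1234.5678)
  expect_identical(hemoflow:::pa_s_to_cp(hemoflow:::cp_to_pa_s(x)), x)
})

test_that("fit_casson round-trips noiseless curves exactly", {
  cur <- synth_viscosity_curve(casson_params(0.004, 0.0032), 50, 0, seed = 1)
  fit <- fit_casson(cur)
  expect_equal(fit$params$tau_y, 0.004, tolerance = 1e-9)
  expect_equal(fit$params$k, 0.0032, tolerance = 1e-9)
  expect_lt(fit$residual, 1e-10)
})

test_that("fit_casson recovers a flat Newtonian curve with zero yield stress", {
  cur <- viscosity_curve(10^seq(0, 3, length.out = 20), rep(3.5, 20))
  fit <- fit_casson(cur)
  expect_equal(fit$params$tau_y, 0, tolerance = 1e-12)
  expect_equal(fit$params$k, 0.0035, tolerance = 1e-9)
})

test_that("fit_casson stays within 5% relative error at 2% noise", {
  # error distribution over 100 seeded replicates
  errs <- t(vapply(1:100, function(s) {
    cur <- synth_viscosity_curve(casson_params(0.004, 0.0032), 50, 0.02,
                                 seed = s)
    f <- fit_casson(cur)
    c(abs(f$params$tau_y - 0.004) / 0.004, abs(f$params$k - 0.0032) / 0.0032)
  }, numeric(2)))
  expect_lt(max(errs[, 1]), 0.05)
  expect_lt(max(errs[, 2]), 0.05)
})

test_that("fit_casson validates its inputs", {
  expect_error(fit_casson(viscosity_curve(c(1, 10), c(5, 4))),
               class = "hemoflow_domain_error")
  bad <- data.frame(shear_rate_per_s = c(1, 10, 100),
                    viscosity_cP = c(5, -4, 3))
  expect_error(fit_casson(bad), class = "hemoflow_domain_error")
})

test_that("casson_tube_flow_rate matches quadrature and limits", {
  p <- casson_params(0.005, 0.0035)
  R <- 0.002; G <- 2000
  # oracle: Q = int_0^R pi r^2 gamma(r) dr with gamma from the inverse law
  q_oracle <- integrate(function(r)
    pi * r^2 * casson_gamma_of_tau(G * r / 2, p$tau_y, p$k),
    0, R, rel.tol = 1e-12)$value
  expect_equal(casson_tube_flow_rate(R, G, p), q_oracle, tolerance = 1e-6)
  # Newtonian limit: exact Poiseuille
  pn <- casson_params(0, 0.0035)
  expect_equal(casson_tube_flow_rate(R, G, pn), pi * G * R^4 / (8 * 0.0035),
               tolerance = 1e-12)
  # unyielded plug fills the tube
  expect_identical(casson_tube_flow_rate(R, 2 * p$tau_y / R * 0.99, p), 0)
  expect_error(casson_tube_flow_rate(-1, G, p), class = "hemoflow_domain_error")
})

test_that("casson_tube_flow_rate is monotone in its arguments", {
  base <- list(R = 0.002, G = 3000, tau_y = 0.008, k = 0.004)
  q0 <- casson_tube_flow_rate(base$R, base$G, casson_params(base$tau_y, base$k))
  expect_gt(casson_tube_flow_rate(base$R, 2 * base$G,
                                  casson_params(base$tau_y, base$k)), q0)
  expect_gt(casson_tube_flow_rate(1.5 * base$R, base$G,
                                  casson_params(base$tau_y, base$k)), q0)
  expect_lt(casson_tube_flow_rate(base$R, base$G,
                                  casson_params(2 * base$tau_y, base$k)), q0)
  expect_lt(casson_tube_flow_rate(base$R, base$G,
                                  casson_params(base$tau_y, 2 * base$k)), q0)
})

clean_50 <- synth_viscosity_curve(casson_params(0.006, 0.0038), 50, 0, seed = 1)

test_that("synth_viscosity_curve is reproducible and correctly scaled", {
  p <- casson_params(0.006, 0.0038)
  a <- synth_viscosity_curve(p, 40, 0.02, seed = 7)
  b <- synth_viscosity_curve(p, 40, 0.02, seed = 7)
  expect_identical(a$viscosity_cP, b$viscosity_cP)
  # noiseless curve equals the model exactly
  clean <- synth_viscosity_curve(p, 40, 0, seed = 1)
  expect_equal(clean$viscosity_cP,
               1e3 * effective_viscosity(clean$shear_rate_per_s, p),
               tolerance = 1e-12)
  # empirical relative deviation has SD close to the requested noise
  devs <- unlist(lapply(1:40, function(s) {
    noisy <- synth_viscosity_curve(p, 50, 0.02, seed = s)
    noisy$viscosity_cP / clean_50$viscosity_cP - 1
  }))
  expect_equal(sd(devs), 0.02, tolerance = 0.1)
})

test_that("viscosity curve CSV round-trips", {
  cur <- synth_viscosity_curve(casson_params(0.005, 0.0035), 12, 0.01,
                               seed = 3, patient_id = "X1")
  f <- withr::local_tempfile(fileext = ".csv")
  write_viscosity_curve(cur, f)
  back <- read_viscosity_curve(f, patient_id = "X1")
  expect_equal(back$shear_rate_per_s, cur$shear_rate_per_s, tolerance = 1e-9)
  expect_equal(back$viscosity_cP, cur$viscosity_cP, tolerance = 1e-9)
})

test_that("tidy and glance report the fitted parameters", {
  fit <- fit_casson(synth_viscosity_curve(casson_params(0.004, 0.0032),
                                          30, 0, seed = 1))
  td <- generics::tidy(fit)
  expect_equal(td$estimate[td$term == "k"], 0.0032, tolerance = 1e-8)
  gl <- generics::glance(fit)
  expect_false(gl$clamped)
  expect_equal(gl$n, 30)
})
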