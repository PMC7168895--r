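test_that("group summary gives mean and n-1 SD, flagging singletons", {
  g <- group_summary(c(2, 4, 6))
  expect_equal(g$mean, 4)
  expect_equal(g$sd, 2)
  s <- group_summary(5)
  expect_equal(s$sd, 0)
  expect_true(s$degenerate)
  expect_error(group_summary(numeric(0)), class = "hemoflow_domain_error")
})

test_that("Mann-Whitney branch agrees with exhaustive enumeration and wilcox.test", {
  # spec-style fixed pair: all of one group above the other
  x <- c(1, 2, 3, 4); y <- c(10, 11, 12)
  # brute-force oracle via the U statistic (count of x > y pairs) over all
  # choose(7, 4) assignments of the pooled values
  pool <- c(x, y)
  idx <- utils::combn(7, 4)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  U_obs <- u_stat(x, y)
  EU <- length(x) * length(y) / 2
  U_all <- apply(idx, 2, function(s) u_stat(pool[s], pool[-s]))
  p_oracle <- mean(abs(U_all - EU) >= abs(U_obs - EU) - 1e-9)
  p_impl <- hemoflow:::mann_whitney_exact(x, y)
  expect_equal(p_impl, p_oracle, tolerance = 1e-12)
  expect_equal(p_oracle, 2 / 35, tolerance = 1e-12)
  # tie-free random samples agree with stats::wilcox.test exact p
  withr::with_seed(5, {
    for (rep in 1:10) {
      a <- round(rnorm(6), 4); b <- round(rnorm(5, 0.8), 4)
      expect_equal(hemoflow:::mann_whitney_exact(a, b),
                   wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-9)
    }
  })
})

test_that("enumeration matches across all pooled sizes up to 12", {
  withr::with_seed(9, {
    for (m in 3:6) for (n in 3:(12 - m)) {
      a <- rnorm(m); b <- rnorm(n, 0.5)
      expect_equal(hemoflow:::mann_whitney_exact(a, b),
                   wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-9)
    }
  })
})

test_that("compare_groups gates on normality and handles degeneracy", {
  withr::with_seed(21, {
    a <- rnorm(16); b <- rnorm(5, 3)
    r <- compare_groups(a, b)
    expect_identical(r$test_used, "t_test")
    expect_equal(r$p_value, t.test(a, b, var.equal = TRUE)$p.value)
    expect_true(r$significant)
    # heavy-tailed data routed to the rank test
    c1 <- exp(rnorm(12, 0, 1.5)); c2 <- exp(rnorm(9, 0.5, 1.5))
    r2 <- compare_groups(c1, c2)
    expect_identical(r2$test_used, "mann_whitney")
  })
  # two identical groups: degenerate, p = 1
  r3 <- compare_groups(rep(2, 5), rep(2, 4))
  expect_true(r3$degenerate)
  expect_equal(r3$p_value, 1)
  expect_error(compare_groups(c(1, 2), c(3, 4, 5)),
               class = "hemoflow_domain_error")
})

test_that("shifted normals are detected with high power at n = 16 vs 5", {
  hits <- withr::with_seed(77, vapply(1:300, function(i) {
    a <- rnorm(16); b <- rnorm(5, 3)   # 3 pooled SDs apart
    compare_groups(a, b)$significant
  }, logical(1)))
  expect_gt(mean(hits), 0.95)
})

test_that("percent increase truncates to one decimal", {
  expect_identical(percent_increase(3.8, 6.2), 63.1)
  expect_identical(percent_increase(2, 3), 50.0)
  expect_identical(percent_increase(4, 4), 0.0)
  # invariant under common rescaling
  expect_identical(percent_increase(0.38, 0.62), 63.1)
  expect_error(percent_increase(0, 1), class = "hemoflow_domain_error")
})

test_that("fold change rounds half-up at the requested precision", {
  expect_identical(fold_change(9.90, 2.90, 1), 3.4)
  expect_identical(fold_change(6.1, 4.3, 1), 1.4)
  expect_identical(fold_change(339, 112, 0), 3)
  expect_identical(fold_change(1, 4, 2), 0.25)
  expect_identical(fold_change(35, 100, 1), 0.4)      # half-up at the midpoint
  expect_identical(fold_change(99, 33, 1), fold_change(9.9, 3.3, 1))
  expect_error(fold_change(-1, 2), class = "hemoflow_domain_error")
})

test_that("p formatting matches the reporting convention", {
  expect_identical(format_p(c(0.0004, 0.011, 0.2)),
                   c("<0.001", "0.011", "0.200"))
})

test_that("type-I error of the gated pipeline is near nominal at n = 16 vs 5", {
  res <- withr::with_seed(2024, t(vapply(1:2000, function(i) {
    a <- rnorm(16); b <- rnorm(5)
    r <- compare_groups(a, b)
    c(sig = r$significant, t_branch = r$test_used == "t_test")
  }, c(sig = FALSE, t_branch = FALSE))))
  t_rate <- mean(res[res[, "t_branch"] == 1, "sig"])
  expect_gt(t_rate, 0.035)
  expect_lt(t_rate, 0.065)
})

test_that("group tables carry the reported layout and are order-invariant", {
  withr::with_seed(3, {
    mk <- function(ids, group, mu) tibble::tibble(
      patient_id = ids, group = group,
      height_mm = rnorm(length(ids), mu, 0.5),
      width_mm = rnorm(length(ids), mu + 1, 0.5),
      ostium_diameter_mm = rnorm(length(ids), mu, 0.3),
      ostium_area_mm2 = rnorm(length(ids), 10 * mu, 2),
      surface_area_mm2 = rnorm(length(ids), 20 * mu, 4),
      avg_shear_rate_ps = rnorm(length(ids), 900 / mu, 30),
      avg_shear_rate_ed = rnorm(length(ids), 300 / mu, 20),
      avg_viscosity_ps = rnorm(length(ids), mu, 0.2),
      avg_viscosity_ed = rnorm(length(ids), mu + 0.5, 0.2),
      wss_min = abs(rnorm(length(ids), mu / 2, 0.2)),
      wss_tavg = abs(rnorm(length(ids), mu, 0.2)),
      wss_max = abs(rnorm(length(ids), 2 * mu, 0.3)))
    pats <- dplyr::bind_rows(mk(sprintf("S%02d", 1:16), "small", 3.4),
                             mk(sprintf("L%02d", 1:5), "large", 6.2))
    tabs <- make_group_tables(pats)
    expect_named(tabs, c("morphology", "shear_rate", "viscosity", "wss"))
    expect_identical(nrow(tabs$morphology), 5L)
    expect_identical(nrow(tabs$wss), 3L)
    expect_true(all(tabs$morphology$n_small == 16))
    expect_true(all(tabs$morphology$n_large == 5))
    # shuffling patients leaves the tables unchanged
    tabs2 <- make_group_tables(pats[sample(nrow(pats)), ])
    expect_equal(tabs2, tabs)
    # missing variable names the offender
    expect_error(make_group_tables(pats[, -3]), "height_mm")
    # single-group cohort: comparisons empty, warning raised
    expect_warning(t1 <- make_group_tables(pats[pats$group == "small", ]),
                   "comparison")
    expect_true(all(is.na(t1$wss$p_value)))
  })
})
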