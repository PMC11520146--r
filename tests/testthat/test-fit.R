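test_that("intercept-only fit recovers log of the constant count", {
  ser <- make_series(rep(7, 20), population = 1000) # offset log(1) = 0
  fit <- fit_quasipoisson(build_design(ser, far_interruption()),
                          terms = character(0))
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), log(7),
               tolerance = 1e-8)
})

test_that("IRLS coefficients match brute-force likelihood maximisation", {
  # small instances (<= 50 weeks, <= 4 parameters), each compared against a
  # generic quasi-Newton maximiser of the Poisson log-likelihood
  cfg_mid <- interruption_config(gap_start = as.Date("2015-06-06"),
                                 reopen_date = as.Date("2015-08-01"))
  set.seed(42)
  cases <- list(
    list(series = make_series(c(2, 3, 5, 8, 13, 20)),
         cfg = far_interruption(), terms = "t"),
    list(series = make_series(rpois(30, lambda = exp(1 + 0.05 * 0:29)),
                              population = 2000),
         cfg = far_interruption(), terms = c("t", "t_sq")),
    list(series = make_series(c(rpois(22, 30), rep(0, 8), rpois(20, 18)),
                              start = as.Date("2015-01-03")),
         cfg = cfg_mid, terms = c("t", "sig", "tpost"))
  )
  for (case in cases) {
    design <- build_design(case$series, case$cfg)
    fit <- fit_quasipoisson(design, terms = case$terms)
    mm <- design_model_matrix(design, case$terms)
    oracle <- oracle_poisson_fit(mm$X, mm$y, mm$offset)
    expect_equal(unname(fit$coefficients), unname(oracle),
                 tolerance = 1e-6)
  }
})

test_that("Pearson dispersion is near 1 for Poisson data", {
  set.seed(11)
  n <- 400
  mu <- exp(3 + 0.4 * (0:(n - 1)) / weeks_per_year)
  ser <- make_series(rpois(n, mu))
  fit <- fit_quasipoisson(build_design(ser, far_interruption()),
                          terms = c("t", "t_sq", "season"))
  expect_gt(fit$dispersion, 0.8)
  expect_lt(fit$dispersion, 1.2)
})

test_that("rescaling the population only shifts the intercept", {
  set.seed(3)
  counts <- rpois(104, exp(2 + 0.3 * (0:103) / weeks_per_year))
  f1 <- fit_quasipoisson(
    build_design(make_series(counts, population = 1000),
                 far_interruption()),
    terms = c("t", "season")
  )
  f2 <- fit_quasipoisson(
    build_design(make_series(counts, population = 10000),
                 far_interruption()),
    terms = c("t", "season")
  )
  b1 <- f1$coefficients; b2 <- f2$coefficients
  expect_equal(b1[["(Intercept)"]] - b2[["(Intercept)"]], log(10),
               tolerance = 1e-8)
  keep <- setdiff(names(b1), "(Intercept)")
  expect_equal(b1[keep], b2[keep], tolerance = 1e-8)
})

test_that("dropping gap rows equals pinning the gap coefficient at -20", {
  sim <- simulate_series(make_default_scenario(seed = 5))
  tot <- sim$series[sim$series$stratum == "total", ]
  design <- build_design(tot, interruption_config())
  fit_dropped <- fit_quasipoisson(design)

  est <- design
  est$offset_adj <- est$offset_log - 20 * est$lam
  glm_pinned <- stats::glm(
    count ~ t + t_sq + season + sig + tpost + tpost_sq + offset(offset_adj),
    family = stats::quasipoisson(), data = est,
    control = stats::glm.control(epsilon = 1e-12, maxit = 200)
  )
  expect_equal(unname(fit_dropped$coefficients),
               unname(stats::coef(glm_pinned)), tolerance = 1e-6)
})

test_that("all-zero model columns are reported as rank deficiency", {
  ser <- make_series(rpois(20, 10)) # no interruption in window
  design <- build_design(ser, far_interruption())
  expect_error(fit_quasipoisson(design, terms = c("t", "sig")), "sig")
})

test_that("rate ratios exponentiate per-year coefficients with Wald bands", {
  # degenerate fit: all effects and variances zero -> RR exactly 1
  null_fit <- structure(list(
    coefficients = setNames(rep(0, 6), c("(Intercept)", "t", "t_sq",
                                         "sig", "tpost", "tpost_sq")),
    vcov = matrix(0, 6, 6, dimnames = list(
      c("(Intercept)", "t", "t_sq", "sig", "tpost", "tpost_sq"),
      c("(Intercept)", "t", "t_sq", "sig", "tpost", "tpost_sq")
    )),
    dispersion = 1, n_obs = 10, df_residual = 4, converged = TRUE
  ), class = "its_fit")
  tbl <- rate_ratio_table(null_fit)
  expect_equal(tbl$rr, rep(1, 5))
  wide <- format_rr_table(tbl)
  expect_equal(wide$step, "1.00 (1.00-1.00)")

  sim <- simulate_series(make_default_scenario(seed = 9))
  fit <- fit_quasipoisson(build_design(
    sim$series[sim$series$stratum == "total", ], interruption_config()
  ))
  tbl2 <- rate_ratio_table(list(total = fit))
  expect_true(all(tbl2$ci_low <= tbl2$rr & tbl2$rr <= tbl2$ci_high))
  expect_true(all(tbl2$ci_low > 0))
  expect_equal(tbl2$rr, exp(unname(fit$coefficients[
    c("t", "t_sq", "sig", "tpost", "tpost_sq")
  ])))
})

test_that("residual diagnostics satisfy their definitional identities", {
  # perfect fit: constant counts, intercept-only -> all residuals zero
  perfect <- fit_quasipoisson(
    build_design(make_series(rep(5, 12)), far_interruption()),
    terms = character(0)
  )
  diag0 <- residual_diagnostics(perfect)
  expect_equal(diag0$residuals$pearson, rep(0, 12), tolerance = 1e-7)
  expect_equal(diag0$residuals$deviance, rep(0, 12), tolerance = 1e-7)

  # Pearson identity: sum r^2 / (n - p) equals the dispersion estimate
  set.seed(21)
  ser <- make_series(rpois(60, exp(2 + 0.5 * (0:59) / weeks_per_year)))
  fit <- fit_quasipoisson(build_design(ser, far_interruption()),
                          terms = c("t", "season"))
  d <- residual_diagnostics(fit)
  expect_equal(sum(d$residuals$pearson^2) / fit$df_residual,
               fit$dispersion, tolerance = 1e-10)
})

test_that("well-specified simulations leave little lag-1 autocorrelation", {
  set.seed(8)
  n <- 400
  mu <- exp(2.5 + 0.3 * (0:(n - 1)) / weeks_per_year)
  ser <- make_series(rpois(n, mu))
  fit <- fit_quasipoisson(build_design(ser, far_interruption()),
                          terms = c("t", "t_sq", "season"))
  d <- residual_diagnostics(fit)
  expect_lt(abs(d$summary$lag1_autocorrelation), 0.15)
})
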