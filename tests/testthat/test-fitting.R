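test_that("chi-square criterion matches hand arithmetic and sigma scaling", {
  expect_equal(chi_square(c(1, 2, 3), c(1, 2, 3), 0.1), 0)
  expect_equal(chi_square(c(1.1, 2, 2.8), c(1, 2, 3), 0.1), 5,
               tolerance = 1e-12)
  expect_equal(chi_square(c(1.1, 2, 2.8), c(1, 2, 3), 0.05),
               4 * chi_square(c(1.1, 2, 2.8), c(1, 2, 3), 0.1),
               tolerance = 1e-12)
  expect_error(chi_square(1:3, 1:4, 0.1), "length mismatch")
})

test_that("Levenberg-Marquardt solves linear least squares exactly", {
  x <- seq(0, 1, length.out = 20)
  y <- 2 * x
  res_fn <- function(p) y - p[1] * x
  fit <- levenberg_marquardt(res_fn, 1.0)
  expect_equal(fit$par, 2, tolerance = 1e-8)
  expect_true(fit$converged)
  # starting at the optimum stays there
  fit0 <- levenberg_marquardt(res_fn, 2.0)
  expect_equal(fit0$par, 2, tolerance = 1e-8)
})

test_that("Levenberg-Marquardt finds the Rosenbrock minimum", {
  res_fn <- function(p) c(10 * (p[2] - p[1]^2), 1 - p[1])
  fit <- levenberg_marquardt(res_fn, c(-1.2, 1),
                             config = fit_config(max_iter = 200L))
  expect_equal(fit$par, c(1, 1), tolerance = 1e-4)
})

test_that("Levenberg-Marquardt agrees with minpack.lm on a nonlinear fit", {
  skip_if_not_installed("minpack.lm")
  set.seed(3)
  x <- seq(0, 5, length.out = 40)
  y <- 3 * exp(-0.7 * x) + rnorm(40, sd = 0.01)
  res_fn <- function(p) y - p[1] * exp(-p[2] * x)
  ours <- levenberg_marquardt(res_fn, c(1, 1))
  ref <- minpack.lm::nls.lm(c(1, 1), fn = res_fn)
  expect_equal(ours$par, unname(coef(ref)), tolerance = 1e-6)
})

test_that("noiseless single-domain recovery is within 2%", {
  prof <- straight_profile()
  truth <- std_params(prof)  # T_theta 180, T_s 360
  model <- make_growth_model(prof, test_ctx$wall, test_ctx$mu, test_ctx$hemo,
                             sim_config(horizon = 60))
  obs <- model(truth)
  fit <- fit_growth_constants(model, obs, n_domains = 1L, fixed = truth)
  expect_rel_equal(fit$T_theta, 180, 0.02)
  expect_rel_equal(fit$T_s, 360, 0.02)
  expect_true(fit$converged)
})

test_that("noisy recovery stays within 3 estimated standard errors", {
  prof <- straight_profile()
  truth <- std_params(prof)
  model <- make_growth_model(prof, test_ctx$wall, test_ctx$mu, test_ctx$hemo,
                             sim_config(horizon = 60))
  obs_clean <- observation_vector(model(truth))
  cfg <- fit_config(sigma_meas = 0.01)
  hits <- 0L
  for (k in 1:20) {
    set.seed(400 + k)
    obs <- obs_clean + rnorm(length(obs_clean), sd = 0.01)
    fit <- fit_growth_constants(model, obs, config = cfg, n_domains = 1L,
                                fixed = truth)
    in_theta <- abs(log(fit$T_theta) - log(180)) <= 3 * fit$se_log[1]
    in_s <- abs(log(fit$T_s) - log(360)) <= 3 * fit$se_log[2]
    if (in_theta && in_s) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("four-domain truth: nested fits and the F-test detect heterogeneity", {
  n_el <- 28L
  prof <- straight_profile(n_elements = n_el)
  part <- domain_partition(prof$s, 4L)
  truth <- std_params(prof, T_theta = c(260, 130, 130, 260),
                      T_s = c(520, 260, 260, 520))
  model4 <- make_growth_model(prof, test_ctx$wall, test_ctx$mu,
                              test_ctx$hemo, sim_config(horizon = 60),
                              partition = part, n_rings = 10L)
  model1 <- make_growth_model(prof, test_ctx$wall, test_ctx$mu,
                              test_ctx$hemo, sim_config(horizon = 60),
                              n_rings = 10L)
  obs_clean <- observation_vector(model4(truth))
  cfg <- fit_config(sigma_meas = 0.01)

  # noiseless: the full model strictly dominates the reduced one
  f1 <- fit_growth_constants(model1, obs_clean, cfg, n_domains = 1L,
                             fixed = truth)
  f4 <- fit_growth_constants(model4, obs_clean, cfg, n_domains = 4L,
                             fixed = truth)
  expect_lt(f4$sse, f1$sse)
  expect_rel_equal(f4$T_theta, c(260, 130, 130, 260), 0.02)

  # noisy replicates: p < 0.05 in at least 90% of 10 seeds
  pvals <- vapply(1:10, function(k) {
    set.seed(k)
    obs <- obs_clean + rnorm(length(obs_clean), sd = 0.01)
    g1 <- fit_growth_constants(model1, obs, cfg, n_domains = 1L,
                               fixed = truth)
    g4 <- fit_growth_constants(model4, obs, cfg, n_domains = 4L,
                               fixed = truth)
    expect_lte(g4$sse, g1$sse + 1e-12)
    nested_f_test(g1$sse, 2L, g4$sse, 8L, length(obs))$p_value
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.9)
})

test_that("delta_r uses rings 2-5 and matches its definition", {
  dr0 <- delta_r(rep(0.6, 6), rep(0.6, 6))
  expect_equal(dr0$delta_r, rep(0, 6))
  expect_equal(dr0$mean_delta_r, 0)
  expect_identical(dr0$rings_used, 2:5)
  expect_length(dr0$rings_used, 4L)

  dr1 <- delta_r(rep(0.66, 6), rep(0.6, 6))
  expect_equal(dr1$delta_r, rep(0.1, 6), tolerance = 1e-12)
  expect_equal(dr1$mean_delta_r, 0.1, tolerance = 1e-12)

  p <- c(0.61, 0.59, 0.65, 0.60, 0.55, 0.62)
  m <- rep(0.6, 6)
  dr2 <- delta_r(p, m)
  expect_equal(dr2$delta_r, (p - m) / m)
  expect_equal(sign(dr2$delta_r), sign(p - m))
  expect_error(delta_r(p, rep(0, 6)), "positive")
})

test_that("delta_l matches hand values and is antisymmetric as defined", {
  expect_equal(delta_l(5, 5), 0)
  expect_equal(delta_l(5.5, 5.0), 0.10, tolerance = 1e-12)
  expect_equal(delta_l(5.0, 5.5), -0.5 / 5.5, tolerance = 1e-12)
})

test_that("linear projection continues the trend and under-predicts convex growth", {
  expect_equal(linear_projection_baseline(1.0, 1.2), 1.4)
  expect_equal(linear_projection_baseline(0.8, 0.8), 0.8)
  # exponential truth: x(t) = exp(k t); projection from t=0,1 to t=2
  k <- 0.25
  proj <- linear_projection_baseline(1, exp(k))
  expect_lt(proj, exp(2 * k))
})

test_that("nested F-test matches hand arithmetic", {
  eq <- nested_f_test(10, 2L, 10, 8L, 11L)
  expect_equal(eq$F, 0)
  expect_equal(eq$p_value, 1)
  hand <- nested_f_test(10, 2L, 5, 8L, 11L)
  expect_equal(hand$F, 0.5, tolerance = 1e-12)
  expect_equal(hand$p_value, pf(0.5, 6, 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(nested_f_test(10, 8L, 5, 2L, 11L), "more parameters")
  expect_error(nested_f_test(10, 2L, 5, 8L, 8L), "dof")
})
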