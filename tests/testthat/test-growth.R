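uniform_stress <- function(n, sigma_theta, sigma_ss = sigma_theta / 2,
                           tau_w = 1) {
  structure(list(sigma_theta = rep(sigma_theta, n),
                 sigma_ss = rep(sigma_ss, n), tau_w = rep(tau_w, n)),
            class = "stress_field")
}

test_that("homeostasis is an exact fixed point of the growth laws", {
  p <- growth_params(150, 300, T_r = 500, sigma_theta_hat = 1e5,
                     sigma_ss_hat = 5e4, tau_w_hat = 1.5)
  st <- uniform_stress(4, 1e5, 5e4, 1.5)
  rates <- growth_rates(growth_state(4), st, p)
  expect_identical(rates$d_lambda_gr, rep(0, 4))
  expect_identical(rates$d_lambda_gtheta, rep(0, 4))
  expect_identical(rates$d_lambda_gs, rep(0, 4))
  # stepping at homeostasis leaves the state unchanged
  s2 <- step_growth(growth_state(4), st, p, dt = 10)
  expect_identical(s2$lambda_gtheta, rep(1, 4))
})

test_that("growth rates match hand evaluation and scale with lambda", {
  # T_theta = 100 d, stress ratio 1.2, wall-shear term at target -> 0.002/day
  p <- growth_params(100, 300, T_tau = 50, sigma_theta_hat = 1e5,
                     sigma_ss_hat = 5e4, tau_w_hat = 2)
  st <- uniform_stress(1, 1.2e5, 5e4, 2)
  r1 <- growth_rates(growth_state(1), st, p)
  expect_equal(r1$d_lambda_gtheta, 0.002, tolerance = 1e-12)
  # multiplicative form: doubling lambda doubles the rate
  s <- growth_state(1)
  s$lambda_gtheta <- 2
  r2 <- growth_rates(s, st, p)
  expect_equal(r2$d_lambda_gtheta, 2 * r1$d_lambda_gtheta)
  # wall-shear term adds (1/T_tau)(ratio - 1)
  st_tau <- uniform_stress(1, 1.2e5, 5e4, 3)
  r3 <- growth_rates(growth_state(1), st_tau, p)
  expect_equal(r3$d_lambda_gtheta, 0.002 + (3 / 2 - 1) / 50, tolerance = 1e-12)
})

test_that("growth tensor is diagonal with det = product of stretches", {
  G0 <- assemble_growth_tensor(growth_state(3))
  expect_equal(G0[, , 2], diag(3))
  s <- growth_state(1)
  s$lambda_gr <- 1.1; s$lambda_gtheta <- 1.2; s$lambda_gs <- 1.3
  G <- assemble_growth_tensor(s)[, , 1]
  expect_equal(det(G), 1.716, tolerance = 1e-12)
  expect_equal(G[lower.tri(G)], rep(0, 3))
  # F = Fe G with Fe = identity is G itself
  expect_equal(diag(3) %*% G, G)
})

test_that("a single Euler step reproduces hand arithmetic", {
  # rate 0.002/day, dt 10 -> lambda 1.02
  p <- growth_params(100, 300, sigma_theta_hat = 1e5, sigma_ss_hat = 5e4)
  st <- uniform_stress(1, 1.2e5, 5e4)
  s1 <- step_growth(growth_state(1), st, p, dt = 10)
  expect_equal(s1$lambda_gtheta, 1.02, tolerance = 1e-12)
})

test_that("fine Euler substeps match the closed-form exponential to 0.1%", {
  # dlambda/dt = ((rho - 1)/T) lambda with rho = 1.2, T = 100 d
  p <- growth_params(100, 300, T_r = 100, sigma_theta_hat = 1e5,
                     sigma_ss_hat = 5e4)
  st <- uniform_stress(1, 1.2e5, 5e4)
  state <- growth_state(1)
  for (k in 1:12) state <- step_growth(state, st, p, dt = 10, substeps = 10L)
  oracle <- exp(0.2 / 100 * 120)
  expect_rel_equal(state$lambda_gtheta, oracle, 0.001)
})

test_that("Euler convergence toward the exponential is first order", {
  p <- growth_params(100, 300, sigma_theta_hat = 1e5, sigma_ss_hat = 5e4)
  st <- uniform_stress(1, 1.3e5, 5e4)
  run <- function(substeps) {
    state <- growth_state(1)
    for (k in 1:6) state <- step_growth(state, st, p, dt = 10,
                                        substeps = substeps)
    state$lambda_gtheta
  }
  exact <- exp(0.3 / 100 * 60)
  e1 <- abs(run(1L) - exact)
  e2 <- abs(run(2L) - exact)
  expect_equal(e1 / e2, 2, tolerance = 0.15)
})

test_that("positivity violations are caught with advice", {
  p <- growth_params(1, 1, T_r = 1, sigma_theta_hat = 1e5, sigma_ss_hat = 5e4)
  st <- uniform_stress(1, 1e3, 5e4)  # strong shrinkage drive
  expect_error(step_growth(growth_state(1), st, p, dt = 50), "reduce dt")
})

test_that("update_geometry applies kinematic increments ring-wise", {
  mm <- ring_metrics(rep(0.6, 6), rep(0.5, 5))
  w <- wall_spec(0.06)
  idn <- list(d_lambda_gr = rep(1, 6), d_lambda_gtheta = rep(1, 6),
              d_lambda_gs = rep(1, 6))
  up0 <- update_geometry(mm, w, idn)
  expect_equal(up0$metrics$radii, mm$radii)
  expect_equal(up0$wall$thickness, w$thickness)

  uni <- list(d_lambda_gr = rep(1.05, 6), d_lambda_gtheta = rep(1.1, 6),
              d_lambda_gs = rep(1.2, 6))
  up1 <- update_geometry(mm, w, uni)
  expect_equal(up1$metrics$radii, mm$radii * 1.1)
  expect_equal(up1$metrics$segment_lengths, mm$segment_lengths * 1.2)
  expect_equal(up1$wall$thickness, 0.06 * 1.05)

  gs <- c(1, 1.1, 1.2, 1.3, 1.4, 1.5)
  up2 <- update_geometry(mm, w, list(d_lambda_gr = rep(1, 6),
                                     d_lambda_gtheta = rep(1, 6),
                                     d_lambda_gs = gs))
  oracle_seg <- mm$segment_lengths * (gs[-6] + gs[-1]) / 2
  expect_equal(up2$metrics$segment_lengths, oracle_seg)
  expect_equal(up2$metrics$total_length, sum(oracle_seg))
})

test_that("a homeostatic start leaves the trajectory constant", {
  prof <- straight_profile()
  params <- std_params(prof, target_scale = 1)  # targets = baseline stresses
  traj <- forward_simulate(prof, test_ctx$wall, test_ctx$mu, test_ctx$hemo,
                           params, sim_config(horizon = 120))
  r0 <- traj$metrics[[1]]$radii
  for (m in traj$metrics) expect_equal(m$radii, r0, tolerance = 1e-9)
  expect_equal(final_metrics(traj)$total_length,
               traj$metrics[[1]]$total_length, tolerance = 1e-9)
})

test_that("fixed-stress growth matches the closed form; feedback accelerates", {
  prof <- straight_profile()
  params <- growth_params(200, 300, sigma_theta_hat = 1e5, sigma_ss_hat = 5e4)
  st <- uniform_stress(26, 1.1e5, 5e4)
  cfg <- sim_config(horizon = 60, substeps = 10L)
  traj <- forward_simulate(prof, test_ctx$wall, test_ctx$mu, test_ctx$hemo,
                           params, cfg, fixed_stress = st)
  # the closed form governs the growth stretch; the recorded loaded radius
  # additionally carries the elastic inflation of the grown tube
  expect_rel_equal(traj$state$lambda_gtheta, exp(0.1 * 60 / 200), 0.002)
  expect_equal(traj$state$lambda_gs, rep(1, 26))  # axial stress at target

  # with live feedback the circumferential rate is non-decreasing
  params_fb <- std_params(prof)
  traj_fb <- forward_simulate(prof, test_ctx$wall, test_ctx$mu,
                              test_ctx$hemo, params_fb,
                              sim_config(horizon = 120))
  radii_mid <- vapply(traj_fb$metrics, function(m) m$radii[3], numeric(1))
  increments <- diff(radii_mid) / radii_mid[-length(radii_mid)]
  expect_true(all(diff(increments) > -1e-12))
})

test_that("smaller T_theta strictly increases the 60-day radius", {
  prof <- straight_profile()
  r60 <- vapply(c(120, 180, 260, 400), function(Tt) {
    params <- std_params(prof, T_theta = Tt, T_s = 360)
    final_metrics(forward_simulate(prof, test_ctx$wall, test_ctx$mu,
                                   test_ctx$hemo, params,
                                   sim_config(horizon = 60)))$radii[3]
  }, numeric(1))
  expect_true(all(diff(r60) < 0))
})

test_that("det G stays positive and equals the grown volume ratio", {
  prof <- straight_profile()
  traj <- forward_simulate(prof, test_ctx$wall, test_ctx$mu, test_ctx$hemo,
                           std_params(prof), sim_config(horizon = 120))
  st <- traj$state
  detG <- st$lambda_gr * st$lambda_gtheta * st$lambda_gs
  expect_true(all(detG > 0))
  G <- assemble_growth_tensor(st)
  expect_equal(apply(G, 3, det), detG, tolerance = 1e-12)
})

test_that("boundary motion translates the end rings linearly in time", {
  prof <- straight_profile()
  params <- std_params(prof, target_scale = 1)  # no growth, isolate motion
  mo <- boundary_motion(inlet_total = 0, outlet_total = 0.3, horizon = 60)
  traj <- forward_simulate(prof, test_ctx$wall, test_ctx$mu, test_ctx$hemo,
                           params, sim_config(horizon = 60), motion = mo)
  l0 <- traj$metrics[[1]]$total_length
  lT <- final_metrics(traj)$total_length
  expect_equal(lT - l0, 0.3, tolerance = 1e-9)
  lH <- traj$metrics[[4]]$total_length  # t = 30 d
  expect_equal(lH - l0, 0.15, tolerance = 1e-9)
})
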