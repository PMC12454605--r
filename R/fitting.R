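# Inverse stage: the tuning cost is a chi-square over the 2n-1 ring
# observables (n radii, n-1 segment lengths) at the fit time point,
# minimized over log time constants with a damped least-squares
# (Levenberg-Marquardt) iteration. Validation uses the relative radius and
# length errors against a later time point, with a linear-projection
# baseline and a nested-model F-test for the multi-domain variant.

#' Observation vector of ring metrics
#'
#' Stacks the n ring radii followed by the n-1 segment lengths (2n-1
#' entries, mm).
#'
#' @param metrics a [ring_metrics].
#' @return numeric vector of length `2 * n_rings - 1`.
#' @export
observation_vector <- function(metrics) {
  c(metrics$radii, metrics$segment_lengths)
}

#' Chi-square error criterion
#'
#' `sum(((obs - pred) / sigma)^2)`.
#'
#' @param predicted,observed observation vectors of equal length.
#' @param sigma_meas measurement error scale (mm), > 0.
#' @return the chi-square value.
#' @export
chi_square <- function(predicted, observed, sigma_meas) {
  if (length(predicted) != length(observed))
    stop_vg("observation length mismatch: %d vs %d",
            length(predicted), length(observed))
  if (sigma_meas <= 0) stop_vg("sigma_meas must be positive")
  sum(((observed - predicted) / sigma_meas)^2)
}

#' Fit configuration
#'
#' @param sigma_meas measurement error scale entering the chi-square (mm);
#'   default 0.02 (imaging-voxel scale). Uniform, so it does not move the
#'   optimum.
#' @param lambda0 initial Levenberg-Marquardt damping.
#' @param factor_up,factor_down damping multipliers on rejected/accepted
#'   steps.
#' @param tol_chi2 relative chi-square decrease below which iteration stops.
#' @param tol_par maximum absolute parameter update below which iteration
#'   stops.
#' @param max_iter iteration cap.
#' @param fd_step relative finite-difference step for the Jacobian.
#' @param init_T_theta,init_T_s initial time constants (days).
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(sigma_meas = 0.02, lambda0 = 1e-3, factor_up = 10,
                       factor_down = 10, tol_chi2 = 1e-10, tol_par = 1e-9,
                       max_iter = 100L, fd_step = 1e-6,
                       init_T_theta = 200, init_T_s = 200) {
  if (sigma_meas <= 0) stop_vg("sigma_meas must be positive")
  structure(list(sigma_meas = sigma_meas, lambda0 = lambda0,
                 factor_up = factor_up, factor_down = factor_down,
                 tol_chi2 = tol_chi2, tol_par = tol_par,
                 max_iter = as.integer(max_iter), fd_step = fd_step,
                 init_T_theta = init_T_theta, init_T_s = init_T_s),
            class = "fit_config")
}

#' Levenberg-Marquardt damped least squares
#'
#' Minimizes `sum(residual_fn(p)^2)` with a finite-difference Jacobian and
#' multiplicative damping: the damping is increased when a trial step
#' increases the cost and decreased when it is accepted. Stops on relative
#' cost change, parameter change, or the iteration cap.
#'
#' @param residual_fn function mapping a parameter vector to a residual
#'   vector.
#' @param initial_params numeric starting point.
#' @param config a [fit_config].
#' @return list: `par`, `chi2` (sum of squared residuals), `sse` (same,
#'   kept under both names), `iterations`, `converged`, `covariance`
#'   (approximate, from the Gauss-Newton Hessian), `residuals`.
#' @export
levenberg_marquardt <- function(residual_fn, initial_params,
                                config = fit_config()) {
  p <- as.numeric(initial_params)
  r <- residual_fn(p)
  if (any(!is.finite(r)))
    stop_vg("non-finite residuals at the initial parameters")
  cost <- sum(r^2)
  lam <- config$lambda0
  converged <- FALSE
  iter <- 0L
  np <- length(p)
  jac <- function(p, r0) {
    J <- matrix(NA_real_, length(r0), np)
    for (j in seq_len(np)) {
      dp <- config$fd_step * max(abs(p[j]), 1)
      pj <- p; pj[j] <- pj[j] + dp
      rj <- tryCatch(residual_fn(pj), error = function(e) rep(NA_real_, length(r0)))
      J[, j] <- (rj - r0) / dp
    }
    J
  }
  while (iter < config$max_iter) {
    iter <- iter + 1L
    J <- jac(p, r)
    if (any(!is.finite(J)))
      stop_vg("non-finite Jacobian at iteration %d", iter)
    A <- crossprod(J)
    g <- crossprod(J, r)
    accepted <- FALSE
    for (try_k in 1:30) {
      step <- tryCatch(
        solve(A + lam * diag(diag(A) + 1e-12, np), -g),
        error = function(e) NULL)
      r_new <- if (is.null(step)) NULL else
        tryCatch(residual_fn(p + as.numeric(step)), error = function(e) NULL)
      if (!is.null(r_new) && all(is.finite(r_new)) &&
          sum(r_new^2) < cost) {
        d_par <- max(abs(step))
        rel_drop <- (cost - sum(r_new^2)) / max(cost, 1e-300)
        p <- p + as.numeric(step)
        r <- r_new
        cost <- sum(r^2)
        lam <- lam / config$factor_down
        accepted <- TRUE
        if (rel_drop < config$tol_chi2 || d_par < config$tol_par)
          converged <- TRUE
        break
      }
      lam <- lam * config$factor_up
    }
    if (!accepted) { converged <- TRUE; break }  # no descent direction left
    if (converged) break
  }
  A <- crossprod(jac(p, r))
  covariance <- tryCatch(solve(A), error = function(e)
    matrix(NA_real_, np, np))
  list(par = p, chi2 = cost, sse = cost, iterations = iter,
       converged = converged, covariance = covariance, residuals = r)
}

#' Fit growth time constants to observed ring geometry
#'
#' Runs the forward growth model from the baseline geometry over the tuning
#' horizon and minimizes the chi-square mismatch of the 2n-1 ring
#' observables at the observation time over `(T_theta, T_s)` (single
#' domain) or `(T_theta^k, T_s^k)` for each of K domains. Time constants
#' are log-parameterized to enforce positivity.
#'
#' @param model forward model: `function(params)` returning a
#'   [ring_metrics] for a [growth_params] object; see [make_growth_model()].
#' @param observed the observed [ring_metrics] (or observation vector) at
#'   the fit time point.
#' @param config a [fit_config].
#' @param n_domains 1 (default) or the number of spatial domains.
#' @param fixed a [growth_params] template providing `T_r`, `T_tau` and the
#'   targets; its `T_theta`/`T_s` are ignored.
#' @return an object of class `fit_result`: `T_theta`, `T_s` (per domain,
#'   days), `chi2`, `sse` (unweighted), `iterations`, `converged`,
#'   `covariance` (log-scale), `se_log` (log-scale standard errors),
#'   `n_obs`, `n_par`.
#' @export
fit_growth_constants <- function(model, observed, config = fit_config(),
                                 n_domains = 1L, fixed = NULL) {
  obs <- if (inherits(observed, "ring_metrics")) observation_vector(observed)
         else as.numeric(observed)
  make_params <- function(logp) {
    Tt <- exp(logp[seq_len(n_domains)])
    Ts <- exp(logp[n_domains + seq_len(n_domains)])
    if (is.null(fixed)) growth_params(Tt, Ts,
                                      sigma_theta_hat = 1, sigma_ss_hat = 1)
    else growth_params(Tt, Ts, T_r = fixed$T_r, T_tau = fixed$T_tau,
                       sigma_theta_hat = fixed$sigma_theta_hat,
                       sigma_ss_hat = fixed$sigma_ss_hat,
                       tau_w_hat = fixed$tau_w_hat)
  }
  residual_fn <- function(logp) {
    m <- model(make_params(logp))
    pred <- if (inherits(m, "ring_metrics")) observation_vector(m)
            else as.numeric(m)
    (obs - pred) / config$sigma_meas
  }
  p0 <- log(c(rep(config$init_T_theta, n_domains),
              rep(config$init_T_s, n_domains)))
  lm <- levenberg_marquardt(residual_fn, p0, config)
  se_log <- sqrt(pmax(diag(lm$covariance), 0))
  structure(list(T_theta = exp(lm$par[seq_len(n_domains)]),
                 T_s = exp(lm$par[n_domains + seq_len(n_domains)]),
                 chi2 = lm$chi2,
                 sse = lm$chi2 * config$sigma_meas^2,
                 iterations = lm$iterations, converged = lm$converged,
                 covariance = lm$covariance, se_log = se_log,
                 n_obs = length(obs), n_par = 2L * n_domains),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%d domain%s): chi2 = %.4g after %d iterations%s\n",
              length(x$T_theta), if (length(x$T_theta) > 1) "s" else "",
              x$chi2, x$iterations,
              if (x$converged) "" else " (not converged)"))
  print(data.frame(domain = seq_along(x$T_theta),
                   T_theta_days = round(x$T_theta, 2),
                   T_s_days = round(x$T_s, 2)))
  invisible(x)
}

#' Build a forward growth model closure for fitting
#'
#' Binds the baseline profile, wall, material and hemodynamic load so the
#' optimizer only varies the growth parameters.
#'
#' @inheritParams forward_simulate
#' @return `function(params)` returning the [ring_metrics] at the horizon.
#' @export
make_growth_model <- function(profile, wall, mu, hemo, config,
                              partition = NULL, motion = NULL,
                              n_rings = 6L) {
  force(profile); force(wall); force(mu); force(hemo); force(config)
  function(params) {
    final_metrics(forward_simulate(profile, wall, mu, hemo, params, config,
                                   partition = partition, motion = motion,
                                   n_rings = n_rings))
  }
}

#' Relative radius error per ring
#'
#' `(r_pred - r_meas) / r_meas`; positive values mean the prediction
#' overestimates the measurement. The summary mean uses the interior rings
#' only (rings 2 to 5 of a 6-ring set), excluding the inlet and outlet
#' rings to avoid boundary-condition bias.
#'
#' @param predicted_radii,measured_radii per-ring radii (mm), equal length.
#' @param interior_rings indices entering the mean (default `2:(n-1)`).
#' @return an object of class `validation_metrics` fragment: list with
#'   `delta_r` (per ring), `mean_delta_r` (interior mean), `rings_used`.
#' @export
delta_r <- function(predicted_radii, measured_radii,
                    interior_rings = NULL) {
  if (length(predicted_radii) != length(measured_radii))
    stop_vg("ring count mismatch")
  if (any(measured_radii <= 0)) stop_vg("measured radii must be positive")
  d <- (predicted_radii - measured_radii) / measured_radii
  n <- length(d)
  interior_rings <- interior_rings %||% seq(2L, n - 1L)
  list(delta_r = d, mean_delta_r = mean(d[interior_rings]),
       rings_used = interior_rings)
}

#' Relative total-length error
#'
#' `(l_pred - l_meas) / l_meas` over the entire vessel from inlet to
#' outlet.
#'
#' @param predicted_total_length,measured_total_length lengths (mm), > 0.
#' @return the signed fraction.
#' @export
delta_l <- function(predicted_total_length, measured_total_length) {
  if (predicted_total_length <= 0 || measured_total_length <= 0)
    stop_vg("lengths must be positive")
  (predicted_total_length - measured_total_length) / measured_total_length
}

#' Linear projection baseline
#'
#' Extrapolates the third (equally spaced) time point linearly from the
#' first two: `x_t2 = x_t1 + (x_t1 - x_t0)`.
#'
#' @param r_t0,r_t1 values at the first two time points (vectorized).
#' @return projected value at the third time point.
#' @export
linear_projection_baseline <- function(r_t0, r_t1) {
  if (any(r_t0 <= 0) || any(r_t1 <= 0)) stop_vg("values must be positive")
  r_t1 + (r_t1 - r_t0)
}

#' Nested-model F-test on sums of squared errors
#'
#' `F = ((SSE_r - SSE_f) / (p_f - p_r)) / (SSE_f / (n - p_f))`, with the
#' p-value from the F(p_f - p_r, n - p_f) distribution. A full-model SSE
#' above the reduced one (numerical noise) clips F at 0.
#'
#' @param sse_reduced,sse_full sums of squared errors.
#' @param p_reduced,p_full parameter counts, `p_full > p_reduced`.
#' @param n_obs number of observations, `> p_full`.
#' @return list: `F`, `p_value`, `df1`, `df2`.
#' @export
nested_f_test <- function(sse_reduced, p_reduced, sse_full, p_full, n_obs) {
  if (p_full <= p_reduced) stop_vg("full model must have more parameters")
  if (n_obs <= p_full) stop_vg("need n_obs > p_full for residual dof")
  df1 <- p_full - p_reduced
  df2 <- n_obs - p_full
  Fv <- max(0, (sse_reduced - sse_full) / df1 / (sse_full / df2))
  list(F = Fv, p_value = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}
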