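# Desk-scale hemodynamic surrogate: a lumped three-element Windkessel (RCR)
# converts the inflow waveform into pressure, thin-wall (Laplace-law)
# relations convert pressure into wall stresses, and Poiseuille flow with a
# Carreau-Yasuda shear-thinning viscosity gives the wall shear stress. The
# Neo-Hookean relations provide the material constants and the membrane
# inflation used to map unloaded to loaded radii.
#
# Units: pressure and stress in Pa, lengths in mm, flow in mm^3/s,
# resistance in Pa*s/mm^3, compliance in mm^3/Pa, viscosity in Pa*s.

#' Lame parameters from elastic modulus and Poisson's ratio
#'
#' `mu = E / (2 (1 + nu))`, `lambda = nu E / ((1 + nu)(1 - 2 nu))`.
#'
#' @param E elastic modulus (kPa), > 0 (0 allowed, degenerate).
#' @param nu Poisson's ratio, `0 <= nu < 0.5`.
#' @return an object of class `material_params` with fields `E`, `nu`, `mu`,
#'   `lame_lambda` (all moduli in kPa).
#' @examples
#' lame_from_E_nu(722, 0.44)
#' @export
lame_from_E_nu <- function(E, nu) {
  if (E < 0) stop_vg("elastic modulus must be non-negative")
  if (nu < 0 || nu >= 0.5)
    stop_vg("Poisson's ratio must be in [0, 0.5); nu = 0.5 is the incompressible limit")
  structure(list(E = E, nu = nu,
                 mu = E / (2 * (1 + nu)),
                 lame_lambda = nu * E / ((1 + nu) * (1 - 2 * nu))),
            class = "material_params")
}

#' Compressible Neo-Hookean strain energy density
#'
#' `W = mu/2 (I1 - 3) - mu ln(J) + lambda/2 (ln J)^2` with `I1 = tr(Fe' Fe)`
#' and `J = det(Fe)`.
#'
#' @param F_e 3 x 3 elastic deformation gradient, `det(F_e) > 0`.
#' @param material a [material_params][lame_from_E_nu] object (moduli set the
#'   energy units).
#' @return energy density (same units as the moduli).
#' @export
neo_hookean_energy <- function(F_e, material) {
  F_e <- as.matrix(F_e)
  J <- det(F_e)
  if (J <= 0) stop_vg("det(F_e) must be positive, got %g", J)
  I1 <- sum(F_e^2)
  material$mu / 2 * (I1 - 3) - material$mu * log(J) +
    material$lame_lambda / 2 * log(J)^2
}

#' Three-element Windkessel parameters
#'
#' @param Rp proximal resistance (Pa s / mm^3).
#' @param C compliance (mm^3 / Pa).
#' @param Rd distal resistance (Pa s / mm^3).
#' @param name optional outlet label.
#' @return an object of class `windkessel_params`.
#' @export
windkessel_params <- function(Rp, C, Rd, name = NULL) {
  if (any(c(Rp, C, Rd) <= 0)) stop_vg("Windkessel parameters must be positive")
  structure(list(Rp = Rp, C = C, Rd = Rd, name = name),
            class = "windkessel_params")
}

#' Packaged aortic outlet Windkessel parameters
#'
#' Loads the four-outlet RCR parameter table distributed with the package
#' (left subclavian, left common carotid, brachiocephalic trunk, distal
#' aorta), as tuned for a mean aortic pressure of about 90 mmHg. Compliance
#' is stored in mm^3/Pa, the unit required for dimensional consistency of
#' the RCR ordinary differential equation.
#'
#' @return a list of four [windkessel_params].
#' @export
load_windkessel_outlets <- function() {
  path <- system.file("extdata", "windkessel_outlets.csv",
                      package = "vesselgrow", mustWork = TRUE)
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i)
    windkessel_params(df$Rp_Pa_s_per_mm3[i], df$C_mm3_per_Pa[i],
                      df$Rd_Pa_s_per_mm3[i], name = df$outlet[i]))
}

#' Parameterized periodic inflow waveform
#'
#' A parabolic-systole pulse: `Q(t) = Q_peak 4 x (1 - x)` for
#' `x = t / (f_sys T)` during systole, 0 in diastole, repeated with period
#' `T`. The peak is chosen so the period mean equals `mean_flow`.
#'
#' @param mean_flow period-mean flow (mm^3/s), > 0.
#' @param period cardiac period (s), default 0.15 (mouse heart rate about
#'   400 beats/min).
#' @param systolic_fraction fraction of the period in systole, default 0.4.
#' @param n_samples samples per period, default 200.
#' @return an object of class `flow_waveform`: `time`, `Q`, `period`,
#'   `mean_flow`.
#' @export
flow_waveform <- function(mean_flow, period = 0.15, systolic_fraction = 0.4,
                          n_samples = 200L) {
  if (mean_flow <= 0) stop_vg("mean flow must be positive")
  tt <- seq(0, period, length.out = n_samples + 1L)[-(n_samples + 1L)]
  x <- tt / (systolic_fraction * period)
  q_shape <- ifelse(x < 1, 4 * x * (1 - x), 0)
  peak <- mean_flow / (2 / 3 * systolic_fraction)
  structure(list(time = tt, Q = peak * q_shape, period = period,
                 mean_flow = mean_flow),
            class = "flow_waveform")
}

#' Integrate the three-element Windkessel to periodic steady state
#'
#' Integrates `dPc/dt = (Q - Pc/Rd)/C` with `P = Q Rp + Pc` over `n_periods`
#' cardiac cycles and reports the last-period pressure trace. At periodic
#' steady state the period-mean pressure is `mean(Q) (Rp + Rd)`,
#' independent of the compliance.
#'
#' @param waveform a [flow_waveform].
#' @param params a [windkessel_params].
#' @param n_periods number of periods to integrate (default 20).
#' @param drift_tol relative last-period mean drift regarded as converged
#'   (default 1e-3); a warning is emitted above it.
#' @return list: `time`, `pressure` (Pa, last period), `mean_pressure` (Pa),
#'   `drift` (relative change of the period mean over the final two
#'   periods).
#' @export
solve_windkessel <- function(waveform, params, n_periods = 20L,
                             drift_tol = 1e-3) {
  if (n_periods < 1L) stop_vg("n_periods must be >= 1")
  Tp <- waveform$period
  qfun <- stats::approxfun(c(waveform$time, Tp),
                           c(waveform$Q, waveform$Q[1]), rule = 2)
  Q_of <- function(t) qfun(t %% Tp)
  rhs <- function(t, y, p) list((Q_of(t) - y[1] / params$Rd) / params$C)
  times <- seq(0, n_periods * Tp, by = Tp / length(waveform$time))
  out <- deSolve::ode(y = c(Pc = mean(waveform$Q) * params$Rd), times = times,
                      func = rhs, parms = NULL, method = "lsoda")
  pc <- out[, "Pc"]
  p_all <- Q_of(out[, "time"]) * params$Rp + pc
  nper <- length(waveform$time)
  last <- p_all[(length(p_all) - nper + 1L):length(p_all)]
  prev <- p_all[(length(p_all) - 2L * nper + 1L):(length(p_all) - nper)]
  drift <- abs(mean(last) - mean(prev)) / max(abs(mean(last)), 1e-12)
  if (drift > drift_tol)
    warn_vg("Windkessel not at periodic steady state: drift %.2e", drift)
  list(time = out[(length(p_all) - nper + 1L):length(p_all), "time"],
       pressure = last, mean_pressure = mean(last), drift = drift)
}

#' Mean pressure of parallel Windkessel outlets
#'
#' Distributes a total mean inflow over outlets in proportion to their
#' steady conductance `1/(Rp + Rd)` and returns the common mean outlet
#' pressure `Q_total R_parallel`.
#'
#' @param waveform a [flow_waveform] carrying the total inflow.
#' @param outlet_list list of [windkessel_params].
#' @param ... passed to [solve_windkessel()].
#' @return list: `mean_pressure` (Pa), `per_outlet` (per-outlet results),
#'   `parallel_resistance`.
#' @export
windkessel_parallel_pressure <- function(waveform, outlet_list, ...) {
  G <- vapply(outlet_list, function(p) 1 / (p$Rp + p$Rd), numeric(1))
  Rpar <- 1 / sum(G)
  per <- lapply(seq_along(outlet_list), function(i) {
    wf_i <- waveform
    frac <- G[i] / sum(G)
    wf_i$Q <- waveform$Q * frac
    wf_i$mean_flow <- waveform$mean_flow * frac
    solve_windkessel(wf_i, outlet_list[[i]], ...)
  })
  list(mean_pressure = mean(vapply(per, `[[`, numeric(1), "mean_pressure")),
       per_outlet = per, parallel_resistance = Rpar)
}

#' Carreau-Yasuda shear-thinning viscosity
#'
#' `mu(g) = mu_inf + (mu0 - mu_inf) [1 + (lambda g)^a]^((n-1)/a)`.
#'
#' @param shear_rate shear rate (1/s), >= 0; vectorized.
#' @param model a [carreau_yasuda_model].
#' @return apparent viscosity (Pa s).
#' @export
carreau_yasuda_viscosity <- function(shear_rate, model = carreau_yasuda_model()) {
  if (any(shear_rate < 0)) stop_vg("shear rate must be non-negative")
  model$mu_inf + (model$mu0 - model$mu_inf) *
    (1 + (model$lambda_cy * shear_rate)^model$a)^((model$n - 1) / model$a)
}

#' Carreau-Yasuda parameter set
#'
#' Defaults are standard whole-blood literature values; every field is
#' configurable.
#'
#' @param mu0 zero-shear viscosity (Pa s).
#' @param mu_inf infinite-shear viscosity (Pa s).
#' @param lambda_cy relaxation time (s).
#' @param a Yasuda exponent.
#' @param n power-law index.
#' @return an object of class `carreau_yasuda_model`.
#' @export
carreau_yasuda_model <- function(mu0 = 0.056, mu_inf = 0.00345,
                                 lambda_cy = 3.313, a = 2, n = 0.3568) {
  if (!(mu0 >= mu_inf && mu_inf > 0))
    stop_vg("need mu0 >= mu_inf > 0")
  structure(list(mu0 = mu0, mu_inf = mu_inf, lambda_cy = lambda_cy,
                 a = a, n = n),
            class = "carreau_yasuda_model")
}

#' Thin-wall stresses driven by mean pressure and flow
#'
#' Per ring: hoop stress `sigma_theta = p r / h`, axial stress
#' `sigma_ss = p r / (2 h)` (capped thin-wall cylinder), and Poiseuille wall
#' shear `tau_w = 4 mu_eff Q / (pi r^3)` with the apparent viscosity
#' evaluated at the wall shear rate `4 Q / (pi r^3)` by fixed-point
#' iteration (at most 20 iterations; falls back to `mu_inf` with a warning
#' on failure).
#'
#' @param ring_metrics a [ring_metrics] (loaded radii, mm) or a numeric
#'   vector of radii.
#' @param wall a [wall_spec] (mm).
#' @param pressure_mean mean transmural pressure (Pa), > 0.
#' @param flow_mean mean flow (mm^3/s), > 0.
#' @param viscosity a [carreau_yasuda_model].
#' @return an object of class `stress_field`: `sigma_theta`, `sigma_ss`,
#'   `tau_w` (Pa, one per ring).
#' @export
thin_wall_stresses <- function(ring_metrics, wall, pressure_mean, flow_mean,
                               viscosity = carreau_yasuda_model()) {
  r <- if (inherits(ring_metrics, "ring_metrics")) ring_metrics$radii
       else as.numeric(ring_metrics)
  h <- wall$thickness
  if (any(r <= 0) || h <= 0 || pressure_mean <= 0)
    stop_vg("radii, thickness and pressure must be positive")
  sigma_theta <- pressure_mean * r / h
  sigma_ss <- pressure_mean * r / (2 * h)
  # wall shear rate in 1/s: flow mm^3/s over r^3 mm^3
  gdot_newt <- 4 * flow_mean / (pi * r^3)
  mu_eff <- rep(viscosity$mu_inf, length(r))
  gdot <- gdot_newt
  converged <- FALSE
  for (it in 1:20) {
    mu_new <- carreau_yasuda_viscosity(gdot, viscosity)
    if (max(abs(mu_new - mu_eff) / mu_new) < 1e-10) {
      mu_eff <- mu_new; converged <- TRUE; break
    }
    mu_eff <- mu_new
    # Poiseuille wall shear rate is set by Q and r alone; the fixed point
    # is on the viscosity value
    gdot <- gdot_newt
  }
  if (!converged) {
    warn_vg("viscosity fixed point did not converge; using mu_inf")
    mu_eff <- rep(viscosity$mu_inf, length(r))
  }
  tau_w <- 4 * mu_eff * flow_mean / (pi * r^3)
  structure(list(sigma_theta = sigma_theta, sigma_ss = sigma_ss,
                 tau_w = tau_w),
            class = "stress_field")
}

#' Export a stress field as CSV
#'
#' @param stress a `stress_field`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stress_field <- function(stress, path) {
  utils::write.csv(data.frame(ring_index = seq_along(stress$sigma_theta),
                              sigma_theta_Pa = stress$sigma_theta,
                              sigma_ss_Pa = stress$sigma_ss,
                              tau_w_Pa = stress$tau_w),
                   path, row.names = FALSE)
  invisible(path)
}

# Membrane inflation residual: incompressible Neo-Hookean membrane with
# axial stretch 1; circumferential stretch lambda satisfies
# mu (lambda^2 - lambda^-2) = p lambda^2 R / H.
inflation_residual <- function(lam, mu, p, R, H) {
  mu * (lam^2 - lam^-2) - p * lam^2 * R / H
}

# Pressure limit: the residual has a root only for p < mu H / R.
inflation_pressure_limit <- function(mu, R, H) mu * H / R

#' Thin-membrane inflation of an unloaded radius
#'
#' Solves `mu (lambda^2 - 1/lambda^2) = p lambda^2 R / H` for the
#' circumferential elastic stretch `lambda` of an incompressible
#' Neo-Hookean membrane with the axial stretch held at 1, by bracketed
#' root-finding. The loaded radius is `lambda R`.
#'
#' @param unloaded_radius unloaded radius R (mm).
#' @param wall a [wall_spec] (unloaded thickness H, mm).
#' @param mu shear modulus (Pa).
#' @param pressure transmural pressure (Pa), >= 0.
#' @return list: `lambda` (elastic stretch), `loaded_radius` (mm).
#' @export
membrane_inflation <- function(unloaded_radius, wall, mu, pressure) {
  R <- unloaded_radius; H <- wall$thickness
  if (R <= 0 || H <= 0 || mu <= 0 || pressure < 0)
    stop_vg("inflation inputs must be positive (pressure may be 0)")
  if (pressure == 0) return(list(lambda = 1, loaded_radius = R))
  p_lim <- inflation_pressure_limit(mu, R, H)
  if (pressure >= p_lim)
    stop_vg("pressure %.4g Pa at or beyond the membrane limit point %.4g Pa",
            pressure, p_lim)
  upper <- 2
  while (inflation_residual(upper, mu, pressure, R, H) < 0) upper <- upper * 2
  root <- stats::uniroot(inflation_residual, c(1, upper), mu = mu,
                         p = pressure, R = R, H = H, tol = 1e-12)
  list(lambda = root$root, loaded_radius = root$root * R)
}

#' Vectorized closed-form membrane inflation
#'
#' The inflation residual of [membrane_inflation()] solves in closed form:
#' `lambda^-4 = 1 - p R / (mu H)`. This vectorized form is what the growth
#' loop uses; the bracketed root-finder and the closed form agree to root
#' tolerance.
#'
#' @param R unloaded radii (mm), vectorized.
#' @param H unloaded thickness (mm), scalar or per-entry.
#' @param mu shear modulus (Pa).
#' @param p transmural pressure (Pa).
#' @return list: `lambda`, `loaded_radius`.
#' @export
inflate_radii <- function(R, H, mu, p) {
  kappa <- p * R / (mu * H)
  if (any(kappa >= 1))
    stop_vg("pressure beyond membrane limit point for %d station(s)",
            sum(kappa >= 1))
  lam <- (1 - kappa)^(-0.25)
  list(lambda = lam, loaded_radius = lam * R)
}

#' Membrane deflation: unloaded radius from a loaded radius
#'
#' Inverse of [inflate_radii()]: given an in vivo (loaded) radius, recovers
#' the unloaded reference radius by a monotone scalar root solve.
#'
#' @param r loaded radii (mm), vectorized.
#' @inheritParams inflate_radii
#' @return unloaded radii (mm).
#' @export
deflate_radii <- function(r, H, mu, p) {
  R_lim <- mu * H / p
  vapply(r, function(ri) {
    f <- function(R) inflate_radii(R, H, mu, p)$loaded_radius - ri
    # unloaded radius lies below both the loaded radius and the limit point
    up <- min(ri, R_lim * (1 - 1e-9))
    lo <- ri * 1e-6
    stats::uniroot(f, c(lo, up), tol = 1e-12)$root
  }, numeric(1))
}
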