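# Stress-homeostasis kinematic growth: diagonal growth tensor
# G = diag(lambda_gr, lambda_gtheta, lambda_gs) in the local (r, theta, s)
# frame, evolving by first-order laws that drive the wall stresses toward
# homeostatic targets. The total deformation is F = Fe . G, with the elastic
# part Fe supplied by the thin-membrane inflation surrogate.

#' Growth-law parameters
#'
#' Time constants (days) and homeostatic target stresses (Pa) of the
#' anisotropic growth laws
#' \deqn{d\lambda_{gr}/dt = (1/T_r)(\sigma_{\theta\theta}/\hat\sigma_{\theta\theta} - 1)\lambda_{gr}}
#' \deqn{d\lambda_{g\theta}/dt = [(1/T_\theta)(\sigma_{\theta\theta}/\hat\sigma_{\theta\theta} - 1) + (1/T_\tau)(\tau_w/\hat\tau_w - 1)]\lambda_{g\theta}}
#' \deqn{d\lambda_{gs}/dt = (1/T_s)(\sigma_{ss}/\hat\sigma_{ss} - 1)\lambda_{gs}}
#' `T_theta` and `T_s` may be vectors (one entry per spatial domain) for the
#' multi-domain variant. `T_tau = Inf` switches the wall-shear term off,
#' the default since no wall-shear target is fitted.
#'
#' @param T_theta circumferential time constant(s), days.
#' @param T_s axial time constant(s), days.
#' @param T_r radial time constant, days (held fixed, not fitted).
#' @param T_tau wall-shear time constant, days (`Inf` disables the term).
#' @param sigma_theta_hat,sigma_ss_hat homeostatic hoop/axial stress (Pa).
#' @param tau_w_hat homeostatic wall shear stress (Pa); only used when
#'   `T_tau` is finite.
#' @return an object of class `growth_params`.
#' @export
growth_params <- function(T_theta, T_s, T_r = 500, T_tau = Inf,
                          sigma_theta_hat, sigma_ss_hat, tau_w_hat = 1) {
  if (any(c(T_theta, T_s, T_r, T_tau) <= 0))
    stop_vg("growth time constants must be positive")
  if (any(c(sigma_theta_hat, sigma_ss_hat, tau_w_hat) <= 0))
    stop_vg("homeostatic target stresses must be positive")
  if (length(T_theta) != length(T_s))
    stop_vg("T_theta and T_s must have the same number of domains")
  structure(list(T_theta = T_theta, T_s = T_s, T_r = T_r, T_tau = T_tau,
                 sigma_theta_hat = sigma_theta_hat,
                 sigma_ss_hat = sigma_ss_hat, tau_w_hat = tau_w_hat,
                 n_domains = length(T_theta)),
            class = "growth_params")
}

#' Initial growth state
#'
#' @param n_elements number of elements (axial stations).
#' @return an object of class `growth_state`: unit stretch ratios
#'   `lambda_gr`, `lambda_gtheta`, `lambda_gs`.
#' @export
growth_state <- function(n_elements) {
  one <- rep(1, n_elements)
  structure(list(lambda_gr = one, lambda_gtheta = one, lambda_gs = one),
            class = "growth_state")
}

#' Axial domain partition
#'
#' Assigns each element to one of `K` equal axial domains by its `s`
#' coordinate (quarters of the centerline for the default `K = 4`).
#'
#' @param s element axial coordinates in `[0, 1]`.
#' @param K number of domains.
#' @return integer vector of domain indices 1..K.
#' @export
domain_partition <- function(s, K = 4L) {
  k <- pmin(floor(s * K) + 1L, K)
  as.integer(k)
}

# Expand possibly per-domain time constants to per-element vectors.
expand_constants <- function(params, domain, n) {
  if (params$n_domains == 1L) {
    list(T_theta = rep(params$T_theta, n), T_s = rep(params$T_s, n))
  } else {
    if (is.null(domain))
      stop_vg("multi-domain growth_params require a domain partition")
    if (max(domain) > params$n_domains)
      stop_vg("partition references domain %d but only %d are parameterized",
              max(domain), params$n_domains)
    list(T_theta = params$T_theta[domain], T_s = params$T_s[domain])
  }
}

#' Growth rates from the current stress state
#'
#' Evaluates the three growth laws element-wise (per day).
#'
#' @param state a [growth_state].
#' @param stress a [stress_field][thin_wall_stresses] with per-element
#'   `sigma_theta`, `sigma_ss`, `tau_w`.
#' @param params a [growth_params].
#' @param domain optional per-element domain indices for multi-domain
#'   constants.
#' @return list of per-element rates `d_lambda_gr`, `d_lambda_gtheta`,
#'   `d_lambda_gs` (1/day).
#' @export
growth_rates <- function(state, stress, params, domain = NULL) {
  if (any(!is.finite(stress$sigma_theta)) || any(!is.finite(stress$sigma_ss)))
    stop_vg("non-finite stresses in growth_rates")
  n <- length(state$lambda_gtheta)
  tc <- expand_constants(params, domain, n)
  drive_theta <- stress$sigma_theta / params$sigma_theta_hat - 1
  drive_ss <- stress$sigma_ss / params$sigma_ss_hat - 1
  drive_tau <- if (is.finite(params$T_tau))
    (stress$tau_w / params$tau_w_hat - 1) / params$T_tau else 0
  list(
    d_lambda_gr = drive_theta / params$T_r * state$lambda_gr,
    d_lambda_gtheta = (drive_theta / tc$T_theta + drive_tau) *
      state$lambda_gtheta,
    d_lambda_gs = drive_ss / tc$T_s * state$lambda_gs)
}

#' Assemble per-element diagonal growth tensors
#'
#' @param state a [growth_state].
#' @return 3 x 3 x n array; slice `[ , , e]` is
#'   `diag(lambda_gr, lambda_gtheta, lambda_gs)` for element `e` in the
#'   local (r, theta, s) frame.
#' @export
assemble_growth_tensor <- function(state) {
  n <- length(state$lambda_gr)
  G <- array(0, dim = c(3, 3, n))
  G[1, 1, ] <- state$lambda_gr
  G[2, 2, ] <- state$lambda_gtheta
  G[3, 3, ] <- state$lambda_gs
  G
}

#' One explicit Euler growth step
#'
#' Advances the growth state by `dt` days at a fixed stress state, with
#' optional equal substeps. Errors if any stretch ratio becomes
#' non-positive.
#'
#' @inheritParams growth_rates
#' @param dt time step (days), > 0.
#' @param substeps number of equal Euler substeps within `dt`.
#' @return the updated [growth_state].
#' @export
step_growth <- function(state, stress, params, dt, substeps = 1L,
                        domain = NULL) {
  if (dt <= 0) stop_vg("dt must be positive")
  h <- dt / substeps
  for (k in seq_len(substeps)) {
    rates <- growth_rates(state, stress, params, domain)
    state$lambda_gr <- state$lambda_gr + h * rates$d_lambda_gr
    state$lambda_gtheta <- state$lambda_gtheta + h * rates$d_lambda_gtheta
    state$lambda_gs <- state$lambda_gs + h * rates$d_lambda_gs
    if (any(c(state$lambda_gr, state$lambda_gtheta, state$lambda_gs) <= 0))
      stop_vg("growth stretch became non-positive; reduce dt or increase substeps")
  }
  state
}

#' Apply a growth increment to ring geometry
#'
#' Kinematic update of the unloaded geometry: ring radii scale by the
#' circumferential increment, segment lengths by the mean axial increment of
#' the adjacent ring pair, and the wall thickness by the mean radial
#' increment.
#'
#' @param metrics a [ring_metrics] (unloaded).
#' @param wall a [wall_spec].
#' @param increment list with per-ring factors `d_lambda_gtheta`,
#'   `d_lambda_gs` and scalar or per-ring `d_lambda_gr`.
#' @return list: updated `metrics` and `wall`.
#' @export
update_geometry <- function(metrics, wall, increment) {
  radii <- metrics$radii * increment$d_lambda_gtheta
  gs <- increment$d_lambda_gs
  seg <- metrics$segment_lengths * (gs[-length(gs)] + gs[-1]) / 2
  h <- wall$thickness * mean(increment$d_lambda_gr)
  list(metrics = ring_metrics(radii, seg),
       wall = wall_spec(h))
}

#' Simulation configuration
#'
#' @param dt growth time step (days), default 10.
#' @param horizon simulated time (days): 60 for tuning (2 to 4 months at 30
#'   days/month), 120 for validation (2 to 6 months).
#' @param substeps Euler substeps per `dt`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(dt = 10, horizon = 60, substeps = 1L) {
  if (dt <= 0) stop_vg("dt must be positive")
  if (abs(horizon / dt - round(horizon / dt)) > 1e-9)
    stop_vg("horizon must be a multiple of dt")
  structure(list(dt = dt, horizon = horizon,
                 substeps = as.integer(substeps)),
            class = "sim_config")
}

#' Linear boundary displacement
#'
#' Axial displacements imposed at the tube ends, interpolated linearly both
#' in time (zero at t = 0) and along the axial coordinate.
#'
#' @param inlet_total,outlet_total total axial displacement (mm) reached at
#'   `horizon`.
#' @param horizon time (days) at which the totals are reached.
#' @return an object of class `boundary_motion`.
#' @export
boundary_motion <- function(inlet_total = 0, outlet_total = 0, horizon = 60) {
  structure(list(inlet_rate = inlet_total / horizon,
                 outlet_rate = outlet_total / horizon),
            class = "boundary_motion")
}

#' Axial tube profile for the growth engine
#'
#' Discretizes the unloaded vessel as axial stations with station radii and
#' inter-station segment lengths. The stations are the growth "elements".
#'
#' @param s station axial coordinates in `[0, 1]` (increasing, endpoints 0
#'   and 1).
#' @param R unloaded station radii (mm).
#' @param seg unloaded segment lengths between stations (mm),
#'   `length(s) - 1` entries.
#' @return an object of class `tube_profile`.
#' @export
tube_profile <- function(s, R, seg) {
  if (length(R) != length(s) || length(seg) != length(s) - 1L)
    stop_vg("inconsistent tube_profile lengths")
  if (any(diff(s) <= 0)) stop_vg("station coordinates must be increasing")
  if (any(R <= 0) || any(seg <= 0)) stop_vg("radii and segments must be positive")
  structure(list(s = s, R = R, seg = seg), class = "tube_profile")
}

#' Unloaded tube profile from measured (loaded) ring metrics
#'
#' Interpolates the measured ring radii onto `n_elements` equally spaced
#' stations and removes the elastic inflation (membrane deflation) to
#' recover the unloaded reference configuration used by the growth engine.
#'
#' @param metrics a [ring_metrics] measured in vivo (loaded).
#' @param wall a [wall_spec] (unloaded thickness).
#' @param mu wall shear modulus (Pa).
#' @param pressure mean transmural pressure (Pa).
#' @param n_elements number of axial stations; `n_elements - 1` should be a
#'   multiple of `n_rings - 1` so rings coincide with stations (default 26).
#' @return a [tube_profile].
#' @export
tube_profile_from_metrics <- function(metrics, wall, mu, pressure,
                                      n_elements = 26L) {
  n_r <- length(metrics$radii)
  s_rings <- seq(0, 1, length.out = n_r)
  s <- seq(0, 1, length.out = n_elements)
  r_loaded <- stats::approx(s_rings, metrics$radii, s)$y
  z_rings <- c(0, cumsum(metrics$segment_lengths))
  z <- stats::approx(s_rings, z_rings, s)$y
  R <- deflate_radii(r_loaded, wall$thickness, mu, pressure)
  tube_profile(s, R, diff(z))
}

pair_mean <- function(x) (x[-length(x)] + x[-1]) / 2

#' Forward growth-and-remodeling simulation
#'
#' Time-steps the coupled loop: membrane inflation of the grown unloaded
#' geometry gives the loaded radii; thin-wall relations give the stresses;
#' the growth laws update the growth stretches; the unloaded geometry is
#' regrown kinematically. Ring metrics are recorded at every step.
#'
#' @param profile a [tube_profile] (unloaded reference at t = 0).
#' @param wall a [wall_spec] (unloaded thickness at t = 0).
#' @param mu wall shear modulus (Pa).
#' @param hemo list with `pressure` (Pa), `flow` (mm^3/s) and optionally
#'   `viscosity` (a [carreau_yasuda_model]).
#' @param params a [growth_params].
#' @param config a [sim_config].
#' @param partition optional per-element domain indices (required for
#'   multi-domain `params`); see [domain_partition()].
#' @param motion optional [boundary_motion].
#' @param n_rings rings recorded per step (default 6).
#' @param fixed_stress optional [stress_field][thin_wall_stresses] held
#'   constant through the run (disables the stress feedback; used for
#'   closed-form verification).
#' @return an object of class `growth_trajectory`: `times` (days),
#'   `metrics` (list of [ring_metrics]), `state` (final [growth_state]),
#'   `mean_sigma_theta` (time average of the element-mean hoop stress, Pa),
#'   `stress0` (baseline stress field).
#' @export
forward_simulate <- function(profile, wall, mu, hemo, params, config,
                             partition = NULL, motion = NULL,
                             n_rings = 6L, fixed_stress = NULL) {
  s <- profile$s
  m <- length(s)
  R0 <- profile$R
  seg0 <- profile$seg
  h0 <- wall$thickness
  visc <- hemo$viscosity %||% carreau_yasuda_model()
  if (!is.null(partition) && length(partition) != m)
    stop_vg("partition must give one domain per element")
  state <- growth_state(m)
  n_steps <- round(config$horizon / config$dt)
  ring_s <- seq(0, 1, length.out = n_rings)

  current_stress <- function() {
    Rg <- R0 * state$lambda_gtheta
    hg <- h0 * state$lambda_gr
    infl <- inflate_radii(Rg, hg, mu, hemo$pressure)
    st <- thin_wall_stresses(infl$loaded_radius, wall_spec(mean(hg)),
                             hemo$pressure, hemo$flow, visc)
    # per-element thickness in the Laplace relations
    st$sigma_theta <- hemo$pressure * infl$loaded_radius / hg
    st$sigma_ss <- st$sigma_theta / 2
    list(stress = st, loaded = infl$loaded_radius)
  }

  snapshot <- function(t) {
    Rg <- R0 * state$lambda_gtheta
    hg <- h0 * state$lambda_gr
    segg <- seg0 * pair_mean(state$lambda_gs)
    r <- inflate_radii(Rg, hg, mu, hemo$pressure)$loaded_radius
    z <- c(0, cumsum(segg))
    if (!is.null(motion))
      z <- z + motion$inlet_rate * t * (1 - s) + motion$outlet_rate * t * s
    radii <- stats::approx(s, r, ring_s)$y
    zr <- stats::approx(s, z, ring_s)$y
    ring_metrics(radii, diff(zr))
  }

  cs0 <- current_stress()
  stress0 <- cs0$stress
  metrics <- vector("list", n_steps + 1L)
  metrics[[1L]] <- snapshot(0)
  sigma_bar <- numeric(n_steps + 1L)
  sigma_bar[1L] <- mean(stress0$sigma_theta)
  for (k in seq_len(n_steps)) {
    for (sub in seq_len(config$substeps)) {
      st <- if (is.null(fixed_stress)) current_stress()$stress
            else fixed_stress
      state <- step_growth(state, st, params, config$dt / config$substeps,
                           substeps = 1L, domain = partition)
    }
    t_k <- k * config$dt
    metrics[[k + 1L]] <- snapshot(t_k)
    sigma_bar[k + 1L] <- mean(current_stress()$stress$sigma_theta)
  }
  structure(list(times = (0:n_steps) * config$dt, metrics = metrics,
                 state = state, mean_sigma_theta = mean(sigma_bar),
                 stress0 = stress0),
            class = "growth_trajectory")
}

#' Final ring metrics of a trajectory
#'
#' @param traj a `growth_trajectory` from [forward_simulate()].
#' @return the [ring_metrics] at the simulation horizon.
#' @export
final_metrics <- function(traj) traj$metrics[[length(traj$metrics)]]

#' Uniform homeostatic targets from a baseline stress field
#'
#' Sets the homeostatic hoop and axial targets to the element-mean baseline
#' stresses scaled by a factor below one, so that the baseline state is
#' growth-positive (the positive-feedback regime of an aneurysmal wall).
#'
#' @param stress a baseline [stress_field][thin_wall_stresses].
#' @param scale target scale factor in (0, 1], default 0.8.
#' @return list with `sigma_theta_hat`, `sigma_ss_hat`, `tau_w_hat` (Pa).
#' @export
homeostatic_targets <- function(stress, scale = 0.8) {
  if (scale <= 0) stop_vg("target scale must be positive")
  list(sigma_theta_hat = scale * mean(stress$sigma_theta),
       sigma_ss_hat = scale * mean(stress$sigma_ss),
       tau_w_hat = mean(stress$tau_w))
}
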