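# Synthetic longitudinal data with known ground truth. The study this
# package emulates had no shareable raw scans, so every downstream stage is
# exercised on generated tube geometries: a structured triangulated tube
# (optionally bulged and curved), grown forward under the growth engine
# with known time constants, re-triangulated independently per time point,
# and perturbed by surface measurement noise along vertex normals. Cohorts
# link lifespan noisily to the growth driving force with right-censoring
# at 25 months, mirroring the 10-mouse study design.

#' Tube geometry specification
#'
#' @param radius base radius (mm) or per-station radius profile evaluated
#'   at `n_axial` stations.
#' @param length tube length (mm).
#' @param n_axial,n_circ mesh resolution (>= 8 each).
#' @param bulge_amplitude Gaussian bulge added to the radius (mm).
#' @param bulge_center,bulge_width bulge position and width in the axial
#'   fraction `s` in `[0, 1]`.
#' @param curvature centerline curvature (1/mm); 0 gives a straight tube.
#' @return an object of class `tube_spec`.
#' @export
tube_spec <- function(radius = 0.6, length = 3, n_axial = 26L, n_circ = 32L,
                      bulge_amplitude = 0, bulge_center = 0.5,
                      bulge_width = 0.15, curvature = 0) {
  if (any(radius <= 0) || length <= 0) stop_vg("radius and length must be positive")
  if (n_axial < 8L || n_circ < 8L) stop_vg("mesh resolution must be >= 8")
  structure(list(radius = radius, length = length,
                 n_axial = as.integer(n_axial), n_circ = as.integer(n_circ),
                 bulge_amplitude = bulge_amplitude,
                 bulge_center = bulge_center, bulge_width = bulge_width,
                 curvature = curvature),
            class = "tube_spec")
}

tube_radius_profile <- function(spec, s) {
  base <- if (length(spec$radius) > 1L)
    stats::approx(seq(0, 1, length.out = length(spec$radius)),
                  spec$radius, s)$y
  else rep(spec$radius, length(s))
  base + spec$bulge_amplitude *
    exp(-0.5 * ((s - spec$bulge_center) / spec$bulge_width)^2)
}

#' Generate a structured triangulated tube mesh
#'
#' Builds an open-ended tube (two boundary loops) from axial rings of
#' `n_circ` vertices, with optional Gaussian bulge and constant-curvature
#' centerline bending.
#'
#' @param spec a [tube_spec].
#' @return a [surface_mesh].
#' @export
make_tube_mesh <- function(spec) {
  na <- spec$n_axial; nc <- spec$n_circ
  s <- seq(0, 1, length.out = na)
  r <- tube_radius_profile(spec, s)
  phi <- 2 * pi * (seq_len(nc) - 1L) / nc
  if (spec$curvature > 0) {
    rho <- 1 / spec$curvature
    if (rho <= max(r))
      stop_vg("curvature radius %.3g mm below tube radius: self-intersection",
              rho)
    ang <- s * spec$length / rho
    cx <- rho * sin(ang); cz <- rho * (1 - cos(ang))
    # local frame: tangent in the bend plane (x, z), normal in-plane, y out
    tx <- cos(ang); tz <- sin(ang)
  }
  verts <- matrix(NA_real_, na * nc, 3L)
  for (i in seq_len(na)) {
    idx <- (i - 1L) * nc + seq_len(nc)
    if (spec$curvature > 0) {
      nrm <- c(-tz[i], 0, tx[i])  # in-plane normal (unit)
      for (j in seq_len(nc)) {
        verts[idx[j], ] <- c(cx[i], 0, cz[i]) +
          r[i] * (cos(phi[j]) * c(0, 1, 0) + sin(phi[j]) * nrm)
      }
      # orient axis along z overall: swap so inlet has lowest z
      verts[idx, 3] <- verts[idx, 3]
    } else {
      verts[idx, ] <- cbind(r[i] * cos(phi), r[i] * sin(phi),
                            s[i] * spec$length)
    }
  }
  if (spec$curvature > 0) {
    # put the centerline arc along z for inlet/outlet labeling
    verts <- verts[, c(2, 3, 1)]
  }
  tris <- matrix(NA_integer_, 2L * (na - 1L) * nc, 3L)
  k <- 0L
  for (i in seq_len(na - 1L)) {
    for (j in seq_len(nc)) {
      jn <- j %% nc + 1L
      a <- (i - 1L) * nc + j
      b <- (i - 1L) * nc + jn
      c2 <- i * nc + j
      d <- i * nc + jn
      tris[k + 1L, ] <- c(a, b, d)
      tris[k + 2L, ] <- c(a, d, c2)
      k <- k + 2L
    }
  }
  surface_mesh(verts, tris)
}

# Approximate outward vertex normals (area-weighted triangle normals).
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$triangles
  nrm <- matrix(0, nrow(v), 3L)
  for (k in seq_len(nrow(f))) {
    p <- v[f[k, ], , drop = FALSE]
    n <- pracma_cross(p[2, ] - p[1, ], p[3, ] - p[1, ])
    nrm[f[k, ], ] <- nrm[f[k, ], ] + matrix(n, 3L, 3L, byrow = TRUE)
  }
  len <- sqrt(rowSums(nrm^2))
  nrm / pmax(len, 1e-12)
}

#' Hemodynamic and material context for the synthetic pipeline
#'
#' Bundles the defaults used by the generator and the fitting stages: wall
#' thickness, wall shear modulus from the elastic modulus, mean pressure
#' from the packaged Windkessel outlets (about 90 mmHg), and mean flow.
#'
#' @param E_kPa wall elastic modulus (kPa), default 722.
#' @param nu Poisson's ratio, default 0.44.
#' @param thickness wall thickness (mm), default 0.06.
#' @param pressure mean pressure (Pa); default the 90 mmHg calibration.
#' @param flow mean flow (mm^3/s); default back-computed as
#'   pressure / parallel resistance of the packaged outlets.
#' @return list with `wall`, `mu` (Pa), `material`, `hemo`.
#' @export
hemo_context <- function(E_kPa = 722, nu = 0.44, thickness = 0.06,
                         pressure = NULL, flow = NULL) {
  material <- lame_from_E_nu(E_kPa, nu)
  mu_Pa <- material$mu * 1000
  if (is.null(pressure) || is.null(flow)) {
    outs <- load_windkessel_outlets()
    Rpar <- 1 / sum(vapply(outs, function(p) 1 / (p$Rp + p$Rd), numeric(1)))
    pressure <- pressure %||% mmHg_to_Pa(90)
    flow <- flow %||% (pressure / Rpar)
  }
  list(wall = wall_spec(thickness), mu = mu_Pa, material = material,
       hemo = list(pressure = pressure, flow = flow,
                   viscosity = carreau_yasuda_model()))
}

#' Default growth parameters for the synthetic study conditions
#'
#' Time constants of 180 days (circumferential) and 360 days (axial) with
#' homeostatic targets at 0.8 of the baseline stress state reproduce, over
#' 120 simulated days, radius growth of the order observed in aneurysmal
#' mice (20-35%).
#'
#' @param ctx a [hemo_context()].
#' @param profile the baseline unloaded [tube_profile].
#' @param T_theta,T_s time constants (days; may be per-domain vectors).
#' @param target_scale homeostatic target scale (< 1: growth-positive).
#' @return a [growth_params].
#' @export
default_growth_params <- function(ctx, profile, T_theta = 180, T_s = 360,
                                  target_scale = 0.8) {
  r0 <- inflate_radii(profile$R, ctx$wall$thickness, ctx$mu,
                      ctx$hemo$pressure)$loaded_radius
  st0 <- thin_wall_stresses(r0, ctx$wall, ctx$hemo$pressure, ctx$hemo$flow,
                            ctx$hemo$viscosity)
  tg <- homeostatic_targets(st0, scale = target_scale)
  growth_params(T_theta, T_s,
                sigma_theta_hat = tg$sigma_theta_hat,
                sigma_ss_hat = tg$sigma_ss_hat,
                tau_w_hat = tg$tau_w_hat)
}

#' Generate longitudinal tube geometries under known growth parameters
#'
#' Grows the baseline tube with the growth engine and the true parameters,
#' rebuilds a surface mesh at each requested time (independently
#' re-triangulated when `remesh = TRUE`), and adds Gaussian measurement
#' noise along vertex normals.
#'
#' @param spec a [tube_spec] for the baseline (loaded, in vivo) geometry.
#' @param true_params a [growth_params] (the ground truth).
#' @param times output times in days (default `c(0, 60, 120)`: the 2, 4 and
#'   6 month scans at 30 days/month).
#' @param ctx a [hemo_context()].
#' @param noise_sd surface noise standard deviation (mm), default 0.
#' @param remesh re-triangulate later time points at a different resolution.
#' @param n_elements growth-engine stations.
#' @param partition_K number of axial domains (`NULL` for single domain).
#' @param seed RNG seed for the noise.
#' @return list: `meshes` (one [surface_mesh] per time), `metrics`
#'   (noise-free [ring_metrics] per time), `trajectory`, `profile`,
#'   `truth` (the parameters), `times`.
#' @export
generate_longitudinal_geometries <- function(spec, true_params,
                                             times = c(0, 60, 120),
                                             ctx = hemo_context(),
                                             noise_sd = 0, remesh = FALSE,
                                             n_elements = 26L,
                                             partition_K = NULL,
                                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- seq(0, 1, length.out = n_elements)
  r_loaded <- tube_radius_profile(spec, s)
  R <- deflate_radii(r_loaded, ctx$wall$thickness, ctx$mu, ctx$hemo$pressure)
  seg <- rep(spec$length / (n_elements - 1L), n_elements - 1L)
  profile <- tube_profile(s, R, seg)
  partition <- if (!is.null(partition_K)) domain_partition(s, partition_K)
  cfg <- sim_config(dt = 10, horizon = max(times), substeps = 1L)
  traj <- forward_simulate(profile, ctx$wall, ctx$mu, ctx$hemo, true_params,
                           cfg, partition = partition)
  meshes <- list(); metrics <- list()
  for (ti in seq_along(times)) {
    k <- which(abs(traj$times - times[ti]) < 1e-9)
    if (length(k) != 1L) stop_vg("time %g is not on the dt grid", times[ti])
    mt <- traj$metrics[[k]]
    res_scale <- if (remesh && ti > 1L) 1L + ti else 0L
    # remeshed resolutions stay multiples of the ring count so vertex rows
    # keep landing on the ring targets
    sp_t <- tube_spec(radius = mt$radii, length = mt$total_length,
                      n_axial = spec$n_axial + res_scale * 5L,
                      n_circ = spec$n_circ + res_scale * 4L)
    mesh <- make_tube_mesh(sp_t)
    if (noise_sd > 0) {
      nrm <- vertex_normals(mesh)
      mesh$vertices <- mesh$vertices +
        nrm * stats::rnorm(nrow(mesh$vertices), sd = noise_sd)
    }
    meshes[[ti]] <- mesh
    metrics[[ti]] <- mt
  }
  list(meshes = meshes, metrics = metrics, trajectory = traj,
       profile = profile, truth = true_params, times = times)
}

#' Cohort specification
#'
#' True time constants are log-normal across subjects; lifespan follows
#' `LS = a + b (T_theta / sigma_bar_theta) + eps`, `eps ~ N(0, s^2)`,
#' right-censored at the cutoff. Defaults give roughly 40% censoring at 25
#' months, mirroring the 4-of-10 censored fraction of the emulated study.
#'
#' @param n_subjects cohort size (default 10).
#' @param T_theta_median,T_theta_sdlog log-normal law of the true
#'   circumferential constant (days).
#' @param T_s_median,T_s_sdlog log-normal law of the true axial constant.
#' @param lifespan_a intercept (months).
#' @param lifespan_b slope on `T_theta / sigma_bar_theta` (months Pa/day).
#' @param lifespan_sd residual SD (months).
#' @param censor_cutoff months (default 25).
#' @param noise_sd mesh surface noise (mm).
#' @param seed RNG seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10L, T_theta_median = 180,
                        T_theta_sdlog = 0.2, T_s_median = 360,
                        T_s_sdlog = 0.2, lifespan_a = 13,
                        lifespan_b = 8000, lifespan_sd = 3,
                        censor_cutoff = 25, noise_sd = 0.01, seed = 1L) {
  if (n_subjects < 1L) stop_vg("need at least one subject")
  if (any(c(T_theta_median, T_s_median, lifespan_sd, censor_cutoff) <= 0))
    stop_vg("cohort scales must be positive")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort with known truths
#'
#' Samples per-subject true time constants, generates longitudinal
#' geometries, draws the lifespan from the linear model on the growth
#' driving force `T_theta / sigma_bar_theta`, and censors at the cutoff.
#'
#' @param spec a [cohort_spec].
#' @param tube a [tube_spec] for the baseline geometry.
#' @param ctx a [hemo_context()].
#' @param geometries if `FALSE`, skip mesh generation and keep ring metrics
#'   only (faster; the metrics are what the fitting stage consumes).
#' @param times scan times in days.
#' @return list: `records` (data frame mirroring the cohort-table schema
#'   plus truth columns), `subjects` (per-subject geometry sets), `spec`.
#' @export
generate_cohort <- function(spec, tube = tube_spec(), ctx = hemo_context(),
                            geometries = FALSE, times = c(0, 60, 120)) {
  set.seed(spec$seed)
  n <- spec$n_subjects
  # floor at the surrogate's validity bound: below ~90-day circumferential
  # constants the 120-day positive-feedback loop reaches the membrane
  # limit point (see the methods vignette)
  Tt <- pmax(stats::rlnorm(n, log(spec$T_theta_median), spec$T_theta_sdlog),
             90)
  Ts <- pmax(stats::rlnorm(n, log(spec$T_s_median), spec$T_s_sdlog), 120)
  eps <- stats::rnorm(n, 0, spec$lifespan_sd)
  subjects <- vector("list", n)
  rec <- data.frame(id = seq_len(n),
                    sex = rep(c("M", "F"), length.out = n))
  sigma_bar <- numeric(n)
  d_max6 <- numeric(n); d_delta <- numeric(n)
  for (i in seq_len(n)) {
    params <- default_growth_params(ctx, profile = {
      s <- seq(0, 1, length.out = 26L)
      r_loaded <- tube_radius_profile(tube, s)
      R <- deflate_radii(r_loaded, ctx$wall$thickness, ctx$mu,
                         ctx$hemo$pressure)
      tube_profile(s, R, rep(tube$length / 25, 25))
    }, T_theta = Tt[i], T_s = Ts[i])
    gl <- generate_longitudinal_geometries(
      tube, params, times = times, ctx = ctx,
      noise_sd = if (geometries) spec$noise_sd else 0,
      remesh = geometries, seed = spec$seed + i)
    subjects[[i]] <- gl
    sigma_bar[i] <- gl$trajectory$mean_sigma_theta
    d6 <- gl$metrics[[length(times)]]$radii * 2
    d2 <- gl$metrics[[1]]$radii * 2
    d_max6[i] <- max(d6)
    d_delta[i] <- max(d6) - max(d2)
  }
  ls_latent <- spec$lifespan_a + spec$lifespan_b * (Tt / sigma_bar) + eps
  censored <- ls_latent >= spec$censor_cutoff
  rec$lifespan <- pmin(ls_latent, spec$censor_cutoff)
  rec$censored <- censored
  rec$T_theta_true <- Tt
  rec$T_s_true <- Ts
  rec$sigma_bar_theta <- sigma_bar
  rec$D_max_6mo <- d_max6
  rec$Delta_D <- d_delta
  rec$lifespan_latent <- ls_latent
  list(records = rec, subjects = subjects, spec = spec)
}
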