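# Orchestration of the tune -> validate -> correlate workflow on mesh
# inputs, with a reproducible run manifest. Tuning fits (T_theta, T_s) on
# the baseline-to-60-day pair; validation re-runs the fitted model to 120
# days and scores it against the third geometry, next to the
# linear-projection baseline; correlation assembles the per-subject fits
# into the Pearson map and Tobit regression.

#' Assemble a run configuration
#'
#' @param ctx a [hemo_context()].
#' @param sim_tune,sim_validate [sim_config()]s for the two stages
#'   (defaults: 60 and 120 day horizons at dt = 10).
#' @param fit a [fit_config()].
#' @param n_rings rings used for measurement (default 6).
#' @param n_elements growth-engine stations.
#' @param n_domains 1 or 4.
#' @param target_scale homeostatic target scale.
#' @param seed integer seed recorded in the manifest.
#' @param out_dir optional output directory for reports.
#' @return an object of class `run_config`.
#' @export
run_config <- function(ctx = hemo_context(), sim_tune = sim_config(horizon = 60),
                       sim_validate = sim_config(horizon = 120),
                       fit = fit_config(), n_rings = 6L, n_elements = 26L,
                       n_domains = 1L, target_scale = 0.8, seed = 1L,
                       out_dir = NULL) {
  structure(list(ctx = ctx, sim_tune = sim_tune, sim_validate = sim_validate,
                 fit = fit, n_rings = n_rings,
                 n_elements = as.integer(n_elements),
                 n_domains = as.integer(n_domains),
                 target_scale = target_scale, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Write a run manifest
#'
#' Records the seed, package version, stage timings and input checksums so
#' a run can be re-executed exactly.
#'
#' @param config a [run_config].
#' @param stage stage label.
#' @param timings named numeric vector of elapsed seconds.
#' @param inputs named character vector of input file paths (checksummed via
#'   file size + md5 when `tools::md5sum` succeeds).
#' @param path output JSON path.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(config, stage, timings = NULL, inputs = NULL,
                           path = NULL) {
  checksums <- if (!is.null(inputs)) {
    vapply(inputs, function(f)
      if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_,
      character(1))
  }
  manifest <- list(stage = stage, seed = config$seed,
                   package_version = as.character(utils::packageVersion("vesselgrow")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   n_rings = config$n_rings, n_elements = config$n_elements,
                   n_domains = config$n_domains,
                   dt = config$sim_tune$dt,
                   horizon_tune = config$sim_tune$horizon,
                   horizon_validate = config$sim_validate$horizon,
                   timings = as.list(timings), inputs = as.list(checksums))
  if (!is.null(path))
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  invisible(manifest)
}

# Baseline measurement bundle shared by tune and validate.
stage_setup <- function(mesh_t0, config) {
  metrics0 <- measure_mesh(mesh_t0, n_rings = config$n_rings)
  ctx <- config$ctx
  profile <- tube_profile_from_metrics(metrics0, ctx$wall, ctx$mu,
                                       ctx$hemo$pressure,
                                       n_elements = config$n_elements)
  partition <- if (config$n_domains > 1L)
    domain_partition(profile$s, config$n_domains)
  fixed <- default_growth_params(ctx, profile,
                                 target_scale = config$target_scale)
  list(metrics0 = metrics0, profile = profile, partition = partition,
       fixed = fixed)
}

#' Tuning stage: fit growth constants on two time points
#'
#' Measures both meshes, reconstructs the unloaded baseline profile, and
#' fits `(T_theta, T_s)` so the 60-day forward simulation matches the
#' second time point's ring observables.
#'
#' @param mesh_t0,mesh_t1 [surface_mesh]es at baseline and the tuning time
#'   point (or paths readable by [read_mesh()]).
#' @param config a [run_config].
#' @return list: `fit` (a [fit_result][fit_growth_constants]), `setup`,
#'   `metrics_t1`, `predicted` (per-ring predicted-vs-observed table),
#'   `manifest`.
#' @export
run_tuning <- function(mesh_t0, mesh_t1, config = run_config()) {
  t_start <- proc.time()[3]
  if (is.character(mesh_t0)) {
    if (!file.exists(mesh_t0)) stop_vg("baseline mesh not found: %s", mesh_t0)
    mesh_t0 <- read_mesh(mesh_t0)
  }
  if (is.character(mesh_t1)) {
    if (!file.exists(mesh_t1)) stop_vg("tuning mesh not found: %s", mesh_t1)
    mesh_t1 <- read_mesh(mesh_t1)
  }
  setup <- stage_setup(mesh_t0, config)
  metrics1 <- measure_mesh(mesh_t1, n_rings = config$n_rings)
  model <- make_growth_model(setup$profile, config$ctx$wall, config$ctx$mu,
                             config$ctx$hemo, config$sim_tune,
                             partition = setup$partition,
                             n_rings = config$n_rings)
  fit <- fit_growth_constants(model, metrics1, config = config$fit,
                              n_domains = config$n_domains,
                              fixed = setup$fixed)
  pred <- model(growth_params(fit$T_theta, fit$T_s,
                              T_r = setup$fixed$T_r,
                              T_tau = setup$fixed$T_tau,
                              sigma_theta_hat = setup$fixed$sigma_theta_hat,
                              sigma_ss_hat = setup$fixed$sigma_ss_hat,
                              tau_w_hat = setup$fixed$tau_w_hat))
  table <- data.frame(ring = seq_along(pred$radii),
                      predicted_radius_mm = pred$radii,
                      observed_radius_mm = metrics1$radii)
  manifest <- write_manifest(config, "tune",
                             timings = c(elapsed_s = proc.time()[3] - t_start),
                             path = if (!is.null(config$out_dir))
                               file.path(config$out_dir, "tune_manifest.json"))
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(unclass(fit)[c("T_theta", "T_s", "chi2", "sse",
                                        "iterations", "converged")],
                         file.path(config$out_dir, "fit_result.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(fit = fit, setup = setup, metrics_t1 = metrics1, predicted = table,
       manifest = manifest)
}

#' Validation stage: predict the third time point
#'
#' Re-runs the forward model with the fitted constants over the validation
#' horizon, scores per-ring radius errors (interior rings), the total
#' length error, and the linear-projection baseline built from the first
#' two time points.
#'
#' @param mesh_t2 the validation [surface_mesh] (or path).
#' @param tuning result of [run_tuning()].
#' @param config a [run_config].
#' @return an object of class `validation_report`: `delta_r` (per ring),
#'   `mean_delta_r`, `delta_l`, `rings_used`, `baseline` (linear-projection
#'   errors), `predicted`, `observed`.
#' @export
run_validation <- function(mesh_t2, tuning, config = run_config()) {
  if (is.character(mesh_t2)) {
    if (!file.exists(mesh_t2)) stop_vg("validation mesh not found: %s", mesh_t2)
    mesh_t2 <- read_mesh(mesh_t2)
  }
  metrics2 <- measure_mesh(mesh_t2, n_rings = config$n_rings)
  setup <- tuning$setup
  fit <- tuning$fit
  params <- growth_params(fit$T_theta, fit$T_s, T_r = setup$fixed$T_r,
                          T_tau = setup$fixed$T_tau,
                          sigma_theta_hat = setup$fixed$sigma_theta_hat,
                          sigma_ss_hat = setup$fixed$sigma_ss_hat,
                          tau_w_hat = setup$fixed$tau_w_hat)
  traj <- forward_simulate(setup$profile, config$ctx$wall, config$ctx$mu,
                           config$ctx$hemo, params, config$sim_validate,
                           partition = setup$partition,
                           n_rings = config$n_rings)
  pred <- final_metrics(traj)
  dr <- delta_r(pred$radii, metrics2$radii)
  dl <- delta_l(pred$total_length, metrics2$total_length)
  base_pred <- linear_projection_baseline(tuning$setup$metrics0$radii,
                                          tuning$metrics_t1$radii)
  base_dr <- delta_r(base_pred, metrics2$radii)
  report <- structure(list(delta_r = dr$delta_r,
                           mean_delta_r = dr$mean_delta_r,
                           rings_used = dr$rings_used, delta_l = dl,
                           baseline = base_dr, predicted = pred,
                           observed = metrics2),
                      class = "validation_report")
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(list(delta_r = report$delta_r,
                              mean_delta_r = report$mean_delta_r,
                              delta_l = report$delta_l,
                              baseline_mean_delta_r = base_dr$mean_delta_r),
                         file.path(config$out_dir, "validation_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Correlation stage across a cohort
#'
#' Builds the correlation variable table (lifespan, maximum 6-month
#' diameter, diameter change, fitted constants and the driving-force ratio
#' `T_theta / sigma_bar_theta`, plus any supplied covariates), computes the
#' Bonferroni-corrected Pearson map, and fits Tobit regressions of lifespan
#' on each fitted-constant covariate.
#'
#' @param records data frame with at least `lifespan`, `censored`,
#'   `T_theta`, `T_s`, `sigma_bar_theta`; extra numeric columns are carried
#'   into the map.
#' @param censor_cutoff months (default 25).
#' @return list: `map` (a [correlation_map][pearson_map]), `tobit` (named
#'   list of [tobit_result][tobit_fit]s), `variables`.
#' @export
run_correlation <- function(records, censor_cutoff = 25) {
  if (nrow(records) < 3L) stop_vg("need at least 3 subjects to correlate")
  req <- c("lifespan", "T_theta", "T_s", "sigma_bar_theta")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0L)
    stop_vg("records missing columns: %s", paste(miss, collapse = ", "))
  records$T_theta_over_sigma <- records$T_theta / records$sigma_bar_theta
  skip <- c("id", "censored", "sigma_bar_theta", "lifespan_latent")
  vars <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                  skip)
  map <- pearson_map(records, vars)
  tobit <- list(
    T_theta = tobit_fit(records$T_theta, records$lifespan, censor_cutoff),
    T_s = tobit_fit(records$T_s, records$lifespan, censor_cutoff),
    T_theta_over_sigma = tobit_fit(records$T_theta_over_sigma,
                                   records$lifespan, censor_cutoff))
  list(map = map, tobit = tobit, variables = vars)
}

#' End-to-end synthetic pipeline
#'
#' Generates a synthetic cohort, tunes every subject on the 0/60-day ring
#' metrics, validates at 120 days, and correlates the fitted constants
#' with the censored lifespans. The per-subject fits run on the generated
#' ring metrics (the same observables the mesh pathway produces).
#'
#' @param spec a [cohort_spec()].
#' @param config a [run_config].
#' @param tube a [tube_spec()].
#' @return list: `records` (with fitted columns), `correlation`,
#'   `validation` (per subject), `cohort`.
#' @export
run_pipeline <- function(spec = cohort_spec(), config = run_config(),
                         tube = tube_spec()) {
  cohort <- generate_cohort(spec, tube = tube, ctx = config$ctx)
  rec <- cohort$records
  rec$T_theta <- NA_real_; rec$T_s <- NA_real_
  validation <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    subj <- cohort$subjects[[i]]
    profile <- subj$profile
    partition <- if (config$n_domains > 1L)
      domain_partition(profile$s, config$n_domains)
    fixed <- subj$truth
    model <- make_growth_model(profile, config$ctx$wall, config$ctx$mu,
                               config$ctx$hemo, config$sim_tune,
                               partition = partition,
                               n_rings = config$n_rings)
    fit <- fit_growth_constants(model, subj$metrics[[2]],
                                config = config$fit,
                                n_domains = config$n_domains, fixed = fixed)
    rec$T_theta[i] <- mean(fit$T_theta)
    rec$T_s[i] <- mean(fit$T_s)
    params <- growth_params(fit$T_theta, fit$T_s, T_r = fixed$T_r,
                            T_tau = fixed$T_tau,
                            sigma_theta_hat = fixed$sigma_theta_hat,
                            sigma_ss_hat = fixed$sigma_ss_hat,
                            tau_w_hat = fixed$tau_w_hat)
    pred <- final_metrics(forward_simulate(profile, config$ctx$wall,
                                           config$ctx$mu, config$ctx$hemo,
                                           params, config$sim_validate,
                                           partition = partition,
                                           n_rings = config$n_rings))
    obs <- subj$metrics[[3]]
    validation[[i]] <- list(
      delta_r = delta_r(pred$radii, obs$radii),
      delta_l = delta_l(pred$total_length, obs$total_length))
  }
  correlation <- run_correlation(rec, censor_cutoff = spec$censor_cutoff)
  list(records = rec, correlation = correlation, validation = validation,
       cohort = cohort)
}
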