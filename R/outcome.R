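# Outcome stage: correlation of fitted growth constants with lifespan and
# postmortem covariates. Lifespan is right-censored (animals alive at 25
# months were euthanized), so the censoring-aware slope comes from a Tobit
# censored-normal maximum-likelihood fit, with the McKelvey-Zavoina
# pseudo-R-squared as the goodness-of-fit measure.

#' Load the packaged mouse cohort table
#'
#' Ten fibulin-4 smooth-muscle-knockout mice: sex, lifespan (months; capped
#' at 25 for the four animals euthanized at the cutoff), postmortem elastic
#' moduli of the ascending (`E_asc`) and descending (`E_desc`) aorta (kPa),
#' and the aortic tortuosity index (`ATI`, treated as an opaque covariate).
#'
#' @return data frame with columns `id`, `sex`, `lifespan`, `censored`,
#'   `E_asc`, `E_desc`, `ATI`.
#' @export
load_cohort_table <- function() {
  path <- system.file("extdata", "cohort_mice.csv",
                      package = "vesselgrow", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$censored <- as.logical(df$censored)
  if (any(df$lifespan > 25 + 1e-9))
    stop_vg("cohort fixture corrupt: lifespan above the 25-month cutoff")
  if (any(df$censored & abs(df$lifespan - 25) > 1e-9))
    stop_vg("cohort fixture corrupt: censored records must have lifespan 25")
  df
}

#' Pairwise Pearson correlation map with Bonferroni flags
#'
#' Pearson r for every variable pair, two-sided p-values from the
#' t-transform with n-2 degrees of freedom, and significance flags at the
#' 95% confidence level after Bonferroni correction over the number of
#' distinct off-diagonal pairs.
#'
#' @param data data frame of numeric variables (rows = subjects).
#' @param variables column names to include (default: all numeric columns).
#' @param alpha family-wise level (default 0.05).
#' @return an object of class `correlation_map`: `r`, `p`, `p_adj`,
#'   `significant` matrices, `m` (number of tests), `n`.
#' @export
pearson_map <- function(data, variables = NULL, alpha = 0.05) {
  if (is.null(variables))
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  X <- as.matrix(data[, variables, drop = FALSE])
  n <- nrow(X)
  if (n < 3L) stop_vg("need at least 3 records for correlation")
  k <- ncol(X)
  r <- matrix(1, k, k, dimnames = list(variables, variables))
  p <- matrix(0, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    xi <- X[, i]; xj <- X[, j]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      r[i, j] <- NA_real_; p[i, j] <- NA_real_
      next
    }
    r[i, j] <- stats::cor(xi, xj)
    tstat <- r[i, j] * sqrt((n - 2) / (1 - r[i, j]^2))
    p[i, j] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  m <- k * (k - 1) / 2
  p_adj <- p * m
  p_adj[p_adj > 1] <- 1
  diag(p_adj) <- 0
  structure(list(r = r, p = p, p_adj = p_adj,
                 significant = p_adj < alpha & row(r) != col(r),
                 m = m, n = n, variables = variables),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("correlation_map: %d variables, n = %d, %d tests (Bonferroni)\n",
              length(x$variables), x$n, x$m))
  print(round(x$r, 2))
  invisible(x)
}

#' Heatmap of a correlation map
#'
#' Base-graphics image of the Pearson matrix; Bonferroni-significant pairs
#' are starred.
#'
#' @param x a [correlation_map][pearson_map].
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.correlation_map <- function(x, ...) {
  k <- length(x$variables)
  pal <- grDevices::hcl.colors(21, "Blue-Red 3", rev = TRUE)
  graphics::image(seq_len(k), seq_len(k), t(x$r[k:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(k), labels = x$variables, las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(k), labels = rev(x$variables), las = 2,
                 cex.axis = 0.8)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    lab <- sprintf("%.2f%s", x$r[i, j],
                   if (isTRUE(x$significant[i, j])) "*" else "")
    graphics::text(j, k + 1 - i, lab, cex = 0.7)
  }
  invisible(x)
}

#' Export a correlation map as CSV
#'
#' @param map a [correlation_map][pearson_map].
#' @param path output path (r matrix; p and adjusted p appended as further
#'   blocks).
#' @return `path`, invisibly.
#' @export
write_correlation_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (blk in c("r", "p", "p_adj")) {
    writeLines(sprintf("# %s", blk), con)
    utils::write.csv(map[[blk]], con)
  }
  invisible(path)
}

tobit_negloglik <- function(theta, X, Y, Y_max) {
  k <- ncol(X)
  beta <- theta[seq_len(k)]
  sigma <- exp(theta[k + 1L])
  mu <- as.numeric(X %*% beta)
  cens <- Y >= Y_max - 1e-12
  ll <- numeric(length(Y))
  ll[!cens] <- stats::dnorm(Y[!cens], mu[!cens], sigma, log = TRUE)
  ll[cens] <- stats::pnorm((Y_max - mu[cens]) / sigma, lower.tail = FALSE,
                           log.p = TRUE)
  -sum(ll)
}

#' Tobit censored regression by maximum likelihood
#'
#' Fits `Y = X beta + u`, `u ~ N(0, sigma^2)`, with right-censoring of `Y`
#' at `Y_max`: uncensored observations contribute normal densities and
#' censored ones the upper-tail probability. `sigma` is optimized on the
#' log scale with a quasi-Newton (BFGS) search started from the ordinary
#' least-squares solution.
#'
#' @param X design matrix (an intercept column is added unless
#'   `add_intercept = FALSE`).
#' @param Y response; values at `Y_max` are treated as censored.
#' @param Y_max censoring cutoff (use `Inf` for no censoring).
#' @param add_intercept prepend a column of ones (default `TRUE`).
#' @return an object of class `tobit_result`: `beta`, `sigma`, `se`
#'   (inverse observed information), `loglik`, `pseudo_r2`
#'   (McKelvey-Zavoina), `converged`, `n_censored`, `X`.
#' @export
tobit_fit <- function(X, Y, Y_max, add_intercept = TRUE) {
  X <- as.matrix(X)
  if (add_intercept) X <- cbind(`(Intercept)` = 1, X)
  Y <- as.numeric(Y)
  cens <- Y >= Y_max - 1e-12
  if (all(cens))
    stop_vg("all observations censored: likelihood is uninformative")
  if (qr(X)$rank < ncol(X)) stop_vg("design matrix is rank deficient")
  ols <- stats::lm.fit(X, Y)
  s0 <- sqrt(mean(ols$residuals^2))
  theta0 <- c(ols$coefficients, log(max(s0, 1e-6)))
  opt <- stats::optim(theta0, tobit_negloglik, X = X, Y = Y, Y_max = Y_max,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  k <- ncol(X)
  beta <- unname(opt$par[seq_len(k)])
  names(beta) <- colnames(X)
  sigma <- unname(exp(opt$par[k + 1L]))
  se <- tryCatch({
    cov_theta <- solve(opt$hessian)
    sqrt(pmax(diag(cov_theta)[seq_len(k)], 0))
  }, error = function(e) rep(NA_real_, k))
  fit <- structure(list(beta = beta, sigma = sigma, se = se,
                        loglik = -opt$value,
                        converged = opt$convergence == 0L,
                        n_censored = sum(cens), X = X, Y = Y, Y_max = Y_max),
                   class = "tobit_result")
  fit$pseudo_r2 <- mz_pseudo_r2(fit)
  fit
}

#' @export
print.tobit_result <- function(x, ...) {
  cat(sprintf(
    "tobit_result: n = %d (%d censored), sigma = %.4g, logLik = %.4g, pseudo-R2 = %.3f\n",
    length(x$Y), x$n_censored, x$sigma, x$loglik, x$pseudo_r2))
  print(data.frame(coef = names(x$beta) %||% seq_along(x$beta),
                   estimate = x$beta, se = x$se, row.names = NULL))
  invisible(x)
}

#' McKelvey-Zavoina pseudo-R-squared
#'
#' `r2 = S / (S + N sigma^2)` with `S = sum((Yhat - mean(Yhat))^2)` over
#' the latent predictions `Yhat = X beta`.
#'
#' @param fit a [tobit_result][tobit_fit].
#' @param X optional design matrix (defaults to the one stored in `fit`;
#'   must already include the intercept column).
#' @return the pseudo-R-squared in `[0, 1]`.
#' @export
mz_pseudo_r2 <- function(fit, X = NULL) {
  X <- X %||% fit$X
  yhat <- as.numeric(as.matrix(X) %*% fit$beta)
  S <- sum((yhat - mean(yhat))^2)
  S / (S + length(yhat) * fit$sigma^2)
}
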