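# Two-level normal hierarchical pooling of community risk estimates:
# beta_hat_c ~ N(beta_c, nu_c), beta_c ~ N(mu, tau^2). The posterior over
# (mu, tau^2) under a flat prior on mu and a uniform prior on tau is
# computed by deterministic numerical integration of the tau marginal on a
# trapezoid grid — same target posterior as rejection-sampling approaches,
# but reproducible and directly checkable against a denser grid.

#' Pool community risk estimates under a two-level normal model
#'
#' Integrates the marginal posterior of the between-community sd `tau`
#' (uniform prior on `tau` over `[0, sqrt(grid_mult * max(var_hat))]`, flat
#' prior on `mu`) on a trapezoid grid; conditional on `tau`, `mu` is normal
#' with inverse-variance weights `1/(var_hat + tau^2)`. Returns mixture
#' moments and shrunken community estimates. With `tau2_fixed = 0` the
#' closed-form fixed-effect inverse-variance-weighted mean is returned.
#'
#' @param beta_hat community effect estimates (same scale, same lag
#'   configuration).
#' @param var_hat their estimation variances (> 0).
#' @param tau2_fixed optionally fix `tau^2` (only 0 and positive scalars).
#' @param grid_points grid size for the `tau` integration.
#' @param grid_mult grid span: `tau^2` up to `grid_mult * max(var_hat)`.
#' @return a `pooled_risk`: `mu_mean`, `mu_var`, `tau2_mean`, `shrunken`
#'   (per-community posterior means), `n_communities`, plus inputs.
#' @export
pool <- function(beta_hat, var_hat, tau2_fixed = NULL, grid_points = 2001,
                 grid_mult = 20) {
  k <- length(beta_hat)
  if (k < 2L) stop("need at least 2 estimates to pool")
  if (length(var_hat) != k) stop("beta_hat and var_hat lengths differ")
  if (any(!is.finite(var_hat)) || any(var_hat <= 0))
    stop("estimation variances must be positive")

  if (!is.null(tau2_fixed)) {
    if (tau2_fixed < 0) stop("tau2_fixed must be >= 0")
    w <- 1 / (var_hat + tau2_fixed)
    mu <- sum(w * beta_hat) / sum(w)
    B <- var_hat / (var_hat + tau2_fixed)
    shrunken <- if (tau2_fixed == 0) rep(mu, k)
                else B * mu + (1 - B) * beta_hat
    return(new_pooled_risk(mu, 1 / sum(w), tau2_fixed, shrunken,
                           beta_hat, var_hat))
  }

  tau <- seq(0, sqrt(grid_mult * max(var_hat)), length.out = grid_points)
  tau2 <- tau^2
  W <- 1 / outer(var_hat, tau2, "+")          # k x grid
  sw <- colSums(W)
  mu_hat <- colSums(W * beta_hat) / sw
  Q <- colSums(W * (beta_hat - rep(mu_hat, each = k))^2)
  log_post <- 0.5 * colSums(log(W)) - 0.5 * log(sw) - 0.5 * Q
  log_post <- log_post - max(log_post)
  dens <- exp(log_post)
  wts <- trapezoid_weights(tau) * dens
  wts <- wts / sum(wts)

  mu_mean <- sum(wts * mu_hat)
  mu_var <- sum(wts * (1 / sw + mu_hat^2)) - mu_mean^2
  tau2_mean <- sum(wts * tau2)
  Bmat <- var_hat / outer(var_hat, tau2, "+")  # k x grid shrinkage factors
  cond <- Bmat * rep(mu_hat, each = k) + (1 - Bmat) * beta_hat
  shrunken <- as.vector(cond %*% wts)
  new_pooled_risk(mu_mean, mu_var, tau2_mean, shrunken, beta_hat, var_hat)
}

trapezoid_weights <- function(x) {
  n <- length(x)
  h <- diff(x)
  w <- numeric(n)
  w[1] <- h[1] / 2
  w[n] <- h[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (h[-1] + h[-(n - 1)]) / 2
  w
}

new_pooled_risk <- function(mu_mean, mu_var, tau2_mean, shrunken,
                            beta_hat, var_hat) {
  structure(list(mu_mean = mu_mean, mu_var = mu_var, tau2_mean = tau2_mean,
                 shrunken = shrunken, beta_hat = beta_hat, var_hat = var_hat,
                 n_communities = length(beta_hat)),
            class = "pooled_risk")
}

#' @export
print.pooled_risk <- function(x, ...) {
  sd <- sqrt(x$mu_var)
  cat(sprintf(
    "Pooled risk over %d communities:\n  mu = %.3g (95%% CI %.3g, %.3g) per unit exposure\n",
    x$n_communities, x$mu_mean, x$mu_mean - 1.96 * sd, x$mu_mean + 1.96 * sd))
  cat(sprintf("  pct per 10 ppb = %.3f\n  tau2 = %.3g\n",
              100 * (exp(10 * x$mu_mean) - 1), x$tau2_mean))
  invisible(x)
}

#' Heterogeneity report for a pooled risk
#'
#' Summarizes the between-community variance `tau^2`, its ratio to the
#' median within-community variance, and the per-community shrinkage
#' factors `var_hat / (var_hat + tau2_mean)` (1 means full pooling toward
#' the overall mean).
#'
#' @param pooled a [pool()] result.
#' @return list with `tau2_mean`, `between_within_ratio`, `shrinkage`.
#' @export
heterogeneity_summary <- function(pooled) {
  stopifnot(inherits(pooled, "pooled_risk"))
  list(tau2_mean = pooled$tau2_mean,
       between_within_ratio = pooled$tau2_mean /
         stats::median(pooled$var_hat),
       shrinkage = pooled$var_hat / (pooled$var_hat + pooled$tau2_mean))
}

#' Pool a table of community risk estimates by lag configuration
#'
#' @param estimates a `risk_estimates` data.frame from [fit_health()].
#' @param ... passed to [pool()].
#' @return data.frame with one row per `lag_spec`: `mu_per_ppb`, `sd`,
#'   `pct_per_10ppb`, `ci_low`, `ci_high` (pct scale), `tau2`.
#' @export
pool_risks <- function(estimates, ...) {
  rows <- lapply(split(estimates, estimates$lag_spec), function(d) {
    p <- pool(d$beta_hat, d$var_hat, ...)
    sd <- sqrt(p$mu_var)
    data.frame(lag_spec = d$lag_spec[1L], mu_per_ppb = p$mu_mean,
               sd = sd,
               pct_per_10ppb = 100 * (exp(10 * p$mu_mean) - 1),
               ci_low = 100 * (exp(10 * (p$mu_mean - 1.96 * sd)) - 1),
               ci_high = 100 * (exp(10 * (p$mu_mean + 1.96 * sd)) - 1),
               tau2 = p$tau2_mean, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
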