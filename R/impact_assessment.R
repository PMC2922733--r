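# Attributable-deaths assessment: the projected change in mean ozone
# exposure (delta x) combined with the pooled log relative risk beta and
# the baseline death count N through M = {exp(beta * dx) - 1} * N, with a
# delta-method confidence interval treating beta and dx as independent.

#' Summarize the projected exposure change from paired draws
#'
#' Each draw set is a collection of community-by-day mean-ozone samples (a
#' matrix with one row per posterior-predictive draw, or a vector of
#' per-draw averages). Per draw the across-community, across-day average is
#' taken; `dx_mean` and `dx_var` are the mean and variance of the paired
#' (future minus reference) averages. Draw sets of unequal size are treated
#' as unpaired and the variances add.
#'
#' @param reference_draws,future_draws matrices (draw x point) or vectors of
#'   per-draw averages.
#' @return an `exposure_delta`: `dx_mean` (ppb), `dx_var` (ppb^2),
#'   `reference_mean`, `future_mean`, `n_draws`, `paired`.
#' @export
delta_exposure <- function(reference_draws, future_draws) {
  ref <- if (is.matrix(reference_draws)) rowMeans(reference_draws)
         else as.numeric(reference_draws)
  fut <- if (is.matrix(future_draws)) rowMeans(future_draws)
         else as.numeric(future_draws)
  if (length(ref) < 2L || length(fut) < 2L)
    stop("need at least 2 draws in each set")
  paired <- length(ref) == length(fut)
  if (paired) {
    d <- fut - ref
    dx_var <- stats::var(d)
  } else {
    dx_var <- stats::var(fut) + stats::var(ref)
  }
  structure(list(dx_mean = mean(fut) - mean(ref), dx_var = dx_var,
                 reference_mean = mean(ref), future_mean = mean(fut),
                 n_draws = c(reference = length(ref), future = length(fut)),
                 paired = paired),
            class = "exposure_delta")
}

#' @export
print.exposure_delta <- function(x, ...) {
  sd <- sqrt(x$dx_var)
  cat(sprintf(
    "Exposure change: %.3f ppb (95%% PI %.3f, %.3f); reference %.1f -> future %.1f ppb\n",
    x$dx_mean, x$dx_mean - 1.96 * sd, x$dx_mean + 1.96 * sd,
    x$reference_mean, x$future_mean))
  invisible(x)
}

#' Attributable deaths with delta-method uncertainty
#'
#' `M = {exp(beta * dx) - 1} * N * years`, with
#' `Var(M) = (N * years * exp(beta*dx))^2 * (dx^2 * beta_var + beta^2 *
#' dx_var)` by the first-order delta method under independence of `beta`
#' and `dx`; the 95% CI is `M +/- 1.96 sqrt(Var(M))` and is symmetric about
#' `M` by construction.
#'
#' @param beta pooled log relative risk per ppb.
#' @param beta_var its variance.
#' @param dx projected mean ozone change, ppb.
#' @param dx_var its variance, ppb^2.
#' @param N baseline deaths in the reference year (per season-year).
#' @param years number of future years aggregated (Table-style decade
#'   totals use 10).
#' @return an `impact_estimate`: `M`, `ci_low`, `ci_high`, `per_year_M`,
#'   `pct_rate_increase`, and the inputs.
#' @export
attributable_deaths <- function(beta, beta_var, dx, dx_var, N, years = 1) {
  if (N <= 0) stop("N must be positive")
  if (years < 1) stop("years must be >= 1")
  if (beta_var < 0 || dx_var < 0) stop("variances must be nonnegative")
  g <- N * years * exp(beta * dx)
  M <- (exp(beta * dx) - 1) * N * years
  var_M <- g^2 * (dx^2 * beta_var + beta^2 * dx_var)
  hw <- 1.96 * sqrt(var_M)
  structure(list(M = M, ci_low = M - hw, ci_high = M + hw,
                 per_year_M = M / years,
                 pct_rate_increase = percent_rate_increase(beta, dx),
                 beta = beta, beta_var = beta_var, dx = dx, dx_var = dx_var,
                 N = N, years = years),
            class = "impact_estimate")
}

#' @export
print.impact_estimate <- function(x, ...) {
  cat(sprintf(
    "Attributable deaths over %d year(s): %.1f (95%% CI %.2f, %.1f)\n",
    x$years, x$M, x$ci_low, x$ci_high))
  cat(sprintf("  per year: %.2f;  mortality rate increase: %.4f%%\n",
              x$per_year_M, x$pct_rate_increase))
  invisible(x)
}

#' Percent mortality-rate increase from an exposure change
#'
#' `100 * (exp(beta * dx) - 1)`; approximately `100 * beta * dx` for small
#' effects.
#'
#' @param beta log relative risk per ppb.
#' @param dx exposure change, ppb.
#' @return percent increase.
#' @export
percent_rate_increase <- function(beta, dx) {
  if (!is.finite(beta) || !is.finite(dx)) stop("inputs must be finite")
  100 * (exp(beta * dx) - 1)
}
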