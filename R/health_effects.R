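# Community-specific quasi-Poisson time-series mortality regression with
# spline confounder control, single-lag and unconstrained distributed-lag
# ozone terms. Fitting is IRLS via stats::glm.fit with Pearson dispersion;
# the distributed-lag cumulative effect is the sum of the lag coefficients
# with variance summed over the full covariance block.

#' Natural cubic spline basis
#'
#' Wrapper around [splines::ns()]: interior knots at equally spaced
#' quantiles, boundary knots at the range, columns linearly independent, and
#' linear (zero second derivative) beyond the boundary knots.
#'
#' @param x numeric values.
#' @param df degrees of freedom (>= 1).
#' @param boundary boundary knots; defaults to `range(x)`.
#' @return basis matrix with `df` columns.
#' @export
ns_basis <- function(x, df, boundary = range(x, na.rm = TRUE)) {
  if (df < 1) stop("df must be >= 1")
  if (length(unique(x[!is.na(x)])) < df + 2)
    stop("need at least df + 2 distinct values")
  unclass(splines::ns(x, df = df, Boundary.knots = boundary))
}

#' Confounder specification for the health model
#'
#' Spline degrees of freedom and indicator sets entering the community
#' mortality regression: a long-term trend spline (per summer, over the
#' gap-compressed day index), same-day and 3-day running-mean temperature
#' splines, same-day and 3-day running-mean dew-point splines, day-of-week
#' indicators, age-stratum intercepts, and age-by-trend spline interactions.
#'
#' @param trend_df_per_summer trend df per summer season.
#' @param temp_df,temp_rm_df same-day / running-mean temperature df.
#' @param dewpt_df,dewpt_rm_df same-day / running-mean dew point df.
#' @param age_trend_df df of the trend spline interacted with age stratum.
#' @return a list of class `confounder_spec`.
#' @export
confounder_spec <- function(trend_df_per_summer = 3, temp_df = 6,
                            temp_rm_df = 6, dewpt_df = 3, dewpt_rm_df = 3,
                            age_trend_df = 3) {
  spec <- list(trend_df_per_summer = trend_df_per_summer, temp_df = temp_df,
               temp_rm_df = temp_rm_df, dewpt_df = dewpt_df,
               dewpt_rm_df = dewpt_rm_df, age_trend_df = age_trend_df)
  if (any(unlist(spec) < 1)) stop("all spline dfs must be >= 1")
  structure(spec, class = "confounder_spec")
}

# lag within summer blocks; NA where the lag crosses a block boundary
lag_in_block <- function(x, block, k) {
  if (k == 0L) return(x)
  n <- length(x)
  out <- c(rep(NA_real_, k), x[seq_len(n - k)])
  ok <- c(rep(FALSE, k), block[seq_len(n - k)] == block[(k + 1):n])
  out[!ok] <- NA_real_
  out
}

# mean of the previous 3 days, within summer blocks
run_mean_prev3 <- function(x, block) {
  (lag_in_block(x, block, 1) + lag_in_block(x, block, 2) +
     lag_in_block(x, block, 3)) / 3
}

#' Build the health-model design for one community
#'
#' Stacks the age-stratum rows of a community series and constructs the full
#' design: ozone term(s) for the requested lag configuration, day-of-week
#' indicators, age-stratum intercepts, the long-term trend spline and its
#' age interactions, and the temperature and dew-point splines (same-day and
#' 3-day running mean). Rows with incomputable lags or missing covariates
#' are dropped and counted.
#'
#' @param series one community's rows of a community mortality table
#'   (`community, date, age_group, deaths, o3_mda8, temp_c, dewpt_c`).
#' @param lag one of `"lag0"`, `"lag1"`, `"lag2"`, `"dl02"` (unconstrained
#'   distributed lag over days 0-2).
#' @param conf a [confounder_spec()].
#' @return list with design matrix `X` (including intercept), response `y`,
#'   `ozone_cols` (column names of the ozone terms), `n_dropped` and
#'   `n_days`.
#' @export
build_design <- function(series, lag = c("lag0", "lag1", "lag2", "dl02"),
                         conf = confounder_spec()) {
  lag <- match.arg(lag)
  if (length(unique(series$community)) != 1L)
    stop("build_design expects a single community")
  # per-date exposure/confounder table
  ud <- unique(series[, c("date", "o3_mda8", "temp_c", "dewpt_c")])
  ud <- ud[order(ud$date), ]
  if (anyDuplicated(ud$date)) stop("conflicting exposure rows per date")
  dt <- as.Date(ud$date)
  summer <- format(dt, "%Y")
  n_summers <- length(unique(summer))
  ud$time <- seq_len(nrow(ud))              # gap-compressed day index
  ud$dow <- factor(as.POSIXlt(dt)$wday)
  ud$oz0 <- ud$o3_mda8
  ud$oz1 <- lag_in_block(ud$o3_mda8, summer, 1L)
  ud$oz2 <- lag_in_block(ud$o3_mda8, summer, 2L)
  ud$rm_temp <- run_mean_prev3(ud$temp_c, summer)
  ud$rm_dewpt <- run_mean_prev3(ud$dewpt_c, summer)

  d <- merge(series[, c("date", "age_group", "deaths")], ud, by = "date")
  d$age_group <- factor(d$age_group)
  oz_terms <- switch(lag, lag0 = "oz0", lag1 = "oz1", lag2 = "oz2",
                     dl02 = c("oz0", "oz1", "oz2"))
  need <- c(oz_terms, "temp_c", "rm_temp", "dewpt_c", "rm_dewpt", "deaths")
  keep <- stats::complete.cases(d[, need])
  n_dropped <- sum(!keep)
  d <- d[keep, ]
  if (nrow(d) == 0L) stop("no rows left after dropping incomputable lags")

  trend_df <- max(1L, round(conf$trend_df_per_summer * n_summers))
  X <- cbind(
    `(Intercept)` = 1,
    as.matrix(d[, oz_terms, drop = FALSE]),
    dow_dummies(d$dow),
    age_dummies(d$age_group),
    label_cols(ns_basis(d$time, trend_df), "trend"),
    age_trend_interactions(d$age_group, d$time, conf$age_trend_df),
    label_cols(ns_basis(d$temp_c, conf$temp_df), "temp"),
    label_cols(ns_basis(d$rm_temp, conf$temp_rm_df), "rmtemp"),
    label_cols(ns_basis(d$dewpt_c, conf$dewpt_df), "dewpt"),
    label_cols(ns_basis(d$rm_dewpt, conf$dewpt_rm_df), "rmdewpt")
  )
  list(X = X, y = d$deaths, ozone_cols = oz_terms, n_dropped = n_dropped,
       n_days = length(unique(d$date)), community = series$community[1L])
}

label_cols <- function(m, prefix) {
  colnames(m) <- paste0(prefix, seq_len(ncol(m)))
  m
}

dow_dummies <- function(f) {
  lv <- levels(f)
  m <- sapply(lv[-1L], function(l) as.numeric(f == l))
  colnames(m) <- paste0("dow", lv[-1L])
  m
}

age_dummies <- function(f) {
  lv <- levels(f)
  if (length(lv) < 2L) return(NULL)
  m <- sapply(lv[-1L], function(l) as.numeric(f == l))
  colnames(m) <- paste0("age", lv[-1L])
  m
}

age_trend_interactions <- function(age, time, df) {
  lv <- levels(age)
  if (length(lv) < 2L) return(NULL)
  basis <- ns_basis(time, df)
  out <- do.call(cbind, lapply(lv[-1L], function(l) {
    m <- basis * as.numeric(age == l)
    colnames(m) <- paste0("age", l, "_trend", seq_len(ncol(m)))
    m
  }))
  out
}

#' Fit the quasi-Poisson health model
#'
#' IRLS Poisson fit with over-dispersion: the Pearson chi-square dispersion
#' scales the coefficient covariance. Aliased (linearly dependent) columns
#' are dropped with a warning. Returns the ozone coefficient(s), their
#' dispersion-scaled covariance block, and — for the distributed-lag
#' configuration — the cumulative risk estimate via
#' [distributed_lag_cumulative()].
#'
#' @param design output of [build_design()].
#' @return list of class `qp_fit` with elements `coef`, `vcov` (scaled),
#'   `dispersion`, `beta_hat`, `var_hat` (cumulative for `dl02`), `n_days`,
#'   `lag`, `community`.
#' @export
fit_quasi_poisson <- function(design) {
  X <- design$X; y <- design$y
  if (all(y == 0)) stop("all-zero counts")
  fit <- stats::glm.fit(X, y, family = stats::quasipoisson(),
                        control = list(maxit = 100))
  if (!fit$converged) stop("IRLS did not converge in 100 iterations")
  if (any(is.na(fit$coefficients))) {
    drop <- names(fit$coefficients)[is.na(fit$coefficients)]
    if (any(design$ozone_cols %in% drop))
      stop("ozone term aliased with confounders")
    warning("dropping aliased columns: ", paste(drop, collapse = ", "))
    X <- X[, !colnames(X) %in% drop, drop = FALSE]
    fit <- stats::glm.fit(X, y, family = stats::quasipoisson(),
                          control = list(maxit = 100))
  }
  mu <- fit$fitted.values
  df_res <- nrow(X) - fit$rank
  dispersion <- sum((y - mu)^2 / mu) / df_res
  R <- qr.R(fit$qr)
  pivot <- fit$qr$pivot
  cov_unscaled <- chol2inv(R)
  cov_unscaled[pivot, pivot] <- cov_unscaled
  V <- dispersion * cov_unscaled
  dimnames(V) <- list(colnames(X), colnames(X))
  oz <- design$ozone_cols
  coef_oz <- fit$coefficients[oz]
  vcov_oz <- V[oz, oz, drop = FALSE]
  if (length(oz) > 1L) {
    cum <- distributed_lag_cumulative(coef_oz, vcov_oz)
    beta_hat <- cum$beta_hat; var_hat <- cum$var_hat
    lag <- "dl02"
  } else {
    beta_hat <- unname(coef_oz); var_hat <- unname(vcov_oz[1, 1])
    lag <- sub("oz", "lag", oz)
  }
  structure(list(coef = fit$coefficients, vcov = V, dispersion = dispersion,
                 ozone_coef = coef_oz, ozone_vcov = vcov_oz,
                 beta_hat = beta_hat, var_hat = var_hat,
                 n_days = design$n_days, lag = lag,
                 community = design$community),
            class = "qp_fit")
}

#' Cumulative effect of an unconstrained distributed lag
#'
#' The overall log relative risk across the lags is the sum of the lag
#' coefficients; its variance is the sum of all entries of their covariance
#' block.
#'
#' @param coef_vector lag coefficients (length 3 for lags 0-2).
#' @param cov_block their covariance matrix (symmetric).
#' @return list with `beta_hat` and `var_hat`.
#' @export
distributed_lag_cumulative <- function(coef_vector, cov_block) {
  cov_block <- as.matrix(cov_block)
  if (nrow(cov_block) != length(coef_vector) ||
      ncol(cov_block) != length(coef_vector))
    stop("covariance block does not match coefficient vector")
  asym <- max(abs(cov_block - t(cov_block)))
  if (asym > 1e-8 * max(abs(cov_block), 1e-300))
    stop("covariance block is not symmetric")
  list(beta_hat = sum(coef_vector), var_hat = sum(cov_block))
}

#' Fit community-specific ozone-mortality risks
#'
#' Runs the quasi-Poisson model for every community and requested lag
#' configuration (separate single-lag models plus one joint distributed-lag
#' model) and collects the risk estimates.
#'
#' @param series community mortality table (possibly several communities).
#' @param lags subset of `c("lag0", "lag1", "lag2", "dl02")`.
#' @param conf a [confounder_spec()].
#' @return data.frame of class `risk_estimates`: `community, lag_spec,
#'   beta_hat` (per ppb), `var_hat`, `dispersion`, `n_days`,
#'   `pct_per_10ppb`.
#' @export
fit_health <- function(series, lags = c("lag0", "lag1", "lag2", "dl02"),
                       conf = confounder_spec()) {
  lags <- match.arg(lags, several.ok = TRUE)
  rows <- list()
  for (c_id in unique(series$community)) {
    d <- series[series$community == c_id, ]
    for (l in lags) {
      f <- fit_quasi_poisson(build_design(d, l, conf))
      rows[[length(rows) + 1L]] <- data.frame(
        community = c_id, lag_spec = l, beta_hat = f$beta_hat,
        var_hat = f$var_hat, dispersion = f$dispersion, n_days = f$n_days,
        pct_per_10ppb = 100 * (exp(10 * f$beta_hat) - 1),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("risk_estimates", "data.frame")
  out
}
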