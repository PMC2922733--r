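# Bayesian space-time ozone-weather model: Y(s,t) = X(s,t) beta_state + e(s,t)
# with mean-zero Gaussian-process residuals under a separable exponential
# covariance sigma^2 * exp(-d_km/rho_s) * exp(-d_days/rho_t).
#
# Internal ordering convention: observations are stacked station-major
# (all days of station 1, then station 2, ...), i.e. vec(E) where E is the
# n_days x n_stations residual matrix, so cov(vec(E)) = sigma^2 R_s (x) R_t.

PANEL_COVARIATES <- c("temp_c", "ghi_wm2", "cloud_pct")

#' Space-time covariance parameters
#'
#' @param sigma2 residual variance, ppb^2.
#' @param rho_s spatial decay scale, km (correlation `exp(-d/rho_s)`).
#' @param rho_t temporal decay scale, days (correlation `exp(-d/rho_t)`).
#' @return an `st_covariance_params` list.
#' @export
st_covariance_params <- function(sigma2, rho_s, rho_t) {
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0")
  if (!is.finite(rho_s) || rho_s <= 0) stop("rho_s must be > 0")
  if (!is.finite(rho_t) || rho_t <= 0) stop("rho_t must be > 0")
  structure(list(sigma2 = sigma2, rho_s = rho_s, rho_t = rho_t),
            class = "st_covariance_params")
}

#' Separable residual correlation
#'
#' `exp(-d_km/rho_s) * exp(-d_days/rho_t)`: the correlation between residuals
#' separated by `d_km` kilometres and `d_days` days. Equals 1 at zero
#' separation and factorizes into its spatial and temporal terms.
#'
#' @param params an [st_covariance_params()] object.
#' @param d_km,d_days nonnegative separation distances (vectorized).
#' @return correlation values in (0, 1].
#' @examples
#' p <- st_covariance_params(110.25, 179, 1.83)
#' residual_correlation(p, 0, 1)    # consecutive days, same site
#' residual_correlation(p, 100, 0)  # 100 km apart, same day
#' @export
residual_correlation <- function(params, d_km, d_days) {
  stopifnot(inherits(params, "st_covariance_params"))
  if (any(d_km < 0) || any(d_days < 0)) stop("distances must be nonnegative")
  exp(-d_km / params$rho_s) * exp(-d_days / params$rho_t)
}

#' Effective range of an exponential correlation
#'
#' The separation (same units as `rho`) at which the correlation falls to
#' 0.05; for the exponential model this is `3 * rho` (`exp(-3)` is about
#' 0.0498).
#'
#' @param rho decay scale (> 0), km or days.
#' @return effective range, same units.
#' @export
effective_range <- function(rho) {
  if (any(!is.finite(rho)) || any(rho <= 0)) stop("rho must be > 0")
  3 * rho
}

# Cholesky with a single jitter retry proportional to the diagonal scale.
chol_jitter <- function(M, rel_jitter = 1e-8) {
  out <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(out)) {
    out <- tryCatch(chol(M + diag(rel_jitter * mean(diag(M)), nrow(M))),
                    error = function(e)
                      stop("correlation matrix is not positive definite even ",
                           "after a diagonal jitter of ", rel_jitter,
                           "; increase the jitter or perturb coordinates"))
  }
  out
}

# ---- LinkedPanel ----------------------------------------------------------

#' Assemble a monitor-by-day linked panel
#'
#' Joins daily ozone responses with colocated (or nearest-station) weather
#' covariates and attaches planar coordinates and day indices. Synthetic
#' generators produce colocated covariates; for separately located monitors
#' run [nearest_link()] first and rename the joined columns accordingly.
#'
#' @param ozone data.frame `station_id, date, o3_mda8`.
#' @param weather long data.frame `station_id, date, variable, value` with
#'   variables `temperature`, `ghi`, `cloud_cover`.
#' @param stations data.frame `station_id, latitude, longitude, state`.
#' @return a data.frame of class `oz_panel` with columns `station_id, date,
#'   o3_mda8, temp_c, ghi_wm2, cloud_pct, state, x_km, y_km, day_index`.
#' @export
make_panel <- function(ozone, weather, stations) {
  validate_stations(stations)
  w <- stats::reshape(weather, idvar = c("station_id", "date"),
                      timevar = "variable", direction = "wide")
  names(w) <- sub("^value\\.temperature$", "temp_c", names(w))
  names(w) <- sub("^value\\.ghi$", "ghi_wm2", names(w))
  names(w) <- sub("^value\\.cloud_cover$", "cloud_pct", names(w))
  d <- merge(ozone, w, by = c("station_id", "date"))
  d <- merge(d, stations[, c("station_id", "latitude", "longitude", "state")],
             by = "station_id")
  pc <- project_coords(d$latitude, d$longitude)
  d$x_km <- pc$x_km
  d$y_km <- pc$y_km
  d$day_index <- as.integer(as.Date(d$date) - min(as.Date(d$date)))
  d <- d[order(d$station_id, d$date),
         c("station_id", "date", "o3_mda8", "temp_c", "ghi_wm2", "cloud_pct",
           "state", "x_km", "y_km", "day_index")]
  rownames(d) <- NULL
  class(d) <- c("oz_panel", "data.frame")
  d
}

# Decompose a panel into the matrices the likelihood and sampler need.
# Y is n_t x n_t? no: n_t (days) x n_s (stations); X matches vec(Y)
# (station-major). obs is the logical mask of non-missing responses in
# vec order.
panel_matrices <- function(panel) {
  need <- c("station_id", "o3_mda8", "temp_c", "ghi_wm2", "cloud_pct",
            "state", "x_km", "y_km", "day_index")
  if (!all(need %in% names(panel)))
    stop("panel is missing columns: ",
         paste(setdiff(need, names(panel)), collapse = ", "))
  stations <- sort(unique(panel$station_id))
  days <- sort(unique(panel$day_index))
  n_s <- length(stations); n_t <- length(days)
  si <- match(panel$station_id, stations)
  ti <- match(panel$day_index, days)
  idx <- (si - 1L) * n_t + ti
  if (anyDuplicated(idx)) stop("duplicate station-day rows in panel")
  n <- n_s * n_t
  Y <- rep(NA_real_, n)
  Y[idx] <- panel$o3_mda8
  # station-level attributes
  st_row <- match(stations, panel$station_id)
  coords <- cbind(panel$x_km[st_row], panel$y_km[st_row])
  state <- panel$state[st_row]
  states <- sort(unique(state))
  # covariates on the full grid (must be present wherever needed)
  covs <- matrix(NA_real_, n, length(PANEL_COVARIATES))
  for (j in seq_along(PANEL_COVARIATES))
    covs[idx, j] <- panel[[PANEL_COVARIATES[j]]]
  # state-blocked design: (intercept, temp, ghi, cloud) per state
  p <- 4L * length(states)
  X <- matrix(0, n, p)
  cn <- character(p)
  state_of_obs <- rep(state, each = n_t)
  for (r in seq_along(states)) {
    rows <- state_of_obs == states[r]
    cols <- (r - 1L) * 4L + 1:4
    X[rows, cols[1]] <- 1
    X[rows, cols[2:4]] <- covs[rows, ]
    cn[cols] <- paste(states[r], c("intercept", PANEL_COVARIATES), sep = ":")
  }
  colnames(X) <- cn
  obs <- !is.na(Y)
  if (any(obs & rowSums(is.na(X)) > 0))
    stop("covariates must be finite wherever the response is present")
  list(stations = stations, days = days, n_s = n_s, n_t = n_t,
       coords = coords, state = state, states = states,
       Y = matrix(Y, n_t, n_s), X = X, obs = obs)
}

# ---- log-likelihood -------------------------------------------------------

kron_chols <- function(Ds, Dt, rho_s, rho_t) {
  Us <- chol_jitter(exp(-Ds / rho_s))
  Ut <- chol_jitter(exp(-Dt / rho_t))
  list(Us = Us, Ut = Ut,
       logdet = 2 * ncol(Dt) * sum(log(diag(Us))) +
                2 * ncol(Ds) * sum(log(diag(Ut))))
}

# Whiten a vec-ordered vector (or each column of a matrix) by the Kronecker
# correlation root: returns vec(Lt^-1 V Ls^-T) with V = matrix(v, n_t, n_s).
kron_whiten <- function(ch, v, n_t, n_s) {
  V <- matrix(v, n_t, n_s)
  M <- backsolve(ch$Ut, V, transpose = TRUE)           # Lt^-1 V
  M <- t(backsolve(ch$Us, t(M), transpose = TRUE))     # ... Ls^-T
  as.vector(M)
}

kron_whiten_mat <- function(ch, X, n_t, n_s) {
  out <- X
  for (j in seq_len(ncol(X)))
    out[, j] <- kron_whiten(ch, X[, j], n_t, n_s)
  out
}

#' Log-likelihood of the space-time ozone model
#'
#' Multivariate normal log density of the residuals `Y - X beta` under the
#' separable exponential covariance. Complete balanced panels use the
#' Kronecker factorization (cost cubic in stations and days separately);
#' incomplete panels fall back to the dense covariance restricted to the
#' observed entries.
#'
#' @param panel an `oz_panel` (see [make_panel()]).
#' @param beta named coefficient vector matching the state-blocked design
#'   (`"<state>:intercept"`, `"<state>:temp_c"`, ...), or a matrix with one
#'   row per state and columns (intercept, temp_c, ghi_wm2, cloud_pct).
#' @param params an [st_covariance_params()] object.
#' @param method `"auto"` (default), `"kronecker"` or `"dense"`.
#' @return the log density (scalar).
#' @export
log_likelihood <- function(panel, beta, params,
                           method = c("auto", "kronecker", "dense")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "st_covariance_params"))
  pm <- panel_matrices(panel)
  beta <- normalize_beta(beta, pm)
  if (any(!is.finite(beta))) stop("non-finite coefficients")
  complete <- all(pm$obs)
  if (method == "kronecker" && !complete)
    stop("Kronecker path requires a complete station-by-day panel")
  resid <- as.vector(pm$Y) - as.vector(pm$X %*% beta)
  Ds <- as.matrix(stats::dist(pm$coords))
  Dt <- abs(outer(pm$days, pm$days, "-"))
  if (complete && method != "dense") {
    ch <- kron_chols(Ds, Dt, params$rho_s, params$rho_t)
    w <- kron_whiten(ch, resid, pm$n_t, pm$n_s)
    n <- length(resid)
    -0.5 * (n * log(2 * pi) + n * log(params$sigma2) + ch$logdet +
            sum(w^2) / params$sigma2)
  } else {
    o <- which(pm$obs)
    si <- (o - 1L) %/% pm$n_t + 1L
    ti <- (o - 1L) %% pm$n_t + 1L
    Cor <- exp(-Ds[si, si, drop = FALSE] / params$rho_s -
                Dt[ti, ti, drop = FALSE] / params$rho_t)
    U <- chol_jitter(Cor)
    w <- backsolve(U, resid[o], transpose = TRUE)
    n <- length(o)
    -0.5 * (n * log(2 * pi) + n * log(params$sigma2) +
            2 * sum(log(diag(U))) + sum(w^2) / params$sigma2)
  }
}

normalize_beta <- function(beta, pm) {
  p <- ncol(pm$X)
  if (is.matrix(beta)) {
    if (nrow(beta) != length(pm$states) || ncol(beta) != 4L)
      stop("beta matrix must be n_states x 4")
    b <- as.vector(t(beta))
    names(b) <- colnames(pm$X)
    return(b)
  }
  if (length(beta) != p) stop("beta has wrong length (expected ", p, ")")
  if (!is.null(names(beta)) && !is.null(colnames(pm$X)))
    beta <- beta[colnames(pm$X)]
  beta
}

# ---- MCMC -----------------------------------------------------------------

#' Prior specification for the space-time model
#'
#' Uniform priors on the decay scales (defaults: `rho_s` on 10-350 km,
#' effective range 30-1050 km; `rho_t` on 0-5 days, effective range 0-15
#' days), a proper non-informative inverse-gamma prior on `sigma2`, and a
#' diffuse normal prior on the regression coefficients.
#'
#' @param rho_s_range,rho_t_range uniform prior supports.
#' @param sigma2_shape,sigma2_rate inverse-gamma hyperparameters.
#' @param beta_var prior variance of each regression coefficient.
#' @return a list of class `oz_priors`.
#' @export
oz_priors <- function(rho_s_range = c(10, 350), rho_t_range = c(0, 5),
                      sigma2_shape = 0.01, sigma2_rate = 0.01,
                      beta_var = 1e6) {
  stopifnot(length(rho_s_range) == 2, rho_s_range[1] > 0,
            diff(rho_s_range) > 0, length(rho_t_range) == 2,
            rho_t_range[1] >= 0, diff(rho_t_range) > 0,
            sigma2_shape > 0, sigma2_rate > 0, beta_var > 0)
  structure(list(rho_s_range = rho_s_range, rho_t_range = rho_t_range,
                 sigma2_shape = sigma2_shape, sigma2_rate = sigma2_rate,
                 beta_var = beta_var), class = "oz_priors")
}

# Reflect x into [lo, hi]; lo may be -Inf (single reflection at hi).
reflect_into <- function(x, lo, hi) {
  if (!is.finite(lo)) {
    if (x > hi) x <- 2 * hi - x
    return(x)
  }
  width <- 2 * (hi - lo)
  y <- (x - lo) %% width
  if (y > hi - lo) y <- width - y
  y + lo
}

#' Fit the space-time ozone model by MCMC
#'
#' Gibbs updates for the state-specific regression coefficients (conjugate
#' normal) and the residual variance (conjugate inverse-gamma), and a joint
#' random-walk Metropolis step on `(log rho_s, log rho_t)` with reflection at
#' the transformed prior bounds. The proposal step size is adapted during
#' burn-in toward a 20-45% acceptance rate and then frozen. Retains
#' `n_iter - burn_in` draws (defaults: 3000 retained after 1000 burn-in).
#'
#' Complete balanced panels use the Kronecker factorization of the
#' covariance; panels with missing responses fall back to a dense observed
#' -entry covariance (quadratic memory, only sensible for small panels).
#'
#' @param panel an `oz_panel`; at least 2 stations and 2 days.
#' @param n_iter total iterations.
#' @param burn_in discarded initial iterations.
#' @param seed integer seed; the chain is reproducible given the seed.
#' @param priors an [oz_priors()] object.
#' @param likelihood internal: set `FALSE` to sample from the priors only
#'   (used to validate chain invariance).
#' @return an `oz_posterior` object: matrices/vectors of retained draws for
#'   `beta`, `sigma2`, `rho_s`, `rho_t`, the Metropolis acceptance rate, and
#'   the panel matrices needed for prediction.
#' @export
fit_mcmc <- function(panel, n_iter = 4000, burn_in = 1000, seed = 1,
                     priors = oz_priors(), likelihood = TRUE) {
  pm <- panel_matrices(panel)
  if (pm$n_s < 2 || pm$n_t < 2) stop("need at least 2 stations and 2 days")
  if (!any(pm$obs)) stop("all responses missing")
  if (burn_in >= n_iter) stop("burn_in must be < n_iter")
  seed_stream(seed, 6L)

  Ds <- as.matrix(stats::dist(pm$coords))
  Dt <- abs(outer(pm$days, pm$days, "-"))
  complete <- all(pm$obs)
  o <- which(pm$obs)
  n <- length(o)
  if (complete) {
    X <- pm$X; y <- as.vector(pm$Y)
    make_state <- function(rs, rt) {
      ch <- kron_chols(Ds, Dt, rs, rt)
      ch$whiten <- function(v) kron_whiten(ch, v, pm$n_t, pm$n_s)
      ch
    }
  } else {
    si <- (o - 1L) %/% pm$n_t + 1L
    ti <- (o - 1L) %% pm$n_t + 1L
    Dso <- Ds[si, si, drop = FALSE]
    Dto <- Dt[ti, ti, drop = FALSE]
    X <- pm$X[o, , drop = FALSE]; y <- as.vector(pm$Y)[o]
    make_state <- function(rs, rt) {
      U <- chol_jitter(exp(-Dso / rs - Dto / rt))
      list(U = U, logdet = 2 * sum(log(diag(U))),
           whiten = function(v) backsolve(U, v, transpose = TRUE))
    }
  }
  p <- ncol(X)
  # per-state sample-size precondition
  state_of <- rep(pm$state, each = pm$n_t)
  if (complete) counts <- table(state_of) else counts <- table(state_of[o])
  if (any(counts < 4L))
    stop("each state needs at least 4 observed station-days")

  # initial values from OLS
  ols <- stats::lm.fit(X, y)
  beta <- ols$coefficients
  beta[is.na(beta)] <- 0
  sigma2 <- max(stats::var(ols$residuals), 1e-6)
  rho_s <- mean(priors$rho_s_range)
  rho_t <- max(mean(priors$rho_t_range), 0.2)

  lls <- log(priors$rho_s_range)
  llt <- c(if (priors$rho_t_range[1] > 0) log(priors$rho_t_range[1]) else -Inf,
           log(priors$rho_t_range[2]))

  st <- make_state(rho_s, rho_t)
  Xw <- if (likelihood) kron_style_whiten_mat(st, X) else NULL
  yw <- if (likelihood) st$whiten(y) else NULL

  n_keep <- n_iter - burn_in
  B <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
  S2 <- RS <- RT <- numeric(n_keep)
  step <- 0.15
  acc_win <- 0L; win_n <- 0L; acc_post <- 0L; post_n <- 0L
  q_cur <- NA_real_

  for (it in seq_len(n_iter)) {
    if (likelihood) {
      # beta | sigma2, rho -- conjugate normal
      A <- crossprod(Xw) / sigma2
      diag(A) <- diag(A) + 1 / priors$beta_var
      Ua <- chol(A)
      m <- backsolve(Ua, backsolve(Ua, crossprod(Xw, yw) / sigma2,
                                   transpose = TRUE))
      beta <- as.vector(m + backsolve(Ua, stats::rnorm(p)))
      # sigma2 | beta, rho -- conjugate inverse-gamma
      rw <- yw - Xw %*% beta
      q_cur <- sum(rw^2)
      sigma2 <- 1 / stats::rgamma(1, shape = priors$sigma2_shape + n / 2,
                                  rate = priors$sigma2_rate + q_cur / 2)
      if (!is.finite(sigma2) || sigma2 <= 0)
        stop("divergent chain (non-finite sigma2) at iteration ", it)
    }
    # (rho_s, rho_t) | beta, sigma2 -- random-walk Metropolis on log scale
    prop_s <- reflect_into(log(rho_s) + stats::rnorm(1, 0, step),
                           lls[1], lls[2])
    prop_t <- reflect_into(log(rho_t) + stats::rnorm(1, 0, step),
                           llt[1], llt[2])
    rs_p <- exp(prop_s); rt_p <- exp(prop_t)
    ok <- rs_p >= priors$rho_s_range[1] && rs_p <= priors$rho_s_range[2] &&
          rt_p > priors$rho_t_range[1] && rt_p <= priors$rho_t_range[2]
    if (ok) {
      if (likelihood) {
        st_p <- make_state(rs_p, rt_p)
        resid <- y - X %*% beta
        w_p <- st_p$whiten(resid)
        ll_p <- -0.5 * (st_p$logdet + sum(w_p^2) / sigma2)
        ll_c <- -0.5 * (st$logdet + q_cur / sigma2)
        if (!is.finite(ll_p) || !is.finite(ll_c))
          stop("divergent chain (non-finite log posterior) at iteration ", it)
        log_acc <- ll_p - ll_c + log(rs_p) - log(rho_s) +
                   log(rt_p) - log(rho_t)
      } else {
        # prior-only run: uniform target, Jacobian for the log-scale walk
        log_acc <- log(rs_p) - log(rho_s) + log(rt_p) - log(rho_t)
      }
      if (log(stats::runif(1)) < log_acc) {
        rho_s <- rs_p; rho_t <- rt_p
        if (likelihood) {
          st <- st_p
          Xw <- kron_style_whiten_mat(st, X)
          yw <- st$whiten(y)
          q_cur <- sum((yw - Xw %*% beta)^2)
        }
        acc_win <- acc_win + 1L
        if (it > burn_in) acc_post <- acc_post + 1L
      }
    }
    win_n <- win_n + 1L
    if (it > burn_in) post_n <- post_n + 1L
    # step-size adaptation, burn-in only
    if (it <= burn_in && win_n >= 50L) {
      rate <- acc_win / win_n
      if (rate < 0.20) step <- max(step * 0.7, 0.01)
      if (rate > 0.45) step <- min(step * 1.4, 2.5)
      acc_win <- 0L; win_n <- 0L
    }
    if (it > burn_in) {
      k <- it - burn_in
      B[k, ] <- beta
      S2[k] <- sigma2; RS[k] <- rho_s; RT[k] <- rho_t
    }
  }

  structure(list(beta = B, sigma2 = S2, rho_s = RS, rho_t = RT,
                 accept_rate = acc_post / max(post_n, 1L),
                 n_iter = n_iter, burn_in = burn_in, seed = seed,
                 priors = priors, pm = pm, complete = complete),
            class = "oz_posterior")
}

kron_style_whiten_mat <- function(st, X) {
  out <- X
  for (j in seq_len(ncol(X))) out[, j] <- st$whiten(X[, j])
  out
}

#' @export
print.oz_posterior <- function(x, ...) {
  cat(sprintf("Space-time ozone posterior: %d retained draws (burn-in %d)\n",
              length(x$sigma2), x$burn_in))
  cat(sprintf("  Metropolis acceptance rate: %.2f\n", x$accept_rate))
  s <- summary(x)
  print(round(s, 3))
  invisible(x)
}

#' Posterior summary (means and 95% intervals)
#' @param object an `oz_posterior`.
#' @param ... unused.
#' @export
summary.oz_posterior <- function(object, ...) {
  draws <- cbind(sigma = sqrt(object$sigma2), sigma2 = object$sigma2,
                 rho_s = object$rho_s, rho_t = object$rho_t, object$beta)
  t(apply(draws, 2, function(v)
    c(mean = mean(v), q2.5 = unname(stats::quantile(v, 0.025)),
      q97.5 = unname(stats::quantile(v, 0.975)))))
}

# ---- posterior prediction -------------------------------------------------

#' Posterior-predictive draws at new locations
#'
#' For each of `n_draws` (evenly thinned) posterior parameter draws, samples
#' the Gaussian process at the new points. With `condition = TRUE` (the
#' default) the draw is the conditional (kriging) distribution of the new
#' locations given the fitted panel's observed residuals, which requires the
#' new points to form a complete grid of new locations over the panel's own
#' days. With `condition = FALSE` the unconditional GP around `X beta` is
#' sampled (pure projection mode) over any regular set of days.
#'
#' @param object an `oz_posterior` from [fit_mcmc()].
#' @param newdata data.frame with columns `location_id, day_index, x_km,
#'   y_km, state, temp_c, ghi_wm2, cloud_pct`.
#' @param n_draws number of posterior-predictive draws (at most the number
#'   of retained posterior draws).
#' @param condition condition on the observed panel residuals?
#' @param include_residual set `FALSE` to suppress the residual field and
#'   return `X beta` draws only.
#' @param seed integer seed.
#' @param ... unused.
#' @return an `oz_prediction`: `draws` (n_draws x rows of `newdata`),
#'   pointwise `mean`, and 95% interval `lower`/`upper`.
#' @export
predict.oz_posterior <- function(object, newdata, n_draws = 100,
                                 condition = TRUE, include_residual = TRUE,
                                 seed = 1, ...) {
  pm <- object$pm
  need <- c("location_id", "day_index", "x_km", "y_km", "state",
            PANEL_COVARIATES)
  if (!all(need %in% names(newdata)))
    stop("newdata is missing columns: ",
         paste(setdiff(need, names(newdata)), collapse = ", "))
  if (any(!is.finite(as.matrix(newdata[, c("x_km", "y_km",
                                           PANEL_COVARIATES)]))))
    stop("newdata covariates and coordinates must be finite")
  n_keep <- length(object$sigma2)
  if (n_draws > n_keep) stop("n_draws exceeds retained posterior draws")
  if (condition && !object$complete)
    stop("conditional prediction requires a complete fitted panel")

  locs <- unique(newdata[, c("location_id", "x_km", "y_km", "state")])
  if (anyDuplicated(locs$location_id))
    stop("location_id must map to a single coordinate/state")
  n_n <- nrow(locs)
  days_new <- sort(unique(newdata$day_index))
  if (condition && !setequal(days_new, pm$days))
    stop("conditional prediction requires newdata on the panel's day grid")
  n_tn <- length(days_new)
  if (nrow(newdata) != n_n * n_tn ||
      anyDuplicated(newdata[, c("location_id", "day_index")]))
    stop("newdata must be a complete location-by-day grid")

  # design matrix for new points in (day fast, location slow) order
  ord <- order(match(newdata$location_id, locs$location_id),
               newdata$day_index)
  nd <- newdata[ord, ]
  Xn <- matrix(0, nrow(nd), ncol(pm$X))
  colnames(Xn) <- colnames(pm$X)
  for (r in seq_along(pm$states)) {
    rows <- nd$state == pm$states[r]
    if (!any(rows)) next
    cols <- (r - 1L) * 4L + 1:4
    Xn[rows, cols[1]] <- 1
    Xn[rows, cols[2]] <- nd$temp_c[rows]
    Xn[rows, cols[3]] <- nd$ghi_wm2[rows]
    Xn[rows, cols[4]] <- nd$cloud_pct[rows]
  }
  if (any(rowSums(Xn != 0) == 0))
    stop("newdata contains states absent from the fitted panel")

  seed_stream(seed, 7L)
  idx <- unique(round(seq(1, n_keep, length.out = n_draws)))
  # pre-draw the noise so draw j is reproducible regardless of condition mode
  coords_new <- as.matrix(locs[, c("x_km", "y_km")])
  Dt_new <- abs(outer(days_new, days_new, "-"))
  Dnn <- as.matrix(stats::dist(coords_new))
  if (condition) {
    cross <- sqrt(outer(coords_new[, 1], pm$coords[, 1], "-")^2 +
                  outer(coords_new[, 2], pm$coords[, 2], "-")^2)
  }
  draws <- matrix(NA_real_, length(idx), nrow(nd))
  for (k in seq_along(idx)) {
    j <- idx[k]
    beta_j <- object$beta[j, ]
    s2 <- object$sigma2[j]; rs <- object$rho_s[j]; rt <- object$rho_t[j]
    mu <- as.vector(Xn %*% beta_j)
    if (include_residual) {
      Ut <- chol_jitter(exp(-Dt_new / rt))
      if (condition) {
        Rno <- exp(-cross / rs)
        Uoo <- chol_jitter(exp(-as.matrix(stats::dist(pm$coords)) / rs))
        K <- t(backsolve(Uoo, backsolve(Uoo, t(Rno), transpose = TRUE)))
        Eobs <- pm$Y - matrix(pm$X %*% normalize_beta(beta_j, pm),
                              pm$n_t, pm$n_s)
        cond_mean <- Eobs %*% t(K)                     # n_t x n_n
        S <- exp(-Dnn / rs) - K %*% t(Rno)
        S <- (S + t(S)) / 2
        # colocated new/observed stations make S numerically singular (near
        # -zero conditional variance); an absolute nugget keeps chol stable
        diag(S) <- diag(S) + 1e-8
        Us <- chol_jitter(S, rel_jitter = 1e-6)
        Z <- matrix(stats::rnorm(n_tn * n_n), n_tn, n_n)
        E <- cond_mean + sqrt(s2) * (t(Ut) %*% Z %*% Us)
      } else {
        Us <- chol_jitter(exp(-Dnn / rs))
        Z <- matrix(stats::rnorm(n_tn * n_n), n_tn, n_n)
        E <- sqrt(s2) * (t(Ut) %*% Z %*% Us)
      }
      mu <- mu + as.vector(E)
    }
    draws[k, ] <- mu
  }
  # map back to the caller's row order
  inv <- order(ord)
  draws <- draws[, inv, drop = FALSE]
  structure(list(draws = draws,
                 mean = colMeans(draws),
                 lower = apply(draws, 2, stats::quantile, 0.025),
                 upper = apply(draws, 2, stats::quantile, 0.975),
                 newdata = newdata, n_draws = nrow(draws)),
            class = "oz_prediction")
}

#' Hold-out validation of the space-time model
#'
#' Removes `n_holdout` whole stations, refits the model on the remainder,
#' predicts the held-out station-days by conditional (kriging) posterior
#' prediction, and reports the root mean-squared error and the fraction of
#' 95% predictive intervals containing the held-out truth.
#'
#' @param panel a complete `oz_panel`.
#' @param n_holdout stations to hold out (must be < station count).
#' @param n_iter,burn_in,seed passed to [fit_mcmc()].
#' @param n_draws posterior-predictive draws per held-out point.
#' @return list with `rmse_ppb`, `coverage`, and `holdout_stations`.
#' @export
validate_holdout <- function(panel, n_holdout = 10, n_iter = 4000,
                             burn_in = 1000, n_draws = 100, seed = 1) {
  stations <- sort(unique(panel$station_id))
  if (n_holdout >= length(stations))
    stop("n_holdout must be smaller than the station count")
  seed_stream(seed, 9L)
  held <- sort(sample(stations, n_holdout))
  train <- panel[!panel$station_id %in% held, ]
  test <- panel[panel$station_id %in% held, ]
  class(train) <- class(panel)
  fit <- fit_mcmc(train, n_iter = n_iter, burn_in = burn_in, seed = seed)
  nd <- data.frame(location_id = test$station_id,
                   day_index = test$day_index,
                   x_km = test$x_km, y_km = test$y_km, state = test$state,
                   temp_c = test$temp_c, ghi_wm2 = test$ghi_wm2,
                   cloud_pct = test$cloud_pct)
  pr <- predict(fit, nd, n_draws = n_draws, condition = TRUE, seed = seed)
  err <- pr$mean - test$o3_mda8
  list(rmse_ppb = sqrt(mean(err^2)),
       coverage = mean(test$o3_mda8 >= pr$lower & test$o3_mda8 <= pr$upper),
       holdout_stations = held)
}
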