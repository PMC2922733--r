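test_that("separable correlation is 1 at the origin, monotone, and factorizes", {
  p <- st_covariance_params(110.25, 179, 1.83)
  expect_equal(residual_correlation(p, 0, 0), 1)
  d <- seq(0, 500, by = 50)
  ck <- residual_correlation(p, d, 0)
  expect_true(all(diff(ck) < 0))
  cd <- residual_correlation(p, 0, 0:6)
  expect_true(all(diff(cd) < 0))
  # product form
  expect_equal(residual_correlation(p, 120, 2.5),
               residual_correlation(p, 120, 0) *
                 residual_correlation(p, 0, 2.5))
  expect_error(residual_correlation(p, -1, 0), "nonnegative")
  expect_error(st_covariance_params(-1, 179, 1.83), "sigma2")
})

test_that("effective range is three decay scales", {
  expect_equal(effective_range(1), 3)
  expect_equal(exp(-effective_range(1) / 1), exp(-3))
  expect_lt(exp(-3), 0.05)
  expect_error(effective_range(0), "rho")
  expect_error(effective_range(-2), "rho")
})

test_that("log-likelihood matches closed forms in degenerate cases", {
  # single observation with zero residual and unit variance
  panel <- structure(data.frame(
    station_id = "A", date = "2000-06-01", o3_mda8 = 5, temp_c = 0,
    ghi_wm2 = 0, cloud_pct = 0, state = "S1", x_km = 0, y_km = 0,
    day_index = 0L, stringsAsFactors = FALSE),
    class = c("oz_panel", "data.frame"))
  beta <- c(`S1:intercept` = 5, `S1:temp_c` = 0, `S1:ghi_wm2` = 0,
            `S1:cloud_pct` = 0)
  ll <- log_likelihood(panel, beta, st_covariance_params(1, 100, 2))
  expect_equal(ll, -0.5 * log(2 * pi))
  # near-independence limit equals a sum of iid normal densities
  sp <- small_panel(seed = 2, n_s = 4, n_t = 6)
  pm_beta <- sp$truth$beta_r
  ll_ind <- log_likelihood(sp$panel, pm_beta,
                           st_covariance_params(50, 1e-6, 1e-6))
  # oracle: residuals via the noiseless surface
  truth0 <- sp$truth; truth0$sigma2 <- 0
  mu <- generate_ozone(sp$weather, sp$net$stations, truth0, seed = 1)
  r <- sp$panel$o3_mda8[order(sp$panel$station_id, sp$panel$date)] -
    mu$o3_mda8
  expect_equal(ll_ind, sum(dnorm(r, 0, sqrt(50), log = TRUE)),
               tolerance = 1e-6)
})

test_that("Kronecker and dense likelihood paths agree on complete panels", {
  set.seed(30)
  for (n_s in c(2, 4, 6)) for (n_t in c(3, 8)) {
    sp <- small_panel(seed = n_s * 10 + n_t, n_s = n_s, n_t = n_t)
    pars <- st_covariance_params(exp(runif(1, 2, 5)), runif(1, 30, 300),
                                 runif(1, 0.3, 4))
    llk <- log_likelihood(sp$panel, sp$truth$beta_r, pars,
                          method = "kronecker")
    lld <- log_likelihood(sp$panel, sp$truth$beta_r, pars, method = "dense")
    expect_lt(abs(llk - lld), 1e-8)
  }
})

test_that("incomplete panels drop missing entries in the dense path", {
  sp <- small_panel(seed = 4, n_s = 4, n_t = 6)
  panel <- sp$panel[-c(3, 10, 17), ]
  class(panel) <- class(sp$panel)
  pars <- st_covariance_params(100, 150, 1.5)
  ll <- log_likelihood(panel, sp$truth$beta_r, pars)
  expect_true(is.finite(ll))
  expect_error(log_likelihood(panel, sp$truth$beta_r, pars,
                              method = "kronecker"), "complete")
})

test_that("the sampler is reproducible and reports a healthy acceptance rate", {
  sp <- small_panel(seed = 3, n_s = 6, n_t = 12)
  f1 <- fit_mcmc(sp$panel, n_iter = 400, burn_in = 100, seed = 7)
  f2 <- fit_mcmc(sp$panel, n_iter = 400, burn_in = 100, seed = 7)
  expect_identical(f1$rho_t, f2$rho_t)
  expect_identical(f1$beta, f2$beta)
  f3 <- fit_mcmc(sp$panel, n_iter = 400, burn_in = 100, seed = 8)
  expect_false(identical(f1$rho_t, f3$rho_t))
  full <- fit_mcmc(sp$panel, n_iter = 2000, burn_in = 500, seed = 7)
  expect_gt(full$accept_rate, 0.1)
  expect_lt(full$accept_rate, 0.6)
})

test_that("regression coefficients agree with least squares when residuals are iid", {
  # ozone built with white noise: GLS and OLS coincide
  net <- generate_network(8, 2, seed = 21)
  states <- sort(unique(net$stations$state))
  truth0 <- synth_truth(states, seed = 21, sigma2 = 0)
  dates <- as.character(seq(as.Date("2000-06-01"), by = "day",
                            length.out = 25))
  w <- generate_weather(net$stations, dates, seed = 21)
  oz <- generate_ozone(w, net$stations, truth0, seed = 21)
  set.seed(99)
  oz$o3_mda8 <- oz$o3_mda8 + rnorm(nrow(oz), 0, 5)
  panel <- make_panel(oz, w, net$stations)
  fit <- fit_mcmc(panel, n_iter = 1500, burn_in = 500, seed = 21)
  # OLS oracle on the same state-blocked design
  for (st in states) {
    sub <- panel[panel$state == st, ]
    ols <- lm(o3_mda8 ~ temp_c + ghi_wm2 + cloud_pct, data = sub)
    pm <- colMeans(fit$beta)[paste0(st, ":", c("intercept", "temp_c",
                                               "ghi_wm2", "cloud_pct"))]
    psd <- apply(fit$beta, 2, sd)[names(pm)]
    expect_true(all(abs(pm - coef(ols)) < 4 * psd))
  }
})

test_that("a prior-only chain reproduces the uniform prior moments", {
  sp <- small_panel(seed = 5, n_s = 4, n_t = 6)
  pp <- fit_mcmc(sp$panel, n_iter = 11000, burn_in = 1000, seed = 5,
                 likelihood = FALSE)
  expect_lt(abs(mean(pp$rho_s) - 180), 12)
  expect_lt(abs(mean(pp$rho_t) - 2.5), 0.2)
  expect_lt(abs(sd(pp$rho_s) - 340 / sqrt(12)), 15)
})

test_that("conditional prediction interpolates observed data as noise vanishes", {
  sp <- small_panel(seed = 6, n_s = 5, n_t = 10, sigma2 = 0.01)
  fit <- fit_mcmc(sp$panel, n_iter = 800, burn_in = 200, seed = 6)
  st1 <- sp$panel[sp$panel$station_id == sp$panel$station_id[1], ]
  nd <- data.frame(location_id = "new", day_index = st1$day_index,
                   x_km = st1$x_km, y_km = st1$y_km, state = st1$state,
                   temp_c = st1$temp_c, ghi_wm2 = st1$ghi_wm2,
                   cloud_pct = st1$cloud_pct)
  pr <- predict(fit, nd, n_draws = 30, condition = TRUE, seed = 6)
  expect_lt(max(abs(pr$mean - st1$o3_mda8)), 0.5)
  # residual field suppressed: draws reduce to X* beta
  pr0 <- predict(fit, nd, n_draws = length(fit$sigma2), condition = TRUE,
                 include_residual = FALSE, seed = 6)
  Xn <- cbind(1, st1$temp_c, st1$ghi_wm2, st1$cloud_pct)
  bcols <- paste0(st1$state[1], ":", c("intercept", "temp_c", "ghi_wm2",
                                       "cloud_pct"))
  expect_equal(pr0$mean, as.vector(Xn %*% colMeans(fit$beta)[bcols]),
               tolerance = 1e-10)
})

test_that("hold-out validation reports RMSE and calibrated interval coverage", {
  sp <- small_panel(seed = 7, n_s = 10, n_t = 20)
  v1 <- validate_holdout(sp$panel, n_holdout = 3, n_iter = 800,
                         burn_in = 200, n_draws = 40, seed = 7)
  v2 <- validate_holdout(sp$panel, n_holdout = 3, n_iter = 800,
                         burn_in = 200, n_draws = 40, seed = 7)
  expect_identical(v1$holdout_stations, v2$holdout_stations)
  expect_equal(v1$rmse_ppb, v2$rmse_ppb)
  expect_true(is.finite(v1$rmse_ppb) && v1$rmse_ppb > 0)
  # conditioning on neighbours must beat the marginal sd
  expect_lt(v1$rmse_ppb, sqrt(110.25))
  expect_gte(v1$coverage, 0.8)
  expect_error(validate_holdout(sp$panel, n_holdout = 10), "smaller")
})
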