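# Independent oracle implementations and small fixtures used across tests.

# Brute-force MDA8: loop every in-day 8-hour window, straightforwardly.
mda8_oracle <- function(hour, conc) {
  by_hour <- rep(NA_real_, 24)
  by_hour[hour + 1] <- conc
  means <- c()
  for (s in 0:16) {
    w <- by_hour[(s + 1):(s + 8)]
    present <- w[!is.na(w)]
    if (length(present) >= 6) means <- c(means, mean(present))
  }
  if (length(means) == 0) NA_real_ else max(means)
}

# Independent two-level-normal posterior by direct Riemann summation over a
# fine tau grid (flat prior on mu, uniform prior on tau).
pool_oracle <- function(beta_hat, var_hat, n_grid = 20001, mult = 20) {
  tau <- seq(0, sqrt(mult * max(var_hat)), length.out = n_grid)
  k <- length(beta_hat)
  lp <- mu_hat <- vv <- numeric(length(tau))
  for (i in seq_along(tau)) {
    w <- 1 / (var_hat + tau[i]^2)
    m <- sum(w * beta_hat) / sum(w)
    lp[i] <- 0.5 * sum(log(w)) - 0.5 * log(sum(w)) -
      0.5 * sum(w * (beta_hat - m)^2)
    mu_hat[i] <- m
    vv[i] <- 1 / sum(w)
  }
  p <- exp(lp - max(lp))
  # trapezoid weights
  h <- diff(tau)
  wt <- c(h[1] / 2, (h[-1] + h[-length(h)]) / 2, h[length(h)] / 2) * p
  wt <- wt / sum(wt)
  list(mu_mean = sum(wt * mu_hat),
       mu_var = sum(wt * (vv + mu_hat^2)) - sum(wt * mu_hat)^2,
       tau2_mean = sum(wt * tau^2))
}

# Compact synthetic panel for space-time model tests.
small_panel <- function(seed = 1, n_s = 6, n_t = 15, n_states = 2,
                        sigma2 = 110.25, rho_s = 179, rho_t = 1.83) {
  net <- generate_network(n_s, min(2, n_s), n_states = n_states, seed = seed)
  truth <- synth_truth(sort(unique(net$stations$state)), seed = seed,
                       sigma2 = sigma2, rho_s = rho_s, rho_t = rho_t)
  dates <- as.character(seq(as.Date("2000-06-01"), by = "day",
                            length.out = n_t))
  w <- generate_weather(net$stations, dates, seed = seed)
  oz <- generate_ozone(w, net$stations, truth, seed = seed)
  list(panel = make_panel(oz, w, net$stations), truth = truth, net = net,
       weather = w, dates = dates)
}
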