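test_that("generators are deterministic under a fixed seed and vary across seeds", {
  n1 <- generate_network(10, 3, seed = 4)
  n2 <- generate_network(10, 3, seed = 4)
  n3 <- generate_network(10, 3, seed = 5)
  expect_identical(n1, n2)
  expect_false(isTRUE(all.equal(n1$stations$latitude,
                                n3$stations$latitude)))
  dates <- as.character(seq(as.Date("2000-06-01"), by = "day",
                            length.out = 10))
  w1 <- generate_weather(n1$stations, dates, seed = 4)
  expect_identical(w1, generate_weather(n1$stations, dates, seed = 4))
  truth <- synth_truth(sort(unique(n1$stations$state)), seed = 4)
  o1 <- generate_ozone(w1, n1$stations, truth, seed = 4)
  expect_identical(o1, generate_ozone(w1, n1$stations, truth, seed = 4))
  cs <- generate_community_series(n1$communities, 1999:2000, truth, seed = 4)
  m1 <- generate_mortality(cs, truth, seed = 4)
  expect_identical(m1, generate_mortality(cs, truth, seed = 4))
  expect_false(identical(m1$deaths,
                         generate_mortality(cs, truth, seed = 5)$deaths))
})

test_that("network communities are disjoint circles each holding a station", {
  net <- generate_network(12, 4, seed = 2)
  cm <- net$communities
  pc <- project_coords(cm$center_lat, cm$center_lon)
  d <- as.matrix(dist(pc))
  for (i in 1:3) for (j in (i + 1):4)
    expect_gt(d[i, j], cm$radius_km[i] + cm$radius_km[j])
  expect_true(all(cm$center_station %in% net$stations$station_id))
  expect_error(generate_network(10, 3, bbox = c(-80, -80, 30, 37)),
               "degenerate")
  expect_error(generate_network(1, 1), "at least 2")
})

test_that("weather reduces to the seasonal mean surface when noise is off", {
  net <- generate_network(5, 2, seed = 9)
  dates <- as.character(seq(as.Date("2000-05-01"), by = "day",
                            length.out = 20))
  w <- generate_weather(net$stations, dates, seed = 9,
                        field_sd = c(temperature = 0, ghi = 0,
                                     cloud_cover = 0),
                        nugget_sd = c(temperature = 0, ghi = 0,
                                      cloud_cover = 0))
  tv <- w[w$variable == "temperature", ]
  doy <- as.integer(format(as.Date(tv$date), "%j"))
  want <- 24.2 + 2 * sin(pi * pmin(pmax((doy - 121) / 152, 0), 1))
  expect_equal(tv$value, want)
  # same surface at every station
  expect_equal(length(unique(round(tv$value[tv$date == dates[5]], 10))), 1L)
})

test_that("weather long-run means match the configured regime", {
  net <- generate_network(10, 2, seed = 3)
  dates <- as.character(seq(as.Date("2000-05-01"), by = "day",
                            length.out = 153))
  w <- generate_weather(net$stations, dates, seed = 3)
  mt <- mean(w$value[w$variable == "temperature"])
  expect_lt(abs(mt - 24.2), 2.5)
  expect_lt(abs(mean(w$value[w$variable == "ghi"]) - 240), 30)
  expect_true(all(w$value[w$variable == "cloud_cover"] >= 0))
})

test_that("ozone equals the regression surface exactly in the noiseless limit", {
  net <- generate_network(6, 2, seed = 8)
  states <- sort(unique(net$stations$state))
  truth0 <- synth_truth(states, seed = 8, sigma2 = 0)
  dates <- as.character(seq(as.Date("2000-06-01"), by = "day",
                            length.out = 12))
  w <- generate_weather(net$stations, dates, seed = 8)
  oz <- generate_ozone(w, net$stations, truth0, seed = 8)
  # reconstruct X beta by hand for one station-day
  s1 <- net$stations$station_id[1]
  st <- net$stations$state[1]
  vals <- sapply(c("temperature", "ghi", "cloud_cover"), function(v)
    w$value[w$station_id == s1 & w$date == dates[3] & w$variable == v])
  b <- truth0$beta_r[st, ]
  want <- b["intercept"] + sum(b[c("temp_c", "ghi_wm2", "cloud_pct")] * vals)
  got <- oz$o3_mda8[oz$station_id == s1 & oz$date == dates[3]]
  expect_equal(got, unname(want))
})

test_that("ozone residual field matches the separable truth in Monte Carlo", {
  net <- generate_network(8, 2, seed = 6)
  states <- sort(unique(net$stations$state))
  # zero regression surface isolates the GP residual
  truth <- synth_truth(states, seed = 6,
                       beta_base = c(intercept = 0, temp_c = 0,
                                     ghi_wm2 = 0, cloud_pct = 0),
                       beta_state_sd = c(0, 0, 0, 0))
  dates <- as.character(seq(as.Date("2000-06-01"), by = "day",
                            length.out = 30))
  w <- generate_weather(net$stations, dates, seed = 6)
  lag1 <- var0 <- c()
  for (r in 1:40) {
    oz <- generate_ozone(w, net$stations, truth, seed = 600 + r)
    E <- matrix(oz$o3_mda8, 30, 8)
    var0 <- c(var0, mean(E^2))
    lag1 <- c(lag1, mean(E[-1, ] * E[-30, ]) / mean(E^2))
  }
  expect_lt(abs(mean(lag1) - exp(-1 / truth$rho_t)), 0.06)
  expect_lt(abs(mean(var0) - truth$sigma2) / truth$sigma2, 0.2)
})

test_that("climate-model distortion honours identity and zero-slope cases", {
  stations <- data.frame(station_id = "ST001", latitude = 33,
                         longitude = -85, state = "S01", variable = "ozone",
                         stringsAsFactors = FALSE)
  dates <- as.character(seq(as.Date("2000-06-01"), by = "day",
                            length.out = 40))
  w <- generate_weather(stations, dates, seed = 1)
  identity_bias <- list(
    temperature = c(intercept = 0, slope = 1, noise_sd = 0),
    ghi = c(intercept = 0, slope = 1, noise_sd = 0),
    cloud_cover = c(intercept = 0, slope = 1, noise_sd = 0))
  g <- distort_to_climate_output(w, stations, identity_bias,
                                 grid = list(nx = 2, ny = 2,
                                             bbox = c(-90, -80, 30, 37)),
                                 seed = 1)
  one <- g[g$cell_id == g$cell_id[1] & g$variable == "temperature", ]
  src <- w[w$variable == "temperature", ]
  expect_equal(one$value[match(src$date, one$date)], src$value)
  # slope zero: output carries no information about the truth
  flat_bias <- identity_bias
  flat_bias$temperature <- c(intercept = 5, slope = 0, noise_sd = 3)
  g0 <- distort_to_climate_output(w, stations, flat_bias,
                                  grid = list(nx = 1, ny = 1,
                                              bbox = c(-90, -80, 30, 37)),
                                  seed = 2)
  gt <- g0$value[g0$variable == "temperature"]
  expect_lt(cor(gt[match(src$date, g0$date[g0$variable == "temperature"])],
                src$value)^2, 0.15)
})

test_that("mortality counts follow the generative rate structure", {
  net <- generate_network(6, 2, seed = 12)
  states <- sort(unique(net$stations$state))
  # no covariate effects: counts are iid Poisson at the baseline rate
  truth <- synth_truth(states, seed = 12, rr = c(lag0 = 0, lag1 = 0,
                                                 lag2 = 0))
  cs <- generate_community_series(net$communities, 1998:2000, truth,
                                  seed = 12)
  m <- generate_mortality(cs, truth, seed = 12,
                          dow_effects = rep(0, 7), seasonal_amp = 0,
                          temp_coef = 0, dewpt_coef = 0)
  pop <- 770000
  expected_daily <- truth$baseline_rate * pop
  got <- sum(m$deaths) / (2 * 3 * 153)   # communities x summers x days
  expect_lt(abs(got - expected_daily) / expected_daily, 0.05)
  # doubling the baseline doubles expected counts
  truth2 <- synth_truth(states, seed = 12,
                        rr = c(lag0 = 0, lag1 = 0, lag2 = 0),
                        baseline_rate = 2 * truth$baseline_rate)
  m2 <- generate_mortality(cs, truth2, seed = 12, dow_effects = rep(0, 7),
                           seasonal_amp = 0, temp_coef = 0, dewpt_coef = 0)
  expect_lt(abs(sum(m2$deaths) / sum(m$deaths) - 2), 0.05)
  expect_error(synth_truth(states, baseline_rate = -1), "baseline_rate")
})

test_that("ground-truth record survives a write/read round trip", {
  truth <- synth_truth(c("S01", "S02"), seed = 3)
  tf <- tempfile(fileext = ".csv")
  write_truth(truth, tf)
  kv <- read_truth(tf)
  expect_equal(unname(kv["sigma2"]), truth$sigma2)
  expect_equal(unname(kv["rr_lag1"]), unname(truth$rr["lag1"]))
  expect_equal(unname(kv["S02:temp_c"]), unname(truth$beta_r["S02", "temp_c"]))
  unlink(tf)
})
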