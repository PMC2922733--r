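# Seeded generators for every input the pipeline consumes, with recorded
# ground truth: a 2-D monitor network, spatially coherent summer weather,
# ozone from the space-time regression with separable GP residuals,
# biased/noisy gridded "climate model" weather, and community mortality
# counts with known lag-specific log relative risks.
#
# One global integer seed fans out to per-generator seeds by fixed offsets
# (network +1, weather +2, ozone +3, climate distortion +4, mortality +5,
# MCMC +6, prediction +7; community series +8, hold-out selection +9).

#' Ground-truth parameter container for synthetic runs
#'
#' Collects every parameter the generators use, so recovery tests can
#' compare estimates against truth. Defaults mirror a realistic summer
#' regime for the southeastern US: mean ozone about 53 ppb, residual
#' variance 110.25 ppb^2 (sd 10.5), spatial decay 179 km, temporal decay
#' 1.83 days, and per-lag log relative risks (per ppb) of 0.00011, 0.00023,
#' 0.00011 at lags 0, 1, 2.
#'
#' @param states character vector of state labels used by the network.
#' @param seed integer seed for the per-state coefficient jitter.
#' @param sigma2,rho_s,rho_t residual GP truth (ppb^2, km, days).
#' @param beta_base named baseline coefficients (intercept ppb, temperature
#'   ppb per deg C, ghi ppb per W/m^2, cloud ppb per percent cloud).
#' @param beta_state_sd sd of the per-state jitter on each coefficient.
#' @param rr named per-lag log relative risks per ppb (lags 0-2).
#' @param baseline_rate deaths per person per summer day.
#' @param calib_bias list per weather variable of `c(intercept, slope,
#'   noise_sd)` describing how climate-model output distorts truth.
#' @return a list of class `synthetic_truth`.
#' @export
synth_truth <- function(states, seed = 1,
                        sigma2 = 110.25, rho_s = 179, rho_t = 1.83,
                        beta_base = c(intercept = 18.87, temp_c = 1.0,
                                      ghi_wm2 = 0.05, cloud_pct = -0.4),
                        beta_state_sd = c(2, 0.08, 0.004, 0.05),
                        rr = c(lag0 = 0.00011, lag1 = 0.00023,
                               lag2 = 0.00011),
                        baseline_rate = 26.9 / 1e4 / 153,
                        calib_bias = default_calib_bias()) {
  stopifnot(sigma2 >= 0, rho_s > 0, rho_t > 0, length(rr) == 3,
            baseline_rate > 0)
  seed_stream(seed, 11L)
  beta_r <- matrix(rep(beta_base, each = length(states)),
                   nrow = length(states),
                   dimnames = list(states, names(beta_base)))
  beta_r <- beta_r + matrix(stats::rnorm(length(beta_r)),
                            nrow = length(states)) %*% diag(beta_state_sd)
  structure(list(states = states, beta_r = beta_r, sigma2 = sigma2,
                 rho_s = rho_s, rho_t = rho_t, rr = rr,
                 baseline_rate = baseline_rate, calib_bias = calib_bias,
                 seed = seed),
            class = "synthetic_truth")
}

#' Default climate-model distortion parameters
#'
#' Intercept, slope and noise sd per variable, chosen so that the squared
#' correlation between truth and model output lands near the low agreement
#' seen in practice (about 0.25 for temperature, 0.03 for solar radiation,
#' 0.01 for cloud cover) given the weather generator's default variability.
#' @export
default_calib_bias <- function() {
  list(temperature = c(intercept = -1.0, slope = 1, noise_sd = 5.2),
       ghi = c(intercept = 10, slope = 1, noise_sd = 228),
       cloud_cover = c(intercept = 0.5, slope = 1, noise_sd = 29.8))
}

#' Write / read the ground-truth record
#'
#' Flat key-value CSV of the scalar truth parameters plus the per-state
#' coefficients; read back by recovery tests only.
#' @param truth a `synthetic_truth`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  kv <- data.frame(
    key = c("seed", "sigma2", "rho_s", "rho_t",
            paste0("rr_", names(truth$rr)), "baseline_rate",
            as.vector(outer(rownames(truth$beta_r),
                            colnames(truth$beta_r), paste, sep = ":"))),
    value = c(truth$seed, truth$sigma2, truth$rho_s, truth$rho_t,
              unname(truth$rr), truth$baseline_rate,
              as.vector(truth$beta_r)))
  utils::write.csv(kv, path, row.names = FALSE)
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  kv <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(kv$value, kv$key)
}

#' Generate a synthetic monitor network with communities
#'
#' Uniform random station locations in a lon/lat bounding box, each assigned
#' a state label by a longitude-strip partition of the box. Communities are
#' disjoint circular regions centred on a spread-out (greedy maximin) subset
#' of the stations, so each community contains at least one station.
#'
#' @param n_stations number of monitors (>= 2).
#' @param n_communities number of communities (each gets one centre station).
#' @param bbox `c(lon_min, lon_max, lat_min, lat_max)` in decimal degrees.
#' @param n_states number of longitude-strip states.
#' @param seed integer seed.
#' @return list with `stations` (station_id, latitude, longitude, state,
#'   variable) and `communities` (community_id, center_station, center_lat,
#'   center_lon, radius_km, state).
#' @export
generate_network <- function(n_stations = 15, n_communities = 3,
                             bbox = c(-90, -80, 30, 37), n_states = 3,
                             seed = 1) {
  if (n_stations < 2) stop("need at least 2 stations")
  if (n_communities < 1 || n_communities > n_stations)
    stop("n_communities must be between 1 and n_stations")
  if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3]) stop("degenerate bbox")
  seed_stream(seed, 1L)
  lon <- stats::runif(n_stations, bbox[1], bbox[2])
  lat <- stats::runif(n_stations, bbox[3], bbox[4])
  strip <- pmin(1L + floor((lon - bbox[1]) / (bbox[2] - bbox[1]) * n_states),
                n_states)
  stations <- data.frame(
    station_id = sprintf("ST%03d", seq_len(n_stations)),
    latitude = lat, longitude = lon,
    state = sprintf("S%02d", strip), variable = "ozone",
    stringsAsFactors = FALSE)
  pc <- project_coords(lat, lon)
  # greedy maximin selection of community centres among the stations
  centre <- integer(n_communities)
  centre[1] <- which.min((pc$x_km - mean(pc$x_km))^2 +
                         (pc$y_km - mean(pc$y_km))^2)
  if (n_communities > 1) {
    for (k in 2:n_communities) {
      d2 <- sapply(seq_len(n_stations), function(i)
        min((pc$x_km[i] - pc$x_km[centre[1:(k - 1)]])^2 +
            (pc$y_km[i] - pc$y_km[centre[1:(k - 1)]])^2))
      d2[centre[1:(k - 1)]] <- -Inf
      centre[k] <- which.max(d2)
    }
  }
  if (n_communities > 1) {
    dmin <- min(stats::dist(cbind(pc$x_km[centre], pc$y_km[centre])))
    radius <- min(0.4 * dmin, 60)
  } else radius <- 60
  communities <- data.frame(
    community_id = sprintf("C%02d", seq_len(n_communities)),
    center_station = stations$station_id[centre],
    center_lat = lat[centre], center_lon = lon[centre],
    radius_km = radius, state = stations$state[centre],
    stringsAsFactors = FALSE)
  list(stations = stations, communities = communities)
}

#' Generate daily summer weather at the monitor network
#'
#' Each variable is a seasonal sinusoid plus a spatially smooth Gaussian
#' field (exponential correlation) evolving as an AR(1) in time, plus
#' independent day-to-day noise. Cloud cover is truncated at zero. Defaults
#' centre temperature near 24.2 deg C, solar radiation near 240 W/m^2 and
#' cloud cover near 4.42%.
#'
#' @param stations station table from [generate_network()].
#' @param dates vector of ISO dates within May-September seasons.
#' @param seed integer seed.
#' @param means,seasonal_amp,field_sd,nugget_sd named per-variable levels.
#' @param ar1 day-to-day autocorrelation of the spatial field.
#' @param range_km spatial decay of the field correlation.
#' @return long data.frame `station_id, date, variable, value`.
#' @export
generate_weather <- function(stations, dates, seed = 1,
                             means = c(temperature = 24.2, ghi = 240,
                                       cloud_cover = 4.42),
                             seasonal_amp = c(temperature = 2, ghi = 25,
                                              cloud_cover = 1),
                             field_sd = c(temperature = 2, ghi = 25,
                                          cloud_cover = 2),
                             nugget_sd = c(temperature = 1.5, ghi = 22,
                                           cloud_cover = 2),
                             ar1 = 0.7, range_km = 200) {
  validate_stations(stations)
  dates <- sort(unique(as.Date(dates)))
  mo <- as.integer(format(dates, "%m"))
  if (any(mo < 5 | mo > 9))
    stop("dates must fall within May-September seasons")
  seed_stream(seed, 2L)
  n_s <- nrow(stations); n_t <- length(dates)
  pc <- project_coords(stations$latitude, stations$longitude)
  Us <- chol_jitter(exp(-as.matrix(stats::dist(pc)) / range_km))
  doy <- as.integer(format(dates, "%j"))
  season <- sin(pi * pmin(pmax((doy - 121) / 152, 0), 1))  # 0 at season ends
  out <- lapply(names(means), function(v) {
    E <- matrix(0, n_t, n_s)
    if (field_sd[[v]] > 0) {
      e <- as.vector(t(Us) %*% stats::rnorm(n_s))
      E[1, ] <- e
      for (t in 2:max(n_t, 2)) {
        if (t > n_t) break
        e <- ar1 * e + sqrt(1 - ar1^2) * as.vector(t(Us) %*% stats::rnorm(n_s))
        E[t, ] <- e
      }
      E <- E * field_sd[[v]]
    }
    if (nugget_sd[[v]] > 0)
      E <- E + matrix(stats::rnorm(n_t * n_s, 0, nugget_sd[[v]]), n_t, n_s)
    val <- means[[v]] + outer(season * seasonal_amp[[v]], rep(1, n_s)) + E
    if (v == "cloud_cover") val <- pmax(val, 0)
    data.frame(station_id = rep(stations$station_id, each = n_t),
               date = rep(as.character(dates), n_s),
               variable = v, value = as.vector(val),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate ozone from the space-time regression truth
#'
#' `Y = X beta_state + e` with `e` drawn from the mean-zero separable
#' exponential GP, sampled through the Kronecker factorization of the
#' space and time correlation roots.
#'
#' @param weather long weather table covering the full station-day grid.
#' @param stations station table (with `state`).
#' @param truth a [synth_truth()] object.
#' @param seed integer seed.
#' @return data.frame `station_id, date, o3_mda8`.
#' @export
generate_ozone <- function(weather, stations, truth, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  seed_stream(seed, 3L)
  dates <- sort(unique(weather$date))
  sids <- sort(unique(stations$station_id))
  n_s <- length(sids); n_t <- length(dates)
  wv <- function(v) {
    d <- weather[weather$variable == v, ]
    m <- matrix(NA_real_, n_t, n_s)
    m[cbind(match(d$date, dates), match(d$station_id, sids))] <- d$value
    if (anyNA(m)) stop("weather must be complete on the station-day grid")
    m
  }
  temp <- wv("temperature"); ghi <- wv("ghi"); cloud <- wv("cloud_cover")
  st <- stations$state[match(sids, stations$station_id)]
  b <- truth$beta_r[st, , drop = FALSE]
  mu <- matrix(rep(b[, "intercept"], each = n_t), n_t, n_s) +
    temp * matrix(rep(b[, "temp_c"], each = n_t), n_t, n_s) +
    ghi * matrix(rep(b[, "ghi_wm2"], each = n_t), n_t, n_s) +
    cloud * matrix(rep(b[, "cloud_pct"], each = n_t), n_t, n_s)
  if (truth$sigma2 > 0) {
    pc <- project_coords(stations$latitude[match(sids, stations$station_id)],
                         stations$longitude[match(sids, stations$station_id)])
    day_idx <- as.integer(as.Date(dates) - min(as.Date(dates)))
    Us <- chol_jitter(exp(-as.matrix(stats::dist(pc)) / truth$rho_s))
    Ut <- chol_jitter(exp(-abs(outer(day_idx, day_idx, "-")) / truth$rho_t))
    Z <- matrix(stats::rnorm(n_t * n_s), n_t, n_s)
    mu <- mu + sqrt(truth$sigma2) * (t(Ut) %*% Z %*% Us)
  }
  data.frame(station_id = rep(sids, each = n_t),
             date = rep(dates, n_s),
             o3_mda8 = as.vector(mu), stringsAsFactors = FALSE)
}

#' Distort weather into gridded "climate model" output
#'
#' Lays a regular grid of cell centres over the bounding box, treats each
#' centre as reporting the nearest station's true series, and applies the
#' per-variable linear bias plus noise `model = a + b * truth + noise`. The
#' default noise levels give the deliberately low truth-model agreement that
#' regional climate model output exhibits. A mean shift can be added to the
#' future temperature output to inject a climate-change signal.
#'
#' @param weather long weather table (truth).
#' @param stations station table.
#' @param calib_bias list per variable of `c(intercept, slope, noise_sd)`.
#' @param grid list with `nx`, `ny` and `bbox` (lon/lat).
#' @param seed integer seed.
#' @param temp_shift_model additive shift applied to the temperature model
#'   output (model-output units).
#' @return data.frame `cell_id, center_lat, center_lon, date, variable,
#'   value`.
#' @export
distort_to_climate_output <- function(weather, stations, calib_bias,
                                      grid = list(nx = 4, ny = 4,
                                                  bbox = c(-90, -80, 30, 37)),
                                      seed = 1, temp_shift_model = 0) {
  seed_stream(seed, 4L)
  gx <- seq(grid$bbox[1], grid$bbox[2], length.out = grid$nx + 1)
  gy <- seq(grid$bbox[3], grid$bbox[4], length.out = grid$ny + 1)
  cx <- (gx[-1] + gx[-length(gx)]) / 2
  cy <- (gy[-1] + gy[-length(gy)]) / 2
  cells <- expand.grid(center_lon = cx, center_lat = cy)
  cells$cell_id <- sprintf("G%03d", seq_len(nrow(cells)))
  # nearest station per cell (shared projection)
  all_pc <- project_coords(c(stations$latitude, cells$center_lat),
                           c(stations$longitude, cells$center_lon))
  ps <- all_pc[seq_len(nrow(stations)), ]
  pg <- all_pc[-seq_len(nrow(stations)), ]
  nearest <- apply(outer(pg$x_km, ps$x_km, "-")^2 +
                   outer(pg$y_km, ps$y_km, "-")^2, 1, which.min)
  out <- lapply(unique(weather$variable), function(v) {
    bias <- calib_bias[[v]]
    if (is.null(bias)) stop("no calibration bias parameters for ", v)
    w <- weather[weather$variable == v, ]
    res <- lapply(seq_len(nrow(cells)), function(i) {
      src <- w[w$station_id == stations$station_id[nearest[i]], ]
      val <- bias[["intercept"]] + bias[["slope"]] * src$value +
        stats::rnorm(nrow(src), 0, bias[["noise_sd"]])
      if (v == "temperature") val <- val + temp_shift_model
      data.frame(cell_id = cells$cell_id[i],
                 center_lat = cells$center_lat[i],
                 center_lon = cells$center_lon[i],
                 date = src$date, variable = v, value = val,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Generate community-level exposure and weather series
#'
#' Per community and summer (May 1 - September 30), daily ozone, mean
#' temperature and dew point as seasonal sinusoids plus AR(1) noise; dew
#' point is temperature minus a noisy offset. Ozone is scaled to the summer
#' regime of the monitor network (mean near 53 ppb, sd near 10, lag-1
#' autocorrelation matching the residual temporal decay).
#'
#' @param communities community table from [generate_network()].
#' @param years integer vector of summer years.
#' @param truth a [synth_truth()].
#' @param seed integer seed.
#' @param o3_mean,o3_sd,o3_seasonal_amp ozone regime.
#' @return data.frame `community, date, o3_mda8, temp_c, dewpt_c`.
#' @export
generate_community_series <- function(communities, years = 1987:2000,
                                      truth = NULL, seed = 1,
                                      o3_mean = 53.3, o3_sd = 10,
                                      o3_seasonal_amp = 4) {
  seed_stream(seed, 8L)
  phi_o3 <- if (is.null(truth)) exp(-1 / 1.83) else exp(-1 / truth$rho_t)
  out <- list()
  for (c_id in communities$community_id) {
    for (y in years) {
      dates <- seq(as.Date(sprintf("%d-05-01", y)),
                   as.Date(sprintf("%d-09-30", y)), by = "day")
      n <- length(dates)
      doy <- as.integer(format(dates, "%j"))
      season <- sin(pi * pmin(pmax((doy - 121) / 152, 0), 1))
      ar1 <- function(n, phi, sd) {
        e <- numeric(n)
        e[1] <- stats::rnorm(1, 0, sd)
        for (t in 2:n) e[t] <- phi * e[t - 1] + stats::rnorm(1, 0,
                                                 sd * sqrt(1 - phi^2))
        e
      }
      o3 <- o3_mean + o3_seasonal_amp * season + ar1(n, phi_o3, o3_sd)
      temp <- 24.2 + 2 * season + ar1(n, 0.7, 2.5)
      dew <- temp - (5 + stats::rnorm(n, 0, 1))
      out[[length(out) + 1L]] <- data.frame(
        community = c_id, date = as.character(dates),
        o3_mda8 = pmax(o3, 0), temp_c = temp, dewpt_c = dew,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Generate daily mortality counts from the health-model truth
#'
#' Counts are Poisson with log rate equal to an age-stratum baseline plus
#' the lag 0-2 ozone terms at the truth's log relative risks, day-of-week
#' effects, a smooth seasonal term, and mild temperature and dew-point
#' terms. Exposure lags never cross a summer boundary; within the first two
#' days of a summer the unavailable lags fall back to the same-day value
#' (those rows are dropped again by the lagged health fits).
#'
#' @param series community series from [generate_community_series()].
#' @param truth a [synth_truth()].
#' @param seed integer seed.
#' @param population community population.
#' @param pop_shares,death_shares per-stratum population and death shares
#'   for the strata `<65`, `65-74`, `>=75`.
#' @param dow_effects length-7 log-rate day-of-week effects (Sun..Sat).
#' @param seasonal_amp,temp_coef,dewpt_coef confounder effect sizes.
#' @return data.frame `community, date, age_group, deaths, o3_mda8, temp_c,
#'   dewpt_c`.
#' @export
generate_mortality <- function(series, truth, seed = 1,
                               population = 770000,
                               pop_shares = c(0.92, 0.05, 0.03),
                               death_shares = c(0.30, 0.25, 0.45),
                               dow_effects = c(0.01, -0.01, 0, 0.005,
                                               -0.005, 0.01, -0.01),
                               seasonal_amp = 0.05, temp_coef = 0.002,
                               dewpt_coef = 0.001) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (truth$baseline_rate <= 0) stop("negative or zero baseline rate")
  seed_stream(seed, 5L)
  ages <- c("under65", "65to74", "75plus")
  out <- list()
  for (c_id in unique(series$community)) {
    d <- series[series$community == c_id, ]
    d <- d[order(d$date), ]
    dt <- as.Date(d$date)
    summer <- format(dt, "%Y")
    lag_k <- function(x, k) {
      out <- c(rep(NA_real_, k), x[seq_len(length(x) - k)])
      same <- c(rep(FALSE, k),
                summer[seq_len(length(x) - k)] ==
                  summer[(k + 1):length(x)])
      out[!same] <- NA_real_
      out
    }
    x0 <- d$o3_mda8
    x1 <- lag_k(x0, 1); x1[is.na(x1)] <- x0[is.na(x1)]
    x2 <- lag_k(x0, 2); x2[is.na(x2)] <- x0[is.na(x2)]
    doy <- as.integer(format(dt, "%j"))
    dow <- as.POSIXlt(dt)$wday + 1L
    log_rel <- truth$rr[["lag0"]] * x0 + truth$rr[["lag1"]] * x1 +
      truth$rr[["lag2"]] * x2 + dow_effects[dow] +
      seasonal_amp * cos(2 * pi * (doy - 200) / 365) +
      temp_coef * (d$temp_c - 24.2) + dewpt_coef * (d$dewpt_c - 19.2)
    for (g in seq_along(ages)) {
      rate_g <- death_shares[g] * truth$baseline_rate * population /
        (pop_shares[g] * population)
      mu <- pop_shares[g] * population * rate_g * exp(log_rel)
      out[[length(out) + 1L]] <- data.frame(
        community = c_id, date = d$date, age_group = ages[g],
        deaths = stats::rpois(nrow(d), mu),
        o3_mda8 = d$o3_mda8, temp_c = d$temp_c, dewpt_c = d$dewpt_c,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
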