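# Exposure metrics and monitor linkage: MDA8, design values, coordinate
# projection, nearest-station joins, and CSV I/O for the tabular inputs.

KM_PER_DEG <- 111.32

#' Project longitude/latitude to planar kilometre coordinates
#'
#' Equirectangular projection about the latitude centroid of the input set:
#' `y = 111.32 * lat`, `x = 111.32 * lon * cos(lat0)`. Euclidean distances on
#' the projected plane approximate great-circle distances at regional scale,
#' which is what the space-time covariance needs.
#'
#' @param latitude,longitude numeric vectors of equal length, decimal degrees.
#' @param lat_origin reference latitude (degrees) for the cosine scaling;
#'   defaults to the mean latitude of the input set.
#' @return data.frame with columns `x_km`, `y_km`.
#' @examples
#' project_coords(c(33, 34), c(-84, -84))
#' @export
project_coords <- function(latitude, longitude, lat_origin = NULL) {
  if (length(latitude) == 0L) stop("no coordinates supplied")
  if (length(latitude) != length(longitude))
    stop("latitude and longitude must have equal length")
  if (any(!is.finite(latitude)) || any(abs(latitude) > 90))
    stop("latitude out of range [-90, 90]")
  if (any(!is.finite(longitude)) || any(abs(longitude) > 180))
    stop("longitude out of range [-180, 180]")
  if (is.null(lat_origin)) lat_origin <- mean(latitude)
  data.frame(
    x_km = KM_PER_DEG * longitude * cos(lat_origin * pi / 180),
    y_km = KM_PER_DEG * latitude
  )
}

validate_stations <- function(stations, what = "stations") {
  need <- c("station_id", "latitude", "longitude")
  if (!is.data.frame(stations) || !all(need %in% names(stations)))
    stop(what, " must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (nrow(stations) == 0L) stop(what, " is empty")
  invisible(stations)
}

#' Link each ozone monitor to its nearest covariate station
#'
#' Closest-distance linkage on the projected plane (common projection over
#' the union of both coordinate sets). If `covariate_stations` carries a
#' `variable` column, linkage is done separately within each variable. Ties
#' are broken by the lexicographically smallest covariate `station_id`.
#'
#' @param ozone_stations data.frame with `station_id`, `latitude`, `longitude`.
#' @param covariate_stations data.frame with `station_id`, `latitude`,
#'   `longitude` and optionally `variable`.
#' @return data.frame with columns `ozone_station_id`, `variable`,
#'   `covariate_station_id`, `distance_km`.
#' @export
nearest_link <- function(ozone_stations, covariate_stations) {
  validate_stations(ozone_stations, "ozone_stations")
  validate_stations(covariate_stations, "covariate_stations")
  if (!"variable" %in% names(covariate_stations))
    covariate_stations$variable <- "covariate"
  out <- lapply(unique(covariate_stations$variable), function(v) {
    cov_v <- covariate_stations[covariate_stations$variable == v, , drop = FALSE]
    cov_v <- cov_v[order(cov_v$station_id), , drop = FALSE]
    all_lat <- c(ozone_stations$latitude, cov_v$latitude)
    all_lon <- c(ozone_stations$longitude, cov_v$longitude)
    pc <- project_coords(all_lat, all_lon)
    n_o <- nrow(ozone_stations)
    po <- pc[seq_len(n_o), ]
    pv <- pc[-seq_len(n_o), ]
    d <- outer(po$x_km, pv$x_km, "-")^2 + outer(po$y_km, pv$y_km, "-")^2
    j <- apply(d, 1L, which.min)  # first minimum = smallest id (sorted)
    data.frame(
      ozone_station_id = ozone_stations$station_id,
      variable = v,
      covariate_station_id = cov_v$station_id[j],
      distance_km = sqrt(d[cbind(seq_len(n_o), j)]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Maximum daily 8-hour average ozone (MDA8) for one station-day
#'
#' Scans the 17 8-hour windows fully contained in the calendar day (start
#' hours 0 to 16). A window is valid when at least 6 of its 8 hourly values
#' are present (the 75% completeness rule); a valid window's mean uses the
#' available hours only. Returns the maximum over valid window means, or
#' `NA` when no window is valid.
#'
#' @param hour integer vector of hours (0-23), no duplicates.
#' @param concentration hourly ozone, ppb; `NA` for missing hours.
#' @return MDA8 in ppb, or `NA_real_`.
#' @examples
#' compute_mda8(0:23, rep(50, 24))
#' @export
compute_mda8 <- function(hour, concentration) {
  if (length(hour) != length(concentration))
    stop("hour and concentration must have equal length")
  if (length(hour) == 0L) return(NA_real_)
  if (any(!is.finite(hour)) || any(hour != floor(hour)) ||
      any(hour < 0) || any(hour > 23))
    stop("hour must be an integer in 0..23")
  if (anyDuplicated(hour)) stop("duplicated hour for one station-day")
  if (any(concentration < 0, na.rm = TRUE))
    stop("negative ozone concentration")
  by_hour <- rep(NA_real_, 24L)
  by_hour[hour + 1L] <- concentration
  best <- NA_real_
  for (s in 0:16) {
    w <- by_hour[s + 1:8]
    if (sum(!is.na(w)) >= 6L) {
      m <- mean(w, na.rm = TRUE)
      if (is.na(best) || m > best) best <- m
    }
  }
  best
}

#' Daily MDA8 series from hourly ozone records
#'
#' @param hourly data.frame with columns `station_id`, `date`, `hour`,
#'   `o3_ppb` (missing hours may be absent or `NA`).
#' @return data.frame `station_id`, `date`, `o3_mda8`, one row per
#'   station-day present in the input.
#' @export
mda8_series <- function(hourly) {
  need <- c("station_id", "date", "hour", "o3_ppb")
  if (!all(need %in% names(hourly)))
    stop("hourly ozone needs columns ", paste(need, collapse = ", "))
  key <- interaction(hourly$station_id, hourly$date, drop = TRUE)
  out <- do.call(rbind, lapply(split(hourly, key), function(d) {
    data.frame(station_id = d$station_id[1L], date = d$date[1L],
               o3_mda8 = compute_mda8(d$hour, d$o3_ppb),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$station_id, out$date), ]
}

#' Ozone design value over three consecutive years
#'
#' The regulatory design value is the 3-year mean of each year's
#' fourth-highest daily MDA8; attainment requires it not to exceed 75 ppb.
#'
#' @param mda8 daily MDA8 values (ppb), `NA` allowed.
#' @param year calendar year of each value; exactly 3 consecutive years.
#' @param threshold attainment threshold, ppb.
#' @return list with `design_value`, per-year `fourth_highest`,
#'   `threshold_ppb` and logical `attains`.
#' @export
design_value <- function(mda8, year, threshold = 75) {
  if (length(mda8) != length(year)) stop("mda8 and year lengths differ")
  yrs <- sort(unique(year))
  if (length(yrs) != 3L || !all(diff(yrs) == 1))
    stop("design value requires exactly 3 consecutive years")
  fourth <- vapply(yrs, function(y) {
    v <- sort(mda8[year == y & !is.na(mda8)], decreasing = TRUE)
    if (length(v) < 4L)
      stop("fewer than 4 valid daily values in year ", y)
    v[4L]
  }, numeric(1))
  names(fourth) <- yrs
  dv <- mean(fourth)
  structure(list(design_value = dv, fourth_highest = fourth,
                 threshold_ppb = threshold, attains = dv <= threshold),
            class = "oz_design_value")
}

#' @export
print.oz_design_value <- function(x, ...) {
  cat(sprintf("Ozone design value: %.1f ppb (threshold %.0f ppb, %s)\n",
              x$design_value, x$threshold_ppb,
              if (x$attains) "attains" else "exceeds"))
  invisible(x)
}

# ---- CSV I/O -------------------------------------------------------------
# All schemas use a header row, UTF-8, and empty fields for missing values.

read_csv_schema <- function(path, required) {
  d <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("file ", path, " is missing columns: ", paste(miss, collapse = ", "))
  d
}

#' Read/write the tabular input schemas
#'
#' Thin wrappers around [utils::read.csv()] / [utils::write.csv()] that
#' enforce the column schemas used throughout the package: stations
#' (`station_id, latitude, longitude, state, variable`), hourly ozone
#' (`station_id, date, hour, o3_ppb`), daily series
#' (`station_id, date, variable, value`), community mortality series
#' (`community, date, age_group, deaths, o3_mda8, temp_c, dewpt_c`),
#' gridded weather (`cell_id, center_lat, center_lon, date, variable, value`)
#' and county definitions (`county_id, center_lat, center_lon, radius_km`).
#' Missing values are encoded as empty fields.
#'
#' @param path file path.
#' @return a data.frame (readers) or the input, invisibly (writer).
#' @name oz_io
NULL

#' @rdname oz_io
#' @export
read_stations <- function(path)
  read_csv_schema(path, c("station_id", "latitude", "longitude", "state"))

#' @rdname oz_io
#' @export
read_hourly_ozone <- function(path)
  read_csv_schema(path, c("station_id", "date", "hour", "o3_ppb"))

#' @rdname oz_io
#' @export
read_daily_series <- function(path)
  read_csv_schema(path, c("station_id", "date", "variable", "value"))

#' @rdname oz_io
#' @export
read_community_series <- function(path)
  read_csv_schema(path, c("community", "date", "age_group", "deaths",
                          "o3_mda8", "temp_c", "dewpt_c"))

#' @rdname oz_io
#' @export
read_grid_weather <- function(path)
  read_csv_schema(path, c("cell_id", "center_lat", "center_lon", "date",
                          "variable", "value"))

#' @rdname oz_io
#' @export
read_counties <- function(path)
  read_csv_schema(path, c("county_id", "center_lat", "center_lon", "radius_km"))

#' @rdname oz_io
#' @param x data.frame to write.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(x)
}
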