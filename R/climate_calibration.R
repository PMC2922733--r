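# Regression calibration of climate-model weather: per-county, per-variable
# ordinary least squares of observed weather on model output over a
# reference year; the fitted value is the calibrated projection. Model
# output is treated as an error-prone version of the unobserved truth and
# the observed series as validation data.

#' Fit a linear calibration of observed weather on model output
#'
#' Ordinary least squares of the observed series on the date-aligned model
#' output. When the model output carries no information (zero variance or a
#' non-finite slope) the fit collapses to the observed mean (slope 0), which
#' is also what a near-zero estimated slope produces naturally — the typical
#' behaviour for cloud cover, where the calibrated projection is simply the
#' reference-year average.
#'
#' @param observed data.frame with columns `date`, `value` (observed).
#' @param model_output data.frame with columns `date`, `value` (climate
#'   model).
#' @param county_id,variable identifiers stored on the fit.
#' @return a `calibration_fit`: intercept, slope, r2, n_days,
#'   reference_mean.
#' @export
fit_calibration <- function(observed, model_output, county_id = NA_character_,
                            variable = NA_character_) {
  m <- merge(observed[, c("date", "value")],
             model_output[, c("date", "value")],
             by = "date", suffixes = c("_obs", "_mod"))
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3L) stop("fewer than 3 matched observed/model pairs")
  x <- m$value_mod; yv <- m$value_obs
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) {
    slope <- 0; intercept <- mean(yv); r2 <- 0
  } else {
    slope <- stats::cov(x, yv) / vx
    intercept <- mean(yv) - slope * mean(x)
    if (!is.finite(slope)) {
      slope <- 0; intercept <- mean(yv); r2 <- 0
    } else {
      r2 <- if (stats::var(yv) == 0) 0 else stats::cor(x, yv)^2
    }
  }
  structure(list(county_id = county_id, variable = variable,
                 intercept = intercept, slope = slope, r2 = r2,
                 n_days = nrow(m), reference_mean = mean(yv)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "Calibration %s / %s: intercept %.3f, slope %.3f, r2 %.3f (n = %d)\n",
    x$county_id, x$variable, x$intercept, x$slope, x$r2, x$n_days))
  invisible(x)
}

#' Apply a calibration fit to future model output
#'
#' Returns `intercept + slope * value` per day, preserving units; cloud
#' cover is truncated at zero.
#'
#' @param fit a [fit_calibration()] result.
#' @param future_model_output data.frame with `date`, `value` and optionally
#'   `variable` (checked against the fit when present).
#' @return the input with `value` replaced by the calibrated series.
#' @export
apply_calibration <- function(fit, future_model_output) {
  stopifnot(inherits(fit, "calibration_fit"))
  if ("variable" %in% names(future_model_output) && !is.na(fit$variable)) {
    v <- unique(future_model_output$variable)
    if (length(v) != 1L || v != fit$variable)
      stop("variable mismatch: fit is for ", fit$variable)
  }
  out <- future_model_output
  out$value <- fit$intercept + fit$slope * out$value
  if (identical(fit$variable, "cloud_cover")) out$value <- pmax(out$value, 0)
  out
}

#' Aggregate gridded output to counties
#'
#' County value per date and variable is the unweighted mean over grid cells
#' whose centres fall inside the county's circular region; counties that
#' contain no cell centre use the nearest centre instead.
#'
#' @param grid_table data.frame `cell_id, center_lat, center_lon, date,
#'   variable, value`.
#' @param county_definitions data.frame `county_id, center_lat, center_lon,
#'   radius_km`.
#' @return data.frame `county_id, date, variable, value`.
#' @export
link_grid_to_county <- function(grid_table, county_definitions) {
  if (nrow(grid_table) == 0L) stop("empty grid table")
  cells <- unique(grid_table[, c("cell_id", "center_lat", "center_lon")])
  pc <- project_coords(c(cells$center_lat, county_definitions$center_lat),
                       c(cells$center_lon, county_definitions$center_lon))
  n_cell <- nrow(cells)
  pcell <- pc[seq_len(n_cell), ]
  pcty <- pc[-seq_len(n_cell), ]
  out <- lapply(seq_len(nrow(county_definitions)), function(i) {
    d <- sqrt((pcell$x_km - pcty$x_km[i])^2 + (pcell$y_km - pcty$y_km[i])^2)
    inside <- cells$cell_id[d <= county_definitions$radius_km[i]]
    if (length(inside) == 0L) inside <- cells$cell_id[which.min(d)]
    g <- grid_table[grid_table$cell_id %in% inside, ]
    agg <- stats::aggregate(value ~ date + variable, data = g, FUN = mean)
    data.frame(county_id = county_definitions$county_id[i],
               date = agg$date, variable = agg$variable, value = agg$value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
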