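test_that("projection reproduces local spherical geometry", {
  p <- project_coords(c(33, 33), c(-84, -84))
  expect_equal(dist(p)[1], 0)
  p <- project_coords(c(33, 34), c(-84, -84))
  expect_equal(dist(p)[1], 111.32, tolerance = 1e-8)
  # collinear, equally spaced points: pairwise distances in ratio 1:1:2
  p <- project_coords(c(30, 31, 32), c(-85, -85, -85))
  d <- as.matrix(dist(p))
  expect_equal(d[1, 2], d[2, 3])
  expect_equal(d[1, 3], 2 * d[1, 2])
  expect_error(project_coords(numeric(0), numeric(0)), "no coordinates")
  expect_error(project_coords(95, 0), "latitude")
  expect_error(project_coords(0, 181), "longitude")
})

test_that("projected distances are symmetric and satisfy the triangle inequality", {
  set.seed(42)
  for (rep in 1:5) {
    p <- project_coords(runif(6, 25, 40), runif(6, -95, -75))
    d <- as.matrix(dist(p))
    expect_equal(d, t(d))
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
  }
})

test_that("nearest_link matches a brute-force search and ignores row order", {
  set.seed(7)
  oz <- data.frame(station_id = sprintf("O%d", 1:5),
                   latitude = runif(5, 30, 36), longitude = runif(5, -89, -81))
  cv <- data.frame(station_id = sprintf("C%d", 1:4),
                   latitude = runif(4, 30, 36), longitude = runif(4, -89, -81),
                   variable = "temperature")
  lk <- nearest_link(oz, cv)
  # oracle: exhaustive search over all pairs on the shared projection
  pc <- project_coords(c(oz$latitude, cv$latitude),
                       c(oz$longitude, cv$longitude))
  for (i in 1:5) {
    d <- sqrt((pc$x_km[i] - pc$x_km[6:9])^2 + (pc$y_km[i] - pc$y_km[6:9])^2)
    expect_equal(lk$covariate_station_id[i], cv$station_id[which.min(d)])
    expect_equal(lk$distance_km[i], min(d))
  }
  # row-order invariance
  lk2 <- nearest_link(oz[5:1, ], cv[c(3, 1, 4, 2), ])
  m <- merge(lk, lk2, by = "ozone_station_id")
  expect_equal(m$covariate_station_id.x, m$covariate_station_id.y)
})

test_that("nearest_link degenerate cases: single covariate, colocation, ties", {
  oz <- data.frame(station_id = c("O1", "O2"),
                   latitude = c(31, 35), longitude = c(-88, -82))
  one <- data.frame(station_id = "C1", latitude = 33, longitude = -85)
  lk <- nearest_link(oz, one)
  expect_true(all(lk$covariate_station_id == "C1"))
  # colocated station wins with distance 0
  cv <- data.frame(station_id = c("CB", "CA"),
                   latitude = c(31, 35), longitude = c(-88, -82))
  lk <- nearest_link(oz, cv)
  expect_equal(lk$covariate_station_id, c("CB", "CA"))
  expect_equal(lk$distance_km, c(0, 0))
  # exact tie broken by lexicographically smallest id
  tie <- data.frame(station_id = c("CZ", "CA"),
                    latitude = c(33, 33), longitude = c(-85, -85))
  lk <- nearest_link(oz[1, ], tie)
  expect_equal(lk$covariate_station_id, "CA")
})

test_that("MDA8 applies the 75 percent completeness rule within the day", {
  expect_equal(compute_mda8(0:23, rep(50, 24)), 50)
  expect_equal(compute_mda8(0:23, c(rep(10, 8), rep(80, 16))), 80)
  # every 8-hour window holds exactly 5 of 8 values: below 6, so missing
  hrs <- c(0:4, 8:12, 16:20)
  expect_true(is.na(compute_mda8(hrs, rep(60, length(hrs)))))
  # a 6-of-8 window is valid and averages the present hours only
  expect_equal(compute_mda8(0:5, c(30, 30, 30, 60, 60, 60)), 45)
  expect_error(compute_mda8(c(0, 24), c(1, 2)), "0..23")
  expect_error(compute_mda8(c(3, 3), c(1, 2)), "duplicated")
  expect_error(compute_mda8(0:2, c(1, -2, 3)), "negative")
})

test_that("MDA8 equals the brute-force window oracle and is monotone", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(6:24, 1)
    hrs <- sort(sample(0:23, n))
    conc <- round(runif(n, 0, 120), 1)
    conc[runif(n) < 0.3] <- NA
    got <- compute_mda8(hrs, conc)
    want <- mda8_oracle(hrs, conc)
    expect_equal(got, want)
    # raising one present value never decreases the output
    if (!is.na(got) && any(!is.na(conc))) {
      j <- which(!is.na(conc))[1]
      conc2 <- conc; conc2[j] <- conc2[j] + 50
      expect_gte(compute_mda8(hrs, conc2), got)
    }
  }
})

test_that("design value is the 3-year mean of yearly fourth-highest MDA8", {
  vals <- c(80, 70, 60, 50, 40, 30)
  dv <- design_value(rep(vals, 3), rep(2000:2002, each = 6))
  expect_equal(dv$design_value, 50)
  expect_true(dv$attains)
  dv <- design_value(c(90, 85, 82, 60, 95, 88, 84, 70, 99, 92, 86, 80),
                     rep(2000:2002, each = 4))
  expect_equal(dv$design_value, mean(c(60, 70, 80)))
  expect_equal(unname(dv$fourth_highest), c(60, 70, 80))
  # randomized series against a sort-based oracle
  set.seed(3)
  for (rep in 1:20) {
    y <- rep(2001:2003, each = 30)
    v <- runif(90, 20, 110)
    v[runif(90) < 0.2] <- NA
    want <- mean(sapply(2001:2003, function(yy)
      sort(v[y == yy & !is.na(v)], decreasing = TRUE)[4]))
    expect_equal(design_value(v, y)$design_value, want)
  }
  expect_error(design_value(c(1, 2, 3), c(2000, 2001, 2002)), "fewer than 4")
  expect_error(design_value(1:8, rep(c(2000, 2003), 4)), "consecutive")
})

test_that("hourly-to-daily MDA8 series and CSV I/O round-trip", {
  hourly <- expand.grid(station_id = c("A", "B"), date = "2000-06-01",
                        hour = 0:23, stringsAsFactors = FALSE)
  hourly$o3_ppb <- ifelse(hourly$station_id == "A", 40, 55)
  ds <- mda8_series(hourly)
  expect_equal(ds$o3_mda8, c(40, 55))
  tf <- tempfile(fileext = ".csv")
  hourly$o3_ppb[1] <- NA
  write_table_csv(hourly, tf)
  back <- read_hourly_ozone(tf)
  expect_equal(back$o3_ppb, hourly$o3_ppb)
  expect_error(read_stations(tf), "missing columns")
  unlink(tf)
})
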