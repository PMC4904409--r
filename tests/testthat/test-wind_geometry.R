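t0 <- as.numeric(as.POSIXct("2013-08-01 08:00:00", tz = "UTC"))

random_field <- function(seed) {
  set.seed(seed)
  x <- sort(runif(4, -5, 5)); y <- sort(runif(3, -5, 5))
  z <- sort(runif(4, 0, 2000)); tt <- t0 + sort(runif(3, 0, 3600))
  dims <- c(4, 3, 4, 3)
  wind_field(x, y, z, tt,
             array(rnorm(prod(dims)), dims),
             array(rnorm(prod(dims)), dims),
             array(abs(rnorm(prod(dims))), dims),
             origin = c(35, 31))
}

test_that("wind interpolation is multilinear and matches the nested oracle", {
  cfg <- sim_config(seed = 1, wind_profile = data.frame(alt = c(0, 2000),
                                                        u = c(3, 3), v = c(0, 0)))
  f <- simulate_wind_field(cfg, list(x = c(-3000, 3000), y = c(-3000, 3000),
                                     t = c(t0, t0 + 3600)))
  w <- interpolate_wind(f, 35.01, 31.005, 777, t0 + 1234)
  expect_equal(w$u, 3, tolerance = 1e-12)
  expect_equal(w$v, 0, tolerance = 1e-12)
  # midpoint between z-levels with U 0 and 4 interpolates to 2
  cfg2 <- sim_config(seed = 1, wind_profile = data.frame(alt = c(0, 1000),
                                                         u = c(0, 4), v = c(0, 0)))
  f2 <- simulate_wind_field(cfg2, list(x = c(-2000, 2000), y = c(-2000, 2000),
                                       t = c(t0, t0 + 600)))
  expect_equal(interpolate_wind(f2, 35, 31, 500, t0 + 300)$u, 2, tolerance = 1e-12)
  # random grids: agreement with brute-force nested 1-D interpolation
  for (sd in 1:5) {
    fld <- random_field(sd)
    qx <- runif(1, min(fld$x), max(fld$x))
    qy <- runif(1, min(fld$y), max(fld$y))
    qz <- runif(1, min(fld$z), max(fld$z))
    qt <- runif(1, min(fld$t), max(fld$t))
    ll <- aeqd_unproject(qx * 1000, qy * 1000, fld$origin)
    got <- interpolate_wind(fld, ll$lon, ll$lat, qz, qt)
    expect_lt(abs(got$u - ref_interp(fld, "U", qx, qy, qz, qt)), 1e-12)
    expect_lt(abs(got$v - ref_interp(fld, "V", qx, qy, qz, qt)), 1e-12)
    expect_lt(abs(got$tke - ref_interp(fld, "TKE", qx, qy, qz, qt)), 1e-12)
  }
})

test_that("temporal extrapolation errors; spatial edge queries clamp", {
  fld <- random_field(7)
  ll <- aeqd_unproject(mean(fld$x) * 1000, mean(fld$y) * 1000, fld$origin)
  expect_error(interpolate_wind(fld, ll$lon, ll$lat, 100, max(fld$t) + 500),
               "time span")
  far <- aeqd_unproject((max(fld$x) + 50) * 1000, mean(fld$y) * 1000, fld$origin)
  w <- interpolate_wind(fld, far$lon, far$lat, 100, mean(fld$t))
  expect_true(is.finite(w$u))
  expect_gte(attr(w, "n_clamped"), 1)
})

test_that("wind decomposition is an exact orthogonal decomposition", {
  # collinear: ground (10,0), wind (2,0)
  d <- decompose_wind(10, 0, 2, 0)
  expect_equal(d$airspeed, 8)
  expect_equal(d$wind_support, 2)
  expect_equal(d$side_wind, 0)
  # perpendicular: ground (10,0), wind (0,3)
  d2 <- decompose_wind(10, 0, 0, 3)
  expect_equal(d2$wind_support, 0)
  expect_equal(abs(d2$side_wind), 3)
  expect_equal(d2$airspeed, sqrt(109))
  # calm wind identity
  d3 <- decompose_wind(7, -4, 0, 0)
  expect_equal(d3$airspeed, sqrt(49 + 16))
  expect_equal(d3$wind_support, 0)
  expect_equal(d3$side_wind, 0)
  # conservation and Pythagoras on random inputs
  set.seed(3)
  for (i in 1:20) {
    g <- rnorm(2, 0, 8); w <- rnorm(2, 0, 4)
    if (sqrt(sum(g^2)) < 1e-6) next
    dd <- decompose_wind(g[1], g[2], w[1], w[2])
    expect_equal(c(dd$air_u + w[1], dd$air_v + w[2]), g, tolerance = 1e-12)
    expect_equal(dd$wind_support^2 + dd$side_wind^2, sum(w^2), tolerance = 1e-9)
  }
  # sign convention: heading north, wind from the west (blowing east) is
  # positive side-wind (wind from the bird's left)
  expect_gt(decompose_wind(0, 10, 3, 0)$side_wind, 0)
  expect_error(decompose_wind(0, 0, 1, 1), "zero ground velocity")
})

test_that("circling direction follows the signed net turn", {
  h_cw <- helix_fixes(helix_s = 70, cw = TRUE)
  h_cc <- helix_fixes(helix_s = 70, cw = FALSE)
  seg <- function(h) {
    data.frame(bird_id = "b1", mode = "thermal",
               i0 = h$helix_idx[1], i1 = h$helix_idx[length(h$helix_idx)])
  }
  expect_equal(as.character(circling_direction(seg(h_cw), h_cw$fixes)), "CW")
  expect_equal(as.character(circling_direction(seg(h_cc), h_cc$fixes)), "CCW")
  # mirrored track flips the label
  m <- h_cw$fixes
  fm <- fixes_from_xy(-m$x, m$y, m$altitude_agl)
  expect_equal(as.character(circling_direction(seg(h_cw), fm)), "CCW")
  # net turn equals full loops times 360 degrees
  net <- attr(circling_direction(seg(h_cw), h_cw$fixes), "net_turn")
  expect_equal(net, 360 * (69 / 20), tolerance = 0.05 * 360 * (69 / 20))
  # short arcs are indeterminate
  h_short <- helix_fixes(helix_s = 6, period = 30)
  expect_warning(d <- circling_direction(seg(h_short), h_short$fixes),
                 "indeterminate")
  expect_true(is.na(d))
})

test_that("flight-versus-wind angle uses the headwind-zero convention", {
  wind_from <- function(from_deg, speed = 5) {
    toward <- (from_deg + 180) %% 360
    data.frame(direction_toward = toward, speed = speed)
  }
  expect_equal(relative_flight_angle(0, wind_from(0)), 0)
  expect_equal(abs(relative_flight_angle(0, wind_from(180))), 180)
  expect_equal(abs(relative_flight_angle(90, wind_from(0))), 90)
  # circular continuity across the wrap
  expect_equal(relative_flight_angle(359.9, wind_from(0)),
               -0.1, tolerance = 1e-9)
  # odd under reflection (swapping the side the wind comes from)
  a <- relative_flight_angle(40, wind_from(10))
  b <- relative_flight_angle(320, wind_from(350))
  expect_equal(a, -b, tolerance = 1e-9)
  # calm wind is undefined
  expect_true(is.na(relative_flight_angle(10, wind_from(0, speed = 0))))
})

test_that("lee/windward partition projects onto the wind axis", {
  h <- helix_fixes(helix_s = 80, radius = 30, period = 20, drift = c(3, 0))
  seg <- data.frame(bird_id = "b1", mode = "thermal",
                    i0 = h$helix_idx[1], i1 = h$helix_idx[80])
  wdf <- data.frame(u = rep(3, 80), v = rep(0, 80))
  p <- lee_windward_partition(seg, h$fixes, wdf)
  expect_setequal(unique(p$side), c("lee", "windward"))
  # fixes east (downwind) of the centre are lee: the drift-compensated
  # helix is a circle about the origin, so sign(x_dc) splits the sides
  # (fixes within 2 m of the dividing axis may fall either way)
  dcx <- 30 * cos(-2 * pi / 20 * seq_len(80))
  clear <- abs(dcx) > 2
  expect_equal(p$side[clear], ifelse(dcx > 0, "lee", "windward")[clear])
  # calm wind: withheld
  calm <- data.frame(u = rep(0, 80), v = rep(0, 80))
  expect_null(lee_windward_partition(seg, h$fixes, calm))
})

test_that("lee-enhanced thermals show higher lee-side climb", {
  s <- small_sim("lee", seed = 5, n_days = 1, thermals_per_day = 4,
                 lee_updraft_bias = 0.4,
                 wind_profile = data.frame(alt = c(0, 3000), u = c(4, 4), v = c(0, 0)))
  segs <- segment_track(s$pp$fixes)
  th <- segs[segs$mode == "thermal", ]
  wdf <- data.frame(u = 4, v = 0)
  lee <- numeric(0); wwd <- numeric(0)
  for (i in seq_len(nrow(th))) {
    p <- lee_windward_partition(th[i, , drop = FALSE], s$pp$fixes, wdf)
    lee <- c(lee, p$lee_climb); wwd <- c(wwd, p$windward_climb)
  }
  expect_gt(mean(lee), mean(wwd))
})

test_that("wind shear classes use the 2 and 6 m/s cut-points", {
  h <- helix_fixes(helix_s = 60)
  seg <- data.frame(bird_id = "b1", mode = "thermal",
                    i0 = h$helix_idx[1], i1 = h$helix_idx[60])
  shear_of <- function(u) {
    wind_shear_class(seg, data.frame(u = rep(u, 60), v = rep(0, 60)), h$fixes)
  }
  expect_equal(shear_of(1)$shear_class, "low")
  expect_equal(shear_of(4)$shear_class, "mid")
  expect_equal(shear_of(2)$shear_class, "mid")
  expect_equal(shear_of(6)$shear_class, "mid")
  expect_equal(shear_of(7)$shear_class, "high")
  expect_equal(shear_of(4)$wind_shear, 4)
})
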