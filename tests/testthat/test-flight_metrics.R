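test_that("best-glide and MacCready speeds match their closed forms", {
  p <- glide_polar(a = 0.01, b = 0, c = 1, v_range = c(1, 30))
  expect_equal(best_glide_speed(p), 10)
  # scaling c by 4 doubles the best-glide speed
  p4 <- glide_polar(a = 0.01, b = 0, c = 4, v_range = c(1, 40))
  expect_equal(best_glide_speed(p4), 20)
  # numeric argmax (golden-section-style oracle via optimize) agrees
  num <- optimize(function(v) v / (p$a * v^2 + p$c), c(1, 30), maximum = TRUE)$maximum
  expect_equal(best_glide_speed(p), num, tolerance = 1e-4)
  # MacCready: sqrt((c + climb)/a), reducing to best glide at zero climb
  expect_equal(maccready_speed(p, 1), sqrt(200), tolerance = 1e-12)
  expect_equal(maccready_speed(p, 0), best_glide_speed(p))
  climbs <- seq(0, 3, by = 0.5)
  v <- vapply(climbs, function(cl) maccready_speed(p, cl), numeric(1))
  expect_true(all(diff(v) > 0))
  expect_message(v0 <- maccready_speed(p, -1), "clamped")
  expect_equal(v0, best_glide_speed(p))
  expect_error(glide_polar(a = -1), "a > 0")
})

test_that("RAFI anchors at 1 (best glide) and 0 (MacCready) and is monotone", {
  p <- glide_polar(a = 0.01, b = 0, c = 1, v_range = c(1, 40))
  vbg <- best_glide_speed(p)
  vmc <- maccready_speed(p, 1.5)
  expect_equal(rafi(vbg, 1.5, p), 1)
  expect_equal(rafi(vmc, 1.5, p), 0)
  expect_equal(rafi((vbg + vmc) / 2, 1.5, p), 0.5)
  vs <- seq(vbg, vmc, length.out = 9)
  r <- vapply(vs, function(v) rafi(v, 1.5, p), numeric(1))
  expect_true(all(diff(r) < 0))
  # ratio definition and the zero-climb degenerate case
  expect_equal(rafi(2 * vbg, 1.5, p, definition = "ratio"), 0.5)
  expect_true(is.na(rafi(vbg, 0, p)))
})

test_that("climb rate is altitudinal change over duration, thermals only", {
  h <- helix_fixes(helix_s = 150, climb = 1.4, drift = c(1, 0))
  seg <- data.frame(bird_id = "b1", mode = "thermal",
                    i0 = h$helix_idx[1], i1 = h$helix_idx[150],
                    start_time = h$fixes$time[h$helix_idx[1]],
                    end_time = h$fixes$time[h$helix_idx[150]])
  ch <- characterize_segment(seg, h$fixes)
  expect_equal(climb_rate(ch), ch$altitudinal_change_m / ch$duration_s)
  glide <- ch; glide$mode <- "glide"
  expect_error(climb_rate(glide), "not a thermal")
})

test_that("circling radius is exactly drift-invariant without noise", {
  for (drift in list(c(0, 0), c(3, 0), c(2, -4))) {
    h <- helix_fixes(helix_s = 80, radius = 30, period = 20, drift = drift)
    seg <- data.frame(bird_id = "b1", mode = "thermal",
                      i0 = h$helix_idx[1], i1 = h$helix_idx[80])
    wdf <- data.frame(u = rep(drift[1], 80), v = rep(drift[2], 80))
    r <- circling_radius(seg, h$fixes, wdf)
    expect_equal(as.numeric(r), 30, tolerance = 1e-6)
  }
})

test_that("circling radius tolerates GPS noise and matches v/omega", {
  set.seed(31)
  rads <- replicate(8, {
    h <- helix_fixes(helix_s = 80, radius = 30, period = 20, drift = c(3, 0),
                     noise_sd = 3)
    seg <- data.frame(bird_id = "b1", mode = "thermal",
                      i0 = h$helix_idx[1], i1 = h$helix_idx[80])
    wdf <- data.frame(u = rep(3, 80), v = rep(0, 80))
    as.numeric(circling_radius(seg, h$fixes, wdf))
  })
  expect_lt(abs(mean(rads) - 30), 1)
  # kinematic cross-check on a clean helix: r = v_h / omega
  h <- helix_fixes(helix_s = 80, radius = 30, period = 20, drift = c(0, 0))
  seg <- data.frame(bird_id = "b1", mode = "thermal",
                    i0 = h$helix_idx[1], i1 = h$helix_idx[80],
                    start_time = h$fixes$time[h$helix_idx[1]],
                    end_time = h$fixes$time[h$helix_idx[80]])
  ch <- characterize_segment(seg, h$fixes)
  om <- ch$mean_angular_speed_degs * pi / 180
  r_kin <- ch$mean_horizontal_speed_ms / om
  wdf <- data.frame(u = rep(0, 80), v = rep(0, 80))
  r_fit <- as.numeric(circling_radius(seg, h$fixes, wdf))
  expect_lt(abs(r_kin - r_fit) / r_fit, 0.05)
  # less than one full loop: undefined
  h2 <- helix_fixes(helix_s = 15, radius = 30, period = 20)
  seg2 <- data.frame(bird_id = "b1", mode = "thermal",
                     i0 = h2$helix_idx[1], i1 = h2$helix_idx[15])
  expect_true(is.na(circling_radius(seg2, h2$fixes,
                                    data.frame(u = rep(0, 15), v = rep(0, 15)))))
})

test_that("soaring-gliding efficiency pairs thermals with following glides", {
  tmpl <- as.POSIXct("2013-08-01 08:00:00", tz = "UTC")
  segs <- data.frame(
    bird_id = "b1",
    mode = c("thermal", "glide", "thermal", "glide"),
    start_time = tmpl + c(0, 152, 400, 700),
    end_time = tmpl + c(149, 280, 620, 800),
    duration_s = c(150, 129, 221, 101),
    travel_distance_m = c(1500, 900, 2000, 1000)
  )
  eff <- soaring_gliding_efficiency(segs)
  # 900 m of glide after 150 s of climb: 6 m per second of climb; the
  # second pair exceeds the 10-s gap and is dropped
  expect_equal(nrow(eff), 1)
  expect_equal(eff$efficiency, 6)
  # no qualifying pairs
  expect_equal(nrow(soaring_gliding_efficiency(segs[c(1, 3), ])), 0)
})

test_that("efficiency recovery on simulated tracks is within 5%", {
  s <- small_sim("eff", seed = 41, n_days = 3,
                 thermal_duration = c(mean = 150, sd = 10),
                 glide_airspeed = 9.5)
  segs <- segment_track(s$pp$fixes)
  eff <- soaring_gliding_efficiency(segs)
  truth <- 900 / 150
  expect_lt(abs(mean(eff$efficiency) - truth) / truth, 0.05)
})

test_that("daily summaries compute path metrics and straightness correctly", {
  # straight out-leg only: straightness 1
  n <- 400
  f <- fixes_from_xy(10 * seq_len(n), rep(0, n), rep(200, n))
  segs0 <- data.frame(bird_id = character(), mode = character(),
                      start_time = as.POSIXct(character(), tz = "UTC"),
                      end_time = as.POSIXct(character(), tz = "UTC"),
                      duration_s = numeric(), travel_distance_m = numeric())
  d <- daily_summary(f, segs0)
  expect_equal(d$straightness, 1, tolerance = 1e-9)
  expect_equal(d$travel_distance_km, 10 * (n - 1) / 1000, tolerance = 1e-9)
  # out-and-back along the same path: maximum displacement is reached at
  # the turn-around, and distance *until* it equals the displacement
  x <- c(10 * seq_len(200), 10 * rev(seq_len(199)))
  f2 <- fixes_from_xy(x, rep(0, length(x)), rep(200, length(x)))
  d2 <- daily_summary(f2, segs0)
  expect_equal(d2$straightness, 1, tolerance = 1e-9)
  expect_equal(d2$max_displacement_km, 10 * 199 / 1000, tolerance = 1e-6)
  # all-passive bursts give flapping proportion zero
  s <- small_sim("io", seed = 10, n_days = 1, thermals_per_day = 3)
  b <- classify_flapping(s$trk$bursts)
  b$flap_label <- "passive"
  segs <- segment_track(s$pp$fixes)
  d3 <- daily_summary(s$pp$fixes, segs, b)
  expect_equal(d3$flapping_proportion, 0)
  expect_gte(d3$n_thermals, 1)
  # a day with fewer than 2 in-flight fixes is skipped
  slow <- fixes_from_xy(c(0, 1, 2), c(0, 0, 0), c(0, 0, 0))
  expect_error(daily_summary(slow, segs0), "no bird-day")
})

test_that("the foraging-day filter applies all three thresholds", {
  day <- data.frame(travel_distance_km = 150, straightness = 0.2,
                    max_displacement_km = 30)
  expect_true(foraging_day_filter(day))
  expect_false(foraging_day_filter(transform(day, travel_distance_km = 250)))
  expect_false(foraging_day_filter(transform(day, straightness = 0.8)))
  expect_false(foraging_day_filter(day, roost_distance_km = 80))
})

test_that("thermal-selection TKE averages the 1-km cells along the thermal", {
  h <- helix_fixes(helix_s = 60)
  seg <- data.frame(bird_id = "b1", mode = "thermal",
                    i0 = h$helix_idx[1], i1 = h$helix_idx[60])
  t0 <- as.numeric(h$fixes$time[1])
  cfg <- sim_config(seed = 1, tke_background = 1.2)
  ext <- list(x = range(h$fixes$x) + c(-2000, 2000),
              y = range(h$fixes$y) + c(-2000, 2000),
              t = c(t0 - 300, t0 + 600))
  f_uni <- simulate_wind_field(cfg, ext)
  expect_equal(thermal_selection_tke(seg, f_uni, h$fixes), 1.2, tolerance = 1e-12)
  # a TKE bump near the thermal raises the value above background
  cfgb <- sim_config(seed = 1, tke_background = 1.2,
                     tke_bumps = data.frame(x = mean(h$fixes$x[h$helix_idx]),
                                            y = 0, sigma = 1500, amplitude = 2))
  f_bump <- simulate_wind_field(cfgb, ext)
  v <- thermal_selection_tke(seg, f_bump, h$fixes)
  expect_gt(v, 1.2)
  # equality with brute-force per-fix averaging
  ii <- seg$i0:seg$i1
  w <- interpolate_wind(f_bump, h$fixes$lon[ii], h$fixes$lat[ii],
                        h$fixes$altitude_agl[ii], h$fixes$time[ii])
  expect_equal(v, mean(w$tke_1km), tolerance = 1e-12)
})
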