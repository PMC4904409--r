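# mock a preprocessed fix table carrying a prescribed smoothed
# vertical-speed series (for the trend-rule unit tests)
trend_fixes <- function(v) {
  n <- length(v)
  f <- fixes_from_xy(10 * seq_len(n + 1), rep(0, n + 1), rep(100, n + 1))
  f$vspeed_smooth <- c(NA, v)
  f
}

test_that("a drifting climbing helix yields exactly one covering thermal", {
  h <- helix_fixes(helix_s = 60, radius = 30, period = 20, climb = 1.3,
                   drift = c(2, 0))
  th <- detect_thermals(h$fixes)
  expect_equal(nrow(th), 1)
  covered <- sum(h$helix_idx >= th$i0 & h$helix_idx <= th$i1)
  expect_gte(covered / length(h$helix_idx), 0.9)
})

test_that("straight glides and sub-45-s loops yield no thermal", {
  n <- 200
  f <- fixes_from_xy(10 * seq_len(n), rep(0, n), 500 - 0.75 * seq_len(n))
  expect_equal(nrow(detect_thermals(f)), 0)
  h40 <- helix_fixes(helix_s = 40, radius = 30, period = 20, climb = 1.3,
                     drift = c(2, 0))
  expect_equal(nrow(detect_thermals(h40$fixes)), 0)
})

test_that("thermal detection is invariant to rigid rotation and translation", {
  h <- helix_fixes(helix_s = 70, radius = 32, period = 18, climb = 1.2,
                   drift = c(2, 1))
  th0 <- detect_thermals(h$fixes)
  a <- 37 * pi / 180
  x <- h$fixes$x; y <- h$fixes$y
  xr <- cos(a) * x - sin(a) * y + 5000
  yr <- sin(a) * x + cos(a) * y - 2000
  fr <- fixes_from_xy(xr, yr, h$fixes$altitude_agl)
  thr <- detect_thermals(fr)
  expect_equal(nrow(thr), nrow(th0))
  expect_equal(thr$i0, th0$i0, tolerance = 1e-8)
  expect_equal(thr$i1, th0$i1, tolerance = 1e-8)
})

test_that("trend runs split into glide and linear segments by the 90% rule", {
  # 100 samples all negative: one glide covering the whole run
  f <- trend_fixes(rep(-0.8, 100))
  tr <- detect_trend_segments(f, NULL)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$mode, "glide")
  expect_equal(as.numeric(tr$end_time) - as.numeric(tr$start_time) + 1, 100)
  # 92 negative with 8 positives interleaved still one glide (0.92 >= 0.90)
  v <- rep(-0.8, 100)
  v[seq(12, 96, by = 12)] <- 0.5
  tr2 <- detect_trend_segments(trend_fixes(v), NULL)
  expect_equal(nrow(tr2), 1)
  expect_equal(tr2$mode, "glide")
  # alternating signs: no segment survives
  v3 <- rep(c(0.5, -0.5), 50)
  expect_equal(nrow(detect_trend_segments(trend_fixes(v3), NULL)), 0)
  # positive trend labels linear soaring
  tr4 <- detect_trend_segments(trend_fixes(rep(1.2, 60)), NULL)
  expect_equal(tr4$mode, "linear")
})

test_that("edge trimming is greedy, terminating and matches the naive rule", {
  # 3 leading positives on a glide: start advances exactly 3 samples
  v <- c(0.5, 0.4, 0.3, rep(-0.8, 40))
  f <- trend_fixes(v)
  seg <- data.frame(bird_id = "b1", mode = "glide", i0 = 2L, i1 = length(v) + 1L,
                    start_time = f$time[2], end_time = f$time[length(v) + 1])
  out <- trim_segment_edges(seg, f)
  expect_equal(out$i0, seg$i0 + 3L)
  expect_equal(out$i1, seg$i1)
  # an already fully in-trend segment is unchanged
  v2 <- rep(-0.8, 30)
  f2 <- trend_fixes(v2)
  seg2 <- data.frame(bird_id = "b1", mode = "glide", i0 = 2L, i1 = 31L,
                     start_time = f2$time[2], end_time = f2$time[31])
  expect_equal(trim_segment_edges(seg2, f2)[c("i0", "i1")], seg2[c("i0", "i1")])
  # symmetric off-trend edges: both trimmed, agreeing with the independent
  # naive implementation on random cases
  set.seed(99)
  for (rep in 1:25) {
    v3 <- sample(c(-1, 1), 60, replace = TRUE, prob = c(0.75, 0.25))
    v3[1:3] <- 1
    v3[58:60] <- 1
    f3 <- trend_fixes(v3)
    seg3 <- data.frame(bird_id = "b1", mode = "glide", i0 = 2L, i1 = 61L,
                       start_time = f3$time[2], end_time = f3$time[61])
    got <- trim_segment_edges(seg3, f3, min_duration = 1)
    ref <- ref_trim(sign(v3), -1)
    expect_equal(got$i0 - 1L, ref[1])
    expect_equal(got$i1 - 1L, ref[2])
  }
  # trimming below the minimum duration voids the segment
  v4 <- c(rep(1, 6), rep(-1, 5), rep(1, 6))
  f4 <- trend_fixes(v4)
  seg4 <- data.frame(bird_id = "b1", mode = "glide", i0 = 2L, i1 = 18L,
                     start_time = f4$time[2], end_time = f4$time[18])
  expect_null(trim_segment_edges(seg4, f4, min_duration = 10))
})

test_that("segment characterisation matches kinematic ground truth", {
  # helix of radius 30 m and period 20 s turns at 18 deg/s
  h <- helix_fixes(helix_s = 80, radius = 30, period = 20, climb = 1.4,
                   drift = c(0, 0), glide_s = 12)
  seg <- data.frame(bird_id = "b1", mode = "thermal",
                    i0 = h$helix_idx[1], i1 = h$helix_idx[80],
                    start_time = h$fixes$time[h$helix_idx[1]],
                    end_time = h$fixes$time[h$helix_idx[80]])
  ch <- characterize_segment(seg, h$fixes)
  expect_equal(ch$mean_angular_speed_degs, 18, tolerance = 1e-6)
  # straight glide at 8 m/s for 100 s travels 800 m
  n <- 101
  f <- fixes_from_xy(8 * seq_len(n), rep(0, n), 500 - 0.75 * seq_len(n))
  seg2 <- data.frame(bird_id = "b1", mode = "glide", i0 = 1L, i1 = as.integer(n),
                     start_time = f$time[1], end_time = f$time[n])
  ch2 <- characterize_segment(seg2, f)
  expect_equal(ch2$travel_distance_m, 800, tolerance = 1e-9)
  # 210 m gained over 150 s of climb
  m <- 151
  hf <- helix_fixes(helix_s = m, radius = 30, period = 20, climb = 1.4, drift = c(1, 0))
  seg3 <- data.frame(bird_id = "b1", mode = "thermal",
                     i0 = hf$helix_idx[1], i1 = hf$helix_idx[m],
                     start_time = hf$fixes$time[hf$helix_idx[1]],
                     end_time = hf$fixes$time[hf$helix_idx[m]])
  ch3 <- characterize_segment(seg3, hf$fixes)
  expect_equal(ch3$altitudinal_change_m, 1.4 * (m - 1), tolerance = 1e-9)
  expect_equal(ch3$mean_vertical_speed_ms,
               ch3$altitudinal_change_m / ch3$duration_s, tolerance = 1e-12)
  # a degenerate single-fix segment is rejected
  seg4 <- seg3; seg4$i1 <- seg4$i0
  expect_error(characterize_segment(seg4, hf$fixes), "degenerate")
})

test_that("segments are pairwise disjoint and confined to flight", {
  s <- small_sim("seg", seed = 21, n_days = 2, thermals_per_day = 5)
  segs <- segment_track(s$pp$fixes)
  segs <- segs[order(segs$i0), ]
  if (nrow(segs) > 1) {
    expect_true(all(segs$i0[-1] > segs$i1[-nrow(segs)]))
  }
  expect_true(all(s$pp$fixes$in_flight[unlist(Map(seq, segs$i0, segs$i1))]))
})

test_that("noise-free mode recovery exceeds 95% for thermals and glides", {
  s <- small_sim("nf", seed = 22, n_days = 2, thermals_per_day = 6,
                 gps_noise_sd = 0, gps_noise_rho = 0)
  segs <- segment_track(s$pp$fixes)
  cm <- truth_confusion(s$trk, segs)
  expect_gte(cm["thermal", "thermal"] / sum(cm["thermal", ]), 0.95)
  expect_gte(cm["glide", "glide"] / sum(cm["glide", ]), 0.95)
})
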