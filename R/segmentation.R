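# Two-stage track segmentation:
#   1. thermal soaring: 2-D path self-intersection (loops), chained, merged
#      and snapped to the enclosing contiguous circling arc;
#   2. gliding / linear soaring: maximal runs in which >= 90% of smoothed
#      vertical-speed samples share a sign, with greedy edge trimming.
# Segment fix ranges are half-open in spirit: a segment covering fixes
# [i0, i1] has duration i1 - i0 + 1 seconds at the 1-Hz cadence.

default_seg_config <- function() {
  list(
    seg.min_thermal_s = 45,
    seg.lookback_s = 120,
    seg.trend_fraction = 0.9,
    seg.min_trend_s = 10,
    seg.merge_gap_s = 10,
    seg.break_run_s = 5,
    seg.extend_min_turn_degs = 8,
    seg.turn_patience_s = 2,
    seg.absorb_gap_s = 5
  )
}

# cross-product orientation of R relative to segment PQ
.ccw <- function(px, py, qx, qy, rx, ry) {
  (qx - px) * (ry - py) - (qy - py) * (rx - px)
}

#' Detect thermal-soaring segments by 2-D path self-intersection
#'
#' Within each contiguous 1-Hz in-flight stretch, every step segment
#' (p[i-1], p[i]) is tested for proper intersection against earlier step
#' segments inside a trailing `lookback` window. Chains of crossings that
#' overlap or fall within `merge_gap` seconds of each other are merged into
#' candidate circling events; each event's boundaries are then snapped to
#' the maximal contiguous arc of consistent signed turning (minimum turn
#' rate `min_turn` deg/s, tolerating up to `patience` seconds of
#' sub-threshold turning) that contains the crossings, since a closed loop
#' is only evidence of circling that began up to one circle earlier. An
#' event is a thermal iff its duration exceeds `min_duration` seconds and
#' its net altitude change is positive.
#'
#' @param fixes preprocessed fixes (see [preprocess_track()]).
#' @param min_duration minimum thermal duration (s), exceeded strictly.
#' @param lookback trailing self-intersection search window (s).
#' @param merge_gap maximum gap (s) between crossing events merged into one
#'   thermal.
#' @param min_turn minimum turn rate (deg/s) for the circling-arc boundary
#'   refinement.
#' @param patience tolerated consecutive sub-threshold seconds during
#'   boundary refinement.
#' @return data.frame with one row per thermal: `bird_id`, `mode`, `i0`,
#'   `i1` (row indices into `fixes`), `start_time`, `end_time`. Stretches
#'   too short to hold a thermal yield zero rows, not an error.
#' @export
detect_thermals <- function(fixes, min_duration = 45, lookback = 120,
                            merge_gap = 10, min_turn = 8, patience = 2) {
  if (is.null(fixes$in_flight) || is.null(fixes$x)) {
    stop("detect_thermals: run preprocessing first")
  }
  out <- list()
  for (idx in flight_stretches(fixes)) {
    n <- length(idx)
    if (n < min_duration + 1) next
    x <- fixes$x[idx]
    y <- fixes$y[idx]
    tt <- as.numeric(fixes$time[idx])
    alt <- fixes$altitude_agl[idx]

    ints <- stretch_crossings(x, y, tt, lookback)
    if (!nrow(ints)) next
    ev <- merge_intervals(ints, tt, merge_gap)
    ev <- refine_circling(ev, x, y, tt, min_turn, patience)
    if (!nrow(ev)) next
    ev <- merge_intervals(ev, tt, merge_gap)

    dur <- tt[ev[, 2]] - tt[ev[, 1]] + 1
    dz <- alt[ev[, 2]] - alt[ev[, 1]]
    keep <- dur > min_duration & dz > 0
    ev <- ev[keep, , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      i0 <- idx[ev[r, 1]]
      i1 <- idx[ev[r, 2]]
      out[[length(out) + 1]] <- data.frame(
        bird_id = fixes$bird_id[i0], mode = "thermal", i0 = i0, i1 = i1,
        start_time = fixes$time[i0], end_time = fixes$time[i1]
      )
    }
  }
  if (!length(out)) {
    return(data.frame(
      bird_id = character(), mode = character(), i0 = integer(),
      i1 = integer(), start_time = as.POSIXct(character(), tz = "UTC"),
      end_time = as.POSIXct(character(), tz = "UTC")
    ))
  }
  do.call(rbind, out)
}

# all proper step-segment crossings within the trailing lookback window;
# returns a matrix of fix-index intervals [lo, hi] (local to the stretch)
stretch_crossings <- function(x, y, tt, lookback) {
  n <- length(x)
  lo <- integer(0)
  hi <- integer(0)
  for (i in 4:n) {
    j0 <- which(tt >= tt[i] - lookback)[1]
    js <- seq.int(max(2, j0), i - 2)
    if (!length(js)) next
    ax <- x[i - 1]; ay <- y[i - 1]; bx <- x[i]; by <- y[i]
    cx <- x[js - 1]; cy <- y[js - 1]; dx <- x[js]; dy <- y[js]
    d1 <- .ccw(ax, ay, bx, by, cx, cy)
    d2 <- .ccw(ax, ay, bx, by, dx, dy)
    d3 <- .ccw(cx, cy, dx, dy, ax, ay)
    d4 <- .ccw(cx, cy, dx, dy, bx, by)
    hit <- which(d1 * d2 < 0 & d3 * d4 < 0)
    if (length(hit)) {
      lo <- c(lo, js[hit[1]] - 1L)
      hi <- c(hi, i)
    }
  }
  cbind(lo = lo, hi = hi)
}

# union of index intervals, merging overlaps and gaps <= merge_gap seconds
merge_intervals <- function(ints, tt, merge_gap) {
  if (!nrow(ints)) return(ints)
  ints <- ints[order(ints[, 1]), , drop = FALSE]
  out <- ints[1, , drop = FALSE]
  for (r in seq_len(nrow(ints))[-1]) {
    k <- nrow(out)
    if (tt[ints[r, 1]] <= tt[out[k, 2]] + merge_gap) {
      out[k, 2] <- max(out[k, 2], ints[r, 2])
    } else {
      out <- rbind(out, ints[r, , drop = FALSE])
    }
  }
  out
}

# snap each event to the maximal contiguous consistent-turn arc that
# contains it; events with no such arc are dropped
refine_circling <- function(ev, x, y, tt, min_turn, patience) {
  n <- length(x)
  if (n < 3 || !nrow(ev)) return(ev[0, , drop = FALSE])
  hd <- (atan2(diff(x), diff(y)) * 180 / pi) %% 360 # heading of step k -> fix k+1
  turn <- wrap_angle(diff(hd)) / diff(tt[-1])       # turn rate at fix k+1..n-? (deg/s)
  # turn[k] describes the direction change at fix k+1 (k = 1..n-2);
  # a 3-s moving average suppresses GPS-jitter turning before thresholding
  if (length(turn) >= 3) {
    turn <- as.numeric(stats::filter(turn, rep(1 / 3, 3), sides = 2))
    turn[is.na(turn)] <- 0
  }
  out_lo <- integer(0)
  out_hi <- integer(0)
  for (r in seq_len(nrow(ev))) {
    a <- ev[r, 1]; b <- ev[r, 2]
    ks <- seq.int(max(1, a - 1), min(n - 2, b - 1))
    s <- sign(sum(turn[ks]))
    if (s == 0) { out_lo <- c(out_lo, a); out_hi <- c(out_hi, b); next }
    I <- turn * s >= min_turn
    # close short FALSE gaps (patience)
    rl <- rle(I)
    len <- rl$lengths
    val <- rl$values
    inner <- which(!val & len <= patience)
    inner <- inner[inner > 1 & inner < length(val)]
    val[inner] <- TRUE
    I <- rep(val, len)
    # maximal TRUE run overlapping the event core
    rl2 <- rle(I)
    ends <- cumsum(rl2$lengths)
    starts <- ends - rl2$lengths + 1
    mid <- max(1, min(length(I), floor((a + b) / 2) - 1))
    cand <- which(rl2$values & starts <= (b - 1) & ends >= (a - 1))
    if (!length(cand)) next
    # prefer the run containing the event midpoint, else the longest overlap
    inmid <- cand[starts[cand] <= mid & ends[cand] >= mid]
    pick <- if (length(inmid)) inmid[1] else cand[which.max(
      pmin(ends[cand], b - 1) - pmax(starts[cand], a - 1)
    )]
    # turn index k corresponds to fix k+1; the 3-point moving average
    # widens a suprathreshold arc by one index on each side, so shrink the
    # run by one before converting to fix indices
    lo <- max(1, starts[pick] + 1)
    hi <- min(n, ends[pick] + 1)
    out_lo <- c(out_lo, lo)
    out_hi <- c(out_hi, hi)
  }
  cbind(lo = out_lo, hi = out_hi)
}

#' Detect gliding and linear-soaring segments by vertical-speed trend
#'
#' Outside detected thermals, finds maximal runs in which at least
#' `trend_fraction` of smoothed vertical-speed samples share a sign
#' (negative: glide; positive: linear soaring). Samples with exactly zero
#' (or missing) smoothed vertical speed count toward neither trend. The
#' scanner closes a candidate at the last position where the in-trend
#' fraction still met the threshold, once the consecutive off-trend run
#' exceeds `break_run` seconds. Candidates are edge-trimmed with
#' [trim_segment_edges()] and runs shorter than `min_duration` seconds are
#' discarded.
#'
#' @param fixes preprocessed fixes.
#' @param thermals thermal table from [detect_thermals()] (their spans are
#'   masked out).
#' @param trend_fraction minimum fraction of same-sign samples.
#' @param min_duration minimum segment duration (s).
#' @param break_run consecutive off-trend seconds that close a candidate.
#' @return data.frame like [detect_thermals()], `mode` in `glide`/`linear`.
#' @export
detect_trend_segments <- function(fixes, thermals, trend_fraction = 0.9,
                                  min_duration = 10, break_run = 5) {
  if (is.null(fixes$vspeed_smooth)) {
    stop("detect_trend_segments: run smooth_vertical_speed() first")
  }
  masked <- rep(FALSE, nrow(fixes))
  if (!is.null(thermals) && nrow(thermals)) {
    for (r in seq_len(nrow(thermals))) {
      masked[thermals$i0[r]:thermals$i1[r]] <- TRUE
    }
  }
  out <- list()
  for (idx in flight_stretches(fixes)) {
    free <- idx[!masked[idx]]
    if (length(free) < 2) next
    # maximal contiguous (in row index) non-thermal runs
    runs <- split(free, cumsum(c(1, diff(free) != 1)))
    for (run in runs) {
      if (length(run) < 2) next
      cand <- scan_trend_run(fixes$vspeed_smooth[run], trend_fraction, break_run)
      for (cc in cand) {
        seg <- data.frame(
          bird_id = fixes$bird_id[run[cc$start]],
          mode = if (cc$trend < 0) "glide" else "linear",
          i0 = run[cc$start], i1 = run[cc$end],
          start_time = fixes$time[run[cc$start]],
          end_time = fixes$time[run[cc$end]]
        )
        seg <- trim_segment_edges(seg, fixes, trend_fraction, min_duration)
        if (!is.null(seg)) out[[length(out) + 1]] <- seg
      }
    }
  }
  if (!length(out)) {
    return(data.frame(
      bird_id = character(), mode = character(), i0 = integer(),
      i1 = integer(), start_time = as.POSIXct(character(), tz = "UTC"),
      end_time = as.POSIXct(character(), tz = "UTC")
    ))
  }
  do.call(rbind, out)
}

# scan one non-thermal run for trend candidates; returns a list of
# list(start, end, trend) with positions local to the run
scan_trend_run <- function(v, trend_fraction, break_run) {
  sgn <- sign(v)
  sgn[is.na(sgn)] <- 0
  n <- length(sgn)
  cands <- list()
  p <- 1
  start <- NA_integer_; trend <- 0; n_in <- 0; n_tot <- 0
  best_end <- NA_integer_; off <- 0
  reset <- function() {
    start <<- NA_integer_; trend <<- 0; n_in <<- 0; n_tot <<- 0
    best_end <<- NA_integer_; off <<- 0
  }
  close_cand <- function() {
    if (!is.na(start) && !is.na(best_end) && best_end >= start) {
      cands[[length(cands) + 1]] <<- list(start = start, end = best_end, trend = trend)
    }
  }
  while (p <= n) {
    g <- sgn[p]
    if (trend == 0) {
      if (g != 0) {
        start <- p; trend <- g; n_in <- 1; n_tot <- 1; best_end <- p; off <- 0
      }
    } else if (g != 0) {
      n_tot <- n_tot + 1
      if (g == trend) {
        n_in <- n_in + 1
        off <- 0
        if (n_in / n_tot >= trend_fraction) best_end <- p
      } else {
        off <- off + 1
        if (off > break_run) {
          close_cand()
          p <- best_end # restart just after the last good position
          reset()
        }
      }
    }
    p <- p + 1
    if (p > n && trend != 0) {
      # close at the last good position; if the run continues past it
      # (the cumulative fraction got stuck), rescan the remainder
      close_cand()
      if (!is.na(best_end) && best_end < n - 1) p <- best_end + 1
      reset()
    }
  }
  cands
}

#' Greedily trim segment edges to maximise the in-trend fraction
#'
#' Repeatedly removes the first or the last sample of the segment -
#' whichever removal raises the fraction of samples following the
#' segment's trend more (ties go to the first) - for as long as some
#' single-sample removal strictly increases that fraction. A segment
#' trimmed below `min_duration` seconds is voided (`NULL`).
#'
#' @param segment one-row segment data.frame (`i0`, `i1`, `mode`).
#' @param fixes preprocessed fixes.
#' @param trend_fraction unused by the rule itself; kept for config symmetry.
#' @param min_duration minimum surviving duration (s).
#' @return the trimmed segment, or `NULL` if voided.
#' @export
trim_segment_edges <- function(segment, fixes, trend_fraction = 0.9,
                               min_duration = 10) {
  trend <- if (segment$mode == "glide") -1 else 1
  v <- fixes$vspeed_smooth[segment$i0:segment$i1]
  sgn <- sign(v)
  sgn[is.na(sgn)] <- 0
  a <- 1L
  b <- length(sgn)
  frac <- function(a, b) {
    s <- sgn[a:b]
    nz <- sum(s != 0)
    if (nz == 0) return(0)
    sum(s == trend) / nz
  }
  repeat {
    if (b - a < 1) break
    f0 <- frac(a, b)
    f_first <- frac(a + 1L, b)
    f_last <- frac(a, b - 1L)
    if (f_first <= f0 && f_last <= f0) break
    if (f_first >= f_last) a <- a + 1L else b <- b - 1L
  }
  i0 <- segment$i0 + a - 1L
  i1 <- segment$i0 + b - 1L
  dur <- as.numeric(fixes$time[i1]) - as.numeric(fixes$time[i0]) + 1
  if (dur < min_duration) return(NULL)
  segment$i0 <- i0
  segment$i1 <- i1
  segment$start_time <- fixes$time[i0]
  segment$end_time <- fixes$time[i1]
  segment
}

#' Complete a segment's characterisation
#'
#' Fills duration, altitudinal change (end minus start altitude), travel
#' distance (sum of step lengths), mean vertical speed (altitudinal change
#' over duration), mean horizontal speed and mean absolute angular speed
#' (heading change per second). Wind support and side-wind are filled for
#' gliding segments only, using the supplied segment-scale wind vector.
#'
#' @param segment one-row segment data.frame with `i0`, `i1`, `mode`.
#' @param fixes preprocessed fixes.
#' @param wind optional wind vector for the segment: list/row with `u`, `v`
#'   (m/s). Used for glides only.
#' @return the segment row with characterisation columns added.
#' @export
characterize_segment <- function(segment, fixes, wind = NULL) {
  i0 <- segment$i0
  i1 <- segment$i1
  if (i1 - i0 < 1) stop("characterize_segment: degenerate single-fix segment")
  tt <- as.numeric(fixes$time[i0:i1])
  x <- fixes$x[i0:i1]
  y <- fixes$y[i0:i1]
  z <- fixes$altitude_agl[i0:i1]
  dur <- tt[length(tt)] - tt[1] + 1
  step <- sqrt(diff(x)^2 + diff(y)^2)
  hd <- (atan2(diff(x), diff(y)) * 180 / pi) %% 360
  ang <- if (length(hd) > 1) {
    mean(abs(wrap_angle(diff(hd))) / diff(tt[-1]))
  } else {
    NA_real_
  }
  segment$duration_s <- dur
  segment$altitudinal_change_m <- z[length(z)] - z[1]
  segment$travel_distance_m <- sum(step)
  segment$mean_vertical_speed_ms <- segment$altitudinal_change_m / dur
  segment$mean_horizontal_speed_ms <- segment$travel_distance_m / dur
  segment$mean_angular_speed_degs <- ang
  segment$start_lon <- fixes$lon[i0]
  segment$start_lat <- fixes$lat[i0]
  segment$wind_support_ms <- NA_real_
  segment$side_wind_ms <- NA_real_
  if (identical(segment$mode, "glide") && !is.null(wind)) {
    gvx <- diff(x) / diff(tt)
    gvy <- diff(y) / diff(tt)
    dec <- decompose_wind(gvx, gvy, rep(wind$u, length(gvx)), rep(wind$v, length(gvy)))
    segment$wind_support_ms <- mean(dec$wind_support)
    segment$side_wind_ms <- mean(dec$side_wind)
  }
  segment
}

# Rejoin same-mode glide/linear segments that a short burst of
# vertical-speed noise split apart (gap <= absorb seconds of contiguous
# flight); the trend rule tolerates off-trend samples but the scanner can
# still break a long run in two.
merge_same_mode <- function(segs, absorb = 5) {
  if (nrow(segs) < 2) return(segs)
  keep <- rep(TRUE, nrow(segs))
  last <- 1
  for (r in 2:nrow(segs)) {
    gap_fix <- segs$i0[r] - segs$i1[last] - 1
    gap_t <- as.numeric(segs$start_time[r]) - as.numeric(segs$end_time[last])
    if (segs$bird_id[r] == segs$bird_id[last] &&
        segs$mode[r] %in% c("glide", "linear") &&
        segs$mode[r] == segs$mode[last] &&
        gap_fix >= 0 && gap_fix <= absorb && gap_t == gap_fix + 1) {
      segs$i1[last] <- segs$i1[r]
      segs$end_time[last] <- segs$end_time[r]
      keep[r] <- FALSE
    } else {
      last <- r
    }
  }
  segs[keep, , drop = FALSE]
}

# Assign short unassigned transition gaps between consecutive segments of
# one contiguous flight stretch to the adjoining trend segment. Around a
# mode change the centred smoothing window mixes both modes, so the first
# seconds of a glide/linear run carry the previous mode's trend and stay
# unclassified; they belong to the segment whose motion has already begun.
# Thermal boundaries are set by the circling arc and are not moved.
absorb_transition_gaps <- function(segs, fixes, absorb = 5) {
  if (nrow(segs) < 2 || absorb <= 0) return(segs)
  trendy <- c("glide", "linear")
  for (r in 2:nrow(segs)) {
    if (segs$bird_id[r] != segs$bird_id[r - 1]) next
    gap_fix <- segs$i0[r] - segs$i1[r - 1] - 1
    gap_t <- as.numeric(segs$start_time[r]) - as.numeric(segs$end_time[r - 1])
    if (gap_fix < 1 || gap_fix > absorb || gap_t != gap_fix + 1) next
    gap_idx <- (segs$i1[r - 1] + 1L):(segs$i0[r] - 1L)
    if (segs$mode[r - 1] == "thermal" && segs$mode[r] %in% trendy) {
      # extend the thermal over leading fixes that are still climbing
      # (raw vertical speed), the glide/linear run takes the rest
      climbing <- fixes$vspeed_raw[gap_idx] > 0
      n_th <- match(FALSE, climbing, nomatch = length(gap_idx) + 1L) - 1L
      if (n_th > 0) {
        segs$i1[r - 1] <- gap_idx[n_th]
        segs$end_time[r - 1] <- fixes$time[gap_idx[n_th]]
      }
      if (n_th < length(gap_idx)) {
        segs$i0[r] <- gap_idx[n_th + 1L]
        segs$start_time[r] <- fixes$time[segs$i0[r]]
      }
    } else if (segs$mode[r - 1] %in% trendy && segs$mode[r] == "thermal") {
      climbing_rev <- rev(fixes$vspeed_raw[gap_idx] > 0)
      n_th <- match(FALSE, climbing_rev, nomatch = length(gap_idx) + 1L) - 1L
      if (n_th > 0) {
        segs$i0[r] <- gap_idx[length(gap_idx) - n_th + 1L]
        segs$start_time[r] <- fixes$time[segs$i0[r]]
      }
      if (n_th < length(gap_idx)) {
        segs$i1[r - 1] <- gap_idx[length(gap_idx) - n_th]
        segs$end_time[r - 1] <- fixes$time[segs$i1[r - 1]]
      }
    } else if (segs$mode[r] %in% trendy) {
      segs$i0[r] <- segs$i1[r - 1] + 1L
      segs$start_time[r] <- fixes$time[segs$i0[r]]
    } else if (segs$mode[r - 1] %in% trendy) {
      segs$i1[r - 1] <- segs$i0[r] - 1L
      segs$end_time[r - 1] <- fixes$time[segs$i1[r - 1]]
    }
  }
  segs
}

#' Segment an in-flight track into thermal, glide and linear modes
#'
#' Runs [detect_thermals()] first (self-intersecting spans resolve to
#' thermal), then [detect_trend_segments()] on the remainder, re-merges
#' same-mode runs split by short noise bursts, assigns short unassigned
#' transition gaps to the adjoining segment (climbing fixes to the thermal,
#' by raw vertical-speed sign), and characterises every segment. If a wind
#' field is supplied, each glide is characterised with the wind
#' interpolated at its fixes (segment mean).
#'
#' @param fixes preprocessed fixes (see [preprocess_track()]).
#' @param wind optional `wind_field` for glide wind support/side-wind.
#' @param config named list overriding [pipeline_config()] segmentation keys.
#' @return segment table (one row per segment, characterised), sorted by
#'   bird and start time; guaranteed pairwise disjoint per bird.
#' @export
segment_track <- function(fixes, wind = NULL, config = list()) {
  cfg <- utils::modifyList(default_seg_config(), config)
  th <- detect_thermals(
    fixes,
    min_duration = cfg$seg.min_thermal_s, lookback = cfg$seg.lookback_s,
    merge_gap = cfg$seg.merge_gap_s, min_turn = cfg$seg.extend_min_turn_degs,
    patience = cfg$seg.turn_patience_s
  )
  tr <- detect_trend_segments(
    fixes, th,
    trend_fraction = cfg$seg.trend_fraction,
    min_duration = cfg$seg.min_trend_s, break_run = cfg$seg.break_run_s
  )
  segs <- rbind(th, tr)
  if (!nrow(segs)) {
    return(cbind(segs, data.frame(
      duration_s = numeric(), altitudinal_change_m = numeric(),
      travel_distance_m = numeric(), mean_vertical_speed_ms = numeric(),
      mean_horizontal_speed_ms = numeric(), mean_angular_speed_degs = numeric(),
      start_lon = numeric(), start_lat = numeric(),
      wind_support_ms = numeric(), side_wind_ms = numeric()
    )))
  }
  segs <- segs[order(segs$bird_id, as.numeric(segs$start_time)), , drop = FALSE]
  segs <- merge_same_mode(segs, cfg$seg.merge_gap_s)
  segs <- absorb_transition_gaps(segs, fixes, cfg$seg.absorb_gap_s)
  rows <- vector("list", nrow(segs))
  for (r in seq_len(nrow(segs))) {
    seg <- segs[r, , drop = FALSE]
    wv <- NULL
    if (!is.null(wind) && identical(seg$mode, "glide")) {
      ii <- seg$i0:seg$i1
      wi <- interpolate_wind(wind, fixes$lon[ii], fixes$lat[ii],
                             fixes$altitude_agl[ii], fixes$time[ii])
      wv <- list(u = mean(wi$u), v = mean(wi$v))
    }
    rows[[r]] <- characterize_segment(seg, fixes, wv)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
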