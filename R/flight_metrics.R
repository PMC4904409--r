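# Per-thermal, per-glide and per-day performance metrics: climb rate,
# drift-compensated circling radius, glide-polar speeds (best glide,
# MacCready), RAFI, soaring-gliding efficiency, daily path statistics and
# the foraging-trip filter.

#' Quadratic glide polar
#'
#' Sink rate (m/s, positive down) as a function of airspeed:
#' `sink(v) = a v^2 + b v + c` over a valid airspeed range. The polar is a
#' declared input of all airspeed-choice metrics; the default coefficients
#' give a large soaring bird with best-glide speed ~13 m/s.
#'
#' @param a,b,c polynomial coefficients (`a > 0`).
#' @param v_range valid airspeed range `c(lo, hi)` (m/s).
#' @return object of class `glide_polar`.
#' @export
glide_polar <- function(a = 0.00325, b = 0, c = 0.55, v_range = c(6, 25)) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c), a > 0,
            length(v_range) == 2, v_range[1] > 0, v_range[2] > v_range[1])
  v <- seq(v_range[1], v_range[2], length.out = 101)
  if (any(a * v^2 + b * v + c <= 0)) {
    stop("glide_polar: sink must be positive over the valid range")
  }
  structure(list(a = a, b = b, c = c, v_range = v_range), class = "glide_polar")
}

polar_sink <- function(polar, v) polar$a * v^2 + polar$b * v + polar$c

#' Best-glide airspeed
#'
#' The airspeed maximising the glide ratio `v / sink(v)`. For the quadratic
#' polar the maximiser is `sqrt(c / a)` for any `b`, clamped to the valid
#' range.
#'
#' @param polar a [glide_polar()].
#' @return airspeed (m/s).
#' @export
best_glide_speed <- function(polar) {
  stopifnot(inherits(polar, "glide_polar"))
  v <- sqrt(polar$c / polar$a)
  min(max(v, polar$v_range[1]), polar$v_range[2])
}

#' MacCready (speed-to-fly) airspeed for an expected climb
#'
#' The inter-thermal airspeed maximising cross-country speed
#' `v * climb / (climb + sink(v))` given the expected climb rate in the
#' next thermal; for the quadratic polar the maximiser is
#' `sqrt((c + climb) / a)`, clamped to the valid range. A negative expected
#' climb is clamped to zero (with a message), where the MacCready speed
#' equals the best-glide speed.
#'
#' @param polar a [glide_polar()].
#' @param climb_expected expected climb rate (m/s).
#' @return airspeed (m/s).
#' @export
maccready_speed <- function(polar, climb_expected) {
  stopifnot(inherits(polar, "glide_polar"))
  if (climb_expected < 0) {
    message("maccready_speed: negative expected climb clamped to 0")
    climb_expected <- 0
  }
  v <- sqrt((polar$c + climb_expected) / polar$a)
  min(max(v, polar$v_range[1]), polar$v_range[2])
}

#' Risk-Averse Flight Index (RAFI) of a glide
#'
#' Measures where the observed gliding airspeed sits between the
#' risk-averse best-glide speed and the risk-prone MacCready speed for the
#' preceding climb. Under the default `"normalized"` definition,
#' `RAFI = (V_mc - V_obs) / (V_mc - V_bg)`, clipped to `[0, 1.2]`: 1 means
#' gliding at best-glide speed (risk-averse), 0 at the MacCready speed
#' (risk-prone). The alternative `"ratio"` definition is `V_bg / V_obs`.
#' With zero preceding climb `V_mc = V_bg` and the normalized index is
#' undefined (`NA`).
#'
#' @param v_observed mean observed gliding airspeed (m/s).
#' @param preceding_climb climb rate of the preceding thermal (m/s).
#' @param polar a [glide_polar()].
#' @param definition `"normalized"` (default) or `"ratio"`.
#' @return dimensionless index.
#' @export
rafi <- function(v_observed, preceding_climb, polar,
                 definition = c("normalized", "ratio")) {
  definition <- match.arg(definition)
  vbg <- best_glide_speed(polar)
  if (definition == "ratio") return(vbg / v_observed)
  vmc <- maccready_speed(polar, preceding_climb)
  if (abs(vmc - vbg) < 1e-9) return(NA_real_)
  pmin(pmax((vmc - v_observed) / (vmc - vbg), 0), 1.2)
}

#' Climb rate of a thermal segment
#'
#' Altitudinal change divided by duration; identical by construction to the
#' segment's mean vertical speed from [characterize_segment()].
#'
#' @param thermal one-row characterised thermal segment.
#' @param fixes preprocessed fixes (used if the segment is uncharacterised).
#' @return climb rate (m/s).
#' @export
climb_rate <- function(thermal, fixes = NULL) {
  if (!identical(thermal$mode, "thermal")) {
    stop("climb_rate: not a thermal segment")
  }
  if (!is.null(thermal$mean_vertical_speed_ms)) {
    return(thermal$mean_vertical_speed_ms)
  }
  characterize_segment(thermal, fixes)$mean_vertical_speed_ms
}

# cumulative wind drift along a point series (m); w is per-fix wind (u, v)
drift_compensate <- function(x, y, tt, w) {
  dt <- diff(tt)
  dx <- cumsum(c(0, w$u[-length(w$u)] * dt))
  dy <- cumsum(c(0, w$v[-length(w$v)] * dt))
  list(x = x - dx, y = y - dy)
}

# algebraic (Kasa) circle fit with one Gauss-Newton refinement step
fit_circle <- function(x, y) {
  n <- length(x)
  if (n < 3) return(list(cx = NA_real_, cy = NA_real_, r = NA_real_))
  A <- cbind(x, y, 1)
  b <- x^2 + y^2
  th <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(th)) return(list(cx = NA_real_, cy = NA_real_, r = NA_real_))
  cx <- th[1] / 2
  cy <- th[2] / 2
  r2 <- th[3] + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0) return(list(cx = NA_real_, cy = NA_real_, r = NA_real_))
  r <- sqrt(r2)
  # one geometric refinement step
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  ok <- d > 1e-12
  if (sum(ok) >= 3) {
    res <- d[ok] - r
    J <- cbind(-(x[ok] - cx) / d[ok], -(y[ok] - cy) / d[ok], -1)
    step <- tryCatch(qr.solve(crossprod(J), -crossprod(J, res)),
                     error = function(e) c(0, 0, 0))
    cx <- cx + step[1]
    cy <- cy + step[2]
    r <- r + step[3]
  }
  list(cx = cx, cy = cy, r = r)
}

#' Drift-compensated circling radius of a thermal
#'
#' Subtracts the cumulative wind drift (integrated interpolated wind) from
#' the projected positions, splits the segment into full 360-degree loops
#' by cumulative turning, fits a circle to each loop by algebraic least
#' squares with one geometric refinement, and returns the mean per-loop
#' radius. Undefined (`NA`) with fewer than one full loop.
#'
#' @param thermal one-row thermal segment.
#' @param fixes preprocessed fixes.
#' @param wind a `wind_field` or per-fix wind data.frame (`u`, `v`).
#' @return radius (m); per-loop radii and the drift-compensated centre are
#'   attached as attributes `loop_radii` and `centre`.
#' @export
circling_radius <- function(thermal, fixes, wind) {
  ii <- thermal$i0:thermal$i1
  w <- thermal_wind(thermal, fixes, wind)
  tt <- as.numeric(fixes$time[ii])
  dc <- drift_compensate(fixes$x[ii], fixes$y[ii], tt, w)
  hd <- (atan2(diff(dc$x), diff(dc$y)) * 180 / pi) %% 360
  cumturn <- cumsum(abs(wrap_angle(diff(hd))))
  n_loops <- floor(max(cumturn, 0) / 360)
  if (n_loops < 1) return(NA_real_)
  loop_id <- pmin(floor(c(0, 0, cumturn) / 360), n_loops - 1)
  radii <- vapply(split(seq_along(loop_id), loop_id), function(pp) {
    fit_circle(dc$x[pp], dc$y[pp])$r
  }, numeric(1))
  ctr <- fit_circle(dc$x, dc$y)
  out <- mean(radii, na.rm = TRUE)
  attr(out, "loop_radii") <- unname(radii)
  attr(out, "centre") <- ctr
  out
}

#' Soaring-gliding efficiency of thermal-glide pairs
#'
#' Pairs each thermal with the glide that follows it within `max_gap`
#' seconds (same bird) and computes the glide's travel distance divided by
#' the preceding thermal's duration (metres of glide per second of climb).
#'
#' @param segments characterised segment table.
#' @param max_gap maximum thermal-to-glide gap (s).
#' @return data.frame with one row per qualifying pair: `bird_id`,
#'   `thermal_start`, `glide_start`, `efficiency`.
#' @export
soaring_gliding_efficiency <- function(segments, max_gap = 10) {
  out <- list()
  for (b in unique(segments$bird_id)) {
    s <- segments[segments$bird_id == b, , drop = FALSE]
    s <- s[order(as.numeric(s$start_time)), , drop = FALSE]
    th <- which(s$mode == "thermal")
    for (i in th) {
      if (i == nrow(s)) next
      nxt <- s[i + 1, ]
      gap <- as.numeric(nxt$start_time) - as.numeric(s$end_time[i])
      if (nxt$mode == "glide" && gap >= 0 && gap <= max_gap) {
        out[[length(out) + 1]] <- data.frame(
          bird_id = b,
          thermal_start = s$start_time[i],
          glide_start = nxt$start_time,
          efficiency = nxt$travel_distance_m / s$duration_s[i]
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(
      bird_id = character(), thermal_start = as.POSIXct(character(), tz = "UTC"),
      glide_start = as.POSIXct(character(), tz = "UTC"), efficiency = numeric()
    ))
  }
  do.call(rbind, out)
}

#' Per-bird-day path, mode and energy summaries
#'
#' Travel distance (sum of distances between samples across the day),
#' maximum displacement from the day's first fix, straightness index
#' (maximum displacement divided by the travel distance accumulated up to
#' and including the fix of maximum displacement), segment counts, daily
#' mean soaring-gliding efficiency, flapping proportion (flapping bursts /
#' in-flight bursts) and mean in-flight ODBA.
#'
#' @param fixes preprocessed fixes.
#' @param segments characterised segment table.
#' @param bursts classified burst table (or `NULL`).
#' @param pair_max_gap thermal-glide pairing gap (s) for efficiency.
#' @return data.frame with one row per bird-day. Days with fewer than 2
#'   in-flight fixes are skipped.
#' @export
daily_summary <- function(fixes, segments, bursts = NULL, pair_max_gap = 10) {
  eff <- soaring_gliding_efficiency(segments, pair_max_gap)
  out <- list()
  for (bd in unique(fixes$bird_day)) {
    f <- fixes[fixes$bird_day == bd, , drop = FALSE]
    if (sum(f$in_flight) < 2) next
    day_date <- as.Date(f$time[1], tz = "UTC")
    step <- sqrt(diff(f$x)^2 + diff(f$y)^2)
    travel_m <- sum(step)
    disp <- sqrt((f$x - f$x[1])^2 + (f$y - f$y[1])^2)
    imax <- which.max(disp)
    travel_until <- if (imax > 1) sum(step[seq_len(imax - 1)]) else 0
    straight <- if (travel_until > 0) disp[imax] / travel_until else 1
    t0 <- min(as.numeric(f$time))
    t1 <- max(as.numeric(f$time))
    sel_seg <- segments$bird_id == f$bird_id[1] &
      as.numeric(segments$start_time) >= t0 & as.numeric(segments$end_time) <= t1
    s <- segments[sel_seg, , drop = FALSE]
    de <- eff[eff$bird_id == f$bird_id[1] &
                as.numeric(eff$thermal_start) >= t0 &
                as.numeric(eff$thermal_start) <= t1, , drop = FALSE]
    flap_prop <- NA_real_
    mean_odba <- NA_real_
    if (!is.null(bursts) && nrow(bursts)) {
      bt <- as.numeric(bursts$time)
      inday <- bursts$bird_id == f$bird_id[1] & bt >= t0 & bt <= t1
      # a burst is in flight if its nearest fix is
      bb <- bursts[inday, , drop = FALSE]
      if (nrow(bb)) {
        near <- findInterval(as.numeric(bb$time), as.numeric(f$time),
                             all.inside = TRUE)
        infl <- f$in_flight[near]
        if (any(infl)) {
          flap_prop <- mean(bb$flap_label[infl] == "flapping")
          mean_odba <- mean(bb$odba[infl])
        }
      }
    }
    out[[length(out) + 1]] <- data.frame(
      bird_id = f$bird_id[1], date = day_date,
      travel_distance_km = travel_m / 1000,
      max_displacement_km = disp[imax] / 1000,
      straightness = straight,
      n_thermals = sum(s$mode == "thermal"),
      n_glides = sum(s$mode == "glide"),
      n_linear = sum(s$mode == "linear"),
      soaring_gliding_efficiency = if (nrow(de)) mean(de$efficiency) else NA_real_,
      flapping_proportion = flap_prop,
      mean_odba = mean_odba
    )
  }
  if (!length(out)) stop("daily_summary: no bird-day with at least 2 in-flight fixes")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Foraging-day filter
#'
#' Flags a bird-day as a foraging day iff its travel distance does not
#' exceed `max_travel_km`, its straightness does not exceed
#' `max_straightness`, and its distance from the main roost does not
#' exceed `roost_km`; long-range (non-foraging) movements fail one of the
#' three.
#'
#' @param day one-row (or multi-row) [daily_summary()] table.
#' @param roost_distance_km distance of the day's farthest point from the
#'   main roost (km); defaults to the day's maximum displacement.
#' @param max_travel_km,max_straightness,roost_km thresholds.
#' @return logical vector, `TRUE` = foraging day.
#' @export
foraging_day_filter <- function(day, roost_distance_km = day$max_displacement_km,
                                max_travel_km = 200, max_straightness = 0.7,
                                roost_km = 60) {
  day$travel_distance_km <= max_travel_km &
    day$straightness <= max_straightness &
    roost_distance_km <= roost_km
}

#' Thermal-selection TKE at the 1-km scale
#'
#' Mean turbulent kinetic energy of the enclosing 1-km grid cells along a
#' thermal, a regional proxy for convective (thermal) intensity at the
#' scale relevant to thermal selection.
#'
#' @param thermal one-row thermal segment.
#' @param field a `wind_field`.
#' @param fixes preprocessed fixes.
#' @return mean TKE (J/kg); `NA` with a warning if the thermal lies outside
#'   the grid's time span.
#' @export
thermal_selection_tke <- function(thermal, field, fixes) {
  ii <- thermal$i0:thermal$i1
  w <- tryCatch(
    interpolate_wind(field, fixes$lon[ii], fixes$lat[ii],
                     fixes$altitude_agl[ii], fixes$time[ii]),
    error = function(e) {
      warning("thermal_selection_tke: ", conditionMessage(e))
      NULL
    }
  )
  if (is.null(w)) return(NA_real_)
  mean(w$tke_1km)
}
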