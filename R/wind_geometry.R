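# Wind annotation and wind-relative circling geometry: 4-D multilinear
# interpolation of gridded U/V/TKE, ground-speed/wind decomposition,
# circling direction, flight-versus-wind angle and the lee/windward
# partition of drifting thermal columns.

#' Interpolate a gridded wind field at track points
#'
#' Multilinear interpolation in x, y, z and t, independently for U, V and
#' TKE. Queries outside the horizontal/vertical hull are clamped to the
#' grid edge (the count is reported in the `n_clamped` attribute); queries
#' outside the time span are an error (no temporal extrapolation).
#' `tke_1km` is the TKE of the enclosing 1-km horizontal grid cell
#' (nearest cell centre), interpolated in altitude and time.
#'
#' @param field a `wind_field`.
#' @param lon,lat,altitude_agl query coordinates (degrees, m).
#' @param time query times (POSIXct or POSIX seconds).
#' @return data.frame with `u`, `v`, `speed`, `direction_toward` (degrees
#'   clockwise from north), `tke`, `tke_1km`.
#' @export
interpolate_wind <- function(field, lon, lat, altitude_agl, time) {
  stopifnot(inherits(field, "wind_field"))
  tq <- as.numeric(time)
  if (any(tq < field$t[1] - 1e-9) || any(tq > field$t[length(field$t)] + 1e-9)) {
    stop("interpolate_wind: query outside the field's time span")
  }
  xy <- aeqd_project(lon, lat, field$origin)
  qx <- xy$x / 1000
  qy <- xy$y / 1000

  axis_locate <- function(ax, q) {
    nclamp <- sum(q < ax[1] | q > ax[length(ax)])
    q <- pmin(pmax(q, ax[1]), ax[length(ax)])
    i <- findInterval(q, ax, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(ax) - 1L)
    w <- (q - ax[i]) / (ax[i + 1] - ax[i])
    list(i = i, w = w, n = nclamp)
  }
  lx <- axis_locate(field$x, qx)
  ly <- axis_locate(field$y, qy)
  lz <- axis_locate(field$z, altitude_agl)
  lt <- axis_locate(field$t, tq)
  n_clamped <- lx$n + ly$n + lz$n

  interp4 <- function(A, lx, ly, lz, lt) {
    out <- 0
    dims <- dim(A)
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) for (ct in 0:1) {
      w <- (if (cx) lx$w else 1 - lx$w) * (if (cy) ly$w else 1 - ly$w) *
        (if (cz) lz$w else 1 - lz$w) * (if (ct) lt$w else 1 - lt$w)
      lin <- (lx$i + cx) +
        dims[1] * (ly$i + cy - 1) +
        dims[1] * dims[2] * (lz$i + cz - 1) +
        dims[1] * dims[2] * dims[3] * (lt$i + ct - 1)
      out <- out + w * A[lin]
    }
    out
  }
  u <- interp4(field$U, lx, ly, lz, lt)
  v <- interp4(field$V, lx, ly, lz, lt)
  tke <- interp4(field$TKE, lx, ly, lz, lt)
  # enclosing 1-km cell: nearest x/y grid node, interpolated in z and t
  ix <- ifelse(lx$w > 0.5, lx$i + 1L, lx$i)
  iy <- ifelse(ly$w > 0.5, ly$i + 1L, ly$i)
  dims <- dim(field$TKE)
  tke_1km <- 0
  for (cz in 0:1) for (ct in 0:1) {
    w <- (if (cz) lz$w else 1 - lz$w) * (if (ct) lt$w else 1 - lt$w)
    lin <- ix + dims[1] * (iy - 1) +
      dims[1] * dims[2] * (lz$i + cz - 1) +
      dims[1] * dims[2] * dims[3] * (lt$i + ct - 1)
    tke_1km <- tke_1km + w * field$TKE[lin]
  }

  out <- data.frame(
    u = u, v = v,
    speed = sqrt(u^2 + v^2),
    direction_toward = (atan2(u, v) * 180 / pi) %% 360,
    tke = tke, tke_1km = tke_1km
  )
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Decompose ground velocity into airspeed, wind support and side-wind
#'
#' The airspeed vector is ground velocity minus wind. Wind support is the
#' wind component along the direction of travel; side-wind is the component
#' perpendicular to it, signed positive when the wind comes from the bird's
#' left. `support^2 + side^2 = |wind|^2` and
#' `airspeed_vector + wind = ground` hold exactly.
#'
#' @param gu,gv ground-velocity components (east, north; m/s).
#' @param wu,wv wind components (m/s).
#' @return data.frame with `air_u`, `air_v`, `airspeed`, `wind_support`,
#'   `side_wind`.
#' @export
decompose_wind <- function(gu, gv, wu, wv) {
  gs <- sqrt(gu^2 + gv^2)
  if (any(gs == 0)) stop("decompose_wind: zero ground velocity has no direction")
  hx <- gu / gs
  hy <- gv / gs
  support <- wu * hx + wv * hy
  # unit vector pointing to the bird's right is (hy, -hx); wind from the
  # left blows toward the right, so project onto it
  side <- wu * hy - wv * hx
  data.frame(
    air_u = gu - wu, air_v = gv - wv,
    airspeed = sqrt((gu - wu)^2 + (gv - wv)^2),
    wind_support = support, side_wind = side
  )
}

#' Circling direction of a thermal segment
#'
#' Sign of the summed signed heading change over the segment: positive
#' (clockwise, headings measured clockwise from north) is `CW`. A net turn
#' below 180 degrees is indeterminate and returns `NA` with a warning.
#'
#' @param thermal one-row thermal segment (`i0`, `i1`).
#' @param fixes preprocessed fixes.
#' @return `"CW"`, `"CCW"` or `NA`. The net turn (degrees) is attached as
#'   attribute `net_turn`.
#' @export
circling_direction <- function(thermal, fixes) {
  ii <- thermal$i0:thermal$i1
  hd <- (atan2(diff(fixes$x[ii]), diff(fixes$y[ii])) * 180 / pi) %% 360
  net <- sum(wrap_angle(diff(hd)))
  lab <- if (abs(net) < 180) {
    warning("circling_direction: net turn below 180 degrees, indeterminate")
    NA_character_
  } else if (net > 0) "CW" else "CCW"
  attr(lab, "net_turn") <- net
  lab
}

#' Flight-versus-wind angle
#'
#' Circular difference between the flight heading and the direction the
#' wind comes from, wrapped to (-180, 180]: 0 = headwind, +/-180 =
#' tailwind. Positive angles mean the wind arrives from the bird's left,
#' so clockwise and counter-clockwise circling events remain separable.
#' Calm wind (speed below `calm`) is undefined and yields `NA`.
#'
#' @param heading flight heading, degrees clockwise from north.
#' @param wind data.frame/list with `direction_toward` and `speed`
#'   (as from [interpolate_wind()]).
#' @param calm calm-wind threshold (m/s).
#' @return angle in degrees, (-180, 180].
#' @export
relative_flight_angle <- function(heading, wind, calm = 0.1) {
  from_dir <- (wind$direction_toward + 180) %% 360
  ang <- wrap_angle(heading - from_dir)
  ang[wind$speed < calm] <- NA_real_
  ang
}

#' Lee/windward partition of a thermal's fixes
#'
#' Projects each drift-compensated fix onto the wind axis through the
#' drift-compensated circle centre: the downwind half of the column is the
#' lee side, the upwind half the windward side. Returns per-fix labels and
#' the lee/windward mean climb rates. With calm wind or an indeterminate
#' centre the partition is withheld (`NULL`).
#'
#' @param thermal one-row thermal segment.
#' @param fixes preprocessed fixes.
#' @param wind a `wind_field`, or a data.frame of per-fix wind (`u`, `v`)
#'   for the thermal's fixes.
#' @param calm calm-wind threshold (m/s).
#' @return list with `side` (per-fix `"lee"`/`"windward"`), `lee_climb`,
#'   `windward_climb` (m/s), or `NULL` if withheld.
#' @export
lee_windward_partition <- function(thermal, fixes, wind, calm = 0.1) {
  ii <- thermal$i0:thermal$i1
  w <- thermal_wind(thermal, fixes, wind)
  wu <- mean(w$u)
  wv <- mean(w$v)
  wsp <- sqrt(wu^2 + wv^2)
  if (!is.finite(wsp) || wsp < calm) return(NULL)
  dc <- drift_compensate(fixes$x[ii], fixes$y[ii], as.numeric(fixes$time[ii]), w)
  ctr <- fit_circle(dc$x, dc$y)
  if (!is.finite(ctr$r)) return(NULL)
  proj <- (dc$x - ctr$cx) * (wu / wsp) + (dc$y - ctr$cy) * (wv / wsp)
  side <- ifelse(proj > 0, "lee", "windward")
  climb <- fixes$vspeed_smooth[ii]
  list(
    side = side,
    lee_climb = mean(climb[side == "lee"], na.rm = TRUE),
    windward_climb = mean(climb[side == "windward"], na.rm = TRUE)
  )
}

# per-fix wind for a thermal from a field or a precomputed data.frame
thermal_wind <- function(thermal, fixes, wind) {
  ii <- thermal$i0:thermal$i1
  if (inherits(wind, "wind_field")) {
    interpolate_wind(wind, fixes$lon[ii], fixes$lat[ii],
                     fixes$altitude_agl[ii], fixes$time[ii])
  } else {
    stopifnot(all(c("u", "v") %in% names(wind)))
    if (nrow(wind) == 1) wind <- wind[rep(1, length(ii)), , drop = FALSE]
    wind
  }
}

#' Wind-shear class of a thermal
#'
#' Wind shear is operationalised as the mean horizontal wind speed
#' interpolated along the thermal (the drift the circling bird must
#' compensate). Classes: low `[0, 2)`, mid `[2, 6]`, high `(6, Inf)` m/s
#' by default.
#'
#' @param thermal one-row thermal segment.
#' @param field a `wind_field` (or per-fix wind data.frame with `u`, `v`).
#' @param fixes preprocessed fixes.
#' @param cutpoints length-2 numeric class cut-points (m/s).
#' @return list with `wind_shear` (m/s), `shear_class`
#'   (`"low"`/`"mid"`/`"high"`), `circling_direction`, and per-fix
#'   `relative_angle` (degrees).
#' @export
wind_shear_class <- function(thermal, field, fixes, cutpoints = c(2, 6)) {
  w <- thermal_wind(thermal, fixes, field)
  shear <- mean(sqrt(w$u^2 + w$v^2))
  cls <- if (shear < cutpoints[1]) "low" else if (shear <= cutpoints[2]) "mid" else "high"
  ii <- thermal$i0:thermal$i1
  wdf <- data.frame(
    direction_toward = (atan2(w$u, w$v) * 180 / pi) %% 360,
    speed = sqrt(w$u^2 + w$v^2)
  )
  ang <- relative_flight_angle(fixes$heading[ii], wdf)
  list(
    wind_shear = shear, shear_class = cls,
    circling_direction = suppressWarnings(circling_direction(thermal, fixes)),
    relative_angle = ang
  )
}
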