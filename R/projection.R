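# Spherical azimuthal equidistant projection about a fixed reference origin.
# Forward and inverse are exact inverses of each other on the sphere, which
# keeps simulated geometry (radii, distances, headings) exact after the
# lon/lat round trip.

EARTH_RADIUS_M <- 6371008.8

#' Project lon/lat to local planar coordinates
#'
#' Azimuthal equidistant projection on a sphere centred at `origin`.
#' `x` points east, `y` north, in metres. Distances and azimuths from the
#' origin are preserved exactly; distortion away from the origin is
#' negligible at foraging-trip scales (tens of km).
#'
#' @param lon,lat numeric vectors, degrees (WGS84 lon/lat treated spherically).
#' @param origin length-2 numeric `c(lon, lat)` of the projection origin.
#' @return data.frame with columns `x`, `y` (metres).
#' @seealso [aeqd_unproject()]
#' @export
aeqd_project <- function(lon, lat, origin) {
  stopifnot(length(origin) == 2, is.finite(origin))
  lam0 <- origin[[1]] * pi / 180
  phi0 <- origin[[2]] * pi / 180
  lam <- lon * pi / 180
  phi <- lat * pi / 180
  dlam <- lam - lam0
  # haversine central angle (stable near the origin)
  h <- sin((phi - phi0) / 2)^2 + cos(phi0) * cos(phi) * sin(dlam / 2)^2
  cang <- 2 * asin(pmin(1, sqrt(h)))
  az <- atan2(
    sin(dlam) * cos(phi),
    cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dlam)
  )
  d <- EARTH_RADIUS_M * cang
  data.frame(x = d * sin(az), y = d * cos(az))
}

#' Inverse azimuthal equidistant projection
#'
#' Maps local planar coordinates (metres east/north of `origin`) back to
#' lon/lat degrees. Exact inverse of [aeqd_project()].
#'
#' @param x,y numeric vectors, metres.
#' @inheritParams aeqd_project
#' @return data.frame with columns `lon`, `lat` (degrees).
#' @export
aeqd_unproject <- function(x, y, origin) {
  stopifnot(length(origin) == 2, is.finite(origin))
  lam0 <- origin[[1]] * pi / 180
  phi0 <- origin[[2]] * pi / 180
  d <- sqrt(x^2 + y^2)
  cang <- d / EARTH_RADIUS_M
  az <- atan2(x, y)
  phi <- asin(pmin(1, pmax(-1, sin(phi0) * cos(cang) + cos(phi0) * sin(cang) * cos(az))))
  lam <- lam0 + atan2(
    sin(az) * sin(cang) * cos(phi0),
    cos(cang) - sin(phi0) * sin(phi)
  )
  out <- data.frame(lon = lam * 180 / pi, lat = phi * 180 / pi)
  # degenerate centre point: azimuth undefined but position is the origin
  out$lon[d == 0] <- origin[[1]]
  out$lat[d == 0] <- origin[[2]]
  out
}

# wrap an angle difference (degrees) into (-180, 180]
wrap_angle <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}
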