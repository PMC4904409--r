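# Flat-file formats: per-fix track CSV, wide ACC-burst CSV, segment CSV and
# a self-describing JSON wind-grid container. All readers are strict on
# their declared schema and all writers round-trip through the matching
# reader.

TRACK_COLUMNS <- c("bird_id", "timestamp", "lon", "lat", "altitude_agl")

fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
parse_time <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Read a GPS track (and optional ACC bursts) from CSV
#'
#' The track CSV mirrors common bio-logging exports: one row per fix with
#' columns `bird_id`, `timestamp` (ISO-8601 UTC), `lon`, `lat`,
#' `altitude_agl` (metres above ground; the altitude datum must be
#' pre-converted by the caller). The optional ACC CSV holds one burst per
#' row, keyed by `bird_id` + `timestamp`, with 114 sample columns
#' (`x_01..x_38`, `y_01..y_38`, `z_01..z_38`, units g; `z` is the heave
#' axis). Rows with unparseable timestamps or non-finite coordinates are
#' counted, reported via a message and the `n_malformed` attribute, and
#' excluded; impossible coordinates or non-increasing timestamps within a
#' bird abort with an integrity error.
#'
#' @param gps_path path to the track CSV.
#' @param acc_path optional path to the ACC burst CSV.
#' @return a list of class `track`: `fixes` (sorted by bird and time, with a
#'   `bird_day` grouping key) and `bursts` (or `NULL`).
#' @export
read_track <- function(gps_path, acc_path = NULL) {
  raw <- read.csv(gps_path, stringsAsFactors = FALSE)
  miss <- setdiff(TRACK_COLUMNS, names(raw))
  if (length(miss)) {
    stop("track schema error: missing column(s) ", paste(miss, collapse = ", "))
  }
  tm <- parse_time(raw$timestamp)
  ok <- !is.na(tm) & is.finite(raw$lon) & is.finite(raw$lat) &
    is.finite(raw$altitude_agl)
  n_bad <- sum(!ok)
  if (n_bad) message("read_track: dropped ", n_bad, " malformed row(s)")
  raw <- raw[ok, , drop = FALSE]
  tm <- tm[ok]
  if (any(abs(raw$lat) > 90) || any(abs(raw$lon) > 180)) {
    stop("track integrity error: coordinates outside valid range")
  }
  ord <- order(raw$bird_id, tm)
  fixes <- data.frame(
    bird_id = raw$bird_id[ord], time = tm[ord],
    lon = raw$lon[ord], lat = raw$lat[ord],
    altitude_agl = raw$altitude_agl[ord]
  )
  for (b in unique(fixes$bird_id)) {
    dtt <- diff(as.numeric(fixes$time[fixes$bird_id == b]))
    if (any(dtt <= 0)) {
      stop("track integrity error: non-increasing timestamps for bird ", b)
    }
  }
  fixes$bird_day <- paste(fixes$bird_id, as.Date(fixes$time, tz = "UTC"))
  bursts <- if (!is.null(acc_path)) read_acc(acc_path) else NULL
  out <- list(fixes = fixes, bursts = bursts)
  attr(out, "n_malformed") <- n_bad
  class(out) <- "track"
  out
}

read_acc <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("bird_id", "timestamp", burst_sample_cols())
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("ACC schema error: missing column(s) ", paste(miss[seq_len(min(4, length(miss)))], collapse = ", "))
  }
  raw$time <- parse_time(raw$timestamp)
  raw$timestamp <- NULL
  raw[order(raw$bird_id, raw$time), c("bird_id", "time", setdiff(names(raw), c("bird_id", "time"))),
      drop = FALSE]
}

#' Write a GPS track (and optional ACC bursts) to CSV
#'
#' Inverse of [read_track()]: files written here parse back to equal values.
#'
#' @param fixes data.frame of fixes (`bird_id`, `time`, `lon`, `lat`,
#'   `altitude_agl`); a `track` or `synthetic_track` object may be given.
#' @param gps_path output path for the track CSV.
#' @param bursts optional ACC burst table.
#' @param acc_path output path for the ACC CSV (required if `bursts` given).
#' @export
write_track <- function(fixes, gps_path, bursts = NULL, acc_path = NULL) {
  if (inherits(fixes, c("track", "synthetic_track"))) {
    if (is.null(bursts)) bursts <- fixes$bursts
    fixes <- fixes$fixes
  }
  out <- data.frame(
    bird_id = fixes$bird_id,
    timestamp = fmt_time(fixes$time),
    lon = sprintf("%.10f", fixes$lon),
    lat = sprintf("%.10f", fixes$lat),
    altitude_agl = sprintf("%.4f", fixes$altitude_agl)
  )
  write.csv(out, gps_path, row.names = FALSE, quote = FALSE)
  if (!is.null(bursts)) {
    if (is.null(acc_path)) stop("acc_path required when bursts are written")
    b <- bursts
    b$timestamp <- fmt_time(b$time)
    b$time <- NULL
    sc <- burst_sample_cols()
    b[sc] <- lapply(b[sc], function(v) sprintf("%.6f", v))
    keep <- c("bird_id", "timestamp", setdiff(names(b), c("bird_id", "timestamp")))
    write.csv(b[keep], acc_path, row.names = FALSE, quote = FALSE)
  }
  invisible(gps_path)
}

SEGMENT_COLUMNS <- c(
  "bird_id", "mode", "start_time", "end_time", "duration_s",
  "altitudinal_change_m", "travel_distance_m", "mean_vertical_speed_ms",
  "mean_horizontal_speed_ms", "mean_angular_speed_degs",
  "start_lon", "start_lat", "wind_support_ms", "side_wind_ms"
)

#' Write a flight-segment table to CSV
#'
#' One row per segment with its mode, timing, altitudinal change, travel
#' distance and mean vertical/horizontal/angular speeds. Wind support and
#' side-wind columns are populated for gliding segments only; for thermal
#' and linear-soaring rows they are empty. Segments of one bird must be
#' pairwise non-overlapping.
#'
#' @param segments segment table as produced by [segment_track()].
#' @param path output CSV path.
#' @export
write_segments <- function(segments, path) {
  if (nrow(segments)) {
    for (b in unique(segments$bird_id)) {
      s <- segments[segments$bird_id == b, , drop = FALSE]
      s <- s[order(as.numeric(s$start_time)), , drop = FALSE]
      if (nrow(s) > 1 &&
          any(as.numeric(s$start_time[-1]) <= as.numeric(s$end_time[-nrow(s)]))) {
        stop("write_segments: overlapping segments for bird ", b)
      }
    }
  }
  num <- function(v, digits = 6) ifelse(is.na(v), "", sprintf(paste0("%.", digits, "f"), v))
  out <- data.frame(
    bird_id = segments$bird_id,
    mode = segments$mode,
    start_time = fmt_time(segments$start_time),
    end_time = fmt_time(segments$end_time),
    duration_s = num(segments$duration_s, 0),
    altitudinal_change_m = num(segments$altitudinal_change_m),
    travel_distance_m = num(segments$travel_distance_m),
    mean_vertical_speed_ms = num(segments$mean_vertical_speed_ms),
    mean_horizontal_speed_ms = num(segments$mean_horizontal_speed_ms),
    mean_angular_speed_degs = num(segments$mean_angular_speed_degs),
    start_lon = num(segments$start_lon, 10),
    start_lat = num(segments$start_lat, 10),
    wind_support_ms = num(segments$wind_support_ms),
    side_wind_ms = num(segments$side_wind_ms)
  )
  if (!nrow(out)) out <- out[, SEGMENT_COLUMNS]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flight-segment table written by [write_segments()]
#'
#' @param path CSV path.
#' @return segment data.frame.
#' @export
read_segments <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(bird_id = "character", mode = "character"))
  miss <- setdiff(SEGMENT_COLUMNS, names(raw))
  if (length(miss)) {
    stop("segment schema error: missing column(s) ", paste(miss, collapse = ", "))
  }
  raw$start_time <- parse_time(raw$start_time)
  raw$end_time <- parse_time(raw$end_time)
  raw
}

#' Construct and validate a gridded wind/turbulence field
#'
#' @param x,y horizontal grid axes (km, local planar frame relative to
#'   `origin`); strictly increasing.
#' @param z vertical axis (m above ground); strictly increasing.
#' @param t time axis (POSIXct or numeric POSIX seconds); strictly increasing.
#' @param U,V,TKE 4-D arrays `[x, y, z, t]`: west-east wind, south-north
#'   wind (m/s) and turbulent kinetic energy (J/kg).
#' @param origin projection origin `c(lon, lat)` degrees.
#' @return object of class `wind_field`.
#' @export
wind_field <- function(x, y, z, t, U, V, TKE, origin) {
  t <- as.numeric(t)
  dims <- c(length(x), length(y), length(z), length(t))
  for (nm in c("x", "y", "z", "t")) {
    ax <- as.numeric(get(nm))
    if (length(ax) < 1 || any(!is.finite(ax)) || is.unsorted(ax, strictly = TRUE)) {
      stop("wind_field: axis ", nm, " must be finite and strictly increasing")
    }
  }
  for (nm in c("U", "V", "TKE")) {
    a <- get(nm)
    if (is.null(a)) stop("wind_field: missing variable ", nm)
    if (!identical(as.integer(dim(a)), as.integer(dims))) {
      stop("wind_field: array ", nm, " does not match the axes (expected dims ",
           paste(dims, collapse = "x"), ")")
    }
  }
  structure(
    list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z), t = t,
         U = U, V = V, TKE = TKE, origin = as.numeric(origin)),
    class = "wind_field"
  )
}

#' Write a wind field to a self-describing JSON container
#'
#' Stores named axes (`x`, `y` in km; `z` in m; `t` in POSIX seconds), the
#' projection origin, array dimensions and the flattened (column-major)
#' U/V/TKE arrays.
#'
#' @param field a `wind_field`.
#' @param path output path (`.json`).
#' @export
write_wind_grid <- function(field, path) {
  stopifnot(inherits(field, "wind_field"))
  doc <- list(
    format = "soarseg-wind-grid-1",
    origin = list(lon = field$origin[[1]], lat = field$origin[[2]]),
    units = list(x = "km", y = "km", z = "m", t = "posix_s",
                 U = "m/s", V = "m/s", TKE = "J/kg"),
    x = field$x, y = field$y, z = field$z, t = field$t,
    dims = dim(field$U),
    U = as.vector(field$U), V = as.vector(field$V), TKE = as.vector(field$TKE)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a wind field written by [write_wind_grid()]
#'
#' @param path JSON path.
#' @return a `wind_field`.
#' @export
read_wind_grid <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("x", "y", "z", "t", "dims", "U", "V", "TKE", "origin")
  miss <- setdiff(need, names(doc))
  if (length(miss)) {
    stop("wind grid error: missing element(s) ", paste(miss, collapse = ", "))
  }
  dims <- as.integer(doc$dims)
  arr <- function(nm) {
    v <- as.numeric(doc[[nm]])
    if (length(v) != prod(dims)) {
      stop("wind grid error: array ", nm, " does not match dims")
    }
    array(v, dims)
  }
  wind_field(doc$x, doc$y, doc$z, doc$t, arr("U"), arr("V"), arr("TKE"),
             origin = c(doc$origin$lon, doc$origin$lat))
}
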