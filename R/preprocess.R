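# Preprocessing: projection + per-fix motion variables, in-flight
# detection, robust vertical-speed smoothing, ODBA and a transparent
# two-feature flapping classifier.

#' Derive per-fix motion variables
#'
#' Projects fixes into a local planar frame and derives ground speed (m/s),
#' heading (degrees clockwise from north) and raw vertical speed (first
#' difference of altitude over elapsed time), per bird. The first fix of a
#' bird inherits the second fix's speed and heading.
#'
#' @param fixes fix data.frame (`bird_id`, `time`, `lon`, `lat`,
#'   `altitude_agl`), sorted by bird and time; a `track`/`synthetic_track`
#'   is accepted.
#' @param origin projection origin `c(lon, lat)`; defaults to the centroid
#'   of the fixes, recorded in the `origin` attribute.
#' @return the fixes with added columns `x`, `y`, `dt`, `ground_speed`,
#'   `heading`, `vspeed_raw`.
#' @export
derive_motion <- function(fixes, origin = NULL) {
  if (inherits(fixes, c("track", "synthetic_track"))) fixes <- fixes$fixes
  if (is.null(origin)) origin <- c(mean(fixes$lon), mean(fixes$lat))
  if (is.null(fixes$bird_day)) {
    fixes$bird_day <- paste(fixes$bird_id, as.Date(fixes$time, tz = "UTC"))
  }
  xy <- aeqd_project(fixes$lon, fixes$lat, origin)
  fixes$x <- xy$x
  fixes$y <- xy$y
  fixes$dt <- NA_real_
  fixes$ground_speed <- NA_real_
  fixes$heading <- NA_real_
  fixes$vspeed_raw <- NA_real_
  for (b in unique(fixes$bird_id)) {
    i <- which(fixes$bird_id == b)
    if (length(i) < 2) next
    tt <- as.numeric(fixes$time[i])
    dt <- diff(tt)
    dx <- diff(fixes$x[i])
    dy <- diff(fixes$y[i])
    dz <- diff(fixes$altitude_agl[i])
    sp <- sqrt(dx^2 + dy^2) / dt
    hd <- (atan2(dx, dy) * 180 / pi) %% 360
    vz <- dz / dt
    fixes$dt[i] <- c(dt[1], dt)
    fixes$ground_speed[i] <- c(sp[1], sp)
    fixes$heading[i] <- c(hd[1], hd)
    fixes$vspeed_raw[i] <- c(vz[1], vz)
  }
  attr(fixes, "origin") <- origin
  fixes
}

#' Flag in-flight fixes by ground speed
#'
#' A fix is in flight iff its ground speed exceeds `threshold` (default
#' 2 m/s). Isolated single-fix state flips (1-s blips) are removed with a
#' 3-fix majority filter.
#'
#' @param fixes output of [derive_motion()].
#' @param threshold in-flight ground-speed threshold (m/s).
#' @return the fixes with a logical `in_flight` column.
#' @export
detect_flight <- function(fixes, threshold = 2) {
  if (nrow(fixes) < 2) stop("detect_flight: need at least 2 fixes")
  if (is.null(fixes$ground_speed)) stop("detect_flight: run derive_motion() first")
  mask <- fixes$ground_speed > threshold
  for (b in unique(fixes$bird_id)) {
    i <- which(fixes$bird_id == b)
    m <- mask[i]
    n <- length(m)
    if (n >= 3) {
      mid <- 2:(n - 1)
      blip <- m[mid] != m[mid - 1] & m[mid] != m[mid + 1]
      m[mid][blip] <- !m[mid][blip]
    }
    mask[i] <- m
  }
  fixes$in_flight <- mask
  fixes
}

# contiguous 1-Hz in-flight stretches: runs where in_flight is TRUE and the
# gap to the previous fix is <= max_gap seconds (gaps are never bridged)
flight_stretches <- function(fixes, max_gap = 2) {
  out <- list()
  for (b in unique(fixes$bird_id)) {
    i <- which(fixes$bird_id == b)
    fl <- fixes$in_flight[i]
    gap <- c(Inf, diff(as.numeric(fixes$time[i])))
    newrun <- !fl | gap > max_gap
    run <- cumsum(newrun)
    for (r in split(i[fl], run[fl])) {
      if (length(r) >= 2) out[[length(out) + 1]] <- r
    }
  }
  out
}

#' Robust local-regression smoothing of vertical speed
#'
#' Smooths the raw vertical-speed series over a centred time window
#' (default 5 s) by locally weighted linear regression with tricube
#' distance weights and two bisquare robustness iterations, the standard
#' robust-lowess construction. Windows are truncated at stretch edges and
#' never bridge gaps longer than `max_gap` seconds; smoothing is applied to
#' contiguous in-flight stretches only (other fixes get `NA`).
#'
#' @param fixes output of [detect_flight()].
#' @param window full window width (s).
#' @param iters number of robustness iterations.
#' @param max_gap maximum within-stretch fix spacing (s).
#' @return the fixes with a `vspeed_smooth` column.
#' @export
smooth_vertical_speed <- function(fixes, window = 5, iters = 2, max_gap = 2) {
  fixes$vspeed_smooth <- NA_real_
  for (idx in flight_stretches(fixes, max_gap)) {
    tt <- as.numeric(fixes$time[idx])
    v <- fixes$vspeed_raw[idx]
    fixes$vspeed_smooth[idx] <- robust_local_smooth(tt, v, window / 2, iters)
  }
  fixes
}

# Vectorized iterated-bisquare local linear regression on a (nearly) 1-Hz
# series. Window = points within half_window seconds, reached through index
# offsets of up to floor(half_window); adequate for dt >= 1 s series.
robust_local_smooth <- function(tt, v, half_window = 2.5, iters = 2) {
  n <- length(v)
  if (n == 1) return(v)
  koff <- -floor(half_window):floor(half_window)
  m <- length(koff)
  S <- matrix(NA_real_, n, m) # time offsets of neighbours
  Y <- matrix(NA_real_, n, m)
  for (j in seq_along(koff)) {
    k <- koff[j]
    src <- seq_len(n) + k
    ok <- src >= 1 & src <= n
    S[ok, j] <- tt[src[ok]] - tt[ok]
    Y[ok, j] <- v[src[ok]]
  }
  D <- abs(S)
  valid <- !is.na(Y) & D <= half_window
  D[!valid] <- NA
  h <- apply(D, 1, max, na.rm = TRUE) + 1
  W0 <- (1 - (D / h)^3)^3
  W0[!valid] <- 0
  W0[is.na(W0)] <- 0

  fit_once <- function(W) {
    Sw <- rowSums(W)
    S1 <- rowSums(W * S, na.rm = TRUE)
    S2 <- rowSums(W * S^2, na.rm = TRUE)
    Sy <- rowSums(W * Y, na.rm = TRUE)
    Sy1 <- rowSums(W * S * Y, na.rm = TRUE)
    den <- Sw * S2 - S1^2
    slope <- ifelse(abs(den) > 1e-12, (Sw * Sy1 - S1 * Sy) / den, 0)
    intercept <- ifelse(Sw > 0, (Sy - slope * S1) / Sw, NA_real_)
    list(a = intercept, b = slope)
  }
  f <- fit_once(W0)
  for (it in seq_len(iters)) {
    # robustness weights per point from the global residual distribution
    # (the lowess construction): a point judged an outlier against its own
    # local fit is down-weighted in every window containing it
    r <- v - f$a
    s6 <- 6 * median(abs(r), na.rm = TRUE)
    delta <- if (is.finite(s6) && s6 > 0) {
      u <- abs(r) / s6
      ifelse(u < 1, (1 - u^2)^2, 0)
    } else {
      # zero robust scale: the majority fits exactly; reject the rest
      (abs(r) <= 1e-12) * 1
    }
    delta[is.na(delta)] <- 0
    Dm <- matrix(NA_real_, n, m)
    for (j in seq_along(koff)) {
      src <- seq_len(n) + koff[j]
      ok <- src >= 1 & src <= n
      Dm[ok, j] <- delta[src[ok]]
    }
    W <- W0 * Dm
    W[is.na(W)] <- 0
    bad <- rowSums(W) == 0 # all neighbours rejected: fall back to base weights
    W[bad, ] <- W0[bad, ]
    f <- fit_once(W)
  }
  f$a
}

#' Overall dynamic body acceleration of one burst
#'
#' Per axis, the static component is the mean over the burst (the running
#' mean window equals the 3.8-s burst, which is short enough to carry no
#' drift); the dynamic component is sample minus static. ODBA is the mean
#' over samples of the sum across axes of absolute dynamic acceleration.
#'
#' @param samples numeric matrix, 38 rows (samples) by 3 columns (axes), in g.
#' @return ODBA in g (scalar). Bursts with missing samples are rejected
#'   (`NA` with a message).
#' @export
compute_odba <- function(samples) {
  samples <- as.matrix(samples)
  if (anyNA(samples) || nrow(samples) != 38 || ncol(samples) != 3) {
    message("compute_odba: burst rejected (",
            sum(is.na(samples)), " missing of ", length(samples), " samples)")
    return(NA_real_)
  }
  dyn <- sweep(samples, 2, colMeans(samples))
  mean(rowSums(abs(dyn)))
}

# vectorized ODBA over a wide burst table
odba_bursts <- function(bursts) {
  ax <- function(p) as.matrix(bursts[, sprintf("%s_%02d", p, 1:38)])
  X <- ax("x"); Y <- ax("y"); Z <- ax("z")
  dx <- X - rowMeans(X)
  dy <- Y - rowMeans(Y)
  dz <- Z - rowMeans(Z)
  rowMeans(abs(dx) + abs(dy) + abs(dz))
}

#' Classify ACC bursts as flapping or passive
#'
#' A transparent two-feature threshold rule standing in for a field-trained
#' supervised classifier: a burst is `flapping` iff its ODBA exceeds
#' `odba_threshold` and the fraction of heave-axis spectral power inside
#' the wingbeat band (default 3-5 Hz) is at least `power_fraction`.
#' Thresholds were fixed once against synthetic fixtures and are
#' config-exposed.
#'
#' @param bursts wide burst table (columns `x_01..z_38`).
#' @param odba_threshold ODBA threshold (g).
#' @param band wingbeat frequency band `c(lo, hi)` (Hz).
#' @param power_fraction minimum in-band power fraction.
#' @return `bursts` with added `odba` and `flap_label` columns.
#' @export
classify_flapping <- function(bursts, odba_threshold = 0.6, band = c(3, 5),
                              power_fraction = 0.5) {
  od <- odba_bursts(bursts)
  Z <- as.matrix(bursts[, sprintf("z_%02d", 1:38)])
  Zc <- Z - rowMeans(Z)
  P <- Mod(stats::mvfft(t(Zc)))^2 # 38 x n
  freq <- (0:37) * 10 / 38
  pos <- freq > 0 & freq <= 5 # one-sided, up to Nyquist
  inband <- pos & freq >= band[1] & freq <= band[2]
  tot <- colSums(P[pos, , drop = FALSE])
  frac <- ifelse(tot > 0, colSums(P[inband, , drop = FALSE]) / tot, 0)
  bursts$odba <- od
  bursts$flap_label <- ifelse(od > odba_threshold & frac >= power_fraction,
                              "flapping", "passive")
  bursts
}

#' Run the full preprocessing chain on a track
#'
#' [derive_motion()], [detect_flight()], [smooth_vertical_speed()] and, if
#' bursts are present, [classify_flapping()], with the package defaults.
#'
#' @param track a `track`/`synthetic_track` or a fix data.frame.
#' @param origin optional projection origin.
#' @param config optional list overriding defaults (see [pipeline_config()]).
#' @return list with `fixes` (preprocessed) and `bursts` (classified or NULL).
#' @export
preprocess_track <- function(track, origin = NULL, config = list()) {
  cfg <- utils::modifyList(pipeline_config(), config)
  bursts <- NULL
  if (inherits(track, c("track", "synthetic_track"))) {
    bursts <- track$bursts
    fixes <- track$fixes
  } else {
    fixes <- track
  }
  fixes <- derive_motion(fixes, origin)
  fixes <- detect_flight(fixes, cfg$flight.speed_threshold_ms)
  fixes <- smooth_vertical_speed(fixes, cfg$smooth.window_s)
  if (!is.null(bursts)) {
    bursts <- classify_flapping(bursts, cfg$acc.odba_threshold_g,
                                cfg$acc.band_hz, cfg$acc.power_fraction)
  }
  list(fixes = fixes, bursts = bursts)
}
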