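# Synthetic soaring-gliding track generator with exact ground truth.
#
# A simulated bird-day alternates circling climbs in drifting thermals with
# straight inter-thermal glides (plus occasional straight "linear soaring"
# climbs), book-ended by low-rate roost fixes so the in-flight filter has
# true negatives. Geometry is built in a local planar frame (metres) and
# converted to lon/lat through an exact azimuthal equidistant projection;
# GPS noise is added last.

#' Simulation configuration for synthetic soaring tracks
#'
#' Defaults are calibrated to published summary statistics for foraging
#' Eurasian griffon vultures: thermal-soaring duration ~150 s and climb rate
#' ~1.4 m/s, gliding sink ~0.75 m/s, adult circling radius ~35.9 m, adult
#' soaring-gliding efficiency ~6 m of glide per second of climb
#' (glide leg length 900 m / 150 s climb), and adult flapping proportion
#' ~0.02. These defaults are a calibration of the generator, not a
#' measurement; see the package vignette.
#'
#' @param seed integer RNG seed; the same seed yields a bit-identical track.
#' @param n_days number of simulated bird-days.
#' @param thermals_per_day number of thermal-glide cycles per day.
#' @param thermal_updraft length-2 `c(mean, sd)` updraft strength (m/s).
#'   The realised climb rate of a thermal is `updraft - glide_sink` (the
#'   bird sinks relative to the air while circling).
#' @param thermal_radius circling radius (m).
#' @param circle_period time to complete one circle (s).
#' @param thermal_duration length-2 `c(mean, sd)` thermal duration (s).
#' @param glide_airspeed airspeed during glides and linear soaring (m/s).
#' @param glide_sink sink rate relative to air (m/s, positive down).
#' @param glide_distance ground distance of a glide leg (m); the leg ends
#'   once this distance is covered.
#' @param wind_profile data.frame with columns `alt` (m), `u`, `v` (m/s);
#'   horizontal wind is interpolated linearly in altitude and is constant in
#'   space and time.
#' @param tke_background background turbulent kinetic energy (J/kg).
#' @param tke_bumps optional data.frame `x`, `y` (m), `sigma` (m),
#'   `amplitude` (J/kg) of Gaussian TKE enhancements.
#' @param flapping_prob_per_burst probability that an in-flight ACC burst is
#'   a flapping burst.
#' @param gps_noise_sd GPS error standard deviation in metres; length 1
#'   (horizontal = vertical) or 2 (`c(horizontal, vertical)`).
#' @param gps_noise_rho lag-1-second autocorrelation of the GPS error
#'   process (AR(1)); receiver filtering makes 1-Hz position errors strongly
#'   autocorrelated. Set to 0 for white noise.
#' @param acc_flap_freq flapping frequency (Hz) of the synthesized wingbeat
#'   sinusoid on the heave axis.
#' @param acc_flap_amplitude amplitude of that sinusoid (g).
#' @param acc_noise_heave,acc_noise_other white-noise sd (g) of passive
#'   bursts on the heave and the other two axes.
#' @param linear_per_day number of straight linear-soaring climbs per day.
#' @param linear_duration duration of a linear-soaring leg (s).
#' @param linear_climb climb rate of a linear-soaring leg (m/s).
#' @param lee_updraft_bias optional fractional enhancement of the updraft on
#'   the downwind (lee) half of the thermal column; 0 = symmetric thermal.
#' @param start_alt altitude above ground at the start of each day's flight (m).
#' @param origin projection origin `c(lon, lat)` in degrees.
#' @param start_date UTC date of the first simulated day.
#' @param bird_id identifier attached to every fix.
#' @param age_class label attached to the track (e.g. "adult", "juvenile").
#' @param ground_fixes number of 600-s-cadence roost fixes before and after
#'   each day's flight.
#' @param acc_interval_s spacing of in-flight ACC bursts (s).
#' @return an object of class `sim_config` (validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_days = 20L,
                       thermals_per_day = 10L,
                       thermal_updraft = c(mean = 2.15, sd = 0.3),
                       thermal_radius = 35.9,
                       circle_period = 20,
                       thermal_duration = c(mean = 150, sd = 30),
                       glide_airspeed = 15.8,
                       glide_sink = 0.75,
                       glide_distance = 900,
                       wind_profile = data.frame(
                         alt = c(0, 2000), u = c(1, 5), v = c(0, 0)
                       ),
                       tke_background = 0.8,
                       tke_bumps = NULL,
                       flapping_prob_per_burst = 0.02,
                       gps_noise_sd = 3,
                       gps_noise_rho = exp(-1 / 20),
                       acc_flap_freq = 4,
                       acc_flap_amplitude = 1,
                       acc_noise_heave = 0.25,
                       acc_noise_other = 0.15,
                       linear_per_day = 1L,
                       linear_duration = 80,
                       linear_climb = 1.8,
                       lee_updraft_bias = 0,
                       start_alt = 300,
                       origin = c(lon = 35, lat = 31),
                       start_date = "2013-08-01",
                       bird_id = "bird01",
                       age_class = "adult",
                       ground_fixes = 4L,
                       acc_interval_s = 60) {
  cfg <- list(
    seed = as.integer(seed), n_days = as.integer(n_days),
    thermals_per_day = as.integer(thermals_per_day),
    thermal_updraft = thermal_updraft, thermal_radius = thermal_radius,
    circle_period = circle_period, thermal_duration = thermal_duration,
    glide_airspeed = glide_airspeed, glide_sink = glide_sink,
    glide_distance = glide_distance, wind_profile = wind_profile,
    tke_background = tke_background, tke_bumps = tke_bumps,
    flapping_prob_per_burst = flapping_prob_per_burst,
    gps_noise_sd = gps_noise_sd, gps_noise_rho = gps_noise_rho,
    acc_flap_freq = acc_flap_freq, acc_flap_amplitude = acc_flap_amplitude,
    acc_noise_heave = acc_noise_heave, acc_noise_other = acc_noise_other,
    linear_per_day = as.integer(linear_per_day),
    linear_duration = linear_duration, linear_climb = linear_climb,
    lee_updraft_bias = lee_updraft_bias,
    start_alt = start_alt, origin = origin, start_date = start_date,
    bird_id = as.character(bird_id), age_class = as.character(age_class),
    ground_fixes = as.integer(ground_fixes), acc_interval_s = acc_interval_s
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  num <- cfg[c(
    "thermal_updraft", "thermal_radius", "circle_period", "thermal_duration",
    "glide_airspeed", "glide_sink", "glide_distance", "tke_background",
    "flapping_prob_per_burst", "gps_noise_sd", "gps_noise_rho",
    "acc_flap_freq", "acc_flap_amplitude", "linear_duration", "linear_climb",
    "start_alt"
  )]
  if (!all(vapply(num, function(x) all(is.finite(x)), logical(1)))) {
    stop("sim_config: all numeric parameters must be finite")
  }
  pos <- c(
    cfg$thermal_updraft[[1]], cfg$thermal_radius, cfg$circle_period,
    cfg$thermal_duration[[1]], cfg$glide_airspeed, cfg$glide_sink,
    cfg$glide_distance, cfg$acc_flap_freq, cfg$linear_duration,
    cfg$linear_climb, cfg$start_alt, cfg$acc_interval_s
  )
  if (any(pos <= 0)) stop("sim_config: rates, radii and durations must be strictly positive")
  p <- cfg$flapping_prob_per_burst
  if (p < 0 || p > 1) stop("sim_config: flapping_prob_per_burst must lie in [0, 1]")
  if (cfg$gps_noise_rho < 0 || cfg$gps_noise_rho >= 1) {
    stop("sim_config: gps_noise_rho must lie in [0, 1)")
  }
  wp <- cfg$wind_profile
  if (!is.data.frame(wp) || !all(c("alt", "u", "v") %in% names(wp)) || nrow(wp) < 1) {
    stop("sim_config: wind_profile needs columns alt, u, v")
  }
  invisible(cfg)
}

# linear interpolation of the wind profile in altitude, clamped at the ends
profile_wind <- function(alt, profile) {
  if (nrow(profile) == 1) {
    return(cbind(u = rep(profile$u, length(alt)), v = rep(profile$v, length(alt))))
  }
  cbind(
    u = stats::approx(profile$alt, profile$u, xout = alt, rule = 2)$y,
    v = stats::approx(profile$alt, profile$v, xout = alt, rule = 2)$y
  )
}

#' Simulate a soaring-gliding GPS/ACC track with known ground truth
#'
#' Generates `n_days` bird-days of 1-Hz in-flight fixes alternating drifting
#' thermal climbs (a helix of configured radius and period whose centre is
#' advected by the wind at the current altitude, ascending at
#' `updraft - glide_sink`) with straight glide legs (configured airspeed
#' plus wind, configured sink), occasional linear-soaring climbs, and
#' 600-s-cadence roost fixes. ACC bursts (38 samples per axis at 10 Hz) are
#' emitted every `acc_interval_s` of flight; a flapping burst carries a
#' sinusoid at `acc_flap_freq` on the heave axis. Gaussian AR(1) GPS noise
#' is added last, after which planar coordinates are converted to lon/lat.
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_track`: a list with elements
#'   `fixes` (bird_id, time, lon, lat, altitude_agl), `bursts` (wide ACC
#'   table with a `truth_flap` column), `truth` (per-fix true mode label and
#'   noise-free coordinates), `truth_params` (one row per simulated leg with
#'   true climb rate, radius, duration, distance and wind) and `config`.
#' @export
simulate_track <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  day0 <- as.POSIXct(paste(config$start_date, "06:00:00"), tz = "UTC")

  all_fix <- vector("list", config$n_days)
  all_par <- vector("list", config$n_days)
  all_bur <- vector("list", config$n_days)

  for (d in seq_len(config$n_days)) {
    t0 <- as.numeric(day0) + (d - 1) * 86400
    day <- simulate_day(config, t0, d)
    all_fix[[d]] <- day$fixes
    all_par[[d]] <- day$params
    all_bur[[d]] <- day$bursts
  }
  fx <- do.call(rbind, all_fix)
  pars <- do.call(rbind, all_par)
  bursts <- do.call(rbind, all_bur)

  # GPS noise, added last, in the planar frame
  sd2 <- rep(config$gps_noise_sd, length.out = 2)
  dt <- c(1, diff(fx$t))
  ex <- ar1_noise(dt, sd2[[1]], config$gps_noise_rho)
  ey <- ar1_noise(dt, sd2[[1]], config$gps_noise_rho)
  ez <- ar1_noise(dt, sd2[[2]], config$gps_noise_rho)
  ll <- aeqd_unproject(fx$x + ex, fx$y + ey, config$origin)

  fixes <- data.frame(
    bird_id = config$bird_id,
    time = as.POSIXct(fx$t, origin = "1970-01-01", tz = "UTC"),
    lon = ll$lon, lat = ll$lat,
    altitude_agl = fx$alt + ez
  )
  truth <- data.frame(
    time = fixes$time, mode = fx$mode,
    x_true = fx$x, y_true = fx$y, alt_true = fx$alt
  )
  out <- list(
    fixes = fixes, bursts = bursts, truth = truth,
    truth_params = pars, config = config
  )
  class(out) <- "synthetic_track"
  out
}

# AR(1) Gaussian noise with per-step decay rho^dt (stationary marginal sd)
ar1_noise <- function(dt, sd, rho) {
  n <- length(dt)
  if (sd == 0) return(numeric(n))
  if (rho == 0) return(rnorm(n, 0, sd))
  e <- numeric(n)
  innov <- rnorm(n)
  e[1] <- sd * innov[1]
  r <- rho^dt
  s <- sd * sqrt(1 - r^2)
  for (i in seq_len(n)[-1]) e[i] <- r[i] * e[i - 1] + s[i] * innov[i]
  e
}

simulate_day <- function(config, t0, day_index) {
  g <- config$ground_fixes
  flight_start <- t0 + g * 600

  # leg schedule: thermals_per_day thermal+glide cycles, linear legs inserted
  n_th <- config$thermals_per_day
  legs <- rep(c("thermal", "glide"), n_th)
  if (config$linear_per_day > 0 && n_th > 0) {
    at <- sort(sample.int(n_th, min(config$linear_per_day, n_th)))
    # insert a linear climb after the glide of the chosen cycles
    for (k in rev(at)) legs <- append(legs, "linear", after = 2 * k)
  }

  pos <- c(0, 0)
  alt <- config$start_alt
  tt <- flight_start
  leg_fix <- list()
  leg_par <- list()
  for (li in seq_along(legs)) {
    lg <- switch(legs[[li]],
      thermal = sim_thermal_leg(config, pos, alt, tt),
      glide = sim_glide_leg(config, pos, alt, tt, config$glide_distance,
                            -config$glide_sink, "glide"),
      linear = sim_glide_leg(config, pos, alt, tt, NA,
                             config$linear_climb, "linear",
                             duration = config$linear_duration)
    )
    leg_fix[[li]] <- lg$fixes
    lg$params$day <- day_index
    leg_par[[li]] <- lg$params
    pos <- c(lg$fixes$x[nrow(lg$fixes)], lg$fixes$y[nrow(lg$fixes)])
    alt <- lg$fixes$alt[nrow(lg$fixes)]
    tt <- lg$fixes$t[nrow(lg$fixes)]
  }
  flight <- do.call(rbind, leg_fix)

  # roost fixes: 600-s cadence, ground speed well below the in-flight threshold
  gb <- data.frame(
    t = t0 + (seq_len(g) - 1) * 600,
    x = rnorm(g, 0, 1), y = rnorm(g, 0, 1), alt = abs(rnorm(g, 0, 0.5)),
    mode = "ground"
  )
  t_end <- flight$t[nrow(flight)]
  ga <- data.frame(
    t = t_end + seq_len(g) * 600,
    x = flight$x[nrow(flight)] + rnorm(g, 0, 1),
    y = flight$y[nrow(flight)] + rnorm(g, 0, 1),
    alt = abs(rnorm(g, 0, 0.5)),
    mode = "ground"
  )
  fixes <- rbind(gb, flight, ga)

  # ACC bursts every acc_interval_s of flight
  bt <- seq(flight_start, t_end, by = config$acc_interval_s)
  bursts <- sim_bursts(config, bt)
  list(fixes = fixes, params = do.call(rbind, leg_par), bursts = bursts)
}

sim_thermal_leg <- function(config, pos, alt, tt) {
  mu <- config$thermal_duration[[1]]
  sdd <- config$thermal_duration[[2]]
  dur <- max(60, round(rnorm(1, mu, sdd)))
  updraft <- rnorm(1, config$thermal_updraft[[1]], config$thermal_updraft[[2]])
  climb <- max(0.2, updraft - config$glide_sink)
  dirn <- sample(c(1, -1), 1) # +1 = clockwise viewed from above
  r <- config$thermal_radius
  om <- 2 * pi / config$circle_period

  tv <- seq_len(dur)
  alt_prev <- alt + climb * (tv - 1)
  w <- profile_wind(alt_prev, config$wind_profile)
  cx <- cumsum(w[, "u"])
  cy <- cumsum(w[, "v"])
  a0 <- runif(1, 0, 2 * pi)
  c0 <- pos - r * c(cos(a0), sin(a0))
  a <- a0 - dirn * om * tv
  x <- c0[1] + cx + r * cos(a)
  y <- c0[2] + cy + r * sin(a)

  alt_t <- alt + climb * tv
  if (config$lee_updraft_bias != 0) {
    wdir <- w / pmax(1e-9, sqrt(w[, "u"]^2 + w[, "v"]^2))
    downwind <- (r * cos(a)) * wdir[, "u"] + (r * sin(a)) * wdir[, "v"] > 0
    climb_t <- climb * (1 + config$lee_updraft_bias * ifelse(downwind, 1, -1))
    alt_t <- alt + cumsum(climb_t)
  }

  wm <- profile_wind(mean(alt_t), config$wind_profile)
  fixes <- data.frame(t = tt + tv, x = x, y = y, alt = alt_t, mode = "thermal")
  params <- data.frame(
    mode = "thermal", start = tt + 1, end = tt + dur, duration = dur,
    climb = (alt_t[dur] - alt) / dur, radius = r,
    direction = if (dirn > 0) "CW" else "CCW",
    distance = sum(sqrt(diff(c(pos[1], x))^2 + diff(c(pos[2], y))^2)),
    wind_u = wm[1, "u"], wind_v = wm[1, "v"], day = NA_integer_
  )
  list(fixes = fixes, params = params)
}

# straight leg at constant airspeed and heading; used for glides
# (stop after covering `distance` over ground) and linear soaring
# (fixed `duration`); `vz` is the vertical speed (negative = sink)
sim_glide_leg <- function(config, pos, alt, tt, distance, vz, mode,
                          duration = NULL) {
  hdg <- runif(1, 0, 360)
  ux <- sin(hdg * pi / 180)
  uy <- cos(hdg * pi / 180)
  wmax <- max(sqrt(config$wind_profile$u^2 + config$wind_profile$v^2))
  nmax <- if (is.null(duration)) {
    min(900, ceiling(distance / max(0.5, config$glide_airspeed - wmax)) + 10)
  } else {
    duration
  }
  tv <- seq_len(nmax)
  alt_prev <- alt + vz * (tv - 1)
  w <- profile_wind(alt_prev, config$wind_profile)
  vx <- config$glide_airspeed * ux + w[, "u"]
  vy <- config$glide_airspeed * uy + w[, "v"]
  step <- sqrt(vx^2 + vy^2)
  cum <- cumsum(step)
  n <- if (is.null(duration)) {
    idx <- which(cum >= distance)
    if (length(idx)) idx[1] else nmax
  } else {
    nmax
  }
  # altitude floor: never descend below 30 m agl
  alt_t <- alt + vz * tv
  low <- which(alt_t < 30)
  if (length(low)) n <- min(n, max(2, low[1] - 1))
  tv <- tv[seq_len(n)]
  x <- pos[1] + cumsum(vx[seq_len(n)])
  y <- pos[2] + cumsum(vy[seq_len(n)])
  wm <- profile_wind(mean(alt_t[seq_len(n)]), config$wind_profile)
  fixes <- data.frame(t = tt + tv, x = x, y = y, alt = alt_t[seq_len(n)], mode = mode)
  params <- data.frame(
    mode = mode, start = tt + 1, end = tt + n, duration = n,
    climb = vz, radius = NA_real_, direction = NA_character_,
    distance = cum[n], wind_u = wm[1, "u"], wind_v = wm[1, "v"],
    day = NA_integer_
  )
  list(fixes = fixes, params = params)
}

sim_bursts <- function(config, times) {
  nb <- length(times)
  if (nb == 0) {
    return(NULL)
  }
  tau <- (0:37) / 10
  flap <- runif(nb) < config$flapping_prob_per_burst
  mk <- function(i) {
    heave <- 1 + rnorm(38, 0, config$acc_noise_heave)
    if (flap[i]) {
      heave <- heave + config$acc_flap_amplitude *
        sin(2 * pi * config$acc_flap_freq * tau + runif(1, 0, 2 * pi))
    }
    c(rnorm(38, 0, config$acc_noise_other),
      rnorm(38, 0, config$acc_noise_other),
      heave)
  }
  m <- t(vapply(seq_len(nb), mk, numeric(114)))
  colnames(m) <- burst_sample_cols()
  out <- data.frame(
    bird_id = config$bird_id,
    time = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
    truth_flap = ifelse(flap, "flapping", "passive")
  )
  cbind(out, as.data.frame(m))
}

burst_sample_cols <- function() {
  c(sprintf("x_%02d", 1:38), sprintf("y_%02d", 1:38), sprintf("z_%02d", 1:38))
}

#' Simulate a gridded wind/turbulence field matching a configuration
#'
#' Builds a 4-D (x, y, z, t) grid with 1-km horizontal and 5-min temporal
#' spacing whose U/V components follow the configuration's altitude profile
#' (constant in x, y and t) and whose TKE is the configured background plus
#' optional Gaussian bumps. The vertical axis uses the profile's own
#' altitude nodes so that interpolation from the grid reproduces the profile
#' exactly.
#'
#' @param config a [sim_config()].
#' @param extent list with elements `x`, `y` (length-2 ranges in metres in
#'   the local planar frame) and `t` (length-2 POSIXct or numeric time range).
#' @return an object of class `wind_field`; see [wind_field()].
#' @export
simulate_wind_field <- function(config, extent) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("x", "y", "t") %in% names(extent))) {
    stop("extent must have elements x, y, t")
  }
  rng <- function(r) {
    r <- as.numeric(r)
    if (length(r) != 2 || any(!is.finite(r)) || r[2] < r[1]) {
      stop("empty or degenerate extent")
    }
    r
  }
  xr <- rng(extent$x); yr <- rng(extent$y); tr <- rng(extent$t)

  km_axis <- function(r) {
    ax <- seq(floor(r[1] / 1000), ceiling(r[2] / 1000), by = 1)
    if (length(ax) < 2) ax <- c(ax, ax + 1)
    ax
  }
  x <- km_axis(xr)
  y <- km_axis(yr)
  wp <- config$wind_profile
  if (nrow(wp) >= 2) {
    z <- wp$alt; uz <- wp$u; vz <- wp$v
  } else {
    z <- c(0, 3000); uz <- rep(wp$u, 2); vz <- rep(wp$v, 2)
  }
  t <- seq(floor(tr[1] / 300) * 300, ceiling(tr[2] / 300) * 300, by = 300)
  if (length(t) < 2) t <- c(t, t + 300)

  dims <- c(length(x), length(y), length(z), length(t))
  U <- array(0, dims); V <- array(0, dims)
  for (k in seq_along(z)) {
    U[, , k, ] <- uz[k]
    V[, , k, ] <- vz[k]
  }
  TKE <- array(config$tke_background, dims)
  if (!is.null(config$tke_bumps)) {
    b <- config$tke_bumps
    gx <- matrix(x * 1000, dims[1], dims[2])
    gy <- matrix(y * 1000, dims[1], dims[2], byrow = TRUE)
    for (i in seq_len(nrow(b))) {
      bump <- b$amplitude[i] *
        exp(-((gx - b$x[i])^2 + (gy - b$y[i])^2) / (2 * b$sigma[i]^2))
      TKE <- TKE + array(bump, dims)
    }
  }
  wind_field(x, y, z, t, U, V, TKE, origin = config$origin)
}

#' Confusion table between true and detected flight modes
#'
#' Cross-tabulates, in seconds, the generator's per-fix true mode labels
#' against the modes assigned by a set of detected flight segments. Each fix
#' counts as one second (the in-flight cadence); fixes covered by no segment
#' fall in the `undetected` column.
#'
#' @param track a `synthetic_track` from [simulate_track()].
#' @param segments a segment table (as produced by [segment_track()] or
#'   [detect_thermals()]); overlapping segments are rejected.
#' @return a matrix with one row per true mode and columns
#'   `thermal`, `glide`, `linear`, `undetected`.
#' @export
truth_confusion <- function(track, segments) {
  stopifnot(inherits(track, "synthetic_track"))
  tt <- as.numeric(track$truth$time)
  lab <- rep("undetected", length(tt))
  covered <- rep(FALSE, length(tt))
  if (!is.null(segments) && nrow(segments)) {
    s0 <- as.numeric(segments$start_time)
    s1 <- as.numeric(segments$end_time)
    if (any(s0 < min(tt)) || any(s1 > max(tt))) {
      stop("detected segments fall outside the track time span")
    }
    for (i in seq_len(nrow(segments))) {
      sel <- tt >= s0[i] & tt <= s1[i]
      if (any(covered & sel)) stop("overlapping detected segments")
      covered <- covered | sel
      lab[sel] <- as.character(segments$mode[i])
    }
  }
  true_modes <- c("ground", "thermal", "glide", "linear")
  det_modes <- c("thermal", "glide", "linear", "undetected")
  table(
    truth = factor(track$truth$mode, levels = true_modes),
    detected = factor(lab, levels = det_modes)
  )
}
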