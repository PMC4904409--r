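# Shared fixtures (built in code) and independent reference implementations
# used as oracles.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# a small simulated bird-day plus its preprocessed fixes
small_sim <- function(key = "default", ...) {
  cached(paste0("sim_", key), {
    cfg <- sim_config(...)
    trk <- simulate_track(cfg)
    pp <- suppressMessages(preprocess_track(trk, origin = cfg$origin))
    list(cfg = cfg, trk = trk, pp = pp)
  })
}

# build a minimal preprocessed fix table directly from planar coordinates
fixes_from_xy <- function(x, y, alt, t0 = as.POSIXct("2013-08-01 08:00:00", tz = "UTC"),
                          origin = c(35, 31), bird_id = "b1") {
  n <- length(x)
  ll <- aeqd_unproject(x, y, origin)
  f <- data.frame(
    bird_id = bird_id,
    time = t0 + seq_len(n) - 1,
    lon = ll$lon, lat = ll$lat, altitude_agl = alt
  )
  f <- derive_motion(f, origin)
  f <- detect_flight(f)
  smooth_vertical_speed(f)
}

# a drifting helix with straight glide legs before and after
helix_fixes <- function(helix_s = 60, radius = 30, period = 20, climb = 1.3,
                        drift = c(2, 0), glide_s = 30, airspeed = 10,
                        cw = TRUE, noise_sd = 0) {
  om <- 2 * pi / period
  tv <- seq_len(helix_s)
  a <- if (cw) -om * tv else om * tv
  hx <- drift[1] * tv + radius * cos(a)
  hy <- drift[2] * tv + radius * sin(a)
  g1 <- seq_len(glide_s)
  pre <- cbind(hx[1] - airspeed * rev(g1), hy[1])
  post <- cbind(hx[helix_s] + airspeed * g1, hy[helix_s])
  x <- c(pre[, 1], hx, post[, 1])
  y <- c(pre[, 2], hy, post[, 2])
  alt <- c(300 - 0.75 * rev(g1), 300 + climb * tv,
           300 + climb * helix_s - 0.75 * g1)
  if (noise_sd > 0) {
    x <- x + rnorm(length(x), 0, noise_sd)
    y <- y + rnorm(length(y), 0, noise_sd)
    alt <- alt + rnorm(length(alt), 0, noise_sd)
  }
  list(fixes = fixes_from_xy(x, y, alt), helix_idx = glide_s + tv)
}

# --- independent oracles -------------------------------------------------

# plain-loop iterated-bisquare local linear regression with lowess-style
# global robustness weights (reference smoother)
ref_smooth <- function(tt, v, half_window = 2.5, iters = 2) {
  n <- length(v)
  fit_all <- function(delta) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- which(abs(tt - tt[i]) <= half_window &
                   abs(seq_len(n) - i) <= floor(half_window))
      d <- abs(tt[j] - tt[i])
      h <- max(d) + 1
      w <- (1 - (d / h)^3)^3 * delta[j]
      if (sum(w) == 0) w <- (1 - (d / h)^3)^3
      X <- cbind(1, tt[j] - tt[i])
      XtWX <- t(X) %*% (w * X)
      cf <- if (abs(det(XtWX)) < 1e-12) {
        c(sum(w * v[j]) / sum(w), 0)
      } else {
        solve(XtWX, t(X) %*% (w * v[j]))
      }
      out[i] <- cf[1]
    }
    out
  }
  fitted <- fit_all(rep(1, n))
  for (it in seq_len(iters)) {
    r <- v - fitted
    s6 <- 6 * median(abs(r))
    delta <- if (s6 > 0) {
      u <- abs(r) / s6
      ifelse(u < 1, (1 - u^2)^2, 0)
    } else {
      (abs(r) <= 1e-12) * 1
    }
    fitted <- fit_all(delta)
  }
  fitted
}

# brute-force nested 1-D multilinear interpolation of a 4-D grid
ref_interp <- function(field, var, qx, qy, qz, qt) {
  ax <- list(field$x, field$y, field$z, field$t)
  A <- field[[var]]
  loc <- function(grid, x) {
    x <- min(max(x, grid[1]), grid[length(grid)])
    i <- findInterval(x, grid, rightmost.closed = TRUE)
    i <- min(max(i, 1), length(grid) - 1)
    list(i = i, w = (x - grid[i]) / (grid[i + 1] - grid[i]))
  }
  lx <- loc(ax[[1]], qx); ly <- loc(ax[[2]], qy)
  lz <- loc(ax[[3]], qz); lt <- loc(ax[[4]], qt)
  # interpolate t, then z, then y, then x
  vt <- function(i, j, k) (1 - lt$w) * A[i, j, k, lt$i] + lt$w * A[i, j, k, lt$i + 1]
  vz <- function(i, j) (1 - lz$w) * vt(i, j, lz$i) + lz$w * vt(i, j, lz$i + 1)
  vy <- function(i) (1 - ly$w) * vz(i, ly$i) + ly$w * vz(i, ly$i + 1)
  (1 - lx$w) * vy(lx$i) + lx$w * vy(lx$i + 1)
}

# brute-force Mann-Whitney U by pair counting (midranks via half-counts)
ref_U <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# closed-form Type-II ANCOVA F for the factor from sums of squares
ref_ancova_F <- function(response, covariate, factor_) {
  full <- lm(response ~ factor_ + covariate)
  red <- lm(response ~ covariate)
  rss_f <- sum(residuals(full)^2)
  rss_r <- sum(residuals(red)^2)
  df1 <- length(coef(full)) - length(coef(red))
  df2 <- length(response) - length(coef(full))
  ((rss_r - rss_f) / df1) / (rss_f / df2)
}

# naive greedy edge trim (independent re-implementation)
ref_trim <- function(sgn, trend) {
  a <- 1; b <- length(sgn)
  frac <- function(a, b) {
    s <- sgn[a:b]
    nz <- sum(s != 0)
    if (nz == 0) 0 else sum(s == trend) / nz
  }
  repeat {
    if (b - a < 1) break
    f0 <- frac(a, b); ff <- frac(a + 1, b); fl <- frac(a, b - 1)
    if (ff <= f0 && fl <= f0) break
    if (ff >= fl) a <- a + 1 else b <- b - 1
  }
  c(a, b)
}
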