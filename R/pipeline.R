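# End-to-end orchestration: simulate (or read) -> preprocess -> segment ->
# annotate with wind -> per-thermal/per-glide/per-day metrics -> group
# statistics, with a deterministic manifest.

#' Default analysis configuration
#'
#' All tunable thresholds of the pipeline with their defaults. Keys use
#' dotted module prefixes; any subset can be overridden via the `config`
#' arguments of the stage functions or [run_pipeline()].
#'
#' @return named list of defaults.
#' @export
pipeline_config <- function() {
  c(
    list(
      flight.speed_threshold_ms = 2,
      smooth.window_s = 5,
      acc.odba_threshold_g = 0.6,
      acc.band_hz = c(3, 5),
      acc.power_fraction = 0.5,
      wind.shear_cutpoints = c(2, 6),
      polar.a = 0.00325, polar.b = 0, polar.c = 0.55,
      polar.v_range = c(6, 25),
      rafi.definition = "normalized",
      filter.max_travel_km = 200,
      filter.max_straightness = 0.7,
      filter.roost_km = 60,
      pair.max_gap_s = 10,
      stats.bin_width = 1
    ),
    default_seg_config()
  )
}

#' Annotate detected thermals with wind context and circling metrics
#'
#' For every thermal segment: climb rate, drift-compensated circling
#' radius, circling direction, wind shear (mean horizontal wind speed along
#' the thermal) and its class, and 1-km-scale TKE.
#'
#' @param segments characterised segment table.
#' @param fixes preprocessed fixes.
#' @param field a `wind_field`.
#' @param config config overrides (see [pipeline_config()]).
#' @return data.frame of thermal annotations (one row per thermal).
#' @export
annotate_thermals <- function(segments, fixes, field, config = list()) {
  cfg <- utils::modifyList(pipeline_config(), config)
  th <- segments[segments$mode == "thermal", , drop = FALSE]
  rows <- vector("list", nrow(th))
  for (r in seq_len(nrow(th))) {
    seg <- th[r, , drop = FALSE]
    ctx <- wind_shear_class(seg, field, fixes, cfg$wind.shear_cutpoints)
    rad <- circling_radius(seg, fixes, field)
    rows[[r]] <- data.frame(
      bird_id = seg$bird_id,
      start_time = seg$start_time,
      duration_s = seg$duration_s,
      climb_rate = climb_rate(seg),
      radius_m = as.numeric(rad),
      circling_direction = if (is.na(ctx$circling_direction)) NA_character_ else ctx$circling_direction,
      wind_shear = ctx$wind_shear,
      shear_class = ctx$shear_class,
      tke_1km = thermal_selection_tke(seg, field, fixes)
    )
  }
  if (!length(rows)) {
    return(data.frame(
      bird_id = character(), start_time = as.POSIXct(character(), tz = "UTC"),
      duration_s = numeric(), climb_rate = numeric(), radius_m = numeric(),
      circling_direction = character(), wind_shear = numeric(),
      shear_class = character(), tke_1km = numeric()
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate glides with observed airspeed and RAFI
#'
#' For every glide: mean airspeed (ground velocity minus interpolated
#' wind), the preceding thermal's climb rate (pairing gap
#' `pair.max_gap_s`), and RAFI under the configured definition and polar.
#'
#' @inheritParams annotate_thermals
#' @return data.frame of glide annotations.
#' @export
annotate_glides <- function(segments, fixes, field, config = list()) {
  cfg <- utils::modifyList(pipeline_config(), config)
  polar <- glide_polar(cfg$polar.a, cfg$polar.b, cfg$polar.c, cfg$polar.v_range)
  segs <- segments[order(segments$bird_id, as.numeric(segments$start_time)), ,
                   drop = FALSE]
  gl <- which(segs$mode == "glide")
  rows <- list()
  for (r in gl) {
    seg <- segs[r, , drop = FALSE]
    ii <- seg$i0:seg$i1
    w <- interpolate_wind(field, fixes$lon[ii], fixes$lat[ii],
                          fixes$altitude_agl[ii], fixes$time[ii])
    tt <- as.numeric(fixes$time[ii])
    gvx <- diff(fixes$x[ii]) / diff(tt)
    gvy <- diff(fixes$y[ii]) / diff(tt)
    nstep <- length(gvx)
    dec <- decompose_wind(gvx, gvy, w$u[seq_len(nstep)], w$v[seq_len(nstep)])
    v_air <- mean(dec$airspeed)
    pre_climb <- NA_real_
    if (r > 1 && segs$bird_id[r - 1] == seg$bird_id &&
        segs$mode[r - 1] == "thermal") {
      gap <- as.numeric(seg$start_time) - as.numeric(segs$end_time[r - 1])
      if (gap >= 0 && gap <= cfg$pair.max_gap_s) {
        pre_climb <- segs$mean_vertical_speed_ms[r - 1]
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      bird_id = seg$bird_id, start_time = seg$start_time,
      duration_s = seg$duration_s, airspeed_ms = v_air,
      preceding_climb = pre_climb,
      wind_support_ms = mean(dec$wind_support),
      side_wind_ms = mean(dec$side_wind),
      rafi = if (is.na(pre_climb)) NA_real_ else {
        rafi(v_air, pre_climb, polar, cfg$rafi.definition)
      }
    )
  }
  if (!length(rows)) {
    return(data.frame(
      bird_id = character(), start_time = as.POSIXct(character(), tz = "UTC"),
      duration_s = numeric(), airspeed_ms = numeric(),
      preceding_climb = numeric(), wind_support_ms = numeric(),
      side_wind_ms = numeric(), rafi = numeric()
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline on simulated scenarios
#'
#' Simulates every scenario (a named list of [sim_config()] objects, e.g.
#' one per bird), preprocesses, segments, annotates with a simulated wind
#' field, computes thermal/glide/day metrics, applies the foraging-day
#' filter and, when at least two age classes are present, runs the group
#' comparisons (rank tests on per-individual means, shear-binned climb
#' differences with AICc model selection, and ANCOVA of circling radius on
#' age class given wind shear). All tables are written to `out_dir`
#' together with a deterministic run manifest; a rerun with the same
#' configuration is bit-identical.
#'
#' @param scenarios named list of `sim_config` objects.
#' @param out_dir output directory (created if needed).
#' @param config config overrides (see [pipeline_config()]).
#' @param seed optional integer; when given, scenario `i` is re-seeded to
#'   `seed + i - 1`.
#' @return (invisibly) list with `fixes`, `bursts`, `segments`, `thermals`,
#'   `glides`, `daily`, `stats`, `manifest`.
#' @export
run_pipeline <- function(scenarios, out_dir, config = list(), seed = NULL) {
  stopifnot(length(scenarios) >= 1)
  cfg <- utils::modifyList(pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  fixes_l <- list(); bursts_l <- list(); seg_l <- list()
  th_l <- list(); gl_l <- list(); age <- character(0)
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    stopifnot(inherits(sc, "sim_config"))
    if (!is.null(seed)) {
      sc$seed <- as.integer(seed + i - 1)
    }
    trk <- stage("simulate", simulate_track(sc))
    pp <- stage("preprocess", preprocess_track(trk, origin = sc$origin, config = cfg))
    field <- stage("wind", simulate_wind_field(sc, list(
      x = range(pp$fixes$x) + c(-2000, 2000),
      y = range(pp$fixes$y) + c(-2000, 2000),
      t = range(as.numeric(pp$fixes$time)) + c(-300, 300)
    )))
    segs <- stage("segment", segment_track(pp$fixes, field, cfg))
    th <- stage("annotate", annotate_thermals(segs, pp$fixes, field, cfg))
    gl <- stage("annotate", annotate_glides(segs, pp$fixes, field, cfg))
    th$age_class <- sc$age_class
    gl$age_class <- sc$age_class
    age[sc$bird_id] <- sc$age_class
    fixes_l[[i]] <- pp$fixes
    bursts_l[[i]] <- pp$bursts
    seg_l[[i]] <- segs
    th_l[[i]] <- th
    gl_l[[i]] <- gl
  }
  fixes <- do.call(rbind, fixes_l)
  bursts <- do.call(rbind, bursts_l)
  segments <- do.call(rbind, seg_l)
  thermals <- do.call(rbind, th_l)
  glides <- do.call(rbind, gl_l)

  daily <- stage("metrics", daily_summary(fixes, segments, bursts, cfg$pair.max_gap_s))
  daily$is_foraging_day <- foraging_day_filter(
    daily,
    max_travel_km = cfg$filter.max_travel_km,
    max_straightness = cfg$filter.max_straightness,
    roost_km = cfg$filter.roost_km
  )
  daily$age_class <- unname(age[daily$bird_id])
  keep <- daily[daily$is_foraging_day, , drop = FALSE]
  if (!nrow(keep)) {
    warning("run_pipeline: all days excluded by the foraging-day filter; ",
            "group statistics are empty")
  }

  stats_out <- stage("stats", pipeline_stats(thermals, glides, keep, cfg))

  # outputs
  p <- function(f) file.path(out_dir, f)
  write_segments(segments, p("segments.csv"))
  write.csv(format_table(thermals), p("thermals.csv"), row.names = FALSE)
  write.csv(format_table(glides), p("glides.csv"), row.names = FALSE)
  write.csv(format_table(daily), p("daily_summary.csv"), row.names = FALSE)
  if (!is.null(stats_out$comparisons)) {
    write.csv(format_table(stats_out$comparisons), p("group_comparisons.csv"),
              row.names = FALSE)
  }
  if (!is.null(stats_out$shear_models)) {
    write.csv(format_table(stats_out$shear_models$models), p("shear_models.csv"),
              row.names = FALSE)
  }

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "soarseg",
    version = as.character(utils::packageVersion("soarseg")),
    seeds = vapply(scenarios, function(s) s$seed, integer(1)),
    config_hash = unname(md5_string(as.character(cfg_json))),
    outputs = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                               pattern = "\\.csv$")))
  )
  names(manifest$outputs) <- basename(names(manifest$outputs))
  jsonlite::write_json(manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    fixes = fixes, bursts = bursts, segments = segments, thermals = thermals,
    glides = glides, daily = daily, stats = stats_out, manifest = manifest
  ))
}

md5_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeChar(s, tf, eos = NULL)
  tools::md5sum(tf)
}

# round numeric columns for stable, diffable CSV output
format_table <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- round(df[[nm]], 6)
    if (inherits(df[[nm]], "POSIXct")) df[[nm]] <- fmt_time(df[[nm]])
  }
  df
}

# group statistics on per-individual means (the unit of analysis for the
# two-group tests); per-thermal values feed the shear bins and the ANCOVA
pipeline_stats <- function(thermals, glides, daily, cfg) {
  out <- list(comparisons = NULL, shear_models = NULL, ancova = NULL)
  if (!nrow(daily) || length(unique(daily$age_class)) < 2) return(out)
  classes <- sort(unique(daily$age_class))
  per_bird <- function(df, value, cls) {
    d <- df[df$age_class == cls & is.finite(df[[value]]), , drop = FALSE]
    if (!nrow(d)) return(numeric(0))
    vapply(split(d[[value]], d$bird_id), mean, numeric(1))
  }
  metrics <- list(
    climb_rate = list(df = thermals, col = "climb_rate"),
    circling_radius = list(df = thermals, col = "radius_m"),
    tke_1km = list(df = thermals, col = "tke_1km"),
    rafi = list(df = glides, col = "rafi"),
    wind_support = list(df = glides, col = "wind_support_ms"),
    efficiency = list(df = daily, col = "soaring_gliding_efficiency"),
    flapping_proportion = list(df = daily, col = "flapping_proportion"),
    odba = list(df = daily, col = "mean_odba")
  )
  rows <- list()
  for (nm in names(metrics)) {
    m <- metrics[[nm]]
    g1 <- per_bird(m$df, m$col, classes[1])
    g2 <- per_bird(m$df, m$col, classes[2])
    if (!length(g1) || !length(g2)) next
    tst <- mww_test(g1, g2)
    rows[[nm]] <- data.frame(
      metric = nm,
      mean_1 = mean(g1), se_1 = sd(g1) / sqrt(length(g1)), n_1 = length(g1),
      mean_2 = mean(g2), se_2 = sd(g2) / sqrt(length(g2)), n_2 = length(g2),
      U = tst$statistic, p_value = tst$p_value
    )
  }
  if (length(rows)) {
    cmp <- do.call(rbind, rows)
    rownames(cmp) <- NULL
    attr(cmp, "groups") <- classes
    out$comparisons <- cmp
  }
  th <- thermals[is.finite(thermals$climb_rate) & is.finite(thermals$wind_shear), ,
                 drop = FALSE]
  if (nrow(th) && length(unique(th$age_class)) == 2) {
    bins <- bin_climb_difference(th$climb_rate, th$wind_shear,
                                 factor(th$age_class, levels = classes),
                                 cfg$stats.bin_width)
    if (nrow(bins) >= 4) out$shear_models <- fit_shear_models(bins)
    thr <- th[is.finite(th$radius_m), , drop = FALSE]
    if (length(unique(thr$age_class)) == 2 &&
        length(unique(thr$wind_shear)) > 1) {
      out$ancova <- tryCatch(
        ancova_test(thr$radius_m, thr$wind_shear, thr$age_class),
        error = function(e) NULL
      )
    }
  }
  out
}
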