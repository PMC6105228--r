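#' Default pipeline configuration
#'
#' All analysis constants with their standard values: 19.9-um arc step,
#' principal-curve df 10 (median) and 60 (inset contours), df = n/2 spline
#' smoothing, 1/8-diameter inset, 5-degree trough-alignment resolution,
#' 0.76-mm / R2 > 0.95 sine-law segment scan, no basal cutoff.
#'
#' @return A named list of configuration values.
#' @export
default_config <- function() {
  list(
    pixel_scale = 16,           # um/px
    frame_interval = 0.170,     # h
    step_um = 19.9,             # arc step, um
    df_median = 10,
    df_inset = 60,
    df_frac = 0.5,              # df = n/2 smoothing rule
    fraction = 1 / 8,           # inset depth
    resolution = 5,             # deg, trough alignment
    s_min = 0,                  # mm, basal cutoff for model fits
    min_len = 0.76,             # mm, segment scan
    r2_min = 0.95,
    threshold_method = "otsu",
    trough_min_extent = 0.5,    # mm
    trough_depth_frac = 0.5,
    seed = 1,
    simulate = list(beta = 0.4, gamma = 1.5, base_angle = 90, length = 4,
                    t_end = 6.10, noise = TRUE)
  )
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) simulate and render, then midline extraction,
#' kinematics, trough detection and alignment, luminescence profiling, and
#' model fitting, writing all tables, maps, a provenance manifest and a log
#' into `out_dir`. Deterministic for a fixed seed.
#'
#' @param config a configuration list (see [default_config()]) or the path
#'   to a YAML file with the same keys. Either `config$simulate` must be
#'   present, or `config$frames` must name a directory of
#'   `bright_*.tif`/`lum_*.tif` frames written by [write_fixture()] (in
#'   which case `pixel_scale` must be set explicitly).
#' @param out_dir output directory.
#' @return Invisibly, a list with the computed objects: `midlines`,
#'   `fields`, `rate`, `troughs`, `alignment`, `lum`, `fits`, `segments`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg); cat(msg, "\n", file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    log_line("stage: ", name)
    tryCatch(expr, error = function(e) {
      log_line("ERROR in ", name, ": ", conditionMessage(e))
      stop("pipeline halted in stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  set.seed(cfg$seed)
  step <- cfg$step_um / 1000

  if (!is.null(cfg$simulate)) {
    frames <- stage("simulate", {
      sim <- cfg$simulate
      params <- gp_params(beta = sim$beta, gamma = sim$gamma,
                          base_angle = sim$base_angle %||% 90,
                          length = sim$length %||% 4)
      traj <- simulate_gp_rod(params,
                              sim_grid(frame_interval = cfg$frame_interval,
                                       t_end = sim$t_end %||% 6.10))
      lm_ <- lum_model(noise = isTRUE(sim$noise))
      render_frames(traj, lm_, pixel_scale = cfg$pixel_scale, seed = cfg$seed)
    })
    write_fixture(frames, file.path(out_dir, "frames"))
    bright <- frames$bright; lum_frames <- frames$lum
    times <- frames$times; base_px <- frames$base_px
    exposure <- frames$exposure_min
  } else {
    if (is.null(cfg$frames)) stop("config needs either 'simulate' or 'frames'")
    if (is.null(config$pixel_scale))
      stop("config key 'pixel_scale' is required for external frames")
    loaded <- stage("load", .read_fixture(cfg$frames))
    bright <- loaded$bright; lum_frames <- loaded$lum
    times <- loaded$times; base_px <- loaded$base_px
    exposure <- loaded$exposure_min
  }

  midlines <- stage("midline", {
    out <- vector("list", length(bright))
    anchor <- NULL
    for (i in seq_along(bright)) {
      out[[i]] <- extract_midline(bright[[i]], cfg$pixel_scale,
                                  base_px = base_px, anchor = anchor,
                                  df_median = cfg$df_median, step = step,
                                  frame_time = times[i],
                                  threshold_method = cfg$threshold_method)
      anchor <- attr(out[[i]], "pair")$base   # orientation stability
      readr::write_csv(tibble::as_tibble(out[[i]]),
                       file.path(out_dir, sprintf("midline_%03d.csv", i)))
    }
    out
  })

  fields <- stage("kinematics", kinematics_fields(midlines, times,
                                                  df_frac = cfg$df_frac))
  rate <- stage("curvature_rate", curvature_rate(fields$C,
                                                 df_frac = cfg$df_frac))
  see_map <- see_ratio_map(fields$C, rate)
  for (nm in c("A", "A_smooth", "C")) write_ts_map(fields[[nm]],
                                                   file.path(out_dir, paste0("map_", nm, ".csv")))
  write_ts_map(rate$dCdt, file.path(out_dir, "map_dCdt.csv"))
  write_ts_map(see_map, file.path(out_dir, "map_see_ratio.csv"))

  troughs <- stage("troughs", detect_extremal_paths(
    rate$dCdt, "trough", min_extent = cfg$trough_min_extent,
    depth_frac = cfg$trough_depth_frac))
  alignment <- purrr::map_dfr(troughs, align_with_angle, a_map = fields$A_smooth,
                              resolution = cfg$resolution)
  if (length(troughs)) {
    readr::write_csv(purrr::imap_dfr(troughs, ~dplyr::mutate(.x, path = .y)),
                     file.path(out_dir, "trough_paths.csv"))
    readr::write_csv(alignment, file.path(out_dir, "trough_alignment.csv"))
  }

  lum <- stage("luminescence", luminescence_analysis(
    lum_frames, midlines, fields$C, cfg$pixel_scale, base_px,
    fraction = cfg$fraction, df_inset = cfg$df_inset,
    exposure_min = exposure, times = times))
  write_ts_map(lum$maps$LRL, file.path(out_dir, "map_LRL.csv"))
  write_ts_map(lum$maps$L_m, file.path(out_dir, "map_L_m.csv"))

  fits <- stage("model_fit", fit_models_by_time(rate$dCdt, fields$A_smooth,
                                                fields$C, s_min = cfg$s_min))
  readr::write_csv(fits, file.path(out_dir, "fits_dCdt.csv"))
  lrl_fits <- stage("model_fit_lrl", fit_models_by_time(
    lum$maps$LRL, fields$A_smooth, fields$C, s_min = cfg$s_min))
  readr::write_csv(lrl_fits, file.path(out_dir, "fits_LRL.csv"))

  segments <- stage("segment_scan", {
    purrr::map_dfr(seq_along(times), function(i) {
      d <- tibble::tibble(s = lum$maps$LRL$s,
                          A = fields$A_smooth$values[i, ],
                          LRL = lum$maps$LRL$values[i, ])
      scan_sine_segments(d[stats::complete.cases(d), ],
                         min_len = cfg$min_len, r2_min = cfg$r2_min,
                         t = times[i])
    })
  })
  readr::write_csv(segments, file.path(out_dir, "sine_segments.csv"))

  stage("maps", {
    render_map(rate$dCdt, a_map = fields$A_smooth,
               file = file.path(out_dir, "map_dCdt.png"))
    render_map(lum$maps$LRL, a_map = fields$A_smooth,
               file = file.path(out_dir, "map_LRL.png"))
  })

  manifest <- c(cfg[setdiff(names(cfg), "simulate")],
                list(simulate = cfg$simulate, frames = length(times),
                     r_version = as.character(getRversion())))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  log_line("done")
  invisible(list(midlines = midlines, fields = fields, rate = rate,
                 see = see_map, troughs = troughs, alignment = alignment,
                 lum = lum, fits = fits, lrl_fits = lrl_fits,
                 segments = segments, out_dir = out_dir))
}

# read a fixture directory written by write_fixture()
.read_fixture <- function(path) {
  man <- yaml::read_yaml(file.path(path, "manifest.yaml"))
  bfiles <- sort(list.files(path, "^bright_.*\\.tif$", full.names = TRUE))
  lfiles <- sort(list.files(path, "^lum_.*\\.tif$", full.names = TRUE))
  bright <- lapply(bfiles, function(f) tiff::readTIFF(f))
  lum <- lapply(lfiles, function(f) tiff::readTIFF(f) * man$lum_scale)
  times <- seq(0, by = man$grid$frame_interval, length.out = man$frames)
  list(bright = bright, lum = lum, times = times,
       base_px = man$base_px, exposure_min = man$exposure_min,
       pixel_scale = man$pixel_scale_um)
}

#' Render a t-s map to an image file
#'
#' Filled contour map in the t-s plane with the optional deflection-angle
#' overlay (10-degree contour intervals; 0/30/60/90 dashed, 85 dotted).
#'
#' @param map a [ts_map].
#' @param a_map optional angle [ts_map] overlay.
#' @param file output path (png or svg, by extension); NULL returns the plot.
#' @param width,height,dpi device settings.
#' @return The ggplot object, invisibly if written to file.
#' @export
render_map <- function(map, a_map = NULL, file = NULL,
                       width = 6, height = 4, dpi = 150) {
  p <- autoplot.ts_map(map, a_map = a_map)
  if (is.null(file)) return(p)
  ggplot2::ggsave(file, p, width = width, height = height, dpi = dpi)
  invisible(p)
}
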