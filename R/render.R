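#' Luminescence reporter model for rendered scenes
#'
#' Describes how reporter luminescence is painted onto a simulated rod: a
#' longitudinal mean-intensity profile along the midline, and a transverse
#' log10 gradient pinned so that the ratio between the two 1/8-diameter inset
#' points equals `lrl_true(s, t)` exactly (the profile is log-linear across
#' the rod width).
#'
#' @param peak_counts scale of the longitudinal profile (counts per exposure).
#' @param rod_diameter rod diameter (mm).
#' @param lrl_kappa,lrl_delay defaults for the built-in LRL ground truth
#'   \eqn{-\kappa \sin A(s, t - \tau)}, with A taken as 0 (vertical, pre-turn)
#'   for \eqn{t < \tau}. The 1.5 h delay mirrors the observed lag between
#'   turning and the first differential-expression signal.
#' @param lrl_fun optional function(s, t, traj) returning the transverse log10
#'   ratio; overrides the built-in ground truth.
#' @param longitudinal optional function(s, t) for the mean profile (counts,
#'   strictly positive); the default is a smooth apically weighted profile.
#' @param noise logical: apply Poisson counting noise plus Gaussian read noise.
#' @param read_noise_sd read-noise sd (counts).
#' @param background background level (counts).
#' @return An object of class `lum_model`.
#' @export
lum_model <- function(peak_counts = 2000, rod_diameter = 0.25,
                      lrl_kappa = 0.5, lrl_delay = 1.5,
                      lrl_fun = NULL, longitudinal = NULL,
                      noise = TRUE, read_noise_sd = 2, background = 20) {
  if (rod_diameter <= 0) stop("rod_diameter must be > 0")
  if (peak_counts <= 0) stop("peak_counts must be > 0")
  structure(list(peak_counts = peak_counts, rod_diameter = rod_diameter,
                 lrl_kappa = lrl_kappa, lrl_delay = lrl_delay,
                 lrl_fun = lrl_fun, longitudinal = longitudinal,
                 noise = noise, read_noise_sd = read_noise_sd,
                 background = background),
            class = "lum_model")
}

#' Longitudinal profile with a drifting bump
#'
#' Helper constructing a longitudinal intensity profile whose gaussian bump
#' drifts basipetally (tipward position decreasing) at a constant speed, for
#' testing recovery of moving median-intensity features.
#'
#' @param base,amplitude baseline and bump height (counts).
#' @param width bump sd (mm).
#' @param start bump centre at t = 0 (mm).
#' @param speed drift speed toward the base (mm/h).
#' @return A function(s, t) of counts.
#' @export
bump_profile <- function(base = 500, amplitude = 1500, width = 0.6,
                         start = 3.2, speed = 0.35) {
  function(s, t) base + amplitude * exp(-(s - (start - speed * t))^2 /
                                          (2 * width^2))
}

# evaluate lrl_true on the trajectory's (t, s) grid
.lrl_truth <- function(traj, lum) {
  nt <- length(traj$times); ns <- length(traj$s)
  out <- matrix(0, nt, ns)
  if (!is.null(lum$lrl_fun)) {
    for (i in seq_len(nt)) out[i, ] <- lum$lrl_fun(traj$s, traj$times[i], traj)
    return(out)
  }
  for (i in seq_len(nt)) {
    tlag <- traj$times[i] - lum$lrl_delay
    if (tlag < 0) {
      out[i, ] <- 0           # pre-turn: organ vertical, sin A = 0
    } else {
      j <- which.min(abs(traj$times - tlag))
      out[i, ] <- -lum$lrl_kappa * sin(traj$A[j, ] * pi / 180)
    }
  }
  out
}

.default_longitudinal <- function(lum, length_mm) {
  force(lum); force(length_mm)
  function(s, t) lum$peak_counts * (0.35 + 0.65 * exp(-(s - 0.8 * length_mm)^2 /
                                                        (2 * 1.2^2)))
}

# dominant bend orientation: +1 if the concave flank lies on the left-normal
# side of the base->tip tangent, -1 on the right. Straight rods default to +1.
.concave_orientation <- function(traj) {
  w <- sum(traj$C * abs(traj$C), na.rm = TRUE)
  if (w < 0) 1 else if (w > 0) -1 else 1
}

#' Render bright-field and luminescence frames from a simulated trajectory
#'
#' The bright channel is the rod silhouette (constant-width band swept along
#' the midline) over a dark background; the luminescence channel carries the
#' [lum_model()] profile with a log-linear transverse gradient whose inset-
#' point ratio equals the ground-truth LRL before noise.
#'
#' @param traj a `rod_trajectory`.
#' @param lum a [lum_model()].
#' @param pixel_scale microns per pixel.
#' @param dim raster dimensions `c(rows, cols)`.
#' @param base_px base position in the raster, `c(row, col)`; the rod is
#'   clamped there, initially deflected toward increasing column, with
#'   gravity along increasing row.
#' @param seed RNG seed for the noise draws.
#' @return An object of class `frame_series`: lists of bright and
#'   luminescence matrices, times, pixel scale, geometry, and the retained
#'   ground truth (trajectory, LRL matrix, concave-side orientation).
#' @export
render_frames <- function(traj, lum, pixel_scale = 16, dim = c(512, 512),
                          base_px = c(round(dim[1] * 0.75), 40),
                          seed = NULL) {
  stopifnot(inherits(traj, "rod_trajectory"), inherits(lum, "lum_model"))
  if (!is.null(seed)) set.seed(seed)
  ps_mm <- pixel_scale / 1000
  r_mm <- lum$rod_diameter / 2
  margin_px <- lum$rod_diameter / ps_mm

  # raster col/row of midline points per frame
  col_of <- function(x) base_px[2] + x / ps_mm
  row_of <- function(y) base_px[1] - y / ps_mm
  for (i in seq_along(traj$times)) {
    cc <- col_of(traj$x[i, ]); rr <- row_of(traj$y[i, ])
    if (any(cc < margin_px | cc > dim[2] - margin_px |
            rr < margin_px | rr > dim[1] - margin_px))
      stop("rod leaves the raster (margin >= rod diameter) at frame ", i,
           " (t = ", format(traj$times[i]), " h)")
  }

  lrl_truth <- .lrl_truth(traj, lum)
  longi <- lum$longitudinal %||% .default_longitudinal(lum, max(traj$s))
  orient <- .concave_orientation(traj)

  bright <- vector("list", length(traj$times))
  lumin <- vector("list", length(traj$times))
  fg <- 0.8; bg <- 0.05

  for (i in seq_along(traj$times)) {
    mx <- traj$x[i, ]; my <- traj$y[i, ]
    # unit tangents by centred differences
    tx <- c(mx[2] - mx[1], diff(mx, lag = 2) / 2, mx[length(mx)] - mx[length(mx) - 1])
    ty <- c(my[2] - my[1], diff(my, lag = 2) / 2, my[length(my)] - my[length(my) - 1])
    tl <- sqrt(tx^2 + ty^2); tx <- tx / tl; ty <- ty / tl

    cols <- floor(min(col_of(mx))) : ceiling(max(col_of(mx)))
    rows <- floor(min(row_of(my))) : ceiling(max(row_of(my)))
    pad <- ceiling(r_mm / ps_mm) + 2
    cols <- max(1, min(cols) - pad) : min(dim[2], max(cols) + pad)
    rows <- max(1, min(rows) - pad) : min(dim[1], max(rows) + pad)
    px <- (rep(cols, each = length(rows)) - base_px[2]) * ps_mm
    py <- (base_px[1] - rep(rows, times = length(cols))) * ps_mm

    # coarse prefilter, then exact nearest-midline assignment
    sub <- seq(1, length(mx), by = 8)
    d2c <- outer(px, mx[sub], "-")^2 + outer(py, my[sub], "-")^2
    keep <- sqrt(.row_mins(d2c)) < r_mm + 8 * (traj$s[2] - traj$s[1]) + 2 * ps_mm
    bmat <- matrix(bg, length(rows), length(cols))
    lmat <- matrix(lum$background, length(rows), length(cols))
    if (any(keep)) {
      qx <- px[keep]; qy <- py[keep]
      d2 <- outer(qx, mx, "-")^2 + outer(qy, my, "-")^2
      ni <- max.col(-d2, ties.method = "first")
      dxp <- qx - mx[ni]; dyp <- qy - my[ni]
      u <- dxp * (-ty[ni]) + dyp * tx[ni]          # signed offset along left normal
      ax <- dxp * tx[ni] + dyp * ty[ni]            # axial offset from nearest point
      s_raw <- traj$s[ni] + ax
      s_at <- pmin(pmax(s_raw, 0), max(traj$s))
      # silhouette: flat cut at the clamped base, rounded (hemispherical) tip
      over_tip <- pmax(s_raw - max(traj$s), 0)
      edge_d <- sqrt((abs(u))^2 + over_tip^2)      # distance to the swept band
      edge_d[s_raw < 0] <- Inf
      inside_frac <- pmin(pmax((r_mm - edge_d) / ps_mm + 0.5, 0), 1)
      bvals <- bg + (fg - bg) * inside_frac
      lrl_at <- approx(traj$s, lrl_truth[i, ], xout = s_at, rule = 2)$y
      lm_at <- longi(s_at, traj$times[i])
      lvals <- lum$background +
        lm_at * 10^(lrl_at * (orient * u) / (0.75 * lum$rod_diameter)) *
        (inside_frac > 0.5)
      bfull <- rep(bg, length(px)); bfull[keep] <- bvals
      lfull <- rep(lum$background, length(px)); lfull[keep] <- lvals
      bmat <- matrix(bfull, length(rows), length(cols))
      lmat <- matrix(lfull, length(rows), length(cols))
    }
    B <- matrix(bg, dim[1], dim[2]); L <- matrix(lum$background, dim[1], dim[2])
    B[rows, cols] <- bmat; L[rows, cols] <- lmat
    if (lum$noise) {
      L <- matrix(stats::rpois(length(L), lambda = pmax(L, 0)) +
                    stats::rnorm(length(L), sd = lum$read_noise_sd),
                  dim[1], dim[2])
      B <- B + matrix(stats::rnorm(length(B), sd = 0.01), dim[1], dim[2])
    }
    bright[[i]] <- B; lumin[[i]] <- L
  }

  structure(list(bright = bright, lum = lumin, times = traj$times,
                 pixel_scale = pixel_scale, dim = dim, base_px = base_px,
                 exposure_min = 1,
                 gravity_image = c(1, 0),  # gravity = increasing row
                 truth = list(traj = traj, lrl = lrl_truth, orient = orient,
                              lum = lum)),
            class = "frame_series")
}

# per-row minimum of a matrix
.row_mins <- function(m) do.call(pmin, as.data.frame(m))

#' @export
print.frame_series <- function(x, ...) {
  cat("<frame_series> ", length(x$times), " frames, ",
      x$dim[1], "x", x$dim[2], " px at ", x$pixel_scale, " um/px\n", sep = "")
  invisible(x)
}

#' Lab-frame (mm) coordinates of a raster position
#'
#' Converts (row, col) raster coordinates of a [render_frames()] series, or
#' of any raster with the same geometry, into the lab frame used throughout
#' the package: x toward increasing column, y upward (decreasing row), in mm.
#'
#' @param row,col raster coordinates (may be fractional).
#' @param pixel_scale microns per pixel.
#' @param base_px raster `c(row, col)` mapped to the lab origin.
#' @return A tibble with columns `x`, `y` (mm).
#' @export
raster_to_lab <- function(row, col, pixel_scale, base_px = c(0, 0)) {
  ps_mm <- pixel_scale / 1000
  tibble::tibble(x = (col - base_px[2]) * ps_mm,
                 y = (base_px[1] - row) * ps_mm)
}

#' Write a rendered series plus ground truth to disk
#'
#' Writes one 16-bit TIFF per frame and channel, the ground-truth table as
#' CSV, and a YAML manifest of all scalar parameters. Output is
#' bit-reproducible for a fixed seed.
#'
#' @param frames a `frame_series`.
#' @param path output directory (created if needed).
#' @return The manifest as a list, invisibly.
#' @export
write_fixture <- function(frames, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nt <- length(frames$times)
  lmax <- max(unlist(frames$lum), 1)
  for (i in seq_len(nt)) {
    tiff::writeTIFF(pmin(pmax(frames$bright[[i]], 0), 1),
                    file.path(path, sprintf("bright_%03d.tif", i)),
                    bits.per.sample = 16)
    tiff::writeTIFF(pmin(pmax(frames$lum[[i]] / lmax, 0), 1),
                    file.path(path, sprintf("lum_%03d.tif", i)),
                    bits.per.sample = 16)
  }
  traj <- frames$truth$traj
  truth <- as_tibble.rod_trajectory(traj)
  truth$LRL <- as.vector(t(frames$truth$lrl))
  readr::write_csv(truth, file.path(path, "truth.csv"))
  p <- traj$params
  manifest <- list(
    frames = nt, pixel_scale_um = frames$pixel_scale,
    dim = as.integer(frames$dim), base_px = as.numeric(frames$base_px),
    lum_scale = lmax, exposure_min = frames$exposure_min,
    concave_orientation = frames$truth$orient,
    params = list(beta = p$beta, gamma = p$gamma, base_angle = p$base_angle,
                  length = p$length, elongation_rate = p$elongation_rate,
                  response = p$response),
    grid = unclass(traj$grid),
    lum = list(peak_counts = frames$truth$lum$peak_counts,
               rod_diameter = frames$truth$lum$rod_diameter,
               lrl_kappa = frames$truth$lum$lrl_kappa,
               lrl_delay = frames$truth$lum$lrl_delay,
               noise = frames$truth$lum$noise,
               read_noise_sd = frames$truth$lum$read_noise_sd,
               background = frames$truth$lum$background))
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"))
  invisible(manifest)
}
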