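#' Assign convex and concave flank labels for a recording
#'
#' The convex flank is the outside of the dominant bend, determined from the
#' curvature-magnitude-weighted mean curvature over all frames; labels are
#' fixed for the whole recording. With the package's lab frame (y up, organ
#' base-to-tip tangent), orientation +1 means the concave flank lies on the
#' left-normal side of the tangent.
#'
#' @param c_map curvature [ts_map] of the recording.
#' @param min_abs_c curvature magnitude below which the recording counts as
#'   never-bending.
#' @param fallback optional orientation (+1 or -1) for a never-bending
#'   recording; without one this is an error.
#' @return A list: `orientation` (+1/-1), `concave` ("left"/"right").
#' @export
assign_sides <- function(c_map, min_abs_c = 1e-6, fallback = NULL) {
  v <- c_map$values[c_map$valid]
  v <- v[!is.na(v)]
  if (!length(v) || max(abs(v)) < min_abs_c) {
    if (is.null(fallback)) stop("no dominant bend in recording")
    orientation <- fallback
  } else {
    w <- sum(v * abs(v))
    if (w == 0) {
      if (is.null(fallback)) stop("no dominant bend in recording")
      orientation <- fallback
    } else {
      # C < 0 during upward bending puts the centre of curvature on the
      # left-normal side, i.e. the concave flank on the left
      orientation <- if (w < 0) 1 else -1
    }
  }
  list(orientation = orientation,
       concave = if (orientation > 0) "left" else "right")
}

# signed side (+1 left / -1 right of the midline tangent) on which a flank lies
.flank_side <- function(flank, midline) {
  pr <- .project_polyline(as.matrix(flank[, c("x", "y")]),
                          as.matrix(midline[, c("x", "y")]))
  # .project_polyline's sign is the side of the *flank point* relative to the
  # midline tangent
  s <- pr$sign[pr$sign != 0]
  if (!length(s)) stop("cannot determine flank side")
  if (mean(s) > 0) 1 else -1
}

#' Inset contour at a fixed fraction of the local diameter
#'
#' Moves each flank vertex inward (toward the midline) by `fraction` times
#' the local diameter, then fits a principal curve at the requested df
#' through the inset points.
#'
#' @param flank tibble of flank vertices (`x`, `y`), base to tip.
#' @param midline a `midline_curve` providing positions and local widths.
#' @param fraction inset depth as a fraction of local diameter.
#' @param df principal-curve equivalent degrees of freedom.
#' @param surface_offset distance (mm) by which the supplied flank polyline
#'   already sits inside the physical surface (half a pixel for contours
#'   traced through boundary-pixel centres); subtracted from the inset depth
#'   so the inset line lands at the intended fraction of the true diameter.
#' @return A `principal_curve` (class also `inset_contour`) whose dense
#'   polyline is the smoothed inset line.
#' @export
inset_contour <- function(flank, midline, fraction = 1 / 8, df = 60,
                          surface_offset = 0) {
  P <- as.matrix(flank[, c("x", "y")])
  M <- as.matrix(midline[, c("x", "y")])
  pr <- .project_polyline(P, M)
  d <- pr$dist
  # local diameter = flank separation at the nearest midline vertex
  nb <- max.col(-(outer(P[, 1], M[, 1], "-")^2 +
                    outer(P[, 2], M[, 2], "-")^2), ties.method = "first")
  w <- midline$width[nb]
  inset_d <- pmax(fraction * w - surface_offset, 0)
  ok <- inset_d < d
  # flank vertices wrapping the tip cap or clamp edge sit too close to the
  # midline for a well-defined inset; drop them rather than the whole flank
  if (mean(ok) < 0.7 || sum(ok) < 10)
    stop("inset would cross the midline (rod too narrow for fraction = ",
         format(fraction), ")")
  P <- P[ok, , drop = FALSE]; d <- d[ok]; inset_d <- inset_d[ok]
  pr <- lapply(pr, function(v) if (length(v) == length(ok)) v[ok] else v)
  ux <- (pr$x - P[, 1]) / d; uy <- (pr$y - P[, 2]) / d
  Q <- cbind(P[, 1] + ux * inset_d, P[, 2] + uy * inset_d)
  # high-df curves on raster-noise points plateau with tiny msd oscillations;
  # a coarser tolerance avoids chasing them
  pc <- fit_principal_curve(tibble::tibble(x = Q[, 1], y = Q[, 2]), df = df,
                            tol = 1e-3, max_iter = 50)
  class(pc) <- c("inset_contour", class(pc))
  pc
}

# intersections of the line through p along unit direction n with a polyline;
# returns the signed line parameter of the intersection nearest to p, or NA
.line_polyline_hit <- function(p, n, poly, max_dist) {
  ax <- poly[-nrow(poly), 1]; ay <- poly[-nrow(poly), 2]
  bx <- poly[-1, 1] - ax; by <- poly[-1, 2] - ay
  den <- n[1] * by - n[2] * bx
  ok <- abs(den) > 1e-12
  wx <- ax - p[1]; wy <- ay - p[2]
  tt <- (wx * by - wy * bx) / den        # along the normal line
  uu <- (wx * n[2] - wy * n[1]) / (-den) # along the segment
  hit <- ok & uu >= 0 & uu <= 1 & abs(tt) <= max_dist
  if (!any(hit)) return(NA_real_)
  tt[hit][which.min(abs(tt[hit]))]
}

# bilinear sample of a raster at lab-frame mm coordinates
.sample_raster <- function(img, x, y, pixel_scale, base_px) {
  ps_mm <- pixel_scale / 1000
  col <- base_px[2] + x / ps_mm
  row <- base_px[1] - y / ps_mm
  r0 <- floor(row); c0 <- floor(col)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(r0) & !is.na(c0) &
    r0 >= 1 & r0 < nrow(img) & c0 >= 1 & c0 < ncol(img)
  if (!any(ok)) return(out)
  fr <- row[ok] - r0[ok]; fc <- col[ok] - c0[ok]
  i <- r0[ok]; j <- c0[ok]
  out[ok] <- (1 - fr) * (1 - fc) * img[cbind(i, j)] +
    fr * (1 - fc) * img[cbind(i + 1, j)] +
    (1 - fr) * fc * img[cbind(i, j + 1)] +
    fr * fc * img[cbind(i + 1, j + 1)]
  out
}

#' Sample luminescence at the median and the two inset contours
#'
#' At each parameterized median point M_i, takes the line normal to the
#' median and intersects it with the concave- and convex-side inset curves
#' (nearest intersection within twice the local width); luminescence is read
#' by bilinear interpolation at M_i and the two intersection points and
#' normalized to counts per minute by the exposure.
#'
#' @param lum_frame luminescence raster (counts).
#' @param midline a `midline_curve`.
#' @param inset_concave,inset_convex `inset_contour` objects for the two
#'   flanks.
#' @param pixel_scale microns per pixel.
#' @param base_px raster origin of the lab frame.
#' @param exposure_min exposure (minutes) for cpm normalization.
#' @return A tibble (class `lum_profiles`) with `s`, `L_m`, `L_v`, `L_c`,
#'   `LRL`, `valid`; attribute `frame_time` is carried over.
#' @export
sample_profiles <- function(lum_frame, midline, inset_concave, inset_convex,
                            pixel_scale, base_px = c(0, 0),
                            exposure_min = 1) {
  n <- nrow(midline)
  x <- midline$x; y <- midline$y
  tx <- c(x[2] - x[1], (x[-(1:2)] - x[-((n - 1):n)]) / 2, x[n] - x[n - 1])
  ty <- c(y[2] - y[1], (y[-(1:2)] - y[-((n - 1):n)]) / 2, y[n] - y[n - 1])
  tl <- sqrt(tx^2 + ty^2); tx <- tx / tl; ty <- ty / tl
  nx <- -ty; ny <- tx

  Qc <- as.matrix(inset_concave$curve[, c("x", "y")])
  Qv <- as.matrix(inset_convex$curve[, c("x", "y")])
  cx <- cy <- vx <- vy <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lim <- 2 * midline$width[i]
    tc <- .line_polyline_hit(c(x[i], y[i]), c(nx[i], ny[i]), Qc, lim)
    tv <- .line_polyline_hit(c(x[i], y[i]), c(nx[i], ny[i]), Qv, lim)
    if (!is.na(tc)) { cx[i] <- x[i] + tc * nx[i]; cy[i] <- y[i] + tc * ny[i] }
    if (!is.na(tv)) { vx[i] <- x[i] + tv * nx[i]; vy[i] <- y[i] + tv * ny[i] }
  }
  L_m <- .sample_raster(lum_frame, x, y, pixel_scale, base_px) / exposure_min
  L_c <- .sample_raster(lum_frame, cx, cy, pixel_scale, base_px) / exposure_min
  L_v <- .sample_raster(lum_frame, vx, vy, pixel_scale, base_px) / exposure_min
  valid <- !is.na(L_c) & !is.na(L_v) & L_c > 0 & L_v > 0
  lrl <- rep(NA_real_, n)
  lrl[valid] <- log10(L_c[valid] / L_v[valid])
  out <- tibble::tibble(s = midline$s, L_m = L_m, L_v = L_v, L_c = L_c,
                        LRL = lrl, valid = valid)
  attr(out, "frame_time") <- attr(midline, "frame_time")
  class(out) <- c("lum_profiles", class(out))
  out
}

#' Smooth luminescence profiles along arc length
#'
#' Each of L_m, L_v, L_c is smoothed against s with a cubic smoothing spline
#' at equivalent df = n/2 (masked samples excluded from the fit); LRL is
#' recomputed from the smoothed L_c and L_v.
#'
#' @param profiles a `lum_profiles` tibble.
#' @param df_frac spline df fraction.
#' @return A smoothed `lum_profiles` tibble.
#' @export
smooth_profiles <- function(profiles, df_frac = 0.5) {
  sm <- function(y) {
    ok <- profiles$valid & !is.na(y)
    if (sum(ok) < 8) return(rep(NA_real_, nrow(profiles)))
    fit <- stats::smooth.spline(profiles$s[ok], y[ok],
                                df = max(2, df_frac * sum(ok)))
    out <- rep(NA_real_, nrow(profiles))
    out[ok] <- stats::predict(fit, profiles$s[ok])$y
    out
  }
  out <- profiles
  out$L_m <- sm(profiles$L_m)
  out$L_v <- sm(profiles$L_v)
  out$L_c <- sm(profiles$L_c)
  ok <- out$valid & !is.na(out$L_c) & !is.na(out$L_v) &
    out$L_c > 0 & out$L_v > 0
  out$LRL <- ifelse(ok, log10(out$L_c / out$L_v), NA_real_)
  out$valid <- ok
  out
}

#' Stack per-frame luminescence profiles into t-s maps
#'
#' @param profiles_list list of `lum_profiles` (one per frame, common arc
#'   step).
#' @param times frame times (h); defaults to the profiles' `frame_time`
#'   attributes.
#' @return List of [ts_map]s: `LRL`, `L_m`, `L_v`, `L_c`.
#' @export
lrl_map <- function(profiles_list, times = NULL) {
  if (is.null(times))
    times <- vapply(profiles_list, function(p) attr(p, "frame_time"), 0)
  stopifnot(all(diff(times) > 0))
  ns_each <- vapply(profiles_list, nrow, 0L)
  s <- profiles_list[[which.max(ns_each)]]$s
  step <- stats::median(diff(s))
  for (p in profiles_list)
    if (abs(stats::median(diff(p$s)) - step) > 0.01 * step)
      stop("inconsistent arc grids across frames")
  nt <- length(times); ns <- length(s)
  mk <- function(col) {
    m <- matrix(NA_real_, nt, ns)
    for (i in seq_len(nt)) {
      p <- profiles_list[[i]]; k <- nrow(p)
      v <- p[[col]]
      v[!p$valid] <- NA_real_
      m[i, seq_len(k)] <- v
    }
    m
  }
  list(LRL = ts_map(times, s, mk("LRL"), field = "LRL", units = "log10"),
       L_m = ts_map(times, s, mk("L_m"), field = "L_m", units = "cpm"),
       L_v = ts_map(times, s, mk("L_v"), field = "L_v", units = "cpm"),
       L_c = ts_map(times, s, mk("L_c"), field = "L_c", units = "cpm"))
}

#' Full luminescence analysis of a rendered or imaged series
#'
#' For each frame: identify the concave and convex flanks from the recording
#' orientation, build 1/8-diameter inset contours (df 60), sample and smooth
#' the profiles, and stack the LRL map.
#'
#' @param lum_frames list of luminescence rasters.
#' @param midlines list of `midline_curve`s with `pair` attributes (from
#'   [extract_midline()]).
#' @param c_map curvature [ts_map] for side assignment.
#' @param pixel_scale microns per pixel.
#' @param base_px raster origin.
#' @param fraction inset fraction of local diameter.
#' @param df_inset principal-curve df of the inset contours.
#' @param exposure_min exposure per frame (minutes).
#' @param times frame times.
#' @param smooth logical: apply [smooth_profiles()].
#' @return List: `profiles` (list of `lum_profiles`), `maps`
#'   (see [lrl_map()]), `sides` (from [assign_sides()]).
#' @export
luminescence_analysis <- function(lum_frames, midlines, c_map, pixel_scale,
                                  base_px = c(0, 0), fraction = 1 / 8,
                                  df_inset = 60, exposure_min = 1,
                                  times = NULL, smooth = TRUE) {
  sides <- assign_sides(c_map)
  profiles <- vector("list", length(lum_frames))
  for (i in seq_along(lum_frames)) {
    ml <- midlines[[i]]
    pair <- attr(ml, "pair")
    if (is.null(pair)) stop("midline ", i, " lacks the contour pair attribute")
    s1 <- .flank_side(pair$side1, ml)
    concave_flank <- if (s1 == sides$orientation) pair$side1 else pair$side2
    convex_flank <- if (s1 == sides$orientation) pair$side2 else pair$side1
    off <- 0.5 * pixel_scale / 1000
    ic <- inset_contour(concave_flank, ml, fraction = fraction, df = df_inset,
                        surface_offset = off)
    iv <- inset_contour(convex_flank, ml, fraction = fraction, df = df_inset,
                        surface_offset = off)
    pr <- sample_profiles(lum_frames[[i]], ml, ic, iv, pixel_scale, base_px,
                          exposure_min = exposure_min)
    if (smooth) pr <- smooth_profiles(pr)
    profiles[[i]] <- pr
  }
  list(profiles = profiles, maps = lrl_map(profiles, times), sides = sides)
}
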