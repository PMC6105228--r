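#' Binarize a bright-field frame
#'
#' Thresholds the frame (Otsu by default), keeps the largest connected
#' foreground component and fills its holes.
#'
#' @param frame single-channel numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold for `method = "fixed"`, on the frame's own scale.
#' @return Logical mask matrix.
#' @export
binarize <- function(frame, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(frame), is.numeric(frame))
  rng <- range(frame, finite = TRUE)
  if (diff(rng) == 0) stop("no foreground: frame is constant")
  f <- (frame - rng[1]) / diff(rng)
  th <- if (method == "otsu") EBImage::otsu(EBImage::Image(f)) else {
    if (is.null(threshold)) stop("threshold required for method = 'fixed'")
    (threshold - rng[1]) / diff(rng)
  }
  mask <- f > th
  if (!any(mask)) stop("no foreground above threshold")
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  tab <- tabulate(as.integer(lab))
  keep <- which.max(tab)
  mask <- matrix(as.integer(lab) == keep, nrow(frame), ncol(frame))
  mask <- EBImage::fillHull(EBImage::Image(mask)) > 0
  mask <- matrix(as.logical(mask), nrow(frame), ncol(frame))
  touching <- sum(any(mask[1, ]), any(mask[nrow(mask), ]),
                  any(mask[, 1]), any(mask[, ncol(mask)]))
  if (touching >= 3)
    stop("foreground touches ", touching, " raster borders; not a clamped rod view")
  mask
}

# geodesic distances on the mask's 8-connected pixel lattice
.mask_graph <- function(mask) {
  idx <- which(mask)
  id <- matrix(NA_integer_, nrow(mask), ncol(mask))
  id[idx] <- seq_along(idx)
  rc <- arrayInd(idx, dim(mask))
  edges <- list()
  shifts <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (k in seq_len(nrow(shifts))) {
    r2 <- rc[, 1] + shifts[k, 1]; c2 <- rc[, 2] + shifts[k, 2]
    ok <- r2 >= 1 & r2 <= nrow(mask) & c2 >= 1 & c2 <= ncol(mask)
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    edges[[k]] <- cbind(id[idx[ok]], id[cbind(r2[ok], c2[ok])])
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  list(g = g, rc = rc, id = id)
}

#' Extract the two flank contours of a rod mask
#'
#' Traces the mask outline, finds the two extremities of maximal geodesic
#' (within-mask) separation, and splits the closed outline there into the two
#' flank polylines, each ordered base to tip. Coordinates are returned in the
#' lab frame (mm, y up) via [raster_to_lab()].
#'
#' @param mask logical matrix from [binarize()].
#' @param pixel_scale microns per pixel.
#' @param base_px raster origin passed to [raster_to_lab()].
#' @param anchor optional lab-frame `c(x, y)` (mm) identifying the base end:
#'   the extremity nearest the anchor becomes the base. Default: the
#'   extremity closer to the raster border.
#' @param min_aspect minimal geodesic-length-to-width ratio; below it the
#'   mask is rejected as not rod-like.
#' @return An object of class `contour_pair`: tibbles `side1`, `side2`
#'   (`x`, `y` in mm), plus `base` and `tip` lab coordinates.
#' @export
extract_contours <- function(mask, pixel_scale = 1, base_px = c(0, 0),
                             anchor = NULL, min_aspect = 3) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  oc <- EBImage::ocontour(EBImage::Image(mask))
  if (length(oc) == 0) stop("no contour found")
  outline <- oc[[which.max(vapply(oc, nrow, 0L))]] + 1L  # (row, col), 1-based

  mg <- .mask_graph(mask)
  v0 <- mg$id[outline[1, 1], outline[1, 2]]
  d0 <- as.vector(igraph::distances(mg$g, v = v0))
  p1 <- which.max(d0)
  d1 <- as.vector(igraph::distances(mg$g, v = p1))
  p2 <- which.max(d1)
  geo_len <- d1[p2]
  width_est <- sum(mask) / max(geo_len, 1)
  if (geo_len / max(width_est, 1) < min_aspect)
    stop("mask is not rod-like (aspect ratio < ", min_aspect, ")")

  ex1 <- mg$rc[p1, ]; ex2 <- mg$rc[p2, ]
  near <- function(p) which.min((outline[, 1] - p[1])^2 + (outline[, 2] - p[2])^2)
  i1 <- near(ex1); i2 <- near(ex2)
  lo <- min(i1, i2); hi <- max(i1, i2)
  n <- nrow(outline)
  seg_a <- outline[lo:hi, , drop = FALSE]
  seg_b <- outline[c(hi:n, 1:lo), , drop = FALSE]
  # the split vertices belong to both arcs; keep them on one side only
  if (nrow(seg_b) > 3) seg_b <- seg_b[-c(1, nrow(seg_b)), , drop = FALSE]

  to_lab <- function(m) raster_to_lab(m[, 1], m[, 2], pixel_scale, base_px)
  e1 <- to_lab(rbind(ex1)); e2 <- to_lab(rbind(ex2))
  ends <- rbind(c(e1$x, e1$y), c(e2$x, e2$y))

  base_i <- if (!is.null(anchor)) {
    which.min((ends[, 1] - anchor[1])^2 + (ends[, 2] - anchor[2])^2)
  } else {
    # extremity closer to any raster border
    border_d <- function(p) min(p[1] - 1, nrow(mask) - p[1],
                                p[2] - 1, ncol(mask) - p[2])
    which.min(c(border_d(ex1), border_d(ex2)))
  }
  base_rc <- if (base_i == 1) ex1 else ex2

  orient <- function(seg) {
    # order base -> tip by proximity of the first vertex to the base extremity
    dhead <- sum((seg[1, ] - base_rc)^2)
    dtail <- sum((seg[nrow(seg), ] - base_rc)^2)
    if (dtail < dhead) seg[nrow(seg):1, , drop = FALSE] else seg
  }
  side1 <- to_lab(orient(seg_a)); side2 <- to_lab(orient(seg_b))
  structure(list(side1 = side1, side2 = side2,
                 base = unlist(if (base_i == 1) e1 else e2),
                 tip = unlist(if (base_i == 1) e2 else e1)),
            class = "contour_pair")
}

# nearest points on polyline Q for each row of P; returns list(point, dist, sign)
# sign: side of Q's local tangent on which P lies (+1 left, -1 right)
.project_polyline <- function(P, Q) {
  n <- nrow(P); m <- nrow(Q)
  ax <- Q[-m, 1]; ay <- Q[-m, 2]
  dxq <- Q[-1, 1] - ax; dyq <- Q[-1, 2] - ay
  len2 <- pmax(dxq^2 + dyq^2, .Machine$double.eps)
  wx <- outer(P[, 1], ax, "-"); wy <- outer(P[, 2], ay, "-")
  tt <- sweep(sweep(wx, 2, dxq, "*") + sweep(wy, 2, dyq, "*"), 2, len2, "/")
  tt <- pmin(pmax(tt, 0), 1)
  qx <- sweep(tt, 2, dxq, "*"); qy <- sweep(tt, 2, dyq, "*")
  rx <- wx - qx; ry <- wy - qy
  d2 <- rx^2 + ry^2
  j <- max.col(-d2, ties.method = "first")
  ii <- cbind(seq_len(n), j)
  cross <- dxq[j] * ry[ii] - dyq[j] * rx[ii]
  list(x = ax[j] + qx[ii], y = ay[j] + qy[ii],
       dist = sqrt(d2[ii]), sign = sign(cross),
       seg = j, tfrac = tt[ii])
}

#' Midpoints between the two flank contours
#'
#' Pairs each vertex of one flank with its nearest point on the other flank,
#' records the midpoint and the flank separation (local width), runs the
#' symmetric pass, and merges near-duplicate midpoints.
#'
#' @param pair a `contour_pair`.
#' @param width_correction additive width correction (mm). Traced contours
#'   run through the centres of boundary pixels, half a pixel inside the
#'   physical surface on each flank, so the raw flank separation
#'   underestimates the diameter by about one pixel; pass the pixel size in
#'   mm to compensate.
#' @return A tibble (class `midpoint_cloud`) with `x`, `y`, `width` (mm).
#' @export
midpoints <- function(pair, width_correction = 0) {
  stopifnot(inherits(pair, "contour_pair"))
  P1 <- as.matrix(pair$side1); P2 <- as.matrix(pair$side2)
  pr12 <- .project_polyline(P1, P2)
  pr21 <- .project_polyline(P2, P1)
  sgn <- c(pr12$sign, -pr21$sign)
  sgn <- sgn[sgn != 0]
  if (length(sgn) > 10 && min(mean(sgn > 0), mean(sgn < 0)) > 0.05)
    stop("flank contours cross")
  pts <- rbind(cbind((P1[, 1] + pr12$x) / 2, (P1[, 2] + pr12$y) / 2),
               cbind((P2[, 1] + pr21$x) / 2, (P2[, 2] + pr21$y) / 2))
  w <- c(pr12$dist, pr21$dist)
  # keep the shaft: flank separation collapses around the tip cap and the
  # clamp edge, where vertex pairing is meaningless
  wmed <- stats::median(w)
  shaft <- w > 0.5 * wmed & w < 1.5 * wmed
  d_base <- sqrt((pts[, 1] - pair$base[1])^2 + (pts[, 2] - pair$base[2])^2)
  d_tip <- sqrt((pts[, 1] - pair$tip[1])^2 + (pts[, 2] - pair$tip[2])^2)
  shaft <- shaft & d_base > 0.75 * wmed & d_tip > 0.75 * wmed
  pts <- pts[shaft, , drop = FALSE]; w <- w[shaft] + width_correction
  spacing <- stats::median(sqrt(rowSums(diff(P1)^2)))
  tol <- spacing / 4
  # greedy duplicate merge on a rounded grid
  key <- paste(round(pts[, 1] / tol), round(pts[, 2] / tol))
  keep <- !duplicated(key)
  out <- tibble::tibble(x = pts[keep, 1], y = pts[keep, 2], width = w[keep])
  class(out) <- c("midpoint_cloud", class(out))
  out
}

#' Fit a principal curve through a planar point cloud
#'
#' Hastie-Stuetzle iteration: initialize on the first principal component,
#' then alternate (i) projection of every point to its nearest point on the
#' current curve, giving arc-length ordinates, and (ii) coordinate-wise cubic
#' smoothing-spline fits against those ordinates at the requested equivalent
#' degrees of freedom (trace of the smoother matrix, the standard spline df
#' convention). Stops when the relative change of the mean squared orthogonal
#' distance falls below `tol`.
#'
#' @param points data frame with columns `x`, `y` (>= 10 rows).
#' @param df equivalent degrees of freedom of the coordinate smoothers.
#' @param tol relative convergence tolerance on the mean squared distance.
#' @param max_iter iteration cap; non-convergence yields a warning and the
#'   last iterate, flagged.
#' @param n_dense number of dense evaluation points along the curve.
#' @return An object of class `principal_curve`: `curve` (tibble `arclen`,
#'   `x`, `y`), `length` (mm), `df`, `msd`, `converged`, `iterations`.
#' @export
fit_principal_curve <- function(points, df = 10, tol = 1e-4, max_iter = 30,
                                n_dense = 512) {
  P <- as.matrix(points[, c("x", "y")])
  if (nrow(P) < 10) stop("need at least 10 points")

  ctr <- colMeans(P)
  v <- svd(sweep(P, 2, ctr))$v[, 1]
  lambda <- as.vector(sweep(P, 2, ctr) %*% v)

  dense <- NULL; msd_prev <- Inf; converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    # smooth.spline caps df at the number of distinct ordinates
    df_use <- max(2, min(df, length(unique(lambda)) - 1))
    fx <- stats::smooth.spline(lambda, P[, 1], df = df_use)
    fy <- stats::smooth.spline(lambda, P[, 2], df = df_use)
    lg <- seq(min(lambda), max(lambda), length.out = n_dense)
    cx <- stats::predict(fx, lg)$y; cy <- stats::predict(fy, lg)$y
    arc <- c(0, cumsum(sqrt(diff(cx)^2 + diff(cy)^2)))
    pr <- .project_polyline(P, cbind(cx, cy))
    d2m <- (P[, 1] - pr$x)^2 + (P[, 2] - pr$y)^2
    seg_len <- sqrt(diff(cx)^2 + diff(cy)^2)
    lambda <- arc[pr$seg] + pr$tfrac * seg_len[pr$seg]
    msd <- mean(d2m)
    if (is.finite(msd_prev) &&
        abs(msd_prev - msd) < tol * max(msd_prev, .Machine$double.eps)) {
      converged <- TRUE
      dense <- tibble::tibble(arclen = arc, x = cx, y = cy)
      break
    }
    msd_prev <- msd
    dense <- tibble::tibble(arclen = arc, x = cx, y = cy)
  }
  if (!converged)
    warning("principal curve did not converge in ", max_iter, " iterations")
  structure(list(curve = dense, length = max(dense$arclen), df = df,
                 msd = msd_prev, converged = converged, iterations = it),
            class = "principal_curve")
}

#' @export
print.principal_curve <- function(x, ...) {
  cat("<principal_curve> length ", format(x$length, digits = 4),
      " mm, df ", x$df, ", msd ", format(x$msd, digits = 3),
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' Resample the median at a fixed arc-length step
#'
#' Evaluates the fitted principal curve at s = 0, step, 2*step, ... from the
#' base, attaching the local organ width interpolated from the midpoint
#' cloud.
#'
#' @param curve a `principal_curve`.
#' @param cloud a `midpoint_cloud` supplying local widths.
#' @param step arc-length step (mm); default 19.9 um.
#' @param base optional lab `c(x, y)`: the curve end nearer this point
#'   becomes s = 0. Default keeps the curve's own orientation.
#' @param frame_time frame time stamp (h) carried as an attribute.
#' @return A tibble (class `midline_curve`) with `s`, `x`, `y`, `width`.
#' @export
resample_median <- function(curve, cloud, step = 0.0199, base = NULL,
                            frame_time = NA_real_) {
  stopifnot(inherits(curve, "principal_curve"))
  cv <- curve$curve
  if (curve$length < 5 * step) stop("curve shorter than 5 steps")
  if (!is.null(base)) {
    dhead <- (cv$x[1] - base[1])^2 + (cv$y[1] - base[2])^2
    dtail <- (cv$x[nrow(cv)] - base[1])^2 + (cv$y[nrow(cv)] - base[2])^2
    if (dtail < dhead) {
      cv <- cv[nrow(cv):1, ]
      cv$arclen <- max(cv$arclen) - cv$arclen
    }
  }
  s <- seq(0, curve$length, by = step)
  x <- stats::approx(cv$arclen, cv$x, xout = s)$y
  y <- stats::approx(cv$arclen, cv$y, xout = s)$y
  # width: inverse-distance-weighted mean of the 4 nearest cloud points
  W <- as.matrix(cloud[, c("x", "y")])
  width <- vapply(seq_along(s), function(i) {
    d2 <- (W[, 1] - x[i])^2 + (W[, 2] - y[i])^2
    k <- order(d2)[seq_len(min(4, nrow(W)))]
    wts <- 1 / pmax(sqrt(d2[k]), 1e-9)
    sum(cloud$width[k] * wts) / sum(wts)
  }, 0)
  out <- tibble::tibble(s = s, x = x, y = y, width = width)
  attr(out, "frame_time") <- frame_time
  class(out) <- c("midline_curve", class(out))
  out
}

#' Extract an arc-length-parameterized midline from a bright-field frame
#'
#' Convenience wrapper: [binarize()] then [extract_contours()],
#' [midpoints()], [fit_principal_curve()] and [resample_median()].
#'
#' @param frame bright-field matrix.
#' @param pixel_scale microns per pixel.
#' @param base_px raster origin for the lab frame.
#' @param anchor optional base anchor (lab mm), see [extract_contours()].
#' @param df_median principal-curve df for the median.
#' @param step arc-length step (mm).
#' @param frame_time time stamp (h).
#' @param threshold_method passed to [binarize()].
#' @return A `midline_curve` tibble with attributes `pair` (the
#'   `contour_pair`) and `cloud` (the `midpoint_cloud`).
#' @export
extract_midline <- function(frame, pixel_scale, base_px = c(0, 0),
                            anchor = NULL, df_median = 10, step = 0.0199,
                            frame_time = NA_real_,
                            threshold_method = "otsu") {
  mask <- binarize(frame, method = threshold_method)
  pair <- extract_contours(mask, pixel_scale, base_px, anchor = anchor)
  cloud <- midpoints(pair, width_correction = pixel_scale / 1000)
  pc <- fit_principal_curve(cloud, df = df_median)
  ml <- resample_median(pc, cloud, step = step, base = pair$base,
                        frame_time = frame_time)
  ml <- .extend_to_mask(ml, mask, pixel_scale, base_px, step)
  attr(ml, "pair") <- pair
  attr(ml, "cloud") <- cloud
  ml
}

# distance travelled from pt along dir (unit, mm) before leaving the mask
.march_in_mask <- function(pt, dir, mask, pixel_scale, base_px, max_dist) {
  ps_mm <- pixel_scale / 1000
  step <- 0.2 * ps_mm
  d <- 0
  while (d < max_dist) {
    q <- pt + (d + step) * dir
    r <- round(base_px[1] - q[2] / ps_mm); c <- round(base_px[2] + q[1] / ps_mm)
    if (r < 1 || r > nrow(mask) || c < 1 || c > ncol(mask) || !mask[r, c])
      break
    d <- d + step
  }
  d
}

# midpoint pairing cannot reach into the clamp edge or the rounded tip cap,
# so the fitted median stops short of the organ ends; extend it tangentially
# to the silhouette boundary (minus half the local width at the rounded tip)
# and re-grid so s = 0 sits at the base edge
.extend_to_mask <- function(ml, mask, pixel_scale, base_px, step) {
  n <- nrow(ml)
  wb <- ml$width[1]; wt <- ml$width[n]
  # local tangent angle and curvature near each end (from ~0.3 mm of curve),
  # so the extension continues the end arc instead of kinking straight
  k <- min(n, max(4L, ceiling(0.3 / step)))
  end_arc <- function(idx) {
    th <- atan2(diff(ml$y[idx]), diff(ml$x[idx]))
    th <- th[1] + c(0, cumsum((diff(th) + pi) %% (2 * pi) - pi))
    fit <- stats::lm(th ~ ml$s[idx][-1])
    list(kappa = unname(stats::coef(fit)[2]))
  }
  kb <- end_arc(1:k)$kappa
  kt <- end_arc((n - k + 1):n)$kappa
  back <- c(ml$x[1] - ml$x[2], ml$y[1] - ml$y[2])
  back <- back / sqrt(sum(back^2))
  fwd <- c(ml$x[n] - ml$x[n - 1], ml$y[n] - ml$y[n - 1])
  fwd <- fwd / sqrt(sum(fwd^2))
  e_base <- .march_in_mask(c(ml$x[1], ml$y[1]), back, mask, pixel_scale,
                           base_px, 3 * wb)
  e_tip <- max(0, .march_in_mask(c(ml$x[n], ml$y[n]), fwd, mask, pixel_scale,
                                 base_px, 3 * wt) - wt / 2)
  arc_march <- function(p0, th0, kappa, len, dirsign) {
    # march distance len from p0, tangent angle th0, signed curvature kappa;
    # dirsign -1 walks backward along the curve
    m <- max(1L, ceiling(len / (step / 4)))
    d <- len / m
    th <- th0; p <- p0
    out <- matrix(0, m, 2)
    for (i in seq_len(m)) {
      th <- th + dirsign * kappa * d
      p <- p + dirsign * d * c(cos(th), sin(th))
      out[i, ] <- p
    }
    out
  }
  th_b <- atan2(ml$y[2] - ml$y[1], ml$x[2] - ml$x[1])
  th_t <- atan2(ml$y[n] - ml$y[n - 1], ml$x[n] - ml$x[n - 1])
  ext_b <- if (e_base > step / 8)
    arc_march(c(ml$x[1], ml$y[1]), th_b, kb, e_base, -1) else NULL
  ext_t <- if (e_tip > step / 8)
    arc_march(c(ml$x[n], ml$y[n]), th_t, kt, e_tip, 1) else NULL
  nb <- if (is.null(ext_b)) 0L else nrow(ext_b)
  px <- c(if (nb) rev(ext_b[, 1]), ml$x, ext_t[, 1])
  py <- c(if (nb) rev(ext_b[, 2]), ml$y, ext_t[, 2])
  arc <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
  s_new <- seq(0, arc[length(arc)], by = step)
  warc <- c(rep(wb, nb), ml$width, rep(wt, if (is.null(ext_t)) 0 else nrow(ext_t)))
  out <- tibble::tibble(
    s = s_new,
    x = stats::approx(arc, px, xout = s_new)$y,
    y = stats::approx(arc, py, xout = s_new)$y,
    width = stats::approx(arc, warc, xout = s_new)$y
  )
  attr(out, "frame_time") <- attr(ml, "frame_time")
  class(out) <- c("midline_curve", class(out))
  out
}
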