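#' Deflection angle along a midline
#'
#' Signed angle between the local base-to-tip tangent and the upward
#' vertical: 0 = vertical, 90 = horizontal toward the initial turning side,
#' negative = overshoot past vertical. Tangents come from centred differences
#' of the midline points; the angle is unwrapped continuously along s.
#'
#' @param midline a `midline_curve` (or any tibble with `s`, `x`, `y`).
#' @param up lab-frame upward unit vector (opposite to gravity).
#' @param side lab-frame unit vector toward the initial turning side.
#' @return A tibble with `s` (mm) and `A` (degrees).
#' @export
deflection_angle <- function(midline, up = c(0, 1), side = c(1, 0)) {
  n <- nrow(midline)
  if (n < 3) stop("need at least 3 midline points")
  x <- midline$x; y <- midline$y
  tx <- c(x[2] - x[1], (x[-(1:2)] - x[-((n - 1):n)]) / 2, x[n] - x[n - 1])
  ty <- c(y[2] - y[1], (y[-(1:2)] - y[-((n - 1):n)]) / 2, y[n] - y[n - 1])
  tl <- sqrt(tx^2 + ty^2)
  if (any(tl == 0)) stop("degenerate (zero-length) tangent")
  tx <- tx / tl; ty <- ty / tl
  a <- atan2(tx * side[1] + ty * side[2], tx * up[1] + ty * up[2])
  # unwrap along s
  if (n > 1) {
    d <- diff(a)
    d <- d - 2 * pi * round(d / (2 * pi))
    a <- a[1] + c(0, cumsum(d))
  }
  tibble::tibble(s = midline$s, A = a * 180 / pi)
}

#' Curvature from a deflection-angle profile
#'
#' Fits a cubic smoothing spline to A(s) at equivalent df = n/2 (the
#' half-the-data-size rule) and evaluates its first derivative: C = dA/ds in
#' mm^-1, with the angle handled in radians internally.
#'
#' @param angle tibble with `s` (mm) and `A` (degrees).
#' @param df_frac equivalent df as a fraction of the sample count.
#' @return A tibble with `s`, `A_smooth` (degrees), `C` (mm^-1). Fewer than
#'   8 samples yields masked (NA) output.
#' @export
curvature <- function(angle, df_frac = 0.5) {
  n <- nrow(angle)
  if (n < 8)
    return(tibble::tibble(s = angle$s, A_smooth = NA_real_, C = NA_real_))
  a_rad <- angle$A * pi / 180
  fit <- stats::smooth.spline(angle$s, a_rad, df = max(2, df_frac * n))
  a_hat <- stats::predict(fit, angle$s)$y
  c_hat <- stats::predict(fit, angle$s, deriv = 1)$y
  tibble::tibble(s = angle$s, A_smooth = a_hat * 180 / pi, C = c_hat)
}

#' Assemble angle and curvature fields from a midline series
#'
#' Computes A(s) and C(s) per frame and stacks them on the common (t, s)
#' grid, masking arc lengths beyond each frame's organ length.
#'
#' @param midlines list of `midline_curve` objects (one per frame, equal
#'   arc step).
#' @param times frame times (h); defaults to the midlines' `frame_time`
#'   attributes.
#' @param df_frac spline df fraction for [curvature()].
#' @param up,side axis conventions for [deflection_angle()].
#' @return List of [ts_map]s: `A` (raw, deg), `A_smooth` (deg), `C` (mm^-1).
#' @export
kinematics_fields <- function(midlines, times = NULL, df_frac = 0.5,
                              up = c(0, 1), side = c(1, 0)) {
  if (is.null(times))
    times <- vapply(midlines, function(m) attr(m, "frame_time"), 0)
  stopifnot(length(times) == length(midlines), all(diff(times) > 0))
  ns_each <- vapply(midlines, nrow, 0L)
  s <- midlines[[which.max(ns_each)]]$s
  nt <- length(times); ns <- length(s)
  A <- As <- C <- matrix(NA_real_, nt, ns)
  for (i in seq_len(nt)) {
    ang <- deflection_angle(midlines[[i]], up = up, side = side)
    cv <- curvature(ang, df_frac = df_frac)
    k <- nrow(ang)
    A[i, seq_len(k)] <- ang$A
    As[i, seq_len(k)] <- cv$A_smooth
    C[i, seq_len(k)] <- cv$C
  }
  list(A = ts_map(times, s, A, field = "A", units = "deg"),
       A_smooth = ts_map(times, s, As, field = "A", units = "deg"),
       C = ts_map(times, s, C, field = "C", units = "mm^-1"))
}

#' Curvature rate and prediction error over time
#'
#' For each arc position s with at least `min_n` valid timepoints, fits a
#' cubic smoothing spline of C against t at equivalent df = n/2. The spline
#' values are the predicted C, its first derivative is the curvature rate
#' dC/dt, and the standard error of the estimate is
#' SEE = sqrt(RSS / (n - df)) with df the spline's equivalent degrees of
#' freedom.
#'
#' @param c_map curvature [ts_map].
#' @param df_frac spline df fraction.
#' @param min_n minimum valid timepoints per s (rows with fewer are masked).
#' @return List: `predicted` ([ts_map] of predicted C), `dCdt` ([ts_map],
#'   mm^-1 h^-1), `see` (tibble `s`, `see`, `n`, `df`).
#' @export
curvature_rate <- function(c_map, df_frac = 0.5, min_n = 8) {
  stopifnot(inherits(c_map, "ts_map"))
  nt <- length(c_map$t); ns <- length(c_map$s)
  pred <- rate <- matrix(NA_real_, nt, ns)
  see <- n_at <- df_at <- rep(NA_real_, ns)
  for (j in seq_len(ns)) {
    ok <- c_map$valid[, j] & !is.na(c_map$values[, j])
    n <- sum(ok)
    if (n < min_n) next
    fit <- stats::smooth.spline(c_map$t[ok], c_map$values[ok, j],
                                df = max(2, df_frac * n))
    pred[ok, j] <- stats::predict(fit, c_map$t[ok])$y
    rate[ok, j] <- stats::predict(fit, c_map$t[ok], deriv = 1)$y
    rss <- sum((c_map$values[ok, j] - pred[ok, j])^2)
    df_eq <- fit$df
    see[j] <- sqrt(rss / max(n - df_eq, 1))
    n_at[j] <- n; df_at[j] <- df_eq
  }
  list(predicted = ts_map(c_map$t, c_map$s, pred, field = "C_pred",
                          units = "mm^-1"),
       dCdt = ts_map(c_map$t, c_map$s, rate, field = "dCdt",
                     units = "mm^-1 h^-1"),
       see = tibble::tibble(s = c_map$s, see = see, n = n_at, df = df_at))
}

#' SEE-to-curvature ratio map
#'
#' log10 of the ratio of the per-s standard error of the estimate to the
#' magnitude of the observed curvature; large values flag (t, s) regions
#' where the curvature-rate estimate is unreliable.
#'
#' @param c_map observed-curvature [ts_map].
#' @param cr result of [curvature_rate()].
#' @return A [ts_map] of log10(SEE / |C|), masked where C = 0.
#' @export
see_ratio_map <- function(c_map, cr) {
  see_row <- matrix(rep(cr$see$see, each = length(c_map$t)),
                    length(c_map$t), length(c_map$s))
  v <- log10(see_row / abs(c_map$values))
  valid <- c_map$valid & !is.na(v) & is.finite(v)
  ts_map(c_map$t, c_map$s, v, valid, field = "log10(SEE/|C|)", units = "")
}

#' Detect trough or height paths in a t-s field
#'
#' For each arc position, locates local extrema of the field over time that
#' are deeper (troughs) or higher (heights) than `depth_frac` of the global
#' extreme, then links extrema across adjacent arc positions by nearest-time
#' continuity (allowing gaps of up to two arc rows). Paths spanning less
#' than `min_extent` of arc length are discarded.
#'
#' @param field a [ts_map] (e.g. the dC/dt map).
#' @param polarity `"trough"` (negative extrema) or `"height"` (positive).
#' @param min_extent minimum arc-length span of a reported path (mm).
#' @param depth_frac fraction of the global extreme an extremum must reach.
#' @param t_window maximum time jump between linked extrema (h).
#' @param max_gap maximum number of consecutive arc rows a path may skip.
#' @return A list of `trough_path` tibbles (`t`, `s`, `value`), each with
#'   attribute `polarity`, ordered by increasing s.
#' @export
detect_extremal_paths <- function(field, polarity = c("trough", "height"),
                                  min_extent = 0.5, depth_frac = 0.5,
                                  t_window = 0.6, max_gap = 2L) {
  polarity <- match.arg(polarity)
  sgn <- if (polarity == "trough") 1 else -1
  V <- field$values * sgn                 # troughs of V (negative extremes)
  if (all(is.na(V))) return(list())
  gmin <- min(V, na.rm = TRUE)
  if (gmin >= 0) return(list())
  thr <- depth_frac * gmin
  ns <- length(field$s); nt <- length(field$t)

  paths <- list()   # each: list(t_idx, rows = tibble, gap, open)
  for (j in seq_len(ns)) {
    v <- V[, j]; ok <- field$valid[, j] & !is.na(v)
    cand <- integer(0)
    for (i in which(ok)) {
      lo <- if (i > 1 && ok[i - 1]) v[i] <= v[i - 1] else TRUE
      hi <- if (i < nt && ok[i + 1]) v[i] <= v[i + 1] else TRUE
      if (lo && hi && v[i] <= thr) cand <- c(cand, i)
    }
    used <- rep(FALSE, length(cand))
    for (p in seq_along(paths)) {
      if (!paths[[p]]$open) next
      if (length(cand)) {
        dt_ <- abs(field$t[cand] - paths[[p]]$t_last)
        pick <- which(dt_ <= t_window & !used)
        if (length(pick)) {
          # nearest in t; deeper wins ties
          best <- pick[order(dt_[pick], v[cand[pick]])][1]
          i <- cand[best]; used[best] <- TRUE
          paths[[p]]$rows <- rbind(paths[[p]]$rows,
                                   data.frame(t = field$t[i], s = field$s[j],
                                              value = field$values[i, j]))
          paths[[p]]$t_last <- field$t[i]
          paths[[p]]$gap <- 0L
          next
        }
      }
      paths[[p]]$gap <- paths[[p]]$gap + 1L
      if (paths[[p]]$gap > max_gap) paths[[p]]$open <- FALSE
    }
    for (k in which(!used)) {
      i <- cand[k]
      paths[[length(paths) + 1]] <-
        list(t_last = field$t[i], gap = 0L, open = TRUE,
             rows = data.frame(t = field$t[i], s = field$s[j],
                               value = field$values[i, j]))
    }
  }
  out <- list()
  for (p in paths) {
    span <- diff(range(p$rows$s))
    if (span >= min_extent) {
      tb <- tibble::as_tibble(p$rows)
      attr(tb, "polarity") <- polarity
      class(tb) <- c("trough_path", class(tb))
      out[[length(out) + 1]] <- tb
    }
  }
  out
}

#' Align a trough path with the deflection-angle field
#'
#' Reads the deflection angle at each path vertex (bilinear interpolation on
#' the t-s grid), snaps the median to the nearest multiple of `resolution`,
#' and reports the RMS deviation of the vertex angles from that aligned
#' angle.
#'
#' @param path a `trough_path`.
#' @param a_map deflection-angle [ts_map] (degrees).
#' @param resolution angular resolution of the alignment (degrees).
#' @return A tibble with `aligned_angle` (deg), `residual` (deg RMS), `n`.
#' @export
align_with_angle <- function(path, a_map, resolution = 5) {
  a <- ts_interp(a_map, path$t, path$s)
  a <- a[!is.na(a)]
  if (!length(a)) stop("path vertices fall outside the angle field")
  aligned <- round(stats::median(a) / resolution) * resolution
  tibble::tibble(aligned_angle = aligned,
                 residual = sqrt(mean((a - aligned)^2)),
                 n = length(a))
}
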