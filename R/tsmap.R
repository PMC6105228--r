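#' A value field on the time-arclength (t-s) plane
#'
#' Container for kymograph-like fields: deflection angle A, curvature C,
#' curvature rate, luminescence profiles, LRL and derived maps. Values are
#' held as a frames-by-arcpoints matrix with a validity mask (false where the
#' organ is shorter than s at that frame, or where an estimate is undefined).
#'
#' @param t frame times (h), strictly increasing.
#' @param s arc-length grid (mm), strictly increasing.
#' @param values numeric matrix, `length(t)` rows by `length(s)` columns.
#' @param valid logical matrix of the same shape; defaults to `!is.na(values)`.
#' @param field short field name (e.g. "A", "C", "LRL").
#' @param units unit string for labelling.
#' @return An object of class `ts_map`.
#' @export
ts_map <- function(t, s, values, valid = NULL, field = "value", units = "") {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(t), ncol(values) == length(s),
            all(diff(t) > 0), all(diff(s) > 0))
  if (is.null(valid)) valid <- !is.na(values)
  stopifnot(identical(dim(valid), dim(values)))
  values[!valid] <- NA_real_
  structure(list(t = t, s = s, values = values, valid = valid,
                 field = field, units = units),
            class = "ts_map")
}

#' @export
print.ts_map <- function(x, ...) {
  cat("<ts_map> ", x$field,
      if (nzchar(x$units)) paste0(" (", x$units, ")"), ": ",
      length(x$t), " frames x ", length(x$s), " arc points, ",
      sum(x$valid), " valid cells\n", sep = "")
  rng <- range(x$values, na.rm = TRUE)
  cat("  t in [", format(min(x$t)), ", ", format(max(x$t)), "] h, s in [",
      format(min(x$s)), ", ", format(max(x$s)), "] mm, values in [",
      format(rng[1], digits = 4), ", ", format(rng[2], digits = 4), "]\n",
      sep = "")
  invisible(x)
}

#' @describeIn ts_map long-format tibble view (`t`, `s`, `value`, `valid`).
#' @param x a `ts_map`.
#' @param ... unused.
#' @method as_tibble ts_map
#' @export
as_tibble.ts_map <- function(x, ...) {
  nt <- length(x$t); ns <- length(x$s)
  tibble::as_tibble(list(
    t = rep(x$t, each = ns),
    s = rep(x$s, nt),
    value = as.vector(base::t(x$values)),
    valid = as.vector(base::t(x$valid))
  ))
}

#' Bilinear interpolation of a ts_map at arbitrary (t, s) points
#'
#' @param map a [ts_map].
#' @param t,s coordinate vectors of equal length.
#' @return Interpolated values (NA outside the grid or the validity mask).
#' @export
ts_interp <- function(map, t, s) {
  stopifnot(inherits(map, "ts_map"), length(t) == length(s))
  it <- findInterval(t, map$t, rightmost.closed = TRUE)
  is_ <- findInterval(s, map$s, rightmost.closed = TRUE)
  out <- rep(NA_real_, length(t))
  ok <- it >= 1 & it < length(map$t) & is_ >= 1 & is_ < length(map$s)
  if (!any(ok)) return(out)
  i <- it[ok]; j <- is_[ok]
  ft <- (t[ok] - map$t[i]) / (map$t[i + 1] - map$t[i])
  fs <- (s[ok] - map$s[j]) / (map$s[j + 1] - map$s[j])
  v00 <- map$values[cbind(i, j)]
  v10 <- map$values[cbind(i + 1, j)]
  v01 <- map$values[cbind(i, j + 1)]
  v11 <- map$values[cbind(i + 1, j + 1)]
  out[ok] <- (1 - ft) * (1 - fs) * v00 + ft * (1 - fs) * v10 +
    (1 - ft) * fs * v01 + ft * fs * v11
  out
}

#' Write a ts_map as a long-format CSV
#'
#' @param map a [ts_map].
#' @param path output file.
#' @export
write_ts_map <- function(map, path) {
  readr::write_csv(as_tibble.ts_map(map), path)
  invisible(path)
}

#' Read a long-format ts_map CSV written by [write_ts_map()]
#'
#' @param path input file.
#' @param field,units labels for the reconstructed map.
#' @return A [ts_map].
#' @export
read_ts_map <- function(path, field = "value", units = "") {
  d <- readr::read_csv(path, show_col_types = FALSE)
  t <- sort(unique(d$t)); s <- sort(unique(d$s))
  v <- matrix(NA_real_, length(t), length(s))
  m <- matrix(FALSE, length(t), length(s))
  i <- match(d$t, t); j <- match(d$s, s)
  v[cbind(i, j)] <- d$value
  m[cbind(i, j)] <- d$valid
  ts_map(t, s, v, m, field = field, units = units)
}

#' Plot a ts_map as a filled contour map in the t-s plane
#'
#' Optionally overlays deflection-angle contours at 10-degree intervals,
#' drawing the 0/30/60/90-degree lines dashed and the 85-degree line dotted
#' (the conventional display for gravitropic t-s maps).
#'
#' @param object a [ts_map].
#' @param a_map optional deflection-angle [ts_map] for the contour overlay.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ts_map
#' @export
autoplot.ts_map <- function(object, a_map = NULL, ...) {
  d <- as_tibble.ts_map(object)
  p <- ggplot2::ggplot(dplyr::filter(d, .data$valid),
                       ggplot2::aes(x = .data$t, y = .data$s)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_viridis_c(name = paste0(object$field,
                                                if (nzchar(object$units))
                                                  paste0(" (", object$units, ")"))) +
    ggplot2::labs(x = "t (h)", y = "s (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(a_map)) {
    da <- dplyr::filter(as_tibble.ts_map(a_map), .data$valid)
    solid <- setdiff(seq(-180, 180, by = 10), c(0, 30, 60, 90))
    p <- p +
      ggplot2::geom_contour(data = da,
                            ggplot2::aes(z = .data$value), breaks = solid,
                            colour = "black", linewidth = 0.25) +
      ggplot2::geom_contour(data = da,
                            ggplot2::aes(z = .data$value),
                            breaks = c(0, 30, 60, 90),
                            colour = "black", linetype = "dashed",
                            linewidth = 0.35) +
      ggplot2::geom_contour(data = da,
                            ggplot2::aes(z = .data$value), breaks = 85,
                            colour = "black", linetype = "dotted",
                            linewidth = 0.35)
  }
  p
}
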