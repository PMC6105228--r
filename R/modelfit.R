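#' Fit the graviproprioception model at one timepoint
#'
#' Least-squares fit of `response = -beta * sin(A) - gamma * C` (plus an
#' optional intercept) over arc positions with `s > s_min`. Coefficient
#' standard errors and two-sided p-values come from the t-distribution; AIC
#' uses the Gaussian log-likelihood with the error variance profiled out
#' (k = number of regression coefficients + 1). Without an intercept the
#' (adjusted) R-squared uses the uncentered total sum of squares, so values
#' are not comparable to centered R-squared.
#'
#' @param data tibble with columns `s` (mm), `A` (degrees), `C` (mm^-1) and
#'   the response column.
#' @param response name of the response column (e.g. `"dCdt"` or `"LRL"`).
#' @param s_min basal cutoff: only `s > s_min` enters the fit (mm).
#' @param intercept include an intercept term.
#' @param t timepoint label (h) carried into the result.
#' @return An object of class `grav_fit` with elements `model` ("gp"),
#'   `response`, `t`, `coef` (tibble: term, estimate, std_error, p_value,
#'   significant), `aic`, `adj_r2`, `r2`, `n`, `s_min`, `collinear`, `fit`
#'   (the underlying `lm`).
#' @export
fit_gp <- function(data, response = "dCdt", s_min = 0, intercept = FALSE,
                   t = NA_real_) {
  .fit_bending(data, response, s_min, intercept, t, use_c = TRUE)
}

#' Fit the sine-law model at one timepoint
#'
#' As [fit_gp()] with the curvature regressor removed:
#' `response = -beta * sin(A)`.
#'
#' @inheritParams fit_gp
#' @return A `grav_fit` with `model = "sine"`.
#' @export
fit_sine <- function(data, response = "dCdt", s_min = 0, intercept = FALSE,
                     t = NA_real_) {
  .fit_bending(data, response, s_min, intercept, t, use_c = FALSE)
}

.fit_bending <- function(data, response, s_min, intercept, t, use_c) {
  stopifnot(response %in% names(data), all(c("s", "A") %in% names(data)))
  if (use_c) stopifnot("C" %in% names(data))
  d <- data[data$s > s_min & !is.na(data[[response]]) & !is.na(data$A), ]
  if (use_c) d <- d[!is.na(d$C), ]
  n_min <- if (use_c) 4 else 3
  if (nrow(d) < n_min)
    stop("need at least ", n_min, " valid samples with s > s_min")
  y <- d[[response]]
  X <- cbind(beta = -sin(d$A * pi / 180))
  if (use_c) X <- cbind(X, gamma = -d$C)
  dd <- data.frame(y = y, X)
  form <- if (intercept) stats::as.formula(paste("y ~", paste(colnames(X), collapse = "+")))
  else stats::as.formula(paste("y ~ 0 +", paste(colnames(X), collapse = "+")))
  fit <- stats::lm(form, data = dd)
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  collinear <- kappa(stats::model.matrix(fit), exact = TRUE) > 1e8
  ct <- sm$coefficients
  # degenerate responses (e.g. exactly zero) give NaN std errors; p = 1 then
  pv <- ct[, 4]; pv[is.nan(pv)] <- 1
  coef_tb <- tibble::tibble(
    term = rownames(ct),
    estimate = unname(ct[, 1]),
    std_error = unname(ct[, 2]),
    p_value = unname(pv),
    significant = unname(pv <= 0.05)
  )
  structure(list(model = if (use_c) "gp" else "sine", response = response,
                 t = t, coef = coef_tb, aic = stats::AIC(fit),
                 adj_r2 = sm$adj.r.squared, r2 = sm$r.squared,
                 n = nrow(d), s_min = s_min, intercept = intercept,
                 collinear = collinear, fit = fit),
            class = "grav_fit")
}

#' @export
print.grav_fit <- function(x, ...) {
  cat("<grav_fit> ", toupper(x$model), " model for ", x$response,
      if (!is.na(x$t)) paste0(" at t = ", format(x$t), " h"),
      " (n = ", x$n, ")\n", sep = "")
  print(x$coef)
  cat("AIC ", format(x$aic, digits = 5), ", adj R2 ",
      format(x$adj_r2, digits = 4),
      if (x$collinear) "  [collinear]", "\n", sep = "")
  invisible(x)
}

#' @method tidy grav_fit
#' @export
tidy.grav_fit <- function(x, ...) {
  dplyr::mutate(x$coef, model = x$model, response = x$response, t = x$t,
                .before = 1)
}

#' @method glance grav_fit
#' @export
glance.grav_fit <- function(x, ...) {
  tibble::tibble(model = x$model, response = x$response, t = x$t,
                 aic = x$aic, adj_r2 = x$adj_r2, r2 = x$r2, n = x$n,
                 s_min = x$s_min, collinear = x$collinear)
}

#' Select between the GP and sine-law fits by AIC
#'
#' @param gp,sine `grav_fit` objects fitted to the same response, timepoint
#'   and samples.
#' @return A one-row tibble: `selected`, `aic_gp`, `aic_sine`, `delta_aic`
#'   (gp - sine), `adj_r2_gp`, `adj_r2_sine`, `higher_adj_r2`.
#' @export
compare_models <- function(gp, sine) {
  stopifnot(inherits(gp, "grav_fit"), inherits(sine, "grav_fit"),
            gp$model == "gp", sine$model == "sine")
  if (gp$response != sine$response || !identical(gp$n, sine$n) ||
      (!is.na(gp$t) && !is.na(sine$t) && gp$t != sine$t))
    stop("fits are not on matched samples")
  tibble::tibble(
    selected = if (gp$aic < sine$aic) "gp" else "sine",
    aic_gp = gp$aic, aic_sine = sine$aic, delta_aic = gp$aic - sine$aic,
    adj_r2_gp = gp$adj_r2, adj_r2_sine = sine$adj_r2,
    higher_adj_r2 = if (gp$adj_r2 > sine$adj_r2) "gp" else "sine"
  )
}

#' Per-timepoint model comparison over whole fields
#'
#' Fits both models to the response field at every timepoint with enough
#' valid samples and returns the Fig.-4-style per-timepoint table.
#'
#' @param response_map response [ts_map] (e.g. dC/dt or LRL).
#' @param a_map,c_map angle (degrees) and curvature [ts_map]s on the same
#'   grid.
#' @param s_min basal cutoff (mm).
#' @param s_max apical cutoff (mm); arc positions beyond it are excluded
#'   (end-of-organ estimates are the least reliable).
#' @param intercept include an intercept.
#' @return A tibble with one row per (t, model): estimates, standard errors,
#'   p-values, AIC, adjusted R-squared, n, and the AIC selection.
#' @export
fit_models_by_time <- function(response_map, a_map, c_map, s_min = 0,
                               s_max = Inf, intercept = FALSE) {
  out <- list()
  for (i in seq_along(response_map$t)) {
    d <- tibble::tibble(s = response_map$s,
                        A = a_map$values[i, ],
                        C = c_map$values[i, ],
                        y = response_map$values[i, ])
    d <- d[response_map$valid[i, ] & a_map$valid[i, ] & c_map$valid[i, ], ]
    d <- d[stats::complete.cases(d) & d$s <= s_max, ]
    if (nrow(d) < 5 || sum(d$s > s_min) < 5) next
    gp <- fit_gp(d, "y", s_min = s_min, intercept = intercept,
                 t = response_map$t[i])
    sn <- fit_sine(d, "y", s_min = s_min, intercept = intercept,
                   t = response_map$t[i])
    cmp <- compare_models(gp, sn)
    grab <- function(f, term) {
      r <- f$coef[f$coef$term == term, ]
      if (!nrow(r)) tibble::tibble(estimate = NA_real_, std_error = NA_real_,
                                   p_value = NA_real_) else
                                     r[, c("estimate", "std_error", "p_value")]
    }
    row <- function(f) {
      b <- grab(f, "beta"); g <- grab(f, "gamma")
      tibble::tibble(t = f$t, model = f$model,
                     beta = b$estimate, beta_se = b$std_error, beta_p = b$p_value,
                     gamma = g$estimate, gamma_se = g$std_error,
                     gamma_p = g$p_value,
                     aic = f$aic, adj_r2 = f$adj_r2, n = f$n,
                     selected = cmp$selected)
    }
    out[[length(out) + 1]] <- dplyr::bind_rows(row(gp), row(sn))
  }
  dplyr::bind_rows(out)
}

#' Scan for hypocotyl segments whose LRL follows the sine law
#'
#' Regresses LRL on sin(A) over every contiguous arc-length window at least
#' `min_len` long, retains windows whose squared correlation exceeds
#' `r2_min`, merges retained windows into maximal non-extendable segments,
#' and reports each segment's sine-law gain beta (slope of LRL on -sin A)
#' from a fit over the whole segment. The correlation criterion (centered
#' R-squared) is used so that angle-independent LRL is rejected; the
#' reported beta is the slope of the sine-law relation.
#'
#' @param data tibble with `s`, `A` (degrees) and the response column,
#'   on a contiguous arc grid.
#' @param response response column name (default `"LRL"`).
#' @param min_len minimum window length (mm).
#' @param r2_min squared-correlation threshold.
#' @param t timepoint label (h).
#' @return A tibble (one row per segment): `t`, `s_start`, `s_end`,
#'   `length`, `beta`, `r2`, `n`.
#' @export
scan_sine_segments <- function(data, response = "LRL", min_len = 0.76,
                               r2_min = 0.95, t = NA_real_) {
  d <- data[!is.na(data[[response]]) & !is.na(data$A), ]
  n <- nrow(d)
  empty <- tibble::tibble(t = numeric(), s_start = numeric(),
                          s_end = numeric(), length = numeric(),
                          beta = numeric(), r2 = numeric(), n = integer())
  if (n < 4) return(empty)
  x <- -sin(d$A * pi / 180); y <- d[[response]]
  cs <- function(v) c(0, cumsum(v))
  Sx <- cs(x); Sy <- cs(y); Sxy <- cs(x * y); Sxx <- cs(x * x); Syy <- cs(y * y)
  win_stats <- function(i, j) {
    m <- j - i + 1
    sx <- Sx[j + 1] - Sx[i]; sy <- Sy[j + 1] - Sy[i]
    sxy <- Sxy[j + 1] - Sxy[i]; sxx <- Sxx[j + 1] - Sxx[i]
    syy <- Syy[j + 1] - Syy[i]
    num <- m * sxy - sx * sy
    vx <- m * sxx - sx^2; vy <- m * syy - sy^2
    r2 <- as.numeric(ifelse(vx > 0 & vy > 0, num^2 / (vx * vy), NA_real_))
    list(beta = as.numeric(ifelse(vx > 0, num / vx, NA_real_)), r2 = r2)
  }
  retained <- matrix(0L, nrow = 0, ncol = 2)
  for (i in seq_len(n)) {
    j <- which(d$s - d$s[i] >= min_len)
    j <- j[j > i]
    if (!length(j)) next
    ws <- win_stats(i, j)
    hit <- which(!is.na(ws$r2) & ws$r2 > r2_min)
    if (length(hit))
      retained <- rbind(retained, cbind(i, j[hit]))
  }
  if (!nrow(retained)) return(empty)
  o <- order(retained[, 1], retained[, 2])
  retained <- retained[o, , drop = FALSE]
  segs <- list(); cur <- retained[1, ]
  for (k in seq_len(nrow(retained))[-1]) {
    if (retained[k, 1] <= cur[2]) cur[2] <- max(cur[2], retained[k, 2])
    else { segs[[length(segs) + 1]] <- cur; cur <- retained[k, ] }
  }
  segs[[length(segs) + 1]] <- cur
  purrr::map_dfr(segs, function(sg) {
    i <- sg[1]; j <- sg[2]
    ws <- win_stats(i, j)
    tibble::tibble(t = t, s_start = d$s[i], s_end = d$s[j],
                   length = d$s[j] - d$s[i],
                   beta = ws$beta, r2 = ws$r2, n = j - i + 1L)
  })
}

#' Time-space map of sine-law beta over detected segments
#'
#' @param segments tibble of segments across frames (rows from
#'   [scan_sine_segments()], with `t` filled in).
#' @param t,s grids of the target map.
#' @return A [ts_map] valued by segment beta, masked outside segments.
#' @export
beta_map <- function(segments, t, s) {
  v <- matrix(NA_real_, length(t), length(s))
  for (k in seq_len(nrow(segments))) {
    i <- which.min(abs(t - segments$t[k]))
    j <- which(s >= segments$s_start[k] & s <= segments$s_end[k])
    v[i, j] <- segments$beta[k]
  }
  ts_map(t, s, v, field = "beta", units = "mm^-1 h^-1 / log10")
}
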