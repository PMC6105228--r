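#' Graviproprioception model parameters
#'
#' Parameters of the bending law \eqn{\partial C/\partial t = -\beta \sin A - \gamma C}
#' for a clamped rod-like organ turned away from the vertical. `gamma = 0`
#' reduces the law to the classical sine law.
#'
#' @param beta curvature-rate gain per unit \eqn{\sin A} (mm^-1 h^-1), >= 0.
#' @param gamma proprioceptive decay rate (h^-1), >= 0.
#' @param base_angle clamped deflection angle at the base s = 0 (degrees from
#'   the vertical; 90 = horizontal).
#' @param length rod length (mm).
#' @param initial_curvature initial curvature profile C(s, 0): a single number
#'   or a function of s (mm^-1).
#' @param elongation_rate optional uniform relative growth rate (h^-1). The
#'   default 0 keeps the arc-length grid fixed, matching analyses based on
#'   partial (not material) derivatives.
#' @param response gravitropic response kernel: `"sine"` uses \eqn{\sin A}
#'   (the model above); `"gaussian"` replaces it with a bell-shaped kernel
#'   peaked at `peak_angle`, useful for constructing scenes whose
#'   curvature-rate trough sits at a designed angle.
#' @param peak_angle,peak_width centre (degrees) and sd (degrees) of the
#'   gaussian response kernel; ignored for `response = "sine"`.
#'
#' @return An object of class `gp_params`.
#' @export
gp_params <- function(beta, gamma, base_angle = 90, length = 4,
                      initial_curvature = 0, elongation_rate = 0,
                      response = c("sine", "gaussian"),
                      peak_angle = NULL, peak_width = 15) {
  response <- match.arg(response)
  stopifnot(is.numeric(beta), is.numeric(gamma), is.numeric(length))
  if (beta < 0 || gamma < 0) stop("beta and gamma must be >= 0")
  if (length <= 0) stop("length must be > 0")
  if (response == "gaussian" && is.null(peak_angle))
    stop("peak_angle is required for the gaussian response kernel")
  structure(list(beta = beta, gamma = gamma, base_angle = base_angle,
                 length = length, initial_curvature = initial_curvature,
                 elongation_rate = elongation_rate, response = response,
                 peak_angle = peak_angle, peak_width = peak_width),
            class = "gp_params")
}

#' Simulation grid
#'
#' @param ds spatial step along the rod (mm).
#' @param dt_inner inner integration step (h); must not exceed `frame_interval`.
#' @param frame_interval output frame cadence (h).
#' @param t_end duration (h).
#' @return An object of class `sim_grid`.
#' @export
sim_grid <- function(ds = 0.02, dt_inner = 0.005,
                     frame_interval = 0.170, t_end = 6.10) {
  if (ds <= 0) stop("ds must be > 0")
  if (dt_inner <= 0 || dt_inner > frame_interval)
    stop("dt_inner must be in (0, frame_interval]")
  structure(list(ds = ds, dt_inner = dt_inner,
                 frame_interval = frame_interval, t_end = t_end),
            class = "sim_grid")
}

# response drive f(A): sinA, or a gaussian kernel peaked at a designed angle
.gp_drive <- function(A_rad, params) {
  if (params$response == "sine") return(sin(A_rad))
  A_deg <- A_rad * 180 / pi
  exp(-(A_deg - params$peak_angle)^2 / (2 * params$peak_width^2))
}

# cumulative trapezoid of y over uniform step h, starting at 0
.cumtrapz <- function(y, h) c(0, cumsum((y[-length(y)] + y[-1]) / 2 * h))

#' Simulate graviproprioceptive bending of a clamped rod
#'
#' Integrates \eqn{\partial C/\partial t = -\beta f(A) - \gamma C} (with
#' \eqn{f = \sin} by default) by explicit Euler stepping on a fixed arc-length
#' grid, recomputing \eqn{A(s,t) = A(0) + \int_0^s C\,ds'} at every step. The
#' base is clamped at `base_angle`. Frames are emitted at `frame_interval`.
#'
#' @param params a [gp_params()] object.
#' @param grid a [sim_grid()] object.
#' @param c_max stability guard: integration aborts if |C| exceeds this bound
#'   (mm^-1), with a suggestion to reduce `dt_inner`.
#' @return An object of class `rod_trajectory`: frame times `times` (h), arc
#'   grid `s` (mm), and frame-by-gridpoint matrices `A` (degrees), `C`
#'   (mm^-1), `dCdt` (mm^-1 h^-1), midline coordinates `x`, `y` (mm; the base
#'   is at the origin, gravity points along -y, and the rod is initially
#'   deflected toward +x).
#' @export
simulate_gp_rod <- function(params, grid, c_max = 50) {
  stopifnot(inherits(params, "gp_params"), inherits(grid, "sim_grid"))
  s <- seq(0, params$length, by = grid$ds)
  ns <- length(s)
  C <- if (is.function(params$initial_curvature)) {
    params$initial_curvature(s)
  } else rep(params$initial_curvature, ns)
  stopifnot(length(C) == ns)
  base_rad <- params$base_angle * pi / 180

  times <- seq(0, grid$t_end, by = grid$frame_interval)
  nt <- length(times)
  A_out <- C_out <- D_out <- X_out <- Y_out <- matrix(NA_real_, nt, ns)

  steps_per_frame <- max(1L, round(grid$frame_interval / grid$dt_inner))
  dt <- grid$frame_interval / steps_per_frame
  growth <- params$elongation_rate
  s_cur <- s

  emit <- function(frame, C, s_cur) {
    ds_cur <- s_cur[2] - s_cur[1]
    A <- base_rad + .cumtrapz(C, ds_cur)
    d <- -params$beta * .gp_drive(A, params) - params$gamma * C
    A_out[frame, ] <<- A * 180 / pi
    C_out[frame, ] <<- C
    D_out[frame, ] <<- d
    # lab frame: y up, gravity -y; tangent = (sin A, cos A)
    X_out[frame, ] <<- .cumtrapz(sin(A), ds_cur)
    Y_out[frame, ] <<- .cumtrapz(cos(A), ds_cur)
  }

  emit(1L, C, s_cur)
  for (frame in seq_len(nt - 1L)) {
    for (k in seq_len(steps_per_frame)) {
      ds_cur <- s_cur[2] - s_cur[1]
      A <- base_rad + .cumtrapz(C, ds_cur)
      C <- C + dt * (-params$beta * .gp_drive(A, params) - params$gamma * C)
      if (growth > 0) {
        # uniform relative elongation dilutes curvature and stretches the grid
        C <- C / (1 + growth * dt)
        s_cur <- s_cur * (1 + growth * dt)
      }
      if (max(abs(C)) > c_max)
        stop("integration unstable (|C| > ", c_max,
             " mm^-1); reduce dt_inner")
    }
    emit(frame + 1L, C, s_cur)
  }

  structure(list(times = times, s = s_cur, A = A_out, C = C_out,
                 dCdt = D_out, x = X_out, y = Y_out,
                 params = params, grid = grid),
            class = "rod_trajectory")
}

#' @export
print.rod_trajectory <- function(x, ...) {
  cat("<rod_trajectory> ", length(x$times), " frames (",
      format(x$times[1]), "-", format(max(x$times)), " h), ",
      length(x$s), " arc points over ", format(max(x$s)), " mm\n", sep = "")
  cat("  beta = ", x$params$beta, " mm^-1 h^-1, gamma = ",
      x$params$gamma, " h^-1, base angle ", x$params$base_angle, " deg\n",
      sep = "")
  invisible(x)
}

#' Tidy a simulated trajectory into a long tibble
#'
#' @param x a `rod_trajectory`.
#' @param ... unused.
#' @return A tibble with one row per (frame, arc point): `t`, `s`, `A`, `C`,
#'   `dCdt`, `x`, `y`.
#' @method as_tibble rod_trajectory
#' @export
as_tibble.rod_trajectory <- function(x, ...) {
  nt <- length(x$times); ns <- length(x$s)
  flat <- function(m) as.vector(base::t(m))
  cols <- list(t = rep(x$times, each = ns), s = rep(x$s, nt),
               A = flat(x$A), C = flat(x$C), dCdt = flat(x$dCdt),
               x = flat(x$x), y = flat(x$y))
  tibble::as_tibble(cols)
}

#' Ground-truth fields of a trajectory as ts_map objects
#'
#' @param traj a `rod_trajectory`.
#' @return A named list of [ts_map] objects: `A` (degrees), `C` (mm^-1),
#'   `dCdt` (mm^-1 h^-1).
#' @export
trajectory_fields <- function(traj) {
  stopifnot(inherits(traj, "rod_trajectory"))
  mk <- function(v, field, units)
    ts_map(traj$times, traj$s, v, field = field, units = units)
  list(A = mk(traj$A, "A", "deg"),
       C = mk(traj$C, "C", "mm^-1"),
       dCdt = mk(traj$dCdt, "dCdt", "mm^-1 h^-1"))
}

#' Add observation noise to ground-truth fields
#'
#' Adds i.i.d. Gaussian noise scaled to each field's own spread, emulating
#' measurement error on fields taken directly from the simulator. The default
#' level (10 percent of the field sd) is the package's standard observation
#' noise for field-level validation.
#'
#' @param fields list of [ts_map]s as returned by [trajectory_fields()].
#' @param rel_sd noise sd as a fraction of each field's value sd.
#' @param which character vector of field names to perturb.
#' @return The list with perturbed value matrices.
#' @export
perturb_fields <- function(fields, rel_sd = 0.1, which = "dCdt") {
  for (nm in which) {
    m <- fields[[nm]]$values
    m <- m + stats::rnorm(length(m), sd = rel_sd * stats::sd(m, na.rm = TRUE))
    fields[[nm]]$values <- m
  }
  fields
}
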