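# shared fixtures, built once per test run

.gk_cache <- new.env(parent = emptyenv())

# identifiability-grade initial curvature: a gentle spatial perturbation so
# that sin A and C decouple across arc length
gk_ic <- function(s) 0.25 * sin(2 * pi * s / 2.2 + 0.7)

# full study-condition scene: GP rod (beta 0.4, gamma 1.5), 0.170-h frames
# over 6.10 h, rendered with default luminescence noise, plus the complete
# image-analysis pass (midlines, kinematics, curvature rate, luminescence)
gk_fixture <- function() {
  if (!is.null(.gk_cache$fix)) return(.gk_cache$fix)
  params <- gp_params(beta = 0.4, gamma = 1.5, initial_curvature = gk_ic)
  traj <- simulate_gp_rod(params, sim_grid())
  frames <- render_frames(traj, lum_model(noise = TRUE), seed = 42)
  midlines <- vector("list", length(frames$times))
  anchor <- NULL
  for (i in seq_along(frames$times)) {
    midlines[[i]] <- extract_midline(frames$bright[[i]], frames$pixel_scale,
                                     base_px = frames$base_px, anchor = anchor,
                                     frame_time = frames$times[i])
    anchor <- attr(midlines[[i]], "pair")$base
  }
  fields <- kinematics_fields(midlines, frames$times)
  rate <- curvature_rate(fields$C)
  lum <- luminescence_analysis(frames$lum, midlines, fields$C,
                               frames$pixel_scale, frames$base_px,
                               times = frames$times)
  .gk_cache$fix <- list(params = params, traj = traj, frames = frames,
                        midlines = midlines, fields = fields, rate = rate,
                        lum = lum)
  .gk_cache$fix
}

# small noiseless scene for geometric unit tests (6 frames)
gk_small <- function() {
  if (!is.null(.gk_cache$small)) return(.gk_cache$small)
  params <- gp_params(beta = 0.4, gamma = 1.5)
  traj <- simulate_gp_rod(params, sim_grid(frame_interval = 0.85, t_end = 4.3))
  frames <- render_frames(traj, lum_model(noise = FALSE), seed = 1)
  .gk_cache$small <- list(params = params, traj = traj, frames = frames)
  .gk_cache$small
}

# interpolate a trajectory truth matrix onto an arbitrary arc grid
gk_truth_on <- function(traj, M, s_grid) {
  t(vapply(seq_along(traj$times),
           function(i) stats::approx(traj$s, M[i, ], xout = s_grid, rule = 1)$y,
           numeric(length(s_grid))))
}

# independent RK4 integrator of the bending law, used as the simulator oracle
gk_rk4_gp <- function(beta, gamma, base_angle, length, ds, dt, t_end) {
  s <- seq(0, length, by = ds)
  C <- rep(0, base::length(s))
  base_rad <- base_angle * pi / 180
  rhs <- function(C) {
    A <- base_rad + c(0, cumsum((C[-base::length(C)] + C[-1]) / 2 * ds))
    -beta * sin(A) - gamma * C
  }
  nsteps <- round(t_end / dt)
  for (k in seq_len(nsteps)) {
    k1 <- rhs(C); k2 <- rhs(C + dt / 2 * k1)
    k3 <- rhs(C + dt / 2 * k2); k4 <- rhs(C + dt * k3)
    C <- C + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(s = s, C = C)
}
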