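test_that("side assignment follows the dominant bend and errors when straight", {
  tt <- seq(0, 2, by = 0.5); sg <- seq(0, 3, by = 0.1)
  up <- ts_map(tt, sg, matrix(-0.2, length(tt), length(sg)), field = "C")
  expect_identical(assign_sides(up)$concave, "left")
  dn <- ts_map(tt, sg, matrix(0.2, length(tt), length(sg)), field = "C")
  expect_identical(assign_sides(dn)$concave, "right")
  flat <- ts_map(tt, sg, matrix(0, length(tt), length(sg)), field = "C")
  expect_error(assign_sides(flat), "no dominant bend")
  expect_identical(assign_sides(flat, fallback = 1)$concave, "left")
})

test_that("LRL is antisymmetric under side swap and scale invariant", {
  fx <- gk_small()
  i <- 3
  ml <- extract_midline(fx$frames$bright[[i]], fx$frames$pixel_scale,
                        base_px = fx$frames$base_px,
                        frame_time = fx$frames$times[i])
  pair <- attr(ml, "pair")
  ic1 <- inset_contour(pair$side1, ml)
  ic2 <- inset_contour(pair$side2, ml)
  pr <- sample_profiles(fx$frames$lum[[i]], ml, ic1, ic2,
                        fx$frames$pixel_scale, fx$frames$base_px)
  swapped <- sample_profiles(fx$frames$lum[[i]], ml, ic2, ic1,
                             fx$frames$pixel_scale, fx$frames$base_px)
  ok <- pr$valid & swapped$valid
  expect_equal(pr$LRL[ok], -swapped$LRL[ok], tolerance = 1e-9)
  scaled <- sample_profiles(fx$frames$lum[[i]] * 7.3, ml, ic1, ic2,
                            fx$frames$pixel_scale, fx$frames$base_px)
  expect_equal(pr$LRL[ok], scaled$LRL[ok], tolerance = 1e-9)
})

test_that("a uniform raster yields equal profiles and zero LRL", {
  fx <- gk_small()
  i <- 2
  ml <- extract_midline(fx$frames$bright[[i]], fx$frames$pixel_scale,
                        base_px = fx$frames$base_px,
                        frame_time = fx$frames$times[i])
  pair <- attr(ml, "pair")
  ic1 <- inset_contour(pair$side1, ml)
  ic2 <- inset_contour(pair$side2, ml)
  uni <- matrix(5, 512, 512)
  pr <- sample_profiles(uni, ml, ic1, ic2, fx$frames$pixel_scale,
                        fx$frames$base_px)
  expect_true(all(abs(pr$L_m - 5) < 1e-9))
  expect_true(all(abs(pr$LRL[pr$valid]) < 1e-9))
})

test_that("a known transverse log gradient is recovered as LRL", {
  # straight horizontal rod with log-linear transverse gradient g per width
  traj <- simulate_gp_rod(gp_params(beta = 0, gamma = 0),
                          sim_grid(frame_interval = 1, t_end = 1))
  g <- -0.4
  lmc <- lum_model(noise = FALSE,
                   lrl_fun = function(s, t, traj) rep(g / 0.75, length(s)))
  fr <- render_frames(traj, lmc, seed = 1)
  ml <- extract_midline(fr$bright[[1]], fr$pixel_scale, base_px = fr$base_px,
                        frame_time = 0)
  pair <- attr(ml, "pair")
  s1 <- gravikine:::.flank_side(pair$side1, ml)
  concave <- if (s1 == 1) pair$side1 else pair$side2
  convex <- if (s1 == 1) pair$side2 else pair$side1
  off <- 0.5 * fr$pixel_scale / 1000
  pr <- sample_profiles(fr$lum[[1]], ml,
                        inset_contour(concave, ml, surface_offset = off),
                        inset_contour(convex, ml, surface_offset = off),
                        fr$pixel_scale, fr$base_px)
  # inset points sit 6/8 of the width apart, so LRL = g * (6/8) per width
  mid <- pr$valid & pr$s > 0.5 & pr$s < 3.5
  expect_lt(abs(mean(pr$LRL[mid]) - g / 0.75), 0.035)
})

test_that("a noiseless constant-LRL fixture reads back within 0.02", {
  traj <- simulate_gp_rod(gp_params(beta = 0, gamma = 0),
                          sim_grid(frame_interval = 1, t_end = 1))
  lmc <- lum_model(noise = FALSE,
                   lrl_fun = function(s, t, traj) rep(-0.3, length(s)))
  fr <- render_frames(traj, lmc, seed = 1)
  ml <- extract_midline(fr$bright[[1]], fr$pixel_scale, base_px = fr$base_px,
                        frame_time = 0)
  pair <- attr(ml, "pair")
  s1 <- gravikine:::.flank_side(pair$side1, ml)
  concave <- if (s1 == 1) pair$side1 else pair$side2
  convex <- if (s1 == 1) pair$side2 else pair$side1
  off <- 0.5 * fr$pixel_scale / 1000
  pr <- sample_profiles(fr$lum[[1]], ml,
                        inset_contour(concave, ml, surface_offset = off),
                        inset_contour(convex, ml, surface_offset = off),
                        fr$pixel_scale, fr$base_px)
  mid <- pr$valid & pr$s > 0.5 & pr$s < 3.5
  expect_lt(abs(mean(pr$LRL[mid]) + 0.3), 0.02)
})

test_that("fixture LRL map matches the ground truth within 0.05 RMS", {
  fx <- gk_fixture()
  maps <- fx$lum$maps
  Lti <- gk_truth_on(fx$traj, fx$frames$truth$lrl, maps$LRL$s)
  ok <- maps$LRL$valid & !is.na(Lti)
  rms <- sqrt(mean((maps$LRL$values[ok] - Lti[ok])^2))
  expect_lt(rms, 0.05)
})

test_that("smoothing preserves profile scale and recomputes LRL", {
  sgrid <- seq(0, 3, by = 0.0199)
  set.seed(2)
  raw <- tibble::tibble(
    s = sgrid,
    L_m = 100 + 20 * sin(sgrid) + rnorm(length(sgrid), sd = 2),
    L_v = 80 + rnorm(length(sgrid), sd = 2),
    L_c = 60 + rnorm(length(sgrid), sd = 2),
    LRL = NA_real_, valid = TRUE)
  class(raw) <- c("lum_profiles", class(raw))
  sm <- smooth_profiles(raw)
  expect_equal(mean(sm$L_v), 80, tolerance = 1)
  expect_equal(sm$LRL, log10(sm$L_c / sm$L_v), tolerance = 1e-12)
})

test_that("a drifting longitudinal bump is tracked by the median profile", {
  params <- gp_params(beta = 0.4, gamma = 1.5)
  traj <- simulate_gp_rod(params, sim_grid(frame_interval = 0.85, t_end = 4.3))
  bump <- bump_profile(start = 3.2, speed = 0.35)
  run <- function(noise, seed) {
    fr <- render_frames(traj, lum_model(noise = noise, longitudinal = bump),
                        seed = seed)
    mls <- vector("list", length(fr$times)); anchor <- NULL
    for (i in seq_along(fr$times)) {
      mls[[i]] <- extract_midline(fr$bright[[i]], fr$pixel_scale,
                                  base_px = fr$base_px, anchor = anchor,
                                  frame_time = fr$times[i])
      anchor <- attr(mls[[i]], "pair")$base
    }
    fields <- kinematics_fields(mls, fr$times)
    la <- luminescence_analysis(fr$lum, mls, fields$C, fr$pixel_scale,
                                fr$base_px, times = fr$times)
    lm_map <- la$maps$L_m
    vapply(seq_along(fr$times), function(i) {
      ok <- lm_map$valid[i, ] & lm_map$s > 0.3 & lm_map$s < max(lm_map$s) - 0.3
      lm_map$s[ok][which.max(lm_map$values[i, ok])] -
        (3.2 - 0.35 * fr$times[i])
    }, 0)
  }
  step <- 0.0199
  # noise-free: the peak is localized within two grid steps at every frame
  expect_lt(max(abs(run(FALSE, 5))), 2 * step)
  # with counting noise the basipetal drift is still tracked frame by frame
  err_noisy <- run(TRUE, 5)
  expect_lt(stats::median(abs(err_noisy)), 2 * step)
  expect_lt(max(abs(err_noisy)), 6 * step)
})
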