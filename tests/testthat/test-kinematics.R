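test_that("deflection angle handles the canonical orientations", {
  up <- tibble::tibble(s = seq(0, 1, by = 0.1), x = 0, y = seq(0, 1, by = 0.1))
  expect_true(all(abs(deflection_angle(up)$A) < 1e-9))
  flat <- tibble::tibble(s = seq(0, 1, by = 0.1), x = seq(0, 1, by = 0.1), y = 0)
  expect_true(all(abs(deflection_angle(flat)$A - 90) < 1e-9))
  # quarter circle, horizontal base to vertical tip, radius r: A linear 90 -> 0
  r <- 2
  th <- seq(0, pi / 2, length.out = 101)
  qc <- tibble::tibble(s = r * th, x = r * sin(th), y = r * (1 - cos(th)))
  a <- deflection_angle(qc)
  expect_equal(a$A, 90 - a$s / r * 180 / pi, tolerance = 0.2)
  expect_error(deflection_angle(tibble::tibble(s = 1:3, x = 1, y = 1)),
               "tangent")
})

test_that("curvature of a linear angle profile is its slope", {
  sgrid <- seq(0, 3, by = 0.0199)
  k <- -0.3  # rad/mm
  a <- tibble::tibble(s = sgrid, A = (1.2 + k * sgrid) * 180 / pi)
  cv <- curvature(a)
  expect_equal(cv$C, rep(k, length(sgrid)), tolerance = 1e-6)
  # fewer than 8 samples: masked
  expect_true(all(is.na(curvature(a[1:5, ])$C)))
})

test_that("circle oracle: curvature is 1/r within one percent, radii 0.5-10", {
  for (r in c(0.5, 1, 2, 5, 10)) {
    sgrid <- seq(0, 3, by = 0.0199)
    a <- tibble::tibble(s = sgrid, A = 90 - sgrid / r * 180 / pi)
    cv <- curvature(a)
    expect_lt(max(abs(abs(cv$C) - 1 / r)) * r, 0.01)
  }
})

test_that("curvature rate and SEE behave on constant and linear series", {
  tt <- seq(0, 6, by = 0.2)
  cm <- ts_map(tt, c(1, 2), cbind(rep(0.2, length(tt)), 0.1 + 0.05 * tt),
               field = "C")
  cr <- curvature_rate(cm)
  expect_lt(max(abs(cr$dCdt$values[, 1])), 1e-6)
  expect_lt(max(abs(cr$see$see[1])), 1e-8)
  expect_equal(unname(cr$dCdt$values[, 2]), rep(0.05, length(tt)),
               tolerance = 1e-6)
})

test_that("curvature rate tracks the simulator truth away from edges", {
  fx <- gk_fixture()
  cr <- fx$rate
  Dti <- gk_truth_on(fx$traj, fx$traj$dCdt, cr$dCdt$s)
  sel <- cr$dCdt$valid & !is.na(Dti) &
    outer(fx$traj$times > 0.75, cr$dCdt$s > 0.5 & cr$dCdt$s < 3.6)
  rms <- sqrt(mean((cr$dCdt$values[sel] - Dti[sel])^2, na.rm = TRUE))
  expect_lt(rms / max(abs(fx$traj$dCdt)), 0.10)
})

test_that("curvature field matches truth in the interior of the organ", {
  fx <- gk_fixture()
  Cti <- gk_truth_on(fx$traj, fx$traj$C, fx$fields$C$s)
  sel <- fx$fields$C$valid & !is.na(Cti) &
    outer(rep(TRUE, length(fx$traj$times)),
          fx$fields$C$s > 0.5 & fx$fields$C$s < 3.2)
  rms <- sqrt(mean((fx$fields$C$values[sel] - Cti[sel])^2, na.rm = TRUE))
  expect_lt(rms / max(abs(fx$traj$C)), 0.05)
})

test_that("SEE ratio map masks zero curvature and flags early times", {
  fx <- gk_fixture()
  sm <- see_ratio_map(fx$fields$C, fx$rate)
  expect_true(all(is.finite(sm$values[sm$valid])))
  # the ratio is larger in the first three quarters of an hour
  early <- fx$traj$times < 0.75
  interior <- sm$s > 0.5 & sm$s < 3
  expect_gt(mean(sm$values[early, interior], na.rm = TRUE),
            mean(sm$values[!early, interior], na.rm = TRUE))
})

test_that("mask is monotone: valid at s implies valid at shorter arcs", {
  fx <- gk_fixture()
  v <- fx$fields$A$valid
  for (i in seq_len(nrow(v))) {
    run <- which(v[i, ])
    if (length(run)) expect_identical(run, seq_len(max(run)))
  }
})

test_that("a constructed gaussian valley is traced as a single path", {
  tt <- seq(0, 6, by = 0.17); sg <- seq(0, 4, by = 0.0199)
  t0 <- 1 + 0.5 * sg
  v <- -vapply(seq_along(sg), function(j) exp(-(tt - t0[j])^2 / 0.3), tt)
  fld <- ts_map(tt, sg, v, field = "test")
  paths <- detect_extremal_paths(fld, "trough", min_extent = 0.5)
  expect_length(paths, 1)
  p <- paths[[1]]
  expect_lt(max(abs(p$t - (1 + 0.5 * p$s))), 0.17)
  expect_gt(diff(range(p$s)), 3.5)
})

test_that("pure sine-law bending yields one trough and no early heights", {
  traj <- simulate_gp_rod(gp_params(beta = 0.4, gamma = 0), sim_grid())
  f <- trajectory_fields(traj)
  troughs <- detect_extremal_paths(f$dCdt, "trough")
  expect_length(troughs, 1)
  # before the tip reaches the vertical there is no decurving ridge
  tip0 <- min(traj$times[traj$A[, ncol(traj$A)] <= 0])
  sub <- ts_map(f$dCdt$t[f$dCdt$t < tip0], f$dCdt$s,
                f$dCdt$values[f$dCdt$t < tip0, ],
                f$dCdt$valid[f$dCdt$t < tip0, ], field = "dCdt")
  expect_length(detect_extremal_paths(sub, "height"), 0)
})

test_that("strong proprioception produces a later decurving height path", {
  fx <- gk_fixture()
  f <- trajectory_fields(fx$traj)
  troughs <- detect_extremal_paths(f$dCdt, "trough")
  heights <- detect_extremal_paths(f$dCdt, "height")
  expect_gte(length(troughs), 1)
  expect_gte(length(heights), 1)
  expect_gt(min(heights[[1]]$t), min(troughs[[1]]$t))
})

test_that("angle alignment snaps to the contour the path follows", {
  tt <- seq(0, 6, by = 0.17); sg <- seq(0, 4, by = 0.0199)
  amap <- ts_map(tt, sg, matrix(75, length(tt), length(sg)), field = "A")
  path <- structure(tibble::tibble(t = c(1, 2, 3), s = c(1, 2, 3),
                                   value = -1), class = c("trough_path",
                                                          class(tibble::tibble())))
  al <- align_with_angle(path, amap)
  expect_identical(al$aligned_angle, 75)
  expect_identical(al$residual, 0)
  # two-vertex degenerate path: rounded mean, residual about the half-spread
  amap2 <- ts_map(tt, sg, outer(rep(1, length(tt)), 70 + 2.5 * sg), field = "A")
  p2 <- structure(tibble::tibble(t = c(1, 2), s = c(1, 3), value = -1),
                  class = c("trough_path", class(tibble::tibble())))
  al2 <- align_with_angle(p2, amap2)
  expect_identical(al2$aligned_angle, 75)
  expect_equal(al2$residual, 2.5, tolerance = 1e-6)
})

test_that("designed response angles are recovered at 5-degree resolution", {
  set.seed(11)
  p <- gp_params(beta = 0.5, gamma = 0, response = "gaussian",
                 peak_angle = 60, peak_width = 12,
                 initial_curvature = function(s) 0.1 * sin(2 * pi * s / 2.5))
  traj <- simulate_gp_rod(p, sim_grid())
  f <- trajectory_fields(traj)
  hits <- replicate(20, {
    fn <- perturb_fields(f, rel_sd = 0.1)
    tp <- detect_extremal_paths(fn$dCdt, "trough")
    if (!length(tp)) return(NA_real_)
    lens <- vapply(tp, function(x) diff(range(x$s)), 0)
    align_with_angle(tp[[which.max(lens)]], f$A)$aligned_angle
  })
  expect_gte(mean(abs(hits - 60) <= 5, na.rm = TRUE), 0.95)
})

test_that("integrating curvature reconstructs the smoothed angle", {
  fx <- gk_fixture()
  for (i in c(1, 10, 20, 36)) {
    ok <- fx$fields$C$valid[i, ]
    sgrid <- fx$fields$C$s[ok]
    Cv <- fx$fields$C$values[i, ok]
    Av <- fx$fields$A_smooth$values[i, ok]
    Aint <- Av[1] + cumsum(c(0, (Cv[-1] + Cv[-length(Cv)]) / 2 *
                               diff(sgrid))) * 180 / pi
    expect_lt(max(abs(Aint - Av)), 0.5)
  }
})
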