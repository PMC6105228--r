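# shared synthetic regression scene: spatially varied angle and curvature
gk_fit_data <- function(gamma, n = 150, noise_frac = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- seq(0.02, 3, length.out = n)
  A <- 90 - 25 * s / 3 + 8 * sin(2 * pi * s / 1.7)
  C <- -0.15 - 0.1 * sin(2 * pi * s / 2.1 + 1)
  y <- -0.4 * sin(A * pi / 180) - gamma * C
  if (noise_frac > 0) y <- y + rnorm(n, sd = noise_frac * sd(y))
  tibble::tibble(s = s, A = A, C = C, dCdt = y)
}

test_that("an exact linear response returns the generating coefficients", {
  d <- gk_fit_data(gamma = 1.5)
  f <- fit_gp(d)
  expect_equal(f$coef$estimate, c(0.4, 1.5), tolerance = 1e-10)
  expect_true(all(f$coef$significant))
  expect_false(f$collinear)
})

test_that("a zero response yields zero, insignificant coefficients", {
  d <- gk_fit_data(gamma = 0)
  d$dCdt <- 0
  f <- fit_gp(d)
  expect_equal(f$coef$estimate, c(0, 0), tolerance = 1e-12)
  expect_false(any(f$coef$significant))
})

test_that("basal cutoff and sample minima are enforced", {
  d <- gk_fit_data(gamma = 1)
  expect_error(fit_gp(d, s_min = 10), "at least 4")
  f <- fit_gp(d, s_min = 1.5)
  expect_identical(f$n, sum(d$s > 1.5))
  expect_identical(f$s_min, 1.5)
})

test_that("tidy and glance expose the fit in broom shape", {
  d <- gk_fit_data(gamma = 1.5)
  f <- fit_gp(d, t = 2)
  td <- tidy(f)
  expect_identical(td$term, c("beta", "gamma"))
  expect_identical(unique(td$t), 2)
  gl <- glance(f)
  expect_true(all(c("aic", "adj_r2", "n") %in% names(gl)))
  expect_identical(gl$model, "gp")
})

test_that("AIC prefers the generating model", {
  sel15 <- replicate(50, {
    d <- gk_fit_data(gamma = 1.5, noise_frac = 0.1)
    compare_models(fit_gp(d), fit_sine(d))$selected
  })
  expect_gte(mean(sel15 == "gp"), 0.95)
  sel0 <- replicate(50, {
    d <- gk_fit_data(gamma = 0, noise_frac = 0.1)
    compare_models(fit_gp(d), fit_sine(d))$selected
  })
  expect_gt(mean(sel0 == "sine"), 0.5)
})

test_that("nesting bounds the AIC penalty when gamma is estimated as zero", {
  # response built purely from sinA: the C regressor adds at most its
  # parameter penalty of two AIC units
  for (seed in 1:10) {
    d <- gk_fit_data(gamma = 0, noise_frac = 0.05, seed = seed)
    cmp <- compare_models(fit_gp(d), fit_sine(d))
    expect_lte(cmp$aic_gp, cmp$aic_sine + 2 + 1e-8)
  }
})

test_that("comparison refuses mismatched samples", {
  d <- gk_fit_data(gamma = 1)
  expect_error(compare_models(fit_gp(d), fit_sine(d[-1, ])), "matched")
})

test_that("field-level noiseless recovery is exact; noisy recovery unbiased", {
  traj <- simulate_gp_rod(gp_params(beta = 0.4, gamma = 1.5,
                                    initial_curvature = gk_ic), sim_grid())
  i <- 8
  d <- tibble::tibble(s = traj$s, A = traj$A[i, ], C = traj$C[i, ],
                      dCdt = traj$dCdt[i, ])
  f <- fit_gp(d)
  expect_equal(f$coef$estimate, c(0.4, 1.5), tolerance = 1e-9)
  base_fields <- trajectory_fields(traj)
  errs <- vapply(1:50, function(sd_) {
    set.seed(sd_)
    fl <- perturb_fields(base_fields, rel_sd = 0.1)
    dn <- tibble::tibble(s = traj$s, A = traj$A[i, ], C = traj$C[i, ],
                         dCdt = fl$dCdt$values[i, ])
    abs(fit_gp(dn)$coef$estimate / c(0.4, 1.5) - 1)
  }, numeric(2))
  expect_lt(stats::median(errs[1, ]), 0.05)
  expect_lt(stats::median(errs[2, ]), 0.05)
})

test_that("fitted beta is positive while the organ bends up", {
  fx <- gk_fixture()
  fits <- fit_models_by_time(fx$rate$dCdt, fx$fields$A_smooth, fx$fields$C,
                             s_min = 0.5, s_max = 3.2)
  gp <- dplyr::filter(fits, .data$model == "gp", .data$t > 0.2, .data$t < 1.5)
  expect_true(all(gp$beta > 0))
})

test_that("segment scan handles exact, piecewise and noise inputs", {
  sgrid <- seq(0, 4, by = 0.0199)
  A <- 90 - 12 * sgrid
  exact <- tibble::tibble(s = sgrid, A = A, LRL = -0.5 * sin(A * pi / 180))
  seg <- scan_sine_segments(exact)
  expect_identical(nrow(seg), 1L)
  expect_equal(seg$beta, 0.5, tolerance = 1e-9)
  expect_equal(seg$r2, 1, tolerance = 1e-9)
  expect_lt(seg$s_start, 0.02); expect_gt(seg$s_end, 3.99)

  piece <- tibble::tibble(s = sgrid, A = A,
                          LRL = ifelse(sgrid > 2, -0.5 * sin(A * pi / 180),
                                       -0.15))
  seg2 <- scan_sine_segments(piece)
  expect_identical(nrow(seg2), 1L)
  expect_lt(abs(seg2$s_start - 2), 2 * 0.0199 + 1e-9)
  expect_equal(seg2$beta, 0.5, tolerance = 0.1)

  set.seed(3)
  empties <- replicate(50, {
    noise <- tibble::tibble(s = seq(0, 3, length.out = 150),
                            A = 90 - 10 * seq(0, 3, length.out = 150),
                            LRL = rnorm(150, sd = 0.1))
    nrow(scan_sine_segments(noise)) == 0
  })
  expect_gte(mean(empties), 0.9)
})

test_that("raising the R2 threshold never lengthens a segment", {
  set.seed(9)
  sgrid <- seq(0, 4, by = 0.0199)
  A <- 90 - 15 * sgrid
  d <- tibble::tibble(s = sgrid, A = A,
                      LRL = -0.4 * sin(A * pi / 180) +
                        rnorm(length(sgrid), sd = 0.01))
  lo <- scan_sine_segments(d, r2_min = 0.9)
  hi <- scan_sine_segments(d, r2_min = 0.97)
  if (nrow(hi) > 0 && nrow(lo) > 0)
    expect_lte(max(hi$length), max(lo$length) + 1e-9)
  expect_lte(sum(hi$length), sum(lo$length) + 1e-9)
})

test_that("beta map paints segments onto the t-s grid", {
  segs <- tibble::tibble(t = c(1, 2), s_start = c(1, 0.5), s_end = c(2, 1.5),
                         length = c(1, 1), beta = c(0.3, 0.6), r2 = 0.99,
                         n = 50L)
  bm <- beta_map(segs, t = c(1, 2, 3), s = seq(0, 3, by = 0.1))
  expect_equal(bm$values[1, 15], 0.3)
  expect_equal(bm$values[2, 11], 0.6)
  expect_true(all(is.na(bm$values[3, ])))
})
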