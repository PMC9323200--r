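test_that("through-origin slope equals the closed form and lm oracle", {
  expect_equal(slope_through_origin(c(1, 2), c(3, 6)), 3)
  expect_equal(slope_through_origin(c(1, 2), c(2, 5)), 12 / 5)
  expect_error(slope_through_origin(c(0), c(0)), "undefined")
  set.seed(31)
  for (i in 1:5) {
    x <- runif(20, 0, 50); y <- 3 * x + rnorm(20, 0, 4)
    b <- slope_through_origin(x, y)
    expect_equal(b, sum(x * y) / sum(x^2), tolerance = 1e-12)
    expect_equal(b, unname(coef(lm(y ~ 0 + x))), tolerance = 1e-10)
  }
})

test_that("noise filter drops only points strictly above 1.1x the fit", {
  prop <- trajectory("t", "agar", "mtl", 1:5, 1:5, 3 * (1:5))
  expect_equal(nrow(filter_noise(prop)), 5L)
  # 20 points on y = 3x plus one spike at 1.5x the line
  x <- seq_len(21)
  y <- 3 * x; y[21] <- 1.5 * 3 * x[21]
  tr <- trajectory("t", "agar", "mtl", x, x, y)
  kept <- filter_noise(tr)
  expect_equal(nrow(kept), 20L)
  expect_false(21 %in% kept$infused_uL)
  # a point lying exactly at 1.1x the fitted value is retained: solve for
  # the last y so that, with it included, y10 = 1.1 * slope * x10 exactly
  xs <- 1:10; ys <- 2 * xs
  b <- sum(2 * xs[1:9]^2) / (sum(xs[1:9]^2) - 0.1 * xs[10]^2)
  ys[10] <- 1.1 * b * xs[10]
  tr3 <- trajectory("t", "agar", "mtl", xs, xs, ys)
  expect_equal(slope_through_origin(tr3), b, tolerance = 1e-12)
  expect_equal(nrow(filter_noise(tr3)), 10L)
  # subset property and below-line immunity
  expect_true(all(kept$measured_uL %in% tr$measured_uL))
  below <- trajectory("t", "agar", "mtl", 1:5, 1:5, c(3, 5, 8, 11, 13))
  bfit <- slope_through_origin(below)
  under <- below$measured_uL < bfit * below$infused_uL
  keptb <- filter_noise(below)
  expect_true(all(below$measured_uL[under] %in% keptb$measured_uL))
})

test_that("mixed model recovers slopes, interactions and the null", {
  # identical slope, no noise: fallback route, interaction exactly 0
  tt <- make_trajectories(n_per_group = c(3, 3), group_slopes = c(3, 3),
                          slope_sd = 0, noise_sd = 0, n_points = 8, seed = 5)
  fit0 <- fit_mixed_model(tt$agar, tt$nhp)
  expect_equal(fit0$base_slope, 3, tolerance = 1e-8)
  expect_equal(fit0$interaction, 0, tolerance = 1e-8)
  # one noiseless trial per group: interaction = slope difference
  a <- trajectory("a1", "agar", "cortical", 1:5, 1:5, 2 * (1:5))
  n <- trajectory("n1", "nhp", "cortical", 1:5, 1:5, 5 * (1:5))
  fit1 <- fit_mixed_model(a, n)
  expect_equal(fit1$interaction, 3, tolerance = 1e-8)
  expect_equal(fit1$base_slope, 2, tolerance = 1e-8)
  # reference switch flips the sign
  fit1n <- fit_mixed_model(a, n, reference = "nhp")
  expect_equal(fit1n$interaction, -3, tolerance = 1e-8)
  # simulated recovery: true interaction 1.0
  sim <- make_trajectories(seed = 101)
  fit <- fit_mixed_model(sim$agar, sim$nhp)
  expect_equal(fit$method, "mixed")
  expect_lt(abs(fit$interaction - 1), 3 * fit$interaction_se)
  expect_equal(length(fit$trial_slopes), 20L)
  # per-trial slopes track the generating slopes
  expect_equal(unname(fit$trial_slopes[paste0("agar:agar-", sprintf("%02d", 1:10))]),
               unname(sim$true_slopes[1:10]), tolerance = 0.15)
  expect_error(fit_mixed_model(list(), list(n)), "at least one trial")
})

test_that("mixed fit methods are coherent", {
  sim <- make_trajectories(n_per_group = c(4, 4), seed = 21)
  fit <- fit_mixed_model(sim$agar, sim$nhp)
  expect_named(coef(fit), c("base_slope", "interaction"))
  pred <- predict(fit)
  expect_equal(length(pred), nrow(fit$data))
  expect_equal(unname(pred + residuals(fit)), fit$data$measured_uL)
  sims <- simulate(fit, nsim = 1, seed = 3)
  expect_equal(length(sims[[1]]$agar), 4L)
  out <- capture.output(summary(fit))
  expect_true(any(grepl("interaction", out)))
})

test_that("percent error matches the published comparison", {
  expect_equal(round(percent_error(230.825, 222.76), 1), 3.5)
  expect_equal(percent_error(100, 100), 0)
  expect_equal(percent_error(100, 90), 10)
  # scale invariance
  expect_equal(percent_error(321 * 7, 289 * 7), percent_error(321, 289))
  expect_error(percent_error(0, 10), "positive")
})

test_that("pooled t-test reproduces the published p and a quadrature oracle", {
  p <- pooled_t_test(c(221.1, 212.2), c(285.3, 204.7))
  expect_equal(round(p, 2), 0.56)
  expect_equal(pooled_t_test(c(1, 2, 3), c(1, 2, 3)), 1)
  # quadrature oracle at the computed statistic and df
  a <- c(221.1, 212.2); b <- c(285.3, 204.7)
  sp2 <- (var(a) + var(b)) / 2
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 2 + 1 / 2))
  expect_equal(p, t_pvalue_quadrature(tstat, 2), tolerance = 1e-6)
  expect_error(pooled_t_test(1, c(2, 3)), "at least two")
})

test_that("threshold-to-percent conversion matches the 8-bit range", {
  expect_equal(threshold_as_percent(110), 43)
  expect_equal(threshold_as_percent(67), 26)
  expect_equal(threshold_as_percent(100), 39)
  expect_equal(threshold_as_percent(0), 0)
  expect_equal(threshold_as_percent(255), 100)
  expect_error(threshold_as_percent(256), "\\[0, 255\\]")
})

test_that("diffusion matching finds the earliest aligned time", {
  # constant series at the reference mean
  s <- lapply(1:3, function(i)
    data.frame(time_min = 0:10, volume_ul = rep(200, 11)))
  dm <- match_diffusion(s, ref_volumes = c(190, 210))
  expect_equal(dm$t_star, 0)
  expect_equal(dm$percent_error, 0)
  # published final volumes: 3.5% error between group means
  agar_final <- c(196.7, 229.2, 260.2, 220.7, 207.0)
  nhp_vols <- c(221.1, 212.2, 285.3, 204.7)
  expect_equal(round(percent_error(mean(nhp_vols), mean(agar_final)), 1), 3.5)
  # saturating growth crossing the reference: analytic first-crossing
  tau <- 8; v_inf <- 300; c0 <- 180
  tt <- seq(0, 60, by = 0.5)
  series <- list(data.frame(time_min = tt,
                            volume_ul = v_inf - c0 * exp(-tt / tau)))
  ref <- 250
  dm2 <- match_diffusion(series, ref, tolerance = 5)
  t_analytic <- -tau * log((v_inf - 0.95 * ref) / c0)  # v(t) = 0.95 ref
  expect_lt(abs(dm2$t_star - t_analytic), 0.5 + 1e-9)
  expect_true(dm2$within_tolerance)
  expect_error(match_diffusion(list(data.frame(time_min = 1, volume_ul = 1),
                                    data.frame(time_min = 2, volume_ul = 1)),
                               100), "overlapping")
})
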