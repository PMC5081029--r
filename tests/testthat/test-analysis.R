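test_that("Hill fit recovers exact Hill data and is scale-equivariant", {
  pca <- seq(6.5, 4.8, by = -0.1)
  f <- 0.8 / (1 + 10^(4 * (pca - 5.7)))
  hf <- fit_hill(list(pca = pca, force = f))
  expect_equal(hf$n_H, 4, tolerance = 1e-6)
  expect_equal(hf$pCa50, 5.7, tolerance = 1e-6)
  expect_equal(hf$F_max, 0.8, tolerance = 1e-6)
  # half-curve coefficients agree for symmetric data
  expect_equal(hf$n_H_lower, 4, tolerance = 1e-6)
  expect_equal(hf$n_H_upper, 4, tolerance = 1e-6)
  # scaling forces rescales F_max only
  hf2 <- fit_hill(list(pca = pca, force = 3 * f))
  expect_equal(hf2$F_max, 2.4, tolerance = 1e-6)
  expect_equal(hf2$n_H, hf$n_H, tolerance = 1e-8)
  expect_equal(hf2$pCa50, hf$pCa50, tolerance = 1e-8)
  # predict() reproduces the fitted values
  expect_equal(predict(hf, pca), f, tolerance = 1e-6)
})

test_that("Hill fit with baseline offset recovers constitutive activation", {
  pca <- seq(7.2, 4.6, by = -0.2)
  f <- 0.1 + 0.5 / (1 + 10^(2 * (pca - 6.0)))
  hf <- fit_hill(list(pca = pca, force = f), offset = TRUE)
  expect_equal(hf$F_0, 0.1, tolerance = 1e-5)
  expect_equal(hf$n_H, 2, tolerance = 1e-5)
  expect_equal(hf$pCa50, 6.0, tolerance = 1e-5)
})

test_that("Hill fit rejects degenerate input", {
  expect_error(fit_hill(list(pca = c(6, 5), force = c(0.1, 0.9))),
               "at least 5")
  # no half-max crossing
  pca <- seq(6.5, 5.8, by = -0.1)
  expect_error(fit_hill(list(pca = pca, force = rep(0.01, length(pca)) +
                               c(1:8) * 1e-4)), "half-max")
})

test_that("twitch metrics reproduce simple geometric cases", {
  t <- seq(0, 200, by = 1)
  f <- ifelse(t <= 100, t / 100, (200 - t) / 100)
  m <- twitch_metrics(list(times = t, force = f))
  expect_equal(m$peak_force, 1)
  expect_equal(m$ttp, 100)
  expect_equal(m$rt50, 50, tolerance = 1e-8)
  expect_equal(m$diastolic_force, 0)
  # rectangle: TTI = h * w by the trapezoid rule
  t2 <- c(0, 1e-9, 100, 100 + 1e-9, 200)
  f2 <- c(0, 2, 2, 0, 0)
  m2 <- twitch_metrics(list(times = t2, force = f2))
  expect_equal(m2$tension_time_integral, 200, tolerance = 1e-5)
  # constant trace is an error
  expect_error(twitch_metrics(list(times = t, force = rep(1, length(t)))),
               "constant")
  # monotone trace: partial results with NA rt50 and a warning
  expect_warning(m3 <- twitch_metrics(list(times = t, force = t / 200)),
                 "relax")
  expect_true(is.na(m3$rt50))
  expect_equal(m3$ttp, 200)
})

test_that("twitch metrics are invariant under uniform time shift", {
  t <- seq(0, 400, by = 2)
  f <- exp(-(t - 120)^2 / 3000)
  m1 <- twitch_metrics(list(times = t, force = f))
  m2 <- twitch_metrics(list(times = t - 50, force = f), onset = -50)
  expect_equal(m1$ttp, m2$ttp)
  expect_equal(m1$rt50, m2$rt50)
  expect_equal(m1$peak_force, m2$peak_force)
})

test_that("curve RMSE has the expected trivial and statistical behaviour", {
  pca <- seq(6.5, 5, by = -0.1)
  f <- 1 / (1 + 10^(3 * (pca - 5.7)))
  curve <- list(pca = pca, force = f)
  expect_equal(rmse_curve(curve, data.frame(pca = pca, force = f)), 0)
  expect_equal(rmse_curve(curve, data.frame(pca = pca, force = f + 0.05)),
               0.05, tolerance = 1e-10)
  # with iid noise the RMSE converges to the noise sd
  set.seed(4)
  pg <- seq(6.5, 5, length.out = 4000)
  fg <- 1 / (1 + 10^(3 * (pg - 5.7)))
  noisy <- fg + stats::rnorm(length(pg), sd = 0.03)
  expect_equal(rmse_curve(list(pca = pg, force = fg),
                          data.frame(pca = pg, force = noisy)),
               0.03, tolerance = 0.05)
  expect_error(rmse_curve(curve, data.frame(pca = c(9, 8.5), force = c(0, 0))),
               "disjoint")
})
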