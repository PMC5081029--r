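test_that("steady force vanishes without an activation path and rises with Ca", {
  p <- set1()  # lam = 0
  s9 <- steady_force(9, p, quick_config(n_runs = 10, duration = 500))
  expect_lt(s9$force, 1e-3)
  lo <- steady_force(6.5, p, quick_config(n_runs = 30, duration = 2000,
                                          seed = 11))
  hi <- steady_force(4.5, p, quick_config(n_runs = 30, duration = 2000,
                                          seed = 12))
  expect_gt(hi$force, lo$force)
  expect_error(steady_force(3.5, p, quick_config()), "pca")
})

test_that("force-pCa curves are monotone in calcium within noise", {
  p <- set2()
  grid <- seq(6.8, 5.0, by = -0.3)
  cv <- force_pca_curve(grid, p, sim_config(n_runs = 40, duration = 2500,
                                            seed = 13))
  d <- diff(cv$force)
  tol <- 2 * sqrt(cv$force_sem[-1]^2 + cv$force_sem[-length(grid)]^2)
  expect_true(all(d > -tol))
  # normalized curve peaks at exactly 1
  cvn <- force_pca_curve(grid, p, sim_config(n_runs = 20, duration = 1500,
                                             seed = 14), normalize = TRUE)
  expect_equal(max(cvn$force), 1)
})

test_that("ktr protocol resets force and fits a monoexponential recovery", {
  p <- set1()
  k <- ktr_protocol(4.6, p, sim_config(n_runs = 60, duration = 3000,
                                       seed = 15), post_duration = 1500)
  expect_s3_class(k, "ktr_result")
  expect_gt(k$ktr, 0)
  expect_lt(k$fit_residual, 0.05)
  tr <- k$trace
  i_reset <- which(tr$times == tr$reset_at)
  expect_equal(tr$force[i_reset], 0)           # all M removed at the reset
  expect_gt(tr$force[i_reset - 1], 0.1)        # steady force before it
  # recovery approaches the pre-reset steady level
  expect_equal(k$F_ss, mean(tr$force[tr$times < tr$reset_at &
                                     tr$times > 0.75 * tr$reset_at]),
               tolerance = 0.15)
})

test_that("ktr increases with calcium over the sub-saturating range", {
  p <- set1()
  k_hi <- ktr_protocol(4.5, p, sim_config(n_runs = 120, duration = 4000,
                                          seed = 16), post_duration = 2000)
  k_lo <- ktr_protocol(5.5, p, sim_config(n_runs = 120, duration = 4000,
                                          seed = 17), post_duration = 2000)
  expect_gt(k_hi$ktr, k_lo$ktr)
})

test_that("single-unit ktr approaches f + g when the blocked state is rare", {
  q <- tm_params(gamma = 0, K_BC = 1000, k_BC_ref = 1, f_ref = 0.05,
                 delta = 0.5, lam = 0, k_Ca_on = 0.125, k_Ca_off = 0.58)
  k <- ktr_protocol(4.0, q, sim_config(n_runs = 400, duration = 1500,
                                       seed = 18, record_dt = 2),
                    n_live = 1, post_duration = 1500)
  expect_equal(k$ktr, 0.1, tolerance = 0.15)
})

test_that("a constant transient reproduces the constant-calcium steady force", {
  p <- set3()
  ca0 <- 0.8
  tr <- calcium_transient(c(0, 400), c(ca0, ca0))
  cfg <- sim_config(n_runs = 60, seed = 19, record_dt = 1)
  tw <- twitch(tr, p, cfg, pad = 200)
  sfc <- steady_force(ca_to_pca(ca0), p,
                      sim_config(n_runs = 60, duration = 600, seed = 20,
                                 avg_frac = 0.5))
  tail_mean <- mean(tw$force[tw$times > 200])
  expect_equal(tail_mean, sfc$force, tolerance = 5 * sfc$sem + 0.01)
})

test_that("softer tropomyosin raises peak and diastolic twitch force", {
  tr <- make_transient()
  p <- set3()
  soft <- p; soft$gamma <- 0.5 * p$gamma
  cfg <- sim_config(n_runs = 150, seed = 21, record_dt = 1)
  m_wt <- twitch_metrics(twitch(tr, p, cfg))
  m_soft <- twitch_metrics(twitch(tr, soft, cfg))
  expect_gt(m_soft$peak_force, m_wt$peak_force)
  expect_gt(m_soft$diastolic_force, m_wt$diastolic_force)
  expect_lt(m_soft$ttp, m_wt$ttp)
  expect_gt(m_soft$rt50, m_wt$rt50)
})
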