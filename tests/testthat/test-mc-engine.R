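test_that("automatic time step bounds the worst-case transition probability", {
  p <- toy_params()
  dt <- choose_dt(p, ca_max = 5, threshold = 0.7)
  # linear in the threshold
  expect_equal(choose_dt(p, 5, 0.35), dt / 2)
  # halving every rate doubles dt
  ph <- p
  for (f in c("k_BC_ref", "f_ref", "k_Ca_on", "k_Ca_off")) ph[[f]] <- p[[f]] / 2
  expect_equal(choose_dt(ph, 5, 0.7), 2 * dt, tolerance = 1e-12)
  # worst-case exit rate 14 / ms at threshold 0.7 gives dt = 0.05 ms
  q <- tm_params(gamma = 0, K_BC = 1, k_BC_ref = 4, f_ref = 4, delta = 0.5,
                 lam = 1, k_Ca_on = 1, k_Ca_off = 2)
  # C1 exits: k_CB 4 + f 4 + lam*k_off 2; at ca 4: + k_on*ca... use C0:
  # exits k_CB 4 + f 4 + k_on*ca 6 = 14
  expect_equal(choose_dt(q, 6, 0.7), 0.7 / 14, tolerance = 1e-12)
})

test_that("synchronous reference stepper conserves units and boundaries", {
  p <- toy_params()
  states <- c(1L, rep(1L, 5), 1L)
  set.seed(1)
  for (i in 1:60) {
    states <- step_filament(states, p, ca = 3, dt = 0.05)
    expect_equal(length(states), 7L)
    expect_identical(states[c(1, 7)], c(1L, 1L))  # boundaries immutable
    expect_true(all(states %in% 1:6))
  }
  # absorbing case: lam = 0 and no calcium pins everything at B0
  p0 <- toy_params(lam = 0)
  s <- c(1L, rep(1L, 5), 1L)
  set.seed(2)
  for (i in 1:20) s <- step_filament(s, p0, ca = 0, dt = 0.1)
  expect_identical(s, c(1L, rep(1L, 5), 1L))
  expect_error(step_filament(c(2L, 1L, 1L), p, 1, 0.05), "boundary")
  expect_error(step_filament(s, p, 1e3, 1), "time-step")
})

test_that("trajectories are reproducible, bounded and conserve occupancy", {
  p <- set1()
  cfg <- quick_config(n_runs = 10, duration = 500, seed = 99)
  t1 <- simulate_filament(p, 5, cfg)
  t2 <- simulate_filament(p, 5, cfg)
  expect_identical(t1$force, t2$force)       # same seed, same trajectory
  t3 <- simulate_filament(p, 5, quick_config(n_runs = 10, duration = 500,
                                             seed = 100))
  expect_false(identical(t1$force, t3$force))
  expect_true(all(t1$force >= 0 & t1$force <= 1))
  expect_equal(rowSums(t1$occupancy), rep(1, nrow(t1$occupancy)),
               tolerance = 1e-12)
  # no calcium and lam = 0: force identically zero
  pz <- set1()
  tz <- simulate_filament(pz, 0, quick_config(n_runs = 5, duration = 200))
  expect_true(all(tz$force == 0))
  expect_error(simulate_filament(p, 5, sim_config(duration = 1e-9)),
               "duration|time step")
})

test_that("single-unit long-run occupancy matches the stationary law", {
  p <- toy_params(gamma = 25)  # context-dependent rates, B,B dummies
  ca <- 2
  cfg <- sim_config(n_runs = 200, duration = 4000, seed = 5, record_dt = 5,
                    avg_frac = 0.5)
  traj <- simulate_filament(p, ca, cfg, n_live = 1)
  pi <- stationary_distribution(build_generator(1, p, ca))
  fex <- pi[5] + pi[6]
  m <- mean(traj$run_means)
  sem <- stats::sd(traj$run_means) / sqrt(length(traj$run_means))
  expect_lt(abs(m - fex), 3.5 * sem)
  # occupancy of each of the six states agrees with pi in the averaged tail
  tail_occ <- colMeans(traj$occupancy[traj$times >= 2000, ])
  expect_equal(unname(tail_occ), pi, tolerance = 0.02)
})

test_that("zero-coupling filament matches the independent single-unit force", {
  p <- set1(); p$gamma <- 0
  ca <- 10  # near-saturating
  cfg <- sim_config(n_runs = 60, duration = 4000, seed = 6, avg_frac = 0.25)
  traj <- simulate_filament(p, ca, cfg, n_live = 24)
  pi <- stationary_distribution(build_generator(1, p, ca))
  fex <- pi[5] + pi[6]
  sem <- stats::sd(traj$run_means) / sqrt(length(traj$run_means))
  expect_lt(abs(mean(traj$run_means) - fex), 3.5 * sem)
})

test_that("results are insensitive to the probability threshold (dt convergence)", {
  p <- set1()
  f <- lapply(c(0.7, 0.35), function(th) {
    cfg <- sim_config(n_runs = 80, duration = 4000, seed = 7, threshold = th)
    traj <- simulate_filament(p, pca_to_ca(5.4), cfg)
    c(mean(traj$run_means),
      stats::sd(traj$run_means) / sqrt(length(traj$run_means)))
  })
  z <- zdiff(f[[1]][1], f[[1]][2], f[[2]][1], f[[2]][2])
  expect_lt(abs(z), 3)
})
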