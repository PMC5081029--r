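test_that("derived rates follow the equilibrium and duty-cycle definitions", {
  p <- tm_params(gamma = 68, K_BC = 1, k_BC_ref = 1.83, f_ref = 0.1,
                 delta = 0.5, lam = 0, k_Ca_on = 0.125, k_Ca_off = 0.58)
  r <- derive_rates(p)
  expect_equal(r[["g_ref"]], 0.1)            # symmetric duty cycle
  expect_equal(r[["k_CB_ref"]], 1.83)        # unit equilibrium
  # Set 1 duty cycle: g = f (1 - delta) / delta
  s1 <- set1()
  expect_equal(derive_rates(s1)[["g_ref"]],
               0.0058 * (1 - 0.4754) / 0.4754, tolerance = 1e-10)
  expect_equal(derive_rates(s1)[["g_ref"]], 0.00640, tolerance = 1e-3)
  # recomputing K_BC from the derived pair recovers the input
  expect_equal(r[["k_BC_ref"]] / r[["k_CB_ref"]], p$K_BC)
})

test_that("parameter validation rejects out-of-domain values", {
  expect_error(tm_params(gamma = -1, K_BC = 1, k_BC_ref = 1, f_ref = 0.1,
                         delta = 0.5, lam = 0, k_Ca_on = 0.1, k_Ca_off = 0.5),
               "gamma")
  expect_error(tm_params(gamma = 1, K_BC = 0, k_BC_ref = 1, f_ref = 0.1,
                         delta = 0.5, lam = 0, k_Ca_on = 0.1, k_Ca_off = 0.5),
               "K_BC")
  expect_error(tm_params(gamma = 1, K_BC = 1, k_BC_ref = 1, f_ref = 0.1,
                         delta = 1.5, lam = 0, k_Ca_on = 0.1, k_Ca_off = 0.5),
               "delta")
  expect_error(tm_angles(phi_B = 30, phi_C = 25, phi_M = 35))
})

test_that("mutation scenarios scale gamma, K_BC and delta and round-trip", {
  p <- set1()
  e180g <- scenario_E180G()
  expect_equal(c(e180g$gamma_scale, e180g$K_BC_scale, e180g$delta_scale),
               c(0.75, 1.10, 1.15))
  d175n <- scenario_D175N()
  expect_equal(c(d175n$gamma_scale, d175n$K_BC_scale, d175n$delta_scale),
               c(0.60, 0.85, 1.00))
  q <- apply_mutation(p, e180g)
  expect_equal(q$gamma, p$gamma * 0.75)
  expect_equal(q$K_BC, p$K_BC * 1.10)
  expect_equal(q$delta, p$delta * 1.15)
  expect_equal(q$f_ref, p$f_ref)   # untouched fields unchanged
  expect_equal(q$lam, p$lam)
  # identity scenario is a no-op
  id <- apply_mutation(p, mutation_scenario())
  expect_equal(id$gamma, p$gamma)
  # reciprocal factors recover the original to numerical precision
  back <- apply_mutation(q, mutation_scenario(1 / 0.75, 1 / 1.10, 1 / 1.15))
  for (f in c("gamma", "K_BC", "delta"))
    expect_equal(back[[f]], p[[f]], tolerance = 1e-12)
  # duty cycle pushed to 1 or beyond is a domain error
  expect_error(apply_mutation(p, mutation_scenario(1, 1, 1 / p$delta)),
               "duty cycle")
})

test_that("packaged parameter sets load with the published values", {
  s1 <- set1()
  expect_equal(s1$gamma, 68)
  expect_equal(s1$K_BC, 1.83)
  expect_equal(s1$delta, 0.4754)
  expect_equal(s1$lam, 0)
  s2 <- set2()
  expect_equal(s2$gamma, 37.64)
  expect_equal(s2$lam, 0.20)
  # mutant sets carry the stated proportional K_BC changes
  expect_equal(param_set("set2_E180G")$K_BC / s2$K_BC, 1.10, tolerance = 1e-4)
  expect_equal(param_set("set2_D175N")$K_BC / s2$K_BC, 0.85, tolerance = 1e-4)
  s3 <- set3()
  expect_equal(s3$delta, 0.715)
  expect_equal(param_set("set4_intact_E180G")$gamma, 51)
  expect_equal(param_set("set5_intact_D175N")$gamma, 40.8)
})

test_that("angles default to the structural values with halfway barriers", {
  a <- tm_angles()
  expect_equal(a$phi_C, 25 * pi / 180)
  expect_equal(a$phi_BC, (a$phi_B + a$phi_C) / 2)
  expect_equal(a$phi_CM, (a$phi_C + a$phi_M) / 2)
  expect_true(a$phi_B < a$phi_BC && a$phi_BC < a$phi_C &&
              a$phi_C < a$phi_CM && a$phi_CM < a$phi_M)
})
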