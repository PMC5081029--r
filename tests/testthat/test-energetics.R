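test_that("chain distortion energy is the quadratic torsion-spring form", {
  expect_equal(distortion_energy(0.3, 0.3, 68), 0)
  expect_equal(distortion_energy(25 * pi / 180, 0, 68), 6.473,
               tolerance = 1e-3)
  expect_equal(distortion_energy(35 * pi / 180, 0, 68), 12.688,
               tolerance = 1e-3)
  # symmetric in its angle arguments
  expect_equal(distortion_energy(0.1, 0.5, 30), distortion_energy(0.5, 0.1, 30))
  expect_error(distortion_energy(0.1, 0.2, -5), "gamma")
})

test_that("neighbor rate scaling matches hand-computed well/barrier factors", {
  p <- set1()
  # blocked neighbors retard B->C through the barrier term only
  expect_equal(rate_scale("BC", "B", "B", p), exp(-2 * 1.6184 / 2.577),
               tolerance = 1e-3)
  expect_equal(rate_scale("BC", "B", "B", p), 0.285, tolerance = 2e-3)
  # closed neighbors accelerate it (well raised more than barrier)
  expect_equal(rate_scale("BC", "C", "C", p), 43.3, tolerance = 1e-3)
  expect_error(rate_scale("BM", "B", "B", p))
})

test_that("rate scaling is left/right symmetric and flat at zero stiffness", {
  p <- set1()
  ctxs <- expand.grid(X = c("B", "C", "M"), Y = c("B", "C", "M"),
                      stringsAsFactors = FALSE)
  p0 <- p; p0$gamma <- 0
  for (tr in c("BC", "CB", "CM", "MC")) {
    for (k in seq_len(nrow(ctxs))) {
      expect_equal(rate_scale(tr, ctxs$X[k], ctxs$Y[k], p),
                   rate_scale(tr, ctxs$Y[k], ctxs$X[k], p))
      expect_equal(rate_scale(tr, ctxs$X[k], ctxs$Y[k], p0), 1)
    }
  }
  # scale approaches 1 monotonically as gamma decreases
  gs <- c(68, 30, 10, 1)
  for (k in seq_len(nrow(ctxs))) {
    s <- vapply(gs, function(g) {
      q <- p; q$gamma <- g
      rate_scale("BC", ctxs$X[k], ctxs$Y[k], q)
    }, numeric(1))
    expect_true(all(diff(abs(log(s))) <= 1e-12))
  }
})

test_that("well energies, not barriers, set the equilibrium shift", {
  p <- set2()
  a <- p$angles
  for (X in c("B", "C", "M")) for (Y in c("B", "C", "M")) {
    Q <- ru_rate_table(X, Y, p, ca = 2)
    dwell <- sum(vapply(c(X, Y), function(n) {
      phi_n <- switch(n, B = a$phi_B, C = a$phi_C, M = a$phi_M)
      distortion_energy(a$phi_C, phi_n, p$gamma) -
        distortion_energy(a$phi_B, phi_n, p$gamma)
    }, numeric(1)))
    expect_equal(Q["B1", "C1"] / Q["C1", "B1"],
                 p$K_BC * exp(-dwell / p$RT), tolerance = 1e-12)
  }
})

test_that("the six-state generator wires calcium and coupling correctly", {
  p <- toy_params(lam = 0)
  Q <- ru_rate_table("B", "C", p, ca = 2)
  # lam = 0 closes the calcium-free activation path entirely
  expect_identical(Q["B0", "C0"], 0)
  expect_identical(Q["C1", "C0"], 0)
  expect_identical(Q["M1", "M0"], 0)
  # direct B-M moves prohibited
  expect_identical(unname(Q["B0", c("M0", "M1")]), c(0, 0))
  expect_identical(unname(Q["M1", c("B0", "B1")]), c(0, 0))
  # no calcium, no binding
  Q0 <- ru_rate_table("B", "B", toy_params(), 0)
  expect_identical(unname(Q0[cbind(c("B0", "C0", "M0"),
                                   c("B1", "C1", "M1"))]), c(0, 0, 0))
  expect_error(ru_rate_table("B", "B", p, -1), "ca")
  # generator rows sum to zero; off-diagonals non-negative in all contexts
  for (X in c("B", "C", "M")) for (Y in c("B", "C", "M")) {
    Qc <- ru_rate_table(X, Y, set1(), 10)
    expect_equal(max(abs(rowSums(Qc))), 0, tolerance = 1e-12)
    off <- Qc; diag(off) <- 0
    expect_true(all(off >= 0))
  }
})

test_that("every calcium/tropomyosin cycle satisfies microscopic reversibility", {
  cycles <- list(c("B0", "B1", "C1", "C0"), c("C0", "C1", "M1", "M0"))
  for (lam in c(0.06, 0.2, 1)) {
    p <- toy_params(lam = lam, gamma = 68)
    for (X in c("B", "C", "M")) for (Y in c("B", "C", "M")) {
      Q <- ru_rate_table(X, Y, p, ca = 1.7)
      for (cy in cycles) {
        fw <- prod(Q[cbind(cy, c(cy[-1], cy[1]))])
        bw <- prod(Q[cbind(c(cy[-1], cy[1]), cy)])
        expect_equal(fw, bw, tolerance = 1e-12)
      }
    }
  }
})

test_that("jointed-chain cantilever stores energy quadratically in tip angle", {
  z <- jointed_chain_energy(10, 5, 0)
  expect_equal(z$energy, 0, tolerance = 1e-12)
  expect_equal(z$tip_angle, 0, tolerance = 1e-8)
  # doubling a small load quadruples the stored energy
  e1 <- jointed_chain_energy(10, 5, 1e-3)$energy
  e2 <- jointed_chain_energy(10, 5, 2e-3)$energy
  expect_equal(e2 / e1, 4, tolerance = 0.02)
  expect_error(jointed_chain_energy(0, 5, 0.1))
  expect_error(jointed_chain_energy(10, -1, 0.1))
  # energy ~ c * tip_angle^2 across a small-load sweep
  loads <- seq(0.002, 0.02, length.out = 8)
  res <- vapply(loads, function(L) {
    z <- jointed_chain_energy(10, 5, L)
    c(z$energy, z$tip_angle)
  }, numeric(2))
  fit <- stats::lm(res[1, ] ~ I(res[2, ]^2))
  expect_gt(summary(fit)$r.squared, 0.999)
})
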