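# Compartmental incorporation curves and residence-time arithmetic.

test_that("parameter constructor enforces the model invariants", {
  expect_error(compartment_params(-22, -19, 0), "lambda1")
  expect_error(compartment_params(-22, -19, -0.1), "lambda1")
  expect_error(compartment_params(-22, -19, 0.2, lambda2 = 0.1), "both lambda2 and p")
  expect_error(compartment_params(-22, -19, 0.2, lambda2 = -0.1, p = 0.5), "lambda2")
  expect_error(compartment_params(-22, -19, 0.2, lambda2 = 0.1, p = 1.2), "p must lie")
  expect_identical(compartment_params(-22, -19, 0.2)$kind, "one")
  expect_identical(compartment_params(-22, -19, 0.2, 0.1, 0.5)$kind, "two")
})

test_that("one-compartment curve starts at dX0, tends to dXinf, rejects bad input", {
  p <- compartment_params(-22.83, -19.23, 0.20)
  expect_equal(predict_one_compartment(p, 0), -22.83)
  expect_equal(predict_one_compartment(p, 1e4), -19.23, tolerance = 1e-9)
  expect_error(predict_one_compartment(p, -1), "non-negative")
  expect_error(predict_one_compartment(compartment_params(9, 6.3, 0.2, 0.3, 0.5), 1),
               "two-compartment")
  # monotone toward the asymptote
  path <- predict_one_compartment(p, seq(0, 120, by = 1))
  expect_true(all(diff(path) > 0))
})

test_that("closed form agrees with independent RK4 ODE integration", {
  # frozen oracle value at t = 5 for (-22.83, -19.23, 0.20):
  # dX = -19.23 - 3.6 exp(-1), computed by rk4_one_compartment
  p <- compartment_params(-22.83, -19.23, 0.20)
  oracle_t5 <- rk4_one_compartment(-22.83, -19.23, 0.20, 5)
  expect_equal(oracle_t5, -20.55436598, tolerance = 1e-7)
  expect_equal(predict_one_compartment(p, 5), oracle_t5, tolerance = 1e-9)
  # full-grid agreement on t in [0, 120]
  for (t in seq(0, 120, by = 12)) {
    expect_equal(predict_one_compartment(p, t),
                 rk4_one_compartment(-22.83, -19.23, 0.20, t),
                 tolerance = 1e-6)
  }
})

test_that("two-compartment curve matches term-wise evaluation and nests model 1", {
  p2 <- compartment_params(9.0, 6.3, lambda1 = 0.24, lambda2 = 0.28, p = 0.52)
  grid <- seq(0, 120, by = 10)
  # independent term-by-term oracle
  termwise <- 6.3 - (6.3 - 9.0) *
    (0.52 * exp(-0.24 * grid) + (1 - 0.52) * exp(-0.28 * grid))
  expect_equal(predict_two_compartment(p2, grid), termwise, tolerance = 1e-12)
  expect_equal(predict_two_compartment(p2, 0), 9.0)

  # p = 1 and p = 0 collapse to one-compartment, to machine precision
  grid100 <- seq(0, 120, length.out = 100)
  for (case in list(list(p = 1, lam = 0.24), list(p = 0, lam = 0.28))) {
    nested <- compartment_params(9.0, 6.3, 0.24, 0.28, case$p)
    single <- compartment_params(9.0, 6.3, case$lam)
    expect_identical(predict_two_compartment(nested, grid100),
                     predict_one_compartment(single, grid100))
  }
})

test_that("curves stay bounded between dX0 and dXinf for random parameters", {
  set.seed(42)
  grid <- seq(0, 300, length.out = 80)
  for (i in 1:25) {
    dX0 <- runif(1, -30, 15)
    dXinf <- runif(1, -30, 15)
    par <- if (i %% 2 == 0) {
      compartment_params(dX0, dXinf, runif(1, 0.005, 1))
    } else {
      compartment_params(dX0, dXinf, runif(1, 0.005, 1), runif(1, 0.005, 1),
                         runif(1))
    }
    path <- predict_incorporation(par, grid)
    expect_true(all(path >= min(dX0, dXinf) - 1e-12 &
                      path <= max(dX0, dXinf) + 1e-12))
  }
})

test_that("residence time is 1/lambda, pool-weighted for two pools", {
  expect_equal(residence_time(compartment_params(8.71, 10.41, 0.05))$tau, 20)
  expect_equal(residence_time(compartment_params(8.67, 10.65, 0.07))$tau,
               14.28571428571429, tolerance = 1e-12)
  expect_equal(round(residence_time(compartment_params(8.67, 10.65, 0.07))$tau), 14)
  # equal pools collapse
  rt <- residence_time(compartment_params(0, 1, 0.1, 0.1, 0.5))
  expect_equal(rt$tau_mean, 10)
  # tau_mean is a convex combination of the pool residence times
  set.seed(7)
  for (i in 1:20) {
    l1 <- runif(1, 0.01, 1); l2 <- runif(1, 0.01, 1); pp <- runif(1)
    tm <- residence_time(compartment_params(0, 1, l1, l2, pp))$tau_mean
    expect_gte(tm, min(1 / l1, 1 / l2) - 1e-12)
    expect_lte(tm, max(1 / l1, 1 / l2) + 1e-12)
  }
  # p = 1 gives tau_mean = tau1
  expect_equal(residence_time(compartment_params(0, 1, 0.2, 0.05, 1))$tau_mean, 5)
})
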