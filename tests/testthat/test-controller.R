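test_that("desired remote insulin action solves the glucose error dynamics", {
  p <- table1_params()
  g <- controller_gains()
  # nominal start: on-reference at 150 mg/dl with reference slope -0.5
  expect_equal(desired_x2(150, 150, -0.5, g, p), 0.5 / 150)
  expect_equal(desired_x2(p$Gb, p$Gb, 0, g, p), 0)
  # the disturbance estimate enters additively over x1
  expect_equal(desired_x2(150, 150, -0.5, g, p, d_hat = 0.6), 1.1 / 150)
  # monotone: a larger estimate demands more insulin action
  x2a <- desired_x2(120, 110, -0.3, g, p, d_hat = 0.1)
  x2b <- desired_x2(120, 110, -0.3, g, p, d_hat = 0.2)
  expect_gt(x2b, x2a)
  expect_error(desired_x2(0.5, 100, 0, g, p), "degenerate")
})

test_that("adaptive and plain first steps coincide at zero estimate", {
  p <- table1_params()
  g <- controller_gains()
  set.seed(11)
  for (i in 1:20) {
    x1 <- runif(1, 60, 300); x1d <- runif(1, 90, 200)
    x1dd <- runif(1, -1, 0)
    expect_identical(desired_x2(x1, x1d, x1dd, g, p, d_hat = 0),
                     desired_x2(x1, x1d, x1dd, g, p))
  }
})

test_that("desired plasma insulin inverts the remote-action dynamics", {
  p <- table1_params()
  g <- controller_gains()
  expect_equal(desired_x3(0, 0, 0, g, p), 7)
  expect_equal(desired_x3(0.01, 0.01, 0, g, p), 7 + 0.0142 * 0.01 / 1.5e-5)
  # linearity in 1/p3: scaling p3 by c scales the excess over Ib by 1/c
  p2x <- patient_params(p3 = 3e-5)
  expect_equal(desired_x3(0.01, 0.01, 0, g, p2x) - 7,
               (desired_x3(0.01, 0.01, 0, g, p) - 7) / 2)
})

test_that("control law realizes the insulin error dynamics", {
  p <- table1_params()
  g <- controller_gains()
  expect_equal(control_law(7, 7, 0, g, p), 0)
  expect_equal(control_law(100, 100, 0, g, p), 0.2814 * 93)
  # larger k3 reduces u when plasma insulin exceeds its desired value
  ghi <- controller_gains(k3 = 1.5)
  expect_lt(control_law(100, 80, 0, ghi, p), control_law(100, 80, 0, g, p))
  # optional pump clamp
  expect_equal(control_law(50, 7, 0, g, p, nonnegative = TRUE), 0)
  expect_lt(control_law(50, 7, 0, g, p), 0)
})

test_that("backward-difference derivative is exact for affine signals", {
  expect_equal(hold_derivative(5, NULL, 0.1), 0)
  expect_equal(hold_derivative(5, 5, 0.1), 0)
  a <- 3.7
  expect_equal(hold_derivative(a * 1.1, a * 1.0, 0.1), a)
  expect_error(hold_derivative(1, 0, 0), "dt")
})

test_that("sampled reference derivative converges to the analytic one", {
  traj <- reference_trajectory()
  dt <- 0.1
  tt <- seq(0, 10, by = dt)
  g <- reference_value(tt, traj)
  num <- diff(g) / dt
  an <- reference_derivatives(tt[-1], traj)$first
  expect_true(all(abs(num - an) / abs(an) < 1e-3))
})

test_that("substituting the desired action closes the glucose loop exactly", {
  # with x2 = x2d, D = 0 and d_hat = 0 the glucose dynamics reduce to
  # e1_dot = -k1 e1 identically
  p <- table1_params()
  g <- controller_gains()
  set.seed(3)
  for (i in 1:30) {
    x1 <- runif(1, 60, 320); x1d <- runif(1, 90, 200)
    x1d_dot <- runif(1, -2, 0)
    x2d <- desired_x2(x1, x1d, x1d_dot, g, p)
    G_dot <- plant_rhs(c(G = x1, X = x2d, I = 7), 0, 0, p)[["G"]]
    e1_dot <- G_dot - x1d_dot
    expect_equal(e1_dot, -g$k1 * (x1 - x1d))
  }
})

test_that("gains must be positive", {
  expect_error(controller_gains(k1 = -1), "positive")
  expect_error(controller_gains(k2 = 0), "positive")
})
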