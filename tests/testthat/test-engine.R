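test_that("basal equilibrium is preserved by the untreated loop", {
  p <- patient_params()
  sc <- glucose_scenario(mode = "none", meals = meal_schedule(),
                         init = c(G = p$Gb, X = 0, I = p$Ib),
                         reference = reference_trajectory(G0 = p$Gb,
                                                          Ginf = p$Gb),
                         horizon = 200)
  sim <- simulate_closed_loop(sc)
  expect_equal(sim$G, rep(p$Gb, length(sim$time)))
  expect_equal(sim$X, rep(0, length(sim$time)))
  expect_equal(sim$I, rep(p$Ib, length(sim$time)))
  expect_true(all(sim$u_applied == 0))
})

test_that("without treatment glucose escapes to the dangerous zone", {
  sim <- untreated_sim()
  expect_gt(max(sim$G), 180)
  expect_true(all(sim$u_commanded == 0))
  expect_true(all(sim$D_hat == 0))
})

test_that("plant integration agrees with an independent stiff solver", {
  p <- patient_params()
  sc <- glucose_scenario(mode = "none", horizon = 200)
  sim <- simulate_closed_loop(sc)
  rhs <- function(t, y, parms) {
    list(c(-p$p1 * (y[1] - p$Gb) - y[1] * y[2] +
             meal_disturbance(t, default_meals()),
           -p$p2 * y[2] + p$p3 * (y[3] - p$Ib),
           -p$n * (y[3] - p$Ib)))
  }
  ref <- deSolve::ode(c(150, 0, 100), seq(0, 200, by = 1), rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(sim$G - ref[, 2])), 0.01)
  expect_lt(max(abs(sim$I - ref[, 4])), 1e-6)
})

test_that("degenerate and mis-specified runs abort with a diagnostic", {
  crash <- glucose_scenario(mode = "none", meals = meal_schedule(),
                            init = c(G = 50, X = 1, I = 7), horizon = 600)
  expect_error(simulate_closed_loop(crash), "guard")
  expect_error(glucose_scenario(horizon = -1), "horizon")
  expect_error(glucose_scenario(report_step = 0.25), "multiple")
})

test_that("result series share one grid and echo the stress configuration", {
  sim <- nominal_adaptive_sim()
  n <- length(sim$time)
  expect_equal(sim$time, seq(0, 1440, by = 1))
  for (f in c("G", "X", "I", "u_commanded", "u_applied", "D_true",
              "D_hat", "G_d", "e1", "e2", "e3")) {
    expect_length(sim[[f]], n)
  }
  expect_identical(sim$u_applied, sim$u_commanded)  # no fault configured
  expect_equal(sim$G_d, reference_value(sim$time, sim$scenario$reference))
  expect_equal(sim$e1, sim$G - sim$G_d)
  bk <- nominal_backstepping_sim()
  expect_true(all(bk$D_hat == 0))
})

test_that("identical scenarios give identical outputs", {
  a <- simulate_closed_loop(glucose_scenario(horizon = 300))
  b <- simulate_closed_loop(glucose_scenario(horizon = 300))
  expect_identical(a[names(a) != "scenario"], b[names(b) != "scenario"])
})

test_that("Lyapunov diagnostics obey the theory where it applies exactly", {
  sim <- nominal_adaptive_sim()
  V <- lyapunov_series(sim)
  expect_true(all(V$V3 >= 0))
  # starting on-reference with no meal yet: V3(0) carries only e2, e3
  expect_equal(V$V3[1], 0.5 * sim$e2[1]^2 + 0.5 * sim$e3[1]^2)
  expect_equal(sim$e1[1], 0)
  # fasting segment (D = 0, constant): non-increasing to 1% per sample
  fast <- V$V3[V$time <= 119]
  expect_true(all(diff(fast) <= 0.01 * fast[-length(fast)]))
  # each between-onset segment dissipates energy end to end
  for (seg in list(c(0, 119), c(121, 479), c(481, 839), c(841, 1440))) {
    v <- V$V3[V$time >= seg[1] & V$time <= seg[2]]
    expect_lt(v[length(v)], v[1])
  }
  expect_error(lyapunov_series(nominal_backstepping_sim()), "adaptive")
})

test_that("first controller sample uses start-up derivatives of zero", {
  sim <- nominal_adaptive_sim()
  p <- sim$scenario$params
  g <- sim$scenario$gains
  x2d0 <- desired_x2(150, 150, reference_derivatives(0,
            sim$scenario$reference)$first, g, p, d_hat = 0)
  expect_equal(sim$e2[1], 0 - x2d0)
})
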