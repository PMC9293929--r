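test_that("meal disturbance evaluates the decaying-exponential closed form", {
  lunch_only <- meal_schedule(meal_event(480, 0.6, 0.01))
  expect_equal(meal_disturbance(480, lunch_only), 0.6)
  expect_equal(meal_disturbance(60, default_meals()), 0)
  # 100 min after lunch: lunch tail 0.6 e^-1, plus the breakfast tail
  expect_equal(meal_disturbance(580, lunch_only), 0.6 * exp(-1))
  expect_equal(meal_disturbance(580, default_meals()),
               0.4 * exp(-0.01 * 460) + 0.6 * exp(-1))
  # reset mode keeps only the most recent meal
  expect_equal(meal_disturbance(580, default_meals(), superpose = FALSE),
               0.6 * exp(-1))
})

test_that("meal disturbance is non-negative and strictly decreasing between onsets", {
  sched <- default_meals()
  tt <- seq(0, 1440, by = 1)
  D <- meal_disturbance(tt, sched)
  expect_true(all(D >= 0))
  for (win in list(121:479, 481:839, 841:1440)) {
    expect_true(all(diff(D[tt %in% win]) < 0))
  }
  # right-continuous jump at each onset
  expect_gt(meal_disturbance(480, sched), meal_disturbance(479.999, sched))
})

test_that("plant right-hand side matches the minimal-model equations", {
  p <- table1_params()
  expect_equal(unname(plant_rhs(basal_equilibrium(p), 0, 0, p)), c(0, 0, 0))
  d <- plant_rhs(plant_state(150, 0, 100), u = 0, D = 0, params = p)
  expect_equal(unname(d), c(0, 1.5e-5 * 93, -0.2814 * 93))
  # with p1 = 0, glucose dynamics reduce to -G*X + D
  set.seed(42)
  for (i in 1:20) {
    st <- plant_state(runif(1, 50, 300), runif(1, -0.05, 0.2),
                      runif(1, 0, 200))
    D <- runif(1, 0, 1)
    expect_equal(plant_rhs(st, 0, D, p)[["G"]], -st[["G"]] * st[["X"]] + D)
  }
})

test_that("basal state is a fixed point for any valid parameter set", {
  set.seed(7)
  for (i in 1:25) {
    p <- patient_params(p1 = runif(1, 0, 0.1), p2 = runif(1, 0.001, 0.1),
                        p3 = runif(1, 1e-6, 1e-3), n = runif(1, 0.05, 0.5),
                        Gb = runif(1, 60, 120), Ib = runif(1, 0, 20))
    eq <- basal_equilibrium(p)
    expect_equal(unname(plant_rhs(eq, 0, 0, p)), c(0, 0, 0))
    u <- runif(1, 0, 10)
    expect_equal(plant_rhs(eq, u, 0, p)[["I"]], u)
  }
})

test_that("plant guard rejects degenerate glucose", {
  p <- table1_params()
  st <- c(G = 0.5, X = 0, I = 7)
  expect_error(plant_rhs(st, 0, 0, p), "degenerate")
})

test_that("reference trajectory decays exponentially to the target", {
  traj <- reference_trajectory(G0 = 150, Ginf = 100, tau = 100)
  expect_equal(reference_value(0, traj), 150)
  expect_equal(reference_value(100, traj), 100 + 50 * exp(-1))
  expect_equal(reference_value(1e6, traj), 100)
  tt <- seq(0, 1440, by = 10)
  gv <- reference_value(tt, traj)
  expect_true(all(diff(gv) < 0))
  expect_true(all(gv >= 100 & gv <= 150))
})

test_that("reference derivatives are exact", {
  traj <- reference_trajectory(G0 = 150, Ginf = 100, tau = 100)
  d <- reference_derivatives(0, traj)
  expect_equal(d$first, -0.5)
  expect_equal(d$second, 0.005)
  flat <- reference_trajectory(G0 = 100, Ginf = 100, tau = 100)
  df <- reference_derivatives(c(0, 50, 500), flat)
  expect_equal(df$first, c(0, 0, 0))
  expect_equal(df$second, c(0, 0, 0))
  # central finite difference of reference_value, step 1e-3 min
  h <- 1e-3
  for (t in c(10, 100, 700)) {
    fd <- (reference_value(t + h, traj) - reference_value(t - h, traj)) / (2 * h)
    an <- reference_derivatives(t, traj)$first
    expect_lt(abs(fd - an) / abs(an), 1e-6)
  }
})

test_that("constructors validate their invariants", {
  expect_error(patient_params(p2 = -1), "p2")
  expect_error(patient_params(Gb = 0), "Gb")
  expect_error(meal_event(100, A = -0.5), "A")
  expect_error(meal_schedule(meal_event(480, 0.6), meal_event(120, 0.4)),
               "increasing")
  expect_error(reference_trajectory(tau = 0), "tau")
  expect_error(plant_state(-5, 0, 7), "G")
})
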