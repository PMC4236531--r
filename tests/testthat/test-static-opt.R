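test_that("the single-muscle frame matches the Lagrange closed form", {
  pb <- frame_problem(c(ankle = 50), matrix(100, 1, 1,
                                            dimnames = list("pf", "ankle")))
  sol <- solve_frame(pb)
  expect_equal(sol$solver_status, "optimal")
  # minimize a_t^2 + a_m^2 s.t. a_t + 100 a_m = 50: split by gain ratio
  expect_equal(unname(sol$muscle_activations), 5000 / 10001, tolerance = 1e-8)
  expect_equal(unname(sol$reserve_activations), 50 / 10001, tolerance = 1e-8)
  expect_lt(max(abs(sol$moment_residual)), 1e-10)
  expect_lt(kkt_residual(pb, sol), 1e-6)
})

test_that("a saturated muscle hands the remaining moment to the reserve", {
  pb <- frame_problem(c(ankle = 50), matrix(30, 1, 1,
                                            dimnames = list("pf", "ankle")))
  sol <- solve_frame(pb)
  expect_equal(unname(sol$muscle_activations), 1, tolerance = 1e-9)
  expect_equal(unname(sol$reserve_moments), 20, tolerance = 1e-6)
  expect_lt(kkt_residual(pb, sol), 1e-6)
  # grid oracle agrees
  orc <- brute_force_oracle(pb, grid_step = 1e-4)
  expect_lt(abs(orc$objective_value - sol$objective_value), 1e-4)
})

test_that("zero demand yields the all-zero solution", {
  pb <- frame_problem(c(hip = 0, knee = 0),
                      matrix(c(40, -20, 0, 90), 2, 2,
                             dimnames = list(c("a", "b"), c("hip", "knee"))))
  sol <- solve_frame(pb)
  expect_equal(unname(sol$muscle_activations), c(0, 0))
  expect_equal(unname(sol$reserve_activations), c(0, 0))
  expect_equal(sol$objective_value, 0)
  expect_equal(kkt_residual(pb, sol), 0)
  orc <- brute_force_oracle(pb, grid_step = 0.05)
  expect_equal(orc$objective_value, 0)
})

test_that("QP solutions match the brute-force grid oracle on random instances", {
  set.seed(11)
  for (i in 1:40) {
    nm <- sample(1:3, 1); nd <- sample(1:2, 1)
    pb <- random_frame_problem(nm, nd)
    sol <- solve_frame(pb)
    expect_equal(sol$solver_status, "optimal")
    step <- 1e-2
    orc <- brute_force_oracle(pb, grid_step = step)
    expect_lte(sol$objective_value, orc$objective_value + 1e-9)
    tot <- sum(abs(sol$muscle_activations)) + sum(abs(sol$reserve_activations))
    expect_lte(orc$objective_value - sol$objective_value, 2 * step * tot + 1e-9)
    expect_lt(kkt_residual(pb, sol), 1e-6)
  }
  big <- frame_problem(c(d = 1), matrix(runif(4, 1, 10), 4, 1))
  expect_error(brute_force_oracle(big, 0.1), "restricted")
})

test_that("KKT residual detects perturbed solutions", {
  pb <- frame_problem(c(ankle = 50), matrix(100, 1, 1,
                                            dimnames = list("pf", "ankle")))
  sol <- solve_frame(pb)
  base <- kkt_residual(pb, sol)
  pert <- sol
  pert$muscle_activations <- sol$muscle_activations - 0.1
  pert$reserve_activations <- (50 - 100 * pert$muscle_activations) / 1
  expect_gt(kkt_residual(pb, pert), base)
  expect_gt(kkt_residual(pb, pert), 0.01)
})

test_that("moment conservation holds exactly at every optimal frame", {
  model <- two_dof_model()
  set.seed(3)
  n <- 30
  tt <- seq(0, 1, length.out = n)
  q <- cbind(hip = -0.4 + 0.3 * sin(pi * tt), knee = -0.8 + 0.4 * tt)
  qd <- cbind(hip = 0.3 * pi * cos(pi * tt), knee = rep(0.4, n))
  mom <- cbind(hip = 60 * sin(pi * tt), knee = 40 * sin(pi * tt)^2 - 10)
  tr <- trial_data("gait", tt, q, qd, mom, body_mass = 61)
  sol <- solve_trial(model, tr)
  # sum of muscle moments + reserve moments reproduces the demand per DOF
  for (k in c("hip", "knee")) {
    muscle_mom <- rowSums(sol$gains[, , k] * sol$muscle_activations)
    expect_lt(max(abs(muscle_mom + sol$reserve_moments[, k] - mom[, k])), 1e-6)
  }
  expect_true(all(sol$muscle_activations >= -1e-8 & sol$muscle_activations <= 1 + 1e-8))
})

test_that("solve_trial agrees with solve_frame and prefers muscles over reserves", {
  model <- tiny_model(F0 = 3000, arm = 0.04)
  tr <- planted_trial(model, ratio = 0.6, n = 21)
  sol <- solve_trial(model, tr)
  # single-frame consistency
  i <- which.max(tr$net_moments[, "ankle"])
  fs <- frame_solution_at(sol, i)
  pb <- frame_problem(c(ankle = tr$net_moments[i, "ankle"]),
                      matrix(sol$gains[i, , ], 1, 1,
                             dimnames = list("pf", "ankle")))
  direct <- solve_frame(pb)
  expect_equal(fs$muscle_activations, direct$muscle_activations, tolerance = 1e-10)
  expect_equal(fs$objective_value, direct$objective_value, tolerance = 1e-10)
  # reserve share is algebraically tiny when muscles can cover the demand:
  # below tau0^2 * demand / (gain^2 + tau0^2)
  gain <- sol$gains[i, 1, 1]
  demand <- tr$net_moments[i, "ankle"]
  expect_lt(max(abs(sol$reserve_moments)), demand / (gain^2 + 1) + 1e-9)
  # zero-moment trial: all-zero activations
  tr0 <- planted_trial(model, ratio = 0, n = 11)
  sol0 <- solve_trial(model, tr0)
  expect_equal(max(abs(sol0$muscle_activations)), 0)
  expect_equal(max(abs(sol0$reserve_moments)), 0)
})

test_that("reserve moments grow monotonically with weakness for fixed demand", {
  model <- tiny_model(F0 = 3000, arm = 0.04)
  tr <- planted_trial(model, ratio = 0.8, n = 21)
  peaks <- vapply(seq(0, 1, by = 0.1), function(w) {
    max(solve_trial(apply_weakness(model, w), tr)$reserve_moments)
  }, numeric(1))
  expect_true(all(diff(peaks) >= -1e-9))
  expect_equal(peaks[11], max(tr$net_moments), tolerance = 1e-9)
})
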