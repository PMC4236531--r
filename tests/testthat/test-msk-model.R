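test_that("Hill curves equal 1 at the isometric optimum and behave at limits", {
  expect_equal(force_length(1), 1)
  expect_equal(force_velocity(0), 1)
  # maximal shortening produces no force; lengthening saturates below plateau
  expect_equal(force_velocity(-1), 0)
  expect_equal(force_velocity(-1.5), 0)
  expect_lte(force_velocity(5), 1.4)
  expect_gt(force_velocity(0.3), 1)
  # continuity across the isometric point
  expect_equal(force_velocity(1e-9), force_velocity(-1e-9), tolerance = 1e-6)
})

test_that("active force is linear in activation and maximal isometric force", {
  set.seed(42)
  for (i in 1:25) {
    F0 <- runif(1, 100, 5000)
    lopt <- runif(1, 0.05, 0.2)
    m <- muscle_params("m", F0, lopt, 10, moment_arms = list(d = 0.05))
    st <- muscle_state(lopt * runif(1, 0.6, 1.4), runif(1, -0.5, 0.5))
    a <- runif(1)
    f1 <- active_force(m, st, a)
    expect_equal(f1, a * active_force(m, st, 1), tolerance = 1e-12)
    m2 <- m; m2$max_isometric_force <- 2 * F0
    expect_equal(active_force(m2, st, a), 2 * f1, tolerance = 1e-12)
    expect_gte(f1, 0)
  }
  m <- muscle_params("m", 1000, 0.1, 10, moment_arms = list(d = 0.05))
  expect_equal(active_force(m, muscle_state(0.1, 0), 1), 1000)
  expect_equal(active_force(m, muscle_state(0.123, -0.3), 0), 0)
  # cross-check against direct curve evaluation
  f <- active_force(m, muscle_state(0.12, -0.3), 0.5)
  expect_equal(f, 0.5 * 1000 * exp(-((1.2 - 1) / 0.45)^2) *
                 (1 - 0.3) / (1 + 0.3 / 0.25), tolerance = 1e-12)
  expect_error(active_force(m, muscle_state(0.1, 0), 1.2), "activation")
})

test_that("weakness scales forces multiplicatively and leaves the input intact", {
  model <- tiny_model(F0 = 1000)
  w3 <- apply_weakness(model, 0.3)
  expect_equal(w3$muscles[[1]]$max_isometric_force, 700)
  expect_equal(model$muscles[[1]]$max_isometric_force, 1000)  # unmodified
  expect_identical(apply_weakness(model, 0), model)
  st <- muscle_state(0.11, -0.1)
  for (w in c(0.2, 0.55, 0.9)) {
    expect_equal(active_force(apply_weakness(model, w)$muscles[[1]], st, 0.7),
                 (1 - w) * active_force(model$muscles[[1]], st, 0.7),
                 tolerance = 1e-12)
  }
  w1 <- apply_weakness(model, 1)
  expect_equal(active_force(w1$muscles[[1]], st, 1), 0)
  expect_error(apply_weakness(model, 1.2), "weakness")
})

test_that("moment arms evaluate their polynomial and reject unspanned DOFs", {
  m <- muscle_params("m", 1000, 0.1, moment_arms = list(knee = c(0.05, -0.01)))
  expect_equal(moment_arm(m, "knee", 0), 0.05)
  expect_equal(moment_arm(m, "knee", 0.5), 0.045)
  expect_equal(moment_arm(m, "knee", c(0, 0.5)), c(0.05, 0.045))
  expect_error(moment_arm(m, "hip", 0), "does not span")
})

test_that("fiber kinematics integrate moment arms exactly", {
  m <- muscle_params("m", 1000, 0.12, moment_arms = list(knee = 0.05))
  # constant arm: closed-form shortening r * q
  st <- muscle_kinematics(m, c(knee = 0.2))
  expect_equal(st$fiber_length, 0.12 - 0.05 * 0.2)
  expect_equal(st$fiber_velocity, 0)
  st <- muscle_kinematics(m, c(knee = 0), c(knee = 1))
  expect_equal(st$fiber_velocity, -0.05)
  # velocity is the time-derivative of length along a trajectory
  biart <- muscle_params("b", 1000, 0.12,
                         moment_arms = list(hip = c(0.05), knee = c(-0.03, 0.008)))
  tt <- seq(0, 1, by = 1e-4)
  qh <- 0.3 * sin(2 * pi * tt); qk <- -0.5 + 0.4 * cos(2 * pi * tt)
  wh <- 0.3 * 2 * pi * cos(2 * pi * tt); wk <- -0.4 * 2 * pi * sin(2 * pi * tt)
  lens <- vels <- numeric(length(tt))
  for (i in seq_along(tt)) {
    s <- muscle_kinematics(biart, c(hip = qh[i], knee = qk[i]),
                           c(hip = wh[i], knee = wk[i]))
    lens[i] <- s$fiber_length; vels[i] <- s$fiber_velocity
  }
  fd <- (lens[3:length(tt)] - lens[1:(length(tt) - 2)]) / (2e-4)
  expect_lt(max(abs(fd - vels[2:(length(tt) - 1)])), 1e-5)
  # inconsistent geometry is an error, not a negative length
  shrink <- muscle_params("s", 10, 0.01, moment_arms = list(knee = 0.05))
  expect_error(muscle_kinematics(shrink, c(knee = 1)), "fiber length")
})

test_that("max feasible moment is the direction-matched capability and scales with weakness", {
  model <- tiny_model(F0 = 1000, arm = 0.05)
  q <- c(ankle = 0)
  expect_equal(max_feasible_moment(model, "ankle", q, sign = 1), 50)
  expect_equal(max_feasible_moment(model, "ankle", q, sign = -1), 0)
  for (w in c(0.25, 0.6, 1)) {
    expect_equal(max_feasible_moment(apply_weakness(model, w), "ankle", q, sign = 1),
                 (1 - w) * 50, tolerance = 1e-12)
  }
  # a model with no muscle spanning the queried direction contributes nothing
  m2 <- two_dof_model()
  q2 <- c(hip = 0, knee = 0)
  expect_gt(max_feasible_moment(m2, "knee", q2, sign = 1), 0)
  expect_gt(max_feasible_moment(m2, "knee", q2, sign = -1), 0)  # biart flexor
})

test_that("the shipped model reads with valid invariants", {
  model <- shipped_model()
  expect_s3_class(model, "msk_model")
  expect_equal(model$dofs$name, c("hip", "knee", "ankle"))
  expect_length(model$muscles, 9)
  expect_true(all(vapply(model$muscles, `[[`, numeric(1), "max_isometric_force") > 0))
  # bi-articular muscles carry arms for both joints
  expect_setequal(model$muscles$hamstrings$spanned_dofs, c("hip", "knee"))
  expect_setequal(model$muscles$gastroc$spanned_dofs, c("knee", "ankle"))
  expect_output(print(model), "planar9")
})
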