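test_that("gap series satisfy the task = capability + gap identity", {
  model <- tiny_model(F0 = 3000, arm = 0.04)
  tr <- planted_trial(model, ratio = 0.9, n = 31)
  for (w in c(0, 0.4, 1)) {
    sol <- solve_trial(apply_weakness(model, w), tr)
    s <- capability_gap(sol, tr, "ankle", w)
    expect_equal(s$task_moment, s$capability_moment + s$gap_moment,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(s$task_moment,
                 unname(tr$net_moments[, "ankle"] / tr$body_mass))
  }
  # complete paralysis: the gap IS the task
  solw1 <- solve_trial(apply_weakness(model, 1), tr)
  s1 <- capability_gap(solw1, tr, "ankle", 1)
  expect_equal(s1$gap_moment, s1$task_moment, tolerance = 1e-12)
  expect_equal(s1$capability_moment, rep(0, 31), tolerance = 1e-12)
  expect_error(capability_gap(solw1, tr, "hip"), "no reserve")
})

test_that("the saturated single-muscle frame yields the closed-form gap", {
  # weakened gain 30 Nm vs demand 50 Nm: muscle saturates, reserve carries 20 Nm
  model <- tiny_model(F0 = 750, arm = 0.04, body_mass = 70)  # gain 30 Nm
  n <- 11
  tt <- seq(0, 1, length.out = n)
  zero <- matrix(0, n, 1, dimnames = list(NULL, "ankle"))
  mom <- zero; mom[6, ] <- 50
  tr <- trial_data("gait", tt, zero, zero, mom, body_mass = 70)
  sol <- solve_trial(model, tr)
  s <- capability_gap(sol, tr, "ankle")
  expect_equal(s$gap_moment[6], 20 / 70, tolerance = 1e-6)
})

test_that("gap detection needs the threshold and reserve leak stays below it", {
  model <- tiny_model(F0 = 3000, arm = 0.04)
  tr <- planted_trial(model, ratio = 0.9, n = 31)
  sol <- solve_trial(model, tr)
  s <- capability_gap(sol, tr, "ankle", 0)
  # at full strength the reserve only leaks: no detected gap
  d <- detect_gap(s, threshold = 0.01)
  expect_false(d$detected)
  expect_length(d$frames, 0)
  # zero-gap series
  s0 <- capability_gap(solve_trial(model, planted_trial(model, 0, n = 11)),
                       planted_trial(model, 0, n = 11), "ankle")
  expect_false(detect_gap(s0)$detected)
  # single spiking frame is localized
  s$gap_moment[17] <- 0.02
  d2 <- detect_gap(s, threshold = 0.01)
  expect_true(d2$detected)
  expect_equal(d2$frames, 17)
  expect_error(detect_gap(s, threshold = 0), "threshold")
})

test_that("tolerance recovery matches the planted capability ratio", {
  model <- tiny_model(F0 = 3000, arm = 0.04)
  # peak demand = ratio x isometric capability: a gap appears once
  # (1 - w) < ratio, i.e. at the first sweep level above 1 - ratio
  for (ratio in c(0.3, 0.6, 0.7)) {
    tr <- planted_trial(model, ratio = ratio, n = 31)
    sw <- weakness_sweep(model, tr)
    tol <- tolerance_level(sw, "ankle", "positive")
    expect_lte(abs(tol - (1 - ratio)), 0.1 + 1e-9)
  }
  # demand always zero: no tolerance level
  sw0 <- weakness_sweep(model, planted_trial(model, 0, n = 11), c(0, 0.5, 1))
  expect_true(is.na(tolerance_level(sw0, "ankle")))
  # demand above full-strength capability: gap already at w = 0
  sw2 <- weakness_sweep(model, planted_trial(model, 1.3, n = 21), c(0, 0.5, 1))
  expect_equal(tolerance_level(sw2, "ankle"), 0)
})

test_that("maximal task requirements resolve directions and match brute force", {
  n <- 50
  tt <- seq(0, 1, length.out = n)
  mom <- matrix(2 * 61 * sin(2 * pi * tt), n, 1, dimnames = list(NULL, "ankle"))
  vel <- matrix(cos(2 * pi * tt), n, 1, dimnames = list(NULL, "ankle"))
  tr <- trial_data("gait", tt, vel * 0, vel, mom, body_mass = 61)
  req <- max_requirements(tr)
  expect_equal(req$max_moment_pos, 2, tolerance = 1e-3)
  expect_equal(req$max_moment_neg, 2, tolerance = 1e-3)
  pow <- (mom / 61) * vel
  expect_equal(req$max_power_pos, max(pow), tolerance = 1e-12)
  expect_equal(req$max_power_neg, -min(pow), tolerance = 1e-12)
  # constant moment
  trc <- trial_data("gait", tt, vel * 0, vel * 0,
                    matrix(1.5 * 61, n, 1, dimnames = list(NULL, "ankle")), 61)
  expect_equal(max_requirements(trc)$max_moment_pos, 1.5)
  expect_equal(max_requirements(trc)$max_moment_neg, 0)
})

test_that("AAN sizing never exceeds ID sizing and interpolates between limits", {
  model <- tiny_model(F0 = 3000, arm = 0.04)
  tr <- planted_trial(model, ratio = 0.8, n = 31)
  sw <- weakness_sweep(model, tr)
  for (lv in sw$levels) {
    r <- id_vs_aan(sw, "ankle", lv)
    expect_lte(r$aan_peak, r$id_peak + 1e-9)
  }
  r0 <- id_vs_aan(sw, "ankle", 0)
  expect_lt(r0$aan_peak, 0.01)
  expect_equal(r0$aan_support_fraction, 0)
  r1 <- id_vs_aan(sw, "ankle", 1)
  expect_equal(r1$aan_peak, r1$id_peak, tolerance = 1e-9)
  rmid <- id_vs_aan(sw, "ankle", 0.6)
  expect_gt(rmid$aan_peak, r0$aan_peak)
  expect_lt(rmid$aan_peak, r1$aan_peak)
  expect_true(rmid$aan_support_fraction > 0 && rmid$aan_support_fraction < 100)
  expect_error(id_vs_aan(sw, "ankle", 0.55), "not present")
})

test_that("tolerance report aggregates sweeps with monotone peak gaps", {
  model <- tiny_model(F0 = 3000, arm = 0.04)
  sw <- weakness_sweep(model, planted_trial(model, 0.6, n = 21))
  rep <- tolerance_report(list(sw))
  s <- attr(rep, "summary")
  pos <- s[s$direction == "positive", ]
  expect_equal(pos$tolerance_weakness, 0.5)  # first level past 1 - 0.6
  # at w = 1 the maximal gap equals the maximal task requirement
  expect_equal(pos$max_gap_moment, pos$max_task_moment, tolerance = 1e-9)
  rows <- rep[rep$direction == "positive", ]
  expect_true(all(diff(rows$peak_gap_moment) >= -1e-9))
})
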