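test_that("vector-sum index matches closed forms and the complex-sum oracle", {
  th <- default_angles

  # uniform curve: index 0, preferred angle undefined
  vs <- vector_sum_index(tuning_curve(th, rep(3, 12)), order = 2)
  expect_lt(vs$index, 1e-12)
  expect_true(is.na(vs$preferred_deg))
  expect_false(vs$preferred_reliable)

  # perfect OS: mass at 0 and 180 only
  vs <- vector_sum_index(tuning_curve(th, as.numeric(th %% 180 == 0)), 2)
  expect_equal(vs$index, 1)
  expect_equal(vs$preferred_deg, 0)

  # cosine curve: index exactly 0.5, preferred at the cosine peak
  for (pref in c(0, 30, 75)) {
    R <- 1 + cos(2 * (th - pref) * pi / 180)
    vs <- vector_sum_index(tuning_curve(th, R), 2)
    expect_equal(vs$index, 0.5, tolerance = 1e-12)
    expect_equal(vs$preferred_deg, pref, tolerance = 1e-9)
  }

  # random curves against the direct complex-sum oracle, both orders
  set.seed(41)
  for (i in 1:20) {
    R <- runif(12, 0.1, 5)
    for (ord in c(1, 2)) {
      vs <- vector_sum_index(tuning_curve(th, R), ord)
      or <- oracle_vs(th, R, ord)
      expect_equal(vs$index, or$index, tolerance = 1e-12)
      expect_equal(vs$preferred_deg, or$pref, tolerance = 1e-9)
    }
  }
})

test_that("index is invariant to response scaling and equivariant to rotation", {
  th <- default_angles
  set.seed(7)
  for (i in 1:10) {
    R <- runif(12, 0.05, 2)
    v0 <- vector_sum_index(tuning_curve(th, R), 2)
    v_scaled <- vector_sum_index(tuning_curve(th, 7.3 * R), 2)
    expect_equal(v_scaled$index, v0$index, tolerance = 1e-12)
    delta <- 40
    v_rot <- vector_sum_index(tuning_curve(th + delta, R), 2)
    expect_equal(v_rot$index, v0$index, tolerance = 1e-12)
    if (!is.na(v0$preferred_deg))
      expect_equal(v_rot$preferred_deg %% 180,
                   (v0$preferred_deg + delta) %% 180, tolerance = 1e-6)
  }
})

test_that("order-2 index of a 180-degree-symmetric curve equals the order-1 index of the folded curve", {
  th <- default_angles
  set.seed(13)
  for (i in 1:10) {
    half <- runif(6, 0.1, 3)
    R <- rep(half, 2) # R(theta) = R(theta + 180)
    v2 <- vector_sum_index(tuning_curve(th, R), 2)$index
    v1 <- vector_sum_index(tuning_curve(2 * th[1:6], half), 1)$index
    expect_equal(v2, v1, tolerance = 1e-12)
  }
})

test_that("index rejects degenerate and negative inputs", {
  th <- default_angles
  expect_error(vector_sum_index(tuning_curve(th, rep(0, 12))), "undefined")
  expect_error(tuning_curve(th, c(-1, rep(1, 11))), "non-negative")
  expect_error(tuning_curve(c(0, 120), c(1, 1)), "at least 3")
})

test_that("cycle averaging recovers the underlying period", {
  dt <- 1e-3
  t <- seq(0, 5 - dt, by = dt)
  pure <- trace(sin(2 * pi * 2 * t), dt = dt, unit = "pA")
  cyc <- cycle_average(pure, 2)
  expect_length(cyc$values, 500)
  expect_equal(cyc$values, sin(2 * pi * 2 * t[1:500]), tolerance = 1e-12)

  const <- cycle_average(trace(rep(4.2, 5000), dt = dt, unit = "pA"), 2)
  expect_equal(const$values, rep(4.2, 500))

  # averaging n cycles shrinks the noise RMSE like 1/sqrt(n)
  set.seed(3)
  rmse <- vapply(1:30, function(i) {
    noisy <- trace(sin(2 * pi * 2 * t[1:4000]) + rnorm(4000),
                   dt = dt, unit = "pA")
    cyc <- cycle_average(noisy, 2)
    sqrt(mean((cyc$values - sin(2 * pi * 2 * t[1:500]))^2))
  }, numeric(1))
  expect_equal(mean(rmse), 1 / sqrt(8), tolerance = 0.1)

  expect_error(cycle_average(pure, 3), "does not divide")
  expect_error(cycle_average(trace(1:100, dt = dt, unit = "pA"), 2),
               "too short")
})

test_that("F1 amplitude uses the peak convention", {
  dt <- 1e-3
  t <- seq(0, 0.5 - dt, by = dt)
  A <- 3.7
  expect_equal(f1_amplitude(trace(A * sin(2 * pi * 2 * t), dt, unit = "pA"), 2),
               A, tolerance = 1e-9)
  expect_equal(f1_amplitude(trace(rep(9, 500), dt, unit = "pA"), 2), 0,
               tolerance = 1e-9)
  # fundamental picked out in the presence of a second harmonic
  v <- 2 * sin(2 * pi * 2 * t) + 5 * sin(2 * pi * 4 * t)
  expect_equal(f1_amplitude(trace(v, dt, unit = "pA"), 2), 2,
               tolerance = 1e-9)
  expect_error(f1_amplitude(trace(v, dt, unit = "pA"), 3), "exactly one period")
})

test_that("light-step rate features behave as specified", {
  # exactly 5 spikes in each 500 ms pre-window over 10 epochs -> 10 Hz
  trials <- replicate(10, seq(0.55, 0.95, by = 0.1), simplify = FALSE)
  tr <- spike_trains(trials, onset_s = 1, offset_s = 2, duration_s = 4)
  expect_equal(baseline_rate(tr), 10)

  empty <- spike_trains(replicate(4, numeric(0), simplify = FALSE),
                        onset_s = 1, offset_s = 2, duration_s = 4)
  expect_equal(baseline_rate(empty), 0)
  expect_equal(peak_offset_rate(empty), 0)

  # PSTH integrates to the total spike count per trial
  ps <- psth(tr, bin_width_s = 0.025)
  expect_equal(sum(ps$values) * 0.025, 5)

  # Poisson generator round trip: recovered baseline within 3 SE
  sp <- step_params(baseline_rate_hz = 20, pre_duration_s = 0.5,
                    n_epochs = 10, seed = 99)
  g <- gen_light_step_spikes(sp)
  se <- sqrt(20 / (10 * 0.5))
  expect_lt(abs(baseline_rate(g) - 20), 3 * se)
})

test_that("OFF OS and orientation-type classification partition their domains", {
  expect_true(classify_off_os(20, 80))
  expect_false(classify_off_os(50, 80))   # strict boundary
  expect_false(classify_off_os(10, 500))
  expect_false(classify_off_os(10, 120))  # strict boundary
  expect_true(classify_off_os(10, 125, peak_max_hz = 135))

  expect_equal(classify_orientation_type(0), "hOS")
  expect_equal(classify_orientation_type(90), "vOS")
  expect_equal(classify_orientation_type(45), "vOS") # half-open convention
  expect_equal(classify_orientation_type(135), "hOS")
  # every orientation gets exactly one label
  a <- seq(0, 179.5, by = 0.5)
  lab <- classify_orientation_type(a)
  expect_true(all(lab %in% c("hOS", "vOS")))
  expect_equal(sum(lab == "vOS"), sum(a >= 45 & a < 135))
})

test_that("orientation angle differences fold correctly", {
  expect_equal(orientation_angle_difference(0, 85), 85)
  expect_equal(orientation_angle_difference(10, 190), 0)
  expect_equal(orientation_angle_difference(0, 95), 85)
  expect_equal(orientation_angle_difference(179, 1), 2)
  expect_true(all(orientation_angle_difference(runif(50, -720, 720),
                                               runif(50, -720, 720)) <= 90))
})
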