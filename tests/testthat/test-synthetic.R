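test_that("control model: zero dopamine gain produces no movement", {
  p <- control_model_params(da_gain = 0)
  s <- simulate_control_trajectory(p, matrix(40, 1000, 2))
  expect_equal(max(abs(s$pos)), 0)
  expect_equal(max(abs(s$v)), 0)
})

test_that("integrator leak follows its closed form", {
  lam <- 0.5; dt <- 0.001; c0 <- 10
  p <- control_model_params(da_gain = 0, integrator_leak = lam, dt = dt)
  s <- simulate_control_trajectory(p, matrix(0, 4000, 2),
                                   p_ref0 = c(c0, c0))
  k <- seq_along(s$t_dense) - 1
  # exact discrete solution ...
  expect_equal(s$p_ref[, 1], c0 * (1 - lam * dt)^k, tolerance = 1e-12)
  # ... and the continuous limit within O(dt)
  cont <- c0 * exp(-lam * s$t_dense)
  expect_lt(max(abs(s$p_ref[, 1] - cont)), c0 * lam^2 * dt * max(s$t_dense))
})

test_that("unstable parameterizations are rejected before simulation", {
  expect_error(control_model_params(position_gain = 500, dt = 0.005),
               "unstable")
  expect_error(control_model_params(da_gain = -1))
})

test_that("peak speed increases strictly with dopamine gain", {
  td <- seq_len(1200) * 0.005
  vref <- cbind(raised_cosine_pulse(td, 1, 0.5, 60), 0)
  pk <- vapply(c(0.25, 0.5, 1, 2), function(g) {
    s <- simulate_control_trajectory(control_model_params(da_gain = g), vref)
    max(sqrt(s$v[, 1]^2 + s$v[, 2]^2))
  }, numeric(1))
  expect_true(all(diff(pk) > 0))
})

test_that("states decay to rest and opponent channels conserve the error", {
  td <- seq_len(8000) * 0.005
  vref <- cbind(raised_cosine_pulse(td, 1, 0.5, 60),
                raised_cosine_pulse(td, 2, 0.5, -40))
  p <- control_model_params(opponent_split = TRUE)
  s <- simulate_control_trajectory(p, vref)
  # the cascade's slow mode decays at roughly leak/(1 + da_gain)
  tail_i <- s$t_dense > 38
  expect_lt(max(abs(s$p_ref[tail_i, ])), 0.01 * max(abs(s$p_ref)))
  expect_lt(max(abs(s$v[tail_i, ])), 0.01 * max(abs(s$v)))
  expect_identical(s$direct + s$indirect, s$err)
  expect_true(all(s$direct >= 0))
  expect_true(all(s$indirect <= 0))
})

test_that("task sessions conform to the task spec and are deterministic", {
  task <- task_spec(fast = TRUE)
  s1 <- simulate_task_session(task, seed = 12)
  s2 <- simulate_task_session(task, seed = 12)
  expect_identical(s1$tracking, s2$tracking)
  expect_identical(s1$events, s2$events)

  ev <- s1$events
  expect_length(ev$cue_onsets, 10L)
  gap <- ev$outcome_times - (ev$cue_onsets + task$tone_duration)
  expect_true(all(gap >= 1.9 & gap <= 2.1))
  itis <- c(ev$cue_onsets[1],
            ev$cue_onsets[-1] - ev$outcome_times[-length(ev$outcome_times)])
  expect_true(all(itis >= 5 & itis <= 10))
  # default profile keeps the published trial structure
  dflt <- task_spec()
  expect_equal(dflt$n_trials, 60)
  expect_equal(dflt$iti_range, c(20, 50))
})

test_that("outcome bouts run toward the spout on sucrose, away on air puff", {
  proj_after_outcome <- function(schedule, seed) {
    sess <- simulate_task_session(
      task_spec(fast = TRUE, outcome_schedule = schedule,
                direction_jitter_sd = 0.3), seed = seed)
    u <- sess$spout / sqrt(sum(sess$spout^2))
    tr <- sess$tracking
    mean(vapply(sess$events$outcome_times, function(tt) {
      p0 <- c(approx(tr$t, tr$x, tt + 0.1)$y, approx(tr$t, tr$y, tt + 0.1)$y)
      p1 <- c(approx(tr$t, tr$x, tt + 1.0)$y, approx(tr$t, tr$y, tt + 1.0)$y)
      sum((p1 - p0) * u)
    }, numeric(1)))
  }
  expect_gt(proj_after_outcome("sucrose", 13), 0)
  expect_lt(proj_after_outcome("airpuff", 13), 0)
})

test_that("tuned units are Poisson at zero gain and silent at zero rate", {
  kin <- structure(list(grid_t = seq(0, 100 - 0.03, by = 0.03),
                        bin_width = 0.03),
                   class = "kinematic_set")
  kin$x <- kin$y <- rep(0, length(kin$grid_t))
  kin$components <- lapply(setNames(kinematic_components(),
                                    kinematic_components()),
                           function(v) rep(0, length(kin$grid_t)))
  u <- generate_unit(tuning_spec("hz8", "none", 1, 8, 0, 0), kin, seed = 61)
  expect_true(abs(length(u$spike_times) - 800) < 3 * sqrt(800))
  u0 <- generate_unit(tuning_spec("off", "none", 1, 0, 0, 0), kin,
                      seed = 62)
  expect_length(u0$spike_times, 0L)
  expect_identical(generate_unit(tuning_spec("d", "none"), kin, seed = 5),
                   generate_unit(tuning_spec("d", "none"), kin, seed = 5))
})

test_that("cohort composition follows the mix, bias and sign settings", {
  sp <- draw_cohort_specs(4000, seed = 71)
  expect_lt(abs(mean(sp$target == "none") - 9 / 106), 0.02)
  coupled <- sp[sp$target != "none", ]
  expect_lt(abs(mean(coupled$sign > 0) - 0.78), 0.03)
  expect_lt(abs(mean(grepl("^vel", coupled$target)) - 66 / 97), 0.03)
  expect_true(all(coupled$lag_bins[coupled$sign < 0] == 5L))
  expect_true(all(coupled$lag_bins[coupled$sign > 0] %in% 0:1))

  # full contralateral bias gives a perfectly crossed table
  horiz <- c(vel_up = 0, vel_down = 0, vel_left = 0.5, vel_right = 0.5,
             acc_up = 0, acc_down = 0, acc_left = 0, acc_right = 0)
  sp2 <- draw_cohort_specs(20, class_mix = horiz, p_uncorrelated = 0,
                           contralateral_bias = 1, seed = 72)
  expect_true(all(sp2$hemisphere[sp2$target == "vel_left"] == "right"))
  expect_true(all(sp2$hemisphere[sp2$target == "vel_right"] == "left"))
})

test_that("generated cohorts carry coherent ground truth and round-trip", {
  co <- generate_cohort(n_units = 4, seed = 81, n_gaba_pairs = 1)
  expect_length(co$bundle$units, 6L)  # 4 cohort + GABA/DA pair
  expect_equal(nrow(co$ground_truth), 6L)
  expect_true(all(c("gaba01", "daPair01") %in% names(co$bundle$units)))
  gt <- co$ground_truth
  expect_equal(gt$cell_class[gt$unit_id == "gaba01"], "GABA")
  # provenance and determinism
  co2 <- generate_cohort(n_units = 4, seed = 81, n_gaba_pairs = 1)
  expect_identical(co$bundle$units[["u001"]]$spike_times,
                   co2$bundle$units[["u001"]]$spike_times)
  dir <- withr::local_tempdir()
  write_session(co$bundle, dir)
  b2 <- read_session(dir)
  n2 <- vapply(b2$units, function(u) length(u$spike_times), integer(1))
  n1 <- vapply(co$bundle$units, function(u) length(u$spike_times),
               integer(1))
  expect_equal(n2[names(n1)], n1)
})

test_that("stim sessions emit the requested non-overlapping trains", {
  ss <- generate_stim_session("chr2", n_trains = 8, seed = 91)
  expect_equal(nrow(ss$stim_trains), 8L)
  st <- ss$stim_trains
  expect_true(all(st$onset[-1] >= st$offset[-nrow(st)]))
  expect_identical(generate_stim_session("chr2", n_trains = 8, seed = 91),
                   ss)
  # stimulation moves the animal more than the control light schedule
  ctrl <- generate_stim_session("control", n_trains = 8, seed = 91)
  sk_c <- stim_kinematics(ss$tracking, ss$stim_trains)
  sk_0 <- stim_kinematics(ctrl$tracking, ctrl$stim_trains)
  expect_gt(mean(sk_c$peak_speed), mean(sk_0$peak_speed))
})
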