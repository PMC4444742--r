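test_that("best_lag recovers constructed shifts with the documented sign", {
  set.seed(31)
  n <- 1200
  rate <- rnorm(n, 10, 2)
  for (k in c(1, 3, 5, 16)) {
    kin <- c(rep(0, k), rate[1:(n - k)])  # kinematics follows rate by k bins
    bl <- best_lag(rate, kin, 0.03, max_lag_s = 0.5)
    expect_equal(bl$lag_s, k * 0.03)
    expect_equal(bl$r, 1, tolerance = 1e-12)
  }
  # zero-variance rate -> undefined
  blc <- best_lag(rep(4, n), rnorm(n), 0.03)
  expect_true(blc$undefined)
  expect_true(is.na(blc$lag_s))
})

test_that("best_lag agrees exactly with the brute-force oracle", {
  set.seed(32)
  for (i in 1:20) {
    n <- 300
    rate <- rnorm(n)
    kin <- 0.3 * c(rate[-(1:2)], 0, 0) + rnorm(n)
    bl <- best_lag(rate, kin, 0.03, max_lag_s = 10 * 0.03)
    want <- oracle_best_lag(rate, kin, 10)
    expect_equal(bl$lag_s, want$l * 0.03)
    expect_equal(bl$r, want$r, tolerance = 1e-12)
  }
})

test_that("shifted_pearson matches hand-computed values and the t transform", {
  expect_equal(shifted_pearson(c(1, 2, 3), c(2, 4, 6), 0, 0.03)$r, 1)
  expect_equal(shifted_pearson(c(1, 2, 3), c(6, 4, 2), 0, 0.03)$r, -1)
  sp <- shifted_pearson(c(1, 2, 3, 4), c(1, 3, 2, 4), 0, 0.03)
  expect_equal(sp$r, 0.8, tolerance = 1e-12)
  expect_equal(sp$p, oracle_pearson_p(0.8, 4), tolerance = 1e-12)
  expect_error(shifted_pearson(1:2, 1:2, 0, 0.03), "3")

  set.seed(33)
  for (i in 1:10) {
    x <- rnorm(50); y <- rnorm(50)
    sp <- shifted_pearson(x, y, 0, 0.03)
    expect_equal(sp$r, oracle_pearson(x, y), tolerance = 1e-12)
    expect_equal(sp$p, oracle_pearson_p(oracle_pearson(x, y), 50),
                 tolerance = 1e-12)
  }
})

test_that("masked bins are dropped pairwise per lag", {
  set.seed(34)
  n <- 500
  rate <- rnorm(n, 10); kin <- 0.5 * rate + rnorm(n)
  mask <- rep(TRUE, n); mask[100:160] <- FALSE
  bl <- best_lag(rate, kin, 0.03, max_lag_s = 0.15, mask = mask)
  ok <- mask
  expect_equal(shifted_pearson(rate, kin, 0, 0.03, mask)$r,
               oracle_pearson(rate[ok], kin[ok]), tolerance = 1e-12)
  expect_lt(bl$n, n)
})

session_kin_fixture <- local({
  cache <- new.env()
  function(seed = 15) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      sess <- simulate_task_session(task_spec(fast = TRUE), seed = seed)
      cache[[key]] <- list(sess = sess,
                           kin = build_kinematics(sess$tracking))
    }
    cache[[key]]
  }
})

test_that("classify_unit recovers a planted coupling with its lag and sign", {
  fx <- session_kin_fixture()
  kt <- fx$sess$kinset_truth
  g <- tuning_gain_for_r(kt$components$vel_up, 5, 0.55, 0.03, 1)
  u <- generate_unit(tuning_spec("rec", "vel_up", 1, 5, g, lag_bins = 2),
                     kt, seed = 77)
  rate <- bin_rate(u, fx$kin$grid_t, 0.03)
  res <- classify_unit(rate, fx$kin)
  expect_equal(res$class_variable, "vel_up")
  expect_equal(res$sign, "positive")
  expect_equal(res$class_lag_s, 2 * 0.03)

  # identity signal: a rate equal to a component classifies to it exactly
  res2 <- classify_unit(fx$kin$components$acc_down, fx$kin)
  expect_equal(res2$class_variable, "acc_down")
  expect_equal(res2$class_r, 1, tolerance = 1e-9)
  expect_equal(res2$class_lag_s, 0)

  # constant rate -> uncorrelated
  res3 <- classify_unit(rep(5, length(fx$kin$grid_t)), fx$kin)
  expect_equal(res3$class_variable, "uncorrelated")
  expect_equal(res3$sign, "none")
})

test_that("classification is invariant to affine rescaling of the rate", {
  fx <- session_kin_fixture()
  kt <- fx$sess$kinset_truth
  g <- tuning_gain_for_r(kt$components$vel_left, 5, 0.5, 0.03, 1)
  u <- generate_unit(tuning_spec("aff", "vel_left", 1, 5, g, 0), kt,
                     seed = 78)
  rate <- bin_rate(u, fx$kin$grid_t, 0.03)$rate
  r1 <- classify_unit(rate, fx$kin)
  r2 <- classify_unit(3.7 * rate + 11, fx$kin)
  expect_identical(r2$class_variable, r1$class_variable)
  expect_identical(r2$sign, r1$sign)
  expect_equal(r2$class_lag_s, r1$class_lag_s)
  expect_equal(r2$class_r, r1$class_r, tolerance = 1e-12)
})

test_that("opponency: opposite directions carry opposite-signed correlation", {
  fx <- session_kin_fixture()
  kt <- fx$sess$kinset_truth
  g <- tuning_gain_for_r(kt$components$vel_up, 5, 0.5, 0.03, 1)
  u <- generate_unit(tuning_spec("opp", "vel_up", 1, 5, g, 0), kt,
                     seed = 79)
  rate <- bin_rate(u, fx$kin$grid_t, 0.03)
  res <- classify_unit(rate, fx$kin)
  o <- opponency(res)
  row <- o[o$quantity == "velocity" & o$axis == "vertical", ]
  expect_true(row$aligned)
  expect_gt(row$r_preferred, 0)
  expect_lt(row$r_opposite, 0)
  expect_true(row$opponent)

  # antisymmetric coupling to signed vx: positive with right, negative
  # with left at a common shift
  rate_vx <- 5 + 0.2 * fx$kin$vx
  sp_r <- shifted_pearson(rate_vx, fx$kin$components$vel_right, 0, 0.03,
                          fx$kin$mask)
  sp_l <- shifted_pearson(rate_vx, fx$kin$components$vel_left, 0, 0.03,
                          fx$kin$mask)
  expect_gt(sp_r$r, 0)
  expect_lt(sp_l$r, 0)
})

test_that("opponency is flagged undefined when a direction is never visited", {
  t <- seq(0, 60, by = 1 / 30)
  tr <- tracking_series(t, rep(0, length(t)), t + 0.5 * sin(t))
  kin <- build_kinematics(tr)
  expect_equal(sd(kin$components$vel_down), 0)  # monotone upward drift
  rate <- 5 + 2 * kin$components$vel_up
  res <- classify_unit(rate, kin)
  expect_equal(res$class_variable, "vel_up")
  o <- opponency(res)
  row <- o[o$quantity == "velocity" & o$axis == "vertical", ]
  expect_false(row$defined)
  expect_true(is.na(row$opponent))
})

test_that("derivative of an exact antiderivative gives r = -1 at lag 0", {
  n <- 2000; dt <- 0.03
  da <- seq(5, 15, length.out = n)      # linear ramp
  gaba <- -cumsum(da) * dt              # discrete antiderivative
  gd <- gaba_da_derivative_test(gaba, da, dt)
  expect_equal(gd$peak_r, -1, tolerance = 1e-9)
  expect_equal(gd$lag_s, 0)
})

test_that("independent units stay below the circular-shift null", {
  set.seed(41)
  n <- 1000; dt <- 0.03
  gaba <- rpois(n, 25 * dt) / dt
  da <- rpois(n, 5 * dt) / dt
  gd <- gaba_da_derivative_test(gaba, da, dt, max_lag_s = 10 * dt)
  deriv <- differentiate(gaba, dt = dt)
  nul <- circular_shift_null(da, deriv, dt, max_lag_s = 10 * dt,
                             n_shuffles = 500, seed = 42)
  expect_lt(abs(gd$peak_r), quantile(nul, 0.99, na.rm = TRUE))
})

test_that("session-wide and peri-event classification agree", {
  agree <- 0; total <- 0
  for (s in c(15, 16)) {
    fx <- session_kin_fixture(s)
    pm <- peri_event_mask(fx$kin$grid_t, fx$sess$events, pre_s = 1,
                          post_s = 2)
    comps <- rep(kinematic_components(), length.out = 10)
    for (i in seq_along(comps)) {
      kt <- fx$sess$kinset_truth
      g <- tuning_gain_for_r(kt$components[[comps[i]]], 5, 0.55, 0.03, 1)
      u <- generate_unit(tuning_spec("pe", comps[i], 1, 5, g, 0), kt,
                         seed = 600 + 20 * s + i)
      rate <- bin_rate(u, fx$kin$grid_t, 0.03)
      full <- classify_unit(rate, fx$kin)
      peri <- classify_unit(rate, fx$kin, extra_mask = pm)
      agree <- agree + (full$class_variable == peri$class_variable)
      total <- total + 1
    }
  }
  expect_gte(agree / total, 0.95)
})

test_that("lag recovery is exact at strong coupling and improves with gain", {
  fx <- session_kin_fixture()
  kt <- fx$sess$kinset_truth
  comp <- kt$components$vel_up
  recovered <- function(r_target, seed0) {
    g <- tuning_gain_for_r(comp, 5, r_target, 0.03, 1)
    hits <- 0
    lags <- c(0L, 1L, 2L, 5L)
    for (j in seq_along(lags)) {
      u <- generate_unit(tuning_spec("pr", "vel_up", 1, 5, g, lags[j]),
                         kt, seed = seed0 + j)
      res <- classify_unit(bin_rate(u, fx$kin$grid_t, 0.03), fx$kin)
      hits <- hits + (res$class_variable == "vel_up" &&
                        isTRUE(all.equal(res$class_lag_s, lags[j] * 0.03)))
    }
    hits / length(lags)
  }
  strong <- recovered(0.85, 810)
  weak <- recovered(0.05, 820)
  expect_equal(strong, 1)
  expect_lte(weak, strong)
})

test_that("shuffle-based significance is available and sane", {
  fx <- session_kin_fixture()
  kt <- fx$sess$kinset_truth
  g <- tuning_gain_for_r(kt$components$vel_up, 5, 0.55, 0.03, 1)
  u <- generate_unit(tuning_spec("sh", "vel_up", 1, 5, g, 0), kt,
                     seed = 90)
  rate <- bin_rate(u, fx$kin$grid_t, 0.03)
  res <- classify_unit(rate, fx$kin, null = "shuffle", n_shuffles = 30,
                       seed = 5, max_lag_s = 0.15)
  expect_equal(res$class_variable, "vel_up")
  p <- res$table$p[res$table$variable == "vel_up"]
  expect_lte(p, 1 / 31 + 1e-12)
})
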