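test_that("tabulate_classes counts classes, signs and hemispheres", {
  res <- list(fake_result("a", "vel_up", 0.5),
              fake_result("b", "vel_left", -0.3),
              fake_result("c", "uncorrelated"))
  units <- list(fake_unit("a", "left"), fake_unit("b", "right"),
                fake_unit("c"))
  ct <- tabulate_classes(res, units)
  expect_equal(ct$counts["velocity", "up"], 1L)
  expect_equal(ct$counts["velocity", "left"], 1L)
  expect_equal(sum(ct$counts), 2L)
  expect_equal(ct$n_uncorrelated, 1L)
  expect_equal(ct$n_positive, 1L)
  expect_equal(ct$n_negative, 1L)
  expect_equal(ct$hemisphere$velocity["right", "left"], 1L)

  empty <- tabulate_classes(list())
  expect_equal(sum(empty$counts), 0L)
  expect_equal(empty$n_classified, 0L)

  # pure function: identical output on identical input
  expect_identical(tabulate_classes(res, units), ct)
})

test_that("2x2 chi-square matches hand values and the closed form", {
  expect_equal(chi_square_2x2(rbind(c(10, 0), c(0, 10)))$chi2, 20)
  z <- chi_square_2x2(rbind(c(5, 5), c(5, 5)))
  expect_equal(z$chi2, 0)
  expect_equal(z$p, 1)
  expect_equal(chi_square_2x2(rbind(c(20, 10), c(10, 20)))$chi2, 20 / 3,
               tolerance = 1e-12)

  set.seed(51)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    got <- chi_square_2x2(tab)
    want <- oracle_chi2_2x2(tab)
    expect_equal(got$chi2, want$chi2, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  expect_error(chi_square_2x2(rbind(c(0, 0), c(3, 4))), "marginal")
  # Yates correction shrinks the statistic when requested
  tab <- rbind(c(12, 5), c(6, 14))
  expect_lt(chi_square_2x2(tab, correct = TRUE)$chi2,
            chi_square_2x2(tab)$chi2)
})

test_that("lateralization test handles crossed, symmetric and sparse tables", {
  mk <- function(tabv) {
    ct <- tabulate_classes(list())
    ct$hemisphere$velocity[] <- tabv
    ct$hemisphere$acceleration[] <- 0L
    ct
  }
  crossed <- mk(matrix(c(0L, 10L, 10L, 0L), 2))  # left hemi prefers right
  lt <- lateralization_test(crossed)
  expect_equal(lt$velocity$chi2, 20)
  expect_identical(lt$acceleration, "insufficient")

  sym <- mk(matrix(c(5L, 5L, 5L, 5L), 2))
  expect_equal(lateralization_test(sym)$velocity$chi2, 0)
})

test_that("rejection of hemisphere independence is powered at bias 0.75", {
  horiz_mix <- c(vel_up = 0, vel_down = 0, vel_left = 0.5, vel_right = 0.5,
                 acc_up = 0, acc_down = 0, acc_left = 0, acc_right = 0)
  rej <- 0
  for (s in 1:200) {
    sp <- draw_cohort_specs(60, class_mix = horiz_mix, p_uncorrelated = 0,
                            contralateral_bias = 0.75, seed = 7000 + s)
    tab <- table(factor(sp$hemisphere, c("left", "right")),
                 factor(kinencode:::variable_direction(sp$target),
                        c("left", "right")))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    rej <- rej + (chi_square_2x2(tab)$p < 0.05)
  }
  expect_gte(rej / 200, 0.8)
})

test_that("one-way rate ANOVA matches the sum-of-squares oracle", {
  res <- c(lapply(1:3, function(i)
             fake_result(paste0("g1_", i), "vel_up", 0.4)),
           lapply(1:3, function(i)
             fake_result(paste0("g2_", i), "vel_down", 0.4)))
  units <- c(lapply(1:3, function(i)
               fake_unit(paste0("g1_", i), mean_rate = i)),
             lapply(1:3, function(i)
               fake_unit(paste0("g2_", i), mean_rate = i + 3)))
  got <- class_rate_anova(res, units, "direction")
  want <- oracle_anova1(c(1, 2, 3, 4, 5, 6),
                        rep(c("up", "down"), each = 3))
  expect_equal(got$F, want$F, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(got$df1, want$df1)
  expect_equal(got$df2, want$df2)

  # identical group values -> F = 0 by convention
  units0 <- c(lapply(1:3, function(i)
                fake_unit(paste0("g1_", i), mean_rate = 5)),
              lapply(1:3, function(i)
                fake_unit(paste0("g2_", i), mean_rate = 5)))
  expect_equal(class_rate_anova(res, units0, "direction")$F, 0)
  expect_error(class_rate_anova(res[1:3], units[1:3]), "2 groups")
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(52)
  ps <- replicate(300, {
    res <- c(lapply(1:6, function(i)
               fake_result(paste0("a", i), "vel_up", 0.4)),
             lapply(1:6, function(i)
               fake_result(paste0("b", i), "vel_left", 0.4)))
    units <- c(lapply(1:6, function(i)
                 fake_unit(paste0("a", i), mean_rate = rnorm(1, 5))),
               lapply(1:6, function(i)
                 fake_unit(paste0("b", i), mean_rate = rnorm(1, 5))))
    class_rate_anova(res, units, "direction")$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("lag asymmetry summarises per-sign lags and matches Welch", {
  mk <- function(id, sgn, lag)
    fake_result(id, "vel_up", r = if (sgn == "positive") 0.4 else -0.4,
                lag_s = lag)
  res <- c(mapply(mk, paste0("p", 1:3), "positive", c(0.01, 0.02, 0.03),
                  SIMPLIFY = FALSE),
           mapply(mk, paste0("n", 1:3), "negative", c(0.10, 0.15, 0.20),
                  SIMPLIFY = FALSE))
  got <- lag_asymmetry_test(res)
  want <- oracle_welch(c(0.01, 0.02, 0.03), c(0.10, 0.15, 0.20))
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  sm <- got$summary
  expect_gt(sm$mean_lag_s[sm$sign == "negative"],
            sm$mean_lag_s[sm$sign == "positive"])

  allzero <- c(mapply(mk, paste0("p", 1:3), "positive", 0, SIMPLIFY = FALSE),
               mapply(mk, paste0("n", 1:3), "negative", 0, SIMPLIFY = FALSE))
  z <- lag_asymmetry_test(allzero)
  expect_equal(z$summary$mean_lag_s, c(0, 0))
  expect_equal(z$flag, "degenerate")
})

test_that("valence comparison builds the sign-by-session-type table", {
  app <- c(replicate(8, fake_result("x", "vel_up", 0.4), simplify = FALSE),
           replicate(2, fake_result("y", "vel_up", -0.4), simplify = FALSE))
  avr <- c(replicate(7, fake_result("x", "vel_up", 0.4), simplify = FALSE),
           replicate(3, fake_result("y", "vel_up", -0.4), simplify = FALSE))
  vt <- valence_test(app, avr)
  expect_equal(unname(vt$table["appetitive", ]), c(8, 2))
  expect_equal(vt$chi2, oracle_chi2_2x2(vt$table)$chi2, tolerance = 1e-12)
})

test_that("stim ANOVA detects planted genotype effects and nulls out", {
  flat <- expand.grid(genotype = c("control", "chr2"),
                      frequency = c(11, 15, 25), rep = 1:3)
  flat$peak_speed <- 5; flat$distance <- 2
  sa <- stim_anova(flat)
  expect_equal(sa$peak_speed$F, c(0, 0, 0))
  expect_equal(sa$distance$F, c(0, 0, 0))

  df <- simulate_stim_summaries(3, effect_speed = 2, effect_distance = 2,
                                seed = 9)
  sa2 <- stim_anova(df)
  expect_lt(sa2$peak_speed$p[sa2$peak_speed$term == "genotype"], 0.05)

  expect_error(stim_anova(data.frame(genotype = "chr2", frequency = 1:4,
                                     peak_speed = 1:4, distance = 1:4)),
               "2 levels")

  power <- mean(vapply(1:200, function(s) {
    d <- simulate_stim_summaries(3, effect_speed = 2, seed = 900 + s)
    sa <- stim_anova(d, "peak_speed")
    sa$peak_speed$p[1] < 0.05
  }, logical(1)))
  expect_gte(power, 0.8)
})
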