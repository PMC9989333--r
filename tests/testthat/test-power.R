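test_that("pooled proportion and Z statistic reproduce the printed formulas", {
  x1 <- binomial_count(10, 100)
  x2 <- binomial_count(20, 100)
  expect_equal(pooled_proportion(x1, x2), 0.15)
  expect_equal(pooled_proportion(binomial_count(0, 50), binomial_count(0, 50)),
               0)
  # equal proportions pool to themselves
  expect_equal(pooled_proportion(binomial_count(3, 30), binomial_count(7, 70)),
               0.1)
  expect_error(pooled_proportion(binomial_count(0, 0), binomial_count(0, 0)),
               "zero trials")

  # hand evaluation: Z = 0.1 / sqrt(0.15 * 0.85 * 0.02)
  expect_equal(z_statistic(x1, x2), 0.1 / sqrt(0.15 * 0.85 * 0.02))
  expect_equal(z_statistic(x1, x2), 1.9803, tolerance = 1e-4)
  # exact null zero and antisymmetry
  expect_identical(z_statistic(x1, x1), 0)
  expect_identical(z_statistic(x1, x2), -z_statistic(x2, x1))
  expect_error(z_statistic(binomial_count(0, 10), binomial_count(0, 10)),
               "degenerate")
  expect_error(binomial_count(5, 3), "successes <= trials")
})

test_that("analytic power is alpha-calibrated and consistent", {
  expect_equal(analytic_power(0.1, 0.1, 50, 80, alpha = 0.05), 0.05)
  expect_equal(analytic_power(0.1, 0.1, 50, 80, alpha = 0.17), 0.17)
  # consistency: power approaches 1 as trials grow
  expect_gt(analytic_power(0.01, 0.02, 1e6, 1e6), 0.999)
  # monotone in effect size and in trial count
  folds <- c(1.1, 1.5, 2, 3)
  pw <- vapply(folds, function(f) {
    analytic_power(1 / 96, f / (95 + f), 2000, 2000)
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
  ns <- c(100, 500, 2000, 8000)
  pw_n <- vapply(ns, function(n) analytic_power(1 / 96, 2 / 97, n, n),
                 numeric(1))
  expect_true(all(diff(pw_n) > 0))
  expect_error(analytic_power(0.1, 0.2, 100, 100, alpha = 1.2), "alpha")
  expect_error(analytic_power(0, 0.2, 100, 100), "strictly")
})

test_that("analytic power agrees with a Monte-Carlo rejection oracle", {
  # independent oracle: 1e5 binomial draws pushed through the Z statistic
  cases <- list(c(p1 = 0.0104, p2 = 0.0206, n1 = 1500, n2 = 900),
                c(p1 = 0.05, p2 = 0.08, n1 = 400, n2 = 400))
  zc <- qnorm(0.975)
  for (cs in cases) {
    mc <- withr::with_seed(123, {
      s1 <- rbinom(1e5, cs[["n1"]], cs[["p1"]])
      s2 <- rbinom(1e5, cs[["n2"]], cs[["p2"]])
      ps <- (s1 + s2) / (cs[["n1"]] + cs[["n2"]])
      se <- sqrt(ps * (1 - ps) * (1 / cs[["n1"]] + 1 / cs[["n2"]]))
      z <- (s2 / cs[["n2"]] - s1 / cs[["n1"]]) / se
      mean(abs(z) > zc, na.rm = TRUE)
    })
    ana <- analytic_power(cs[["p1"]], cs[["p2"]], cs[["n1"]], cs[["n2"]])
    se_mc <- sqrt(mc * (1 - mc) / 1e5)
    # normal approximation accuracy dominates at small p; allow 3 MC SE + 2%
    expect_lt(abs(ana - mc), 3 * se_mc + 0.02)
  }
})

test_that("scenario_power is null-calibrated and ordered in fold and size", {
  m <- build_basic_model("constant")
  base_args <- list(model = m, pair = c("ancestral", "derived"),
                    region_length = 2e5, window_length = 2e4,
                    replicates = 3, seed = 404)
  null <- do.call(scenario_power, c(base_args, fold = 1))
  expect_equal(nrow(null), 2)
  expect_setequal(null$scenario, c("shift_in_pop1", "shift_in_pop2"))
  expect_equal(null$power, c(0.05, 0.05))  # analytic mode: exactly alpha

  p12 <- do.call(scenario_power, c(base_args, fold = 1.2, n1 = 20, n2 = 20))
  p20 <- do.call(scenario_power, c(base_args, fold = 2.0, n1 = 20, n2 = 20))
  expect_gt(min(p20$power), min(p12$power))
  expect_true(all(p20$mean_trials1 > 0))
})

test_that("power_surface covers the grid and reports scenario minima", {
  m <- build_basic_model("constant")
  surf <- power_surface(m, c("ancestral", "derived"),
                        folds = c(1, 2), sizes = c(2, 10),
                        region_length = 1e5, window_length = 2e4,
                        replicates = 2, seed = 7)
  expect_equal(nrow(surf), 2 * 2 * 2)  # folds x sizes x scenarios
  expect_true(all(surf$power >= 0 & surf$power <= 1))
  mins <- report_min_power(surf)
  expect_equal(nrow(mins), 4)
  for (i in seq_len(nrow(mins))) {
    rows <- surf$fold == mins$fold[i] & surf$n1 == mins$n1[i]
    expect_equal(mins$min_power[i], min(surf$power[rows]))
  }
  expect_error(power_surface(m, c("ancestral", "derived"), folds = 2,
                             sizes = 1), "smallest admissible")
})
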