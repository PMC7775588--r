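test_that("standardizing constants match the distribution families", {
  expect_equal(predictor_spec("normal")[c("mean", "sd")], list(mean = 0, sd = 1))
  expect_equal(predictor_spec("exponential")[c("mean", "sd")],
               list(mean = 1, sd = 1))
  # Beta(1.5, 1.5): sd = sqrt(ab / ((a+b)^2 (a+b+1))) = 0.25
  expect_equal(predictor_spec("beta")[c("mean", "sd")],
               list(mean = 0.5, sd = 0.25))
  expect_equal(predictor_spec("t5")$sd, sqrt(5 / 3))
  expect_equal(predictor_spec("t6")$sd, sqrt(6 / 4))
  expect_error(draw_standardized_predictor(list(family = "cauchy"), 10),
               "unknown")
})

test_that("standardized draws have population mean 0, sd 1 and the family's shape", {
  n <- 2e5
  shapes <- list(
    # family, skewness, kurtosis, skew tol, kurt tol (heavy-tailed
    # families get wide bands: their moment estimators have huge variance)
    list("normal", 0, 0, 0.05, 0.1),
    list("exponential", 2, 6, 0.25, 1.5),
    list("beta", 0, -1, 0.05, 0.1),
    list("t5", 0, 6, 1.0, 9),
    list("t6", 0, 3, 0.6, 3)
  )
  for (sh in shapes) {
    z <- draw_standardized_predictor(sh[[1]], n, seed = 101)
    expect_lt(abs(mean(z)), 0.015)
    expect_lt(abs(sd(z) - 1), 0.02)
    expect_equal(sample_skewness(z), sh[[2]], tolerance = sh[[4]] + 1e-9)
    expect_equal(sample_excess_kurtosis(z), sh[[3]], tolerance = sh[[5]] + 1e-9)
  }
  # determinism
  expect_identical(draw_standardized_predictor("t5", 100, seed = 3),
                   draw_standardized_predictor("t5", 100, seed = 3))
})

test_that("c-prime inverts the squared-semipartial R-squared increase", {
  expect_equal(cprime_from_r2_increase(0, 0.7), 0)
  expect_equal(cprime_from_r2_increase(0.13, 0.600), sqrt(0.13 / 0.64))
  expect_equal(round(cprime_from_r2_increase(0.13, 0.600), 4), 0.4507)
  # worked-example round trip: a = 0.6, c' = 0.4 <-> d = 0.16 * 0.64
  expect_equal(cprime_from_r2_increase(0.4^2 * (1 - 0.36), 0.6), 0.4)
  expect_error(cprime_from_r2_increase(-0.1, 0.5))
  expect_error(cprime_from_r2_increase(0.5, 1))
})

test_that("population error variances give unit-variance variables", {
  p <- population_params(mediation_condition(n = 50, a = 0.6, b = 0.6,
                                             r2_increase = 0.1024))
  expect_equal(p$var_em, 0.64)
  expect_equal(p$c_prime, 0.4)
  expect_equal(p$var_ey, 0.192)
  expect_equal(diag(implied_covariance(p)), c(x = 1, m = 1, y = 1))

  ps <- population_params(mediation_condition("serial", 50, a = 0.6, b = 0.36))
  expect_equal(ps$var_em2, 0.64)
  expect_equal(ps$var_ey, 0.64)
  expect_equal(diag(implied_covariance(ps)),
               c(x = 1, m1 = 1, m2 = 1, y = 1))
  # Monte-Carlo variance oracle for the serial algebra
  sim <- simulate_from_params(ps, 1e6, seed = 9)
  expect_equal(var(sim$m2), 1, tolerance = 0.01)
  expect_equal(var(sim$y), 1, tolerance = 0.01)

  expect_error(population_params(
    mediation_condition(n = 50, a = 0.714, b = 0.714, r2_increase = 0.26)),
    "infeasible")
})

test_that("generated datasets carry the rescaled true effects and hit the targets", {
  cnd <- mediation_condition(n = 1e5, a = 0.6, b = 0.6)
  d <- generate_dataset(cnd, seed = 11)
  tr <- attr(d, "true_effects")
  expect_equal(unname(tr["unstandardized"]), 0.36 * 3 / 4)
  expect_equal(unname(tr["standardized"]), 0.36)
  expect_equal(colMeans(as.data.frame(d)), c(x = 3, m = 5, y = 4),
               tolerance = 0.05)
  expect_equal(vapply(as.data.frame(d), sd, 0), c(x = 4, m = 5, y = 3),
               tolerance = 0.02)
  # nil effect
  tr0 <- attr(generate_dataset(mediation_condition(n = 10, a = 0, b = 0),
                               seed = 1), "true_effects")
  expect_equal(unname(tr0), c(0, 0))
  # determinism
  expect_identical(generate_dataset(cnd[, ], seed = 5)$y[1:10],
                   generate_dataset(cnd[, ], seed = 5)$y[1:10])
})

test_that("a nonnormal predictor propagates damped skewness to the mediator", {
  cnd <- mediation_condition(n = 2e5, a = 0.6, b = 0.6,
                             distribution = "exponential")
  d <- generate_dataset(cnd, seed = 13)
  # cumulant algebra: skew(m) = a^3 * skew(x) = 0.432 on unit-variance scale
  expect_equal(sample_skewness(d$m), 0.6^3 * 2, tolerance = 0.1)
  expect_equal(sample_excess_kurtosis(d$m), 0.6^4 * 6, tolerance = 0.4)
})

test_that("the condition grid applies the R-squared and feasibility drop rules", {
  grid <- build_condition_grid()
  expect_setequal(unique(grid$n), c(50L, 100L, 150L, 200L, 500L))
  expect_true(all(grid$r2 <= 0.80))
  # the large-effect, large-direct-path cell is variance-infeasible
  expect_false(any(grid$model == "simple" & grid$a == 0.714 &
                     grid$b == 0.714 & grid$r2_increase == 0.26))
  # the nil cell is retained with zero true effect
  nil <- dplyr::filter(grid, a == 0, b == 0, r2_increase == 0)
  expect_true(nrow(nil) > 0 && all(nil$true_std == 0))
  # every retained condition has feasible population parameters
  sub <- grid[grid$n == 50, ]
  for (i in seq_len(nrow(sub))) {
    expect_no_error(population_params(sub[i, ]))
  }
})

test_that("study config round-trips through YAML", {
  cfg <- list(models = "simple", ns = c(50, 100),
              ab_pairs = list(c(0.6, 0.6), c(0, 0)), reps = 10)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  got <- read_study_config(path)
  expect_equal(got$ns, c(50, 100))
  expect_equal(got$ab_pairs[[1]], c(a = 0.6, b = 0.6))
  grid <- build_condition_grid(got)
  expect_true(all(grid$model == "simple"))
  expect_setequal(unique(grid$n), c(50L, 100L))
})
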