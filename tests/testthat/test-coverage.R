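test_that("coverage classification uses the closed tolerable range", {
  expect_equal(classify_coverage(c(0.95, 0.90, 1.0)),
               c("within", "below", "above"))
  expect_equal(classify_coverage(c(0.935, 0.965)), c("within", "within"))
  expect_equal(classify_coverage(c(0.9349, 0.9651)), c("below", "above"))
  expect_error(classify_coverage(1.2))
})

test_that("a stub interval with known hit probability recovers that probability", {
  p_true <- 0.8
  stub <- function(data, effect_type, level, seed) {
    set.seed(seed)
    if (runif(1) < p_true) list(lower = -1e9, upper = 1e9)
    else list(lower = 1e8, upper = 1e8 + 1)
  }
  cnd <- mediation_condition(n = 10, a = 0.6, b = 0.6)
  res <- run_condition(cnd, methods = list(coin = stub),
                       effect_types = "unstandardized",
                       n_reps = 400, master_seed = 5)
  # binomial consistency: within 3 * sqrt(p(1-p)/R)
  expect_lt(abs(res$coverage - p_true), 3 * sqrt(p_true * 0.2 / 400))
  # an always-infinite interval covers everything
  wide <- function(data, effect_type, level, seed) {
    list(lower = -Inf, upper = Inf)
  }
  res2 <- run_condition(cnd, methods = list(wide = wide),
                        effect_types = "standardized",
                        n_reps = 20, master_seed = 6)
  expect_equal(res2$coverage, 1)
})

test_that("failed replications are excluded from the denominator and counted", {
  flaky <- function(data, effect_type, level, seed) {
    set.seed(seed)
    if (runif(1) < 0.3) list(lower = NA_real_, upper = NA_real_,
                             status = "failed-upper")
    else list(lower = -1e9, upper = 1e9)
  }
  cnd <- mediation_condition(n = 10, a = 0, b = 0)
  res <- run_condition(cnd, methods = list(flaky = flaky),
                       effect_types = "unstandardized",
                       n_reps = 200, master_seed = 7)
  expect_lt(res$n_converged, res$n_reps)
  expect_equal(res$coverage, 1)  # every converged interval covered
})

test_that("identical master seeds reproduce the whole coverage table", {
  cnd <- mediation_condition(n = 50, a = 0.6, b = 0.6)
  r1 <- run_condition(cnd, methods = c("boot", "mc"), n_reps = 25,
                      master_seed = 11, B = 100, mc_draws = 200)
  r2 <- run_condition(cnd, methods = c("boot", "mc"), n_reps = 25,
                      master_seed = 11, B = 100, mc_draws = 200)
  expect_equal(r1, r2)
  r3 <- run_condition(cnd, methods = c("boot", "mc"), n_reps = 25,
                      master_seed = 12, B = 100, mc_draws = 200)
  expect_false(isTRUE(all.equal(r1$coverage, r3$coverage)))
})

test_that("nil-effect conditions are covered almost always", {
  cnd <- mediation_condition(n = 50, a = 0, b = 0)
  res <- run_condition(cnd, methods = c("boot", "mc"), n_reps = 150,
                       master_seed = 13, B = 200, mc_draws = 500)
  expect_true(all(res$coverage > 0.95))
})

test_that("infeasible conditions are refused before any replication runs", {
  bad <- mediation_condition(n = 50, a = 0.714, b = 0.714,
                             r2_increase = 0.26)
  expect_error(run_condition(bad, methods = "mc", n_reps = 2,
                             master_seed = 1), "infeasible")
})

test_that("the summary table is tidy, keyed and schema-stable", {
  empty <- summarize_coverage(NULL)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("model", "distribution", "n", "method", "effect_type",
                    "coverage", "classification") %in% names(empty)))

  cnd <- mediation_condition(n = 50, a = 0.6, b = 0.6)
  res <- run_condition(cnd, methods = c("boot", "mc"), n_reps = 10,
                       master_seed = 21, B = 100, mc_draws = 100)
  smry <- summarize_coverage(res)
  # 2 methods x 2 effect types
  expect_equal(nrow(smry), 4)
  keys <- smry[, c("model", "distribution", "n", "a", "b", "r2_increase",
                   "method", "effect_type")]
  expect_equal(nrow(dplyr::distinct(keys)), nrow(smry))
  expect_s3_class(plot_coverage(smry), "ggplot")
})

test_that("run_study binds per-condition results under one master seed", {
  grid <- build_condition_grid(list(
    models = "simple", ns = 50, ab_pairs = list(c(0, 0), c(0.6, 0.6)),
    r2_increase = 0, distributions = "normal"
  ))
  expect_equal(nrow(grid), 2)
  res <- run_study(grid, methods = "mc", n_reps = 10, master_seed = 31,
                   mc_draws = 100)
  expect_equal(nrow(res), 4)
  res2 <- run_study(grid, methods = "mc", n_reps = 10, master_seed = 31,
                    mc_draws = 100)
  expect_equal(res, res2)
})

test_that("heavy-tailed predictors under-cover the ML profile interval but not ADF", {
  # exponential predictor, medium standardized effect (0.361), n = 150:
  # the ML likelihood treats the predictor-variance estimate as if its
  # sampling variance were the normal-theory 2 sigma^4 / n, but excess
  # kurtosis 6 makes it four times larger, so the standardized-effect
  # interval is too narrow; the fourth-moment ADF weight matrix absorbs it
  cnd <- mediation_condition(n = 150, a = 0.600, b = 0.600,
                             distribution = "exponential")
  res <- run_condition(cnd, methods = c("lbci", "lbci-adf"),
                       effect_types = "standardized",
                       n_reps = 400, master_seed = 41)
  cov_ml <- res$coverage[res$method == "lbci"]
  cov_adf <- res$coverage[res$method == "lbci-adf"]
  expect_lt(cov_ml, cov_adf)
  expect_lt(cov_ml, 0.935)
})
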