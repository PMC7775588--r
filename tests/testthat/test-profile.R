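test_that("a locally constant derived parameter yields a point interval", {
  fn <- function(th) sum((th - 1)^2) * 50
  gr <- function(th) 100 * (th - 1)
  res <- profile_search(fn, gr, function(th) 2.5, theta_hat = c(1, 1))
  expect_equal(res$lower, 2.5)
  expect_equal(res$upper, 2.5)
  expect_equal(res$status, "degenerate")
})

test_that("generic search matches the closed-form profile CI for a normal variance", {
  set.seed(61)
  n <- 40
  v <- rnorm(n, sd = 1.3)
  s2 <- mean((v - mean(v))^2)           # ML variance
  fn <- function(th) n * (log(2 * pi) + th[1] + s2 / exp(th[1]))
  gr <- function(th) n * (1 - s2 / exp(th[1]))
  res <- profile_search(fn, gr, function(th) exp(th[1]),
                        theta_hat = c(lv = log(s2)))
  # closed form: endpoints solve n * (s2/v - 1 + log(v/s2)) = qchisq(.95, 1)
  q <- qchisq(0.95, 1)
  dev1 <- function(vv) n * (s2 / vv - 1 + log(vv / s2)) - q
  lo <- uniroot(dev1, c(s2 / 10, s2), tol = 1e-12)$root
  hi <- uniroot(dev1, c(s2, s2 * 10), tol = 1e-12)$root
  expect_equal(res$status, "converged")
  expect_equal(res$lower, lo, tolerance = 1e-4)
  expect_equal(res$upper, hi, tolerance = 1e-4)
})

test_that("profile interval for ab matches a brute-force constrained extremum", {
  d <- generate_dataset(mediation_condition(n = 50, a = 0.6, b = 0.6,
                                            r2_increase = 0.02), seed = 63)
  mom <- compute_moments(d)
  ci <- profile_ci(mom, engine = "ml", effect_type = "unstandardized",
                   fast = FALSE)
  # oracle: dense (a, b) grid over the separable profile deviance built
  # straight from textbook residual-variance formulas
  s <- mom$cov_ml
  n <- mom$n
  vem <- function(a) s["m", "m"] - 2 * a * s["x", "m"] + a^2 * s["x", "x"]
  vey <- function(b) {
    vu <- s["y", "y"] - 2 * b * s["m", "y"] + b^2 * s["m", "m"]
    cux <- s["x", "y"] - b * s["x", "m"]
    vu - cux^2 / s["x", "x"]
  }
  a_hat <- s["x", "m"] / s["x", "x"]
  b_grid <- seq(-1, 2.5, length.out = 2001)
  a_grid <- seq(a_hat - 1, a_hat + 1, length.out = 2001)
  da <- n * (log(vapply(a_grid, vem, 0)) - log(min(vapply(a_grid, vem, 0))))
  db <- n * (log(vapply(b_grid, vey, 0)) - log(min(vapply(b_grid, vey, 0))))
  keep <- outer(da, db, `+`) <= qchisq(0.95, 1)
  ab <- outer(a_grid, b_grid)
  res_lo <- min(ab[keep])
  res_hi <- max(ab[keep])
  tol <- 0.005  # oracle grid resolution
  expect_equal(ci$lower, res_lo, tolerance = tol)
  expect_equal(ci$upper, res_hi, tolerance = tol)
  # and the closed-block fast path agrees with the generic search
  fast <- profile_ci(mom, engine = "ml", effect_type = "unstandardized")
  expect_equal(fast$lower, ci$lower, tolerance = 1e-4)
  expect_equal(fast$upper, ci$upper, tolerance = 1e-4)
})

test_that("the interval contains the estimate and widens with the level", {
  d <- generate_dataset(mediation_condition(n = 80, a = 0.6, b = 0.6), seed = 67)
  for (engine in c("ml", "adf", "ml-fixed-x")) {
    for (eff in c("unstandardized", "standardized")) {
      ci95 <- profile_ci(d, engine = engine, effect_type = eff)
      ci90 <- profile_ci(d, engine = engine, effect_type = eff, level = 0.90)
      expect_equal(ci95$status, "converged")
      expect_lte(ci95$lower, ci95$estimate)
      expect_gte(ci95$upper, ci95$estimate)
      expect_lt(ci95$lower, ci90$lower)
      expect_gt(ci95$upper, ci90$upper)
    }
  }
})

test_that("free-x and fixed-x profiles agree for the unstandardized effect", {
  d <- generate_dataset(mediation_condition(n = 70, a = 0.376, b = 0.376),
                        seed = 71)
  ml <- profile_ci(d, engine = "ml", effect_type = "unstandardized",
                   fast = FALSE)
  fx <- profile_ci(d, engine = "ml-fixed-x", effect_type = "unstandardized",
                   fast = FALSE)
  # sigma_x^2 separates from the likelihood and does not enter a*b
  expect_equal(fx$lower, ml$lower, tolerance = 1e-4)
  expect_equal(fx$upper, ml$upper, tolerance = 1e-4)
})

test_that("ML standardized-effect intervals are invariant to affine rescaling", {
  d <- generate_dataset(mediation_condition(n = 90, a = 0.6, b = 0.6), seed = 73)
  ci <- profile_ci(d, engine = "ml", effect_type = "standardized")
  d2 <- transform(as.data.frame(d), x = 2 * x - 1, m = 0.3 * m + 4,
                  y = 10 * y)
  ci2 <- profile_ci(d2, engine = "ml", effect_type = "standardized")
  expect_equal(ci2$lower, ci$lower, tolerance = 1e-4)
  expect_equal(ci2$upper, ci$upper, tolerance = 1e-4)
})

test_that("fx and ml intervals differ more for the standardized effect", {
  # the fixed parameter enters the standardized effect's standardizer but
  # not a*b, so |lbci - lbci-fx| should be larger for the standardized
  # effect on average
  set.seed(77)
  seeds <- sample.int(1e6, 30)
  d_un <- d_st <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    d <- generate_dataset(mediation_condition(n = 100, a = 0.6, b = 0.6),
                          seed = seeds[i])
    mom <- compute_moments(d)
    ml_u <- profile_ci(mom, engine = "ml", effect_type = "unstandardized",
                       fast = FALSE)
    fx_u <- profile_ci(mom, engine = "ml-fixed-x",
                       effect_type = "unstandardized", fast = FALSE)
    ml_s <- profile_ci(mom, engine = "ml", effect_type = "standardized")
    fx_s <- profile_ci(mom, engine = "ml-fixed-x",
                       effect_type = "standardized")
    d_un[i] <- abs(ml_u$lower - fx_u$lower) + abs(ml_u$upper - fx_u$upper)
    d_st[i] <- abs(ml_s$lower - fx_s$lower) + abs(ml_s$upper - fx_s$upper)
  }
  expect_lt(mean(d_un), mean(d_st))
})

test_that("serial-model profiles cover both effect scales", {
  d <- generate_dataset(
    mediation_condition("serial", n = 120, a = 0.6, b = 0.36), seed = 79)
  for (engine in c("ml", "adf")) {
    ci <- profile_ci(d, engine = engine, effect_type = "standardized")
    expect_equal(ci$status, "converged")
    expect_true(ci$lower < ci$estimate && ci$estimate < ci$upper)
  }
})
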