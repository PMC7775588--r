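# shared helpers: moment statistics and small structural simulators

sample_skewness <- function(v) {
  z <- v - mean(v)
  mean(z^3) / mean(z^2)^1.5
}

sample_excess_kurtosis <- function(v) {
  z <- v - mean(v)
  mean(z^4) / mean(z^2)^2 - 3
}

# simulate cases directly from structural equations (independent of
# generate_dataset) for variance oracles
simulate_from_params <- function(params, n, seed = 1) {
  set.seed(seed)
  x <- rnorm(n, mean = params$mean_x, sd = sqrt(params$var_x))
  if (inherits(params, "simple_params")) {
    m <- params$i_m + params$a * x + rnorm(n, sd = sqrt(params$var_em))
    y <- params$i_y + params$b * m + params$c_prime * x +
      rnorm(n, sd = sqrt(params$var_ey))
    data.frame(x = x, m = m, y = y)
  } else {
    m1 <- params$i_m1 + params$a * x + rnorm(n, sd = sqrt(params$var_em1))
    m2 <- params$i_m2 + params$b1 * m1 + params$d_xm2 * x +
      rnorm(n, sd = sqrt(params$var_em2))
    y <- params$i_y + params$b2 * m2 + params$d_m1y * m1 +
      params$c_prime * x + rnorm(n, sd = sqrt(params$var_ey))
    data.frame(x = x, m1 = m1, m2 = m2, y = y)
  }
}

# small full-rank simple-model dataset for exact-arithmetic checks
toy_simple_data <- function(n = 40, seed = 123) {
  set.seed(seed)
  x <- rnorm(n, 3, 2)
  m <- 1 + 0.7 * x + rnorm(n)
  y <- 2 + 0.5 * m + 0.3 * x + rnorm(n)
  data.frame(x = x, m = m, y = y)
}
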