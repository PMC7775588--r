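# Vectorized bootstrap of the indirect-effect estimates: B resamples are
# drawn as an index matrix and every OLS path estimate is computed from
# per-resample cross-product sums (identical to refitting lm on each
# resample, asserted in tests). Rank-deficient resamples are redrawn.
boot_indirect_draws <- function(data, model = NULL, B = 2000, seed = NULL) {
  model <- infer_model(data, model)
  df <- as.data.frame(data)[model_vars(model)]
  n <- nrow(df)
  if (n < 3) stop("need at least 3 cases to bootstrap", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  est_fun <- if (model == "simple") boot_est_simple else boot_est_serial
  idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  est <- est_fun(df, idx)
  bad <- which(!est$ok)
  n_redraws <- 0L
  rounds <- 0L
  while (length(bad) > 0 && rounds < 25L) {
    n_redraws <- n_redraws + length(bad)
    idx2 <- matrix(sample.int(n, n * length(bad), replace = TRUE), n,
                   length(bad))
    est2 <- est_fun(df, idx2)
    est$unstd[bad] <- est2$unstd
    est$std[bad] <- est2$std
    est$ok[bad] <- est2$ok
    bad <- bad[!est2$ok]
    rounds <- rounds + 1L
  }
  list(unstd = est$unstd, std = est$std, n_redraws = n_redraws)
}

boot_est_simple <- function(df, idx) {
  n <- nrow(idx)
  x <- matrix(df$x[idx], n); m <- matrix(df$m[idx], n)
  y <- matrix(df$y[idx], n)
  mx <- colMeans(x); mm <- colMeans(m); my <- colMeans(y)
  cxx <- colMeans(x * x) - mx^2
  cmm <- colMeans(m * m) - mm^2
  cyy <- colMeans(y * y) - my^2
  cxm <- colMeans(x * m) - mx * mm
  cxy <- colMeans(x * y) - mx * my
  cmy <- colMeans(m * y) - mm * my
  det2 <- cmm * cxx - cxm^2
  a <- cxm / cxx
  b <- (cmy * cxx - cxy * cxm) / det2
  unstd <- a * b
  std <- unstd * sqrt(cxx / cyy)
  ok <- is.finite(unstd) & is.finite(std) & cxx > 0 & cyy > 0 & det2 > 0
  list(unstd = unstd, std = std, ok = ok)
}

boot_est_serial <- function(df, idx) {
  n <- nrow(idx)
  x <- matrix(df$x[idx], n); m1 <- matrix(df$m1[idx], n)
  m2 <- matrix(df$m2[idx], n); y <- matrix(df$y[idx], n)
  mx <- colMeans(x); mm1 <- colMeans(m1); mm2 <- colMeans(m2)
  my <- colMeans(y)
  cxx <- colMeans(x * x) - mx^2
  c11 <- colMeans(m1 * m1) - mm1^2
  c22 <- colMeans(m2 * m2) - mm2^2
  cyy <- colMeans(y * y) - my^2
  cx1 <- colMeans(x * m1) - mx * mm1
  cx2 <- colMeans(x * m2) - mx * mm2
  cxy <- colMeans(x * y) - mx * my
  c12 <- colMeans(m1 * m2) - mm1 * mm2
  c1y <- colMeans(m1 * y) - mm1 * my
  c2y <- colMeans(m2 * y) - mm2 * my

  a <- cx1 / cxx
  det_m2 <- c11 * cxx - cx1^2
  b1 <- (c12 * cxx - cx2 * cx1) / det_m2
  # y ~ m1 + m2 + x: Cramer's rule for the m2 coefficient
  det_y <- c11 * (c22 * cxx - cx2^2) - c12 * (c12 * cxx - cx2 * cx1) +
    cx1 * (c12 * cx2 - c22 * cx1)
  det_b2 <- c11 * (c2y * cxx - cx2 * cxy) - c1y * (c12 * cxx - cx2 * cx1) +
    cx1 * (c12 * cxy - c2y * cx1)
  b2 <- det_b2 / det_y
  unstd <- a * b1 * b2
  std <- unstd * sqrt(cxx / cyy)
  ok <- is.finite(unstd) & is.finite(std) & cxx > 0 & cyy > 0 &
    det_m2 > 0 & det_y > 0
  list(unstd = unstd, std = std, ok = ok)
}

# Full-sample indirect estimates from the same cross-product formulas.
indirect_hat <- function(data, model = NULL) {
  model <- infer_model(data, model)
  df <- as.data.frame(data)[model_vars(model)]
  idx <- matrix(seq_len(nrow(df)), nrow(df), 1)
  est <- if (model == "simple") boot_est_simple(df, idx)
         else boot_est_serial(df, idx)
  c(unstandardized = est$unstd[1], standardized = est$std[1])
}

#' Nonparametric percentile bootstrap interval for an indirect effect
#'
#' Draws `B` resamples of the cases with replacement, re-estimates the
#' indirect effect by OLS in each (with standardizers recomputed within
#' each resample for the standardized effect), and takes the empirical
#' percentiles — 2.5th and 97.5th at the default 95% level — with linear
#' interpolation between order statistics.
#'
#' @param data A data frame with the model's columns.
#' @param effect_type `"unstandardized"` or `"standardized"`.
#' @param B Number of bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed; the interval is deterministic given
#'   the seed.
#' @param model `"simple"`, `"serial"`, or `NULL` to infer.
#' @return A one-row tibble (class `indirect_ci`); `n_redraws` counts
#'   rank-deficient resamples that were redrawn (a warning is raised if
#'   they exceed 5% of `B`).
#' @export
#' @examples
#' d <- generate_dataset(mediation_condition(n = 100, a = 0.6, b = 0.6), seed = 4)
#' bootstrap_percentile_ci(d, "standardized", B = 500, seed = 5)
bootstrap_percentile_ci <- function(data, effect_type = c("unstandardized",
                                                          "standardized"),
                                    B = 2000, level = 0.95, seed = NULL,
                                    model = NULL) {
  effect_type <- match.arg(effect_type)
  stopifnot(B >= 2)
  draws <- boot_indirect_draws(data, model, B = B, seed = seed)
  if (draws$n_redraws > 0.05 * B) {
    warning("more than 5% of bootstrap resamples were rank-deficient and ",
            "redrawn", call. = FALSE)
  }
  v <- if (effect_type == "unstandardized") draws$unstd else draws$std
  alpha <- (1 - level) / 2
  qs <- stats::quantile(v, c(alpha, 1 - alpha), names = FALSE, type = 7)
  est <- indirect_hat(data, model)[[effect_type]]
  status <- if (qs[1] == qs[2]) "degenerate" else "converged"
  interval_row(method = "boot", effect_type = effect_type, estimate = est,
               lower = qs[1], upper = qs[2], level = level, status = status,
               n_redraws = draws$n_redraws)
}
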