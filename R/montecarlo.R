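#' Monte Carlo (parametric simulation) interval for an indirect effect
#'
#' Simulates the sampling distribution of the product of paths by drawing
#' `n_draws` independent normal values per path, centered at the OLS
#' estimates with SDs equal to their standard errors (zero cross-path
#' covariance; the a and b estimates are uncorrelated in the simple
#' model, and the serial model uses three independent normals). The 2.5th
#' and 97.5th percentiles of the products form the 95% interval. The
#' standardized variant multiplies both limits by `sd_x / sd_y` with the
#' sample standardizers treated as fixed.
#'
#' @param fit A [ols_fit()] result, or a data frame (fitted on the fly).
#' @param effect_type `"unstandardized"` or `"standardized"`.
#' @param n_draws Number of simulation draws (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @param model `"simple"`, `"serial"`, or `NULL` to infer (data input only).
#' @return A one-row tibble (class `indirect_ci`).
#' @export
#' @examples
#' d <- generate_dataset(mediation_condition(n = 100, a = 0.6, b = 0.6), seed = 6)
#' monte_carlo_ci(d, "unstandardized", seed = 7)
monte_carlo_ci <- function(fit, effect_type = c("unstandardized",
                                                "standardized"),
                           n_draws = 1000, level = 0.95, seed = NULL,
                           model = NULL) {
  effect_type <- match.arg(effect_type)
  if (!inherits(fit, "med_ols")) fit <- ols_fit(fit, model)
  if (!is.null(seed)) set.seed(seed)

  path_names <- if (fit$model == "simple") c("a", "b") else c("a", "b1", "b2")
  prod <- rep(1, n_draws)
  for (pn in path_names) {
    p <- fit$paths[[pn]]
    if (p$se < 0) stop("negative standard error", call. = FALSE)
    prod <- prod * stats::rnorm(n_draws, mean = p$estimate, sd = p$se)
  }
  alpha <- (1 - level) / 2
  qs <- stats::quantile(prod, c(alpha, 1 - alpha), names = FALSE, type = 7)
  est <- Reduce(`*`, lapply(path_names, function(pn) fit$paths[[pn]]$estimate))
  if (effect_type == "standardized") {
    ratio <- fit$sds[["x"]] / fit$sds[["y"]]
    qs <- qs * ratio
    est <- est * ratio
  }
  status <- if (qs[1] == qs[2]) "degenerate" else "converged"
  interval_row(method = "mc", effect_type = effect_type, estimate = est,
               lower = qs[1], upper = qs[2], level = level, status = status)
}
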