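#' Confidence interval for an indirect effect by any supported method
#'
#' Front door dispatching to [bootstrap_percentile_ci()] (`"boot"`),
#' [profile_ci()] (`"lbci"`, `"lbci-adf"`, `"lbci-fx"`) or
#' [monte_carlo_ci()] (`"mc"`).
#'
#' @param data A data frame with columns `x,m,y` or `x,m1,m2,y`.
#' @param method One of `"boot"`, `"lbci"`, `"lbci-adf"`, `"lbci-fx"`,
#'   `"mc"`.
#' @param effect_type `"unstandardized"` or `"standardized"`.
#' @param model `"simple"`, `"serial"`, or `NULL` to infer.
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed for the resampling/simulation methods.
#' @param B Bootstrap resamples (default 2000).
#' @param n_draws Monte Carlo draws (default 1000).
#' @return A one-row tibble (class `indirect_ci`) with `method`,
#'   `effect_type`, `estimate`, `lower`, `upper`, `level`, `status`.
#' @export
#' @examples
#' d <- generate_dataset(mediation_condition(n = 100, a = 0.6, b = 0.6), seed = 8)
#' indirect_ci(d, method = "lbci", effect_type = "standardized")
indirect_ci <- function(data, method = c("boot", "lbci", "lbci-adf",
                                         "lbci-fx", "mc"),
                        effect_type = c("unstandardized", "standardized"),
                        model = NULL, level = 0.95, seed = NULL,
                        B = 2000, n_draws = 1000) {
  method <- match.arg(method)
  effect_type <- match.arg(effect_type)
  switch(method,
    boot = bootstrap_percentile_ci(data, effect_type, B = B, level = level,
                                   seed = seed, model = model),
    mc = monte_carlo_ci(data, effect_type, n_draws = n_draws, level = level,
                        seed = seed, model = model),
    profile_ci(data, model = model,
               engine = switch(method, lbci = "ml", `lbci-adf` = "adf",
                               `lbci-fx` = "ml-fixed-x"),
               effect_type = effect_type, level = level)
  )
}
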