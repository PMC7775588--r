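#' Unstandardized indirect effect
#'
#' The product of the path coefficients along the mediated route:
#' `a * b` for the simple model, `a * b1 * b2` for the serial model.
#'
#' @param params A [simple_params()] or [serial_params()] object.
#' @return A single number.
#' @export
#' @examples
#' indirect_unstandardized(simple_params(a = 0.1975, b = 0.714))
indirect_unstandardized <- function(params) {
  if (inherits(params, "simple_params")) {
    params$a * params$b
  } else if (inherits(params, "serial_params")) {
    params$a * params$b1 * params$b2
  } else {
    stop("not a mediation_params object", call. = FALSE)
  }
}

#' Completely standardized indirect effect
#'
#' The indirect effect on the z-score scale: the unstandardized product
#' multiplied by `sqrt(var_x / Var(y))`, where `Var(y)` is the outcome
#' variance implied by the full parameter set (including, for the serial
#' model, the estimated cross paths `d_xm2` and `d_m1y`; the fitted model is
#' saturated, so at the optimum this equals the sample variance of `y`).
#'
#' @param params A [simple_params()] or [serial_params()] object.
#' @return A single number.
#' @export
#' @examples
#' # unit-variance worked example: implied Var(y) = 1, effect = 0.36
#' indirect_standardized(simple_params(a = 0.6, b = 0.6, c_prime = 0.4,
#'                                     var_em = 0.64, var_ey = 0.192))
indirect_standardized <- function(params) {
  ab <- indirect_unstandardized(params)
  var_y <- implied_variance_y(params)
  if (var_y <= 0) {
    stop("implied outcome variance is not positive", call. = FALSE)
  }
  ab * sqrt(params$var_x / var_y)
}

# Implied Var(y) without forming the whole covariance matrix.
implied_variance_y <- function(params) {
  if (inherits(params, "simple_params")) {
    params$b^2 * params$var_em + params$var_ey +
      params$var_x * (params$a * params$b + params$c_prime)^2
  } else {
    sig <- implied_covariance(params)
    sig["y", "y"]
  }
}

#' Standardize an indirect effect by sample standard deviations
#'
#' Converts an unstandardized indirect effect to the completely standardized
#' scale using the standard deviations of the predictor and the outcome:
#' `ab * sd_x / sd_y`.
#'
#' @param ab Unstandardized indirect effect.
#' @param sd_x Standard deviation of the predictor.
#' @param sd_y Standard deviation of the outcome (> 0).
#' @return A number (vectorized over its arguments).
#' @export
#' @examples
#' standardize_by_sds(0.27, sd_x = 4, sd_y = 3)  # 0.36
standardize_by_sds <- function(ab, sd_x, sd_y) {
  if (any(sd_y <= 0)) stop("sd_y must be positive", call. = FALSE)
  ab * sd_x / sd_y
}
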