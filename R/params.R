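#' Population or fitted parameters of a simple mediation model
#'
#' Container for the structural parameters of the three-variable path model
#' `m = i_m + a*x + e_m`, `y = i_y + b*m + c'*x + e_y`, together with the
#' predictor's mean and variance and the two error variances. The object is
#' used both for population values (when generating data) and for estimates
#' (when fitting).
#'
#' @param a Path from predictor to mediator.
#' @param b Path from mediator to outcome.
#' @param c_prime Direct path from predictor to outcome.
#' @param var_x Predictor variance (>= 0).
#' @param var_em Error variance of the mediator (>= 0).
#' @param var_ey Error variance of the outcome (>= 0).
#' @param i_m,i_y Intercepts of the two regressions.
#' @param mean_x Predictor mean.
#'
#' @return An object of class `c("simple_params", "mediation_params")`.
#' @seealso [serial_params()], [indirect_unstandardized()],
#'   [indirect_standardized()], [implied_covariance()]
#' @export
#' @examples
#' p <- simple_params(a = 0.6, b = 0.6, c_prime = 0.4,
#'                    var_em = 0.64, var_ey = 0.192)
#' indirect_standardized(p)
simple_params <- function(a, b, c_prime = 0, var_x = 1, var_em = 1, var_ey = 1,
                          i_m = 0, i_y = 0, mean_x = 0) {
  if (any(c(var_x, var_em, var_ey) < 0)) {
    stop("variances must be non-negative", call. = FALSE)
  }
  structure(
    list(a = a, b = b, c_prime = c_prime,
         var_x = var_x, var_em = var_em, var_ey = var_ey,
         i_m = i_m, i_y = i_y, mean_x = mean_x),
    class = c("simple_params", "mediation_params")
  )
}

#' Population or fitted parameters of a serial mediation model
#'
#' The four-variable path model with two mediators in series:
#' `m1 = i_m1 + a*x + e_m1`, `m2 = i_m2 + b1*m1 + d_xm2*x + e_m2`,
#' `y = i_y + b2*m2 + d_m1y*m1 + c'*x + e_y`. The cross paths `d_xm2`
#' (predictor to second mediator) and `d_m1y` (first mediator to outcome)
#' are zero in the populations studied but are estimated, so the fitted
#' model is saturated.
#'
#' @param a Path from predictor to first mediator.
#' @param b1 Path from first to second mediator.
#' @param b2 Path from second mediator to outcome.
#' @param c_prime Direct path from predictor to outcome.
#' @param d_xm2 Path from predictor to second mediator (population 0).
#' @param d_m1y Path from first mediator to outcome (population 0).
#' @param var_x,var_em1,var_em2,var_ey Variances (>= 0).
#' @param i_m1,i_m2,i_y Intercepts.
#' @param mean_x Predictor mean.
#'
#' @return An object of class `c("serial_params", "mediation_params")`.
#' @export
#' @examples
#' p <- serial_params(a = 0.6, b1 = sqrt(0.36), b2 = sqrt(0.36),
#'                    var_em1 = 0.64, var_em2 = 0.64, var_ey = 0.64)
#' indirect_unstandardized(p)
serial_params <- function(a, b1, b2, c_prime = 0, d_xm2 = 0, d_m1y = 0,
                          var_x = 1, var_em1 = 1, var_em2 = 1, var_ey = 1,
                          i_m1 = 0, i_m2 = 0, i_y = 0, mean_x = 0) {
  if (any(c(var_x, var_em1, var_em2, var_ey) < 0)) {
    stop("variances must be non-negative", call. = FALSE)
  }
  structure(
    list(a = a, b1 = b1, b2 = b2, c_prime = c_prime,
         d_xm2 = d_xm2, d_m1y = d_m1y,
         var_x = var_x, var_em1 = var_em1, var_em2 = var_em2, var_ey = var_ey,
         i_m1 = i_m1, i_m2 = i_m2, i_y = i_y, mean_x = mean_x),
    class = c("serial_params", "mediation_params")
  )
}

#' @export
print.mediation_params <- function(x, ...) {
  kind <- if (inherits(x, "simple_params")) "simple" else "serial"
  cat("<mediation_params:", kind, "model>\n")
  vals <- unlist(x)
  print(round(vals, 4))
  invisible(x)
}

# Path matrix A and error-variance diagonal Psi for the reduced form
# Sigma = (I - A)^-1 Psi (I - A)^-T, variables ordered x, m[, m2], y.
path_matrices <- function(params) {
  if (inherits(params, "simple_params")) {
    A <- matrix(0, 3, 3, dimnames = list(c("x", "m", "y"), c("x", "m", "y")))
    A["m", "x"] <- params$a
    A["y", "m"] <- params$b
    A["y", "x"] <- params$c_prime
    psi <- c(params$var_x, params$var_em, params$var_ey)
  } else if (inherits(params, "serial_params")) {
    nm <- c("x", "m1", "m2", "y")
    A <- matrix(0, 4, 4, dimnames = list(nm, nm))
    A["m1", "x"] <- params$a
    A["m2", "m1"] <- params$b1
    A["m2", "x"] <- params$d_xm2
    A["y", "m2"] <- params$b2
    A["y", "m1"] <- params$d_m1y
    A["y", "x"] <- params$c_prime
    psi <- c(params$var_x, params$var_em1, params$var_em2, params$var_ey)
  } else {
    stop("not a mediation_params object", call. = FALSE)
  }
  list(A = A, psi = psi)
}

#' Model-implied covariance matrix of the observed variables
#'
#' Solves the recursive structural system to its reduced form and returns
#' the covariance matrix implied by the path coefficients and (error)
#' variances: `Sigma = (I - A)^-1 Psi (I - A)^-T`. For the simple model this
#' gives, e.g., `Var(y) = b^2 var_em + var_ey + var_x (a b + c')^2`.
#'
#' @param params A [simple_params()] or [serial_params()] object.
#' @return A symmetric covariance matrix with dimnames `x, m, y` (simple)
#'   or `x, m1, m2, y` (serial).
#' @export
#' @examples
#' implied_covariance(simple_params(a = 0.6, b = 0.6, c_prime = 0.4,
#'                                  var_em = 0.64, var_ey = 0.192))
implied_covariance <- function(params) {
  pm <- path_matrices(params)
  p <- nrow(pm$A)
  inv <- solve(diag(p) - pm$A)
  sigma <- inv %*% diag(pm$psi, p) %*% t(inv)
  dimnames(sigma) <- dimnames(pm$A)
  (sigma + t(sigma)) / 2
}

#' Model-implied means of the observed variables
#'
#' @param params A [simple_params()] or [serial_params()] object.
#' @return Named vector of implied means.
#' @export
implied_means <- function(params) {
  pm <- path_matrices(params)
  p <- nrow(pm$A)
  nu <- if (inherits(params, "simple_params")) {
    c(params$mean_x, params$i_m, params$i_y)
  } else {
    c(params$mean_x, params$i_m1, params$i_m2, params$i_y)
  }
  mu <- drop(solve(diag(p) - pm$A, nu))
  names(mu) <- rownames(pm$A)
  mu
}
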