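#' Fit the mediation regressions by ordinary least squares
#'
#' Fits every regression of the (saturated) mediation path model by OLS:
#' `m ~ x` and `y ~ m + x` for the simple model; `m1 ~ x`, `m2 ~ m1 + x` and
#' `y ~ m1 + m2 + x` for the serial model. Standardized coefficients are
#' obtained by scaling the unstandardized ones with sample standard
#' deviations (denominator n - 1), which is identical to refitting z-scored
#' data in exact arithmetic.
#'
#' @param data A data frame with columns `x, m, y` (simple) or
#'   `x, m1, m2, y` (serial).
#' @param model `"simple"`, `"serial"`, or `NULL` to infer from the columns.
#' @return An object of class `med_ols` with components
#'   \describe{
#'     \item{coefficients}{tibble with one row per path: `equation`, `term`,
#'       `estimate`, `std.error`, `std.estimate`.}
#'     \item{paths}{named list of the structural path estimates and SEs.}
#'     \item{sds}{sample standard deviations of all variables.}
#'     \item{sigma}{residual SDs of the regressions.}
#'     \item{n}{sample size.}
#'   }
#' @seealso [generics::tidy()], [generics::glance()], [indirect_estimates()]
#' @export
#' @examples
#' d <- generate_dataset(mediation_condition(n = 100, a = 0.6, b = 0.6), seed = 1)
#' fit <- ols_fit(d)
#' tidy(fit)
ols_fit <- function(data, model = NULL) {
  model <- infer_model(data, model)
  vars <- model_vars(model)
  data <- as.data.frame(data)[vars]
  n <- nrow(data)
  eqs <- model_equations(model)
  max_k <- max(vapply(eqs, function(e) length(e$rhs), 1L))
  if (n <= max_k + 2L) {
    stop("sample too small for the mediation regressions", call. = FALSE)
  }
  sds <- vapply(data, stats::sd, 0)

  rows <- list()
  sigma <- numeric(0)
  for (eq in eqs) {
    fml <- stats::reformulate(eq$rhs, response = eq$lhs)
    fit <- stats::lm(fml, data = data)
    if (fit$rank < length(eq$rhs) + 1L) {
      stop("rank-deficient design in regression ", deparse(fml), call. = FALSE)
    }
    sm <- summary(fit)
    co <- sm$coefficients
    terms <- setdiff(rownames(co), "(Intercept)")
    rows[[eq$lhs]] <- tibble::tibble(
      equation = eq$lhs,
      term = c("(Intercept)", terms),
      estimate = unname(co[c("(Intercept)", terms), 1]),
      std.error = unname(co[c("(Intercept)", terms), 2]),
      std.estimate = unname(c(NA_real_,
                              co[terms, 1] * sds[terms] / sds[eq$lhs]))
    )
    sigma[eq$lhs] <- sm$sigma
  }
  coefs <- dplyr::bind_rows(rows)

  path_of <- function(equation, term) {
    i <- which(coefs$equation == equation & coefs$term == term)
    list(estimate = coefs$estimate[i], se = coefs$std.error[i],
         std = coefs$std.estimate[i])
  }
  paths <- if (model == "simple") {
    list(a = path_of("m", "x"), b = path_of("y", "m"),
         c_prime = path_of("y", "x"))
  } else {
    list(a = path_of("m1", "x"), b1 = path_of("m2", "m1"),
         b2 = path_of("y", "m2"), c_prime = path_of("y", "x"),
         d_xm2 = path_of("m2", "x"), d_m1y = path_of("y", "m1"))
  }

  structure(
    list(model = model, n = n, coefficients = coefs, paths = paths,
         sds = sds, sigma = sigma),
    class = "med_ols"
  )
}

#' Indirect-effect point estimates from an OLS fit
#'
#' @param fit A [ols_fit()] result.
#' @return A tibble with columns `effect_type` and `estimate`: the
#'   unstandardized product of paths and its completely standardized
#'   counterpart (`* sd_x / sd_y`).
#' @export
indirect_estimates <- function(fit) {
  stopifnot(inherits(fit, "med_ols"))
  unstd <- if (fit$model == "simple") {
    fit$paths$a$estimate * fit$paths$b$estimate
  } else {
    fit$paths$a$estimate * fit$paths$b1$estimate * fit$paths$b2$estimate
  }
  tibble::tibble(
    effect_type = c("unstandardized", "standardized"),
    estimate = c(unstd, standardize_by_sds(unstd, fit$sds[["x"]],
                                           fit$sds[["y"]]))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.med_ols <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.med_ols <- function(x, ...) {
  eff <- indirect_estimates(x)
  tibble::tibble(
    model = x$model, n = x$n,
    indirect = eff$estimate[eff$effect_type == "unstandardized"],
    indirect.std = eff$estimate[eff$effect_type == "standardized"]
  )
}

#' @export
print.med_ols <- function(x, ...) {
  cat("<med_ols> ", x$model, " mediation model, n = ", x$n, "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

infer_model <- function(data, model = NULL) {
  if (!is.null(model)) {
    return(match.arg(model, c("simple", "serial")))
  }
  nm <- names(data)
  if (all(c("x", "m", "y") %in% nm)) return("simple")
  if (all(c("x", "m1", "m2", "y") %in% nm)) return("serial")
  stop("cannot infer model: need columns x,m,y or x,m1,m2,y", call. = FALSE)
}

model_vars <- function(model) {
  if (model == "simple") c("x", "m", "y") else c("x", "m1", "m2", "y")
}

model_equations <- function(model) {
  if (model == "simple") {
    list(list(lhs = "m", rhs = "x"),
         list(lhs = "y", rhs = c("m", "x")))
  } else {
    list(list(lhs = "m1", rhs = "x"),
         list(lhs = "m2", rhs = c("m1", "x")),
         list(lhs = "y", rhs = c("m1", "m2", "x")))
  }
}
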