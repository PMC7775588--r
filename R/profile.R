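#' Generic profile (likelihood-ratio inversion) bound search
#'
#' Finds the lower and upper limits of a derived parameter `g(theta)` over
#' the region where the discrepancy function rises by at most
#' `qchisq(level, 1)` above its minimum: the set of values of `g` not
#' rejected by a 1-df likelihood-ratio (or ADF chi-square) test. For a
#' candidate value `c`, the profiled discrepancy `P(c) = min { D(theta) :
#' g(theta) = c }` is computed by an augmented-Lagrangian inner
#' minimization (BFGS, warm-started across candidates); the limit solves
#' `P(c) = D(theta_hat) + qchisq(level, 1)` by bracket expansion and root
#' finding, so each endpoint satisfies the constraint with equality.
#'
#' @param fn Discrepancy function of the free-parameter vector (e.g. -2lnL
#'   or the scaled ADF statistic).
#' @param gr Gradient of `fn` (analytic or numeric).
#' @param g Derived-parameter function of the free-parameter vector.
#' @param theta_hat Unconstrained optimum of `fn`.
#' @param level Confidence level in (0, 1); 0.95 by default.
#' @param scale Optional step scale for the bound search; by default the
#'   delta-method SE of `g` from the numeric Hessian of `fn`.
#' @param restarts Perturbed restarts of a failed inner minimization
#'   before a bound is declared failed (default 5).
#' @return A list with `lower`, `upper`, `estimate`, and `status`
#'   (`"converged"`, `"failed-lower"`, `"failed-upper"`, or `"degenerate"`
#'   for a locally constant `g`). A failed side carries the best feasible
#'   value found.
#' @export
profile_search <- function(fn, gr, g, theta_hat, level = 0.95, scale = NULL,
                           restarts = 5) {
  crit <- stats::qchisq(level, df = 1)
  d_hat <- fn(theta_hat)
  g_hat <- g(theta_hat)
  k <- length(theta_hat)

  g_grad <- function(th) {
    h <- 1e-6
    out <- numeric(k)
    for (i in seq_len(k)) {
      up <- th; up[i] <- up[i] + h
      dn <- th; dn[i] <- dn[i] - h
      out[i] <- (g(up) - g(dn)) / (2 * h)
    }
    out
  }

  gg_hat <- g_grad(theta_hat)
  if (sqrt(sum(gg_hat^2)) < 1e-10) {
    # derived parameter locally constant: the constraint set is irrelevant
    return(list(lower = g_hat, upper = g_hat, estimate = g_hat,
                status = "degenerate"))
  }

  if (is.null(scale)) {
    hess <- numeric_hessian(gr, theta_hat)
    se <- tryCatch(
      sqrt(drop(gg_hat %*% (2 * solve(hess)) %*% gg_hat)),
      error = function(e) NA_real_
    )
    scale <- if (is.finite(se) && se > 0) se else max(abs(g_hat), 0.1) / 10
  }

  rho0 <- 50 / scale^2
  tol_c <- 1e-7 * max(1, scale)

  # profiled discrepancy at g = ctarget (augmented Lagrangian)
  prof <- function(ctarget, warm) {
    lam <- 0
    rho <- rho0
    th <- warm
    viol <- Inf
    for (outer in 1:12) {
      obj <- function(t) {
        v <- g(t) - ctarget
        fn(t) + lam * v + rho * v * v
      }
      obj_gr <- function(t) {
        v <- g(t) - ctarget
        gr(t) + (lam + 2 * rho * v) * g_grad(t)
      }
      opt <- tryCatch(
        stats::optim(th, obj, obj_gr, method = "BFGS",
                     control = list(maxit = 300, reltol = 1e-13)),
        error = function(e) NULL
      )
      if (is.null(opt) || !all(is.finite(opt$par))) {
        return(list(val = NA_real_, theta = warm, ok = FALSE))
      }
      th <- opt$par
      prev <- viol
      viol <- g(th) - ctarget
      if (abs(viol) < tol_c) break
      lam <- lam + 2 * rho * viol
      if (abs(viol) > 0.5 * abs(prev)) rho <- rho * 5
    }
    list(val = fn(th), theta = th, ok = abs(viol) < 100 * tol_c)
  }

  one_side <- function(dir) {
    target <- d_hat + crit
    warm <- theta_hat
    step <- scale
    c_in <- g_hat
    c_out <- NA_real_
    tried <- 0
    for (i in 1:60) {
      c_try <- g_hat + dir * step
      sol <- prof(c_try, warm)
      if (!sol$ok) {
        tried <- tried + 1
        if (tried > restarts) break
        # deterministic restart: step about one SE along the gradient of g
        warm <- theta_hat + tried * dir * scale * gg_hat / sum(gg_hat^2)
        next
      }
      warm <- sol$theta
      if (sol$val >= target) {
        c_out <- c_try
        break
      }
      c_in <- c_try
      step <- step * 1.6
    }
    if (!is.finite(c_out)) {
      return(list(value = c_in, ok = FALSE))
    }
    f <- function(cc) {
      sol <- prof(cc, warm)
      if (sol$ok) warm <<- sol$theta
      sol$val - target
    }
    root <- tryCatch(
      stats::uniroot(f, lower = min(c_in, c_out), upper = max(c_in, c_out),
                     tol = 2.5e-5 * scale),
      error = function(e) NULL
    )
    if (is.null(root)) list(value = c_in, ok = FALSE)
    else list(value = root$root, ok = TRUE)
  }

  lo <- one_side(-1)
  hi <- one_side(+1)
  status <- if (!lo$ok) "failed-lower" else if (!hi$ok) "failed-upper"
            else "converged"
  list(lower = lo$value, upper = hi$value, estimate = g_hat, status = status)
}

numeric_hessian <- function(gr, theta, h = 1e-5) {
  k <- length(theta)
  hess <- matrix(0, k, k)
  for (i in seq_len(k)) {
    up <- theta; up[i] <- up[i] + h
    dn <- theta; dn[i] <- dn[i] - h
    hess[i, ] <- (gr(up) - gr(dn)) / (2 * h)
  }
  (hess + t(hess)) / 2
}

#' Profile likelihood-based confidence interval for an indirect effect
#'
#' Inverts the 1-df chi-square test on the chosen discrepancy function:
#' the interval is the range of the indirect effect over all parameter
#' vectors whose discrepancy lies within `qchisq(level, 1)` (3.8415 at
#' 0.95) of the minimum. Engines: normal-theory maximum likelihood
#' (`"ml"`, method tag `lbci`), ADF/WLS (`"adf"`, tag `lbci-adf`), and ML
#' with the predictor variance fixed at its sample value (`"ml-fixed-x"`,
#' tag `lbci-fx`).
#'
#' For the unstandardized effect in the simple model under an ML engine the
#' profile has a closed block decomposition (the likelihood factors into
#' the x, m|x and y|m,x regressions), used as a fast path; the generic
#' search gives the same limits and is used everywhere else.
#'
#' @param data A data frame with the model's columns, a [compute_moments()]
#'   result, or a fitted `med_fit`.
#' @param model `"simple"`, `"serial"`, or `NULL` to infer.
#' @param engine `"ml"`, `"adf"`, or `"ml-fixed-x"`.
#' @param effect_type `"unstandardized"` or `"standardized"`.
#' @param level Confidence level (default 0.95).
#' @param fast Use the closed-form fast path when available (default TRUE).
#' @return A one-row tibble (class `indirect_ci`) with `method`,
#'   `effect_type`, `estimate`, `lower`, `upper`, `level`, `status`.
#' @export
#' @examples
#' d <- generate_dataset(mediation_condition(n = 100, a = 0.6, b = 0.6), seed = 3)
#' profile_ci(d, engine = "ml", effect_type = "unstandardized")
profile_ci <- function(data, model = NULL,
                       engine = c("ml", "adf", "ml-fixed-x"),
                       effect_type = c("unstandardized", "standardized"),
                       level = 0.95, fast = TRUE) {
  engine <- match.arg(engine)
  effect_type <- match.arg(effect_type)
  fit <- if (inherits(data, "med_fit")) data
         else if (engine == "adf") adf_fit(data, model)
         else ml_fit(data, model, fixed_x = engine == "ml-fixed-x")
  model <- fit$model
  moments <- fit$moments
  method <- switch(engine, ml = "lbci", adf = "lbci-adf",
                   `ml-fixed-x` = "lbci-fx")
  if (inherits(data, "med_fit")) {
    engine <- switch(fit$estimator, ML = "ml", ADF = "adf",
                     `ML-fixed-X` = "ml-fixed-x")
    method <- switch(engine, ml = "lbci", adf = "lbci-adf",
                     `ml-fixed-x` = "lbci-fx")
  }

  if (fast && model == "simple" && effect_type == "unstandardized" &&
      engine %in% c("ml", "ml-fixed-x")) {
    res <- profile_ab_ml_simple(moments, level)
  } else {
    g <- make_effect_fn(model, effect_type, moments, fit$fixed_x)
    res <- profile_search(fit$deviance$fn, fit$deviance$gr, g,
                          fit$theta, level = level)
  }

  interval_row(method = method, effect_type = effect_type,
               estimate = res$estimate, lower = res$lower,
               upper = res$upper, level = level, status = res$status)
}

# Closed-block ML profile of ab in the simple model. The -2lnL separates
# into the x block (free of ab), the m|x block (a only) and the y|m,x
# block (b only, with c' and the error variance profiled out), so the
# profile deviance is D(a, b) = n log(vem(a)/vem_hat) + n log(vey(b)/
# vey_hat) with both v's quadratics; the bound extremizes a*b over
# D(a, b) <= qchisq(level, 1) via a 1-D search in a with b solved in
# closed form.
profile_ab_ml_simple <- function(moments, level = 0.95) {
  s <- moments$cov_ml
  n <- moments$n
  q <- stats::qchisq(level, df = 1)
  cxx <- s["x", "x"]; cxm <- s["x", "m"]; cmm <- s["m", "m"]
  cxy <- s["x", "y"]; cmy <- s["m", "y"]; cyy <- s["y", "y"]

  # m | x block: vem(a) = cmm - 2a cxm + a^2 cxx
  a_hat <- cxm / cxx
  vem_hat <- cmm - cxm^2 / cxx
  # y | m,x block with c' profiled out: vey(b) = A b^2 + B b + C
  A <- cmm - cxm^2 / cxx
  B <- -2 * cmy + 2 * cxy * cxm / cxx
  C <- cyy - cxy^2 / cxx
  b_hat <- -B / (2 * A)
  vey_hat <- C - B^2 / (4 * A)
  if (vem_hat <= 0 || vey_hat <= 0 || A <= 0) {
    stop("degenerate sample covariance in profile fast path", call. = FALSE)
  }

  # a-range where the m-block alone fits the budget: vem(a) = vem_hat e^{q/n}
  tgt_m <- vem_hat * exp(q / n)
  disc_a <- sqrt(cxm^2 - cxx * (cmm - tgt_m))
  a_lo <- (cxm - disc_a) / cxx
  a_hi <- (cxm + disc_a) / cxx

  b_range <- function(a) {
    vem_a <- cmm - 2 * a * cxm + a^2 * cxx
    r <- q - n * log(vem_a / vem_hat)
    tgt_y <- vey_hat * exp(r / n)
    disc <- sqrt(max(B^2 - 4 * A * (C - tgt_y), 0))
    c((-B - disc) / (2 * A), (-B + disc) / (2 * A))
  }

  extremum <- function(sign) {
    f <- function(a) {
      br <- b_range(a)
      sign * max(sign * a * br)
    }
    grid <- seq(a_lo, a_hi, length.out = 201)
    vals <- vapply(grid, f, 0)
    i <- which.max(sign * vals)
    lo <- grid[max(i - 1, 1)]
    hi <- grid[min(i + 1, length(grid))]
    opt <- stats::optimize(f, c(lo, hi), maximum = sign > 0,
                           tol = 1e-10)
    if (sign > 0) opt$objective else opt$objective
  }

  list(lower = extremum(-1), upper = extremum(+1),
       estimate = a_hat * b_hat, status = "converged")
}

interval_row <- function(method, effect_type, estimate, lower, upper,
                         level, status, n_redraws = NA_integer_) {
  out <- tibble::tibble(
    method = method, effect_type = effect_type,
    estimate = estimate, lower = lower, upper = upper,
    level = level, status = status, n_redraws = n_redraws
  )
  class(out) <- c("indirect_ci", class(out))
  out
}
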