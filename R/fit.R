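# Free-parameter vector <-> mediation_params mapping used by the fitting
# engines and the profile search. Variances enter on the log scale so every
# theta is feasible. Means are always profiled out at their saturated
# optimum (the sample means), so theta covers the covariance structure only.

theta_names <- function(model, fixed_x = FALSE) {
  nm <- if (model == "simple") {
    c("a", "b", "c_prime", "lvx", "lvem", "lvey")
  } else {
    c("a", "b1", "d_xm2", "b2", "d_m1y", "c_prime",
      "lvx", "lvem1", "lvem2", "lvey")
  }
  if (fixed_x) setdiff(nm, "lvx") else nm
}

params_from_theta <- function(theta, model, moments, fixed_x = FALSE) {
  th <- as.list(theta)
  vx <- if (fixed_x) moments$cov_ml["x", "x"] else exp(th$lvx)
  mn <- moments$means
  if (model == "simple") {
    simple_params(
      a = th$a, b = th$b, c_prime = th$c_prime,
      var_x = vx, var_em = exp(th$lvem), var_ey = exp(th$lvey),
      i_m = mn[["m"]] - th$a * mn[["x"]],
      i_y = mn[["y"]] - th$b * mn[["m"]] - th$c_prime * mn[["x"]],
      mean_x = mn[["x"]]
    )
  } else {
    serial_params(
      a = th$a, b1 = th$b1, b2 = th$b2, c_prime = th$c_prime,
      d_xm2 = th$d_xm2, d_m1y = th$d_m1y,
      var_x = vx, var_em1 = exp(th$lvem1), var_em2 = exp(th$lvem2),
      var_ey = exp(th$lvey),
      i_m1 = mn[["m1"]] - th$a * mn[["x"]],
      i_m2 = mn[["m2"]] - th$b1 * mn[["m1"]] - th$d_xm2 * mn[["x"]],
      i_y = mn[["y"]] - th$b2 * mn[["m2"]] - th$d_m1y * mn[["m1"]] -
        th$c_prime * mn[["x"]],
      mean_x = mn[["x"]]
    )
  }
}

theta_from_params <- function(params, fixed_x = FALSE) {
  if (inherits(params, "simple_params")) {
    th <- c(a = params$a, b = params$b, c_prime = params$c_prime,
            lvx = log(params$var_x), lvem = log(params$var_em),
            lvey = log(params$var_ey))
  } else {
    th <- c(a = params$a, b1 = params$b1, d_xm2 = params$d_xm2,
            b2 = params$b2, d_m1y = params$d_m1y, c_prime = params$c_prime,
            lvx = log(params$var_x), lvem1 = log(params$var_em1),
            lvem2 = log(params$var_em2), lvey = log(params$var_ey))
  }
  if (fixed_x) th <- th[setdiff(names(th), "lvx")]
  th
}

# Regression blocks of the saturated model: each endogenous variable
# regressed on its structural predictors. The normal likelihood factors
# along these blocks, giving a separable -2lnL and analytic gradients.
ml_blocks <- function(model) {
  if (model == "simple") {
    list(
      list(resp = "x", preds = character(0), coefs = character(0), lv = "lvx"),
      list(resp = "m", preds = "x", coefs = "a", lv = "lvem"),
      list(resp = "y", preds = c("m", "x"), coefs = c("b", "c_prime"),
           lv = "lvey")
    )
  } else {
    list(
      list(resp = "x", preds = character(0), coefs = character(0), lv = "lvx"),
      list(resp = "m1", preds = "x", coefs = "a", lv = "lvem1"),
      list(resp = "m2", preds = c("m1", "x"), coefs = c("b1", "d_xm2"),
           lv = "lvem2"),
      list(resp = "y", preds = c("m1", "m2", "x"),
           coefs = c("d_m1y", "b2", "c_prime"), lv = "lvey")
    )
  }
}

# -2lnL (means profiled) and its analytic gradient w.r.t. theta. Blocks are
# precompiled to positional indices so the closures stay cheap inside the
# profile search's inner loops.
make_ml_deviance <- function(moments, model, fixed_x = FALSE) {
  s <- moments$cov_ml
  n <- moments$n
  p <- length(moments$vars)
  const <- n * p * log(2 * pi)
  nm <- theta_names(model, fixed_x)
  vx_fixed <- s["x", "x"]
  k <- length(nm)
  blocks <- lapply(ml_blocks(model), function(bl) {
    list(is_x = bl$resp == "x",
         ci = match(bl$coefs, nm),
         li = match(bl$lv, nm),
         cpp = s[bl$preds, bl$preds, drop = FALSE],
         cpr = s[bl$preds, bl$resp],
         crr = s[bl$resp, bl$resp])
  })

  fn <- function(theta) {
    val <- const
    for (bl in blocks) {
      if (bl$is_x) {
        v <- if (fixed_x) vx_fixed else exp(theta[bl$li])
        q <- vx_fixed
      } else {
        v <- exp(theta[bl$li])
        beta <- theta[bl$ci]
        q <- bl$crr - 2 * sum(beta * bl$cpr) + sum(beta * (bl$cpp %*% beta))
      }
      val <- val + n * (log(v) + q / v)
    }
    unname(val)
  }

  gr <- function(theta) {
    g <- numeric(k)
    for (bl in blocks) {
      if (bl$is_x) {
        if (!fixed_x) g[bl$li] <- n * (1 - vx_fixed / exp(theta[bl$li]))
      } else {
        v <- exp(theta[bl$li])
        beta <- theta[bl$ci]
        q <- bl$crr - 2 * sum(beta * bl$cpr) + sum(beta * (bl$cpp %*% beta))
        g[bl$ci] <- n * 2 * (drop(bl$cpp %*% beta) - bl$cpr) / v
        g[bl$li] <- n * (1 - q / v)
      }
    }
    names(g) <- nm
    g
  }

  list(fn = fn, gr = gr)
}

# Fast derived-effect function g(theta) for the profile search, avoiding
# construction of mediation_params objects in the inner loops.
make_effect_fn <- function(model, effect_type, moments, fixed_x = FALSE) {
  nm <- theta_names(model, fixed_x)
  i <- function(x) match(x, nm)
  vx_fixed <- moments$cov_ml["x", "x"]
  if (model == "simple") {
    ia <- i("a"); ib <- i("b"); ic <- i("c_prime")
    ivx <- i("lvx"); ivm <- i("lvem"); ivy <- i("lvey")
    if (effect_type == "unstandardized") {
      function(theta) theta[ia] * theta[ib]
    } else {
      function(theta) {
        vx <- if (fixed_x) vx_fixed else exp(theta[ivx])
        ab <- theta[ia] * theta[ib]
        vy <- theta[ib]^2 * exp(theta[ivm]) + exp(theta[ivy]) +
          vx * (ab + theta[ic])^2
        ab * sqrt(vx / vy)
      }
    }
  } else {
    ia <- i("a"); ib1 <- i("b1"); ib2 <- i("b2"); ic <- i("c_prime")
    idx <- i("d_xm2"); idm <- i("d_m1y")
    ivx <- i("lvx"); iv1 <- i("lvem1"); iv2 <- i("lvem2"); ivy <- i("lvey")
    if (effect_type == "unstandardized") {
      function(theta) theta[ia] * theta[ib1] * theta[ib2]
    } else {
      function(theta) {
        vx <- if (fixed_x) vx_fixed else exp(theta[ivx])
        a <- theta[ia]; b1 <- theta[ib1]; b2 <- theta[ib2]
        # reduced-form loadings of y on (x, e_m1, e_m2, e_y)
        t_x <- b2 * (b1 * a + theta[idx]) + theta[idm] * a + theta[ic]
        w1 <- b2 * b1 + theta[idm]
        vy <- t_x^2 * vx + w1^2 * exp(theta[iv1]) + b2^2 * exp(theta[iv2]) +
          exp(theta[ivy])
        a * b1 * b2 * sqrt(vx / vy)
      }
    }
  }
}

# Closed-form reduced-form loading matrix: each variable as a linear
# combination of (x, errors); Sigma = L diag(psi) L'.
sigma_vech_from_theta <- function(theta, model, moments, fixed_x = FALSE) {
  nm <- theta_names(model, fixed_x)
  th <- stats::setNames(as.numeric(theta), nm)
  vx <- if (fixed_x) moments$cov_ml["x", "x"] else exp(th[["lvx"]])
  if (model == "simple") {
    a <- th[["a"]]; b <- th[["b"]]; cp <- th[["c_prime"]]
    vem <- exp(th[["lvem"]]); vey <- exp(th[["lvey"]])
    tot <- a * b + cp
    # vech order (p = 3): xx, mx, yx, mm, ym, yy
    c(vx,
      a * vx,
      tot * vx,
      a^2 * vx + vem,
      a * tot * vx + b * vem,
      tot^2 * vx + b^2 * vem + vey)
  } else {
    a <- th[["a"]]; b1 <- th[["b1"]]; b2 <- th[["b2"]]
    dx <- th[["d_xm2"]]; dm <- th[["d_m1y"]]; cp <- th[["c_prime"]]
    psi <- c(vx, exp(th[["lvem1"]]), exp(th[["lvem2"]]), exp(th[["lvey"]]))
    l <- rbind(
      x  = c(1, 0, 0, 0),
      m1 = c(a, 1, 0, 0),
      m2 = c(b1 * a + dx, b1, 1, 0),
      y  = c(b2 * (b1 * a + dx) + dm * a + cp, b2 * b1 + dm, b2, 1)
    )
    vech(l %*% (psi * t(l)))
  }
}

# ADF discrepancy T = (n - 1) * (s - sigma(theta))' W^-1 (s - sigma(theta)),
# with numeric Jacobian of the implied vech for the gradient.
make_adf_deviance <- function(moments, model, fixed_x = FALSE) {
  s_vech <- vech(moments$cov_ml)
  w <- adf_weight_matrix(moments)
  ch <- tryCatch(chol(w), error = function(e) NULL)
  if (is.null(ch)) {
    stop("singular ADF weight matrix (sample size too small for the number ",
         "of covariance elements)", call. = FALSE)
  }
  w_inv <- chol2inv(ch)
  n1 <- moments$n - 1

  sig <- function(theta) sigma_vech_from_theta(theta, model, moments, fixed_x)

  fn <- function(theta) {
    r <- s_vech - sig(theta)
    unname(n1 * drop(r %*% w_inv %*% r))
  }

  gr <- function(theta) {
    k <- length(theta)
    r <- s_vech - sig(theta)
    jac <- matrix(0, length(r), k)
    h <- 1e-6
    for (i in seq_len(k)) {
      up <- theta; up[i] <- up[i] + h
      dn <- theta; dn[i] <- dn[i] - h
      jac[, i] <- (sig(up) - sig(dn)) / (2 * h)
    }
    drop(-2 * n1 * crossprod(jac, w_inv %*% r))
  }

  list(fn = fn, gr = gr, w_inv = w_inv)
}

# Saturated-model point estimates computed from the ML-divisor covariance
# (identical to OLS path estimates) as a named theta vector.
saturated_theta <- function(moments, model, fixed_x = FALSE) {
  s <- moments$cov_ml
  th <- stats::setNames(numeric(0), character(0))
  for (bl in ml_blocks(model)) {
    if (bl$resp == "x") {
      if (!fixed_x) th[["lvx"]] <- log(s["x", "x"])
    } else {
      cpp <- s[bl$preds, bl$preds, drop = FALSE]
      cpr <- s[bl$preds, bl$resp]
      beta <- drop(solve(cpp, cpr))
      th[bl$coefs] <- beta
      th[[bl$lv]] <- log(s[bl$resp, bl$resp] - sum(beta * cpr))
    }
  }
  th[theta_names(model, fixed_x)]
}

#' Fit the saturated mediation path model by maximum likelihood
#'
#' Estimates are started at the OLS-derived values (exact for the saturated
#' model) and polished by BFGS on the profiled -2 log-likelihood; means are
#' fitted at their saturated optimum. With `fixed_x = TRUE` the predictor
#' variance is held at the ML (divisor n) sample variance and removed from
#' the free parameters; for the saturated model this changes no other
#' estimate.
#'
#' @param moments A [compute_moments()] result, or a data frame (moments
#'   are computed on the fly).
#' @param model `"simple"`, `"serial"`, or `NULL` to use the moments' model.
#' @param fixed_x Treat the predictor as fixed (nonstochastic)?
#' @return A `med_fit` object: `params` (the estimates), `estimator`
#'   (`"ML"` or `"ML-fixed-X"`), `statistic` (the -2 log-likelihood at the
#'   optimum), `converged`, plus the internal deviance functions used for
#'   profiling.
#' @export
#' @examples
#' d <- generate_dataset(mediation_condition(n = 100, a = 0.6, b = 0.6), seed = 2)
#' fit <- ml_fit(compute_moments(d))
#' glance(fit)
ml_fit <- function(moments, model = NULL, fixed_x = FALSE) {
  if (is.data.frame(moments)) moments <- compute_moments(moments, model)
  model <- model %||% moments$model
  dev <- make_ml_deviance(moments, model, fixed_x)
  th0 <- saturated_theta(moments, model, fixed_x)
  opt <- stats::optim(th0, dev$fn, dev$gr, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  th <- stats::setNames(opt$par, names(th0))
  grad <- dev$gr(th)
  converged <- opt$convergence == 0 && max(abs(grad)) < 1e-4 * moments$n
  structure(
    list(params = params_from_theta(th, model, moments, fixed_x),
         theta = th, model = model, fixed_x = fixed_x,
         estimator = if (fixed_x) "ML-fixed-X" else "ML",
         statistic = dev$fn(th), statistic_type = "minus2loglik",
         converged = converged, moments = moments, deviance = dev),
    class = "med_fit"
  )
}

#' Fit the saturated mediation path model by ADF (WLS) estimation
#'
#' Minimizes the asymptotically distribution-free discrepancy
#' `F = (s - sigma(theta))' W^-1 (s - sigma(theta))` over the covariance
#' structure, where `W` is the fourth-moment weight matrix
#' ([adf_weight_matrix()]); means are fitted saturated and excluded. The
#' statistic reported (and profiled) is `(n - 1) * F`, which is 0 at the
#' just-identified optimum.
#'
#' @inheritParams ml_fit
#' @return A `med_fit` object with `estimator = "ADF"` and `statistic`
#'   equal to `(n - 1) * F` at the optimum.
#' @export
adf_fit <- function(moments, model = NULL, fixed_x = FALSE) {
  if (is.data.frame(moments)) moments <- compute_moments(moments, model)
  model <- model %||% moments$model
  dev <- make_adf_deviance(moments, model, fixed_x)
  th0 <- saturated_theta(moments, model, fixed_x)
  opt <- stats::optim(th0, dev$fn, dev$gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  th <- stats::setNames(opt$par, names(th0))
  # just-identified: the optimum reproduces s, so T should be ~ 0
  converged <- opt$convergence == 0 && dev$fn(th) < 1e-6
  structure(
    list(params = params_from_theta(th, model, moments, fixed_x),
         theta = th, model = model, fixed_x = fixed_x,
         estimator = "ADF",
         statistic = dev$fn(th), statistic_type = "adf_statistic",
         converged = converged, moments = moments, deviance = dev),
    class = "med_fit"
  )
}

#' @export
print.med_fit <- function(x, ...) {
  cat("<med_fit> ", x$model, " model, estimator ", x$estimator,
      ", statistic = ", signif(x$statistic, 6),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.med_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta)) |>
    dplyr::mutate(
      estimate = ifelse(startsWith(.data$term, "lv"),
                        exp(.data$estimate), .data$estimate),
      term = sub("^lv", "var_", .data$term)
    )
}

#' @exportS3Method generics::glance
glance.med_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, estimator = x$estimator, n = x$moments$n,
    statistic = x$statistic, statistic_type = x$statistic_type,
    converged = x$converged,
    indirect = indirect_unstandardized(x$params),
    indirect.std = indirect_standardized(x$params)
  )
}
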