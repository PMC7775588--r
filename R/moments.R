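#' Sample moments of a mediation dataset
#'
#' Means, covariance matrices under both divisor conventions, and all
#' central fourth moments. The ML-divisor (n) covariance feeds the
#' normal-theory likelihood; the fourth moments feed the ADF weight matrix.
#'
#' @param data A data frame with the model's columns (`x, m, y` or
#'   `x, m1, m2, y`).
#' @param model `"simple"`, `"serial"`, or `NULL` to infer.
#' @return An object of class `sample_moments`: a list with `n`, `vars`,
#'   `means`, `cov_ml` (divisor n), `cov_unbiased` (divisor n - 1), and
#'   `m4`, the p x p x p x p array of central fourth moments (divisor n),
#'   symmetric under all index permutations.
#' @export
#' @examples
#' d <- generate_dataset(mediation_condition(n = 200, a = 0.6, b = 0.6), seed = 1)
#' mom <- compute_moments(d)
#' mom$cov_ml
compute_moments <- function(data, model = NULL) {
  model <- infer_model(data, model)
  vars <- model_vars(model)
  z <- as.matrix(as.data.frame(data)[vars])
  n <- nrow(z)
  p <- ncol(z)
  if (n <= p) stop("need more cases than variables", call. = FALSE)
  means <- colMeans(z)
  zc <- sweep(z, 2, means)
  cov_ml <- crossprod(zc) / n
  m4 <- array(0, dim = rep(p, 4), dimnames = rep(list(vars), 4))
  for (i in seq_len(p)) for (j in i:p) {
    zij <- zc[, i] * zc[, j]
    for (k in j:p) for (l in k:p) {
      v <- sum(zij * zc[, k] * zc[, l]) / n
      for (perm in perms4(c(i, j, k, l))) {
        m4[perm[1], perm[2], perm[3], perm[4]] <- v
      }
    }
  }
  structure(
    list(n = n, model = model, vars = vars, means = means,
         cov_ml = cov_ml, cov_unbiased = cov_ml * n / (n - 1), m4 = m4),
    class = "sample_moments"
  )
}

# All permutations of a length-4 index vector (as a list of vectors).
perms4 <- function(idx) {
  ords <- perm4_orders
  lapply(seq_len(nrow(ords)), function(r) idx[ords[r, ]])
}

perm4_orders <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
perm4_orders <- perm4_orders[apply(perm4_orders, 1, function(r)
  length(unique(r)) == 4L), , drop = FALSE]

#' Multivariate-normal -2 log-likelihood from sample moments
#'
#' Evaluates the full-information normal -2 log-likelihood of the
#' model-implied mean and covariance structure against the data, which is
#' computable from the sample moments alone:
#' `n * (p*log(2*pi) + log|Sigma| + tr(Sigma^-1 S_ml) + (xbar - mu)' Sigma^-1 (xbar - mu))`.
#' At the saturated optimum (implied = sample moments) this reduces to
#' `n * (p*log(2*pi) + log|S_ml| + p)`.
#'
#' @param params A [simple_params()] or [serial_params()] object.
#' @param moments A [compute_moments()] result.
#' @return The -2 log-likelihood (a single number).
#' @export
minus_two_loglik <- function(params, moments) {
  sigma <- implied_covariance(params)
  mu <- implied_means(params)
  p <- length(mu)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    stop("implied covariance is not positive definite", call. = FALSE)
  }
  logdet <- 2 * sum(log(diag(ch)))
  sigma_inv <- chol2inv(ch)
  dm <- moments$means - mu
  moments$n * (p * log(2 * pi) + logdet +
                 sum(sigma_inv * moments$cov_ml) +
                 drop(dm %*% sigma_inv %*% dm))
}

# vech indexing: pairs (i, j) with i <= j, matching lower-triangle order.
vech_pairs <- function(p) {
  out <- NULL
  for (j in seq_len(p)) for (i in j:p) out <- rbind(out, c(i, j))
  out
}

vech <- function(mat) mat[lower.tri(mat, diag = TRUE)]

#' ADF (fourth-moment) weight matrix of the sample covariances
#'
#' The asymptotic covariance matrix of the half-vectorized sample
#' covariances estimated without normality assumptions:
#' `W[(ij),(kl)] = m4[ijkl] - s_ij * s_kl` (biased central moments,
#' divisor n). Under normality `W[(ij),(kl)]` converges to
#' `s_ik s_jl + s_il s_jk`, which serves as a sanity oracle in tests.
#'
#' @param moments A [compute_moments()] result.
#' @return A `p(p+1)/2` square symmetric matrix in vech order.
#' @export
adf_weight_matrix <- function(moments) {
  s <- moments$cov_ml
  pr <- vech_pairs(ncol(s))
  q <- nrow(pr)
  w <- matrix(0, q, q)
  for (r in seq_len(q)) for (c in r:q) {
    i <- pr[r, 1]; j <- pr[r, 2]; k <- pr[c, 1]; l <- pr[c, 2]
    w[r, c] <- w[c, r] <- moments$m4[i, j, k, l] - s[i, j] * s[k, l]
  }
  w
}
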