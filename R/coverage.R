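#' Classify a coverage probability against the tolerable range
#'
#' The nominal coverage of a 95% interval is 0.95; estimated coverage in
#' the closed interval \[0.935, 0.965\] is classified as robust
#' (`"within"`), smaller values as `"below"` (interval too narrow), larger
#' as `"above"` (too wide).
#'
#' @param coverage Vector of proportions in \[0, 1\].
#' @param lower,upper Tolerable-range bounds (defaults 0.935 and 0.965).
#' @return Character vector: `"below"`, `"within"`, or `"above"`.
#' @export
#' @examples
#' classify_coverage(c(0.95, 0.90, 1.0))
classify_coverage <- function(coverage, lower = 0.935, upper = 0.965) {
  stopifnot(all(coverage >= 0 & coverage <= 1, na.rm = TRUE))
  dplyr::case_when(
    coverage < lower ~ "below",
    coverage > upper ~ "above",
    TRUE ~ "within"
  )
}

normalize_methods <- function(methods) {
  builtin <- c("boot", "lbci", "lbci-adf", "lbci-fx", "mc")
  if (is.character(methods)) {
    stopifnot(all(methods %in% builtin))
    methods <- stats::setNames(as.list(methods), methods)
  }
  stopifnot(is.list(methods), !is.null(names(methods)),
            all(nzchar(names(methods))))
  methods
}

# One replication: every requested interval for every effect type.
# Returns a tibble of rows (method, effect_type, lower, upper, status).
replicate_intervals <- function(data, methods, effect_types, level,
                                seeds, B, mc_draws) {
  out <- vector("list", length(methods) * length(effect_types))
  i <- 0L
  moments <- NULL
  need_moments <- any(vapply(seq_along(methods), function(k) {
    !is.function(methods[[k]]) &&
      methods[[k]] %in% c("lbci", "lbci-adf", "lbci-fx")
  }, TRUE))
  if (need_moments) moments <- compute_moments(data)

  for (k in seq_along(methods)) {
    meth <- methods[[k]]
    tag <- names(methods)[k]
    if (is.function(meth)) {
      for (et in effect_types) {
        i <- i + 1L
        res <- meth(data, effect_type = et, level = level, seed = seeds[k])
        out[[i]] <- tibble::tibble(
          method = tag, effect_type = et,
          lower = res$lower, upper = res$upper,
          status = res$status %||% "converged"
        )
      }
      next
    }
    rows <- switch(meth,
      boot = {
        draws <- boot_indirect_draws(data, B = B, seed = seeds[k])
        alpha <- (1 - level) / 2
        purrr::map(effect_types, function(et) {
          v <- if (et == "unstandardized") draws$unstd else draws$std
          qs <- stats::quantile(v, c(alpha, 1 - alpha), names = FALSE,
                                type = 7)
          tibble::tibble(method = "boot", effect_type = et,
                         lower = qs[1], upper = qs[2],
                         status = if (qs[1] == qs[2]) "degenerate"
                                  else "converged")
        })
      },
      mc = {
        fit <- ols_fit(data)
        purrr::map(effect_types, function(et) {
          ci <- monte_carlo_ci(fit, et, n_draws = mc_draws, level = level,
                               seed = seeds[k])
          ci[c("method", "effect_type", "lower", "upper", "status")]
        })
      },
      {
        engine <- switch(meth, lbci = "ml", `lbci-adf` = "adf",
                         `lbci-fx` = "ml-fixed-x")
        fit <- tryCatch(
          if (engine == "adf") adf_fit(moments)
          else ml_fit(moments, fixed_x = engine == "ml-fixed-x"),
          error = function(e) NULL
        )
        purrr::map(effect_types, function(et) {
          if (is.null(fit)) {
            return(tibble::tibble(method = meth, effect_type = et,
                                  lower = NA_real_, upper = NA_real_,
                                  status = "failed-lower"))
          }
          ci <- tryCatch(
            profile_ci(fit, effect_type = et, level = level),
            error = function(e) NULL
          )
          if (is.null(ci)) {
            tibble::tibble(method = meth, effect_type = et,
                           lower = NA_real_, upper = NA_real_,
                           status = "failed-lower")
          } else {
            ci[c("method", "effect_type", "lower", "upper", "status")]
          }
        })
      }
    )
    for (r in rows) {
      i <- i + 1L
      out[[i]] <- r
    }
  }
  dplyr::bind_rows(out)
}

#' Estimate coverage probabilities for one simulation condition
#'
#' Replicates the condition `n_reps` times: each replication generates a
#' dataset, forms every requested interval for the requested effect types,
#' and tests whether the closed interval contains the true (rescaled)
#' population effect. Replications whose bound search failed are excluded
#' from that method's denominator and counted. The whole run is
#' reproducible given `master_seed`; data generation and each procedure's
#' internal randomness use independently derived sub-seeds.
#'
#' @param condition A one-row condition (see [mediation_condition()] /
#'   [build_condition_grid()]).
#' @param methods Character vector of built-in method tags among
#'   `"boot", "lbci", "lbci-adf", "lbci-fx", "mc"`, or a named list that
#'   may also contain custom functions
#'   `function(data, effect_type, level, seed)` returning a list with
#'   `lower`, `upper` (and optionally `status`).
#' @param effect_types Effect scales to assess.
#' @param n_reps Number of replications (>= 1).
#' @param master_seed Integer seed for the whole condition run.
#' @param B Bootstrap resamples per replication (default 2000).
#' @param mc_draws Monte Carlo draws per replication (default 1000).
#' @param level Confidence level (default 0.95).
#' @return A tibble with one row per method x effect type: the condition
#'   cell, `n_reps`, `n_converged`, `coverage`, `classification`
#'   (see [classify_coverage()]) and `mean_width`.
#' @export
#' @examples
#' cnd <- mediation_condition(n = 50, a = 0.6, b = 0.6)
#' run_condition(cnd, methods = "mc", n_reps = 20, master_seed = 1)
run_condition <- function(condition,
                          methods = c("boot", "lbci", "lbci-adf",
                                      "lbci-fx", "mc"),
                          effect_types = c("unstandardized", "standardized"),
                          n_reps = 1000, master_seed = 1, B = 2000,
                          mc_draws = 1000, level = 0.95) {
  stopifnot(n_reps >= 1)
  methods <- normalize_methods(methods)
  condition <- tibble::as_tibble(as.list(condition))
  population_params(condition)  # propagate infeasibility before any work
  truth <- c(unstandardized = condition$true_unstd,
             standardized = condition$true_std)

  set.seed(master_seed)
  n_m <- length(methods)
  seed_mat <- matrix(sample.int(2^31 - 2, n_reps * (n_m + 1)), n_reps)

  per_rep <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    data <- generate_dataset(condition, seed = seed_mat[r, 1])
    rows <- replicate_intervals(data, methods, effect_types, level,
                                seeds = seed_mat[r, -1], B = B,
                                mc_draws = mc_draws)
    rows$rep <- r
    per_rep[[r]] <- rows
  }
  all_rows <- dplyr::bind_rows(per_rep)
  all_rows$true_value <- truth[all_rows$effect_type]
  # infinite bounds are legitimate (an uninformative side); only NA fails
  all_rows$converged <- all_rows$status %in% c("converged", "degenerate") &
    !is.na(all_rows$lower) & !is.na(all_rows$upper)
  all_rows$contains <- all_rows$converged &
    all_rows$lower <= all_rows$true_value &
    all_rows$true_value <= all_rows$upper

  agg <- all_rows |>
    dplyr::group_by(.data$method, .data$effect_type) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      n_converged = sum(.data$converged),
      coverage = sum(.data$contains) / sum(.data$converged),
      mean_width = mean((.data$upper - .data$lower)[.data$converged]),
      .groups = "drop"
    ) |>
    dplyr::mutate(classification = classify_coverage(.data$coverage))

  out <- dplyr::bind_cols(
    condition[rep(1, nrow(agg)),
              c("model", "n", "a", "b", "r2_increase", "c_prime",
                "distribution")],
    agg
  )
  class(out) <- c("coverage_result", class(out))
  out
}

#' Run the coverage study over a grid of conditions
#'
#' @param conditions A tibble of conditions (e.g. [build_condition_grid()]).
#' @param master_seed Seed for the study; each condition receives an
#'   independently derived sub-seed, so results do not depend on the order
#'   in which conditions are processed.
#' @inheritParams run_condition
#' @return Row-bound [run_condition()] results for every condition.
#' @export
run_study <- function(conditions, methods = c("boot", "lbci", "lbci-adf",
                                              "lbci-fx", "mc"),
                      effect_types = c("unstandardized", "standardized"),
                      n_reps = 1000, master_seed = 1, B = 2000,
                      mc_draws = 1000, level = 0.95) {
  set.seed(master_seed)
  cond_seeds <- sample.int(2^31 - 2, nrow(conditions))
  out <- purrr::map(seq_len(nrow(conditions)), function(i) {
    run_condition(conditions[i, ], methods = methods,
                  effect_types = effect_types, n_reps = n_reps,
                  master_seed = cond_seeds[i], B = B, mc_draws = mc_draws,
                  level = level)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("coverage_result", class(res))
  res
}

#' Tidy long-format summary of coverage results
#'
#' @param results [run_condition()] / [run_study()] output (rows may be
#'   bound across conditions); an empty input yields an empty table with
#'   the full column set.
#' @return A tibble keyed by model, distribution, n, a, b, r2_increase,
#'   method and effect_type, with `coverage`, `classification`,
#'   `n_converged` and `mean_width`, sorted by key.
#' @export
summarize_coverage <- function(results) {
  cols <- c("model", "distribution", "n", "a", "b", "r2_increase",
            "method", "effect_type", "n_reps", "n_converged", "coverage",
            "classification", "mean_width")
  if (is.null(results) || nrow(results) == 0) {
    out <- tibble::as_tibble(stats::setNames(
      c(rep(list(character(0)), 2), rep(list(numeric(0)), 4),
        rep(list(character(0)), 2), rep(list(numeric(0)), 3),
        list(character(0)), list(numeric(0))),
      cols
    ))
  } else {
    out <- results |>
      dplyr::select(dplyr::all_of(cols)) |>
      dplyr::arrange(.data$model, .data$distribution, .data$n, .data$a,
                     .data$b, .data$r2_increase, .data$method,
                     .data$effect_type)
  }
  class(out) <- c("coverage_summary", class(out))
  out
}
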