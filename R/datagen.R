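#' Predictor distribution specification
#'
#' The five predictor distributions of the simulation design, with the
#' population constants used to standardize draws to mean 0 and SD 1:
#' normal (0, 1); exponential with rate 1 (mean 1, SD 1; skewness 2, excess
#' kurtosis 6); beta(1.5, 1.5) (mean 0.5, SD 0.25; excess kurtosis -1);
#' t with 5 df (SD sqrt(5/3); excess kurtosis 6); t with 6 df
#' (SD sqrt(6/4); excess kurtosis 3).
#'
#' @param family One of `"normal"`, `"exponential"`, `"beta"`, `"t5"`, `"t6"`.
#' @return A list with `family`, the standardizing constants `mean` and `sd`,
#'   and the population `skewness` and excess `kurtosis` of the standardized
#'   variable.
#' @export
#' @examples
#' predictor_spec("exponential")
predictor_spec <- function(family = c("normal", "exponential", "beta",
                                      "t5", "t6")) {
  family <- match.arg(family)
  consts <- switch(family,
    normal      = list(mean = 0,   sd = 1,           skewness = 0, kurtosis = 0),
    exponential = list(mean = 1,   sd = 1,           skewness = 2, kurtosis = 6),
    beta        = list(mean = 0.5, sd = 0.25,        skewness = 0, kurtosis = -1),
    t5          = list(mean = 0,   sd = sqrt(5 / 3), skewness = 0, kurtosis = 6),
    t6          = list(mean = 0,   sd = sqrt(6 / 4), skewness = 0, kurtosis = 3)
  )
  c(list(family = family), consts)
}

#' Draw a standardized nonnormal predictor
#'
#' Draws n i.i.d. values from the requested family and rescales them by the
#' family's population mean and SD so the population mean and SD of the
#' output are 0 and 1 for every family.
#'
#' @param spec A [predictor_spec()] or a family name.
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A numeric vector of length `n`.
#' @export
#' @examples
#' z <- draw_standardized_predictor("beta", 1000, seed = 1)
#' c(mean(z), sd(z))
draw_standardized_predictor <- function(spec, n, seed = NULL) {
  if (is.character(spec)) spec <- predictor_spec(spec)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  raw <- switch(spec$family,
    normal      = stats::rnorm(n),
    exponential = stats::rexp(n, rate = 1),
    beta        = stats::rbeta(n, 1.5, 1.5),
    t5          = stats::rt(n, df = 5),
    t6          = stats::rt(n, df = 6),
    stop("unknown predictor family: ", spec$family, call. = FALSE)
  )
  (raw - spec$mean) / spec$sd
}

#' Direct effect implied by a target R-squared increase
#'
#' The direct path c' is chosen so that adding the predictor to the
#' outcome regression (after the mediator) increases the population
#' R-squared by `d`. On the standardized scale that increase is the squared
#' semipartial correlation `c'^2 (1 - a^2)`, so `c' = sqrt(d / (1 - a^2))`
#' (taken positive).
#'
#' @param d Target R-squared increase, in `[0, 1)`.
#' @param a Standardized path from predictor to (first) mediator, `|a| < 1`.
#' @return The direct path c'; 0 when `d = 0`. Vectorized.
#' @export
#' @examples
#' cprime_from_r2_increase(0.13, 0.600)  # 0.4507
cprime_from_r2_increase <- function(d, a) {
  stopifnot(all(d >= 0), all(d < 1), all(abs(a) < 1))
  sqrt(d / (1 - a^2))
}

#' Population parameters of a simulation condition (unit-variance scale)
#'
#' Error variances are chosen so that every variable has unit population
#' variance before rescaling: `var_em = 1 - a^2` and
#' `var_ey = 1 - b^2 - c'^2 - 2abc'` for the simple model; for the serial
#' model (with `b1 = b2 = sqrt(b)`), `var_em1 = 1 - a^2`, `var_em2 = 1 - b`
#' and `var_ey = 1 - b - c'^2 - 2abc'`.
#'
#' @param condition A condition row from [mediation_condition()] or
#'   [build_condition_grid()].
#' @return A [simple_params()] or [serial_params()] object; errors if any
#'   implied error variance is negative (infeasible condition).
#' @export
#' @examples
#' population_params(mediation_condition(n = 100, a = 0.6, b = 0.6,
#'                                       r2_increase = 0.13))
population_params <- function(condition) {
  cnd <- as.list(condition)
  a <- cnd$a
  b <- cnd$b
  cp <- cnd$c_prime %||% cprime_from_r2_increase(cnd$r2_increase %||% 0, a)
  if (identical(cnd$model %||% "simple", "simple")) {
    var_em <- 1 - a^2
    var_ey <- 1 - b^2 - cp^2 - 2 * a * b * cp
    if (var_em < 0 || var_ey < 0) {
      stop("infeasible condition: negative error variance", call. = FALSE)
    }
    simple_params(a = a, b = b, c_prime = cp,
                  var_x = 1, var_em = var_em, var_ey = var_ey)
  } else {
    if (b < 0) stop("serial model requires b >= 0 (b1 = b2 = sqrt(b))",
                    call. = FALSE)
    var_em1 <- 1 - a^2
    var_em2 <- 1 - b
    var_ey <- 1 - b - cp^2 - 2 * a * b * cp
    if (var_em1 < 0 || var_em2 < 0 || var_ey < 0) {
      stop("infeasible condition: negative error variance", call. = FALSE)
    }
    serial_params(a = a, b1 = sqrt(b), b2 = sqrt(b), c_prime = cp,
                  var_x = 1, var_em1 = var_em1, var_em2 = var_em2,
                  var_ey = var_ey)
  }
}

#' Rescaling targets for simulated data
#'
#' After generation on the standardized scale, variables are rescaled to
#' nonzero means and non-unit SDs (x, m, y to means 3, 5, 4 and SDs 4, 5, 3;
#' serial mediators m1 to mean 5, SD 5 and m2 to mean 2, SD 2) so that
#' unstandardized and standardized coefficients differ.
#'
#' @param model `"simple"` or `"serial"`.
#' @return A list with named vectors `means` and `sds`.
#' @export
rescale_targets <- function(model = c("simple", "serial")) {
  model <- match.arg(model)
  if (model == "simple") {
    list(means = c(x = 3, m = 5, y = 4), sds = c(x = 4, m = 5, y = 3))
  } else {
    list(means = c(x = 3, m1 = 5, m2 = 2, y = 4),
         sds = c(x = 4, m1 = 5, m2 = 2, y = 3))
  }
}

#' Define a single simulation condition
#'
#' @param model `"simple"` or `"serial"`.
#' @param n Sample size.
#' @param a,b Standardized population paths. For the serial model `b` is the
#'   product `b1 * b2`, with `b1 = b2 = sqrt(b)`.
#' @param r2_increase Population R-squared increase `d` due to the direct
#'   path; c' is derived via [cprime_from_r2_increase()].
#' @param distribution Predictor family (see [predictor_spec()]).
#' @return A one-row tibble with the condition cell plus the derived
#'   `c_prime` and true rescaled effects `true_unstd` and `true_std`.
#' @export
#' @examples
#' mediation_condition(n = 500, a = 0.6, b = 0.6)
mediation_condition <- function(model = "simple", n = 100, a = 0, b = 0,
                                r2_increase = 0, distribution = "normal") {
  model <- match.arg(model, c("simple", "serial"))
  cp <- cprime_from_r2_increase(r2_increase, a)
  tg <- rescale_targets(model)
  std_true <- a * b
  tibble::tibble(
    model = model, n = as.integer(n), a = a, b = b,
    r2_increase = r2_increase, c_prime = cp,
    distribution = distribution,
    true_std = std_true,
    true_unstd = std_true * tg$sds[["y"]] / tg$sds[["x"]]
  )
}

#' Generate a mediation dataset for one condition
#'
#' Variables are built structurally on the standardized scale — the
#' predictor from its (possibly nonnormal) family, each downstream variable
#' as its linear structural equation plus a conditionally normal error with
#' the unit-variance error SD from [population_params()] — and then affinely
#' rescaled to the targets in [rescale_targets()]. The predictor and each
#' error vector use independent sub-seeds derived from `seed`, so interval
#' procedures seeded separately never share a stream with data generation.
#'
#' @param condition A one-row condition (see [mediation_condition()]).
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @return A tibble with columns `x, m, y` (or `x, m1, m2, y`) of class
#'   `mediation_data`, carrying the condition and the true rescaled
#'   population effects as attributes (`attr(, "true_effects")`).
#' @export
#' @examples
#' d <- generate_dataset(mediation_condition(n = 50, a = 0.6, b = 0.6), seed = 7)
#' attr(d, "true_effects")
generate_dataset <- function(condition, seed = NULL) {
  cnd <- tibble::as_tibble(as.list(condition)[c(
    "model", "n", "a", "b", "r2_increase", "c_prime", "distribution",
    "true_std", "true_unstd"
  )])
  pars <- population_params(cnd)
  n <- cnd$n
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 4L)
  x <- draw_standardized_predictor(cnd$distribution, n, seed = sub_seeds[1])
  if (cnd$model == "simple") {
    set.seed(sub_seeds[2])
    m <- pars$a * x + stats::rnorm(n, sd = sqrt(pars$var_em))
    set.seed(sub_seeds[3])
    y <- pars$b * m + pars$c_prime * x + stats::rnorm(n, sd = sqrt(pars$var_ey))
    out <- tibble::tibble(x = x, m = m, y = y)
  } else {
    set.seed(sub_seeds[2])
    m1 <- pars$a * x + stats::rnorm(n, sd = sqrt(pars$var_em1))
    set.seed(sub_seeds[3])
    m2 <- pars$b1 * m1 + stats::rnorm(n, sd = sqrt(pars$var_em2))
    set.seed(sub_seeds[4])
    y <- pars$b2 * m2 + pars$c_prime * x + stats::rnorm(n, sd = sqrt(pars$var_ey))
    out <- tibble::tibble(x = x, m1 = m1, m2 = m2, y = y)
  }
  tg <- rescale_targets(cnd$model)
  for (v in names(out)) {
    out[[v]] <- tg$means[[v]] + tg$sds[[v]] * out[[v]]
  }
  attr(out, "condition") <- cnd
  attr(out, "true_effects") <- c(unstandardized = cnd$true_unstd,
                                 standardized = cnd$true_std)
  class(out) <- c("mediation_data", class(out))
  out
}

#' Default factor levels of the simulation design
#'
#' Sample sizes 50–500; eight (a, b) pairs covering nil, small, medium and
#' large standardized indirect effects (0, 0.141, 0.361, 0.510) including
#' the unequal-path pairs; R-squared increases 0, 0.02, 0.13, 0.26; five
#' predictor distributions.
#'
#' @return A named list of the default levels.
#' @export
study_defaults <- function() {
  list(
    models = c("simple", "serial"),
    ns = c(50L, 100L, 150L, 200L, 500L),
    ab_pairs = list(
      c(a = 0, b = 0),
      c(a = 0.376, b = 0.376),
      c(a = 0.600, b = 0.600),
      c(a = 0.714, b = 0.714),
      c(a = 0.1975, b = 0.714),
      c(a = 0.714, b = 0.1975),
      c(a = 0.5056, b = 0.714),
      c(a = 0.714, b = 0.5056)
    ),
    r2_increase = c(0, 0.02, 0.13, 0.26),
    distributions = c("normal", "exponential", "beta", "t5", "t6"),
    max_r2 = 0.80,
    reps = 1000L,
    boot_B = 2000L,
    mc_draws = 1000L,
    level = 0.95
  )
}

#' Build the full condition grid of the simulation study
#'
#' Cartesian product of model, sample size, (a, b) pair, R-squared increase
#' and predictor distribution, dropping cells whose implied population
#' R-squared for the outcome exceeds `max_r2` (0.80 by default) and cells
#' that are variance-infeasible (a negative implied error variance).
#'
#' @param config Optional list overriding entries of [study_defaults()]
#'   (e.g. from [read_study_config()]).
#' @return A tibble of retained conditions, one row per cell, with derived
#'   `c_prime`, true effects, and the implied outcome `r2`.
#' @export
#' @examples
#' grid <- build_condition_grid(list(models = "simple", ns = c(50, 500)))
#' nrow(grid)
build_condition_grid <- function(config = NULL) {
  cfg <- study_defaults()
  config <- config %||% list()
  cfg[names(config)] <- config  # shallow override: entries replace wholesale
  pairs <- dplyr::bind_rows(lapply(cfg$ab_pairs, function(p) {
    if (is.null(names(p))) p <- c(a = p[[1]], b = p[[2]])
    tibble::tibble(a = p[["a"]], b = p[["b"]])
  }))
  grid <- tidyr::expand_grid(
    model = cfg$models,
    n = as.integer(cfg$ns),
    pairs,
    r2_increase = cfg$r2_increase,
    distribution = cfg$distributions
  )
  rows <- purrr::pmap(grid, function(model, n, a, b, r2_increase, distribution) {
    cnd <- mediation_condition(model, n, a, b, r2_increase, distribution)
    pars <- tryCatch(population_params(cnd), error = function(e) NULL)
    if (is.null(pars)) return(NULL)
    cnd$r2 <- 1 - pars$var_ey  # unit-variance outcome: R^2 = 1 - error var
    if (cnd$r2 > cfg$max_r2) return(NULL)
    cnd
  })
  dplyr::bind_rows(rows)
}

#' Read a simulation study configuration file
#'
#' YAML or JSON with any of the entries of [study_defaults()] (`models`,
#' `ns`, `ab_pairs` as a list of two-element `[a, b]` vectors,
#' `r2_increase`, `distributions`, `max_r2`, `reps`, `boot_B`, `mc_draws`,
#' `level`).
#'
#' @param path File path (`.yaml`, `.yml`, or `.json`).
#' @return A config list suitable for [build_condition_grid()].
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$ab_pairs)) {
    cfg$ab_pairs <- lapply(seq_len(NROW(cfg$ab_pairs)), function(i) {
      p <- if (is.matrix(cfg$ab_pairs)) cfg$ab_pairs[i, ] else cfg$ab_pairs[[i]]
      c(a = as.numeric(p[[1]]), b = as.numeric(p[[2]]))
    })
  }
  cfg
}

`%||%` <- function(x, y) if (is.null(x)) y else x
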