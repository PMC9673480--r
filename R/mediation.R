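#' Specify a mediation analysis
#'
#' Defines the exposure (X), mediator (M), outcome (Y) triple, adjustment
#' covariates, the optional exposure-mediator interaction with its two fixed
#' exposure levels, and the Monte Carlo settings for the indirect-effect
#' confidence interval.
#'
#' @param exposure Exposure column (continuous, or a 0/1 indicator when
#'   dichotomised).
#' @param mediator,outcome Mediator and outcome columns (typically
#'   log-transformed hormone concentrations).
#' @param covariates Character vector of adjustment covariates.
#' @param exposure_mediator_interaction Include X-by-M interaction and report
#'   level-specific effects.
#' @param exposure_levels Numeric length-2 vector: the two exposure values at
#'   which level-specific effects are evaluated (reference first). Used only
#'   with the interaction.
#' @param n_draws Monte Carlo draws for the CI (>= 1000; default 20000).
#' @param ci_level Confidence level in (0, 1); default 0.95.
#' @param seed Integer seed for the Monte Carlo CI; required when the
#'   analysis is run.
#' @return An object of class `mediation_spec`.
#' @export
mediation_spec <- function(exposure, mediator, outcome, covariates = character(),
                           exposure_mediator_interaction = FALSE,
                           exposure_levels = c(0, 1),
                           n_draws = 20000, ci_level = 0.95, seed = NULL) {
  if (n_draws < 1000) stop("n_draws must be >= 1000", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)", call. = FALSE)
  structure(list(exposure = exposure, mediator = mediator, outcome = outcome,
                 covariates = covariates,
                 exposure_mediator_interaction = isTRUE(exposure_mediator_interaction),
                 exposure_levels = exposure_levels,
                 n_draws = as.integer(n_draws), ci_level = ci_level,
                 seed = seed),
            class = "mediation_spec")
}

#' Product-of-coefficients effect decomposition
#'
#' Given the mediator-model slope `a1`, the outcome-model mediator slope
#' `b1`, interaction `b3` and the total effect `c1`, the indirect effect at
#' exposure level `x` is `a1 * (b1 + b3 * x)`, the direct effect is
#' `c1 - indirect` (so direct + indirect = c1 identically), and the
#' proportion mediated is `100 * indirect / c1` (undefined when `c1 = 0`).
#'
#' @param a1,b1,b3,c1 Coefficients; `b3 = 0` when no interaction.
#' @param level_x Numeric vector of exposure levels to decompose at.
#' @return A tibble with one row per level: `level`, `indirect`, `direct`,
#'   `proportion_mediated` (percent).
#' @examples
#' decompose_effects(a1 = 0.5, b1 = 0.8, b3 = 0, c1 = 0.6, level_x = c(0, 1))
#' @export
decompose_effects <- function(a1, b1, b3 = 0, c1, level_x = 0) {
  indirect <- a1 * (b1 + b3 * level_x)
  direct <- c1 - indirect
  pm <- if (isTRUE(all.equal(c1, 0)) || c1 == 0) {
    rep(NA_real_, length(level_x))
  } else {
    100 * indirect / c1
  }
  tibble::tibble(level = level_x, indirect = indirect, direct = direct,
                 proportion_mediated = pm)
}

#' Monte Carlo confidence interval for the indirect effect
#'
#' Samples the mediator-model coefficient `a` from its normal sampling
#' distribution and the outcome-model coefficients `(b1, b3)` jointly from
#' theirs (the two models are fit separately, so the draws are independent
#' between models), forms the product `a * (b1 + b3 * x)` per draw, and
#' returns percentile interval endpoints.
#'
#' @param a_hat Mediator-model slope estimate.
#' @param vcov_a Its sampling variance (scalar or 1x1 matrix).
#' @param b_vec_hat Outcome-model coefficient estimate(s): `b1`, or
#'   `c(b1, b3)` with interaction.
#' @param vcov_b Covariance matrix of `b_vec_hat` (symmetric PSD).
#' @param level_x Exposure level at which the indirect effect is evaluated.
#' @param n_draws Number of draws (>= 1000).
#' @param ci_level Confidence level.
#' @param seed Integer seed.
#' @return A list: `lo`, `hi`, `p_cover_zero` (two-sided Monte Carlo
#'   p-value of the indirect effect against zero), `point` (plug-in
#'   product), `draws` (the sampled indirect effects).
#' @examples
#' monte_carlo_ci(0.5, 0.1^2, 0.8, matrix(0.1^2), n_draws = 5000, seed = 1)
#' @export
monte_carlo_ci <- function(a_hat, vcov_a, b_vec_hat, vcov_b, level_x = 0,
                           n_draws = 20000, ci_level = 0.95, seed) {
  if (n_draws < 1000) stop("n_draws must be >= 1000", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  va <- as.numeric(vcov_a)[1]
  Vb <- as.matrix(vcov_b)
  k <- length(b_vec_hat)
  if (!isTRUE(all.equal(Vb, t(Vb), tolerance = 1e-8))) {
    stop("vcov_b must be symmetric", call. = FALSE)
  }
  ev <- eigen(Vb, symmetric = TRUE, only.values = TRUE)$values
  if (va < 0 || any(ev < -1e-8 * max(abs(ev), 1))) {
    stop("covariance matrices must be positive semi-definite", call. = FALSE)
  }
  draws <- withr::with_seed(seed, {
    a_star <- rnorm(n_draws, a_hat, sqrt(max(va, 0)))
    b_star <- if (sum(abs(Vb)) == 0) {
      matrix(rep(b_vec_hat, each = n_draws), nrow = n_draws)
    } else {
      MASS::mvrnorm(n_draws, mu = b_vec_hat, Sigma = Vb, tol = 1e-6)
    }
    b_star <- matrix(b_star, nrow = n_draws)
    b3_star <- if (k >= 2) b_star[, 2] else 0
    a_star * (b_star[, 1] + b3_star * level_x)
  })
  alpha <- 1 - ci_level
  qs <- unname(quantile(draws, c(alpha / 2, 1 - alpha / 2)))
  b3_hat <- if (k >= 2) b_vec_hat[2] else 0
  list(lo = qs[1], hi = qs[2],
       p_cover_zero = 2 * min(mean(draws < 0), mean(draws > 0)),
       point = unname(a_hat * (b_vec_hat[1] + b3_hat * level_x)),
       draws = draws)
}

#' Run the four-step counterfactual mediation analysis
#'
#' Implements the stepwise procedure on one shared complete-case set (rows
#' complete for every variable used in any step):
#' \enumerate{
#'   \item total-effect model: `outcome ~ exposure + covariates` gives `c1`;
#'   \item mediator model: `mediator ~ exposure + covariates` gives `a1`;
#'   \item outcome model: `outcome ~ exposure + mediator
#'     (+ exposure:mediator) + covariates` gives `b1` (and `b3`);
#'   \item the indirect effect `a1 * (b1 + b3 * x)` per exposure level, with
#'     its Monte Carlo confidence interval.
#' }
#' All models carry the per-subject random intercept. The direct effect is
#' `c1 - indirect`, so the decomposition identity holds exactly. The
#' total-effect model is additionally refit on its own (larger)
#' complete-case set and reported as `c1_full` / `n_total_effect`, since
#' mediator missingness often shrinks the mediation sample.
#'
#' @param data Preprocessed visit table.
#' @param spec A [mediation_spec()]; `spec$seed` must be set (or pass
#'   `seed`).
#' @param grouping Subject identifier for the random intercept.
#' @param seed Overrides `spec$seed`.
#' @return An object of class `mediation_result`.
#' @export
run_mediation <- function(data, spec, grouping = "dyad_id", seed = NULL) {
  stopifnot(inherits(spec, "mediation_spec"))
  seed <- seed %||% spec$seed
  if (is.null(seed)) stop("a seed is required for the Monte Carlo CI", call. = FALSE)
  vars <- unique(c(spec$exposure, spec$mediator, spec$outcome,
                   spec$covariates, grouping))
  miss <- setdiff(vars, names(data))
  if (length(miss) > 0) {
    stop(sprintf("data is missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (spec$exposure_mediator_interaction &&
      length(spec$exposure_levels) != 2) {
    stop("exposure_mediator_interaction requires two exposure_levels",
         call. = FALSE)
  }
  x_num <- data[[spec$exposure]]
  if (!is.numeric(x_num)) {
    stop("exposure must be numeric (dichotomise to a 0/1 indicator first)",
         call. = FALSE)
  }

  # full-sample total-effect model (its own complete cases only)
  spec1 <- model_spec(spec$outcome, c(spec$exposure, spec$covariates),
                      grouping = grouping)
  fit1_full <- fit_lmm(data, spec1)

  # shared complete-case set across all steps
  shared <- data[complete.cases(data[vars]), , drop = FALSE]
  if (nrow(shared) == 0) stop("no complete cases across mediation steps", call. = FALSE)

  fit1 <- fit_lmm(shared, spec1)
  c1 <- unname(fit1$coef[spec$exposure])

  spec2 <- model_spec(spec$mediator, c(spec$exposure, spec$covariates),
                      grouping = grouping)
  fit2 <- fit_lmm(shared, spec2)
  a1 <- unname(fit2$coef[spec$exposure])
  var_a <- fit2$vcov[spec$exposure, spec$exposure]

  terms3 <- c(spec$exposure, spec$mediator, spec$covariates)
  inter3 <- if (spec$exposure_mediator_interaction) {
    list(c(spec$exposure, spec$mediator))
  } else {
    list()
  }
  spec3 <- model_spec(spec$outcome, terms3, interactions = inter3,
                      grouping = grouping)
  fit3 <- fit_lmm(shared, spec3)
  b1 <- unname(fit3$coef[spec$mediator])
  p_interaction <- NA_real_
  if (spec$exposure_mediator_interaction) {
    idx <- interaction_coef_idx(fit3, c(spec$exposure, spec$mediator))
    b3 <- unname(fit3$coef[idx])
    bsel <- c(spec$mediator, names(fit3$coef)[idx])
    p_interaction <- unname(fit3$p_value[idx])
  } else {
    b3 <- 0
    bsel <- spec$mediator
  }
  b_vec <- unname(fit3$coef[bsel])
  Vb <- fit3$vcov[bsel, bsel, drop = FALSE]

  levels_x <- if (spec$exposure_mediator_interaction) spec$exposure_levels else 0
  dec <- decompose_effects(a1, b1, b3, c1, levels_x)
  mc <- purrr::map(levels_x, function(x) {
    monte_carlo_ci(a1, var_a, b_vec, Vb, level_x = x,
                   n_draws = spec$n_draws, ci_level = spec$ci_level,
                   seed = seed)
  })
  dec$ci_lo <- vapply(mc, `[[`, numeric(1), "lo")
  dec$ci_hi <- vapply(mc, `[[`, numeric(1), "hi")
  dec$p_indirect <- vapply(mc, `[[`, numeric(1), "p_cover_zero")
  dec$indirect_significant <- dec$ci_lo > 0 | dec$ci_hi < 0

  structure(list(
    spec = spec,
    c1 = c1, a1 = a1, b1 = b1, b3 = b3,
    c1_se = unname(fit1$se[spec$exposure]),
    a1_se = unname(fit2$se[spec$exposure]),
    b1_se = unname(fit3$se[spec$mediator]),
    p_interaction = p_interaction,
    effects = dec,
    c1_full = unname(fit1_full$coef[spec$exposure]),
    c1_full_se = unname(fit1_full$se[spec$exposure]),
    p_c1_full = unname(fit1_full$p_value[spec$exposure]),
    n_complete = fit1$n_obs, n_total_effect = fit1_full$n_obs,
    n_subjects = fit1$n_subjects,
    steps = list(total = fit1, mediator = fit2, outcome = fit3,
                 total_full = fit1_full),
    n_draws = spec$n_draws, ci_level = spec$ci_level, seed = seed
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("<mediation_result>",
      sprintf("%s -> %s -> %s\n", x$spec$exposure, x$spec$mediator,
              x$spec$outcome))
  cat(sprintf("  n (all steps): %d   n (total-effect model): %d\n",
              x$n_complete, x$n_total_effect))
  cat(sprintf("  c1 = %.4g  a1 = %.4g  b1 = %.4g  b3 = %.4g\n",
              x$c1, x$a1, x$b1, x$b3))
  if (!is.na(x$p_interaction)) {
    cat(sprintf("  exposure-mediator interaction p = %.3g\n", x$p_interaction))
  }
  print(as.data.frame(x$effects), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Screen the exposure-mediator interaction and dichotomise if significant
#'
#' Tests the exposure-by-mediator interaction in the outcome model
#' (`outcome ~ exposure + mediator + exposure:mediator + covariates`, with
#' subject random intercept). If significant at `alpha`, returns a spec with
#' the exposure replaced by its adiposity indicator (`bmi` at or above
#' `th$bmi_cut` -> `bmi_high`; `fmi` strictly above `th$fmi_cut` ->
#' `fmi_high`) and the interaction retained at levels 0/1; otherwise the
#' continuous interaction-free spec is returned. The screening p-value is
#' attached as attribute `p_interaction`.
#'
#' @param data Preprocessed visit table (must contain the indicator columns
#'   added by [preprocess_visits()] when dichotomisation triggers).
#' @param spec A [mediation_spec()] with continuous exposure.
#' @param th An [adiposity_thresholds()].
#' @param alpha Screening level (default 0.05).
#' @param grouping Subject identifier.
#' @return A [mediation_spec()], possibly dichotomised.
#' @export
screen_and_dichotomize <- function(data, spec, th = adiposity_thresholds(),
                                   alpha = 0.05, grouping = "dyad_id") {
  x <- data[[spec$exposure]]
  ux <- unique(x[!is.na(x)])
  if (!is.numeric(x) || length(ux) <= 2) {
    stop("exposure is already categorical; screening requires a continuous exposure",
         call. = FALSE)
  }
  shared <- data[complete.cases(data[unique(c(spec$exposure, spec$mediator,
                                              spec$outcome, spec$covariates,
                                              grouping))]), , drop = FALSE]
  spec3 <- model_spec(spec$outcome,
                      c(spec$exposure, spec$mediator, spec$covariates),
                      grouping = grouping)
  scr <- test_interaction(shared, spec3, c(spec$exposure, spec$mediator),
                          alpha = alpha)
  out <- spec
  if (scr$significant) {
    indicator <- switch(spec$exposure,
                        bmi = "bmi_high", fmi = "fmi_high",
                        paste0(spec$exposure, "_high"))
    if (!indicator %in% names(data)) {
      stop(sprintf(paste0("interaction is significant but indicator column '%s' ",
                          "is absent; run preprocess_visits() first"), indicator),
           call. = FALSE)
    }
    out$exposure <- indicator
    out$exposure_mediator_interaction <- TRUE
    out$exposure_levels <- c(0, 1)
  }
  attr(out, "p_interaction") <- scr$p_value
  out
}
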