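#' Maternal body composition and milk hormones (research question 1)
#'
#' For each exposure (maternal BMI, FMI) and each hormone (leptin, insulin,
#' adiponectin): screens the exposure-by-maternal-plasma interaction in the
#' outcome model, dichotomises the exposure at the adiposity threshold when
#' the interaction is significant, and runs the four-step mediation with the
#' maternal plasma hormone as mediator and log milk hormone as outcome.
#' Covariates: infant sex, visit and visit-centred age. Colostrum (V1) rows
#' are excluded (no maternal plasma is drawn at V1).
#'
#' @param data Preprocessed visit table ([preprocess_visits()]).
#' @param exposures Subset of `c("bmi", "fmi")`.
#' @param hormones Subset of `c("leptin", "insulin", "adiponectin")`.
#' @param covariates Adjustment covariates.
#' @param seed Integer seed for the Monte Carlo CIs.
#' @param n_draws,ci_level Monte Carlo settings.
#' @param th An [adiposity_thresholds()].
#' @return A tibble with one row per exposure-hormone pair: screening
#'   p-value, whether dichotomised, `n_complete`, and the full
#'   [run_mediation()] result in the list-column `result`.
#' @export
run_rq1 <- function(data, exposures = c("bmi", "fmi"),
                    hormones = c("leptin", "insulin", "adiponectin"),
                    covariates = c("infant_sex", "visit", "centered_age"),
                    seed, n_draws = 20000, ci_level = 0.95,
                    th = adiposity_thresholds()) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  data <- dplyr::filter(data, .data$visit != "V1")
  grid <- tidyr::expand_grid(exposure = exposures, hormone = hormones)
  purrr::pmap_dfr(grid, function(exposure, hormone) {
    mediator <- paste0("log_mplasma_", hormone)
    outcome <- paste0("log_milk_", hormone)
    for (col in c(mediator, outcome, exposure)) {
      if (!col %in% names(data)) {
        stop(sprintf("column '%s' is missing from the visit table", col),
             call. = FALSE)
      }
    }
    spec0 <- mediation_spec(exposure, mediator, outcome, covariates,
                            n_draws = n_draws, ci_level = ci_level,
                            seed = seed)
    spec <- screen_and_dichotomize(data, spec0, th = th)
    res <- run_mediation(data, spec, seed = seed)
    tibble::tibble(
      exposure = exposure, hormone = hormone,
      p_interaction_screen = attr(spec, "p_interaction"),
      dichotomized = spec$exposure_mediator_interaction,
      n_complete = res$n_complete, n_total_effect = res$n_total_effect,
      result = list(res)
    )
  })
}

# outcome -> covariate sets for the infant-outcome analyses
rq2_outcome_covariates <- function(outcome) {
  intake_outcomes <- c("total_24h_ml", "per_feed_ml")
  if (outcome %in% intake_outcomes) {
    c("milk_energy_kcal_l", "infant_sex", "infant_weight_g", "centered_age")
  } else {
    c("milk_energy_kcal_l", "total_24h_ml", "birth_weight_g", "infant_sex",
      "centered_age")
  }
}

#' Milk hormones, infant milk intake and growth (research question 2)
#'
#' For each milk hormone (exposure, log scale) and infant outcome: runs the
#' four-step mediation with the infant plasma hormone (log scale) as
#' mediator. Intake outcomes adjust for milk energy, infant sex, weight and
#' centred age; growth outcomes adjust for milk energy, total intake, birth
#' weight, infant sex and centred age. Because infant blood is drawn at V2
#' and only one of V3/V4, the mediation complete-case sample is smaller than
#' the total-effect sample; both are reported. A hormone-by-sex interaction
#' in the total-effect model is screened, and per-sex exposure estimates are
#' attached when it is significant.
#'
#' @param data Preprocessed visit table with intake summaries joined (see
#'   [summarize_intake_all()]; columns `total_24h_ml`, `per_feed_ml`).
#' @param hormones Milk hormones to use as exposures.
#' @param outcomes Infant outcome columns.
#' @param seed Integer seed.
#' @param n_draws,ci_level Monte Carlo settings.
#' @param sex_alpha Screening level for the hormone-by-sex interaction.
#' @return A tibble with one row per hormone-outcome pair, including
#'   `n_total_effect` vs `n_complete`, per-sex estimates when the sex
#'   interaction triggers, and the `result` list-column.
#' @export
run_rq2 <- function(data,
                    hormones = c("leptin", "insulin", "adiponectin"),
                    outcomes = c("total_24h_ml", "per_feed_ml",
                                 "infant_weight_g", "infant_length_cm",
                                 "infant_fmi", "infant_bodyfat_pct"),
                    seed, n_draws = 20000, ci_level = 0.95,
                    sex_alpha = 0.05) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  data <- dplyr::filter(data, .data$visit != "V1")
  grid <- tidyr::expand_grid(hormone = hormones, outcome = outcomes)
  purrr::pmap_dfr(grid, function(hormone, outcome) {
    exposure <- paste0("log_milk_", hormone)
    mediator <- paste0("log_iplasma_", hormone)
    covs <- rq2_outcome_covariates(outcome)
    for (col in c(exposure, mediator, outcome, covs)) {
      if (!col %in% names(data)) {
        stop(sprintf("column '%s' is missing from the visit table", col),
             call. = FALSE)
      }
    }
    if (all(is.na(data[[outcome]]))) {
      stop(sprintf("outcome column '%s' is empty", outcome), call. = FALSE)
    }
    spec <- mediation_spec(exposure, mediator, outcome, covs,
                           n_draws = n_draws, ci_level = ci_level, seed = seed)
    res <- run_mediation(data, spec, seed = seed)

    # hormone-by-sex screen in the total-effect model, per-sex estimates
    sex_fit <- test_interaction(
      data[complete.cases(data[c(exposure, outcome, covs, "dyad_id")]), ],
      model_spec(outcome, c(exposure, covs)),
      c(exposure, "infant_sex"), alpha = sex_alpha)
    by_sex <- NULL
    if (sex_fit$significant) {
      b <- sex_fit$fit$coef
      V <- sex_fit$fit$vcov
      idx <- interaction_coef_idx(sex_fit$fit, c(exposure, "infant_sex"))[1]
      est_ref <- unname(b[exposure])
      est_alt <- unname(b[exposure] + b[idx])
      se_alt <- sqrt(V[exposure, exposure] + V[idx, idx] + 2 * V[exposure, idx])
      by_sex <- tibble::tibble(
        sex = c("female", "male"),
        estimate = c(est_ref, est_alt),
        se = c(unname(sex_fit$fit$se[exposure]), se_alt))
      # treatment coding: reference level of infant_sex carries the main effect
      ref_level <- sort(unique(as.character(data$infant_sex)))[1]
      by_sex$sex <- c(ref_level, setdiff(c("female", "male"), ref_level))
    }
    tibble::tibble(
      hormone = hormone, outcome = outcome,
      c1_full = res$c1_full, p_c1_full = res$p_c1_full,
      n_total_effect = res$n_total_effect, n_complete = res$n_complete,
      p_sex_interaction = sex_fit$p_value,
      by_sex = list(by_sex),
      result = list(res)
    )
  })
}

#' Simulation study: bias, coverage and interaction-screen behaviour
#'
#' Repeatedly generates cohorts from `params` (varying only the seed),
#' runs the mediation analysis for one hormone, and summarises bias and
#' empirical SE of the indirect and direct effects, Monte Carlo CI coverage
#' of the true values, and the rejection rate of the exposure-mediator
#' interaction screen.
#'
#' @param params A [cohort_params()]; its effect values are the truth.
#' @param n_reps Number of replicates.
#' @param seed Master seed; per-replicate seeds derive from it.
#' @param hormone Hormone analysed (default `"leptin"`).
#' @param n_draws Monte Carlo draws per CI (default 5000 to keep large
#'   replicate grids affordable; CI endpoints are already stable there).
#' @param screen Also run the interaction screen each replicate.
#' @return A list with `replicates` (one row per replicate) and `summary`
#'   (one row, bias / empirical SE / coverage / rejection rate).
#' @export
run_simulation_study <- function(params, n_reps, seed, hormone = "leptin",
                                 n_draws = 5000, screen = FALSE) {
  stopifnot(inherits(params, "cohort_params"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  rep_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max, n_reps))
  truth_ind <- params$a1 * params$b1   # at the generator's centred reference
  truth_dir <- params$c1_prime
  mediator <- paste0("log_mplasma_", hormone)
  outcome <- paste0("log_milk_", hormone)
  covs <- c("infant_sex", "visit", "centered_age")

  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    p <- params
    p$seed <- rep_seeds[r]
    p$make_feed_logs <- FALSE  # visit table only; feed logs unused here
    ch <- generate_cohort(p)
    tbl <- preprocess_visits(ch$visit_table)
    tbl <- dplyr::filter(tbl, .data$visit != "V1")
    spec <- mediation_spec("bmi", mediator, outcome, covs,
                           n_draws = n_draws, seed = rep_seeds[r])
    res <- run_mediation(tbl, spec)
    eff <- res$effects[1, ]
    out <- tibble::tibble(
      rep = r, seed = rep_seeds[r],
      indirect = eff$indirect, direct = eff$direct,
      ci_lo = eff$ci_lo, ci_hi = eff$ci_hi,
      covers_truth = eff$ci_lo <= truth_ind & truth_ind <= eff$ci_hi,
      covers_zero = eff$ci_lo <= 0 & 0 <= eff$ci_hi,
      n_complete = res$n_complete
    )
    if (screen) {
      scr <- screen_and_dichotomize(tbl, spec)
      out$screen_rejected <- isTRUE(scr$exposure_mediator_interaction)
    }
    out
  })
  summary <- tibble::tibble(
    n_reps = n_reps,
    true_indirect = truth_ind, true_direct = truth_dir,
    mean_indirect = mean(reps$indirect), mean_direct = mean(reps$direct),
    bias_indirect = mean(reps$indirect) - truth_ind,
    bias_direct = mean(reps$direct) - truth_dir,
    emp_se_indirect = sd(reps$indirect), emp_se_direct = sd(reps$direct),
    coverage_truth = mean(reps$covers_truth),
    coverage_zero = mean(reps$covers_zero),
    screen_rejection_rate = if (screen) mean(reps$screen_rejected) else NA_real_,
    low_rep_warning = n_reps < 30
  )
  list(replicates = reps, summary = summary)
}
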