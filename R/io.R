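#' Write a synthetic cohort to disk
#'
#' The visit table and feed logs are written as UTF-8 CSV (one header row,
#' empty cell = missing, ISO-8601 timestamps); the generating truth as JSON.
#'
#' @param cohort A `milk_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "milk_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    visits = file.path(dir, "visit_table.csv"),
    feeds = file.path(dir, "feed_logs.csv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(cohort$visit_table, paths$visits, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  utils::write.csv(cohort$feed_logs, paths$feeds, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  tr <- cohort$truth
  jsonlite::write_json(
    list(effects = tr$effects, bmi_anchor = tr$bmi_anchor, seed = tr$seed,
         subject_intercepts = tr$subject_intercepts,
         precensor_hormones = tr$precensor_hormones,
         true_daily_intake = tr$true_daily_intake),
    paths$truth, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}

#' Read a synthetic cohort written by [write_cohort()]
#'
#' @param dir Directory containing `visit_table.csv`, `feed_logs.csv`,
#'   `truth.json`.
#' @return A `milk_cohort` list (visit_table, feed_logs, truth).
#' @export
read_cohort <- function(dir) {
  visit_table <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "visit_table.csv"), na.strings = "",
                    fileEncoding = "UTF-8"))
  flag_cols <- grep("_below_lod$", names(visit_table), value = TRUE)
  for (fc in flag_cols) visit_table[[fc]] <- as.logical(visit_table[[fc]])
  feed_logs <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "feed_logs.csv"), na.strings = "",
                    fileEncoding = "UTF-8"))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  truth <- structure(list(
    effects = tr$effects, bmi_anchor = tr$bmi_anchor, seed = tr$seed,
    subject_intercepts = tibble::as_tibble(tr$subject_intercepts),
    precensor_hormones = tibble::as_tibble(tr$precensor_hormones),
    true_daily_intake = tibble::as_tibble(tr$true_daily_intake)
  ), class = "cohort_truth")
  structure(list(visit_table = visit_table, feed_logs = feed_logs,
                 truth = truth), class = "milk_cohort")
}

#' Serialise a mediation result to JSON
#'
#' Writes every coefficient, the per-level decomposition with its Monte
#' Carlo CI, sample sizes, seed, and the coefficient table of each step
#' model.
#'
#' @param x A `mediation_result`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mediation_json <- function(x, path) {
  stopifnot(inherits(x, "mediation_result"))
  steps <- purrr::map(x$steps, function(f) {
    list(formula = f$formula, engine = f$engine, n_obs = f$n_obs,
         n_subjects = f$n_subjects,
         varcomp = as.list(f$varcomp), converged = f$converged,
         coef = tidy(f), vcov = unname(as.matrix(f$vcov)))
  })
  jsonlite::write_json(list(
    exposure = x$spec$exposure, mediator = x$spec$mediator,
    outcome = x$spec$outcome, covariates = x$spec$covariates,
    c1 = x$c1, a1 = x$a1, b1 = x$b1, b3 = x$b3,
    c1_full = x$c1_full, p_interaction = x$p_interaction,
    effects = x$effects,
    n_complete = x$n_complete, n_total_effect = x$n_total_effect,
    n_draws = x$n_draws, ci_level = x$ci_level, seed = x$seed,
    steps = steps
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
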