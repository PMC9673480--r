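#' Tidy a mixed-model fit
#'
#' @param x A `milk_lmm` object.
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect term: `term`, `estimate`,
#'   `std.error`, `statistic` (Wald z), `p.value`.
#' @method tidy milk_lmm
#' @export
tidy.milk_lmm <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std.error = unname(x$se),
                 statistic = unname(x$coef / x$se),
                 p.value = unname(x$p_value))
}

#' One-row model summary of a mixed-model fit
#'
#' @param x A `milk_lmm` object.
#' @param ... Unused.
#' @return A one-row tibble: sample sizes, variance components, engine and
#'   convergence.
#' @method glance milk_lmm
#' @export
glance.milk_lmm <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_subjects = x$n_subjects,
                 var_subject = unname(x$varcomp["subject"]),
                 var_residual = unname(x$varcomp["residual"]),
                 engine = x$engine, method = x$method,
                 converged = x$converged)
}

#' Tidy a mediation result
#'
#' @param x A `mediation_result` object.
#' @param ... Unused.
#' @return A tibble with one row per exposure level: indirect and direct
#'   effects, Monte Carlo CI, proportion mediated (percent), significance.
#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) {
  out <- x$effects
  out$exposure <- x$spec$exposure
  out$mediator <- x$spec$mediator
  out$outcome <- x$spec$outcome
  out$c1 <- x$c1
  dplyr::select(out, "exposure", "mediator", "outcome", "level", "c1",
                "indirect", "direct", "proportion_mediated",
                "ci_lo", "ci_hi", "p_indirect", "indirect_significant")
}

#' One-row summary of a mediation result
#'
#' @param x A `mediation_result` object.
#' @param ... Unused.
#' @return A one-row tibble with the path coefficients, interaction p-value,
#'   sample sizes and Monte Carlo settings.
#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(c1 = x$c1, a1 = x$a1, b1 = x$b1, b3 = x$b3,
                 c1_full = x$c1_full, p_interaction = x$p_interaction,
                 n_complete = x$n_complete, n_total_effect = x$n_total_effect,
                 n_subjects = x$n_subjects, n_draws = x$n_draws,
                 ci_level = x$ci_level, seed = x$seed)
}

#' Forest-style plot of a mediation decomposition
#'
#' Shows the indirect effect per exposure level with its Monte Carlo CI,
#' alongside the direct and total effects.
#'
#' @param object A `mediation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mediation_result
#' @export
autoplot.mediation_result <- function(object, ...) {
  eff <- object$effects
  lv <- factor(eff$level)
  df <- dplyr::bind_rows(
    tibble::tibble(level = lv, effect = "indirect", estimate = eff$indirect,
                   lo = eff$ci_lo, hi = eff$ci_hi),
    tibble::tibble(level = lv, effect = "direct", estimate = eff$direct,
                   lo = NA_real_, hi = NA_real_),
    tibble::tibble(level = lv, effect = "total", estimate = object$c1,
                   lo = NA_real_, hi = NA_real_)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$effect,
                                   colour = .data$level)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
      height = 0.15, na.rm = TRUE,
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(
      x = "effect (outcome-model scale)", y = NULL, colour = "exposure level",
      title = sprintf("%s → %s → %s", object$spec$exposure,
                      object$spec$mediator, object$spec$outcome),
      subtitle = sprintf("Monte Carlo %g%% CI on the indirect effect, %d draws",
                         100 * object$ci_level, object$n_draws)) +
    ggplot2::theme_minimal()
}

#' Hormone trajectory plot across visits
#'
#' Median and interquartile band of a hormone by visit, on a log y-axis.
#'
#' @param data Visit table.
#' @param hormone,compartment Which concentration column
#'   (`<compartment>_<hormone>`) to show.
#' @return A ggplot object.
#' @export
plot_hormone_trajectory <- function(data, hormone, compartment = "milk") {
  col <- paste0(compartment, "_", hormone)
  stopifnot(col %in% names(data))
  df <- data |>
    dplyr::filter(!is.na(.data[[col]])) |>
    dplyr::group_by(.data$visit) |>
    dplyr::summarise(med = median(.data[[col]]),
                     q1 = quantile(.data[[col]], 0.25),
                     q3 = quantile(.data[[col]], 0.75), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$visit, y = .data$med, group = 1)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = sprintf("%s (median, IQR)", col)) +
    ggplot2::theme_minimal()
}
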