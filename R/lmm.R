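#' Specify a linear mixed model with a per-subject random intercept
#'
#' @param outcome Outcome column name. Set `log_outcome = TRUE` to model the
#'   natural log of the column.
#' @param fixed_terms Character vector of fixed-effect column names, in
#'   order.
#' @param interactions List of length-2 character vectors, each a pair of
#'   `fixed_terms` to interact.
#' @param grouping Subject identifier column for the random intercept.
#' @param method `"REML"` (default) or `"ML"`.
#' @param log_outcome Model `log(outcome)` instead of the raw outcome.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome, fixed_terms, interactions = list(),
                       grouping = "dyad_id", method = c("REML", "ML"),
                       log_outcome = FALSE) {
  method <- match.arg(method)
  if (outcome %in% fixed_terms) {
    stop("outcome must not appear among fixed_terms", call. = FALSE)
  }
  for (pair in interactions) {
    if (!all(pair %in% fixed_terms)) {
      stop("interaction members must appear in fixed_terms", call. = FALSE)
    }
  }
  structure(list(outcome = outcome, fixed_terms = fixed_terms,
                 interactions = interactions, grouping = grouping,
                 method = method, log_outcome = isTRUE(log_outcome)),
            class = "model_spec")
}

spec_formula <- function(spec) {
  lhs <- if (spec$log_outcome) sprintf("log(%s)", spec$outcome) else spec$outcome
  rhs <- spec$fixed_terms
  for (pair in spec$interactions) rhs <- c(rhs, paste(pair, collapse = ":"))
  if (length(rhs) == 0) rhs <- "1"
  list(
    fixed = as.formula(paste(lhs, "~", paste(rhs, collapse = " + "))),
    mixed = as.formula(paste(lhs, "~", paste(rhs, collapse = " + "),
                             sprintf("+ (1 | %s)", spec$grouping)))
  )
}

spec_vars <- function(spec) {
  unique(c(spec$outcome, spec$fixed_terms, spec$grouping))
}

#' Fit a linear mixed-effect model with subject random intercept
#'
#' Fits `outcome ~ fixed_terms (+ interactions) + (1 | subject)` by REML
#' (default) via \pkg{lme4}, on complete cases of the model's variables.
#' When every subject contributes a single observation the random intercept
#' is not identifiable and the model reduces to ordinary least squares, as
#' do degenerate fits the mixed-model optimiser rejects.
#'
#' @param data A data frame containing every variable of `spec`.
#' @param spec A [model_spec()].
#' @return An object of class `milk_lmm` carrying fixed-effect estimates
#'   (`coef`), their covariance (`vcov`), Wald z p-values, variance
#'   components, sample sizes, the convergence flag and the engine used.
#' @examples
#' d <- data.frame(id = rep(1:10, each = 2), x = rnorm(20))
#' d$y <- 1 + 0.5 * d$x + rnorm(20)
#' fit_lmm(d, model_spec("y", "x", grouping = "id"))
#' @export
fit_lmm <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- spec_vars(spec)
  miss <- setdiff(vars, names(data))
  if (length(miss) > 0) {
    stop(sprintf("data is missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df <- tibble::as_tibble(data)[vars]
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) == 0) stop("no complete cases for this model", call. = FALSE)
  n_subjects <- length(unique(df[[spec$grouping]]))
  if (n_subjects < 2) stop("need >= 2 subjects", call. = FALSE)
  ff <- spec_formula(spec)
  max_per_subject <- max(table(df[[spec$grouping]]))

  engine <- "lmer"; converged <- TRUE; fit <- NULL
  mixed <- NULL
  if (max_per_subject > 1) {
    # extraction is inside the tryCatch too: degenerate fits (e.g. zero
    # residual variance) can yield an unusable covariance matrix
    mixed <- tryCatch({
      m <- suppressWarnings(
        lme4::lmer(ff$mixed, data = df, REML = spec$method == "REML",
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore")))
      V <- suppressWarnings(as.matrix(vcov(m)))
      if (any(!is.finite(V))) stop("non-finite covariance")
      vc <- lme4::VarCorr(m)
      msgs <- m@optinfo$conv$lme4$messages
      list(fit = m, beta = lme4::fixef(m), V = V,
           varcomp = c(subject = as.numeric(vc[[spec$grouping]][1, 1]),
                       residual = attr(vc, "sc")^2),
           converged = is.null(msgs) || length(msgs) == 0)
    }, error = function(e) NULL)
  }
  if (is.null(mixed)) {
    engine <- "ols"
    fit <- lm(ff$fixed, data = df)
    beta <- coef(fit)
    V <- vcov(fit)
    varcomp <- c(subject = 0, residual = summary(fit)$sigma^2)
  } else {
    fit <- mixed$fit; beta <- mixed$beta; V <- mixed$V
    varcomp <- mixed$varcomp; converged <- mixed$converged
  }
  if (any(is.na(beta))) {
    stop("rank-deficient design: some coefficients are not estimable",
         call. = FALSE)
  }
  dimnames(V) <- list(names(beta), names(beta))
  se <- sqrt(diag(V))
  z <- beta / se
  trm <- terms(ff$fixed)
  mm <- stats::model.matrix(ff$fixed, df)
  structure(list(
    coef = beta, se = se, vcov = V,
    p_value = 2 * pnorm(-abs(z)),
    n_obs = nrow(df), n_subjects = n_subjects,
    varcomp = varcomp, converged = converged,
    engine = engine, method = spec$method,
    formula = paste(deparse(ff$fixed), collapse = " "),
    term_labels = attr(trm, "term.labels"),
    assign = attr(mm, "assign"),
    spec = spec, fit = fit
  ), class = "milk_lmm")
}

#' @export
print.milk_lmm <- function(x, ...) {
  cat("<milk_lmm> ", x$formula, "\n")
  cat(sprintf("  engine: %s (%s)  n_obs: %d  n_subjects: %d  converged: %s\n",
              x$engine, x$method, x$n_obs, x$n_subjects, x$converged))
  print(round(cbind(estimate = x$coef, se = x$se, p = x$p_value), 4))
  invisible(x)
}

# Indices of fixed-effect columns belonging to the interaction of a term pair
interaction_coef_idx <- function(fit, term_pair) {
  lbl <- c(paste(term_pair, collapse = ":"), paste(rev(term_pair), collapse = ":"))
  k <- which(fit$term_labels %in% lbl)
  if (length(k) == 0) return(integer(0))
  which(fit$assign %in% k)
}

#' Wald test of an exposure-mediator (or any) interaction
#'
#' Fits the model with the requested interaction added (if absent) and
#' performs a Wald chi-square test of its coefficient(s) against zero. For a
#' single-column interaction this is the usual z-test.
#'
#' @param data Data frame.
#' @param spec A [model_spec()]; the interaction is appended when missing.
#' @param term_pair Length-2 character vector naming the interacting terms.
#' @param alpha Significance level (default 0.05).
#' @return A list: `p_value`, `significant`, `estimate` (named coefficient
#'   vector of the interaction columns), `fit`.
#' @export
test_interaction <- function(data, spec, term_pair, alpha = 0.05) {
  if (!all(term_pair %in% spec$fixed_terms)) {
    stop("both interaction terms must be among the spec's fixed_terms",
         call. = FALSE)
  }
  have <- any(vapply(spec$interactions, function(p) setequal(p, term_pair),
                     logical(1)))
  if (!have) spec$interactions <- c(spec$interactions, list(term_pair))
  fit <- fit_lmm(data, spec)
  idx <- interaction_coef_idx(fit, term_pair)
  if (length(idx) == 0) stop("interaction columns not found in fit", call. = FALSE)
  b <- fit$coef[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  W <- as.numeric(t(b) %*% solve(V, b))
  p <- stats::pchisq(W, df = length(idx), lower.tail = FALSE)
  list(p_value = p, significant = p < alpha, estimate = b, fit = fit)
}

#' Back-transform a log-scale estimate to a percent difference
#'
#' `100 * (exp(beta) - 1)`: the percent change in the outcome's original
#' scale per unit contrast on the log scale.
#'
#' @param beta Numeric vector of log-scale estimates.
#' @return Percent differences.
#' @examples
#' percent_difference(-0.78)  # -54.2
#' percent_difference(1.6)    # +395
#' @export
percent_difference <- function(beta) {
  100 * (exp(beta) - 1)
}

#' Outcome change per percent increase of a log-transformed exposure
#'
#' For an outcome modelled in original units against a log-transformed
#' exposure, a `pct` percent exposure increase shifts the outcome by
#' `beta * log(1 + pct/100)`.
#'
#' @param beta Slope in outcome units per unit log-exposure.
#' @param pct Percent increase in the exposure (> -100).
#' @return Outcome change in outcome units.
#' @examples
#' effect_per_percent_increase(140.2, 10)  # ~13.4 g
#' @export
effect_per_percent_increase <- function(beta, pct) {
  if (any(pct <= -100)) stop("pct must be > -100", call. = FALSE)
  beta * log(1 + pct / 100)
}

#' Adjacent-visit hormone trajectory contrasts
#'
#' Fits `log(concentration) ~ visit + infant_sex + centered_age` with a
#' per-subject random intercept and returns the log-scale change between
#' each pair of adjacent visits together with its back-transformed percent
#' difference. (A random-intercept model: compound-symmetric within-subject
#' covariance, not an unstructured one.)
#'
#' @param data Preprocessed visit table (see [preprocess_visits()]).
#' @param hormone `"leptin"`, `"insulin"` or `"adiponectin"`.
#' @param compartment `"milk"`, `"mplasma"` or `"iplasma"`.
#' @param covariates Adjustment covariates (default infant sex and
#'   visit-centred age).
#' @return A tibble with one row per adjacent visit pair: `from`, `to`,
#'   `estimate` (log scale), `se`, `p_value`, `percent_difference`.
#' @export
visit_contrasts <- function(data, hormone, compartment = "milk",
                            covariates = c("infant_sex", "centered_age")) {
  col <- paste0("log_", compartment, "_", hormone)
  if (!col %in% names(data)) {
    src <- paste0(compartment, "_", hormone)
    if (!src %in% names(data)) {
      stop(sprintf("column '%s' not found", src), call. = FALSE)
    }
    data[[col]] <- ifelse(!is.na(data[[src]]) & data[[src]] > 0,
                          log(data[[src]]), NA_real_)
  }
  data <- data[!is.na(data[[col]]), , drop = FALSE]
  vis <- sort(unique(data$visit))
  if (length(vis) < 2) stop("need data at >= 2 visits", call. = FALSE)
  data$visit <- factor(data$visit, levels = vis)
  fit <- fit_lmm(data, model_spec(col, c("visit", covariates)))
  # treatment coding against the first visit: contrast V[k] -> V[k+1]
  cn <- paste0("visit", vis)
  full <- setNames(rep(0, length(vis)), cn)
  fullV <- matrix(0, length(vis), length(vis), dimnames = list(cn, cn))
  present <- intersect(cn, names(fit$coef))
  full[present] <- fit$coef[present]
  fullV[present, present] <- fit$vcov[present, present]
  purrr::map_dfr(seq_len(length(vis) - 1), function(k) {
    est <- full[k + 1] - full[k]
    v <- fullV[k + 1, k + 1] + fullV[k, k] - 2 * fullV[k + 1, k]
    se <- sqrt(v)
    tibble::tibble(from = vis[k], to = vis[k + 1],
                   estimate = unname(est), se = se,
                   p_value = 2 * pnorm(-abs(est / se)),
                   percent_difference = percent_difference(unname(est)))
  })
}
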