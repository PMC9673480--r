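#' Default per-visit hormone medians
#'
#' Median hormone concentrations by compartment, hormone and visit used to
#' calibrate the synthetic cohort. Units follow field convention: milk leptin
#' and insulin in pg/mL, milk adiponectin in ng/mL, maternal plasma leptin in
#' ng/mL, plasma insulin in pg/mL, maternal plasma adiponectin in ug/mL,
#' infant plasma in the same units as maternal plasma.
#'
#' @return A nested named list: `medians[[compartment]][[hormone]]` is a named
#'   numeric vector over visits.
#' @export
default_hormone_medians <- function() {
  list(
    milk = list(
      leptin      = c(V1 = 419, V2 = 90,  V3 = 48,  V4 = 33),
      insulin     = c(V1 = 416, V2 = 202, V3 = 218, V4 = 211),
      adiponectin = c(V1 = 8.2, V2 = 2.4, V3 = 1.9, V4 = 2.0)
    ),
    mplasma = list(
      leptin      = c(V2 = 4.7, V3 = 4.3, V4 = 5.1),
      insulin     = c(V2 = 131, V3 = 163, V4 = 127),
      adiponectin = c(V2 = 4.4, V3 = 7.0, V4 = 4.0)
    ),
    iplasma = list(
      leptin      = c(V2 = 2.8,  V3 = 1.7,  V4 = 2.2),
      insulin     = c(V2 = 135,  V3 = 80,   V4 = 105),
      adiponectin = c(V2 = 23.6, V3 = 19.1, V4 = 10.1)
    )
  )
}

#' Default natural-log-scale dispersions per hormone and compartment
#'
#' Total between+within SD of log concentration, chosen so that simulated
#' interquartile ranges resemble those of a longitudinal breastfeeding cohort
#' (log IQR ratio / 1.349).
#'
#' @return Nested named list mirroring [default_hormone_medians()].
#' @export
default_log_sd <- function() {
  list(
    milk    = list(leptin = 1.10, insulin = 0.41, adiponectin = 0.62),
    mplasma = list(leptin = 1.20, insulin = 0.49, adiponectin = 0.46),
    iplasma = list(leptin = 0.67, insulin = 0.47, adiponectin = 0.37)
  )
}

# Sex- and visit-specific infant reference means (male, female) with SDs,
# used to generate infant anthropometry, body composition and milk intake.
infant_norms <- function() {
  tibble::tribble(
    ~visit, ~variable,            ~male,  ~female, ~sd,
    "V2",   "infant_weight_g",     5820,   5210,    810,
    "V3",   "infant_weight_g",     7570,   6880,    850,
    "V4",   "infant_weight_g",     8730,   8110,    920,
    "V2",   "infant_length_cm",    60.1,   58.2,    2.8,
    "V3",   "infant_length_cm",    67.0,   64.7,    2.6,
    "V4",   "infant_length_cm",    70.8,   68.9,    2.5,
    "V2",   "infant_fmi",          3.5,    3.5,     0.7,
    "V3",   "infant_fmi",          4.1,    4.4,     1.0,
    "V4",   "infant_fmi",          4.8,    5.3,     1.0,
    "V2",   "infant_bodyfat_pct",  21.7,   22.8,    3.1,
    "V3",   "infant_bodyfat_pct",  24.1,   27.0,    4.4,
    "V4",   "infant_bodyfat_pct",  27.3,   30.7,    3.6,
    "V2",   "total_intake_ml",     813,    761,     157,
    "V3",   "total_intake_ml",     844,    840,     184,
    "V4",   "total_intake_ml",     641,    600,     221
  )
}

#' Parameters for the synthetic dyad cohort generator
#'
#' Bundles every knob of the synthetic mother-infant cohort: sample size,
#' postpartum visit windows, per-visit hormone medians and log-scale
#' dispersions, the log-scale mediation structure linking maternal adiposity
#' (exposure X), maternal plasma hormone (mediator M) and milk hormone
#' (outcome Y), below-LOD censoring, the infant blood-sampling split and
#' per-visit retention.
#'
#' The mediation structure, shared by all three hormones, is
#' \deqn{\log M = \log m_v + a_1 X_c + u_i + \epsilon}
#' \deqn{\log Y = \log y_v + c_1' X_c + b_1 M_c + b_3 X_c M_c + \beta_{sex}
#'   \mathrm{female} + \beta_{age} \mathrm{age}_c + v_i + \epsilon'}
#' where \eqn{X_c} is mean-centred exposure, \eqn{M_c = \log M - \log m_v}
#' the centred log mediator, and \eqn{m_v, y_v} the configured per-visit
#' medians (centring keeps marginal medians calibrated; slopes are invariant
#' to it). An optional second structure (`rq2_*`) routes log milk insulin
#' through infant plasma insulin into infant weight for infant-outcome
#' analyses.
#'
#' @param n_dyads Number of mother-infant dyads.
#' @param seed Integer seed; required, no hidden global RNG state is used.
#' @param a1 Exposure-to-mediator slope (log-mediator units per exposure unit).
#' @param b1 Mediator-to-outcome slope (log-outcome per log-mediator).
#' @param b3 Exposure-by-mediator interaction coefficient.
#' @param c1_prime Direct exposure-to-outcome slope.
#' @param covariate_effects Named list of outcome-model covariate slopes,
#'   entries `sex_female` (log-outcome shift for female infants) and
#'   `centered_age` (per month).
#' @param subject_sd,resid_sd Optional named lists with entries `mediator` and
#'   `outcome` overriding the random-intercept / residual SDs of the mediator
#'   (maternal plasma) and outcome (milk) channels. Default `NULL` splits each
#'   channel's total `log_sd` variance equally between subject and residual.
#' @param hormone_medians,log_sd Nested lists as in
#'   [default_hormone_medians()] / [default_log_sd()].
#' @param visit_windows Named list of `(lo, hi)` month intervals for V2-V4.
#' @param exposure_dist List describing maternal BMI (mean at V2, SD,
#'   per-visit drift, within-mother visit noise) and the linear BMI-to-FMI
#'   map with its noise.
#' @param lod_censor Logical; censor values below `censor_limits` to `NA` with
#'   a below-LOD flag.
#' @param censor_limits Named list of detection thresholds in measured units.
#'   Channels missing from the list are never censored (assay dilution makes
#'   plasma leptin/adiponectin and milk adiponectin effectively uncensored at
#'   observed concentrations).
#' @param infant_blood_split Fraction of infants blood-sampled at V3 (the
#'   rest at V4); all infants are sampled at V2.
#' @param dropout Named per-visit retention probabilities.
#' @param v1_collection_rate Fraction of dyads with a colostrum (V1) sample.
#' @param rq2_a1,rq2_b1,rq2_c1_prime Optional infant-outcome mediation
#'   structure: log milk insulin -> log infant plasma insulin -> infant
#'   weight (g).
#' @param feed_noise_sd Per-weighing scale noise (g) in generated feed logs.
#' @param feed_miss_rate,feed_spike_rate Per-feed probabilities of a missing
#'   weight and of an unrealistically high (> 400 g) feed.
#' @param make_feed_logs Generate per-visit feed logs (default `TRUE`).
#'   Turning this off skips the feed-log block for simulation studies that
#'   only use the visit table; the visit table itself is unaffected (all its
#'   draws precede the feed-log block in the RNG stream).
#' @param milk_energy Mean/SD (kcal/L) of milk energy concentration.
#' @param birth_weight Mean/SD (g) of birth weight.
#'
#' @return An object of class `cohort_params` (a validated list).
#' @seealso [generate_cohort()]
#' @examples
#' p <- cohort_params(n_dyads = 50, seed = 1, a1 = 0.5, b1 = 0.8)
#' @export
cohort_params <- function(n_dyads = 223,
                          seed,
                          a1 = 0, b1 = 0, b3 = 0, c1_prime = 0,
                          covariate_effects = list(sex_female = 0, centered_age = 0),
                          subject_sd = NULL,
                          resid_sd = NULL,
                          hormone_medians = default_hormone_medians(),
                          log_sd = default_log_sd(),
                          visit_windows = list(V2 = c(1.0, 3.49),
                                               V3 = c(3.5, 5.99),
                                               V4 = c(6.0, 8.5)),
                          exposure_dist = list(bmi_mean = 23.6, bmi_sd = 3.0,
                                               drift = c(V2 = 0, V3 = -0.45, V4 = -0.9),
                                               visit_noise_sd = 0.25,
                                               fmi_intercept = -9.6, fmi_slope = 0.7,
                                               fmi_noise_sd = 0.5),
                          lod_censor = TRUE,
                          censor_limits = list(milk_leptin = 11, milk_insulin = 12,
                                               mplasma_insulin = 12, iplasma_insulin = 12),
                          infant_blood_split = 0.5,
                          dropout = c(V2 = 1.0, V3 = 0.94, V4 = 0.91),
                          v1_collection_rate = 0.65,
                          rq2_a1 = 0, rq2_b1 = 0, rq2_c1_prime = 0,
                          make_feed_logs = TRUE,
                          feed_noise_sd = 4,
                          feed_miss_rate = 0.02,
                          feed_spike_rate = 0.005,
                          milk_energy = c(mean = 633, sd = 102),
                          birth_weight = c(mean = 3510, sd = 364)) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("`seed` is required: cohort generation must be reproducible.", call. = FALSE)
  }
  if (!is.numeric(n_dyads) || length(n_dyads) != 1 || n_dyads < 1) {
    stop("`n_dyads` must be a positive count.", call. = FALSE)
  }
  p <- list(
    n_dyads = as.integer(n_dyads), seed = as.integer(seed),
    a1 = a1, b1 = b1, b3 = b3, c1_prime = c1_prime,
    covariate_effects = covariate_effects,
    subject_sd = subject_sd, resid_sd = resid_sd,
    hormone_medians = hormone_medians, log_sd = log_sd,
    visit_windows = visit_windows, exposure_dist = exposure_dist,
    lod_censor = isTRUE(lod_censor), censor_limits = censor_limits,
    infant_blood_split = infant_blood_split, dropout = dropout,
    v1_collection_rate = v1_collection_rate,
    rq2_a1 = rq2_a1, rq2_b1 = rq2_b1, rq2_c1_prime = rq2_c1_prime,
    make_feed_logs = isTRUE(make_feed_logs),
    feed_noise_sd = feed_noise_sd,
    feed_miss_rate = feed_miss_rate, feed_spike_rate = feed_spike_rate,
    milk_energy = milk_energy, birth_weight = birth_weight
  )
  validate_cohort_params(p)
  structure(p, class = "cohort_params")
}

validate_cohort_params <- function(p) {
  win <- p$visit_windows
  lo <- vapply(win, `[`, numeric(1), 1)
  hi <- vapply(win, `[`, numeric(1), 2)
  if (any(hi <= lo)) stop("visit windows must have lo < hi", call. = FALSE)
  if (is.unsorted(as.vector(rbind(lo, hi)), strictly = FALSE)) {
    stop("visit windows must be non-overlapping and increasing", call. = FALSE)
  }
  meds <- unlist(p$hormone_medians)
  if (any(!is.finite(meds)) || any(meds <= 0)) {
    stop("hormone medians must be strictly positive", call. = FALSE)
  }
  sds <- unlist(c(p$log_sd, p$subject_sd, p$resid_sd,
                  p$exposure_dist[c("bmi_sd", "visit_noise_sd", "fmi_noise_sd")],
                  p$feed_noise_sd))
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (any(p$dropout < 0 | p$dropout > 1)) {
    stop("retention probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p$infant_blood_split < 0 || p$infant_blood_split > 1) {
    stop("infant_blood_split must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("<cohort_params>\n")
  cat("  dyads:", x$n_dyads, " seed:", x$seed, "\n")
  cat(sprintf("  mediation: a1 = %g, b1 = %g, b3 = %g, c1' = %g\n",
              x$a1, x$b1, x$b3, x$c1_prime))
  cat("  lod_censor:", x$lod_censor,
      " blood split (V3):", x$infant_blood_split, "\n")
  invisible(x)
}

# Random-intercept / residual SD for a channel, honouring overrides.
channel_sds <- function(p, compartment, hormone) {
  total <- p$log_sd[[compartment]][[hormone]]
  role <- switch(compartment, mplasma = "mediator", milk = "outcome", NA_character_)
  subj <- if (!is.na(role) && !is.null(p$subject_sd[[role]])) {
    p$subject_sd[[role]]
  } else {
    total / sqrt(2)
  }
  resid <- if (!is.na(role) && !is.null(p$resid_sd[[role]])) {
    p$resid_sd[[role]]
  } else {
    total / sqrt(2)
  }
  c(subject = subj, resid = resid)
}
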