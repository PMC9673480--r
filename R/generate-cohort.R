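#' Generate a synthetic longitudinal mother-infant dyad cohort
#'
#' Draws a seeded cohort with one row per retained dyad-visit, a 24-h
#' test-weighing feed log per postpartum visit, and a `cohort_truth` object
#' recording the generating parameters, realised subject random intercepts
#' and pre-censoring hormone values, so that downstream estimation can be
#' validated by parameter recovery.
#'
#' Hormones are log-normal with per-visit medians set by
#' `params$hormone_medians`; the mediation structure of [cohort_params()]
#' links maternal BMI to maternal plasma (mediator) and milk (outcome)
#' hormones on the log scale. Infant plasma is sampled at V2 for every
#' infant and at exactly one of V3/V4 per infant (`infant_blood_split`).
#' When `lod_censor` is on, values below the configured detection limits are
#' replaced by `NA` with the matching `*_below_lod` flag set.
#'
#' @param params A [cohort_params()] object.
#' @return A list of class `milk_cohort` with elements
#'   \describe{
#'     \item{visit_table}{tibble, one row per retained dyad-visit.}
#'     \item{feed_logs}{tibble of per-feed weighing events (long format).}
#'     \item{truth}{`cohort_truth`: generating effects, subject intercepts,
#'       pre-censoring hormone values and true daily intake totals.}
#'   }
#' @examples
#' ch <- generate_cohort(cohort_params(n_dyads = 30, seed = 42))
#' dplyr::count(ch$visit_table, visit)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  validate_cohort_params(params)
  withr::with_seed(params$seed, generate_cohort_impl(params))
}

generate_cohort_impl <- function(p) {
  n <- p$n_dyads
  hormones <- c("leptin", "insulin", "adiponectin")
  ed <- p$exposure_dist
  norms <- infant_norms()

  dyad_id <- sprintf("D%04d", seq_len(n))
  sex <- ifelse(runif(n) < 0.5, "female", "male")
  height_m <- rnorm(n, 1.69, 0.06)
  bmi_base <- rnorm(n, ed$bmi_mean, ed$bmi_sd)
  birth_weight_g <- rnorm(n, p$birth_weight[["mean"]], p$birth_weight[["sd"]])

  # subject random intercepts per hormone channel + infant phenotype channels
  subj <- list()
  for (comp in c("milk", "mplasma", "iplasma")) {
    for (h in hormones) {
      subj[[paste(comp, h, sep = "_")]] <-
        rnorm(n, 0, channel_sds(p, comp, h)[["subject"]])
    }
  }
  subj$infant_weight <- rnorm(n, 0, 450)
  subj$infant_length <- rnorm(n, 0, 1.8)
  subj$infant_fmi <- rnorm(n, 0, 0.55)
  subj$infant_bodyfat <- rnorm(n, 0, 2.2)
  subj$intake <- rnorm(n, 0, 110)
  subj$milk_energy <- rnorm(n, 0, p$milk_energy[["sd"]] * 0.6)

  v3_blood <- runif(n) < p$infant_blood_split

  # grand-mean exposure anchor for centring (mean BMI across visits)
  bmi_anchor <- ed$bmi_mean + mean(ed$drift)

  visits <- names(p$visit_windows)  # V2..V4
  rows <- list()
  truth_rows <- list()
  feed_meta <- list()

  # V1 colostrum rows: milk hormones only
  has_v1 <- runif(n) < p$v1_collection_rate
  if (any(has_v1)) {
    idx <- which(has_v1)
    age_m <- runif(length(idx), 1, 3) / 30.44  # 24-72 h in months
    v1 <- tibble::tibble(
      dyad_id = dyad_id[idx], visit = "V1",
      infant_age_months = age_m, infant_sex = sex[idx],
      birth_weight_g = birth_weight_g[idx]
    )
    for (h in hormones) {
      sds <- channel_sds(p, "milk", h)
      lmu <- log(p$hormone_medians$milk[[h]][["V1"]])
      v1[[paste0("milk_", h)]] <-
        exp(lmu + subj[[paste0("milk_", h)]][idx] + rnorm(length(idx), 0, sds[["resid"]]))
    }
    rows[["V1"]] <- v1
  }

  for (v in visits) {
    keep <- which(runif(n) < p$dropout[[v]])
    m <- length(keep)
    if (m == 0) next
    win <- p$visit_windows[[v]]
    age <- runif(m, win[1], win[2])
    cage <- age - mean(win)  # generating centred age; analyses re-centre empirically

    bmi <- bmi_base[keep] + ed$drift[[v]] + rnorm(m, 0, ed$visit_noise_sd)
    fmi <- ed$fmi_slope * bmi + ed$fmi_intercept + rnorm(m, 0, ed$fmi_noise_sd)
    fmi <- pmax(fmi, 0.5)
    # centre the exposure at its per-visit mean so the configured per-visit
    # medians stay the marginal medians; slopes are invariant, the per-visit
    # shift is absorbed by the visit term the analysis models include
    xc <- bmi - (ed$bmi_mean + ed$drift[[v]])

    row <- tibble::tibble(
      dyad_id = dyad_id[keep], visit = v,
      infant_age_months = age, infant_sex = sex[keep],
      birth_weight_g = birth_weight_g[keep],
      maternal_height_m = height_m[keep],
      maternal_weight_kg = bmi * height_m[keep]^2,
      bmi = bmi, fmi = fmi, ffmi = bmi - fmi,
      fm_kg = fmi * height_m[keep]^2,
      ffm_kg = (bmi - fmi) * height_m[keep]^2,
      milk_energy_kcal_l = pmax(
        p$milk_energy[["mean"]] + subj$milk_energy[keep] +
          rnorm(m, 0, p$milk_energy[["sd"]] * 0.8), 300)
    )

    female <- as.numeric(sex[keep] == "female")
    for (h in hormones) {
      sds_m <- channel_sds(p, "mplasma", h)
      sds_y <- channel_sds(p, "milk", h)
      lmu_m <- log(p$hormone_medians$mplasma[[h]][[v]])
      lmu_y <- log(p$hormone_medians$milk[[h]][[v]])
      log_med <- lmu_m + p$a1 * xc + subj[[paste0("mplasma_", h)]][keep] +
        rnorm(m, 0, sds_m[["resid"]])
      mc <- log_med - lmu_m
      log_out <- lmu_y + p$c1_prime * xc + p$b1 * mc + p$b3 * xc * mc +
        p$covariate_effects$sex_female * female +
        p$covariate_effects$centered_age * cage +
        subj[[paste0("milk_", h)]][keep] + rnorm(m, 0, sds_y[["resid"]])
      row[[paste0("mplasma_", h)]] <- exp(log_med)
      row[[paste0("milk_", h)]] <- exp(log_out)

      # infant plasma, only where sampled (V2 always; V3 or V4 per split)
      sampled <- v == "V2" | (v == "V3" & v3_blood[keep]) | (v == "V4" & !v3_blood[keep])
      sds_i <- channel_sds(p, "iplasma", h)
      lmu_i <- log(p$hormone_medians$iplasma[[h]][[v]])
      yc <- log_out - lmu_y
      rq2a <- if (h == "insulin") p$rq2_a1 else 0
      log_ip <- lmu_i + rq2a * yc + subj[[paste0("iplasma_", h)]][keep] +
        rnorm(m, 0, sds_i[["resid"]])
      ip <- exp(log_ip)
      ip[!sampled] <- NA_real_
      row[[paste0("iplasma_", h)]] <- ip
      if (h == "insulin") {
        ipc_ins <- ifelse(sampled, log_ip - lmu_i, NA_real_)
        yc_ins <- yc
      }
    }

    # infant anthropometry / body composition / intake from sex-visit norms
    nv <- norms[norms$visit == v, ]
    pick <- function(varname) {
      r <- nv[nv$variable == varname, ]
      mu <- ifelse(sex[keep] == "male", r$male, r$female)
      list(mu = mu, sd = r$sd)
    }
    w <- pick("infant_weight_g")
    rq2_med <- ifelse(is.na(ipc_ins), 0, p$rq2_b1 * ipc_ins)
    row$infant_weight_g <- w$mu + subj$infant_weight[keep] +
      p$rq2_c1_prime * yc_ins + rq2_med + rnorm(m, 0, w$sd * 0.55)
    l <- pick("infant_length_cm")
    row$infant_length_cm <- l$mu + subj$infant_length[keep] + rnorm(m, 0, l$sd * 0.55)
    f <- pick("infant_fmi")
    row$infant_fmi <- pmax(f$mu + subj$infant_fmi[keep] + rnorm(m, 0, f$sd * 0.55), 0.5)
    bf <- pick("infant_bodyfat_pct")
    row$infant_bodyfat_pct <- pmax(bf$mu + subj$infant_bodyfat[keep] +
                                     rnorm(m, 0, bf$sd * 0.55), 3)
    ti <- pick("total_intake_ml")
    row$total_intake_true_ml <- pmax(ti$mu + subj$intake[keep] +
                                       rnorm(m, 0, ti$sd * 0.55), 150)

    rows[[v]] <- row
  }

  visit_table <- dplyr::bind_rows(rows)
  visit_table <- dplyr::arrange(visit_table, .data$dyad_id, .data$visit)

  # truth keeps pre-censoring hormone values
  hcols <- as.vector(outer(c("milk_", "mplasma_", "iplasma_"), hormones, paste0))
  precensor <- dplyr::select(visit_table, "dyad_id", "visit",
                             dplyr::any_of(hcols))

  # LOD censoring
  for (col in hcols) {
    flag <- paste0(col, "_below_lod")
    if (!col %in% names(visit_table)) next
    lim <- p$censor_limits[[col]]
    vals <- visit_table[[col]]
    if (p$lod_censor && !is.null(lim)) {
      below <- !is.na(vals) & vals < lim
      vals[below] <- NA_real_
      visit_table[[col]] <- vals
      visit_table[[flag]] <- below
    } else {
      visit_table[[flag]] <- ifelse(is.na(vals), NA, FALSE)
    }
  }

  # true daily totals drive the feed logs
  feed_src <- dplyr::filter(visit_table, .data$visit != "V1")
  n_feeds_mean <- c(V2 = 9.5, V3 = 9.3, V4 = 7.0)
  feed_logs <- vector("list", nrow(feed_src))
  if (p$make_feed_logs && nrow(feed_src) > 0) {
    seeds <- sample.int(.Machine$integer.max, nrow(feed_src))
    nf <- pmax(4L, as.integer(round(rnorm(nrow(feed_src),
                                          n_feeds_mean[feed_src$visit], 1.3))))
    miss_k <- rbinom(nrow(feed_src), nf, p$feed_miss_rate)
    spike_k <- rbinom(nrow(feed_src), nf, p$feed_spike_rate)
    miss_k <- pmin(miss_k, nf - spike_k)
    for (i in seq_len(nrow(feed_src))) {
      fl <- generate_feed_log(
        daily_total_ml = feed_src$total_intake_true_ml[i],
        n_feeds = nf[i], noise_sd = p$feed_noise_sd,
        miss_k = miss_k[i], spike_k = spike_k[i], seed = seeds[i],
        base_weight_g = feed_src$infant_weight_g[i]
      )
      fl$dyad_id <- feed_src$dyad_id[i]
      fl$visit <- feed_src$visit[i]
      feed_logs[[i]] <- fl
    }
  }
  feed_logs <- dplyr::bind_rows(feed_logs)
  if (nrow(feed_logs) > 0) {
    feed_logs <- dplyr::select(feed_logs, "dyad_id", "visit", dplyr::everything())
  }

  truth <- structure(list(
    effects = list(a1 = p$a1, b1 = p$b1, b3 = p$b3, c1_prime = p$c1_prime,
                   rq2_a1 = p$rq2_a1, rq2_b1 = p$rq2_b1,
                   rq2_c1_prime = p$rq2_c1_prime,
                   covariate_effects = p$covariate_effects),
    bmi_anchor = bmi_anchor,
    seed = p$seed,
    subject_intercepts = tibble::as_tibble(c(list(dyad_id = dyad_id), subj)),
    precensor_hormones = precensor,
    true_daily_intake = dplyr::select(feed_src, "dyad_id", "visit",
                                      "total_intake_true_ml")
  ), class = "cohort_truth")

  structure(list(visit_table = visit_table, feed_logs = feed_logs,
                 truth = truth),
            class = "milk_cohort")
}

#' Generate one 24-hour test-weighing feed log
#'
#' Builds `n_feeds` timestamped pre/post weighings inside a 24-h window
#' starting 08:00, whose weight differences sum exactly to `daily_total_ml`
#' before perturbation (density 1 g/mL). Optionally deletes weights
#' (`miss_k`), forces unrealistically high feeds above 400 g (`spike_k`),
#' and adds per-weighing scale noise.
#'
#' @param daily_total_ml True 24-h intake in mL (> 0).
#' @param n_feeds Number of feeds (>= 1).
#' @param noise_sd SD (g) of weighing noise added to each post weight.
#' @param miss_k Number of feeds with a deleted (missing) post weight.
#' @param spike_k Number of feeds forced to a > 400 g difference.
#' @param seed Integer seed.
#' @param base_weight_g Approximate infant weight (g) anchoring pre weights.
#' @return A tibble with one row per feed: `event_index`, `start_time`
#'   (ISO-8601), `pre_weight_g`, `post_weight_g`, `breast`.
#' @examples
#' generate_feed_log(800, 8, noise_sd = 0, miss_k = 0, spike_k = 0, seed = 7)
#' @export
generate_feed_log <- function(daily_total_ml, n_feeds, noise_sd = 0,
                              miss_k = 0, spike_k = 0, seed,
                              base_weight_g = 5500) {
  if (daily_total_ml <= 0) stop("daily_total_ml must be > 0", call. = FALSE)
  if (n_feeds < 1) stop("n_feeds must be >= 1", call. = FALSE)
  if (miss_k < 0 || spike_k < 0) stop("miss_k and spike_k must be >= 0", call. = FALSE)
  if (miss_k + spike_k > n_feeds) {
    stop("miss_k + spike_k must not exceed n_feeds", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  withr::with_seed(seed, {
    # Dirichlet split of the daily total across feeds
    g <- rgamma(n_feeds, shape = 8, rate = 1)
    vol <- daily_total_ml * g / sum(g)
    # feed times in the 08:00-07:59 window
    hours <- sort(runif(n_feeds, 0, 24))
    start <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC") + hours * 3600
    pre <- base_weight_g + cumsum(c(0, vol[-n_feeds])) +
      rnorm(n_feeds, 0, noise_sd)
    post <- pre + vol + rnorm(n_feeds, 0, noise_sd)
    perturb <- sample.int(n_feeds, miss_k + spike_k)
    if (spike_k > 0) {
      sp <- perturb[seq_len(spike_k)]
      post[sp] <- pre[sp] + 401 + runif(spike_k, 0, 120)
    }
    if (miss_k > 0) {
      ms <- perturb[spike_k + seq_len(miss_k)]
      post[ms] <- NA_real_
    }
    tibble::tibble(
      event_index = seq_len(n_feeds),
      start_time = format(start, "%Y-%m-%dT%H:%M:%SZ"),
      pre_weight_g = pre,
      post_weight_g = post,
      breast = sample(c("left", "right", "both"), n_feeds,
                      replace = TRUE, prob = c(0.45, 0.45, 0.1))
    )
  })
}

#' @export
print.milk_cohort <- function(x, ...) {
  cat("<milk_cohort>\n")
  cat("  visit rows:", nrow(x$visit_table),
      " dyads:", length(unique(x$visit_table$dyad_id)), "\n")
  cat("  feed events:", nrow(x$feed_logs), "\n")
  e <- x$truth$effects
  cat(sprintf("  truth: a1 = %g, b1 = %g, b3 = %g, c1' = %g\n",
              e$a1, e$b1, e$b3, e$c1_prime))
  invisible(x)
}
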