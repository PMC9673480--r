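test_that("cohort generation is deterministic under a fixed seed", {
  p <- quick_params(n_dyads = 40, seed = 7)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a$visit_table, b$visit_table)
  expect_identical(a$feed_logs, b$feed_logs)
  expect_identical(a$truth$subject_intercepts, b$truth$subject_intercepts)

  c <- generate_cohort(quick_params(n_dyads = 40, seed = 8))
  expect_false(identical(a$visit_table, c$visit_table))
})

test_that("parameter validation rejects bad inputs", {
  expect_error(cohort_params(n_dyads = 0, seed = 1), "positive")
  expect_error(cohort_params(n_dyads = 10), "seed")
  expect_error(cohort_params(n_dyads = 10, seed = 1, dropout = c(V2 = 1.2)),
               "retention")
  expect_error(cohort_params(n_dyads = 10, seed = 1,
                             visit_windows = list(V2 = c(1, 4),
                                                  V3 = c(3.5, 6),
                                                  V4 = c(6, 8.5))),
               "window")
  bad_med <- default_hormone_medians()
  bad_med$milk$leptin[["V2"]] <- -1
  expect_error(cohort_params(n_dyads = 10, seed = 1,
                             hormone_medians = bad_med), "positive")
})

test_that("zero-effect cohorts show no exposure-outcome association", {
  tbl <- quick_analysis_table(quick_params(n_dyads = 1000, seed = 31))
  r <- cor(tbl$bmi, tbl$log_milk_leptin, use = "complete.obs")
  # ~3 Monte Carlo SEs at n > 1000 rows
  expect_lt(abs(r), 0.06)
})

test_that("per-visit medians calibrate to the configured values", {
  ch <- generate_cohort(quick_params(n_dyads = 2000, seed = 5))
  med <- default_hormone_medians()
  tbl <- ch$visit_table
  for (case in list(c("milk", "leptin", "V2"), c("milk", "insulin", "V3"),
                    c("milk", "adiponectin", "V4"), c("mplasma", "leptin", "V2"),
                    c("iplasma", "insulin", "V3"), c("milk", "leptin", "V1"))) {
    col <- paste0(case[1], "_", case[2])
    target <- med[[case[1]]][[case[2]]][[case[3]]]
    obs <- median(tbl[[col]][tbl$visit == case[3]], na.rm = TRUE)
    expect_lt(abs(obs - target) / target, 0.10)
  }
})

test_that("visit ages fall inside their windows and drift shows in BMI", {
  tbl <- generate_cohort(quick_params(n_dyads = 400, seed = 11))$visit_table
  v2 <- tbl[tbl$visit == "V2", ]; v4 <- tbl[tbl$visit == "V4", ]
  expect_true(all(v2$infant_age_months >= 1.0 & v2$infant_age_months <= 3.49))
  expect_true(all(v4$infant_age_months >= 6.0 & v4$infant_age_months <= 8.5))
  expect_gt(mean(v2$bmi), mean(v4$bmi))  # postpartum weight loss
})

test_that("infant blood sampling is V2 for all, exactly one of V3/V4", {
  ch <- generate_cohort(quick_params(n_dyads = 600, seed = 13))
  tbl <- ch$visit_table
  expect_true(all(!is.na(tbl$iplasma_leptin[tbl$visit == "V2"])))
  wide <- tidyr::pivot_wider(tbl[tbl$visit %in% c("V3", "V4"), ],
                             id_cols = "dyad_id", names_from = "visit",
                             values_from = "iplasma_leptin")
  n_sampled <- (!is.na(wide$V3)) + (!is.na(wide$V4))
  expect_true(all(n_sampled == 1))
  frac_v3 <- mean(!is.na(wide$V3))
  expect_lt(abs(frac_v3 - 0.5), 3 * sqrt(0.25 / nrow(wide)))
})

test_that("LOD censoring replaces sub-threshold values and truth keeps them", {
  p <- quick_params(n_dyads = 400, seed = 17, lod_censor = TRUE)
  ch <- generate_cohort(p)
  tbl <- ch$visit_table
  flagged <- !is.na(tbl$milk_leptin_below_lod) & tbl$milk_leptin_below_lod
  expect_gt(sum(flagged), 0)  # milk leptin medians near the 11 pg/mL limit
  expect_true(all(is.na(tbl$milk_leptin[flagged])))
  expect_true(all(tbl$milk_leptin[!flagged & !is.na(tbl$milk_leptin)] >= 11))
  pre <- ch$truth$precensor_hormones
  joined <- dplyr::left_join(tbl[flagged, c("dyad_id", "visit")], pre,
                             by = c("dyad_id", "visit"))
  expect_true(all(joined$milk_leptin < 11))
})

test_that("feed logs conserve the daily total and honour forced perturbations", {
  fl <- generate_feed_log(800, 8, noise_sd = 0, miss_k = 0, spike_k = 0, seed = 3)
  expect_equal(nrow(fl), 8)
  expect_equal(sum(fl$post_weight_g - fl$pre_weight_g), 800)

  sp <- generate_feed_log(800, 8, noise_sd = 0, miss_k = 0, spike_k = 1, seed = 3)
  d <- sp$post_weight_g - sp$pre_weight_g
  expect_equal(sum(d > 400), 1)

  ms <- generate_feed_log(600, 6, noise_sd = 5, miss_k = 2, spike_k = 0, seed = 3)
  expect_equal(sum(is.na(ms$post_weight_g)), 2)

  expect_error(generate_feed_log(600, 4, 0, miss_k = 3, spike_k = 2, seed = 1),
               "exceed")
  expect_error(generate_feed_log(-5, 4, 0, 0, 0, seed = 1), "daily_total_ml")
  expect_identical(generate_feed_log(700, 7, 2, 1, 1, seed = 9),
                   generate_feed_log(700, 7, 2, 1, 1, seed = 9))
})

test_that("feed-log events are timestamped within the 24-h window from 08:00", {
  fl <- generate_feed_log(750, 9, noise_sd = 0, miss_k = 0, spike_k = 0, seed = 21)
  t <- as.POSIXct(fl$start_time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  t0 <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC")
  expect_true(all(t >= t0 & t < t0 + 24 * 3600))
  expect_false(is.unsorted(t))
})

test_that("cohort CSV/JSON round trip preserves the truth", {
  ch <- generate_cohort(quick_params(n_dyads = 15, seed = 23))
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  back <- read_cohort(dir)
  expect_equal(back$truth$effects$a1, ch$truth$effects$a1)
  expect_equal(back$truth$seed, ch$truth$seed)
  expect_equal(nrow(back$visit_table), nrow(ch$visit_table))
  expect_equal(back$visit_table$milk_leptin, ch$visit_table$milk_leptin,
               tolerance = 1e-12)
  expect_equal(back$truth$subject_intercepts$milk_leptin,
               ch$truth$subject_intercepts$milk_leptin, tolerance = 1e-12)
})
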