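# Small, fast cohort parameter sets used across test files.

# Clean cohort: no censoring, full retention, colostrum for everyone,
# noise-free feed logs. Effects default to zero unless overridden.
quick_params <- function(n_dyads = 120, seed = 1, lod_censor = FALSE, ...) {
  cohort_params(
    n_dyads = n_dyads, seed = seed,
    lod_censor = lod_censor,
    dropout = c(V2 = 1, V3 = 1, V4 = 1),
    v1_collection_rate = 1,
    feed_noise_sd = 0, feed_miss_rate = 0, feed_spike_rate = 0,
    ...
  )
}

# Generate + preprocess, postpartum visits only.
quick_analysis_table <- function(params) {
  ch <- generate_cohort(params)
  tbl <- preprocess_visits(ch$visit_table)
  dplyr::filter(tbl, visit != "V1")
}

# Plain longitudinal toy (no cohort machinery): n subjects x k visits with a
# known fixed-effect structure and random intercept, for lmm unit tests.
toy_longitudinal <- function(n = 15, k = 3, beta = c(intercept = 1, x = 0.5),
                             sd_u = 0.5, sd_e = 0.3, seed = 42) {
  withr::with_seed(seed, {
    id <- rep(seq_len(n), each = k)
    x <- rnorm(n * k)
    u <- rep(rnorm(n, 0, sd_u), each = k)
    y <- beta[["intercept"]] + beta[["x"]] * x + u + rnorm(n * k, 0, sd_e)
    data.frame(dyad_id = id, x = x, y = y)
  })
}
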