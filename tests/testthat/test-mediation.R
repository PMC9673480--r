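test_that("effect decomposition follows the product-of-coefficients identity", {
  d <- decompose_effects(a1 = 0.5, b1 = 0.8, b3 = 0, c1 = 0.6, level_x = c(0, 1))
  expect_equal(d$indirect, c(0.4, 0.4))       # interaction-free collapse
  expect_equal(d$direct + d$indirect, rep(0.6, 2))

  d2 <- decompose_effects(a1 = 0, b1 = 3, b3 = 2, c1 = 1, level_x = 0.7)
  expect_equal(unlist(d2[, c("indirect", "direct", "proportion_mediated")]),
               c(indirect = 0, direct = 1, proportion_mediated = 0))

  # worked splits on reported-scale coefficients
  ow <- decompose_effects(a1 = 1, b1 = 0.81, b3 = 0, c1 = 1.6, level_x = 1)
  expect_equal(ow$direct, 0.79)
  expect_equal(round(ow$proportion_mediated), 51)

  ins <- decompose_effects(a1 = 1, b1 = 0.0039, b3 = 0, c1 = 0.0249, level_x = 0)
  expect_equal(ins$direct, 0.021)
  expect_equal(round(100 * ins$direct / 0.0249), 84)

  expect_true(is.na(decompose_effects(0.5, 0.8, 0, c1 = 0)$proportion_mediated))
})

test_that("Monte Carlo CI handles degenerate and null cases", {
  mc <- monte_carlo_ci(2, 0, 3, matrix(0), n_draws = 2000, seed = 1)
  expect_equal(c(mc$lo, mc$hi), c(6, 6))

  null <- monte_carlo_ci(0, 1, 0, matrix(1), n_draws = 2e5, seed = 2)
  expect_lt(null$lo, 0); expect_gt(null$hi, 0)
  expect_lt(abs(null$lo + null$hi), 0.05)  # symmetric about 0

  expect_error(monte_carlo_ci(1, 1, 1, matrix(1), n_draws = 10, seed = 1),
               "n_draws")
  expect_error(monte_carlo_ci(1, 1, c(1, 1),
                              matrix(c(1, 2, 2, 1), 2), seed = 1),
               "positive semi-definite")
  expect_error(monte_carlo_ci(1, -0.1, 1, matrix(1), seed = 1),
               "positive semi-definite")
  expect_error(monte_carlo_ci(1, 1, 1, matrix(1), n_draws = 2000), "seed")
})

test_that("Monte Carlo CI matches a brute-force product-distribution oracle", {
  # independent reimplementation: direct product of two independent normals
  oracle <- withr::with_seed(99, {
    quantile(rnorm(1e6, 0.5, 0.1) * rnorm(1e6, 0.8, 0.1),
             c(0.025, 0.975), names = FALSE)
  })
  mc <- monte_carlo_ci(0.5, 0.01, 0.8, matrix(0.01), n_draws = 1e6, seed = 123)
  expect_lt(abs(mc$lo - oracle[1]), 0.005)
  expect_lt(abs(mc$hi - oracle[2]), 0.005)
})

test_that("interaction draws produce level-dependent intervals", {
  Vb <- matrix(c(0.01, 0.002, 0.002, 0.04), 2)
  mc0 <- monte_carlo_ci(0.5, 0.01, c(0.8, 0.3), Vb, level_x = 0,
                        n_draws = 50000, seed = 11)
  mc1 <- monte_carlo_ci(0.5, 0.01, c(0.8, 0.3), Vb, level_x = 1,
                        n_draws = 50000, seed = 11)
  expect_equal(mc0$point, 0.4)
  expect_equal(mc1$point, 0.55)
  expect_gt(mc1$hi, mc0$hi)
  expect_true(mc0$lo <= mc0$point & mc0$point <= mc0$hi)
  expect_true(mc1$lo <= mc1$point & mc1$point <= mc1$hi)
})

test_that("run_mediation recovers a generated mediation structure", {
  tbl <- quick_analysis_table(quick_params(n_dyads = 400, seed = 202,
                                           a1 = 0.5, b1 = 0.8, c1_prime = 0.2))
  spec <- mediation_spec("bmi", "log_mplasma_leptin", "log_milk_leptin",
                         c("infant_sex", "visit", "centered_age"),
                         n_draws = 10000, seed = 7)
  res <- run_mediation(tbl, spec)
  eff <- res$effects
  mc_se <- (eff$ci_hi - eff$ci_lo) / (2 * 1.96)
  expect_lt(abs(eff$indirect - 0.40), 3 * mc_se)
  expect_lt(abs(res$a1 - 0.5), 3 * res$a1_se)
  expect_lt(abs(res$b1 - 0.8), 3 * res$b1_se)
  # decomposition identity to machine precision
  expect_equal(eff$direct + eff$indirect, res$c1, tolerance = 1e-12)
  expect_true(eff$indirect_significant)
  # same spec + seed reruns identically
  res2 <- run_mediation(tbl, spec)
  expect_identical(tidy(res), tidy(res2))
})

test_that("product equals difference of coefficients in the fixed-effect case", {
  # one row per subject, no interaction: a1*b1 == c1 - c1'' algebraically
  withr::with_seed(33, {
    n <- 150
    x <- rnorm(n)
    m <- 0.4 * x + rnorm(n)
    y <- 0.3 * x + 0.7 * m + rnorm(n)
    d <- data.frame(dyad_id = seq_len(n), x = x, m = m, y = y)
  })
  spec <- mediation_spec("x", "m", "y", n_draws = 1000, seed = 3)
  res <- run_mediation(d, spec)
  c1pp <- res$steps$outcome$coef[["x"]]
  expect_equal(res$effects$indirect, res$c1 - c1pp, tolerance = 1e-8)
})

test_that("mediation with interaction reports level-specific effects", {
  tbl <- quick_analysis_table(quick_params(n_dyads = 500, seed = 303,
                                           a1 = 0.4, b1 = 0.6, b3 = 0.25,
                                           c1_prime = 0.3))
  spec <- mediation_spec("bmi_high", "log_mplasma_leptin", "log_milk_leptin",
                         c("infant_sex", "visit", "centered_age"),
                         exposure_mediator_interaction = TRUE,
                         exposure_levels = c(0, 1),
                         n_draws = 5000, seed = 17)
  res <- run_mediation(tbl, spec)
  expect_equal(nrow(res$effects), 2)
  expect_false(is.na(res$p_interaction))
  expect_equal(res$effects$indirect, res$a1 * (res$b1 + res$b3 * c(0, 1)))
  expect_equal(res$effects$direct + res$effects$indirect, rep(res$c1, 2))
})

test_that("null mediation structures yield CIs covering zero", {
  covered <- vapply(1:25, function(i) {
    tbl <- quick_analysis_table(quick_params(n_dyads = 150, seed = 400 + i))
    spec <- mediation_spec("bmi", "log_mplasma_leptin", "log_milk_leptin",
                           c("infant_sex", "visit", "centered_age"),
                           n_draws = 2000, seed = i)
    eff <- run_mediation(tbl, spec)$effects
    eff$ci_lo <= 0 && 0 <= eff$ci_hi
  }, logical(1))
  expect_gte(mean(covered), 0.84)  # 95% nominal, 25 draws
})

test_that("interaction screening dichotomises only when warranted", {
  tbl <- quick_analysis_table(quick_params(n_dyads = 500, seed = 505,
                                           a1 = 0.4, b1 = 0.6, b3 = 0.3,
                                           c1_prime = 0.3))
  spec0 <- mediation_spec("bmi", "log_mplasma_leptin", "log_milk_leptin",
                          c("infant_sex", "visit", "centered_age"),
                          n_draws = 2000, seed = 5)
  spec <- screen_and_dichotomize(tbl, spec0)
  expect_true(spec$exposure_mediator_interaction)
  expect_equal(spec$exposure, "bmi_high")
  expect_equal(spec$exposure_levels, c(0, 1))
  expect_lt(attr(spec, "p_interaction"), 0.05)
  res <- run_mediation(tbl, spec, seed = 5)
  expect_equal(nrow(res$effects), 2)

  # already-categorical exposure is a contract violation
  expect_error(screen_and_dichotomize(tbl, mediation_spec(
    "bmi_high", "log_mplasma_leptin", "log_milk_leptin", seed = 1)),
    "categorical")
})

test_that("run_mediation validates its contract", {
  tbl <- quick_analysis_table(quick_params(n_dyads = 50, seed = 2))
  expect_error(run_mediation(tbl, mediation_spec(
    "bmi", "log_mplasma_cortisol", "log_milk_leptin", seed = 1)),
    "log_mplasma_cortisol")
  expect_error(run_mediation(tbl, mediation_spec(
    "bmi", "log_mplasma_leptin", "log_milk_leptin")),
    "seed")
  expect_error(mediation_spec("bmi", "m", "y", n_draws = 100), "n_draws")
  expect_error(mediation_spec("bmi", "m", "y", ci_level = 1.2), "ci_level")
})

test_that("mediation results serialise to JSON with full provenance", {
  tbl <- quick_analysis_table(quick_params(n_dyads = 80, seed = 3))
  res <- run_mediation(tbl, mediation_spec(
    "bmi", "log_mplasma_leptin", "log_milk_leptin",
    c("infant_sex", "visit", "centered_age"), n_draws = 1000, seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_mediation_json(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$c1, res$c1, tolerance = 1e-12)
  expect_equal(back$seed, 4)
  expect_equal(back$n_complete, res$n_complete)
  expect_named(back$steps, c("total", "mediator", "outcome", "total_full"))
})
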