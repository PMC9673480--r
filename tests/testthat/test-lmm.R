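test_that("constant outcome with intercept only returns the constant", {
  d <- data.frame(dyad_id = rep(1:6, each = 2), y = 5.0)
  # lm's perfect-fit warning is expected on exactly constant data
  fit <- suppressWarnings(
    fit_lmm(d, model_spec("y", character(), grouping = "dyad_id")))
  expect_equal(unname(fit$coef[["(Intercept)"]]), 5.0, tolerance = 1e-10)
  expect_equal(unname(fit$varcomp[["residual"]]), 0, tolerance = 1e-10)
})

test_that("one observation per subject reduces to ordinary least squares", {
  withr::with_seed(10, {
    d <- data.frame(dyad_id = 1:40, x = rnorm(40), z = rnorm(40))
    d$y <- 2 + 0.7 * d$x - 0.3 * d$z + rnorm(40, 0, 0.4)
  })
  fit <- fit_lmm(d, model_spec("y", c("x", "z")))
  expect_equal(fit$engine, "ols")
  # normal-equations oracle
  X <- cbind(1, d$x, d$z)
  beta_hat <- solve(t(X) %*% X, t(X) %*% d$y)[, 1]
  expect_equal(unname(fit$coef), unname(beta_hat), tolerance = 1e-6)
})

test_that("mixed-model coefficients equal the GLS oracle at the fitted theta", {
  d <- toy_longitudinal(n = 18, k = 3, seed = 77)
  fit <- fit_lmm(d, model_spec("y", "x"))
  expect_equal(fit$engine, "lmer")
  # GLS with the estimated variance components, independent linear algebra
  ids <- d$dyad_id
  n <- nrow(d)
  V <- diag(fit$varcomp[["residual"]], n) +
    fit$varcomp[["subject"]] * outer(ids, ids, `==`)
  X <- cbind(1, d$x)
  Vi_X <- solve(V, X)
  beta_gls <- solve(t(X) %*% Vi_X, t(Vi_X) %*% d$y)[, 1]
  expect_equal(unname(fit$coef), unname(beta_gls), tolerance = 1e-4)
  vcov_gls <- solve(t(X) %*% Vi_X)
  expect_equal(unname(diag(fit$vcov)), unname(diag(vcov_gls)), tolerance = 1e-3)
})

test_that("the exposure-mediator slope is recovered on a synthetic cohort", {
  tbl <- quick_analysis_table(quick_params(n_dyads = 400, seed = 101,
                                           a1 = 0.5, b1 = 0.8, c1_prime = 0.2))
  fit <- fit_lmm(tbl, model_spec("log_mplasma_leptin",
                                 c("bmi", "infant_sex", "visit", "centered_age")))
  a1_hat <- fit$coef[["bmi"]]
  expect_lt(abs(a1_hat - 0.5), 3 * fit$se[["bmi"]])
})

test_that("fit_lmm validates inputs and reports structure", {
  d <- toy_longitudinal(n = 10, k = 2)
  expect_error(fit_lmm(d, model_spec("y", "missing_col")), "missing_col")
  expect_error(model_spec("y", c("x", "y")), "outcome")
  expect_error(model_spec("y", "x", interactions = list(c("x", "z"))),
               "fixed_terms")
  fit <- fit_lmm(d, model_spec("y", "x"))
  expect_equal(fit$n_obs, 20)
  expect_equal(fit$n_subjects, 10)
  expect_true(isSymmetric(fit$vcov))
  expect_equal(rownames(fit$vcov), names(fit$coef))
  td <- tidy(fit)
  expect_equal(td$estimate, unname(fit$coef))
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("interaction Wald test holds its size and detects strong effects", {
  # type-I error under b3 = 0
  reject <- withr::with_seed(55, {
    vapply(1:400, function(i) {
      n <- 80; k <- 2
      id <- rep(seq_len(n), each = k)
      x <- rep(rnorm(n), each = k)
      m <- rnorm(n * k)
      y <- 0.3 * x + 0.5 * m + rep(rnorm(n, 0, 0.5), each = k) +
        rnorm(n * k, 0, 0.5)
      d <- data.frame(dyad_id = id, x = x, m = m, y = y)
      test_interaction(d, model_spec("y", c("x", "m")), c("x", "m"))$significant
    }, logical(1))
  })
  expect_lt(abs(mean(reject) - 0.05), 0.03)

  # power under a large interaction
  withr::with_seed(56, {
    n <- 120; k <- 2
    id <- rep(seq_len(n), each = k)
    x <- rep(rnorm(n), each = k)
    m <- rnorm(n * k)
    y <- 0.3 * x + 0.5 * m + 0.6 * x * m + rep(rnorm(n, 0, 0.5), each = k) +
      rnorm(n * k, 0, 0.5)
    d <- data.frame(dyad_id = id, x = x, m = m, y = y)
    res <- test_interaction(d, model_spec("y", c("x", "m")), c("x", "m"))
    expect_true(res$significant)
  })

  expect_error(
    test_interaction(toy_longitudinal(), model_spec("y", "x"), c("x", "q")),
    "fixed_terms")
})

test_that("log-scale back-transforms are exact closed forms", {
  expect_equal(percent_difference(log(2)), 100)
  expect_equal(percent_difference(0), 0)
  expect_equal(percent_difference(-0.78), 100 * (exp(-0.78) - 1))
  expect_equal(round(percent_difference(-0.78), 1), -54.2)
  expect_equal(round(percent_difference(1.6)), 395)
  expect_equal(effect_per_percent_increase(140.2, 10), 140.2 * log(1.1))
  expect_equal(round(effect_per_percent_increase(140.2, 10), 1), 13.4)
  expect_equal(round(effect_per_percent_increase(-89.8, 10), 2), -8.56)
  expect_equal(effect_per_percent_increase(123, 0), 0)
  expect_error(effect_per_percent_increase(1, -100), "-100")
})

test_that("adjacent-visit contrasts recover a halving trajectory", {
  med <- default_hormone_medians()
  med$milk$leptin <- c(V1 = 320, V2 = 160, V3 = 80, V4 = 40)
  tbl <- preprocess_visits(generate_cohort(
    quick_params(n_dyads = 300, seed = 61, hormone_medians = med))$visit_table)
  vc <- visit_contrasts(tbl, "leptin", "milk")
  expect_equal(nrow(vc), 3)
  for (i in 1:3) {
    expect_lt(abs(vc$estimate[i] - (-log(2))), 3 * vc$se[i])
  }
  expect_equal(vc$percent_difference, 100 * (exp(vc$estimate) - 1))
  single <- tbl[tbl$visit == "V2", ]
  expect_error(visit_contrasts(single, "leptin", "milk"), "2 visits")
})

test_that("orthogonal covariates leave other estimates unchanged on balance", {
  withr::with_seed(91, {
    n <- 40; k <- 2
    id <- rep(seq_len(n), each = k)
    x <- rep(rnorm(n), each = k)
    z <- rep(c(-1, 1), n)           # balanced within subject, orthogonal to x
    y <- 1 + 0.5 * x + rep(rnorm(n, 0, 0.5), each = k) + rnorm(n * k, 0, 0.3)
    d <- data.frame(dyad_id = id, x = x, z = z, y = y)
  })
  f1 <- fit_lmm(d, model_spec("y", "x"))
  f2 <- fit_lmm(d, model_spec("y", c("x", "z")))
  expect_equal(f1$coef[["x"]], f2$coef[["x"]], tolerance = 1e-6)
})
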