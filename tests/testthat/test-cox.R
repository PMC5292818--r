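test_that("the 4-subject worked example matches its closed form", {
  toy <- cox_toy()
  fit <- fit_cox(toy$covariates, toy$survival)
  expect_equal(fit$beta, log(2) / 2, tolerance = 1e-6)
  expect_equal(fit$hr, sqrt(2), tolerance = 1e-6)
  # null log partial likelihood = -(log 4 + log 3)
  expect_equal(unname(attr(fit, "loglik")["null"]), -(log(4) + log(3)),
               tolerance = 1e-12)
  # and the fitted optimum agrees with a grid search of the written-out
  # partial likelihood
  grid <- seq(-2, 2, by = 1e-4)
  beta_grid <- grid[which.max(cox_toy_loglik(grid))]
  expect_equal(fit$beta, beta_grid, tolerance = 1e-3)
  expect_equal(unname(attr(fit, "loglik")["final"]),
               cox_toy_loglik(fit$beta), tolerance = 1e-10)
})

test_that("Newton-Raphson equals grid search on small problems", {
  set.seed(8)
  for (rep in 1:3) {
    n <- 8
    x <- round(rnorm(n), 2)
    surv <- data.frame(time_months = sample(1:6, n, replace = TRUE),
                       event = c(TRUE, TRUE, runif(n - 2) < 0.6))
    fit <- fit_cox(data.frame(x = x), surv)
    # brute-force partial likelihood on a grid (Breslow ties)
    pl <- function(b) {
      eta <- b * x
      ll <- 0
      for (tau in unique(surv$time_months[surv$event])) {
        D <- which(surv$event & surv$time_months == tau)
        R <- which(surv$time_months >= tau)
        ll <- ll + sum(eta[D]) - length(D) * log(sum(exp(eta[R])))
      }
      ll
    }
    grid <- seq(-4, 4, by = 1e-3)
    expect_equal(fit$beta, grid[which.max(vapply(grid, pl, numeric(1)))],
                 tolerance = 2e-3)
  }
})

test_that("fit agrees with the survival package on both tie methods", {
  skip_if_not_installed("survival")
  set.seed(19)
  n <- 150
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4), c = rnorm(n, 2))
  eta <- 0.5 * X[, "a"] - 0.7 * X[, "b"]
  t_raw <- rexp(n) / (0.05 * exp(eta))
  surv <- data.frame(time_months = pmax(round(pmin(t_raw, 36), 1), 0.1),
                     event = t_raw <= 36)
  for (m in c("breslow", "efron")) {
    fit <- fit_cox(as.data.frame(X), surv, ties = m)
    ref <- survival::coxph(
      survival::Surv(surv$time_months, surv$event) ~ a + b + c,
      data = as.data.frame(X), ties = m)
    expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
    expect_equal(unname(attr(fit, "loglik")), unname(ref$loglik),
                 tolerance = 1e-8)
  }
})

test_that("duplicating every subject leaves the Breslow estimate unchanged", {
  toy <- cox_toy()
  fit1 <- fit_cox(toy$covariates, toy$survival)
  fit2 <- fit_cox(rbind(toy$covariates, toy$covariates),
                  rbind(toy$survival, toy$survival))
  expect_equal(fit2$beta, fit1$beta, tolerance = 1e-6)
})

test_that("covariate scaling transforms beta and fixes z and loglik", {
  set.seed(23)
  n <- 80
  covs <- data.frame(x = rnorm(n))
  t_raw <- rexp(n) / (0.05 * exp(0.8 * covs$x))
  surv <- data.frame(time_months = pmin(t_raw, 36), event = t_raw <= 36)
  f1 <- fit_cox(covs, surv)
  f2 <- fit_cox(data.frame(x = 10 * covs$x), surv)
  expect_equal(f2$beta, f1$beta / 10, tolerance = 1e-8)
  expect_equal(f2$z, f1$z, tolerance = 1e-6)
  expect_equal(attr(f2, "loglik"), attr(f1, "loglik"), tolerance = 1e-10)
})

test_that("hazard_ratio_ci and wald_test satisfy their identities", {
  hc <- hazard_ratio_ci(-7.550, 1.535)
  expect_equal(signif(hc$hr, 3), 5.26e-04)
  expect_equal(hazard_ratio_ci(0, 2)$hr, 1)
  hc2 <- hazard_ratio_ci(-9.398, 2.598)
  expect_equal(signif(hc2$ci_high, 2), 0.013)
  expect_error(hazard_ratio_ci(1, 0), "positive")

  expect_equal(wald_test(0, 1)$p, 1)
  expect_equal(wald_test(1.95996, 1)$p, 0.05, tolerance = 1e-5)
  # high-precision tail: erfc oracle at z = 5
  expect_equal(wald_test(5, 1)$p, 5.733031e-07, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with names", {
  toy <- cox_toy()
  expect_error(fit_cox(data.frame(flat = rep(1, 4)), toy$survival),
               "flat")
  covs <- data.frame(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  expect_error(fit_cox(covs, toy$survival), "collinear")
  no_events <- data.frame(time_months = 1:4, event = rep(FALSE, 4))
  expect_error(fit_cox(data.frame(x = rnorm(4)), no_events),
               "at least one event")
  neg <- data.frame(time_months = c(-1, 2, 3, 4), event = c(TRUE, rep(FALSE, 3)))
  expect_error(fit_cox(data.frame(x = rnorm(4)), neg), "> 0")
})

test_that("monotone likelihood is detected and flagged", {
  # covariate perfectly orders the events: unbounded beta
  surv <- data.frame(time_months = 1:6,
                     event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  covs <- data.frame(x = c(3, 2.5, 2, 1, 0.5, 0))
  expect_warning(fit <- fit_cox(covs, surv), "monotone")
  expect_false(attr(fit, "converged"))
  expect_true(attr(fit, "separated"))
})

test_that("significant_factors filters by Wald p", {
  toy <- cox_toy()
  fit <- fit_cox(toy$covariates, toy$survival)
  expect_identical(significant_factors(fit, alpha = 1), "x")
  expect_identical(significant_factors(fit, alpha = 1e-10), character(0))
})

test_that("a simulated clinical effect is recovered within 3 SE", {
  atlas <- make_source_atlas(2, c(10, 10, 10), 2, seed = 71)
  coh <- simulate_survival_cohort(atlas, true_beta = c(adas_cog = 0.10),
                                  baseline_rate = 0.02, censor_month = 36,
                                  n = 2000, seed = 72, noise_sd = 0)
  fit <- fit_cox(coh$clinical[, c("subject_id", "adas_cog")], coh$survival)
  expect_lt(abs(fit$beta - 0.10), 3 * fit$se)
})

test_that("the five-model suite chains significance correctly", {
  # a world where one structural network, one metabolic network and two
  # clinical variables carry risk
  atl_s <- make_source_atlas(3, c(12, 12, 8), 2, seed = 81, affected_ids = 1L)
  atl_m <- make_source_atlas(3, c(12, 12, 8), 2, seed = 82, affected_ids = 2L)
  coh <- simulate_survival_cohort(
    list(structural = atl_s, metabolic = atl_m),
    true_beta = c(structural_IC_01 = -0.8, metabolic_IC_02 = -0.8,
                  adas_cog = 0.12, apoe_e4 = 0.6),
    baseline_rate = 0.02, censor_month = 36, n = 600, seed = 83,
    noise_sd = 0)
  truth <- as.data.frame(coh$truth$covariates)
  mri <- data.frame(subject_id = coh$survival$subject_id,
                    structural_IC_01 = truth$structural_IC_01,
                    structural_IC_02 = truth$structural_IC_02)
  pet <- data.frame(subject_id = coh$survival$subject_id,
                    metabolic_IC_02 = truth$metabolic_IC_02,
                    metabolic_IC_03 = truth$metabolic_IC_03)
  suite <- suppressMessages(
    run_model_suite(mri, pet, coh$clinical, coh$survival))
  expect_true("structural_IC_01" %in% suite$significant$mri)
  expect_true("metabolic_IC_02" %in% suite$significant$pet)
  expect_true(all(c("structural_IC_01", "metabolic_IC_02") %in%
                    suite$carried$two_modality))
  expect_true(all(c("adas_cog", "apoe_e4") %in%
                    suite$significant$clinical))
  expect_true(all(suite$significant$two_modality %in%
                    suite$carried$comprehensive))
  expect_s3_class(suite$models$comprehensive, "cox_result")

  # identical feature tables for both modalities: collinear, named error
  pet_dup <- mri
  names(pet_dup) <- c("subject_id", "metabolic_IC_01", "metabolic_IC_02")
  pet_dup$metabolic_IC_01 <- mri$structural_IC_01
  pet_dup$metabolic_IC_02 <- mri$structural_IC_02
  expect_error(
    suppressMessages(run_model_suite(mri, pet_dup, coh$clinical,
                                     coh$survival)),
    "collinear")
})

test_that("empty stages are skipped with a reason", {
  atlas <- make_source_atlas(2, c(10, 10, 10), 2, seed = 91)
  coh <- simulate_survival_cohort(atlas, true_beta = c(adas_cog = 0.15),
                                  baseline_rate = 0.02, n = 300, seed = 92,
                                  noise_sd = 0)
  empty_mri <- data.frame(subject_id = coh$survival$subject_id)
  empty_pet <- data.frame(subject_id = coh$survival$subject_id)
  suite <- suppressMessages(
    run_model_suite(empty_mri, empty_pet, coh$clinical, coh$survival))
  expect_null(suite$models$mri)
  expect_null(suite$models$two_modality)
  expect_match(suite$skipped$two_modality, "empty")
  expect_s3_class(suite$models$clinical, "cox_result")
  expect_true("adas_cog" %in% suite$significant$clinical)
  expect_s3_class(suite$models$comprehensive, "cox_result")
})

test_that("cox CSV export mirrors the reporting schema", {
  toy <- cox_toy()
  fit <- fit_cox(toy$covariates, toy$survival)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cox_csv(fit, f)
  tab <- read.csv(f)
  expect_named(tab, c("covariate", "beta", "se", "p", "hr",
                      "ci_low", "ci_high"))
  expect_equal(tab$hr, exp(tab$beta), tolerance = 1e-6)
})
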