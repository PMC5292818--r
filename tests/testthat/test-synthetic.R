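test_that("source atlases are unit-norm, near-orthogonal and deterministic", {
  a1 <- make_source_atlas(1, c(10, 10, 10), 2, seed = 1)
  expect_equal(sqrt(sum(a1$source_maps^2)), 1, tolerance = 1e-12)

  expect_identical(make_source_atlas(4, c(15, 15, 15), 2, seed = 5),
                   make_source_atlas(4, c(15, 15, 15), 2, seed = 5))

  a8 <- make_source_atlas(8, c(20, 20, 20), 3, seed = 7)
  G <- tcrossprod(a8$source_maps)            # all 28 pairwise cosines
  expect_equal(diag(G), rep(1, 8), tolerance = 1e-12)
  diag(G) <- 0
  expect_lt(max(abs(G)), 0.3)

  expect_error(make_source_atlas(50, c(10, 10, 10), 3, seed = 1),
               "grid too small")
  expect_error(make_source_atlas(2, c(4, 4, 4), 3, seed = 1), "grid")
})

test_that("noiseless reference cohorts are exactly low-rank", {
  pl <- make_planted(n_per_group = 10, k = 4, grid = c(12, 12, 8),
                     noise_frac = 0, seed = 2)
  expect_lte(qr(pl$ref$matrix$data)$rank, 4L)
})

test_that("noiseless data regressed on known sources recovers true mixing", {
  pl <- make_planted(n_per_group = 8, k = 3, grid = c(12, 12, 8),
                     noise_frac = 0, seed = 4)
  M <- pl$atlas$source_maps
  # least-squares oracle: A_hat = X M' (M M')^{-1}
  A_hat <- pl$ref$matrix$data %*% t(M) %*% solve(tcrossprod(M))
  expect_equal(A_hat, pl$ref$truth$true_mixing, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("under zero group shift the loading t-test rejects at ~alpha", {
  alpha <- 0.05
  n_rep <- 500
  rejections <- 0L
  tests <- 0L
  atlas <- make_source_atlas(3, c(10, 10, 10), 2, seed = 9)
  for (r in seq_len(n_rep)) {
    ref <- simulate_reference_cohort(atlas, 10, group_shift = 0,
                                     noise_sd = 0, seed = 5000 + r)
    st <- compare_loadings(ref$truth$true_mixing, ref$matrix$group_labels)
    rejections <- rejections + sum(st$p < alpha)
    tests <- tests + nrow(st)
  }
  rate <- rejections / tests
  se <- sqrt(alpha * (1 - alpha) / tests)
  expect_lt(abs(rate - alpha), 3 * se)
})

test_that("group shift moves affected loading means by the stated amount", {
  atlas <- make_source_atlas(4, c(12, 12, 12), 2, seed = 3,
                             affected_ids = c(1L, 3L))
  ref <- simulate_reference_cohort(atlas, 2000, group_shift = 0.8,
                                   noise_sd = 0, seed = 11)
  A <- ref$truth$true_mixing
  grp <- ref$matrix$group_labels
  for (j in atlas$affected_ids) {
    diff <- mean(A[grp == "case", j]) - mean(A[grp == "control", j])
    se <- sqrt(2 / 2000)
    expect_lt(abs(diff - 0.8), 3 * se)
  }
  # unaffected components keep equal means
  diff2 <- mean(A[grp == "case", 2]) - mean(A[grp == "control", 2])
  expect_lt(abs(diff2), 3 * sqrt(2 / 2000))
})

test_that("survival generator matches the exponential closed form", {
  atlas <- make_source_atlas(2, c(10, 10, 10), 2, seed = 21)
  coh <- simulate_survival_cohort(atlas, true_beta = c(adas_cog = 0),
                                  baseline_rate = 0.05, censor_month = 36,
                                  n = 2000, seed = 31, noise_sd = 0)
  frac <- mean(coh$survival$event)
  p <- 1 - exp(-0.05 * 36)                 # 0.8347
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 2000))
})

test_that("censoring is administrative at exactly the horizon", {
  atlas <- make_source_atlas(2, c(10, 10, 10), 2, seed = 21)
  coh <- simulate_survival_cohort(atlas, true_beta = c(cdr_sb = 0.2),
                                  baseline_rate = 0.02, censor_month = 36,
                                  n = 300, seed = 7, noise_sd = 0)
  cens <- coh$survival[!coh$survival$event, ]
  expect_gt(nrow(cens), 0)
  expect_true(all(cens$time_months == 36))
  expect_true(all(coh$survival$time_months > 0))

  # vanishing hazard: everyone censored
  all_cens <- simulate_survival_cohort(atlas, true_beta = c(cdr_sb = 0),
                                       baseline_rate = 1e-9, censor_month = 36,
                                       n = 50, seed = 8, noise_sd = 0)
  expect_true(all(!all_cens$survival$event))
  expect_error(
    simulate_survival_cohort(atlas, true_beta = c(cdr_sb = 0),
                             baseline_rate = 0, censor_month = 36,
                             n = 50, seed = 8),
    "baseline_rate")
})

test_that("cohorts are bit-identical for identical seeds", {
  atlas <- make_source_atlas(3, c(10, 10, 10), 2, seed = 2)
  a <- simulate_survival_cohort(atlas, true_beta = c(adas_cog = 0.1),
                                baseline_rate = 0.02, n = 60, seed = 99)
  b <- simulate_survival_cohort(atlas, true_beta = c(adas_cog = 0.1),
                                baseline_rate = 0.02, n = 60, seed = 99)
  expect_identical(a, b)
  r1 <- simulate_reference_cohort(atlas, 10, 1, 0.01, seed = 5)
  r2 <- simulate_reference_cohort(atlas, 10, 1, 0.01, seed = 5)
  expect_identical(r1, r2)
})

test_that("clinical tables respect their invariants", {
  atlas <- make_source_atlas(2, c(10, 10, 10), 2, seed = 2)
  coh <- simulate_survival_cohort(atlas, true_beta = c(apoe_e4 = 0.5),
                                  baseline_rate = 0.02, n = 500, seed = 12)
  cl <- coh$clinical
  expect_false(anyNA(cl))
  expect_true(all(cl$apoe_e4 %in% 0:2))
  expect_true(all(cl$mmse >= 0 & cl$mmse <= 30))
  expect_true(all(cl$cdr_sb >= 0))
  expect_true(all(cl$gender %in% 0:1))
  # cognitive scales co-vary as configured
  expect_gt(cor(cl$adas_cog, cl$cdr_sb), 0.2)
  expect_lt(cor(cl$adas_cog, cl$mmse), -0.2)
})

test_that("unknown hazard covariates are rejected by name", {
  atlas <- make_source_atlas(2, c(10, 10, 10), 2, seed = 2)
  expect_error(
    simulate_survival_cohort(atlas, true_beta = c(nonexistent = 1),
                             baseline_rate = 0.02, n = 20, seed = 1),
    "nonexistent")
})

test_that("write_cohort produces volumes, CSV and ground-truth JSON", {
  atlas <- make_source_atlas(2, c(8, 8, 8), 2, seed = 13)
  coh <- simulate_survival_cohort(atlas, true_beta = c(adas_cog = 0.1),
                                  baseline_rate = 0.02, n = 10, seed = 14)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "subjects.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  niis <- list.files(file.path(dir, "structural"), pattern = "\\.nii$")
  expect_length(niis, 10L)
  v <- read_volume(file.path(dir, "structural", "mci_0001.nii"))
  expect_equal(v$data[coh$matrices$structural$mask],
               coh$matrices$structural$data[1, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  tab <- read.csv(file.path(dir, "subjects.csv"))
  expect_setequal(tab$subject_id, coh$survival$subject_id)
  expect_true(all(c("time_months", "event", "adas_cog") %in% names(tab)))
})
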