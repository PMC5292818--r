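test_that("compare_loadings matches the pooled-t formula", {
  A <- cbind(c(1, 2, 3, 4, 5, 6))
  labels <- factor(rep(c("a", "b"), each = 3))
  st <- compare_loadings(A, labels)
  # textbook pooled t for {1,2,3} vs {4,5,6}
  expect_equal(abs(st$t), 3.674235, tolerance = 1e-6)
  expect_equal(st$df, 4)
  expect_equal(st$p, 0.02131164, tolerance = 1e-6)

  # identical group loadings: t = 0, p = 1
  A0 <- cbind(rep(c(1, 2, 3), 2))
  st0 <- compare_loadings(A0, labels)
  expect_equal(st0$t, 0)
  expect_equal(st0$p, 1)

  # swapping labels negates t, keeps p
  st_sw <- compare_loadings(A, factor(rep(c("b", "a"), each = 3)))
  expect_equal(st_sw$t, -st$t)
  expect_equal(st_sw$p, st$p)

  # zero pooled variance: flagged, p = 1
  Ac <- cbind(rep(1, 6))
  expect_warning(stc <- compare_loadings(Ac, labels), "zero pooled variance")
  expect_equal(stc$p, 1)

  expect_error(compare_loadings(A, factor(c("a", "a", "a", "a", "a", "b"))),
               ">= 2 subjects")
})

test_that("compare_loadings agrees with t.test on random data", {
  set.seed(14)
  A <- matrix(rnorm(40 * 6), 40, 6)
  labels <- factor(rep(c("x", "y"), 20))
  st <- compare_loadings(A, labels)
  for (j in 1:6) {
    ref <- t.test(A[labels == "x", j], A[labels == "y", j],
                  var.equal = TRUE)
    expect_equal(st$t[j], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(st$p[j], ref$p.value, tolerance = 1e-12)
  }
  stw <- compare_loadings(A, labels, var_equal = FALSE)
  refw <- t.test(A[labels == "x", 1], A[labels == "y", 1])
  expect_equal(stw$t[1], unname(refw$statistic), tolerance = 1e-12)
  expect_equal(stw$p[1], refw$p.value, tolerance = 1e-12)
})

test_that("bonferroni_select divides alpha by the component count", {
  expect_identical(bonferroni_select(c(0.0005, 0.002, 0.04), 0.05),
                   c(1L, 2L))
  expect_identical(suppressMessages(bonferroni_select(rep(1, 5), 0.05)),
                   integer(0))
  # k = 1 reduces to a plain alpha test
  expect_identical(bonferroni_select(0.04, 0.05), 1L)
  expect_identical(suppressMessages(bonferroni_select(0.06, 0.05)),
                   integer(0))
  expect_error(bonferroni_select(c(0.1), 1.2), "alpha")
})

test_that("zscore_map centres, scales and is affine-invariant", {
  z <- zscore_map(c(0, 0, 0, 4))
  expect_equal(z, c(-0.5773503, -0.5773503, -0.5773503, 1.7320508),
               tolerance = 1e-6)
  set.seed(3)
  v <- rnorm(100)
  z1 <- zscore_map(v)
  expect_equal(mean(z1), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z1^2)), 1, tolerance = 1e-12)
  expect_equal(zscore_map(3.2 * v + 7), z1, tolerance = 1e-10)
  expect_error(zscore_map(rep(2, 10)), "constant")
})

test_that("binarize_template uses an inclusive positive threshold", {
  tp <- suppressWarnings(binarize_template(c(2.9, 3.0, 3.1), 3.0,
                                           component_id = 1L))
  expect_identical(tp$in_mask, c(FALSE, TRUE, TRUE))
  expect_true(tp$usable)
  expect_equal(tp$n_voxels, 2L)

  expect_warning(empty <- binarize_template(c(-1, -2, -0.5), 3.0,
                                            component_id = 2L), "empty")
  expect_false(empty$usable)

  set.seed(5)
  z <- zscore_map(rnorm(2000))
  half <- binarize_template(z, 1e-9, component_id = 3L)
  expect_equal(half$n_voxels / 2000, 0.5, tolerance = 0.1)
})

test_that("extract_network_features averages in-template voxels", {
  sm <- structure(list(
    data = matrix(c(7, 7, 7, 7,
                    1, 2, 3, 4), 2, 4, byrow = TRUE,
                  dimnames = list(c("s1", "s2"), NULL)),
    mask = array(TRUE, c(4, 1, 1)), subject_ids = c("s1", "s2"),
    group_labels = NULL, modality = "structural",
    voxel_size = c(1, 1, 1), affine = diag(4)), class = "subject_matrix")
  tp <- binarize_template(c(0, 5, 5, 0), 3.0, component_id = 4L,
                          modality = "structural")
  ft <- extract_network_features(sm, list(tp))
  expect_named(ft, c("subject_id", "structural_IC_04"))
  expect_equal(ft$structural_IC_04, c(7, 2.5))

  bad <- binarize_template(c(5, 5), 3.0, component_id = 5L)
  expect_error(extract_network_features(sm, list(bad)), "2 voxels")
  empty <- suppressWarnings(binarize_template(c(-1, -1, -1, -1), 3.0,
                                              component_id = 6L))
  expect_error(extract_network_features(sm, list(empty)), "empty")
})

test_that("features via subject_matrix equal direct 3-D computation", {
  pl <- make_planted(n_per_group = 6, k = 3, grid = c(10, 10, 8),
                     noise_frac = 0.05, seed = 51)
  sm <- pl$ref$matrix
  z <- zscore_map(pl$atlas$source_maps[2, ])
  tp <- binarize_template(z, 3.0, component_id = 2L, mask3d = sm$mask)
  ft <- extract_network_features(sm, list(tp))
  for (i in c(1L, 5L)) {
    vol <- unstack_subject(sm, i)
    expect_equal(ft[[2]][i], mean(vol$data[tp$mask]))
  }
})

test_that("selection finds shifted components and respects the null", {
  hits <- 0L
  fp <- 0L
  n_rep <- 10
  for (r in seq_len(n_rep)) {
    atlas <- make_source_atlas(4, c(14, 14, 10), 2, seed = 600 + r,
                               affected_ids = 2L)
    ref <- simulate_reference_cohort(atlas, 30, group_shift = 2,
                                     noise_sd = 0.05 * signal_rms(atlas),
                                     seed = 700 + r)
    dec <- suppressWarnings(infomax_ica(ref$matrix, order = 4,
                                        seed = 800 + r))
    sel <- select_networks(dec, ref$matrix$group_labels)
    # which estimated component carries the planted source?
    mt <- match_sources(atlas$source_maps, dec$sources)
    planted <- mt$b[mt$a == 2L]
    chosen <- sel$stats$component[sel$stats$selected]
    if (planted %in% chosen) hits <- hits + 1L
    fp <- fp + length(setdiff(chosen, planted))
  }
  expect_gte(hits, 9L)
  expect_lte(fp / (n_rep * 3), 0.05)  # false selections among 3 null comps
})

test_that("templates are bit-identical across repeated runs", {
  pl <- make_planted(n_per_group = 20, k = 3, grid = c(12, 12, 8),
                     noise_frac = 0.05, group_shift = 2, seed = 61)
  run_once <- function() {
    dec <- infomax_ica(pl$ref$matrix, order = 3, seed = 5)
    select_networks(dec, pl$ref$matrix$group_labels,
                    mask3d = pl$ref$matrix$mask)
  }
  expect_identical(run_once(), run_once())
})

test_that("templates and Z-maps export as NIfTI", {
  pl <- make_planted(n_per_group = 10, k = 2, grid = c(10, 10, 8),
                     noise_frac = 0.05, seed = 71)
  dec <- suppressWarnings(infomax_ica(pl$ref$matrix, order = 2, seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_zmaps(dec, pl$ref$matrix$mask, dir)
  expect_length(paths, 2L)
  z1 <- read_volume(paths[1])
  expect_equal(z1$data[pl$ref$matrix$mask], zscore_map(dec$sources[1, ]),
               tolerance = 1e-12, ignore_attr = TRUE)

  tp <- binarize_template(zscore_map(dec$sources[1, ]), 2.0,
                          component_id = 1L, mask3d = pl$ref$matrix$mask)
  f <- file.path(dir, "tpl.nii")
  write_template(tp, f)
  expect_equal(read_volume(f)$data > 0.5, tp$mask)

  no3d <- binarize_template(zscore_map(dec$sources[1, ]), 2.0)
  expect_error(write_template(no3d, f), "3-D embedding")
})
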