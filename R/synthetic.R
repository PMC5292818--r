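# Synthetic cohorts with retained ground truth.
#
# The generator states a simple world with the statistical structure the
# analysis assumes: subject images are linear mixtures of near-orthogonal
# spatial sources (smoothed spherical blobs), group membership shifts the
# mean loading of designated "affected" components, and conversion times in
# the survival cohort follow a proportional-hazards (exponential baseline)
# model on imaging loadings and clinical covariates, administratively
# censored at a fixed horizon (36 months by default).

#' Build an atlas of blob-shaped spatial sources
#'
#' Places `n_components` non-overlapping Gaussian blobs (sd = `blob_radius`/2,
#' support truncated at 2.5 sd) at random centres, each flattened to a
#' unit-Euclidean-norm voxel map. Centres are rejected until pairwise
#' separation >= 2*`blob_radius`, which keeps the maps pairwise
#' near-orthogonal (|cosine| < 0.3).
#'
#' @param n_components number of sources (>= 1).
#' @param grid_dims integer length-3 voxel grid.
#' @param blob_radius blob radius in voxels.
#' @param seed RNG seed; fixed seed gives a bit-identical atlas.
#' @param affected_ids indices of components that will carry group/risk
#'   effects downstream (default: component 1).
#' @return A `source_atlas`: `n_components`, `grid_dims`, `source_maps`
#'   (components x voxels, rows unit norm, voxels in column-major order),
#'   `affected_ids`, `centers`.
#' @export
make_source_atlas <- function(n_components, grid_dims, blob_radius, seed,
                              affected_ids = 1L) {
  n_components <- assert_count(n_components, "n_components")
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L)
  blob_radius <- assert_number(blob_radius, "blob_radius", min = 1)
  if (any(grid_dims < 2 * blob_radius + 1)) {
    stop("grid too small: blobs of this radius do not fit inside the grid",
         call. = FALSE)
  }
  affected_ids <- sort(unique(as.integer(affected_ids)))
  if (length(affected_ids) &&
      (min(affected_ids) < 1L || max(affected_ids) > n_components)) {
    stop("`affected_ids` must be component indices in 1..n_components",
         call. = FALSE)
  }
  lo <- rep(ceiling(blob_radius) + 1, 3L)
  hi <- grid_dims - ceiling(blob_radius)
  centers <- with_seed(seed, {
    cs <- matrix(NA_real_, 0L, 3L)
    tries <- 0L
    stuck <- 0L
    while (nrow(cs) < n_components) {
      tries <- tries + 1L
      if (tries > 4000L * n_components) {
        stop(sprintf(
          "grid too small to place %d non-overlapping blob centers (radius %g)",
          n_components, blob_radius), call. = FALSE)
      }
      cand <- vapply(1:3, function(a) {
        if (hi[a] <= lo[a]) lo[a] else stats::runif(1, lo[a], hi[a])
      }, numeric(1))
      if (nrow(cs) == 0L ||
          min(sqrt(rowSums(sweep(cs, 2L, cand)^2))) >= 2 * blob_radius) {
        cs <- rbind(cs, cand)
        stuck <- 0L
      } else {
        stuck <- stuck + 1L
        if (stuck > 200L) {
          # a bad early placement can make completion impossible;
          # restart the whole configuration
          cs <- matrix(NA_real_, 0L, 3L)
          stuck <- 0L
        }
      }
    }
    cs
  })
  coords <- as.matrix(expand.grid(x = seq_len(grid_dims[1L]),
                                  y = seq_len(grid_dims[2L]),
                                  z = seq_len(grid_dims[3L])))
  sigma <- blob_radius / 2
  maps <- matrix(0, n_components, prod(grid_dims))
  for (k in seq_len(n_components)) {
    d2 <- rowSums(sweep(coords, 2L, centers[k, ])^2)
    v <- exp(-d2 / (2 * sigma^2))
    v[d2 > (2.5 * sigma)^2] <- 0
    maps[k, ] <- v / sqrt(sum(v^2))
  }
  structure(list(n_components = n_components, grid_dims = grid_dims,
                 source_maps = maps, affected_ids = affected_ids,
                 centers = centers),
            class = "source_atlas")
}

#' @export
print.source_atlas <- function(x, ...) {
  cat(sprintf("<source_atlas> %d sources on %s grid, affected: %s\n",
              x$n_components, paste(x$grid_dims, collapse = "x"),
              if (length(x$affected_ids)) paste(x$affected_ids, collapse = ",")
              else "none"))
  invisible(x)
}

#' Simulate a two-group reference cohort
#'
#' Each subject's voxel row is `loading %*% source_maps` plus iid Gaussian
#' noise. Loadings are N(5, 1) per component; subjects in the second group
#' get `group_shift` added to their loadings on the atlas's affected
#' components, so `group_shift` is expressed in loading-SD units.
#'
#' @param atlas a [make_source_atlas()] atlas.
#' @param n_per_group subjects per group (>= 2); groups are balanced.
#' @param group_shift mean loading difference (group2 - group1) on affected
#'   components.
#' @param noise_sd iid voxel noise SD (>= 0).
#' @param seed RNG seed.
#' @return list with `matrix` (a `subject_matrix`, whole-grid mask, labels
#'   `control`/`case`) and `truth` (`true_mixing`, `group_shift`,
#'   `affected_ids`, `noise_sd`).
#' @export
simulate_reference_cohort <- function(atlas, n_per_group, group_shift,
                                      noise_sd, seed) {
  stopifnot(inherits(atlas, "source_atlas"))
  n_per_group <- assert_count(n_per_group, "n_per_group", min = 2L)
  noise_sd <- assert_number(noise_sd, "noise_sd", min = 0)
  group_shift <- assert_number(group_shift, "group_shift")
  n <- 2L * n_per_group
  k <- atlas$n_components
  out <- with_seed(seed, {
    mixing <- matrix(stats::rnorm(n * k, mean = 5, sd = 1), n, k)
    labels <- factor(rep(c("control", "case"), each = n_per_group),
                     levels = c("control", "case"))
    if (length(atlas$affected_ids)) {
      mixing[labels == "case", atlas$affected_ids] <-
        mixing[labels == "case", atlas$affected_ids] + group_shift
    }
    data <- mixing %*% atlas$source_maps
    if (noise_sd > 0) {
      data <- data + matrix(stats::rnorm(length(data), sd = noise_sd),
                            nrow = n)
    }
    list(mixing = mixing, labels = labels, data = data)
  })
  mask <- array(TRUE, atlas$grid_dims)
  sm <- structure(list(
    data = `dimnames<-`(out$data, list(sprintf("sub_%03d", seq_len(n)), NULL)),
    mask = mask, subject_ids = sprintf("sub_%03d", seq_len(n)),
    group_labels = out$labels, modality = "structural",
    voxel_size = c(1, 1, 1), affine = diag(4)), class = "subject_matrix")
  truth <- list(true_mixing = out$mixing, group_shift = group_shift,
                affected_ids = atlas$affected_ids, noise_sd = noise_sd)
  list(matrix = sm, truth = truth)
}

#' Default clinical covariate distribution settings
#'
#' Gaussian means/SDs and APOE e4 allele-count probabilities chosen to mimic
#' a mild-cognitive-impairment cohort at baseline: ADAS-cog ~ N(10.8, 4.9),
#' CDR-SB ~ N(1.6, 0.9) truncated at 0, MMSE ~ N(27.4, 1.8) clamped to
#' [0, 30], age ~ N(73.4, 7.5) years, education ~ N(16, 2.6) years,
#' P(male) = 0.62, APOE e4 allele count 0/1/2 with probabilities
#' (0.444, 0.427, 0.128). ADAS-cog, CDR-SB and MMSE are drawn jointly
#' (Gaussian copula) with correlations +0.5 (ADAS, CDR-SB) and -0.5
#' (ADAS, MMSE), reflecting that the cognitive scales co-vary.
#'
#' @return named list of settings, each overridable.
#' @export
default_clinical_params <- function() {
  list(
    adas_cog  = c(mean = 10.8, sd = 4.9),
    cdr_sb    = c(mean = 1.6,  sd = 0.9),
    mmse      = c(mean = 27.4, sd = 1.8),
    age       = c(mean = 73.4, sd = 7.5),
    education = c(mean = 16.0, sd = 2.6),
    p_male    = 0.62,
    apoe_probs = c(0.444, 0.427, 0.128),
    cor_adas_cdr  = 0.5,
    cor_adas_mmse = -0.5
  )
}

simulate_clinical <- function(n, params) {
  p <- utils::modifyList(default_clinical_params(), params %||% list())
  # joint draw for the three cognitive scales via a correlation matrix
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- p$cor_adas_cdr
  R[1, 3] <- R[3, 1] <- p$cor_adas_mmse
  L <- chol(R)
  z <- matrix(stats::rnorm(n * 3L), n, 3L) %*% L
  adas <- pmax(0, p$adas_cog["mean"] + p$adas_cog["sd"] * z[, 1L])
  cdr  <- pmax(0, p$cdr_sb["mean"] + p$cdr_sb["sd"] * z[, 2L])
  mmse <- pmin(30, pmax(0, round(p$mmse["mean"] + p$mmse["sd"] * z[, 3L])))
  data.frame(
    apoe_e4 = sample(0:2, n, replace = TRUE, prob = p$apoe_probs),
    adas_cog = round(adas, 1),
    cdr_sb = round(cdr * 2) / 2,   # CDR-SB moves in half-point steps
    mmse = mmse,
    age = round(stats::rnorm(n, p$age["mean"], p$age["sd"]), 1),
    gender = stats::rbinom(n, 1L, p$p_male),
    education = pmax(6, round(stats::rnorm(n, p$education["mean"],
                                           p$education["sd"])))
  )
}

#' Simulate a survival (conversion) cohort
#'
#' Subjects receive per-component imaging loadings N(5, 1) (one set per
#' atlas), a clinical table from [default_clinical_params()] settings, and a
#' conversion time drawn by inverse transform from an exponential
#' proportional-hazards model: hazard `baseline_rate * exp(eta)` with
#' `eta = sum(true_beta * centered covariates)`. Covariates named in
#' `true_beta` are matched against the imaging loading columns
#' (`<modality>_IC_<k>`) and clinical columns; centring makes
#' `baseline_rate` the hazard at covariate means. Times beyond
#' `censor_month` are censored and stored with `time = censor_month`,
#' `event = FALSE`; times are reported to 0.1 month.
#'
#' @param atlas a single atlas or a named list of atlases (names become
#'   modality tags; a single unnamed atlas is tagged `structural`).
#' @param clinical_params overrides for [default_clinical_params()].
#' @param true_beta named numeric vector of log-hazard coefficients.
#' @param baseline_rate events per month at covariate means (> 0).
#' @param censor_month administrative censoring horizon (> 0).
#' @param n cohort size (>= 10).
#' @param seed RNG seed.
#' @param noise_sd voxel noise SD for the generated images (intensity units;
#'   unit-norm source maps put the per-voxel signal RMS near
#'   `sqrt(k * 26 / n_voxels)`, so the 0.01 default is ~5% noise on a 14^3
#'   grid).
#' @return list with `matrices` (named list of `subject_matrix`, one per
#'   modality), `clinical` (data.frame with `subject_id`), `survival`
#'   (data.frame `subject_id`, `time_months`, `event`), and `truth`
#'   (`true_mixing` per modality, `true_beta`, `baseline_rate`,
#'   `censor_month`, `covariates` — the exact design matrix whose centred
#'   version produced `eta`).
#' @export
simulate_survival_cohort <- function(atlas, clinical_params = list(),
                                     true_beta, baseline_rate, censor_month = 36,
                                     n, seed, noise_sd = 0.01) {
  atlases <- if (inherits(atlas, "source_atlas")) {
    list(structural = atlas)
  } else {
    stopifnot(is.list(atlas), length(atlas) >= 1L)
    if (is.null(names(atlas)) || any(!nzchar(names(atlas)))) {
      stop("a list of atlases must be named by modality", call. = FALSE)
    }
    atlas
  }
  for (a in atlases) stopifnot(inherits(a, "source_atlas"))
  n <- assert_count(n, "n", min = 10L)
  censor_month <- assert_number(censor_month, "censor_month", min = 0,
                                strict = TRUE)
  baseline_rate <- assert_number(baseline_rate, "baseline_rate", min = 0,
                                 strict = TRUE)
  if (is.null(names(true_beta)) && length(true_beta) > 0) {
    stop("`true_beta` must be a named vector", call. = FALSE)
  }

  res <- with_seed(seed, {
    ids <- sprintf("mci_%04d", seq_len(n))
    mixing <- lapply(atlases, function(a) {
      matrix(stats::rnorm(n * a$n_components, mean = 5, sd = 1),
             n, a$n_components)
    })
    clinical <- simulate_clinical(n, clinical_params)

    loading_cols <- do.call(cbind, lapply(names(atlases), function(m) {
      x <- mixing[[m]]
      colnames(x) <- sprintf("%s_IC_%02d", m, seq_len(ncol(x)))
      x
    }))
    design <- cbind(loading_cols, as.matrix(clinical))
    unknown <- setdiff(names(true_beta), colnames(design))
    if (length(unknown)) {
      stop(sprintf("true_beta names not found among covariates: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    eta <- if (length(true_beta)) {
      xb <- design[, names(true_beta), drop = FALSE]
      as.vector(scale(xb, center = TRUE, scale = FALSE) %*% true_beta)
    } else rep(0, n)

    t_raw <- stats::rexp(n) / (baseline_rate * exp(eta))
    event <- t_raw <= censor_month
    time <- ifelse(event, pmax(0.1, round(t_raw, 1)), censor_month)

    mats <- lapply(names(atlases), function(m) {
      a <- atlases[[m]]
      d <- mixing[[m]] %*% a$source_maps
      if (noise_sd > 0) {
        d <- d + matrix(stats::rnorm(length(d), sd = noise_sd), nrow = n)
      }
      structure(list(
        data = `dimnames<-`(d, list(ids, NULL)),
        mask = array(TRUE, a$grid_dims), subject_ids = ids,
        group_labels = NULL, modality = m,
        voxel_size = c(1, 1, 1), affine = diag(4)),
        class = "subject_matrix")
    })
    names(mats) <- names(atlases)

    list(
      matrices = mats,
      clinical = cbind(data.frame(subject_id = ids), clinical),
      survival = data.frame(subject_id = ids, time_months = time,
                            event = event),
      truth = list(true_mixing = mixing, true_beta = true_beta,
                   baseline_rate = baseline_rate, censor_month = censor_month,
                   covariates = design, eta = eta)
    )
  })
  res
}

#' Write a simulated cohort to disk
#'
#' Per-subject NIfTI volumes, a combined covariate/survival CSV, and the
#' ground truth as JSON (matrices flattened row-major with dimensions kept).
#'
#' @param cohort result of [simulate_survival_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(cohort$matrices)) {
    sm <- cohort$matrices[[m]]
    sub <- file.path(dir, m)
    dir.create(sub, showWarnings = FALSE)
    for (i in seq_len(nrow(sm$data))) {
      write_volume(unstack_subject(sm, i),
                   file.path(sub, paste0(sm$subject_ids[i], ".nii")))
    }
  }
  tab <- merge(cohort$survival, cohort$clinical, by = "subject_id")
  utils::write.csv(tab, file.path(dir, "subjects.csv"), row.names = FALSE)
  truth <- cohort$truth
  truth$true_mixing <- lapply(truth$true_mixing, function(m) {
    list(dim = dim(m), values = as.vector(t(m)))
  })
  truth$covariates <- list(dim = dim(truth$covariates),
                           colnames = colnames(truth$covariates),
                           values = as.vector(t(truth$covariates)))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
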