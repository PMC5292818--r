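# Component selection, Z-maps, binary network templates, template-mean
# features.

#' Two-sample t-test on each mixing-matrix column
#'
#' Pooled-variance (Student) two-sample t per component, comparing the two
#' reference groups' loadings; Welch's unequal-variance form is available by
#' `var_equal = FALSE`. Components with zero pooled variance get `t = 0`,
#' `p = 1` with a warning.
#'
#' @param decomposition a `decomposition` (or bare mixing matrix).
#' @param labels two-level factor over subjects.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return data.frame: `component`, `t`, `df`, `p`.
#' @export
compare_loadings <- function(decomposition, labels, var_equal = TRUE) {
  A <- if (inherits(decomposition, "decomposition")) decomposition$mixing
       else as.matrix(decomposition)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("`labels` must have exactly two levels",
                                  call. = FALSE)
  if (length(labels) != nrow(A)) {
    stop("`labels` length must equal the number of subjects", call. = FALSE)
  }
  g1 <- labels == levels(labels)[1L]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L) stop("both groups need >= 2 subjects", call. = FALSE)

  res <- lapply(seq_len(ncol(A)), function(j) {
    x1 <- A[g1, j]; x2 <- A[g2, j]
    v1 <- stats::var(x1); v2 <- stats::var(x2)
    if (var_equal) {
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      df <- n1 + n2 - 2
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    } else {
      se <- sqrt(v1 / n1 + v2 / n2)
      df <- (v1 / n1 + v2 / n2)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
    if (!is.finite(se) || se == 0) {
      warning(sprintf("component %d has zero pooled variance; p set to 1", j))
      return(c(t = 0, df = df, p = 1))
    }
    tt <- (mean(x1) - mean(x2)) / se
    c(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
  })
  out <- as.data.frame(do.call(rbind, res))
  cbind(data.frame(component = seq_len(ncol(A))), out)
}

#' Bonferroni component selection
#'
#' Selects indices with `p < alpha / k`, `k = length(p_values)` (the number
#' of estimated components, not the number selected). An empty selection is
#' a valid outcome.
#'
#' @param p_values per-component two-sided p-values.
#' @param alpha familywise level in (0, 1).
#' @return integer vector of selected component indices (possibly empty).
#' @export
bonferroni_select <- function(p_values, alpha = 0.05) {
  alpha <- assert_number(alpha, "alpha", min = 0, strict = TRUE)
  if (alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  k <- length(p_values)
  sel <- which(p_values < alpha / k)
  if (!length(sel)) message("Bonferroni selection is empty at alpha = ", alpha)
  as.integer(sel)
}

#' Z-score a source map
#'
#' Centres and scales a voxel vector by its in-mask mean and population SD.
#' Invariant under positive affine rescaling of the input.
#'
#' @param source_row numeric voxel vector (one source map).
#' @return Z-scored vector.
#' @export
zscore_map <- function(source_row) {
  s <- sd_pop(source_row)
  if (!is.finite(s) || s == 0) {
    stop("source map is constant; cannot Z-score", call. = FALSE)
  }
  (source_row - mean(source_row)) / s
}

#' Binarize a Z-map into a network template
#'
#' Inclusive positive-tail threshold: voxels with `Z >= z_threshold` form
#' the template. An empty template is returned flagged `usable = FALSE`.
#'
#' @param zmap Z-scored voxel vector (in-mask flattening order).
#' @param z_threshold positive threshold, default 3.0.
#' @param component_id integer label of the originating component.
#' @param modality modality tag.
#' @param t_stat,p_value the selection statistics carried for reporting.
#' @param mask3d optional 3-D cohort mask to embed the template for export.
#' @return A `network_template`: `in_mask` (logical over voxels),
#'   `mask` (3-D logical array or NULL), `component_id`, `modality`,
#'   `z_threshold`, `t_stat`, `p_value`, `n_voxels`, `usable`.
#' @export
binarize_template <- function(zmap, z_threshold = 3.0, component_id = NA_integer_,
                              modality = "structural", t_stat = NA_real_,
                              p_value = NA_real_, mask3d = NULL) {
  z_threshold <- assert_number(z_threshold, "z_threshold", min = 0,
                               strict = TRUE)
  sel <- zmap >= z_threshold
  usable <- any(sel)
  if (!usable) {
    warning(sprintf("template for component %s is empty at Z >= %g",
                    component_id, z_threshold))
  }
  m3 <- NULL
  if (!is.null(mask3d)) {
    m3 <- array(FALSE, dim(mask3d))
    m3[mask3d] <- sel
  }
  structure(list(in_mask = sel, mask = m3, component_id = component_id,
                 modality = modality, z_threshold = z_threshold,
                 t_stat = t_stat, p_value = p_value,
                 n_voxels = sum(sel), usable = usable),
            class = "network_template")
}

#' @export
print.network_template <- function(x, ...) {
  cat(sprintf("<network_template> %s_IC_%02d: %d voxels at Z >= %g%s\n",
              x$modality, x$component_id, x$n_voxels, x$z_threshold,
              if (x$usable) "" else " (EMPTY)"))
  invisible(x)
}

#' Write a network template as a NIfTI mask
#'
#' Exports the template's 3-D {0,1} mask.
#'
#' @param template a `network_template` built with `mask3d` (so the 3-D
#'   embedding exists).
#' @param path output `.nii` path.
#' @param voxel_size,affine geometry for the exported volume.
#' @return `path`, invisibly.
#' @export
write_template <- function(template, path, voxel_size = c(1, 1, 1),
                           affine = NULL) {
  stopifnot(inherits(template, "network_template"))
  if (is.null(template$mask)) {
    stop("template lacks a 3-D embedding; rebuild with `mask3d`",
         call. = FALSE)
  }
  vol <- image_volume(array(as.numeric(template$mask), dim(template$mask)),
                      voxel_size = voxel_size, affine = affine)
  write_volume(vol, path)
}

#' Template-mean features for an independent cohort
#'
#' For each subject and template, the mean of the subject's voxel values
#' inside the template mask — the network-level covariate entering the
#' survival models. Columns are named `<modality>_IC_<id>`.
#'
#' @param cohort a `subject_matrix` (same voxel geometry as the templates).
#' @param templates list of `network_template`.
#' @return data.frame with `subject_id` and one numeric column per template.
#' @export
extract_network_features <- function(cohort, templates) {
  stopifnot(inherits(cohort, "subject_matrix"))
  if (inherits(templates, "network_template")) templates <- list(templates)
  out <- data.frame(subject_id = cohort$subject_ids,
                    stringsAsFactors = FALSE)
  for (tp in templates) {
    stopifnot(inherits(tp, "network_template"))
    if (!tp$usable) {
      stop(sprintf("template %s_IC_%02d is empty and cannot yield features",
                   tp$modality, tp$component_id), call. = FALSE)
    }
    if (length(tp$in_mask) != ncol(cohort$data)) {
      stop(sprintf(
        "template %s_IC_%02d covers %d voxels but the cohort matrix has %d",
        tp$modality, tp$component_id, length(tp$in_mask), ncol(cohort$data)),
        call. = FALSE)
    }
    if (!is.null(tp$mask) && !all(dim(tp$mask) == dim(cohort$mask))) {
      stop("template and cohort 3-D geometries differ", call. = FALSE)
    }
    nm <- sprintf("%s_IC_%02d", tp$modality, tp$component_id)
    out[[nm]] <- rowMeans(cohort$data[, tp$in_mask, drop = FALSE])
  }
  out
}

#' Select group-separating components and build their templates
#'
#' Convenience wrapper chaining [compare_loadings()], [bonferroni_select()],
#' [zscore_map()] and [binarize_template()] for one modality.
#'
#' @param decomposition a `decomposition` from the reference cohort.
#' @param labels two-level group factor.
#' @param alpha familywise level for Bonferroni selection.
#' @param z_threshold template threshold.
#' @param modality modality tag for naming.
#' @param mask3d optional 3-D mask for template embedding.
#' @return list: `stats` (selection table with `selected` flag),
#'   `templates` (list of usable `network_template` for selected components).
#' @export
select_networks <- function(decomposition, labels, alpha = 0.05,
                            z_threshold = 3.0, modality = "structural",
                            mask3d = NULL) {
  st <- compare_loadings(decomposition, labels)
  sel <- bonferroni_select(st$p, alpha)
  st$selected <- st$component %in% sel
  templates <- list()
  for (j in sel) {
    tp <- binarize_template(zscore_map(decomposition$sources[j, ]),
                            z_threshold = z_threshold, component_id = j,
                            modality = modality, t_stat = st$t[j],
                            p_value = st$p[j], mask3d = mask3d)
    if (tp$usable) templates[[length(templates) + 1L]] <- tp
  }
  list(stats = st, templates = templates)
}
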