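# Volume-level operations and cohort flattening.

#' Global-mean intensity normalization (SUVr)
#'
#' Divides a volume by the mean intensity over a reference mask (the "global
#' cerebrum" in metabolic imaging), producing a standard uptake value ratio
#' image whose in-mask mean is exactly 1.
#'
#' @param volume an [image_volume()].
#' @param brain_mask logical/0-1 3-D array with the volume's dimensions.
#' @return An [image_volume()] of ratios.
#' @export
compute_suvr <- function(volume, brain_mask) {
  stopifnot(inherits(volume, "image_volume"))
  brain_mask <- as_mask(brain_mask, dim(volume$data))
  if (!any(brain_mask)) stop("`brain_mask` is empty", call. = FALSE)
  m <- mean(volume$data[brain_mask])
  if (!is.finite(m) || m <= 0) {
    stop(sprintf("in-mask mean must be positive for SUVr (got %g)", m),
         call. = FALSE)
  }
  image_volume(volume$data / m, voxel_size = volume$voxel_size,
               affine = volume$affine)
}

#' Gaussian smoothing by FWHM
#'
#' Separable 3-D Gaussian filter. The kernel width is given as full width at
#' half maximum in millimetres and converted per axis to voxel units through
#' the volume's voxel size: `sigma = fwhm / (2 * sqrt(2 * log(2)))`. Kernel
#' rows are renormalized at the array edges so constant volumes are preserved
#' exactly; `fwhm_mm = 0` is the identity.
#'
#' @param volume an [image_volume()].
#' @param fwhm_mm non-negative kernel FWHM in mm (scalar, applied per axis).
#' @return Smoothed [image_volume()].
#' @export
smooth_gaussian <- function(volume, fwhm_mm) {
  stopifnot(inherits(volume, "image_volume"))
  fwhm_mm <- assert_number(fwhm_mm, "fwhm_mm", min = 0)
  if (fwhm_mm == 0) return(volume)
  sigma_mm <- fwhm_to_sigma(fwhm_mm)
  x <- volume$data
  for (ax in 1:3) {
    sig_vox <- sigma_mm / volume$voxel_size[ax]
    x <- convolve_axis(x, ax, gaussian_kernel(sig_vox))
  }
  image_volume(x, voxel_size = volume$voxel_size, affine = volume$affine)
}

#' @rdname smooth_gaussian
#' @param fwhm FWHM value to convert.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-half):half)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# 1-D convolution along axis `ax` of a 3-D array, truncated kernel
# renormalized per position (rows of the banded operator sum to 1).
convolve_axis <- function(x, ax, kernel) {
  if (length(kernel) == 1L) return(x)
  d <- dim(x)
  perm <- c(ax, setdiff(1:3, ax))
  xp <- aperm(x, perm)
  n <- d[ax]
  m <- matrix(xp, nrow = n)
  half <- (length(kernel) - 1L) / 2L
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    keep <- j >= 1L & j <= n
    w <- kernel[keep]
    W[i, j[keep]] <- w / sum(w)
  }
  out <- W %*% m
  aperm(array(out, dim = d[perm]), order(perm))
}

as_mask <- function(mask, dims) {
  if (is.null(dim(mask)) || length(dim(mask)) != 3L) {
    stop("mask must be a 3-D array", call. = FALSE)
  }
  if (!all(dim(mask) == dims)) {
    stop(sprintf("mask dimensions (%s) do not match volume dimensions (%s)",
                 paste(dim(mask), collapse = "x"),
                 paste(dims, collapse = "x")), call. = FALSE)
  }
  m <- mask
  storage.mode(m) <- "logical"
  m
}

#' Stack a cohort of volumes into a subject-by-voxel matrix
#'
#' Flattens the in-mask voxels of each subject's volume into one row. The
#' flattening order is fixed: R column-major array order, i.e. the first
#' (x) axis varies fastest, then y, then z. This order is part of the
#' contract — templates and features computed through the matrix agree with
#' direct 3-D computation.
#'
#' @param volumes list of [image_volume()] with identical dimensions.
#' @param mask logical/0-1 3-D array; `NULL` selects the default analysis
#'   mask: voxels nonzero in every subject.
#' @param labels per-subject group labels (factor or character), or `NULL`.
#' @param modality `"structural"` or `"metabolic"` (free-form allowed).
#' @param subject_ids optional character ids; defaults to `sub_001`, ...
#' @return A `subject_matrix`: list with `data` (n x V matrix), `mask`,
#'   `subject_ids`, `group_labels`, `modality`, `voxel_size`, `affine`.
#' @export
stack_cohort <- function(volumes, mask = NULL, labels = NULL,
                         modality = "structural", subject_ids = NULL) {
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  dims <- dim(volumes[[1L]]$data)
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (!inherits(v, "image_volume")) {
      stop(sprintf("subject %d is not an image_volume", i), call. = FALSE)
    }
    if (!all(dim(v$data) == dims)) {
      stop(sprintf(
        "subject %d has dimensions %s, expected %s",
        i, paste(dim(v$data), collapse = "x"), paste(dims, collapse = "x")),
        call. = FALSE)
    }
  }
  if (is.null(mask)) {
    mask <- array(TRUE, dims)
    for (v in volumes) mask <- mask & (v$data != 0)
  }
  mask <- as_mask(mask, dims)
  if (!any(mask)) stop("analysis mask is empty", call. = FALSE)
  n <- length(volumes)
  if (is.null(subject_ids)) subject_ids <- sprintf("sub_%03d", seq_len(n))
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    if (length(labels) != n) stop("`labels` length must equal cohort size",
                                  call. = FALSE)
  }
  data <- matrix(NA_real_, n, sum(mask),
                 dimnames = list(subject_ids, NULL))
  for (i in seq_len(n)) data[i, ] <- volumes[[i]]$data[mask]
  structure(list(data = data, mask = mask, subject_ids = subject_ids,
                 group_labels = labels, modality = modality,
                 voxel_size = volumes[[1L]]$voxel_size,
                 affine = volumes[[1L]]$affine),
            class = "subject_matrix")
}

#' @export
print.subject_matrix <- function(x, ...) {
  cat(sprintf("<subject_matrix> %d subjects x %d voxels (%s), mask %s\n",
              nrow(x$data), ncol(x$data), x$modality,
              paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

#' Re-embed one subject's row into 3-D
#'
#' Inverse of [stack_cohort()] for a single subject: in-mask voxels are
#' restored to their 3-D positions, out-of-mask voxels are `fill`.
#'
#' @param sm a `subject_matrix`.
#' @param i subject index.
#' @param fill value outside the mask.
#' @return An [image_volume()].
#' @export
unstack_subject <- function(sm, i, fill = 0) {
  stopifnot(inherits(sm, "subject_matrix"))
  i <- assert_count(i, "i")
  if (i > nrow(sm$data)) stop("subject index out of range", call. = FALSE)
  arr <- array(fill, dim(sm$mask))
  arr[sm$mask] <- sm$data[i, ]
  image_volume(arr, voxel_size = sm$voxel_size, affine = sm$affine)
}

# Embed a voxel-vector (one value per in-mask voxel, in flattening order)
# into 3-D.
embed_in_mask <- function(values, mask, fill = 0) {
  stopifnot(length(values) == sum(mask))
  arr <- array(fill, dim(mask))
  arr[mask] <- values
  arr
}
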