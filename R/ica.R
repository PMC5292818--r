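# Spatial ICA: MDL model-order selection, PCA whitening, natural-gradient
# Infomax with a logistic nonlinearity.
#
# Conventions. The data matrix is subjects x voxels; voxels are treated as
# the i.i.d. samples of a subjects-dimensional signal (spatial ICA). The
# decomposition is data ~ mixing %*% sources with mixing subjects x k and
# sources k x voxels. Sources are normalized to unit (population) variance
# with the largest-magnitude voxel positive; mixing columns absorb the
# rescaling, so mixing %*% sources always reproduces the retained rank-k
# subspace of the (row-centred) data exactly.

#' Estimate ICA model order by minimum description length
#'
#' Computes eigenvalues of the subjects-covariance matrix (voxels as
#' samples) and minimizes, over candidate order `k`,
#' `-N*(p-k)*log(GM_k/AM_k) + 0.5*k*(2p-k+1)*log(N)`, where `GM_k`/`AM_k`
#' are the geometric/arithmetic means of the `p-k` smallest eigenvalues,
#' `p` the number of subjects and `N` the effective sample size (number of
#' voxels by default; spatial smoothing makes this optimistic, so `n_eff`
#' can be overridden).
#'
#' @param data a `subject_matrix` (or bare matrix), subjects x voxels.
#' @param n_eff effective number of i.i.d. samples; default `ncol(data)`.
#' @return Estimated order (integer in `0..p-1`), with attribute `"mdl"`
#'   holding the criterion over k.
#' @export
estimate_order_mdl <- function(data, n_eff = NULL) {
  X <- if (inherits(data, "subject_matrix")) data$data else as.matrix(data)
  p <- nrow(X)
  N <- ncol(X)
  if (p < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (N < p + 1L) stop("need more voxels than subjects", call. = FALSE)
  n_eff <- if (is.null(n_eff)) N else assert_count(n_eff, "n_eff", min = 2L)
  Xc <- X - rowMeans(X)
  lam <- eigen(tcrossprod(Xc) / N, symmetric = TRUE, only.values = TRUE)$values
  if (max(lam) <= 1e-12 * p) {
    stop("degenerate covariance: subject rows are (numerically) all equal",
         call. = FALSE)
  }
  lam <- pmax(lam, .Machine$double.eps)
  ks <- 0:(p - 1L)
  mdl <- vapply(ks, function(k) {
    tail_lam <- lam[(k + 1L):p]
    gm <- mean(log(tail_lam))
    am <- log(mean(tail_lam))
    fit <- -n_eff * (p - k) * (gm - am)
    pen <- 0.5 * k * (2 * p - k + 1) * log(n_eff)
    fit + pen
  }, numeric(1))
  k_hat <- ks[which.min(mdl)]
  structure(as.integer(k_hat), mdl = stats::setNames(mdl, ks))
}

#' PCA whitening of a subject-by-voxel matrix
#'
#' Row-centres the data, eigendecomposes the subjects-covariance
#' (`tcrossprod(Xc)/N`), and projects onto the top `order` eigenvectors with
#' unit output covariance (same `1/N` convention). The returned `dewhiten`
#' matrix maps whitened rows back to subject space:
#' `dewhiten %*% whitened` is the rank-`order` approximation of the centred
#' data.
#'
#' @param data a `subject_matrix` or matrix.
#' @param order retained subspace dimension, `1 <= order <= p-1`.
#' @return list: `whitened` (order x voxels), `dewhiten` (p x order),
#'   `whitener` (order x p), `row_means`, `eigenvalues`.
#' @export
whiten <- function(data, order) {
  X <- if (inherits(data, "subject_matrix")) data$data else as.matrix(data)
  p <- nrow(X)
  N <- ncol(X)
  order <- assert_count(order, "order")
  if (order > p - 1L) {
    stop(sprintf("order (%d) must be <= n_subjects - 1 (%d)", order, p - 1L),
         call. = FALSE)
  }
  mu <- rowMeans(X)
  Xc <- X - mu
  eg <- eigen(tcrossprod(Xc) / N, symmetric = TRUE)
  lam <- eg$values
  rank <- sum(lam > max(lam) * 1e-10)
  if (order > rank) {
    stop(sprintf("order (%d) exceeds the numerical rank of the data (%d)",
                 order, rank), call. = FALSE)
  }
  E <- eg$vectors[, seq_len(order), drop = FALSE]
  d <- sqrt(lam[seq_len(order)])
  whitener <- (t(E) / d)
  list(whitened = whitener %*% Xc,
       dewhiten = E * rep(d, each = p),
       whitener = whitener,
       row_means = mu,
       eigenvalues = lam)
}

#' Infomax independent component analysis
#'
#' Whitens the data to `order` dimensions and runs natural-gradient Infomax
#' with the logistic nonlinearity: `W <- W + lr * (I + (1 - 2*g(U)) %*% t(U) / N) %*% W`
#' with `U = W %*% Y`, `g(u) = 1/(1+exp(-u))`. The unmixing matrix is
#' initialized as a random orthogonal matrix drawn from `seed`; the learning
#' rate is annealed (halved) whenever the angle between successive updates
#' exceeds 60 degrees; iteration stops when the relative weight-change norm
#' drops below `tol` or after `max_iter` sweeps. Non-convergence is reported
#' as a warning and flagged on the (still returned) result.
#'
#' @param data a `subject_matrix` or subjects x voxels matrix.
#' @param order number of components; default [estimate_order_mdl()].
#' @param lrate initial learning rate.
#' @param tol convergence tolerance on the relative weight change.
#' @param max_iter maximum sweeps (default 2048; gradient ascent at tol 1e-6 typically needs 1000-2000).
#' @param seed RNG seed for the orthogonal initialization.
#' @param w_init optional explicit initial unmixing matrix (order x order);
#'   overrides the seeded initialization.
#' @return A `decomposition`: `mixing` (subjects x k), `sources`
#'   (k x voxels, unit population variance, positive peak), `order`,
#'   `row_means`, `convergence` (iterations, final update norm, converged),
#'   `seed`.
#' @export
infomax_ica <- function(data, order = NULL, lrate = 0.01, tol = 1e-6,
                        max_iter = 2048L, seed = 1L, w_init = NULL) {
  X <- if (inherits(data, "subject_matrix")) data$data else as.matrix(data)
  if (is.null(order)) order <- as.integer(estimate_order_mdl(X))
  order <- assert_count(order, "order")
  wh <- whiten(X, order)
  Y <- wh$whitened
  k <- order
  N <- ncol(Y)

  W <- if (!is.null(w_init)) {
    stopifnot(all(dim(w_init) == c(k, k)))
    w_init
  } else {
    with_seed(seed, {
      qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
    })
  }

  I_k <- diag(k)
  lr <- lrate
  prev_delta <- NULL
  final_norm <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    U <- W %*% Y
    g <- 1 / (1 + exp(-U))
    delta <- lr * ((I_k + (1 - 2 * g) %*% t(U) / N) %*% W)
    if (!all(is.finite(delta)) || max(abs(W + delta)) > 1e8) {
      # diverged: restart colder
      lr <- lr / 5
      W <- with_seed(seed + iter, qr.Q(qr(matrix(stats::rnorm(k * k), k, k))))
      prev_delta <- NULL
      next
    }
    if (!is.null(prev_delta)) {
      num <- sum(delta * prev_delta)
      den <- sqrt(sum(delta^2) * sum(prev_delta^2))
      if (den > 0 && num / den < cos(60 * pi / 180)) lr <- lr / 2
    }
    W <- W + delta
    prev_delta <- delta
    final_norm <- sqrt(sum(delta^2)) / sqrt(sum(W^2))
    if (final_norm < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf(
      "Infomax did not converge in %d iterations (final update norm %.3g)",
      max_iter, final_norm))
  }

  sources <- W %*% Y
  mixing <- wh$dewhiten %*% solve(W)
  dec <- structure(list(mixing = mixing, sources = sources, order = k,
                        row_means = wh$row_means,
                        convergence = list(iterations = iter,
                                           final_update_norm = final_norm,
                                           converged = converged),
                        seed = seed),
                   class = "decomposition")
  normalize_decomposition(dec)
}

#' Normalize a decomposition's scale and sign conventions
#'
#' Rescales each source row to unit population variance and flips signs so
#' the source value of largest magnitude is positive; mixing columns absorb
#' both, leaving `mixing %*% sources` unchanged. Idempotent.
#'
#' @param dec a `decomposition`.
#' @return The normalized `decomposition`.
#' @export
normalize_decomposition <- function(dec) {
  stopifnot(inherits(dec, "decomposition"))
  S <- dec$sources
  A <- dec$mixing
  for (i in seq_len(nrow(S))) {
    s <- sd_pop(S[i, ])
    if (s > 0 && abs(s - 1) > 1e-12) {   # tolerance keeps this idempotent
      S[i, ] <- S[i, ] / s
      A[, i] <- A[, i] * s
    }
    if (S[i, which.max(abs(S[i, ]))] < 0) {
      S[i, ] <- -S[i, ]
      A[, i] <- -A[, i]
    }
  }
  dec$sources <- S
  dec$mixing <- A
  dec
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf(
    "<decomposition> %d components, %d subjects x %d voxels; %s in %d iter\n",
    x$order, nrow(x$mixing), ncol(x$sources),
    if (x$convergence$converged) "converged" else "NOT converged",
    x$convergence$iterations))
  invisible(x)
}

#' Export decomposition sources as per-component NIfTI Z-maps
#'
#' Z-scores each source row ([zscore_map()]), embeds it in the cohort's
#' 3-D mask (zero outside) and writes one volume per component, named
#' `<prefix>_01.nii`, `<prefix>_02.nii`, ...
#'
#' @param decomposition a `decomposition`.
#' @param mask logical 3-D analysis mask with `sum(mask) == ncol(sources)`.
#' @param dir output directory (created if needed).
#' @param voxel_size,affine geometry for the exported volumes.
#' @param prefix file-name prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_zmaps <- function(decomposition, mask, dir, voxel_size = c(1, 1, 1),
                        affine = NULL, prefix = "IC") {
  stopifnot(inherits(decomposition, "decomposition"))
  if (sum(mask) != ncol(decomposition$sources)) {
    stop("mask voxel count does not match the source maps", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(decomposition$order)
  for (i in seq_len(decomposition$order)) {
    z <- zscore_map(decomposition$sources[i, ])
    vol <- image_volume(embed_in_mask(z, mask),
                        voxel_size = voxel_size, affine = affine)
    paths[i] <- file.path(dir, sprintf("%s_%02d.nii", prefix, i))
    write_volume(vol, paths[i])
  }
  invisible(paths)
}

#' Match two source sets by absolute correlation
#'
#' Greedy best-first assignment on |correlation| between rows of
#' `sources_a` and rows of `sources_b` (adequate for the well-separated
#' sources it is used on). Used to compare recovered components with ground
#' truth or across runs.
#'
#' @param sources_a,sources_b matrices with equally many columns.
#' @return data.frame with `a`, `b`, `abs_cor`, one row per matched pair.
#' @export
match_sources <- function(sources_a, sources_b) {
  C <- abs(stats::cor(t(sources_a), t(sources_b)))
  ka <- nrow(C); kb <- ncol(C)
  out <- data.frame(a = integer(0), b = integer(0), abs_cor = numeric(0))
  for (step in seq_len(min(ka, kb))) {
    ij <- arrayInd(which.max(C), dim(C))
    out <- rbind(out, data.frame(a = ij[1L], b = ij[2L],
                                 abs_cor = C[ij[1L], ij[2L]]))
    C[ij[1L], ] <- -Inf
    C[, ij[2L]] <- -Inf
  }
  out[order(out$a), ]
}
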