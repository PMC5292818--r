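# Cox proportional-hazards fitting by maximum partial likelihood.
#
# Newton-Raphson with step-halving on the log partial likelihood, Breslow
# (default) or Efron handling of tied event times, standard errors from the
# inverse observed information. Written out directly rather than delegated:
# the chained model suite below is the analytical heart of the pipeline and
# its tests compare this implementation against independent oracles
# (grid-search maximization and the survival package).

#' Hazard ratio with Wald confidence interval
#'
#' `hr = exp(beta)`, bounds `exp(beta -/+ z * se)` with `z` the
#' `(1 + level)/2` normal quantile (1.959964 at the default 95% level).
#'
#' @param beta log hazard ratio.
#' @param se standard error (> 0).
#' @param level confidence level in (0, 1).
#' @return list `hr`, `ci_low`, `ci_high` (vectorized over `beta`/`se`).
#' @export
hazard_ratio_ci <- function(beta, se, level = 0.95) {
  if (any(se <= 0)) stop("`se` must be positive", call. = FALSE)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  list(hr = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

#' Wald test
#'
#' @param beta coefficient estimate.
#' @param se standard error (> 0).
#' @return list `z = beta/se`, `p = 2 * (1 - pnorm(|z|))` (vectorized).
#' @export
wald_test <- function(beta, se) {
  if (any(se <= 0)) stop("`se` must be positive", call. = FALSE)
  z <- beta / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Log partial likelihood, score and information at `beta`.
# X sorted by DEcreasing time; `time`, `event` in the same order.
cox_quantities <- function(beta, X, time, event, ties) {
  n <- nrow(X); m <- ncol(X)
  eta <- as.vector(X %*% beta)
  eta <- pmin(eta, 500)                     # guard exp overflow
  r <- exp(eta)
  cr <- cumsum(r)
  rX <- X * r
  crX <- apply(rX, 2L, cumsum)
  if (m == 1L) crX <- matrix(crX, ncol = 1L)
  # cumulative sums for the m x m second-moment matrix, pair by pair
  pairs <- which(upper.tri(matrix(0, m, m), diag = TRUE), arr.ind = TRUE)
  crXX <- sapply(seq_len(nrow(pairs)), function(q) {
    cumsum(r * X[, pairs[q, 1L]] * X[, pairs[q, 2L]])
  })
  if (nrow(pairs) == 1L) crXX <- matrix(crXX, ncol = 1L)
  unfold <- function(v) {
    M <- matrix(0, m, m)
    M[pairs] <- v
    M[pairs[, c(2L, 1L), drop = FALSE]] <- v
    M
  }

  ll <- 0
  U <- numeric(m)
  Info <- matrix(0, m, m)
  ut <- unique(time[event])
  for (tau in ut) {
    D <- which(event & time == tau)
    d <- length(D)
    last <- max(which(time == tau))      # risk set = positions 1..last
    S0 <- cr[last]
    S1 <- crX[last, ]
    S2 <- unfold(crXX[last, ])
    sum_eta <- sum(eta[D])
    if (ties == "breslow") {
      ll <- ll + sum_eta - d * log(S0)
      U <- U + colSums(X[D, , drop = FALSE]) - d * S1 / S0
      Info <- Info + d * (S2 / S0 - tcrossprod(S1 / S0))
    } else {                             # efron
      S0D <- sum(r[D])
      S1D <- colSums(rX[D, , drop = FALSE])
      S2D <- matrix(0, m, m)
      for (i in D) S2D <- S2D + r[i] * tcrossprod(X[i, ])
      xbar_sum <- colSums(X[D, , drop = FALSE])
      ll <- ll + sum_eta
      for (l in seq_len(d) - 1L) {
        f <- l / d
        s0 <- S0 - f * S0D
        s1 <- S1 - f * S1D
        s2 <- S2 - f * S2D
        ll <- ll - log(s0)
        U <- U - s1 / s0
        Info <- Info + (s2 / s0 - tcrossprod(s1 / s0))
      }
      U <- U + xbar_sum
    }
  }
  list(loglik = ll, score = U, info = Info)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the log partial likelihood by Newton-Raphson with step-halving;
#' tied event times handled by Breslow's (default) or Efron's approximation.
#' Standard errors come from the inverse observed information at the
#' optimum. Convergence requires the score norm to fall below `tol`.
#' A monotone partial likelihood (risk separation) is detected as unbounded
#' coefficient growth and reported as a flagged non-convergence; the result
#' is still returned with a diagnostic.
#'
#' @param covariates data.frame with a `subject_id` column plus numeric
#'   covariate columns (or a bare numeric matrix aligned with `survival`).
#' @param survival data.frame with `time_months` (or `time`), logical/0-1
#'   `event`, and `subject_id` when `covariates` has one.
#' @param ties `"breslow"` or `"efron"`.
#' @param tol convergence tolerance on the score norm.
#' @param max_iter maximum Newton iterations.
#' @return A `cox_result`: data.frame with one row per covariate (`term`,
#'   `beta`, `se`, `z`, `p`, `hr`, `ci_low`, `ci_high`) and attributes
#'   `loglik` (null, final), `iterations`, `converged`, `n`, `n_events`,
#'   `ties`.
#' @export
fit_cox <- function(covariates, survival, ties = c("breslow", "efron"),
                    tol = 1e-6, max_iter = 50L) {
  ties <- match.arg(ties)
  al <- align_tables(covariates, survival)
  X <- al$X; time <- al$time; event <- al$event

  if (any(time <= 0)) stop("all survival times must be > 0", call. = FALSE)
  if (sum(event) < 1L) stop("at least one event is required", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant covariate(s): %s",
                 paste(colnames(X)[sds == 0], collapse = ", ")), call. = FALSE)
  }
  qrX <- qr(scale(X))
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("collinear covariate(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }

  ord <- order(time, decreasing = TRUE)
  Xs <- X[ord, , drop = FALSE]
  ts <- time[ord]
  ev <- event[ord]
  m <- ncol(X)

  beta <- numeric(m)
  q0 <- cox_quantities(beta, Xs, ts, ev, ties)
  loglik_null <- q0$loglik
  q <- q0
  converged <- FALSE
  separated <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(q$info, q$score),
                     error = function(e) q$score / (max(diag(q$info)) + 1e-12))
    halves <- 0L
    repeat {
      cand <- beta + step
      qc <- cox_quantities(cand, Xs, ts, ev, ties)
      if (is.finite(qc$loglik) && qc$loglik >= q$loglik - 1e-12) break
      step <- step / 2
      halves <- halves + 1L
      if (halves > 30L) break
    }
    beta <- beta + step
    q <- cox_quantities(beta, Xs, ts, ev, ties)
    if (sqrt(sum(q$score^2)) < tol ||
        max(abs(step)) < 1e-10 * (1 + max(abs(beta)))) {
      # second clause: the Newton step has hit float resolution; the score
      # norm can stall just above a tight tol through cumsum round-off
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 25) {
      separated <- TRUE
      break
    }
  }
  if (separated) {
    warning(paste("monotone partial likelihood: a covariate perfectly orders",
                  "the risk sets; estimates are unbounded"))
  } else if (!converged) {
    warning(sprintf("Cox fit did not converge in %d iterations (score norm %.3g)",
                    max_iter, sqrt(sum(q$score^2))))
  }

  se <- sqrt(diag(solve(q$info)))
  wt <- wald_test(beta, se)
  ci <- hazard_ratio_ci(beta, se)
  res <- data.frame(term = colnames(X), beta = beta, se = se,
                    z = wt$z, p = pmax(wt$p, .Machine$double.xmin),
                    hr = ci$hr, ci_low = ci$ci_low, ci_high = ci$ci_high,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res,
            loglik = c(null = loglik_null, final = q$loglik),
            iterations = iter, converged = converged && !separated,
            separated = separated, n = nrow(X), n_events = sum(event),
            ties = ties, class = c("cox_result", "data.frame"))
}

#' @export
print.cox_result <- function(x, digits = 4, ...) {
  cat(sprintf("Cox model (%s ties): n = %d, events = %d, loglik = %.4f%s\n",
              attr(x, "ties"), attr(x, "n"), attr(x, "n_events"),
              attr(x, "loglik")[["final"]],
              if (attr(x, "converged")) "" else "  [NOT converged]"))
  df <- as.data.frame(x)
  df$hr <- signif(df$hr, 3)
  df$ci_low <- signif(df$ci_low, 3)
  df$ci_high <- signif(df$ci_high, 3)
  df$p <- signif(df$p, 3)
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}

# Align a covariate table and survival table; returns X, time, event.
align_tables <- function(covariates, survival) {
  time_col <- if ("time_months" %in% names(survival)) "time_months" else "time"
  if (!time_col %in% names(survival) || !"event" %in% names(survival)) {
    stop("`survival` needs `time_months` (or `time`) and `event` columns",
         call. = FALSE)
  }
  if (is.data.frame(covariates) && "subject_id" %in% names(covariates) &&
      "subject_id" %in% names(survival)) {
    if (!setequal(covariates$subject_id, survival$subject_id)) {
      stop("covariate and survival tables cover different subjects",
           call. = FALSE)
    }
    surv <- survival[match(covariates$subject_id, survival$subject_id), ]
    X <- as.matrix(covariates[, setdiff(names(covariates), "subject_id"),
                              drop = FALSE])
  } else {
    X <- as.matrix(if (is.data.frame(covariates)) {
      covariates[, setdiff(names(covariates), "subject_id"), drop = FALSE]
    } else covariates)
    if (nrow(X) != nrow(survival)) {
      stop("covariates and survival tables have different row counts",
           call. = FALSE)
    }
    surv <- survival
  }
  if (anyNA(X)) stop("covariates contain missing values", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  list(X = X, time = as.numeric(surv[[time_col]]),
       event = as.logical(surv$event))
}

#' Names of significant covariates
#'
#' @param result a `cox_result`.
#' @param alpha Wald-p threshold (default 0.05).
#' @return character vector of covariate names with `p < alpha`.
#' @export
significant_factors <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "cox_result"))
  result$term[result$p < alpha]
}

#' Run the chained five-model Cox suite
#'
#' Fits (1) a structural-imaging-only model, (2) a metabolic-imaging-only
#' model, (3) a two-modality model on the covariates that were significant
#' in (1) or (2), (4) a clinical-only model, and (5) a comprehensive model
#' on the covariates significant in (3) plus those significant in (4)
#' (or all clinical variables when `all_clinical = TRUE`). A stage whose
#' covariate set is empty is skipped with a logged reason; downstream
#' stages fall back to whatever significant covariates exist.
#'
#' @param mri_features,pet_features,clinical data.frames keyed by
#'   `subject_id` (features from [extract_network_features()]; clinical
#'   variables as columns).
#' @param survival data.frame `subject_id`, `time_months`, `event`.
#' @param alpha per-stage Wald significance threshold for carrying
#'   covariates forward.
#' @param ties tie-handling passed to [fit_cox()].
#' @param all_clinical enter every clinical variable (not just the
#'   significant ones) into the comprehensive model.
#' @return A `cox_suite`: `models` (named list of `cox_result` or NULL),
#'   `carried` (covariates entering stages 3 and 5), `significant`
#'   (per-stage significant covariates), `skipped` (named reasons).
#' @export
run_model_suite <- function(mri_features, pet_features, clinical, survival,
                            alpha = 0.05, ties = "breslow",
                            all_clinical = FALSE) {
  stopifnot(is.data.frame(survival))
  models <- list(mri = NULL, pet = NULL, two_modality = NULL,
                 clinical = NULL, comprehensive = NULL)
  skipped <- list()
  signif_of <- function(stage) {
    if (is.null(models[[stage]])) character(0)
    else significant_factors(models[[stage]], alpha)
  }
  fit_stage <- function(stage, table) {
    covs <- setdiff(names(table), "subject_id")
    if (!length(covs)) {
      skipped[[stage]] <<- "empty covariate set"
      message(sprintf("stage '%s' skipped: empty covariate set", stage))
      return(NULL)
    }
    fit_cox(table, survival, ties = ties)
  }

  feature_tab <- merge(mri_features, pet_features, by = "subject_id")
  models$mri <- fit_stage("mri", mri_features)
  models$pet <- fit_stage("pet", pet_features)

  carried3 <- c(signif_of("mri"), signif_of("pet"))
  models$two_modality <- fit_stage(
    "two_modality", feature_tab[, c("subject_id", carried3), drop = FALSE])

  models$clinical <- fit_stage("clinical", clinical)

  clin_in <- if (all_clinical) setdiff(names(clinical), "subject_id")
             else signif_of("clinical")
  carried5 <- c(signif_of("two_modality"), clin_in)
  all_tab <- merge(feature_tab, clinical, by = "subject_id")
  models$comprehensive <- fit_stage(
    "comprehensive", all_tab[, c("subject_id", carried5), drop = FALSE])

  structure(list(
    models = models,
    carried = list(two_modality = carried3, comprehensive = carried5),
    significant = lapply(stats::setNames(names(models), names(models)),
                         signif_of),
    skipped = skipped,
    alpha = alpha, ties = ties),
    class = "cox_suite")
}

#' @export
print.cox_suite <- function(x, ...) {
  cat("<cox_suite> five-stage chained Cox analysis\n")
  for (nm in names(x$models)) {
    if (is.null(x$models[[nm]])) {
      cat(sprintf("  %-13s skipped (%s)\n", nm,
                  x$skipped[[nm]] %||% "no fit"))
    } else {
      cat(sprintf("  %-13s %d covariates, significant: %s\n", nm,
                  nrow(x$models[[nm]]),
                  if (length(x$significant[[nm]]))
                    paste(x$significant[[nm]], collapse = ", ")
                  else "none"))
    }
  }
  invisible(x)
}

#' Write a Cox result table as CSV
#'
#' Columns mirror the standard reporting schema: covariate, beta, SE, p,
#' HR and the 95% CI bounds.
#'
#' @param result a `cox_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cox_csv <- function(result, path) {
  stopifnot(inherits(result, "cox_result"))
  df <- as.data.frame(result)[, c("term", "beta", "se", "p", "hr",
                                  "ci_low", "ci_high")]
  names(df)[1L] <- "covariate"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
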