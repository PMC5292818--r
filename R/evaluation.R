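# Logistic combination of risk factors and ROC-based prediction metrics.

#' Combine risk factors into a single index by logistic regression
#'
#' Maximum-likelihood logistic fit (IRLS via `stats::glm.fit`); the fitted
#' probability per subject is the combined risk index. Complete separation
#' is detected (fitted probabilities numerically 0/1 with diverging
#' coefficients), flagged with a warning, and the coefficients are capped
#' at |30| — the index then still ranks subjects but its scale is nominal.
#'
#' @param factors data.frame with `subject_id` plus numeric columns, or a
#'   numeric matrix.
#' @param labels binary outcome (logical, 0/1, or two-level factor) aligned
#'   with `factors` rows.
#' @param tol,max_iter IRLS control.
#' @return list: `weights` (named), `intercept`, `index` (fitted
#'   probabilities), `converged`, `separation`.
#' @export
fit_logistic <- function(factors, labels, tol = 1e-10, max_iter = 100L) {
  X <- as.matrix(if (is.data.frame(factors)) {
    factors[, setdiff(names(factors), "subject_id"), drop = FALSE]
  } else factors)
  y <- to_binary(labels)
  if (length(y) != nrow(X)) stop("labels length must match factors rows",
                                 call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present",
                                   call. = FALSE)
  if (any(apply(X, 2L, stats::sd) == 0)) {
    stop("constant factor column", call. = FALSE)
  }
  if (qr(scale(X))$rank < ncol(X)) stop("collinear factor columns",
                                        call. = FALSE)
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = tol,
                                                maxit = max_iter)),
    warning = function(w) invokeRestart("muffleWarning"))
  coefs <- fit$coefficients
  separation <- any(abs(coefs[-1L]) > 30) ||
    (any(fit$fitted.values > 1 - 1e-10) && any(fit$fitted.values < 1e-10) &&
     max(abs(coefs)) > 15)
  if (separation) {
    warning("complete separation detected; logistic coefficients capped at |30|")
    coefs <- pmin(pmax(coefs, -30), 30)
  }
  eta <- as.vector(cbind(1, X) %*% coefs)
  list(weights = coefs[-1L], intercept = unname(coefs[1L]),
       index = 1 / (1 + exp(-eta)), converged = fit$converged,
       separation = separation)
}

to_binary <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must be two-level", call. = FALSE)
    as.integer(labels == levels(labels)[2L])
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else {
    v <- as.numeric(labels)
    if (!all(v %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    as.integer(v)
  }
}

#' ROC curve
#'
#' One operating point per distinct score, inclusive decision rule
#' (`score >= threshold` is called positive). The curve starts at (0, 0)
#' (threshold `+Inf`) and ends at (1, 1); FPR and TPR are non-decreasing.
#'
#' @param index numeric scores (higher = more likely positive).
#' @param labels binary outcome.
#' @return data.frame: `threshold`, `fpr`, `tpr`, ordered along the curve.
#' @export
roc_curve <- function(index, labels) {
  y <- to_binary(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present",
                                   call. = FALSE)
  thr <- sort(unique(index), decreasing = TRUE)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  tpr <- vapply(thr, function(t) sum(index >= t & y == 1L) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(index >= t & y == 0L) / n_neg, numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_curve()]; algebraically equal to the
#' pairwise concordance probability (ties counted 1/2).
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(index, labels) {
  rc <- roc_curve(index, labels)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

#' Classification metrics at an ROC operating point
#'
#' Evaluates sensitivity, specificity and accuracy (as percentages) at the
#' operating threshold chosen by `rule`: `"youden"` (default) maximizes
#' Youden's J = sensitivity + specificity - 1, breaking ties toward the
#' threshold with the higher sensitivity; `"fixed"` uses `threshold`
#' directly. The decision rule is inclusive (`score >= threshold`).
#'
#' @inheritParams roc_curve
#' @param rule `"youden"` or `"fixed"`.
#' @param threshold operating threshold for `rule = "fixed"`.
#' @return list: `accuracy`, `sensitivity`, `specificity` (percent),
#'   `threshold`, `youden_j`.
#' @export
classification_metrics <- function(index, labels, rule = c("youden", "fixed"),
                                   threshold = 0.5) {
  rule <- match.arg(rule)
  y <- to_binary(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present",
                                   call. = FALSE)
  eval_at <- function(t) {
    pred <- as.integer(index >= t)
    tp <- sum(pred == 1L & y == 1L); fn <- sum(pred == 0L & y == 1L)
    tn <- sum(pred == 0L & y == 0L); fp <- sum(pred == 1L & y == 0L)
    c(sens = tp / (tp + fn), spec = tn / (tn + fp),
      acc = (tp + tn) / length(y))
  }
  if (rule == "fixed") {
    m <- eval_at(threshold)
    t_star <- threshold
  } else {
    cand <- sort(unique(index), decreasing = TRUE)
    mm <- vapply(cand, eval_at, numeric(3))
    j <- mm["sens", ] + mm["spec", ] - 1
    best <- which(j == max(j))
    pick <- best[which.max(mm["sens", best])]   # ties -> higher sensitivity
    m <- mm[, pick]
    t_star <- cand[pick]
  }
  list(accuracy = 100 * m[["acc"]], sensitivity = 100 * m[["sens"]],
       specificity = 100 * m[["spec"]], threshold = t_star,
       youden_j = m[["sens"]] + m[["spec"]] - 1)
}

#' Evaluate a set of risk factors against a binary outcome
#'
#' Chains [fit_logistic()], [auc()] and [classification_metrics()]: the
#' standard in-sample evaluation of each Cox stage's significant factors
#' against converter status.
#'
#' @param factors data.frame (`subject_id` + columns) or matrix.
#' @param labels binary converter status.
#' @param rule operating-point rule for [classification_metrics()].
#' @return list: `auc`, `accuracy`, `sensitivity`, `specificity`,
#'   `threshold`, `index`, `logistic` (the [fit_logistic()] object),
#'   `curve` (the ROC data.frame).
#' @export
evaluate_factors <- function(factors, labels, rule = "youden") {
  lg <- fit_logistic(factors, labels)
  cm <- classification_metrics(lg$index, labels, rule = rule)
  list(auc = auc(lg$index, labels), accuracy = cm$accuracy,
       sensitivity = cm$sensitivity, specificity = cm$specificity,
       threshold = cm$threshold, index = lg$index, logistic = lg,
       curve = roc_curve(lg$index, labels))
}
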