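#' Forward stepwise regression with rehabilitation-outcome diagnostics
#'
#' Greedy forward selection over a candidate list: at each step the
#' candidate that most improves the criterion (adjusted R-squared for
#' linear models, AUC for logistic models) is added; selection stops when
#' no candidate improves it by more than 1e-6. Given the same candidate
#' order and data the procedure is deterministic (ties keep the earlier
#' candidate). Only complete cases over the outcome and candidates are
#' used.
#'
#' The returned fit carries the diagnostics conventionally reported with
#' such models: per-term variance inflation factors and tolerances
#' (tolerance <= 0.40 flags multicollinearity), the Durbin-Watson
#' statistic of the residuals in data order (values near 2 indicate
#' independent errors), and for logistic models the AUC with a
#' DeLong-type confidence interval plus accuracy, sensitivity and
#' specificity at the classification threshold.
#'
#' @param data Data frame containing the outcome and candidates.
#' @param outcome Name of the outcome column (numeric for linear,
#'   logical/0-1 for logistic).
#' @param candidates Character vector of candidate predictor columns, in
#'   entry-preference order.
#' @param family `"linear"` or `"logistic"`.
#' @param criterion `"adjusted_r2"` (linear default) or `"auc"`
#'   (logistic default).
#' @param threshold Classification threshold for the logistic confusion
#'   metrics.
#' @param cv_folds Optional number of folds; when given, the selection
#'   criterion is cross-validated instead of in-sample (internal
#'   validation; off by default).
#' @param seed Seed for the fold assignment when `cv_folds` is used.
#' @return Object of class `"stepwise_fit"`: `selected`, `coefficients`
#'   (estimate, 95% CI, standardized estimate, p-value per term),
#'   `diagnostics`, the underlying `model`, and bookkeeping. Methods:
#'   `print`, `summary`, `coef`, `predict`.
#' @examples
#' d <- data.frame(y = rnorm(50))
#' d$x <- d$y + rnorm(50, sd = 0.1); d$z <- rnorm(50)
#' forward_stepwise(d, "y", c("x", "z"), family = "linear")
#' @export
forward_stepwise <- function(data, outcome, candidates,
                             family = c("linear", "logistic"),
                             criterion = NULL, threshold = 0.5,
                             cv_folds = NULL, seed = 1L) {
  family <- match.arg(family)
  if (is.null(criterion))
    criterion <- if (family == "linear") "adjusted_r2" else "auc"
  criterion <- match.arg(criterion, c("adjusted_r2", "auc"))
  if (length(candidates) < 1) stop_input("need at least one candidate")
  missing_cols <- setdiff(c(outcome, candidates), names(data))
  if (length(missing_cols))
    stop_input("columns not in data: %s", paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[, c(outcome, candidates)]),
            c(outcome, candidates), drop = FALSE]
  y <- d[[outcome]]
  if (family == "logistic") {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop_input("logistic outcome must be 0/1")
  }
  if (length(unique(y)) < 2)
    stop_input("degenerate design: outcome is constant")

  fit_fun <- function(terms) {
    f <- stats::reformulate(if (length(terms)) terms else "1", response = outcome)
    if (family == "linear") stats::lm(f, data = d)
    else stats::glm(f, data = d, family = stats::binomial())
  }
  crit_fun <- function(model) {
    if (criterion == "adjusted_r2") summary(model)$adj.r.squared
    else classification_metrics(stats::fitted(model), y == 1, threshold)$auc
  }
  cv_crit <- function(terms) {
    set.seed(seed)
    folds <- sample(rep_len(seq_len(cv_folds), nrow(d)))
    preds <- numeric(nrow(d))
    for (f in seq_len(cv_folds)) {
      tr <- d[folds != f, , drop = FALSE]
      fml <- stats::reformulate(if (length(terms)) terms else "1",
                                response = outcome)
      m <- if (family == "linear") stats::lm(fml, data = tr)
           else stats::glm(fml, data = tr, family = stats::binomial())
      preds[folds == f] <- stats::predict(m, newdata = d[folds == f, , drop = FALSE],
                                          type = "response")
    }
    if (criterion == "auc") classification_metrics(preds, y == 1, threshold)$auc
    else {
      ss_res <- sum((y - preds)^2); ss_tot <- sum((y - mean(y))^2)
      1 - ss_res / ss_tot
    }
  }
  evaluate <- function(terms) {
    if (!is.null(cv_folds)) cv_crit(terms) else crit_fun(fit_fun(terms))
  }

  selected <- character(0)
  current <- if (criterion == "adjusted_r2") -Inf else 0.5
  remaining <- candidates
  while (length(remaining)) {
    vals <- vapply(remaining, function(cand)
      tryCatch(evaluate(c(selected, cand)), error = function(e) -Inf),
      numeric(1))
    best <- which.max(vals)  # ties -> earlier candidate
    if (vals[best] > current + 1e-6) {
      selected <- c(selected, remaining[best])
      current <- vals[best]
      remaining <- remaining[-best]
    } else break
  }

  model <- fit_fun(selected)
  coefs <- summarize_coefficients(model, d, outcome, selected, family)
  diagnostics <- model_diagnostics(model, d, y, selected, family, threshold)
  structure(list(outcome = outcome, candidates = candidates,
                 family = family, criterion = criterion,
                 criterion_value = if (length(selected)) current else NA_real_,
                 selected = selected, coefficients = coefs,
                 diagnostics = diagnostics, model = model,
                 n = nrow(d), threshold = threshold),
            class = "stepwise_fit")
}

summarize_coefficients <- function(model, d, outcome, selected, family) {
  sm <- summary(model)$coefficients
  ci <- suppressMessages(stats::confint.default(model))
  # standardized estimates: refit on z-scored outcome (linear only) and predictors
  std <- rep(NA_real_, nrow(sm))
  if (length(selected)) {
    zd <- d
    for (v in selected) {
      s <- stats::sd(d[[v]])
      if (s > 0) zd[[v]] <- (d[[v]] - mean(d[[v]])) / s
    }
    if (family == "linear") {
      s_y <- stats::sd(d[[outcome]])
      zd[[outcome]] <- (d[[outcome]] - mean(d[[outcome]])) / s_y
      zm <- stats::lm(stats::reformulate(selected, response = outcome), data = zd)
    } else {
      zm <- stats::glm(stats::reformulate(selected, response = outcome),
                       data = zd, family = stats::binomial())
    }
    zc <- stats::coef(zm)
    std <- zc[rownames(sm)]
  }
  p_col <- grep("^Pr\\(", colnames(sm))
  data.frame(term = rownames(sm),
             estimate = sm[, "Estimate"],
             ci_low = ci[rownames(sm), 1],
             ci_high = ci[rownames(sm), 2],
             standardized = as.numeric(std),
             p_value = sm[, p_col],
             row.names = NULL, stringsAsFactors = FALSE)
}

model_diagnostics <- function(model, d, y, selected, family, threshold) {
  vt <- if (length(selected) >= 2) {
    vif_tolerance(d[, selected, drop = FALSE])
  } else if (length(selected) == 1) {
    data.frame(term = selected, vif = 1, tolerance = 1,
               stringsAsFactors = FALSE)
  } else {
    data.frame(term = character(0), vif = numeric(0), tolerance = numeric(0))
  }
  out <- list(vif = stats::setNames(vt$vif, vt$term),
              tolerance = stats::setNames(vt$tolerance, vt$term),
              durbin_watson = durbin_watson(stats::residuals(model)))
  if (family == "linear") {
    out$r2 <- summary(model)$r.squared
    out$adjusted_r2 <- summary(model)$adj.r.squared
  } else {
    cm <- classification_metrics(stats::fitted(model), y == 1, threshold)
    out[names(cm)] <- cm
  }
  out
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("Forward stepwise %s model for '%s' (n = %d)\n",
              x$family, x$outcome, x$n))
  cat("Selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("%s = %.4f\n", x$criterion,
              if (is.na(x$criterion_value)) NA else x$criterion_value))
  invisible(x)
}

#' @export
summary.stepwise_fit <- function(object, ...) {
  print(object)
  cat("\nCoefficients:\n")
  cf <- object$coefficients
  cf[, -1] <- lapply(cf[, -1], function(v) signif(v, 3))
  print(cf, row.names = FALSE)
  dg <- object$diagnostics
  cat(sprintf("\nDurbin-Watson: %.3f\n", dg$durbin_watson))
  if (!is.null(dg$adjusted_r2))
    cat(sprintf("R2 = %.3f, adjusted R2 = %.3f\n", dg$r2, dg$adjusted_r2))
  if (!is.null(dg$auc))
    cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), accuracy = %.3f, sensitivity = %.3f, specificity = %.3f\n",
                dg$auc, dg$auc_ci[1], dg$auc_ci[2], dg$accuracy,
                dg$sensitivity, dg$specificity))
  if (length(dg$tolerance)) {
    cat("Tolerance (1/VIF):\n")
    print(round(dg$tolerance, 3))
  }
  invisible(object)
}

#' @export
coef.stepwise_fit <- function(object, ...) stats::coef(object$model)

#' @export
predict.stepwise_fit <- function(object, newdata, ...) {
  if (object$family == "logistic")
    stats::predict(object$model, newdata = newdata, type = "response")
  else stats::predict(object$model, newdata = newdata)
}

#' Variance inflation factors and tolerances
#'
#' For each predictor column, `vif = 1 / (1 - R2_j)` where `R2_j` is the
#' R-squared of regressing that predictor on all the others; tolerance is
#' its reciprocal. A perfectly collinear predictor gets an infinite VIF
#' (tolerance 0).
#'
#' @param design Data frame or matrix of numeric predictors (>= 2
#'   columns).
#' @return Data frame with columns `term`, `vif`, `tolerance`.
#' @examples
#' vif_tolerance(data.frame(a = 1:10, b = rnorm(10)))
#' @export
vif_tolerance <- function(design) {
  design <- as.data.frame(design)
  if (ncol(design) < 2) stop_input("need at least two predictors for VIF")
  terms <- names(design)
  vif <- vapply(terms, function(tm) {
    r2 <- summary(stats::lm(stats::reformulate(setdiff(terms, tm), response = tm),
                            data = design))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(term = terms, vif = unname(vif), tolerance = unname(1 / vif),
             stringsAsFactors = FALSE)
}

#' Durbin-Watson statistic
#'
#' `d = sum((e_t - e_{t-1})^2) / sum(e_t^2)` over the residuals in their
#' given order; ranges over [0, 4], with values near 2 consistent with
#' independent errors.
#'
#' @param residuals Numeric vector of ordered residuals.
#' @return The statistic.
#' @examples
#' durbin_watson(c(1, -1, 1, -1))  # 3
#' @export
durbin_watson <- function(residuals) {
  e <- as.numeric(residuals)
  if (length(e) < 2) stop_input("need at least two residuals")
  ss <- sum(e^2)
  if (ss == 0) return(0)
  sum(diff(e)^2) / ss
}

#' Discrimination and confusion metrics for a binary classifier
#'
#' AUC by the rank (Mann-Whitney) formulation, a DeLong-type normal
#' approximation for its 95% confidence interval, and accuracy,
#' sensitivity and specificity at the given probability threshold.
#'
#' @param scores Numeric scores or probabilities.
#' @param labels Logical (or 0/1) true labels.
#' @param threshold Classification threshold (default 0.5).
#' @return List: `auc`, `auc_ci` (length 2), `accuracy`, `sensitivity`,
#'   `specificity`.
#' @examples
#' classification_metrics(c(.9, .8, .4, .3), c(TRUE, TRUE, FALSE, FALSE))
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop_input("scores and labels must have equal length")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop_input("need both positive and negative labels")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong structural components
  pos <- scores[labels]; neg <- scores[!labels]
  v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)), numeric(1))
  v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)), numeric(1))
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  if (!is.finite(se)) se <- 0
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  pred <- scores >= threshold
  list(auc = auc,
       auc_ci = ci,
       accuracy = mean(pred == labels),
       sensitivity = mean(pred[labels]),
       specificity = mean(!pred[!labels]))
}

#' Compare models with and without the rating covariate
#'
#' Reports the drop in the selection criterion when the early-rating term
#' is removed: the criterion of each fit and their difference
#' (with minus without). A positive delta means the rating term carries
#' predictive information beyond the other covariates.
#'
#' @param fit_with,fit_without Two [forward_stepwise()] fits on the same
#'   data, differing in whether the rating covariate was available.
#' @return List: `criterion`, `value_with`, `value_without`, `delta`.
#' @export
ablation_compare <- function(fit_with, fit_without) {
  stopifnot(inherits(fit_with, "stepwise_fit"),
            inherits(fit_without, "stepwise_fit"))
  if (fit_with$criterion != fit_without$criterion)
    stop_input("fits use different criteria (%s vs %s)",
               fit_with$criterion, fit_without$criterion)
  value_of <- function(f) {
    if (f$criterion == "adjusted_r2") {
      if (is.null(f$diagnostics$adjusted_r2)) NA_real_
      else f$diagnostics$adjusted_r2
    } else f$diagnostics$auc
  }
  vw <- value_of(fit_with); vo <- value_of(fit_without)
  list(criterion = fit_with$criterion, value_with = vw,
       value_without = vo, delta = vw - vo)
}
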