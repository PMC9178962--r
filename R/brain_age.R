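# Brain-age model: sparse (lasso) linear prediction of age from regional
# mean MS, trained on the normative cohort, with brain-age gaps for new
# cohorts. Gap = predicted - calendar age, so an older-looking brain gets a
# positive gap; the convention can be flipped.

#' Train a lasso age-prediction model on normative regional MS
#'
#' L1-penalized linear regression of age on regional mean MS with the
#' penalty chosen by k-fold cross-validated mean squared error
#' (`glmnet::cv.glmnet`); folds are seeded so training is deterministic.
#'
#' @param ms subjects x regions matrix of regional mean MS.
#' @param age numeric vector of ages.
#' @param n_folds number of CV folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @param use_1se use the one-standard-error rule instead of the minimum-CV
#'   penalty (default FALSE).
#' @return object of class `brain_age_model`: intercept, per-region
#'   weights (years per MS unit), chosen penalty, CV summary and sparsity.
#' @export
train_age_model <- function(ms, age, n_folds = 5L, seed = 1L, use_1se = FALSE) {
  ms <- as.matrix(ms)
  if (stats::sd(age) == 0) stop_msa("age vector is constant; cannot train")
  if (nrow(ms) < n_folds) stop_msa("need at least n_folds subjects")
  foldid <- withr_seed(seed, sample(rep_len(seq_len(n_folds), nrow(ms))))
  cv <- glmnet::cv.glmnet(ms, age, alpha = 1, foldid = foldid, family = "gaussian")
  lambda <- if (use_1se) cv$lambda.1se else cv$lambda.min
  cf <- as.matrix(stats::coef(cv, s = lambda))
  w <- cf[-1L, 1L]
  names(w) <- colnames(ms)
  structure(list(intercept = cf[1L, 1L], weights = w, lambda = lambda,
                 use_1se = use_1se,
                 cv_mse = cv$cvm[cv$lambda == lambda],
                 n_nonzero = sum(w != 0), n_regions = length(w),
                 n_subjects = nrow(ms), n_folds = n_folds, seed = seed,
                 regions = colnames(ms)),
            class = "brain_age_model")
}

#' @export
print.brain_age_model <- function(x, ...) {
  cat(sprintf("Lasso brain-age model: %d/%d regions with non-zero weight\n",
              x$n_nonzero, x$n_regions))
  cat(sprintf("  lambda = %.4g (%s, %d-fold CV on %d subjects), CV RMSE = %.2f years\n",
              x$lambda, if (x$use_1se) "1se" else "min", x$n_folds, x$n_subjects,
              sqrt(x$cv_mse)))
  invisible(x)
}

#' Predict age from regional MS
#'
#' @param object a `brain_age_model`.
#' @param ms subjects x regions matrix with the training regions.
#' @param ... unused.
#' @return numeric vector of predicted ages.
#' @export
predict.brain_age_model <- function(object, ms, ...) {
  ms <- as.matrix(ms)
  miss <- setdiff(object$regions, colnames(ms))
  if (length(miss)) stop_msa("MS table lacks model regions: %s",
                             paste(utils::head(miss, 5), collapse = ", "))
  drop(ms[, object$regions, drop = FALSE] %*% object$weights) + object$intercept
}

#' Estimate a linear age-bias correction
#'
#' Regression to the mean makes raw predicted ages too old for young
#' subjects and too young for old ones (raw gaps correlate negatively with
#' age). This fits `predicted ~ age` on held-out normative data; corrected
#' predictions are `(predicted - intercept) / slope`.
#'
#' @param model a `brain_age_model`.
#' @param ms,age held-out normative MS matrix and ages.
#' @return list `intercept`, `slope`, plus the raw `gap_age_correlation`.
#' @export
estimate_bias_correction <- function(model, ms, age) {
  pred <- predict(model, ms)
  fit <- stats::lm(pred ~ age)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       gap_age_correlation = stats::cor(pred - age, age))
}

#' Brain-age gaps for a cohort
#'
#' @param model a `brain_age_model`.
#' @param ms subjects x regions matrix.
#' @param age calendar ages.
#' @param convention `"predicted_minus_calendar"` (default: positive gap =
#'   older-looking brain) or `"calendar_minus_predicted"`.
#' @param bias_correction optional [estimate_bias_correction()] result to
#'   apply before computing gaps.
#' @return data frame `subject_id, predicted_age, calendar_age, gap` with
#'   attributes recording the convention and the gap-age correlation.
#' @export
compute_gaps <- function(model, ms, age,
                         convention = c("predicted_minus_calendar",
                                        "calendar_minus_predicted"),
                         bias_correction = NULL) {
  convention <- match.arg(convention)
  pred <- predict(model, ms)
  if (!is.null(bias_correction))
    pred <- (pred - bias_correction$intercept) / bias_correction$slope
  gap <- pred - age
  if (convention == "calendar_minus_predicted") gap <- -gap
  out <- data.frame(subject_id = rownames(as.matrix(ms)) %||% seq_along(age),
                    predicted_age = pred, calendar_age = age, gap = gap,
                    stringsAsFactors = FALSE)
  attr(out, "convention") <- convention
  attr(out, "bias_corrected") <- !is.null(bias_correction)
  attr(out, "gap_age_correlation") <- stats::cor(gap, age)
  out
}

#' Compare brain-age gaps between groups
#'
#' Two-sample t-test on gaps; the difference is reported as patient minus
#' control.
#'
#' @param gaps data frame from [compute_gaps()].
#' @param group vector of group labels (`control` / `patient`).
#' @param var_equal pooled-variance t (default).
#' @return list `difference` (patient - control mean gap), `t`, `df`, `p`,
#'   `group_means`.
#' @export
compare_gaps <- function(gaps, group, var_equal = TRUE) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop_msa("need exactly two groups")
  tt <- col_t_twosample(matrix(gaps$gap, ncol = 1), g, var_equal = var_equal)
  means <- stats::setNames(c(tt$mean1, tt$mean2), tt$levels)
  pat <- grep("patient", tt$levels)
  diff <- if (length(pat) == 1L) means[pat] - means[-pat] else tt$mean2 - tt$mean1
  list(difference = unname(diff), t = unname(tt$t), df = unname(tt$df),
       p = unname(tt$p), group_means = means)
}
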