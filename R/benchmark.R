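# Multivariate logistic regression benchmark: maximum-likelihood fit over
# the same design matrix the network sees (raw units, categorical features
# expanded against their reference level), Wald odds-ratio intervals, and
# the impact-score-versus-coefficient correlation.

#' Fit the logistic regression benchmark
#'
#' Maximum-likelihood logistic regression of the outcome on every design
#' column, with 95% Wald confidence intervals for the odds ratios
#' (`exp(b +/- 1.96 SE)`). By default it is fit on the same (typically
#' under-sampled) training indices as the network; rebalancing shifts the
#' intercept but not the slopes.
#'
#' @param cohort an `ehr_cohort`.
#' @param indices training index vector.
#' @param eval_indices optional held-out indices on which the benchmark AUC
#'   is computed.
#' @param outcome label column (default `"y"`).
#' @return an object of class `lr_fit`: `coefficients` (named, no
#'   intercept), `intercept`, `or_ci` (data frame feature/or/low/high),
#'   `auc`, and the underlying design metadata for prediction.
#' @export
fit_logistic <- function(cohort, indices, eval_indices = NULL, outcome = "y") {
  y <- cohort[[outcome]][indices]
  .assert(length(unique(y)) == 2, "both outcome classes must be present")
  D <- build_design_matrix(cohort$specs, cohort$features)
  orig_names <- colnames(D)
  safe <- make.names(orig_names, unique = TRUE)
  dat <- as.data.frame(D[indices, , drop = FALSE])
  names(dat) <- safe
  dat$.y <- y
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
  sm <- summary(fit)$coefficients
  if (!fit$converged || any(!is.finite(sm[, "Std. Error"])) ||
      any(sm[-1, "Std. Error"] > 50)) {
    worst <- rownames(sm)[-1][which.max(sm[-1, "Std. Error"])]
    stop("logistic fit failed (separation or non-convergence), worst feature: ",
         orig_names[match(worst, safe)], call. = FALSE)
  }
  coefs <- stats::setNames(sm[-1, "Estimate"], orig_names)
  ses <- stats::setNames(sm[-1, "Std. Error"], orig_names)
  zc <- stats::qnorm(0.975)
  or_ci <- data.frame(
    feature = orig_names,
    coef = unname(coefs),
    or = exp(unname(coefs)),
    low = exp(unname(coefs - zc * ses)),
    high = exp(unname(coefs + zc * ses)),
    row.names = NULL, stringsAsFactors = FALSE)
  obj <- structure(
    list(coefficients = coefs, intercept = unname(sm[1, "Estimate"]),
         se = ses, or_ci = or_ci, auc = NA_real_,
         specs = cohort$specs, design_names = orig_names),
    class = "lr_fit")
  if (!is.null(eval_indices)) {
    obj$auc <- .rank_auc(cohort[[outcome]][eval_indices],
                         predict_proba(obj, cohort$features[eval_indices, ,
                                                            drop = FALSE]))
  }
  obj
}

#' @rdname predict_proba
#' @export
predict_proba.lr_fit <- function(model, features, ...) {
  D <- if (is.matrix(features)) features
       else build_design_matrix(model$specs, features)
  .sigmoid(model$intercept +
             drop(D[, model$design_names, drop = FALSE] %*% model$coefficients))
}

#' @export
print.lr_fit <- function(x, ...) {
  cat(sprintf("<lr_fit> %d coefficients%s\n", length(x$coefficients),
              if (is.na(x$auc)) "" else sprintf(", held-out AUC %.3f", x$auc)))
  print(x$or_ci, digits = 3)
  invisible(x)
}

#' Correlation between impact scores and logistic coefficients
#'
#' Pearson correlation across features between population impact scores and
#' the fitted log-odds coefficients of the benchmark. Logit-scale impact
#' scores of a model that is itself logistic equal the coefficients, giving
#' correlation 1 by construction.
#'
#' @param impacts a `score_set`, or list of `score_result`s, of impact
#'   scores.
#' @param fit an `lr_fit`.
#' @return the correlation coefficient, with attribute `"scale"` recording
#'   the impact-score scale.
#' @export
coefficient_correlation <- function(impacts, fit) {
  if (inherits(impacts, "score_set")) impacts <- impacts$impact
  pop <- stats::setNames(vapply(impacts, `[[`, 0, "population"),
                         vapply(impacts, `[[`, "", "target"))
  shared <- intersect(names(pop), names(fit$coefficients))
  .assert(length(shared) >= 3,
          "need at least 3 shared features for a correlation")
  r <- stats::cor(pop[shared], fit$coefficients[shared])
  attr(r, "scale") <- impacts[[1]]$scale
  r
}
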