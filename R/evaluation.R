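#' Logit-transform raw risk scores
#'
#' Risk predictions are mapped to the linear-predictor scale before the
#' association fit. Raw risks are clipped to `[eps, 1 - eps]` first, since
#' tree-based scores can produce exact 0/1 risks.
#'
#' @param raw risk estimates in `[0, 1]`.
#' @param eps clipping bound (default `1e-6`).
#' @return `qlogis(clipped raw)`.
#' @export
logit_transform_grs <- function(raw, eps = 1e-6) {
  stopifnot(all(raw >= 0), all(raw <= 1))
  qlogis(pmin(pmax(raw, eps), 1 - eps))
}

#' Univariate GRS association model with Wald test
#'
#' Fits `logit P(Y=1 | GRS) = b0 + b1 * GRS` on logit-transformed risk
#' scores and reports the two-sided Wald p-value for `b1`. A constant GRS
#' carries no association evidence: the fit is flagged degenerate with
#' `b1 = 0` and `wald_p = 1`.
#'
#' @param grs raw risk scores in `[0, 1]` (they are logit-transformed
#'   internally unless `transform = FALSE`).
#' @param outcome binary 0/1 vector with both classes present.
#' @param transform apply [logit_transform_grs()] first (default TRUE).
#' @return List of class `grs_association`: `intercept`,
#'   `grs_coefficient`, `wald_p`, `degenerate`, `fit` (the glm, or NULL).
#' @export
fit_association_model <- function(grs, outcome, transform = TRUE) {
  y <- phenotype_vector(outcome)
  if (length(unique(y)) < 2L) {
    stop("outcome has a single class; the association model is undefined")
  }
  s <- if (transform) logit_transform_grs(grs) else grs
  if (var(s) < 1e-12) {
    return(structure(list(intercept = qlogis(mean(y)), grs_coefficient = 0,
                          wald_p = 1, degenerate = TRUE, fit = NULL),
                     class = "grs_association"))
  }
  fit <- glm(y ~ s, family = binomial())
  sm <- summary(fit)$coefficients
  structure(list(intercept = sm[1L, 1L], grs_coefficient = sm[2L, 1L],
                 wald_p = sm[2L, 4L], degenerate = FALSE, fit = fit),
            class = "grs_association")
}

#' @export
print.grs_association <- function(x, ...) {
  if (x$degenerate) {
    cat("GRS association: degenerate (constant score), p = 1\n")
  } else {
    cat(sprintf("GRS association: b1 = %.4f, two-sided Wald p = %.3g\n",
                x$grs_coefficient, x$wald_p))
  }
  invisible(x)
}

#' Adjusted gene-environment association model
#'
#' Fits `logit P(Y=1) = b0 + b1 GRS + b2 E + b3 GRS*E + sum_i g_i C_i` and
#' reports Wald p-values for the GRS main effect and the GRS-by-environment
#' interaction.
#'
#' @param grs raw risk scores (logit-transformed internally).
#' @param environment numeric exposure vector E.
#' @param outcome binary 0/1 vector.
#' @param covariates optional data frame / matrix of adjustment covariates.
#' @param transform logit-transform the GRS first (default TRUE).
#' @return List with the coefficient table (`coefficients`), `grs_p` and
#'   `interaction_p`.
#' @export
fit_adjusted_gxe_model <- function(grs, environment, outcome,
                                   covariates = NULL, transform = TRUE) {
  y <- phenotype_vector(outcome)
  s <- if (transform) logit_transform_grs(grs) else grs
  if (var(environment) < 1e-12) {
    # constant exposure: the model collapses to the univariate GRS fit
    base <- fit_association_model(s, y, transform = FALSE)
    return(list(coefficients = if (is.null(base$fit)) NULL
                  else summary(base$fit)$coefficients,
                grs_p = base$wald_p, interaction_p = NA_real_,
                fit = base$fit))
  }
  df <- data.frame(y = y, grs = s, env = environment)
  form <- y ~ grs + env + grs:env
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
    form <- stats::reformulate(c("grs", "env", "grs:env", names(covariates)),
                               response = "y")
  }
  fit <- glm(form, family = binomial(), data = df)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design; collinear terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  list(coefficients = sm,
       grs_p = sm["grs", 4L],
       interaction_p = sm["grs:env", 4L],
       fit = fit)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random case scores higher than a random control,
#' with half credit for ties — required for the discrete scores tree-based
#' GRS produce. Invariant under strictly monotone transformations.
#'
#' @param scores numeric risk scores.
#' @param labels binary 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- phenotype_vector(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC requires both classes")
  r <- rank(scores)   # midranks give ties half credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics at a fixed risk threshold
#'
#' @param risks predicted case probabilities.
#' @param labels binary 0/1 labels.
#' @param threshold classification cut-off (default 0.5; predictions
#'   strictly above it are classified as cases).
#' @return Named vector: `accuracy`, `sensitivity`, `specificity`. No
#'   prevalence adjustment is applied.
#' @export
classification_metrics <- function(risks, labels, threshold = 0.5) {
  labels <- phenotype_vector(labels)
  pred <- as.integer(risks > threshold)
  c(accuracy = mean(pred == labels),
    sensitivity = if (any(labels == 1L)) mean(pred[labels == 1L] == 1L) else NA_real_,
    specificity = if (any(labels == 0L)) mean(pred[labels == 0L] == 0L) else NA_real_)
}

#' Estimate statistical power from replicate p-values
#'
#' The fraction of association tests on influential data that reject at
#' `level`, with its binomial Monte-Carlo standard error.
#'
#' @param p_values Wald p-values, one per replicate.
#' @param level significance level (default 0.05).
#' @return List with `estimate` and `se`.
#' @export
estimate_power <- function(p_values, level = 0.05) {
  stopifnot(length(p_values) >= 1)
  est <- mean(p_values < level)
  list(estimate = est, se = sqrt(est * (1 - est) / length(p_values)))
}

#' Estimate the type-I error rate from null-replicate p-values
#'
#' The fraction of association tests rejecting at `level` when outcome and
#' predictors are independent (all generating coefficients zero).
#'
#' @inheritParams estimate_power
#' @return List with `estimate` and `se`.
#' @export
estimate_type1 <- function(p_values, level = 0.05) {
  estimate_power(p_values, level)
}

#' Evaluate a fitted GRS model on test data
#'
#' Computes the test-set risk predictions, the univariate Wald association
#' test on the logit scale, the AUC, and the classification metrics of the
#' association model's fitted probabilities at threshold 0.5.
#'
#' @param model any fitted GRS model (a `grs_model` or `grs_true_model`).
#' @param genotypes test `snp_matrix`.
#' @param outcome test 0/1 outcome.
#' @param environment exposure matrix, only used by true models with
#'   environmental terms.
#' @return A list of class `grs_evaluation`: `auc`, `wald_p`,
#'   `grs_coefficient`, `degenerate`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate_grs <- function(model, genotypes, outcome, environment = NULL) {
  y <- phenotype_vector(outcome)
  risks <- if (inherits(model, "grs_true_model")) {
    predict(model, genotypes, environment = environment)
  } else {
    predict(model, genotypes)
  }
  assoc <- fit_association_model(risks, y)
  fitted_p <- if (assoc$degenerate) rep(mean(y), length(y))
              else as.numeric(stats::fitted(assoc$fit))
  metrics <- classification_metrics(fitted_p, y)
  structure(list(auc = auc(risks, y), wald_p = assoc$wald_p,
                 grs_coefficient = assoc$grs_coefficient,
                 degenerate = assoc$degenerate,
                 accuracy = metrics[["accuracy"]],
                 sensitivity = metrics[["sensitivity"]],
                 specificity = metrics[["specificity"]]),
            class = "grs_evaluation")
}

#' @export
print.grs_evaluation <- function(x, ...) {
  cat(sprintf("GRS evaluation: AUC %.3f, Wald p %.3g, accuracy %.3f (sens %.3f, spec %.3f)\n",
              x$auc, x$wald_p, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}
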