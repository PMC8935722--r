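#' Elastic-net penalty value
#'
#' `R_alpha(beta) = (1 - alpha)/2 * ||beta||_2^2 + alpha * ||beta||_1`,
#' evaluated over the non-intercept coefficients: `alpha = 1` is the lasso,
#' `alpha = 0` the ridge penalty.
#'
#' @param beta coefficient vector (intercept excluded).
#' @param alpha mixing parameter in `[0, 1]`.
#' @export
penalty_value <- function(beta, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  (1 - alpha) / 2 * sum(beta^2) + alpha * sum(abs(beta))
}

#' Configuration for the elastic-net genetic risk score
#'
#' @param alpha_grid mixing parameters tried; the pair (alpha, lambda)
#'   minimizing the cross-validated deviance is selected.
#' @param lambda_selection `"min_cv_loss"` (default: the deviance-minimizing
#'   lambda) or `"one_se"` (largest lambda within one standard error — more
#'   conservative, tends towards intercept-only fits on weak signals).
#' @param n_folds cross-validation folds, stratified by outcome.
#' @param coding `"additive_012"` (minor-allele counts, default) or
#'   `"binary_01"` (dominant/recessive indicator pairs, which lets the
#'   linear model express distinct dominant and recessive effects).
#' @param lambda optional fixed penalty weight; when supplied,
#'   cross-validation is skipped and the path is solved down to this value
#'   (0 gives the unpenalized logistic fit) using the first alpha of the
#'   grid.
#' @param seed integer seed for the fold assignment.
#' @return A list of class `enet_config`.
#' @export
enet_config <- function(alpha_grid = c(0.5, 0.75, 0.9, 0.99),
                        lambda_selection = c("min_cv_loss", "one_se"),
                        n_folds = 10L,
                        coding = c("additive_012", "binary_01"),
                        lambda = NULL,
                        seed = 1L) {
  lambda_selection <- match.arg(lambda_selection)
  coding <- match.arg(coding)
  stopifnot(all(alpha_grid >= 0), all(alpha_grid <= 1), n_folds >= 2)
  structure(list(alpha_grid = alpha_grid, lambda_selection = lambda_selection,
                 n_folds = as.integer(n_folds), coding = coding,
                 lambda = lambda, seed = as.integer(seed)),
            class = "enet_config")
}

# Outcome-stratified fold ids so every fold sees both classes even on
# imbalanced data.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Fit an elastic-net logistic genetic risk score
#'
#' Penalized logistic regression
#' `min_{b0, beta} -1/N * loglik + lambda * R_alpha(beta)` solved by
#' coordinate descent along a warm-started lambda path (via glmnet). For
#' each alpha in the grid, lambda is chosen by K-fold cross-validated
#' deviance on shared stratified folds; the (alpha, lambda) pair with the
#' smallest CV loss wins. Interaction terms are deliberately not expanded:
#' the model is linear in the chosen SNP coding.
#'
#' @param genotypes a `snp_matrix`.
#' @param outcome binary 0/1 vector (both classes must be present).
#' @param config an [enet_config()].
#' @return An object of class `c("grs_enet", "grs_model")`.
#' @export
fit_elastic_net <- function(genotypes, outcome, config = enet_config()) {
  g <- as_snp_matrix(genotypes)
  y <- phenotype_vector(outcome, g)
  if (length(unique(y)) < 2L) {
    stop("training outcome has a single class; cannot fit a logistic model")
  }
  x <- switch(config$coding,
    additive_012 = encode_additive(g),
    binary_01 = {
      b <- encode_dominant_recessive(g)
      attributes(b)[c("source_snp", "mode", "class")] <- NULL
      storage.mode(b) <- "double"
      b
    }
  )
  set.seed(config$seed)
  if (!is.null(config$lambda)) {
    alpha <- config$alpha_grid[1L]
    path <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha)
    lam <- sort(unique(c(path$lambda, config$lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                          lambda = lam, thresh = 1e-14, maxit = 1e6)
    b <- coef(fit, s = config$lambda, exact = FALSE)
    beta <- stats::setNames(as.numeric(b), rownames(b))
    return(structure(list(fit = fit, lambda = config$lambda, alpha = alpha,
                          cv_loss = NA_real_, coefficients = beta,
                          config = config, method = "enet"),
                     class = c("grs_enet", "grs_model")))
  }
  foldid <- stratified_folds(y, config$n_folds)
  best <- NULL
  for (alpha in config$alpha_grid) {
    cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                               foldid = foldid, type.measure = "deviance")
    lambda <- if (config$lambda_selection == "min_cv_loss") cvfit$lambda.min
              else cvfit$lambda.1se
    loss <- cvfit$cvm[match(lambda, cvfit$lambda)]
    if (is.null(best) || loss < best$loss) {
      best <- list(fit = cvfit$glmnet.fit, lambda = lambda, alpha = alpha,
                   loss = loss)
    }
  }
  b <- coef(best$fit, s = best$lambda)
  beta <- stats::setNames(as.numeric(b), rownames(b))
  structure(list(fit = best$fit, lambda = best$lambda, alpha = best$alpha,
                 cv_loss = best$loss, coefficients = beta,
                 config = config, method = "enet"),
            class = c("grs_enet", "grs_model"))
}

#' @export
predict.grs_enet <- function(object, newdata, ...) {
  g <- as_snp_matrix(newdata)
  x <- switch(object$config$coding,
    additive_012 = encode_additive(g),
    binary_01 = {
      b <- encode_dominant_recessive(g)
      attributes(b)[c("source_snp", "mode", "class")] <- NULL
      storage.mode(b) <- "double"
      b
    }
  )
  drop(predict(object$fit, newx = x, s = object$lambda, type = "response"))
}

#' @export
print.grs_enet <- function(x, ...) {
  nz <- sum(x$coefficients[-1L] != 0)
  cat(sprintf("elastic net GRS (%s coding): alpha %.2f, lambda %.5f, %d nonzero SNP coefficients\n",
              x$config$coding, x$alpha, x$lambda, nz))
  invisible(x)
}

#' @export
coef.grs_enet <- function(object, ...) object$coefficients
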