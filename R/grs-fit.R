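#' Fit a genetic risk score model
#'
#' The common front door for all GRS learners. Dispatches on `method` to
#' the probability-estimation random forest (`"rf"`), the forest with
#' prior shadow-variable selection (`"rfvim"`), logic regression
#' (`"logicreg"`), bagged logic regression (`"logicbag"`) or the
#' elastic-net logistic reference (`"enet"`). Every fitted object answers
#' `predict(model, genotypes)` with case probabilities in `[0, 1]`.
#'
#' Defaults are desk-scale (500 trees, 100 bags, 50 shadow iterations);
#' pass an explicit `config` or the size arguments for full-scale fits
#' (2000 trees, 500 bags, 100 iterations, 500000 annealing steps).
#'
#' @param genotypes a `snp_matrix` or \{0,1,2\} matrix.
#' @param outcome binary 0/1 phenotype vector.
#' @param method one of `"rf"`, `"rfvim"`, `"logicreg"`, `"logicbag"`,
#'   `"enet"`.
#' @param config an optional [forest_config()], [logic_config()] or
#'   [enet_config()] matching the method; built from `seed` and the
#'   method's defaults when NULL.
#' @param n_bags ensemble size for `"logicbag"`.
#' @param boruta_iterations shadow iterations for `"rfvim"`.
#' @param num_trees trees per forest for `"rf"` / `"rfvim"` when `config`
#'   is NULL.
#' @param seed integer seed used when `config` is NULL.
#' @return A fitted model inheriting from class `grs_model`.
#' @examples
#' set.seed(1)
#' g <- simulate_genotypes(rep(0.3, 5), 300)
#' y <- rbinom(300, 1, plogis(-0.5 + (g[, 1] != 0)))
#' m <- grs_fit(g, y, method = "rf", num_trees = 100)
#' head(predict(m, g))
#' @export
grs_fit <- function(genotypes,
                    outcome,
                    method = c("rf", "rfvim", "logicreg", "logicbag", "enet"),
                    config = NULL,
                    n_bags = 100L,
                    boruta_iterations = 50L,
                    num_trees = 500L,
                    seed = 1L) {
  method <- match.arg(method)
  switch(method,
    rf = fit_probability_forest(genotypes, outcome,
      config %||% forest_config(num_trees = num_trees, seed = seed)),
    rfvim = fit_rf_vim(genotypes, outcome,
      config %||% forest_config(num_trees = num_trees, seed = seed),
      n_iterations = boruta_iterations),
    logicreg = fit_logic_regression(genotypes, outcome,
      config %||% logic_config(seed = seed)),
    logicbag = fit_logic_bagging(genotypes, outcome,
      config %||% logic_config(seed = seed), n_bags = n_bags),
    enet = fit_elastic_net(genotypes, outcome,
      config %||% enet_config(seed = seed))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.grs_model <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Plot the risk distribution of a fitted GRS by outcome class
#'
#' @param x a fitted `grs_model`.
#' @param genotypes genotype matrix to score.
#' @param outcome 0/1 labels used to stratify the histogram.
#' @param ... passed to [graphics::hist()].
#' @export
plot.grs_model <- function(x, genotypes, outcome, ...) {
  risks <- predict(x, genotypes)
  y <- phenotype_vector(outcome)
  graphics::hist(risks[y == 0L], col = grDevices::rgb(0, 0, 1, 0.4),
                 xlim = c(0, 1), main = "GRS distribution by class",
                 xlab = "predicted risk", ...)
  graphics::hist(risks[y == 1L], col = grDevices::rgb(1, 0, 0, 0.4),
                 add = TRUE, ...)
  graphics::legend("topright", fill = grDevices::rgb(c(0, 1), 0, c(1, 0), 0.4),
                   legend = c("controls", "cases"))
  invisible(x)
}
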