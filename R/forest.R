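#' Configuration for probability-estimation random forests
#'
#' @param num_trees number of trees (2000 for full-scale runs; smaller
#'   values are adequate for calibration experiments).
#' @param mtry candidate features drawn (without replacement) at each
#'   split; defaults to `floor(sqrt(p))` at fit time.
#' @param min_node_size minimum in-bag samples per leaf; defaults to
#'   `max(1, floor(0.01 * N))` at fit time.
#' @param seed integer seed.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(num_trees = 2000L, mtry = NULL,
                          min_node_size = NULL, seed = 1L) {
  stopifnot(num_trees >= 1)
  structure(list(num_trees = as.integer(num_trees),
                 mtry = if (!is.null(mtry)) as.integer(mtry),
                 min_node_size = if (!is.null(min_node_size)) as.integer(min_node_size),
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Gini impurity of a binary node
#'
#' `i(t) = 2 p (1 - p)` for class-1 fraction `p` — the split criterion of
#' the probability-estimation trees.
#'
#' @param p1 class-1 fraction in `[0, 1]`.
#' @export
gini_impurity <- function(p1) {
  stopifnot(all(p1 >= 0), all(p1 <= 1))
  2 * p1 * (1 - p1)
}

#' Best genotype split of a node
#'
#' Reference semantics of the tree-growing step: among the candidate
#' features, evaluate both ordered cut points per SNP (`{0} | {1,2}` and
#' `{0,1} | {2}`) and return the split minimizing the weighted child Gini
#' impurity. Returns NULL when no split reduces impurity while leaving at
#' least `min_node_size` samples in both children. Ties break on the
#' lowest feature index, then the lower cut point.
#'
#' @param x node genotype matrix (entries 0/1/2).
#' @param y node outcomes (0/1).
#' @param candidates feature column indices eligible for splitting.
#' @param min_node_size minimum child size.
#' @return NULL or a list with `feature`, `cut` (0 or 1: left child is
#'   `genotype <= cut`) and `impurity` (weighted child Gini).
#' @export
best_split <- function(x, y, candidates = seq_len(ncol(x)), min_node_size = 1L) {
  n <- length(y)
  parent <- gini_impurity(mean(y))
  best <- NULL
  best_imp <- parent - 1e-12
  for (j in sort(candidates)) {
    for (cut in c(0L, 1L)) {
      left <- x[, j] <= cut
      nl <- sum(left)
      if (nl < min_node_size || n - nl < min_node_size) next
      imp <- (nl * gini_impurity(mean(y[left])) +
              (n - nl) * gini_impurity(mean(y[!left]))) / n
      if (imp < best_imp) {
        best_imp <- imp
        best <- list(feature = j, cut = cut, impurity = imp)
      }
    }
  }
  best
}

#' Fit a probability-estimation random forest genetic risk score
#'
#' Grows `num_trees` trees on independent bootstrap samples of the
#' \{0,1,2\}-coded genotypes. Leaves store the in-bag empirical class-1
#' fraction (a risk estimate, not a majority vote), and the forest risk is
#' the arithmetic mean of the tree leaf probabilities. Out-of-bag indices
#' are recorded per tree for [permutation_vim()].
#'
#' @param genotypes a `snp_matrix` (or \{0,1,2\} matrix).
#' @param outcome binary 0/1 vector.
#' @param config a [forest_config()].
#' @return An object of class `c("grs_forest", "grs_model")`.
#' @export
fit_probability_forest <- function(genotypes, outcome, config = forest_config()) {
  g <- as_snp_matrix(genotypes)
  y <- phenotype_vector(outcome, g)
  X <- unclass(g)
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(ncol(X)))) else config$mtry
  mtry <- min(mtry, ncol(X))
  mns <- if (is.null(config$min_node_size)) max(1L, floor(0.01 * nrow(X)))
         else config$min_node_size
  forest <- cpp_fit_forest(X, y, config$num_trees, mtry, mns, config$seed)
  structure(list(forest = forest, train_x = X, train_y = y,
                 mtry = mtry, min_node_size = mns, config = config,
                 snp_ids = colnames(g), method = "rf"),
            class = c("grs_forest", "grs_model"))
}

#' @export
predict.grs_forest <- function(object, newdata, ...) {
  X <- unclass(as_snp_matrix(newdata))
  if (ncol(X) != ncol(object$train_x)) {
    stop("newdata has ", ncol(X), " SNPs but the forest was trained on ",
         ncol(object$train_x))
  }
  cpp_predict_forest(object$forest$trees, X)
}

#' @export
print.grs_forest <- function(x, ...) {
  cat(sprintf("probability forest GRS: %d trees, mtry %d, min.node.size %d, %d SNPs\n",
              x$config$num_trees, x$mtry, x$min_node_size, ncol(x$train_x)))
  invisible(x)
}

#' Out-of-bag permutation variable importance
#'
#' For every feature a tree actually splits on, the feature's values are
#' permuted among the tree's out-of-bag samples and the increase in OOB
#' misclassification rate (classifying at threshold 0.5) over the
#' unpermuted baseline is recorded; the importance is the mean increase
#' over trees with OOB data. Features never used by a tree contribute
#' exactly zero for that tree.
#'
#' @param model a fitted `grs_forest`.
#' @param seed seed for the permutations.
#' @return Named numeric vector of per-SNP importances.
#' @export
permutation_vim <- function(model, seed = model$config$seed) {
  stopifnot(inherits(model, "grs_forest"))
  v <- cpp_permutation_vim(model$forest$trees, model$forest$oob,
                           model$train_x, model$train_y, seed)
  names(v) <- model$snp_ids
  v
}

#' Shadow-variable (Boruta-style) SNP selection
#'
#' In each iteration, every SNP receives a shadow copy with independently
#' permuted rows (destroying any genotype-outcome relationship while
#' preserving the marginal distribution); a forest is fitted on originals
#' plus shadows and a SNP scores a "hit" when its permutation importance
#' exceeds the maximum importance over all shadows. After `n_iterations`,
#' exact one-sided binomial tests against hit probability 0.5 classify
#' each SNP: `confirmed` (more hits than chance, p < alpha), `rejected`
#' (fewer, p < alpha) or `tentative`.
#'
#' @param genotypes a `snp_matrix`.
#' @param outcome binary 0/1 vector.
#' @param config a [forest_config()] used for each internal forest.
#' @param n_iterations shadow iterations.
#' @param alpha significance threshold of the binomial tests (default 1%).
#' @return A list of class `vim_report`: `importance` (mean importance of
#'   the originals over iterations), `hits`, `n_iterations`, `decisions`.
#' @export
boruta_select <- function(genotypes, outcome, config = forest_config(),
                          n_iterations = 100L, alpha = 0.01) {
  g <- as_snp_matrix(genotypes)
  y <- phenotype_vector(outcome, g)
  X <- unclass(g)
  p <- ncol(X)
  hits <- integer(p)
  imp_sum <- numeric(p)
  seeds <- derive_seeds(config$seed, n_iterations)
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(2L * p))) else
    min(config$mtry * 2L, 2L * p)
  mns <- if (is.null(config$min_node_size)) max(1L, floor(0.01 * nrow(X)))
         else config$min_node_size
  for (it in seq_len(n_iterations)) {
    set.seed(seeds[it])
    shadow <- apply(X, 2L, sample)
    Xi <- cbind(X, shadow)
    forest <- cpp_fit_forest(Xi, y, config$num_trees, mtry, mns, seeds[it])
    vim <- cpp_permutation_vim(forest$trees, forest$oob, Xi, y, seeds[it])
    orig <- vim[seq_len(p)]
    imp_sum <- imp_sum + orig
    hits <- hits + (orig > max(vim[p + seq_len(p)]))
  }
  pv_hi <- pbinom(hits - 1L, n_iterations, 0.5, lower.tail = FALSE)
  pv_lo <- pbinom(hits, n_iterations, 0.5)
  decisions <- ifelse(pv_hi < alpha, "confirmed",
               ifelse(pv_lo < alpha, "rejected", "tentative"))
  structure(list(importance = stats::setNames(imp_sum / n_iterations, colnames(g)),
                 hits = stats::setNames(hits, colnames(g)),
                 n_iterations = n_iterations, alpha = alpha,
                 decisions = stats::setNames(decisions, colnames(g))),
            class = "vim_report")
}

#' @export
print.vim_report <- function(x, ...) {
  cat(sprintf("shadow-variable selection: %d iterations, alpha = %g\n",
              x$n_iterations, x$alpha))
  cat(sprintf("  confirmed %d, tentative %d, rejected %d\n",
              sum(x$decisions == "confirmed"), sum(x$decisions == "tentative"),
              sum(x$decisions == "rejected")))
  invisible(x)
}

#' Export a variable-importance report as a data frame
#'
#' @param x a `vim_report`.
#' @param ... unused.
#' @return Data frame with columns `snp`, `importance`, `hits`, `decision`.
#' @export
as.data.frame.vim_report <- function(x, ...) {
  data.frame(snp = names(x$decisions), importance = unname(x$importance),
             hits = unname(x$hits), decision = unname(x$decisions),
             row.names = NULL)
}

#' Random forest GRS with prior shadow-variable selection
#'
#' Runs [boruta_select()] and fits a probability forest restricted to the
#' confirmed SNPs; tentative SNPs are not selected. When no SNP is
#' confirmed, the constant training-prevalence predictor is returned.
#'
#' @inheritParams boruta_select
#' @return An object of class `c("grs_rfvim", "grs_model")`.
#' @export
fit_rf_vim <- function(genotypes, outcome, config = forest_config(),
                       n_iterations = 100L, alpha = 0.01) {
  g <- as_snp_matrix(genotypes)
  y <- phenotype_vector(outcome, g)
  report <- boruta_select(g, y, config, n_iterations, alpha)
  selected <- which(report$decisions == "confirmed")
  forest <- if (length(selected)) {
    cfg <- config
    cfg$mtry <- if (is.null(config$mtry)) NULL else
      min(config$mtry, length(selected))
    fit_probability_forest(unclass(g)[, selected, drop = FALSE], y, cfg)
  } else NULL
  structure(list(forest = forest, selected = selected, report = report,
                 prevalence = mean(y), n_snps = ncol(g), config = config,
                 method = "rfvim"),
            class = c("grs_rfvim", "grs_model"))
}

#' @export
predict.grs_rfvim <- function(object, newdata, ...) {
  X <- unclass(as_snp_matrix(newdata))
  if (is.null(object$forest)) {
    return(rep(object$prevalence, nrow(X)))
  }
  predict(object$forest, X[, object$selected, drop = FALSE])
}

#' @export
print.grs_rfvim <- function(x, ...) {
  cat(sprintf("forest GRS with shadow-variable selection: %d of %d SNPs confirmed\n",
              length(x$selected), x$n_snps))
  if (!length(x$selected)) cat("  no SNP confirmed: constant-prevalence predictor\n")
  invisible(x)
}
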