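#' Search configuration for logic regression
#'
#' @param max_trees maximum number of logic trees in the model (`ntrees`).
#' @param max_total_leaves total leaf budget summed over all trees
#'   (`nleaves`); must be at least `max_trees`.
#' @param search `"greedy"` (deterministic best-neighbor descent) or
#'   `"annealing"` (simulated annealing).
#' @param iterations annealing iteration budget. The desk-scale default is
#'   50000; set 500000 for exhaustive searches.
#' @param t_start,t_end start and end temperatures of the geometric cooling
#'   schedule (ignored when `auto_tune = TRUE`).
#' @param auto_tune when TRUE (default), a pilot random walk chooses the
#'   start temperature so roughly 90% of proposed deteriorations are
#'   accepted initially, and the end temperature so late acceptance is
#'   essentially zero.
#' @param seed integer seed for stochastic search.
#' @return A list of class `logic_config`.
#' @export
logic_config <- function(max_trees = 2L, max_total_leaves = 4L,
                         search = c("greedy", "annealing"),
                         iterations = 50000L, t_start = 10, t_end = 0.01,
                         auto_tune = TRUE, seed = 1L) {
  search <- match.arg(search)
  stopifnot(max_trees >= 1, max_total_leaves >= max_trees, iterations >= 1,
            t_start > t_end, t_end > 0)
  structure(list(max_trees = as.integer(max_trees),
                 max_total_leaves = as.integer(max_total_leaves),
                 search = search, iterations = as.integer(iterations),
                 t_start = t_start, t_end = t_end,
                 auto_tune = isTRUE(auto_tune), seed = as.integer(seed)),
            class = "logic_config")
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(drop(p), 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

# Logistic regression of y on the tree columns by iteratively reweighted
# least squares. Duplicate tree columns are collapsed onto their first
# occurrence and constant columns are absorbed into the intercept before
# fitting; coefficients are clipped at |beta| <= clip so that perfectly
# separating trees yield bounded predictions. Returns the deviance
# (-2 log-likelihood), the intercept, per-tree coefficients (0 for
# collapsed/constant trees) and a convergence flag.
fit_logistic_trees <- function(Z, y, clip = 15, tol = 1e-8, max_iter = 50L) {
  n <- length(y)
  M <- if (is.null(Z)) 0L else ncol(Z)
  keep <- integer()
  if (M > 0L) {
    keys <- apply(Z, 2L, paste, collapse = "")
    for (j in seq_len(M)) {
      const <- all(Z[, j] == Z[1L, j])
      dup <- j > 1L && keys[j] %in% keys[seq_len(j - 1L)]
      if (!const && !dup) keep <- c(keep, j)
    }
  }
  X <- cbind(rep(1, n), if (length(keep)) Z[, keep, drop = FALSE])
  k <- ncol(X)
  beta <- numeric(k)
  beta[1L] <- qlogis(pmin(pmax(mean(y), 1e-6), 1 - 1e-6))
  dev <- binomial_deviance(y, plogis(X %*% beta))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(
      drop(solve(XtW %*% X + diag(1e-12, k), XtW %*% z)),
      error = function(e) beta
    )
    beta_new <- pmin(pmax(beta_new, -clip), clip)
    dev_new <- binomial_deviance(y, plogis(X %*% beta_new))
    if (dev_new > dev + 1e-10 && iter > 1L) break   # clipped step worsened
    beta <- beta_new
    if (abs(dev - dev_new) < tol) { dev <- dev_new; converged <- TRUE; break }
    dev <- dev_new
  }
  coefs <- numeric(M)
  if (length(keep)) coefs[keep] <- beta[-1L]
  list(deviance = dev, intercept = beta[1L], coefficients = coefs,
       converged = converged)
}

#' Score a set of logic trees by logistic deviance
#'
#' Evaluates each tree on the binary feature matrix, fits the logistic
#' model `logit P(Y=1) = b0 + sum_m b_m L_m(x)` and returns its deviance —
#' the score minimized by the logic-regression search.
#'
#' @param trees list of logic trees (possibly empty for intercept-only).
#' @param x N x F binary feature matrix.
#' @param y binary outcome vector.
#' @return List with `deviance`, `intercept`, `coefficients`, `converged`.
#' @export
score_logic_model <- function(trees, x, y) {
  Z <- if (length(trees)) {
    vapply(trees, evaluate_tree, integer(length(y)), x = x)
  } else NULL
  if (!is.null(Z) && is.null(dim(Z))) Z <- matrix(Z, ncol = length(trees))
  fit_logistic_trees(Z, y)
}

greedy_logic_search <- function(x, y, config) {
  trees <- list()
  cur <- score_logic_model(trees, x, y)
  repeat {
    cands <- enumerate_neighbors(trees, ncol(x), config$max_trees,
                                 config$max_total_leaves)
    if (!length(cands)) break
    best_dev <- cur$deviance
    best_idx <- 0L
    for (i in seq_along(cands)) {
      s <- score_logic_model(cands[[i]], x, y)
      if (s$deviance < best_dev - 1e-8) {
        best_dev <- s$deviance
        best_idx <- i
      }
    }
    if (best_idx == 0L) break
    trees <- cands[[best_idx]]
    cur <- score_logic_model(trees, x, y)
  }
  list(trees = trees, fit = cur)
}

# Pilot-walk temperature selection: propose random moves from the initial
# state along an accept-everything walk, record the positive deviance
# increments, and pick T0 so a typical deterioration is accepted with
# probability ~0.9 and T_end so it is accepted with probability ~0.001.
auto_tune_temperatures <- function(x, y, config, n_pilot = 100L) {
  trees <- list()
  cur <- score_logic_model(trees, x, y)
  deltas <- numeric()
  for (i in seq_len(n_pilot)) {
    cand <- sample_neighbor(trees, ncol(x), config$max_trees,
                            config$max_total_leaves)
    if (is.null(cand)) break
    s <- score_logic_model(cand, x, y)
    d <- s$deviance - cur$deviance
    if (d > 0) deltas <- c(deltas, d)
    trees <- cand
    cur <- s
  }
  ref <- if (length(deltas)) stats::median(deltas) else 1
  list(t_start = max(ref / (-log(0.9)), 1e-3),
       t_end = max(ref / (-log(0.001)), 1e-6))
}

anneal_logic_search <- function(x, y, config) {
  temps <- if (config$auto_tune) {
    auto_tune_temperatures(x, y, config)
  } else {
    list(t_start = config$t_start, t_end = config$t_end)
  }
  trees <- list()
  cur <- score_logic_model(trees, x, y)
  best_trees <- trees
  best <- cur
  iters <- config$iterations
  ratio <- temps$t_end / temps$t_start
  for (i in seq_len(iters)) {
    temp <- temps$t_start * ratio^(if (iters > 1L) (i - 1L) / (iters - 1L) else 1)
    cand <- sample_neighbor(trees, ncol(x), config$max_trees,
                            config$max_total_leaves)
    if (is.null(cand)) next
    s <- score_logic_model(cand, x, y)
    delta <- s$deviance - cur$deviance
    if (delta <= 0 || runif(1L) < exp(-delta / temp)) {
      trees <- cand
      cur <- s
      if (cur$deviance < best$deviance) {
        best_trees <- trees
        best <- cur
      }
    }
  }
  list(trees = best_trees, fit = best)
}

#' Fit a logic regression genetic risk score
#'
#' Genotypes are binarized into dominant/recessive indicators
#' (`SNP_D = 1(g != 0)`, `SNP_R = 1(g == 2)`) and a logistic model over
#' Boolean logic trees is searched by greedy descent or simulated
#' annealing, scored by deviance.
#'
#' @param genotypes a `snp_matrix` (or \{0,1,2\} matrix).
#' @param outcome binary 0/1 vector.
#' @param config a [logic_config()].
#' @return An object of class `c("grs_logicreg", "grs_model")`.
#' @export
fit_logic_regression <- function(genotypes, outcome, config = logic_config()) {
  g <- as_snp_matrix(genotypes)
  y <- phenotype_vector(outcome, g)
  x <- encode_dominant_recessive(g)
  set.seed(config$seed)
  res <- if (config$search == "greedy") {
    greedy_logic_search(x, y, config)
  } else {
    anneal_logic_search(x, y, config)
  }
  structure(list(trees = res$trees, intercept = res$fit$intercept,
                 coefficients = res$fit$coefficients,
                 deviance = res$fit$deviance,
                 feature_names = colnames(x), config = config,
                 method = "logicreg"),
            class = c("grs_logicreg", "grs_model"))
}

predict_logic_trees <- function(object, x) {
  eta <- rep(object$intercept, nrow(x))
  for (m in seq_along(object$trees)) {
    if (object$coefficients[m] != 0) {
      eta <- eta + object$coefficients[m] * evaluate_tree(object$trees[[m]], x)
    }
  }
  plogis(eta)
}

#' @export
predict.grs_logicreg <- function(object, newdata, ...) {
  predict_logic_trees(object, encode_dominant_recessive(newdata))
}

#' @export
print.grs_logicreg <- function(x, ...) {
  cat(sprintf("logic regression GRS (%s search): deviance %.3f\n",
              x$config$search, x$deviance))
  cat(sprintf("  intercept %.4f\n", x$intercept))
  for (m in seq_along(x$trees)) {
    cat(sprintf("  %+.4f * [%s]\n", x$coefficients[m],
                tree_to_expression(x$trees[[m]], x$feature_names)))
  }
  invisible(x)
}

#' Fit a bagged logic regression ensemble
#'
#' Fits `n_bags` logic regression models by greedy search, each on a
#' bootstrap resample of the data (N draws with replacement), and predicts
#' by averaging the member predicted probabilities — trading the global
#' annealing search for variance reduction through aggregation.
#'
#' @inheritParams fit_logic_regression
#' @param n_bags ensemble size (500 for full-scale runs).
#' @return An object of class `c("grs_logicbag", "grs_model")`.
#' @export
fit_logic_bagging <- function(genotypes, outcome, config = logic_config(),
                              n_bags = 500L) {
  g <- as_snp_matrix(genotypes)
  y <- phenotype_vector(outcome, g)
  x <- encode_dominant_recessive(g)
  set.seed(config$seed)
  members <- vector("list", n_bags)
  for (b in seq_len(n_bags)) {
    idx <- sample.int(length(y), replace = TRUE)
    res <- greedy_logic_search(x[idx, , drop = FALSE], y[idx], config)
    members[[b]] <- list(trees = res$trees, intercept = res$fit$intercept,
                         coefficients = res$fit$coefficients)
  }
  structure(list(members = members, feature_names = colnames(x),
                 config = config, n_bags = n_bags, method = "logicbag"),
            class = c("grs_logicbag", "grs_model"))
}

#' @export
predict.grs_logicbag <- function(object, newdata, ...) {
  x <- encode_dominant_recessive(newdata)
  preds <- vapply(object$members, predict_logic_trees,
                  numeric(nrow(x)), x = x)
  if (is.null(dim(preds))) preds <- matrix(preds, ncol = length(object$members))
  rowMeans(preds)
}

#' @export
print.grs_logicbag <- function(x, ...) {
  cat(sprintf("logic bagging GRS: %d greedy members, budgets ntrees=%d nleaves=%d\n",
              x$n_bags, x$config$max_trees, x$config$max_total_leaves))
  invisible(x)
}
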