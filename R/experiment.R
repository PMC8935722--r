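#' Cyclic train/validation/test replicate assignment
#'
#' Replicate i trains; its wrap-around successor (i + 1, or 1 after the
#' last) is the independent test set and its predecessor (i - 1, or R
#' before the first) the validation set used for hyperparameter tuning.
#'
#' @param i training replicate index in `1..R`.
#' @param R total number of replicates.
#' @return List with `train`, `validation`, `test`.
#' @export
cyclic_scheme_indices <- function(i, R = 100L) {
  stopifnot(i >= 1, i <= R)
  list(train = i,
       validation = if (i == 1L) R else i - 1L,
       test = if (i == R) 1L else i + 1L)
}

#' Default hyperparameter grids
#'
#' Materializes the tuning grids: forests cross
#' `mtry = floor(c(0.5, 1, 2) * floor(sqrt(p)))` with
#' `min.node.size = floor(c(0.01, 0.05, 0.1) * N)`; logic models cross
#' `ntrees = 1..6` with `nleaves = 1..10` keeping only feasible
#' combinations (`nleaves >= ntrees`, the leaf budget being the total over
#' all trees); the elastic net tries `alpha = 0.5, 0.75, 0.9, 0.99` with
#' lambda chosen by cross-validation inside the fit.
#'
#' @param p number of SNPs.
#' @param N training sample size.
#' @param nleaves_max upper leaf budget (10 for simulation-scale panels,
#'   20 for larger real-data panels).
#' @return Named list of data frames (`rf`, `rfvim`, `logicreg`,
#'   `logicbag`, `enet`), one row per grid point.
#' @export
default_grids <- function(p, N, nleaves_max = 10L) {
  root <- floor(sqrt(p))
  forest <- expand.grid(
    mtry = pmax(1L, as.integer(floor(c(0.5, 1, 2) * root))),
    min_node_size = pmax(1L, as.integer(floor(c(0.01, 0.05, 0.1) * N)))
  )
  logic <- expand.grid(ntrees = 1:6, nleaves = seq_len(nleaves_max))
  logic <- logic[logic$nleaves >= logic$ntrees, , drop = FALSE]
  rownames(logic) <- NULL
  list(rf = forest, rfvim = forest, logicreg = logic, logicbag = logic,
       enet = data.frame(alpha = c(0.5, 0.75, 0.9, 0.99)))
}

# Fit one method with a hyperparameter-grid row. `scale` carries the
# ensemble sizes (num_trees, n_bags, boruta_iterations, search,
# iterations) shared across grid points.
fit_with_setting <- function(method, genotypes, outcome, setting, scale, seed) {
  switch(method,
    rf = fit_probability_forest(genotypes, outcome,
      forest_config(num_trees = scale$num_trees, mtry = setting$mtry,
                    min_node_size = setting$min_node_size, seed = seed)),
    rfvim = fit_rf_vim(genotypes, outcome,
      forest_config(num_trees = scale$num_trees, mtry = setting$mtry,
                    min_node_size = setting$min_node_size, seed = seed),
      n_iterations = scale$boruta_iterations),
    logicreg = fit_logic_regression(genotypes, outcome,
      logic_config(max_trees = setting$ntrees,
                   max_total_leaves = setting$nleaves,
                   search = scale$search, iterations = scale$iterations,
                   seed = seed)),
    logicbag = fit_logic_bagging(genotypes, outcome,
      logic_config(max_trees = setting$ntrees,
                   max_total_leaves = setting$nleaves, search = "greedy",
                   seed = seed), n_bags = scale$n_bags),
    enet = fit_elastic_net(genotypes, outcome,
      enet_config(alpha_grid = setting$alpha, seed = seed)),
    stop("unknown method: ", method)
  )
}

default_scale <- function(paper_scale = FALSE) {
  if (paper_scale) {
    list(num_trees = 2000L, n_bags = 500L, boruta_iterations = 100L,
         search = "annealing", iterations = 500000L)
  } else {
    list(num_trees = 500L, n_bags = 100L, boruta_iterations = 50L,
         search = "greedy", iterations = 50000L)
  }
}

#' Tune hyperparameters on the first validation iterations
#'
#' For every grid row, fits the method on training replicates
#' `1..tuning_reps` and averages the AUC on the corresponding cyclic
#' validation replicates; the row with the highest mean validation AUC
#' wins (ties go to the first row in grid order). The chosen setting is
#' then frozen for all replicates of the study.
#'
#' @param method a GRS method name.
#' @param replicates list of datasets from [simulate_grs_data()].
#' @param grid data frame of hyperparameter settings (one row each).
#' @param tuning_reps number of leading train/validation pairs averaged.
#' @param scale ensemble-size settings, see [run_simulation_study()].
#' @param seed integer seed.
#' @return List with `setting` (the chosen row), `mean_auc` per grid row.
#' @export
tune_hyperparameters <- function(method, replicates, grid,
                                 tuning_reps = 10L,
                                 scale = default_scale(), seed = 1L) {
  R <- length(replicates)
  tuning_reps <- min(tuning_reps, R)
  mean_auc <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    aucs <- numeric(tuning_reps)
    for (i in seq_len(tuning_reps)) {
      idx <- cyclic_scheme_indices(i, R)
      train <- replicates[[idx$train]]
      val <- replicates[[idx$validation]]
      model <- fit_with_setting(method, train$genotypes, train$outcome,
                                grid[k, , drop = FALSE], scale,
                                seed = seed + i)
      aucs[i] <- auc(predict(model, val$genotypes), val$outcome)
    }
    mean_auc[k] <- mean(aucs)
  }
  list(setting = grid[which.max(mean_auc), , drop = FALSE],
       mean_auc = mean_auc)
}

#' Run a simulation study end to end
#'
#' Generates the replicates of a design, optionally tunes each method's
#' hyperparameters on the first `tuning_reps` cyclic validation pairs,
#' then for every replicate fits the frozen setting on the training set
#' and evaluates on the cyclic test set: AUC (test and train), the
#' univariate Wald association test on the logit-transformed GRS, and
#' classification metrics. Aggregates the rejection fraction (power under
#' an influential design, type-I error under a null design) with binomial
#' Monte-Carlo standard errors.
#'
#' @param design a [simulation_design()].
#' @param methods subset of
#'   `c("rf", "rfvim", "logicreg", "logicbag", "enet", "true_model")`.
#' @param grids named list of per-method grids as in [default_grids()];
#'   single-row grids skip tuning. NULL uses one default setting per
#'   method (no tuning).
#' @param tuning_reps leading replicates used for tuning.
#' @param level significance level for power / type-I aggregation.
#' @param paper_scale use full-scale ensemble sizes (2000 trees, 500 bags,
#'   100 shadow iterations, annealing with 500000 steps).
#' @param calibration_n calibration sample for the design intercept.
#' @return An object of class `grs_study`: `results` (one row per
#'   replicate and method), `summary` (per-method aggregates), `settings`
#'   (chosen hyperparameters), `design`.
#' @export
run_simulation_study <- function(design,
                                 methods = c("rf", "enet"),
                                 grids = NULL,
                                 tuning_reps = 10L,
                                 level = 0.05,
                                 paper_scale = FALSE,
                                 calibration_n = 2e5) {
  scale <- default_scale(paper_scale)
  replicates <- simulate_grs_data(design, calibration_n = calibration_n)
  R <- length(replicates)
  p <- design$n_snps
  if (is.null(grids)) {
    defaults <- default_grids(p, design$n)
    grids <- list(rf = defaults$rf[5L, , drop = FALSE],     # mtry=sqrt(p), 5% node size
                  rfvim = defaults$rfvim[5L, , drop = FALSE],
                  logicreg = data.frame(ntrees = 2L, nleaves = 4L),
                  logicbag = data.frame(ntrees = 2L, nleaves = 4L),
                  enet = data.frame(alpha = NA_real_))
  }
  settings <- list()
  rows <- list()
  for (method in methods) {
    if (method == "true_model") {
      setting <- NULL
    } else {
      grid <- grids[[method]]
      setting <- if (nrow(grid) > 1L) {
        tune_hyperparameters(method, replicates, grid, tuning_reps, scale,
                             seed = design$seed)$setting
      } else {
        grid
      }
      settings[[method]] <- setting
    }
    for (i in seq_len(R)) {
      idx <- cyclic_scheme_indices(i, R)
      train <- replicates[[idx$train]]
      test <- replicates[[idx$test]]
      row <- tryCatch({
        model <- if (method == "true_model") {
          train$true_model
        } else if (method == "enet" && is.na(setting$alpha[1L])) {
          fit_elastic_net(train$genotypes, train$outcome,
                          enet_config(seed = design$seed + i))
        } else {
          fit_with_setting(method, train$genotypes, train$outcome, setting,
                           scale, seed = design$seed + i)
        }
        ev <- evaluate_grs(model, test$genotypes, test$outcome,
                           environment = test$environment)
        tr <- evaluate_grs(model, train$genotypes, train$outcome,
                           environment = train$environment)
        data.frame(replicate = i, method = method, test_auc = ev$auc,
                   train_auc = tr$auc, wald_p = ev$wald_p,
                   accuracy = ev$accuracy, sensitivity = ev$sensitivity,
                   specificity = ev$specificity, failed = FALSE)
      }, error = function(e) {
        data.frame(replicate = i, method = method, test_auc = NA_real_,
                   train_auc = NA_real_, wald_p = NA_real_,
                   accuracy = NA_real_, sensitivity = NA_real_,
                   specificity = NA_real_, failed = TRUE)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$method), function(d) {
    ok <- d[!d$failed, , drop = FALSE]
    pw <- estimate_power(ok$wald_p, level)
    data.frame(method = d$method[1L], n_replicates = nrow(ok),
               mean_test_auc = mean(ok$test_auc),
               se_test_auc = sd(ok$test_auc) / sqrt(nrow(ok)),
               mean_train_auc = mean(ok$train_auc),
               rejection_rate = pw$estimate, rejection_se = pw$se,
               mean_accuracy = mean(ok$accuracy),
               mean_sensitivity = mean(ok$sensitivity),
               mean_specificity = mean(ok$specificity))
  }))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, settings = settings,
                 design = design, level = level),
            class = "grs_study")
}

#' @export
print.grs_study <- function(x, ...) {
  cat(sprintf("simulation study: %s scenario, %d replicates, level %.2f\n",
              x$design$scenario, x$design$n_replicates, x$level))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Repeated stratified train/test splits with a tuning sub-split
#'
#' The generic real-data scheme: `n_splits` independent splits into
#' `test_fraction` test and the rest training data; each training half is
#' further split into tuning-training and validation data, with the
#' validation size `floor(tune_fraction * n_train)`. All splits are
#' stratified by outcome.
#'
#' @param outcome 0/1 vector defining the strata.
#' @param n_splits number of repetitions.
#' @param test_fraction fraction of samples held out for testing.
#' @param tune_fraction fraction of the training half used for validation
#'   during hyperparameter tuning.
#' @param seed integer seed.
#' @return List of `n_splits` lists with index vectors `train`, `test`,
#'   `tune_train`, `tune_validation`.
#' @export
repeated_split_scheme <- function(outcome, n_splits = 100L,
                                  test_fraction = 0.5, tune_fraction = 0.25,
                                  seed = 1L) {
  y <- phenotype_vector(outcome)
  stopifnot(length(y) >= 4L)
  seeds <- derive_seeds(seed, n_splits)
  lapply(seq_len(n_splits), function(s) {
    set.seed(seeds[s])
    test <- integer()
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      test <- c(test, sample(idx, round(test_fraction * length(idx))))
    }
    test <- sort(test)
    train <- setdiff(seq_along(y), test)
    val <- integer()
    for (cls in c(0L, 1L)) {
      idx <- train[y[train] == cls]
      val <- c(val, sample(idx, floor(tune_fraction * length(idx))))
    }
    val <- sort(val)
    list(train = train, test = test,
         tune_train = setdiff(train, val), tune_validation = val)
  })
}
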