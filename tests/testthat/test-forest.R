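test_that("node impurity and split search follow the Gini criterion", {
  expect_equal(gini_impurity(0.5), 0.5)
  expect_equal(gini_impurity(0), 0)
  expect_equal(gini_impurity(0.3), 0.42)

  # perfect separation by a dominant split
  x <- matrix(c(0L, 0L, 1L, 2L, 1L, 2L), ncol = 1)
  y <- c(0L, 0L, 1L, 1L, 1L, 1L)
  s <- best_split(x, y, min_node_size = 1)
  expect_equal(s$feature, 1L)
  expect_equal(s$cut, 0L)
  expect_equal(s$impurity, 0)

  # constant feature yields no split
  expect_null(best_split(matrix(1L, 6, 1), y, min_node_size = 1))
})

test_that("best_split matches a brute-force oracle on random fixtures", {
  oracle <- function(x, y, mns) {
    best <- NULL
    for (j in seq_len(ncol(x))) {
      for (cut in 0:1) {
        left <- x[, j] <= cut
        if (sum(left) < mns || sum(!left) < mns) next
        pl <- mean(y[left]); pr <- mean(y[!left])
        imp <- (sum(left) * 2 * pl * (1 - pl) +
                sum(!left) * 2 * pr * (1 - pr)) / length(y)
        if (is.null(best) || imp < best$impurity - 1e-12) {
          best <- list(feature = j, cut = cut, impurity = imp)
        }
      }
    }
    if (!is.null(best) && best$impurity >= 2 * mean(y) * (1 - mean(y)) - 1e-12) {
      return(NULL)
    }
    best
  }
  set.seed(16)
  for (rep in 1:20) {
    x <- matrix(sample(0:2, 6 * 3, replace = TRUE), 6, 3)
    y <- sample(0:1, 6, replace = TRUE)
    if (length(unique(y)) < 2) next
    expect_equal(best_split(x, y, min_node_size = 1), oracle(x, y, 1))
  }
})

test_that("the compiled tree grower agrees with best_split at the root", {
  set.seed(17)
  g <- simulate_genotypes(rep(0.3, 4), 400)
  y <- rbinom(400, 1, plogis(-0.5 + 1.5 * (unclass(g)[, 2] != 0)))
  fit <- fit_probability_forest(g, y, forest_config(num_trees = 20, mtry = 4,
                                                    min_node_size = 150,
                                                    seed = 1))
  for (t in seq_len(20)) {
    tree <- fit$forest$trees[[t]]
    if (tree$feature[1] < 0) next               # no valid root split
    inbag <- setdiff(seq_len(400), fit$forest$oob[[t]] + 1L)
    # in-bag multiset is not recorded; check the root split is optimal for
    # some bootstrap draw by validating against the full-sample oracle,
    # which shares the optimum at this signal strength
    ref <- best_split(unclass(g), y, min_node_size = 150)
    expect_equal(tree$feature[1] + 1L, ref$feature)
    expect_equal(tree$cut[1], ref$cut)
  }
})

test_that("probability forests estimate risks rather than vote shares", {
  # one SNP stratum with true risk 0.8: a probability forest should say
  # ~0.8 where majority voting would say 1.0
  set.seed(18)
  n <- 3000
  g <- simulate_genotypes(0.4, n)
  risk <- ifelse(unclass(g)[, 1] != 0, 0.8, 0.3)
  y <- rbinom(n, 1, risk)
  fit <- fit_probability_forest(g, y, forest_config(num_trees = 200,
                                                    min_node_size = 50,
                                                    seed = 2))
  pred <- predict(fit, snp_matrix(matrix(c(1L, 0L), ncol = 1)))
  expect_lt(abs(pred[1] - 0.8), 0.05)
  expect_lt(abs(pred[2] - 0.3), 0.05)
  expect_true(all(pred >= 0 & pred <= 1))

  # min_node_size = N: single-leaf trees predicting in-bag prevalence
  flat <- fit_probability_forest(g, y, forest_config(num_trees = 50,
                                                     min_node_size = n,
                                                     seed = 3))
  expect_lt(max(abs(predict(flat, g) - mean(y))), 0.02)
})

test_that("permutation importance singles out the informative SNP", {
  set.seed(19)
  g <- simulate_genotypes(rep(0.3, 6), 800)
  y <- as.integer(unclass(g)[, 3] != 0)        # noise-free signal in SNP 3
  fit <- fit_probability_forest(g, y, forest_config(num_trees = 100, seed = 4))
  vim <- permutation_vim(fit)
  expect_equal(which.max(vim), 3L, ignore_attr = TRUE)
  expect_gt(vim[3], max(vim[-3]) + 0.05)
  expect_lt(max(abs(vim[-3])), 0.05)           # uninvolved features near zero
})

test_that("shadow-variable selection confirms signal and rejects pure noise", {
  set.seed(20)
  g <- simulate_genotypes(rep(0.3, 10), 1500)
  y <- rbinom(1500, 1, plogis(-0.6 + 1.2 * (unclass(g)[, 1] != 0)))
  rep_strong <- boruta_select(g, y, forest_config(num_trees = 150, seed = 5),
                              n_iterations = 25)
  expect_equal(unname(rep_strong$decisions[1]), "confirmed")

  ynull <- rbinom(1500, 1, 0.5)
  rep_null <- boruta_select(g, ynull, forest_config(num_trees = 150, seed = 6),
                            n_iterations = 25)
  expect_lte(sum(rep_null$decisions == "confirmed"), 1L)

  fit_null <- fit_rf_vim(g, ynull, forest_config(num_trees = 150, seed = 6),
                         n_iterations = 25)
  if (length(fit_null$selected) == 0) {
    expect_equal(predict(fit_null, g), rep(mean(ynull), 1500))
  }
  fit_strong <- fit_rf_vim(g, y, forest_config(num_trees = 150, seed = 5),
                           n_iterations = 25)
  expect_true(1L %in% fit_strong$selected)
  pr <- predict(fit_strong, g)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("forest risk estimates track an independent reference forest", {
  skip_if_not_installed("ranger")
  set.seed(21)
  fix <- make_dominant_fixture(n = 500, p = 5, beta = 1.2)
  fit <- fit_probability_forest(fix$genotypes, fix$outcome,
                                forest_config(num_trees = 500, seed = 7))
  df <- data.frame(y = factor(fix$outcome), unclass(fix$genotypes))
  rf <- ranger::ranger(y ~ ., data = df, num.trees = 500, probability = TRUE,
                       seed = 7)
  test <- make_dominant_fixture(n = 300, p = 5, beta = 1.2, seed = 99)
  newdf <- data.frame(unclass(test$genotypes))
  names(newdf) <- names(df)[-1]
  ours <- predict(fit, test$genotypes)
  theirs <- predict(rf, data = newdf)$predictions[, "1"]
  expect_gt(cor(ours, theirs), 0.9)
  expect_lt(mean(abs(ours - theirs)), 0.1)
})
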