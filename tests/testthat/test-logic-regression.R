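leaf <- grsforge:::logic_leaf
node <- grsforge:::logic_node

# the two-conjunct example tree (!X1 & X2) | (X1 & !X3)
example_tree <- node("or",
                     node("and", leaf(1, TRUE), leaf(2)),
                     node("and", leaf(1), leaf(3, TRUE)))

test_that("tree evaluation matches the Boolean expression on the full truth table", {
  expect_equal(evaluate_tree(example_tree, c(1, 1, 0)), 1L)
  expect_equal(evaluate_tree(example_tree, c(0, 0, 0)), 0L)
  grid <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  got <- evaluate_tree(example_tree, grid)
  oracle <- as.integer((!grid[, 1] & grid[, 2]) | (grid[, 1] & !grid[, 3]))
  expect_equal(got, oracle)
  expect_error(evaluate_tree(leaf(9), matrix(0, 1, 3)), "feature 9")
})

test_that("printing and parsing round-trip arbitrary trees", {
  expect_equal(tree_to_expression(leaf(1)), "X1")
  expect_equal(tree_to_expression(example_tree), "(!X1 & X2) | (X1 & !X3)")
  set.seed(10)
  for (rep in 1:20) {
    tr <- random_tree(n_features = 5, max_leaves = 10)
    text <- tree_to_expression(tr)
    x <- matrix(rbinom(40 * 5, 1, 0.5), 40, 5)
    expect_equal(evaluate_tree(parse_expression(text), x),
                 evaluate_tree(tr, x))
    # independent interpreter: R's own logical operators on the string
    expect_equal(evaluate_tree(tr, x), eval_expression_oracle(text, x))
  }
  expect_error(parse_expression("X1 & ("), "parse error")
})

test_that("the move set respects budgets and matches the expected counts", {
  F <- 6                      # binary features, i.e. 2p after D/R encoding
  single <- list(leaf(2))
  # budget 1 leaf, 1 tree: only leaf alternations (2F - 1 literals) + delete
  n1 <- grsforge:::enumerate_neighbors(single, F, max_trees = 1,
                                       max_total_leaves = 1)
  expect_length(n1, (2 * F - 1) + 1)
  leaves_of <- function(m) if (length(m)) sum(vapply(m, grsforge:::count_leaves, 0L)) else 0L
  expect_true(all(vapply(n1, leaves_of, 0L) <= 1))

  # intercept-only model: only add-tree moves, one per literal
  n0 <- grsforge:::enumerate_neighbors(list(), F, 2, 4)
  expect_length(n0, 2 * F)
  expect_true(all(vapply(n0, length, 0L) == 1L))

  # at the leaf budget no candidate exceeds it
  two <- list(node("and", leaf(1), leaf(2)))
  n2 <- grsforge:::enumerate_neighbors(two, F, 2, 2)
  expect_true(all(vapply(n2, leaves_of, 0L) <= 2))
})

test_that("random neighbor proposals draw from the enumerated move set", {
  F <- 3
  trees <- list(node("or", leaf(1), leaf(2, TRUE)))
  enumerated <- grsforge:::enumerate_neighbors(trees, F, 2, 3)
  sig <- function(m) paste(vapply(m, tree_to_expression, ""), collapse = " + ")
  enum_multiset <- table(vapply(enumerated, sig, ""))
  set.seed(11)
  n_draws <- 8000
  draws <- replicate(n_draws, sig(grsforge:::sample_neighbor(trees, F, 2, 3)))
  expect_true(all(draws %in% names(enum_multiset)))
  tab <- table(factor(draws, levels = names(enum_multiset)))
  expect_true(all(tab > 0))                   # every neighbor reachable
  # uniform over the move multiset: expected counts are proportional to the
  # multiplicity of each resulting model among the enumerated moves
  expected <- as.numeric(enum_multiset) / length(enumerated) * n_draws
  expect_true(all(abs(tab - expected) < 6 * sqrt(expected)))
})

test_that("deviance scoring matches a reference GLM and handles degeneracies", {
  y <- rep(c(0L, 1L), each = 50)
  x <- matrix(rbinom(100 * 4, 1, 0.5), 100, 4)
  # intercept-only on balanced data: closed form 2N log 2
  expect_equal(score_logic_model(list(), x, y)$deviance, 2 * 100 * log(2),
               tolerance = 1e-6)
  set.seed(12)
  trees <- list(leaf(1), node("and", leaf(2), leaf(3, TRUE)))
  s <- score_logic_model(trees, x, y)
  z1 <- evaluate_tree(trees[[1]], x)
  z2 <- evaluate_tree(trees[[2]], x)
  ref <- glm(y ~ z1 + z2, family = binomial())
  expect_equal(s$deviance, ref$deviance, tolerance = 1e-6)
  expect_equal(s$coefficients, unname(coef(ref)[2:3]), tolerance = 1e-4)

  # a perfectly separating tree drives the deviance towards zero
  ysep <- x[, 1]
  expect_lt(score_logic_model(list(leaf(1)), x, ysep)$deviance, 0.5)

  # duplicate trees collapse onto the first; constant trees are absorbed
  dup <- score_logic_model(list(leaf(1), leaf(1)), x, y)
  expect_equal(dup$coefficients[2], 0)
  const <- score_logic_model(list(node("or", leaf(1), leaf(1, TRUE))), x, y)
  expect_equal(const$coefficients, 0)
  expect_equal(const$deviance, 2 * 100 * log(2), tolerance = 1e-6)
})

test_that("greedy search recovers a noise-free signal and reaches the global optimum", {
  set.seed(13)
  g <- simulate_genotypes(rep(0.4, 3), 120)
  y <- as.integer(unclass(g)[, 1] != 0)       # Y = SNP1_D exactly
  fit <- fit_logic_regression(g, y, logic_config(max_trees = 1,
                                                 max_total_leaves = 2))
  x <- encode_dominant_recessive(g)
  expect_length(fit$trees, 1)
  # the tree matches the signal up to negation (absorbed by the sign of
  # its coefficient), so the fitted risks separate the classes perfectly
  z <- evaluate_tree(fit$trees[[1]], x)
  expect_true(identical(z, y) || identical(z, 1L - y))
  if (!identical(z, y)) expect_lt(fit$coefficients[1], 0)
  expect_equal(auc(predict(fit, g), y), 1)

  # global optimality against exhaustive enumeration on clear-signal
  # instances (<= 4 features, 2-leaf budget)
  for (rep in 1:3) {
    set.seed(20 + rep)
    x2 <- matrix(rbinom(150 * 4, 1, 0.5), 150, 4)
    y2 <- rbinom(150, 1, ifelse(x2[, 1] & x2[, 3], 0.9, 0.15))
    res <- grsforge:::greedy_logic_search(x2, y2,
      logic_config(max_trees = 2, max_total_leaves = 2))
    expect_equal(res$fit$deviance, exhaustive_best_deviance(x2, y2),
                 tolerance = 1e-6)
  }

  # on any instance, greedy stops only where no single move improves
  set.seed(33)
  x3 <- matrix(rbinom(60 * 4, 1, 0.5), 60, 4)
  y3 <- rbinom(60, 1, plogis(-0.2 + 0.8 * x3[, 2] - 0.8 * x3[, 1]))
  res3 <- grsforge:::greedy_logic_search(x3, y3,
    logic_config(max_trees = 2, max_total_leaves = 2))
  nb <- grsforge:::enumerate_neighbors(res3$trees, 4, 2, 2)
  nbd <- vapply(nb, function(m) score_logic_model(m, x3, y3)$deviance, 0)
  expect_gte(min(nbd), res3$fit$deviance - 1e-8)
})

test_that("annealing search only improves on the intercept-only score", {
  set.seed(14)
  g <- simulate_genotypes(rep(0.3, 4), 150)
  y <- rbinom(150, 1, plogis(-0.4 + (unclass(g)[, 2] != 0)))
  x <- encode_dominant_recessive(g)
  base <- score_logic_model(list(), x, y)$deviance
  cfg <- logic_config(max_trees = 2, max_total_leaves = 3,
                      search = "annealing", iterations = 500, seed = 3)
  fit1 <- fit_logic_regression(g, y, cfg)
  expect_lte(fit1$deviance, base)
  fit2 <- fit_logic_regression(g, y, cfg)
  expect_equal(fit1, fit2)                    # same seed, same model
  expect_true(all(predict(fit1, g) > 0 & predict(fit1, g) < 1))
})

test_that("logic bagging averages member probabilities and is order-invariant", {
  x <- encode_dominant_recessive(snp_matrix(matrix(c(0L, 1L, 2L), ncol = 1)))
  member <- function(b0) list(trees = list(), intercept = b0,
                              coefficients = numeric())
  bag <- structure(list(members = list(member(qlogis(0.2)), member(qlogis(0.4))),
                        feature_names = colnames(x), n_bags = 2,
                        config = logic_config(), method = "logicbag"),
                   class = c("grs_logicbag", "grs_model"))
  g <- snp_matrix(matrix(c(0L, 1L), ncol = 1))
  expect_equal(predict(bag, g), rep(0.3, 2), tolerance = 1e-12)

  set.seed(15)
  fix <- make_dominant_fixture(n = 80, p = 3)
  fit <- fit_logic_bagging(fix$genotypes, fix$outcome,
                           logic_config(max_trees = 1, max_total_leaves = 2),
                           n_bags = 8)
  pr <- predict(fit, fix$genotypes)
  fit_rev <- fit
  fit_rev$members <- rev(fit$members)
  expect_equal(predict(fit_rev, fix$genotypes), pr)
  member_preds <- vapply(fit$members, grsforge:::predict_logic_trees,
                         numeric(80), x = encode_dominant_recessive(fix$genotypes))
  expect_true(all(pr >= apply(member_preds, 1, min) - 1e-12))
  expect_true(all(pr <= apply(member_preds, 1, max) + 1e-12))
})
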