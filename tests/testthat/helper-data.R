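# Small fixture builders shared across test files. All fixtures are built
# in code under fixed seeds; nothing is read from disk.

# genotype matrix with a known dominant effect on the first SNP
make_dominant_fixture <- function(n = 200, p = 5, beta = 1, seed = 42) {
  set.seed(seed)
  g <- simulate_genotypes(runif(p, 0.2, 0.4), n)
  eta <- -beta * 0.6 + beta * (unclass(g)[, 1] != 0)
  y <- rbinom(n, 1, plogis(eta))
  list(genotypes = g, outcome = y)
}

# brute-force AUC oracle: explicit loop over all case-control pairs
auc_pairs_oracle <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (a in cases) {
    for (b in controls) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(cases) * length(controls))
}

# random logic tree with at most max_leaves leaves over n_features features
random_tree <- function(n_features, max_leaves) {
  grow <- function(budget) {
    if (budget <= 1 || runif(1) < 0.4) {
      return(grsforge:::logic_leaf(sample.int(n_features, 1),
                                   runif(1) < 0.5))
    }
    split <- sample.int(budget - 1, 1)
    grsforge:::logic_node(sample(c("and", "or"), 1),
                          grow(split), grow(budget - split))
  }
  grow(max_leaves)
}

# independent Boolean interpreter: evaluate the printed expression with
# R's own logical operators, row by row
eval_expression_oracle <- function(expr_text, x) {
  vars <- as.data.frame(x == 1)
  names(vars) <- paste0("X", seq_len(ncol(x)))
  as.integer(with(vars, eval(parse(text = expr_text))))
}

# exhaustive search over all logic models with at most `max_leaves` total
# leaves (and max_trees trees), returning the minimal deviance. Structures
# enumerated directly: single literals, two-literal trees, and pairs of
# single literals — the complete model space for a 2-leaf budget.
exhaustive_best_deviance <- function(x, y, max_trees = 2, max_leaves = 2) {
  stopifnot(max_leaves <= 2)
  F <- ncol(x)
  literals <- list()
  for (f in seq_len(F)) {
    for (neg in c(FALSE, TRUE)) {
      literals[[length(literals) + 1]] <- grsforge:::logic_leaf(f, neg)
    }
  }
  models <- list(list())
  for (l in literals) models[[length(models) + 1]] <- list(l)
  if (max_leaves >= 2) {
    for (i in seq_along(literals)) {
      for (j in seq_along(literals)) {
        for (op in c("and", "or")) {
          models[[length(models) + 1]] <-
            list(grsforge:::logic_node(op, literals[[i]], literals[[j]]))
        }
        if (max_trees >= 2) {
          models[[length(models) + 1]] <- list(literals[[i]], literals[[j]])
        }
      }
    }
  }
  min(vapply(models, function(m) score_logic_model(m, x, y)$deviance, 0))
}
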