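# Logic trees: binary trees whose internal nodes hold AND/OR and whose
# leaves hold possibly negated binary features. A leaf is
# list(feature = j, neg = TRUE/FALSE); an internal node is
# list(op = "and"|"or", left = , right = ). A model's tree set is an
# unnamed list of such trees (possibly empty = intercept-only model).

logic_leaf <- function(feature, neg = FALSE) {
  list(feature = as.integer(feature), neg = isTRUE(neg))
}

logic_node <- function(op, left, right) {
  stopifnot(op %in% c("and", "or"))
  list(op = op, left = left, right = right)
}

is_leaf <- function(node) is.null(node$op)

#' Evaluate a logic tree on binary feature data
#'
#' Recursively evaluates the Boolean expression represented by the tree on
#' each row of a 0/1 feature matrix: leaves read (and possibly negate) a
#' feature column, AND nodes take the minimum and OR nodes the maximum of
#' their two children.
#'
#' @param tree a logic tree node.
#' @param x an N x F binary matrix (or a single-row vector).
#' @return Integer 0/1 vector of length N.
#' @export
evaluate_tree <- function(tree, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (is_leaf(tree)) {
    if (tree$feature < 1L || tree$feature > ncol(x)) {
      stop("leaf references feature ", tree$feature,
           " but data has only ", ncol(x), " features")
    }
    v <- as.integer(x[, tree$feature] != 0)
    return(if (tree$neg) 1L - v else v)
  }
  l <- evaluate_tree(tree$left, x)
  r <- evaluate_tree(tree$right, x)
  if (tree$op == "and") l * r else pmax(l, r)
}

count_leaves <- function(tree) {
  if (is_leaf(tree)) 1L else count_leaves(tree$left) + count_leaves(tree$right)
}

# Preorder lists of paths ("l"/"r" steps from the root) to all nodes /
# all leaves / all internal nodes. Fixed traversal order makes move
# enumeration and tie-breaking deterministic.
node_paths <- function(tree, path = character()) {
  if (is_leaf(tree)) return(list(path))
  c(list(path),
    node_paths(tree$left, c(path, "l")),
    node_paths(tree$right, c(path, "r")))
}

leaf_paths <- function(tree, path = character()) {
  if (is_leaf(tree)) return(list(path))
  c(leaf_paths(tree$left, c(path, "l")),
    leaf_paths(tree$right, c(path, "r")))
}

internal_paths <- function(tree, path = character()) {
  if (is_leaf(tree)) return(list())
  c(list(path),
    internal_paths(tree$left, c(path, "l")),
    internal_paths(tree$right, c(path, "r")))
}

get_subtree <- function(tree, path) {
  for (step in path) tree <- if (step == "l") tree$left else tree$right
  tree
}

set_subtree <- function(tree, path, value) {
  if (length(path) == 0L) return(value)
  if (path[1L] == "l") {
    tree$left <- set_subtree(tree$left, path[-1L], value)
  } else {
    tree$right <- set_subtree(tree$right, path[-1L], value)
  }
  tree
}

#' Print a logic tree as a Boolean expression
#'
#' Leaves print as the feature name (prefixed with `!` when negated);
#' internal nodes combine their children with `&` or `|`, parenthesizing
#' internal children, e.g. `(!X1 & X2) | (X1 & !X3)`.
#'
#' @param tree a logic tree.
#' @param feature_names character vector of feature names; defaults to
#'   `X1, X2, ...`.
#' @return A single string.
#' @export
tree_to_expression <- function(tree, feature_names = NULL) {
  fmt <- function(node, top) {
    if (is_leaf(node)) {
      nm <- if (is.null(feature_names)) paste0("X", node$feature)
            else feature_names[node$feature]
      return(if (node$neg) paste0("!", nm) else nm)
    }
    sym <- if (node$op == "and") " & " else " | "
    s <- paste0(fmt(node$left, FALSE), sym, fmt(node$right, FALSE))
    if (top) s else paste0("(", s, ")")
  }
  fmt(tree, TRUE)
}

#' Parse a Boolean expression into a logic tree
#'
#' Accepts the grammar printed by [tree_to_expression()]: identifiers,
#' prefix `!` negation, `&` (binding tighter) and `|`, and parentheses.
#' Unparenthesized chains like `A | B | C` associate to the left.
#'
#' @param text expression string.
#' @param feature_names names resolving identifiers to feature indices;
#'   `X<j>` identifiers resolve positionally when NULL.
#' @return A logic tree.
#' @export
parse_expression <- function(text, feature_names = NULL) {
  tokens <- regmatches(text, gregexpr("[A-Za-z_][A-Za-z0-9_.]*|[!&|()]", text))[[1L]]
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { tok <- peek(); pos <<- pos + 1L; tok }
  expect <- function(tok) {
    got <- advance()
    if (!identical(got, tok)) {
      stop(sprintf("parse error at token %d: expected '%s', got '%s'",
                   pos - 1L, tok, got))
    }
  }
  parse_or <- function() {
    node <- parse_and()
    while (identical(peek(), "|")) {
      advance()
      node <- logic_node("or", node, parse_and())
    }
    node
  }
  parse_and <- function() {
    node <- parse_factor()
    while (identical(peek(), "&")) {
      advance()
      node <- logic_node("and", node, parse_factor())
    }
    node
  }
  parse_factor <- function() {
    tok <- peek()
    if (identical(tok, "!")) {
      advance()
      sub <- parse_factor()
      if (!is_leaf(sub)) stop("negation is only defined on leaves")
      sub$neg <- !sub$neg
      return(sub)
    }
    if (identical(tok, "(")) {
      advance()
      node <- parse_or()
      expect(")")
      return(node)
    }
    tok <- advance()
    if (is.na(tok) || !grepl("^[A-Za-z_]", tok)) {
      stop(sprintf("parse error at token %d: expected an identifier, got '%s'",
                   pos - 1L, tok))
    }
    feature <- if (is.null(feature_names)) {
      j <- suppressWarnings(as.integer(sub("^X", "", tok)))
      if (is.na(j)) stop("unknown feature name '", tok,
                         "' (supply feature_names)")
      j
    } else {
      j <- match(tok, feature_names)
      if (is.na(j)) stop("unknown feature name '", tok, "'")
      j
    }
    logic_leaf(feature)
  }
  out <- parse_or()
  if (pos <= length(tokens)) {
    stop(sprintf("parse error: trailing input at token %d ('%s')", pos, peek()))
  }
  out
}

# All neighbors of a tree-set under the logic-regression move set, in a
# fixed deterministic order: (a) alternate a leaf's literal, (b) flip an
# operator, (c) grow — replace any node s by (s op new-literal), (d) prune —
# replace an internal node by one of its children, (e) add a single-literal
# tree, (f) delete a tree. Budgets (max_trees, max total leaves) are
# respected by every candidate.
enumerate_neighbors <- function(trees, n_features, max_trees, max_total_leaves) {
  out <- list()
  add <- function(cand) out[[length(out) + 1L]] <<- cand
  total_leaves <- if (length(trees)) sum(vapply(trees, count_leaves, 0L)) else 0L
  literals <- expand.grid(neg = c(FALSE, TRUE), feature = seq_len(n_features))
  literals <- literals[order(literals$feature, literals$neg), ]
  # (a) alternate a leaf
  for (t in seq_along(trees)) {
    for (path in leaf_paths(trees[[t]])) {
      cur <- get_subtree(trees[[t]], path)
      for (k in seq_len(nrow(literals))) {
        f <- literals$feature[k]; ng <- literals$neg[k]
        if (f == cur$feature && ng == cur$neg) next
        nt <- trees
        nt[[t]] <- set_subtree(trees[[t]], path, logic_leaf(f, ng))
        add(nt)
      }
    }
  }
  # (b) flip an operator
  for (t in seq_along(trees)) {
    for (path in internal_paths(trees[[t]])) {
      node <- get_subtree(trees[[t]], path)
      node$op <- if (node$op == "and") "or" else "and"
      nt <- trees
      nt[[t]] <- set_subtree(trees[[t]], path, node)
      add(nt)
    }
  }
  # (c) grow a branch / split a node
  if (total_leaves < max_total_leaves) {
    for (t in seq_along(trees)) {
      for (path in node_paths(trees[[t]])) {
        sub <- get_subtree(trees[[t]], path)
        for (op in c("and", "or")) {
          for (k in seq_len(nrow(literals))) {
            nt <- trees
            nt[[t]] <- set_subtree(trees[[t]], path,
              logic_node(op, sub, logic_leaf(literals$feature[k],
                                             literals$neg[k])))
            add(nt)
          }
        }
      }
    }
  }
  # (d) prune a branch
  for (t in seq_along(trees)) {
    for (path in internal_paths(trees[[t]])) {
      node <- get_subtree(trees[[t]], path)
      for (side in c("l", "r")) {
        nt <- trees
        nt[[t]] <- set_subtree(trees[[t]], path,
                               if (side == "l") node$left else node$right)
        add(nt)
      }
    }
  }
  # (e) add a tree
  if (length(trees) < max_trees && total_leaves < max_total_leaves) {
    for (k in seq_len(nrow(literals))) {
      add(c(trees, list(logic_leaf(literals$feature[k], literals$neg[k]))))
    }
  }
  # (f) delete a tree
  for (t in seq_along(trees)) add(trees[-t])
  out
}

# Draw one neighbor uniformly from the set enumerate_neighbors() would
# produce, without materializing it — used by simulated annealing where
# one random neighbor is proposed per iteration.
sample_neighbor <- function(trees, n_features, max_trees, max_total_leaves) {
  M <- length(trees)
  leaves <- if (M) vapply(trees, count_leaves, 0L) else integer()
  L <- sum(leaves)
  n_lit <- 2L * n_features
  can_grow <- L < max_total_leaves
  counts <- c(
    a = L * (n_lit - 1L),
    b = L - M,                                  # internal nodes overall
    c = if (can_grow) (2L * L - M) * 2L * n_lit else 0L,
    d = 2L * (L - M),
    e = if (M < max_trees && can_grow) n_lit else 0L,
    f = M
  )
  total <- sum(counts)
  if (total == 0L) return(NULL)
  u <- sample.int(total, 1L)
  lit_of <- function(k) logic_leaf((k - 1L) %/% 2L + 1L, (k - 1L) %% 2L == 1L)
  pick_tree <- function(sizes, idx) {   # locate (tree, within-tree offset)
    t <- 1L
    while (idx > sizes[t]) { idx <- idx - sizes[t]; t <- t + 1L }
    c(t, idx)
  }
  cat_id <- 1L
  for (nm in names(counts)) {
    if (u <= counts[[nm]]) { cat_id <- nm; break }
    u <- u - counts[[nm]]
  }
  if (cat_id == "a") {
    per_leaf <- n_lit - 1L
    leaf_idx <- (u - 1L) %/% per_leaf + 1L
    choice <- (u - 1L) %% per_leaf + 1L
    tl <- pick_tree(leaves, leaf_idx)
    path <- leaf_paths(trees[[tl[1L]]])[[tl[2L]]]
    cur <- get_subtree(trees[[tl[1L]]], path)
    cur_k <- (cur$feature - 1L) * 2L + cur$neg + 1L
    if (choice >= cur_k) choice <- choice + 1L
    trees[[tl[1L]]] <- set_subtree(trees[[tl[1L]]], path, lit_of(choice))
    return(trees)
  }
  if (cat_id == "b") {
    tl <- pick_tree(pmax(leaves - 1L, 0L), u)
    path <- internal_paths(trees[[tl[1L]]])[[tl[2L]]]
    node <- get_subtree(trees[[tl[1L]]], path)
    node$op <- if (node$op == "and") "or" else "and"
    trees[[tl[1L]]] <- set_subtree(trees[[tl[1L]]], path, node)
    return(trees)
  }
  if (cat_id == "c") {
    per_node <- 2L * n_lit
    node_idx <- (u - 1L) %/% per_node + 1L
    choice <- (u - 1L) %% per_node
    op <- if (choice < n_lit) "and" else "or"
    lit <- lit_of(choice %% n_lit + 1L)
    tl <- pick_tree(2L * leaves - 1L, node_idx)
    path <- node_paths(trees[[tl[1L]]])[[tl[2L]]]
    sub <- get_subtree(trees[[tl[1L]]], path)
    trees[[tl[1L]]] <- set_subtree(trees[[tl[1L]]], path,
                                   logic_node(op, sub, lit))
    return(trees)
  }
  if (cat_id == "d") {
    node_idx <- (u - 1L) %/% 2L + 1L
    side <- if ((u - 1L) %% 2L == 0L) "l" else "r"
    tl <- pick_tree(pmax(leaves - 1L, 0L), node_idx)
    path <- internal_paths(trees[[tl[1L]]])[[tl[2L]]]
    node <- get_subtree(trees[[tl[1L]]], path)
    trees[[tl[1L]]] <- set_subtree(trees[[tl[1L]]], path,
                                   if (side == "l") node$left else node$right)
    return(trees)
  }
  if (cat_id == "e") return(c(trees, list(lit_of(u))))
  trees[-u]   # cat f
}
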