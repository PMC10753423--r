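# Shared fixtures and independent oracles for property tests.

# --- registries and random condition trees ---------------------------------

make_test_registry <- function(n_bool = 4, n_num = 4, n_cat = 2) {
  vars <- c(
    lapply(seq_len(n_bool), function(i) {
      kb_variable(paste0("b", i), "boolean", paste("test boolean", i))
    }),
    lapply(seq_len(n_num), function(i) {
      kb_variable(paste0("n", i), "numeric", paste("test numeric", i), units = "u")
    }),
    lapply(seq_len(n_cat), function(i) {
      kb_variable(paste0("c", i), "categorical", paste("test categorical", i),
                  allowed_values = c("red", "green", "blue", "yellow"))
    }))
  stats::setNames(vars, vapply(vars, function(v) v$var_id, ""))
}

# a predicate whose truth value is freely settable by choosing the stored
# value (is_known / is_missing are excluded: their truth is tied to
# missingness itself)
random_settable_predicate <- function(vdef) {
  switch(vdef$kind,
    boolean = cnd_pred(vdef$var_id, sample(c("eq", "ne"), 1), sample(c(TRUE, FALSE), 1)),
    numeric = cnd_pred(vdef$var_id, sample(c("eq", "ne", "ge", "le", "gt", "lt"), 1),
                       sample(1:9, 1)),
    categorical = {
      if (runif(1) < 0.4) {
        cnd_pred(vdef$var_id, "in_set", as.list(sample(vdef$allowed_values, 2)))
      } else {
        cnd_pred(vdef$var_id, sample(c("eq", "ne"), 1),
                 sample(vdef$allowed_values, 1))
      }
    })
}

# a value that makes the predicate evaluate to `truth`; NULL for UNKNOWN
value_for_predicate <- function(pred, vdef, truth) {
  if (is.na(truth)) return(NULL)
  v <- pred$value
  pos_neg <- switch(pred$op,
    eq = list(v, alt_value(vdef, v)),
    ne = list(alt_value(vdef, v), v),
    ge = list(v, v - 1),
    le = list(v, v + 1),
    gt = list(v + 1, v),
    lt = list(v - 1, v),
    in_set = list(unlist(v)[1],
                  setdiff(vdef$allowed_values, unlist(v))[1]))
  if (truth) pos_neg[[1]] else pos_neg[[2]]
}

alt_value <- function(vdef, v) {
  switch(vdef$kind,
    boolean = !v,
    numeric = v + 1,
    categorical = setdiff(vdef$allowed_values, v)[1])
}

# random tree over <= max_vars distinct variables, depth <= max_depth;
# every leaf predicate is on its own variable so leaf truths are independent
random_tree <- function(registry, max_vars = 6, max_depth = 4) {
  n_leaves <- sample(seq_len(max_vars), 1)
  vars <- sample(names(registry), n_leaves)
  nodes <- lapply(vars, function(v) random_settable_predicate(registry[[v]]))
  depth_used <- 1
  while (length(nodes) > 1) {
    if (runif(1) < 0.2 && depth_used < max_depth) {
      i <- sample(length(nodes), 1)
      nodes[[i]] <- cnd_not(nodes[[i]])
      depth_used <- depth_used + 1
      next
    }
    take <- if (length(nodes) == 2) 2 else sample(2:3, 1)
    idx <- sample(length(nodes), take)
    combined <- if (runif(1) < 0.5) cnd_nary_test("and", nodes[idx])
                else cnd_nary_test("or", nodes[idx])
    nodes <- c(nodes[-idx], list(combined))
    depth_used <- depth_used + 1
  }
  # optional top-level negation
  if (runif(1) < 0.15) cnd_not(nodes[[1]]) else nodes[[1]]
}

cnd_nary_test <- function(kind, children) {
  do.call(if (kind == "and") cnd_and else cnd_or, children)
}

# --- truth-table Kleene oracle ----------------------------------------------
# Codes: 1 = TRUE, 0 = FALSE, 0.5 = UNKNOWN, combined by explicit lookup
# tables (independent of R's NA semantics used by the implementation).

K_NOT <- c("1" = 0, "0.5" = 0.5, "0" = 1)
k_and2 <- function(a, b) {
  tab <- matrix(c(0, 0, 0,
                  0, 0.5, 0.5,
                  0, 0.5, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("0", "0.5", "1"), c("0", "0.5", "1")))
  tab[as.character(a), as.character(b)]
}
k_or2 <- function(a, b) {
  tab <- matrix(c(0, 0.5, 1,
                  0.5, 0.5, 1,
                  1, 1, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("0", "0.5", "1"), c("0", "0.5", "1")))
  tab[as.character(a), as.character(b)]
}

# evaluate a tree given leaf truth codes keyed by variable id
oracle_eval <- function(node, leaf_code) {
  if (node$kind == "pred") return(leaf_code[[node$var]])
  if (node$kind == "not") return(unname(K_NOT[as.character(oracle_eval(node$children[[1]], leaf_code))]))
  vals <- vapply(node$children, oracle_eval, 0, leaf_code = leaf_code)
  Reduce(if (node$kind == "and") k_and2 else k_or2, vals)
}

logical_to_code <- function(x) if (is.na(x)) 0.5 else if (x) 1 else 0
code_to_logical <- function(x) if (x == 0.5) NA else x == 1

# enumerate all leaf truth assignments (3^k) for a tree; returns a list of
# named code vectors keyed by variable
leaf_assignments <- function(vars, states = c(1, 0, 0.5)) {
  grids <- rep(list(states), length(vars))
  g <- expand.grid(grids)
  lapply(seq_len(nrow(g)), function(i) stats::setNames(as.numeric(g[i, ]), vars))
}

# build patient values realizing a leaf truth assignment
values_for_assignment <- function(tree, registry, codes) {
  values <- list()
  for (p in cond_predicates(tree)) {
    truth <- code_to_logical(codes[[p$var]])
    val <- value_for_predicate(p, registry[[p$var]], truth)
    if (!is.null(val)) values[[p$var]] <- val
  }
  values
}

# --- dense-grid satisfiability oracle ---------------------------------------
# exhaustive enumeration over a fixed dense numeric grid (thresholds in the
# tests are integers 1..9, so a half-unit grid over 0..10 is exact),
# booleans and allowed values.

dense_grid_satisfiable <- function(cond, registry) {
  vars <- cond_vars(cond)
  domains <- lapply(vars, function(v) {
    vdef <- registry[[v]]
    switch(vdef$kind,
      boolean = list(TRUE, FALSE),
      numeric = as.list(seq(0, 10, by = 0.5)),
      categorical = as.list(vdef$allowed_values))
  })
  g <- expand.grid(lapply(domains, seq_along))
  for (i in seq_len(nrow(g))) {
    assign <- stats::setNames(
      lapply(seq_along(vars), function(k) domains[[k]][[g[i, k]]]), vars)
    if (isTRUE(evaluate_condition(cond, assign, registry))) return(TRUE)
  }
  FALSE
}

# --- tiny knowledge bases ----------------------------------------------------

small_config <- function(seed, n_recs = 8, n_rules = 10, n_vars = 8,
                         n_conditions = n_rules, ...) {
  kb_structure_config(n_recommendations = n_recs, n_rules = n_rules,
                      n_variables = n_vars, n_unique_conditions = n_conditions,
                      seed = seed, ...)
}
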