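# Condition grammar, three-valued evaluation, canonical form, satisfiability.

test_that("parser handles the rule grammar with standard precedence", {
  c1 <- parse_condition(
    '"self-reported asthma" = TRUE AND "current number of cigarettes/day" >= 1')
  expect_identical(c1$kind, "and")
  expect_identical(c1$children[[1]]$op, "eq")
  expect_identical(c1$children[[1]]$var, "self-reported asthma")
  expect_identical(c1$children[[2]]$op, "ge")
  expect_identical(c1$children[[2]]$value, 1)

  leaf <- parse_condition('"x" = TRUE')
  expect_identical(leaf$kind, "pred")
  expect_true(leaf$value)

  # NOT > AND > OR
  c2 <- parse_condition('a = 1 OR NOT b = 2 AND c = 3')
  expect_identical(c2$kind, "or")
  expect_identical(c2$children[[2]]$kind, "and")
  expect_identical(c2$children[[2]]$children[[1]]$kind, "not")

  c3 <- parse_condition("x IS KNOWN AND y IS MISSING")
  expect_identical(c3$children[[1]]$op, "is_known")
  expect_identical(c3$children[[2]]$op, "is_missing")

  c4 <- parse_condition('col IN ("red", "blue")')
  expect_identical(c4$op, "in_set")
  expect_identical(unlist(c4$value), c("red", "blue"))

  # literals case-insensitive, single quotes allowed
  expect_true(parse_condition("x = true")$value)
  expect_identical(parse_condition("x = 'abc'")$value, "abc")
})

test_that("parser reports position-annotated syntax errors", {
  err <- tryCatch(parse_condition('"x" = TRUE AND OR'), rc_parse_error = identity)
  expect_s3_class(err, "rc_parse_error")
  expect_match(conditionMessage(err), "line 1, column 16")
  expect_error(parse_condition('"x" >'), class = "rc_parse_error")
  expect_error(parse_condition('"x" = TRUE extra'), class = "rc_parse_error")
  expect_error(parse_condition('"unterminated'), class = "rc_parse_error")
  expect_error(parse_condition("= 5"), class = "rc_parse_error")
})

test_that("serialization round-trips through the parser", {
  set.seed(41)
  registry <- make_test_registry()
  for (i in 1:50) {
    tree <- random_tree(registry)
    reparsed <- parse_condition(cond_to_text(tree))
    expect_identical(condition_key(reparsed), condition_key(tree))
  }
})

test_that("evaluation implements strong Kleene semantics on the worked example", {
  registry <- list(
    asthma = kb_variable("asthma", "boolean", "self-reported asthma"),
    cig_day = kb_variable("cig_day", "numeric", "cigarettes per day"))
  cond <- parse_condition('"asthma" = TRUE AND "cig_day" >= 1')
  expect_true(evaluate_condition(cond, list(asthma = TRUE, cig_day = 10), registry))
  expect_false(evaluate_condition(cond, list(asthma = TRUE, cig_day = 0), registry))
  # missing smoking data: undecided, not FALSE
  expect_identical(evaluate_condition(cond, list(asthma = TRUE), registry), NA)
  # a decided FALSE short-circuits the unknown
  expect_false(evaluate_condition(cond, list(asthma = FALSE), registry))
  # everything missing -> UNKNOWN; NOT(UNKNOWN) -> UNKNOWN
  expect_identical(evaluate_condition(cond, list(), registry), NA)
  expect_identical(evaluate_condition(cnd_not(cond), list(), registry), NA)
  # is_known / is_missing are decided by missingness itself
  expect_false(evaluate_condition(cnd_pred("cig_day", "is_known"), list(), registry))
  expect_true(evaluate_condition(cnd_pred("cig_day", "is_missing"), list(), registry))
})

test_that("evaluation agrees with the truth-table oracle on random trees", {
  set.seed(101)
  registry <- make_test_registry()
  for (i in 1:200) {
    tree <- random_tree(registry, max_vars = 4, max_depth = 4)
    vars <- cond_vars(tree)
    for (codes in leaf_assignments(vars)) {
      got <- evaluate_condition(tree, values_for_assignment(tree, registry, codes),
                                registry)
      expect_identical(logical_to_code(got), unname(oracle_eval(tree, codes)))
    }
  }
})

test_that("a type mismatch between stored value and kind signals an ingestion bug", {
  registry <- list(n1 = kb_variable("n1", "numeric", "x"))
  expect_error(evaluate_condition(cnd_pred("n1", "ge", 5), list(n1 = "12"), registry),
               class = "rc_type_error")
})

test_that("De Morgan duality holds under three-valued evaluation", {
  set.seed(77)
  registry <- make_test_registry()
  for (i in 1:40) {
    p <- random_settable_predicate(registry[[sample(names(registry), 1)]])
    q <- random_settable_predicate(registry[[sample(names(registry), 1)]])
    lhs <- cnd_not(cnd_and(p, q))
    rhs <- cnd_or(cnd_not(p), cnd_not(q))
    vars <- unique(c(p$var, q$var))
    for (codes in leaf_assignments(vars)) {
      vals <- values_for_assignment(cnd_and(p, q), registry, codes)
      expect_identical(evaluate_condition(lhs, vals, registry),
                       evaluate_condition(rhs, vals, registry))
    }
  }
})

test_that("canonicalization is order-invariant, idempotent and evaluation-preserving", {
  registry <- make_test_registry()
  p <- cnd_pred("b1", "eq", TRUE)
  q <- cnd_pred("n1", "ge", 5)
  expect_identical(condition_key(cnd_and(p, q)), condition_key(cnd_and(q, p)))
  # NOT absorbed by operator inverses
  expect_identical(canonicalize_condition(cnd_not(cnd_pred("n1", "ge", 5))),
                   cnd_pred("n1", "lt", 5))
  expect_identical(canonicalize_condition(cnd_not(cnd_pred("b1", "eq", TRUE))),
                   cnd_pred("b1", "ne", TRUE))
  # flattening of nested conjunctions
  r <- cnd_pred("n2", "lt", 3)
  expect_identical(condition_key(cnd_and(p, cnd_and(q, r))),
                   condition_key(cnd_and(cnd_and(p, q), r)))

  set.seed(55)
  for (i in 1:60) {
    tree <- random_tree(registry, max_vars = 4)
    canon <- canonicalize_condition(tree)
    # idempotent
    expect_identical(cond_to_text(canonicalize_condition(canon)), cond_to_text(canon))
    # evaluation-preserving on every leaf assignment
    vars <- cond_vars(tree)
    for (codes in leaf_assignments(vars)) {
      vals <- values_for_assignment(tree, registry, codes)
      expect_identical(evaluate_condition(canon, vals, registry),
                       evaluate_condition(tree, vals, registry))
    }
  }
})

test_that("satisfiability decides planted contradictions and returns verifying witnesses", {
  registry <- make_test_registry()
  expect_false(check_satisfiability(
    cnd_and(cnd_pred("b1", "eq", TRUE), cnd_pred("b1", "eq", FALSE)), registry)$satisfiable)
  expect_false(check_satisfiability(
    cnd_and(cnd_pred("n1", "ge", 1), cnd_pred("n1", "eq", 0)), registry)$satisfiable)
  res <- check_satisfiability(
    cnd_and(cnd_pred("b1", "eq", TRUE), cnd_pred("n1", "ge", 1)), registry)
  expect_true(res$satisfiable)
  expect_true(evaluate_condition(
    cnd_and(cnd_pred("b1", "eq", TRUE), cnd_pred("n1", "ge", 1)), res$witness, registry))
  # boundary thresholds are probed (>= vs > at the same cutoff)
  expect_true(check_satisfiability(
    cnd_and(cnd_pred("n1", "ge", 5), cnd_pred("n1", "le", 5)), registry)$satisfiable)
  expect_false(check_satisfiability(
    cnd_and(cnd_pred("n1", "gt", 5), cnd_pred("n1", "lt", 5)), registry)$satisfiable)
})

test_that("satisfiability refuses oversized conditions with a message", {
  registry <- make_test_registry(n_bool = 14, n_num = 0, n_cat = 0)
  preds <- lapply(paste0("b", 1:13), function(v) cnd_pred(v, "eq", TRUE))
  res <- check_satisfiability(do.call(cnd_and, preds), registry, max_vars = 12)
  expect_true(is.na(res$satisfiable))
  expect_match(res$reason, "13 variables")
})

test_that("Kleene stability: decided verdicts survive completion of missing data", {
  set.seed(202)
  registry <- make_test_registry()
  for (i in 1:30) {
    tree <- random_tree(registry, max_vars = 3)
    vars <- cond_vars(tree)
    for (codes in leaf_assignments(vars)) {
      base <- evaluate_condition(tree, values_for_assignment(tree, registry, codes),
                                 registry)
      if (is.na(base)) next
      unknown_vars <- vars[codes[vars] == 0.5]
      if (!length(unknown_vars)) next
      # complete the unknowns every possible way: the verdict must not move
      for (completion in leaf_assignments(unknown_vars, states = c(1, 0))) {
        full <- codes
        full[unknown_vars] <- completion
        done <- evaluate_condition(tree, values_for_assignment(tree, registry, full),
                                   registry)
        expect_identical(done, base)
      }
    }
  }
})
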