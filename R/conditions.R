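# Condition language: predicates over typed patient variables combined with
# AND / OR / NOT, evaluated under strong Kleene three-valued semantics so that
# rules referencing missing data yield UNKNOWN instead of firing spuriously.

PRED_OPS <- c("eq", "ne", "ge", "le", "gt", "lt", "in_set", "is_known", "is_missing")

#' Build a predicate node
#'
#' A predicate compares one knowledge-base variable against a literal, tests
#' set membership, or tests whether the variable is known/missing for the
#' patient. Operator/kind compatibility (e.g. order comparisons only on
#' numeric or ordinal variables) is enforced when a condition is validated
#' against a variable registry, not at construction time.
#'
#' @param var variable id (character scalar).
#' @param op one of `"eq"`, `"ne"`, `"ge"`, `"le"`, `"gt"`, `"lt"`,
#'   `"in_set"`, `"is_known"`, `"is_missing"`.
#' @param value literal matching the variable's kind; a vector for
#'   `"in_set"`; `NULL` for `"is_known"`/`"is_missing"`.
#' @return a condition node (list with class `rc_cond`).
#' @export
#' @examples
#' cnd_pred("self_reported_asthma", "eq", TRUE)
cnd_pred <- function(var, op, value = NULL) {
  stopifnot(is.character(var), length(var) == 1L, nzchar(var))
  op <- match.arg(op, PRED_OPS)
  if (op %in% c("is_known", "is_missing")) {
    value <- NULL
  } else if (is.null(value)) {
    stop("predicate on '", var, "': operator '", op, "' requires a literal value")
  }
  structure(list(kind = "pred", var = var, op = op, value = value), class = "rc_cond")
}

#' Combine conditions with Boolean connectives
#'
#' `cnd_and()` and `cnd_or()` take two or more operands; `cnd_not()` takes
#' exactly one. Operands may be predicates or nested conditions.
#'
#' @param ... condition nodes.
#' @param x a condition node.
#' @return a condition node.
#' @export
cnd_and <- function(...) cnd_nary("and", list(...))

#' @rdname cnd_and
#' @export
cnd_or <- function(...) cnd_nary("or", list(...))

#' @rdname cnd_and
#' @export
cnd_not <- function(x) {
  stopifnot(inherits(x, "rc_cond"))
  structure(list(kind = "not", children = list(x)), class = "rc_cond")
}

cnd_nary <- function(kind, children) {
  if (length(children) == 1L && is.list(children[[1]]) &&
      !inherits(children[[1]], "rc_cond")) {
    children <- children[[1]]
  }
  if (length(children) < 2L) {
    stop(toupper(kind), " requires at least 2 operands")
  }
  for (ch in children) stopifnot(inherits(ch, "rc_cond"))
  structure(list(kind = kind, children = children), class = "rc_cond")
}

#' Variables referenced by a condition
#'
#' @param cond a condition node.
#' @return character vector of distinct variable ids, sorted.
#' @export
cond_vars <- function(cond) {
  acc <- character(0)
  walk <- function(n) {
    if (n$kind == "pred") {
      acc[[length(acc) + 1L]] <<- n$var
    } else {
      for (ch in n$children) walk(ch)
    }
  }
  walk(cond)
  sort(unique(acc))
}

cond_predicates <- function(cond) {
  acc <- list()
  walk <- function(n) {
    if (n$kind == "pred") acc[[length(acc) + 1L]] <<- n else for (ch in n$children) walk(ch)
  }
  walk(cond)
  acc
}

# ---------------------------------------------------------------------------
# Text serialization

quote_str <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

format_literal <- function(value) {
  if (is.logical(value)) {
    if (value) "TRUE" else "FALSE"
  } else if (is.numeric(value)) {
    format(value, digits = 15, scientific = FALSE, trim = TRUE)
  } else {
    quote_str(as.character(value))
  }
}

#' Serialize a condition to its textual grammar
#'
#' The inverse of [parse_condition()]: emits a fully parenthesized expression
#' in the documented grammar (quoted variable names, `=`, `!=`, `>=`, `<=`,
#' `>`, `<`, `IN (...)`, `IS KNOWN`, `IS MISSING`, `AND`, `OR`, `NOT`).
#'
#' @param cond a condition node.
#' @return character scalar.
#' @export
cond_to_text <- function(cond) {
  switch(cond$kind,
    pred = {
      v <- quote_str(cond$var)
      switch(cond$op,
        eq = paste(v, "=", format_literal(cond$value)),
        ne = paste(v, "!=", format_literal(cond$value)),
        ge = paste(v, ">=", format_literal(cond$value)),
        le = paste(v, "<=", format_literal(cond$value)),
        gt = paste(v, ">", format_literal(cond$value)),
        lt = paste(v, "<", format_literal(cond$value)),
        in_set = paste0(v, " IN (", paste(vapply(cond$value, format_literal, ""),
                                          collapse = ", "), ")"),
        is_known = paste(v, "IS KNOWN"),
        is_missing = paste(v, "IS MISSING")
      )
    },
    not = paste0("NOT ", wrap_child(cond$children[[1]])),
    and = paste0("(", paste(vapply(cond$children, cond_to_text, ""), collapse = " AND "), ")"),
    or  = paste0("(", paste(vapply(cond$children, cond_to_text, ""), collapse = " OR "), ")")
  )
}

wrap_child <- function(node) {
  if (node$kind == "pred") paste0("(", cond_to_text(node), ")") else cond_to_text(node)
}

#' @export
print.rc_cond <- function(x, ...) {
  cat("<condition> ", cond_to_text(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.rc_cond <- function(x, ...) cond_to_text(x)

# ---------------------------------------------------------------------------
# Parser: tokenizer + recursive descent with standard precedence NOT > AND > OR.

tokenize_condition <- function(text) {
  n <- nchar(text)
  toks <- list()
  i <- 1L
  push <- function(type, value, pos) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[ \t\r\n]$", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("LPAREN", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("RPAREN", ")", i); i <- i + 1L; next }
    if (ch == ",") { push("COMMA", ",", i); i <- i + 1L; next }
    if (ch %in% c('"', "'")) {
      # quoted string: variable name or string literal; backslash escapes the quote
      j <- i + 1L
      out <- character(0)
      closed <- FALSE
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\" && j < n && substr(text, j + 1L, j + 1L) == ch) {
          out <- c(out, ch); j <- j + 2L
        } else if (cj == ch) {
          closed <- TRUE; j <- j + 1L; break
        } else {
          out <- c(out, cj); j <- j + 1L
        }
      }
      if (!closed) parse_fail(text, i, "unterminated string")
      push("STRING", paste(out, collapse = ""), i)
      i <- j
      next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr("^(>=|<=|!=|=|>|<)", substr(text, i, n)))
    if (length(m) == 1L && nzchar(m)) {
      push("OP", m, i); i <- i + nchar(m); next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?",
                            substr(text, i, n)))
    if (length(m) == 1L && nzchar(m)) {
      push("NUMBER", m, i); i <- i + nchar(m); next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[A-Za-z_][A-Za-z0-9_./-]*", substr(text, i, n)))
    if (length(m) == 1L && nzchar(m)) {
      up <- toupper(m)
      if (up %in% c("AND", "OR", "NOT", "IN", "IS", "KNOWN", "MISSING")) {
        push(up, m, i)
      } else if (up %in% c("TRUE", "FALSE")) {
        push("BOOL", up == "TRUE", i)
      } else {
        push("IDENT", m, i)
      }
      i <- i + nchar(m)
      next
    }
    parse_fail(text, i, paste0("unexpected character '", ch, "'"))
  }
  push("EOF", "", n + 1L)
  toks
}

pos_to_line_col <- function(text, pos) {
  before <- substr(text, 1L, max(pos - 1L, 0L))
  nl <- gregexpr("\n", before, fixed = TRUE)[[1]]
  if (identical(nl[1], -1L)) {
    c(line = 1L, col = pos)
  } else {
    c(line = length(nl) + 1L, col = pos - nl[length(nl)])
  }
}

parse_fail <- function(text, pos, msg) {
  lc <- pos_to_line_col(text, pos)
  stop(structure(
    class = c("rc_parse_error", "error", "condition"),
    list(message = sprintf("condition syntax error at line %d, column %d: %s",
                           lc[["line"]], lc[["col"]], msg),
         call = NULL, line = lc[["line"]], column = lc[["col"]])
  ))
}

#' Parse a condition expression
#'
#' Parses the textual rule grammar into a condition tree. Precedence is
#' `NOT` > `AND` > `OR`; parentheses group. Variable names are double- or
#' single-quoted strings (may contain spaces) or bare identifiers. Literals:
#' `TRUE`/`FALSE` (case-insensitive), plain decimal numbers, quoted strings.
#' Predicates: `var = lit`, `var != lit`, `var >= lit`, `var <= lit`,
#' `var > lit`, `var < lit`, `var IN (lit, ...)`, `var IS KNOWN`,
#' `var IS MISSING`.
#'
#' @param text a single character string.
#' @return a condition node.
#' @export
#' @examples
#' parse_condition(
#'   '"self-reported asthma" = TRUE AND "current number of cigarettes/day" >= 1')
parse_condition <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- tokenize_condition(text)
  idx <- 1L
  peek <- function() toks[[idx]]
  advance <- function() { t <- toks[[idx]]; idx <<- idx + 1L; t }
  expect <- function(type, what) {
    t <- peek()
    if (t$type != type) parse_fail(text, t$pos, paste0("expected ", what,
      ", found '", if (t$type == "EOF") "end of input" else t$value, "'"))
    advance()
  }

  parse_or <- function() {
    left <- parse_and()
    ops <- list(left)
    while (peek()$type == "OR") {
      advance()
      ops[[length(ops) + 1L]] <- parse_and()
    }
    if (length(ops) == 1L) left else cnd_nary("or", ops)
  }
  parse_and <- function() {
    left <- parse_not()
    ops <- list(left)
    while (peek()$type == "AND") {
      advance()
      ops[[length(ops) + 1L]] <- parse_not()
    }
    if (length(ops) == 1L) left else cnd_nary("and", ops)
  }
  parse_not <- function() {
    if (peek()$type == "NOT") {
      advance()
      cnd_not(parse_not())
    } else {
      parse_primary()
    }
  }
  parse_literal <- function() {
    t <- peek()
    if (t$type == "BOOL") { advance(); return(t$value) }
    if (t$type == "NUMBER") { advance(); return(as.numeric(t$value)) }
    if (t$type == "STRING") { advance(); return(t$value) }
    parse_fail(text, t$pos, paste0("expected a literal, found '",
      if (t$type == "EOF") "end of input" else t$value, "'"))
  }
  parse_primary <- function() {
    t <- peek()
    if (t$type == "LPAREN") {
      advance()
      inner <- parse_or()
      expect("RPAREN", "')'")
      return(inner)
    }
    if (!t$type %in% c("STRING", "IDENT")) {
      parse_fail(text, t$pos, paste0("expected a variable or '(', found '",
        if (t$type == "EOF") "end of input" else t$value, "'"))
    }
    advance()
    var <- t$value
    t2 <- peek()
    if (t2$type == "OP") {
      advance()
      op <- switch(t2$value, "=" = "eq", "!=" = "ne", ">=" = "ge",
                   "<=" = "le", ">" = "gt", "<" = "lt")
      return(cnd_pred(var, op, parse_literal()))
    }
    if (t2$type == "IS") {
      advance()
      t3 <- peek()
      if (t3$type == "KNOWN") { advance(); return(cnd_pred(var, "is_known")) }
      if (t3$type == "MISSING") { advance(); return(cnd_pred(var, "is_missing")) }
      parse_fail(text, t3$pos, "expected KNOWN or MISSING after IS")
    }
    if (t2$type == "IN") {
      advance()
      expect("LPAREN", "'(' after IN")
      vals <- list(parse_literal())
      while (peek()$type == "COMMA") {
        advance()
        vals[[length(vals) + 1L]] <- parse_literal()
      }
      expect("RPAREN", "')'")
      return(cnd_pred(var, "in_set", vals))
    }
    parse_fail(text, t2$pos, paste0("expected a comparison operator after '", var, "'"))
  }

  result <- parse_or()
  t <- peek()
  if (t$type != "EOF") {
    parse_fail(text, t$pos, paste0("unexpected trailing input '", t$value, "'"))
  }
  result
}

# ---------------------------------------------------------------------------
# Validation against a variable registry

# registry: named list var_id -> variable definition (see kb_variable)
check_condition <- function(cond, registry, context = "condition") {
  issues <- character(0)
  for (p in cond_predicates(cond)) {
    v <- registry[[p$var]]
    if (is.null(v)) {
      issues <- c(issues, sprintf("%s references undeclared variable '%s'", context, p$var))
      next
    }
    if (p$op %in% c("is_known", "is_missing")) next
    kind <- v$kind
    if (kind == "timeseries") {
      issues <- c(issues, sprintf(
        "%s: variable '%s' is a time series and cannot be used in a predicate directly; use a derived variable",
        context, p$var))
      next
    }
    if (p$op %in% c("ge", "le", "gt", "lt") && !kind %in% c("numeric", "ordinal")) {
      issues <- c(issues, sprintf(
        "%s: order comparison on variable '%s' of kind '%s' (numeric or ordinal required)",
        context, p$var, kind))
    }
    if (p$op == "in_set" && !kind %in% c("categorical", "ordinal")) {
      issues <- c(issues, sprintf(
        "%s: IN on variable '%s' of kind '%s' (categorical or ordinal required)",
        context, p$var, kind))
    }
    lit_ok <- switch(kind,
      boolean = p$op %in% c("eq", "ne") && is.logical(p$value),
      numeric = is.numeric(p$value),
      categorical = ,
      ordinal = if (p$op == "in_set") {
        all(vapply(p$value, is.character, TRUE))
      } else {
        is.character(p$value)
      },
      TRUE)
    if (!isTRUE(lit_ok)) {
      issues <- c(issues, sprintf(
        "%s: literal for variable '%s' does not match its kind '%s'", context, p$var, kind))
    } else if (kind %in% c("categorical", "ordinal")) {
      lits <- if (p$op == "in_set") unlist(p$value) else p$value
      bad <- setdiff(lits, v$allowed_values)
      if (length(bad)) {
        issues <- c(issues, sprintf(
          "%s: value(s) %s not among allowed values of variable '%s'",
          context, paste0("'", bad, "'", collapse = ", "), p$var))
      }
    }
  }
  issues
}

# ---------------------------------------------------------------------------
# Evaluation (strong Kleene). UNKNOWN is represented by logical NA: R's
# `!`, `all()` and `any()` (with na.rm = FALSE) implement exactly the strong
# Kleene truth tables.

#' Evaluate a condition for a patient
#'
#' Strong Kleene three-valued semantics: a predicate on a missing variable
#' yields UNKNOWN (`NA`), except `IS KNOWN` (FALSE) and `IS MISSING` (TRUE).
#' `AND`/`OR`/`NOT` combine by the Kleene tables; the result is `TRUE`,
#' `FALSE` or `NA` (UNKNOWN). A rule fires only on `TRUE`.
#'
#' @param cond a condition node (validated against `registry`).
#' @param values named list of typed patient values; a variable absent from
#'   the list is missing. A [patient_record()] may be passed instead.
#' @param registry named list of variable definitions (e.g. `kb$variables`).
#' @return logical scalar: `TRUE`, `FALSE` or `NA`.
#' @export
evaluate_condition <- function(cond, values, registry) {
  if (inherits(values, "rc_patient")) values <- values$values
  eval_node(cond, values, registry)
}

eval_node <- function(node, values, registry) {
  switch(node$kind,
    pred = eval_pred(node, values, registry),
    not = !eval_node(node$children[[1]], values, registry),
    and = {
      out <- TRUE
      for (ch in node$children) {
        v <- eval_node(ch, values, registry)
        if (isFALSE(v)) return(FALSE)
        out <- out & v
      }
      out
    },
    or = {
      out <- FALSE
      for (ch in node$children) {
        v <- eval_node(ch, values, registry)
        if (isTRUE(v)) return(TRUE)
        out <- out | v
      }
      out
    }
  )
}

eval_pred <- function(p, values, registry) {
  val <- values[[p$var]]
  if (p$op == "is_known") return(!is.null(val))
  if (p$op == "is_missing") return(is.null(val))
  if (is.null(val)) return(NA)
  vdef <- registry[[p$var]]
  kind <- if (is.null(vdef)) "<undeclared>" else vdef$kind
  type_ok <- switch(kind,
    boolean = is.logical(val) && length(val) == 1L && !is.na(val),
    numeric = is.numeric(val) && length(val) == 1L && !is.na(val),
    categorical = ,
    ordinal = is.character(val) && length(val) == 1L && !is.na(val),
    FALSE)
  if (!isTRUE(type_ok)) {
    stop(structure(
      class = c("rc_type_error", "error", "condition"),
      list(message = sprintf(
        "stored value for variable '%s' does not match its declared kind '%s' (ingestion bug)",
        p$var, kind),
        call = NULL, variable = p$var)))
  }
  if (kind == "ordinal" && p$op %in% c("ge", "le", "gt", "lt")) {
    a <- match(val, vdef$allowed_values)
    b <- match(p$value, vdef$allowed_values)
    return(switch(p$op, ge = a >= b, le = a <= b, gt = a > b, lt = a < b))
  }
  switch(p$op,
    eq = identical_scalar(val, p$value),
    ne = !identical_scalar(val, p$value),
    ge = val >= p$value,
    le = val <= p$value,
    gt = val > p$value,
    lt = val < p$value,
    in_set = as.character(val) %in% as.character(unlist(p$value))
  )
}

identical_scalar <- function(a, b) {
  if (is.numeric(a) && is.numeric(b)) return(a == b)
  if (is.logical(a) && is.logical(b)) return(a == b)
  if (is.character(a) && is.character(b)) return(a == b)
  FALSE
}

# ---------------------------------------------------------------------------
# Canonical normal form

INVERSE_OP <- c(eq = "ne", ne = "eq", ge = "lt", lt = "ge", gt = "le", le = "gt",
                is_known = "is_missing", is_missing = "is_known")

#' Canonicalize a condition
#'
#' Produces a deterministic normal form: negation is pushed inward by De
#' Morgan's laws (valid under Kleene semantics) and absorbed into predicates
#' where an inverse operator exists (`NOT x >= 5` becomes `x < 5`); nested
#' `AND`/`AND` and `OR`/`OR` are flattened; duplicate operands are removed;
#' operands are sorted by their serialized text. Two conditions count as the
#' same logical condition iff their canonical forms (equivalently, their
#' [condition_key()]s) are identical. Canonicalization preserves the
#' three-valued evaluation on every assignment.
#'
#' @param cond a condition node.
#' @return a condition node in canonical form.
#' @export
canonicalize_condition <- function(cond) {
  canon(cond, negate = FALSE)
}

canon <- function(node, negate) {
  if (node$kind == "pred") {
    p <- node
    if (negate) {
      inv <- if (p$op %in% names(INVERSE_OP)) INVERSE_OP[[p$op]] else NULL
      if (!is.null(inv)) {
        p <- cnd_pred(p$var, inv, p$value)
      } else {
        # in_set has no inverse operator: NOT remains on the predicate
        return(cnd_not(canon_pred(p)))
      }
    }
    return(canon_pred(p))
  }
  if (node$kind == "not") {
    return(canon(node$children[[1]], negate = !negate))
  }
  kind <- node$kind
  if (negate) kind <- if (kind == "and") "or" else "and"  # De Morgan
  kids <- list()
  for (ch in node$children) {
    c2 <- canon(ch, negate = negate)
    if (c2$kind == kind) {
      kids <- c(kids, c2$children)   # flatten
    } else {
      kids[[length(kids) + 1L]] <- c2
    }
  }
  keys <- vapply(kids, cond_to_text, "")
  keep <- !duplicated(keys)
  kids <- kids[keep]
  kids <- kids[order(keys[keep], method = "radix")]
  if (length(kids) == 1L) return(kids[[1]])
  structure(list(kind = kind, children = kids), class = "rc_cond")
}

canon_pred <- function(p) {
  if (p$op == "in_set") {
    vals <- unlist(p$value)
    vals <- sort(unique(as.character(vals)), method = "radix")
    return(cnd_pred(p$var, "in_set", as.list(vals)))
  }
  p
}

#' Canonical identity key of a condition
#'
#' The serialized text of the canonical form; two conditions are the same
#' unique logical condition iff their keys are equal.
#'
#' @param cond a condition node.
#' @return character scalar.
#' @export
condition_key <- function(cond) cond_to_text(canonicalize_condition(cond))

# ---------------------------------------------------------------------------
# Satisfiability by interval abstraction

#' Decide satisfiability of a condition over fully known assignments
#'
#' Exhaustive search over a finite abstraction of the variable domains:
#' booleans over \{TRUE, FALSE\}; categorical/ordinal variables over their
#' allowed values; numeric variables discretized into the intervals induced
#' by all thresholds appearing in predicates on that variable (each
#' threshold, each midpoint between consecutive thresholds, and one probe
#' below/above the extremes). Conditions are decomposed at a top-level AND
#' into connected components sharing variables, so conjunctions of many
#' independent predicates stay cheap. Returns a concrete witness assignment
#' whenever satisfiable.
#'
#' @param cond a condition node.
#' @param registry named list of variable definitions.
#' @param max_vars refuse conditions referencing more than this many
#'   variables (search-space guard, default 12).
#' @return list with `satisfiable` (TRUE/FALSE, or NA on refusal), `witness`
#'   (named list of values, or NULL) and, on refusal, `reason`.
#' @export
check_satisfiability <- function(cond, registry, max_vars = 12L) {
  vars <- cond_vars(cond)
  if (length(vars) > max_vars) {
    return(list(satisfiable = NA, witness = NULL,
                reason = sprintf("condition references %d variables, above the limit of %d",
                                 length(vars), max_vars)))
  }
  ccond <- canonicalize_condition(cond)
  thresholds <- numeric_thresholds(ccond)
  parts <- if (ccond$kind == "and") ccond$children else list(ccond)
  comps <- connected_components(parts)
  witness <- list()
  for (comp in comps) {
    sub <- if (length(comp) == 1L) comp[[1]] else
      structure(list(kind = "and", children = comp), class = "rc_cond")
    res <- sat_grid(sub, registry, thresholds)
    if (is.na(res$satisfiable)) return(res)
    if (!isTRUE(res$satisfiable)) {
      return(list(satisfiable = FALSE, witness = NULL))
    }
    witness <- c(witness, res$witness)
  }
  list(satisfiable = TRUE, witness = witness)
}

numeric_thresholds <- function(cond) {
  th <- list()
  for (p in cond_predicates(cond)) {
    if (p$op %in% c("eq", "ne", "ge", "le", "gt", "lt") && is.numeric(p$value)) {
      th[[p$var]] <- c(th[[p$var]], p$value)
    }
  }
  th
}

connected_components <- function(parts) {
  n <- length(parts)
  if (n <= 1L) return(list(parts))
  vsets <- lapply(parts, cond_vars)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && length(intersect(vsets[[i]], vsets[[j]]))) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(unique(comp), function(cid) parts[comp == cid])
}

var_probes <- function(vdef, thresholds) {
  switch(vdef$kind,
    boolean = list(TRUE, FALSE),
    categorical = ,
    ordinal = as.list(vdef$allowed_values),
    numeric = {
      t <- sort(unique(thresholds))
      if (!length(t)) return(list(0))
      probes <- c(t, t[1] - 1)
      if (length(t) > 1L) probes <- c(probes, (t[-1] + t[-length(t)]) / 2)
      probes <- c(probes, t[length(t)] + 1)
      as.list(sort(unique(probes)))
    },
    stop("cannot probe variable '", vdef$var_id, "' of kind '", vdef$kind, "'")
  )
}

sat_grid <- function(cond, registry, thresholds) {
  vars <- cond_vars(cond)
  domains <- lapply(vars, function(v) {
    vdef <- registry[[v]]
    if (is.null(vdef)) stop("undeclared variable '", v, "' in satisfiability check")
    var_probes(vdef, thresholds[[v]])
  })
  sizes <- vapply(domains, length, 1L)
  total <- prod(sizes)
  if (total > 2e5) {
    return(list(satisfiable = NA, witness = NULL,
                reason = sprintf("discretized search space has %.0f assignments, above the limit of %d",
                                 total, 200000L)))
  }
  idx <- rep(1L, length(vars))
  for (step in seq_len(total)) {
    assign <- stats::setNames(
      lapply(seq_along(vars), function(k) domains[[k]][[idx[k]]]), vars)
    if (isTRUE(eval_node(cond, assign, registry))) {
      return(list(satisfiable = TRUE, witness = assign))
    }
    # mixed-radix increment
    k <- 1L
    while (k <= length(idx)) {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= sizes[k]) break
      idx[k] <- 1L
      k <- k + 1L
    }
  }
  list(satisfiable = FALSE, witness = NULL)
}
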