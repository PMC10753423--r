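# Cohort validation harness: map a study table onto KB variables, run the
# engine on every participant, summarize trigger statistics, classify
# untriggered rules into a four-way reason taxonomy, and cross-check the
# production pipeline against an independent reference evaluator.

#' Define a cohort-to-KB variable mapping
#'
#' Each entry links one cohort column to one KB variable through a transform:
#' `identity` (value passed to [normalize_value()] as-is), `recode_table`
#' (named lookup `raw -> value`, with optional `.default`), `threshold_bin`
#' (numeric `breaks` + `labels`, e.g. recoding a continuous inhaled
#' corticosteroid dose to low/medium/high), or `computed` (an R expression
#' evaluated with the row's columns in scope, for variables derived from
#' several columns).
#'
#' @param entries list of entries; each a list with `column`, `var_id`,
#'   `transform` (default `"identity"`), and the transform's parameters
#'   (`table`, `breaks`/`labels`, or `expr` as text or expression).
#' @return list of class `rc_mapping`.
#' @export
variable_mapping <- function(entries) {
  for (e in entries) {
    stopifnot(!is.null(e$var_id))
    tr <- e$transform %||% "identity"
    if (!tr %in% c("identity", "recode_table", "threshold_bin", "computed")) {
      stop("unknown transform '", tr, "' for variable '", e$var_id, "'")
    }
    if (tr != "computed" && is.null(e$column)) {
      stop("mapping entry for '", e$var_id, "' needs a source column")
    }
  }
  structure(list(entries = entries), class = "rc_mapping")
}

#' Variables a mapping can feed
#'
#' @param mapping an [variable_mapping()].
#' @return character vector of distinct KB variable ids.
#' @export
mapped_variables <- function(mapping) {
  unique(vapply(mapping$entries, function(e) e$var_id, ""))
}

apply_transform <- function(e, row) {
  switch(e$transform %||% "identity",
    identity = row[[e$column]],
    recode_table = {
      raw <- as.character(row[[e$column]])
      if (raw %in% names(e$table)) {
        e$table[[raw]]
      } else if (".default" %in% names(e$table)) {
        e$table[[".default"]]
      } else {
        stop("recode table for '", e$var_id, "' has no entry for '", raw,
             "' and no .default")
      }
    },
    threshold_bin = {
      x <- suppressWarnings(as.numeric(row[[e$column]]))
      if (is.na(x)) stop("threshold_bin for '", e$var_id, "': value '",
                         row[[e$column]], "' is not numeric")
      e$labels[[findInterval(x, e$breaks) + 1L]]
    },
    computed = {
      ex <- e$expr
      if (is.character(ex)) ex <- parse(text = ex)[[1]]
      eval(ex, envir = as.list(row))
    }
  )
}

#' Map a cohort table onto patient records
#'
#' One record per row. Values produced by the transforms go through
#' [normalize_value()]; empty cells (`NA` or `""`) are missing; KB variables
#' not covered by the mapping are missing for everyone (no imputation, no
#' random attribution). Normalization failures are reported per (row,
#' column) in the `failures` attribute and leave that value missing — the
#' record is still produced.
#'
#' @param cohort data.frame, one row per participant; must contain a
#'   `patient_id` column or row identifiers are generated.
#' @param mapping an [variable_mapping()].
#' @param kb the knowledge base.
#' @return list of [patient_record()]s, with attributes `failures`
#'   (data.frame row/column/var_id/raw/message) and
#'   `feedable_variable_fraction` (mapped KB variables / all KB variables).
#' @export
apply_mapping <- function(cohort, mapping, kb) {
  stopifnot(is.data.frame(cohort), inherits(mapping, "rc_mapping"))
  cols_needed <- unlist(lapply(mapping$entries, function(e) {
    if (identical(e$transform %||% "identity", "computed")) NULL else e$column
  }))
  missing_cols <- setdiff(cols_needed, names(cohort))
  if (length(missing_cols)) {
    stop("cohort table lacks mapped column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (e in mapping$entries) {
    if (is.null(kb$variables[[e$var_id]])) {
      stop("mapping targets undeclared KB variable '", e$var_id, "'")
    }
  }
  ids <- if ("patient_id" %in% names(cohort)) as.character(cohort$patient_id)
         else sprintf("row_%04d", seq_len(nrow(cohort)))
  failures <- list()
  records <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, , drop = FALSE]
    values <- list()
    for (e in mapping$entries) {
      raw <- tryCatch(apply_transform(e, row), error = function(err) err)
      if (inherits(raw, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          row = i, column = e$column %||% "<computed>", var_id = e$var_id,
          raw = NA_character_, message = conditionMessage(raw),
          stringsAsFactors = FALSE)
        next
      }
      if (is.null(raw) || length(raw) != 1L || is.na(raw) ||
          (is.character(raw) && !nzchar(trimws(raw)))) {
        next  # explicit missing
      }
      val <- tryCatch(normalize_value(kb$variables[[e$var_id]], raw),
                      rc_ingestion_error = function(err) err)
      if (inherits(val, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          row = i, column = e$column %||% "<computed>", var_id = e$var_id,
          raw = as.character(raw), message = conditionMessage(val),
          stringsAsFactors = FALSE)
        next
      }
      values[[e$var_id]] <- val
    }
    records[[i]] <- patient_record(ids[i], values = values)
  }
  fail_df <- if (length(failures)) do.call(rbind, failures) else
    data.frame(row = integer(0), column = character(0), var_id = character(0),
               raw = character(0), message = character(0), stringsAsFactors = FALSE)
  attr(records, "failures") <- fail_df
  attr(records, "feedable_variable_fraction") <-
    if (length(kb$variables)) length(mapped_variables(mapping)) / length(kb$variables) else NA_real_
  records
}

#' Run the engine on a cohort and summarize trigger statistics
#'
#' Evaluates every rule for every participant and reports: per-patient fired
#' counts with median/IQR/max; per-rule fire totals; the number and fraction
#' of rules fired at least once, with median/IQR/max of their fire counts;
#' and the rules never fired (reason classification is a separate step, see
#' [classify_untriggered()]).
#'
#' @param kb a knowledge base.
#' @param records list of [patient_record()]s.
#' @return list of class `rc_cohort_report`.
#' @export
run_cohort <- function(kb, records) {
  rule_ids <- names(kb$rules)
  per_rule <- stats::setNames(integer(length(rule_ids)), rule_ids)
  per_patient <- integer(length(records))
  for (i in seq_along(records)) {
    res <- trigger_rules(kb, records[[i]])
    per_patient[i] <- nrow(res$fired)
    if (nrow(res$fired)) {
      per_rule[res$fired$rule_id] <- per_rule[res$fired$rule_id] + 1L
    }
  }
  fired_counts <- per_rule[per_rule > 0L]
  q <- function(x) if (length(x)) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE) else rep(NA_real_, 3)
  qp <- q(per_patient); qr <- q(as.numeric(fired_counts))
  structure(list(
    n_participants = length(records),
    total_recommendations = sum(per_patient),
    per_patient_counts = per_patient,
    per_patient_summary = list(median = qp[2], iqr = c(qp[1], qp[3]),
                               max = if (length(per_patient)) max(per_patient) else NA_integer_),
    per_rule_fire_counts = per_rule,
    n_rules_fired_at_least_once = length(fired_counts),
    fraction_rules_fired = if (length(per_rule)) length(fired_counts) / length(per_rule) else NA_real_,
    fired_counts_summary = list(median = qr[2], iqr = c(qr[1], qr[3]),
                                max = if (length(fired_counts)) max(fired_counts) else NA_integer_),
    untriggered = stats::setNames(rep(NA_character_, sum(per_rule == 0L)),
                                  names(per_rule)[per_rule == 0L])
  ), class = "rc_cohort_report")
}

#' @export
print.rc_cohort_report <- function(x, ...) {
  cat(sprintf("<cohort report> %d participants, %d recommendations generated (median %s, IQR %s-%s, max %s per participant)\n",
              x$n_participants, x$total_recommendations,
              format(x$per_patient_summary$median),
              format(x$per_patient_summary$iqr[1]), format(x$per_patient_summary$iqr[2]),
              format(x$per_patient_summary$max)))
  cat(sprintf("rules fired at least once: %d/%d (%.1f%%)\n",
              x$n_rules_fired_at_least_once, length(x$per_rule_fire_counts),
              100 * x$fraction_rules_fired))
  invisible(x)
}

#' Classify why rules never fired on a cohort
#'
#' Assigns each untriggered rule exactly one reason, in fixed precedence
#' order: `out_of_scope` (the rule's target group is outside the configured
#' study scope), then `unavailable_variable` (the condition references a
#' variable the mapping cannot feed), then `unsatisfiable` (no fully known
#' assignment can make the condition true), then `no_matching_participant`
#' (the residual: the data simply contained nobody with all the required
#' characteristics).
#'
#' @param kb a knowledge base.
#' @param report an [run_cohort()] report.
#' @param mapping the [variable_mapping()] used (or a character vector of
#'   feedable variable ids).
#' @param scope character vector of target groups inside the study scope
#'   (rules targeting `"all"` are always in scope).
#' @return the report with `untriggered` filled: named character vector
#'   rule_id -> reason.
#' @export
classify_untriggered <- function(kb, report, mapping, scope = TARGET_GROUPS) {
  fed <- if (inherits(mapping, "rc_mapping")) mapped_variables(mapping) else as.character(mapping)
  reasons <- report$untriggered
  for (rid in names(reasons)) {
    ru <- kb$rules[[rid]]
    if (!ru$target_group %in% unique(c("all", scope))) {
      reasons[[rid]] <- "out_of_scope"
    } else if (length(setdiff(cond_vars(ru$condition), fed))) {
      reasons[[rid]] <- "unavailable_variable"
    } else {
      sat <- check_satisfiability(ru$condition, kb$variables)
      reasons[[rid]] <- if (isFALSE(sat$satisfiable)) "unsatisfiable"
                        else "no_matching_participant"
    }
  }
  report$untriggered <- reasons
  report
}

# ---------------------------------------------------------------------------
# Engine-vs-reference consistency check
#
# The production route is the package pipeline: strict normalization
# (apply_mapping) + canonicalized-tree evaluation (trigger_rules). The
# reference route is deliberately independent: a lenient value reader
# (tolerates comma decimals, trailing unit text and stray capitalization),
# a fresh re-parse of each rule's condition text, and a numerically coded
# Kleene evaluator (TRUE=1, UNKNOWN=0.5, FALSE=0; AND=min, OR=max,
# NOT=1-x). On cleanly formatted data the two routes must agree exactly;
# formatting corruption shows up as missed recommendations traced to the
# affected variables.

lenient_read_value <- function(vdef, raw) {
  if (is.na(raw)) return(NULL)
  s <- trimws(as.character(raw))
  if (!nzchar(s)) return(NULL)
  switch(vdef$kind,
    numeric = {
      s2 <- gsub(",", ".", s, fixed = TRUE)       # comma decimal separator
      s2 <- sub("^([+-]?[0-9.eE+-]+).*$", "\\1", s2)  # strip trailing unit text
      x <- suppressWarnings(as.numeric(s2))
      if (is.na(x)) NULL else x
    },
    boolean = {
      key <- tolower(s)
      if (key %in% c("true", "yes", "1")) TRUE
      else if (key %in% c("false", "no", "0")) FALSE
      else NULL
    },
    categorical = ,
    ordinal = {
      hit <- which(tolower(vdef$allowed_values) == tolower(s))
      if (length(hit)) vdef$allowed_values[hit[1]] else NULL
    },
    NULL)
}

kleene_code <- function(p, values, registry) {
  v <- tryCatch(eval_pred(p, values, registry), error = function(e) NA)
  if (is.na(v)) 0.5 else if (v) 1 else 0
}

reference_eval <- function(node, values, registry) {
  switch(node$kind,
    pred = kleene_code(node, values, registry),
    not = 1 - reference_eval(node$children[[1]], values, registry),
    and = min(vapply(node$children, reference_eval, 0, values = values,
                     registry = registry)),
    or = max(vapply(node$children, reference_eval, 0, values = values,
                    registry = registry)))
}

#' Cross-check the production pipeline against a reference evaluator
#'
#' Runs the full production path (strict normalization + engine) and an
#' independent reference route (lenient value reading, fresh condition
#' re-parse, numerically coded Kleene evaluation) on the same cohort table,
#' and compares the fired sets per (patient, rule).
#'
#' @param kb a knowledge base.
#' @param cohort cohort data.frame.
#' @param mapping an [variable_mapping()] (identity-style transforms are
#'   applied on both routes; the routes differ in value normalization and
#'   evaluation machinery).
#' @return list with `missed` (data.frame patient_id/rule_id/variables:
#'   reference fired but production did not, traced to the variables whose
#'   readings differ), `spurious` (production fired but reference did not),
#'   and `agreement` (|intersection| / |union| of the two fired sets; 1 when
#'   both are empty).
#' @export
consistency_check <- function(kb, cohort, mapping) {
  records <- apply_mapping(cohort, mapping, kb)
  registry <- kb$variables
  ref_conditions <- lapply(kb$rules, function(ru) parse_condition(ru$condition_text))
  cond_texts <- vapply(kb$rules, function(ru) ru$condition_text, "")
  ids <- vapply(records, function(r) r$patient_id, "")

  rule_pr <- vapply(kb$rules, function(ru) ru$pr_id, "")
  pr_rec <- vapply(kb$personalized, function(p) p$rec_id, "")
  rule_rec <- unname(pr_rec[match(rule_pr, names(kb$personalized))])
  excluded_recs <- names(kb$recommendations)[vapply(kb$recommendations,
    function(r) isTRUE(r$excluded), TRUE)]
  active_idx <- which(is.na(rule_rec) | !rule_rec %in% excluded_recs)
  rule_ids <- names(kb$rules)

  missed <- list(); spurious <- list()
  n_both <- 0L; n_union <- 0L

  for (i in seq_along(records)) {
    prod_res <- trigger_rules(kb, records[[i]])
    prod_fired <- prod_res$fired$rule_id

    # reference route rebuilds values from the raw table row
    row <- cohort[i, , drop = FALSE]
    ref_values <- list()
    for (e in mapping$entries) {
      raw <- tryCatch(apply_transform(e, row), error = function(err) NULL)
      if (is.null(raw) || length(raw) != 1L) next
      val <- lenient_read_value(registry[[e$var_id]], raw)
      if (!is.null(val)) ref_values[[e$var_id]] <- val
    }
    ref_fired <- character(0)
    ref_cache <- new.env(parent = emptyenv())
    for (k in active_idx) {
      key <- cond_texts[k]
      code <- if (exists(key, envir = ref_cache, inherits = FALSE)) {
        get(key, envir = ref_cache)
      } else {
        v <- reference_eval(ref_conditions[[k]], ref_values, registry)
        assign(key, v, envir = ref_cache)
        v
      }
      if (code == 1) ref_fired <- c(ref_fired, rule_ids[k])
    }

    both <- intersect(prod_fired, ref_fired)
    n_both <- n_both + length(both)
    n_union <- n_union + length(union(prod_fired, ref_fired))
    for (rid in setdiff(ref_fired, prod_fired)) {
      vars <- cond_vars(kb$rules[[rid]]$condition)
      diff_vars <- vars[vapply(vars, function(v) {
        !identical(records[[i]]$values[[v]], ref_values[[v]])
      }, TRUE)]
      missed[[length(missed) + 1L]] <- data.frame(
        patient_id = ids[i], rule_id = rid,
        variables = paste(diff_vars, collapse = ";"), stringsAsFactors = FALSE)
    }
    for (rid in setdiff(prod_fired, ref_fired)) {
      spurious[[length(spurious) + 1L]] <- data.frame(
        patient_id = ids[i], rule_id = rid, stringsAsFactors = FALSE)
    }
  }
  empty_missed <- data.frame(patient_id = character(0), rule_id = character(0),
                             variables = character(0), stringsAsFactors = FALSE)
  empty_spur <- data.frame(patient_id = character(0), rule_id = character(0),
                           stringsAsFactors = FALSE)
  list(
    missed = if (length(missed)) do.call(rbind, missed) else empty_missed,
    spurious = if (length(spurious)) do.call(rbind, spurious) else empty_spur,
    agreement = if (n_union == 0L) 1 else n_both / n_union
  )
}

# ---------------------------------------------------------------------------
# Clinical-adequacy review annotations
#
# Reviewing whether a triggered recommendation was clinically adequate for a
# given patient is expert judgment; the package only gives that judgment a
# structured, attachable form.

#' Annotate a triggered recommendation with a reviewer verdict
#'
#' @param patient_id,pr_id the (participant, personalized recommendation)
#'   pair under review.
#' @param reviewer reviewer identity (free text, non-empty).
#' @param verdict one of `"correct"`, `"needs_improvement"`, `"incorrect"`.
#' @param suggestion improvement text; required unless the verdict is
#'   `"correct"`.
#' @return list of class `rc_review`.
#' @export
adequacy_review <- function(patient_id, pr_id, reviewer, verdict,
                            suggestion = NULL) {
  verdict <- match.arg(verdict, c("correct", "needs_improvement", "incorrect"))
  if (!chr1(reviewer) || !nzchar(reviewer)) stop("reviewer must be non-empty")
  if (verdict != "correct" && (!chr1(suggestion) || !nzchar(suggestion))) {
    stop("a '", verdict, "' verdict requires a suggestion")
  }
  structure(list(patient_id = patient_id, pr_id = pr_id, reviewer = reviewer,
                 verdict = verdict, suggestion = suggestion),
            class = "rc_review")
}

#' Attach adequacy reviews to a cohort report and summarize them
#'
#' @param report an [run_cohort()] report.
#' @param reviews list of [adequacy_review()]s.
#' @return the report with a `reviews` element and a `review_summary` table
#'   (counts per verdict).
#' @export
annotate_report <- function(report, reviews) {
  for (r in reviews) stopifnot(inherits(r, "rc_review"))
  report$reviews <- reviews
  report$review_summary <- count_field(reviews, "verdict")
  report
}
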