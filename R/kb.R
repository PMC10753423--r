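# Knowledge-base domain types, validation, descriptive statistics and
# serialization. A knowledge base bundles source recommendations (guideline
# provenance + evidence metadata), plain-language personalized
# recommendations, a typed variable registry, logical rules, and the
# harmonized-level-of-evidence crosswalk.

KB_SCHEMA <- "cord-kb/1"

SOURCE_DOC_TYPES <- c("international_guideline", "national_guideline", "other")
TARGET_GROUPS <- c("all", "asthma", "copd", "healthy", "rhinitis")
HLE_LEVELS <- c("A", "B", "C", "D")
VAR_KINDS <- c("boolean", "numeric", "categorical", "ordinal", "timeseries")
DATA_SOURCES <- c("self_report", "sensor", "external", "derived")
DELIVERY_FORMATS <- c("text", "image", "video", "link")

# domain -> subdomain nesting of the knowledge areas covered by the KB
DOMAIN_SUBDOMAINS <- list(
  chronic_respiratory_disease = "symptoms",
  concomitant_diseases = c("food_allergy", "rhinitis", "respiratory_infections",
                           "sleep_disorders"),
  exposure_to_external_agents = c("allergens", "occupational_hazards",
                                  "smoking_habits", "atmospheric_pollution"),
  nonpharmacological_therapies = c("breathing_exercises_and_airway_clearance",
                                   "physical_activity_and_exercise",
                                   "oxygen_therapy_and_ventilatory_support"),
  pharmacological_therapies = c("adherence_and_inhaler_technique",
                                "devices_and_active_principles", "vaccinations"),
  others = c("anxiety_depression_stress", "nutrition")
)

chr1 <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Create a source recommendation
#'
#' A guideline-derived recommendation with its provenance and evidence
#' metadata. All fields are mandatory except the original level of evidence
#' and the harmonized level of evidence (HLE), which are absent (`NULL`) when
#' the source document reports none.
#'
#' @param rec_id opaque identifier, unique within the KB.
#' @param source_doc_type one of `"international_guideline"`,
#'   `"national_guideline"`, `"other"`.
#' @param original_text verbatim recommendation text from the source.
#' @param page page reference in the source document (text).
#' @param source_ref citation key of the source document.
#' @param domain,subdomain knowledge domain/subdomain (see
#'   `respcoach:::DOMAIN_SUBDOMAINS`).
#' @param target_group one of `"all"`, `"asthma"`, `"copd"`, `"healthy"`,
#'   `"rhinitis"`.
#' @param source_priority integer 1 (highest) to 3 (lowest).
#' @param original_loe level of evidence as printed in the source, or `NULL`.
#' @param hle harmonized level of evidence `"A"`..`"D"`, or `NULL`.
#' @param excluded logical; excluded recommendations stay in the KB with a
#'   rationale but their rules are never fired.
#' @param exclusion_rationale text, required when `excluded` is `TRUE`.
#' @return list of class `rc_recommendation`.
#' @export
source_recommendation <- function(rec_id, source_doc_type, original_text, page,
                                  source_ref, domain, subdomain, target_group,
                                  source_priority, original_loe = NULL,
                                  hle = NULL, excluded = FALSE,
                                  exclusion_rationale = NULL) {
  structure(list(
    rec_id = rec_id, source_doc_type = source_doc_type,
    original_text = original_text, page = as.character(page),
    source_ref = source_ref, original_loe = original_loe, hle = hle,
    domain = domain, subdomain = subdomain, target_group = target_group,
    source_priority = as.integer(source_priority),
    excluded = isTRUE(excluded), exclusion_rationale = exclusion_rationale
  ), class = "rc_recommendation")
}

#' Create a personalized recommendation
#'
#' The plain-language, actionable adaptation of a source recommendation,
#' delivered to the patient when its rule fires.
#'
#' @param pr_id opaque identifier, unique within the KB.
#' @param rec_id id of the source recommendation it adapts.
#' @param plain_text plain-language text sent to the patient.
#' @param priority integer 1 (highest) to 5 (lowest); drives delivery order.
#' @param delivery_formats subset of `"text"`, `"image"`, `"video"`, `"link"`.
#' @param cluster_id optional overlap-cluster label used by delivery
#'   throttling; `NULL` means no cluster.
#' @return list of class `rc_personalized`.
#' @export
personalized_recommendation <- function(pr_id, rec_id, plain_text, priority,
                                        delivery_formats = "text",
                                        cluster_id = NULL) {
  structure(list(
    pr_id = pr_id, rec_id = rec_id, plain_text = plain_text,
    delivery_formats = as.character(delivery_formats),
    priority = as.integer(priority), cluster_id = cluster_id
  ), class = "rc_personalized")
}

#' Declare a knowledge-base variable
#'
#' A typed, unit-annotated patient datum. Categorical and ordinal variables
#' must declare their allowed values (ordinal order = declaration order).
#' Time-series variables cannot be referenced by predicates directly; instead
#' a derived variable (kind boolean or categorical, `data_source "derived"`)
#' carries a `derived` specification that the engine materializes from the
#' patient's series before rule evaluation (see [detect_change()] and
#' [series_trend()]).
#'
#' @param var_id opaque identifier, unique within the KB.
#' @param kind one of `"boolean"`, `"numeric"`, `"categorical"`, `"ordinal"`,
#'   `"timeseries"`.
#' @param definition human-readable definition (mandatory).
#' @param data_source one of `"self_report"`, `"sensor"`, `"external"`,
#'   `"derived"`.
#' @param units unit annotation or `NULL`.
#' @param allowed_values character vector, required iff `kind` is
#'   categorical/ordinal.
#' @param derived optional derivation spec: a list with `type` (`"change"` or
#'   `"trend"`), `series_var`, and for changes `mode`/`direction`/`threshold`/
#'   `window` (see [change_spec()]), for trends `window`, `higher_is_better`,
#'   `dead_band`.
#' @return list of class `rc_variable`.
#' @export
kb_variable <- function(var_id, kind, definition, data_source = "self_report",
                        units = NULL, allowed_values = NULL, derived = NULL) {
  if (!is.null(derived)) {
    for (f in c("threshold", "window_months", "window_days", "dead_band")) {
      if (!is.null(derived[[f]])) derived[[f]] <- as.numeric(derived[[f]])
    }
    if (!is.null(derived$higher_is_better)) {
      derived$higher_is_better <- isTRUE(derived$higher_is_better)
    }
  }
  structure(list(
    var_id = var_id, kind = kind, units = units,
    allowed_values = if (is.null(allowed_values)) NULL else as.character(allowed_values),
    data_source = data_source, definition = definition, derived = derived
  ), class = "rc_variable")
}

#' Create a logical rule
#'
#' Binds one personalized recommendation to one target group and one logical
#' condition over registry variables. The rule fires for a patient when its
#' condition evaluates to TRUE under three-valued semantics.
#'
#' @param rule_id opaque identifier, unique within the KB.
#' @param pr_id id of the personalized recommendation this rule triggers.
#' @param target_group one of the target-group labels.
#' @param condition a condition node or a character string in the condition
#'   grammar (parsed immediately).
#' @return list of class `rc_rule`.
#' @export
kb_rule <- function(rule_id, pr_id, target_group, condition) {
  if (is.character(condition)) {
    condition <- parse_condition(condition)
  } else {
    stopifnot(inherits(condition, "rc_cond"))
  }
  condition_text <- cond_to_text(condition)  # normalized spelling: stable under round-trips
  structure(list(
    rule_id = rule_id, pr_id = pr_id, target_group = target_group,
    condition_text = condition_text, condition = condition
  ), class = "rc_rule")
}

#' Assemble a knowledge base
#'
#' Bundles entities into a versioned knowledge base. The constructor is
#' permissive; call [validate_kb()] for the full invariant check (loading via
#' [load_kb()] validates automatically).
#'
#' @param version version string (dotted integers, e.g. `"1.0"`).
#' @param recommendations list of [source_recommendation()]s.
#' @param personalized list of [personalized_recommendation()]s.
#' @param variables list of [kb_variable()]s.
#' @param rules list of [kb_rule()]s.
#' @param hle_map evidence-level crosswalk: data.frame with columns
#'   `source_ref`, `original_loe`, `hle`. On top of it, [harmonize_level()]
#'   applies an identity mapping for levels already graded A-D.
#' @param created creation timestamp (ISO 8601 string).
#' @return list of class `rc_kb`.
#' @export
knowledge_base <- function(version = "1.0", recommendations = list(),
                           personalized = list(), variables = list(),
                           rules = list(), hle_map = NULL,
                           created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) {
  if (is.null(hle_map)) {
    hle_map <- data.frame(source_ref = character(0), original_loe = character(0),
                          hle = character(0), stringsAsFactors = FALSE)
  }
  kb <- structure(list(
    schema = KB_SCHEMA, version = version, created = created,
    recommendations = set_entity_names(recommendations, "rec_id"),
    personalized = set_entity_names(personalized, "pr_id"),
    variables = set_entity_names(variables, "var_id"),
    rules = set_entity_names(rules, "rule_id"),
    hle_map = hle_map
  ), class = "rc_kb")
  kb
}

set_entity_names <- function(x, id_field) {
  if (!length(x)) return(stats::setNames(list(), character(0)))
  names(x) <- vapply(x, function(e) as.character(e[[id_field]]), "")
  x
}

#' @export
print.rc_kb <- function(x, ...) {
  cat(sprintf("<knowledge base %s> version %s: %d recommendations, %d personalized, %d variables, %d rules\n",
              x$schema, x$version, length(x$recommendations), length(x$personalized),
              length(x$variables), length(x$rules)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Validation

issue <- function(severity, entity, message) {
  data.frame(severity = severity, entity = entity, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a knowledge base
#'
#' Checks every structural invariant and returns the violations as a data
#' frame; it reports and never throws. A KB with zero error-severity issues
#' satisfies all type invariants. Absent original level of evidence / HLE is
#' not an issue (those fields are the only optional extraction fields).
#'
#' @param kb a knowledge base.
#' @return data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `entity` (id), `message`; zero rows iff the KB is valid.
#' @export
validate_kb <- function(kb) {
  iss <- list()
  add <- function(severity, entity, message) {
    iss[[length(iss) + 1L]] <<- issue(severity, entity, message)
  }
  if (!chr1(kb$version) || !nzchar(kb$version)) {
    add("error", "<kb>", "version must be a non-empty string")
  }

  vids <- names(kb$variables)
  dup <- unique(vids[duplicated(vids)])
  for (d in dup) add("error", d, sprintf("duplicate variable id '%s'", d))
  for (v in kb$variables) {
    id <- v$var_id
    if (!chr1(id) || !nzchar(id)) { add("error", "<variable>", "variable with empty id"); next }
    if (!chr1(v$kind) || !v$kind %in% VAR_KINDS) {
      add("error", id, sprintf("invalid variable kind '%s'", paste(v$kind, collapse = "/")))
      next
    }
    if (v$kind %in% c("categorical", "ordinal")) {
      if (!length(v$allowed_values)) {
        add("error", id, "categorical/ordinal variable must declare allowed_values")
      } else if (anyDuplicated(v$allowed_values)) {
        add("error", id, "allowed_values must be distinct")
      }
    } else if (length(v$allowed_values)) {
      add("error", id, "allowed_values only permitted for categorical/ordinal variables")
    }
    if (!chr1(v$data_source) || !v$data_source %in% DATA_SOURCES) {
      add("error", id, "invalid data_source")
    }
    if (!chr1(v$definition) || !nzchar(v$definition)) {
      add("error", id, "mandatory field 'definition' is missing or empty")
    }
    if (!is.null(v$derived)) {
      d <- v$derived
      sv <- kb$variables[[d$series_var %||% ""]]
      if (is.null(sv)) {
        add("error", id, sprintf("derived variable references undeclared series '%s'",
                                 d$series_var %||% "<none>"))
      } else if (sv$kind != "timeseries") {
        add("error", id, sprintf("derived variable's source '%s' is not a time series", sv$var_id))
      }
      if (!identical(d$type, "change") && !identical(d$type, "trend")) {
        add("error", id, "derived spec type must be 'change' or 'trend'")
      }
    }
  }
  registry <- kb$variables

  rids <- names(kb$recommendations)
  for (d in unique(rids[duplicated(rids)])) {
    add("error", d, sprintf("duplicate recommendation id '%s'", d))
  }
  for (r in kb$recommendations) {
    id <- r$rec_id %||% "<recommendation>"
    for (f in c("rec_id", "original_text", "page", "source_ref")) {
      if (!chr1(r[[f]]) || !nzchar(r[[f]])) {
        add("error", id, sprintf("mandatory field '%s' is missing or empty", f))
      }
    }
    if (!chr1(r$source_doc_type) || !r$source_doc_type %in% SOURCE_DOC_TYPES) {
      add("error", id, "invalid source_doc_type")
    }
    if (!is.null(r$hle) && (!chr1(r$hle) || !r$hle %in% HLE_LEVELS)) {
      add("error", id, "hle must be one of A, B, C, D, or absent")
    }
    if (!chr1(r$domain) || !r$domain %in% names(DOMAIN_SUBDOMAINS)) {
      add("error", id, sprintf("invalid domain '%s'", paste(r$domain, collapse = "/")))
    } else if (!chr1(r$subdomain) || !r$subdomain %in% DOMAIN_SUBDOMAINS[[r$domain]]) {
      add("error", id, sprintf("subdomain '%s' is not valid for domain '%s'",
                               paste(r$subdomain, collapse = "/"), r$domain))
    }
    if (!chr1(r$target_group) || !r$target_group %in% TARGET_GROUPS) {
      add("error", id, "invalid target_group")
    }
    if (!is.numeric(r$source_priority) || length(r$source_priority) != 1L ||
        !r$source_priority %in% 1:3) {
      add("error", id, "source_priority must be 1, 2 or 3")
    }
    if (isTRUE(r$excluded) && (!chr1(r$exclusion_rationale) || !nzchar(r$exclusion_rationale))) {
      add("error", id, "excluded recommendation requires an exclusion_rationale")
    }
  }

  pids <- names(kb$personalized)
  for (d in unique(pids[duplicated(pids)])) {
    add("error", d, sprintf("duplicate personalized recommendation id '%s'", d))
  }
  for (p in kb$personalized) {
    id <- p$pr_id %||% "<personalized>"
    if (is.null(kb$recommendations[[p$rec_id %||% ""]])) {
      add("error", id, sprintf("rec_id '%s' does not resolve", p$rec_id %||% "<none>"))
    }
    if (!chr1(p$plain_text) || !nzchar(p$plain_text)) {
      add("error", id, "plain_text is missing or empty")
    }
    if (!is.numeric(p$priority) || length(p$priority) != 1L || !p$priority %in% 1:5) {
      add("error", id, "priority must be an integer in 1..5")
    }
    if (!length(p$delivery_formats) || !all(p$delivery_formats %in% DELIVERY_FORMATS)) {
      add("error", id, "delivery_formats must be a non-empty subset of text/image/video/link")
    }
  }

  ruids <- names(kb$rules)
  for (d in unique(ruids[duplicated(ruids)])) {
    add("error", d, sprintf("duplicate rule id '%s'", d))
  }
  seen_pair <- character(0)
  for (ru in kb$rules) {
    id <- ru$rule_id %||% "<rule>"
    if (is.null(kb$personalized[[ru$pr_id %||% ""]])) {
      add("error", id, sprintf("pr_id '%s' does not resolve", ru$pr_id %||% "<none>"))
    }
    if (!chr1(ru$target_group) || !ru$target_group %in% TARGET_GROUPS) {
      add("error", id, "invalid target_group")
    }
    pair <- paste0(ru$pr_id, "\r", ru$target_group)
    if (pair %in% seen_pair) {
      add("error", id, sprintf(
        "duplicate rule for personalized recommendation '%s' and target group '%s'",
        ru$pr_id, ru$target_group))
    }
    seen_pair <- c(seen_pair, pair)
    if (!inherits(ru$condition, "rc_cond")) {
      add("error", id, "rule has no parsed condition")
    } else {
      for (msg in check_condition(ru$condition, registry, sprintf("rule '%s'", id))) {
        add("error", id, msg)
      }
    }
  }

  hm <- kb$hle_map
  if (nrow(hm)) {
    bad <- !hm$hle %in% HLE_LEVELS
    for (i in which(bad)) {
      add("error", "<hle_map>", sprintf("hle_map entry (%s, %s) maps to invalid level '%s'",
                                        hm$source_ref[i], hm$original_loe[i], hm$hle[i]))
    }
  }

  if (!length(iss)) {
    return(data.frame(severity = character(0), entity = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, iss)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Harmonize a source level of evidence
#'
#' Maps a source document's original evidence grading onto the harmonized
#' A-D scale: an absent original level stays absent; otherwise the KB's
#' crosswalk (`hle_map`) is consulted; original levels already graded A-D
#' map to themselves by default; anything else is absent.
#'
#' @param kb a knowledge base (its `hle_map` is used).
#' @param source_ref citation key of the source document.
#' @param original_loe original level of evidence, or `NULL`/`NA` for absent.
#' @return `"A"`, `"B"`, `"C"`, `"D"`, or `NA_character_` for absent.
#' @export
harmonize_level <- function(kb, source_ref, original_loe = NULL) {
  if (is.null(original_loe) || length(original_loe) != 1L || is.na(original_loe) ||
      !nzchar(original_loe)) {
    return(NA_character_)
  }
  hm <- kb$hle_map
  hit <- which(hm$source_ref == source_ref & hm$original_loe == original_loe)
  if (length(hit)) return(hm$hle[hit[1]])
  if (original_loe %in% HLE_LEVELS) return(original_loe)
  NA_character_
}

# ---------------------------------------------------------------------------
# Descriptive statistics

hist_bucket <- function(x, breaks_lo, labels) {
  # breaks_lo: lower bound of each bucket (ascending); x assigned to the last
  # bucket whose lower bound it reaches
  idx <- findInterval(x, breaks_lo)
  counts <- tabulate(idx, nbins = length(labels))
  stats::setNames(as.integer(counts), labels)
}

summary_stats <- function(x) {
  if (!length(x)) {
    return(list(mean = NA_real_, sd = NA_real_, min = NA_real_, max = NA_real_))
  }
  list(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0,
       min = min(x), max = max(x))
}

#' Descriptive statistics of a knowledge base
#'
#' Entity counts; rules per recommendation; distinct variables per rule;
#' variable usage (number of rules whose condition references the variable)
#' bucketed as 1 / 2-3 / 4-10 / >10; unique logical conditions (canonical
#' forms) and their reuse bucketed as 1 / 2-3 / >=4; and counts by domain,
#' subdomain, target group, HLE, source priority and personalized priority.
#'
#' @param kb a valid knowledge base.
#' @return list of class `rc_kb_stats`.
#' @export
kb_stats <- function(kb) {
  rules <- kb$rules
  n_rules <- length(rules)

  # rules per recommendation, through the personalized link
  rule_rec <- vapply(rules, function(ru) {
    pr <- kb$personalized[[ru$pr_id]]
    if (is.null(pr)) NA_character_ else pr$rec_id
  }, "")
  rec_counts <- if (length(kb$recommendations)) {
    cnt <- table(factor(rule_rec, levels = names(kb$recommendations)))
    stats::setNames(as.integer(cnt), names(cnt))
  } else {
    integer(0)
  }

  cond_keys <- vapply(rules, function(ru) condition_key(ru$condition), "")
  vars_per_rule <- vapply(rules, function(ru) length(cond_vars(ru$condition)), 1L)

  usage <- stats::setNames(integer(length(kb$variables)), names(kb$variables))
  for (ru in rules) {
    vs <- cond_vars(ru$condition)
    usage[vs] <- usage[vs] + 1L
  }
  used <- usage[usage > 0L]

  reuse <- if (n_rules) as.integer(table(cond_keys)) else integer(0)

  vpr_hist <- if (n_rules) {
    stats::setNames(tabulate(vars_per_rule, nbins = max(vars_per_rule)),
                    as.character(seq_len(max(vars_per_rule))))
  } else {
    integer(0)
  }

  out <- list(
    n_recommendations = length(kb$recommendations),
    n_excluded_recommendations = sum(vapply(kb$recommendations,
                                            function(r) isTRUE(r$excluded), TRUE)),
    n_personalized = length(kb$personalized),
    n_rules = n_rules,
    n_variables = length(kb$variables),
    n_unique_conditions = length(unique(cond_keys)),
    rules_per_recommendation = c(
      summary_stats(if (length(rec_counts)) as.numeric(rec_counts) else numeric(0)),
      list(histogram = if (length(rec_counts) && any(rec_counts > 0)) {
        stats::setNames(tabulate(rec_counts, nbins = max(rec_counts)),
                        as.character(seq_len(max(rec_counts))))
      } else integer(0))),
    vars_per_rule = c(summary_stats(as.numeric(vars_per_rule)),
                      list(histogram = vpr_hist)),
    variable_usage_histogram = hist_bucket(as.numeric(used), c(1, 2, 4, 11),
                                           c("1", "2-3", "4-10", ">10")),
    n_unused_variables = sum(usage == 0L),
    condition_reuse_histogram = hist_bucket(as.numeric(reuse), c(1, 2, 4),
                                            c("1", "2-3", "4+")),
    max_condition_reuse = if (length(reuse)) max(reuse) else 0L,
    by_domain = count_field(kb$recommendations, "domain"),
    by_subdomain = count_field(kb$recommendations, "subdomain"),
    by_target_group = count_field(kb$rules, "target_group"),
    by_hle = count_field(kb$recommendations, "hle", absent = "absent"),
    by_source_priority = count_field(kb$recommendations, "source_priority"),
    by_priority = count_field(kb$personalized, "priority")
  )
  structure(out, class = "rc_kb_stats")
}

count_field <- function(entities, field, absent = NULL) {
  vals <- vapply(entities, function(e) {
    v <- e[[field]]
    if (is.null(v)) absent %||% NA_character_ else as.character(v)
  }, "")
  if (!length(vals)) return(stats::setNames(integer(0), character(0)))
  tb <- table(vals)
  stats::setNames(as.integer(tb), names(tb))
}

#' @export
print.rc_kb_stats <- function(x, ...) {
  cat(sprintf("recommendations: %d (%d excluded), personalized: %d, rules: %d, variables: %d, unique conditions: %d\n",
              x$n_recommendations, x$n_excluded_recommendations, x$n_personalized,
              x$n_rules, x$n_variables, x$n_unique_conditions))
  cat(sprintf("rules/recommendation: mean %.2f sd %.2f max %s\n",
              x$rules_per_recommendation$mean, x$rules_per_recommendation$sd,
              format(x$rules_per_recommendation$max)))
  cat(sprintf("variables/rule: mean %.2f sd %.2f range %s..%s\n",
              x$vars_per_rule$mean, x$vars_per_rule$sd,
              format(x$vars_per_rule$min), format(x$vars_per_rule$max)))
  cat("variable usage buckets: ",
      paste(names(x$variable_usage_histogram), x$variable_usage_histogram,
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("condition reuse buckets: ",
      paste(names(x$condition_reuse_histogram), x$condition_reuse_histogram,
            sep = "=", collapse = ", "),
      " (max ", x$max_condition_reuse, ")\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Serialization (UTF-8 JSON, schema "cord-kb/1", deterministic key order)

kb_to_plain <- function(kb) {
  ord <- function(x) x[order(names(x), method = "radix")]
  list(
    meta = list(schema = KB_SCHEMA, version = kb$version, created = kb$created),
    variables = unname(lapply(ord(kb$variables), function(v) {
      drop_null(list(var_id = v$var_id, kind = v$kind, units = v$units,
                     allowed_values = v$allowed_values,
                     data_source = v$data_source, definition = v$definition,
                     derived = v$derived))
    })),
    recommendations = unname(lapply(ord(kb$recommendations), function(r) {
      drop_null(list(rec_id = r$rec_id, source_doc_type = r$source_doc_type,
                     original_text = r$original_text, page = r$page,
                     source_ref = r$source_ref, original_loe = r$original_loe,
                     hle = r$hle, domain = r$domain, subdomain = r$subdomain,
                     target_group = r$target_group,
                     source_priority = r$source_priority,
                     excluded = if (isTRUE(r$excluded)) TRUE else NULL,
                     exclusion_rationale = r$exclusion_rationale))
    })),
    personalized = unname(lapply(ord(kb$personalized), function(p) {
      drop_null(list(pr_id = p$pr_id, rec_id = p$rec_id,
                     plain_text = p$plain_text,
                     delivery_formats = as.list(p$delivery_formats),
                     priority = p$priority, cluster_id = p$cluster_id))
    })),
    rules = unname(lapply(ord(kb$rules), function(ru) {
      list(rule_id = ru$rule_id, pr_id = ru$pr_id,
           target_group = ru$target_group, condition = ru$condition_text)
    })),
    hle_map = if (nrow(kb$hle_map)) {
      lapply(seq_len(nrow(kb$hle_map)), function(i) {
        list(source_ref = kb$hle_map$source_ref[i],
             original_loe = kb$hle_map$original_loe[i],
             hle = kb$hle_map$hle[i])
      })
    } else {
      list()
    }
  )
}

drop_null <- function(x) x[!vapply(x, is.null, TRUE)]

#' Write a knowledge base to a file
#'
#' Serializes to the UTF-8 JSON dialect (`schema "cord-kb/1"`); entities are
#' emitted sorted by id and with a fixed key order so that files are stable
#' under diff. Conditions are stored as text in the rule grammar.
#' Round-trip guarantee: `load_kb(save_kb(kb, path))` is structurally equal
#' to `kb`.
#'
#' @param kb a valid knowledge base.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_kb <- function(kb, path) {
  stopifnot(inherits(kb, "rc_kb"))
  json <- jsonlite::toJSON(kb_to_plain(kb), auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, useBytes = TRUE)
  invisible(path)
}

#' Read and validate a knowledge base file
#'
#' Parses the JSON dialect written by [save_kb()], reconstructs every entity
#' (conditions are re-parsed from their textual form) and runs
#' [validate_kb()]. Any error-severity issue aborts the load with a message
#' listing every violated invariant and the offending entity ids.
#'
#' @param path path to a KB file.
#' @return a validated knowledge base.
#' @export
load_kb <- function(path) {
  if (!file.exists(path)) stop("KB file not found: ", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("KB parse error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  meta <- raw$meta
  if (!identical(meta$schema, KB_SCHEMA)) {
    stop("KB parse error: unsupported schema '", meta$schema %||% "<none>",
         "' (expected '", KB_SCHEMA, "')")
  }
  as_chr_or_null <- function(x) if (is.null(x)) NULL else as.character(x)
  variables <- lapply(raw$variables, function(v) {
    kb_variable(v$var_id, v$kind, v$definition %||% "",
                data_source = v$data_source %||% "self_report",
                units = as_chr_or_null(v$units),
                allowed_values = if (is.null(v$allowed_values)) NULL else
                  unlist(v$allowed_values),
                derived = v$derived)
  })
  recommendations <- lapply(raw$recommendations, function(r) {
    source_recommendation(r$rec_id, r$source_doc_type %||% "", r$original_text %||% "",
                          r$page %||% "", r$source_ref %||% "",
                          r$domain %||% "", r$subdomain %||% "",
                          r$target_group %||% "", r$source_priority %||% NA_integer_,
                          original_loe = as_chr_or_null(r$original_loe),
                          hle = as_chr_or_null(r$hle),
                          excluded = isTRUE(r$excluded),
                          exclusion_rationale = as_chr_or_null(r$exclusion_rationale))
  })
  personalized <- lapply(raw$personalized, function(p) {
    personalized_recommendation(p$pr_id, p$rec_id %||% "", p$plain_text %||% "",
                                p$priority %||% NA_integer_,
                                delivery_formats = unlist(p$delivery_formats %||% list("text")),
                                cluster_id = as_chr_or_null(p$cluster_id))
  })
  rules <- lapply(raw$rules, function(ru) {
    cond <- tryCatch(parse_condition(ru$condition),
                     rc_parse_error = function(e) {
                       stop("KB parse error in rule '", ru$rule_id, "': ",
                            conditionMessage(e), call. = FALSE)
                     })
    kb_rule(ru$rule_id, ru$pr_id %||% "", ru$target_group %||% "", cond)
  })
  hm <- if (length(raw$hle_map)) {
    data.frame(
      source_ref = vapply(raw$hle_map, function(e) as.character(e$source_ref), ""),
      original_loe = vapply(raw$hle_map, function(e) as.character(e$original_loe), ""),
      hle = vapply(raw$hle_map, function(e) as.character(e$hle), ""),
      stringsAsFactors = FALSE)
  } else {
    NULL
  }
  kb <- knowledge_base(version = meta$version %||% "1.0",
                       recommendations = recommendations,
                       personalized = personalized, variables = variables,
                       rules = rules, hle_map = hm,
                       created = meta$created %||% "")
  iss <- validate_kb(kb)
  errs <- iss[iss$severity == "error", , drop = FALSE]
  if (nrow(errs)) {
    stop("KB validation failed for '", path, "':\n",
         paste(sprintf("  [%s] %s", errs$entity, errs$message), collapse = "\n"),
         call. = FALSE)
  }
  kb
}

#' Structural equality of two knowledge bases
#'
#' Compares content and version; the creation timestamp is ignored.
#'
#' @param a,b knowledge bases.
#' @return logical scalar.
#' @export
kb_equal <- function(a, b) {
  pa <- kb_to_plain(a); pb <- kb_to_plain(b)
  pa$meta$created <- pb$meta$created <- NULL
  identical(pa, pb)
}
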