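# Versioned knowledge-base updates with an audit trail: single changes are
# applied atomically (the new KB validates or the change is rejected and the
# original is untouched), versions increase monotonically, excluded
# recommendations are flagged rather than deleted, and any two KB versions
# can be diffed into a changelog whose replay reproduces the target.
#
# Personalized recommendations travel with their rule (they are one-to-one):
# add_rule / update_rule / remove_rule payloads may carry a `personalized`
# component. Variables are added or updated, never removed — the registry is
# a harmonized, append-only vocabulary.

CHANGE_ACTIONS <- c("add_recommendation", "update_recommendation",
                    "exclude_recommendation", "add_rule", "update_rule",
                    "remove_rule", "add_variable", "update_variable")

#' Create a changelog entry
#'
#' @param action one of `respcoach:::CHANGE_ACTIONS`.
#' @param target_id id of the affected entity (for `add_rule`, the new rule's
#'   id).
#' @param payload structured diff: the full entity for `add_*`; a named list
#'   of replaced fields for `update_*` (for rules, may contain `condition`
#'   text, `target_group`, and a `personalized` sub-list); nothing for
#'   `remove_rule`; `exclude_recommendation` uses `rationale`.
#' @param editor who makes the change (non-empty free text; access control is
#'   a deployment concern).
#' @param rationale why (non-empty).
#' @param change_id optional id; generated when omitted.
#' @param timestamp ISO timestamp.
#' @return list of class `rc_change`.
#' @export
change_entry <- function(action, target_id, payload = list(), editor = "editor",
                         rationale = "routine update", change_id = NULL,
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) {
  if (!action %in% CHANGE_ACTIONS) stop("unknown change action '", action, "'")
  if (!chr1(editor) || !nzchar(editor)) stop("editor must be non-empty")
  if (!chr1(rationale) || !nzchar(rationale)) stop("rationale must be non-empty")
  structure(list(change_id = change_id %||% paste0("chg_", action, "_", target_id),
                 timestamp = timestamp, editor = editor, action = action,
                 target_id = target_id, payload = payload, rationale = rationale),
            class = "rc_change")
}

change_rejected <- function(entry, why) {
  stop(structure(
    class = c("rc_change_rejected", "error", "condition"),
    list(message = sprintf("change '%s' (%s on '%s') rejected: %s",
                           entry$change_id, entry$action, entry$target_id, why),
         call = NULL, entry = entry)))
}

bump_version <- function(version) {
  parts <- suppressWarnings(as.integer(strsplit(version, ".", fixed = TRUE)[[1]]))
  if (anyNA(parts) || !length(parts)) return(paste0(version, ".1"))
  parts[length(parts)] <- parts[length(parts)] + 1L
  paste(parts, collapse = ".")
}

entity_from_payload <- function(payload, what) {
  switch(what,
    recommendation = do.call(source_recommendation, payload),
    personalized = do.call(personalized_recommendation, payload),
    variable = do.call(kb_variable, payload),
    rule = kb_rule(payload$rule_id, payload$pr_id, payload$target_group,
                   payload$condition))
}

#' Apply one change to a knowledge base
#'
#' Pure and atomic: returns a new KB with a bumped version, or rejects the
#' change (condition class `rc_change_rejected`) leaving the input untouched.
#' A change is rejected when its target is unknown, when the resulting KB
#' would fail [validate_kb()] (all violations are cited), or — for rule
#' additions/updates with `check_sat = TRUE` — when the new condition is
#' unsatisfiable (the diagnostic cites the satisfiability verdict).
#' `exclude_recommendation` never deletes: it sets the excluded flag with the
#' entry's rationale and the recommendation's rules become inert.
#'
#' @param kb a knowledge base.
#' @param entry an [change_entry()].
#' @param check_sat reject rules whose condition cannot be satisfied
#'   (default TRUE).
#' @return the updated knowledge base.
#' @export
apply_change <- function(kb, entry, check_sat = TRUE) {
  stopifnot(inherits(kb, "rc_kb"), inherits(entry, "rc_change"))
  new <- kb
  tid <- entry$target_id
  pl <- entry$payload

  update_fields <- function(entity, fields) {
    for (f in names(fields)) entity[[f]] <- fields[[f]]
    entity
  }

  switch(entry$action,
    add_recommendation = {
      if (!is.null(kb$recommendations[[tid]])) change_rejected(entry, "id already exists")
      new$recommendations[[tid]] <- entity_from_payload(pl, "recommendation")
    },
    update_recommendation = {
      if (is.null(kb$recommendations[[tid]])) change_rejected(entry, "unknown recommendation")
      new$recommendations[[tid]] <- update_fields(kb$recommendations[[tid]], pl)
    },
    exclude_recommendation = {
      if (is.null(kb$recommendations[[tid]])) change_rejected(entry, "unknown recommendation")
      rec <- kb$recommendations[[tid]]
      rec$excluded <- TRUE
      rec$exclusion_rationale <- pl$rationale %||% entry$rationale
      new$recommendations[[tid]] <- rec
    },
    add_variable = {
      if (!is.null(kb$variables[[tid]])) change_rejected(entry, "id already exists")
      new$variables[[tid]] <- entity_from_payload(pl, "variable")
    },
    update_variable = {
      if (is.null(kb$variables[[tid]])) change_rejected(entry, "unknown variable")
      new$variables[[tid]] <- update_fields(kb$variables[[tid]], pl)
    },
    add_rule = {
      if (!is.null(kb$rules[[tid]])) change_rejected(entry, "id already exists")
      if (!is.null(pl$personalized)) {
        pr <- entity_from_payload(pl$personalized, "personalized")
        if (!is.null(kb$personalized[[pr$pr_id]])) {
          change_rejected(entry, "personalized id already exists")
        }
        new$personalized[[pr$pr_id]] <- pr
      }
      rule <- tryCatch(entity_from_payload(pl, "rule"),
                       error = function(e) change_rejected(entry, conditionMessage(e)))
      new$rules[[tid]] <- rule
    },
    update_rule = {
      if (is.null(kb$rules[[tid]])) change_rejected(entry, "unknown rule")
      rule <- kb$rules[[tid]]
      if (!is.null(pl$condition)) {
        rule$condition <- tryCatch(parse_condition(pl$condition),
                                   error = function(e) change_rejected(entry, conditionMessage(e)))
        rule$condition_text <- cond_to_text(rule$condition)
      }
      if (!is.null(pl$target_group)) rule$target_group <- pl$target_group
      if (!is.null(pl$personalized)) {
        pr <- kb$personalized[[rule$pr_id]]
        if (is.null(pr)) change_rejected(entry, "rule's personalized recommendation not found")
        new$personalized[[rule$pr_id]] <- update_fields(pr, pl$personalized)
      }
      new$rules[[tid]] <- rule
    },
    remove_rule = {
      if (is.null(kb$rules[[tid]])) change_rejected(entry, "unknown rule")
      pr_id <- kb$rules[[tid]]$pr_id
      new$rules[[tid]] <- NULL
      # drop the personalized recommendation if no other rule uses it
      still_used <- any(vapply(new$rules, function(ru) ru$pr_id == pr_id, TRUE))
      if (!still_used) new$personalized[[pr_id]] <- NULL
    }
  )

  if (check_sat && entry$action %in% c("add_rule", "update_rule")) {
    rule <- new$rules[[tid]]
    sat <- check_satisfiability(rule$condition, new$variables)
    if (isFALSE(sat$satisfiable)) {
      change_rejected(entry, sprintf(
        "condition '%s' is unsatisfiable (no fully known assignment makes it true)",
        rule$condition_text))
    }
  }

  iss <- validate_kb(new)
  errs <- iss[iss$severity == "error", , drop = FALSE]
  if (nrow(errs)) {
    change_rejected(entry, paste0("resulting KB would be invalid:\n",
      paste(sprintf("  [%s] %s", errs$entity, errs$message), collapse = "\n")))
  }
  new$version <- bump_version(kb$version)
  new
}

#' Assemble a changelog
#'
#' @param base_version version the entries apply to.
#' @param entries list of [change_entry()]s.
#' @param result_version version after replay.
#' @return list of class `rc_changelog`.
#' @export
changelog <- function(base_version, entries = list(), result_version = NULL) {
  structure(list(base_version = base_version, entries = entries,
                 result_version = result_version),
            class = "rc_changelog")
}

#' @export
print.rc_changelog <- function(x, ...) {
  cat(sprintf("<changelog> %s -> %s, %d entries\n", x$base_version,
              x$result_version %||% "?", length(x$entries)))
  for (e in x$entries) {
    cat(sprintf("  %s %s (%s)\n", e$action, e$target_id, e$rationale))
  }
  invisible(x)
}

rec_payload <- function(r) {
  drop_null(list(rec_id = r$rec_id, source_doc_type = r$source_doc_type,
                 original_text = r$original_text, page = r$page,
                 source_ref = r$source_ref, domain = r$domain,
                 subdomain = r$subdomain, target_group = r$target_group,
                 source_priority = r$source_priority,
                 original_loe = r$original_loe, hle = r$hle,
                 excluded = if (isTRUE(r$excluded)) TRUE else NULL,
                 exclusion_rationale = r$exclusion_rationale))
}

var_payload <- function(v) {
  drop_null(list(var_id = v$var_id, kind = v$kind, definition = v$definition,
                 data_source = v$data_source, units = v$units,
                 allowed_values = v$allowed_values, derived = v$derived))
}

pr_payload <- function(p) {
  drop_null(list(pr_id = p$pr_id, rec_id = p$rec_id, plain_text = p$plain_text,
                 priority = p$priority, delivery_formats = p$delivery_formats,
                 cluster_id = p$cluster_id))
}

changed_fields <- function(old, new, fields) {
  out <- list()
  for (f in fields) {
    if (!identical(old[[f]], new[[f]])) out[[f]] <- new[[f]]
  }
  out
}

#' Diff two knowledge bases into a replayable changelog
#'
#' Produces a minimal entry list such that `replay(a, diff_kb(a, b))` is
#' structurally equal to `b`; `diff_kb(kb, kb)` is empty. A recommendation
#' present in `a` but absent from `b`, or a removed variable, cannot be
#' expressed in the action vocabulary (recommendations are excluded, not
#' deleted; the variable registry is append-only) and raises an error.
#'
#' @param a,b knowledge bases.
#' @param editor,rationale audit fields stamped on the generated entries.
#' @return an `rc_changelog`.
#' @export
diff_kb <- function(a, b, editor = "diff", rationale = "version diff") {
  entries <- list()
  add <- function(e) entries[[length(entries) + 1L]] <<- e
  mk <- function(action, target, payload) {
    change_entry(action, target, payload, editor = editor, rationale = rationale,
                 timestamp = "1970-01-01T00:00:00Z")
  }

  gone_vars <- setdiff(names(a$variables), names(b$variables))
  if (length(gone_vars)) {
    stop("diff_kb: variable(s) removed in the target KB cannot be expressed (append-only registry): ",
         paste(gone_vars, collapse = ", "))
  }
  gone_recs <- setdiff(names(a$recommendations), names(b$recommendations))
  if (length(gone_recs)) {
    stop("diff_kb: recommendation(s) deleted in the target KB cannot be expressed (use exclusion): ",
         paste(gone_recs, collapse = ", "))
  }

  for (vid in names(b$variables)) {
    if (is.null(a$variables[[vid]])) {
      add(mk("add_variable", vid, var_payload(b$variables[[vid]])))
    } else {
      ch <- changed_fields(a$variables[[vid]], b$variables[[vid]],
                           c("kind", "definition", "data_source", "units",
                             "allowed_values", "derived"))
      if (length(ch)) add(mk("update_variable", vid, ch))
    }
  }

  for (rid in names(b$recommendations)) {
    old <- a$recommendations[[rid]]
    new <- b$recommendations[[rid]]
    if (is.null(old)) {
      add(mk("add_recommendation", rid, rec_payload(new)))
      next
    }
    if (!isTRUE(old$excluded) && isTRUE(new$excluded)) {
      add(mk("exclude_recommendation", rid,
             list(rationale = new$exclusion_rationale %||% rationale)))
      old$excluded <- TRUE
      old$exclusion_rationale <- new$exclusion_rationale
    }
    ch <- changed_fields(old, new, c("source_doc_type", "original_text", "page",
                                     "source_ref", "domain", "subdomain",
                                     "target_group", "source_priority",
                                     "original_loe", "hle"))
    if (length(ch)) add(mk("update_recommendation", rid, ch))
  }

  for (rid in setdiff(names(a$rules), names(b$rules))) {
    add(mk("remove_rule", rid, list()))
  }
  for (rid in names(b$rules)) {
    old <- a$rules[[rid]]
    new <- b$rules[[rid]]
    if (is.null(old)) {
      pr <- b$personalized[[new$pr_id]]
      add(mk("add_rule", rid, list(rule_id = rid, pr_id = new$pr_id,
                                   target_group = new$target_group,
                                   condition = new$condition_text,
                                   personalized = if (!is.null(pr) &&
                                     is.null(a$personalized[[new$pr_id]])) pr_payload(pr))))
      next
    }
    upd <- list()
    if (!identical(old$condition_text, new$condition_text)) upd$condition <- new$condition_text
    if (!identical(old$target_group, new$target_group)) upd$target_group <- new$target_group
    old_pr <- a$personalized[[old$pr_id]]
    new_pr <- b$personalized[[new$pr_id]]
    if (!is.null(old_pr) && !is.null(new_pr) && identical(old$pr_id, new$pr_id)) {
      chp <- changed_fields(old_pr, new_pr, c("plain_text", "priority",
                                              "delivery_formats", "cluster_id", "rec_id"))
      if (length(chp)) upd$personalized <- chp
    }
    if (length(upd)) add(mk("update_rule", rid, upd))
  }

  changelog(a$version, entries, result_version = b$version)
}

#' Replay a changelog on a base knowledge base
#'
#' Sequentially applies the entries with [apply_change()]; any rejection
#' aborts the whole replay with no partial state (the base KB is returned to
#' the caller unchanged because application is pure). The changelog's base
#' version must match the base KB's version; after a successful replay the
#' result carries the changelog's `result_version` (when recorded).
#'
#' @param base a knowledge base.
#' @param log an `rc_changelog`.
#' @param check_sat see [apply_change()].
#' @return the resulting knowledge base.
#' @export
replay <- function(base, log, check_sat = TRUE) {
  stopifnot(inherits(base, "rc_kb"), inherits(log, "rc_changelog"))
  if (!identical(log$base_version, base$version)) {
    stop("changelog base version '", log$base_version,
         "' does not match KB version '", base$version, "'")
  }
  kb <- base
  for (e in log$entries) kb <- apply_change(kb, e, check_sat = check_sat)
  if (!is.null(log$result_version)) kb$version <- log$result_version
  kb
}

#' Write / read a changelog file (append-only structured text)
#'
#' @param log an `rc_changelog`.
#' @param path file path.
#' @return `save_changelog()`: `path` invisibly; `load_changelog()`: an
#'   `rc_changelog`.
#' @export
save_changelog <- function(log, path) {
  plain <- list(base_version = log$base_version,
                result_version = log$result_version,
                entries = lapply(log$entries, unclass))
  writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_changelog
#' @export
load_changelog <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- lapply(raw$entries, function(e) {
    change_entry(e$action, e$target_id, payload = simplify_payload(e$payload),
                 editor = e$editor, rationale = e$rationale,
                 change_id = e$change_id, timestamp = e$timestamp)
  })
  changelog(raw$base_version, entries, raw$result_version %||% NULL)
}

simplify_payload <- function(pl) {
  if (is.null(pl)) return(list())
  out <- lapply(pl, function(x) {
    if (is.list(x) && length(x) && is.null(names(x))) unlist(x)
    else if (is.list(x) && !is.null(names(x))) simplify_payload(x)
    else x
  })
  out
}

#' Mutate a knowledge base randomly (simulation helper)
#'
#' Applies a few random, expressible edits (recommendation text/priority
#' updates, rule condition/priority tweaks, exclusions, rule additions and
#' removals, variable additions) and returns the result; used to exercise
#' diff/replay round-trips on generated KBs.
#'
#' @param kb a knowledge base.
#' @param n_changes number of edits.
#' @param seed integer seed.
#' @return a new knowledge base.
#' @export
mutate_kb <- function(kb, n_changes = 3L, seed = 1L) {
  with_seed(seed, {
    for (i in seq_len(n_changes)) {
      kind <- resample(c("upd_rec", "upd_rule_priority", "upd_rule_condition",
                         "exclude", "add_rule", "remove_rule", "add_variable"))
      entry <- (function() switch(kind,
        upd_rec = {
          if (!length(kb$recommendations)) return(NULL)
          rid <- resample(names(kb$recommendations))
          change_entry("update_recommendation", rid,
                       list(original_text = sprintf("Amended synthetic text %d.", i)),
                       rationale = "simulated edit")
        },
        upd_rule_priority = {
          if (!length(kb$rules)) return(NULL)
          rid <- resample(names(kb$rules))
          change_entry("update_rule", rid,
                       list(personalized = list(priority = resample(1:5))),
                       rationale = "simulated edit")
        },
        upd_rule_condition = {
          if (!length(kb$rules)) return(NULL)
          rid <- resample(names(kb$rules))
          vars <- cond_vars(kb$rules[[rid]]$condition)
          vdef <- kb$variables[[vars[1]]]
          change_entry("update_rule", rid,
                       list(condition = cond_to_text(random_predicate(vdef))),
                       rationale = "simulated edit")
        },
        exclude = {
          active <- Filter(function(r) !isTRUE(r$excluded), kb$recommendations)
          if (!length(active)) return(NULL)
          change_entry("exclude_recommendation", resample(names(active)),
                       list(rationale = "simulated exclusion"),
                       rationale = "simulated exclusion")
        },
        add_rule = {
          if (!length(kb$recommendations) || !length(kb$variables)) return(NULL)
          scalar_vars <- Filter(function(v) v$kind != "timeseries" && is.null(v$derived),
                                kb$variables)
          if (!length(scalar_vars)) return(NULL)
          vdef <- scalar_vars[[resample(seq_along(scalar_vars))]]
          rid <- sprintf("rule_mut_%02d", i)
          change_entry("add_rule", rid, list(
            rule_id = rid, pr_id = sprintf("pr_mut_%02d", i),
            target_group = resample(TARGET_GROUPS),
            condition = cond_to_text(random_predicate(vdef)),
            personalized = list(pr_id = sprintf("pr_mut_%02d", i),
                                rec_id = resample(names(kb$recommendations)),
                                plain_text = sprintf("Synthetic added recommendation %d.", i),
                                priority = resample(1:5))),
            rationale = "simulated addition")
        },
        remove_rule = {
          if (length(kb$rules) < 2L) return(NULL)
          change_entry("remove_rule", resample(names(kb$rules)), list(),
                       rationale = "simulated removal")
        },
        add_variable = {
          vid <- sprintf("var_mut_%02d", i)
          change_entry("add_variable", vid, list(
            var_id = vid, kind = "boolean",
            definition = sprintf("Synthetic added variable %d", i)),
            rationale = "simulated addition")
        }))()
      if (is.null(entry)) next
      kb <- tryCatch(apply_change(kb, entry),
                     rc_change_rejected = function(e) kb)
    }
    kb
  })
}
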