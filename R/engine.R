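# The inference and delivery core: evaluate every rule for a patient under
# three-valued semantics, partition rules into fired / unknown / false,
# prompt for the most valuable missing variables, optionally fall back on
# case-based reasoning when a single variable is missing, and order fired
# recommendations for delivery by priority with seeded tie-breaking and
# cluster throttling.

#' Evaluate every rule of a knowledge base for one patient
#'
#' Each active rule's condition is evaluated with [evaluate_condition()]
#' (conditions shared by several rules are evaluated once): TRUE rules are
#' `fired`, UNKNOWN rules are `unknown` together with the exact missing
#' variable ids, FALSE rules are `false`. Rules of excluded recommendations
#' are inert and reported separately under `excluded`; rules whose target
#' group conflicts with the record's group label (when the record carries
#' one; `"all"` never conflicts) are reported under `out_of_group`. The
#' three primary lists partition the active, in-group rules. Derived
#' longitudinal variables are materialized before evaluation.
#'
#' @param kb a valid knowledge base.
#' @param patient a [patient_record()] with normalized values.
#' @param as_of evaluation time for derived variables (see
#'   [materialize_derived()]).
#' @return list of class `rc_trigger_result`: `patient_id`, `fired`
#'   (data.frame rule_id/pr_id), `unknown` (named list rule_id -> missing
#'   var_ids), `false` (rule ids), `excluded`, `out_of_group`,
#'   `fallback_fired` (filled by [cbr_fallback()] users).
#' @export
trigger_rules <- function(kb, patient, as_of = NULL) {
  stopifnot(inherits(kb, "rc_kb"), inherits(patient, "rc_patient"))
  patient <- materialize_derived(kb, patient, as_of)
  registry <- kb$variables
  values <- patient$values

  fired_rule <- character(0); fired_pr <- character(0)
  unknown <- list()
  false_ <- character(0)
  excluded <- character(0)
  out_of_group <- character(0)

  # vectorized rule -> recommendation resolution (kept linear in KB size)
  rule_pr <- vapply(kb$rules, function(ru) ru$pr_id, "")
  pr_rec <- vapply(kb$personalized, function(p) p$rec_id, "")
  rule_rec <- unname(pr_rec[match(rule_pr, names(kb$personalized))])
  excluded_recs <- names(kb$recommendations)[vapply(kb$recommendations,
    function(r) isTRUE(r$excluded), TRUE)]
  rule_is_excluded <- !is.na(rule_rec) & rule_rec %in% excluded_recs

  cache <- new.env(parent = emptyenv())
  for (k in seq_along(kb$rules)) {
    ru <- kb$rules[[k]]
    if (rule_is_excluded[k]) {
      excluded <- c(excluded, ru$rule_id)
      next
    }
    if (!is.null(patient$group) && ru$target_group != "all" &&
        ru$target_group != patient$group) {
      out_of_group <- c(out_of_group, ru$rule_id)
      next
    }
    key <- ru$condition_text
    v <- if (exists(key, envir = cache, inherits = FALSE)) {
      get(key, envir = cache)
    } else {
      res <- evaluate_condition(ru$condition, values, registry)
      assign(key, res, envir = cache)
      res
    }
    if (isTRUE(v)) {
      fired_rule <- c(fired_rule, ru$rule_id)
      fired_pr <- c(fired_pr, ru$pr_id)
    } else if (isFALSE(v)) {
      false_ <- c(false_, ru$rule_id)
    } else {
      miss <- setdiff(cond_vars(ru$condition), names(values))
      unknown[[ru$rule_id]] <- miss
    }
  }
  structure(list(
    patient_id = patient$patient_id,
    fired = data.frame(rule_id = fired_rule, pr_id = fired_pr,
                       stringsAsFactors = FALSE),
    unknown = unknown,
    false = false_,
    excluded = excluded,
    out_of_group = out_of_group,
    fallback_fired = data.frame(rule_id = character(0), support = integer(0),
                                agreeing = integer(0), stringsAsFactors = FALSE)
  ), class = "rc_trigger_result")
}

#' @export
print.rc_trigger_result <- function(x, ...) {
  cat(sprintf("<trigger result %s> fired %d, unknown %d, false %d, excluded %d\n",
              x$patient_id, nrow(x$fired), length(x$unknown), length(x$false),
              length(x$excluded)))
  invisible(x)
}

#' Rank missing variables worth asking the patient about
#'
#' Considers rules left UNKNOWN that miss at most `limit` variables (the
#' cheap-to-unblock ones) and returns the missing variables ordered by how
#' many such rules each would help decide (descending), ties broken by
#' variable id.
#'
#' @param result an [trigger_rules()] result.
#' @param limit only consider rules missing at most this many variables
#'   (default 2).
#' @return character vector of variable ids (possibly empty).
#' @export
request_missing <- function(result, limit = 2L) {
  stopifnot(limit >= 1L)
  pools <- result$unknown[vapply(result$unknown, length, 1L) <= limit]
  if (!length(pools)) return(character(0))
  counts <- table(unlist(pools))
  ord <- order(-as.integer(counts), names(counts), method = "radix")
  names(counts)[ord]
}

#' Case-based-reasoning fallback for a rule blocked by one missing variable
#'
#' When a rule is UNKNOWN for the patient because exactly one required
#' variable is missing, looks at historical patients who match the index
#' patient on every *known* variable referenced by the rule's condition
#' (boolean/categorical/ordinal: same value; numeric: the historical value
#' satisfies exactly the same predicates of that condition as the index
#' value does) and provides the recommendation when most of them received
#' it: `support >= min_support` and `agreeing / support > majority`.
#' Recommendations provided this way are provisional.
#'
#' @param kb a knowledge base.
#' @param rule a [kb_rule()] (or its id in `kb`).
#' @param patient the index [patient_record()].
#' @param cohort_history list of historical cases, each a list with
#'   `patient` (a patient record) and `fired` (character vector of pr_ids
#'   that patient received).
#' @param min_support minimum number of similar historical patients
#'   (default 5).
#' @param majority required agreeing fraction, strict (default 0.5).
#' @return list with `provide` (logical), `support`, `agreeing`, and
#'   `refused` (TRUE with a `reason` when the one-missing-variable
#'   precondition does not hold).
#' @export
cbr_fallback <- function(kb, rule, patient, cohort_history,
                         min_support = 5L, majority = 0.5) {
  if (is.character(rule)) rule <- kb$rules[[rule]]
  stopifnot(inherits(rule, "rc_rule"))
  vars <- cond_vars(rule$condition)
  missing_vars <- setdiff(vars, names(patient$values))
  if (length(missing_vars) != 1L) {
    return(list(provide = FALSE, support = 0L, agreeing = 0L, refused = TRUE,
                reason = sprintf("rule misses %d variables; the fallback applies to exactly one",
                                 length(missing_vars))))
  }
  known <- setdiff(vars, missing_vars)
  preds <- cond_predicates(rule$condition)
  similar <- 0L
  agreeing <- 0L
  for (case in cohort_history) {
    hp <- case$patient
    ok <- TRUE
    for (v in known) {
      hv <- hp$values[[v]]
      if (is.null(hv)) { ok <- FALSE; break }
      iv <- patient$values[[v]]
      vdef <- kb$variables[[v]]
      if (!is.null(vdef) && vdef$kind == "numeric") {
        for (p in preds) {
          if (p$var != v || p$op %in% c("is_known", "is_missing")) next
          a <- eval_pred(p, stats::setNames(list(iv), v), kb$variables)
          b <- eval_pred(p, stats::setNames(list(hv), v), kb$variables)
          if (!identical(a, b)) { ok <- FALSE; break }
        }
        if (!ok) break
      } else if (!identical_scalar(hv, iv)) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    similar <- similar + 1L
    if (rule$pr_id %in% case$fired) agreeing <- agreeing + 1L
  }
  list(provide = similar >= min_support && agreeing / max(similar, 1L) > majority,
       support = similar, agreeing = agreeing, refused = FALSE)
}

# ---------------------------------------------------------------------------
# Delivery policy

#' Delivery policy parameters
#'
#' @param seed integer seed for the tie-breaking shuffle (Mersenne-Twister,
#'   R's default generator; the seed is recorded in the delivery log so the
#'   random order stays auditable).
#' @param cluster_cooldown_days after delivering from a cluster, suppress
#'   further items of that cluster for this many days.
#' @param cluster_min_intervening additionally require at least this many
#'   intervening deliveries before repeating a cluster.
#' @param max_per_session maximum recommendations per delivery, or `NULL`
#'   for no cap.
#' @return list of class `rc_policy`.
#' @export
delivery_policy <- function(seed = 1L, cluster_cooldown_days = 0,
                            cluster_min_intervening = 0L,
                            max_per_session = NULL) {
  stopifnot(cluster_cooldown_days >= 0, cluster_min_intervening >= 0L,
            is.null(max_per_session) || max_per_session >= 0L)
  structure(list(seed = as.integer(seed),
                 cluster_cooldown_days = cluster_cooldown_days,
                 cluster_min_intervening = as.integer(cluster_min_intervening),
                 max_per_session = max_per_session),
            class = "rc_policy")
}

#' An empty delivery history
#'
#' The history is an append-only log of `(timestamp, patient_id, pr_id,
#' cluster_id, seed, provisional)` rows with nondecreasing timestamps.
#'
#' @return data.frame of class `rc_history`.
#' @export
delivery_history <- function() {
  structure(data.frame(timestamp = as.Date(character(0)),
                       patient_id = character(0), pr_id = character(0),
                       cluster_id = character(0), seed = integer(0),
                       provisional = logical(0), stringsAsFactors = FALSE),
            class = c("rc_history", "data.frame"))
}

#' Append deliveries to a history
#'
#' @param history an `rc_history`.
#' @param timestamp delivery time (coercible to `Date`).
#' @param patient_id patient identifier.
#' @param pr_ids personalized recommendation ids delivered, in order.
#' @param cluster_ids matching cluster labels (`NA` for none).
#' @param seed the policy seed used for this delivery.
#' @param provisional logical vector flagging CBR-provided items.
#' @return the extended history.
#' @export
record_delivery <- function(history, timestamp, patient_id, pr_ids,
                            cluster_ids = rep(NA_character_, length(pr_ids)),
                            seed = NA_integer_,
                            provisional = rep(FALSE, length(pr_ids))) {
  if (!length(pr_ids)) return(history)
  timestamp <- as.Date(timestamp)
  if (nrow(history) && timestamp < max(history$timestamp)) {
    stop("delivery history timestamps must be nondecreasing")
  }
  add <- data.frame(timestamp = rep(timestamp, length(pr_ids)),
                    patient_id = patient_id, pr_id = pr_ids,
                    cluster_id = as.character(cluster_ids),
                    seed = as.integer(seed), provisional = provisional,
                    stringsAsFactors = FALSE)
  structure(rbind(as.data.frame(history), add), class = c("rc_history", "data.frame"))
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

#' Order fired recommendations for delivery
#'
#' Applies the delivery policy: (1) items whose cluster was delivered within
#' the cooldown of `now`, or within the last `cluster_min_intervening`
#' deliveries, are dropped; (2) the survivors are sorted by priority
#' ascending (1 = highest); (3) ties in priority are shuffled with the
#' seeded generator; (4) the list is truncated to `max_per_session`;
#' (5) within one output at most one item per cluster is kept (the earliest
#' in the sorted order, i.e. the highest-priority survivor). Deterministic
#' given identical inputs including the policy seed.
#'
#' @param fired data.frame with columns `pr_id`, `priority` and optionally
#'   `cluster_id` (`NA` = no cluster).
#' @param history an `rc_history` (typically this patient's deliveries).
#' @param policy a [delivery_policy()].
#' @param now current time (coercible to `Date`).
#' @return character vector of pr_ids in delivery order.
#' @export
rank_for_delivery <- function(fired, history = delivery_history(),
                              policy = delivery_policy(), now = Sys.Date()) {
  stopifnot(is.data.frame(fired), all(c("pr_id", "priority") %in% names(fired)))
  if (!nrow(fired)) return(character(0))
  now <- as.Date(now)
  cluster <- if ("cluster_id" %in% names(fired)) as.character(fired$cluster_id)
             else rep(NA_character_, nrow(fired))

  blocked <- character(0)
  if (nrow(history)) {
    recent_time <- history$cluster_id[!is.na(history$cluster_id) &
      as.numeric(now - history$timestamp) < policy$cluster_cooldown_days]
    last_k <- utils::tail(history, policy$cluster_min_intervening)
    recent_count <- last_k$cluster_id[!is.na(last_k$cluster_id)]
    blocked <- unique(c(recent_time, recent_count))
  }
  keep <- is.na(cluster) | !(cluster %in% blocked)
  fired <- fired[keep, , drop = FALSE]
  cluster <- cluster[keep]
  if (!nrow(fired)) return(character(0))

  perm <- with_seed(policy$seed, {
    shuffled <- sample.int(nrow(fired))   # random tie-break order
    shuffled[order(fired$priority[shuffled], method = "radix")]  # stable sort keeps the shuffle within ties
  })
  out_pr <- fired$pr_id[perm]
  out_cl <- cluster[perm]

  if (!is.null(policy$max_per_session)) {
    n <- min(length(out_pr), policy$max_per_session)
    out_pr <- out_pr[seq_len(n)]
    out_cl <- out_cl[seq_len(n)]
  }
  keep2 <- is.na(out_cl) | !duplicated(out_cl, incomparables = NA)
  out_pr[keep2]
}

#' Build a delivery report for one patient
#'
#' Runs the full single-patient path: trigger rules, optionally apply the
#' CBR fallback to one-variable-short rules, rank the fired recommendations
#' under the policy, and assemble the report rows (plain text, source
#' citation, the triggering condition, provisional flag) that accompany each
#' delivered recommendation.
#'
#' @param kb a knowledge base.
#' @param patient a [patient_record()].
#' @param policy a [delivery_policy()].
#' @param history an `rc_history`.
#' @param now delivery time.
#' @param cohort_history optional CBR case base (see [cbr_fallback()]); when
#'   supplied, unknown rules missing exactly one variable are tried.
#' @param cbr_min_support,cbr_majority CBR parameters.
#' @return list with `delivered` (data.frame: pr_id, priority, plain_text,
#'   source_ref, original_text, condition, provisional), `result` (the
#'   trigger result) and `asked` (variables worth requesting).
#' @export
deliver_recommendations <- function(kb, patient, policy = delivery_policy(),
                                    history = delivery_history(),
                                    now = Sys.Date(), cohort_history = NULL,
                                    cbr_min_support = 5L, cbr_majority = 0.5) {
  result <- trigger_rules(kb, patient)
  fired <- result$fired
  provisional <- rep(FALSE, nrow(fired))

  if (!is.null(cohort_history) && length(result$unknown)) {
    one_short <- names(result$unknown)[vapply(result$unknown, length, 1L) == 1L]
    fb_rule <- character(0); fb_support <- integer(0); fb_agree <- integer(0)
    for (rid in one_short) {
      ru <- kb$rules[[rid]]
      fb <- cbr_fallback(kb, ru, patient, cohort_history,
                         min_support = cbr_min_support, majority = cbr_majority)
      if (isTRUE(fb$provide)) {
        fired <- rbind(fired, data.frame(rule_id = rid, pr_id = ru$pr_id,
                                         stringsAsFactors = FALSE))
        provisional <- c(provisional, TRUE)
        fb_rule <- c(fb_rule, rid)
        fb_support <- c(fb_support, fb$support)
        fb_agree <- c(fb_agree, fb$agreeing)
      }
    }
    result$fallback_fired <- data.frame(rule_id = fb_rule, support = fb_support,
                                        agreeing = fb_agree, stringsAsFactors = FALSE)
  }

  meta <- lapply(fired$pr_id, function(pid) kb$personalized[[pid]])
  items <- data.frame(
    pr_id = fired$pr_id,
    rule_id = fired$rule_id,
    priority = vapply(meta, function(p) p$priority, 1L),
    cluster_id = vapply(meta, function(p) p$cluster_id %||% NA_character_, ""),
    provisional = provisional,
    stringsAsFactors = FALSE)
  items <- items[!duplicated(items$pr_id), , drop = FALSE]

  ordered <- rank_for_delivery(items, history, policy, now)
  rows <- items[match(ordered, items$pr_id), , drop = FALSE]
  delivered <- do.call(rbind, c(list(data.frame(
    pr_id = character(0), priority = integer(0), plain_text = character(0),
    source_ref = character(0), original_text = character(0),
    condition = character(0), provisional = logical(0),
    stringsAsFactors = FALSE)),
    lapply(seq_len(nrow(rows)), function(i) {
      pr <- kb$personalized[[rows$pr_id[i]]]
      rec <- kb$recommendations[[pr$rec_id]]
      ru <- kb$rules[[rows$rule_id[i]]]
      data.frame(pr_id = pr$pr_id, priority = pr$priority,
                 plain_text = pr$plain_text, source_ref = rec$source_ref,
                 original_text = rec$original_text,
                 condition = ru$condition_text,
                 provisional = rows$provisional[i], stringsAsFactors = FALSE)
    })))
  list(delivered = delivered, result = result,
       asked = request_missing(result))
}
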