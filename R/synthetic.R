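# Synthetic fixtures: generate knowledge bases that reproduce a configured
# structural profile (counts, histograms, usage/reuse buckets) and synthetic
# cross-sectional cohorts with controlled variable availability. The
# generated content is a structural emulation only — entity texts, thresholds
# and value distributions are synthetic, not clinical.

#' Configure the structural profile of a generated knowledge base
#'
#' Exact-count marginals (all optional except the four totals): histograms of
#' rules per recommendation, distinct variables per rule (over rules, i.e.
#' weighted by condition reuse), variable usage buckets (number of rules each
#' variable appears in: 1 / 2-3 / 4-10 / >10) and condition reuse buckets
#' (rules per unique condition: 1 / 2-3 / >=4, plus the maximum reuse).
#' Inconsistent configurations are rejected with a diagnostic naming the
#' violated identity. Marginals left `NULL` are chosen freely by the
#' generator.
#'
#' @param n_recommendations,n_rules,n_variables,n_unique_conditions totals.
#'   One personalized recommendation is created per rule.
#' @param rules_per_recommendation named integer vector: count of
#'   recommendations with `"1"`, `"2"`, ... rules.
#' @param vars_per_rule named integer vector over `"1"`..`"9"`: count of
#'   rules whose condition references that many distinct variables.
#' @param variable_usage_buckets named integer vector over
#'   `c("1","2-3","4-10",">10")`.
#' @param condition_reuse_buckets named integer vector over
#'   `c("1","2-3","4+")`.
#' @param max_condition_reuse the largest number of rules sharing one
#'   condition (required when the `"4+"` bucket is nonzero).
#' @param kind_mix fractions of boolean/numeric/categorical variables.
#' @param priority_mix integer counts of personalized priorities 1..5
#'   (sums to `n_rules`).
#' @param source_priority_mix integer counts of source priorities 1..3
#'   (sums to `n_recommendations`).
#' @param target_group_mix named counts over target groups for
#'   recommendations (defaults to shares typical of a CORD knowledge base).
#' @param plant_contradictions number of single-use conditions rewritten into
#'   planted logical contradictions (for validation-harness tests).
#' @param cluster_count when positive, assign this many overlap-cluster
#'   labels across roughly a quarter of the personalized recommendations.
#' @param seed integer seed; generation is deterministic per seed.
#' @return list of class `rc_kb_config`.
#' @export
kb_structure_config <- function(n_recommendations, n_rules, n_variables,
                                n_unique_conditions = n_rules,
                                rules_per_recommendation = NULL,
                                vars_per_rule = NULL,
                                variable_usage_buckets = NULL,
                                condition_reuse_buckets = NULL,
                                max_condition_reuse = NULL,
                                kind_mix = c(boolean = 0.5, numeric = 0.3, categorical = 0.2),
                                priority_mix = NULL,
                                source_priority_mix = NULL,
                                target_group_mix = NULL,
                                plant_contradictions = 0L,
                                cluster_count = 0L,
                                seed = 1L) {
  fail <- function(...) stop("infeasible KB structure config: ", sprintf(...), call. = FALSE)
  if (n_rules < n_recommendations) {
    fail("n_rules (%d) < n_recommendations (%d): every recommendation needs at least one rule",
         n_rules, n_recommendations)
  }
  if (n_unique_conditions > n_rules) {
    fail("n_unique_conditions (%d) exceeds n_rules (%d)", n_unique_conditions, n_rules)
  }
  if (!is.null(rules_per_recommendation)) {
    k <- as.integer(names(rules_per_recommendation))
    if (sum(rules_per_recommendation) != n_recommendations) {
      fail("sum of rules_per_recommendation counts (%d) != n_recommendations (%d)",
           sum(rules_per_recommendation), n_recommendations)
    }
    if (sum(k * rules_per_recommendation) != n_rules) {
      fail("rules implied by rules_per_recommendation (%d) != n_rules (%d)",
           sum(k * rules_per_recommendation), n_rules)
    }
  }
  if (!is.null(vars_per_rule)) {
    if (sum(vars_per_rule) != n_rules) {
      fail("sum of vars_per_rule counts (%d) != n_rules (%d)", sum(vars_per_rule), n_rules)
    }
    if (max(as.integer(names(vars_per_rule))[vars_per_rule > 0]) > n_variables) {
      fail("vars_per_rule requires more distinct variables than n_variables")
    }
  }
  if (!is.null(variable_usage_buckets)) {
    if (!identical(names(variable_usage_buckets), c("1", "2-3", "4-10", ">10"))) {
      fail("variable_usage_buckets must be named 1 / 2-3 / 4-10 / >10")
    }
    if (sum(variable_usage_buckets) != n_variables) {
      fail("sum of variable_usage_buckets (%d) != n_variables (%d)",
           sum(variable_usage_buckets), n_variables)
    }
  }
  if (!is.null(condition_reuse_buckets)) {
    if (!identical(names(condition_reuse_buckets), c("1", "2-3", "4+"))) {
      fail("condition_reuse_buckets must be named 1 / 2-3 / 4+")
    }
    if (sum(condition_reuse_buckets) != n_unique_conditions) {
      fail("sum of condition_reuse_buckets (%d) != n_unique_conditions (%d)",
           sum(condition_reuse_buckets), n_unique_conditions)
    }
    b <- condition_reuse_buckets
    if (b[["4+"]] > 0 && is.null(max_condition_reuse)) {
      fail("max_condition_reuse is required when the 4+ bucket is nonzero")
    }
    if (b[["4+"]] > 0 && max_condition_reuse < 4) fail("max_condition_reuse must be >= 4")
    lo <- b[["1"]] + 2 * b[["2-3"]] +
      if (b[["4+"]] > 0) 4 * (b[["4+"]] - 1) + max_condition_reuse else 0
    hi <- b[["1"]] + 3 * b[["2-3"]] +
      if (b[["4+"]] > 0) max_condition_reuse * b[["4+"]] else 0
    if (n_rules < lo || n_rules > hi) {
      fail("condition reuse buckets cannot total n_rules=%d (feasible range %d..%d)",
           n_rules, lo, hi)
    }
  }
  if (!is.null(priority_mix) && sum(priority_mix) != n_rules) {
    fail("priority_mix must sum to n_rules (one personalized recommendation per rule)")
  }
  if (!is.null(source_priority_mix) && sum(source_priority_mix) != n_recommendations) {
    fail("source_priority_mix must sum to n_recommendations")
  }
  if (!is.null(vars_per_rule) && !is.null(variable_usage_buckets)) {
    total_usage <- sum(as.integer(names(vars_per_rule)) * vars_per_rule)
    lo_usage <- sum(variable_usage_buckets * c(1, 2, 4, 11))
    if (lo_usage > total_usage) {
      fail("usage buckets need at least %d rule-variable incidences but vars_per_rule provides %d",
           lo_usage, total_usage)
    }
  }
  structure(list(
    n_recommendations = as.integer(n_recommendations),
    n_rules = as.integer(n_rules), n_variables = as.integer(n_variables),
    n_unique_conditions = as.integer(n_unique_conditions),
    rules_per_recommendation = rules_per_recommendation,
    vars_per_rule = vars_per_rule,
    variable_usage_buckets = variable_usage_buckets,
    condition_reuse_buckets = condition_reuse_buckets,
    max_condition_reuse = max_condition_reuse,
    kind_mix = kind_mix, priority_mix = priority_mix,
    source_priority_mix = source_priority_mix,
    target_group_mix = target_group_mix,
    plant_contradictions = as.integer(plant_contradictions),
    cluster_count = as.integer(cluster_count),
    seed = as.integer(seed)
  ), class = "rc_kb_config")
}

#' Structural profile of the full-scale knowledge base
#'
#' The configuration matching the published structural description of the
#' production knowledge base: 358 source recommendations operationalized as
#' 405 rules (each with its personalized recommendation) over 116 variables
#' and 208 unique logical conditions; variable usage buckets 31/35/30/20;
#' condition reuse 156/44/8 with a maximum of 62; variables per rule ranging
#' 1 (34 rules) to 9 (3 rules). Histogram entries the published description
#' only summarizes (means/SDs) are filled with counts chosen to match those
#' summaries; see the package vignette.
#'
#' @param seed integer seed.
#' @param plant_contradictions see [kb_structure_config()].
#' @return an `rc_kb_config`.
#' @export
full_kb_structure_config <- function(seed = 1L, plant_contradictions = 0L) {
  kb_structure_config(
    n_recommendations = 358L, n_rules = 405L, n_variables = 116L,
    n_unique_conditions = 208L,
    rules_per_recommendation = c("1" = 341L, "2" = 1L, "3" = 2L, "4" = 14L),
    vars_per_rule = stats::setNames(
      c(34L, 106L, 96L, 68L, 38L, 33L, 17L, 10L, 3L), as.character(1:9)),
    variable_usage_buckets = c("1" = 31L, "2-3" = 35L, "4-10" = 30L, ">10" = 20L),
    condition_reuse_buckets = c("1" = 156L, "2-3" = 44L, "4+" = 8L),
    max_condition_reuse = 62L,
    priority_mix = c(47L, 102L, 120L, 90L, 46L),
    source_priority_mix = c(165L, 142L, 51L),
    plant_contradictions = plant_contradictions,
    seed = seed
  )
}

# --- internal construction steps -------------------------------------------

shuffle <- function(x) x[sample.int(length(x))]
resample <- function(x, size = 1L) x[sample.int(length(x), size)]


realize_reuse <- function(config) {
  b <- config$condition_reuse_buckets
  if (is.null(b)) {
    r <- rep(1L, config$n_unique_conditions)
    extra <- config$n_rules - config$n_unique_conditions
    i <- 1L
    while (extra > 0L) {
      r[i] <- r[i] + 1L
      extra <- extra - 1L
      i <- if (i == length(r)) 1L else i + 1L
    }
    return(r)
  }
  r <- c(rep(1L, b[["1"]]), rep(2L, b[["2-3"]]),
         if (b[["4+"]] > 0) c(rep(4L, b[["4+"]] - 1L), config$max_condition_reuse))
  need <- config$n_rules - sum(r)
  # raise 2-3 bucket entries to 3
  idx23 <- which(r == 2L)
  k <- min(need, length(idx23))
  if (k > 0L) { r[idx23[seq_len(k)]] <- 3L; need <- need - k }
  # spread the rest over 4+ entries (excluding the max), capped at the max
  idx4 <- which(r == 4L)
  while (need > 0L && length(idx4)) {
    for (i in idx4) {
      if (need == 0L) break
      if (r[i] < config$max_condition_reuse) { r[i] <- r[i] + 1L; need <- need - 1L }
    }
    if (all(r[idx4] >= config$max_condition_reuse)) break
  }
  if (need != 0L) {
    stop("infeasible KB structure config: condition reuse buckets cannot absorb n_rules")
  }
  r
}

assign_sizes <- function(reuse, config) {
  n <- length(reuse)
  if (is.null(config$vars_per_rule)) {
    return(sample.int(min(3L, config$n_variables), n, replace = TRUE))
  }
  cap <- as.integer(config$vars_per_rule)
  ks <- as.integer(names(config$vars_per_rule))
  sizes <- integer(n)
  for (i in order(-reuse)) {
    ok <- which(cap >= reuse[i] & ks <= config$n_variables)
    if (!length(ok)) {
      stop(sprintf(
        "infeasible KB structure config: no vars_per_rule bucket can absorb a condition reused %d times",
        reuse[i]))
    }
    pick <- ok[which.max(cap[ok])]
    sizes[i] <- ks[pick]
    cap[pick] <- cap[pick] - reuse[i]
  }
  sizes
}

var_bucket_bounds <- function(config) {
  n <- config$n_variables
  if (is.null(config$variable_usage_buckets)) {
    return(list(lo = rep(0L, n), hi = rep(Inf, n)))
  }
  b <- config$variable_usage_buckets
  lo <- rep(c(1L, 2L, 4L, 11L), b)
  hi <- rep(c(1, 3, 10, Inf), b)
  ord <- sample.int(n)   # which variable lands in which bucket
  list(lo = lo[order(ord)], hi = hi[order(ord)])
}

# Degree-constrained bipartite incidence between conditions (weighted by
# reuse) and variables (usage must land inside its bucket interval):
# greedy deficit-first assignment followed by bounded swap repair.
build_incidence <- function(reuse, sizes, bounds, n_variables) {
  n_cond <- length(reuse)
  lo <- bounds$lo; hi <- bounds$hi
  usage <- rep(0, n_variables)
  members <- vector("list", n_cond)

  cond_count <- rep(0L, n_variables)  # spread: conditions a variable is in
  for (i in order(-reuse)) {
    r <- reuse[i]; s <- sizes[i]
    eligible <- which(usage + r <= hi)
    if (length(eligible) < s) {
      stop(sprintf(
        "infeasible KB structure config: condition reused %d times needs %d variables but only %d have headroom",
        r, s, length(eligible)))
    }
    deficit <- pmax(lo[eligible] - usage[eligible], 0)
    # deficit-first, then spread over variables in fewer conditions (keeps the
    # number of same-variable-set conditions low), seeded random tie-break
    ord <- order(-pmin(deficit, r), -deficit, cond_count[eligible],
                 stats::runif(length(eligible)))
    chosen <- eligible[ord][seq_len(s)]
    members[[i]] <- chosen
    usage[chosen] <- usage[chosen] + r
    cond_count[chosen] <- cond_count[chosen] + 1L
  }

  # repair: move weight toward variables still under their lower bound
  max_iter <- 50L * n_cond
  iter <- 0L
  repeat {
    needy <- which(usage < lo)
    if (!length(needy)) break
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("infeasible KB structure config: usage-bucket repair did not converge; ",
           sum(pmax(lo - usage, 0)), " incidences short")
    }
    d <- needy[1]
    moved <- FALSE
    for (i in order(reuse)) {       # smallest reuse first: finest adjustment
      r <- reuse[i]
      if (usage[d] + r > hi[d] || d %in% members[[i]]) next
      for (pos in seq_along(members[[i]])) {
        u <- members[[i]][pos]
        if (usage[u] - r >= lo[u]) {
          members[[i]][pos] <- d
          usage[u] <- usage[u] - r
          usage[d] <- usage[d] + r
          moved <- TRUE
          break
        }
      }
      if (moved) break
    }
    if (!moved) {
      stop("infeasible KB structure config: no swap can satisfy variable usage bucket ",
           "(variable short by ", lo[d] - usage[d], ")")
    }
  }
  members
}

random_predicate <- function(vdef, widen = FALSE) {
  switch(vdef$kind,
    boolean = if (widen) {
      # widened space used to resolve canonical-form collisions on variables
      # shared by many single-variable conditions
      form <- resample(c("eqT", "eqF", "neT", "neF", "known"))
      switch(form,
        eqT = cnd_pred(vdef$var_id, "eq", TRUE),
        eqF = cnd_pred(vdef$var_id, "eq", FALSE),
        neT = cnd_pred(vdef$var_id, "ne", TRUE),
        neF = cnd_pred(vdef$var_id, "ne", FALSE),
        known = cnd_pred(vdef$var_id, "is_known"))
    } else {
      cnd_pred(vdef$var_id, "eq", stats::runif(1) < 0.8)
    },
    numeric = cnd_pred(vdef$var_id, resample(c("ge", "le", "gt", "lt")),
                       round(stats::runif(1, 10, 90), 1)),
    categorical = ,
    ordinal = {
      if (length(vdef$allowed_values) > 1L && stats::runif(1) < 0.3) {
        k <- resample(2:min(3L, length(vdef$allowed_values)))
        cnd_pred(vdef$var_id, "in_set",
                 as.list(resample(vdef$allowed_values, k)))
      } else {
        cnd_pred(vdef$var_id, "eq", resample(vdef$allowed_values))
      }
    },
    stop("cannot build a predicate on kind ", vdef$kind))
}

build_condition <- function(vdefs, widen = FALSE) {
  preds <- lapply(vdefs, random_predicate, widen = widen)
  if (length(preds) == 1L) return(preds[[1]])
  if (length(preds) >= 2L && stats::runif(1) < 0.3) {
    # group one pair of predicates under OR; the condition stays satisfiable
    i <- sample(length(preds) - 1L, 1L)
    grouped <- cnd_or(preds[[i]], preds[[i + 1L]])
    preds <- c(preds[-(i:(i + 1L))], list(grouped))
  }
  if (length(preds) == 1L) preds[[1]] else cnd_nary("and", preds)
}

plant_contradiction <- function(cond, vdefs) {
  # rewrite the predicate(s) on the first variable into a conjunction that no
  # assignment satisfies, preserving the referenced variable set
  v <- vdefs[[1]]
  conflict <- switch(v$kind,
    boolean = list(cnd_pred(v$var_id, "eq", TRUE), cnd_pred(v$var_id, "eq", FALSE)),
    numeric = {
      t <- round(stats::runif(1, 10, 90), 1)
      list(cnd_pred(v$var_id, "ge", t), cnd_pred(v$var_id, "lt", t))
    },
    list(cnd_pred(v$var_id, "eq", v$allowed_values[1]),
         cnd_pred(v$var_id, "eq", v$allowed_values[min(2L, length(v$allowed_values))])))
  others <- if (length(vdefs) > 1L) lapply(vdefs[-1], random_predicate) else list()
  cnd_nary("and", c(conflict, others))
}

scale_counts <- function(weights, n) {
  # largest-remainder rounding of weight shares to integer counts summing n
  raw <- weights / sum(weights) * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

# subdomain sampling weights shaped like an implemented CORD knowledge base
SUBDOMAIN_WEIGHTS <- c(
  symptoms = 109, food_allergy = 3, rhinitis = 7, respiratory_infections = 18,
  sleep_disorders = 7, allergens = 30, occupational_hazards = 4,
  smoking_habits = 16, breathing_exercises_and_airway_clearance = 18,
  physical_activity_and_exercise = 40, adherence_and_inhaler_technique = 39,
  devices_and_active_principles = 31, vaccinations = 11,
  anxiety_depression_stress = 9, nutrition = 16)

SUBDOMAIN_DOMAIN <- stats::setNames(
  rep(names(DOMAIN_SUBDOMAINS), lengths(DOMAIN_SUBDOMAINS)),
  unlist(DOMAIN_SUBDOMAINS))

SOURCE_REF_POOL <- c("GINA 2018", "GOLD 2018", "NICE 2017", "BTS 2016",
                     "ARIA 2010", "ACSM 2011", "PA 2018", "NOC 2018")

#' Generate a knowledge base matching a structural profile
#'
#' Deterministic per seed. The emitted KB passes [validate_kb()] with zero
#' errors and [kb_stats()] reproduces every marginal configured in `config`
#' exactly. The rule-variable incidence is built by greedy deficit-first
#' stub matching with bounded swap repair; conditions are synthesized as
#' satisfiable random trees over their assigned variables and deduplicated
#' by canonical form; infeasible configurations abort with a diagnostic
#' naming the violated identity.
#'
#' @param config an [kb_structure_config()].
#' @return a validated `rc_kb`; rules whose condition was deliberately made
#'   unsatisfiable are listed in the `"planted_unsatisfiable"` attribute.
#' @export
generate_kb <- function(config) {
  stopifnot(inherits(config, "rc_kb_config"))
  with_seed(config$seed, generate_kb_impl(config))
}

generate_kb_impl <- function(config) {
  nv <- config$n_variables
  kinds <- rep(names(config$kind_mix), scale_counts(config$kind_mix, nv))
  kinds <- shuffle(kinds)
  var_ids <- sprintf("var_%03d", seq_len(nv))
  variables <- lapply(seq_len(nv), function(i) {
    kind <- kinds[i]
    kb_variable(var_ids[i], kind,
                definition = sprintf("Synthetic %s variable %d (structural emulation)", kind, i),
                data_source = sample(c("self_report", "sensor", "external"), 1L,
                                     prob = c(0.7, 0.2, 0.1)),
                units = if (kind == "numeric") "units" else NULL,
                allowed_values = if (kind %in% c("categorical", "ordinal")) {
                  paste0("level_", letters[seq_len(resample(3:5))])
                } else NULL)
  })
  names(variables) <- var_ids

  reuse <- realize_reuse(config)
  sizes <- assign_sizes(reuse, config)
  bounds <- var_bucket_bounds(config)
  members <- build_incidence(reuse, sizes, bounds, nv)

  # synthesize unique conditions
  seen <- new.env(parent = emptyenv())
  conditions <- vector("list", length(reuse))
  planted <- integer(0)
  plant_pool <- which(reuse == 1L)
  if (config$plant_contradictions > 0L) {
    if (length(plant_pool) < config$plant_contradictions) {
      stop("infeasible KB structure config: not enough single-use conditions to plant contradictions")
    }
    planted <- resample(plant_pool, config$plant_contradictions)
  }
  for (i in seq_along(reuse)) {
    vdefs <- variables[members[[i]]]
    for (try in 1:40) {
      cond <- if (i %in% planted) plant_contradiction(cond = NULL, vdefs = vdefs)
              else build_condition(vdefs, widen = try > 3L)
      key <- condition_key(cond)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        conditions[[i]] <- cond
        break
      }
      if (try == 40L) {
        stop("infeasible KB structure config: could not synthesize ",
             config$n_unique_conditions, " distinct conditions (collision on condition ", i, ")")
      }
    }
  }

  # recommendations
  nr <- config$n_recommendations
  rpr <- config$rules_per_recommendation
  rec_rule_counts <- if (is.null(rpr)) {
    base <- rep(1L, nr)
    extra <- config$n_rules - nr
    if (extra > 0L) {
      bump <- resample(seq_len(nr), min(extra, nr))
      # distribute round-robin if extra exceeds nr
      while (extra > 0L) {
        for (i in bump) {
          if (extra == 0L) break
          base[i] <- base[i] + 1L
          extra <- extra - 1L
        }
      }
    }
    base
  } else {
    shuffle(rep(as.integer(names(rpr)), rpr))
  }

  grp_weights <- config$target_group_mix %||%
    c(all = 6, asthma = 162, copd = 145, healthy = 42, rhinitis = 3)
  rec_groups <- shuffle(rep(names(grp_weights), scale_counts(grp_weights, nr)))
  sp_mix <- config$source_priority_mix %||% scale_counts(c(165, 142, 51), nr)
  rec_sp <- shuffle(rep(1:3, sp_mix))
  sub_counts <- scale_counts(SUBDOMAIN_WEIGHTS, nr)
  rec_sub <- shuffle(rep(names(sub_counts), sub_counts))
  hle_pool <- shuffle(rep(c("A", "B", "C", "D", NA_character_),
                          scale_counts(c(82, 42, 36, 39, 159), nr)))

  rec_ids <- sprintf("rec_%04d", seq_len(nr))
  recommendations <- lapply(seq_len(nr), function(i) {
    hle <- if (is.na(hle_pool[i])) NULL else hle_pool[i]
    source_recommendation(
      rec_ids[i],
      source_doc_type = sample(SOURCE_DOC_TYPES, 1L, prob = c(0.47, 0.43, 0.10)),
      original_text = sprintf("Synthetic source recommendation %d (structural emulation).", i),
      page = as.character(resample(1:200)),
      source_ref = resample(SOURCE_REF_POOL),
      domain = SUBDOMAIN_DOMAIN[[rec_sub[i]]], subdomain = rec_sub[i],
      target_group = rec_groups[i], source_priority = rec_sp[i],
      original_loe = hle, hle = hle)
  })

  # rules + personalized (one personalized recommendation per rule)
  n_rules <- config$n_rules
  cond_of_rule <- shuffle(rep(seq_along(reuse), reuse))
  pr_mix <- config$priority_mix %||% scale_counts(c(47, 102, 120, 90, 46), n_rules)
  pr_priorities <- shuffle(rep(1:5, pr_mix))
  clusters <- rep(NA_character_, n_rules)
  if (config$cluster_count > 0L) {
    member_n <- max(2L, round(0.25 * n_rules / config$cluster_count))
    pick <- resample(seq_len(n_rules), min(n_rules, config$cluster_count * member_n))
    clusters[pick] <- paste0("cluster_", (seq_along(pick) %% config$cluster_count) + 1L)
  }

  rules <- vector("list", n_rules)
  personalized <- vector("list", n_rules)
  planted_rule_ids <- character(0)
  k <- 0L
  for (i in seq_len(nr)) {
    groups_i <- unique(c(rec_groups[i],
                         setdiff(TARGET_GROUPS, rec_groups[i])))
    for (j in seq_len(rec_rule_counts[i])) {
      k <- k + 1L
      rule_id <- sprintf("rule_%04d", k)
      pr_id <- sprintf("pr_%04d", k)
      ci <- cond_of_rule[k]
      personalized[[k]] <- personalized_recommendation(
        pr_id, rec_ids[i],
        plain_text = sprintf("Synthetic personalized recommendation %d.", k),
        priority = pr_priorities[k],
        delivery_formats = unique(c("text", resample(DELIVERY_FORMATS, resample(0:2)))),
        cluster_id = if (is.na(clusters[k])) NULL else clusters[k])
      rules[[k]] <- kb_rule(rule_id, pr_id, groups_i[min(j, length(groups_i))],
                            conditions[[ci]])
      if (ci %in% planted) planted_rule_ids <- c(planted_rule_ids, rule_id)
    }
  }

  kb <- knowledge_base(version = "1.0", recommendations = recommendations,
                       personalized = personalized, variables = variables,
                       rules = rules,
                       created = "1970-01-01T00:00:00Z")
  iss <- validate_kb(kb)
  if (any(iss$severity == "error")) {
    stop("generator produced an invalid KB (internal error):\n",
         paste(iss$message[iss$severity == "error"], collapse = "\n"))
  }
  attr(kb, "planted_unsatisfiable") <- planted_rule_ids
  kb
}

# ---------------------------------------------------------------------------
# Cohort generation

#' Configure a synthetic cohort
#'
#' @param n_patients number of participants.
#' @param availability probability that a feedable variable is observed for a
#'   participant: a single number (MCAR) or a named per-variable vector.
#'   Derived and time-series variables are never observed (they would require
#'   longitudinal follow-up the cross-sectional cohort does not have).
#' @param boolean_p probability a boolean variable is TRUE when observed.
#' @param corrupt_numeric_format variable ids whose numeric values are
#'   written to the raw cohort table with a comma decimal separator —
#'   the formatting-corruption fixture for [consistency_check()].
#' @param seed integer seed.
#' @return list of class `rc_cohort_config`.
#' @export
cohort_config <- function(n_patients, availability = 1, boolean_p = 0.5,
                          corrupt_numeric_format = character(0), seed = 1L) {
  stopifnot(n_patients >= 0, all(availability >= 0), all(availability <= 1))
  structure(list(n_patients = as.integer(n_patients), availability = availability,
                 boolean_p = boolean_p,
                 corrupt_numeric_format = corrupt_numeric_format,
                 seed = as.integer(seed)),
            class = "rc_cohort_config")
}

#' Generate a synthetic patient cohort for a knowledge base
#'
#' Observation is sampled per variable per participant (missing completely
#' at random at the configured availability); observed values are drawn
#' respecting the variable kinds and allowed values. Returns both typed
#' patient records and the raw wide table (one column per variable, string
#' cells, empty = missing) that [apply_mapping()] would ingest.
#'
#' @param kb a knowledge base.
#' @param config an [cohort_config()].
#' @return list with `records` (list of [patient_record()]), `table`
#'   (data.frame of raw strings with a `patient_id` column) and `mapping`
#'   (the identity [variable_mapping()] for the table).
#' @export
generate_cohort <- function(kb, config) {
  stopifnot(inherits(kb, "rc_kb"), inherits(config, "rc_cohort_config"))
  with_seed(config$seed, generate_cohort_impl(kb, config))
}

generate_cohort_impl <- function(kb, config) {
  n <- config$n_patients
  feedable <- Filter(function(v) {
    v$kind %in% c("boolean", "numeric", "categorical", "ordinal") && is.null(v$derived)
  }, kb$variables)
  ids <- sprintf("patient_%04d", seq_len(n))
  tab <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  typed <- list()
  for (v in feedable) {
    p <- if (length(config$availability) == 1L) config$availability
         else config$availability[[v$var_id]] %||% 0
    obs <- stats::runif(n) < p
    col <- rep("", n)
    vals <- switch(v$kind,
      boolean = stats::runif(n) < config$boolean_p,
      numeric = round(stats::runif(n, 0, 100), 1),
      categorical = ,
      ordinal = sample(v$allowed_values, n, replace = TRUE))
    if (v$kind == "boolean") {
      col[obs] <- ifelse(vals[obs], "true", "false")
    } else if (v$kind == "numeric") {
      col[obs] <- sprintf("%.1f", vals[obs])
      if (v$var_id %in% config$corrupt_numeric_format) {
        col[obs] <- sub(".", ",", col[obs], fixed = TRUE)
      }
    } else {
      col[obs] <- vals[obs]
    }
    tab[[v$var_id]] <- col
    vals[!obs] <- NA
    typed[[v$var_id]] <- vals
  }
  records <- lapply(seq_len(n), function(i) {
    values <- list()
    for (vid in names(typed)) {
      x <- typed[[vid]][i]
      if (!is.na(x)) values[[vid]] <- x
    }
    patient_record(ids[i], values = values)
  })
  mapping <- variable_mapping(lapply(names(typed), function(vid) {
    list(column = vid, var_id = vid, transform = "identity")
  }))
  list(records = records, table = tab, mapping = mapping)
}

# ---------------------------------------------------------------------------
# Bundled demo fixtures

#' Bundled demo knowledge base and use-case patient
#'
#' `demo_kb()` loads the small knowledge base shipped with the package: the
#' smoking-cessation rule (asthma AND at least one cigarette per day), the
#' stress-reduction rule (asthma AND an anxiety score at or above the HADS-A
#' screening cutoff of 8) and a longitudinal weight-loss rule gated on the
#' derived flag "lost at least 10% of body weight within 6 months".
#' `demo_patient()` loads the use-case record: a young adult with
#' uncontrolled asthma and persistent rhinitis — self-reported asthma,
#' indoor-allergen sensitization and prescribed medication present;
#' nonsmoker, no secondhand smoke exposure, low-dose inhaled corticosteroid,
#' no hospitalizations in the prior year, FEV1 percent-predicted in the
#' normal range; anxiety score and weight series missing.
#'
#' @return `demo_kb()`: an `rc_kb`; `demo_patient()`: an `rc_patient`;
#'   `demo_fixtures()`: a list with both.
#' @export
demo_kb <- function() {
  load_kb(system.file("extdata", "demo-kb.json", package = "respcoach",
                      mustWork = TRUE))
}

#' @rdname demo_kb
#' @export
demo_patient <- function() {
  kb <- demo_kb()
  load_patient(system.file("extdata", "demo-patient.json", package = "respcoach",
                           mustWork = TRUE), kb = kb)
}

#' @rdname demo_kb
#' @export
demo_fixtures <- function() {
  kb <- demo_kb()
  patient <- load_patient(system.file("extdata", "demo-patient.json",
                                      package = "respcoach", mustWork = TRUE), kb = kb)
  list(kb = kb, patient = patient)
}
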