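# Cohort mapping, trigger statistics, untriggered-reason taxonomy, and the
# engine-vs-reference consistency check.

toy_kb <- function() {
  vars <- list(
    kb_variable("asthma", "boolean", "self-reported asthma"),
    kb_variable("cig_day", "numeric", "cigarettes/day", units = "n/day"),
    kb_variable("ics_dose", "categorical", "inhaled corticosteroid dose",
                allowed_values = c("low", "medium", "high")),
    kb_variable("age", "numeric", "age in years", units = "years"))
  recs <- lapply(1:4, function(i) {
    source_recommendation(paste0("rec", i), "international_guideline",
                          paste("text", i), "1", "GINA 2018",
                          "chronic_respiratory_disease", "symptoms",
                          "asthma", 1)
  })
  prs <- lapply(1:4, function(i) {
    personalized_recommendation(paste0("pr", i), paste0("rec", i),
                                paste("plain", i), priority = i)
  })
  rules <- list(
    kb_rule("r_smoke", "pr1", "asthma", '"asthma" = TRUE AND "cig_day" >= 1'),
    kb_rule("r_dose", "pr2", "asthma", '"ics_dose" IN ("medium", "high")'),
    kb_rule("r_age", "pr3", "copd", '"age" >= 40'),
    kb_rule("r_contra", "pr4", "healthy", '"age" >= 50 AND "age" < 50'))
  knowledge_base(recommendations = recs, personalized = prs,
                 variables = vars, rules = rules)
}

toy_cohort <- function() {
  data.frame(patient_id = c("p1", "p2", "p3"),
             has_asthma = c("yes", "no", "yes"),
             cigs = c("10", "0", ""),
             dose = c("Medium", "low", "HIGH"),
             stringsAsFactors = FALSE)
}

toy_mapping <- function() {
  variable_mapping(list(
    list(column = "has_asthma", var_id = "asthma"),
    list(column = "cigs", var_id = "cig_day"),
    list(column = "dose", var_id = "ics_dose")))
}

test_that("apply_mapping builds one normalized record per row and reports coverage", {
  kb <- toy_kb()
  records <- apply_mapping(toy_cohort(), toy_mapping(), kb)
  expect_length(records, 3)
  # 3 of 4 KB variables feedable
  expect_equal(attr(records, "feedable_variable_fraction"), 0.75)
  expect_true(records[[1]]$values$asthma)
  expect_identical(records[[1]]$values$cig_day, 10)
  expect_identical(records[[1]]$values$ics_dose, "medium")   # canonical label
  expect_identical(records[[3]]$values$ics_dose, "high")
  # empty cell is missing, not an error
  expect_null(records[[3]]$values$cig_day)
  # unmapped variable (age) missing for everyone
  expect_true(all(vapply(records, function(r) is.null(r$values$age), TRUE)))
  expect_identical(nrow(attr(records, "failures")), 0L)
})

test_that("apply_mapping logs normalization failures per row/column, record still produced", {
  kb <- toy_kb()
  cohort <- toy_cohort()
  cohort$cigs[1] <- "ten"
  records <- apply_mapping(cohort, toy_mapping(), kb)
  fails <- attr(records, "failures")
  expect_identical(nrow(fails), 1L)
  expect_identical(fails$row, 1L)
  expect_identical(fails$column, "cigs")
  expect_null(records[[1]]$values$cig_day)
  expect_true(records[[1]]$values$asthma)   # other values survive
})

test_that("mapping transforms: recode tables, threshold bins, computed columns", {
  kb <- toy_kb()
  cohort <- data.frame(patient_id = "p1", smoker = "S", dose_ug = "600",
                       year_born = "1960", stringsAsFactors = FALSE)
  mapping <- variable_mapping(list(
    list(column = "smoker", var_id = "asthma", transform = "recode_table",
         table = list(S = "true", N = "false", .default = "false")),
    list(column = "dose_ug", var_id = "ics_dose", transform = "threshold_bin",
         breaks = c(400, 800), labels = c("low", "medium", "high")),
    list(var_id = "age", transform = "computed",
         expr = "2023 - as.numeric(year_born)")))
  rec <- apply_mapping(cohort, mapping, kb)[[1]]
  expect_true(rec$values$asthma)
  expect_identical(rec$values$ics_dose, "medium")
  expect_identical(rec$values$age, 63)
})

test_that("empty mapping yields all-missing records; unknown targets are rejected", {
  kb <- toy_kb()
  records <- apply_mapping(toy_cohort(), variable_mapping(list()), kb)
  expect_true(all(vapply(records, function(r) length(r$values) == 0L, TRUE)))
  expect_error(
    apply_mapping(toy_cohort(),
                  variable_mapping(list(list(column = "cigs", var_id = "nope"))), kb),
    "undeclared KB variable")
})

test_that("run_cohort produces hand-checkable counts and conserves totals", {
  kb <- toy_kb()
  records <- apply_mapping(toy_cohort(), toy_mapping(), kb)
  report <- run_cohort(kb, records)
  # hand evaluation: p1 fires r_smoke + r_dose; p2 nothing; p3 r_dose only
  expect_identical(report$n_participants, 3L)
  expect_identical(report$per_patient_counts, c(2L, 0L, 1L))
  expect_identical(unname(report$per_rule_fire_counts),
                   c(1L, 2L, 0L, 0L))
  expect_identical(report$n_rules_fired_at_least_once, 2L)
  expect_identical(report$total_recommendations, 3L)
  expect_identical(sum(report$per_patient_counts), sum(report$per_rule_fire_counts))
  expect_identical(sort(names(report$untriggered)), c("r_age", "r_contra"))

  zero <- run_cohort(kb, list())
  expect_identical(zero$n_participants, 0L)
  expect_identical(zero$total_recommendations, 0L)
})

test_that("untriggered rules get exactly one reason in fixed precedence order", {
  kb <- toy_kb()
  records <- apply_mapping(toy_cohort(), toy_mapping(), kb)
  report <- run_cohort(kb, records)
  # scope covers asthma only: out_of_scope wins even though the rules'
  # variable is also unmapped (fixed precedence)
  classified <- classify_untriggered(kb, report, toy_mapping(), scope = "asthma")
  expect_identical(classified$untriggered[["r_age"]], "out_of_scope")
  expect_identical(classified$untriggered[["r_contra"]], "out_of_scope")

  # with every group in scope, the unmapped variable becomes the reason
  classified2 <- classify_untriggered(kb, report, toy_mapping(),
                                      scope = c("asthma", "copd", "healthy"))
  expect_identical(classified2$untriggered[["r_age"]], "unavailable_variable")
  expect_identical(classified2$untriggered[["r_contra"]], "unavailable_variable")

  # with age mapped, the planted contradiction surfaces
  mapping_age <- variable_mapping(c(toy_mapping()$entries,
                                    list(list(column = "cigs", var_id = "age"))))
  report3 <- run_cohort(kb, apply_mapping(toy_cohort(), mapping_age, kb))
  classified3 <- classify_untriggered(kb, report3, mapping_age,
                                      scope = c("asthma", "copd", "healthy"))
  expect_identical(classified3$untriggered[["r_contra"]], "unsatisfiable")
  # total and single-valued
  expect_true(all(classified3$untriggered %in%
    c("out_of_scope", "unavailable_variable", "unsatisfiable", "no_matching_participant")))
})

test_that("removing a mapped variable can only decrease per-rule fire counts", {
  kb <- generate_kb(small_config(31, n_recs = 8, n_rules = 12, n_vars = 8,
                                 n_conditions = 10))
  coh <- generate_cohort(kb, cohort_config(30, availability = 0.9, seed = 4))
  full_counts <- run_cohort(kb, apply_mapping(coh$table, coh$mapping, kb))$per_rule_fire_counts
  reduced <- variable_mapping(coh$mapping$entries[-1])
  red_counts <- run_cohort(kb, apply_mapping(coh$table, reduced, kb))$per_rule_fire_counts
  expect_true(all(red_counts <= full_counts))
})

test_that("consistency check: clean pipeline agrees exactly, corrupted formats are traced", {
  kb <- generate_kb(small_config(17, n_recs = 10, n_rules = 15, n_vars = 10,
                                 n_conditions = 13))
  coh <- generate_cohort(kb, cohort_config(40, availability = 0.8, seed = 8))
  clean <- consistency_check(kb, coh$table, coh$mapping)
  expect_identical(nrow(clean$missed), 0L)
  expect_identical(nrow(clean$spurious), 0L)
  expect_identical(clean$agreement, 1)

  num_vars <- names(Filter(function(v) v$kind == "numeric", kb$variables))
  corrupted <- generate_cohort(kb, cohort_config(40, availability = 0.8, seed = 8,
                                                 corrupt_numeric_format = num_vars))
  res <- consistency_check(kb, corrupted$table, corrupted$mapping)
  expect_gt(nrow(res$missed), 0)
  expect_lt(res$agreement, 1)
  traced <- unique(unlist(strsplit(res$missed$variables, ";")))
  expect_true(all(traced %in% num_vars))
})

test_that("adequacy reviews are structured annotations, not automation", {
  r1 <- adequacy_review("p1", "pr2", "reviewer A", "correct")
  r2 <- adequacy_review("p1", "pr1", "reviewer A", "needs_improvement",
                        suggestion = "condition should also require current smoking")
  expect_error(adequacy_review("p1", "pr1", "reviewer A", "needs_improvement"),
               "requires a suggestion")
  expect_error(adequacy_review("p1", "pr1", "", "correct"), "non-empty")
  expect_error(adequacy_review("p1", "pr1", "reviewer A", "fine"))

  kb <- toy_kb()
  report <- run_cohort(kb, apply_mapping(toy_cohort(), toy_mapping(), kb))
  report <- annotate_report(report, list(r1, r2))
  expect_identical(unname(report$review_summary), c(1L, 1L))
  expect_identical(names(report$review_summary), c("correct", "needs_improvement"))
})
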