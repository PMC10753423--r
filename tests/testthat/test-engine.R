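# Ingestion normalization, rule triggering, missing-data prompting, CBR
# fallback, and the delivery policy.

test_that("normalize_value canonicalizes raw input and never silently drops it", {
  num <- kb_variable("x", "numeric", "n", units = "u")
  expect_identical(normalize_value(num, "12"), 12)
  expect_identical(normalize_value(num, " 3.5 "), 3.5)
  expect_error(normalize_value(num, "12,5"), class = "rc_ingestion_error")
  expect_error(normalize_value(num, "12 kg"), class = "rc_ingestion_error")

  boo <- kb_variable("b", "boolean", "b")
  expect_true(normalize_value(boo, "Yes"))
  expect_true(normalize_value(boo, "1"))
  expect_false(normalize_value(boo, "FALSE"))
  err <- tryCatch(normalize_value(boo, "maybe"), rc_ingestion_error = identity)
  expect_s3_class(err, "rc_ingestion_error")
  expect_identical(err$variable, "b")
  expect_identical(err$raw, "maybe")

  cat_ <- kb_variable("c", "categorical", "c", allowed_values = c("asthma", "copd"))
  # minor formatting differences (capitalization, padding) map to the canonical label
  expect_identical(normalize_value(cat_, "Asthma "), "asthma")
  expect_identical(normalize_value(cat_, "COPD"), "copd")
  expect_error(normalize_value(cat_, "ashtma"), class = "rc_ingestion_error")
})

test_that("the demo use-case patient triggers nothing: smoking FALSE, stress/weight UNKNOWN", {
  fx <- demo_fixtures()
  res <- trigger_rules(fx$kb, fx$patient)
  expect_identical(nrow(res$fired), 0L)
  expect_true("rule_smoking" %in% res$false)
  expect_identical(res$unknown$rule_stress, "hads_anxiety")
  expect_true("rule_weight" %in% names(res$unknown))
  # one cigarette per day flips the smoking rule on
  smoker <- fx$patient
  smoker$values$cigarettes_per_day <- 1
  res2 <- trigger_rules(fx$kb, smoker)
  expect_identical(res2$fired$pr_id, "pr_smoking")
  expect_identical(fx$kb$personalized$pr_smoking$plain_text, "Smoking cessation is advised")
  # providing the anxiety score decides the stress rule
  anxious <- fx$patient
  anxious$values$hads_anxiety <- 12
  res3 <- trigger_rules(fx$kb, anxious)
  expect_true("rule_stress" %in% res3$fired$rule_id)
  calm <- fx$patient
  calm$values$hads_anxiety <- 2
  expect_true("rule_stress" %in% trigger_rules(fx$kb, calm)$false)
})

test_that("trigger_rules partitions active rules and an empty KB yields empty lists", {
  empty <- trigger_rules(knowledge_base(), patient_record("p0"))
  expect_identical(nrow(empty$fired), 0L)
  expect_length(empty$unknown, 0)
  expect_length(empty$false, 0)

  for (seed in 1:10) {
    kb <- generate_kb(small_config(seed, n_recs = 8, n_rules = 12, n_vars = 8,
                                   n_conditions = 10))
    coh <- generate_cohort(kb, cohort_config(5, availability = 0.6, seed = seed))
    for (p in coh$records) {
      res <- trigger_rules(kb, p)
      expect_identical(nrow(res$fired) + length(res$unknown) + length(res$false) +
                         length(res$excluded), length(kb$rules))
      # per-rule oracle: independent re-evaluation of each rule
      for (ru in kb$rules) {
        v <- evaluate_condition(ru$condition, p$values, kb$variables)
        if (isTRUE(v)) expect_true(ru$rule_id %in% res$fired$rule_id)
        else if (isFALSE(v)) expect_true(ru$rule_id %in% res$false)
        else expect_true(ru$rule_id %in% names(res$unknown))
      }
    }
  }
})

test_that("filling in a missing variable never flips fired to false (end-to-end Kleene stability)", {
  set.seed(404)
  kb <- generate_kb(small_config(21, n_recs = 8, n_rules = 12, n_vars = 8,
                                 n_conditions = 10))
  coh <- generate_cohort(kb, cohort_config(8, availability = 0.5, seed = 3))
  full <- generate_cohort(kb, cohort_config(8, availability = 1, seed = 3))
  for (i in seq_along(coh$records)) {
    partial <- trigger_rules(kb, coh$records[[i]])
    completed <- coh$records[[i]]
    for (v in names(full$records[[i]]$values)) {
      if (is.null(completed$values[[v]])) completed$values[[v]] <- full$records[[i]]$values[[v]]
    }
    res_full <- trigger_rules(kb, completed)
    expect_true(all(partial$fired$rule_id %in% res_full$fired$rule_id))
    expect_true(all(partial$false %in% res_full$false))
  }
})

test_that("request_missing ranks variables by the number of rules they unblock", {
  kb <- demo_fixtures()$kb
  res <- trigger_rules(kb, demo_fixtures()$patient)
  # both undecided rules miss exactly one variable; ties order by id
  expect_identical(request_missing(res, limit = 1),
                   c("hads_anxiety", "significant_weight_loss_6mo"))
  expect_identical(request_missing(res), c("hads_anxiety", "significant_weight_loss_6mo"))

  # synthetic: v unblocks 3 rules, w unblocks 1 -> v first
  fake <- structure(list(unknown = list(r1 = "v", r2 = "v", r3 = c("v", "w"), r4 = "w"),
                         fired = data.frame(), false = character(0)),
                    class = "rc_trigger_result")
  expect_identical(request_missing(fake, limit = 2), c("v", "w"))
  none <- structure(list(unknown = list()), class = "rc_trigger_result")
  expect_identical(request_missing(none), character(0))
})

test_that("CBR fallback follows support and majority thresholds", {
  kb <- demo_fixtures()$kb
  rule <- kb$rules$rule_stress
  patient <- patient_record("p", values = list(self_reported_asthma = TRUE))
  make_case <- function(id, got) {
    list(patient = patient_record(id, values = list(self_reported_asthma = TRUE,
                                                    hads_anxiety = 10)),
         fired = if (got) "pr_stress" else character(0))
  }
  hist10 <- lapply(1:10, function(i) make_case(paste0("h", i), i <= 7))
  res <- cbr_fallback(kb, rule, patient, hist10)
  expect_true(res$provide)      # 10 similar, 7/10 > 0.5
  expect_identical(res$support, 10L)
  expect_identical(res$agreeing, 7L)

  expect_false(cbr_fallback(kb, rule, patient, list())$provide)   # no support
  hist4 <- lapply(1:4, function(i) make_case(paste0("h", i), TRUE))
  expect_false(cbr_fallback(kb, rule, patient, hist4)$provide)    # 4 < min_support
  # exactly half agreeing is not "most"
  hist_even <- lapply(1:10, function(i) make_case(paste0("h", i), i <= 5))
  expect_false(cbr_fallback(kb, rule, patient, hist_even)$provide)

  # two missing variables: refusal, not an exception
  p2 <- patient_record("p2")
  ref <- cbr_fallback(kb, rule, p2, hist10)
  expect_true(ref$refused)
  expect_false(ref$provide)

  # numeric similarity is predicate-level: only patients on the same side of
  # the cutoffs count as similar
  rule_smk <- kb$rules$rule_smoking
  p3 <- patient_record("p3", values = list(cigarettes_per_day = 5))   # asthma missing
  sim <- list(
    list(patient = patient_record("s1", values = list(self_reported_asthma = TRUE,
                                                      cigarettes_per_day = 20)),
         fired = "pr_smoking"),
    list(patient = patient_record("s2", values = list(self_reported_asthma = TRUE,
                                                      cigarettes_per_day = 0)),
         fired = character(0)))
  res3 <- cbr_fallback(kb, rule_smk, p3, sim, min_support = 1)
  expect_identical(res3$support, 1L)   # s2 fails the >= 1 predicate match
  expect_identical(res3$agreeing, 1L)
  expect_true(res3$provide)
})

test_that("delivery ranking is priority-first with reproducible seeded tie-breaks", {
  fired <- data.frame(pr_id = c("a", "b", "c"), priority = c(3, 1, 2),
                      stringsAsFactors = FALSE)
  expect_identical(rank_for_delivery(fired, policy = delivery_policy(seed = 9)),
                   c("b", "c", "a"))
  single <- data.frame(pr_id = "only", priority = 4, stringsAsFactors = FALSE)
  expect_identical(rank_for_delivery(single), "only")

  ties <- data.frame(pr_id = letters[1:5], priority = rep(2, 5),
                     stringsAsFactors = FALSE)
  p42 <- delivery_policy(seed = 42)
  first <- rank_for_delivery(ties, policy = p42)
  expect_identical(rank_for_delivery(ties, policy = p42), first)   # reproducible
  expect_setequal(first, letters[1:5])                             # permutation
  # matches the documented generator: Mersenne-Twister shuffle under the seed
  ref <- respcoach:::with_seed(42L, sample.int(5))
  expect_identical(first, ties$pr_id[ref])
  # a different seed explores a different permutation eventually
  others <- vapply(1:20, function(s) {
    paste(rank_for_delivery(ties, policy = delivery_policy(seed = s)), collapse = "")
  }, "")
  expect_gt(length(unique(others)), 1)
})

test_that("delivery ranking enforces cap, cluster uniqueness and throttling", {
  fired <- data.frame(pr_id = c("a", "b", "c", "d"),
                      priority = c(1, 2, 2, 3),
                      cluster_id = c("k1", "k1", NA, "k2"),
                      stringsAsFactors = FALSE)
  # within one output at most one item per cluster: b (k1, lower priority) drops
  out <- rank_for_delivery(fired, policy = delivery_policy(seed = 1))
  expect_identical(out, c("a", "c", "d"))
  expect_identical(rank_for_delivery(fired,
    policy = delivery_policy(seed = 1, max_per_session = 2)), c("a", "c"))

  # cooldown: k1 delivered yesterday blocks a and b for a 3-day cooldown
  hist <- record_delivery(delivery_history(), Sys.Date() - 1, "p", "a",
                          cluster_ids = "k1", seed = 1L)
  out2 <- rank_for_delivery(fired, history = hist,
                            policy = delivery_policy(seed = 1, cluster_cooldown_days = 3),
                            now = Sys.Date())
  expect_identical(out2, c("c", "d"))
  # after the cooldown has fully elapsed the cluster is allowed again
  out3 <- rank_for_delivery(fired, history = hist,
                            policy = delivery_policy(seed = 1, cluster_cooldown_days = 1),
                            now = Sys.Date())
  expect_identical(out3, c("a", "c", "d"))

  # min-intervening: k1 among the last 2 deliveries is blocked
  hist2 <- record_delivery(delivery_history(), Sys.Date() - 30, "p",
                           c("a", "x"), cluster_ids = c("k1", NA), seed = 1L)
  out4 <- rank_for_delivery(fired, history = hist2,
                            policy = delivery_policy(seed = 1, cluster_min_intervening = 2))
  expect_identical(out4, c("c", "d"))
})

test_that("deliver_recommendations assembles the patient-facing report", {
  fx <- demo_fixtures()
  smoker <- fx$patient
  smoker$values$cigarettes_per_day <- 3
  rep <- deliver_recommendations(fx$kb, smoker, policy = delivery_policy(seed = 5))
  expect_identical(rep$delivered$pr_id, "pr_smoking")
  expect_identical(rep$delivered$plain_text, "Smoking cessation is advised")
  expect_identical(rep$delivered$source_ref, "GINA 2018")
  expect_match(rep$delivered$condition, "cigarettes_per_day")
  expect_false(rep$delivered$provisional)
  expect_true("hads_anxiety" %in% rep$asked)

  # with a CBR case base, the one-variable-short stress rule is provided provisionally
  cases <- lapply(1:6, function(i) {
    list(patient = patient_record(paste0("h", i),
                                  values = list(self_reported_asthma = TRUE)),
         fired = "pr_stress")
  })
  rep2 <- deliver_recommendations(fx$kb, fx$patient, policy = delivery_policy(seed = 5),
                                  cohort_history = cases)
  expect_true("pr_stress" %in% rep2$delivered$pr_id)
  expect_true(rep2$delivered$provisional[rep2$delivered$pr_id == "pr_stress"])
  expect_identical(rep2$result$fallback_fired$rule_id, "rule_stress")
})
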