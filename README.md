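# respcoach

Rule-based clinical knowledge bases and an individualized coaching engine for
chronic obstructive respiratory disease (CORD) self-management.

Mobile-health decision support for patients with asthma or COPD matches
patient characteristics against a knowledge base of guideline-derived
recommendations and delivers the applicable ones as plain-language, actionable
advice. `respcoach` implements the machinery such a system needs, end to end,
for teams building or auditing this kind of knowledge base:

- **Knowledge-base model** — source recommendations with provenance and a
  harmonized A–D level of evidence (absent when the source reports none),
  plain-language personalized recommendations on a 1 (highest) to 5 priority
  scale, a typed variable registry (boolean, numeric, categorical, ordinal,
  time series), and logical rules; schema validation, descriptive statistics,
  and a diff-stable JSON file dialect (`cord-kb/1`).
- **Condition language** — IF-THEN conditions such as
  `"self_reported_asthma" = TRUE AND "cigarettes_per_day" >= 1`, combined with
  `AND`/`OR`/`NOT`. Evaluation uses strong Kleene three-valued logic: a
  predicate on a missing variable is *unknown*, and a rule fires only on a
  definite TRUE — missing data can never trigger a recommendation, not even
  through negation. Conditions have a canonical form (used to count unique
  logical conditions) and a satisfiability checker based on interval
  abstraction of numeric thresholds, which finds rules that can never fire.
- **Longitudinal limits** — consensus change limits ("lost ≥ 10% of body
  weight within 6 months") and trends are computed from timestamped series
  and materialized as ordinary variables, so the rule engine stays purely
  propositional.
- **Coaching engine** — value normalization at the ingestion boundary,
  rule triggering that partitions rules into fired / unknown (with the exact
  missing variables) / false, prompting for the most valuable missing
  variables, a case-based-reasoning fallback when exactly one variable is
  missing, and delivery ordering: priority first, seeded random tie-breaks
  (auditable), per-cluster cooldown and intervening-delivery throttling.
- **Cohort validation harness** — map a study table onto KB variables
  (recode tables, threshold bins, computed columns; no imputation), run the
  engine on every participant, summarize trigger statistics, classify every
  untriggered rule into one of four reasons (out of scope → unavailable
  variable → unsatisfiable → no matching participant), and cross-check the
  production pipeline against an independent reference evaluator.
- **Synthetic fixtures** — generators for knowledge bases that reproduce a
  configured structural profile *exactly* (counts, histograms, variable-usage
  and condition-reuse buckets; built by degree-constrained stub matching with
  swap repair) and for patient cohorts with controlled variable availability.
- **Lifecycle** — atomic versioned updates with an audit trail; any two KB
  versions diff into a changelog whose replay reproduces the target.

## Worked example

The bundled demo knowledge base contains three rules printed in full: smoking
cessation (asthma AND ≥ 1 cigarette/day), stress reduction (asthma AND
HADS-A anxiety ≥ 8), and a longitudinal weight-loss rule. The bundled
use-case patient is a young adult with uncontrolled asthma and persistent
rhinitis: nonsmoker, low-dose inhaled corticosteroid, no anxiety score
recorded.

```r
library(respcoach)
fx <- demo_fixtures()
res <- trigger_rules(fx$kb, fx$patient)
res
#> <trigger result demo_patient> fired 0, unknown 2, false 1, excluded 0
```

The nonsmoking use-case patient triggers nothing: the smoking rule is
definitely FALSE (0 cigarettes/day), while the stress and weight rules are
*unknown*, each blocked by one missing variable that the engine suggests
asking about:

```r
request_missing(res)
#> [1] "hads_anxiety"                "significant_weight_loss_6mo"
```

One cigarette per day flips the smoking rule on, and delivery assembles the
patient-facing report with the supporting source recommendation:

```r
smoker <- fx$patient
smoker$values$cigarettes_per_day <- 1
deliver_recommendations(fx$kb, smoker, delivery_policy(seed = 7))$delivered[, 1:4]
#>        pr_id priority                    plain_text source_ref
#> 1 pr_smoking        1 Smoking cessation is advised  GINA 2018
```

The weight-loss limit is met by an 80 → 72 kg drop within 6 months (−10%),
but not by 80 → 73 kg (−8.75%):

```r
s <- rc_series("body_weight", c("2023-01-01", "2023-06-01"), c(80, 72))
detect_change(s, change_spec("relative_percent", "decrease", 10,
                             window_months = 6), as_of = "2023-06-01")[c("flag", "magnitude")]
#> $flag
#> [1] TRUE
#> $magnitude
#> [1] -10
```

A full-scale structurally realistic knowledge base and a synthetic cohort:

```r
kb <- generate_kb(full_kb_structure_config(seed = 1))
kb_stats(kb)
#> recommendations: 358 (0 excluded), personalized: 405, rules: 405, variables: 116, unique conditions: 208
#> rules/recommendation: mean 1.13 sd 0.60 max 4
#> variables/rule: mean 3.51 sd 1.78 range 1..9
#> variable usage buckets: 1=31, 2-3=35, 4-10=30, >10=20
#> condition reuse buckets: 1=156, 2-3=44, 4+=8 (max 62)
```

## Command line

A thin CLI wraps the same functions
(`Rscript <pkg>/exec/respcoach <command>`): `validate`, `recommend`,
`cohort`, `generate`, `stats`, `diff`, `replay`. Exit codes: 0 success,
1 domain failure, 2 usage/parse error. Reports are written as JSON/CSV files
together with a manifest (input hashes, KB version, seed, tool version).

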