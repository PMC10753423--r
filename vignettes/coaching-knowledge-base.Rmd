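---
title: "Methods: a rule-based coaching knowledge base under missing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a rule-based coaching knowledge base under missing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`respcoach` models the knowledge layer of a clinical decision support system
for chronic obstructive respiratory disease (CORD) self-management: a
curated set of guideline-derived recommendations is operationalized into
IF-THEN rules over typed patient variables, and an inference engine delivers
the applicable recommendations to a patient in plain language, ordered by
clinical priority. This vignette documents the model, its assumptions, the
parameters that matter, and the design decisions taken where the design was
genuinely open.

## The knowledge-base model

A knowledge base couples four entity sets:

* **Source recommendations** carry provenance (document type, citation key,
  page, verbatim text), a knowledge domain/subdomain, a target group
  (`all`, `asthma`, `copd`, `healthy`, `rhinitis`), and a source priority on
  a 1–3 scale (1 = highest). Evidence grading is heterogeneous across
  guideline systems, so each recommendation stores both the original level
  of evidence and a **harmonized level of evidence** (HLE) on an A–D scale.
  Both are the only optional fields: when a source reports no grading, both
  stay absent — `harmonize_level()` maps absent to absent, consults the KB's
  crosswalk first, and falls back to the identity on A–D. The full
  source-specific crosswalk is curation content, not code; the identity
  default is the only mapping safe to assume.
* **Personalized recommendations** are the plain-language adaptations
  actually delivered, each with delivery-format metadata (text, image,
  video, link), a 1–5 priority (1 = highest, consistent with the source
  scale's "smaller = more important" convention) and an optional overlap
  cluster label used by delivery throttling.
* **Variables** form a typed registry: boolean, numeric (unit-annotated),
  categorical/ordinal (with declared allowed values), or time series. One
  rule per concept is enforced by construction: conditions may only
  reference registered variables, and validation checks every
  operator/kind combination.
* **Rules** bind one personalized recommendation and one target group to a
  logical condition. A recommendation applicable to several patient groups
  is split into several rules, one per group, so each rule stays a single
  testable unit; uniqueness of `(personalized id, target group)` is an
  invariant.

`validate_kb()` reports every violated invariant (never throws), and
`load_kb()`/`save_kb()` round-trip a diff-stable JSON dialect
(`cord-kb/1`, sorted entities, fixed key order) so that versions can be
compared line by line.

## Three-valued evaluation under missing data

Patient records are sparse by nature: a variable absent from a record is
*missing*, never defaulted. Conditions are therefore evaluated in **strong
Kleene three-valued logic**: a predicate on a missing variable is UNKNOWN,
`AND`/`OR`/`NOT` combine by the Kleene truth tables, and a rule fires only
on a definite TRUE.

The choice matters most for negation. Under a two-valued closed-world
reading, `NOT "smoker" = TRUE` would fire for a patient whose smoking status
was simply never asked. Under Kleene semantics it stays UNKNOWN, which
matches the operational behavior a knowledge-base team expects: rules whose
data are unavailable simply do not trigger. The explicit predicates
`IS KNOWN` / `IS MISSING` remain available when a rule deliberately wants to
react to missingness itself. Kleene evaluation is monotone: once a verdict
is decided (TRUE or FALSE) on partial data, no completion of the missing
variables can change it. The test suite checks this stability exhaustively
on small conditions and checks the evaluator against an enumeration oracle
built from explicit truth tables.

Internally the implementation rides on R's native `NA` logic, which is
exactly strong Kleene for `!`, `&`, `|`, `all()` and `any()`; the oracle in
the tests deliberately avoids that machinery.

## Canonical conditions and satisfiability

Two rules often share "the same" condition written differently. The
canonical form — negation pushed inward by De Morgan's laws (valid in
Kleene logic), `NOT` absorbed into predicates where an inverse operator
exists (`NOT x >= 5` ⇒ `x < 5`), nested conjunctions/disjunctions
flattened, duplicates removed, operands sorted by serialized text — defines
condition identity. Unique-condition counts in `kb_stats()` are counts of
canonical forms.

`check_satisfiability()` decides whether *any* fully known assignment makes
a condition TRUE. The search is exhaustive over a finite abstraction:
booleans over both values, categorical/ordinal variables over their allowed
values, and numeric variables discretized into the intervals induced by the
thresholds appearing in predicates on that variable (each threshold, each
midpoint, one probe beyond each extreme). For the predicate language —
comparisons against constants — this abstraction is exact: within one
induced interval no predicate changes truth value. Top-level conjunctions
are decomposed into connected components sharing variables, so the common
case (a conjunction of independent per-variable predicates) stays linear.
Guards: conditions referencing more than 12 variables, or components whose
discretized space exceeds 200,000 assignments, are refused with a message
rather than searched. Satisfiable verdicts always return a concrete witness,
which the tests re-evaluate.

## Longitudinal limits

Change limits are clinical consensus statements of the form "lost at least
10% of body weight within 6 months". `detect_change()` evaluates every
ordered pair of observations inside the window and flags when *any* pair
meets the threshold in the configured direction: the limit describes a
patient-state episode, not an endpoint comparison, so a drop-and-regain
still counts. Relative change is `(v2 - v1)/v1 × 100`; pairs with a zero
baseline are skipped and counted. Fewer than two observations at or before
the evaluation time give UNKNOWN, which propagates into rule evaluation as
a missing derived variable. Windows given in months use calendar-month
arithmetic with the day-of-month clamped (the clinically usual reading);
fixed-length windows in days are available where exact durations matter.

`series_trend()` classifies the least-squares slope of the in-window
observations, with a dead band — by default 5% of the in-window value range
per window — inside which the series counts as stable, and a per-variable
"higher is better" flag mapping the slope sign to improving/worsening.
Fewer than three observations give `unknown`. Derived variables declared in
the registry are materialized into the patient record before rule
evaluation, so the engine itself stays purely propositional.

## The coaching engine

**Normalization.** All raw input crosses `normalize_value()`: whitespace
trimmed; numerics must parse as plain decimals; booleans accept
true/false, yes/no, 1/0 case-insensitively; categorical values match the
allowed list case-insensitively and are returned as the canonical label.
Anything else raises a typed ingestion error naming the variable and the
raw text — a value is never silently dropped. This strictness is
deliberate: the validation harness exists precisely to surface formatting
problems, and a lenient production reader would hide them.

**Triggering** partitions the active rules of the KB into fired / unknown
(with the exact missing variable ids) / false. Rules whose recommendation
has been excluded are inert and reported in a separate bucket, as are rules
filtered out by the record's group label when it carries one (group
membership is otherwise expected to be encoded in the condition itself, as
in the smoking example). Conditions shared by several rules are evaluated
once per patient.

**Missing-data strategies.** `request_missing()` ranks the variables worth
asking the patient about: those blocking rules that miss at most `limit`
variables (default 2), ordered by how many such rules each would help
decide. When exactly one variable is missing, `cbr_fallback()` can provide
the recommendation anyway if most similar historical patients received it:
similarity means agreeing on every *known* variable the rule's condition
references (numeric values compare at the predicate level — same side of
each cutoff — rather than exact equality), and "most" means support of at
least 5 similar patients with a strict majority agreeing. Both parameters
are configurable and the provided recommendations are flagged provisional.

**Delivery.** Fired recommendations are ordered by priority; ties are
shuffled with R's default Mersenne-Twister generator under a caller-supplied
seed that is recorded in the delivery log, so the "random" order remains
auditable and reproducible. Cluster throttling drops an item when its
cluster appears within the cooldown window (successive deliveries of one
cluster end up separated by at least `cluster_cooldown_days` days) or among
the last `cluster_min_intervening` deliveries; within a single output at
most one item per cluster survives, and the list is capped at
`max_per_session`. The delivered report carries, next to each plain-language
text, the source recommendation and the triggering condition, so the system
never behaves as a black box toward the patient.

## The cohort validation harness

`apply_mapping()` turns a study table into patient records through explicit
transforms (identity, recode tables, threshold binning — e.g. a continuous
inhaled-corticosteroid dose to low/medium/high — and computed columns).
Missing cells stay missing: no imputation, no random attribution.
Normalization failures are logged per row and column and leave the single
value missing. The fraction of KB variables the mapping can feed is reported
alongside.

`run_cohort()` + `classify_untriggered()` reproduce the internal-validation
accounting: per-patient and per-rule trigger statistics, and a four-way
reason taxonomy for rules that never fired. The reasons are assigned in a
fixed precedence order — out of scope, then unavailable variable, then
unsatisfiable, then no matching participant — because scope and data
availability are properties of the study design, satisfiability of the KB
itself, and the residual of the cohort; a fixed order makes the taxonomy
total and deterministic even where the categories overlap.

`consistency_check()` runs two independent routes over the same raw table
and compares fired sets per (patient, rule): the production route (strict
normalization, canonicalized trees, the engine) and a reference route that
re-parses every condition from its text and evaluates it with a numerically
coded Kleene evaluator (TRUE = 1, UNKNOWN = 0.5, FALSE = 0; AND = min,
OR = max, NOT = 1 − x), reading values with a lenient parser that tolerates
comma decimals and trailing unit text. On cleanly formatted data the routes
agree exactly. The corrupted-format fixture (numeric cells written with
comma decimals) makes the strict route drop those values — the affected
rules stay UNKNOWN and are *missed* relative to the reference — emulating
the classic deployment failure in which numeric answers are not read as
numbers; every missed entry is traced to the variables whose readings
differ.

## Synthetic generators

No clinical content ships with the generators: they emulate *structure*.
`kb_structure_config()` fixes exact-count marginals — totals, rules per
recommendation, distinct variables per rule, variable-usage buckets
(1 / 2–3 / 4–10 / >10 rules), condition-reuse buckets (1 / 2–3 / ≥4, plus
the maximum) — and `generate_kb()` realizes them exactly, for every seed:

1. the reuse multiset is realized from its buckets by deterministic
   waterfill (singles stay 1; the 2–3 bucket is topped up to 3; the
   remainder spreads over the ≥4 bucket below the configured maximum);
2. condition sizes are assigned against the vars-per-rule histogram by
   first-fit decreasing on reuse weight (single-use conditions fill the
   remainder exactly);
3. the rule-variable incidence is built by degree-constrained stub matching:
   a greedy pass that prefers variables furthest below their usage bucket's
   lower bound and spreads load across variables in fewer conditions,
   followed by bounded swap repair; infeasible configurations abort with a
   diagnostic naming the violated identity;
4. condition trees are synthesized per variable set — conjunctions of
   per-variable predicates, occasionally grouping a pair under OR — which
   keeps every generated condition satisfiable by construction; collisions
   under canonical form are re-drawn (with a widened predicate space on
   retry) until all conditions are distinct.

The full-scale profile (`full_kb_structure_config()`) encodes the published
structural description of the production knowledge base: 358
recommendations, 405 rules/personalized recommendations, 116 variables, 208
unique conditions, usage buckets 31/35/30/20, reuse buckets 156/44/8 with a
maximum of 62. Two histograms are only summarized in that description, so
their counts were chosen here, once, to match every published figure:
rules per recommendation 341/1/2/14 over 1–4 (mean 1.13, SD 0.60, max 4)
and variables per rule 34/106/96/68/38/33/17/10/3 over 1–9 (mean 3.51,
SD 1.78, 34 single-variable rules, 3 nine-variable rules, 63 rules needing
at least 6 variables). The exact-count marginals are honored exactly;
mean/SD summaries are emergent and checked only within tolerance.

`generate_cohort()` samples variable availability missing-completely-at-
random at a configured rate (the full-scale default emulates a study that
could feed 74 of 116 variables), draws values respecting kinds and allowed
values (booleans Bernoulli(0.5), numerics uniform on 0–100 with one
decimal, categoricals uniform over allowed values), and emits both typed
records and the raw string table an ingestion pipeline would read.
`plant_contradictions` rewrites a chosen number of single-use conditions
into planted contradictions for harness tests, and
`corrupt_numeric_format` writes selected numeric columns with comma
decimals for the consistency fixture.

What the generators do **not** emulate: clinically plausible value
distributions, correlations between variables, realistic per-rule trigger
rates, or the clinical content of conditions. Passing tests therefore
demonstrate that the machinery is correct and that the structural
constraints are achievable — not that any clinical conclusion transfers to
real cohorts.

## Lifecycle and audit trail

Updates go through `apply_change()`: each entry (add/update recommendation,
exclude recommendation, add/update/remove rule, add/update variable) is
applied atomically — the result validates or the change is rejected with
diagnostics and the original KB is untouched — and bumps the dotted version.
Rule additions and edits are additionally vetted by the satisfiability
checker, so a contradictory condition is rejected at edit time with the
verdict cited. Exclusion never deletes: the recommendation keeps its
history, its rules stay serialized but inert. Two vocabulary decisions keep
the audit trail closed under diff/replay: personalized recommendations are
one-to-one with rules and travel inside the rule actions, and the variable
registry is append-only (a harmonized vocabulary loses meaning if entries
vanish); `diff_kb()` refuses deletions it cannot express. For any two KBs
related by expressible edits, `replay(a, diff_kb(a, b))` reproduces `b`
structurally — a property the tests exercise over mutated generated KBs.
Editor identity is a free-text audit field; access control is a deployment
concern.

## Numerical and degenerate-input choices

* Numeric comparisons are exact after decimal parsing — thresholds are
  clinical cutoffs, not measured floats, so no epsilon is applied.
* Sorting uses radix order on serialized text, stable and locale-independent.
* Empty knowledge bases, empty cohorts and empty mappings are valid inputs
  with all-zero/all-missing results.
* `detect_change()` with fewer than two in-scope observations, and
  `series_trend()` with fewer than three, return unknown rather than a
  guess; a zero baseline in relative mode skips the pair and reports it.
* `rank_for_delivery()` with an empty fired set returns an empty order;
  items without a cluster are never throttled.

## Problem sizes

The test suite exercises the evaluator against its enumeration oracle on
1,000 random trees (all leaf assignments, ≈ 180,000 comparisons), Kleene
stability exhaustively on trees over up to 4 variables, satisfiability
against a dense-grid oracle on 500 conditions, the delivery invariants over
10,000 simulated steps, the generator across 20 seeds at the full 405-rule
scale, pipeline self-consistency on a 1,000-patient synthetic cohort, and
lifecycle round-trips over 50 generated KB pairs. The acceptance script runs
the cohort harness at 728 participants, the size of the population study
this kind of knowledge base is validated against.

## Known limitations

* The harmonized-evidence crosswalk defaults to the identity on A–D;
  source-specific gradings (e.g. "Level II") map to absent unless a
  crosswalk is curated.
* Satisfiability is decided over fully known assignments; conditions that
  can only be TRUE through `IS MISSING` are reported unsatisfiable in that
  sense, which is the relevant one for "can this rule ever fire on complete
  data".
* The CBR fallback's similarity is confined to the variables the rule's
  condition references; broader patient similarity is out of scope.
* Cluster membership is metadata supplied by curators; the package
  throttles clusters but does not discover them.
* Multi-editor concurrency and guideline-source monitoring are deployment
  concerns outside the library.
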