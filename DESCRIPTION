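Package: respcoach
Title: Rule-Based Knowledge Base and Individualized Coaching Engine for
    Chronic Respiratory Disease Self-Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, validating and running a clinical knowledge
    base of guideline-derived self-management recommendations for chronic
    obstructive respiratory diseases. Provides a typed variable registry, an
    IF-THEN Boolean condition language with strong Kleene three-valued
    evaluation under missing data, satisfiability checking by interval
    abstraction, longitudinal change and trend detection, a prioritized and
    throttled recommendation delivery policy with a case-based-reasoning
    fallback, a cohort validation harness with a non-trigger reason taxonomy
    and an engine-versus-reference consistency check, structural synthetic
    generators for knowledge bases and patient cohorts, versioned knowledge
    base updates with an audit trail, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
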