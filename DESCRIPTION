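Package: fedomop
Title: Disclosure-Controlled Extraction and Federated GLM Analysis of OMOP CDM Databases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for turning OMOP Common Data Model relational databases into
    analysis-ready person-level tables under DataSHIELD-style disclosure control,
    and for fitting generalized linear models across a simulated multi-site
    federation by summing per-site sufficient statistics each IRLS iteration,
    which reproduces the pooled fit exactly. Includes runtime schema
    introspection with pattern-based column classification, filter pushdown to
    the database, vocabulary-driven concept translation, wide pivoting of
    longitudinal events with time-point completion, a unique-person subset
    threshold applied to every exposed object, and a synthetic CDM generator
    with a known logistic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
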