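Package: knowsub
Title: Substance-Centric Knowledge Engine for Chemical Hazard Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale knowledge engine for regulatory screening of
    chemical substances in the style of REACH PBT/vPvB assessment. Stores
    substances, their identifiers and derived decisions as an RDF graph with
    Turtle input/output and a SPARQL SELECT/ASK subset for dynamic views;
    validates CAS and EC identifiers by their public check-digit schemes and
    reports duplicates and contraindicative identifier sets on a quality
    dashboard; represents decision knowledge as modules of hierarchical
    questions and decisions, non-monotonic scoring rules with three-valued
    conditions, and acyclic decision workflows; derives decision states by
    stateless re-evaluation with full explanations (responsible facts with
    timestamps) and workflow reasoning traces; drives interactive interviews;
    keeps an append-only timestamped fact history with time-machine
    reconstruction of past decision states and decision memos; and bulk
    imports/exports substance tables as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
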