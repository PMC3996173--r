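Package: ongolink
Title: Incremental Probabilistic Record Linkage with an Event-Sourced Linkage Map
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An on-going (incremental) probabilistic record-linkage engine of
    the kind operated by specialised linkage units for health research.
    Implements Fellegi-Sunter agreement/disagreement weighting with
    configurable field comparators and blocking passes; an append-only,
    event-sourced linkage map storing the full history of person-groups with
    point-in-time queries, snapshots and rollback; pluggable grouping
    strategies (transitive-closure merging versus best-link matching against a
    population spine); pair-information-based group unwinding for deleted and
    amended records; project-based and bring-your-own linkage scenarios; an
    automated verify-clean-link-group pipeline with reproducible extractions;
    and a synthetic person-record generator with ground truth for evaluating
    pairwise precision and recall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
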