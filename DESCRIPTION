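Package: upcause
Title: Causal Reasoning over Signed Molecular Networks for Upstream
    Regulator Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers signed upstream molecular hypotheses from
    differential-expression calls using a knowledge base of curated causal
    statements (source entity, signed relation, target entity). Candidate
    regulators are scored with a Fisher exact enrichment p-value and an
    exact correctness p-value computed from the combinatorial null
    distribution of the (#correct - #incorrect) score under random
    re-assignment of up/down labels, then filtered on significance and
    explanatory coverage, clustered by cosine similarity of supporting
    evidence with average linkage, and merged into biological network
    models exportable as SIF and GraphML. Ships a synthetic knowledge-base
    and experiment generator with planted perturbations so the whole
    pipeline is testable without licensed content.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
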