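Package: meshopr
Title: MeSH Over-Representation Profiles for Biomedical Entities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds MeSH over-representation profiles (MeSHOPs): given a
    controlled vocabulary with hierarchical tree positions, an annotated
    article corpus, and per-entity bibliographies, computes for each entity a
    vector of (term, p-value) pairs measuring over-representation of each
    annotation term among the entity's articles relative to a background,
    using one-sided Fisher's exact tests on 2x2 contingency tables.
    Annotations are propagated upward through the vocabulary hierarchy before
    counting.  Includes specificity filtering of profiles to the most
    specific significant terms, class-specific backgrounds, temporal slicing
    of bibliographies, Euclidean profile distances with complete-linkage
    clustering, word-cloud export, and a synthetic corpus generator with
    planted enrichment signal for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
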