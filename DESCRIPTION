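Package: tepinkit
Title: Time-Evolving Protein Interaction Networks and Temporal Protein
    Complex Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds time-evolving protein interaction networks from a
    static protein-protein interaction network and a time-course gene
    expression matrix, calling each protein's active time points with a
    deviation-degree rule (active when expression strictly exceeds the
    gene's own mean plus one standard deviation).  Snapshot edges are
    weighted by complex-derived connected affinity plus Pearson
    co-expression and non-positive edges are discarded as likely false
    positives.  Temporal protein complexes are mined per snapshot with a
    bundled Markov clustering implementation, merged across time points,
    and filtered for redundancy by overlap score.  Evaluation utilities
    cover overlap-score matching against a reference complex catalogue,
    sensitivity/specificity/F-measure summaries, exact hypergeometric
    function-enrichment p-values, and a seeded synthetic-data generator
    with planted complexes and co-expression windows for end-to-end
    validation.
License: MIT + file LICENSE
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
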