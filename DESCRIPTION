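Package: cupp
Title: Conserved Unique Peptide Pattern Clustering and Annotation of
    Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Alignment-free clustering of protein families into groups
    defined by conserved short peptides with ambiguous positions, and fast
    annotation of query proteins against a compiled peptide library.
    Proteins are decomposed into fixed-length peptide variants by a sliding
    window; an incremental clustering scheme with a dissimilarity based on
    shared peptide start positions recovers peptide-defined groups within a
    family (such as a CAZy glycoside hydrolase family); the groups are
    finalized into weighted peptide models and merged into a cross-family
    lookup index used to assign family, group, subfamily and EC function
    to query sequences. Includes a cluster-aware cross-validation
    framework and a synthetic family generator for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
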