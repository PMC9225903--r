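Package: snptag
Title: Tag SNP Selection by Fuzzy LD Clustering and Constrained Binary
    Particle Swarm Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects informative (tag) SNPs from phased haplotype data.
    Pairwise linkage disequilibrium (Lewontin |D'|) defines a fuzzy
    similarity relation over loci; its max-min transitive closure is
    lambda-cut into equivalence classes whose centers form a reduced
    candidate set. A cardinality-constrained binary particle swarm
    optimizer with phase-switched velocity, probability-mapping and
    position rules then picks a fixed-size tag set, and the tag set is
    scored by leave-one-out imputation of non-tag genotypes with
    per-locus RBF-kernel support vector classifiers. Includes a
    block-structured haplotype simulator with known ground truth, phased
    VCF and plain-text matrix input, broom-style tidiers, ggplot2
    autoplot methods and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
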