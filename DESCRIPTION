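Package: nichepair
Title: Paired Anterior-Nares and Nasopharyngeal Microbiota Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the joint analysis of paired upper-airway microbiota
    samples (anterior-nares nasal swabs and nasopharyngeal aspirates) from a
    multicenter infant bronchiolitis cohort design. Provides genus-level
    abundance table handling (taxonomy collapse, relative abundance,
    rarefaction), alpha and beta diversity (Shannon, Bray-Curtis, weighted
    UniFrac), a permutation test for intra-individual cross-site concordance,
    an ensemble co-occurrence/co-exclusion network over four association
    metrics with a compositionality-aware permutation null, PAM k-medoids
    dominance profiling with gap-statistic and silhouette model selection,
    and fixed- and mixed-effects logistic models relating microbiota profiles
    to severity outcomes. A seeded synthetic-cohort generator emulating the
    paired two-site study structure makes the whole pipeline testable
    end-to-end without access to the original sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    vegan,
    ape,
    lme4,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    phyloseq,
    phangorn,
    optparse
Config/testthat/edition: 3
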