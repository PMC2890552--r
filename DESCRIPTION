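Package: retqtl
Title: Candidate Gene Prioritization for Retinal Degeneration QTL from
    Dye-Swap Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline from two-color dye-swap cDNA microarray
    intensities and strain SNP tables to ranked candidate genes for
    age-related retinal degeneration quantitative trait loci (QTL).
    Implements per-chip lowess intensity correction, cross-chip standard
    deviation rescaling, dye-swap dye-effect estimation and removal,
    missing-value gene filtering, one-group and two-sample t contrasts with
    SAM-style permutation false discovery rates, MAPPFinder-style Gene
    Ontology overrepresentation (standardized hypergeometric Z score with
    permutation p values), strain-haplotype SNP filtering with a two-criterion
    evidence score for genes in QTL intervals, comparative-Ct qPCR relative
    expression with ANOVA and Holm-Sidak pairwise comparisons, and outer
    nuclear layer thickness genotype association.  Includes seeded synthetic
    data generators for every input type with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
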