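Package: minscreen
Title: Design and Analysis of Forward Screens for Dominant Quantitative
    Modifiers of Tumor Multiplicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing mutagenesis screens that seek
    dominant quantitative modifiers of an overdispersed count phenotype, such
    as intestinal tumor multiplicity in Apc(Min/+) mice. Implements a
    segregating three-component finite mixture model (unaffected, suppressor,
    enhancer kindreds) with maximum-likelihood estimation of the modifier
    induction rate and the distribution of multiplicative fold effects;
    negative-binomial power calculations for clustered progeny tests and
    screen-size design under a false-discovery-rate nonempty-list criterion;
    enrichment achieved by preselecting kindreds with multiple extreme
    animals; residual-heterozygosity expectations under repeated sib mating;
    and construction of isogenic single-nucleotide-variant mapping panels
    from multi-line variant tables (filtering, line-specific partitioning,
    mutation-spectrum summaries, marker ranking and selection, gap reports)
    together with classification of genotyping-assay validation results.
    Synthetic-data generators reproduce the statistical structure every
    stage assumes, so the full workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
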