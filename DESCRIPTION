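Package: codonNeutral
Title: Codon-Aware Neutral Models for Somatic Missense Mutation Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tests whether the amino-acid substitutions observed in a somatic
    mutation cohort are more evolutionarily radical or conservative than
    expected under a codon-aware neutral model. The model enumerates every
    single-nucleotide missense event reachable from a gene's coding sequence,
    weights events by base-substitution (mutational signature) probabilities,
    scores them with BLOSUM62, and compares observed cohort summaries (mean
    score, radical fraction) against Monte Carlo neutral replicates via
    one-sided empirical p-values. Domain-level burden is assessed with
    enrichment ratios and chi-square / likelihood-ratio G goodness-of-fit
    tests. Includes a MAF-lite cohort reader, HGVSp protein-change parsing,
    a synthetic cohort generator with tunable selection pressure, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SomaticMutation, StatisticalMethod, Sequencing, VariantAnnotation
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
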