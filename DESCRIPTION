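Package: hlapop
Title: Population Genetics of HLA Samples with Typing Ambiguities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for population-genetic analysis of HLA typing data that
    carry allele-level ambiguity.  Provides an ambiguity-preserving genotype
    representation (genotype-list strings and tabular dialects), NMDP-style
    multiple-allele-code expansion with spurious-pair accounting, allele-name
    parsing and resolution recoding, interpretation of probe-reactivity
    patterns against typing-kit descriptions, maximum-likelihood allele and
    haplotype frequency estimation by expectation-maximization over ambiguity
    sets, Hardy-Weinberg testing by nested likelihood ratios, the
    Ewens-Watterson selective-neutrality test with an exact small-sample null,
    sample-size significance thresholds for allele frequencies, and a
    standardized analysis report.  A synthetic-data generator produces
    Hardy-Weinberg samples, typing kits and kit-masked ambiguous typings so
    the whole chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
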