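Package: glycoloc
Title: Post-GWAS Comparison of Genetic Regulation of Protein N-Glycosylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the genetic regulation of a post-translational
    modification (N-glycosylation) on two proteins from GWAS summary
    statistics: fixed-effect inverse-variance meta-analysis with genomic
    control, window-based locus definition, approximate conditional and joint
    analysis (COJO-style) from summary statistics plus an LD reference,
    approximate-Bayes-factor colocalisation with transitive trait grouping and
    pairwise-conditional colocalisation (PwCoCo), the SMR test with the HEIDI
    heterogeneity filter, and bidirectional inverse-variance-weighted
    Mendelian randomisation. A synthetic-cohort generator with controlled
    causal architecture (shared versus protein-specific causal variants,
    LD-structured genotypes, compositional glycan-peak phenotypes) makes the
    whole cascade testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lmtest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
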