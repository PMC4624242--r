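Package: strainprofiler
Title: Variant-Score Profiling, Ortholog Detection and MLST Phylogeny for
    Haploid Bacterial Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for panels of closely related
    haploid bacterial strains (e.g. soybean-fermenting Bacillus subtilis).
    Filters variant calls by depth and quality, classifies each variant at
    four impact levels (high, moderate, low, modifier) against a reference
    genome, computes impact-weighted log variant scores per gene with
    strain-specific constants, and profiles strains by unscaled principal
    component analysis and complete-linkage hierarchical clustering.
    Detects orthologs between gene sets by reciprocal best hits under dual
    80 percent identity and coverage criteria, and performs multilocus
    sequence typing with allelic profiles, Kimura 2-parameter distances,
    neighbor-joining trees and bootstrap supports. Includes a synthetic
    strain generator with planted ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
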