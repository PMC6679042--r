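Package: rohscan
Title: Runs of Homozygosity, ROH Islands and Selection-Signature Screening
    for Multi-Breed SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) in SNP-array genotype panels
    and screens multiple populations for ROH islands - genomic regions where
    more than half of a breed's individuals carry overlapping ROH - as
    signatures of selection. Provides bit-exact PLINK bed/bim/fam input and
    output, SNP quality control, an exact and a sliding-window ROH caller
    under segment constraints (minimum length, homozygous-SNP count,
    heterozygote/missing allowances, density and gap rules), per-breed
    incidence tracks and island calling, cross-breed island overlap and
    private-island classification, per-locus genotype frequencies with an
    exact Hardy-Weinberg test, identity-by-state PCA for population
    stratification, and a multi-breed panel simulator with implanted
    autozygous tracts and a truth set for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
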