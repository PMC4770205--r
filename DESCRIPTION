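Package: clonecall
Title: Tumor Purity, Ploidy and Subclonal Deconvolution from Copy Ratios
    and B-Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers tumor purity, genome ploidy, subclonal prevalences and
    allele-specific copy number from paired tumor/normal sequencing
    summaries: a segment table of tumor/normal copy-number ratios plus
    tumor B-allele frequencies at germline heterozygous loci.  A
    closed-form forward model maps allele-specific copy-number states
    (x, y, p) to expected copy ratio and heterozygous-deviation score,
    forming a branch lattice on the R-HDS plane; a three-step heuristic
    (ploidy adjustment, prevalence detection by grid search and
    hierarchical clustering, per-segment state assignment) automates the
    interpretation.  Fitted states feed a somatic-variant chronology
    classifier, and a segment-level tumor-mixture simulator with known
    clone trees supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
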