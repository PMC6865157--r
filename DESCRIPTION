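Package: varident
Title: Identifying Actual Disease Variants in a Gene Region by Genotypic
    Likelihood-Ratio Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes actual disease variants from synthetic
    (linkage-disequilibrium-induced) association signals in case-control
    genotype data for a gene region.  Candidate disease-variant models are
    screened exhaustively with a genotypic multinomial likelihood-ratio
    test whose variance is corrected by resampling pseudo-case samples
    from the control panel; sets of putative disease variants are
    collapsed into one virtual disease variant at the haplotype level.
    Includes the sufficient-causal-component disease-model calculus
    linking odds ratios, causal proportions and penetrance, a synthetic
    haplotype-panel generator emulating the APOE region of the 1000
    Genomes Project, and simulation tools for estimating Type I and
    Type II error rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
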