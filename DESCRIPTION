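Package: hereg
Title: IBS-Based Haseman-Elston Regression for SNP Heritability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates SNP heritability from population (GWAS-style) genotype
    data with an identity-by-state Haseman-Elston regression: pairwise squared
    phenotype differences (or cross-products) regressed on a genomic
    relationship matrix built from standardized genotypes.  Provides the exact
    two-locus linkage-disequilibrium algebra behind the method, closed-form
    expectations of the regression coefficient under single- and multi-marker
    tagging, analytic standard errors based on the effective number of markers,
    an observed-to-liability-scale transformation for ascertained case-control
    samples, a single-component GREML comparator, and simulators for AR(1)-LD
    genotypes, polygenic quantitative traits, and liability-threshold
    case-control studies.  Reads PLINK binary filesets and plain-text dosage
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
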