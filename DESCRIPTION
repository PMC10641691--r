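Package: rrsgs
Title: Genomic Selection Toolkit for Reciprocal Recurrent Selection Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-generational genomic evaluation in reciprocal
    recurrent selection (RRS) tree breeding programs. Implements pedigree
    (A, A-inverse, dominance D), genomic (additive G and dominance G_D) and
    blended single-step (H, H-inverse) relationship matrices; average-information
    REML with Henderson mixed-model-equation BLUP for pedigree (ABLUP), genomic
    (GBLUP) and single-step (HBLUP) models; SNP quality control with
    expected-frequency imputation; growth-curve harmonization of measurements
    taken at heterogeneous ages onto common reference ages; realized
    predictive ability, bias, rank-concordance and coincidence-rate
    assessment; and a synthetic breeding-program generator (two divergent
    founder species, polymix half-sib and interspecific hybrid families,
    gene-dropped SNP genotypes, additive-dominance trait architecture) with
    known ground truth for validating the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
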