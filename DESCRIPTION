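Package: epmediate
Title: Gene-Endophenotype-Reading Mediation Analysis with Family-Clustered Bootstrap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for candidate-gene endophenotype mediation studies of reading
    (dis)ability. Implements a multiple-predictor/multiple-mediator path model
    linking SNP genotypes to a reading composite through cognitive and sensory
    endophenotypes, with family-clustered bias-corrected bootstrap confidence
    intervals for specific and total indirect effects, maximum-likelihood
    goodness-of-fit indices (chi-square, RMSEA with confidence interval, CFI,
    SRMR), and post-hoc power via the noncentral chi-square RMSEA method and the
    joint-significance method for indirect effects. Includes genotype quality
    control (allele frequencies, Hardy-Weinberg tests, additive versus
    presence/absence coding by minor-allele frequency), trial-level scoring of
    rapid auditory processing, rapid naming, multisensory cued attention and a
    motion-illusion psychometric function, and a family-structured synthetic
    cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
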