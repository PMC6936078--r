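Package: snpmatchr
Title: Bayesian Sample Identity Verification from Sequencing Allele Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decides whether two next-generation-sequencing samples derive
    from the same human individual. Reference and alternate read counts are
    collected by pileup at a fixed panel of common exonic SNPs and combined,
    through a beta-binomial genotype evidence model with Hardy-Weinberg
    genotype-pair priors, into a single posterior probability of identity.
    Works across data types (RNA-Seq, exome, MethylCap-Seq) and down to very
    low coverage. Includes panel construction from candidate VCFs and capture
    BEDs, reusable per-sample fingerprints, all-vs-all comparison, ROC
    evaluation, and a synthetic-cohort simulator with pedigree support.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    Rsamtools,
    jsonlite,
    rlang,
    stats,
    utils,
    vcfR
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
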