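Package: cystevol
Title: Clonal Evolution Analysis of Neoplastic Pancreatic Cysts and
    Associated Invasive Carcinomas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-region sequencing analysis of mucinous pancreatic cysts
    (IPMN/MCN) and their associated invasive carcinomas. Implements
    cross-sample somatic mutation re-genotyping with coverage-scaled
    presence/absence thresholds, targeted-panel copy-ratio estimation with
    GC correction, tiered genome-wide loss-of-heterozygosity comparison from
    germline heterozygous SNP minor-allele frequencies, alteration-cluster
    maximum-parsimony phylogenetics with clonal-mixing correction and
    ancestry classification (cancerization of ducts, independent clones),
    and a hierarchical Poisson-Gamma Bayesian model of the time between
    high-grade dysplasia and invasive cancer. Includes a synthetic cohort
    simulator that emulates the study design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
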