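Package: snpabc
Title: Coalescent Simulation and Approximate Bayesian Computation for
    SNP-Based Demographic History Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the demographic history of structured
    populations from unlinked biallelic SNPs by approximate Bayesian
    computation (ABC).  Provides a declarative scenario language for
    divergence/admixture histories, a Hudson-style coalescent simulator of
    independent SNP loci (compiled core), a DIYABC-style 26-component
    summary-statistic vector (gene diversity, Weir-Cockerham F_ST, Nei 1972
    distance, three-sample admixture estimates), a genotype quality-control
    filter cascade (biallelic, missingness, MAF, exact Hardy-Weinberg test,
    F_ST outliers, LD pruning), reference-table construction, scenario choice
    by the direct and logistic-regression approaches with prior error rates,
    local-linear-regression posterior estimation with logit transforms,
    posterior-predictive model checking, and divergence-time recalibration
    into calendar years.  A synthetic-data module generates study-structured
    datasets with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    nnet,
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
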