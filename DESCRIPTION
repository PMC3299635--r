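Package: rohscan
Title: Runs-of-Homozygosity Detection, Burden Testing and Homozygosity Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control analysis of runs of homozygosity (ROH) from SNP
    genotype panels. Implements sliding-window ROH detection with PLINK-style
    window semantics and an exhaustive brute-force oracle, separation of common
    (identical-by-state) from rare (likely identical-by-descent) runs using a
    regional carrier-frequency rule with mean+3SD length-outlier retention,
    case-control homozygosity burden statistics with permutation empirical
    p-values, covariate-adjusted logistic models (method-of-moments inbreeding
    coefficient, identity-by-state multidimensional scaling, LD pruning), and
    two permutation-corrected homozygosity-mapping schemes over consensus
    regions and gene intervals. A synthetic-data module generates diploid
    genotype panels under Hardy-Weinberg equilibrium with planted autozygous
    segments, common low-heterozygosity clusters and configurable inbreeding,
    so every stage of the pipeline can be validated against known truth.
License: MIT
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
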