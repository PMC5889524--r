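Package: popdrift
Title: Population Structure, Divergence Dating and Gene-Flow Inference from SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the structure, divergence and admixture of
    closely related populations from diploid SNP genotype panels: unbiased
    (Weir-Cockerham) F_ST and allele-sharing distances with neighbor-joining
    trees, EIGENSOFT-style PCA and K-means clustering on top principal
    components, ancestry-informative-marker panel selection scored by the
    Matthews correlation coefficient, linkage-disequilibrium-based effective
    population size trajectories with F_ST divergence dating, and D/f2/f3/f4
    statistics with delete-m block-jackknife errors plus F4-regression
    estimation of admixture proportions. Includes seed-deterministic
    synthetic-data generators (Balding-Nichols drift, frequency-mixture
    admixture, forward Wright-Fisher haplotypes) so every stage has a
    known-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    vcfR,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
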