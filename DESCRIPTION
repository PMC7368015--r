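Package: micropart
Title: Joint Variance Partitioning of Host Genetics and the Rumen
    Microbiome for Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Partitions the variance of a quantitative phenotype (such as
    dairy-cow methane emission) into a host polygenic component and a
    microbiome component by jointly fitting a mixed model with a
    four-component scale-mixture ("BayesR"-style) prior on microbial-taxon
    effects, sampled by Markov chain Monte Carlo.  Includes the companion
    analyses: genomic REML heritability of microbial abundances and
    community summaries (Bray-Curtis PCoA, Chao1, PCA on centred log-ratio
    data), single-SNP mixed linear model association with P3D variance
    components, SNP quality control, compositional transforms, pedigree
    and Yang-et-al. genomic relationship matrices, and a synthetic-data
    generator with recorded ground truth for recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
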