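# micropart

Joint variance partitioning of a quantitative phenotype between **host
genetics** and the **rumen microbiome**, for studies asking how much of a
trait like dairy-cow methane emission is heritable, how much is
"microbiable", and whether the microbiome itself is under host genetic
control.

## The model

For `n` animals, the phenotype is modelled as

    y | γ, u, β, σ²e  ~  N(Xγ + Zu + Mβ, I σ²e)

with fixed effects `X` (intercept, herd, parity, days in milk and a
Wilmink lactation term), a polygenic effect `u ~ N(0, K σ²u)` whose
covariance `K` is a pedigree **A** or Yang-et-al. genomic **G** matrix, and
`M` the matrix of transformed taxon abundances.  Each taxon effect carries
a K-component scale-mixture-of-normals prior (the BayesR family):

    βᵢ | zᵢ = k ~ N(0, σ²k),   σ²k = rk σ²1,  r = (1, 10, 100, 1000)
    zᵢ ~ cat(π),               π ~ Dir(125, 25, 5, 1)

so most taxa are shrunk hard towards zero while a few may carry large
effects.  An MCMC sampler (Gibbs updates for location effects, π and the
scalar variances; Metropolis–Hastings for the component indicators and the
tied mixture variances) accumulates the posterior of `var(Mβ)` at every
cycle; the package reports posterior means, 95% highest-posterior-density
intervals of the explained-variance shares, DIC for model comparison (e.g.
4- vs 2-component mixtures) and per-taxon variance contributions.

Around the core model: SNP quality control, log-standard and centred
log-ratio abundance transforms, genus collapsing, pedigree/genomic
relationship matrices, genomic REML heritability scans with
Benjamini–Yekutieli FDR control, P3D/EMMAX single-SNP mixed-model
association, Bray–Curtis PCoA, Chao1 and compositional PCA, and a
synthetic-data generator (gene-dropped genotypes, zero-inflated OTU
counts, model-exact phenotypes) with recorded ground truth.

## Worked example

```r
library(micropart)

# 1. simulate a small herd: genotypes + pedigree, OTU counts, phenotype
sim <- sim_genotypes(n = 300, m = 2000, n_families = 20, seed = 42)
G   <- grm_yang(sim$genotypes)
otu <- sim_otu_counts(G, p = 200, heritable_fraction = 0.2,
                      otu_h2 = 0.25, zero_inflation = 0.3, seed = 43)
covs <- data.frame(animal_id = rownames(G),
                   herd = sample(paste0("H", 1:6), 300, TRUE),
                   parity = sample(1:4, 300, TRUE),
                   dim = sample(1:350, 300, TRUE))
X <- build_fixed_design(covs)
M <- log_standardize(filter_prevalence(otu))
truth <- sim_phenotype(X, G, M, h2_target = 0.25,
                       microbiability_target = 0.07, seed = 44)

# 2. joint Bayesian variance partitioning
cfg <- run_config(chain_length = 10000, burn_in = 2000, thin = 5)
fit <- microbiability(truth$y, X = X, kinship = G, microbiome = M,
                      config = cfg, seed = 45)
fit
#> Bayesian mixture-prior variance partitioning (mb_fit)
#>   n = 300 animals, 200 taxa, K = 4 components, polygenic term
#>   chain: 10000 iterations (burn-in 2000, thin 5, 1600 saved)
#>   host_genetics   28.8%  (95% HPD 12.3% - 45.6%)
#>   microbiome       5.3%  (95% HPD 0.1% - 12.2%)
#>   residual        66.0%  (95% HPD 45.2% - 82.6%)
#>   DIC = 795.2 (pD = 94.0)
```

The simulation targeted a host share of 25% and a microbiome share of 7%;
the posterior puts the host share at 28.8% and the microbiome share at
5.3%, with both HPD intervals covering the truth.  `summary(fit)` adds the
mixture occupancies and the top taxa by posterior variance contribution;
`plot(fit)` draws the chain traces; `coef`, `fitted`, `residuals` and
`simulate` behave as for any fitted model.

```r
# 3. heritability of community traits (REML + BY adjustment)
pco <- pcoa(bray_curtis(otu), n_axes = 2)
tr  <- cbind(pcoa1 = pco$coordinates[, 1],
             chao1 = apply(otu$counts, 1, chao1))
trc <- apply(tr, 2, function(v) precorrect_phenotype(v, X))
h2_scan(trc, G)
#>      id   estimate         se statistic      p_value   p_adjusted method
#> 1 pcoa1 0.54363839 0.09793740 5.5508761 1.421207e-08 4.263622e-08     BY
#> 2 chao1 0.06455155 0.08552527 0.7547659 2.251947e-01 3.377921e-01     BY
```

Here the leading community-composition axis is strongly heritable (the
simulated OTU table gave a fifth of the taxa a latent heritability of
0.25), while richness is not — `estimate` is the REML h², `p_adjusted`
the Benjamini–Yekutieli value.

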