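---
title: "Partitioning phenotypic variance between host genetics and the rumen microbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning phenotypic variance between host genetics and the rumen microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Enteric methane from dairy cattle is a quantitative phenotype shaped by the
host's genome and by the composition of its rumen microbial community.  Two
questions follow: how much of the phenotypic variance is attributable to
host additive genetics (heritability, $h^2$), how much to variation in
microbial abundances ("microbiability"), and — separately — to what extent
the microbial abundances are themselves under host genetic control.
`micropart` implements a joint Bayesian answer to the first question and the
REML/association machinery for the second, together with the preprocessing,
relationship-matrix and community-summary steps both need.

## The joint model

For $n$ animals with phenotype $\mathbf{y}$ (e.g. methane in l/day),

$$\mathbf{y} \mid \boldsymbol\gamma, \mathbf{u}, \boldsymbol\beta, \sigma^2_e
  \sim N(\mathbf{X}\boldsymbol\gamma + \mathbf{Z}\mathbf{u} +
  \mathbf{M}\boldsymbol\beta,\; \mathbf{I}\sigma^2_e),$$

where $\mathbf{X}$ holds an intercept, herd and parity dummies, days in milk
(DIM) and a Wilmink lactation-curve term $e^{-k\,\mathrm{DIM}}$;
$\mathbf{u} \sim N(0, \mathbf{K}\sigma^2_u)$ is the polygenic effect with
$\mathbf{K}$ a pedigree ($\mathbf{A}$) or SNP-based ($\mathbf{G}$,
Yang-et-al. estimator) relationship matrix; and $\mathbf{M}$ is the
$n \times m$ matrix of transformed taxon abundances with effects
$\boldsymbol\beta$.

Each taxon effect gets a $K$-component scale-mixture-of-normals prior
(the BayesR family), with component indicators $z_i$:

$$\beta_i \mid z_i = k \sim N(0, \sigma^2_k), \qquad
  z_i \sim \mathrm{cat}(\pi_1, \dots, \pi_K), \qquad
  \boldsymbol\pi \sim \mathrm{Dir}(\alpha_1, \dots, \alpha_K).$$

The component variances are tied to fixed, strictly increasing ratios
$\sigma^2_k = r_k\,\sigma^2_1$ with $r = (1, 10, 100, 1000)$ by default, and
only the common scale $\sigma^2_1$ is sampled.  Component 1 is the
strongest-shrinkage ("negligible effect") class and component $K$ the
mildest; combined with the default $\mathrm{Dir}(125, 25, 5, 1)$ prior,
which concentrates prior mass on the first class, this induces a sparse
model in which most taxa are shrunk towards zero while a small number may
carry large effects.  This orientation — most prior mass on the
*most*-shrunken class — is what makes the mixture a variable-selection
prior; reversing it would instead assert that most taxa have the largest
effects.  Both $\alpha$ and $r$ are configurable (`run_config()`), including
the two-component special case and more extreme ratio ladders such as
1:100:1000:10000 used for prior-sensitivity analyses.

Variance components $\sigma^2_e$ and $\sigma^2_u$ carry flat priors, and
$\sigma^2_1$ an (improper) flat prior on the log scale.

### The MCMC scheme

* $\boldsymbol\gamma$, the rotated polygenic coefficients, and each
  $\beta_i$ have normal full conditionals: Gibbs updates with an
  incrementally maintained residual.
* The polygenic term is reparameterised through one eigendecomposition
  $\mathbf{K} = \mathbf{U}\mathbf{D}\mathbf{U}'$:
  $\mathbf{u} = \mathbf{L}\mathbf{a}$ with
  $\mathbf{L} = \mathbf{U}\mathbf{D}^{1/2}$ (zero eigenvalues dropped), so
  $\mathbf{a}$ has iid prior $N(0, \sigma^2_u)$, $\mathbf{L}'\mathbf{L}$ is
  diagonal, and the whole $\mathbf{a}$-block is drawn jointly from
  independent normals at the cost of two matrix-vector products per
  iteration.  $\mathbf{u}'\mathbf{K}^{-1}\mathbf{u} = \mathbf{a}'\mathbf{a}$
  for the variance update.
* Indicators $z_i$ move by a $\pm 1$ random-walk Metropolis-Hastings step:
  interior components propose either neighbour with probability 0.5,
  boundary components their single neighbour with probability 1, and the
  Hastings correction uses both proposal densities (so for $K = 2$, where
  every state is a boundary, the corrections cancel exactly).
* $\boldsymbol\pi$ is conjugate: $\mathrm{Dir}(\alpha + n_k)$ Gibbs.
* $\sigma^2_e \sim e'e/\chi^2_{n-2}$ and
  $\sigma^2_u \sim \mathbf{a}'\mathbf{a}/\chi^2_{q-2}$ (flat-prior
  scaled-inverse-chi-square conditionals; $q$ = rank of $\mathbf{K}$).
* The tied component variances move jointly by a log-normal random walk on
  $\sigma^2_1$, accepted with the likelihood ratio of $\boldsymbol\beta$
  under current and proposed variances times the proposal Jacobian
  $\sigma^{2\prime}_1/\sigma^2_1$ — the form consistent with the flat
  prior on the variance itself.  (Dropping the Jacobian would implicitly
  put a flat prior on $\log\sigma^2_1$, which is improper at zero; because
  the density $N(0;0,\sigma^2)$ diverges as $\sigma^2 \to 0$, a chain under
  that implied prior can fall into the degenerate all-shrunken spike and
  never leave.)  The ratio constraint holds exactly at every iteration, and
  the step size is tuned towards a 20–50% acceptance rate during burn-in
  only, so the post-burn-in kernel is fixed and valid.

All randomness flows through R's RNG, so a fixed seed reproduces a chain
bit for bit.

### What is reported

`var(Zu)` is read off as $\sigma^2_u$; `var(Mβ)` has no closed form under
the mixture, so the sample variance (divisor $n-1$) of the vector
$\mathbf{M}\boldsymbol\beta$ is computed at every saved cycle and its
posterior summarised.  Explained-variance proportions divide each component
by $\sigma^2_u + \mathrm{var}(\mathbf{M}\boldsymbol\beta) + \sigma^2_e$;
fixed-effect variance is deliberately excluded from the denominator, so the
shares answer "of the variance the model treats as random, how much is
host/microbiome/noise".  Intervals are 95% highest-posterior-density
intervals (shortest contiguous interval over the sorted draws).  Model
comparison uses DIC with $p_D = \bar D - D(\hat\theta)$ evaluated at the
posterior means of the linear predictor and $\sigma^2_e$.  Per-taxon
contributions are posterior means of $\mathrm{var}(m_i\beta_i) =
\beta_i^2\,\mathrm{var}(m_i)$.

### Defaults and tunables

| parameter | default | meaning |
|---|---|---|
| `chain_length` / `burn_in` / `thin` | 100000 / 10000 / 20 | chain protocol; saved draws = (100000-10000)/20 |
| `n_components` | 4 | mixture size K (2 enables the two-component comparison) |
| `dirichlet_alpha` | 125, 25, 5, 1 | prior counts; strong enough for sparsity, weak enough to learn |
| `variance_ratios` | 1, 10, 100, 1000 | $\sigma^2_k / \sigma^2_1$, increasing |
| `prevalence_min` | 0.5 | taxon kept iff present in ≥ half the samples (boundary inclusive) |
| `pseudo_count` | 0.001 | added before the natural log in the log-std transform |
| `clr_zero` | 0.5 | additive zero replacement before CLR |
| `wilmink_k` | 0.05 | lactation-curve decay per day (the classical choice) |
| `mh_step_sd` | 0.1 | initial log-scale step for the variance move |

Initialisation: $\boldsymbol\gamma$ at least squares, $\mathbf{u} = 0$,
$\boldsymbol\beta = 0$, all $z_i = 1$, $\boldsymbol\pi$ at its prior mean,
$\sigma^2_e = \mathrm{var}(y)/2$, $\sigma^2_u = \mathrm{var}(y)/4$, and
$\sigma^2_1 = \mathrm{var}(y) / (2\,m \sum_k \pi^0_k r_k)$ so the
prior-expected $\mathrm{var}(\mathbf{M}\boldsymbol\beta)$ at the start is
half the phenotypic variance.  Starting the mixture variances much smaller
can trap the chain in a fully-shrunken state for many iterations (all
$\beta_i \approx 0$ keeps the variance scale down, which keeps the
$\beta_i$ down); the half-variance start avoids that failure mode without
affecting the target distribution.

Numerical guards: variance draws floored at $10^{-12}$; any variance
exceeding $10^{12}$ aborts with a divergence diagnostic; relationship-matrix
eigenvalues are clipped at zero, with matrices whose negative eigenvalue
mass exceeds 5% of the largest eigenvalue rejected as non-PSD (the Yang GRM
is legitimately very slightly indefinite at finite marker counts because of
its adjusted diagonal); near-singular matrices entering REML get a logged
$10^{-6}$ ridge.

## Preprocessing

SNP quality control applies, in order: individual call rate ≥ 0.99, SNP
call rate ≥ 0.98, Hardy-Weinberg equilibrium ($p \ge 10^{-8}$; exact
enumeration test when any expected genotype cell is below 5, chi-square
otherwise), and minor allele frequency ≥ 0.02.  Residual missing genotypes
are imputed to the SNP mean so that matrix algebra downstream sees complete
data.

Abundances reach $\mathbf{M}$ by one of two routes, run separately: the
log-standard route ($\ln(c + 0.001)$, then per-taxon z-score with divisor
$n-1$) and the compositional route (centred log-ratio per sample after
additive zero replacement; rows sum to zero).  CLR output is *not*
column-standardised by default — its per-taxon scales are part of the
compositional geometry — but a `standardize` flag provides that variant.
Sequencing-instrument structure can enter either as within-instrument
standardisation plus an instrument dummy in $\mathbf{X}$ (default) or as
fully instrument-nested taxon effects (`nested_instrument = TRUE`, doubling
the columns of $\mathbf{M}$).

## Heritability of microbial traits and association

For one pre-corrected trait (a genus or OTU abundance, an ordination axis,
or Chao1 richness), $\mathbf{y} = \mathbf{1}\mu + \mathbf{u} + \mathbf{e}$
with $\mathbf{u} \sim N(0, \mathbf{G}\sigma^2_g)$ is fitted by REML:
one eigendecomposition of $\mathbf{G}$, a 1-D profile optimisation over
$h^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$, a delta-method SE from the
numerical information matrix (evaluated just inside the boundary when the
estimate hits it), and a one-sided Wald p-value (variance ratios cannot be
negative).  Scans over many traits share the eigendecomposition and adjust
p-values by the Benjamini-Yekutieli step-up procedure, which is valid under
arbitrary dependence.

Single-SNP association uses the P3D/EMMAX strategy: variance components are
estimated once under the null model and frozen, each SNP is then a
generalised least-squares fixed effect with covariance
$\sigma^2_g\mathbf{G} + \sigma^2_e\mathbf{I}$, tested by
$t = \hat g / SE$ with $df = n - 2$ (mean plus SNP; the polygenic effect's
effective dimension is not charged to the test), and Bonferroni-adjusted.
Exact per-SNP REML is available behind `per_snp_reml = TRUE`.  Note that
P3D deliberately absorbs structure-correlated signal into the polygenic
term, which costs power for causal SNPs that are themselves correlated with
relatedness — the usual trade-off of this approximation.

## Community summaries

Bray-Curtis dissimilarity is computed on raw filtered counts (conventional
use; Bray-Curtis requires non-negative input, so transformed matrices are
not meaningful inputs — a `relative` flag switches to proportions).
Principal coordinates come from classical scaling of
$-\tfrac12 D^2$; negative eigenvalues are dropped without Cailliez
correction and their mass fraction recorded.  Chao1 uses the bias-corrected
form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$, defined even without doubletons.
PCA on the CLR matrix (Aitchison geometry) supplies the compositional
ordination; its duality with classical scaling of Euclidean CLR distances
is exercised in the tests.

## The synthetic-data generator

The generator emulates the structure of a 750-cow study rather than any
real dataset:

* **Genotypes/pedigree** — sire families built founders-first (one sire,
  founder dams with two offspring each), founder genotypes at
  Hardy-Weinberg proportions with frequencies uniform on the configured
  MAF range, offspring by per-SNP Mendelian gene dropping.
* **OTU counts** — per-taxon latent log-abundance = polygenic value
  (variance `otu_h2`, covariance from the same relationship-matrix
  machinery the phenotype uses) + environment, exponentiated into the mean
  of a negative binomial; structural zeros injected independently;
  two instruments with an additive latent offset for the second.
  The count layer attenuates observed-scale heritability relative to the
  latent target, so recovery studies score the recorded latent matrix.
* **Phenotype** — assembled exactly as
  $\mathbf{X}\boldsymbol\gamma + \mathbf{u} + \mathbf{M}\boldsymbol\beta +
  \mathbf{e}$ with $\boldsymbol\beta$ drawn from the configured mixture;
  $\mathbf{u}$ and $\mathbf{M}\boldsymbol\beta$ are rescaled to hit the
  target variance shares exactly while $\mathbf{e}$ is drawn, not rescaled,
  so realised totals fluctuate naturally.  Fixed effects cover 6 herds,
  4 parities, DIM uniform on 1–350 and the Wilmink term.

What it does **not** emulate: phylogenetic correlation among taxa,
taxon-taxon interaction networks, linkage disequilibrium beyond family
co-segregation, measurement error in $\mathbf{M}$, and diet/season
covariates.  Passing recovery tests on these simulations therefore
demonstrates correctness of the estimator under its own assumptions, not
robustness to everything real rumen data can do.

## Problem sizes used by the test suite

The statistical checks run at sizes chosen to make their Monte-Carlo error
small relative to the tolerance being asserted while keeping a laptop-class
runtime: the conjugate-posterior oracle at $n = 100$, $p = 30$ with a 20k
chain; exact enumeration of the indicator posterior at $n = 30$, $p = 5$,
$K = 2$ (all $2^5$ label vectors, $\beta$ integrated analytically) against
a 500k chain; parameter-recovery and coverage at the full emulated scale
($n = 750$, 5000 SNPs, 500 OTUs, 20 replicates, 8k chains); REML recovery
at $n = 500$, 2000 SNPs, 50 replicates; association calibration over 10k
SNPs.  Null calibration averages posterior shares over five independent
pure-noise datasets because a single draw of noise at $n = 750$ produces
REML $\hat h^2$ up to $\approx 0.09$ by chance (SE $\approx 0.05$) — the
meaningful statement is about the average, not one dataset.

## Known limitations

* The flat prior on $\sigma^2_u$ inflates small-variance posteriors
  slightly; under a null, the posterior mean of the host share is positive
  (order of one SE), as for any boundary parameter with a one-sided
  posterior.
* DIC differences between the 4- and 2-component models are small unless
  the middle components carry real likelihood mass; at low microbiome
  signal the comparison is close to a coin flip, which is worth remembering
  when reading 1-unit DIC gaps.
* Single chain per fit (by design); convergence is inspected through the
  saved-sample trace (`plot()` on a fit, or `write_trace()`), not through
  multi-chain diagnostics.
* The BIOM format and HDF5 sidecars are out of scope; all interchange is
  TSV/JSON.
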