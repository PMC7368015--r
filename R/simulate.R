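## Synthetic-data generator: genotypes and pedigree by Mendelian gene
## dropping, zero-inflated OTU counts with a heritable subset, and
## phenotypes assembled exactly from the model
## y = X gamma + Z u + M beta + e, with the ground truth recorded.

#' Simulate genotypes and a pedigree by gene dropping
#'
#' Builds `n_families` sire families: each family has one founder sire and
#' founder dams with two offspring each (full-sib pairs), cycling until `n`
#' animals exist.  Founder genotypes are drawn at Hardy-Weinberg
#' proportions from per-SNP allele frequencies uniform on `maf_range`;
#' non-founders receive one Mendelian allele from each parent,
#' independently per SNP.
#'
#' @param n total number of animals (founders + offspring).
#' @param m number of SNPs.
#' @param maf_range interval in (0, 0.5] for the drawn allele frequencies.
#' @param n_families number of sire families (<= n).
#' @param seed integer seed.
#' @return list: `genotypes` (n x m 0/1/2 matrix with a `"map"` attribute,
#'   chromosomes assigned round-robin over 29 autosomes), `pedigree`
#'   (animal/sire/dam data.frame, founders have NA parents), `freqs` (the
#'   drawn allele frequencies).
#' @export
sim_genotypes <- function(n, m, maf_range = c(0.05, 0.5), n_families = 10,
                          seed = NULL) {
  stopifnot(n >= 1, m >= 1)
  if (n_families > n) stop("n_families cannot exceed n")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must lie within (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])

  ## pedigree: sires first, then repeat (dam founder, two offspring)
  id <- function(i) sprintf("A%05d", i)
  animal <- id(seq_len(n_families))
  sire <- dam <- rep(NA_character_, n_families)
  cur <- n_families
  fam <- 0L
  while (cur < n) {
    fam <- fam %% n_families + 1L
    dam_id <- id(cur + 1L)
    animal <- c(animal, dam_id); sire <- c(sire, NA); dam <- c(dam, NA)
    cur <- cur + 1L
    for (k in 1:2) {
      if (cur >= n) break
      animal <- c(animal, id(cur + 1L))
      sire <- c(sire, id(fam)); dam <- c(dam, dam_id)
      cur <- cur + 1L
    }
  }
  ped <- data.frame(animal = animal, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)

  g <- matrix(NA_real_, n, m, dimnames = list(animal, sprintf("snp%05d", seq_len(m))))
  founder <- is.na(ped$sire) & is.na(ped$dam)
  nf <- sum(founder)
  g[founder, ] <- matrix(rbinom(nf * m, 2, rep(p, each = nf)), nf, m)
  transmit <- function(gp) (gp == 2) + (gp == 1) * rbinom(m, 1, 0.5)
  for (i in which(!founder)) {
    gs <- g[ped$sire[i], ]
    gd <- g[ped$dam[i], ]
    g[i, ] <- transmit(gs) + transmit(gd)
  }
  attr(g, "map") <- data.frame(snp = colnames(g),
                               chrom = rep_len(1:29, m),
                               pos = seq_len(m) * 1000L,
                               stringsAsFactors = FALSE)
  list(genotypes = g, pedigree = ped, freqs = p)
}

#' Simulate a zero-inflated OTU count table with heritable taxa
#'
#' For each heritable taxon the latent log-abundance is a polygenic value
#' (variance `otu_h2`, covariance proportional to the relationship matrix)
#' plus independent environment (variance `1 - otu_h2`); the latent value
#' is exponentiated into the mean of a negative binomial count, structural
#' zeros are injected independently at rate `zero_inflation`, and samples
#' are split between two sequencing instruments with an additive offset on
#' the latent scale for the second platform.
#'
#' @param K relationship matrix of the sampled animals (row names = IDs).
#' @param p number of taxa.
#' @param heritable_fraction fraction of taxa given a polygenic component.
#' @param otu_h2 heritability of the latent log-abundance for heritable
#'   taxa, in \[0, 1).
#' @param zero_inflation structural-zero probability in \[0, 1\].
#' @param instrument_split fraction of samples on the first instrument.
#' @param dispersion negative-binomial size parameter.
#' @param instrument_offset latent-scale shift of the second instrument.
#' @param base_log_mean range of per-taxon log mean counts (log scale).
#' @param seed integer seed.
#' @return An [otu_tbl()] with synthetic greengenes-style taxonomy; the
#'   per-taxon heritability targets and the realised latent log-abundance
#'   matrix are recorded in `attr(, "truth")` (elements `otu_h2`, `latent`)
#'   for recovery studies.  Note the count layer (negative binomial noise,
#'   structural zeros) attenuates heritability on the observed scale
#'   relative to the latent targets.
#' @export
sim_otu_counts <- function(K, p, heritable_fraction = 0.2, otu_h2 = 0.25,
                           zero_inflation = 0.3, instrument_split = 0.5,
                           dispersion = 2, instrument_offset = 0.5,
                           base_log_mean = c(log(5), log(500)),
                           seed = NULL) {
  if (otu_h2 < 0 || otu_h2 >= 1) stop("otu_h2 must lie in [0, 1)")
  stopifnot(heritable_fraction >= 0, heritable_fraction <= 1,
            zero_inflation >= 0, zero_inflation <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(K)
  ids <- rownames(K)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
  e <- .kin_eigen(unclass(K))
  keep <- e$values > 1e-10 * max(e$values)
  L <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  q <- ncol(L)

  n_her <- round(p * heritable_fraction)
  h2_tax <- c(rep(otu_h2, n_her), rep(0, p - n_her))
  mu_tax <- runif(p, base_log_mean[1], base_log_mean[2])
  instrument <- rep(c("MiSeq", "HiSeq"),
                    c(round(n * instrument_split),
                      n - round(n * instrument_split)))
  offs <- ifelse(instrument == "HiSeq", instrument_offset, 0)

  counts <- matrix(0, n, p, dimnames = list(ids, sprintf("OTU%04d", seq_len(p))))
  latent <- matrix(0, n, p, dimnames = dimnames(counts))
  for (t in seq_len(p)) {
    gval <- if (h2_tax[t] > 0) {
      drop(L %*% rnorm(q, 0, sqrt(h2_tax[t])))
    } else 0
    latent[, t] <- mu_tax[t] + gval + rnorm(n, 0, sqrt(1 - h2_tax[t])) + offs
    cnt <- rnbinom(n, size = dispersion, mu = exp(latent[, t]))
    cnt[runif(n) < zero_inflation] <- 0
    counts[, t] <- cnt
  }
  taxonomy <- .sim_taxonomy(p)
  out <- otu_tbl(counts, taxonomy = taxonomy, instrument = instrument)
  attr(out, "truth") <- list(otu_h2 = h2_tax, mu_tax = mu_tax,
                             zero_inflation = zero_inflation,
                             dispersion = dispersion, latent = latent)
  out
}

## plausible greengenes-style lineages with shared genera and some taxa
## unclassified at genus rank
.sim_taxonomy <- function(p) {
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria", "Euryarchaeota")
  genera <- paste0("Genus", sprintf("%02d", seq_len(max(2, ceiling(p / 4)))))
  vapply(seq_len(p), function(i) {
    ph <- phyla[1 + (i %% length(phyla))]
    base <- sprintf("k__Bacteria;p__%s;c__Class%02d;o__Order%02d;f__Family%02d",
                    ph, i %% 7 + 1, i %% 5 + 1, i %% 9 + 1)
    if (i %% 5 == 0) {
      paste0(base, ";g__")                 # unclassified at genus
    } else {
      paste0(base, ";g__", genera[1 + (i %% length(genera))])
    }
  }, character(1))
}

#' Simulate a phenotype from the joint generative model
#'
#' Assembles `y = X gamma + u + M beta + e`: the polygenic vector `u` is a
#' multivariate normal with covariance proportional to the relationship
#' matrix (via its symmetric square root), `beta` is drawn from the
#' K-component scale mixture (`z ~ cat(pi_true)`, component variances in
#' the configured increasing ratios), and both terms are rescaled so their
#' realised variance shares hit `h2_target` and `microbiability_target`
#' exactly; the residual is drawn, not rescaled, so total-variance shares
#' fluctuate naturally.
#'
#' @param X fixed design matrix or [build_fixed_design()].
#' @param K relationship matrix.
#' @param M transformed microbiome matrix (e.g. [log_standardize()]).
#' @param h2_target,microbiability_target intended variance shares.
#' @param pi_true mixture proportions for the taxon-effect components.
#' @param variance_ratios increasing component variance multipliers.
#' @param gamma_true fixed-effect vector (default: modest random effects).
#' @param sigma_p2 total phenotypic variance scale.
#' @param seed integer seed.
#' @return list: `y`, and `truth` (sigma_u2, sigma_e2, beta_true, z_true,
#'   pi_true, gamma_true, targets and realised shares).
#' @export
sim_phenotype <- function(X, K, M, h2_target = 0.25,
                          microbiability_target = 0.07,
                          pi_true = c(0.90, 0.06, 0.03, 0.01),
                          variance_ratios = c(1, 10, 100, 1000),
                          gamma_true = NULL, sigma_p2 = 1, seed = NULL) {
  if (inherits(X, "fixed_design")) X <- X$X
  X <- as.matrix(X); M <- as.matrix(M)
  n <- nrow(X)
  stopifnot(nrow(M) == n, all(dim(K) == n),
            h2_target >= 0, microbiability_target >= 0,
            h2_target + microbiability_target < 1)
  if (abs(sum(pi_true) - 1) > 1e-8) stop("pi_true must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(M)
  Kn <- length(pi_true)

  e <- .kin_eigen(unclass(K))
  keep <- e$values > 1e-10 * max(e$values)
  L <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  u <- drop(L %*% rnorm(ncol(L)))
  if (h2_target > 0) {
    u <- u * sqrt(h2_target * sigma_p2 / var(u))
  } else u <- u * 0

  z <- sample.int(Kn, p, replace = TRUE, prob = pi_true)
  beta <- rnorm(p, 0, sqrt(variance_ratios[z]))
  mb <- drop(M %*% beta)
  if (microbiability_target > 0 && var(mb) > 0) {
    sc <- sqrt(microbiability_target * sigma_p2 / var(mb))
    beta <- beta * sc
    mb <- mb * sc
  } else {
    beta <- beta * 0; mb <- mb * 0
  }

  sigma_e2 <- (1 - h2_target - microbiability_target) * sigma_p2
  eps <- rnorm(n, 0, sqrt(sigma_e2))
  if (is.null(gamma_true)) {
    gamma_true <- rnorm(ncol(X), 0, 0.5 * sqrt(sigma_p2))
    if ("intercept" %in% colnames(X))
      gamma_true[colnames(X) == "intercept"] <- 10 * sqrt(sigma_p2)
  }
  y <- drop(X %*% gamma_true) + u + mb + eps

  denom <- var(u) + var(mb) + var(eps)
  truth <- list(sigma_u2 = var(u), sigma_e2 = sigma_e2,
                beta_true = beta, z_true = z, pi_true = pi_true,
                gamma_true = gamma_true,
                h2_target = h2_target,
                microbiability_target = microbiability_target,
                realized_prop_u = var(u) / denom,
                realized_prop_m = var(mb) / denom)
  list(y = y, truth = truth)
}

#' Write a complete synthetic scenario to disk
#'
#' Generates genotypes + pedigree, fixed-effect covariates (6 herds, 4
#' parities, DIM uniform on 1..350 with a Wilmink lactation-curve term),
#' zero-inflated OTU counts, and the phenotype, then writes every table in
#' the dialects the loaders read, plus a `truth.json` ground-truth record.
#' Output is deterministic given `(name, seed)`.
#'
#' @param name `"paper_like"` (n = 750, 5000 SNPs, 500 OTUs, h2 0.25,
#'   microbiability 0.07), `"tiny"` (n = 60, 200 SNPs, 40 OTUs), or
#'   `"null"` (paper_like sizes, zero genetic and microbial effects).
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return Invisibly, the named list of file paths written.
#' @export
make_scenario <- function(name = c("paper_like", "tiny", "null"), dir,
                          seed = 1) {
  name <- match.arg(name)
  dims <- switch(name,
    paper_like = list(n = 750, m = 5000, p = 500, fam = 50,
                      h2 = 0.25, mb = 0.07),
    tiny       = list(n = 60, m = 200, p = 40, fam = 6,
                      h2 = 0.25, mb = 0.07),
    null       = list(n = 750, m = 5000, p = 500, fam = 50,
                      h2 = 0, mb = 0))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  gsim <- sim_genotypes(dims$n, dims$m, n_families = dims$fam)
  ## the relationship matrix driving the simulation uses only polymorphic
  ## SNPs; the written genotype file keeps everything for QC to handle
  p_obs <- colMeans(gsim$genotypes) / 2
  G <- grm_yang(gsim$genotypes[, p_obs > 0 & p_obs < 1, drop = FALSE])
  otu <- sim_otu_counts(G, dims$p, heritable_fraction = 0.2, otu_h2 = 0.25)

  n <- dims$n
  pheno <- data.frame(
    animal_id = rownames(gsim$genotypes),
    herd = sample(paste0("H", 1:6), n, replace = TRUE),
    parity = sample(1:4, n, replace = TRUE,
                    prob = c(0.4, 0.3, 0.2, 0.1)),
    dim = sample(1:350, n, replace = TRUE),
    instrument = unname(otu$instrument),
    stringsAsFactors = FALSE)
  Xd <- build_fixed_design(pheno)
  M <- log_standardize(filter_prevalence(otu, 0.5))
  sim <- sim_phenotype(Xd, G, M, h2_target = dims$h2,
                       microbiability_target = dims$mb)
  pheno$methane <- sim$y
  pheno <- pheno[c("animal_id", "methane", "herd", "parity", "dim",
                   "instrument")]

  paths <- list(
    phenotype = file.path(dir, "phenotype.tsv"),
    genotypes = file.path(dir, "genotypes.tsv"),
    pedigree = file.path(dir, "pedigree.tsv"),
    otu = file.path(dir, "otu_counts.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    truth = file.path(dir, "truth.json"))
  .write_tsv(pheno, paths$phenotype)
  gdf <- data.frame(animal_id = rownames(gsim$genotypes),
                    stringsAsFactors = FALSE)
  gmat <- gsim$genotypes
  storage.mode(gmat) <- "integer"
  .write_tsv(cbind(gdf, as.data.frame(gmat)), paths$genotypes)
  .write_tsv(data.frame(animal = gsim$pedigree$animal,
                        sire = ifelse(is.na(gsim$pedigree$sire), "0",
                                      gsim$pedigree$sire),
                        dam = ifelse(is.na(gsim$pedigree$dam), "0",
                                     gsim$pedigree$dam),
                        stringsAsFactors = FALSE), paths$pedigree)
  write_otu_table(otu, paths$otu, paths$taxonomy)
  truth <- sim$truth
  truth$taxa <- colnames(M)          # beta_true indexes the filtered taxa
  truth$otu_h2 <- attr(otu, "truth")$otu_h2
  truth$scenario <- name
  truth$seed <- seed
  jsonlite::write_json(truth, paths$truth, digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
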