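# Shared simulated panel for the REML/GWAS tests (moderate size, built once)
panel <- local({
  sim <- sim_genotypes(n = 400, m = 1200, n_families = 30, seed = 101)
  G <- grm_yang(sim$genotypes)
  list(sim = sim, G = G, ek = reml_eigen(G))
})

sim_polygenic_trait <- function(h2, ek, seed) {
  set.seed(seed)
  q <- length(ek$values)
  u <- drop(ek$vectors %*% (sqrt(ek$values) * rnorm(q)))
  if (h2 > 0) u <- u * sqrt(h2 / var(u)) else u <- u * 0
  u + rnorm(q, 0, sqrt(1 - h2))
}

test_that("REML recovers simulated heritability and beats a lambda grid", {
  h_null <- h_mid <- numeric(10)
  for (r in 1:10) {
    y0 <- sim_polygenic_trait(0, panel$ek, seed = 200 + r)
    y3 <- sim_polygenic_trait(0.3, panel$ek, seed = 300 + r)
    f0 <- reml_h2(y0, panel$ek)
    f3 <- reml_h2(y3, panel$ek)
    h_null[r] <- f0$h2
    h_mid[r] <- f3$h2
    # optimiser at least as good as a coarse grid (run on two replicates)
    if (r <= 2) {
      grid <- reml_profile(y3, panel$ek, seq(0.01, 0.99, length.out = 50))
      expect_gte(f3$loglik, max(grid) - 1e-6)
    }
  }
  expect_lt(median(h_null), 0.05)
  expect_equal(mean(h_mid), 0.3, tolerance = 0.08)
  f <- reml_h2(sim_polygenic_trait(0.3, panel$ek, 1), panel$ek)
  expect_true(f$h2 >= 0 && f$h2 <= 1)
  expect_gte(f$se_h2, 0)
})

test_that("REML is invariant to a joint permutation of y and G", {
  y <- sim_polygenic_trait(0.3, panel$ek, seed = 77)
  f1 <- reml_h2(y, panel$G)
  perm <- sample(length(y))
  f2 <- reml_h2(y[perm], panel$G[perm, perm])
  expect_equal(f1$h2, f2$h2, tolerance = 1e-5)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-5)
})

test_that("h2 scan ranks heritability levels and handles edge traits", {
  traits <- sapply(c(0, 0.2, 0.4), function(h2)
    rowMeans(sapply(1:5, function(r)
      sim_polygenic_trait(h2, panel$ek, seed = 1000 * h2 + r))))
  # averaging 5 replicate traits tightens each estimate
  colnames(traits) <- c("null", "low", "high")
  scan <- h2_scan(traits, panel$ek)
  expect_equal(scan$id, c("null", "low", "high"))
  expect_true(all(diff(scan$estimate) > -0.05))   # rank order (near-)correct
  expect_true(all(scan$p_adjusted >= scan$p_value - 1e-12))

  # duplicate trait columns give identical rows
  dup <- cbind(a = traits[, 3], b = traits[, 3])
  sd2 <- h2_scan(dup, panel$ek)
  expect_equal(sd2$estimate[1], sd2$estimate[2])

  const <- cbind(ok = traits[, 2], flat = rep(1, nrow(traits)))
  expect_warning(s3 <- h2_scan(const, panel$ek), "constant")
  expect_equal(nrow(s3), 1)
})

test_that("null h2 scan yields no BY-significant traits", {
  set.seed(55)
  traits <- matrix(rnorm(nrow(panel$G) * 10), ncol = 10)
  scan <- h2_scan(traits, panel$ek)
  expect_equal(sum(scan$p_adjusted < 0.05, na.rm = TRUE), 0)
})

test_that("Benjamini-Yekutieli adjustment matches its formula", {
  # m = 2: c(2) = 1.5; step-up of (m c(m) p_(j) / j)
  expect_equal(benjamini_yekutieli(c(0.01, 0.04)), c(0.03, 0.06))
  expect_equal(benjamini_yekutieli(0.2), 0.2)    # m = 1 -> unchanged

  set.seed(13)
  p <- runif(25)^2
  # independent implementation straight from the definition
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  raw <- m * cm * p[o] / seq_len(m)
  adj_sorted <- rev(cummin(rev(pmin(raw, 1))))
  byhand <- numeric(m); byhand[o] <- pmin(adj_sorted, 1)
  expect_equal(benjamini_yekutieli(p), byhand, tolerance = 1e-12)
  # BY >= BH elementwise, order-invariant
  expect_true(all(benjamini_yekutieli(p) >= p.adjust(p, "BH") - 1e-12))
  perm <- sample(m)
  expect_equal(benjamini_yekutieli(p[perm]), byhand[perm])
})

test_that("GWAS reduces to per-SNP OLS when G = I and sigma_g2 ~ 0", {
  set.seed(14)
  n <- 120
  geno <- matrix(rbinom(n * 30, 2, 0.4), n, 30)
  y <- rnorm(n)
  I <- diag(n)
  scan <- suppressMessages(gwas_scan(y, I, geno))
  ols <- t(sapply(seq_len(30), function(j) {
    fit <- summary(lm(y ~ geno[, j]))$coefficients
    fit[2, 1:2]
  }))
  # P3D with an identity kinship: variance components make V = c*I, and the
  # GLS effect equals OLS exactly; SEs agree up to the df convention
  expect_equal(scan$estimate, unname(ols[, 1]), tolerance = 1e-6)
  expect_equal(scan$se, unname(ols[, 2]), tolerance = 0.05)
})

test_that("GWAS detects a causal SNP and respects Bonferroni bookkeeping", {
  set.seed(15)
  geno <- panel$sim$genotypes
  n <- nrow(geno)
  u <- sim_polygenic_trait(0.3, panel$ek, seed = 500)
  j_causal <- 600
  x <- geno[, j_causal]
  xs <- (x - mean(x)) / sd(x)
  y <- u + xs * sqrt(0.15 / 0.85)        # sizeable causal effect
  scan <- suppressMessages(gwas_scan(y, panel$ek, geno))
  expect_equal(which.min(scan$p_value), j_causal)
  expect_gt(scan$estimate[j_causal], 0)  # sign matches the simulated effect
  expect_true(all(scan$p_adjusted >= scan$p_value - 1e-12))
  expect_true(all(scan$p_adjusted <= 1))
  expect_equal(scan$p_adjusted, pmin(1, scan$p_value * ncol(geno)))

  # monomorphic SNP is skipped with NA
  g2 <- cbind(geno, mono = rep(2, n))
  scan2 <- suppressMessages(gwas_scan(y, panel$ek, g2))
  expect_true(is.na(scan2$estimate[ncol(g2)]))

  # per-SNP REML agrees with P3D on a handful of SNPs
  sub <- geno[, c(1, 300, j_causal)]
  s_p3d <- suppressMessages(gwas_scan(y, panel$ek, sub))
  s_ex <- suppressMessages(gwas_scan(y, panel$ek, sub, per_snp_reml = TRUE))
  expect_equal(s_ex$estimate, s_p3d$estimate, tolerance = 0.05)
})
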