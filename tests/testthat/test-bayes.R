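test_that("K = 1 fixed-variance chain matches the conjugate ridge posterior", {
  set.seed(16)
  n <- 80; p <- 12
  M <- matrix(rnorm(n * p), n, p)
  beta_true <- rnorm(p, 0, 0.5)
  y <- drop(M %*% beta_true) + rnorm(n)
  s2e <- 1; s2b <- 0.25
  cfg <- run_config(chain_length = 6000, burn_in = 1000, thin = 2,
                    n_components = 1)
  fit <- microbiability(y, X = matrix(0, n, 0), kinship = NULL,
                        microbiome = M, config = cfg, seed = 16,
                        fix_sigma_e = s2e, fix_comp_var = s2b,
                        save_beta = TRUE)
  # analytic posterior: N((M'M/s2e + I/s2b)^-1 M'y/s2e, (...)^-1)
  Prec <- crossprod(M) / s2e + diag(p) / s2b
  Sig <- solve(Prec)
  mu <- drop(Sig %*% crossprod(M, y)) / s2e
  bm <- rowMeans(fit$beta_samples)
  for (j in seq_len(p)) {
    se_j <- mcse(fit$beta_samples[j, ])
    expect_lt(abs(bm[j] - mu[j]), 4 * se_j + 1e-8)
  }
  # posterior variances too
  bv <- apply(fit$beta_samples, 1, var)
  expect_equal(bv, diag(Sig), tolerance = 0.15, ignore_attr = TRUE)
})

test_that("residual bookkeeping: fitted + residual reproduces y", {
  qd <- quick_data(n = 50, p = 8, seed = 17)
  cfg <- run_config(chain_length = 400, burn_in = 100, thin = 3)
  fit <- microbiability(qd$y, kinship = qd$G, microbiome = qd$M,
                        config = cfg, seed = 17)
  expect_equal(fitted(fit) + residuals(fit), qd$y, tolerance = 1e-12)
  expect_length(coef(fit)$beta, 8)
  expect_length(coef(fit)$gamma, 1)
})

test_that("chains are bit-reproducible under a fixed seed", {
  qd <- quick_data(n = 40, p = 6, seed = 18)
  cfg <- run_config(chain_length = 500, burn_in = 100, thin = 2)
  f1 <- microbiability(qd$y, kinship = qd$G, microbiome = qd$M,
                       config = cfg, seed = 99)
  f2 <- microbiability(qd$y, kinship = qd$G, microbiome = qd$M,
                       config = cfg, seed = 99)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$z, f2$z)
  f3 <- microbiability(qd$y, kinship = qd$G, microbiome = qd$M,
                       config = cfg, seed = 100)
  expect_false(identical(f1$samples$sigma_e2, f3$samples$sigma_e2))
})

test_that("structural invariants hold at every saved cycle", {
  qd <- quick_data(n = 60, p = 15, seed = 19)
  cfg <- run_config(chain_length = 1200, burn_in = 200, thin = 2)
  fit <- microbiability(qd$y, kinship = qd$G, microbiome = qd$M,
                        config = cfg, seed = 19)
  s <- fit$samples
  # shares in [0,1], summing to 1 with the residual share
  expect_true(all(s$prop_u >= 0 & s$prop_u <= 1))
  expect_true(all(s$prop_m >= 0 & s$prop_m <= 1))
  tot <- s$prop_u + s$prop_m + s$sigma_e2 / (s$sigma_u2 + s$var_m + s$sigma_e2)
  expect_equal(tot, rep(1, nrow(s)), tolerance = 1e-12)
  # component variances obey the ratio constraint exactly, every cycle
  cv <- fit$comp_var_samples
  for (k in 1:4) {
    expect_identical(cv[, k], s$base_var * cfg$variance_ratios[k])
  }
  # mixture proportions live on the simplex
  expect_equal(rowSums(fit$pi_samples), rep(1, nrow(s)), tolerance = 1e-12)
  expect_true(all(fit$pi_samples >= 0))
  # z labels are valid components
  expect_true(all(fit$z %in% 1:4))
  # variances stay positive
  expect_true(all(s$sigma_e2 > 0 & s$sigma_u2 > 0 & s$base_var > 0))
})

test_that("Dirichlet conjugacy: long-run pi matches (alpha + n_k) mean", {
  # freeze everything except pi by fixing variances and beta near zero
  set.seed(20)
  n <- 40; p <- 60
  M <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  cfg <- run_config(chain_length = 8000, burn_in = 1000, thin = 2)
  fit <- microbiability(y, X = matrix(0, n, 0), kinship = NULL,
                        microbiome = M, config = cfg, seed = 20,
                        fix_sigma_e = 1, fix_comp_var = c(1, 10, 100, 1000) * 1e-8)
  # with beta ~ 0 all components are equally likely a priori, so the z
  # counts stay near the pi draws; check pi_mean against the Dirichlet mean
  # given the average counts (a self-consistency check of the Gibbs step)
  nk <- rowMeans(apply(fit$z, 2, tabulate, nbins = 4))
  expected <- (cfg$dirichlet_alpha + nk) / (sum(cfg$dirichlet_alpha) + p)
  expect_equal(fit$pi_mean, expected, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("indicator MH respects symmetry and shrinkage monotonicity", {
  # with equal component variances and equal pi the z distribution is
  # uniform: boundary corrections must cancel
  set.seed(21)
  n <- 30; p <- 10
  M <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  # odd thinning: with acceptance ~ 1 the two-state indicator chain
  # alternates deterministically, and even thinning would sample one phase
  cfg <- run_config(chain_length = 4000, burn_in = 500, thin = 3,
                    n_components = 2, dirichlet_alpha = c(1, 1),
                    variance_ratios = c(1, 10))
  fit <- microbiability(y, X = matrix(0, n, 0), kinship = NULL,
                        microbiome = M, config = cfg, seed = 21,
                        fix_sigma_e = 1,
                        fix_comp_var = c(0.01, 0.010000001),
                        fix_pi = c(0.5, 0.5))
  occ <- mean(fit$z == 1)
  expect_equal(occ, 0.5, tolerance = 0.05)

  # beta == 0 favours the strong-shrinkage (small variance) component
  fit2 <- microbiability(rep(0, n) + rnorm(n, 0, 1e-6), X = matrix(0, n, 0),
                         kinship = NULL,
                         microbiome = M, config = cfg, seed = 22,
                         fix_sigma_e = 1, fix_comp_var = c(1e-6, 1),
                         fix_pi = c(0.5, 0.5))
  # (occupancy is bounded away from 1 by the dwell dynamics: once a site
  # jumps to the wide component its beta is redrawn at the wide scale and
  # takes a while to shrink back, so assert a clear majority rather than
  # near-certainty)
  expect_gt(mean(fit2$z == 1), 0.75)
})

test_that("scaled inverse chi-square draws have the right scale", {
  # e'e/chisq(n-2): with sigma fixed by a degenerate response the draw mean
  # is ee/(n-4); verified through the chain's residual-variance samples on
  # a null model with known residual sum of squares is impractical, so
  # check the distributional identity directly instead
  set.seed(23)
  ee <- 100; n <- 102
  draws <- ee / rchisq(50000, n - 2)
  expect_equal(mean(draws), ee / (n - 4), tolerance = 0.01)
})

test_that("HPD intervals: normal quantiles, degenerate and skewed cases", {
  set.seed(24)
  x <- rnorm(10000)
  h <- hpd_interval(x)
  expect_equal(h[1], -1.96, tolerance = 0.1)
  expect_equal(h[2], 1.96, tolerance = 0.1)

  expect_equal(hpd_interval(rep(2, 30)), c(2, 2))
  expect_error(hpd_interval(rnorm(10)), "at least 20")

  ex <- rexp(10000)
  h_ex <- hpd_interval(ex)
  eq <- quantile(ex, c(0.025, 0.975))
  expect_lt(diff(h_ex), diff(eq))        # HPD shorter than equal-tail
  # HPD hugs the mode of the skewed density
  expect_lt(h_ex[1], 0.05)
})

test_that("summary and accessors expose the posterior decomposition", {
  qd <- quick_data(n = 50, p = 8, seed = 25)
  cfg <- run_config(chain_length = 600, burn_in = 100, thin = 2)
  fit <- microbiability(qd$y, kinship = qd$G, microbiome = qd$M,
                        config = cfg, seed = 25)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.mb_fit")
  expect_equal(sum(fit$summary$prop_mean), 1, tolerance = 1e-8)
  expect_true(all(fit$summary$prop_hpd_low <= fit$summary$prop_mean + 1e-9))
  expect_true(all(fit$summary$prop_hpd_high >= fit$summary$prop_mean - 1e-9))
  expect_length(fit$taxon_var, 8)
  expect_true(all(fit$taxon_var >= 0))
  expect_output(print(fit), "host_genetics")
  expect_output(print(sm), "mixture proportions")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(50, 3))
})

test_that("per-taxon contribution picks out a one-hot large effect", {
  set.seed(26)
  n <- 150; p <- 20
  M <- scale(matrix(rnorm(n * p), n, p))
  beta <- rep(0, p); beta[7] <- 1.5
  y <- drop(M %*% beta) + rnorm(n)
  cfg <- run_config(chain_length = 2000, burn_in = 500, thin = 3)
  fit <- microbiability(y, kinship = NULL, microbiome = M, config = cfg,
                        seed = 26)
  expect_equal(which.max(fit$taxon_var), 7, ignore_attr = TRUE)
  # var of a standardised column times beta^2 ~ beta^2
  expect_equal(unname(fit$taxon_var[7]), 1.5^2, tolerance = 0.35)
  # and var(M beta) posterior mean tracks the realised explained variance
  expect_equal(mean(fit$samples$var_m), var(drop(M %*% beta)),
               tolerance = 0.35)
})

test_that("trace file is written and matches the saved samples", {
  qd <- quick_data(n = 40, p = 5, seed = 27)
  tf <- withr::local_tempfile(fileext = ".tsv")
  cfg <- run_config(chain_length = 300, burn_in = 100, thin = 2,
                    trace_file = tf)
  fit <- microbiability(qd$y, kinship = qd$G, microbiome = qd$M,
                        config = cfg, seed = 27)
  tr <- read.table(tf, header = TRUE, sep = "\t")
  expect_equal(nrow(tr), nrow(fit$samples))
  expect_equal(tr$prop_m, fit$samples$prop_m, tolerance = 1e-12)
})

test_that("divergence and conformability guards trigger", {
  qd <- quick_data(n = 30, p = 4, seed = 28)
  expect_error(microbiability(qd$y, kinship = qd$G[1:10, 1:10],
                              microbiome = qd$M),
               "conformable")
  D <- diag(30); D[1, 2] <- D[2, 1] <- 2   # eigenvalues 1 +/- 2: indefinite
  expect_error(microbiability(qd$y, kinship = D, microbiome = qd$M,
                              config = run_config(chain_length = 200,
                                                  burn_in = 50, thin = 1)),
               "positive semi-definite")
})
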