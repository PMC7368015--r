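test_that("snp_qc applies the four filters in order and matches brute force", {
  set.seed(1)
  n <- 100; m <- 200
  g <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(sprintf("A%03d", 1:n), paste0("s", 1:m)))
  # engineer failures: s1 monomorphic (MAF), s2 low SNP call rate (one
  # missing genotype per animal keeps individual call rates at 0.995)
  g[, 1] <- 0
  g[1:10, 2] <- NA
  qc <- suppressMessages(snp_qc(g))
  expect_false(any(c("s1", "s2") %in% colnames(qc)))
  expect_equal(attr(qc, "qc_log")[["snp_call"]], 1L)
  expect_gte(attr(qc, "qc_log")[["maf"]], 1L)
  expect_false(anyNA(qc))

  # brute-force recount of the survivor set
  keep <- vapply(3:m, function(j) {
    x <- g[, j]
    cr <- mean(!is.na(x))
    p <- mean(x, na.rm = TRUE) / 2
    cr >= 0.98 && min(p, 1 - p) >= 0.02 &&
      hwe_test(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
               sum(x == 2, na.rm = TRUE)) >= 1e-8
  }, logical(1))
  expect_equal(colnames(qc), paste0("s", (3:m)[keep]))
})

test_that("individuals failing call rate are removed before SNP filters", {
  g <- matrix(rbinom(300, 2, 0.5), 30, 10,
              dimnames = list(sprintf("A%02d", 1:30), paste0("s", 1:10)))
  g[1, 1:5] <- NA                       # individual A01: call rate 0.5
  qc <- suppressMessages(snp_qc(g))
  expect_false("A01" %in% rownames(qc))
  expect_equal(attr(qc, "qc_log")[["ind_call"]], 1L)
})

test_that("HWE test: perfect proportions retained, exact path sensible", {
  # counts (25, 50, 25) are exactly Hardy-Weinberg -> p ~ 1
  expect_gt(hwe_test(25, 50, 25), 0.9)
  # gross heterozygote excess is rejected
  expect_lt(hwe_test(0, 100, 0), 1e-8)
  # exact path (small expected cells) agrees with chi-square direction
  expect_gt(hwe_test(90, 9, 1), 0.05)
  expect_lt(hwe_test(85, 2, 13), 1e-6)
})

test_that("prevalence filter boundary is inclusive and matches brute force", {
  cnt <- rbind(c(1, 1, 0, 5), c(2, 0, 0, 5), c(0, 3, 0, 5), c(0, 0, 1, 5))
  otu <- otu_tbl(cnt)
  kept <- filter_prevalence(otu, 0.5)
  # OTU1 present in 2/4 -> retained; OTU3 in 1/4 -> removed
  expect_setequal(colnames(kept$counts), c("OTU0001", "OTU0002", "OTU0004"))

  set.seed(2)
  big <- otu_tbl(matrix(rbinom(20 * 50, 3, 0.3), 20, 50))
  kept2 <- filter_prevalence(big, 0.5)
  brute <- colSums(big$counts > 0) >= ceiling(0.5 * 20)
  expect_equal(colnames(kept2$counts), colnames(big$counts)[brute])

  expect_error(filter_prevalence(otu_tbl(diag(4)), 1), "every taxon")
})

test_that("log_standardize: ln(0 + 0.001), exact z-scores, unit columns", {
  expect_equal(log(0.001), -6.907755, tolerance = 1e-6)
  set.seed(3)
  cnt <- matrix(rpois(15, 20), 5, 3)
  otu <- otu_tbl(cnt)
  M <- log_standardize(otu)
  expect_lt(max(abs(colMeans(M))), 1e-10)
  expect_equal(unname(apply(M, 2, var)), rep(1, 3), tolerance = 1e-10)
  # hand-computed z-scores
  lg <- log(cnt + 0.001)
  byhand <- apply(lg, 2, function(x) (x - mean(x)) / sd(x))
  expect_equal(unclass(M), byhand, ignore_attr = TRUE)
  expect_equal(attr(M, "transform_tag"), "log_std")

  cnt0 <- cnt; cnt0[, 2] <- 7
  expect_error(log_standardize(otu_tbl(cnt0)), "zero-variance")
})

test_that("per-instrument standardisation centres within each platform", {
  set.seed(8)
  otu <- otu_tbl(matrix(rpois(40 * 6, 20) + 1, 40, 6),
                 instrument = rep(c("MiSeq", "HiSeq"), each = 20))
  M <- log_standardize(otu, by_instrument = TRUE)
  for (g in c("MiSeq", "HiSeq")) {
    rows <- otu$instrument == g
    expect_lt(max(abs(colMeans(M[rows, , drop = FALSE]))), 1e-10)
    expect_equal(unname(apply(M[rows, ], 2, var)), rep(1, 6),
                 tolerance = 1e-10)
  }
})

test_that("clr transform: closed forms, zero rows, scale invariance", {
  even <- otu_tbl(matrix(c(1, 1, 1, 1), 1, 4))
  expect_equal(unname(as.vector(clr_transform(even))), rep(0, 4))

  two <- otu_tbl(matrix(c(2, 8), 1, 2))
  expect_equal(unname(as.vector(clr_transform(two))),
               c(-0.6931472, 0.6931472), tolerance = 1e-6)

  set.seed(4)
  cnt <- matrix(rpois(40, 10) + 1, 8, 5)   # zero-free
  M <- clr_transform(otu_tbl(cnt))
  expect_lt(max(abs(rowSums(M))), 1e-10)
  # multiplying a sample's counts by a positive scalar changes nothing
  cnt2 <- cnt; cnt2[3, ] <- cnt2[3, ] * 7
  M2 <- clr_transform(otu_tbl(cnt2))
  expect_equal(unclass(M2), unclass(M), tolerance = 1e-12)

  expect_error(clr_transform(otu_tbl(rbind(c(0, 0), c(1, 2)))), "all-zero")
})

test_that("genus collapse sums counts and groups unclassified by deepest rank", {
  otu <- toy_otu()
  coll <- collapse_to_genus(otu)
  # OTU1 + OTU2 share g__Blautia -> summed
  blautia <- grep("g__Blautia", colnames(coll$counts))
  expect_length(blautia, 1)
  expect_equal(unname(coll$counts[, blautia]),
               unname(otu$counts[, 1] + otu$counts[, 2]))
  # OTU3 unclassified at genus -> grouped by its deepest rank (order)
  expect_true(any(grepl("o__Bacteroidales$", colnames(coll$counts))))
  expect_equal(ncol(coll$counts), 3)
  expect_equal(rowSums(coll$counts), rowSums(otu$counts))

  # all-distinct genera leave the table unchanged except ids
  distinct <- otu_tbl(otu$counts[, c(1, 4)],
                      taxonomy = otu$taxonomy[c(1, 4)])
  cd <- collapse_to_genus(distinct)
  expect_equal(unname(cd$counts), unname(otu$counts[, c(1, 4)]))

  expect_error(collapse_to_genus(otu_tbl(diag(3))), "taxonomy")
})

test_that("fixed design: dummy coding count, Wilmink behaviour, invariance", {
  pheno <- fixed_covariates(300, seed = 5)
  fd <- build_fixed_design(pheno)
  expect_equal(ncol(fd$X), 1 + 5 + 3 + 2)   # intercept+herd+parity+dim+wilmink
  expect_true(all(fd$X[, "intercept"] == 1))
  expect_equal(qr(fd$X)$rank, ncol(fd$X))
  # Wilmink term decreasing in DIM, equal to 1 at DIM = 0
  expect_equal(exp(-fd$wilmink_k * 0), 1)
  w <- fd$X[order(pheno$dim), "wilmink"]
  expect_true(all(diff(w) <= 0))

  # permuting rows permutes the design and leaves the LS fit invariant
  y <- rnorm(300) + fd$X %*% rnorm(ncol(fd$X))
  perm <- sample(300)
  fd2 <- build_fixed_design(pheno[perm, ])
  g1 <- attr(precorrect_phenotype(y, fd), "gamma_hat")
  g2 <- attr(precorrect_phenotype(y[perm], fd2), "gamma_hat")
  expect_equal(g1, g2, tolerance = 1e-8)

  ph1 <- pheno; ph1$herd <- "H1"
  expect_warning(build_fixed_design(ph1), "single level")
})

test_that("pre-correction returns residuals orthogonal to the design", {
  set.seed(6)
  pheno <- fixed_covariates(120, seed = 6)
  fd <- build_fixed_design(pheno)
  y <- rnorm(120)
  yc <- precorrect_phenotype(y, fd)
  expect_lt(max(abs(crossprod(fd$X, yc))), 1e-8)
  # an exact linear combination is annihilated
  y2 <- drop(fd$X %*% rnorm(ncol(fd$X)))
  expect_lt(max(abs(precorrect_phenotype(y2, fd))), 1e-8)
})

test_that("prevalence filter + standardisation commute with sample order", {
  set.seed(7)
  otu <- otu_tbl(matrix(rbinom(30 * 20, 4, 0.4), 30, 20,
                        dimnames = list(sprintf("S%02d", 1:30), NULL)))
  M1 <- log_standardize(filter_prevalence(otu))
  perm <- sample(30)
  otu2 <- otu_tbl(otu$counts[perm, ])
  M2 <- log_standardize(filter_prevalence(otu2))
  expect_equal(unclass(M2[rownames(M1), ]), unclass(M1), tolerance = 1e-12,
               ignore_attr = TRUE)
})
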