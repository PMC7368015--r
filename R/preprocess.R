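## SNP quality control, OTU filtering/transforms, fixed-effect design and
## phenotype pre-correction.

#' SNP quality control
#'
#' Applies, in order: individual call rate, SNP call rate, Hardy-Weinberg
#' equilibrium, and minor allele frequency filters.  Remaining missing
#' genotypes are imputed to the SNP mean so downstream matrix operations see
#' a complete matrix.
#'
#' @param geno animals x SNPs matrix of allele counts 0/1/2 (NA = missing).
#' @param ind_call_min minimum individual call rate (default 0.99).
#' @param snp_call_min minimum SNP call rate (default 0.98).
#' @param hwe_p_min HWE test p-value threshold (default 1e-8); an exact test
#'   is used when any expected genotype cell is below 5, a chi-square test
#'   otherwise.
#' @param maf_min minimum minor allele frequency (default 0.02).
#' @param impute impute residual missing genotypes to the SNP mean.
#' @return The filtered (and imputed) genotype matrix; attrition counts are
#'   attached as attribute `"qc_log"` and reported via `message()`.
#' @export
snp_qc <- function(geno, ind_call_min = 0.99, snp_call_min = 0.98,
                   hwe_p_min = 1e-8, maf_min = 0.02, impute = TRUE) {
  stopifnot(is.matrix(geno))
  bad <- !(is.na(geno) | geno == 0 | geno == 1 | geno == 2)
  if (any(bad)) stop("genotype codes outside {0, 1, 2, missing}")
  map <- attr(geno, "map")
  log <- c(ind_call = 0L, snp_call = 0L, hwe = 0L, maf = 0L)

  cr_ind <- rowMeans(!is.na(geno))
  keep_i <- cr_ind >= ind_call_min
  log["ind_call"] <- sum(!keep_i)
  geno <- geno[keep_i, , drop = FALSE]

  cr_snp <- colMeans(!is.na(geno))
  keep <- cr_snp >= snp_call_min
  log["snp_call"] <- sum(!keep)
  geno <- geno[, keep, drop = FALSE]
  if (!is.null(map)) map <- map[keep, , drop = FALSE]

  hwe_p <- apply(geno, 2, function(x) {
    hwe_test(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
             sum(x == 2, na.rm = TRUE))
  })
  keep <- hwe_p >= hwe_p_min
  log["hwe"] <- sum(!keep)
  geno <- geno[, keep, drop = FALSE]
  if (!is.null(map)) map <- map[keep, , drop = FALSE]

  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min
  log["maf"] <- sum(!keep)
  geno <- geno[, keep, drop = FALSE]
  if (!is.null(map)) map <- map[keep, , drop = FALSE]

  if (ncol(geno) == 0L)
    stop("all SNPs removed by QC; attrition: ",
         paste(names(log), log, sep = "=", collapse = ", "))
  if (impute && anyNA(geno)) {
    mu <- colMeans(geno, na.rm = TRUE)
    idx <- which(is.na(geno), arr.ind = TRUE)
    geno[idx] <- mu[idx[, 2]]
  }
  message(sprintf(
    "snp_qc: removed %d individuals (call rate), %d SNPs (call rate), %d (HWE), %d (MAF); %d SNPs remain",
    log["ind_call"], log["snp_call"], log["hwe"], log["maf"], ncol(geno)))
  attr(geno, "qc_log") <- log
  attr(geno, "map") <- map
  geno
}

#' Hardy-Weinberg equilibrium test for one SNP
#'
#' Exact (full enumeration over heterozygote counts, mid-free two-sided) when
#' any expected genotype count is below 5, chi-square otherwise.
#'
#' @param n0,n1,n2 counts of genotypes 0, 1, 2.
#' @return p-value.
#' @export
hwe_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0L) return(1)
  nA <- 2 * n0 + n1        # count of the '0' allele
  p <- nA / (2 * n)
  if (p == 0 || p == 1) return(1)
  exp_cnt <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (min(exp_cnt) >= 5) {
    chi2 <- sum((c(n0, n1, n2) - exp_cnt)^2 / exp_cnt)
    return(pchisq(chi2, df = 1, lower.tail = FALSE))
  }
  ## exact test: enumerate all heterozygote counts compatible with (nA, n)
  n_rare <- min(nA, 2 * n - nA)
  het <- seq(n_rare %% 2, n_rare, by = 2)
  lp <- lgamma(n + 1) - lgamma((n_rare - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((2 * n - n_rare - het) / 2 + 1) + het * log(2) +
    lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs_het <- n1
  sum(pr[pr <= pr[match(obs_het, het)] + 1e-12])
}

#' Prevalence filter for OTU tables
#'
#' Keeps a taxon iff it is present (count > 0) in at least
#' `ceiling(min_prevalence * n)` samples; the boundary is inclusive, so a
#' taxon present in exactly half the samples survives the default filter.
#'
#' @param otu an [otu_tbl()].
#' @param min_prevalence minimum presence fraction (default 0.5).
#' @return Filtered [otu_tbl()].
#' @export
filter_prevalence <- function(otu, min_prevalence = 0.5) {
  stopifnot(inherits(otu, "otu_tbl"))
  n <- nrow(otu$counts)
  need <- ceiling(min_prevalence * n)
  keep <- colSums(otu$counts > 0) >= need
  if (!any(keep)) stop("prevalence filter removed every taxon")
  otu_tbl(otu$counts[, keep, drop = FALSE],
          taxonomy = otu$taxonomy[names(which(keep))],
          instrument = otu$instrument)
}

#' Log-transform and column-standardise abundances
#'
#' Adds a small constant to every count, natural-log transforms, then
#' z-scores each taxon column (mean 0, variance 1, divisor n - 1).  With
#' `by_instrument = TRUE` the standardisation is computed within instrument
#' group, so that platform-level location/scale differences cannot leak into
#' the design matrix.
#'
#' @param otu an [otu_tbl()] (already prevalence-filtered).
#' @param pseudo constant added before the log (default 0.001).
#' @param by_instrument standardise within instrument groups.
#' @return Matrix of class `"microbiota_matrix"` with attributes
#'   `transform_tag = "log_std"` and `instrument`.
#' @export
log_standardize <- function(otu, pseudo = 0.001, by_instrument = FALSE) {
  stopifnot(inherits(otu, "otu_tbl"))
  lg <- log(otu$counts + pseudo)
  zscore <- function(x) {
    s <- apply(x, 2, sd)
    if (any(s == 0))
      stop("cannot standardise zero-variance taxon: ",
           paste(colnames(x)[s == 0], collapse = ", "))
    scale(x, center = TRUE, scale = s)
  }
  if (by_instrument && !is.null(otu$instrument)) {
    M <- lg
    for (g in unique(otu$instrument)) {
      rows <- which(otu$instrument == g)
      M[rows, ] <- zscore(lg[rows, , drop = FALSE])
    }
  } else {
    M <- zscore(lg)
  }
  M <- M[, , drop = FALSE]  # drop scale() attributes
  attr(M, "scaled:center") <- NULL
  attr(M, "scaled:scale") <- NULL
  structure(M, transform_tag = "log_std", instrument = otu$instrument,
            class = c("microbiota_matrix", "matrix", "array"))
}

#' Centred log-ratio transform
#'
#' Per sample: zeros are replaced by `zero_replacement`, then
#' \eqn{x_{ij} = \ln c_{ij} - \frac{1}{m}\sum_j \ln c_{ij}}, so every row
#' sums to zero.  Output columns can optionally be z-scored afterwards.
#'
#' @param otu an [otu_tbl()].
#' @param zero_replacement additive replacement for zero counts (default 0.5).
#' @param standardize additionally z-score columns after the CLR.
#' @return `"microbiota_matrix"` with `transform_tag = "clr"`.
#' @export
clr_transform <- function(otu, zero_replacement = 0.5, standardize = FALSE) {
  stopifnot(inherits(otu, "otu_tbl"))
  cnt <- otu$counts
  if (any(rowSums(cnt) == 0)) stop("all-zero sample; CLR undefined")
  cnt[cnt == 0] <- zero_replacement
  lg <- log(cnt)
  M <- lg - rowMeans(lg)
  tag <- "clr"
  if (standardize) {
    s <- apply(M, 2, sd)
    if (any(s == 0)) stop("cannot standardise zero-variance taxon")
    M <- scale(M, center = TRUE, scale = s)
    M <- M[, , drop = FALSE]
    tag <- "clr_std"
  }
  structure(M, transform_tag = tag, instrument = otu$instrument,
            class = c("microbiota_matrix", "matrix", "array"))
}

#' Collapse an OTU table to genus level
#'
#' Sums counts over OTUs sharing the same genus; OTUs unclassified at genus
#' rank are grouped by their deepest assigned rank.  Taxon IDs of the result
#' are the lineage strings truncated at the grouping rank.
#'
#' @param otu an [otu_tbl()] with taxonomy.
#' @return Collapsed [otu_tbl()].
#' @export
collapse_to_genus <- function(otu) {
  stopifnot(inherits(otu, "otu_tbl"))
  if (is.null(otu$taxonomy)) stop("taxonomy required to collapse to genus")
  label <- vapply(otu$taxonomy, function(tx) {
    ranks <- trimws(strsplit(tx, ";", fixed = TRUE)[[1]])
    assigned <- ranks[!grepl("^[a-z]__$", ranks) & nzchar(ranks)]
    g <- grep("^g__", assigned, value = TRUE)
    if (length(g)) {
      paste(assigned[seq_len(match(g[1], assigned))], collapse = ";")
    } else {
      paste(assigned, collapse = ";")   # deepest assigned rank
    }
  }, character(1))
  groups <- unique(label)
  out <- sapply(groups, function(g)
    rowSums(otu$counts[, label == g, drop = FALSE]))
  out <- matrix(out, nrow = nrow(otu$counts),
                dimnames = list(rownames(otu$counts), groups))
  otu_tbl(out, taxonomy = setNames(groups, groups),
          instrument = otu$instrument)
}

#' Build the fixed-effect design matrix
#'
#' Columns: intercept, herd dummies (reference level dropped), parity
#' dummies (reference dropped), days in milk, and the Wilmink lactation
#' term `exp(-k * DIM)` capturing early-lactation nonlinearity.  Optionally
#' an instrument dummy block.
#'
#' @param pheno phenotype data.frame with `herd`, `parity`, `dim` and
#'   optionally `instrument`.
#' @param wilmink_k Wilmink decay rate (default 0.05).
#' @param add_instrument include instrument dummies when the column exists.
#' @return list of class `"fixed_design"`: `X` (full-column-rank matrix with
#'   an intercept), `column_names`, `wilmink_k`.
#' @export
build_fixed_design <- function(pheno, wilmink_k = 0.05,
                               add_instrument = FALSE) {
  n <- nrow(pheno)
  X <- matrix(1, n, 1, dimnames = list(pheno$animal_id, "intercept"))
  add_dummies <- function(X, f, nm) {
    f <- factor(f)
    if (nlevels(f) < 2L) {
      warning("factor '", nm, "' has a single level; dummy block omitted")
      return(X)
    }
    D <- outer(f, levels(f)[-1], `==`) + 0
    colnames(D) <- paste0(nm, levels(f)[-1])
    cbind(X, D)
  }
  X <- add_dummies(X, pheno$herd, "herd")
  X <- add_dummies(X, pheno$parity, "parity")
  if (add_instrument && !is.null(pheno$instrument))
    X <- add_dummies(X, pheno$instrument, "instrument")
  X <- cbind(X, dim = as.numeric(pheno$dim),
             wilmink = exp(-wilmink_k * as.numeric(pheno$dim)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  structure(list(X = X, column_names = colnames(X), wilmink_k = wilmink_k),
            class = "fixed_design")
}

#' Pre-correct a trait for fixed effects
#'
#' Returns `y - X %*% gamma_hat` with `gamma_hat` the ordinary least-squares
#' fit; the result is orthogonal to the columns of X.
#'
#' @param y numeric trait vector.
#' @param X a `"fixed_design"` or plain design matrix.
#' @return Corrected vector with attribute `"gamma_hat"`.
#' @export
precorrect_phenotype <- function(y, X) {
  if (inherits(X, "fixed_design")) X <- X$X
  stopifnot(length(y) == nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design in pre-correction")
  fit <- lm.fit(X, y)
  structure(unname(fit$residuals), gamma_hat = coef(fit))
}
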