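## Single-SNP mixed linear model association with P3D variance components.

#' Single-SNP mixed-model association scan
#'
#' Fits \eqn{y = 1\mu + Zu + Xg + e} for one SNP at a time, with
#' \eqn{u \sim N(0, G\sigma^2_g)} controlling background relatedness.
#' Variance components are estimated once under the null model
#' (no SNP) and reused for every test (the P3D/EMMAX strategy); each SNP
#' effect is then a generalised least-squares estimate with covariance
#' \eqn{\sigma^2_g G + \sigma^2_e I}, tested by a t test
#' (\eqn{t = \hat g / SE}, df = n - 2), with Bonferroni adjustment
#' (multiplication by the number of tests).
#'
#' @param y pre-corrected trait vector.
#' @param K relationship matrix or cached [reml_eigen()].
#' @param geno animals x SNPs allele-count matrix (0/1/2, complete).
#' @param per_snp_reml re-estimate variance components for every SNP
#'   (exact but slow) instead of the P3D approximation.
#' @return data.frame of class `"scan_result"`: `id`, `estimate` (allele
#'   substitution effect), `se`, `statistic` (t), `p_value`, `p_adjusted`
#'   (Bonferroni), `method`, plus `chrom`/`pos` when the genotype matrix
#'   carries a map.  Monomorphic SNPs are skipped (NA rows).
#' @export
gwas_scan <- function(y, K, geno, per_snp_reml = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(geno) == n)
  ek <- if (is.list(K) && !is.null(K$vectors)) K else reml_eigen(K)
  m <- ncol(geno)
  ids <- colnames(geno)
  if (is.null(ids)) ids <- paste0("snp", seq_len(m))

  null_fit <- reml_h2(y, ek)
  sg2 <- null_fit$sigma_g2
  se2 <- null_fit$sigma_e2

  est <- se <- tval <- pval <- rep(NA_real_, m)
  mono <- apply(geno, 2, function(x) var(x) == 0)
  if (any(mono))
    message("skipping ", sum(mono), " monomorphic SNP(s)")

  if (per_snp_reml) {
    for (j in which(!mono)) {
      X <- cbind(1, geno[, j])
      fj <- reml_h2(y, ek, X = X)
      w <- 1 / (fj$sigma_g2 * ek$values + fj$sigma_e2)
      res <- .gls_snp(crossprod(ek$vectors, y),
                      crossprod(ek$vectors, X), w)
      est[j] <- res[1]; se[j] <- res[2]
    }
  } else {
    w <- 1 / (sg2 * ek$values + se2)
    yt <- crossprod(ek$vectors, y)
    onet <- crossprod(ek$vectors, rep(1, n))
    Gt <- crossprod(ek$vectors, geno)      # rotated SNP columns
    S11 <- sum(w * onet^2)
    S1y <- sum(w * onet * yt)
    Sx1 <- colSums(Gt * as.vector(w * onet))
    Sxy <- colSums(Gt * as.vector(w * yt))
    Sxx <- colSums(Gt^2 * w)
    det2 <- S11 * Sxx - Sx1^2
    est <- (S11 * Sxy - Sx1 * S1y) / det2
    se <- sqrt(S11 / det2)
    est[mono] <- NA_real_; se[mono] <- NA_real_
  }
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df = n - 2)
  out <- data.frame(id = ids, estimate = est, se = se, statistic = tval,
                    p_value = pval,
                    p_adjusted = pmin(1, pval * sum(!mono)),
                    method = "bonferroni", stringsAsFactors = FALSE)
  map <- attr(geno, "map")
  if (!is.null(map) && nrow(map) == m) {
    out$chrom <- map$chrom
    out$pos <- map$pos
  }
  class(out) <- c("scan_result", "data.frame")
  attr(out, "vc") <- c(sigma_g2 = sg2, sigma_e2 = se2)
  out
}

## GLS for a 2-column design in the rotated basis; returns c(effect, se)
.gls_snp <- function(yt, Xt, w) {
  XtWX <- crossprod(Xt, Xt * w)
  XtWy <- crossprod(Xt, yt * w)
  b <- solve(XtWX, XtWy)
  covb <- solve(XtWX)
  c(b[2], sqrt(covb[2, 2]))
}

#' Manhattan-style plot of an association scan
#'
#' @param scan a `"scan_result"` with `chrom` and `pos` columns.
#' @param alpha genome-wide significance level before Bonferroni division.
#' @param ... passed to [graphics::plot()].
#' @return The scan, invisibly.
#' @export
plot_manhattan <- function(scan, alpha = 0.05, ...) {
  stopifnot(all(c("chrom", "pos", "p_value") %in% names(scan)))
  ord <- order(scan$chrom, scan$pos)
  s <- scan[ord, ]
  x <- seq_len(nrow(s))
  graphics::plot(x, -log10(s$p_value), pch = 20, cex = 0.5,
                 col = 1 + (as.integer(factor(s$chrom)) %% 2),
                 xlab = "SNP index (by chromosome)",
                 ylab = expression(-log[10](p)), ...)
  graphics::abline(h = -log10(alpha / sum(!is.na(s$p_value))), lty = 2)
  invisible(scan)
}
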