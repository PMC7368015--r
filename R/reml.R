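## Genomic REML for a single random effect, heritability scans and
## multiple-testing adjustment.

## -2 * restricted log-likelihood for y = Xb + u + e, u ~ N(0, sg2 K),
## evaluated in the eigenbasis of K (yt = U'y, Xt = U'X, d = eigenvalues)
.neg2_reml <- function(sg2, se2, d, yt, Xt) {
  w <- sg2 * d + se2
  Wi <- 1 / w
  XtWX <- crossprod(Xt, Xt * Wi)
  XtWy <- crossprod(Xt, yt * Wi)
  bhat <- solve(XtWX, XtWy)
  resid_q <- sum(yt^2 * Wi) - sum(XtWy * bhat)
  sum(log(w)) + determinant(XtWX, logarithm = TRUE)$modulus[1] + resid_q
}

#' REML heritability for one trait
#'
#' Maximises the restricted likelihood of
#' \eqn{y = 1\mu + u + e}, \eqn{u \sim N(0, G\sigma^2_g)},
#' \eqn{e \sim N(0, I\sigma^2_e)} over the heritability ratio by a single
#' eigendecomposition of G and 1-D optimisation.  The standard error of
#' \eqn{h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)} comes from the inverse
#' numerical information matrix via the delta method, and the p-value is a
#' one-sided Wald test (variance ratios are non-negative).
#'
#' @param y numeric trait vector, pre-corrected for fixed effects (see
#'   [precorrect_phenotype()]).
#' @param K relationship matrix (usually genomic), or a cached
#'   eigendecomposition from [reml_eigen()].
#' @param X optional fixed-effect matrix (default intercept only).
#' @return list of class `"reml_fit"`: `sigma_g2`, `sigma_e2`, `h2`,
#'   `se_h2`, `p_value`, `loglik` (restricted), `converged`.
#' @export
reml_h2 <- function(y, K, X = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  ek <- if (is.list(K) && !is.null(K$vectors)) K else reml_eigen(K)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  stopifnot(nrow(ek$vectors) == n, nrow(X) == n)
  yt <- crossprod(ek$vectors, y)
  Xt <- crossprod(ek$vectors, X)
  d <- ek$values
  vp <- var(y)
  if (vp == 0) stop("constant trait")

  ## profile -2lR over h2, total variance concentrated out analytically
  prof <- function(h2) {
    w <- h2 * d + (1 - h2)
    Wi <- 1 / w
    XtWX <- crossprod(Xt, Xt * Wi)
    XtWy <- crossprod(Xt, yt * Wi)
    bhat <- solve(XtWX, XtWy)
    rq <- sum(yt^2 * Wi) - sum(XtWy * bhat)
    nc <- n - ncol(X)
    nc * log(rq / nc) + sum(log(w)) +
      determinant(XtWX, logarithm = TRUE)$modulus[1] + nc
  }
  opt <- optimize(prof, c(1e-6, 1 - 1e-6), tol = 1e-9)
  h2 <- opt$minimum
  w <- h2 * d + (1 - h2)
  Wi <- 1 / w
  XtWX <- crossprod(Xt, Xt * Wi)
  XtWy <- crossprod(Xt, yt * Wi)
  rq <- sum(yt^2 * Wi) - sum(crossprod(Xt, yt * Wi) * solve(XtWX, XtWy))
  s_tot <- rq / (n - ncol(X))
  sg2 <- h2 * s_tot
  se2 <- (1 - h2) * s_tot

  ## numerical observed information in (sg2, se2); cov = 2 * H^{-1} of -2lR.
  ## At a boundary the curvature is evaluated at a slightly interior point
  ## so the finite differences stay in the parameter space.
  f2 <- function(par) .neg2_reml(par[1], par[2], d, yt, Xt)
  tot <- sg2 + se2
  par0 <- pmax(c(sg2, se2), 1e-3 * tot)
  h <- rep(1e-4 * tot, 2)
  H <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- (f2(par0 + ei + ej) - f2(par0 + ei - ej) -
                  f2(par0 - ei + ej) + f2(par0 - ei - ej)) /
      (4 * h[i] * h[j])
  }
  se_h2 <- tryCatch({
    covm <- 2 * solve(H)
    g <- c(par0[2], -par0[1]) / sum(par0)^2
    sqrt(max(drop(t(g) %*% covm %*% g), 0))
  }, error = function(e) NA_real_)

  converged <- h2 > 2e-6 && h2 < 1 - 2e-6
  h2c <- min(max(h2, 0), 1)
  p <- if (is.na(se_h2) || se_h2 == 0) NA_real_ else
    pnorm(h2c / se_h2, lower.tail = FALSE)
  structure(list(sigma_g2 = sg2, sigma_e2 = se2, h2 = h2c, se_h2 = se_h2,
                 p_value = p, loglik = -opt$objective / 2,
                 converged = converged),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "REML: h2 = %.3f (SE %.3f), sigma_g2 = %.4g, sigma_e2 = %.4g, p = %.3g%s\n",
    x$h2, x$se_h2, x$sigma_g2, x$sigma_e2, x$p_value,
    if (!x$converged) " [boundary]" else ""))
  invisible(x)
}

#' Profiled restricted log-likelihood on a heritability grid
#'
#' Evaluates the same profiled restricted log-likelihood that [reml_h2()]
#' maximises at user-supplied heritability values — useful for checking the
#' optimiser against a grid search and for likelihood-surface plots.
#'
#' @inheritParams reml_h2
#' @param h2_grid heritability values in (0, 1).
#' @return Numeric vector of restricted log-likelihood values.
#' @export
reml_profile <- function(y, K, h2_grid, X = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  ek <- if (is.list(K) && !is.null(K$vectors)) K else reml_eigen(K)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  yt <- crossprod(ek$vectors, y)
  Xt <- crossprod(ek$vectors, X)
  d <- ek$values
  nc <- n - ncol(X)
  vapply(h2_grid, function(h2) {
    w <- h2 * d + (1 - h2)
    Wi <- 1 / w
    XtWX <- crossprod(Xt, Xt * Wi)
    XtWy <- crossprod(Xt, yt * Wi)
    rq <- sum(yt^2 * Wi) - sum(XtWy * solve(XtWX, XtWy))
    -0.5 * (nc * log(rq / nc) + sum(log(w)) +
              determinant(XtWX, logarithm = TRUE)$modulus[1] + nc)
  }, numeric(1))
}

#' Cache the eigendecomposition of a relationship matrix
#'
#' REML and the P3D association scan share one eigendecomposition of G; a
#' near-singular G gets a logged ridge of 1e-6 on the diagonal.
#'
#' @param K relationship matrix.
#' @return list with `values`, `vectors` (as [base::eigen()]).
#' @export
reml_eigen <- function(K) {
  e <- .kin_eigen(unclass(K))
  if (min(e$values) < 1e-8) {
    message("relationship matrix near-singular; adding 1e-6 to the diagonal")
    e$values <- e$values + 1e-6
  }
  e
}

#' Heritability scan over many microbial traits
#'
#' Runs [reml_h2()] per trait column (genus or OTU abundances, ordination
#' axes, Chao1) against one shared eigendecomposition, and adjusts the
#' Wald p-values with the Benjamini-Yekutieli procedure.
#'
#' @param traits numeric matrix, one pre-corrected trait per column.
#' @param K relationship matrix or cached [reml_eigen()].
#' @param adjust `"BY"` (default) or `"bonferroni"`.
#' @return data.frame of class `"scan_result"` with columns `id`,
#'   `estimate` (h2), `se`, `statistic`, `p_value`, `p_adjusted`, `method`.
#' @export
h2_scan <- function(traits, K, adjust = c("BY", "bonferroni")) {
  adjust <- match.arg(adjust)
  traits <- as.matrix(traits)
  ids <- colnames(traits)
  if (is.null(ids)) ids <- paste0("trait", seq_len(ncol(traits)))
  ek <- if (is.list(K) && !is.null(K$vectors)) K else reml_eigen(K)
  rows <- lapply(seq_len(ncol(traits)), function(j) {
    yj <- traits[, j]
    if (var(yj) == 0) {
      warning("trait ", ids[j], " is constant; skipped")
      return(NULL)
    }
    f <- reml_h2(yj, ek)
    data.frame(id = ids[j], estimate = f$h2, se = f$se_h2,
               statistic = f$h2 / f$se_h2, p_value = f$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (adjust == "BY") benjamini_yekutieli(out$p_value) else
    pmin(1, out$p_value * nrow(out))
  out$method <- adjust
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjustment valid under arbitrary dependence:
#' \eqn{\tilde p_{(i)} = \min_{j \ge i} \min(1, m\, c(m)\, p_{(j)} / j)}
#' with \eqn{c(m) = \sum_{k=1}^m 1/k}.  Delegates to
#' `stats::p.adjust(method = "BY")`.
#'
#' @param p vector of p-values.
#' @return Adjusted p-values, order matched to the input.
#' @export
benjamini_yekutieli <- function(p) {
  p.adjust(p, method = "BY")
}
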