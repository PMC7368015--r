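#' Joint Bayesian variance partitioning of host genetics and microbiome
#'
#' Fits \eqn{y = X\gamma + Zu + M\beta + e} by MCMC, with
#' \eqn{u \sim N(0, K\sigma^2_u)} for a relationship matrix K (pedigree or
#' genomic) and a K-component scale-mixture-of-normals prior on the taxon
#' effects \eqn{\beta}.  Component variances are tied to fixed ratios
#' (default 1:10:100:1000, component 1 the most heavily shrunken class) and
#' the mixture proportions get a Dirichlet prior (default
#' Dir(125, 25, 5, 1)).  Updates: Gibbs for \eqn{\gamma}, \eqn{u},
#' \eqn{\beta}, \eqn{\pi}, \eqn{\sigma^2_e}, \eqn{\sigma^2_u};
#' random-walk Metropolis-Hastings for the component indicators (move to a
#' neighbouring component, with boundary balancing corrections) and for the
#' tied component variances (joint log-normal proposal, likelihood-ratio
#' acceptance, step size tuned during burn-in only).
#'
#' The posterior of the explained-variance shares is accumulated every
#' saved cycle: `var_m` is the sample variance (divisor n-1) of the vector
#' \eqn{M\beta}, `var_u` is \eqn{\sigma^2_u}, and the proportions divide by
#' \eqn{\sigma^2_u + var(M\beta) + \sigma^2_e}.
#'
#' @param y numeric response vector (e.g. methane, l/day), or a formula for
#'   the formula method.
#' @param X fixed-effect design: a [build_fixed_design()] result, a plain
#'   matrix, or NULL for intercept-only.  A zero-column matrix omits fixed
#'   effects entirely.
#' @param kinship relationship matrix (pedigree A or genomic G), or NULL to
#'   omit the polygenic term.
#' @param microbiome transformed abundance matrix M (see
#'   [log_standardize()] / [clr_transform()]).
#' @param config a [run_config()]; chain protocol and mixture prior.
#' @param seed integer seed (overrides `config$seed`).
#' @param nested_instrument fit separate taxon effects per instrument group
#'   (doubles the columns of M) instead of shared effects.
#' @param fix_sigma_e,fix_comp_var,fix_pi optionally freeze the residual
#'   variance, the component variances (vector of length K), or the mixture
#'   proportions at given values instead of sampling them (used for
#'   conjugate checks and calibration studies).
#' @param save_beta keep the full matrix of saved \eqn{\beta} samples.
#' @param data,... formula-method arguments; `...` passes through.
#' @return Object of class `"mb_fit"`; see Details.  Key elements:
#'   `summary` (posterior means and 95% HPD intervals of the variance
#'   shares), `samples` (per-saved-cycle draws), `dic`, `taxon_var`
#'   (posterior mean per-taxon variance contribution), `pi_mean`.
#' @references The model generalises the BayesR mixture-prior regression by
#'   adding an explicit polygenic term alongside the taxon effects.
#' @export
#' @examples
#' set.seed(1)
#' sim <- sim_genotypes(n = 80, m = 150, n_families = 8, seed = 1)
#' G <- grm_yang(sim$genotypes)
#' M <- matrix(rnorm(80 * 30), 80, 30)
#' y <- rnorm(80)
#' cfg <- run_config(chain_length = 600, burn_in = 100, thin = 5)
#' fit <- microbiability(y, kinship = G, microbiome = M, config = cfg,
#'                       seed = 7)
#' fit$summary
microbiability <- function(y, X = NULL, kinship = NULL, microbiome,
                           config = run_config(), seed = config$seed,
                           nested_instrument = FALSE,
                           fix_sigma_e = NULL, fix_comp_var = NULL,
                           fix_pi = NULL, save_beta = FALSE, ...) {
  UseMethod("microbiability")
}

#' @rdname microbiability
#' @export
microbiability.formula <- function(y, X = NULL, kinship = NULL, microbiome,
                                   config = run_config(), seed = config$seed,
                                   nested_instrument = FALSE,
                                   fix_sigma_e = NULL, fix_comp_var = NULL,
                                   fix_pi = NULL, save_beta = FALSE,
                                   data, ...) {
  mf <- stats::model.frame(y, data)
  resp <- stats::model.response(mf)
  Xm <- stats::model.matrix(y, mf)
  microbiability.default(resp, X = Xm, kinship = kinship,
                         microbiome = microbiome, config = config,
                         seed = seed, nested_instrument = nested_instrument,
                         fix_sigma_e = fix_sigma_e,
                         fix_comp_var = fix_comp_var, fix_pi = fix_pi,
                         save_beta = save_beta, ...)
}

#' @rdname microbiability
#' @export
microbiability.default <- function(y, X = NULL, kinship = NULL, microbiome,
                                   config = run_config(), seed = config$seed,
                                   nested_instrument = FALSE,
                                   fix_sigma_e = NULL, fix_comp_var = NULL,
                                   fix_pi = NULL, save_beta = FALSE, ...) {
  cl <- match.call()
  config <- validate_run_config(config)
  y <- as.numeric(y)
  n <- length(y)
  if (n <= 2) stop("need more than 2 observations")

  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (inherits(X, "fixed_design")) X <- X$X
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X and y are not conformable")

  M <- as.matrix(microbiome)
  if (nrow(M) != n) stop("microbiome matrix and y are not conformable")
  if (nested_instrument) {
    instr <- attr(microbiome, "instrument")
    if (is.null(instr)) stop("nested_instrument needs an instrument attribute")
    groups <- unique(instr)
    M <- do.call(cbind, lapply(groups, function(g) {
      Mi <- M
      Mi[instr != g, ] <- 0
      colnames(Mi) <- paste0(colnames(M), "@", g)
      Mi
    }))
  }
  p <- ncol(M)
  K <- config$n_components

  has_polygenic <- !is.null(kinship)
  if (has_polygenic) {
    if (!all(dim(kinship) == n)) stop("kinship matrix and y not conformable")
    e <- .kin_eigen(unclass(kinship))
    keep <- e$values > 1e-10 * max(e$values)
    q <- sum(keep)
    if (q <= 2) stop("relationship matrix rank too low for the polygenic term")
    L <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), q)
    eigvals <- e$values[keep]
  } else {
    L <- matrix(0, n, 1); eigvals <- 1
  }

  ## initial values
  gamma0 <- if (ncol(X) > 0) {
    fit0 <- lm.fit(X, y)
    ifelse(is.na(fit0$coefficients), 0, fit0$coefficients)
  } else numeric(0)
  vy <- var(y)
  sigma_e2 <- if (is.null(fix_sigma_e)) vy / 2 else fix_sigma_e
  sigma_u2 <- vy / 4
  if (!is.null(fix_comp_var)) {
    if (length(fix_comp_var) != K) stop("fix_comp_var must have length K")
    ## frozen variances must still obey the configured ratios
    base_var <- fix_comp_var[1]
    config$variance_ratios <- fix_comp_var / base_var
  } else {
    ## start the mixture at a scale where the prior-expected var(M beta)
    ## is half the phenotypic variance: too-small starting variances can
    ## trap the chain in a fully-shrunken state early on
    pr <- config$dirichlet_alpha / sum(config$dirichlet_alpha)
    base_var <- vy / (2 * max(p, 1) * sum(pr * config$variance_ratios))
  }
  pi0 <- if (is.null(fix_pi)) {
    config$dirichlet_alpha / sum(config$dirichlet_alpha)
  } else {
    if (length(fix_pi) != K || abs(sum(fix_pi) - 1) > 1e-8)
      stop("fix_pi must be a length-K probability vector")
    fix_pi
  }

  if (!is.null(seed)) set.seed(seed)
  res <- .mix_mcmc_cpp(y, X, L, M, eigvals, K,
                       config$variance_ratios, config$dirichlet_alpha,
                       config$chain_length, config$burn_in, config$thin,
                       as.numeric(gamma0), sigma_e2, sigma_u2, base_var,
                       pi0, has_polygenic,
                       update_sigma_e = is.null(fix_sigma_e),
                       update_sigma_u = has_polygenic,
                       update_comp_var = is.null(fix_comp_var),
                       update_pi = is.null(fix_pi) && K > 1,
                       step_sd = config$mh_step_sd, tune_step = TRUE,
                       save_z = TRUE, save_beta = save_beta)

  for (nm in c("sigma_u2", "sigma_e2", "base_var", "var_m", "deviance",
               "beta_mean", "beta2_mean", "fitted_mean", "u_mean"))
    res[[nm]] <- as.numeric(res[[nm]])
  total <- res$sigma_u2 + res$var_m + res$sigma_e2
  prop_u <- res$sigma_u2 / total
  prop_m <- res$var_m / total
  samples <- data.frame(sigma_u2 = res$sigma_u2, sigma_e2 = res$sigma_e2,
                        var_m = res$var_m, base_var = res$base_var,
                        prop_u = prop_u, prop_m = prop_m,
                        deviance = res$deviance)
  comp_var_samples <- outer(res$base_var, config$variance_ratios)
  colnames(comp_var_samples) <- paste0("comp_var", seq_len(K))

  ## DIC at the posterior mean of the linear predictor and sigma_e2
  dbar <- mean(res$deviance)
  se2_bar <- mean(res$sigma_e2)
  dhat <- n * log(2 * pi * se2_bar) + sum((y - res$fitted_mean)^2) / se2_bar
  dic <- 2 * dbar - dhat

  ## per-taxon variance contribution: posterior mean of var(m_i beta_i)
  colv <- apply(M, 2, var)
  taxon_var <- colv * res$beta2_mean
  names(taxon_var) <- colnames(M)

  summ <- data.frame(
    component = c("host_genetics", "microbiome", "residual"),
    var_mean = c(mean(res$sigma_u2), mean(res$var_m), mean(res$sigma_e2)),
    prop_mean = c(mean(prop_u), mean(prop_m),
                  mean(res$sigma_e2 / total)),
    prop_hpd_low = NA_real_, prop_hpd_high = NA_real_)
  hu <- hpd_interval(prop_u); hm <- hpd_interval(prop_m)
  he <- hpd_interval(res$sigma_e2 / total)
  summ$prop_hpd_low <- c(hu[1], hm[1], he[1])
  summ$prop_hpd_high <- c(hu[2], hm[2], he[2])

  out <- structure(list(
    summary = summ, samples = samples, pi_samples = res$pi,
    comp_var_samples = comp_var_samples, gamma_samples = res$gamma,
    z = res$z, beta_samples = res$beta,
    beta_mean = as.numeric(res$beta_mean),
    taxon_var = taxon_var, pi_mean = colMeans(res$pi),
    fitted_mean = as.numeric(res$fitted_mean),
    u_mean = if (has_polygenic) as.numeric(res$u_mean) else NULL,
    dic = dic, p_eff = dbar - dhat,
    y = y, n = n, p = p, K = K, has_polygenic = has_polygenic,
    config = config, seed = seed, call = cl,
    z_accept = res$z_accept), class = "mb_fit")
  if (!is.null(config$trace_file)) write_trace(out, config$trace_file)
  out
}

#' Write the saved-sample trace of a fit to TSV
#'
#' One row per saved cycle: variance components, explained-variance shares,
#' mixture proportions and deviance — the convergence-inspection record.
#'
#' @param fit an `"mb_fit"`.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  df <- cbind(fit$samples, as.data.frame(fit$pi_samples))
  names(df)[(ncol(fit$samples) + 1):ncol(df)] <-
    paste0("pi", seq_len(fit$K))
  .write_tsv(df, path)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval over the sorted samples containing
#' `ceiling(mass * n)` points.
#'
#' @param samples numeric vector of posterior draws (>= 20).
#' @param mass target probability mass (default 0.95).
#' @return Length-2 vector `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  n <- length(samples)
  if (n < 20) stop("need at least 20 samples for an HPD interval")
  s <- sort(samples)
  k <- ceiling(mass * n)
  if (k >= n) return(c(s[1], s[n]))
  width <- s[(k + 1):n] - s[seq_len(n - k)]
  i <- which.min(width)
  c(s[i], s[i + k])
}

#' @export
print.mb_fit <- function(x, digits = 3, ...) {
  cat("Bayesian mixture-prior variance partitioning (mb_fit)\n")
  cat(sprintf("  n = %d animals, %d taxa, K = %d components%s\n", x$n, x$p,
              x$K, if (x$has_polygenic) ", polygenic term" else ""))
  cat(sprintf("  chain: %d iterations (burn-in %d, thin %d, %d saved)\n",
              x$config$chain_length, x$config$burn_in, x$config$thin,
              nrow(x$samples)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-14s %5.1f%%  (95%% HPD %.1f%% - %.1f%%)\n",
                s$component[i], 100 * s$prop_mean[i],
                100 * s$prop_hpd_low[i], 100 * s$prop_hpd_high[i]))
  }
  cat(sprintf("  DIC = %.1f (pD = %.1f)\n", x$dic, x$p_eff))
  invisible(x)
}

#' @export
summary.mb_fit <- function(object, ...) {
  occ <- rowMeans(apply(object$z, 2, tabulate, nbins = object$K)) /
    max(object$p, 1)
  top <- sort(object$taxon_var, decreasing = TRUE)
  structure(list(fit = object, summary = object$summary,
                 pi_mean = object$pi_mean, occupancy = occ,
                 top_taxa = head(top, 10), dic = object$dic),
            class = "summary.mb_fit")
}

#' @export
print.summary.mb_fit <- function(x, ...) {
  print(x$fit)
  cat("  posterior mean mixture proportions:",
      paste(sprintf("%.3f", x$pi_mean), collapse = ", "), "\n")
  cat("  mean component occupancy of taxa:",
      paste(sprintf("%.3f", x$occupancy), collapse = ", "), "\n")
  cat("  top taxa by posterior mean variance contribution:\n")
  nm <- names(x$top_taxa)
  if (is.null(nm)) nm <- paste0("taxon", seq_along(x$top_taxa))
  for (i in seq_along(x$top_taxa)) {
    cat(sprintf("    %-24s %.4g\n", nm[i], x$top_taxa[i]))
  }
  invisible(x)
}

#' @export
coef.mb_fit <- function(object, ...) {
  g <- colMeans(object$gamma_samples)
  list(gamma = g, beta = object$beta_mean)
}

#' @export
fitted.mb_fit <- function(object, ...) object$fitted_mean

#' @export
residuals.mb_fit <- function(object, ...) object$y - object$fitted_mean

#' @export
plot.mb_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  s <- x$samples
  graphics::plot(s$prop_u, type = "l", xlab = "saved cycle",
                 ylab = "prop. host genetics", main = "var(Zu) share", ...)
  graphics::plot(s$prop_m, type = "l", xlab = "saved cycle",
                 ylab = "prop. microbiome", main = "var(M beta) share", ...)
  graphics::plot(s$sigma_e2, type = "l", xlab = "saved cycle",
                 ylab = "sigma_e^2", main = "residual variance", ...)
  graphics::plot(s$base_var, type = "l", log = "y", xlab = "saved cycle",
                 ylab = "component 1 variance", main = "mixture base variance",
                 ...)
  invisible(x)
}

#' @export
simulate.mb_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(object$samples), nsim, replace = TRUE)
  out <- vapply(idx, function(i) {
    object$fitted_mean +
      rnorm(object$n, 0, sqrt(object$samples$sigma_e2[i]))
  }, numeric(object$n))
  as.data.frame(out)
}
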