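#' MCMC and preprocessing run configuration
#'
#' Bundles the chain protocol, mixture prior and preprocessing settings used
#' across the pipeline.  Defaults reproduce the study protocol: a 100,000
#' iteration chain with 10,000 burn-in cycles and every 20th remaining sample
#' saved, a Dirichlet(125, 25, 5, 1) prior on the mixture proportions, and
#' component variances constrained to the ratios 1:10:100:1000 (component 1
#' is the strongest-shrinkage class, component K the mildest).
#'
#' @param chain_length total MCMC iterations.
#' @param burn_in iterations discarded before saving; must be < `chain_length`.
#' @param thin stride between saved post-burn-in samples.
#' @param n_components number of mixture components K (>= 1).
#' @param dirichlet_alpha K positive Dirichlet prior counts for the mixture
#'   proportions.  Default for K = 4 is `c(125, 25, 5, 1)` (most prior mass on
#'   the heavily shrunken class); for other K a geometric ladder `5^((K-1):0)`.
#' @param variance_ratios K strictly increasing positive multipliers; the
#'   k-th component variance is `ratio[k]` times the first (smallest) one, so
#'   the default `c(1, 10, 100, 1000)` enforces
#'   \eqn{\sigma^2_4 = 10\sigma^2_3 = 100\sigma^2_2 = 1000\sigma^2_1}.
#' @param seed optional integer seed applied before sampling.
#' @param transform abundance transform feeding the design matrix M:
#'   `"log_std"` (add pseudo-count, natural log, column z-score) or `"clr"`
#'   (centred log-ratio).
#' @param prevalence_min minimum fraction of samples a taxon must be present
#'   in (count > 0) to be retained.
#' @param pseudo_count constant added before the log in the `log_std` path.
#' @param wilmink_k decay rate of the Wilmink lactation-curve covariate
#'   `exp(-wilmink_k * DIM)`.
#' @param clr_zero zero replacement used before the CLR transform.
#' @param mh_step_sd initial random-walk SD for the log-scale component
#'   variance update (auto-tuned during burn-in only).
#' @param trace_file optional path; when set, the saved-sample trace is
#'   written there as TSV after the run.
#' @return A validated list of class `"run_config"`.
#' @seealso [read_run_config()] to load settings from a YAML file.
#' @export
#' @examples
#' cfg <- run_config(chain_length = 5000, burn_in = 1000, thin = 5)
#' cfg$dirichlet_alpha
run_config <- function(chain_length = 100000L, burn_in = 10000L, thin = 20L,
                       n_components = 4L,
                       dirichlet_alpha = NULL, variance_ratios = NULL,
                       seed = NULL, transform = c("log_std", "clr"),
                       prevalence_min = 0.5, pseudo_count = 0.001,
                       wilmink_k = 0.05, clr_zero = 0.5,
                       mh_step_sd = 0.1, trace_file = NULL) {
  transform <- match.arg(transform)
  K <- as.integer(n_components)
  if (K < 1L) stop("n_components must be >= 1")
  if (is.null(dirichlet_alpha)) {
    dirichlet_alpha <- if (K == 4L) c(125, 25, 5, 1) else 5^((K - 1L):0)
  }
  if (is.null(variance_ratios)) variance_ratios <- 10^(0:(K - 1L))
  cfg <- list(chain_length = as.integer(chain_length),
              burn_in = as.integer(burn_in), thin = as.integer(thin),
              n_components = K,
              dirichlet_alpha = as.numeric(dirichlet_alpha),
              variance_ratios = as.numeric(variance_ratios),
              seed = if (is.null(seed)) NULL else as.integer(seed),
              transform = transform,
              prevalence_min = prevalence_min, pseudo_count = pseudo_count,
              wilmink_k = wilmink_k, clr_zero = clr_zero,
              mh_step_sd = mh_step_sd, trace_file = trace_file)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$chain_length <= cfg$burn_in)
    stop("chain_length must exceed burn_in")
  if (cfg$thin < 1L) stop("thin must be >= 1")
  K <- cfg$n_components
  if (length(cfg$dirichlet_alpha) != K || any(cfg$dirichlet_alpha <= 0))
    stop("dirichlet_alpha must hold ", K, " positive values")
  if (length(cfg$variance_ratios) != K || any(cfg$variance_ratios <= 0))
    stop("variance_ratios must hold ", K, " positive values")
  if (K > 1L && any(diff(cfg$variance_ratios) <= 0))
    stop("variance_ratios must be strictly increasing")
  if (cfg$prevalence_min < 0 || cfg$prevalence_min > 1)
    stop("prevalence_min must lie in [0, 1]")
  if (cfg$pseudo_count <= 0) stop("pseudo_count must be positive")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat keys mirror the arguments of [run_config()]; keys absent from the
#' file keep their defaults, and arguments supplied through `...` override
#' file values (the same precedence a command-line flag would have).
#'
#' @param path YAML file.
#' @param ... overrides passed on to [run_config()].
#' @return A `"run_config"` object.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(run_config)))
  vals <- vals[keep]
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("MCMC run configuration\n")
  cat(sprintf("  chain: %d iterations, burn-in %d, thin %d (%d saved)\n",
              x$chain_length, x$burn_in, x$thin,
              (x$chain_length - x$burn_in) %/% x$thin))
  cat(sprintf("  mixture: K = %d, Dirichlet(%s), variance ratios %s\n",
              x$n_components, paste(x$dirichlet_alpha, collapse = ", "),
              paste(x$variance_ratios, collapse = ":")))
  cat(sprintf("  transform: %s (prevalence >= %g, pseudo-count %g)\n",
              x$transform, x$prevalence_min, x$pseudo_count))
  invisible(x)
}
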