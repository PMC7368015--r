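## Relationship matrices: pedigree additive A (tabular method) and the
## Yang-et-al. SNP-based genomic G.

#' Pedigree additive relationship matrix (tabular method)
#'
#' Recursive tabular construction after a topological sort:
#' \eqn{A_{ii} = 1 + \tfrac12 A_{sire,dam}} and
#' \eqn{A_{ij} = \tfrac12 (A_{j,sire(i)} + A_{j,dam(i)})}; an unknown parent
#' contributes 0.  Parents referenced but absent from the animal column are
#' auto-added as founders with a warning; a cyclic pedigree is an error.
#'
#' @param ped data.frame with character columns `animal`, `sire`, `dam`
#'   (NA = unknown), as from [read_pedigree()].
#' @return Symmetric matrix with animal IDs as dimnames and attribute
#'   `"kind" = "pedigree_A"`.
#' @export
pedigree_A <- function(ped) {
  .require_cols(ped, c("animal", "sire", "dam"), "pedigree")
  ped <- as.data.frame(lapply(ped[c("animal", "sire", "dam")], as.character),
                       stringsAsFactors = FALSE)
  animals <- ped$animal
  if (anyDuplicated(animals)) stop("duplicate animal IDs in pedigree")
  extra <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), animals)
  if (length(extra)) {
    warning("adding ", length(extra), " referenced parent(s) as founders")
    ped <- rbind(data.frame(animal = extra, sire = NA_character_,
                            dam = NA_character_, stringsAsFactors = FALSE),
                 ped)
    animals <- ped$animal
  }
  n <- nrow(ped)
  sire <- match(ped$sire, animals)
  dam <- match(ped$dam, animals)
  ## Kahn topological sort: parents strictly before offspring
  ord <- integer(0)
  placed <- logical(n)
  repeat {
    ok_s <- is.na(sire) | placed[ifelse(is.na(sire), 1L, sire)]
    ok_d <- is.na(dam) | placed[ifelse(is.na(dam), 1L, dam)]
    ready <- which(!placed & ok_s & ok_d)
    if (!length(ready)) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) < n)
    stop("pedigree contains a cycle (animal is its own ancestor)")
  pos <- match(seq_len(n), ord)       # original index -> position in sort
  s_pos <- pos[sire]                  # per original animal, sorted position
  d_pos <- pos[dam]                   # of its parents (NA propagates)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    oi <- ord[i]
    s <- s_pos[oi]; d <- d_pos[oi]
    if (i > 1L) {
      js <- seq_len(i - 1L)
      rel <- numeric(i - 1L)
      if (!is.na(s)) rel <- rel + A[s, js]
      if (!is.na(d)) rel <- rel + A[d, js]
      A[i, js] <- A[js, i] <- 0.5 * rel
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A <- A[pos, pos, drop = FALSE]
  dimnames(A) <- list(animals, animals)
  attr(A, "kind") <- "pedigree_A"
  A
}

#' Yang-et-al. genomic relationship matrix
#'
#' Off-diagonals
#' \eqn{G_{jk} = \frac1m \sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)}}
#' and the estimator's own-relationship diagonal
#' \eqn{G_{jj} = 1 + \frac1m \sum_i
#'   \frac{x_{ij}^2 - (1+2p_i)x_{ij} + 2p_i^2}{2p_i(1-p_i)}}.
#'
#' @param geno post-QC animals x SNPs allele-count matrix (no monomorphic
#'   SNPs; missing values imputed).
#' @param freqs optional externally supplied allele frequencies; defaults to
#'   sample frequencies.
#' @return Symmetric matrix with attribute `"kind" = "genomic_G"`.
#' @export
grm_yang <- function(geno, freqs = NULL) {
  stopifnot(is.matrix(geno))
  if (anyNA(geno)) stop("missing genotypes; run snp_qc(impute = TRUE) first")
  p <- if (is.null(freqs)) colMeans(geno) / 2 else freqs
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNP reached grm_yang; QC should remove it")
  m <- ncol(geno)
  denom <- 2 * p * (1 - p)
  Zs <- sweep(geno, 2, 2 * p, `-`) * rep(1 / sqrt(denom), each = nrow(geno))
  G <- tcrossprod(Zs) / m
  diag(G) <- 1 + rowSums(sweep(geno^2, 2, denom, `/`) -
                           sweep(geno, 2, (1 + 2 * p) / denom, `*`) +
                           rep((2 * p^2) / denom, each = nrow(geno))) / m
  dimnames(G) <- list(rownames(geno), rownames(geno))
  attr(G, "kind") <- "genomic_G"
  G
}

## Eigendecomposition of a relationship matrix, shared by the MCMC and REML
## paths.  Small negative eigenvalues are clipped to zero — the Yang GRM's
## adjusted diagonal routinely makes it very slightly indefinite at finite
## marker counts — while genuinely indefinite input (e.g. a dissimilarity
## matrix passed by mistake) is an error.
.kin_eigen <- function(K, tol = 0.05) {
  if (!isSymmetric(K, check.attributes = FALSE))
    stop("relationship matrix must be symmetric")
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values), 1))
    stop("relationship matrix is not positive semi-definite (min eigenvalue ",
         format(min(e$values)), ")")
  e$values[e$values < 0] <- 0
  e
}
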