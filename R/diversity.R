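## Community summaries used as quantitative traits: Bray-Curtis PCoA,
## Chao1 richness, and PCA on CLR-transformed abundances.

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{D_{jk} = 1 - 2\sum_i \min(c_{ij}, c_{ik}) /
#' (\sum_i c_{ij} + \sum_i c_{ik})}, computed on raw (filtered) counts by
#' default; set `relative = TRUE` to use per-sample relative abundances.
#'
#' @param otu an [otu_tbl()] or a samples x taxa count matrix.
#' @param relative divide each sample by its total first.
#' @return Symmetric dissimilarity matrix with zero diagonal, values in
#'   \[0, 1\].
#' @export
bray_curtis <- function(otu, relative = FALSE) {
  cnt <- if (inherits(otu, "otu_tbl")) otu$counts else as.matrix(otu)
  if (any(cnt < 0)) stop("counts must be non-negative")
  if (any(rowSums(cnt) == 0))
    stop("all-zero sample; Bray-Curtis undefined")
  if (relative) cnt <- cnt / rowSums(cnt)
  D <- as.matrix(vegan::vegdist(cnt, method = "bray"))
  dimnames(D) <- list(rownames(cnt), rownames(cnt))
  D
}

#' Principal coordinate analysis (classical MDS)
#'
#' Double-centres \eqn{-\tfrac12 D^2}, eigendecomposes, and keeps the top
#' `n_axes` non-negative eigenvalues.  Negative eigenvalues are dropped (no
#' Cailliez correction); their mass fraction is reported as an attribute.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @param n_axes number of coordinate axes to return.
#' @return list of class `"ordination"`: `coordinates` (samples x axes,
#'   column means zero), `eigenvalues`, `explained_fraction` (of the positive
#'   eigenvalue mass), `method`.
#' @export
pcoa <- function(D, n_axes = 2) {
  D <- as.matrix(D)
  if (!isSymmetric(D, check.attributes = FALSE) || any(abs(diag(D)) > 1e-12))
    stop("D must be symmetric with zero diagonal")
  ## cmdscale itself warns about non-Euclidean (negative-eigenvalue) input;
  ## that case is handled explicitly below
  mds <- suppressWarnings(cmdscale(as.dist(D), k = nrow(D) - 1, eig = TRUE))
  pos <- mds$eig[mds$eig > 1e-12 * max(abs(mds$eig))]
  n_pos <- length(pos)
  if (n_axes > n_pos) {
    warning("only ", n_pos, " positive eigenvalues; truncating axes")
    n_axes <- n_pos
  }
  coords <- mds$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PCoA", seq_len(n_axes))
  neg_mass <- sum(abs(mds$eig[mds$eig < 0])) / sum(abs(mds$eig))
  structure(list(coordinates = coords,
                 eigenvalues = pos[seq_len(n_axes)],
                 explained_fraction = pos[seq_len(n_axes)] / sum(pos),
                 method = "pcoa"),
            negative_mass = neg_mass, class = "ordination")
}

#' Chao1 richness estimator (bias-corrected)
#'
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} with \eqn{F_1} the number
#' of singleton taxa and \eqn{F_2} the number of doubletons; defined even
#' when no doubletons are observed.
#'
#' @param counts non-negative integer abundance vector for one sample.
#' @return Estimated richness (>= observed richness).
#' @export
chao1 <- function(counts) {
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("Chao1 is defined on non-negative integer counts")
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' PCA on CLR-transformed abundances
#'
#' Column-centres the CLR matrix and eigendecomposes its covariance
#' (equivalently, classical MDS of Euclidean distances — the Aitchison
#' geometry for compositions).
#'
#' @param M_clr a `"microbiota_matrix"` with `transform_tag` `"clr"` (or a
#'   plain matrix).
#' @param n_axes number of component scores to return.
#' @return `"ordination"` with `method = "pca_clr"`.
#' @export
pca_clr <- function(M_clr, n_axes = 2) {
  tag <- attr(M_clr, "transform_tag")
  if (!is.null(tag) && !startsWith(tag, "clr"))
    warning("input transform_tag is '", tag, "', expected a CLR matrix")
  if (nrow(M_clr) < 2) stop("need at least 2 samples for PCA")
  pc <- prcomp(unclass(M_clr), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- ev > 1e-12 * max(ev)
  n_axes <- min(n_axes, sum(keep))
  coords <- pc$x[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(n_axes))
  structure(list(coordinates = coords,
                 eigenvalues = ev[seq_len(n_axes)],
                 explained_fraction = ev[seq_len(n_axes)] / sum(ev[keep]),
                 method = "pca_clr"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d samples, %d axes\n", x$method,
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("  explained:",
      paste(sprintf("%.1f%%", 100 * x$explained_fraction), collapse = ", "),
      "\n")
  invisible(x)
}
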