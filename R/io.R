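## Table input/output.  All tables are plain TSV; row order is canonicalised
## by sorting on animal ID so loaders are insensitive to input order.

#' OTU count table
#'
#' Container for a samples x taxa count matrix with optional taxonomy strings
#' and a per-sample sequencing-instrument label.
#'
#' @param counts numeric matrix, samples in rows (rownames = animal IDs),
#'   taxa in columns (colnames = taxon IDs); non-negative.
#' @param taxonomy optional named character vector of lineage strings
#'   (semicolon-separated greengenes-style ranks), names matching taxa.
#' @param instrument optional character vector of instrument labels, one per
#'   sample.
#' @return An object of class `"otu_tbl"`.
#' @export
otu_tbl <- function(counts, taxonomy = NULL, instrument = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("S%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("OTU%04d", seq_len(ncol(counts)))
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) {
      if (length(taxonomy) != ncol(counts))
        stop("unnamed taxonomy must have one entry per taxon")
    } else {
      taxonomy <- taxonomy[colnames(counts)]
    }
    names(taxonomy) <- colnames(counts)
    if (anyNA(taxonomy)) stop("taxonomy missing for some taxa")
  }
  if (!is.null(instrument)) {
    instrument <- as.character(instrument)
    if (length(instrument) != nrow(counts))
      stop("instrument must have one label per sample")
    names(instrument) <- rownames(counts)
  }
  structure(list(counts = counts, taxonomy = taxonomy,
                 instrument = instrument), class = "otu_tbl")
}

#' @export
print.otu_tbl <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d taxa\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  zero fraction: %.2f\n", mean(x$counts == 0)))
  if (!is.null(x$instrument))
    cat("  instruments:",
        paste(names(table(x$instrument)), table(x$instrument),
              sep = "=", collapse = ", "), "\n")
  if (!is.null(x$taxonomy)) cat("  taxonomy: present\n")
  invisible(x)
}

#' @export
dim.otu_tbl <- function(x) dim(x$counts)

## full-precision TSV writer: doubles via %.17g so read/write round-trips
.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  tryCatch(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, eol = "\n"),
    error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "")
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("format error in ", what, ": missing column(s) ",
         paste(miss, collapse = ", "))
}

#' Read a phenotype table
#'
#' Expects TSV columns `animal_id`, `methane` (response, l/day), `herd`,
#' `parity`, `dim` (days in milk) and optionally `instrument`.
#'
#' @param path TSV file.
#' @return data.frame sorted by `animal_id`.
#' @export
read_phenotypes <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("animal_id", "methane", "herd", "parity", "dim"),
                "phenotype table")
  df$animal_id <- as.character(df$animal_id)
  df[order(df$animal_id), , drop = FALSE]
}

#' Read a genotype matrix
#'
#' Two dialects are supported: a plain TSV with an `animal_id` column
#' followed by one 0/1/2 column per SNP (missing = NA), and PLINK
#' `.ped`/`.map` text files (pass the `.ped` path; the `.map` is looked up
#' alongside).
#'
#' @param path genotype file (`.tsv`-style matrix or `.ped`).
#' @param map_path optional explicit `.map` path for the PLINK dialect.
#' @return numeric matrix (animals x SNPs, rownames = IDs) with a `"map"`
#'   attribute data.frame (`snp`, `chrom`, `pos`) when positions are known.
#' @export
read_genotypes <- function(path, map_path = NULL) {
  if (grepl("\\.ped$", path)) return(.read_plink(path, map_path))
  df <- .read_tsv(path)
  .require_cols(df, "animal_id", "genotype matrix")
  ids <- as.character(df$animal_id)
  g <- as.matrix(df[setdiff(names(df), "animal_id")])
  storage.mode(g) <- "double"
  ok <- is.na(g) | g %in% c(0, 1, 2)
  if (!all(ok))
    stop("format error: genotype codes outside {0, 1, 2, missing}")
  rownames(g) <- ids
  g[order(ids), , drop = FALSE]
}

## minimal PLINK .ped/.map parser (alphanumeric alleles, 0 = missing);
## allele counts are of the minor allele per SNP
.read_plink <- function(ped_path, map_path = NULL) {
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(ped_path)) stop("file not found: ", ped_path)
  if (!file.exists(map_path)) stop("file not found: ", map_path)
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  names(map)[1:4] <- c("chrom", "snp", "cm", "pos")[seq_len(min(4, ncol(map)))]
  ped <- read.table(ped_path, header = FALSE, stringsAsFactors = FALSE)
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop("format error: .ped has ", ncol(ped), " columns, expected ",
         6 + 2 * m, " for ", m, " SNPs")
  ids <- as.character(ped[[2]])
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m)])
  g <- matrix(NA_real_, nrow(ped), m, dimnames = list(ids, map$snp))
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    al <- al[al != "0"]
    alleles <- sort(unique(al))
    if (length(alleles) > 2)
      stop("format error: SNP ", map$snp[j], " has >2 alleles")
    ## count the rarer allele; ties broken by sort order
    counted <- alleles[which.min(tabulate(match(al, alleles)))]
    gj <- (a1[, j] == counted) + (a2[, j] == counted)
    gj[a1[, j] == "0" | a2[, j] == "0"] <- NA
    g[, j] <- gj
  }
  g <- g[order(ids), , drop = FALSE]
  attr(g, "map") <- data.frame(snp = map$snp, chrom = map$chrom,
                               pos = map$pos, stringsAsFactors = FALSE)
  g
}

#' Read a pedigree
#'
#' CSV or TSV with columns `animal`, `sire`, `dam`; `0`, `NA` or empty mark
#' an unknown parent.
#'
#' @param path pedigree file.
#' @return data.frame with character columns `animal`, `sire`, `dam`
#'   (unknown parent = NA).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  .require_cols(df, c("animal", "sire", "dam"), "pedigree")
  for (cl in c("animal", "sire", "dam")) {
    df[[cl]] <- as.character(df[[cl]])
    df[[cl]][df[[cl]] %in% c("0", "", "NA")] <- NA
  }
  df
}

#' Read an OTU count table (with optional taxonomy sidecar)
#'
#' The count TSV has columns `animal_id`, optionally `instrument`, then one
#' column per taxon.  The taxonomy TSV has columns `taxon_id`, `taxonomy`.
#'
#' @param path count TSV.
#' @param taxonomy_path optional taxonomy TSV.
#' @return An [otu_tbl()].
#' @export
read_otu_table <- function(path, taxonomy_path = NULL) {
  df <- .read_tsv(path)
  .require_cols(df, "animal_id", "OTU table")
  ids <- as.character(df$animal_id)
  instrument <- if ("instrument" %in% names(df)) df$instrument else NULL
  cnt <- as.matrix(df[setdiff(names(df), c("animal_id", "instrument"))])
  storage.mode(cnt) <- "double"
  rownames(cnt) <- ids
  o <- order(ids)
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    tx <- .read_tsv(taxonomy_path)
    .require_cols(tx, c("taxon_id", "taxonomy"), "taxonomy table")
    taxonomy <- setNames(tx$taxonomy, tx$taxon_id)
  }
  otu_tbl(cnt[o, , drop = FALSE], taxonomy = taxonomy,
          instrument = if (is.null(instrument)) NULL else instrument[o])
}

#' Write an OTU table (counts + taxonomy sidecar)
#'
#' @param otu an [otu_tbl()].
#' @param path count TSV destination.
#' @param taxonomy_path optional taxonomy TSV destination.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(otu, path, taxonomy_path = NULL) {
  df <- data.frame(animal_id = rownames(otu$counts),
                   stringsAsFactors = FALSE)
  if (!is.null(otu$instrument)) df$instrument <- unname(otu$instrument)
  df <- cbind(df, as.data.frame(otu$counts))
  .write_tsv(df, path)
  if (!is.null(taxonomy_path) && !is.null(otu$taxonomy))
    .write_tsv(data.frame(taxon_id = names(otu$taxonomy),
                          taxonomy = unname(otu$taxonomy),
                          stringsAsFactors = FALSE), taxonomy_path)
  invisible(path)
}

#' Load and align all input tables on shared animal IDs
#'
#' Reads whichever of the phenotype, genotype, pedigree and OTU files are
#' supplied, intersects their animal IDs (the pedigree keeps ancestors),
#' reports and drops unmatched IDs, and returns tables in a deterministic
#' (ID-sorted) row order.
#'
#' @param paths named list with any of `phenotype`, `genotypes`, `map`,
#'   `pedigree`, `otu`, `taxonomy`.
#' @param config a [run_config()] (reserved for dialect options).
#' @return list with elements `phenotype`, `genotypes`, `pedigree`, `otu`
#'   (those supplied), aligned to the common IDs.
#' @export
load_tables <- function(paths, config = run_config()) {
  out <- list()
  if (!is.null(paths$phenotype)) out$phenotype <- read_phenotypes(paths$phenotype)
  if (!is.null(paths$genotypes))
    out$genotypes <- read_genotypes(paths$genotypes, paths$map)
  if (!is.null(paths$pedigree)) out$pedigree <- read_pedigree(paths$pedigree)
  if (!is.null(paths$otu)) out$otu <- read_otu_table(paths$otu, paths$taxonomy)
  id_sets <- list()
  if (!is.null(out$phenotype)) id_sets$phenotype <- out$phenotype$animal_id
  if (!is.null(out$genotypes)) id_sets$genotypes <- rownames(out$genotypes)
  if (!is.null(out$otu)) id_sets$otu <- rownames(out$otu$counts)
  if (length(id_sets)) {
    ids <- sort(Reduce(intersect, id_sets))
    if (length(ids) == 0L) stop("no overlapping animal IDs across tables")
    orphans <- sort(unique(unlist(lapply(id_sets, setdiff, ids))))
    if (length(orphans))
      warning("dropping ", length(orphans), " unmatched ID(s): ",
              paste(head(orphans, 10), collapse = ", "),
              if (length(orphans) > 10) ", ..." else "")
    if (!is.null(out$phenotype))
      out$phenotype <- out$phenotype[match(ids, out$phenotype$animal_id), ,
                                     drop = FALSE]
    if (!is.null(out$genotypes)) {
      map <- attr(out$genotypes, "map")
      out$genotypes <- out$genotypes[ids, , drop = FALSE]
      attr(out$genotypes, "map") <- map
    }
    if (!is.null(out$otu)) {
      out$otu$counts <- out$otu$counts[ids, , drop = FALSE]
      if (!is.null(out$otu$instrument))
        out$otu$instrument <- out$otu$instrument[ids]
    }
    out$ids <- ids
  }
  out
}

#' Write / read a scan result table
#'
#' Scan results (REML heritability or SNP association) are plain TSVs with a
#' stable column order and full-precision floats, so a write/read cycle is
#' lossless to double precision.
#'
#' @param scan data.frame of class `"scan_result"` (or compatible).
#' @param path destination TSV.
#' @return `path` (write) or the scan data.frame (read).
#' @export
write_scan <- function(scan, path) {
  .write_tsv(scan, path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  df <- .read_tsv(path)
  class(df) <- c("scan_result", "data.frame")
  df
}

#' Write / read a relationship matrix as TSV with an ID header
#'
#' @param K symmetric matrix with dimnames.
#' @param path destination TSV.
#' @return `path` (write) or the matrix (read).
#' @export
write_relationship <- function(K, path) {
  df <- data.frame(id = rownames(K), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(K))
  .write_tsv(df, path)
}

#' @rdname write_relationship
#' @export
read_relationship <- function(path) {
  df <- .read_tsv(path)
  ids <- as.character(df$id)
  K <- as.matrix(df[setdiff(names(df), "id")])
  dimnames(K) <- list(ids, ids)
  K
}
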