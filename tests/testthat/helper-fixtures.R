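# Shared fixture builders; everything is generated in code.

# small identity-kinship dataset for quick sampler runs
quick_data <- function(n = 60, p = 10, seed = 1) {
  set.seed(seed)
  G <- diag(n)
  dimnames(G) <- list(sprintf("A%03d", 1:n), sprintf("A%03d", 1:n))
  list(G = G, M = matrix(rnorm(n * p), n, p,
                         dimnames = list(rownames(G), paste0("OTU", 1:p))),
       y = rnorm(n))
}

# toy OTU table with known structure
toy_otu <- function() {
  cnt <- rbind(c(5, 0, 3, 1), c(3, 0, 0, 2), c(0, 1, 4, 2), c(2, 0, 5, 0))
  dimnames(cnt) <- list(paste0("S", 1:4), paste0("OTU", 1:4))
  otu_tbl(cnt,
          taxonomy = c(
            OTU1 = "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Lachnospiraceae;g__Blautia",
            OTU2 = "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Lachnospiraceae;g__Blautia",
            OTU3 = "k__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__;g__",
            OTU4 = "k__Archaea;p__Euryarchaeota;c__Methanobacteria;o__Methanobacteriales;f__Methanobacteriaceae;g__Methanobrevibacter"),
          instrument = c("MiSeq", "MiSeq", "HiSeq", "HiSeq"))
}

# batch-means Monte Carlo standard error for a (possibly autocorrelated) chain
mcse <- function(x, n_batch = 20) {
  n <- length(x)
  b <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch), function(i)
    mean(x[((i - 1) * b + 1):(i * b)]), numeric(1))
  sd(means) / sqrt(n_batch)
}

# phenotype covariate table in the study's structure
fixed_covariates <- function(n, seed = 1, herds = 6, parities = 4) {
  set.seed(seed)
  data.frame(animal_id = sprintf("A%05d", seq_len(n)),
             herd = sample(paste0("H", seq_len(herds)), n, replace = TRUE),
             parity = sample(seq_len(parities), n, replace = TRUE,
                             prob = c(0.4, 0.3, 0.2, 0.1)[seq_len(parities)]),
             dim = sample(1:350, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
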