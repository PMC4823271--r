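# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# GenotypeData from a plain dosage matrix (individuals x SNPs).
makeGeno <- function(dosage, chrom = "1", gene = NA_character_) {
  n <- ncol(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("snp", seq_len(n))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  GenotypeData(dosage, data.frame(
    chrom = rep(chrom, length.out = n),
    pos = seq_len(n) * 100L,
    alleleMinor = "A", alleleMajor = "G",
    gene = rep(gene, length.out = n),
    stringsAsFactors = FALSE))
}

# GenotypeData assembled from phased haplotypes (rows = haplotypes,
# consecutive pairs form an individual).
phasedToGeno <- function(H) {
  stopifnot(nrow(H) %% 2 == 0)
  G <- H[seq(1, nrow(H), 2), , drop = FALSE] + H[seq(2, nrow(H), 2), , drop = FALSE]
  makeGeno(G)
}

# Covariate table with variation in site/gender/handedness.
makeCovariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(id = paste0("ind", seq_len(n)),
             site = sample(paste0("site", 1:3), n, replace = TRUE),
             gender = rbinom(n, 1, 0.5),
             handedness = rbinom(n, 1, 0.87),
             stringsAsFactors = FALSE)
}

# Enrichment pool with heterogeneous gene sizes (the Table-1-like
# spread of SNPs per gene).
makeEnrichmentPool <- function(seed, nGene = 200) {
  set.seed(seed)
  sizes <- pmin(pmax(round(exp(rnorm(nGene, log(20), 1))), 2), 271)
  gene <- rep(paste0("g", seq_len(nGene)), times = sizes)
  snps <- paste0("s", seq_along(gene))
  list(snpGene = stats::setNames(gene, snps),
       genes = paste0("g", seq_len(nGene)))
}
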