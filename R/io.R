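#' Read PLINK text genotypes (.ped/.map)
#'
#' Whitespace-delimited text PLINK: the .map supplies chromosome, SNP id
#' and 1-based position; the .ped supplies six leading columns (FID,
#' IID, PAT, MAT, SEX, PHENO; only IID is consumed) followed by two
#' allele columns per SNP. The minor allele is determined per SNP from
#' the data (ties broken alphabetically); dosage counts minor alleles;
#' a genotype containing the "0" code is missing. More than two alleles
#' at a SNP is an error naming the SNP.
#'
#' @param pedPath path to the .ped file.
#' @param mapPath path to the .map file.
#' @return \linkS4class{GenotypeData}.
#' @export
readPlinkText <- function(pedPath, mapPath) {
  map <- utils::read.table(mapPath, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4) stop("malformed .map: expected 4 columns")
  colnames(map)[1:4] <- c("chrom", "snp", "cm", "pos")
  ped <- utils::read.table(pedPath, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  nSnps <- nrow(map)
  if (ncol(ped) != 6 + 2 * nSnps)
    stop(sprintf("malformed .ped: %d columns, expected %d for %d SNPs",
                 ncol(ped), 6 + 2 * nSnps, nSnps))
  ids <- ped[[2]]
  n <- nrow(ped)
  dosage <- matrix(NA_real_, n, nSnps, dimnames = list(ids, map$snp))
  minor <- major <- character(nSnps)
  for (j in seq_len(nSnps)) {
    a1 <- ped[[6 + 2 * j - 1]]
    a2 <- ped[[6 + 2 * j]]
    miss <- a1 == "0" | a2 == "0"
    alleles <- c(a1[!miss], a2[!miss])
    ut <- sort(table(alleles))
    if (length(ut) > 2)
      stop(sprintf("SNP %s has more than two alleles (%s)",
                   map$snp[j], paste(names(ut), collapse = "/")))
    if (length(ut) == 0) { minor[j] <- "A"; major[j] <- "B"; next }
    if (length(ut) == 1) {
      major[j] <- names(ut); minor[j] <- setdiff(c("A", "B"), names(ut))[1]
    } else {
      nm <- names(ut)
      if (ut[1] == ut[2]) nm <- sort(nm)     # tie: alphabetical minor
      minor[j] <- nm[1]; major[j] <- nm[2]
    }
    dosage[!miss, j] <- (a1[!miss] == minor[j]) + (a2[!miss] == minor[j])
  }
  snps <- data.frame(chrom = as.character(map$chrom), pos = as.integer(map$pos),
                     alleleMinor = minor, alleleMajor = major,
                     gene = NA_character_, stringsAsFactors = FALSE)
  GenotypeData(dosage, snps)
}

#' Write PLINK text genotypes (.ped/.map)
#'
#' @param geno \linkS4class{GenotypeData}.
#' @param pedPath,mapPath output paths.
#' @return invisibly, the two paths.
#' @export
writePlinkText <- function(geno, pedPath, mapPath) {
  si <- snpInfo(geno)
  utils::write.table(
    data.frame(si$chrom, si$snp, 0, si$pos),
    mapPath, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  G <- dosageMatrix(geno)
  n <- nrow(G)
  lines <- vapply(seq_len(n), function(i) {
    gt <- character(2 * ncol(G))
    for (j in seq_len(ncol(G))) {
      d <- G[i, j]
      pair <- if (is.na(d)) c("0", "0")
      else if (d == 0) c(si$alleleMajor[j], si$alleleMajor[j])
      else if (d == 1) c(si$alleleMinor[j], si$alleleMajor[j])
      else c(si$alleleMinor[j], si$alleleMinor[j])
      gt[c(2 * j - 1, 2 * j)] <- pair
    }
    paste(c("FAM", rownames(G)[i], "0", "0", "0", "-9", gt), collapse = " ")
  }, character(1))
  writeLines(lines, pedPath)
  invisible(c(pedPath, mapPath))
}

#' Read a TSV dosage matrix
#'
#' Rows are individuals, columns SNPs, values 0/1/2 with "NA" for
#' missing; the first column holds individual ids. SNP annotation comes
#' from a companion map TSV (columns snp, chrom, pos, alleleMinor,
#' alleleMajor, optionally gene).
#'
#' @param dosagePath path to the dosage TSV.
#' @param mapPath path to the SNP map TSV.
#' @return \linkS4class{GenotypeData}.
#' @export
readDosageTsv <- function(dosagePath, mapPath) {
  d <- utils::read.table(dosagePath, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  ids <- d[[1]]
  M <- as.matrix(d[, -1, drop = FALSE])
  rownames(M) <- ids
  map <- utils::read.table(mapPath, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  map <- map[match(colnames(M), map$snp), ]
  GenotypeData(M, map[, setdiff(colnames(map), "snp"), drop = FALSE])
}

#' Write a TSV dosage matrix and companion SNP map
#'
#' @param geno \linkS4class{GenotypeData}.
#' @param dosagePath,mapPath output paths.
#' @return invisibly, the two paths.
#' @export
writeDosageTsv <- function(geno, dosagePath, mapPath) {
  G <- dosageMatrix(geno)
  df <- data.frame(id = rownames(G), G, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, dosagePath, quote = FALSE, row.names = FALSE,
                     sep = "\t", na = "NA")
  utils::write.table(snpInfo(geno), mapPath, quote = FALSE,
                     row.names = FALSE, sep = "\t", na = "NA")
  invisible(c(dosagePath, mapPath))
}

#' Read a phenotype/covariate table
#'
#' Header TSV with columns id, site, gender, handedness and one or more
#' phenotype columns.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readPhenoTsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a phenotype/covariate table
#' @param pheno data.frame with an id column.
#' @param path TSV path.
#' @return invisibly, the path.
#' @export
writePhenoTsv <- function(pheno, path) {
  utils::write.table(pheno, path, quote = FALSE, row.names = FALSE,
                     sep = "\t", na = "NA")
  invisible(path)
}
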