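#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix of minor-allele dosages with
#'   \emph{individuals in rows and SNPs in columns} (the orientation of
#'   the dosage TSV dialect); values 0/1/2 or NA. Row names are
#'   individual ids, column names SNP ids (generated when absent).
#' @param snps data.frame of SNP annotation with columns \code{chrom},
#'   \code{pos}, \code{alleleMinor}, \code{alleleMajor} and optionally
#'   \code{gene}; one row per SNP, in column order of \code{dosage}.
#' @param samples optional data.frame of per-individual covariates and
#'   phenotypes, one row per individual.
#'
#' @return A \linkS4class{GenotypeData} object.
#' @examples
#' d <- matrix(c(0, 1, 2, 1, 0, 1), nrow = 3,
#'             dimnames = list(paste0("ind", 1:3), c("s1", "s2")))
#' snps <- data.frame(chrom = "1", pos = c(100L, 200L),
#'                    alleleMinor = "A", alleleMajor = "G")
#' g <- GenotypeData(d, snps)
#' dim(dosageMatrix(g))
#' @export
GenotypeData <- function(dosage, snps, samples = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("snp", seq_len(ncol(dosage)))
  if (nrow(snps) != ncol(dosage))
    stop("snps must have one row per dosage column")
  if (!"gene" %in% colnames(snps)) snps$gene <- NA_character_
  rd <- S4Vectors::DataFrame(snps)
  rownames(rd) <- colnames(dosage)
  cd <- if (is.null(samples)) S4Vectors::DataFrame(row.names = rownames(dosage))
        else S4Vectors::DataFrame(samples, row.names = rownames(dosage))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = t(dosage)), rowData = rd, colData = cd)
  methods::new("GenotypeData", se)
}

#' @rdname dosageMatrix
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' Extract the dosage matrix in analysis orientation
#'
#' @param x A \linkS4class{GenotypeData} object.
#' @return Numeric matrix, individuals in rows, SNPs in columns.
#' @export
setMethod("dosageMatrix", "GenotypeData", function(x) {
  t(SummarizedExperiment::assay(x, "dosage"))
})

#' @rdname snpInfo
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' SNP annotation as a plain data.frame
#'
#' @param x A \linkS4class{GenotypeData} object.
#' @return data.frame with columns \code{snp}, \code{chrom}, \code{pos},
#'   \code{alleleMinor}, \code{alleleMajor}, \code{gene}.
#' @export
setMethod("snpInfo", "GenotypeData", function(x) {
  rd <- as.data.frame(rowData(x))
  data.frame(snp = rownames(x), rd, row.names = NULL,
             stringsAsFactors = FALSE)
})

#' @rdname sampleInfo
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' Sample covariates and phenotypes as a plain data.frame
#'
#' @param x A \linkS4class{GenotypeData} object.
#' @return data.frame with an \code{id} column followed by colData.
#' @export
setMethod("sampleInfo", "GenotypeData", function(x) {
  cd <- as.data.frame(colData(x))
  data.frame(id = colnames(x), cd, row.names = NULL,
             stringsAsFactors = FALSE)
})

#' Attach or replace sample covariates/phenotypes
#'
#' @param x A \linkS4class{GenotypeData} object.
#' @param samples data.frame with an \code{id} column matching the
#'   individuals in \code{x} (any order).
#' @return \code{x} with colData replaced.
#' @export
setSampleInfo <- function(x, samples) {
  stopifnot("id" %in% colnames(samples))
  idx <- match(colnames(x), samples$id)
  if (anyNA(idx)) stop("samples table is missing some individuals in the genotype data")
  cd <- samples[idx, setdiff(colnames(samples), "id"), drop = FALSE]
  colData(x) <- S4Vectors::DataFrame(cd, row.names = colnames(x))
  x
}

#' @importFrom SummarizedExperiment colData<-
NULL

setMethod("show", "GenotypeData", function(object) {
  d <- SummarizedExperiment::assay(object, "dosage")
  cat("GenotypeData:", ncol(d), "individuals x", nrow(d), "SNPs\n")
  cat("  chromosomes:", paste(unique(as.character(rowData(object)$chrom)), collapse = ", "), "\n")
  nm <- mean(is.na(d))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * nm))
  cv <- colnames(colData(object))
  if (length(cv)) cat("  sample columns:", paste(cv, collapse = ", "), "\n")
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport\n")
  cat("  SNPs removed:", nrow(object@removedSnps))
  if (nrow(object@removedSnps))
    cat(" (", paste(sprintf("%s: %d", names(table(object@removedSnps$reason)),
                            as.integer(table(object@removedSnps$reason))), collapse = ", "), ")")
  cat("\n  individuals removed:", nrow(object@removedSamples))
  if (nrow(object@removedSamples))
    cat(" (", paste(sprintf("%s: %d", names(table(object@removedSamples$reason)),
                            as.integer(table(object@removedSamples$reason))), collapse = ", "), ")")
  cat("\n  thresholds:", paste(sprintf("%s=%s", names(object@thresholds),
                                       unlist(object@thresholds)), collapse = ", "), "\n")
})

setMethod("show", "PruneResult", function(object) {
  cat("PruneResult:", length(object@kept), "SNPs kept",
      sprintf("(window=%d, step=%d, r2<=%g)\n",
              object@window, object@step, object@r2Threshold))
})

setMethod("show", "ExactTestResult", function(object) {
  cat(sprintf("Exact resampling test: n = %d of m = %d positive correlations\n",
              object@n, object@m))
  cat(sprintf("  max one-sided p among positives: %.4g\n", object@maxP))
  cat(sprintf("  p_exact = %.4g; Bonferroni x%d -> p = %.4g\n",
              object@pExact, object@nPhenotypes, object@pCorrected))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("Enrichment: observed %d SNP p-values < %g; permutation p = %.4g (%d permutations)\n",
              object@observed, object@threshold, object@p, object@nPerm))
})

setMethod("show", "HaplotypeFreqs", function(object) {
  cat("HaplotypeFreqs:", length(object@freq), "haplotypes,",
      ncol(object@hapAlleles), "SNPs\n")
  o <- order(object@freq, decreasing = TRUE)
  top <- utils::head(o, 8)
  for (i in top)
    cat(sprintf("  %s  %.4f\n", object@haplotypes[i], object@freq[i]))
  if (!object@converged) cat("  (EM did not converge)\n")
})
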