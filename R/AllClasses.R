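#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' GenotypeData: diploid dosage genotypes with SNP and sample annotation
#'
#' S4 container for additive-coded genotypes, extending
#' \linkS4class{SummarizedExperiment}. The single assay \code{"dosage"}
#' holds SNPs in rows and individuals in columns, each entry counting
#' copies of the minor allele (0, 1, 2 or \code{NA} for a missing call).
#' \code{rowData} carries the SNP map (\code{chrom}, \code{pos},
#' \code{alleleMinor}, \code{alleleMajor}, \code{gene}); \code{colData}
#' carries per-individual covariates and phenotypes.
#'
#' Positions must be non-decreasing within each chromosome and the two
#' allele labels distinct per SNP, which validity enforces.
#'
#' @seealso [GenotypeData()] for the constructor, [dosageMatrix()],
#'   [snpInfo()], [sampleInfo()] for accessors.
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

.validGenotypeData <- function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    ok <- is.na(d) | d == 0 | d == 1 | d == 2
    if (!all(ok)) msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  rd <- rowData(object)
  need <- c("chrom", "pos", "alleleMinor", "alleleMajor")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ", paste(miss, collapse = ", ")))
  if (!length(miss) && nrow(rd) > 1) {
    if (any(unlist(tapply(rd$pos, as.character(rd$chrom), function(p) diff(p) < 0))))
      msg <- c(msg, "positions must be non-decreasing within chromosome")
    if (any(rd$alleleMinor == rd$alleleMajor))
      msg <- c(msg, "allele labels must be distinct per SNP")
  }
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeData", .validGenotypeData)

#' QC report: items removed by a quality-control step
#'
#' Each removed SNP or individual is recorded with exactly one primary
#' reason (the first failed criterion in the documented order), together
#' with the thresholds applied.
#'
#' @slot removedSnps data.frame with columns \code{id}, \code{reason}.
#' @slot removedSamples data.frame with columns \code{id}, \code{reason}.
#' @slot thresholds named list of thresholds used.
#' @export
setClass("QCReport", representation(
  removedSnps = "data.frame",
  removedSamples = "data.frame",
  thresholds = "list"
))

#' LD pruning result
#'
#' @slot kept character vector of surviving SNP ids.
#' @slot window integer window size in SNPs.
#' @slot step integer slide in SNPs.
#' @slot r2Threshold numeric pairwise r-squared ceiling.
#' @export
setClass("PruneResult", representation(
  kept = "character",
  window = "integer",
  step = "integer",
  r2Threshold = "numeric"
))

#' Exact combination test over polygenic-score resamplings
#'
#' Joins two pieces of evidence across \code{m} discovery/target splits:
#' the number \code{n} of positive semi-partial correlations (binomial
#' with success probability 1/2 under the null) and the largest one-sided
#' p-value \code{maxP} among the positive ones (each uniform on (0, 0.5)
#' under the null).
#'
#' @slot m integer number of resamplings.
#' @slot n integer number of positive correlations.
#' @slot maxP numeric largest one-sided p among positive correlations
#'   (0.5 by convention when \code{n == 0}).
#' @slot pExact numeric combined exact p-value.
#' @slot pCorrected numeric Bonferroni-corrected p-value.
#' @slot nPhenotypes integer Bonferroni factor.
#' @export
setClass("ExactTestResult", representation(
  m = "integer", n = "integer", maxP = "numeric",
  pExact = "numeric", pCorrected = "numeric", nPhenotypes = "integer"
))

#' Result of the gene-preserving enrichment permutation test
#'
#' @slot observed integer count of candidate SNP p-values below the threshold.
#' @slot nullDist integer vector, the permutation null distribution.
#' @slot p numeric permutation p-value, add-one rule.
#' @slot threshold numeric p-value threshold defining the statistic.
#' @slot nPerm integer number of permutations.
#' @export
setClass("EnrichmentResult", representation(
  observed = "integer", nullDist = "integer", p = "numeric",
  threshold = "numeric", nPerm = "integer"
))

#' EM haplotype frequency estimate for a SNP block
#'
#' @slot haplotypes character vector of haplotype allele strings
#'   (one character per SNP, minor-allele letter vs major).
#' @slot hapAlleles integer matrix (haplotype x SNP) of minor-allele
#'   indicators.
#' @slot freq numeric simplex of haplotype frequencies.
#' @slot dosage numeric matrix (individual x haplotype) of expected
#'   haplotype counts from the EM posterior; rows sum to 2.
#' @slot logLik numeric final log-likelihood.
#' @slot iterations integer EM iterations used.
#' @slot converged logical.
#' @export
setClass("HaplotypeFreqs", representation(
  haplotypes = "character", hapAlleles = "matrix", freq = "numeric",
  dosage = "matrix", logLik = "numeric", iterations = "integer",
  converged = "logical"
))
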