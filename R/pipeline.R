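#' Default pipeline configuration
#'
#' Every threshold of the workflow with its protocol default. Stage
#' toggles switch quality control, pruning, polygenic scoring,
#' univariate association, enrichment and haplotype analysis on or off.
#' A seed is mandatory for any stochastic stage: there is no silent
#' default.
#'
#' @param seed integer seed (required).
#' @param ... overrides for any configuration key; unknown keys are
#'   rejected.
#' @return named list.
#' @export
pipelineConfig <- function(seed, ...) {
  if (missing(seed)) stop("seed is required in the configuration")
  cfg <- list(
    seed = as.integer(seed),
    # stage toggles
    doQc = TRUE, doPrune = TRUE, doPrs = TRUE, doAssoc = TRUE,
    doEnrich = FALSE, doHaplo = FALSE,
    # synthetic input (used when no genotype paths are given)
    simIndividuals = 400L, simBlocks = 40L, simSnpsPerBlock = 5L,
    simCausal = 0L, simTargetR2 = 0.05,
    # QC thresholds
    callRateMin = 0.98, mafMin = 0.01, hweAlpha = 1e-4,
    missMax = 0.02, hetSd = 3.0, ibdMax = 0.1875,
    # pruning
    pruneWindow = 50L, pruneStep = 5L, pruneR2 = 0.5,
    # polygenic scoring
    m = 10L, fracDiscovery = 0.7, pThreshold = 0.5, nPhenotypes = 1L,
    phenotype = "pheno",
    # enrichment
    enrichThreshold = 0.05, enrichPerm = 500L,
    # haplotypes
    fourGameteFreq = 0.05, rareHapFreq = 0.01,
    # input/output
    dosagePath = NA_character_, mapPath = NA_character_,
    phenoPath = NA_character_, outDir = NA_character_
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Read a flat key=value configuration file
#'
#' One \code{key = value} pair per line; \code{#} starts a comment.
#' Values are parsed as logical/numeric where possible.
#'
#' @param path file path.
#' @return named list suitable for splicing into [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- lapply(kv, function(x) {
    v <- x[2]
    if (v %in% c("TRUE", "FALSE", "true", "false")) return(as.logical(toupper(v)))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  })
  stats::setNames(vals, vapply(kv, `[[`, character(1), 1))
}

#' Run the full two-stage human pipeline
#'
#' Orchestrates (optional) simulation, SNP and sample quality control,
#' LD pruning, the polygenic score resampling procedure, univariate
#' association and, when enabled, enrichment and haplotype analyses.
#' When \code{outDir} is set, every stage output and a manifest
#' (thresholds, seed, versions) are written there; identical
#' configurations yield identical outputs.
#'
#' @param config list from [pipelineConfig()].
#' @return list with elements \code{geno}, \code{pheno}, \code{qc},
#'   \code{prune}, \code{prs}, \code{assoc}, \code{enrich},
#'   \code{haplo}, \code{manifest} (stages not run are NULL).
#' @export
runFullPipeline <- function(config) {
  cfg <- do.call(pipelineConfig, config)
  stageFail <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  out <- list()
  if (!is.na(cfg$dosagePath)) {
    geno <- readDosageTsv(cfg$dosagePath, cfg$mapPath)
    pheno <- readPhenoTsv(cfg$phenoPath)
  } else {
    geno <- tryCatch(simulateGenotypes(cfg$simIndividuals, cfg$simBlocks,
                                       cfg$simSnpsPerBlock, seed = cfg$seed),
                     error = function(e) stageFail("simulate", e))
    causal <- if (cfg$simCausal > 0)
      sample(colnames(dosageMatrix(geno)), cfg$simCausal) else character(0)
    pheno <- simulatePhenotypes(geno,
      causalSnps = causal,
      effectSizes = if (length(causal)) "h2" else numeric(0),
      targetR2 = if (length(causal)) cfg$simTargetR2 else NA,
      seed = cfg$seed + 1)
  }
  out$qc <- NULL
  if (cfg$doQc) {
    s <- tryCatch({
      r1 <- snpQC(geno, cfg$callRateMin, cfg$mafMin, cfg$hweAlpha)
      r2 <- sampleQC(r1$geno, cfg$missMax, cfg$hetSd)
      list(geno = r2$geno, snpReport = r1$report, sampleReport = r2$report)
    }, error = function(e) stageFail("qc", e))
    geno <- s$geno
    out$qc <- s[c("snpReport", "sampleReport")]
  }
  out$prune <- NULL
  if (cfg$doPrune) {
    pr <- tryCatch(ldPrune(geno, cfg$pruneWindow, cfg$pruneStep, cfg$pruneR2),
                   error = function(e) stageFail("prune", e))
    geno <- applyPrune(geno, pr)
    out$prune <- pr
  }
  out$prs <- NULL
  if (cfg$doPrs) {
    out$prs <- tryCatch(
      runPrsPipeline(geno, pheno, cfg$phenotype, m = cfg$m,
                     fracDiscovery = cfg$fracDiscovery,
                     pThreshold = cfg$pThreshold,
                     nPhenotypes = cfg$nPhenotypes, seed = cfg$seed + 2),
      error = function(e) stageFail("prs", e))
  }
  out$assoc <- NULL
  if (cfg$doAssoc) {
    out$assoc <- tryCatch(univariateAssoc(geno, pheno, cfg$phenotype),
                          error = function(e) stageFail("assoc", e))
  }
  out$enrich <- NULL
  if (cfg$doEnrich && cfg$doAssoc) {
    si <- snpInfo(geno)
    snpGene <- stats::setNames(si$gene, si$snp)
    pv <- stats::setNames(out$assoc$p, out$assoc$snp)
    keepP <- !is.na(pv)
    genes <- unique(snpGene[names(pv)[keepP]])
    cand <- utils::head(genes, max(1, round(length(genes) / 5)))
    out$enrich <- tryCatch(
      enrichmentTest(pv[keepP], snpGene, cand, cfg$enrichThreshold,
                     cfg$enrichPerm, seed = cfg$seed + 3),
      error = function(e) stageFail("enrich", e))
  }
  out$haplo <- NULL
  if (cfg$doHaplo) {
    out$haplo <- tryCatch({
      blocks <- fourGameteBlocks(geno, cfg$fourGameteFreq)
      sizes <- vapply(blocks, length, integer(1))
      blk <- blocks[[which.max(sizes)]]
      hf <- emHaplotypeFreqs(geno, blk)
      ph <- pheno[match(rownames(dosageMatrix(geno)), pheno$id), , drop = FALSE]
      assoc <- haplotypeAssociation(hf, ph, cfg$phenotype,
                                    rareFreq = cfg$rareHapFreq)
      list(blocks = blocks, freqs = hf, association = assoc)
    }, error = function(e) stageFail("haplo", e))
  }
  out$geno <- geno
  out$pheno <- pheno
  out$manifest <- list(
    package = "resamplePRS",
    version = as.character(utils::packageVersion("resamplePRS")),
    rVersion = R.version.string,
    config = cfg[setdiff(names(cfg), c("dosagePath", "mapPath", "phenoPath", "outDir"))],
    inputs = cfg[c("dosagePath", "mapPath", "phenoPath")],
    nIndividuals = nrow(dosageMatrix(geno)),
    nSnps = ncol(dosageMatrix(geno))
  )
  if (!is.na(cfg$outDir)) .writePipelineOutputs(out, cfg)
  out
}

# Persist stage outputs as TSV/JSON under cfg$outDir.
.writePipelineOutputs <- function(out, cfg) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(cfg$outDir, x)
  writeDosageTsv(out$geno, fp("genotypes.dosage.tsv"), fp("genotypes.map.tsv"))
  writePhenoTsv(out$pheno, fp("phenotypes.tsv"))
  if (!is.null(out$qc)) {
    rs <- out$qc$snpReport@removedSnps
    ri <- out$qc$sampleReport@removedSamples
    qcTab <- rbind(
      data.frame(item = rs$id, kind = rep("snp", nrow(rs)), reason = rs$reason),
      data.frame(item = ri$id, kind = rep("sample", nrow(ri)), reason = ri$reason))
    utils::write.table(qcTab, fp("qc_removed.tsv"), quote = FALSE,
                       row.names = FALSE, sep = "\t")
    jsonlite::write_json(
      list(snp = as.list(out$qc$snpReport@thresholds),
           sample = as.list(out$qc$sampleReport@thresholds)),
      fp("qc_thresholds.json"), auto_unbox = TRUE)
  }
  if (!is.null(out$prune))
    writeLines(out$prune@kept, fp("pruned_kept_snps.txt"))
  if (!is.null(out$prs)) {
    splitsTab <- data.frame(
      split = vapply(out$prs$runs, `[[`, numeric(1), "split"),
      nSelected = vapply(out$prs$runs, function(r) length(r$selected), numeric(1)),
      r = vapply(out$prs$runs, `[[`, numeric(1), "r"),
      pOneSided = vapply(out$prs$runs, `[[`, numeric(1), "pOneSided"))
    utils::write.table(splitsTab, fp("prs_splits.tsv"), quote = FALSE,
                       row.names = FALSE, sep = "\t")
    ex <- out$prs$exact
    jsonlite::write_json(
      list(m = ex@m, n = ex@n, maxP = ex@maxP, pExact = ex@pExact,
           pCorrected = ex@pCorrected, nPhenotypes = ex@nPhenotypes),
      fp("prs_exact_test.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(out$assoc))
    utils::write.table(out$assoc, fp("univariate_assoc.tsv"), quote = FALSE,
                       row.names = FALSE, sep = "\t")
  if (!is.null(out$enrich)) {
    en <- out$enrich
    jsonlite::write_json(
      list(observed = en@observed, p = en@p, threshold = en@threshold,
           nPerm = en@nPerm),
      fp("enrichment.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(out$haplo)) {
    ha <- out$haplo$association
    tab <- ha$perHaplotype
    tab$omnibusP <- ha$omnibusP
    utils::write.table(tab, fp("haplotype_assoc.tsv"), quote = FALSE,
                       row.names = FALSE, sep = "\t")
  }
  jsonlite::write_json(out$manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(NULL)
}
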