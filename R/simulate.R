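#' Simulate strain-level phenotype data for inbred panels
#'
#' Emulates a recombinant-inbred panel: each strain receives an additive
#' genetic effect drawn with variance \code{h2True * totalVariance} and
#' each replicate animal an environmental residual with variance
#' \code{(1 - h2True) * totalVariance}, so the intraclass correlation of
#' the simulated values equals \code{h2True} in expectation.
#'
#' @param nStrains number of strains (>= 2).
#' @param nPerStrain replicate animals per strain (>= 2).
#' @param h2True target narrow-sense heritability in [0, 1].
#' @param grandMean grand mean, phenotype units.
#' @param totalVariance total phenotypic variance, phenotype units squared.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param session session label attached to the table; the provoked
#'   long inter-trial-interval session is the default impulsivity
#'   readout, \code{"baseline"} the training condition.
#' @return data.frame with columns \code{strain}, \code{animal},
#'   \code{session}, \code{value} (the strain table used by
#'   [strainAnova()]).
#' @examples
#' st <- simulateStrainData(12, 10, h2True = 0.4, seed = 1)
#' strainAnova(st)@h2
#' @export
simulateStrainData <- function(nStrains, nPerStrain, h2True,
                               grandMean = 20, totalVariance = 100,
                               seed, session = c("longITI", "baseline")) {
  session <- match.arg(session)
  if (nStrains < 2 || nPerStrain < 2)
    stop("need at least 2 strains and 2 replicates per strain")
  if (h2True < 0 || h2True > 1) stop("h2True must lie in [0, 1]")
  if (totalVariance <= 0) stop("totalVariance must be positive")
  if (missing(seed)) stop("seed is required")
  set.seed(.substreamSeed(seed, "strain"))
  strains <- sprintf("S%02d", seq_len(nStrains))
  eff <- stats::rnorm(nStrains, 0, sqrt(h2True * totalVariance))
  res <- stats::rnorm(nStrains * nPerStrain, 0,
                      sqrt((1 - h2True) * totalVariance))
  data.frame(
    strain = rep(strains, each = nPerStrain),
    animal = rep(seq_len(nPerStrain), times = nStrains),
    session = session,
    value = grandMean + rep(eff, each = nPerStrain) + res,
    stringsAsFactors = FALSE
  )
}

#' Simulate a probe-by-strain expression matrix with target correlations
#'
#' Designated probes are generated so their strain-level Spearman
#' correlation with the strain phenotype means approaches the requested
#' target (via a Gaussian copula; targets of exactly +/-1 use the exact
#' rank construction). Remaining probes are independent noise.
#'
#' @param strains strain table from [simulateStrainData()] (or any
#'   data.frame with \code{strain} and \code{value}).
#' @param nProbes total number of probes.
#' @param rhoTargets numeric vector of target Spearman correlations in
#'   [-1, 1]; probe \code{i} targets \code{rhoTargets[i]}. Length must
#'   not exceed \code{nProbes}.
#' @param seed integer seed.
#' @return numeric matrix, probes in rows (named \code{probe<i>}),
#'   strains in columns.
#' @export
simulateExpression <- function(strains, nProbes, rhoTargets = numeric(0), seed) {
  if (length(rhoTargets) > nProbes) stop("more rho targets than probes")
  if (length(rhoTargets) && any(abs(rhoTargets) > 1))
    stop("rho targets must lie in [-1, 1]")
  if (missing(seed)) stop("seed is required")
  set.seed(.substreamSeed(seed, "expression"))
  sm <- tapply(strains$value, strains$strain, mean)
  sm <- sm[sort(names(sm))]
  ns <- length(sm)
  expr <- matrix(stats::rnorm(nProbes * ns), nrow = nProbes,
                 dimnames = list(paste0("probe", seq_len(nProbes)), names(sm)))
  if (length(rhoTargets)) {
    z <- stats::qnorm((rank(sm) - 0.5) / ns)  # normal scores of phenotype ranks
    for (i in seq_along(rhoTargets)) {
      rho <- rhoTargets[i]
      if (abs(rho) == 1) {
        expr[i, ] <- rho * rank(sm)  # exact rank (or reversed-rank) construction
      } else {
        r <- 2 * sin(pi * rho / 6)   # Pearson latent correlation for Spearman target
        expr[i, ] <- r * z + sqrt(1 - r^2) * stats::rnorm(ns)
      }
    }
  }
  expr
}

#' Simulate LD-structured diploid genotypes
#'
#' Each individual is formed from two independently simulated haplotypes,
#' so linkage disequilibrium and four-gamete structure are genuine. Along
#' a haplotype, the allele at each SNP copies the previous SNP's allele
#' with probability \code{1 - 2 * recomb} (its block's recombination
#' fraction) and is otherwise drawn fresh at that SNP's allele frequency;
#' block boundaries use \code{betweenBlockRecomb} (0.5 = independent
#' blocks). With zero within-block recombination all SNPs of a block are
#' exact allele copies (pairwise r-squared 1).
#'
#' @param nIndividuals number of individuals.
#' @param nBlocks number of haplotype blocks.
#' @param snpsPerBlock SNPs per block.
#' @param mafRange length-2 numeric in (0, 0.5], allele-frequency range
#'   from which per-SNP frequencies are drawn.
#' @param withinBlockRecomb recombination fraction between adjacent SNPs
#'   inside a block, in [0, 0.5].
#' @param betweenBlockRecomb recombination fraction across block
#'   boundaries, in [0, 0.5] (default 0.5, independence).
#' @param seed integer seed.
#' @return A \linkS4class{GenotypeData} object; rowData records the
#'   block id as \code{gene} (\code{gene<block>}) plus the theoretical
#'   marginal minor-allele frequency \code{mafTarget}.
#' @examples
#' g <- simulateGenotypes(200, 5, 10, seed = 1)
#' dim(dosageMatrix(g))
#' @export
simulateGenotypes <- function(nIndividuals, nBlocks, snpsPerBlock,
                              mafRange = c(0.05, 0.5),
                              withinBlockRecomb = 0.02,
                              betweenBlockRecomb = 0.5, seed) {
  if (any(mafRange <= 0) || any(mafRange > 0.5) || mafRange[1] > mafRange[2])
    stop("mafRange must lie within (0, 0.5]")
  if (withinBlockRecomb < 0 || withinBlockRecomb > 0.5 ||
      betweenBlockRecomb < 0 || betweenBlockRecomb > 0.5)
    stop("recombination fractions must lie in [0, 0.5]")
  if (missing(seed)) stop("seed is required")
  set.seed(.substreamSeed(seed, "genotypes"))
  nSnps <- nBlocks * snpsPerBlock
  p <- stats::runif(nSnps, mafRange[1], mafRange[2])
  blockOf <- rep(seq_len(nBlocks), each = snpsPerBlock)
  newBlock <- c(TRUE, diff(blockOf) != 0)
  copyProb <- ifelse(newBlock, 1 - 2 * betweenBlockRecomb,
                     1 - 2 * withinBlockRecomb)
  copyProb[1] <- 0
  # theoretical marginal frequency under the copy chain
  maf <- numeric(nSnps)
  maf[1] <- p[1]
  for (j in 2:nSnps) maf[j] <- copyProb[j] * maf[j - 1] + (1 - copyProb[j]) * p[j]

  nHap <- 2L * nIndividuals
  H <- matrix(0L, nHap, nSnps)
  H[, 1] <- stats::rbinom(nHap, 1L, p[1])
  for (j in 2:nSnps) {
    copy <- stats::runif(nHap) < copyProb[j]
    fresh <- stats::rbinom(nHap, 1L, p[j])
    H[, j] <- ifelse(copy, H[, j - 1], fresh)
  }
  G <- H[seq(1, nHap, by = 2), , drop = FALSE] +
       H[seq(2, nHap, by = 2), , drop = FALSE]
  dimnames(G) <- list(paste0("ind", seq_len(nIndividuals)),
                      paste0("snp", seq_len(nSnps)))
  allelePairs <- rbind(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
  pick <- sample.int(4L, nSnps, replace = TRUE)
  snps <- data.frame(
    chrom = "1",
    pos = as.integer(seq_len(nSnps)) * 1000L,
    alleleMinor = allelePairs[pick, 1],
    alleleMajor = allelePairs[pick, 2],
    gene = paste0("gene", blockOf),
    block = blockOf,
    mafTarget = maf,
    stringsAsFactors = FALSE
  )
  out <- GenotypeData(G, snps)
  metadata(out)$haplotypes <- H
  metadata(out)$simSpec <- list(
    nIndividuals = nIndividuals, nBlocks = nBlocks,
    snpsPerBlock = snpsPerBlock, mafRange = mafRange,
    withinBlockRecomb = withinBlockRecomb,
    betweenBlockRecomb = betweenBlockRecomb, seed = seed)
  out
}

#' Simulate phenotypes with additive SNP effects and covariates
#'
#' Builds a continuous phenotype as the sum of additive per-allele SNP
#' effects, categorical study-site shifts, gender and handedness effects
#' and Gaussian noise; optionally adds an ordinal 0-5 binge score by
#' thresholding a latent Gaussian that shares the genetic signal.
#'
#' @param geno \linkS4class{GenotypeData}.
#' @param causalSnps character vector of causal SNP ids (may be empty).
#' @param effectSizes per-allele effects, one per causal SNP; or the
#'   single string \code{"h2"} combined with \code{targetR2} to draw
#'   standard-normal effects rescaled so the genetic component explains
#'   \code{targetR2} of the phenotypic variance.
#' @param targetR2 fraction of phenotypic variance explained by the
#'   causal SNPs when \code{effectSizes = "h2"}.
#' @param covariateEffects named list with \code{site} (numeric vector,
#'   one shift per site level), \code{gender}, \code{handedness}.
#' @param noiseSd residual standard deviation.
#' @param nSites number of study sites.
#' @param binge logical; also generate the ordinal 0-5 binge score.
#' @param seed integer seed.
#' @return data.frame: \code{id}, \code{site}, \code{gender},
#'   \code{handedness}, \code{pheno}, and \code{binge} if requested.
#'   Attribute \code{"truth"} records the realized effect vector and the
#'   realized genetic variance fraction.
#' @export
simulatePhenotypes <- function(geno, causalSnps = character(0),
                               effectSizes = numeric(0), targetR2 = NA,
                               covariateEffects = list(site = c(0, 0.3, -0.2),
                                                       gender = 0.2,
                                                       handedness = 0.1),
                               noiseSd = 1, nSites = 3, binge = FALSE, seed) {
  if (missing(seed)) stop("seed is required")
  G <- dosageMatrix(geno)
  if (!all(causalSnps %in% colnames(G)))
    stop("causal SNP(s) absent from the genotype matrix")
  set.seed(.substreamSeed(seed, "phenotypes"))
  n <- nrow(G)
  site <- sample(paste0("site", seq_len(nSites)), n, replace = TRUE)
  gender <- stats::rbinom(n, 1, 0.5)
  handedness <- stats::rbinom(n, 1, 0.87)  # right-handed majority
  gval <- numeric(n)
  eff <- numeric(length(causalSnps))
  if (length(causalSnps)) {
    Gc <- G[, causalSnps, drop = FALSE]
    if (identical(effectSizes, "h2")) {
      if (is.na(targetR2) || targetR2 <= 0 || targetR2 >= 1)
        stop("targetR2 in (0,1) required with effectSizes = 'h2'")
      eff <- stats::rnorm(length(causalSnps))
      raw <- as.numeric(Gc %*% eff)
      vg <- stats::var(raw)
      # scale so vg / (vg + noiseSd^2) = targetR2
      sc <- sqrt(targetR2 * noiseSd^2 / ((1 - targetR2) * vg))
      eff <- eff * sc
      gval <- raw * sc
    } else {
      if (length(effectSizes) != length(causalSnps))
        stop("effectSizes must match causalSnps")
      eff <- effectSizes
      gval <- as.numeric(Gc %*% eff)
    }
  }
  siteShift <- covariateEffects$site[as.integer(factor(site, levels = paste0("site", seq_len(nSites))))]
  covval <- siteShift + covariateEffects$gender * gender +
    covariateEffects$handedness * handedness
  noise <- if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else numeric(n)
  pheno <- gval + covval + noise
  out <- data.frame(id = rownames(G), site = site, gender = gender,
                    handedness = handedness, pheno = pheno,
                    stringsAsFactors = FALSE)
  if (binge) {
    latentG <- if (length(causalSnps) && stats::sd(gval) > 0)
      scale(gval)[, 1] else numeric(n)
    latent <- latentG + stats::rnorm(n)
    # thresholds chosen for a rare, right-skewed 0-5 score
    cuts <- stats::qnorm(c(0.90, 0.95, 0.975, 0.99, 0.995)) * stats::sd(latent)
    out$binge <- as.integer(cut(latent, c(-Inf, cuts, Inf), labels = FALSE)) - 1L
  }
  vgr <- if (length(causalSnps)) stats::var(gval) / stats::var(pheno) else 0
  attr(out, "truth") <- list(causalSnps = causalSnps, effectSizes = eff,
                             realizedR2 = vgr, noiseSd = noiseSd,
                             covariateEffects = covariateEffects)
  out
}

#' Simulate a session of task trial outcomes
#'
#' Allocates trials multinomially over the four five-choice outcome
#' categories with the given premature-response probability; the
#' remainder is split among correct, incorrect and omitted trials in
#' fixed proportions (0.7 / 0.1 / 0.2 of the non-premature mass).
#'
#' @param nTrials total number of trials.
#' @param pPremature probability of a premature response, in [0, 1].
#' @param seed integer seed.
#' @return one-row data.frame with counts \code{correct},
#'   \code{incorrect}, \code{omissions}, \code{premature}.
#' @export
simulateTaskTrials <- function(nTrials, pPremature, seed) {
  if (pPremature < 0 || pPremature > 1) stop("pPremature must lie in [0, 1]")
  if (missing(seed)) stop("seed is required")
  set.seed(.substreamSeed(seed, "trials"))
  rest <- 1 - pPremature
  probs <- c(correct = 0.7 * rest, incorrect = 0.1 * rest,
             omissions = 0.2 * rest, premature = pPremature)
  cnt <- as.integer(stats::rmultinom(1, nTrials, probs))
  data.frame(correct = cnt[1], incorrect = cnt[2],
             omissions = cnt[3], premature = cnt[4])
}
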