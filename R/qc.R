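#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on genotype counts: conditions on the observed
#' allele counts, enumerates every compatible heterozygote count, and
#' sums the probabilities of all tables no more probable than the
#' observed one (no mid-p adjustment).
#'
#' @param nAA,nAa,naa genotype counts (minor homozygote, heterozygote,
#'   major homozygote).
#' @return exact two-sided p-value in (0, 1].
#' @examples
#' hweExactTest(0, 100, 0)  # extreme heterozygote excess
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) stop("genotype counts must be non-negative")
  n <- nAA + nAa + naa
  if (n == 0) return(1)
  nA <- 2 * nAA + nAa           # minor allele count
  hets <- seq.int(nA %% 2, min(nA, 2 * n - nA), by = 2)
  # log P(nAa = h | allele counts) up to a constant
  logp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    h * log(2) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[hets == nAa]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' SNP-level quality control
#'
#' Removes SNPs failing any of three criteria, recording one primary
#' reason per SNP in the order call-rate, minor allele frequency,
#' Hardy-Weinberg (exact test, [hweExactTest()]).
#'
#' @param geno \linkS4class{GenotypeData}.
#' @param callRateMin minimum call rate (default 0.98, i.e. < 98\%
#'   excluded).
#' @param mafMin minimum minor allele frequency (default 0.01).
#' @param hweAlpha Hardy-Weinberg exclusion level (default 1e-4;
#'   p <= hweAlpha excluded).
#' @return list with elements \code{geno} (filtered
#'   \linkS4class{GenotypeData}) and \code{report}
#'   (\linkS4class{QCReport}).
#' @export
snpQC <- function(geno, callRateMin = 0.98, mafMin = 0.01, hweAlpha = 1e-4) {
  G <- dosageMatrix(geno)
  if (!ncol(G) || !nrow(G)) stop("empty genotype matrix")
  callRate <- colMeans(!is.na(G))
  maf <- .alleleFreq(G)
  maf <- pmin(maf, 1 - maf)
  hwe <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j][!is.na(G[, j])]
    hweExactTest(sum(g == 2), sum(g == 1), sum(g == 0))
  }, numeric(1))
  reason <- rep(NA_character_, ncol(G))
  reason[hwe <= hweAlpha] <- "HWE"
  reason[maf < mafMin | is.na(maf)] <- "MAF"
  reason[callRate < callRateMin] <- "call-rate"   # primary reason order
  removed <- !is.na(reason)
  report <- methods::new("QCReport",
    removedSnps = data.frame(id = colnames(G)[removed],
                             reason = reason[removed],
                             stringsAsFactors = FALSE),
    removedSamples = data.frame(id = character(0), reason = character(0)),
    thresholds = list(callRateMin = callRateMin, mafMin = mafMin,
                      hweAlpha = hweAlpha))
  list(geno = geno[!removed, ], report = report)
}

#' Sample-level quality control
#'
#' Removes individuals with missingness above \code{missMax} or
#' heterozygosity rate outside mean +/- \code{hetSd} standard
#' deviations, both statistics computed on the pre-filter cohort.
#'
#' @param geno \linkS4class{GenotypeData} with >= 3 individuals.
#' @param missMax maximum per-individual missing fraction (default 0.02).
#' @param hetSd width of the heterozygosity band in SDs (default 3).
#' @return list with \code{geno} and \code{report} as in [snpQC()].
#' @export
sampleQC <- function(geno, missMax = 0.02, hetSd = 3.0) {
  G <- dosageMatrix(geno)
  if (nrow(G) < 3) stop("need at least 3 individuals")
  missRate <- rowMeans(is.na(G))
  hetRate <- rowMeans(G == 1, na.rm = TRUE)
  mu <- mean(hetRate); sdev <- stats::sd(hetRate)
  hetBad <- abs(hetRate - mu) > hetSd * sdev & sdev > 0
  reason <- rep(NA_character_, nrow(G))
  reason[hetBad] <- "heterozygosity"
  reason[missRate > missMax] <- "missingness"
  removed <- !is.na(reason)
  report <- methods::new("QCReport",
    removedSnps = data.frame(id = character(0), reason = character(0)),
    removedSamples = data.frame(id = rownames(G)[removed],
                                reason = reason[removed],
                                stringsAsFactors = FALSE),
    thresholds = list(missMax = missMax, hetSd = hetSd))
  list(geno = geno[, !removed], report = report)
}

#' Pairwise identity-by-descent estimates (method of moments)
#'
#' PLINK-style moment estimator: per pair, observed identity-by-state
#' counts are decomposed against their expectations under IBD states
#' 0/1/2. Expectations use the finite-sample (without-replacement)
#' allele-count formulas rather than plug-in frequencies, which would
#' otherwise bias pi-hat upward at rarer alleles; pi-hat =
#' P(IBD=1)/2 + P(IBD=2), truncated into [0, 1].
#'
#' @param geno \linkS4class{GenotypeData}.
#' @return data.frame with columns \code{id1}, \code{id2}, \code{pihat}.
#' @export
ibdEstimate <- function(geno) {
  G <- dosageMatrix(geno)
  n <- nrow(G)
  x <- colSums(G, na.rm = TRUE)                  # minor allele count
  Tn <- 2 * colSums(!is.na(G))                   # total alleles observed
  poly <- x > 0 & x < Tn & Tn >= 8
  G <- G[, poly, drop = FALSE]; x <- x[poly]; Tn <- Tn[poly]
  y <- Tn - x
  D <- Tn * (Tn - 1) * (Tn - 2) * (Tn - 3)
  # exact hypergeometric expectations for a pair's four alleles
  e0_ibs0 <- 2 * x * (x - 1) * y * (y - 1) / D
  e0_ibs1 <- (4 * x * (x - 1) * (x - 2) * y + 4 * x * y * (y - 1) * (y - 2)) / D
  e1_ibs1 <- 2 * x * y / (Tn * (Tn - 1))
  pairs <- utils::combn(n, 2)
  out <- data.frame(id1 = rownames(G)[pairs[1, ]],
                    id2 = rownames(G)[pairs[2, ]],
                    pihat = NA_real_, pihatRaw = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    a <- G[pairs[1, k], ]; b <- G[pairs[2, k], ]
    keep <- !is.na(a) & !is.na(b)
    diffs <- abs(a[keep] - b[keep])
    N0 <- sum(diffs == 2); N1 <- sum(diffs == 1)
    E00 <- sum(e0_ibs0[keep]); E01 <- sum(e0_ibs1[keep]); E11 <- sum(e1_ibs1[keep])
    P0 <- if (E00 > 0) N0 / E00 else 0
    P1 <- if (E11 > 0) (N1 - P0 * E01) / E11 else 0
    # signed estimate first: its null mean is zero, unlike the bounded one
    out$pihatRaw[k] <- (1 - P0 - P1) + P1 / 2
    P0 <- max(0, P0); P1 <- max(0, P1)
    if (P0 + P1 > 1) { s <- P0 + P1; P0 <- P0 / s; P1 <- P1 / s }
    P2 <- 1 - P0 - P1
    out$pihat[k] <- min(1, max(0, P1 / 2 + P2))
  }
  out
}

#' Remove cryptically related individuals
#'
#' Flags every pair with estimated pi-hat above \code{ibdMax} and, pair
#' by pair in decreasing pi-hat order, removes the member with the
#' higher genotype missingness (ties: the second member) until no
#' surviving pair exceeds the threshold.
#'
#' @param geno \linkS4class{GenotypeData}.
#' @param ibdMax pi-hat ceiling (default 0.1875, halfway between second-
#'   and third-degree relatives).
#' @return list with \code{geno}, \code{report}, and \code{ibd} (the
#'   pairwise estimates).
#' @export
relatednessFilter <- function(geno, ibdMax = 0.1875) {
  ibd <- ibdEstimate(geno)
  G <- dosageMatrix(geno)
  missRate <- rowMeans(is.na(G))
  names(missRate) <- rownames(G)
  drop <- character(0)
  flagged <- ibd[ibd$pihat > ibdMax, , drop = FALSE]
  flagged <- flagged[order(-flagged$pihat), , drop = FALSE]
  for (k in seq_len(nrow(flagged))) {
    i <- flagged$id1[k]; j <- flagged$id2[k]
    if (i %in% drop || j %in% drop) next
    drop <- c(drop, if (missRate[i] > missRate[j]) i else j)
  }
  report <- methods::new("QCReport",
    removedSnps = data.frame(id = character(0), reason = character(0)),
    removedSamples = data.frame(id = drop,
                                reason = rep("relatedness", length(drop)),
                                stringsAsFactors = FALSE),
    thresholds = list(ibdMax = ibdMax))
  keep <- !(colnames(geno) %in% drop)
  list(geno = geno[, keep], report = report, ibd = ibd)
}

#' Sliding-window LD pruning
#'
#' Greedy pruning: within each window of \code{window} SNPs (per
#' chromosome), while any kept pair has squared genotype correlation
#' above \code{r2Max}, the pair scanned first in position order loses
#' its lower-MAF member (tie: the later SNP); the window then slides by
#' \code{step}. The output satisfies the invariant that no kept pair
#' within a window exceeds the threshold.
#'
#' @param geno \linkS4class{GenotypeData}, position-sorted.
#' @param window window size in SNPs (default 50).
#' @param step slide in SNPs (default 5).
#' @param r2Max pairwise r-squared threshold (default 0.5).
#' @return \linkS4class{PruneResult}.
#' @export
ldPrune <- function(geno, window = 50, step = 5, r2Max = 0.5) {
  si <- snpInfo(geno)
  if (any(unlist(tapply(si$pos, si$chrom, function(p) diff(p) < 0))))
    stop("SNPs must be position-sorted within chromosome")
  G <- dosageMatrix(geno)
  maf <- pmin(.alleleFreq(G), 1 - .alleleFreq(G))
  keep <- rep(TRUE, ncol(G))
  for (chr in unique(si$chrom)) {
    idx <- which(si$chrom == chr)
    start <- 1
    repeat {
      w <- idx[seq(start, min(start + window - 1, length(idx)))]
      repeat {
        live <- w[keep[w]]
        removedOne <- FALSE
        if (length(live) > 1) {
          for (a in seq_len(length(live) - 1)) {
            for (b in seq((a + 1), length(live))) {
              i <- live[a]; j <- live[b]
              r2 <- .pairR2(G[, i], G[, j])
              if (!is.na(r2) && r2 > r2Max) {
                victim <- if (maf[i] < maf[j]) i else j
                keep[victim] <- FALSE
                removedOne <- TRUE
                break
              }
            }
            if (removedOne) break
          }
        }
        if (!removedOne) break
      }
      if (start + window - 1 >= length(idx)) break
      start <- start + step
    }
  }
  methods::new("PruneResult", kept = colnames(G)[keep],
               window = as.integer(window), step = as.integer(step),
               r2Threshold = r2Max)
}

#' Apply a prune result to a GenotypeData object
#'
#' @param geno \linkS4class{GenotypeData}.
#' @param prune \linkS4class{PruneResult} from [ldPrune()].
#' @return the pruned \linkS4class{GenotypeData}.
#' @export
applyPrune <- function(geno, prune) {
  geno[rownames(geno) %in% prune@kept, ]
}
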