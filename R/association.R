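#' Univariate additive-model SNP association with Bonferroni correction
#'
#' Per-SNP ordinary least squares of the phenotype on minor-allele
#' dosage with covariates; corrected p = min(1, nTests * raw p).
#' Monomorphic SNPs are kept in the output flagged \code{excluded}.
#'
#' @param geno \linkS4class{GenotypeData} (QC'd).
#' @param pheno sample table.
#' @param phenotype phenotype column name.
#' @param covariates covariate column names.
#' @param nTests Bonferroni universe (default: number of SNPs tested).
#' @return data.frame: \code{snp}, \code{phenotype}, \code{beta},
#'   \code{p}, \code{pBonferroni}, \code{alleleMinor}, \code{alleleMajor},
#'   \code{excluded}.
#' @export
univariateAssoc <- function(geno, pheno, phenotype,
                            covariates = c("site", "gender", "handedness"),
                            nTests = NULL) {
  reg <- snpRegression(geno, pheno, phenotype, covariates = covariates)
  if (is.null(nTests)) nTests <- sum(!reg$excluded)
  si <- snpInfo(geno)
  data.frame(
    snp = rownames(reg),
    phenotype = phenotype,
    beta = reg$beta,
    p = reg$p,
    pBonferroni = pmin(1, nTests * reg$p),
    alleleMinor = si$alleleMinor[match(rownames(reg), si$snp)],
    alleleMajor = si$alleleMajor[match(rownames(reg), si$snp)],
    excluded = reg$excluded,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Gene-preserving SNP-set enrichment permutation test
#'
#' The test statistic is the number of candidate-gene SNP p-values below
#' \code{threshold}. The null distribution draws random gene sets of the
#' same gene count from the pool, keeping each gene's SNPs intact so
#' intra-gene LD is preserved. Permutation p uses the add-one rule and
#' is therefore never zero.
#'
#' @param pvalues named numeric vector of per-SNP association p-values
#'   for the whole pool.
#' @param snpGene named character vector mapping each SNP id to its gene.
#' @param candidateGenes character vector of candidate gene names.
#' @param threshold p-value threshold defining the statistic (0.05 or
#'   0.10 in the standard protocol).
#' @param nPerm number of permutations (default 500).
#' @param seed integer seed.
#' @return \linkS4class{EnrichmentResult}.
#' @export
enrichmentTest <- function(pvalues, snpGene, candidateGenes,
                           threshold = 0.05, nPerm = 500, seed) {
  if (missing(seed)) stop("seed is required")
  snps <- names(pvalues)
  genes <- unique(snpGene[snps])
  if (!all(candidateGenes %in% genes)) stop("candidate gene absent from the pool")
  if (length(candidateGenes) > length(genes))
    stop("pool smaller than the candidate set")
  set.seed(.substreamSeed(seed, "enrichment"))
  below <- pvalues < threshold
  geneCount <- tapply(below, snpGene[snps], sum)   # per-gene count of low p
  observed <- sum(geneCount[candidateGenes])
  nullDist <- vapply(seq_len(nPerm), function(i) {
    sum(geneCount[sample(names(geneCount), length(candidateGenes))])
  }, numeric(1))
  methods::new("EnrichmentResult",
               observed = as.integer(observed),
               nullDist = as.integer(nullDist),
               p = (1 + sum(nullDist >= observed)) / (1 + nPerm),
               threshold = threshold, nPerm = as.integer(nPerm))
}

# Four-gamete frequencies for a SNP pair. From phased haplotypes: direct
# counting. From unphased genotypes: two-SNP EM.
.gameteFreqPair <- function(a, b, phased) {
  if (phased) {
    tab <- table(factor(a, levels = 0:1), factor(b, levels = 0:1))
    as.numeric(tab) / sum(tab)
  } else {
    em <- .emPair(a, b)
    em$freq
  }
}

# Minimal 2-SNP EM on dosage vectors (0/1/2), haplotypes 00,10,01,11.
.emPair <- function(a, b, tol = 1e-10, maxIter = 500) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  dh <- a == 1 & b == 1                 # double heterozygotes (phase unknown)
  # known haplotype contributions from all other genotype classes
  cnt <- numeric(4)                     # 00, 10, 01, 11 (alleles minorA minorB)
  addPair <- function(h1, h2, w) { cnt[h1] <<- cnt[h1] + w; cnt[h2] <<- cnt[h2] + w }
  for (i in which(!dh)) {
    ha <- c(a[i] >= 1, a[i] == 2)       # allele at SNP a on hap1, hap2 (unordered)
    hb <- c(b[i] >= 1, b[i] == 2)
    # for non-double-het, phase is determined up to labeling: pair the
    # "extra" alleles; any consistent assignment gives the same counts
    al <- sort(c(a[i] == 2, a[i] >= 1))  # logical alleles sorted
    bl <- sort(c(b[i] == 2, b[i] >= 1))
    h1 <- 1 + al[2] + 2 * bl[2]
    h2 <- 1 + al[1] + 2 * bl[1]
    addPair(h1, h2, 1)
  }
  nDH <- sum(dh)
  if (nDH == 0) {
    f <- cnt / sum(cnt)
    return(list(freq = f, iterations = 0L))
  }
  f <- rep(0.25, 4)
  for (it in seq_len(maxIter)) {
    # double het resolves as (00,11) with prob f1*f4 / (f1*f4 + f2*f3), else (10,01)
    w14 <- f[1] * f[4]; w23 <- f[2] * f[3]
    pr <- if (w14 + w23 > 0) w14 / (w14 + w23) else 0.5
    newCnt <- cnt
    newCnt[1] <- newCnt[1] + nDH * pr
    newCnt[4] <- newCnt[4] + nDH * pr
    newCnt[2] <- newCnt[2] + nDH * (1 - pr)
    newCnt[3] <- newCnt[3] + nDH * (1 - pr)
    fNew <- newCnt / sum(newCnt)
    if (max(abs(fNew - f)) < tol) { f <- fNew; break }
    f <- fNew
  }
  list(freq = f, iterations = it)
}

#' Four-gamete haplotype-block partition
#'
#' Greedy extension along position-sorted SNPs: a SNP joins the current
#' block while, for every pair it forms with SNPs already in the block,
#' the least-frequent ("fourth") gamete has frequency <= threshold; a
#' fourth-gamete frequency strictly above the threshold indicates
#' historical recombination and starts a new block. Gamete frequencies
#' come from phased haplotypes when supplied, otherwise from a two-SNP
#' EM on the unphased genotypes.
#'
#' @param geno \linkS4class{GenotypeData}, or an integer haplotype
#'   matrix (haplotypes in rows, SNPs in columns, values 0/1) when
#'   \code{phased = TRUE}.
#' @param freqThreshold fourth-gamete frequency threshold (default 0.05).
#' @param phased treat \code{geno} as phased haplotypes.
#' @return list of blocks; each block is an integer vector of SNP column
#'   indices. Every SNP belongs to exactly one block.
#' @export
fourGameteBlocks <- function(geno, freqThreshold = 0.05, phased = FALSE) {
  if (phased) {
    H <- geno
    S <- ncol(H)
    getcol <- function(j) H[, j]
  } else {
    if (!methods::is(geno, "GenotypeData"))
      stop("unphased input must be a GenotypeData object")
    G <- dosageMatrix(geno)
    si <- snpInfo(geno)
    if (any(unlist(tapply(si$pos, si$chrom, function(p) diff(p) < 0))))
      stop("SNPs must be position-sorted within chromosome")
    S <- ncol(G)
    getcol <- function(j) G[, j]
  }
  if (S == 0) return(list())
  blocks <- list()
  current <- 1L
  if (S > 1) for (j in 2:S) {
    compatible <- TRUE
    for (i in current) {
      f <- .gameteFreqPair(getcol(i), getcol(j), phased)
      present <- sum(f > 0)
      if (present == 4 && min(f) > freqThreshold) { compatible <- FALSE; break }
    }
    if (compatible) current <- c(current, j)
    else { blocks[[length(blocks) + 1]] <- current; current <- j }
  }
  blocks[[length(blocks) + 1]] <- current
  blocks
}

#' EM haplotype frequencies for a SNP block
#'
#' Multinomial EM over all haplotype pairs compatible with each
#' individual's unphased multilocus genotype (full enumeration; intended
#' for blocks of up to ~15 SNPs). The log-likelihood is non-decreasing
#' across iterations. Expected per-individual haplotype dosages are
#' computed from the final posterior and sum to 2.
#'
#' @param geno \linkS4class{GenotypeData} or a dosage matrix
#'   (individuals x SNPs, values 0/1/2, no missing).
#' @param snpIndices columns forming the block (default: all).
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param maxIter maximum EM iterations (default 1000).
#' @return \linkS4class{HaplotypeFreqs}.
#' @export
emHaplotypeFreqs <- function(geno, snpIndices = NULL, tol = 1e-8, maxIter = 1000) {
  G <- if (methods::is(geno, "GenotypeData")) dosageMatrix(geno) else as.matrix(geno)
  if (is.null(snpIndices)) snpIndices <- seq_len(ncol(G))
  G <- G[, snpIndices, drop = FALSE]
  if (anyNA(G)) stop("missing genotypes not supported in the EM block")
  S <- ncol(G); n <- nrow(G)
  if (S > 15) stop("block too large for haplotype enumeration (> 15 SNPs)")
  minorChar <- if (methods::is(geno, "GenotypeData"))
    snpInfo(geno)$alleleMinor[snpIndices] else rep("1", S)
  majorChar <- if (methods::is(geno, "GenotypeData"))
    snpInfo(geno)$alleleMajor[snpIndices] else rep("0", S)

  hapKey <- function(h) sum(h * 2^(seq_len(S) - 1))
  pairsOf <- vector("list", n)
  hapSet <- new.env(hash = TRUE)
  for (i in seq_len(n)) {
    g <- G[i, ]
    het <- which(g == 1)
    base <- as.integer(g == 2)
    if (!length(het)) {
      pairsOf[[i]] <- matrix(c(hapKey(base), hapKey(base)), ncol = 2)
    } else {
      nh <- length(het)
      combos <- as.matrix(expand.grid(rep(list(0:1), nh)))
      # fix the first het site on haplotype 1 to avoid double counting
      combos <- combos[combos[, 1] == 1, , drop = FALSE]
      prs <- matrix(0, nrow(combos), 2)
      for (r in seq_len(nrow(combos))) {
        h1 <- base; h1[het] <- combos[r, ]
        h2 <- base; h2[het] <- 1 - combos[r, ]
        prs[r, ] <- c(hapKey(h1), hapKey(h2))
      }
      pairsOf[[i]] <- prs
    }
    for (k in unique(as.vector(pairsOf[[i]])))
      assign(as.character(k), TRUE, envir = hapSet)
  }
  keys <- sort(as.numeric(ls(hapSet)))
  H <- length(keys)
  idx <- stats::setNames(seq_len(H), as.character(keys))
  pairsIdx <- lapply(pairsOf, function(m)
    matrix(idx[as.character(m)], ncol = 2))

  f <- rep(1 / H, H)
  ll <- -Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    expCnt <- numeric(H)
    llNew <- 0
    for (i in seq_len(n)) {
      pm <- pairsIdx[[i]]
      w <- f[pm[, 1]] * f[pm[, 2]] * ifelse(pm[, 1] == pm[, 2], 1, 2)
      tot <- sum(w)
      if (tot <= 0) { w <- rep(1 / length(w), length(w)); tot <- 1
      } else w <- w / tot
      llNew <- llNew + log(tot)
      for (r in seq_len(nrow(pm))) {
        expCnt[pm[r, 1]] <- expCnt[pm[r, 1]] + w[r]
        expCnt[pm[r, 2]] <- expCnt[pm[r, 2]] + w[r]
      }
    }
    f <- expCnt / (2 * n)
    if (is.finite(ll) && abs(llNew - ll) < tol) { ll <- llNew; converged <- TRUE; break }
    ll <- llNew
  }
  hapAlleles <- t(vapply(keys, function(k)
    as.integer(intToBits(k))[seq_len(S)], integer(S)))
  hapStr <- apply(hapAlleles, 1, function(h)
    paste(ifelse(h == 1, minorChar, majorChar), collapse = ""))
  # posterior expected haplotype dosages at the final frequencies
  dosage <- matrix(0, n, H, dimnames = list(rownames(G), hapStr))
  for (i in seq_len(n)) {
    pm <- pairsIdx[[i]]
    w <- f[pm[, 1]] * f[pm[, 2]] * ifelse(pm[, 1] == pm[, 2], 1, 2)
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
    for (r in seq_len(nrow(pm))) {
      dosage[i, pm[r, 1]] <- dosage[i, pm[r, 1]] + w[r]
      dosage[i, pm[r, 2]] <- dosage[i, pm[r, 2]] + w[r]
    }
  }
  methods::new("HaplotypeFreqs",
               haplotypes = hapStr, hapAlleles = hapAlleles, freq = f,
               dosage = dosage, logLik = ll, iterations = as.integer(it),
               converged = converged)
}

#' Haplotype-block association tests
#'
#' Haplotypes rarer than \code{rareFreq} are pooled into a single
#' "rare" column. The omnibus test is the nested-model F-test of all
#' (H - 1) expected haplotype dosage terms (most frequent haplotype as
#' reference) added to the covariate-only model; per-haplotype tests add
#' a single dosage term.
#'
#' @param hapFreqs \linkS4class{HaplotypeFreqs} for the block.
#' @param pheno sample table, rows aligned with the dosage matrix rows.
#' @param phenotype phenotype column name.
#' @param covariates covariate column names.
#' @param rareFreq pooling threshold (default 0.01).
#' @return list with \code{omnibusP}, \code{omnibusF}, \code{df}, and
#'   \code{perHaplotype} (data.frame: haplotype, frequency, beta, p).
#' @export
haplotypeAssociation <- function(hapFreqs, pheno, phenotype,
                                 covariates = c("site", "gender", "handedness"),
                                 rareFreq = 0.01) {
  D <- hapFreqs@dosage
  f <- hapFreqs@freq
  common <- f >= rareFreq
  if (!any(common)) stop("no haplotype above the pooling threshold")
  Dc <- D[, common, drop = FALSE]
  if (any(!common))
    Dc <- cbind(Dc, rare = rowSums(D[, !common, drop = FALSE]))
  fc <- c(f[common], if (any(!common)) sum(f[!common]))
  labels <- c(hapFreqs@haplotypes[common], if (any(!common)) "rare")
  y <- pheno[[phenotype]]
  X <- .covariateDesign(pheno, covariates)
  ref <- which.max(fc)
  Xalt <- cbind(X, Dc[, -ref, drop = FALSE])
  fit0 <- stats::lm.fit(X, y)
  qrAlt <- qr(Xalt)
  fit1 <- stats::lm.fit(Xalt, y)
  if (qrAlt$rank < ncol(Xalt))
    warning("aliased haplotype dosages: singular design, omnibus uses the rank")
  rss0 <- sum(fit0$residuals^2)
  rss1 <- sum(fit1$residuals^2)
  dfNum <- qrAlt$rank - qr(X)$rank
  dfDen <- length(y) - qrAlt$rank
  Fv <- ((rss0 - rss1) / dfNum) / (rss1 / dfDen)
  omnibusP <- stats::pf(Fv, dfNum, dfDen, lower.tail = FALSE)
  per <- lapply(seq_len(ncol(Dc)), function(h) {
    Xh <- cbind(h = Dc[, h], X)
    fit <- stats::lm.fit(Xh, y)
    rdf <- length(y) - qr(Xh)$rank
    s2 <- sum(fit$residuals^2) / rdf
    XtXinv <- tryCatch(solve(crossprod(Xh)), error = function(e) NULL)
    if (is.null(XtXinv)) return(c(NA, NA))
    se <- sqrt(s2 * XtXinv[1, 1])
    b <- fit$coefficients[1]
    c(b, 2 * stats::pt(-abs(b / se), rdf))
  })
  per <- do.call(rbind, per)
  list(omnibusP = omnibusP, omnibusF = Fv, df = c(dfNum, dfDen),
       perHaplotype = data.frame(haplotype = labels, frequency = fc,
                                 beta = per[, 1], p = per[, 2],
                                 row.names = NULL, stringsAsFactors = FALSE))
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the two covariate-residualized variables with
#' a two-sided p-value on n - 2 - k degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param covData data.frame of covariates for the same individuals.
#' @param covariates covariate column names.
#' @return list with \code{r} and \code{p}.
#' @export
partialCorr <- function(x, y, covData,
                        covariates = c("site", "gender", "handedness")) {
  X <- .covariateDesign(covData, covariates)
  if (qr(X)$rank < ncol(X)) stop("collinear covariates")
  rx <- .residualize(x, X)[, 1]
  ry <- .residualize(y, X)[, 1]
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) stop("degenerate input after adjustment")
  r <- stats::cor(rx, ry)
  n <- length(x); k <- ncol(X) - 1
  df <- n - 2 - k
  tv <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tv), df))
}
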