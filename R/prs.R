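#' Repeated discovery/target splits of a cohort
#'
#' @param ids character vector of individual ids (>= 10).
#' @param fracDiscovery fraction assigned to the discovery sample
#'   (default 0.7; discovery size is \code{round(fracDiscovery * N)}).
#' @param m number of independent resamplings (default 10).
#' @param seed integer seed; identical seeds give identical splits.
#' @return list of \code{m} lists with elements \code{discovery} and
#'   \code{target}.
#' @export
splitCohort <- function(ids, fracDiscovery = 0.7, m = 10, seed) {
  if (length(ids) < 10) stop("cohort too small (need >= 10 individuals)")
  if (missing(seed)) stop("seed is required")
  set.seed(.substreamSeed(seed, "splits"))
  nd <- round(fracDiscovery * length(ids))
  lapply(seq_len(m), function(i) {
    disc <- sample(ids, nd)
    list(discovery = sort(disc), target = sort(setdiff(ids, disc)))
  })
}

#' Per-SNP covariate-adjusted linear regression
#'
#' For every SNP, ordinary least squares of the phenotype on minor
#' allele dosage plus study site (categorical), gender and handedness;
#' returns the dosage coefficient and its two-sided p-value. SNPs that
#' are monomorphic in the analyzed individuals are flagged excluded.
#'
#' @param geno \linkS4class{GenotypeData}.
#' @param pheno sample table with columns \code{id}, \code{site},
#'   \code{gender}, \code{handedness} and the phenotype.
#' @param phenotype name of the phenotype column.
#' @param ids optional subset of individuals (e.g. a discovery sample).
#' @param covariates covariate column names (default site, gender,
#'   handedness).
#' @return data.frame with rownames = SNP ids and columns \code{beta},
#'   \code{se}, \code{t}, \code{p}, \code{excluded}.
#' @export
snpRegression <- function(geno, pheno, phenotype,
                          ids = NULL,
                          covariates = c("site", "gender", "handedness")) {
  G <- dosageMatrix(geno)
  rownames(pheno) <- pheno$id
  if (is.null(ids)) ids <- intersect(rownames(G), pheno$id)
  G <- G[ids, , drop = FALSE]
  ph <- pheno[ids, , drop = FALSE]
  if (anyNA(ph[[phenotype]])) stop("phenotype must be complete for included individuals")
  X <- .covariateDesign(ph, covariates)
  .snpOls(ph[[phenotype]], G, X)
}

#' Select SNPs below a discovery p-value threshold
#'
#' Strict inequality: a p-value exactly at the threshold is not
#' selected.
#'
#' @param results data.frame from [snpRegression()].
#' @param pThreshold selection threshold (default 0.5, the moderate
#'   polygenic threshold).
#' @return character vector of selected SNP ids.
#' @export
selectSnps <- function(results, pThreshold = 0.5) {
  if (!nrow(results)) stop("empty result set")
  sel <- !results$excluded & !is.na(results$p) & results$p < pThreshold
  rownames(results)[sel]
}

#' Weighted polygenic score per individual
#'
#' score_i = sum over selected SNPs of beta_s * dosage_is. A missing
#' dosage is replaced by twice the discovery-sample allele frequency of
#' that SNP (mean imputation without target leakage).
#'
#' @param geno \linkS4class{GenotypeData}.
#' @param selected character vector of SNP ids to score.
#' @param betas named numeric vector of per-allele weights covering
#'   every selected SNP.
#' @param ids individuals to score (default all).
#' @param refFreq named numeric vector of discovery allele frequencies
#'   used for missing-dosage imputation (default: frequencies among the
#'   scored individuals).
#' @return named numeric vector of scores.
#' @export
scoreIndividuals <- function(geno, selected, betas, ids = NULL, refFreq = NULL) {
  G <- dosageMatrix(geno)
  if (is.null(ids)) ids <- rownames(G)
  if (!length(selected)) return(stats::setNames(numeric(length(ids)), ids))
  if (!all(selected %in% names(betas))) stop("betas missing for some selected SNPs")
  Gs <- G[ids, selected, drop = FALSE]
  if (anyNA(Gs)) {
    f <- if (is.null(refFreq)) .alleleFreq(Gs) else refFreq[selected]
    for (j in seq_len(ncol(Gs))) {
      nas <- is.na(Gs[, j])
      if (any(nas)) Gs[nas, j] <- 2 * f[j]
    }
  }
  drop(Gs %*% betas[selected])
}

#' Semi-partial correlation of a score with a covariate-adjusted phenotype
#'
#' Pearson correlation between the raw polygenic score and the residual
#' of the phenotype on the covariates (only the phenotype is adjusted:
#' the score is built from genotypes and is expected to be uncorrelated
#' with site, gender and handedness). The one-sided p-value for r > 0
#' uses the t transform with n - 2 - k degrees of freedom, k the number
#' of covariate model columns beyond the intercept.
#'
#' @param score numeric vector.
#' @param pheno sample table containing the phenotype and covariates for
#'   the same individuals, in the same order.
#' @param phenotype phenotype column name.
#' @param covariates covariate column names.
#' @return list with \code{r} and \code{pOneSided}.
#' @export
semipartialR <- function(score, pheno, phenotype,
                         covariates = c("site", "gender", "handedness")) {
  if (stats::sd(score) == 0) stop("zero-variance score")
  X <- .covariateDesign(pheno, covariates)
  ry <- .residualize(pheno[[phenotype]], X)[, 1]
  if (stats::sd(ry) == 0) stop("degenerate phenotype after adjustment")
  r <- stats::cor(score, ry)
  n <- length(score)
  k <- ncol(X) - 1
  df <- n - 2 - k
  tv <- r * sqrt(df / (1 - r^2))
  list(r = r, pOneSided = stats::pt(tv, df, lower.tail = FALSE))
}

#' Exact combination test over polygenic-score resamplings
#'
#' Combines, across \code{m} discovery/target resamplings, (i) the count
#' \code{n} of positive semi-partial correlations and (ii) the largest
#' one-sided p-value \code{max(p)} among the positive ones:
#' \deqn{p = \frac{\sum_{k=n+1}^{m} \binom{m}{k} +
#'   \binom{m}{n} (max(p)/0.5)^n}{2^m},}
#' the first term vanishing at n = m. At max(p) = 0.5 this reduces to
#' the binomial tail P(Bin(m, 1/2) >= n); when n = 0, max(p) is defined
#' as 0.5 so the test returns 1. Bonferroni correction multiplies by the
#' number of phenotypes tested in the family.
#'
#' @param r numeric vector of semi-partial correlations, one per split.
#' @param pOneSided numeric vector of one-sided p-values; every entry
#'   attached to a positive correlation must be <= 0.5 (a one-sided p of
#'   a positive correlation cannot exceed 0.5).
#' @param nPhenotypes Bonferroni factor (default 1).
#' @return \linkS4class{ExactTestResult}.
#' @examples
#' # n = 6 of m = 10 positive: corrected p is 1 for any max(p)
#' r <- c(rep(0.1, 6), rep(-0.1, 4))
#' p <- c(rep(0.2, 6), rep(0.8, 4))
#' exactResamplingTest(r, p, nPhenotypes = 6)
#' @export
exactResamplingTest <- function(r, pOneSided, nPhenotypes = 1) {
  m <- length(r)
  if (m < 1) stop("need at least one resampling")
  if (length(pOneSided) != m) stop("r and pOneSided must have equal length")
  pos <- r > 0
  if (any(pos & (is.na(pOneSided) | pOneSided > 0.5)))
    stop("one-sided p of a positive correlation cannot exceed 0.5")
  n <- sum(pos)
  maxP <- if (n > 0) max(pOneSided[pos]) else 0.5
  tail <- if (n < m) sum(choose(m, seq(n + 1, m))) else 0
  pExact <- (tail + choose(m, n) * (maxP / 0.5)^n) / 2^m
  pExact <- min(1, pExact)
  methods::new("ExactTestResult",
               m = as.integer(m), n = as.integer(n), maxP = maxP,
               pExact = pExact,
               pCorrected = min(1, nPhenotypes * pExact),
               nPhenotypes = as.integer(nPhenotypes))
}

#' End-to-end polygenic score resampling pipeline
#'
#' For each of \code{m} discovery/target splits: per-SNP covariate-
#' adjusted regression in the discovery sample, selection at
#' \code{pThreshold}, weighted scoring of the target sample with
#' discovery betas (missing dosages imputed from discovery allele
#' frequencies), and the semi-partial correlation of score with
#' phenotype in the target sample; finally the exact combination test.
#'
#' @param geno QC'd, pruned \linkS4class{GenotypeData}.
#' @param pheno sample table (\code{id}, covariates, phenotypes).
#' @param phenotype phenotype column name.
#' @param m number of resamplings (default 10).
#' @param fracDiscovery discovery fraction (default 0.7).
#' @param pThreshold discovery selection threshold (default 0.5).
#' @param nPhenotypes Bonferroni factor for the exact test (default 1).
#' @param covariates covariate column names.
#' @param seed integer seed (required; governs the splits).
#' @return list with \code{runs} (per-split list: discovery/target ids,
#'   selected SNPs, betas, target scores, \code{r}, \code{pOneSided})
#'   and \code{exact} (\linkS4class{ExactTestResult}).
#' @export
runPrsPipeline <- function(geno, pheno, phenotype, m = 10,
                           fracDiscovery = 0.7, pThreshold = 0.5,
                           nPhenotypes = 1,
                           covariates = c("site", "gender", "handedness"),
                           seed) {
  if (missing(seed)) stop("seed is required")
  G <- dosageMatrix(geno)
  ids <- intersect(rownames(G), pheno$id)
  splits <- splitCohort(ids, fracDiscovery, m, seed)
  rownames(pheno) <- pheno$id
  runs <- lapply(seq_along(splits), function(i) {
    sp <- splits[[i]]
    reg <- snpRegression(geno, pheno, phenotype, ids = sp$discovery,
                         covariates = covariates)
    selected <- selectSnps(reg, pThreshold)
    betas <- stats::setNames(reg$beta, rownames(reg))
    discFreq <- .alleleFreq(G[sp$discovery, , drop = FALSE])
    score <- scoreIndividuals(geno, selected, betas, ids = sp$target,
                              refFreq = discFreq)
    sr <- semipartialR(score, pheno[sp$target, , drop = FALSE], phenotype,
                       covariates)
    list(split = i, discovery = sp$discovery, target = sp$target,
         selected = selected, betas = betas[selected], score = score,
         r = sr$r, pOneSided = sr$pOneSided)
  })
  exact <- exactResamplingTest(vapply(runs, `[[`, numeric(1), "r"),
                               vapply(runs, `[[`, numeric(1), "pOneSided"),
                               nPhenotypes)
  list(runs = runs, exact = exact)
}
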