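test_that("univariate association handles noiseless, null and single-test cases", {
  set.seed(1)
  n <- 150
  G <- sapply(1:20, function(j) rbinom(n, 2, runif(1, 0.1, 0.5)))
  colnames(G) <- paste0("s", 1:20)
  geno <- makeGeno(G)
  cov <- makeCovariates(n, seed = 2)

  cov$pheno <- G[, "s5"]                       # noiseless y = g
  res <- univariateAssoc(geno, cov, "pheno")
  expect_lt(res$p[res$snp == "s5"], 1e-200)
  expect_lt(res$pBonferroni[res$snp == "s5"], 1e-200)

  resOne <- univariateAssoc(geno, cov, "pheno", nTests = 1)
  expect_equal(resOne$pBonferroni, pmin(1, resOne$p))

  cov$pheno <- sample(rnorm(n))                # permuted: null everywhere
  resNull <- univariateAssoc(geno, cov, "pheno")
  expect_gt(mean(resNull$pBonferroni > 0.9, na.rm = TRUE), 0.9)
})

test_that("high-signal replicates rank the causal SNP first", {
  first <- replicate(30, {
    g <- simulateGenotypes(300, 40, 1, seed = sample.int(1e7, 1))
    ph <- simulatePhenotypes(g, causalSnps = "snp13", effectSizes = 0.6,
                             noiseSd = 1, seed = sample.int(1e7, 1))
    res <- univariateAssoc(g, ph, "pheno")
    res$snp[which.min(res$p)] == "snp13"
  })
  expect_gte(mean(first), 0.9)
})

test_that("enrichment counts SNP p-values below threshold and never returns p = 0", {
  snpGene <- setNames(rep(c("gA", "gB", "gC"), each = 1), paste0("s", 1:3))
  pv <- setNames(c(0.01, 0.2, 0.03), paste0("s", 1:3))
  en <- enrichmentTest(pv, snpGene, c("gA", "gB", "gC"), threshold = 0.05,
                       nPerm = 50, seed = 1)
  expect_identical(en@observed, 2L)
  expect_gt(en@p, 0)
  expect_error(enrichmentTest(pv, snpGene, c("gA", "gB", "gC", "gD"),
                              nPerm = 10, seed = 1), "absent")
})

test_that("enrichment detects injected signal at the stated strength", {
  rej <- replicate(40, {
    pool <- makeEnrichmentPool(sample.int(1e7, 1))
    pv <- setNames(runif(length(pool$snpGene)), names(pool$snpGene))
    cand <- pool$genes[1:37]
    ci <- names(pool$snpGene)[pool$snpGene %in% cand]
    hit <- runif(length(ci)) < 0.30
    pv[ci][hit] <- runif(sum(hit), 0, 0.05)
    enrichmentTest(pv, pool$snpGene, cand, 0.05, nPerm = 200,
                   seed = sample.int(1e7, 1))@p < 0.05
  })
  expect_gte(mean(rej), 0.8)
})

test_that("four-gamete rule joins two-gamete pairs and splits four-gamete pairs", {
  # only two gametes present: one block
  H2 <- rbind(matrix(rep(c(0, 0), 50), ncol = 2, byrow = TRUE),
              matrix(rep(c(1, 1), 50), ncol = 2, byrow = TRUE))
  expect_length(fourGameteBlocks(H2, phased = TRUE), 1)

  # gamete frequencies 0.70/0.12/0.12/0.06: fourth exceeds 0.05, boundary
  H4 <- rbind(matrix(rep(c(0, 0), 70), ncol = 2, byrow = TRUE),
              matrix(rep(c(1, 0), 12), ncol = 2, byrow = TRUE),
              matrix(rep(c(0, 1), 12), ncol = 2, byrow = TRUE),
              matrix(rep(c(1, 1), 6), ncol = 2, byrow = TRUE))
  expect_length(fourGameteBlocks(H4, phased = TRUE), 2)

  # exactly at the threshold: still compatible (strictly-above rule)
  H5 <- rbind(matrix(rep(c(0, 0), 70), ncol = 2, byrow = TRUE),
              matrix(rep(c(1, 0), 13), ncol = 2, byrow = TRUE),
              matrix(rep(c(0, 1), 12), ncol = 2, byrow = TRUE),
              matrix(rep(c(1, 1), 5), ncol = 2, byrow = TRUE))
  expect_length(fourGameteBlocks(H5, phased = TRUE), 1)
})

test_that("four-gamete partition matches the exhaustive oracle on a 12-SNP toy", {
  set.seed(8)
  pool <- matrix(rbinom(12 * 6, 1, 0.5), nrow = 6)    # 6 founder haplotypes
  H <- pool[sample(6, 600, replace = TRUE, prob = c(.3, .25, .2, .1, .1, .05)), ]
  # inject recombination between SNPs 6 and 7 so a boundary exists
  H[301:600, 7:12] <- H[sample(301:600), 7:12]
  got <- fourGameteBlocks(H, phased = TRUE, freqThreshold = 0.05)
  oracle <- oracleFourGamete(H, 0.05)
  expect_identical(got, oracle)
  expect_identical(sort(unlist(got)), 1:12)   # partition covers all SNPs once
})

test_that("EM haplotype frequencies equal direct counts without phase ambiguity", {
  G <- rbind(c(2, 2), c(0, 0), c(2, 0), c(2, 0), c(0, 0))
  hf <- emHaplotypeFreqs(G)
  # haplotypes: 11 x2, 00 x2, 10 x2 from two individuals, rest 00
  counts <- c(`00` = 4, `10` = 4, `11` = 2)
  expect_equal(sum(hf@freq), 1, tolerance = 1e-12)
  f <- setNames(hf@freq, hf@haplotypes)
  expect_equal(unname(f["00"]), 0.4, tolerance = 1e-12)
  expect_equal(unname(f["10"]), 0.4, tolerance = 1e-12)
  expect_equal(unname(f["11"]), 0.2, tolerance = 1e-12)
})

test_that("EM resolves a double heterozygote toward the majority phase", {
  # individuals: (2,2) (0,0) (2,0) x2 and one ambiguous (1,1); the
  # cohort's 11/00 haplotypes outweigh 10/01, so EM assigns the
  # ambiguous pair predominantly to (11, 00)
  G <- rbind(c(2, 2), c(0, 0), c(2, 0), c(2, 0), c(1, 1))
  hf <- emHaplotypeFreqs(G, tol = 1e-12)
  mle <- oracleHapMle2(G)
  # align haplotype order 00,10,01,11
  ord <- match(c("00", "10", "01", "11"), hf@haplotypes)
  expect_equal(hf@freq[ord], mle$freq, tolerance = 2e-3)
  # EM must do at least as well as the numerically optimized oracle
  expect_gte(hf@logLik, mle$logLik - 1e-6)
  expect_lte(hf@logLik, mle$logLik + 1e-4)
  expect_true(all(abs(rowSums(hf@dosage) - 2) < 1e-9))
})

test_that("EM log-likelihood is monotone and recovery from masked phase works", {
  set.seed(12)
  founder <- matrix(rbinom(6 * 4, 1, 0.5), nrow = 4)
  truth <- c(0.4, 0.3, 0.2, 0.1)
  H <- founder[sample(4, 1000, replace = TRUE, prob = truth), ]
  geno <- phasedToGeno(H)
  hf <- emHaplotypeFreqs(geno, seq_len(6))
  expect_true(hf@converged)
  f <- setNames(hf@freq, hf@haplotypes)
  realized <- table(apply(H, 1, paste, collapse = "")) / nrow(H)
  for (hs in names(realized)) {
    si <- snpInfo(geno)
    lab <- paste(ifelse(strsplit(hs, "")[[1]] == "1",
                        si$alleleMinor, si$alleleMajor), collapse = "")
    expect_lt(abs(f[lab] - realized[hs]), 0.02)
  }
})

test_that("haplotype association finds a noiseless haplotype effect", {
  set.seed(14)
  founders <- rbind(c(0, 0), c(1, 0))
  H <- founders[sample(2, 400, replace = TRUE, prob = c(0.6, 0.4)), ]
  geno <- phasedToGeno(H)
  hf <- emHaplotypeFreqs(geno)
  cov <- makeCovariates(nrow(hf@dosage), seed = 15)
  si <- snpInfo(geno)
  lab10 <- paste0(si$alleleMinor[1], si$alleleMajor[2])
  cov$pheno <- 0.5 * hf@dosage[, lab10]
  ha <- haplotypeAssociation(hf, cov, "pheno")
  per <- ha$perHaplotype
  expect_lt(per$p[per$haplotype == lab10], 1e-200)
  expect_lt(ha$omnibusP, 1e-200)
  expect_true(all(abs(rowSums(hf@dosage) - 2) < 1e-9))
})

test_that("omnibus haplotype p-values are roughly uniform under the null", {
  set.seed(16)
  founders <- rbind(c(0, 0, 0), c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
  ps <- replicate(100, {
    H <- founders[sample(4, 300, replace = TRUE, prob = c(.4, .3, .2, .1)), ]
    geno <- phasedToGeno(H)
    hf <- emHaplotypeFreqs(geno)
    cov <- makeCovariates(nrow(hf@dosage), seed = sample.int(1e7, 1))
    cov$pheno <- rnorm(nrow(cov))
    haplotypeAssociation(hf, cov, "pheno")$omnibusP
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("a latent-model ordinal outcome points to the causal haplotype", {
  set.seed(18)
  founders <- rbind(c(0, 0, 0), c(1, 1, 0), c(0, 1, 1))
  wins <- replicate(20, {
    H <- founders[sample(3, 600, replace = TRUE, prob = c(.5, .3, .2)), ]
    geno <- phasedToGeno(H)
    hf <- emHaplotypeFreqs(geno)
    n <- nrow(hf@dosage)
    cov <- makeCovariates(n, seed = sample.int(1e7, 1))
    si <- snpInfo(geno)
    labC <- paste0(si$alleleMajor[1], si$alleleMinor[2], si$alleleMinor[3])
    latent <- 0.6 * hf@dosage[, labC] + rnorm(n)
    cuts <- quantile(latent, c(.75, .85, .92, .96, .985))
    cov$binge <- as.integer(cut(latent, c(-Inf, cuts, Inf), labels = FALSE)) - 1L
    ha <- haplotypeAssociation(hf, cov, "binge")
    per <- ha$perHaplotype
    per$haplotype[which.min(per$p)] == labC
  })
  expect_gt(mean(wins), 0.5)
})

test_that("partial correlation matches the residualize-both oracle", {
  set.seed(20)
  n <- 10
  cov <- makeCovariates(n, seed = 21)
  x <- rnorm(n); y <- rnorm(n)
  got <- partialCorr(x, y, cov)
  X <- model.matrix(~ site + gender + handedness,
                    data = transform(cov, site = factor(site)))
  rx <- residuals(lm.fit(X, x)); ry <- residuals(lm.fit(X, y))
  r <- cor(rx, ry)
  k <- ncol(X) - 1; df <- n - 2 - k
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(r * sqrt(df / (1 - r^2))), df),
               tolerance = 1e-12)

  expect_equal(partialCorr(x, x, cov)$r, 1, tolerance = 1e-12)
  plain <- partialCorr(x, y, data.frame(z = rep(1, n)), covariates = "z")
  expect_equal(plain$r, cor(x, y), tolerance = 1e-12)
})
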