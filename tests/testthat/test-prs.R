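test_that("cohort splitting honors sizes, determinism and distinctness", {
  ids <- paste0("i", 1:10)
  sp <- splitCohort(ids, 0.7, m = 3, seed = 1)
  expect_true(all(vapply(sp, function(s) length(s$discovery), numeric(1)) == 7))
  expect_true(all(vapply(sp, function(s) length(s$target), numeric(1)) == 3))
  for (s in sp) {
    expect_length(intersect(s$discovery, s$target), 0)
    expect_setequal(c(s$discovery, s$target), ids)
  }
  expect_identical(splitCohort(ids, 0.7, 3, seed = 5),
                   splitCohort(ids, 0.7, 3, seed = 5))
  expect_error(splitCohort(paste0("i", 1:9), seed = 1), "too small")

  big <- splitCohort(paste0("i", 1:1000), m = 10, seed = 2)
  discs <- lapply(big, `[[`, "discovery")
  for (a in 1:9) for (b in (a + 1):10)
    expect_false(identical(discs[[a]], discs[[b]]))
})

test_that("per-SNP regression recovers noiseless effects and matches lm", {
  set.seed(2)
  n <- 120
  G <- cbind(s1 = rbinom(n, 2, 0.3), s2 = rbinom(n, 2, 0.4),
             s3 = rep(1, n))                       # s3 constant
  cov <- makeCovariates(n, seed = 3)
  cov$pheno <- 0.5 * G[, "s1"]                     # noiseless, covariates inert
  geno <- makeGeno(G)
  reg <- snpRegression(geno, cov, "pheno")
  expect_equal(reg["s1", "beta"], 0.5, tolerance = 1e-12)
  expect_true(reg["s3", "excluded"])

  # against a full lm fit, coefficient and p to near machine precision
  cov$pheno <- 0.3 * G[, "s2"] + rnorm(n)
  reg2 <- snpRegression(geno, cov, "pheno")
  fit <- lm(pheno ~ g + site + gender + handedness,
            data = transform(cov, g = G[, "s2"]))
  sm <- summary(fit)$coefficients["g", ]
  expect_equal(reg2["s2", "beta"], unname(sm["Estimate"]), tolerance = 1e-10)
  expect_equal(reg2["s2", "p"], unname(sm["Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("SNP selection applies a strict p-value threshold", {
  res <- data.frame(p = c(0.01, 0.49, 0.5, 0.9),
                    excluded = FALSE,
                    row.names = paste0("s", 1:4))
  expect_setequal(selectSnps(res, 0.5), c("s1", "s2"))
  res$p <- rep(0.6, 4)
  expect_length(selectSnps(res, 0.5), 0)
  expect_error(selectSnps(res[0, , drop = FALSE]), "empty")
})

test_that("polygenic scoring is linear, order-invariant and imputes from reference", {
  G <- rbind(i1 = c(1, 2, 0, 2), i2 = c(0, 1, 2, 1))
  colnames(G) <- paste0("s", 1:4)
  geno <- makeGeno(G)
  betas <- c(s1 = 0.2, s2 = -0.1, s3 = 0.3, s4 = 0.05)
  expect_equal(unname(scoreIndividuals(geno, c("s1", "s2"), betas)["i1"]), 0)
  expect_equal(unname(scoreIndividuals(geno, character(0), betas)), c(0, 0))

  sAB <- scoreIndividuals(geno, c("s1", "s2", "s3", "s4"), betas)
  sA <- scoreIndividuals(geno, c("s1", "s3"), betas)
  sB <- scoreIndividuals(geno, c("s2", "s4"), betas)
  expect_equal(sAB, sA + sB)

  # permuting SNPs and individuals leaves scores unchanged
  perm <- c("s3", "s1", "s4", "s2")
  sPerm <- scoreIndividuals(makeGeno(G[c("i2", "i1"), perm]),
                            perm, betas)
  expect_equal(sPerm[names(sAB)], sAB)

  # missing dosage imputed as twice the reference allele frequency
  Gm <- G; Gm["i1", "s1"] <- NA
  sm <- scoreIndividuals(makeGeno(Gm), "s1", betas,
                         refFreq = c(s1 = 0.25))
  expect_equal(unname(sm["i1"]), 0.2 * 2 * 0.25)
})

test_that("semi-partial correlation matches the residualize-then-correlate oracle", {
  set.seed(4)
  n <- 8
  cov <- makeCovariates(n, seed = 5)
  cov$pheno <- rnorm(n)
  score <- rnorm(n)
  got <- semipartialR(score, cov, "pheno")
  X <- model.matrix(~ site + gender + handedness,
                    data = transform(cov, site = factor(site)))
  ry <- residuals(lm.fit(X, cov$pheno))
  r <- cor(score, ry)
  k <- ncol(X) - 1
  tv <- r * sqrt((n - 2 - k) / (1 - r^2))
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$pOneSided, pt(tv, n - 2 - k, lower.tail = FALSE),
               tolerance = 1e-12)

  # orthogonal (absent) covariates reduce to the plain Pearson correlation
  plain <- semipartialR(score, data.frame(pheno = cov$pheno), "pheno",
                        covariates = character(0))
  expect_equal(plain$r, cor(score, cov$pheno), tolerance = 1e-12)
  expect_error(semipartialR(rep(1, n), cov, "pheno"), "zero-variance")
})

test_that("exact combination test reproduces its boundary cases", {
  # n = 10 of 10 positives at the uniform bound: only the top term
  r <- rep(0.2, 10); p <- rep(0.5, 10)
  expect_equal(exactResamplingTest(r, p)@pExact, 1 / 1024)
  # no positives: total mass, p = 1
  rneg <- rep(-0.2, 10); pneg <- rep(0.8, 10)
  et0 <- exactResamplingTest(rneg, pneg)
  expect_equal(et0@pExact, 1)
  expect_equal(et0@maxP, 0.5)
  # inconsistent input: positive correlation with one-sided p > 0.5
  expect_error(exactResamplingTest(c(0.1), c(0.7)), "cannot exceed 0.5")
})

test_that("exact test is monotone in n and in max(p)", {
  m <- 10
  for (maxP in c(0.05, 0.2, 0.45)) {
    pe <- vapply(0:m, function(n) {
      r <- c(rep(1, n), rep(-1, m - n))
      p <- c(rep(maxP, n), rep(0.9, m - n))
      exactResamplingTest(r, p)@pExact
    }, numeric(1))
    expect_true(all(diff(pe) <= 1e-12))
    expect_true(all(pe > 0 & pe <= 1))
  }
  for (n in c(1, 5, 10)) {
    pe <- vapply(seq(0.05, 0.5, by = 0.05), function(mp) {
      r <- c(rep(1, n), rep(-1, m - n))
      p <- c(rep(mp, n), rep(0.9, m - n))
      exactResamplingTest(r, p)@pExact
    }, numeric(1))
    expect_true(all(diff(pe) >= -1e-12))
  }
})

test_that("PRS pipeline is reproducible and its runs respect the contracts", {
  g <- simulateGenotypes(100, 30, 1, seed = 51)
  ph <- simulatePhenotypes(g, seed = 52)
  res1 <- runPrsPipeline(g, ph, "pheno", seed = 53)
  res2 <- runPrsPipeline(g, ph, "pheno", seed = 53)
  expect_equal(res1$exact@pExact, res2$exact@pExact)
  expect_identical(vapply(res1$runs, `[[`, numeric(1), "r"),
                   vapply(res2$runs, `[[`, numeric(1), "r"))
  for (run in res1$runs) {
    expect_length(intersect(run$discovery, run$target), 0)
    expect_equal(length(run$discovery), 70)
    reg <- snpRegression(g, ph, "pheno", ids = run$discovery)
    expect_true(all(reg[run$selected, "p"] < 0.5))
  }
})

test_that("one-sided p-values of positive-r splits are uniform on (0, 0.5) under the null", {
  pooled <- c()
  for (i in 1:40) {
    g <- simulateGenotypes(150, 40, 1, seed = 6000 + i)
    ph <- simulatePhenotypes(g, seed = 6500 + i)
    res <- runPrsPipeline(g, ph, "pheno", seed = 7000 + i)
    rs <- vapply(res$runs, `[[`, numeric(1), "r")
    ps <- vapply(res$runs, `[[`, numeric(1), "pOneSided")
    pooled <- c(pooled, ps[rs > 0])
  }
  ks <- suppressWarnings(ks.test(pooled / 0.5, "punif"))
  # splits within a replicate are dependent, so the bound is lenient
  expect_gt(ks$p.value, 0.001)
})

test_that("exact test is calibrated when the resamplings are independent", {
  hits <- logical(60)
  for (i in 1:60) {
    rs <- numeric(10); ps <- numeric(10)
    for (j in 1:10) {
      g <- simulateGenotypes(100, 30, 1, seed = 80000 + i * 37 + j)
      ph <- simulatePhenotypes(g, seed = 85000 + i * 41 + j)
      res <- runPrsPipeline(g, ph, "pheno", m = 1, seed = 88000 + i * 43 + j)
      rs[j] <- res$runs[[1]]$r; ps[j] <- res$runs[[1]]$pOneSided
    }
    hits[i] <- exactResamplingTest(rs, ps)@pExact < 0.05
  }
  expect_lte(mean(hits), 0.13)   # 95% binomial envelope around 0.05 at 60 draws
})
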