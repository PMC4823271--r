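# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles, without calling the package
# implementation paths they check.

# Step-up FDR selection evaluated literally from its definition.
oracleBhSelect <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- max(c(0, which(ps <= seq_len(m) / m * q)))
  if (k == 0) rep(FALSE, m) else p <= ps[k]
}

# Exact Hardy-Weinberg p by direct enumeration of heterozygote counts:
# P(nAa = h | nA, n) computed from the conditional distribution via
# unnormalized exp(log) weights summed over the full support.
oracleHwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  w <- sapply(hs, function(h) {
    aa <- (nA - h) / 2; bb <- n - aa - h
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n))
  })
  w <- w / sum(w)   # numerical safety; weights already sum to 1 analytically
  obs <- w[hs == nAa]
  sum(w[w <= obs * (1 + 1e-12)])
}

# Greedy sliding-window pruning re-implemented naively on a dosage
# matrix (single chromosome).
oracleLdPrune <- function(G, window, step, r2Max) {
  maf <- pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)
  keep <- rep(TRUE, ncol(G))
  start <- 1
  repeat {
    w <- seq(start, min(start + window - 1, ncol(G)))
    repeat {
      live <- w[keep[w]]
      removed <- FALSE
      if (length(live) > 1) {
        for (a in seq_len(length(live) - 1)) {
          for (b in seq(a + 1, length(live))) {
            i <- live[a]; j <- live[b]
            if (var(G[, i]) < 1e-12 || var(G[, j]) < 1e-12) next
            if (cor(G[, i], G[, j])^2 > r2Max) {
              victim <- if (maf[i] < maf[j]) i else j
              keep[victim] <- FALSE; removed <- TRUE; break
            }
          }
          if (removed) break
        }
      }
      if (!removed) break
    }
    if (start + window - 1 >= ncol(G)) break
    start <- start + step
  }
  which(keep)
}

# Four-gamete partition on phased haplotypes by exhaustive pairwise
# gamete counting with the same greedy left-to-right extension rule.
oracleFourGamete <- function(H, thr) {
  S <- ncol(H)
  blocks <- list(); current <- 1L
  if (S > 1) for (j in 2:S) {
    ok <- TRUE
    for (i in current) {
      tab <- table(paste(H[, i], H[, j]))
      f <- as.numeric(tab) / nrow(H)
      if (length(f) == 4 && min(f) > thr) { ok <- FALSE; break }
    }
    if (ok) current <- c(current, j)
    else { blocks[[length(blocks) + 1]] <- current; current <- j }
  }
  blocks[[length(blocks) + 1]] <- current
  blocks
}

# Observed-data log-likelihood of haplotype frequencies for unphased
# 2-SNP genotypes; used with optim() as an EM oracle.
oracleHapLoglik2 <- function(f, G) {
  # f: freq of haplotypes 00, 10, 01, 11 (minor allele indicators)
  ll <- 0
  for (i in seq_len(nrow(G))) {
    a <- G[i, 1]; b <- G[i, 2]
    pairs <- list()
    for (h1 in 0:3) for (h2 in h1:3) {
      al <- (h1 %% 2) + (h2 %% 2)
      bl <- (h1 %/% 2) + (h2 %/% 2)
      if (al == a && bl == b)
        pairs[[length(pairs) + 1]] <- c(h1 + 1, h2 + 1)
    }
    pr <- sum(sapply(pairs, function(pp)
      f[pp[1]] * f[pp[2]] * if (pp[1] == pp[2]) 1 else 2))
    ll <- ll + log(pr)
  }
  ll
}

# Maximize oracleHapLoglik2 over the simplex via optim on logits.
oracleHapMle2 <- function(G) {
  obj <- function(theta) {
    f <- exp(c(theta, 0)); f <- f / sum(f)
    -oracleHapLoglik2(f, G)
  }
  fit <- optim(c(0, 0, 0), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  f <- exp(c(fit$par, 0)); f <- f / sum(f)
  list(freq = f, logLik = -fit$value)
}
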