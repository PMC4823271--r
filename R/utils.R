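# Internal numerical helpers shared across modules.

# Deterministic per-stage substream: derive a child seed from the global
# seed and a stage label so each generator draws from its own stream.
.substreamSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000000L) * 2011L + (h %% 1999L)
}

# Covariate design matrix (with intercept) from a sample table.
# site is treated as categorical; gender/handedness as given.
.covariateDesign <- function(samples, covariates = c("site", "gender", "handedness")) {
  covariates <- intersect(covariates, colnames(samples))
  df <- samples[, covariates, drop = FALSE]
  varying <- vapply(df, function(v) length(unique(v)) > 1, logical(1))
  df <- df[, varying, drop = FALSE]
  if (!ncol(df)) return(matrix(1, nrow(samples), 1,
                               dimnames = list(NULL, "(Intercept)")))
  if ("site" %in% colnames(df)) df$site <- factor(df$site)
  stats::model.matrix(~ ., data = df)
}

# Residualize columns of y (vector or matrix) on design X via QR.
.residualize <- function(y, X) {
  qrX <- qr(X)
  as.matrix(qr.resid(qrX, as.matrix(y)))
}

# Per-SNP OLS of y on dosage + covariates by Frisch-Waugh residualization.
# G: n x s dosage matrix (no NA fast path; NA falls back to lm per SNP).
# X: covariate design including intercept.
# Returns data.frame(beta, se, t, p, excluded).
.snpOls <- function(y, G, X) {
  n <- length(y)
  k <- qr(X)$rank
  df <- n - k - 1
  if (df < 1) stop("not enough observations for per-SNP regression")
  if (anyNA(G) || anyNA(y)) {
    out <- t(vapply(seq_len(ncol(G)), function(j) {
      g <- G[, j]
      keep <- !is.na(g) & !is.na(y)
      if (length(unique(g[keep])) < 2) return(c(NA, NA, NA, NA, 1))
      fit <- stats::lm.fit(cbind(g = g[keep], X[keep, , drop = FALSE]), y[keep])
      rdf <- fit$df.residual
      s2 <- sum(fit$residuals^2) / rdf
      XtXinv <- tryCatch(solve(crossprod(cbind(g = g[keep], X[keep, , drop = FALSE]))),
                         error = function(e) NULL)
      if (is.null(XtXinv)) return(c(NA, NA, NA, NA, 1))
      se <- sqrt(s2 * XtXinv[1, 1])
      b <- fit$coefficients["g"]
      tv <- b / se
      c(b, se, tv, 2 * stats::pt(-abs(tv), rdf), 0)
    }, numeric(5)))
  } else {
    qrX <- qr(X)
    ry <- qr.resid(qrX, y)
    RG <- qr.resid(qrX, G)
    ssg <- colSums(RG^2)
    excluded <- ssg < 1e-12 | apply(G, 2, function(g) length(unique(g)) < 2)
    beta <- colSums(RG * ry) / ssg
    rss <- pmax(sum(ry^2) - beta^2 * ssg, 0)
    se <- sqrt(rss / df / ssg)
    tv <- beta / se
    p <- 2 * stats::pt(-abs(tv), df)
    beta[excluded] <- NA; se[excluded] <- NA; tv[excluded] <- NA; p[excluded] <- NA
    out <- cbind(beta, se, tv, p, as.numeric(excluded))
  }
  res <- data.frame(beta = out[, 1], se = out[, 2], t = out[, 3],
                    p = out[, 4], excluded = out[, 5] > 0)
  rownames(res) <- colnames(G)
  res
}

# Minor-allele frequency per SNP column, NA-aware.
.alleleFreq <- function(G) colMeans(G, na.rm = TRUE) / 2

# Pairwise r^2 between two dosage vectors, pairwise-complete.
.pairR2 <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 2) return(NA_real_)
  va <- stats::var(a[keep]); vb <- stats::var(b[keep])
  if (va < 1e-12 || vb < 1e-12) return(NA_real_)
  stats::cor(a[keep], b[keep])^2
}
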