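#' Percentage of premature responses in the five-choice task
#'
#' premature / (correct + incorrect + omissions + premature) * 100.
#'
#' @param correct,incorrect,omissions,premature non-negative trial counts;
#'   alternatively pass a one-row data.frame as \code{correct}.
#' @return percentage in [0, 100].
#' @examples
#' prematurePct5csrtt(60, 10, 20, 10)  # 10
#' @export
prematurePct5csrtt <- function(correct, incorrect, omissions, premature) {
  if (is.data.frame(correct)) {
    df <- correct
    correct <- df$correct; incorrect <- df$incorrect
    omissions <- df$omissions; premature <- df$premature
  }
  counts <- c(correct, incorrect, omissions, premature)
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- correct + incorrect + omissions + premature
  if (any(total <= 0)) stop("empty session: total trial count is zero")
  100 * premature / total
}

#' Percentage of premature responses in the monetary incentive delay task
#'
#' (responses before target onset / total responses) * 100.
#'
#' @param prematureResponses count of responses before the target.
#' @param totalResponses total response count (> 0).
#' @return percentage in [0, 100].
#' @export
prematurePctMid <- function(prematureResponses, totalResponses) {
  if (any(totalResponses <= 0)) stop("totalResponses must be positive")
  if (any(prematureResponses < 0) || any(prematureResponses > totalResponses))
    stop("prematureResponses must lie in [0, totalResponses]")
  100 * prematureResponses / totalResponses
}

#' Variance-stabilizing arcsine transform of a percentage
#'
#' x' = 2 * arcsin(sqrt(x / 100)); monotone from [0, 100] onto [0, pi].
#'
#' @param x percentage(s) in [0, 100].
#' @return value(s) in radians.
#' @export
arcsineTransform <- function(x) {
  if (any(x < 0 | x > 100)) stop("percentages must lie in [0, 100]")
  2 * asin(sqrt(x / 100))
}

#' One-way strain ANOVA with narrow-sense heritability
#'
#' Decomposes the total sum of squares into between-strain (SSM) and
#' residual (SSE) components; the heritability estimate is the ANOVA
#' R-squared, h2 = SSM / SST, the fraction of phenotypic variance
#' attributable to strain. When the input is a percentage the protocol
#' applies the arcsine transform first (\code{arcsine = TRUE}).
#'
#' A degenerate table with zero within-strain variance returns
#' \code{F = Inf}, \code{h2 = 1} flagged via \code{p = 0}, not an error.
#'
#' @param strains data.frame with columns \code{strain} and \code{value}.
#' @param arcsine apply [arcsineTransform()] to \code{value} first.
#' @return An \linkS4class{AnovaResult}-style S4 object with slots
#'   \code{F}, \code{df1}, \code{df2}, \code{SSM}, \code{SST}, \code{p},
#'   \code{h2}.
#' @examples
#' st <- data.frame(strain = c("a", "a", "b", "b"), value = c(0, 1, 2, 3))
#' strainAnova(st)@F  # 8
#' @export
strainAnova <- function(strains, arcsine = FALSE) {
  if (!all(c("strain", "value") %in% colnames(strains)))
    stop("strains must have columns 'strain' and 'value'")
  y <- strains$value
  if (arcsine) y <- arcsineTransform(y)
  g <- factor(strains$strain)
  if (nlevels(g) < 2) stop("need at least 2 strains")
  if (any(table(g) < 2)) stop("need at least 2 replicates per strain")
  N <- length(y)
  gm <- mean(y)
  means <- tapply(y, g, mean)
  ni <- as.integer(table(g))
  ssm <- sum(ni * (means[levels(g)] - gm)^2)
  sst <- sum((y - gm)^2)
  sse <- sst - ssm
  df1 <- nlevels(g) - 1L
  df2 <- N - nlevels(g)
  if (sse <= .Machine$double.eps * sst) {
    return(methods::new("AnovaResult", F = Inf, df1 = df1, df2 = df2,
                        SSM = ssm, SST = sst, p = 0, h2 = 1))
  }
  Fv <- (ssm / df1) / (sse / df2)
  methods::new("AnovaResult", F = Fv, df1 = df1, df2 = df2,
               SSM = ssm, SST = sst,
               p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
               h2 = ssm / sst)
}

#' One-way ANOVA result with heritability
#'
#' @slot F F statistic (between mean square over residual mean square).
#' @slot df1 between-strain degrees of freedom (strains - 1).
#' @slot df2 residual degrees of freedom (N - strains).
#' @slot SSM between-strain sum of squares.
#' @slot SST total sum of squares.
#' @slot p upper-tail F p-value.
#' @slot h2 narrow-sense heritability estimate SSM / SST.
#' @export
setClass("AnovaResult", representation(
  F = "numeric", df1 = "integer", df2 = "integer",
  SSM = "numeric", SST = "numeric", p = "numeric", h2 = "numeric"
))

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("One-way strain ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              object@df1, object@df2, object@F, object@p))
  cat(sprintf("  h2 = SSM/SST = %.3f\n", object@h2))
})

#' Heritability from a reported F statistic
#'
#' Inverts the ANOVA identity R2 = F * df1 / (F * df1 + df2), recovering
#' the between-group variance fraction from a published F and its
#' degrees of freedom.
#'
#' @param F non-negative F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return heritability estimate in [0, 1).
#' @examples
#' heritabilityFromF(6.88, 11, 94)  # about 0.446
#' @export
heritabilityFromF <- function(F, df1, df2) {
  if (any(F < 0)) stop("F must be non-negative")
  F * df1 / (F * df1 + df2)
}

#' Spearman screen of strain phenotype means against expression probes
#'
#' Correlates the per-strain phenotype mean with every probe's
#' strain-level expression by Spearman rank correlation (midranks for
#' ties), two-sided. For panels of up to 9 strains the p-value is the
#' exact permutation probability (via [stats::cor.test()]); for larger
#' panels it uses the t transform t = rho * sqrt((n-2)/(1-rho^2)) on
#' n - 2 degrees of freedom, whose extreme tail is far better behaved
#' than the AS 89 approximation. Either way the two-sided p is floored
#' at 2/n!, the probability of a perfect monotone arrangement.
#'
#' @param strainMeans named numeric vector of per-strain phenotype means.
#' @param expr probe x strain expression matrix; column names must match
#'   the strain labels (order-free); at least 5 strains in common.
#' @param gene optional character vector of gene symbols per probe.
#' @param region optional region label recycled across probes.
#' @return data.frame with one row per probe: \code{probe}, \code{gene},
#'   \code{region}, \code{rho}, \code{p}, \code{selected} (all FALSE
#'   until [bhFdrSelect()] is applied).
#' @export
spearmanScreen <- function(strainMeans, expr, gene = NULL, region = NA_character_) {
  common <- intersect(names(strainMeans), colnames(expr))
  if (length(common) < 5) stop("fewer than 5 strains in common")
  x <- strainMeans[common]
  E <- expr[, common, drop = FALSE]
  ns <- length(common)
  res <- t(apply(E, 1, function(e) {
    if (ns <= 9) {
      ct <- suppressWarnings(stats::cor.test(x, e, method = "spearman",
                                             exact = TRUE))
      c(ct$estimate, ct$p.value)
    } else {
      rho <- stats::cor(x, e, method = "spearman")
      tv <- rho * sqrt((ns - 2) / max(1 - rho^2, .Machine$double.eps))
      c(rho, 2 * stats::pt(-abs(tv), ns - 2))
    }
  }))
  # two-sided p cannot undercut the perfect-arrangement probability 2/n!
  pFloor <- if (ns <= 170) 2 / factorial(ns) else .Machine$double.xmin
  data.frame(
    probe = rownames(expr),
    gene = if (is.null(gene)) NA_character_ else gene,
    region = region,
    rho = res[, 1],
    p = pmin(pmax(res[, 2], pFloor), 1),
    selected = FALSE,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg selection at a given false discovery rate
#'
#' Step-up rule: with p-values sorted ascending, find the largest k with
#' p(k) <= (k/m) q and select every record with p <= p(k). Implemented
#' through [stats::p.adjust()] (the adjusted-p formulation selects the
#' identical set).
#'
#' @param records data.frame with a \code{p} column (e.g. from
#'   [spearmanScreen()]).
#' @param q target false discovery rate.
#' @return \code{records} with its \code{selected} column set.
#' @export
bhFdrSelect <- function(records, q = 0.05) {
  if (!nrow(records)) stop("empty record list")
  if (any(records$p <= 0 | records$p > 1 | is.na(records$p)))
    stop("p-values must lie in (0, 1]")
  records$selected <- stats::p.adjust(records$p, method = "BH") <= q
  records
}
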