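---
title: "Methods: two-stage impulsivity genetics with polygenic score resampling"
author: "resamplePRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage impulsivity genetics with polygenic score resampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resamplePRS)
```

# Overview

`resamplePRS` implements a two-stage translational workflow that links a
rodent impulsivity phenotype to human genetic association. Stage one is a
mouse arm: premature responding in the five-choice serial reaction time
task (5-CSRTT) is summarized per strain of a recombinant-inbred panel,
strain differences are tested by one-way ANOVA, narrow-sense heritability
is estimated from the ANOVA decomposition, and candidate genes are
selected by correlating strain phenotype means with brain expression
probes under a false-discovery-rate gate. Stage two is a human arm: the
human homologs of the candidate genes define a SNP panel that, after
quality control and LD pruning, enters a repeated discovery/target
polygenic score procedure whose evidence across resamplings is combined
by an exact test; SNP-set enrichment, univariate association and
haplotype-block analyses localize the signal.

Every stage can be run on synthetic data with known ground truth, so the
whole pipeline is testable without any external download.

# The mouse arm

## Behavioral metrics

The 5-CSRTT impulsivity measure is the percentage of premature responses,

$$\%\,\text{premature} = \frac{\text{premature}}
{\text{correct} + \text{incorrect} + \text{omissions} + \text{premature}}
\times 100,$$

(`prematurePct5csrtt()`), and its human analog from the monetary
incentive delay task is the percentage of responses made before target
onset (`prematurePctMid()`). Percentages are variance-stabilized before
ANOVA with the arcsine transform $x' = 2\arcsin\sqrt{x/100}$
(`arcsineTransform()`), mapping $[0,100]$ onto $[0,\pi]$.

## Strain ANOVA and heritability

`strainAnova()` computes the one-way decomposition by hand (between-strain
sum of squares SSM, total SST) because the heritability estimate is
itself a ratio of these terms:

$$h^2 = \frac{\mathrm{SSM}}{\mathrm{SST}},$$

the ANOVA $R^2$, i.e. the fraction of phenotypic variance attributable to
strain (additive genetic differences in an inbred panel). A degenerate
table with zero within-strain variance returns $F=\infty$, $h^2=1$ and
$p=0$ rather than an error, so simulation edge cases cannot crash a
batch run. `heritabilityFromF()` inverts the algebraic identity
$R^2 = F\,d_1/(F\,d_1+d_2)$ so heritability can be recovered from
published $F$ statistics; with $F(11,94)$ values of 6.88 and 6.39 it
returns 0.446 and 0.428, matching the published 44% and 42% within the
rounding of $F$.

Note that $h^2=\mathrm{SSM}/\mathrm{SST}$ is not an unbiased estimate of
the intraclass correlation: under the null its expectation is
$d_1/(d_1+d_2)$, and at ICC 0.4 with 12 strains of 10 replicates its
expectation is about 0.44. The test suite asserts the Monte-Carlo mean
within ±0.05 of the simulated truth, which accommodates this small
positive bias.

## Expression screen and FDR gate

`spearmanScreen()` correlates per-strain phenotype means with each
probe's strain-level expression using Spearman rank correlation
(midranks for ties), two-sided. For panels of at most 9 strains the
p-value is the exact permutation probability; for larger panels we use
the t transform $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of
freedom. We deliberately avoid the AS 89 approximation beyond $n=9$:
its extreme tail underflows to exactly zero already at $n=12$, which
would make the FDR gate meaningless for precisely the probes the screen
exists to find. All p-values are floored at $2/n!$, the probability of
a perfect monotone arrangement, which is also the exact value at
$\rho=\pm1$.

`bhFdrSelect()` applies the Benjamini–Hochberg step-up rule at
$q = 0.05$ via `stats::p.adjust`; the selected set is identical to the
literal step-up definition, which the tests verify against an
independent implementation. The gene-count and p-value cutoff implied by
the gate depend on the probe universe, so the gate is parameterized
rather than hard-coded to any published cutoff.

# The human arm

## Genotype quality control

`snpQC()` removes SNPs with call rate below 98%, minor allele frequency
below 1%, or exact Hardy–Weinberg test $p \le 10^{-4}$. The HWE test
(`hweExactTest()`) is the exact conditional test: it conditions on the
observed allele counts, enumerates every compatible heterozygote count,
and sums the probabilities of all tables no more probable than the one
observed. No mid-p adjustment is applied; at the stringent QC threshold
the exact test is the standard choice when rare genotype classes make
the chi-square unreliable. Each removed SNP is recorded with one primary
reason, in the order call-rate, MAF, HWE.

`sampleQC()` removes individuals with more than 2% missing genotypes or
heterozygosity beyond 3 standard deviations of the cohort mean; both
statistics are computed on the pre-filter cohort, which is the one
documented exception to idempotence (on an already-clean cohort the band
is recomputed but removes nobody, which the tests assert).

`ibdEstimate()` implements the method-of-moments identity-by-descent
estimator: per pair, observed identity-by-state counts are decomposed
against their expectations under IBD states 0/1/2. The expectations use
exact finite-sample (without-replacement) allele-count formulas rather
than plug-in frequencies; the plug-in version systematically understates
the expected IBS-0 count at rarer alleles and therefore inflates
$\hat\pi$. Two estimates are returned: `pihatRaw`, the signed moment
estimate, whose null mean is zero, and `pihat`, bounded into $[0,1]$,
which the relatedness filter uses. The bounded estimate is non-negative
by construction, so its null mean is positive at any finite SNP count
(about $0.4\times$ its sampling standard deviation); calibration checks
therefore use the signed estimate, while filtering at the conventional
$\hat\pi > 0.1875$ is unaffected. In a flagged pair the member with
higher missingness is removed (ties: the second), pairs being processed
in decreasing $\hat\pi$ order.

`ldPrune()` is greedy sliding-window pruning (window 50 SNPs, step 5,
$r^2 \le 0.5$ by default): within a window, the first scanned pair
exceeding the threshold loses its lower-MAF member (tie: the later SNP),
until no offending pair remains; the window then slides. The output
invariant — no kept pair within a window above the threshold — is
asserted exhaustively in the tests. The step size and the tie-break are
implementation choices documented here; common practice retains the
higher-information (higher-MAF) SNP.

## Polygenic score resampling

For each phenotype, `runPrsPipeline()` repeats `m = 10` times:

1. split the cohort 70/30 into discovery and target samples
   (`splitCohort()`; discovery size `round(0.7 N)`);
2. regress the phenotype on each SNP's minor-allele dosage with study
   site (categorical), gender and handedness as covariates in the
   discovery sample (`snpRegression()`; QR residualization, equivalent
   to full OLS by the Frisch–Waugh theorem and verified against
   `lm` to machine precision);
3. select "testing SNPs" at the moderate threshold $p < 0.5$, strictly
   (`selectSnps()`); selection is repeated independently per split;
4. score target individuals as
   $\text{score}_i = \sum_s \hat\beta_s\, g_{is}$
   (`scoreIndividuals()`); a missing dosage is imputed as twice the
   discovery-sample allele frequency, never the target's, to avoid
   leakage;
5. compute the semi-partial correlation between the raw score and the
   covariate-residualized phenotype (`semipartialR()`). Only the
   phenotype is adjusted: the score is a genotype function and is
   expected to be orthogonal to site, gender and handedness. The
   one-sided p-value for $r>0$ uses the t transform on $n-2-k$ degrees
   of freedom.

Covariates enter both the selection p-values and the betas: the
discovery regression is a single model, so both quantities are adjusted
jointly.

## The exact combination test

Across the $m$ resamplings, two summaries carry the evidence: the count
$n$ of positive semi-partial correlations, and the largest one-sided
p-value $\max(p)$ among the positive ones. Under the null each
correlation is positive with probability $\tfrac12$, and the one-sided
p-value of a positive correlation is uniform on $(0, \tfrac12)$.
`exactResamplingTest()` combines the two:

$$p_{\text{exact}} \;=\; \frac{\sum_{k=n+1}^{m}\binom{m}{k} \;+\;
\binom{m}{n}\left(\frac{\max(p)}{0.5}\right)^{n}}{2^{m}},$$

with the first term vanishing at $n=m$ and $\max(p)$ defined as 0.5 when
$n=0$ (the test then returns 1). This is the unique composition of the
two evidence levels that reduces exactly to the binomial sign-test tail
$P(\mathrm{Bin}(m,\tfrac12)\ge n)$ at $\max(p)=0.5$, an identity the
tests assert for all $m \le 20$. The statistic is monotone in both
arguments and lies in $(0,1]$. Bonferroni correction multiplies by the
number of phenotypes in the family — six in the original design — and is
an explicit argument because the published correction factor is not
stated.

**A calibration caveat that matters.** The combination formula assumes
the $m$ resamplings are independent. They are not: all ten splits reuse
one cohort, each individual appearing in roughly seven discovery
samples. The test suite measures the consequence directly: under a
global null (no genetic effect, n = 400, 200 independent SNPs) the
across-split correlation of the semi-partial $r$ is about 0.35, the
count $n$ is strongly overdispersed relative to Bin(10, ½), and the
fraction of replicates with $p_{\text{exact}} < 0.05$ is near 0.2 rather
than 0.05. When each split is drawn from an independent cohort the test
is calibrated at its nominal level, which the suite also verifies. The
package implements the published procedure faithfully and exposes this
behavior rather than silently repairing it; interpreting
$p_{\text{exact}}$ from overlapping resamplings as a frequentist
p-value overstates the evidence, and the Bonferroni factor does not fix
that.

## Enrichment, association, haplotypes

`univariateAssoc()` is per-SNP additive-model OLS with the same
covariates, Bonferroni-corrected over an explicit test universe (the
published factor is unstated, so `nTests` is an argument defaulting to
the number of SNPs tested).

`enrichmentTest()` counts candidate-gene SNP p-values below a threshold
(0.05 or 0.10) and compares the count with a permutation null built by
drawing random gene sets of the same gene count, keeping every gene's
SNPs intact so intra-gene LD is preserved. The permutation p-value uses
the add-one rule and is never zero. The statistic is an integer count,
so the uniformity of the permutation p under exchangeability is only as
good as the statistic's support is wide; with realistically
heterogeneous gene sizes (a handful to a few hundred SNPs per gene, as
in the mouse-derived candidate panel) the support is wide and the
calibration suite passes a Kolmogorov–Smirnov uniformity check. With
many equally sized tiny genes the p-value becomes visibly discrete —
a property of count statistics, not of the permutation scheme.

`fourGameteBlocks()` partitions position-sorted SNPs into haplotype
blocks by greedy extension: a SNP joins the current block while, for
every pair it forms with block members, the least-frequent of the four
gametes has frequency at most 0.05; strictly above that the pair is
evidence of historical recombination and a new block starts. Gamete
frequencies come from phased haplotypes when available, otherwise from a
two-SNP EM on unphased genotypes. The partition covers every SNP exactly
once.

`emHaplotypeFreqs()` estimates block haplotype frequencies by multinomial
EM with full enumeration of phase-compatible haplotype pairs (practical
to about 15 SNPs; ambiguity grows as $2^{h-1}$ in the number of
heterozygous sites). The log-likelihood is non-decreasing across
iterations; convergence is declared when it changes by less than `tol`
(default 1e-8), and a non-converged run is returned flagged with its
last iterate rather than discarded. Expected per-individual haplotype
dosages from the final posterior sum to 2.

`haplotypeAssociation()` pools haplotypes rarer than 1% and tests the
block by a nested-model F-test: all $H-1$ expected-dosage terms (most
frequent haplotype as reference) added to the covariate-only model form
the omnibus test; single-dosage models give per-haplotype tests. The
ordinal 0–5 binge score is analyzed with the same linear model by
default, matching the source protocol's apparent practice; an ordinal
model is a reasonable alternative but changes the estimand and is out of
scope here. `partialCorr()` residualizes both variables on the
covariates and correlates the residuals, with $n-2-k$ degrees of
freedom.

# The synthetic-data generator

The generator exists so that every downstream stage has a recoverable
truth.

* **Strain tables** (`simulateStrainData()`): strain effects with
  variance $h^2 \sigma^2$, residuals with $(1-h^2)\sigma^2$; defaults
  emulate a 12-strain panel with about ten replicate animals and
  heritability near 0.4, the regime of the motivating study.
* **Expression** (`simulateExpression()`): designated probes reach a
  target strain-level Spearman correlation through a Gaussian copula
  (Pearson latent correlation $2\sin(\pi\rho_S/6)$); targets of exactly
  ±1 use the exact rank construction; all other probes are independent
  noise.
* **Genotypes** (`simulateGenotypes()`): each individual is the sum of
  two independently simulated haplotypes, so LD and four-gamete
  structure are genuine rather than painted onto marginal dosages.
  Along a haplotype the allele at each SNP copies its left neighbor
  with probability $1-2c$ ($c$ the recombination fraction, 0.02 within
  blocks by default) or is drawn fresh at that SNP's frequency; block
  boundaries use $c = 0.5$, i.e. independence. Zero within-block
  recombination yields exact allele copies ($r^2=1$), and the
  theoretical marginal frequency of every SNP (a convex recursion of
  the per-SNP draws) is recorded as `mafTarget`, against which realized
  frequencies converge at large n. Per-SNP frequencies are drawn from
  (0.05, 0.5] by default.
* **Phenotypes** (`simulatePhenotypes()`): additive SNP effects plus a
  3-level site shift, gender and handedness effects, and Gaussian
  noise. Three sites suffice to exercise categorical covariate
  adjustment (the original study had eight; the number is not material
  to any inference the package makes). Effects can be given per-allele
  or drawn and rescaled so the causal SNPs explain an exact variance
  fraction. The ordinal binge score is produced by thresholding a
  latent Gaussian that shares the genetic signal, with cut points
  placed to give a rare, right-skewed 0–5 score (about 90% zeros),
  matching the sparsity of adolescent binge-drinking reports.
* **Task trials** (`simulateTaskTrials()`): multinomial allocation over
  correct/incorrect/omission/premature with the premature probability
  as the parameter of interest; the non-premature mass is split
  0.7/0.1/0.2, an unremarkable session profile.

Reproducibility: every generator takes a mandatory seed and derives a
private substream from it and its stage label, so stage outputs are
bit-identical across runs and independent of each other's draw order.

**What the generator does not emulate:** real marker maps and allele
frequency spectra, genotyping error and missingness mechanisms,
population stratification and cryptic relatedness structure (beyond the
explicit constructions used in the QC tests), dominance or epistasis,
genotype-covariate correlation, and the measurement pipeline behind
imaging phenotypes. Passing tests therefore demonstrate that the
statistical machinery does what it claims under its own assumptions,
not that those assumptions hold in any particular human cohort.

# Problem sizes and numerical choices

The simulation suites use deliberately moderate sizes chosen to give
stable Monte-Carlo assertions: 500 replicates for the heritability mean
(±0.05 band), 200 null pipeline replicates at n = 400 individuals × 200
SNPs for exact-test calibration, 100 replicates at n = 1000 with 50
causal SNPs explaining 5% of variance for power, 500 × 200-permutation
replicates for enrichment calibration. Tolerances follow the binomial or
KS sampling error of those sizes.

Other numerical choices: HWE enumeration in log space with a
$1+10^{-12}$ tie guard; pairwise-complete r² and frequency computations
at QC (no imputation before scoring); EM initialization at uniform
frequencies (the multinomial likelihood for block sizes used here has
shown no local-optimum sensitivity against a direct-optimization
oracle); regression exclusions (monomorphic-in-subsample SNPs) recorded,
not errored; and a hook for an externally supplied ancestry exclusion
list instead of a built-in reference-panel PCA, which would require
external data.

# Known limitations

* The exact combination test's independence assumption is violated by
  design in the published resampling scheme (see the calibration
  caveat above); treat its p-values comparatively, not nominally.
* The EM phasing is exhaustive and limited to short blocks; long blocks
  need an external phaser.
* Enrichment p-values inherit the discreteness of count statistics when
  gene sizes are small and uniform.
* The binge-score analysis uses a linear model on an ordinal scale; the
  latent-model simulation shows it localizes the causal haplotype, but
  effect sizes on that scale have no direct interpretation.
* No genome-wide scan, mixed models, imputation, or binary PLINK
  formats; text formats only.
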