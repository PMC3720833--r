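---
title: "Gene-based association tests over shared sufficient statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based association tests over shared sufficient statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A single-SNP genome-wide association scan tests each variant separately and
can miss genes that harbour several independent, individually sub-threshold
effects.  Gene-based tests aggregate the evidence across all SNPs mapped to
a gene into one statistic and one p-value per gene.  `genetest` implements
six such statistics side by side — GWiS, BIMBAM average Bayes factors,
VEGAS, GATES, MinSNP and MinSNP-Gene — plus a conventional single-SNP scan,
with two deliberate engineering constraints taken from the tools this
package follows:

* every method consumes the same per-gene **sufficient statistic** — the
  centered genotype inner-product matrix $G = X_c'X_c$, the
  genotype–phenotype products $g = X_c'y_c$, and the phenotype sum of
  squares $s_{yy}$ — computed once per gene; and
* every permutation-based method consumes the same seeded **Fisher–Yates
  shuffle stream**, so two methods run on the same data never differ
  because they saw different permutations.

Genes are processed one at a time, so memory scales with the largest gene,
not the chromosome.

## The statistics

**GWiS.** Greedy Bayesian model selection.  A model is a subset of $k$
SNPs allowed non-zero coefficients; the score of a $k$-SNP model with
residual sum of squares $\mathrm{RSS}_k$ is

$$ S(k) \;=\; \frac{n}{2}\ln\frac{s_{yy}}{\mathrm{RSS}_k}
   \;-\; \frac{k}{2}\ln n \;-\; \ln\binom{M_e}{k}, $$

a likelihood-ratio term, a BIC penalty, and a subset-selection penalty in
which $M_e$ is the *effective number of tests* in the gene — computed from
the genotypes alone as $M_e = P - \sum_i \max(\lambda_i - 1, 0)$ over the
eigenvalues of the SNP correlation matrix, clamped to $[1, P]$.  This rule
is phenotype-independent and has the right limits ($M_e = P$ for
uncorrelated SNPs, $M_e = 1$ for perfect copies).  The binomial is
generalized to real $M_e$ through the Gamma function.  Forward search adds
the SNP with the maximal score increase (tracked by incremental
Gram–Schmidt orthonormalization under the $G$ inner product, so each step
is $O(P)$) until no SNP increases the score; exact ties break to the
lowest SNP index, and the model size is capped at $\lceil M_e \rceil$.
For dichotomous traits the likelihood term is replaced by half the
deviance reduction from IRLS logistic fits, with the same penalties.

**BIMBAM.** The gene statistic is the arithmetic mean of the per-SNP
Bayes factors (of the factors, not their logarithms — the distinction
changes the statistic, so it is worth stating).  The single-SNP linear BF
uses the two-column design $(1, x)$ with independent Gaussian priors:
SD $\tau_0 = 10^6$ on the intercept (effectively flat) and an adjustable
$\sigma_a$ (default 0.2 on the dosage scale) on the additive effect.  With
the residual variance fixed at its null maximum-likelihood value
$s_{yy}/n$, the marginal likelihoods are exact Gaussian integrals and the
BF is closed-form; the implementation is validated against adaptive
quadrature of the same integral.  Fixing the residual variance keeps the
statistic a pure function of the sufficient statistics and makes the
$\sigma_a = 0$ limit exact ($\mathrm{BF} \equiv 1$).  For dichotomous
traits the posterior mode of the penalized logistic model is found by
Fletcher–Reeves conjugate gradients (IRLS fallback on stall) and the
marginal likelihood by the Laplace determinant at the mode, validated
against two-dimensional grid integration.

**VEGAS.** The sum of the single-SNP chi-squares in the gene, with
p-values from permutation (genotype data) or multivariate-normal z-score
simulation (summary data).  For $M$ independent null SNPs the statistic is
$\chi^2_M$, which the tests verify.

**GATES.** The extended Simes procedure: with ascending single-SNP
p-values $p_{(1)} \le \dots \le p_{(M)}$,
$P_{\text{gene}} = \min_j \, M_e \, p_{(j)} / M_e(j)$, where $M_e(j)$ is
the effective number of independent p-values among the top $j$ SNPs
(same eigenvalue rule, applied to the leading submatrix of the p-value
correlation matrix).  No permutations are needed.  The p-value correlation
is approximated by the absolute genotype correlation; the estimator enters
only as the input matrix of `gates_m_e()`, so a different mapping can be
substituted without touching the procedure or its tests.  With independent
SNPs $M_e(j) = j$ and GATES reduces exactly to Simes.

**MinSNP and MinSNP-Gene.** MinSNP reports the best per-SNP p-value in
the gene — parametric F tails for common SNPs, empirical permutation
p-values for SNPs with MAF below `maf_switch` (default 0.01, where the
parametric tail is unreliable) — with no gene-size correction.
MinSNP-Gene instead takes the best F statistic as the gene statistic and
ranks it against the permuted max-F null, which corrects for gene size;
on independent SNPs it approaches the Šidák bound $1-(1-p_{\min})^M$.

## Permutations and the null for summary data

Phenotype permutations use a hand-rolled Fisher–Yates shuffle from a
seeded stream; `(seed, n_perm)` fully determines the stream, and thread
decomposition assigns contiguous blocks, so results never depend on the
thread count.  Empirical p-values use the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$, never exactly zero;
the number of permutations is fixed rather than adaptive to honour the
shared-stream guarantee.  With covariates, genotypes and phenotype are
residualized once globally before shuffling (for linear models this equals
joint fitting, by Frisch–Waugh; refitting per gene would cost more and
change nothing).

For summary data there is no phenotype to permute.  Under the null the
single-SNP z-scores of a gene are multivariate normal with correlation
equal to the LD matrix $R$, so null draws are coloured from iid normals
via an LDL factorization $R = LDL'$ (unit lower triangular $L$, diagonal
$D$; pivots below $10^{-10}$ trigger a ridge $R + \epsilon I$ escalating
tenfold from $10^{-8}$ to at most $10^{-2}$, which handles duplicated
SNPs).

### The GWiS permutation gate

Following the reference procedure, genes whose GWiS score is 0 (the null
model wins) skip permutation and report no p-value — they cannot be
significant, and permutations are the expensive step.  For *calibration
studies* this gate must be bypassed: conditioning on a positive score
selects exactly the near-significant tail, whose conditional p-values are
small by construction, so no gated procedure can look uniform.  The
package therefore ranks, when `gate = FALSE`, the continuous forward-search
maximum over non-empty models (sign kept, no floor at zero); under the
global null these p-values are exactly uniform, which the acceptance suite
verifies.  The default remains `gate = TRUE`.

## Summary mode: rebuilding the sufficient statistic

Given per-SNP records $(\beta_j, \mathrm{se}_j, f_j, n_j)$ and the
phenotype moments, the centered products are recovered by inverting the
single-SNP least-squares relations:

$$ S_{xx,j} = \frac{S_{yy}}{\mathrm{se}_j^2 (n-2) + \beta_j^2},
   \qquad S_{xy,j} = \beta_j \, S_{xx,j},
   \qquad S_{yy} = (n-1)\,\mathrm{var}(y). $$

This inversion is exact, so the diagonal of $G$ and the whole of $g$ are
reconstructed to machine precision; only the off-diagonal LD comes from
the reference panel, as $r_{ij}^{\text{panel}}\sqrt{S_{xx,i}S_{xx,j}}$.
(The classical Hardy–Weinberg variance $2f(1-f)$ is exposed through
`cov_from_panel()` and used when the se-based inversion is unavailable.)
Panel haplotypes are fetched through a byte-offset index — one seek per
SNP, no genome-wide correlation matrix ever materializes — and pairwise
correlations are cached per gene and freed when the gene completes.
Panel allele orientation is checked against the study MAF and flipped
when the folded frequencies disagree; this cannot resolve genuinely
ambiguous A/T–C/G SNPs with MAF near 0.5, a known limitation of any
summary-mode analysis.  Case-control summary data uses the linear
approximation throughout, with a logged notice.

With the study itself written out as its own panel (integer dosages split
into pseudo-haplotypes) the reconstruction is exact, and the acceptance
suite confirms that every method's summary-mode statistic matches
genotype mode — at machine precision for GWiS, VEGAS, MinSNP-Gene and
BIMBAM, and on the log10 scale for GATES, where genotype mode uses exact
F tails and summary mode chi-square tails.

## The simulator

`simulate_case_control()` reproduces the package's standard evaluation
design: 500 cases, 5500 controls, 10,000 independent Hardy–Weinberg SNPs
with MAF uniform on (0.05, 0.45), 10 causal SNPs with multiplicative
homozygote relative risk 1.5, baseline prevalence 0.01.  "Multiplicative
risk 1.5 for the homozygotes" is read literally: the per-allele relative
risk is $\sqrt{1.5}$ so the homozygote ratio is 1.5; the per-allele-1.5
alternative is a config switch.  Genotypes for cases and controls are
drawn from the exact conditional genotype distributions implied by the
penetrance model — the same joint law as prospective sampling continued
until both group sizes are reached, without discarding ~99% of draws at
1% prevalence.  `simulate_gene_structure()` tiles SNPs into
non-overlapping genes with lengths uniform on {10..100}; at 10,000 SNPs
this yields ≈182 genes averaging ≈55 SNPs.

`simulate_ld_genotypes()` generates LD-structured dosages from a Gaussian
copula on haplotype alleles.  Naive thresholding attenuates correlation
(the tetrachoric effect), so the latent correlation is calibrated per
pair by numerically inverting the threshold-correlation map (1-D Gaussian
quadrature plus root finding), then eigenvalue-clamped to keep the latent
matrix positive semi-definite; observed dosage correlations land within
±0.05 of the target.

What the simulator does *not* emulate: realistic coalescent haplotype
structure, population stratification, relatedness, genotyping error, or
imputation uncertainty beyond fractional dosages.  Passing tests
therefore demonstrate correctness of the statistics and their null
calibration under clean HWE sampling, not robustness to confounding.

## Numerical choices and defaults

| parameter | default | role |
|---|---|---|
| `flank_bp` | 0 bp | symmetric gene flank for SNP assignment (1-based inclusive coordinates) |
| `eps_collinear` | $10^{-8}\times$ SNP variance | declare a SNP in the span of the selected set (scale-free) |
| IRLS | tol $10^{-8}$, 25 iterations, step-halving | logistic fits; likelihood never decreases |
| separation flag | $\max\lvert\beta\rvert>10$ without convergence | Wald statistics suppressed for that SNP |
| `sigma_a` | 0.2 | prior SD of a SNP effect (BIMBAM), user-settable |
| `tau0` | $10^6$ | effectively flat intercept prior |
| CG | gradient $\infty$-norm $<10^{-6}$, 200 iterations | Fletcher–Reeves mode search |
| `maf_switch` | 0.01 | MinSNP parametric/empirical switch |
| `n_perm` | 1000 genotype mode, $10^6$ summary mode | CLI defaults |
| ridge | $10^{-8}\dots10^{-2}$, floor $10^{-10}$ | LDL degenerate pivots |

Missing dosages are imputed to the per-SNP mean (and counted in a
message); dosages outside $[0,2]$ and duplicate SNP ids within a
chromosome are hard errors.  Monomorphic SNPs are excluded from fits
rather than fitted.  Genes with no SNPs are kept in the report with empty
cells.  Multiple-testing across genes is *not* applied — gene p-values
are reported raw, with `adjust_gene_pvalues()` available on request.

## Validation scale

The test suite validates at desk scale, chosen to keep the full suite
within minutes while leaving each check statistically sharp: oracle
equivalences on genes of 5–10 SNPs (exhaustive subset enumeration up to
8 SNPs); null calibration on 500 genes × 200 permutations (and 2,000
genes for the GATES type-I rate); full-vs-summary consistency on 50
simulated genes at $n = 1000$, the smallest sample size of the original
full-vs-summary comparisons; and the complete 500/5,500 × 10,000-SNP
case-control replica, run end-to-end through the single-SNP scan in each
of 10 replicates for the power sanity check.  The replica itself takes
well under a minute per replicate.

## Known limitations

* Logistic-model permutations refit every shuffle; they are exact but
  slow, as in the original implementations — the linear approximation is
  the practical route for large permutation counts.
* Only single-SNP Bayes factors are averaged (multi-SNP BIMBAM models are
  out of scope), and a single $\sigma_a$ is used rather than a prior grid.
* The GATES p-value correlation estimator is the absolute genotype
  correlation; the published polynomial mapping can be slotted in through
  `gates_pvalue(r_p = ...)`.
* Rare-variant statistics, mixed models and relatedness correction are
  out of scope.
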