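# genetest

Gene-based association tests for genome-wide SNP data, computed over shared
sufficient statistics and a shared permutation stream.

## What it does and who it is for

A single-SNP GWAS tests each variant on its own and can miss genes whose
association is spread over several independent, individually sub-threshold
effects. `genetest` is for statistical geneticists who want to run the
leading gene-based statistics *side by side on identical inputs*: six
gene-level tests plus a conventional single-SNP scan, on either
individual-level genotype dosages (fractional, imputation-ready) or per-SNP
summary statistics with LD reconstructed on demand from a reference
haplotype panel.

Two design rules make the comparison clean:

* all methods consume one per-gene sufficient statistic — `G = Xc'Xc`,
  `g = Xc'yc`, `s_yy` — computed once;
* all permutation methods consume one seeded Fisher–Yates shuffle stream,
  so p-values never differ because two methods saw different shuffles.

## The statistics

| method | gene statistic | p-value |
|---|---|---|
| GWiS | greedy forward model selection maximizing `(n/2)ln(s_yy/RSS_k) − (k/2)ln n − ln C(Me,k)`, with `Me` the effective number of tests from the SNP correlation eigenvalues | permutation |
| BIMBAM | arithmetic mean of single-SNP Bayes factors, Gaussian prior `N(0, sigma_a^2)` on the effect (closed form; Laplace + Fletcher–Reeves for logistic) | permutation |
| VEGAS | sum of single-SNP chi-squares | permutation / MVN simulation |
| GATES | extended Simes: `min_j Me p_(j) / Me(j)` | analytic |
| MinSNP | best per-SNP p (permutation p below MAF 0.01) | itself |
| MinSNP-Gene | best per-SNP F | permutation (max-F null) |

In summary mode the centered products are recovered exactly from
`(beta, se, n)` and the phenotype moments — only the LD off-diagonals come
from the panel — and the permutation null is replaced by multivariate-normal
z-scores coloured through an LDL factorization of the LD matrix.

## Worked example

Simulate a small case-control study (300 cases / 700 controls, 400 SNPs,
4 causal with homozygote relative risk 2.5), tile genes over the SNPs, and
run four methods with 500 shared permutations:

```r
library(genetest)

sim   <- simulate_case_control(sim_config(n_cases = 300, n_controls = 700,
                                          n_snps = 400, n_causal = 4,
                                          hom_risk = 2.5, seed = 7))
genes <- simulate_gene_structure(400, c(10, 40), seed = 8,
                                 positions = sim$block$snps$pos)
scan  <- gene_scan(sim$block, sim$phenotype, genes,
                   methods = c("gwis", "vegas", "gates", "minsnp_gene"),
                   plan = permutation_plan(seed = 9, n_perm = 500))
print(scan)
#> gene scan (genotype mode, linear model): 18 genes, methods: gwis, vegas, gates, minsnp_gene
#> permutations: 500 (seed 9)
#> 72 method-gene results, 15 with p <= 0.05
summary(scan, n = 5)
#> top gene results:
#>   gene_id      method    statistic      p_value n_permutations model_size snp_count
#>  gene0008       gates 4.343330e-10 4.343330e-10              0         16        16
#>  gene0015       gates 4.400557e-07 4.400557e-07              0         15        15
#>  gene0006       gates 5.533904e-04 5.533904e-04              0         32        32
#>  gene0006        gwis 2.358964e+00 1.996008e-03            500          1        32
#>  gene0006 minsnp_gene 1.853640e+01 1.996008e-03            500          1        32
```

The four causal SNPs fall in genes 0004, 0006, 0008 and 0015; three of
those four top the ranking (permutation p-values bottom out at
`1/(n_perm+1) = 1/501 ≈ 0.002`, while the analytic GATES p can go lower).
`model_size` is the number of SNPs a method actually used: GWiS selected a
1-SNP model inside the 32-SNP gene0006. `scan$report` holds the same
results as one wide row per gene; `write_combined_report()` writes it with
provenance headers, and `adjust_gene_pvalues()` appends Bonferroni/BH
columns if you want them.

A thin command-line driver over the same functions ships in
`inst/cli/genetest.R` (`run` and `simulate` subcommands).

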