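# moirank

Rank-based multiple contrast tests for quantitative-trait association when
the mode of inheritance is unknown.

## The problem

Association between a di-allelic marker (genotypes aa / aA / AA, ordered by
risk-allele count) and a quantitative trait is usually tested by linear
regression on genotype scores 0/1/2 — which presumes an additive genetic
model, normal errors and equal variances — or by the Kruskal-Wallis test,
which detects any heterogeneity but identifies no genetic model and yields
no confidence intervals. Both struggle with skewed traits, ordinal scores,
detection-limit censoring, rare-homozygote unbalance and variance
heterogeneity.

`moirank` is for statistical geneticists and biostatisticians analysing
candidate SNPs against such traits. It implements a purely nonparametric
max-T multiple contrast test on **unweighted relative effects**

```
p_i = ∫ G dF_i,   G = (F1 + F2 + F3) / 3,   p1 + p2 + p3 = 3/2,
```

estimated by pseudo-ranks with mid-rank tie handling. Marcus-type contrasts
`c_q' p` test the dominant, additive and recessive models simultaneously
(all-pairs contrasts give a CI-bearing alternative to Kruskal-Wallis);
statistics `T_q = δ̂_q / se_q` are referred to a multivariate t distribution
with estimated correlation `R̂` and Welch-Satterthwaite degrees of freedom,
yielding an equicoordinate critical value, simultaneous confidence
intervals (plain or range-preserving Fisher-transformed) and compatible
max-T adjusted p-values. Everything is invariant under strictly increasing
transformations of the trait and assumes neither normality nor equal
variances. A pairwise-rankings variant (with intransitivity detection) and
the full genotype–phenotype simulation machinery (two-locus LD genotype
model, variance-explained phenotypes, comparator tests) are included.

## Worked example

```r
library(moirank)

d <- generate_fixture("dominant", n = 150, seed = 1)  # id, trait, genotype
fit <- moi_test(d)          # data frame in; Marcus contrasts, t approximation
fit
#> Nonparametric multiple contrast test (marcus contrasts, global ranking)
#> N = 150  n = ( 50, 50, 50 )  alpha = 0.05  approx = t (df = 97.42 )  interval = fisher
#> Relative effects p_hat: ( 0.3349, 0.6224, 0.5427 )
#>   contrast estimate   lower  upper statistic    p_adj
#>   dominant   0.2476  0.1528 0.3379    5.8559 1.34e-07
#>   additive   0.2077  0.0927 0.3173    4.0959 1.94e-04
#>  recessive   0.0640 -0.0423 0.1689    1.3785 3.04e-01
#> Equicoordinate quantile: 2.2898  global p = 1.34e-07  -> reject global null
```

Reading the output: the relative effects say a random aA or AA subject
tends to have higher trait values than a random subject from the "average"
genotype distribution (p̂₂ = 0.62, p̂₃ = 0.54) while aa subjects tend lower
(p̂₁ = 0.33) — the dominant signature this dataset was generated with. The
dominant contrast estimate 0.248 has simultaneous 95% interval
[0.153, 0.338] excluding 0 and adjusted p = 1.3e-07; the recessive interval
covers 0 (p = 0.30). Intervals and p-values can never contradict each
other. `tidy(fit)`, `glance(fit)` and `autoplot(fit)` give a per-contrast
tibble, a one-row summary and a forest plot.

Simulation studies use the same two-step model as the methodology's
evaluation:

```r
sc <- moi_scenario(N = 500, q1 = 0.3, q2 = 0.3, delta = delta_max(0.3, 0.3)/2,
                   h2 = 0, dist = "lognormal", reps = 2000, seed = 1)
run_study(sc, methods = c("np:marcus", "kw", "param_homo:marcus"))
```

A thin CLI wraps the same functions
(`inst/cli/moirank test --input data.tsv ...`, `simulate`, `fixtures`);
TSV and single-SNP VCF input are supported via `read_moi_data()`.

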