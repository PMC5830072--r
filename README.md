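# nonaddscan

Genome-wide scans for **non-additive genetic effects** — dominance,
recessive and overdominance gene action — on continuous traits in related
populations, built for the setting where they matter most: fitness-related
traits such as dairy-bull fertility (Sire Conception Rate, the US national
phenotypic evaluation of service-sire fertility, expressed in percentage
points of conception rate relative to the average evaluated bull).

Standard association scans test only the additive dose–response of an
allele and miss loci whose heterozygote or homozygote classes deviate from
the linear pattern. `nonaddscan` tests each marker under four single-column
genotype codings of the B-allele dosage:

| mode of action | AA | AB | BB |
|---|---|---|---|
| additive       | 0 | 1 | 2 |
| dominance      | 0 | 1 | 1 |
| recessive      | 0 | 0 | 1 |
| overdominance  | 0 | 1 | 0 |

## The model

Relatedness is handled with the animal model
`y = Xβ + Zu + e`, `u ~ N(0, G σ²u)`, `e ~ N(0, I σ²e)`, where `G` is the
genomic relationship matrix (VanRaden method 1) and each individual carries
one record (`Z = I`). Testing every marker with a full mixed-model refit is
needlessly expensive, so the scan is **two-step**:

1. **Null fit** — the model above is fitted once, without any marker, by
   REML (1-D profile of the heritability on the eigenbasis of `G`), giving
   `σ̂²u`, `σ̂²e`, `β̂` and the null covariance `V₀ = G σ̂²u + I σ̂²e`.
2. **Score test** — each coded, mean-centred marker vector `x` is tested
   against the frozen null with

   `z = x′V₀⁻¹(y − Xβ̂) / sqrt(x′V₀⁻¹x)`,

   which approximates the Wald test and is treated as standard normal.
   Equivalently `β = x′V₀⁻¹(y − Xβ̂)/(x′V₀⁻¹x)` and `se = (x′V₀⁻¹x)^(−1/2)`.

Genomic control (median-based λ by default) deflates inflated statistics,
and significance is declared at the Bonferroni threshold `α/m`. Reporting
includes composite-LD `r²` among top markers, genotype-class phenotype
summaries, and Manhattan-ready tables. A synthetic-data generator with
paternal half-sib families, a polygenic term drawn from the realised `G`,
and planted QTLs under any of the four codings makes every stage testable
without proprietary data.

## Worked example

Simulate 600 half-sib bulls (60 sires × 10 offspring), 1,000 markers, one
planted dominance QTL (effect 0.9 phenotype units at marker `snp00137`),
polygenic heritability 0.3; then run the two-step scan:

```r
library(nonaddscan)

cfg <- sim_config(n_sires = 60, offspring_per_sire = 10, n_snps = 1000,
                  qtl_specs = list(qtl_spec(137, "dominance", 0.9)),
                  sigma_u2 = 0.3, sigma_e2 = 0.7, seed = 11)
ds <- simulate_dataset(cfg)

qc <- qc_filter(ds$gm)                        # sex chrom / monomorphic / MAF
nf <- fit_null(ds$y, G = compute_grm(qc$gm))  # step 1: REML null fit
nf
#> null_fit (animal model, REML):
#>   sigma_u2 = 0.3406  sigma_e2 = 0.7377  h2 = 0.3159
#>   restricted logLik = -858.570  converged = TRUE (21 iter)

sc <- genome_scan(qc$gm, ds$y, nf)            # step 2: all four codings
sc
#> scan_result: 1000 markers, models: dominance, recessive, overdominance, additive
#>   lambda: dominance 0.970, recessive 0.858, overdominance 0.996, additive 0.987

results_table(sc, bonferroni_threshold(0.01, 1000))
#>     snp_id chr   pos         model   maf n_AA n_AB n_BB  beta     se p_nonadd    p_add
#> 1 snp00137  21 50000     dominance 0.179  403  179   18 0.773 0.0953 5.17e-16 3.02e-14
#> 2 snp00137  21 50000 overdominance 0.179  403  179   18 0.714 0.0944 3.71e-14 3.02e-14
```

The REML step recovers the simulated variance partition (ĥ² = 0.32 for a
true 0.3), the λ values near 1 show the null covariance has absorbed the
family structure, and the planted QTL is recovered under its true coding
with `β̂ = 0.77 ± 0.10` (true 0.9) at `p = 5 × 10⁻¹⁶` — ahead of the
additive test of the same marker, the signature of non-additive gene
action. The genotype-class summary shows why: carriers (AB, BB) share an
elevated trait mean while the classes differ only between carrier and
non-carrier:

```r
genotype_phenotype_summary(qc$gm, ds$y, "snp00137")
#>   class   n   mean median     q1    q3
#> 1    AA 403 0.0419 0.0588 -0.567 0.627
#> 2    AB 179 0.8259 0.7654  0.183 1.356
#> 3    BB  18 0.8585 0.7145  0.392 1.578
```

The same pipeline runs from the shell over PLINK text files
(`inst/cli/nonaddscan simulate|scan|report --config cfg.yaml ...`), or in
R via `run_simulate()`, `run_scan()` and `run_report()`.

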