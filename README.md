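# admixscreen

Supervised continental-ancestry estimation for clinical carrier
screening, with the downstream statistics that make ancestry clinically
actionable: self-report concordance testing, ancestry-stratified carrier
rates, and residual-risk arithmetic.

## Who this is for

Genetic-testing laboratories and population geneticists who need to

* estimate each patient's continental ancestry proportions against a
  fixed reference panel of population allele frequencies (no cohort
  re-estimation, so single samples are estimable),
* build such a reference panel: QC, LD pruning and two-stage selection
  of ancestry-informative markers (AIMs) by Wright's Fst,
* quantify how unreliable self-reported ethnicity is across intake
  instruments, and
* translate ancestry-dependent carrier rates into residual risks after
  a negative screen.

## The model

For individual *i* with genotype `g_im` (copies of allele 1 at marker
*m*) and fixed population allele frequencies `f_km`, the ancestry vector
`Q_i = (q_i1, ..., q_iK)` on the simplex maximizes

    L(Q_i) = sum_m { g_im * ln(sum_k q_ik * f_km)
                   + (2 - g_im) * ln(sum_k q_ik * (1 - f_km)) }

by expectation-maximization from a uniform start (the supervised
special case of the FRAPPE/ADMIXTURE admixture likelihood; concave in
`Q_i`, so the optimum is unique). Iteration stops when the
log-likelihood improves by less than `epsilon = 0.01`.

AIM selection ranks markers by the fixation index
`Fst = (H_T - H_S) / H_T` on continental-mean frequencies (global
ranking first, then per-pair enrichment); concordance between paired
self-report sources uses the exact binomial McNemar test computed in
log-space; carrier-rate splits at an ancestry percentile use Fisher's
exact test; and the residual carrier risk after a negative screen with
detection rate *d* and carrier rate *c* is `c(1-d) / (1-cd)`, reported
as "1 in N".

## Worked example

Everything below is reproducible — the package ships a simulator that
generates cohorts with exactly the statistical structure the estimator
assumes.

```r
library(admixscreen)

panel  <- simulatePanel(K = 3, M = 400,
                        populationIds = c("African", "European", "East Asian"),
                        seed = 42)
cohort <- simulateCohort(panel, n = 150, dirichletAlpha = 1, seed = 43)
est    <- estimateAncestry(cohort$genotypes, panel)
est
#> AncestryEstimate: 150 samples, K = 3 populations
#>   populations: African, European, East Asian
#>   converged: 150/150 (median 21 iterations)

round(head(ancestryProportions(est), 3), 3)
#>            African European East Asian
#> sample0001   0.247    0.422      0.330
#> sample0002   0.267    0.715      0.018
#> sample0003   0.152    0.044      0.804

mean(abs(ancestryProportions(est) - cohort$Q))   # recovery error vs truth
#> [1] 0.0262
```

Each row is one patient's estimated ancestry composition (rows sum
to 1). The mean absolute error against the simulated truth, 0.026,
is typical for a 400-marker panel; at the full 1142-AIM scale it drops
below 0.02.

Stratify carrier rates by ancestry and compute residual risk:

```r
meta  <- simulateMetadata(cohort$Q, baselineCarrierRate = 0.01,
                          carrierEffect = 4, carrierComponent = "African",
                          disease = "sickle_cell", formNoise = 0.1, seed = 44)
split <- carrierRateSplit(ancestryProportions(est)[, "African"],
                          meta$sickle_cell == "carrier")    # 80th-percentile split
split[c("threshold", "rate_below", "rate_above", "p_value")]
#> $threshold   [1] 0.529
#> $rate_below  [1] 0.0417
#> $rate_above  [1] 0.167
#> $p_value     [1] 0.0279
```

Carriers concentrate above the 80th-percentile African-ancestry
threshold (16.7% vs 4.2%, Fisher p = 0.028) because the simulation
linked carrier odds to that component — the pattern seen for sickle
cell anemia in admixed clinical cohorts.

```r
rr <- residualRisk(carrierRate = 0.01606, detectionRate = 0.72)
sprintf("risk %.5f -> 1 in %d", rr$risk, rr$denominator)
#> [1] "risk 0.00455 -> 1 in 220"
```

A patient from the lower-ancestry stratum who screens negative on a
72%-detection panel retains a 1-in-220 chance of being a carrier.

Exact concordance statistics from paired self-report counts (form,
consult, both):

```r
overlapPercentages(134, 396, 120)
#>   pct_form_in_consult pct_consult_in_form
#> 1                89.6                30.3
mcnemarExact(134 - 120, 396 - 120)
#> [1] 2.627144e-64
```

Only 30.3% of patients who reported this ancestry during a consult had
selected it on the requisition form — massively asymmetric reporting
(exact McNemar p = 2.6e-64 on the 14 vs 276 discordant pairs).

## Command line

A launcher for shell pipelines is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "admixscreen", package = "admixscreen"))')
$CLI simulate  --n-samples 200 --n-markers 1142 --n-populations 6 --seed 7 --out-dir work
$CLI aimselect --panel work/simulated_panel.tsv --genotypes work/simulated_genotypes.tsv --out work/aims
$CLI estimate  --genotypes work/simulated_genotypes.tsv --panel work/aims_panel.tsv --out work/ancestry
$CLI concordance   --metadata work/simulated_metadata.csv --out work/concordance
$CLI carrier-rates --ancestry work/ancestry.tsv --metadata work/simulated_metadata.csv \
                   --disease disease --component African --out work/rates
```

Every subcommand writes a `.config.json` sidecar recording its
parameters, seed and package version.

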