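---
title: "Supervised ancestry estimation and carrier-risk stratification: models and methods"
author: "admixscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised ancestry estimation and carrier-risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixscreen)
```

## The problem

Clinical carrier screening has historically been ordered, and residual
risks quoted, on the basis of a patient's self-reported ethnicity. Two
kinds of quantitative questions follow. First, how consistent are
self-reports across intake instruments (a check-all-that-apply
requisition form versus a genetic counselor's family-history consult)?
Second, when a self-reported group is genetically admixed, how strongly
do carrier rates — and therefore the residual risk after a negative
screen — depend on the individual's actual genetic ancestry?

`admixscreen` implements the statistical machinery for both: a
supervised continental-ancestry estimator, the marker-selection pipeline
that feeds it, and the downstream concordance and carrier-rate
statistics.

## The ancestry model

Each individual $i$ carries a genotype vector $g_{im} \in \{0,1,2\}$,
the number of copies of a designated "allele 1" at biallelic SNP $m$,
over $M$ ancestry-informative markers. A fixed, externally supplied
frequency matrix $F$ gives $f_{km}$, the allele-1 frequency of marker
$m$ in ancestral population $k = 1,\dots,K$. The estimand is
$Q_i = (q_{i1}, \dots, q_{iK})$ on the simplex, where $q_{ik}$ is the
probability that a random allele of individual $i$ originates from
population $k$.

Treating the $2M$ alleles as independent draws from the mixture
frequency $\sum_k q_{ik} f_{km}$, the per-individual log-likelihood is

$$
L(Q_i) = \sum_m \Big\{ g_{im} \ln \big[\textstyle\sum_k q_{ik} f_{km}\big]
 + (2 - g_{im}) \ln \big[\textstyle\sum_k q_{ik}(1 - f_{km})\big] \Big\}.
$$

This is the supervised special case of the classical admixture
likelihood (FRAPPE/ADMIXTURE family): because $F$ is fixed, $L$ is
concave in $Q_i$ and each individual's problem is independent.

### EM updates

The E-step attributes each observed allele copy to source populations:

$$
a_{imk} = \frac{q_{ik} f_{km}}{\sum_p q_{ip} f_{pm}}, \qquad
b_{imk} = \frac{q_{ik} (1 - f_{km})}{\sum_p q_{ip} (1 - f_{pm})},
$$

and the M-step averages the attributions:

$$
q_{ik}^{(n+1)} = \frac{1}{2M} \sum_m
 \big[ g_{im} a_{imk}^{(n)} + (2 - g_{im}) b_{imk}^{(n)} \big].
$$

Iteration stops when $L(Q^{(n+1)}) - L(Q^{(n)}) < \varepsilon$ with
$\varepsilon = 0.01$ by default — a strict tolerance is affordable
precisely because $F$ is not being estimated. `estimateAncestry()`
applies the rule per sample by default (the likelihoods are
independent); a cohort-total mode is available since the stopping rule
can equally be read on the aggregate.

Numerical choices:

* **Initialization** is uniform, $q^{(0)} = (1/K, \dots, 1/K)$. By
  concavity the optimum is unique up to flat directions, so the start
  affects iteration count only.
* **Frequency clamping**: $F$ is clamped to $[\delta, 1-\delta]$ with
  $\delta = 10^{-6}$ so monomorphic markers cannot produce infinite
  logs.
* **Missing genotypes** are excluded from both $L$ and the M-step for
  that sample, with the M-step normalization switched to
  $1/(2 M_{\mathrm{obs}})$, which keeps $Q$ exactly on the simplex. A
  missing call is never imputed as dosage 0 — zero-filling would bias
  $Q$ toward populations where allele 1 is rare. A sample with no
  usable markers is flagged rather than estimated.
* **Degenerate cases**: $K = 1$ converges to $q = (1)$ in one
  iteration; exact ties in `maxAncestralGroup()` break to the first
  population and carry a `tied` flag.

The tests verify the EM guarantee (monotone log-likelihood, simplex
conservation at every iteration on 100 seeded random instances) and, on
small instances ($K \le 3$, $M \le 20$), agreement within $10^{-4}$
log-likelihood with an independent simplex-constrained numerical
maximizer.

## Marker selection

The estimator assumes the markers are informative and independent, so
selection runs in four steps.

1. **Panel/population QC** (`qcFilter`): reference populations with
   allele-frequency coverage below 90% of markers are dropped; markers
   with genotype call rate below 99.9% are dropped; markers still
   missing any frequency are dropped. Both defaults are exposed.
2. **LD pruning** (`ldPrune`): greedy left-to-right removal within a
   fixed-count sliding window (default $R^2 > 0.5$, window 1000
   markers), in the style of plink's pairwise-independence command;
   the later marker of an offending pair is removed. Pairs with fewer
   than two complete observations carry no evidence and are treated as
   $r^2 = 0$. Window semantics are marker-count based (the default
   step is a tenth of the window); genomic-distance windows are not
   implemented.
3. **Continental aggregation** (`continentalFrequencies`): population
   frequencies are averaged, unweighted, within continental groups.
   Because the aggregation is an unweighted mean of frequency tables
   (no sample counts are available for the reference panels), the Fst
   estimator downstream is the Nei-style $G_{ST}$ on group means rather
   than a sample-size-corrected estimator such as Weir–Cockerham.
4. **Two-stage AIM selection** (`selectAims`): stage 1 takes the
   `nGlobal` markers with the highest global
   $F_{ST} = (H_T - H_S)/H_T$ across all groups; stage 2 considers
   every unordered pair of groups and adds, per pair, the `nPerPair`
   markers of highest pairwise Fst not yet selected — this balances the
   panel and sharpens resolution between closely related groups. A
   published panel built this way totals 1142 AIMs, but its
   stage-1/stage-2 split is not public; the defaults (`nGlobal = 600`,
   `nPerPair` chosen to land near the total after deduplication) are
   exposed as configuration, and the reference panel's marker
   identities are deliberately out of scope. Ranking ties break by
   marker id so the selection is deterministic.

## Concordance between self-report sources

For each controlled ethnicity label (a 12-option check-all-that-apply
vocabulary; free-text write-ins map through a synonym table, and a bare
"Other" without clarification is excluded from analysis),
`buildConcordance()` counts $n_{\mathrm{form}}$, $n_{\mathrm{consult}}$
and $n_{\mathrm{both}}$ over samples having both report sources. The
marginal-homogeneity test is McNemar's, driven by the discordant counts
$b = n_{\mathrm{form}} - n_{\mathrm{both}}$ and
$c = n_{\mathrm{consult}} - n_{\mathrm{both}}$, and is computed
**exactly**: under the null the $b + c$ discordant samples are
$\mathrm{Binomial}(b+c, 1/2)$, and the two-sided p doubles the smaller
tail (capped at 1), evaluated in log-space so that p-values near
$10^{-64}$ do not underflow. The exact-binomial variant (rather than
the $\chi^2$ approximation) is the one that reproduces published
clinical tables from their printed count triples including
small-discordance rows, and that equivalence is itself a test in this
package; a "minlike" two-sided rule is exposed as an option. Overlap
percentages are rounded half-up to one decimal, matching table
formatting conventions.

## Carrier rates, stratification and residual risk

Within a self-reported group, `carrierRateSplit()` splits samples at a
threshold on one ancestry component — by default the group's own 80th
percentile, computed by linear interpolation (R quantile type 7; the
method is a declared convention, since published thresholds cannot be
re-derived without the underlying cohort) — into a low stratum
(ancestry $\le$ threshold) and a high stratum ($>$ threshold), and
compares carrier rates with a two-sided Fisher's exact test.
`ancestryByCarrierTest()` compares the ancestry component between
carriers and non-carriers with a two-sided Mann-Whitney U test (exact
for minimum group size $\le 8$ without ties, tie-corrected normal
approximation otherwise).

Residual risk after a negative screen follows Bayes' rule for a panel
that detects a fraction $d$ of carriers in a population with carrier
rate $c$:

$$
\mathrm{risk} = \frac{c\,(1-d)}{1 - c\,d}, \qquad N = \mathrm{round}(1/\mathrm{risk}),
$$

reported as "1 in $N$". This formula reproduces both published cystic
fibrosis residual risks at a 72% detection rate (1/220 at $c = 1.606\%$
and 1/94 at $c = 3.7\%$); note the published figures mix a
full-precision rate (1.606%) with a rounded one (3.7%) — only those
exact inputs return those exact denominators, so both conventions are
documented here rather than silently normalized.

## The synthetic-data generator

`simulatePanel()`, `simulateCohort()` and `simulateMetadata()` generate
data with exactly the statistical structure the estimator assumes:

* frequencies $f_{km} \sim \mathrm{Beta}(0.5, 0.5)$ i.i.d. — U-shaped,
  mimicking an AIM panel where frequencies are pushed toward fixation;
* ancestry $Q_i \sim \mathrm{Dirichlet}(\alpha)$, with $\alpha = 1$ for
  admixed cohorts and $\alpha = 0.1$ for near-pure cohorts;
* genotypes $g_{im} \sim \mathrm{Binomial}(2, \sum_k q_{ik} f_{km})$,
  the estimator's own likelihood, with optional missingness completely
  at random;
* self-report labels equal to the majority ancestry population with
  configurable replacement noise per source, and carrier status from a
  logistic link,
  $\mathrm{logit}\,P(\mathrm{carrier}) = \mathrm{logit}(c_0) + \beta\, q_{ik}$
  (the generative form is a modeling choice; the clinical observation
  it emulates is only a monotone rate–ancestry association).

Because generator and estimator share the likelihood, recovery
experiments are well-posed: at the study scale ($K = 6$, $M = 1142$,
$n = 200$, $\alpha = 1$) the mean absolute error of $\hat{Q}$ against
truth is below 0.03, and error decreases as $M$ grows (checked at
$M \in \{100, 500, 1142\}$ across the suites). External validation on
reference individuals of known origin is emulated by an $\alpha = 0.1$
cohort: for simulated individuals that are themselves near-pure (true
majority component $\ge 0.9$, the analogue of reference panels whose
members have all four grandparents from one group), the maximum
estimated ancestral component matches the simulated majority ancestry
in $\ge 99\%$ of cases. Genuinely admixed individuals (true maximum
component around 0.3–0.55) are excluded from that particular check, as
"the majority ancestry" is not a meaningful target for them.

What the simulator does **not** emulate — and hence what passing tests
do not certify about real data: linkage disequilibrium between markers
(the model assumes independence; real panels approximate it by
pruning), genotyping error, reference-panel misspecification
(frequencies estimated from finite, possibly unrepresentative samples),
and populations poorly described by any of the $K$ reference groups.
Estimates on real cohorts inherit all four caveats.

## Problem sizes and reproducibility

The test suites run the recovery experiment at $n = 200$ samples,
$M = 1142$ markers, $K = 6$ populations (matching the published panel
size), the AIM-selection oracle comparison at 8 groups by 5000 markers,
and the enumeration oracles at their exhaustive-feasible sizes
(McNemar $n \le 20$, Fisher margins $\le 30$, Mann-Whitney group sizes
$\le 7$). All simulation entry points take explicit seeds, and the
whole stack is bit-reproducible given a seed — re-running any CLI
subcommand with identical inputs reproduces outputs exactly.

## Known limitations

* Supervised only: the package never estimates allele frequencies from
  the cohort. Cohorts that are systematically unlike the reference
  panel will be projected onto it regardless.
* No uncertainty quantification on $\hat{Q}$ (no standard errors or
  bootstrap); downstream splits treat $\hat{Q}$ as known.
* Strand-ambiguous (A/T, C/G) markers whose counted alleles disagree
  with the panel are dropped during harmonization rather than
  strand-flipped: without strand metadata a flip cannot be
  distinguished from a strand difference.
* The X chromosome is treated like the autosomes (dosage 0–2);
  male hemizygosity is not modeled.
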