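---
title: "Latent-trait modeling of graded tau pathology and its quantitative-trait genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-trait modeling of graded tau pathology and its quantitative-trait genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauLT)
```

## The problem

Progressive supranuclear palsy (PSP) neuropathology is routinely scored
semi-quantitatively: for each brain region and each of four tau lesion
types — neurofibrillary tangles (NFT), oligodendroglial coiled bodies
(CB), tufted astrocytes (TA) and neuropil threads — a rater assigns
none/mild/moderate/severe (0–3). A panel of 18 regions × 4 lesions gives
72 ordinal items per case. These items are too many, too coarse and too
correlated to serve directly as phenotypes in genetic association
studies. tauLT reduces each case's profile to one (or a family of)
continuous latent severity score(s) and pushes those scores through a
standard quantitative-trait genetics workflow.

## The graded response model

Samejima's graded response model treats each item $i$ as an ordinal
probe of a latent severity $\theta$. The probability of scoring at or
above category $k$ is a two-parameter logistic,

$$P^*_{ik}(\theta) = \frac{1}{1 + e^{-a_i(\theta - b_{ik})}},
\qquad b_{i1} < b_{i2} < \dots < b_{i,K-1},$$

with boundary conventions $P^*_{i0} = 1$ and $P^*_{iK} = 0$; category
probabilities are successive differences $P_{ik} = P^*_{ik} -
P^*_{i,k+1}$. The discrimination $a_i > 0$ measures how sharply the item
separates mild from severe cases; the thresholds $b_{ik}$ locate the
category boundaries on the latent scale.

**Identification.** The latent prior is fixed at $N(0,1)$; scores are
reported on that raw scale (roughly $[-2.5, 2.5]$ in practice) with an
optional z-scoring flag in `buildTraitSet()`. No post-hoc rescaling is
applied.

**Estimation.** `fitGRM()` maximises the marginal likelihood by
Bock–Aitkin EM. The E-step computes each case's posterior weights over a
quadrature grid; the M-step solves one small ordinal-logistic problem
per item by bounded quasi-Newton (L-BFGS-B) with an analytic gradient,
on an unconstrained parameterisation $(\log a,\; b_1,\; \log \Delta b)$
that enforces positivity and threshold monotonicity by construction.
M-steps are warm-started from the previous iterate, so late EM
iterations cost a handful of gradient evaluations.

Numerical choices, all configurable:

* **Quadrature**: 61 equally spaced nodes on $[-7, 7]$ with
  standard-normal weights renormalised to sum to one. The integration
  error is far below reporting precision; validation tests use 10,001
  nodes on $[-8, 8]$ and agree with continuous-integral oracles to
  $10^{-6}$.
* **Convergence**: EM stops when the largest absolute parameter change
  drops below $10^{-4}$, or after 500 iterations (then flagged
  non-converged).
* **Probability floor**: $\varepsilon = 10^{-10}$ inside logarithms and
  information denominators.
* **Starting values**: $a_i = 1$; $b_{ik}$ from inverse-normal
  transforms of the observed cumulative category frequencies.
* **Degenerate items**: an item observed in a single category carries no
  information and is dropped with a warning (an error under
  `strict = TRUE`). Categories never observed are collapsed for fitting
  and the original labels recorded, so reported thresholds keep their
  0–3 meaning.
* **Missing scores** are treated as missing at random: their likelihood
  factor is simply omitted, the standard marginal-ML treatment.

**Scoring.** `eapScores()` returns the expected a posteriori (EAP)
severity and its posterior SD per case. A case with no observed items
falls back to the prior exactly (EAP 0, SD 1). EAP is monotone: raising
any single response never lowers the score (property-tested
exhaustively on small grids).

**Information.** `itemInformation()` implements Samejima's item
information

$$I_i(\theta) = a_i^2 \sum_k
\frac{\left[P^*_{ik}(1-P^*_{ik}) - P^*_{i,k+1}(1-P^*_{i,k+1})\right]^2}{P_{ik}(\theta)},$$

which equals the expected negative curvature of the item
log-likelihood (checked against finite differences). Test information is
the sum over items, and `informationCurveAUC()` ranks regions by the
trapezoid area of their summed information curves over $[-4, 4]$ —
the basis for judging which anatomical structures actually inform the
severity estimate. Regions whose items are nearly constant (e.g. a
structure affected in almost every case, or almost none) rank at the
bottom.

## The phenotype family

`buildTraitSet()` emits 15 phenotypes by default: $\{$NFT, CB, TA,
threads$\}$ × $\{$overall, forebrain, hindbrain$\}$ plus overall /
forebrain / hindbrain traits pooling all lesions. Each phenotype gets
its **own** GRM fit on its item subset rather than a shared fit with
subsetted scoring: scale identification is per model, and the per-lesion
traits are meant to be distinct-but-correlated measures, not projections
of one model. Extra user-defined phenotypes can be appended (`extra=`),
covering workflows that tested 16 rather than 15 traits.

The schema (`pspSchema()`) partitions regions at the
mesencephalic/diencephalic junction: basal nucleus, caudate putamen,
globus pallidus, hypothalamus, motor cortex, subthalamic nucleus,
thalamic fasciculus and ventral thalamus are forebrain; brainstem and
cerebellar structures are hindbrain. Region lists in circulation
enumerate 19 structures while the panel is usually described as 18
regions (72 items); both presets ship, and the 18-region default drops
the oculomotor complex so the item count matches — a configuration
choice with no modelling content. Temporal cortex may be present in a
panel but is excluded from every phenotype's item set: its score
distribution is skewed and incomplete, and excluded items provably never
influence scores (tested by permuting them). Information curves *can*
still be drawn for excluded items; they are never used in scoring.

## Genetics: QC, association, eQTL

* `hweExactTest()` is the exact conditional test on the heterozygote
  count given allele counts; the P value sums probabilities of
  configurations no more probable than the observed one. Variants are
  **retained** when $P \ge \alpha$ — the conventional direction, kept
  even where protocol text can be read the other way. A mid-P option
  exists but is off by default.
* `filterVariants()` / `filterSamples()` apply MAF, missingness, HWE and
  imputation-$R^2$ rules. Array-stage defaults are MAF ≥ 0.1% and
  missingness ≤ 2%; the imputed-stage convention is MAF ≥ 2% with
  $R^2 \ge 0.9$. Filters are idempotent.
* `kingKinship()` implements the KING-robust moment estimator
  $\hat\phi = (N_{Aa,Aa} - 2N_{AA,aa})/(N_{Aa}^{(i)} + N_{Aa}^{(j)})$
  over jointly called hard calls (imputed dosages are rounded within
  0.1, else treated as missing). Duplicates score exactly 0.5. Note the
  estimator needs a few thousand variants before its sampling noise
  drops safely below the third-degree cutoff $2^{-9/2} \approx 0.0442$;
  with only hundreds of variants, chance kinship above the cutoff will
  chain samples into spurious components.
* `pruneRelateds()` resolves the relatedness graph per connected
  component (a consistent generalisation of pairwise resolution),
  keeping the best call rate, ties broken lexicographically —
  deterministic by construction.
* `pcaOutlierLoop()` standardises genotypes by $2p$ and
  $\sqrt{2p(1-p)}$, removes samples beyond 6 SD on any of the top 10
  PCs, and refits, up to 5 iterations (stopping early when nothing is
  removed); the final PCs are returned for covariate use. LD pruning
  before PCA is not applied by default.
* `qtGwas()` is per-variant OLS of the latent trait on allele dosage
  plus covariates (age at death, sex; optionally PCs), complete cases
  per variant, two-sided t tests on residual df. No genomic control.
* `combineStages()` offers the pooled re-fit with a stage indicator
  (default for two-cohort latent-trait analyses) and fixed-effect
  inverse-variance meta-analysis; both are tested against refit/hand
  oracles. `selectStage2Snps()` takes hits below $P < 10^{-5}$ and
  LD-prunes at $r^2 > 0.95$, greedily by ascending P.
* `cisEqtl()` tests variants within ±1 Mb of the gene body (inclusive at
  exactly the boundary, measured from gene start *and* end, 1-based
  inclusive coordinates) by a linear model with covariates; batch
  effects such as flowcell enter as fixed categorical covariates — a
  deliberate simplification of a random-effects formulation, exact under
  balanced designs and deterministic at desk scale. BH q-values are
  computed over all tested pairs with `p.adjust`.

## What the synthetic cohorts emulate — and what they do not

`simulateCohort()` draws per-lesion latent severities from an
exchangeable multivariate normal (correlation 0.6 by default: the four
lesion processes are related but distinct), shifts the targeted factors
additively by planted genotype (per allele) and covariate effects, and
draws item responses from the graded-response probabilities
(discriminations in $[0.8, 2.5]$, thresholds centred in $[-1, 1]$).
Genotypes are Hardy–Weinberg draws at configured MAFs; cohort size
defaults to 882, the scale of a large combined autopsy series; age at
death is $N(74.9, 7.8^2)$ years and sex is Bernoulli(0.46), matching
that cohort's demographics; age/sex effects default to zero so covariate
adjustment can be exercised in both regimes. `simulateRelateds()` builds
duplicate, parent–offspring and full-sib genotype pairs by explicit
gamete draws; `simulateExpression()` adds cis-regulated expression with
Gaussian noise. A `lowInfoRegion` preset makes one region's items
near-constant (discrimination 0.08, thresholds shifted +3) to reproduce
the bottom-of-the-ranking behaviour of uninformative structures. The
truth record closes over every generating parameter, and identical
configs are byte-identical.

Not emulated: realistic LD beyond simple correlated blocks, ancestry
admixture beyond a shifted-frequency outlier subpopulation, rater
drift or systematic missingness in pathology scores, heritable latent
traits within families (related individuals get related genotypes but
independent severities), and RNA-seq count noise (expression is
Gaussian). Passing tests therefore certify the estimators and the
pipeline plumbing under the stated generative model — not robustness to
those real-data complications.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations are sized for a
single-CPU desk run while keeping Monte-Carlo error well inside the
asserted margins: parameter recovery uses 20 replicates of 1,000 cases ×
18 items; null GWAS calibration uses 2,000 variants at n = 400;
planted-effect coverage uses 10,000 regressions at n = 1,000; kinship
expectations use 10,000 SNPs; the exact-HWE sweep enumerates all 23,425
genotype configurations up to n = 50; end-to-end pipeline checks run 150
cases × 5,000 variants.

## Known limitations

* One latent dimension per phenotype; no multidimensional IRT, partial
  credit or nominal models, person-fit or DIF statistics.
* The EM reports but does not fix non-convergence; very small samples
  (a few hundred cases) can need a few hundred iterations at the
  default tolerance.
* eQTL inference is fixed-effects only.
* Case–control association, haplotype tests and external annotation are
  out of scope.
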