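---
title: "Additive and dominance GBLUP: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive and dominance GBLUP: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adgblup)
```

## The problem

Genomic prediction in livestock ranks selection candidates by genetic merit
estimated from genome-wide SNP genotypes. In populations organised as large
paternal half-sib families — a few dozen sires each mated to many dams, one
measured offspring generation — marker-based relationship matrices replace
pedigree relationships, and the question this package is built around is
whether modelling *dominance* (within-locus interaction) variance on top of
additive variance changes variance-component estimates and cross-validated
prediction accuracy.

## Models

For a vector of phenotypes $y$ (one record per animal):

* **MAG** (additive-only): $y = Xb + Zu + e$, with
  $u \sim N(0, G\sigma^2_a)$ and $e \sim N(0, I\sigma^2_e)$.
* **MADG** (additive + dominance): $y = Xb + Zu + Zv + e$, adding
  $v \sim N(0, D\sigma^2_d)$.

$X$ carries the intercept, sex (2 levels) and herd (7 levels in the
motivating population) as treatment-coded fixed effects; the reference level
of each factor is the lexicographically first, and `build_fixed_design()`
refuses rank-deficient designs. $Z$ is the identity here — replicate records
were not available in the motivating study — but prediction for animals
without records flows through the genomic covariances, so no generality is
lost in cross-validation.

## Relationship matrices

With dose $x_{ji} \in \{0,1,2\}$ counting A1 alleles and $p_i$ the A1
frequency at locus $i$ (of $m$), the additive design is the VanRaden
centring $W_{1,ji} = x_{ji} - 2p_i$ and

$$G = \frac{W_1 W_1^\top}{2\sum_i p_i(1-p_i)}.$$

The dominance design uses the classical dominance-deviation coding
$\{A_1A_1, A_1A_2, A_2A_2\} \to \{-2q_i^2,\; 2p_iq_i,\; -2p_i^2\}$
($q_i = 1-p_i$) and

$$D = \frac{W_2 W_2^\top}{4\sum_i p_i^2(1-p_i)^2}.$$

Choices worth stating:

* **Which coding.** The scaling $4\sum p^2q^2 = \sum(2pq)^2$ identifies the
  classical dominance-deviation parameterisation; the coding above has zero
  expectation under Hardy–Weinberg proportions at every $p$ and is symmetric
  under allele relabelling, which makes $G$ and $D$ invariant to which
  allele a chip happens to count. Both invariances are property-tested.
* **Which frequency.** $p_i$ is the frequency of the *counted* allele
  estimated from the post-QC sample, frozen once and reused for $W_1$,
  $W_2$ and both denominators. Forcing $p_i$ to be the minor frequency
  would only flip signs in $W_1$ columns and change nothing in $G$; using
  one consistent snapshot keeps simulation truth and fitted model aligned.
* **Missing genotypes.** A missing dose contributes $0$ to either design —
  exactly the value mean-imputation ($x \to 2p_i$) produces after additive
  centring, and the Hardy–Weinberg expectation of the dominance code. A
  categorical coding has no meaningful value at a fractional imputed dose,
  so the zero convention is used directly. `impute_missing()` (marker-mean
  $2p_i$) remains available for export and inspection.
* **Stabilisation.** A ridge of $10^{-6}$ on the diagonal (recorded in the
  object) keeps the mixed-model coefficient matrix invertible when $n$
  exceeds the effective marker rank; matrices are accumulated in marker
  blocks so the full $n \times m$ design need not be resident, and the
  block size changes results only within floating-point reassociation
  ($10^{-10}$, tested).

## Quality control

Thresholds follow standard SNP-chip practice: marker call rate $\ge$ 95%,
exact Hardy–Weinberg test $p \ge 10^{-6}$, MAF $\ge$ 0.01, individual
missingness $\le$ 10%, autosomes only. The filter order is fixed and
logged — individual missingness, then call rate, MAF, HWE, autosome
restriction — with each marker counted at the first filter that removes it;
order matters for borderline counts, so the report records it. The HWE test
is the exact conditional test on the heterozygote count given allele counts
(the standard SNP-HWE recurrence, no mid-$p$), verified exhaustively against
direct enumeration for all genotype totals up to 50.

## REML estimation

Variance components maximise the restricted log-likelihood
$-\tfrac12[\log|V| + \log|X^\top V^{-1}X| + y^\top P y + (n-p)\log 2\pi]$
with $V = \sigma^2_a G\; (+\; \sigma^2_d D) + \sigma^2_e I$. The optimiser
is average-information (AI) REML with safeguards chosen for small-$n$
ridge-shaped likelihoods:

* **Starting values**: $\sigma^2_e$ = half the phenotypic variance, the
  genetic terms splitting the other half equally; the first step is an EM
  step, after which AI (Newton-type) updates take over.
* **Monotonicity**: an AI update is step-halved toward the current point
  until the restricted log-likelihood does not decrease; if no admissible
  step remains, the monotone EM update is taken instead.
* **Boundaries**: a genetic component whose Newton update turns negative is
  projected onto zero with the Newton step re-solved for the remaining
  components (an active-set move), accepted only if the likelihood does not
  drop. At convergence the score of every pinned component is checked; a
  positive score releases it back into the interior. Pinned components are
  reported as exactly `0.00`, with standard errors still taken from the
  full average-information matrix evaluated at the boundary — the
  convention that matches published variance-component tables that show
  `0.00` with a finite SE. The residual variance is bounded below at
  $10^{-4}\,\mathrm{var}(y)$ rather than zero so $V$ stays positive
  definite.
* **Convergence**: absolute log-likelihood change $< 10^{-8}$ *and* maximum
  relative component change $< 10^{-6}$, at most 200 iterations; the full
  iteration trace is kept on the fit object.
* **Uncertainty**: component SEs are square roots of the diagonal of the
  inverse AI matrix; ratio SEs (heritability $h^2$, dominance proportion
  $d^2$) use the delta method on that matrix. With all genetic variance on
  the total, $h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_d + \sigma^2_e)$ under
  MADG and $\sigma^2_a/(\sigma^2_a+\sigma^2_e)$ under MAG; both ratios are
  always reported separately so no single "ratio" column is ambiguous.

BLUPs solve Henderson's mixed-model equations at the final components,
computed as $\hat u = \sigma^2_a G P y$ (and $\hat v = \sigma^2_d D P y$);
the test suite checks the MME residual directly and cross-checks the whole
engine against `lme4` on grouped data, where a block-diagonal kinship makes
the model an ordinary random-intercept fit.

## Cross-validation

`cross_validate()` reproduces the study design: individuals are randomly
partitioned into $k = 5$ folds of near-equal size (498 animals give folds of
100/100/100/99/99), the partition repeated twice, giving 10 accuracy cells.
For each cell the variance components are re-estimated on the training
records only, BLUPs propagate to the masked animals through the genomic
relationships, and accuracy is the Pearson correlation between predicted
genetic values and the validation phenotypes adjusted by the
*training-estimated* fixed effects ($y - X\hat b$). Choices exposed and
their defaults:

* **Accuracy definition**: adjusted phenotypes by default; correlation with
  raw phenotypes behind `accuracy_def = "raw"` (the source study does not
  state its definition; the adjusted form is the most common in GBLUP
  cross-validation).
* **Scored prediction**: the breeding value $\hat u$ by default (the
  quantity a breeder ranks on); $\hat u + \hat v$ behind
  `score = "total"`.
* **Degenerate cells**: if a training fit pins the scored genetic variance
  at zero, every prediction equals the prior mean and a correlation is
  undefined; such a cell is scored 0 on the grounds that an uninformative
  predictor has no predictive ability. This keeps the null-trait summary
  (mean accuracy $\approx 0$) well defined. A cell whose training fit fails
  to converge is recorded as missing and the summary averages the rest,
  with a warning.
* Fold randomisation is plain uniform — no stratification by herd or sex —
  matching a simple random division; fixed-effect levels absent from a
  training fold are merged into the reference level with a warning.

The summary is the mean and the SE of the mean over the 10 cells.

## The synthetic population

`simulate_founders_and_gametes()` emulates the motivating population's
structure at configurable scale: `sim_scenario()` defaults to 498 offspring
of 26 sires in 7 herds (295 males, 203 females assigned exactly), 8% of
offspring in full-sib pairs (under the study's "<12%" bound), and 5,000
unlinked SNPs with allele frequencies uniform on [0.05, 0.5]. Sires and
dams are drawn from Hardy–Weinberg proportions; each offspring receives one
allele per locus from each parent by independent Mendelian sampling. Dams
are unique except where a full-sib pair shares one; the real study describes
only the sire side, so unrelated dams are the default assumption.

Phenotypes are built generatively as the fitted model's own data-generating
process: marker effects $a_i \sim N(0, \sigma^2_a / 2\sum p q)$ and
$d_i \sim N(0, \sigma^2_d / 4\sum (pq)^2)$ use the *same* codings and
denominators as $G$ and $D$, so the scenario variances are true variances
under the fitted model and parameter recovery is a sharp test rather than an
approximation. Fixed effects default to a male–female difference of 3 trait
units and herd effects evenly spaced on $[-4, 4]$ — systematic effects of
roughly a third to a half of the SL-like trait's residual SD, large enough
that ignoring them would visibly bias the analysis. The default trait
architecture (mean 83.5, $\sigma^2_a = 40$, $\sigma^2_d = 0$,
$\sigma^2_e = 40$) mirrors the staple-length-like setting; dominance-heavy
($0/22.29/8.07$) and null ($0/0/80$) architectures are used alongside it in
the analysis scripts.

What the simulator deliberately does **not** reproduce: linkage and LD
(loci are unlinked, which makes analytic expectations exact but removes the
LD structure real chips have), selection, multi-generation pedigrees, dam
family structure, and genotyping error. Passing tests therefore demonstrate
correctness of the estimation machinery under the stated generative model,
not robustness to real-data artefacts.

## Problem sizes used in the checks

Unit and property tests run on a 180-animal, 600-marker population so the
whole suite stays quick. The acceptance-level checks run at the study's
name-plate scale — 498 animals, 5,000 markers — with 50 replicates for
parameter recovery (95% Wald-interval coverage of
$(\sigma^2_a, \sigma^2_d, \sigma^2_e)$, staple-length-like $h^2$ recovery,
dominance-heavy $d^2$ recovery) and the full 5-fold-twice design for
cross-validation. Three independent null-trait draws are averaged when
checking that a heritability-free trait predicts at zero accuracy, damping
Monte-Carlo error.

## Known limitations

* Wald SEs and the delta method are asymptotic; at $n \approx 500$ the
  coverage of ratio intervals is approximate (the component intervals
  themselves cover at roughly the nominal rate in the recovery study).
* Once the residual floor binds ($\sigma^2_e$ at $10^{-4}\,\mathrm{var}(y)$),
  the model is effectively interpolating; fits in that corner are flagged by
  the boundary indicator and should be read sceptically.
* Dominance variance is weakly identified in half-sib designs — full sibs
  are the main carriers of dominance covariance and they are rare here by
  construction — so MADG standard errors are large at this scale; that is a
  property of the design, faithfully reproduced, not of the estimator.
* The PLINK reader supports the SNP-major PLINK 1 binary dialect only.
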