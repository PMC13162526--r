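---
title: "Genomic prediction for cassava root cyanogenic potential: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction for cassava root cyanogenic potential: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcngp)
```

## The problem

Cyanogenic potential (HCN) of fresh cassava roots is scored on an ordinal
1–9 picrate scale, can only be phenotyped at crop maturity (about twelve
months after planting), and the assay is slow and labor intensive. Genomic
selection replaces late, expensive phenotyping with predictions from
genome-wide SNP markers, so parents can be chosen from one-month-old
seedlings. HCN is an oligogenic trait: two major loci (on chromosomes 14
and 16) explain roughly 7% and 30% of the phenotypic variance, with a small
polygenic tail and appreciable non-additive variation. This architecture is
exactly the regime in which prediction models differ: equal-shrinkage
methods (GBLUP, Bayesian ridge regression) dilute large marker effects,
variable-selection priors (Bayes A/B/C, Bayesian Lasso) concentrate them,
and kernel methods (RKHS) can absorb some non-additive signal.

`hcngp` implements the full two-stage analysis: plot-level trial data are
reduced to clone BLUEs by a linear mixed model, and the BLUEs are the
response for seven whole-genome prediction models compared under repeated
k-fold cross-validation. A gene-dropping simulator supplies data with the
same statistical structure, so every stage is testable without field data.

## Stage 1: from plots to clone BLUEs

The response for a plot is the mean of up to six subsample scores. The
mixed model is

$$y = \mu + \text{clone} + \text{block(trial)} + \text{clone:trial} + \varepsilon,$$

fitted twice by REML (via `lme4`): once with clone fixed, giving the BLUEs
used downstream, and once with clone random, giving the variance components
$(\sigma^2_c, \sigma^2_b, \sigma^2_{cl}, \sigma^2_e)$. Location and year
are folded into a single *trial* factor (location–year combinations),
since trials, not calendar years, are the blocks of the design. Broad-sense
heritability uses the plot-basis formula

$$H^2 = \frac{\sigma^2_c}{\sigma^2_c + \sigma^2_{cl} + \sigma^2_e},$$

deliberately without dividing the interaction and residual terms by the
numbers of locations or replicates; the conventional clone-mean basis would
give larger values, and `broad_sense_H2()` implements the plot-basis form
exactly. Note this means $H^2$ and the narrow-sense heritability estimated
later from BLUEs are on different bases (BLUEs average over trials, which
shrinks their error variance), so $h^2 > H^2$ on simulated data is not a
contradiction.

Ordinal scores are treated as Gaussian throughout, a known mismatch for a
1–9 scale and a documented limitation of this whole family of analyses; no
threshold (probit) model is offered.

## Relationship matrices

`vanraden_grm()` builds $G = ZZ'/(2\sum_i p_i(1-p_i))$ from dosages centered
by twice the allele frequency; frequencies come from the analyzed sample
unless a base-population estimate is supplied. Residual missing calls are
mean-imputed (`impute_and_center()`), which preserves allele frequencies.
$G$ is invariant to marker polarity flips when frequencies are re-estimated,
so the arbitrary choice of counting alternate alleles is harmless. Singular
$G$ (duplicated clones, more clones than markers) is handled by blending,
$G^* = (1-b)G + bI$ with $b = 0.02$ by default — the standard bending that
preserves breeding-value ranking; the blend is recorded on the result.
`kinship_diagnostics()` and `grm_pca()` summarize relatedness and
population structure (full sibs near 0.5, duplicates near the diagonal).

The RKHS kernel is $K_{ij} = \exp(-d_{ij}\theta)$ with $d_{ij}$ the squared
Euclidean distance between dosage profiles divided by the marker count.
The per-marker scaling makes $\theta$ portable across marker counts; with
it, typical between-family distances are $O(1)$ and $\theta = 1$ is a
sensible default (a grid such as $\{0.25, 0.5, 1, 2, 5\}$ can be explored
through the configuration). A single kernel is used; no multi-kernel
averaging.

## Prediction models

* **GBLUP** (`fit_gblup()`): $y = 1\beta + g + \varepsilon$,
  $g \sim N(0, K\sigma^2_g)$, with a distinct residual variance
  $\sigma^2_e$. REML is computed by EM updates in the eigenbasis of $K$
  — monotone in the REML objective, with an Aitken acceleration step that
  is accepted only when it improves the objective — to relative tolerance
  $10^{-6}$. Training values come from the mixed-model equations;
  validation clones are predicted by the Gaussian conditional mean
  $\hat g_v = K_{vt} K_{tt}^{-1} \hat g_t$.
* **Bayesian alphabet** (`fit_bayes()`): one single-site Gibbs core (in
  C++) with the marker-effect prior switched per family — scaled-t
  (Bayes A), spike plus scaled-t (Bayes B), spike plus common-variance
  Gaussian (Bayes C), common Gaussian (BRR), double-exponential via the
  normal–exponential mixture with inverse-Gaussian latent scales (BL).
  Inclusion indicators use the marginal likelihood ratio; marker update
  order is fixed (input order) for reproducibility; chains are
  bit-identical for a fixed seed because all randomness flows through R's
  RNG. $\pi$ (the prior exclusion probability for Bayes B/C) is fixed at
  0.95 by default, matching the oligogenic prior belief, and is
  configurable rather than estimated.
* **RKHS** (`fit_rkhs()`): Gaussian-process regression sampled in the
  whitened eigenbasis of the kernel; with $K = G$ it is the Bayesian
  counterpart of GBLUP (the test suite verifies GEBV correlation > 0.98).

### Priors and the residual scale

The residual variance has a scaled inverse chi-square prior with
`df0 = 5`. The reported analysis also fixes the scale at `S0 = 500`, but
on a 1–9 score the implied prior residual variance (hundreds of
score-units²) is far from any plausible value, and with `df0·S0 = 2500`
added to a residual sum of squares of order $n$ it would swamp the
likelihood. The package therefore accepts `s0 = 500` (or any value)
explicitly but defaults to a data-derived scale with prior mode
$(1-R^2)\,\mathrm{var}(y)$, the convention of standard whole-genome
regression software, with $R^2 = 0.5$. Marker-variance hyperpriors use 5
degrees of freedom with scales derived from $\mathrm{var}(y)$, $R^2$ and
the summed marker variance (divided by $1-\pi$ for the spike models).

Per-iteration narrow-sense heritability is
$\mathrm{var}(Z b)/(\mathrm{var}(Z b) + \sigma^2_e)$, averaged after
burn-in. Defaults are the reported settings: 6000 iterations, 700
burn-in. `chain_diagnostics()` estimates effective sample sizes (Geyer
initial positive sequence) and warns below 100 for the residual variance.

## Cross-validation and accuracy

`make_folds()` partitions the clones uniformly into $k = 5$ folds,
repeated 5 times (25 evaluation cells). Every model is evaluated on the
*same* fold plan, making the comparison paired. Per cell:

* predictive ability $r_a$ = Pearson correlation between validation BLUEs
  and predictions;
* validation-set narrow-sense heritability $h^2_{val}$, estimated by the
  kernel-regression sampler on the validation clones only, with the
  VanRaden $G$ as kernel *for all models* — one consistent denominator
  keeps accuracies comparable across models;
* accuracy $= r_a / \sqrt{h^2_{val}}$. Since variance components are
  sampled positive, $h^2_{val} > 0$ and negative accuracies arise only
  from negative predictive ability.

### A caution on validation-set heritability

At validation-set size (~50 related clones) the genetic/residual split is
weakly identified: most eigenvalues of a family-structured $G$ are similar,
so $\sigma^2_u d_i + \sigma^2_e$ is nearly constant across coordinates and
the likelihood is almost flat along the ratio. The posterior mean then sits
near its prior ($R^2 = 0.5$), moving tens of points between pure-noise and
pure-signal responses rather than spanning (0, 1). The test suite therefore
checks separation and agreement-in-ranking with the REML route rather than
absolute bounds. The same weak identification is visible in full-scale
analyses of this kind, where per-fold $h^2$ can differ wildly between
models fitted to identical folds. For the same reason, posterior-mean
$h^2$ from the whole-genome regressions is left-shifted relative to REML
on family-structured data: in the package's recovery experiments
(`tests/testthat/test-acceptance.R`) REML recovers simulated heritabilities
of 0.20/0.35/0.50 essentially unbiasedly, while the Gibbs posterior mean
under the standard weakly-informative priors lands about 0.01–0.12 low,
with the 0.50 level at the edge of its tolerance band.

## The synthetic study population

`sim_config()` defaults define the emulated conditions:

* **Families.** 12 founders, 25 full-sib families of 12 by gene dropping;
  families sharing a parent are half-sib. Markers are simulated in linkage
  equilibrium: family co-segregation alone supplies the marker–QTL
  correlation that the estimators exploit. Real DArTseq panels have LD,
  which this deliberately does not model; passing tests show the
  estimators work under family-driven covariance, not that they reproduce
  LD-driven accuracy levels.
* **Trait.** One QTL per specified chromosome — chosen as the highest-MAF
  marker there, deterministic given the genotypes — with effects scaled so
  realized variance fractions hit their targets exactly (defaults 0.30 on
  chr16, 0.07 on chr14); a polygenic tail over the remaining markers
  (default 3% of variance), projected onto the QTL-orthogonal complement
  so fractions compose; and a dominance deviation at the QTL (heterozygote
  coding residualized on dosage). The default dominance share of total
  genetic variance is 0.17 = 1 − 0.35/0.42, the non-additive share implied
  by a broad-sense heritability of 0.42 against a narrow-sense 0.35.
* **Trials.** Augmented design per location: 29 blocks of 15 plots with 2
  repeated check clones per block; test clones appear once per location.
  Grand mean 6.1 with location shifts (−0.8, +0.3, +0.5) reproducing a
  low/mid/high site pattern (≈5.3 / 6.4 / 6.6); clone-by-location,
  block and plot residual variances default to 0.15 / 0.10 / 0.40
  score-units², chosen so the plot-basis $H^2$ of the default trait is
  ≈0.42. Six subsample scores per plot add Gaussian noise
  (`subsample_sd = 0.5` — a free parameter; no field estimate of
  within-plot picrate variance exists) and are mapped to the 1–9 scale by
  half-integer cut points (round, then clamp).
* **Determinism.** Identical configuration and seed give bit-identical
  genotypes, traits and trials.

`simulate_clone_values()` provides the clone-level shortcut used by the
recovery and model-comparison experiments: phenotypes with unit variance
whose genetic fraction equals the simulated one, i.e. the idealized BLUE
vector.

## Experiment sizes

The test suite and `scripts/acceptance.R` run the statistical experiments
at sizes chosen for a single CPU: heritability recovery at $n = 300$,
$m = 2000$ over 10 seeds with the paper-default 6000/700 chains; the
model-ordering comparison at $n = 252$, $m = 1000$, 5 folds × 10 seeds
with shortened 1500/300 chains (ordering stabilizes well before full
chain length); the full-pipeline acceptance run at 252 clones, 1000
markers, 3 locations, 25 CV cells for all seven models. On the oligogenic
architecture the suite verifies the expected qualitative ordering — the
equal-shrinkage BRR is the least accurate model, and RKHS is at least as
accurate as GBLUP on average — without asserting any field-data accuracy
values, which depend on LD, population size and trait heritability not
emulated here.

## Known limitations

* Linkage equilibrium between markers; no LD decay, no selection cycles.
* Ordinal scores modeled as Gaussian end to end.
* BLUE standard errors are not propagated into stage 2 (equal weighting),
  matching the two-stage convention.
* Validation-set $h^2$ is weakly identified at fold size; accuracies are
  comparable across models but their absolute scale inherits the
  denominator's prior sensitivity.
* Mean imputation of residual missing calls; no genotype-likelihood or
  haplotype-based imputation.
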