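---
title: "Models and methods: metafounder and UPG single-step evaluation with LR validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(metagblup)
```

# The problem

Small livestock breeds often lack the genotyped reference population that
genomic selection needs, while a closely related large breed runs a mature
genomic evaluation next door. Whether the small breed can borrow accuracy by
joining a combined evaluation depends on three methodological ingredients,
all implemented here:

1. **Population structure**: how differentiated are the breeds (pairwise
   Wright's Fst from allele frequencies), and can genotyped animals be
   assigned to breed strata from a genotype PCA?
2. **Genetic grouping for missing pedigree**: unknown parents are replaced
   either by *unknown parent groups* (UPGs; unrelated, non-inbred phantom
   bases) or by *metafounders*, pseudo-founders whose within- and
   between-base relatedness is encoded in a Γ matrix.
3. **Validation**: the LR method compares "partial" evaluations (focal
   phenotypes removed) with "whole" ones to estimate bias, dispersion and
   accuracy without waiting for progeny data.

The package is a desk-scale re-implementation of this whole chain, driven by
a synthetic-data generator, because the motivating industry datasets
(millions of records) are proprietary.

# Models

For trait 1 the animal model is $y = X\beta + Z_a u + e$; traits 2 and 3 add
correlated maternal genetic effects $u_m$ (of the dam), a maternal permanent
environmental effect (mpe, dam-indexed) and a sire × flock-year interaction
(sfy): $y = X\beta + Z_a u + Z_m u_m + Z_{mpe}\,mpe + Z_{sfy}\,sfy + e$.
The only fixed effect is the contemporary group (flock × year); phenotypes
are assumed pre-adjusted for other known fixed effects, which is the
convention of large national evaluations. The genetic covariance is
$\mathrm{Var}(u, u_m) = G_0 \otimes K$ with $G_0$ the 5 × 5
direct + maternal covariance (direct slots for all three traits, maternal
slots for traits 2–3) and $K$ the relationship over model entities:

* **BLUP-UPG**: the QP-transformed system solves the *total* breeding value
  $u = Qg + u^*$ jointly with random group effects $g$
  ($\mathrm{Var}(g) = G_0 \otimes I$), so the entity precision is
  $\begin{pmatrix} A^{-1} & -A^{-1}Q\\ -Q'A^{-1} & Q'A^{-1}Q + I\end{pmatrix}$.
  Working on $(u, g)$ rather than $(u^*, g)$ keeps each record's incidence a
  single animal column and still returns the group solutions.
* **BLUP-MF**: metafounders enter the pedigree as pseudo-parents with base
  block Γ; the Γ-augmented inverse uses generalised Henderson rules with
  $D_i = a_{ii} - \tfrac14(a_{ss} + a_{dd} + 2a_{sd})$ and $\Gamma^{-1}$ on
  the base block.
* **ssGBLUP**: the genomic information enters as
  $H^{-1} = K^{-1} + \Delta$, where Δ carries $G^{-1} - A_{22}^{-1}$ on the
  genotyped block. Under UPG there are additional coupling blocks
  $-(G^{-1}-A_{22}^{-1})Q_2$ and $Q_2'(G^{-1}-A_{22}^{-1})Q_2$ against the
  group equations; under metafounders there are none, because the groups
  live inside $A_\Gamma$. VanRaden's $G = ZZ'/s$ uses observed allele
  frequencies ($s = 2\sum p_i(1-p_i)$) for UPG and $p = 0.5$ ($s = m/2$) for
  metafounders, and is blended $0.95\,G + 0.05\,A_{22}$ (or
  $A_{\Gamma 22}$) for invertibility.

Variance components are *inputs*, never estimated; this mirrors practice
where official evaluation components are reused.

# Γ estimation

Two routes build the group × group ancestral relationship matrix:

* **GLS**: per-marker base allele frequencies of every group are estimated
  by least squares of the 0/1/2 calls on the group-fraction design,
  $2\hat p_i = (Q'Q)^{-1}Q'm_i$, then
  $\Gamma_0 = \frac{2}{n}\sum_i (2p_i-1)^2$ on the diagonal and
  $\gamma_{kl} = \frac{2}{n}\sum_i (2p_{i(k)}-1)(2p_{i(l)}-1)$ off it. The
  weighting is ordinary least squares — the simplest member of the
  generalised family; pedigree-covariance weighting was considered and not
  implemented because at the package's problem sizes the OLS solve is
  already within the acceptance tolerances and keeps the per-marker solve a
  single cached normal-equations factorisation.
* **Trend**: assumes a linear increase of relationship inside each closed
  population. Within population, cohorts $r \le s$ get
  $\Gamma_0 + (r-1)\,\cdot\,\text{interval}\,\cdot\,2\Delta F_{(\gamma)}$;
  between populations the block is the constant $\gamma_{kl}$. The yearly
  pedigree-inbreeding increase ΔF comes from the linear model
  $f_i = \sum_j q_{ij} b_j + t_i c + \sum_j t_i q_{ij} d_j + e_i$ fitted on
  animals with both parents known. Because the ancestry fractions sum to 1,
  the shared slope $c$ is exactly aliased with the per-population slopes;
  the pivoted fit places it last so it is aliased to zero, consistent with
  its reported "effectively zero, ignored" role. Birth years are centred to
  the earliest year so $b_j$ is the cohort-zero baseline. Non-positive
  $d_j$ estimates (impossible in a closed population) are replaced by the
  mean of the positive ones, and $\Delta F_{(\gamma)} = \Delta F(1 -
  \Gamma_0/2)$ converts to the metafounder scale.

`check_gamma()` enforces symmetry and projects an indefinite Γ to the
nearest PSD matrix by eigenvalue clipping, with a logged maximum
adjustment; deficient eigenvalues are raised to a small positive floor
(default `1e-6`) rather than zero, because the metafounder-augmented
pedigree inverse needs $\Gamma^{-1}$.

# LR validation

Validation animals are the genotyped + phenotyped animals born at or after
the cutoff year; scenarios vary which breed strata contribute genotypes and
phenotypes to the pre-cutoff reference, while phenotypes of non-genotyped
animals (which carry no breed label) are always retained. The partial
evaluation removes all validation phenotypes; the whole evaluation restores
them. One reading of the source design adds only the scenario breed's
validation phenotypes to the whole run; the tables accompanying it show all
validation phenotypes restored, and the package follows the latter (the
canonical LR construction — otherwise the metrics of the other validation
groups would compare two phenotype-free evaluations).

Metrics per validation group: bias $\hat\Delta_p = \bar u_p - \bar u_w$,
dispersion $b_p = \mathrm{cov}(u_w, u_p)/\mathrm{var}(u_p)$, accuracy ratio
$\rho = \mathrm{cor}(u_p, u_w)$, and accuracy
$acc = \sqrt{\mathrm{cov}(u_p, u_w)/\text{den}}$ with
$\text{den} = (1-\bar F + \overline{\mathrm{diag}(QQ')} - \overline{QQ'})\,
\sigma^2_a$ for UPG models and $(1-\bar F)\,\sigma^2_a$ for metafounder
models. $\bar F$ is the *classical* pedigree inbreeding of the focal
animals (a Γ-scaled alternative would change only the overall level);
$\overline{QQ'}$ averages over the focal rows only — the source is
ambiguous on this point and the focal-only choice matches the
"focal individuals" wording of the denominator. $\sigma^2_{a,\infty}$ is
taken equal to $\sigma^2_a$, which slightly understates accuracy under
selection but cancels in comparisons. Confidence intervals treat focal
animals as unrelated with equal accuracy: the slope CI comes from the OLS
regression of $u_w$ on $u_p$, the bias CI from the paired-difference
standard error.

# The synthetic generator

`sim_config()` encodes the study conditions: seven founder populations (six
large-breed lines, one small breed) drifted from shared ancestral
frequencies with per-population $F$ chosen so pairwise Fst spans roughly
0.002–0.05; birth years spanning four 5-year cohorts; directed crossing
(small-breed sires on a slice of the large breed's ewes) producing an
admixed stratum; a fraction of dams unrecorded *in the pedigree only* (the
genetic dam still transmits alleles, so recorded-pedigree quantities are
estimates, as in field data); and genotyping concentrated in recent
cohorts. Three traits follow the heritability pattern 0.74/0.57/0.38 with
maternal genetic, maternal permanent environmental and sire × flock-year
components on traits 2–3; phenotypic variances are 1 per trait, so
components are directly interpretable as proportions. Mating is random
(no selection), which is what makes the LR calibration properties
(Δp ≈ 0, b ≈ 1) hold as testable ground truth.

True breeding values have two parts: a **marker-determined component**
(default 95 % of additive variance) built from per-marker effects on the
simulated panel, centred at the ancestral frequencies — the standard
shortcut when no linkage map is simulated (the panel *is* the causal
genome), which gives genomic prediction a real signal and makes the LR
accuracy estimator agree with realized accuracy. The default share mirrors
the 0.95/0.05 blend of the single-step covariance, so the fitted models
are correctly specified for the generated data — the right setting for
*calibration* studies; lower shares probe robustness instead. The rest is
a **pedigree-polygenic remainder** generated by the mendelian-sampling
recursion $u_i = \tfrac12 u_s + \tfrac12 u_d + \phi_i$,
$\phi_i \sim N(0, G_0 D_i)$, whose cost is linear in pedigree size (a
Cholesky of A would not be). What the generator does *not* emulate:
linkage and LD structure, genotyping error, selection and assortative
mating, overlapping-generation demography, trait recording gaps. Passing
tests therefore demonstrate internal consistency of the estimators under
the stated model, not robustness to those real-data features.

# Numerical choices

* Sparse Cholesky (CHOLMOD via Matrix) is the default solver, with a
  Jacobi-preconditioned conjugate gradient (relative residual `1e-10`)
  used automatically above 150 000 equations; both are tested to agree.
* Classical pedigree inbreeding uses a Meuwissen–Luo style ancestor-tracing
  algorithm; the Γ-augmented relationship uses a dense tabular recursion
  gated at 8 000 entities, because its sparse inverse needs every parent
  pair's relationship under the Γ base. Package problem sizes (hundreds to
  a few thousand animals) sit well below the gate.
* Least-squares base frequencies are clipped to [0, 1] (the solve can exit
  the parameter space on sparse designs); the clip count is reported.
* The Mendelian-conflict marker filter removes a marker when opposing
  homozygotes occur in more than 1 % of checkable parent–offspring pairs
  (the source states removal but no rate; 1 % is configurable).
* PCA boundary constants of the published breed-assignment inequalities are
  data-specific (PCA axes are sign- and scale-indeterminate), so the
  synthetic pipeline fits its own: a Fisher discriminant direction between
  labelled purebreds and offsets at quantile midpoints between adjacent
  groups.
* The `c` tolerance of the inbreeding-trend fit is `1e-3` per year;
  `c` is aliased to zero whenever ancestry fractions sum to one.
* The UPG ssGBLUP uses the classical $A_{22}$ by default; a group-augmented
  variant ($A_{22} + Q_2Q_2'$) sits behind `a22_grouped`.

# Problem sizes used in the shipped checks

The test suite exercises the estimators at the largest sizes that keep the
whole suite comfortably interactive: dense-oracle equivalence at 120–300
animals, the no-genotype reduction at 2 000 animals, Γ recovery at 7
populations × 5 000 markers with ≥ 500 genotyped animals per population, LR
calibration on 20 replicates of 3 000 animals (1 600 causal markers, h² =
0.38, complete pedigree, ~2 200 genotyped), and the two-breed headline
comparison on 10
replicates with a ~10:1 reference-size ratio. These sizes are the package's
chosen study conditions, scaled from the motivating industry design while
preserving its structure (reference imbalance, crossbred stratum, missing
dams, recent-cohort genotyping).

# Known limitations

* No REML/Gibbs variance-component estimation, no dominance, no APY-style
  approximations for very large genotype sets.
* Dense steps (A22 extraction, G inversion, Γ-augmented recursion) cap the
  practical scale at a few thousand genotyped animals.
* UPG accuracy denominators assume the focal-rows-only averaging
  convention; if group fractions vary strongly *within* a validation group
  the alternative convention could shift accuracies by a few points.
* The generator's unlinked causal markers make genomic prediction slightly
  more effective per marker than a linked genome of equal size would be;
  directional comparisons between models are unaffected.
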