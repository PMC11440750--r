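# metagblup

Single-step genomic evaluation of closely related livestock populations
with **metafounders** or **unknown parent groups (UPGs)**, validated by the
**LR method** — a desk-scale, fully tested pipeline for the situation where
a small breed (few genotypes) considers joining the combined genomic
evaluation of a large, closely related breed.

The package is aimed at quantitative geneticists and breeding-program
analysts who want to study — on transparent synthetic data — how reference
population composition, genetic grouping (UPG vs metafounder) and
pedigree-vs-genomic information interact in multi-breed single-step BLUP.

## What it implements

* **Synthetic populations** (`sim_config()`, `simulate_population()`):
  multiple founder lines drifted from shared ancestral allele frequencies,
  directed crossing producing an admixed stratum, unrecorded dams, 5-year
  birth cohorts, recent-cohort genotyping, and three maternally structured
  traits with heritabilities 0.74 / 0.57 / 0.38.
* **Population structure** (`fst_matrix()`, `genotype_pca()`,
  `assign_breed()`): pairwise Wright's Fst
  $\widehat{F}_{st} = \frac{\frac1n\sum_i (p_i' - p_i)^2}
  {\frac1n\sum_i [p_i'(1-p_i) + p_i(1-p_i')]}$, genotype PCA, and
  PCA-boundary breed assignment (`PC2 - a\,PC1 + c \gtrless 0`).
* **Genetic grouping** (`assign_groups()`, `estimate_gamma_gls()`,
  `build_gamma_trend()`): metafounders/UPGs per population × 5-year cohort;
  Γ estimated per marker from base allele frequencies
  ($2\hat p = (Q'Q)^{-1}Q'm$, $\Gamma_0 = \frac2n\sum(2p_i-1)^2$,
  $\gamma_{kl} = \frac2n\sum(2p_{i(k)}-1)(2p_{i(l)}-1)$) or built from a
  linear inbreeding trend ($\Delta F_{(\gamma)} = \Delta F(1-\Gamma_0/2)$).
* **Relationship matrices** (`a_inverse()`, `a_gamma()`, `g_vanraden()`,
  `h_inverse_upg()`, `h_inverse_mf()`): sparse pedigree inverses with
  inbreeding, Γ-augmented pedigree (metafounders as pseudo-parents),
  VanRaden G under observed or 0.5 allele frequencies with 0.95/0.05
  blending, and both single-step H-inverses (QP/UPG block form and the
  metafounder form).
* **Mixed-model equations** (`run_evaluation()`): multitrait Henderson
  systems with contemporary group, direct + maternal genetics, maternal
  permanent environment and sire × flock-year terms; sparse Cholesky or
  preconditioned conjugate-gradient solving; six model variants
  (BLUP/ssGBLUP × UPG/MF-GLS/MF-Trend).
* **LR validation** (`make_scenario_datasets()`, `lr_metrics()`,
  `run_scenario_grid()`): partial/whole evaluations per reference-
  composition scenario; bias $\hat\Delta_p$, dispersion $b_p$, accuracy
  ratio $\rho$, and accuracy
  $acc = \sqrt{\mathrm{cov}(\hat u_p, \hat u_w)/(1-\bar F+\overline{\mathrm{diag}(QQ')}-\overline{QQ'})\sigma^2_a}$
  (UPG) or $\sqrt{\mathrm{cov}(\hat u_p, \hat u_w)/(1-\bar F)\sigma^2_a}$
  (metafounders), with regression-based confidence intervals.

## Worked example

```r
library(metagblup)

vc1 <- varcomp(matrix(0.38, dimnames = list("dir1", "dir1")),
               matrix(numeric(0), 0, 0), matrix(numeric(0), 0, 0),
               matrix(0.62, dimnames = list("t1", "t1")))
cfg <- sim_config(n_populations = 2, pop_names = c("M", "D"),
                  drift_F = c(0.015, 0.035), n_markers = 600,
                  years = 2006:2019, n_flocks_per_pop = c(5, 1),
                  n_per_year_per_flock = 30,
                  crossing_rates = matrix(c(0.85, 0.15, 0, 1), 2, 2, byrow = TRUE),
                  missing_dam_rate = 0.2, genotyped_from_year = 2011,
                  varcomp = vc1, seed = 701)
pop <- simulate_population(cfg)
pop
#> sim_population: 2520 animals, 1620 genotyped, 600 markers, 2 populations

ds  <- list(pedigree = pop$pedigree, phenotypes = pop$phenotypes,
            genotypes = pop$genotypes)
gd  <- assign_groups(pop$pedigree)          # population x 5-year cohorts
frac <- pop$population_fractions[match(pop$genotypes$animal_ids,
                                       pop$pedigree$id), "D"]
truth <- ifelse(frac >= 0.875, "D", ifelse(frac <= 0.125, "M", "C"))
pca <- genotype_pca(pop$genotypes, 2)
lab <- do.call(assign_breed, c(list(scores = pca),
                               fit_breed_boundaries(pca, truth)))

grid <- run_scenario_grid(
  ds, list(scenario_def("All", 2018), scenario_def("D", 2018)),
  list(blup = model_spec("blup", "upg", groupdef = gd, traits = 1),
       ssg  = model_spec("ssgblup", "upg", groupdef = gd, traits = 1)),
  lab, vc1, trait = 1)
subset(grid, validation_group == "D",
       select = c(scenario, model, n_focal, delta_p, b_p, rho, acc))
#>    scenario model n_focal delta_p   b_p   rho   acc
#> 3     D-All  blup      66  0.0165 0.846 0.682 0.461
#> 6     D-All   ssg      66  0.0485 0.901 0.914 0.805
#> 9       D-D  blup      66  0.0492 0.834 0.671 0.457
#> 12      D-D   ssg      66  0.0135 0.835 0.778 0.643
```

Reading the numbers: for the small breed's 66 validation animals the
single-step model with the combined reference (`D-All`, row `ssg`) is the
most accurate (0.805), the small-breed-only reference loses accuracy
(0.643), and pedigree BLUP trails both (≈ 0.46 either way). Biases are
near 0 and slopes near 1 — calibrated predictions, as expected under
random mating (single replicates wander; the test suite checks these
properties over 10–20 replicates).

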