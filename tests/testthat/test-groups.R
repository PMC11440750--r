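test_that("group assignment counts cohorts per population correctly", {
  ped <- data.frame(id = 1:20, sire = 0, dam = 0,
                    year = rep(1960:1969, 2), pop = rep(c("A", "B"), each = 10))
  gd <- assign_groups(ped, interval_years = 5)
  expect_equal(nrow(gd$groups), 4)            # 2 cohorts per population
  gd1 <- assign_groups(ped, interval_years = 10)
  expect_equal(nrow(gd1$groups), 2)           # interval = span: one each

  # counting oracle over populations with different spans, incl. a
  # short-lived one that keeps a single group
  set.seed(31)
  spans <- list(A = 1960:1979, B = 1970:1981, C = 1980:1982)
  ped2 <- do.call(rbind, lapply(names(spans), function(p)
    data.frame(sire = 0, dam = 0, year = sample(spans[[p]], 30, TRUE), pop = p)))
  ped2 <- data.frame(id = seq_len(nrow(ped2)), ped2)
  gd2 <- assign_groups(ped2, 5)
  expected <- sum(sapply(names(spans), function(p) {
    yr <- ped2$year[ped2$pop == p]
    span <- diff(range(yr)) + 1
    if (span <= 5) 1 else ceiling(span / 5)
  }))
  expect_equal(nrow(gd2$groups), expected)
  expect_equal(nrow(gd2$groups[gd2$groups$pop == "C", ]), 1)
  expect_error(assign_groups(transform(ped, year = NA)), "year")
})

test_that("group fractions: founders, half-unknown parents, recursion oracle", {
  ped <- data.frame(id = 1:4, sire = c(0, 0, 1, 1), dam = c(0, 0, 0, 3),
                    year = c(1960, 1960, 1972, 1974),
                    pop = c("A", "A", "A", "A"))
  gd <- assign_groups(ped, 5)     # cohorts 1960-64 / 65-69 / 70-74
  Q <- group_fractions(ped, gd)
  expect_equal(unname(rowSums(Q)), rep(1, 4))
  expect_equal(unname(Q[1, ]), c(1, 0, 0))    # founder -> own cohort group
  # animal 3: known sire (group-pure cohort 1), unknown dam in cohort 3
  expect_equal(unname(Q[3, ]), c(0.5, 0, 0.5))

  ped2 <- random_pedigree(50, n_founders = 8, missing_dam = 0.25, seed = 32,
                          years = 1990:2009)
  ped2$pop <- "P"
  gd2 <- assign_groups(ped2, 5)
  Q2 <- group_fractions(ped2, gd2)
  cohort_of <- function(i) {
    g <- gd2$groups
    tail(which(g$year_lo <= ped2$year[i]), 1)
  }
  orc <- oracle_fractions(ped2, gd2$groups$group, cohort_of)
  expect_equal(unname(Q2), unname(orc))
})

test_that("base allele frequencies solve the ancestry least-squares system", {
  set.seed(33)
  # purebred-only: collapses to per-population means / 2
  calls <- rbind(matrix(rbinom(40 * 30, 2, 0.3), 40, 30),
                 matrix(rbinom(30 * 30, 2, 0.7), 30, 30))
  g <- genotype_set(calls, animal_ids = 1:70)
  Q <- cbind(A = rep(c(1, 0), c(40, 30)), B = rep(c(0, 1), c(40, 30)))
  P <- base_allele_frequencies(g, Q)
  expect_equal(unname(P["A", ]), unname(colMeans(calls[1:40, ]) / 2))
  expect_equal(unname(P["B", ]), unname(colMeans(calls[41:70, ]) / 2))

  # admixed rows: matches a dense normal-equations oracle per marker
  Qa <- rbind(Q, cbind(A = runif(20, 0.2, 0.8), B = 0))
  Qa[71:90, "B"] <- 1 - Qa[71:90, "A"]
  calls_a <- rbind(calls, matrix(rbinom(20 * 30, 2, 0.5), 20, 30))
  ga <- genotype_set(calls_a, animal_ids = 1:90)
  Pa <- base_allele_frequencies(ga, Qa)
  for (j in c(1, 15, 30)) {
    beta <- solve(t(Qa) %*% Qa, t(Qa) %*% calls_a[, j]) / 2
    expect_equal(unname(Pa[, j]), pmin(pmax(as.vector(beta), 0), 1))
  }
  # single population: plain mean / 2
  P1 <- base_allele_frequencies(g, matrix(1, 70, 1, dimnames = list(NULL, "A")))
  expect_equal(unname(P1[1, ]), unname(colMeans(calls) / 2))
  # unrepresented population named in the error
  expect_error(base_allele_frequencies(g, cbind(Q, C = 0)), "C")
})

test_that("ancestral relationship formulas reproduce hand-evaluated values", {
  expect_equal(gamma_ancestral(c(0.5, 0.5)), 0)
  expect_equal(gamma_ancestral(c(0, 1, 0)), 2)
  expect_equal(gamma_ancestral(c(0.2, 0.8)), 0.72)
  expect_equal(gamma_between(c(0.2, 0.8), c(0.8, 0.2)), -0.72)
  expect_equal(gamma_between(c(0.5, 0.5), c(0.1, 0.9)), 0)
  set.seed(34)
  p <- runif(40); q <- runif(40)
  expect_equal(gamma_between(p, p), gamma_ancestral(p))
  expect_gte(gamma_ancestral(p), 0); expect_lte(gamma_ancestral(p), 2)
  expect_gte(gamma_between(p, q), -2); expect_lte(gamma_between(p, q), 2)
})

test_that("inbreeding trend fit: exact interpolation, replacement rule, LS oracle", {
  # one pure population, noiseless f = 0.001 * t
  ped <- data.frame(id = 1:40, sire = c(0, 0, rep(1, 38)),
                    dam = c(0, 0, rep(2, 38)), year = 1960 + (0:39))
  Q <- matrix(1, 40, 1, dimnames = list(NULL, "P"))
  f <- 0.001 * (ped$year - 1960)
  fit <- fit_inbreeding_trend(ped, Q, F = f)
  expect_equal(unname(fit$d["P"]), 0.001, tolerance = 1e-10)
  expect_equal(unname(fit$delta_f["P"]), 0.001, tolerance = 1e-10)
  expect_false(fit$c_used)

  # replacement rule: raw slopes (-0.001, 0.002, 0.004)
  set.seed(35)
  n <- 120
  pop <- rep(c("A", "B", "C"), each = 40)
  ped3 <- data.frame(id = 1:n, sire = rep(c(0, 1), c(6, n - 6)),
                     dam = rep(c(0, 2), c(6, n - 6)),
                     year = 2000 + rep(0:19, 6))
  Q3 <- model.matrix(~ 0 + pop); colnames(Q3) <- c("A", "B", "C")
  t3 <- ped3$year - 2000
  d_true <- c(A = -0.001, B = 0.002, C = 0.004)
  f3 <- 0.01 + d_true[pop] * t3
  fit3 <- fit_inbreeding_trend(ped3, Q3, F = f3)
  expect_equal(unname(fit3$delta_f), c(0.003, 0.002, 0.004), tolerance = 1e-9)

  # noisy mixed-ancestry fixture vs dense normal-equations oracle (without
  # the aliased shared slope)
  set.seed(36)
  Qm <- cbind(A = runif(n), B = 0); Qm[, "B"] <- 1 - Qm[, "A"]
  fm <- 0.01 * Qm[, "A"] + 0.002 * t3 * Qm[, "A"] + 0.004 * t3 * Qm[, "B"] +
    rnorm(n, 0, 0.002)
  fitm <- fit_inbreeding_trend(ped3, Qm, F = fm)
  X <- cbind(Qm, Qm * t3)
  both <- ped3$sire != 0
  beta <- solve(t(X[both, ]) %*% X[both, ], t(X[both, ]) %*% fm[both])
  expect_equal(unname(fitm$b), unname(beta[1:2]), tolerance = 1e-8)
  expect_equal(unname(fitm$d), unname(beta[3:4]), tolerance = 1e-8)
})

test_that("metafounder-scale inbreeding increase follows the scale relation", {
  expect_equal(delta_f_gamma(0.01, 0.5), 0.0075)
  expect_equal(delta_f_gamma(0.02, 0), 0.02)
  expect_equal(delta_f_gamma(0.02, 2), 0)
  expect_error(delta_f_gamma(-0.01, 0.5))
})

test_that("trend Gamma reproduces the printed block structure", {
  ped <- data.frame(id = 1:30, sire = 0, dam = 0,
                    year = rep(2000:2014, 2), pop = rep(c("K", "L"), each = 15))
  gd <- assign_groups(ped, 5)    # 3 cohorts each
  g0 <- c(K = 0.48, L = 0.60)
  gb <- matrix(c(0.48, 0.30, 0.30, 0.60), 2, 2, dimnames = list(c("K", "L"), c("K", "L")))
  dfg <- c(K = 0.001, L = 0)
  gm <- build_gamma_trend(gd, g0, gb, dfg)
  Kb <- gm$values[1:3, 1:3]
  expect_equal(unname(Kb), matrix(c(0.48, 0.48, 0.48,
                                    0.48, 0.49, 0.49,
                                    0.48, 0.49, 0.50), 3, 3))
  # zero increase: constant block
  expect_equal(unname(gm$values[4:6, 4:6]), matrix(0.60, 3, 3))
  # between-population block is the constant cross-relationship
  expect_equal(unname(gm$values[1:3, 4:6]), matrix(0.30, 3, 3))
  expect_equal(gm$values, t(gm$values))
  # within-population diagonal is monotone non-decreasing
  expect_true(all(diff(diag(Kb)) >= 0))

  # single-cohort population: 1x1 block at gamma0
  ped1 <- data.frame(id = 1:10, sire = 0, dam = 0, year = 2000:2009, pop = "K")
  gd1 <- assign_groups(ped1, 10)
  gm1 <- build_gamma_trend(gd1, c(K = 0.5), matrix(0.5, 1, 1, dimnames = list("K", "K")),
                           c(K = 0.002))
  expect_equal(unname(gm1$values), matrix(0.5, 1, 1))
})

test_that("GLS Gamma recovers simulated base relationships", {
  cfg <- sim_config(n_populations = 3, pop_names = c("A", "B", "C"),
                    drift_F = c(0.02, 0.04, 0.08), n_markers = 2000,
                    years = 2000:2005, founder_years = 6, n_flocks_per_pop = 2,
                    n_per_year_per_flock = 20, crossing_rates = diag(3),
                    genotyped_from_year = 2000, missing_dam_rate = 0, seed = 37)
  pop <- simulate_pedigree_genotypes(cfg)   # founders only, all genotyped
  Q <- pop$population_fractions[match(pop$genotypes$animal_ids, pop$pedigree$id), ]
  gm <- estimate_gamma_gls(pop$genotypes, Q)
  truth <- pop$founder_freqs$pop
  for (p in c("A", "B", "C"))
    expect_lt(abs(gm$values[p, p] - gamma_ancestral(truth[p, ])), 0.05)
  expect_lt(abs(gm$values["A", "B"] - gamma_between(truth["A", ], truth["B", ])), 0.05)

  # all animals on one group: the plug-in solve collapses to the pooled
  # ancestral relationship (sampling-variance correction disabled)
  Q1 <- matrix(1, nrow(Q), 1, dimnames = list(NULL, "all"))
  gm1 <- estimate_gamma_gls(pop$genotypes, Q1, bias_correction = FALSE)
  expect_equal(unname(gm1$values[1, 1]),
               gamma_ancestral(colMeans(pop$genotypes$calls) / 2))
  expect_error(estimate_gamma_gls(pop$genotypes, cbind(Q, D = 0)), "D")
})

test_that("lightly represented groups estimate Gamma with more variance", {
  reps <- sapply(1:6, function(s) {
    cfg <- sim_config(n_populations = 2, pop_names = c("A", "B"),
                      drift_F = c(0.03, 0.03), n_markers = 400,
                      years = 2000:2003, founder_years = 4, n_flocks_per_pop = 2,
                      n_per_year_per_flock = 25, crossing_rates = diag(2),
                      genotyped_from_year = 2000, missing_dam_rate = 0, seed = 400 + s)
    pop <- simulate_pedigree_genotypes(cfg)
    gids <- pop$genotypes$animal_ids
    lab <- pop$pedigree$pop[match(gids, pop$pedigree$id)]
    keep <- c(gids[lab == "A"], gids[lab == "B"][1:2])  # 2 animals only for B
    g2 <- genotype_set(pop$genotypes$calls[match(keep, gids), ], keep)
    Q <- cbind(A = as.numeric(lab[match(keep, gids)] == "A"),
               B = as.numeric(lab[match(keep, gids)] == "B"))
    gm <- estimate_gamma_gls(g2, Q)
    truth <- pop$founder_freqs$pop
    c(big = gm$values["A", "A"] - gamma_ancestral(truth["A", ]),
      small = gm$values["B", "B"] - gamma_ancestral(truth["B", ]))
  })
  # estimation error (vs true base frequencies) much larger for the group
  # represented by 2 animals than for the one with ~100
  expect_gt(mean(reps["small", ]^2), mean(reps["big", ]^2))
})

test_that("Gamma validation projects indefinite matrices and keeps valid ones", {
  gd_ok <- matrix(c(0.5, 0.3, 0.3, 0.5), 2, 2)
  expect_equal(check_gamma(gd_ok)$values, (gd_ok + t(gd_ok)) / 2)
  bad <- matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2)   # eigenvalues 1.0, -0.8
  expect_warning(fixed <- check_gamma(bad, floor = 0), "projected")
  ev <- eigen(fixed$values, symmetric = TRUE)$values
  expect_gte(min(ev), -1e-10)
  # eigen oracle for the projection
  e <- eigen((bad + t(bad)) / 2, symmetric = TRUE)
  proj <- e$vectors %*% diag(pmax(e$values, 0)) %*% t(e$vectors)
  expect_equal(unname(fixed$values), proj, tolerance = 1e-12)
  # default repair keeps the matrix invertible for the augmented pedigree
  expect_warning(fixed2 <- check_gamma(bad), "projected")
  expect_gte(min(eigen(fixed2$values, symmetric = TRUE)$values), 1e-7)
  expect_error(check_gamma(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
})

test_that("Gamma and group definitions round-trip through text files", {
  gm <- structure(list(values = matrix(c(0.5, 0.3, 0.3, 0.6), 2, 2,
                                       dimnames = list(c("g1", "g2"), c("g1", "g2"))),
                       method = "trend", groups = c("g1", "g2")),
                  class = "gamma_matrix")
  f <- tempfile(fileext = ".csv")
  write_gamma(gm, f)
  gm2 <- read_gamma(f)
  expect_equal(gm2$values, gm$values)
  expect_equal(gm2$method, "trend")
  ped <- data.frame(id = 1:10, sire = 0, dam = 0, year = 2000:2009, pop = "K")
  gd <- assign_groups(ped, 5)
  fy <- tempfile(fileext = ".yaml")
  write_group_definition(gd, fy)
  gd2 <- read_group_definition(fy)
  expect_equal(gd2$groups, gd$groups)
  expect_equal(gd2$interval_years, 5)
  unlink(c(f, fy))
})
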