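# A 25-animal x 20-marker QC fixture with known defects, built in code.
make_qc_fixture <- function() {
  set.seed(101)
  n <- 25; m <- 20
  # moderate frequencies keep every unengineered animal under the
  # heterozygosity threshold
  calls <- matrix(rbinom(n * m, 2, 0.15), n, m)
  # animal 3: call rate 0.85 (3 of 20 missing)
  calls[3, 1:3] <- NA
  # animal 8: heterozygosity 0.6 (> 0.50)
  calls[8, ] <- rep(c(1L, 0L), c(12, 8))
  # marker 7: one alternate allele among all animals -> MAF 0.02 after
  # removal of animals 3 and 8 leaves it < 0.05 regardless
  calls[, 7] <- 0L; calls[5, 7] <- 1L
  # marker 12: common, kept
  calls[, 12] <- rep(c(0L, 1L, 2L), length.out = n)
  g <- genotype_set(calls, animal_ids = 1:25)
  calls[1, 12] <- 1L   # heterozygous parent cannot conflict at marker 12
  # pedigree making marker 15 conflict-ridden: parent 1 vs offspring 20-25
  ped <- data.frame(id = 1:25, sire = c(rep(0, 19), rep(1, 6)), dam = 0)
  calls[1, 15] <- 2L
  calls[20:25, 15] <- 0L
  g <- genotype_set(calls, animal_ids = 1:25)
  list(g = g, ped = ped)
}

test_that("QC removes exactly the engineered animals and markers, with reasons", {
  fx <- make_qc_fixture()
  res <- qc_genotypes(fx$g, pedigree = fx$ped)
  expect_setequal(res$report$removed_animals$id, c(3, 8))
  expect_equal(res$report$removed_animals$reason[res$report$removed_animals$id == 3],
               "call_rate")
  expect_equal(res$report$removed_animals$reason[res$report$removed_animals$id == 8],
               "heterozygosity")
  rm <- res$report$removed_markers
  expect_true("SNP_7" %in% rm$marker[rm$reason == "maf"])
  expect_true("SNP_15" %in% rm$marker[rm$reason == "mendelian_conflict"])
  expect_false("SNP_12" %in% rm$marker)
  # no overlap between removed and retained
  expect_length(intersect(res$genotypes$marker_ids, rm$marker), 0)
  expect_length(intersect(res$genotypes$animal_ids,
                          res$report$removed_animals$id), 0)
})

test_that("QC is idempotent and clean data passes untouched", {
  fx <- make_qc_fixture()
  once <- qc_genotypes(fx$g, pedigree = fx$ped)
  twice <- qc_genotypes(once$genotypes, pedigree = fx$ped)
  expect_identical(once$genotypes$calls, twice$genotypes$calls)
  expect_equal(nrow(twice$report$removed_animals), 0)
  expect_equal(nrow(twice$report$removed_markers), 0)

  # deterministic clean matrix: cyclic shifts of a fixed column keep every
  # animal's heterozygosity at 0.3 and every marker's MAF at 0.35
  v <- c(1, 1, 1, 0, 0, 2, 0, 2, 0, 0)
  clean_m <- sapply(1:20, function(j) v[((seq_len(10) + j) %% 10) + 1])
  clean <- genotype_set(clean_m, animal_ids = 1:10)
  res <- qc_genotypes(clean)
  expect_equal(unname(res$report$n_markers), c(20L, 20L))
  expect_equal(unname(res$report$n_animals), c(10L, 10L))
})

test_that("allele frequencies match a counting oracle and flag empty markers", {
  set.seed(3)
  calls <- matrix(rbinom(120, 2, 0.3), 12, 10)
  calls[sample(120, 15)] <- NA
  calls[, 4] <- NA
  g <- genotype_set(calls, animal_ids = 1:12)
  p <- allele_frequencies(g)
  for (j in (1:10)[-4]) {
    v <- calls[, j]
    expect_equal(unname(p[j]), sum(v, na.rm = TRUE) / (2 * sum(!is.na(v))))
  }
  expect_true(is.na(p[4]))
  expect_equal(attr(p, "all_missing"), "SNP_4")
  expect_equal(unname(allele_frequencies(genotype_set(matrix(1, 3, 2),
                                                      animal_ids = 1:3))),
               c(0.5, 0.5), ignore_attr = TRUE)
  expect_error(allele_frequencies(g, integer(0)), "empty")
})

test_that("Fst reproduces hand-evaluated values and its invariants", {
  expect_equal(fst_pair(0.2, 0.4), 0.04 / 0.44)
  expect_equal(fst_pair(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(fst_pair(rep(1, 5), rep(0, 5)), 1)
  expect_error(fst_pair(c(0, 0), c(0, 0)), "fixed")
  set.seed(4)
  p1 <- runif(50); p2 <- runif(50)
  expect_equal(fst_pair(p1, p2), fst_pair(p2, p1))
  expect_gte(fst_pair(p1, p2), 0)
  expect_lte(fst_pair(p1, p2), 1)
})

test_that("Fst matrix equals looped pairwise calls and drift is monotone", {
  cfg <- sim_config(n_populations = 3, pop_names = c("A", "B", "C"),
                    drift_F = c(0.005, 0.02, 0.06), n_markers = 800,
                    years = 2004:2009, founder_years = 6,
                    n_flocks_per_pop = 2, n_per_year_per_flock = 15,
                    crossing_rates = diag(3), genotyped_from_year = 2004,
                    seed = 21)
  pop <- simulate_pedigree_genotypes(cfg)
  lab <- pop$pedigree$pop
  fm <- fst_matrix(pop$genotypes, lab)
  expect_equal(fm, t(fm))
  expect_equal(unname(diag(fm)), rep(0, 3))
  for (a in c("A", "B")) for (b in setdiff(c("B", "C"), a)) {
    pa <- allele_frequencies(pop$genotypes, pop$genotypes$animal_ids[lab == a])
    pb <- allele_frequencies(pop$genotypes, pop$genotypes$animal_ids[lab == b])
    expect_equal(fm[a, b], fst_pair(pa, pb))
  }
  # larger drift separation -> larger Fst
  expect_gt(fm["A", "C"], fm["A", "B"])
  # a population with < 2 animals is skipped with a warning
  lab2 <- lab; lab2[lab2 == "C"] <- "A"; lab2[1] <- "C"
  expect_warning(fm2 <- fst_matrix(pop$genotypes, lab2), "skipped")
  expect_true(is.na(fm2["A", "C"]))
})

test_that("genotype PCA matches a dense SVD oracle and separates populations", {
  set.seed(5)
  calls <- matrix(rbinom(200 * 60, 2, 0.5), 200, 60)
  g <- genotype_set(calls, animal_ids = 1:200)
  sc <- genotype_pca(g, k = 3)
  pr <- prcomp(calls, center = TRUE, scale. = FALSE)
  for (k in 1:3) {
    expect_lt(min(max(abs(sc$coordinates[, k] - pr$x[, k])),
                  max(abs(sc$coordinates[, k] + pr$x[, k]))), 1e-6)
    expect_equal(sc$explained_variance_fraction[k],
                 unname(pr$sdev[k]^2 / sum(pr$sdev^2)), tolerance = 1e-8)
  }
  expect_true(all(diff(sc$explained_variance_fraction) <= 1e-12))

  # two well-separated populations: PC1 splits them
  cfg <- sim_config(n_populations = 2, pop_names = c("A", "B"),
                    drift_F = c(0.1, 0.1), n_markers = 500, years = 2004:2009,
                    founder_years = 6, n_flocks_per_pop = 2,
                    n_per_year_per_flock = 12, crossing_rates = diag(2),
                    genotyped_from_year = 2004, seed = 22)
  pop <- simulate_pedigree_genotypes(cfg)
  sc2 <- genotype_pca(pop$genotypes, 2)
  lab <- pop$pedigree$pop
  sep <- abs(mean(sc2$coordinates[lab == "A", 1]) -
               mean(sc2$coordinates[lab == "B", 1])) /
    (sd(sc2$coordinates[lab == "A", 1]) + sd(sc2$coordinates[lab == "B", 1]))
  expect_gt(sep, 2)
  expect_gt(sc2$explained_variance_fraction[1], sc2$explained_variance_fraction[2])

  # duplicated animals get identical coordinates
  calls2 <- rbind(calls[1:20, ], calls[1:2, ])
  g2 <- genotype_set(calls2, animal_ids = 1:22)
  sc3 <- genotype_pca(g2, 2)
  expect_equal(sc3$coordinates[21, ], sc3$coordinates[1, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  # invariance (up to sign) to marker order
  perm <- sample(60)
  sc4 <- genotype_pca(genotype_set(calls[, perm], animal_ids = 1:200,
                                   marker_ids = paste0("S", 1:60)), 2)
  expect_lt(min(max(abs(sc4$coordinates[, 1] - sc$coordinates[, 1])),
                max(abs(sc4$coordinates[, 1] + sc$coordinates[, 1]))), 1e-6)
})

test_that("breed assignment applies the published boundary inequalities", {
  sc <- structure(list(coordinates = cbind(PC1 = c(0, 0, 0), PC2 = c(0, -50, -20))),
                  class = "pca_scores")
  rownames(sc$coordinates) <- 1:3
  expect_equal(unname(assign_breed(sc)), c("M", "D", "C"))
  expect_error(assign_breed(sc, offset_upper = 10, offset_lower = 5), "overlap")
})

test_that("fitted boundaries recover labels in a synthetic two-breed sample", {
  set.seed(6)
  n <- 300
  pc1 <- c(rnorm(150, 3), rnorm(60, 0), rnorm(90, -4))
  pc2 <- rnorm(n, 0, 0.8)
  truth <- rep(c("M", "C", "D"), c(150, 60, 90))
  sc <- structure(list(coordinates = cbind(PC1 = pc1, PC2 = pc2)),
                  class = "pca_scores")
  rownames(sc$coordinates) <- 1:n
  bnd <- fit_breed_boundaries(sc, truth)
  lab <- do.call(assign_breed, c(list(scores = sc), bnd))
  expect_gt(mean(lab == truth), 0.9)
})

test_that("pedigree breed fractions: unit founders, F1, and a recursion oracle", {
  ped <- data.frame(id = 1:6, sire = c(0, 0, 1, 1, 3, 5), dam = c(0, 0, 2, 2, 4, 4),
                    pop = c("A", "B", "A", "A", "A", "A"))
  fr <- breed_fractions(ped)
  expect_equal(unname(fr[1, ]), c(1, 0))
  expect_equal(unname(fr[3, ]), c(0.5, 0.5))   # F1 of A x B
  expect_equal(unname(fr[5, ]), c(0.5, 0.5))
  expect_equal(unname(rowSums(fr)), rep(1, 6))

  ped2 <- random_pedigree(50, n_founders = 8, missing_dam = 0.2, seed = 7)
  ped2$pop <- sample(c("A", "B", "C"), 50, replace = TRUE)
  fr2 <- breed_fractions(ped2)
  pops <- colnames(fr2)
  orc <- oracle_fractions(ped2, pops,
                          function(i) match(ped2$pop[i], pops))
  expect_equal(unname(fr2), unname(orc))
  ped3 <- ped; ped3$pop[1] <- NA
  expect_warning(fr3 <- breed_fractions(ped3), "unlabelled")
  expect_equal(sum(fr3[, "unknown"] > 0), 5)   # founder 1 and descendants
})

test_that("PLINK raw-style genotype text round-trips", {
  set.seed(8)
  calls <- matrix(rbinom(60, 2, 0.5), 6, 10)
  calls[2, 3] <- NA
  g <- genotype_set(calls, animal_ids = 11:16)
  f <- tempfile(fileext = ".raw")
  write_genotypes_raw(g, f)
  g2 <- read_genotypes_raw(f)
  expect_equal(g2$animal_ids, g$animal_ids)
  expect_equal(unname(g2$calls), unname(calls))
  unlink(f)
})

test_that("VCF genotypes convert to dosage calls", {
  skip_if_not_installed("vcfR")
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t101\t102",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t200\trs2\tA\tG\t.\tPASS\t.\tGT\t1/1\t./.",
    "1\t300\trs3\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1"), f)
  g <- read_genotypes_vcf(f)
  expect_equal(sort(g$animal_ids), c(101L, 102L))
  m <- g$calls[as.character(c(101, 102)), ]
  expect_equal(unname(m[, "rs1"]), c(0, 1))
  expect_equal(unname(m[1, "rs2"]), 2)
  expect_true(is.na(m[2, "rs2"]))
  expect_equal(unname(m[, "rs3"]), c(1, 2))
  unlink(f)
})

test_that("QC reports, PCA scores and sparse matrices export to text", {
  fx <- make_qc_fixture()
  res <- qc_genotypes(fx$g, pedigree = fx$ped)
  f1 <- tempfile(fileext = ".tsv")
  write_qc_report(res$report, f1)
  tab <- read.table(f1, header = TRUE, sep = "\t", comment.char = "#")
  expect_setequal(tab$item[tab$kind == "animal"], c("3", "8"))
  expect_true(grepl("min_maf=0.05", readLines(f1, n = 1)))

  set.seed(9)
  g <- genotype_set(matrix(rbinom(400, 2, 0.5), 20, 20), animal_ids = 1:20)
  sc <- genotype_pca(g, 2)
  f2 <- tempfile(fileext = ".csv")
  write_pca_scores(sc, f2)
  got <- read.csv(f2, comment.char = "#")
  expect_equal(got$PC1, unname(sc$coordinates[, "PC1"]), tolerance = 1e-8)

  ped <- random_pedigree(30, n_founders = 5, seed = 10)
  ar <- a_inverse(ped)
  f3 <- tempfile()
  write_relationship_triplets(ar$Ainv, f3)
  M <- read_relationship_triplets(f3)
  expect_lt(max(abs(as.matrix(M) - as.matrix(ar$Ainv))), 1e-12)
  unlink(c(f1, f2, f3, paste0(f3, ".ids")))
})
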