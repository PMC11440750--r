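# Synthetic multi-line sheep population generator: founder frequency drift,
# pedigree + gene-dropping genotypes, and maternally influenced phenotypes.

#' Default variance components
#'
#' A 5 x 5 direct + maternal genetic covariance matrix `G0` (slots: direct
#' trait 1-3, maternal trait 2-3), diagonal maternal permanent environmental
#' `M0` and sire-by-flock-year `S0` matrices (traits 2-3), and a 3 x 3
#' residual covariance `R0`. With a phenotypic variance of 1 per trait the
#' direct heritabilities are 0.74, 0.57 and 0.38, the pattern of a highly
#' heritable wool quality trait, a moderately heritable fleece weight trait
#' and a moderately heritable liveweight trait with maternal influence.
#'
#' @return list of class `varcomp` with `G0`, `M0`, `S0`, `R0`.
#' @export
default_varcomp <- function() {
  h2 <- c(0.74, 0.57, 0.38)
  mat <- c(0.10, 0.12)          # maternal genetic, traits 2-3
  mpe <- c(0.05, 0.08)
  sfy <- c(0.03, 0.04)
  res <- c(1 - h2[1], 1 - h2[2] - mat[1] - mpe[1] - sfy[1],
           1 - h2[3] - mat[2] - mpe[2] - sfy[2])
  sd5 <- sqrt(c(h2, mat))
  corr <- matrix(c(
    1.00, 0.30, 0.20, -0.05, -0.05,
    0.30, 1.00, 0.40, -0.20, -0.05,
    0.20, 0.40, 1.00, -0.05, -0.20,
    -0.05, -0.20, -0.05, 1.00, 0.30,
    -0.05, -0.05, -0.20, 0.30, 1.00), 5, 5)
  G0 <- corr * tcrossprod(sd5)
  rcor <- matrix(c(1, 0.15, 0.10, 0.15, 1, 0.20, 0.10, 0.20, 1), 3, 3)
  R0 <- rcor * tcrossprod(sqrt(res))
  slots <- c("dir1", "dir2", "dir3", "mat2", "mat3")
  dimnames(G0) <- list(slots, slots)
  dimnames(R0) <- list(paste0("t", 1:3), paste0("t", 1:3))
  varcomp(G0, diag(mpe), diag(sfy), R0)
}

#' Assemble and validate variance components
#'
#' @param G0 5x5 (or trait-subset) direct+maternal genetic covariance.
#' @param M0 diagonal maternal permanent environmental variances.
#' @param S0 diagonal sire-by-flock-year variances.
#' @param R0 residual covariance across traits.
#' @return list of class `varcomp`.
#' @export
varcomp <- function(G0, M0, S0, R0) {
  G0 <- as.matrix(G0); R0 <- as.matrix(R0)
  M0 <- as.matrix(M0); S0 <- as.matrix(S0)
  for (nm in c("G0", "R0")) {
    M <- get(nm)
    if (!isSymmetric(M, tol = 1e-10)) stop(nm, " must be symmetric")
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop(nm, " must be positive semidefinite")
  }
  for (nm in c("M0", "S0")) {
    M <- get(nm)
    if (any(M[row(M) != col(M)] != 0) || any(diag(M) < 0))
      stop(nm, " must be diagonal with non-negative entries")
  }
  structure(list(G0 = G0, M0 = M0, S0 = S0, R0 = R0), class = "varcomp")
}

#' Simulation configuration
#'
#' Defaults emulate a multi-line Merino-type structure: 7 founder
#' populations (6 large-breed lines and one small breed) whose pairwise Fst
#' falls in the few-thousandths to ~0.05 range, four 5-year birth cohorts,
#' directed crossing producing an admixed stratum, and a fraction of
#' unrecorded dams.
#'
#' @param n_populations number of founder populations.
#' @param pop_names population labels.
#' @param drift_F per-population drift from the shared ancestral
#'   frequencies (variance `p(1-p)*F`).
#' @param n_markers number of biallelic markers.
#' @param years inclusive birth-year range.
#' @param n_flocks_per_pop flocks per population.
#' @param n_per_year_per_flock newborns per flock and year.
#' @param founder_years initial years whose animals are unparented founders.
#' @param crossing_rates populations x populations matrix; entry `[k, l]` is
#'   the probability that a dam of population `k` is mated to a sire of
#'   population `l`. Rows must sum to 1 (diagonal = within-line mating).
#' @param missing_dam_rate probability that a dam goes unrecorded in the
#'   pedigree (the genetic dam still exists).
#' @param marker_share fraction of the additive genetic variance carried by
#'   the marker panel (markers act as the causal loci, the standard
#'   shortcut when no linkage map is simulated); the remainder is a
#'   pedigree-polygenic component. The default mirrors the 0.95/0.05
#'   genomic/pedigree blend of the single-step covariance, so the fitted
#'   models are correctly specified for the generated data.
#' @param genotyped_from_year animals born in or after this year are
#'   genotyped (genotyping concentrates in recent cohorts).
#' @param ancestral_freq ancestral-frequency sampler over \[0.05, 0.95\];
#'   default Uniform(0.05, 0.95).
#' @param varcomp variance components, see [default_varcomp()].
#' @param seed integer seed; a fixed seed reproduces the population exactly.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 7,
                       pop_names = NULL,
                       drift_F = NULL,
                       n_markers = 1000,
                       years = 2000:2019,
                       n_flocks_per_pop = NULL,
                       n_per_year_per_flock = 12,
                       founder_years = 3,
                       crossing_rates = NULL,
                       missing_dam_rate = 0.1,
                       marker_share = 0.95,
                       genotyped_from_year = NULL,
                       ancestral_freq = function(n) runif(n, 0.05, 0.95),
                       varcomp = default_varcomp(),
                       seed = 1L) {
  if (is.null(pop_names))
    pop_names <- if (n_populations == 7)
      c("RF", "SAMM", "Mer", "MerFM", "MerS", "MerUF", "DM")[1:7] else
      paste0("P", seq_len(n_populations))
  stopifnot(length(pop_names) == n_populations)
  if (is.null(drift_F))
    drift_F <- rep(c(0.004, 0.020, 0.002, 0.003, 0.004, 0.003, 0.005),
                   length.out = n_populations)
  stopifnot(all(drift_F >= 0), length(drift_F) == n_populations)
  if (is.null(n_flocks_per_pop)) n_flocks_per_pop <- 2L
  n_flocks_per_pop <- rep(as.integer(n_flocks_per_pop),
                          length.out = n_populations)
  if (is.null(crossing_rates)) {
    crossing_rates <- diag(n_populations)
    if (n_populations >= 2) {
      # small-breed sires used on a slice of the other populations' ewes
      k <- n_populations
      crossing_rates[-k, k] <- 0.08
      diag(crossing_rates)[-k] <- 1 - 0.08
    }
  }
  crossing_rates <- as.matrix(crossing_rates)
  stopifnot(nrow(crossing_rates) == n_populations,
            ncol(crossing_rates) == n_populations,
            all(crossing_rates >= 0))
  if (any(abs(rowSums(crossing_rates) - 1) > 1e-8))
    stop("crossing_rates rows must sum to 1")
  stopifnot(missing_dam_rate >= 0, missing_dam_rate <= 1, n_markers >= 1,
            marker_share >= 0, marker_share <= 1)
  if (is.null(genotyped_from_year))
    genotyped_from_year <- years[max(1L, length(years) - 9L)]
  dimnames(crossing_rates) <- list(pop_names, pop_names)
  structure(list(n_populations = n_populations, pop_names = pop_names,
                 drift_F = setNames(drift_F, pop_names),
                 n_markers = as.integer(n_markers), years = years,
                 n_flocks_per_pop = setNames(as.integer(n_flocks_per_pop), pop_names),
                 n_per_year_per_flock = as.integer(n_per_year_per_flock),
                 founder_years = as.integer(founder_years),
                 crossing_rates = crossing_rates,
                 missing_dam_rate = missing_dam_rate,
                 marker_share = marker_share,
                 genotyped_from_year = as.integer(genotyped_from_year),
                 ancestral_freq = ancestral_freq,
                 varcomp = varcomp, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate per-population founder allele frequencies
#'
#' Shared ancestral frequencies are drawn from `cfg$ancestral_freq`; each
#' population's frequencies are then drawn around them with variance
#' `p(1-p)*F_pop` (a Beta draw matching that mean and variance), emulating
#' drift since a common ancestral population. `drift_F = 0` copies the
#' ancestral frequencies unchanged.
#'
#' @param cfg a [sim_config()].
#' @return list with `ancestral` (length `n_markers`) and `pop` (populations
#'   x markers matrix), frequencies in (0, 1).
#' @export
simulate_founder_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p0 <- cfg$ancestral_freq(cfg$n_markers)
  if (!is.numeric(p0) || length(p0) != cfg$n_markers || any(p0 <= 0 | p0 >= 1))
    stop("invalid ancestral frequency distribution spec")
  P <- matrix(0, cfg$n_populations, cfg$n_markers,
              dimnames = list(cfg$pop_names, NULL))
  for (k in seq_len(cfg$n_populations)) {
    Fk <- cfg$drift_F[k]
    if (Fk <= 0) { P[k, ] <- p0; next }
    # Beta with mean p0 and variance p0(1-p0)F: shape scale (1-F)/F
    s <- (1 - Fk) / Fk
    P[k, ] <- rbeta(cfg$n_markers, p0 * s, (1 - p0) * s)
  }
  P <- pmin(pmax(P, 1e-6), 1 - 1e-6)
  list(ancestral = p0, pop = P)
}

#' Simulate pedigree and gene-dropped genotypes
#'
#' Founder animals (first `founder_years` cohorts) draw genotypes from their
#' population's founder frequencies; later animals are produced by sampling
#' a dam from their own population and a sire from the population chosen by
#' `crossing_rates`, and inherit one allele per parent per locus. A
#' `missing_dam_rate` fraction of dams is erased from the recorded pedigree
#' (the true dam still transmits alleles, so recorded-pedigree quantities
#' are estimates, as in field data). Population labels follow the dam.
#'
#' @param cfg a [sim_config()].
#' @param founder_freqs output of [simulate_founder_frequencies()]; computed
#'   when `NULL`.
#' @return list of class `sim_population` (without phenotypes): `pedigree`
#'   (recorded, with `id, sire, dam, year, flock, pop, sex`),
#'   `true_pedigree` (recorded plus hidden dams), `genotypes` (a
#'   [genotype_set()] of the genotyped animals), `population_fractions`
#'   (true ancestry), `founder_freqs`.
#' @export
simulate_pedigree_genotypes <- function(cfg, founder_freqs = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(founder_freqs)) founder_freqs <- simulate_founder_frequencies(cfg)
  set.seed(cfg$seed + 1L)
  pops <- cfg$pop_names
  K <- cfg$n_populations
  flocks <- unlist(lapply(seq_len(K), function(k)
    rep(k, cfg$n_flocks_per_pop[k])))          # flock -> population
  nfl <- length(flocks)
  years <- cfg$years
  n_total <- nfl * cfg$n_per_year_per_flock * length(years)

  id <- seq_len(n_total)
  sire <- dam <- integer(n_total)
  year <- flock <- pop <- integer(n_total)
  sex <- integer(n_total)                       # 1 male, 2 female
  i <- 0L
  for (y in years) for (f in seq_len(nfl)) {
    idx <- i + seq_len(cfg$n_per_year_per_flock)
    year[idx] <- y; flock[idx] <- f; pop[idx] <- flocks[f]
    i <- i + cfg$n_per_year_per_flock
  }
  sex <- sample(rep_len(1:2, n_total))

  founder_cut <- years[1] + cfg$founder_years - 1L
  M <- matrix(0L, n_total, cfg$n_markers)
  Pf <- founder_freqs$pop
  frac <- matrix(0, n_total, K, dimnames = list(id, pops))
  # candidate-parent pools, indexed by population/sex/year (and flock for dams)
  males <- split(which(sex == 1L), paste(pop[sex == 1L], year[sex == 1L]))
  fem_fl <- split(which(sex == 2L),
                  paste(pop[sex == 2L], flock[sex == 2L], year[sex == 2L]))
  fem_pop <- split(which(sex == 2L), paste(pop[sex == 2L], year[sex == 2L]))
  window <- function(pool, keys) unlist(pool[keys], use.names = FALSE)
  for (i in seq_len(n_total)) {
    p <- pop[i]; y <- year[i]
    new_founder <- y <= founder_cut
    if (!new_founder) {
      sp <- sample.int(K, 1L, prob = cfg$crossing_rates[p, ])
      yrs <- (y - 4L):(y - 2L)
      sires_ok <- window(males, paste(sp, yrs))
      dams_ok <- window(fem_fl, paste(p, flock[i], yrs))
      if (!length(dams_ok)) dams_ok <- window(fem_pop, paste(p, yrs))
      if (!length(sires_ok) || !length(dams_ok)) new_founder <- TRUE
      else {
        s <- if (length(sires_ok) == 1L) sires_ok else sample(sires_ok, 1L)
        d <- if (length(dams_ok) == 1L) dams_ok else sample(dams_ok, 1L)
        sire[i] <- s; dam[i] <- d
        M[i, ] <- rbinom(cfg$n_markers, 1L, M[s, ] / 2) +
          rbinom(cfg$n_markers, 1L, M[d, ] / 2)
        frac[i, ] <- (frac[s, ] + frac[d, ]) / 2
      }
    }
    if (new_founder) {
      M[i, ] <- rbinom(cfg$n_markers, 2L, Pf[p, ])
      frac[i, p] <- 1
    }
  }
  recorded_dam <- dam
  hide <- dam != 0L & runif(n_total) < cfg$missing_dam_rate
  recorded_dam[hide] <- 0L
  storage.mode(M) <- "integer"

  ped <- data.frame(id = id, sire = sire, dam = recorded_dam, year = year,
                    flock = flock, pop = pops[pop], sex = c("M", "F")[sex],
                    stringsAsFactors = FALSE)
  true_ped <- data.frame(id = id, sire = sire, dam = dam, year = year,
                         flock = flock, pop = pops[pop],
                         stringsAsFactors = FALSE)
  geno_ids <- id[year >= cfg$genotyped_from_year]
  genotypes <- genotype_set(M[geno_ids, , drop = FALSE], geno_ids,
                            paste0("SNP_", seq_len(cfg$n_markers)))
  structure(list(pedigree = ped, true_pedigree = true_ped,
                 genotypes = genotypes, population_fractions = frac,
                 founder_freqs = founder_freqs, dosages_all = M, config = cfg),
            class = "sim_population")
}

#' Simulate phenotypes and true breeding values
#'
#' True breeding values for the five genetic slots (direct traits 1-3,
#' maternal traits 2-3) follow the mendelian-sampling recursion
#' \eqn{u_i = \tfrac12 u_s + \tfrac12 u_d + \phi_i} with
#' \eqn{\phi_i \sim N(0, G_0 D_i)},
#' \eqn{D_i = \tfrac12 - \tfrac14(F_s + F_d)}, over the true pedigree, so
#' cost is linear in pedigree size. Trait 1 records are contemporary group
#' (flock x year) + direct TBV + residual; traits 2-3 add the dam's maternal
#' TBV, a maternal permanent environmental draw, and a sire-by-flock-year
#' draw. Residuals are multivariate across traits with covariance `R0`.
#'
#' @param pop a `sim_population` from [simulate_pedigree_genotypes()].
#' @param varcomp variance components (defaults to the config's).
#' @param seed integer seed (defaults to the config's + 2).
#' @param cg_sd standard deviation of contemporary-group effects.
#' @return the population with `phenotypes` (data frame `id, flock, year,
#'   cg, sire, dam, t1, t2, t3`), `tbv` (animals x 5 slots) and a `truth`
#'   list of every simulated effect draw (phenotypes decompose exactly into
#'   these draws).
#' @export
simulate_phenotypes <- function(pop, varcomp = NULL, seed = NULL, cg_sd = 0.7) {
  stopifnot(inherits(pop, "sim_population"))
  cfg <- pop$config
  if (is.null(varcomp)) varcomp <- cfg$varcomp
  stopifnot(inherits(varcomp, "varcomp"))
  if (is.null(seed)) seed <- cfg$seed + 2L
  set.seed(seed)
  ped <- pop$true_pedigree
  n <- nrow(ped)
  G0 <- varcomp$G0
  ns <- nrow(G0)
  F <- pedigree_inbreeding(ped)
  pr <- ped_parent_rows(ped)
  # marker-determined genetic component: the panel carries `marker_share` of
  # the additive variance (per-marker effects, ancestral-frequency centred)
  share <- if (is.null(pop$dosages_all)) 0 else cfg$marker_share
  Um <- matrix(0, n, ns)
  if (share > 0) {
    p0 <- pop$founder_freqs$ancestral
    m <- length(p0)
    alpha <- matrix(rnorm(m * ns), m, ns) %*% chol(G0 + diag(1e-10, ns)) *
      sqrt(share / sum(2 * p0 * (1 - p0)))
    Um <- sweep(pop$dosages_all, 2L, 2 * p0) %*% alpha
  } else alpha <- NULL
  # pedigree-polygenic remainder by mendelian-sampling recursion
  Lg <- t(chol(G0 * (1 - share) + diag(1e-10, ns)))
  U <- matrix(0, n, ns, dimnames = list(ped$id, colnames(G0)))
  phi <- matrix(rnorm(n * ns), n, ns)
  for (i in seq_len(n)) {
    s <- pr$s[i]; d <- pr$d[i]
    fs <- if (is.na(s)) -1 else F[s]
    fd <- if (is.na(d)) -1 else F[d]
    Di <- 0.5 - 0.25 * (fs + fd)
    u <- sqrt(Di) * as.vector(Lg %*% phi[i, ])
    if (!is.na(s)) u <- u + 0.5 * U[s, ]
    if (!is.na(d)) u <- u + 0.5 * U[d, ]
    U[i, ] <- u
  }
  U <- U + Um
  cg_code <- ped$flock * 10000L + ped$year
  cg_lev <- sort(unique(cg_code))
  cg_eff <- rnorm(length(cg_lev), 0, cg_sd)
  names(cg_eff) <- cg_lev

  # trait and maternal-slot structure follows the variance components, so a
  # single-trait direct-only parameterisation is generated the same way
  nt <- nrow(varcomp$R0)
  slots <- rownames(G0)
  mat_traits <- as.integer(sub("mat", "", grep("^mat", slots, value = TRUE)))
  nm <- length(mat_traits)
  M0d <- if (nm) diag(as.matrix(varcomp$M0)) else numeric(0)
  S0d <- if (nm) diag(as.matrix(varcomp$S0)) else numeric(0)
  mpe_draw <- if (nm) matrix(rnorm(n * nm), n, nm) %*% diag(sqrt(M0d), nm) else
    matrix(0, n, 0)
  rownames(mpe_draw) <- ped$id
  sfy_code <- ifelse(ped$sire > 0L,
                     paste(ped$sire, ped$flock, ped$year, sep = "_"), NA)
  sfy_lev <- unique(sfy_code[!is.na(sfy_code)])
  sfy_draw <- if (nm) matrix(rnorm(length(sfy_lev) * nm), ncol = nm) %*%
    diag(sqrt(S0d), nm) else matrix(0, length(sfy_lev), 0)
  rownames(sfy_draw) <- sfy_lev

  E <- matrix(rnorm(n * nt), n, nt) %*% chol(varcomp$R0)

  y <- matrix(NA_real_, n, nt)
  for (tt in seq_len(nt)) {
    ym <- cg_eff[as.character(cg_code)] + U[, paste0("dir", tt)] + E[, tt]
    k <- match(tt, mat_traits)
    if (!is.na(k)) {
      has_dam <- !is.na(pr$d)
      ym[has_dam] <- ym[has_dam] + U[pr$d[has_dam], paste0("mat", tt)] +
        mpe_draw[pr$d[has_dam], k]
      has_s <- !is.na(sfy_code)
      ym[has_s] <- ym[has_s] + sfy_draw[sfy_code[has_s], k]
    }
    y[, tt] <- ym
  }
  colnames(y) <- paste0("t", seq_len(nt))
  phe <- data.frame(id = ped$id, flock = ped$flock, year = ped$year,
                    cg = cg_code, sire = pop$pedigree$sire,
                    dam = pop$pedigree$dam, y)
  pop$phenotypes <- phe
  pop$tbv <- U
  pop$truth <- list(cg_effects = cg_eff, mpe = mpe_draw, sfy = sfy_draw,
                    residual = E, F = F, marker_effects = alpha,
                    marker_share = share, seed = seed)
  pop
}

#' Simulate a complete study population
#'
#' Convenience wrapper: founder frequencies, pedigree + genotypes, then
#' phenotypes, all driven by one [sim_config()].
#'
#' @param cfg a [sim_config()].
#' @return a `sim_population` with genotypes, phenotypes, TBVs and truth.
#' @export
simulate_population <- function(cfg) {
  pop <- simulate_pedigree_genotypes(cfg)
  simulate_phenotypes(pop)
}

#' @exportS3Method base::print
print.sim_population <- function(x, ...) {
  cat("sim_population:", nrow(x$pedigree), "animals,",
      length(x$genotypes$animal_ids), "genotyped,",
      x$config$n_markers, "markers,",
      length(unique(x$pedigree$pop)), "populations\n")
  invisible(x)
}
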