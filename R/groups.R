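# Metafounder / unknown-parent-group definition and Gamma estimation.

#' Define metafounders / unknown parent groups
#'
#' One group per population x birth-year cohort. Cohorts are consecutive
#' `interval_years`-year intervals starting at each population's first birth
#' year; a population whose year span fits inside a single interval keeps a
#' single group.
#'
#' @param pedigree sorted pedigree with `pop` and `year`.
#' @param interval_years cohort width in years.
#' @return object of class `group_definition`: data frame `groups`
#'   (`group`, `pop`, `cohort`, `year_lo`, `year_hi`) ordered by population
#'   and cohort, plus the interval width.
#' @export
assign_groups <- function(pedigree, interval_years = 5) {
  validate_pedigree(pedigree, require_year = TRUE, require_pop = TRUE)
  pops <- unique(as.character(pedigree$pop))
  rows <- list()
  for (p in pops) {
    yr <- pedigree$year[pedigree$pop == p]
    lo <- min(yr); hi <- max(yr)
    nco <- if (hi - lo + 1 <= interval_years) 1L else
      ceiling((hi - lo + 1) / interval_years)
    for (k in seq_len(nco)) {
      y0 <- lo + (k - 1L) * interval_years
      y1 <- if (k == nco) hi else y0 + interval_years - 1L
      if (nco == 1L) y1 <- hi
      rows[[length(rows) + 1L]] <- data.frame(
        group = if (nco == 1L) p else paste0(p, ":", k),
        pop = p, cohort = k, year_lo = y0, year_hi = y1,
        stringsAsFactors = FALSE)
    }
  }
  groups <- do.call(rbind, rows)
  structure(list(groups = groups, interval_years = interval_years),
            class = "group_definition")
}

#' @exportS3Method base::print
print.group_definition <- function(x, ...) {
  cat("group_definition:", nrow(x$groups), "groups over",
      length(unique(x$groups$pop)), "populations (",
      x$interval_years, "-year cohorts )\n")
  invisible(x)
}

# group index (row of groupdef$groups) for a population/year pair
group_lookup <- function(groupdef, pop, year) {
  g <- groupdef$groups
  idx <- integer(length(pop))
  for (i in seq_along(pop)) {
    hit <- which(g$pop == pop[i] & year[i] >= g$year_lo)
    hit <- hit[year[i] <= g$year_hi[hit] | g$cohort[hit] == max(g$cohort[g$pop == pop[i]])]
    if (!length(hit)) stop("no group for population ", pop[i], " year ", year[i])
    idx[i] <- hit[length(hit)]
  }
  idx
}

# per-animal metafounder index for each missing parent slot (NA when the
# parent is known); unknown parents take the group of the offspring's
# population and cohort
map_unknown_parents <- function(pedigree, groupdef) {
  pr <- ped_parent_rows(pedigree)
  own <- group_lookup(groupdef, as.character(pedigree$pop), pedigree$year)
  list(s = ifelse(is.na(pr$s), own, NA_integer_),
       d = ifelse(is.na(pr$d), own, NA_integer_))
}

#' Expected group (metafounder) fractions per animal
#'
#' Recursive parental averaging: each missing parent slot contributes 1/2 to
#' the group of the animal's population and cohort; known parents contribute
#' half their own row. Rows sum to 1.
#'
#' @param pedigree sorted pedigree with `pop` and `year`.
#' @param groupdef a [group_definition][assign_groups()].
#' @return animals x groups matrix `Q`.
#' @export
group_fractions <- function(pedigree, groupdef) {
  validate_pedigree(pedigree, require_year = TRUE, require_pop = TRUE)
  g <- groupdef$groups
  pr <- ped_parent_rows(pedigree)
  up <- map_unknown_parents(pedigree, groupdef)
  n <- nrow(pedigree); ng <- nrow(g)
  Q <- matrix(0, n, ng, dimnames = list(pedigree$id, g$group))
  for (i in seq_len(n)) {
    row <- numeric(ng)
    if (is.na(pr$s[i])) row[up$s[i]] <- row[up$s[i]] + 0.5 else
      row <- row + 0.5 * Q[pr$s[i], ]
    if (is.na(pr$d[i])) row[up$d[i]] <- row[up$d[i]] + 0.5 else
      row <- row + 0.5 * Q[pr$d[i], ]
    Q[i, ] <- row
  }
  Q
}

#' Base allele frequencies by least squares on ancestry fractions
#'
#' Per marker i, solves \eqn{2\hat p_i = (Q'Q)^{-1} Q' m_i} where `Q` holds
#' the ancestry (line or group) fractions of the genotyped animals and
#' `m_i` the 0/1/2 calls. Frequencies are clipped to \[0, 1\].
#'
#' @param g a [genotype_set()] with complete calls.
#' @param Q ancestry-fraction rows for the genotyped animals of `g`
#'   (columns = populations or groups).
#' @return populations x markers frequency matrix with a `"clipped"`
#'   attribute counting out-of-range solutions.
#' @export
base_allele_frequencies <- function(g, Q) {
  stopifnot(inherits(g, "genotype_set"))
  Q <- as.matrix(Q)
  stopifnot(nrow(Q) == length(g$animal_ids))
  if (anyNA(g$calls)) stop("complete calls required")
  QtQ <- crossprod(Q)
  ev <- eigen(QtQ, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * max(ev)) {
    rep_ <- colSums(Q)
    stop("singular ancestry design; unrepresented columns: ",
         paste(colnames(Q)[rep_ < 1e-6], collapse = ", "))
  }
  P <- solve(QtQ, crossprod(Q, g$calls)) / 2  # populations x markers
  clipped <- sum(P < 0 | P > 1)
  P <- pmin(pmax(P, 0), 1)
  rownames(P) <- colnames(Q)
  attr(P, "clipped") <- clipped
  attr(P, "representation") <- colSums(Q)
  P
}

#' Ancestral self-relationship from allele frequencies
#'
#' \eqn{\Gamma_0 = (2/n) \sum_i (2p_i - 1)^2}, in \[0, 2\].
#'
#' @param p allele-frequency vector of the ancestral population.
#' @return scalar.
#' @export
gamma_ancestral <- function(p) {
  stopifnot(length(p) > 0, all(p >= 0 & p <= 1))
  mean((2 * p - 1)^2) * 2
}

#' Ancestral cross-relationship between two populations
#'
#' \eqn{\gamma_{k,l} = (2/n) \sum_i (2p_{i(k)} - 1)(2p_{i(l)} - 1)}, in
#' \[-2, 2\]; equals [gamma_ancestral()] when `p_k == p_l`.
#'
#' @param p_k,p_l allele-frequency vectors of the two populations.
#' @return scalar.
#' @export
gamma_between <- function(p_k, p_l) {
  stopifnot(length(p_k) == length(p_l))
  mean((2 * p_k - 1) * (2 * p_l - 1)) * 2
}

#' Linear trend of pedigree inbreeding over birth year
#'
#' Fits \eqn{f_i = \sum_j q_{ij} b_j + t_i c + \sum_j t_i q_{ij} d_j + e_i}
#' by ordinary least squares on the animals with both parents known, with
#' `t` the birth year centred to the earliest year. The per-population
#' yearly increase \eqn{\Delta F_j} is the estimate of `d_j`; non-positive
#' estimates (biologically impossible in closed populations) are replaced by
#' the mean of the positive ones. The shared slope `c` is dropped from the
#' resolved rates when its magnitude is below `c_tol`.
#'
#' @param pedigree sorted pedigree with `year`.
#' @param Q_pop animals x populations ancestry fractions (rows aligned with
#'   the pedigree).
#' @param F optional precomputed inbreeding (else [pedigree_inbreeding()]).
#' @param c_tol tolerance under which the shared yearly slope is ignored.
#' @return object of class `inbreeding_trend`: `b`, `c`, `d`,
#'   `delta_f` (resolved rates), `c_used`, `n_used`.
#' @export
fit_inbreeding_trend <- function(pedigree, Q_pop, F = NULL, c_tol = 1e-3) {
  validate_pedigree(pedigree, require_year = TRUE)
  Q_pop <- as.matrix(Q_pop)
  if (is.null(F)) F <- pedigree_inbreeding(pedigree)
  both <- pedigree$sire != 0L & pedigree$dam != 0L
  if (!any(both)) stop("no animals with both parents known")
  t <- pedigree$year - min(pedigree$year)
  Qb <- Q_pop[both, , drop = FALSE]
  tb <- t[both]
  npop <- ncol(Q_pop)
  # the shared slope c is aliased with the per-population slopes whenever the
  # fraction rows sum to 1 (t = sum_j t q_j); placing it last lets the pivoted
  # fit alias it to 0, mirroring its "ignored because ~0" role
  X <- cbind(Qb, Qb * tb, c = tb)
  colnames(X) <- c(paste0("b_", colnames(Q_pop)), paste0("d_", colnames(Q_pop)), "c")
  fit <- lm(F[both] ~ 0 + X)
  beta <- coef(fit)
  names(beta) <- colnames(X)
  if (anyNA(beta[seq_len(2 * npop)]))
    stop("rank-deficient inbreeding-trend design; some population absent ",
         "among fully pedigreed animals")
  b <- beta[seq_len(npop)]
  d <- beta[npop + seq_len(npop)]
  cc <- beta[2L * npop + 1L]
  if (is.na(cc)) cc <- 0
  c_used <- abs(cc) >= c_tol
  raw <- unname(d) + if (c_used) cc else 0
  pos <- raw > 0
  delta_f <- raw
  delta_f[!pos] <- if (any(pos)) mean(raw[pos]) else 0
  names(b) <- names(d) <- names(delta_f) <- colnames(Q_pop)
  structure(list(b = b, c = unname(cc), d = d, delta_f = delta_f,
                 c_used = c_used, n_used = sum(both)),
            class = "inbreeding_trend")
}

#' Metafounder-scale yearly inbreeding increase
#'
#' \eqn{\Delta F_{(\gamma)} = \Delta F (1 - \Gamma_0 / 2)}.
#'
#' @param delta_f pedigree-scale yearly increase (>= 0).
#' @param gamma0 ancestral self-relationship in \[0, 2\].
#' @return scalar (or vector) on the metafounder scale.
#' @export
delta_f_gamma <- function(delta_f, gamma0) {
  stopifnot(all(delta_f >= 0), all(gamma0 >= 0 & gamma0 <= 2))
  delta_f * (1 - gamma0 / 2)
}

#' Build the Gamma matrix by the trend construction
#'
#' Within a population with cohorts r <= s the entry is
#' \eqn{\Gamma_0 + (r-1) \cdot interval \cdot 2\Delta F_{(\gamma)}} (linear
#' relationship increase in a closed population); between populations the
#' block is the constant \eqn{\gamma_{k,l}}.
#'
#' @param groupdef a [group_definition][assign_groups()] with cohorts
#'   ordered in time.
#' @param gamma0 named per-population ancestral self-relationships.
#' @param gamma_between_mat populations x populations matrix of ancestral
#'   cross-relationships (only off-diagonals used).
#' @param delta_f_g named per-population metafounder-scale yearly increases.
#' @return object of class `gamma_matrix` with `values`, `method = "trend"`
#'   and the per-population inputs.
#' @export
build_gamma_trend <- function(groupdef, gamma0, gamma_between_mat, delta_f_g) {
  g <- groupdef$groups
  for (p in unique(g$pop)) {
    co <- g$cohort[g$pop == p]
    if (is.unsorted(co, strictly = TRUE)) stop("cohorts unordered for population ", p)
  }
  ng <- nrow(g)
  V <- matrix(0, ng, ng, dimnames = list(g$group, g$group))
  interval <- groupdef$interval_years
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    pi_ <- g$pop[i]; pj <- g$pop[j]
    if (pi_ == pj) {
      r <- min(g$cohort[i], g$cohort[j])
      V[i, j] <- gamma0[[pi_]] + (r - 1) * interval * 2 * delta_f_g[[pi_]]
    } else V[i, j] <- gamma_between_mat[pi_, pj]
  }
  structure(list(values = V, method = "trend", gamma0 = gamma0,
                 delta_f_gamma = delta_f_g, groups = g$group),
            class = "gamma_matrix")
}

#' Estimate Gamma by least squares on group fractions
#'
#' Estimates per-group base allele frequencies by the (ordinary) least
#' squares solve of [base_allele_frequencies()] against the group-fraction
#' design, then fills Gamma with [gamma_ancestral()] on the diagonal and
#' [gamma_between()] off it. Because
#' \eqn{E[(2\hat p - 1)^2] = (2p - 1)^2 + 4\,\mathrm{Var}(\hat p)}, the
#' naive plug-in inflates the entries of lightly represented groups; by
#' default the sampling (co)variance of the per-marker solve,
#' \eqn{(Q'Q)^{-1} s_i^2/4} with \eqn{s_i^2} the residual variance of
#' marker i, is subtracted. The weighting is ordinary least squares — the
#' simplest member of the generalised family; pedigree-relationship
#' weighting is not applied.
#'
#' @param g a [genotype_set()] with complete calls.
#' @param Q_groups group-fraction rows of the genotyped animals.
#' @param min_representation error when a group's summed fraction falls
#'   below this effective number of animals.
#' @param bias_correction subtract the frequency-sampling variance term.
#' @return object of class `gamma_matrix` with `values`, `method = "gls"`,
#'   per-group effective representation and the estimated base frequencies.
#' @export
estimate_gamma_gls <- function(g, Q_groups, min_representation = 1,
                               bias_correction = TRUE) {
  Q_groups <- as.matrix(Q_groups)
  rep_ <- colSums(Q_groups)
  empty <- colnames(Q_groups)[rep_ < min_representation]
  if (length(empty))
    stop("groups without genomic representation: ", paste(empty, collapse = ", "))
  P <- base_allele_frequencies(g, Q_groups)
  m <- ncol(P)
  Zc <- 2 * P - 1                       # groups x markers
  V <- tcrossprod(Zc) * (2 / m)         # (2/n) sum (2p_k-1)(2p_l-1)
  if (bias_correction) {
    resid <- g$calls - Q_groups %*% (2 * P)
    df <- max(nrow(Q_groups) - ncol(Q_groups), 1L)
    s2 <- colSums(resid^2) / df
    # Cov(p_hat_i) = (Q'Q)^{-1} s2_i / 4; Gamma bias = (2/n) sum_i 4 Cov
    V <- V - (2 / m) * solve(crossprod(Q_groups)) * sum(s2)
  }
  dimnames(V) <- list(rownames(P), rownames(P))
  structure(list(values = V, method = "gls", representation = rep_,
                 base_frequencies = P, clipped = attr(P, "clipped"),
                 groups = rownames(P)),
            class = "gamma_matrix")
}

#' Validate (and if needed repair) a Gamma matrix
#'
#' Checks symmetry and positive semidefiniteness; a matrix with eigenvalues
#' below `floor` is projected to the nearest PSD matrix by eigenvalue
#' clipping, with a warning reporting the largest adjustment. The small
#' positive default floor keeps the repaired matrix invertible, which the
#' metafounder-augmented pedigree inverse requires.
#'
#' @param gamma matrix or `gamma_matrix`.
#' @param tol eigenvalue tolerance below which repair triggers.
#' @param floor value the deficient eigenvalues are raised to.
#' @return a `gamma_matrix` that is symmetric PSD.
#' @export
check_gamma <- function(gamma, tol = 1e-8, floor = 1e-6) {
  obj <- if (inherits(gamma, "gamma_matrix")) gamma else
    structure(list(values = as.matrix(gamma), method = "unspecified",
                   groups = rownames(as.matrix(gamma))), class = "gamma_matrix")
  V <- obj$values
  if (!isSymmetric(V, tol = 1e-8)) stop("Gamma must be symmetric")
  V <- (V + t(V)) / 2
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) < floor - tol) {
    Vp <- e$vectors %*% diag(pmax(e$values, floor), nrow(V)) %*% t(e$vectors)
    Vp <- (Vp + t(Vp)) / 2
    warning(sprintf("Gamma projected to nearest PSD matrix (max adjustment %.3g)",
                    max(abs(Vp - V))))
    dimnames(Vp) <- dimnames(obj$values)
    obj$values <- Vp
  }
  obj$psd_checked <- TRUE
  obj
}

#' @exportS3Method base::print
print.gamma_matrix <- function(x, ...) {
  cat("gamma_matrix (", x$method, "): ", nrow(x$values), " groups; diag in [",
      sprintf("%.3f, %.3f", min(diag(x$values)), max(diag(x$values))), "]\n", sep = "")
  invisible(x)
}

#' Write / read a Gamma matrix as labelled CSV with a metadata header
#'
#' @param gamma a `gamma_matrix`.
#' @param path file path.
#' @return `read_gamma()` returns a `gamma_matrix`.
#' @export
write_gamma <- function(gamma, path) {
  stopifnot(inherits(gamma, "gamma_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method: ", gamma$method), con)
  write.csv(as.data.frame(gamma$values), con, row.names = TRUE)
  invisible(path)
}

#' @rdname write_gamma
#' @export
read_gamma <- function(path) {
  hdr <- readLines(path, n = 1L)
  method <- sub("^# method: ", "", hdr)
  V <- as.matrix(read.csv(path, comment.char = "#", row.names = 1L,
                          check.names = FALSE))
  structure(list(values = V, method = method, groups = rownames(V)),
            class = "gamma_matrix")
}

#' Write / read a group definition as YAML
#'
#' @param groupdef a `group_definition`.
#' @param path file path.
#' @export
write_group_definition <- function(groupdef, path) {
  yaml::write_yaml(list(interval_years = groupdef$interval_years,
                        groups = lapply(seq_len(nrow(groupdef$groups)), function(i)
                          as.list(groupdef$groups[i, ]))), path)
  invisible(path)
}

#' @rdname write_group_definition
#' @export
read_group_definition <- function(path) {
  y <- yaml::read_yaml(path)
  groups <- do.call(rbind, lapply(y$groups, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  structure(list(groups = groups, interval_years = y$interval_years),
            class = "group_definition")
}
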