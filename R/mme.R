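# Multitrait Henderson mixed-model equations for BLUP / ssGBLUP under
# unknown-parent-group (QP) or metafounder grouping.

#' Specify an evaluation model
#'
#' @param method `"blup"` (pedigree only) or `"ssgblup"` (single step).
#' @param grouping `"upg"` (unknown parent groups as random effects in the
#'   QP-transformed system), `"mf"` (metafounders inside the Gamma-augmented
#'   pedigree), or `"none"` (classical, unknown parents = unrelated base).
#' @param traits trait indices modelled (subset of 1:3 for the default
#'   variance components; traits 2-3 carry maternal, mpe and sire-flock-year
#'   terms when their variances are non-zero).
#' @param gamma a `gamma_matrix` (required for `grouping = "mf"`).
#' @param groupdef a [group_definition][assign_groups()] (required for
#'   `"upg"` and `"mf"`).
#' @param a22_grouped for `"upg"` ssGBLUP: compute the genotyped pedigree
#'   block from the group-augmented relationship rather than the classical
#'   one (default classical).
#' @param blend_weights weights for [blend_g()].
#' @return list of class `model_spec`.
#' @export
model_spec <- function(method = c("blup", "ssgblup"),
                       grouping = c("none", "upg", "mf"),
                       traits = 1:3, gamma = NULL, groupdef = NULL,
                       a22_grouped = FALSE, blend_weights = c(0.95, 0.05)) {
  method <- match.arg(method)
  grouping <- match.arg(grouping)
  if (grouping == "mf" && is.null(gamma)) stop("metafounder model needs a gamma matrix")
  if (grouping %in% c("upg", "mf") && is.null(groupdef))
    stop("grouping model needs a group definition")
  structure(list(method = method, grouping = grouping, traits = traits,
                 gamma = gamma, groupdef = groupdef,
                 a22_grouped = a22_grouped, blend_weights = blend_weights),
            class = "model_spec")
}

#' Build the relationship structure for an evaluation
#'
#' Returns the sparse precision (inverse relationship) matrix over the model
#' entities: animals then groups for the UPG/QP model, metafounders then
#' animals for the metafounder model, animals only otherwise. For ssGBLUP
#' the genomic information enters as the appropriate H-inverse (VanRaden G
#' on observed frequencies for UPG/none, on 0.5 frequencies for
#' metafounders, blended 0.95/0.05 with the matching pedigree block).
#'
#' @param pedigree sorted pedigree.
#' @param genotypes a [genotype_set()] of genotyped animals or `NULL`.
#' @param spec a [model_spec()].
#' @return list with `Kinv`, `entity_ids`, `animal_idx` (entity positions of
#'   the pedigree animals), `Q` (animals x groups, UPG only), `F`
#'   (classical pedigree inbreeding), `geno_ids`.
#' @export
build_relationship <- function(pedigree, genotypes, spec) {
  validate_pedigree(pedigree)
  use_g <- spec$method == "ssgblup" && !is.null(genotypes) &&
    length(genotypes$animal_ids) > 0
  geno_ids <- if (use_g) genotypes$animal_ids else integer(0)
  if (use_g && !all(geno_ids %in% pedigree$id))
    stop("genotyped animals missing from pedigree")
  n <- nrow(pedigree)
  wG <- spec$blend_weights[1]; wA <- spec$blend_weights[2]

  if (spec$grouping == "mf") {
    gam <- check_gamma(spec$gamma)
    ag <- a_gamma(pedigree, spec$groupdef, gam)
    if (is.null(ag$Ainv)) stop("Gamma is singular; cannot build the augmented inverse")
    ng <- ag$n_groups
    animal_idx <- ng + seq_len(n)
    Kinv <- ag$Ainv
    if (use_g) {
      gpos <- ng + match(geno_ids, pedigree$id)
      A22g <- ag$A[gpos, gpos, drop = FALSE]
      G <- g_vanraden(genotypes, "0.5")
      G05 <- blend_g(G, A22g, wG, wA)
      Kinv <- h_inverse_mf(Kinv, G05, spd_inverse(A22g, "A_Gamma22"), gpos)
    }
    return(list(Kinv = Kinv, entity_ids = ag$ids, animal_idx = animal_idx,
                Q = NULL, F = ag$F, geno_ids = geno_ids,
                self = ag$self, grouping = "mf"))
  }

  ar <- a_inverse(pedigree)
  if (spec$grouping == "upg") {
    Q <- group_fractions(pedigree, spec$groupdef)
    Kinv <- upg_augmented_inverse(ar$Ainv, Q)
    entity_ids <- c(as.character(pedigree$id), colnames(Q))
  } else {
    Q <- matrix(0, n, 0)
    Kinv <- Matrix::forceSymmetric(methods::as(ar$Ainv, "CsparseMatrix"))
    entity_ids <- as.character(pedigree$id)
  }
  animal_idx <- seq_len(n)
  if (use_g) {
    gpos <- match(geno_ids, pedigree$id)
    A22 <- a_matrix(pedigree)[gpos, gpos, drop = FALSE]
    if (spec$grouping == "upg" && spec$a22_grouped)
      # group-augmented variant: Var(u)/sigma2 = A + QQ' when the random
      # groups carry identity covariance
      A22 <- A22 + tcrossprod(Q[gpos, , drop = FALSE])
    G <- g_vanraden(genotypes, "observed")
    G05 <- blend_g(G, A22, wG, wA)
    Kinv <- h_inverse_upg(Kinv, G05, spd_inverse(A22, "A22"), gpos,
                          Q[gpos, , drop = FALSE])
  }
  list(Kinv = Kinv, entity_ids = entity_ids, animal_idx = animal_idx,
       Q = Q, F = ar$F, geno_ids = geno_ids, grouping = spec$grouping)
}

# genetic slot bookkeeping: direct slots for every modelled trait, maternal
# slots for modelled traits with a mat slot in G0
model_slots <- function(traits, varcomp) {
  G0 <- varcomp$G0
  dir_slots <- paste0("dir", traits)
  if (!all(dir_slots %in% rownames(G0)))
    stop("G0 lacks slots: ", paste(setdiff(dir_slots, rownames(G0)), collapse = ", "))
  mat_traits <- traits[paste0("mat", traits) %in% rownames(G0)]
  mat_slots <- if (length(mat_traits)) paste0("mat", mat_traits) else character(0)
  slots <- c(dir_slots, mat_slots)
  list(slots = slots, traits = traits, mat_traits = mat_traits,
       G0s = G0[slots, slots, drop = FALSE])
}

#' Assemble the multitrait mixed-model equations
#'
#' Henderson system with per-record residual precision sub-blocks (records
#' missing a trait use the inverse of the corresponding `R0` sub-matrix),
#' contemporary group as the only fixed effect per trait, correlated direct
#' and maternal genetic effects with precision `G0^-1` Kronecker the entity
#' relationship inverse, and independent maternal permanent environmental
#' (dam-indexed) and sire-by-flock-year random effects.
#'
#' @param phenotypes data frame with `id`, `cg`, `sire`, `dam`, `flock`,
#'   `year` and trait columns `t1`, `t2`, ...
#' @param rel output of [build_relationship()].
#' @param varcomp a [varcomp()].
#' @param traits modelled trait indices.
#' @return list of class `mme_system` with sparse `LHS`, `rhs`, and the
#'   index maps needed to unpack solutions.
#' @export
build_mme <- function(phenotypes, rel, varcomp, traits = 1:3) {
  stopifnot(inherits(varcomp, "varcomp"))
  sl <- model_slots(traits, varcomp)
  n_e <- length(rel$entity_ids)
  ns <- length(sl$slots)
  ped_pos <- function(ids) rel$animal_idx[match(as.character(ids),
                                                rel$entity_ids[rel$animal_idx])]
  phe <- phenotypes
  tcols <- paste0("t", traits)
  stopifnot(all(tcols %in% names(phe)))
  has_any <- rowSums(!is.na(as.matrix(phe[, tcols, drop = FALSE]))) > 0
  phe <- phe[has_any, , drop = FALSE]
  arow <- ped_pos(phe$id)
  if (anyNA(arow)) stop("phenotyped animal absent from pedigree")

  # effect level maps
  cg_levels <- lapply(traits, function(t)
    sort(unique(phe$cg[!is.na(phe[[paste0("t", t)]])])))
  names(cg_levels) <- tcols
  M0d <- diag(as.matrix(varcomp$M0)); S0d <- diag(as.matrix(varcomp$S0))
  # M0/S0 diagonals are aligned with the full maternal slot order of G0
  full_mat <- as.integer(sub("mat", "", grep("^mat", rownames(varcomp$G0),
                                             value = TRUE)))
  mt_all <- sl$mat_traits
  midx <- match(mt_all, full_mat)
  mpe_traits <- mt_all[M0d[midx] > 0]
  sfy_traits <- mt_all[S0d[midx] > 0]
  dam_ok <- !is.na(phe$dam) & phe$dam > 0
  sire_ok <- !is.na(phe$sire) & phe$sire > 0
  mpe_levels <- sort(unique(phe$dam[dam_ok]))
  sfy_code <- ifelse(sire_ok, paste(phe$sire, phe$flock, phe$year, sep = "_"), NA)
  sfy_levels <- sort(unique(sfy_code[!is.na(sfy_code)]))

  # equation layout
  off <- 0L
  cg_off <- integer(length(traits)); names(cg_off) <- tcols
  for (t in tcols) { cg_off[t] <- off; off <- off + length(cg_levels[[t]]) }
  gen_off <- off; off <- off + ns * n_e
  mpe_off <- setNames(rep(NA_integer_, length(mpe_traits)), mpe_traits)
  for (t in as.character(mpe_traits)) { mpe_off[t] <- off; off <- off + length(mpe_levels) }
  sfy_off <- setNames(rep(NA_integer_, length(sfy_traits)), sfy_traits)
  for (t in as.character(sfy_traits)) { sfy_off[t] <- off; off <- off + length(sfy_levels) }
  n_eq <- off

  slot_col <- function(slot, entity_pos)
    gen_off + (match(slot, sl$slots) - 1L) * n_e + entity_pos

  # per-trait design columns for every record (NA = effect absent)
  dam_pos <- ped_pos(phe$dam)
  nrec <- nrow(phe)
  design <- list()
  for (t in traits) {
    tc <- paste0("t", t)
    cols <- cbind(
      cg = cg_off[tc] + match(phe$cg, cg_levels[[tc]]),
      dir = slot_col(paste0("dir", t), arow),
      mat = if (t %in% sl$mat_traits)
        ifelse(dam_ok, slot_col(paste0("mat", t), dam_pos), NA) else rep(NA, nrec),
      mpe = if (t %in% mpe_traits)
        ifelse(dam_ok, mpe_off[as.character(t)] + match(phe$dam, mpe_levels), NA)
      else rep(NA, nrec),
      sfy = if (t %in% sfy_traits)
        ifelse(sire_ok, sfy_off[as.character(t)] + match(sfy_code, sfy_levels), NA)
      else rep(NA, nrec))
    cols[is.na(phe[[tc]]), ] <- NA   # trait unobserved: no equations touched
    design[[tc]] <- cols
  }

  R0 <- as.matrix(varcomp$R0)[traits, traits, drop = FALSE]
  dimnames(R0) <- list(tcols, tcols)
  Y <- as.matrix(phe[, tcols, drop = FALSE])
  patt <- apply(!is.na(Y), 1L, function(z) paste(as.integer(z), collapse = ""))
  ii <- jj <- xx <- list(); ri <- rx <- list()
  for (pt in unique(patt)) {
    recs <- which(patt == pt)
    obs <- which(strsplit(pt, "")[[1]] == "1")
    Einv <- solve(R0[obs, obs, drop = FALSE])
    for (a in seq_along(obs)) for (b in seq_along(obs)) {
      ta <- tcols[obs[a]]; tb <- tcols[obs[b]]
      w <- Einv[a, b]
      Da <- design[[ta]][recs, , drop = FALSE]
      Db <- design[[tb]][recs, , drop = FALSE]
      yb <- Y[recs, obs[b]]
      for (ca in 1:5) {
        colsa <- Da[, ca]
        oka <- !is.na(colsa)
        if (!any(oka)) next
        # RHS once per (ta, tb, ca)
        ri[[length(ri) + 1L]] <- colsa[oka]
        rx[[length(rx) + 1L]] <- w * yb[oka]
        for (cb in 1:5) {
          colsb <- Db[, cb]
          ok <- oka & !is.na(colsb)
          if (!any(ok)) next
          ii[[length(ii) + 1L]] <- colsa[ok]
          jj[[length(jj) + 1L]] <- colsb[ok]
          xx[[length(xx) + 1L]] <- rep(w, sum(ok))
        }
      }
    }
  }
  LHS <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(n_eq, n_eq))
  rhs <- numeric(n_eq)
  riv <- unlist(ri); rxv <- unlist(rx)
  if (length(riv)) {
    agg <- rowsum(rxv, riv)
    rhs[as.integer(rownames(agg))] <- agg[, 1]
  }

  # random-effect precisions
  G0inv <- solve(sl$G0s)
  LHS <- LHS + gen_block(G0inv, rel$Kinv, gen_off, n_eq)
  for (t in as.character(mpe_traits)) {
    k <- match(as.numeric(t), full_mat)
    LHS <- LHS + diag_block(1 / M0d[k], length(mpe_levels), mpe_off[t], n_eq)
  }
  for (t in as.character(sfy_traits)) {
    k <- match(as.numeric(t), full_mat)
    LHS <- LHS + diag_block(1 / S0d[k], length(sfy_levels), sfy_off[t], n_eq)
  }
  structure(list(LHS = Matrix::forceSymmetric(LHS), rhs = rhs, n_eq = n_eq,
                 layout = list(cg_off = cg_off, cg_levels = cg_levels,
                               gen_off = gen_off, slots = sl$slots, n_e = n_e,
                               mpe_off = mpe_off, mpe_levels = mpe_levels,
                               sfy_off = sfy_off, sfy_levels = sfy_levels),
                 rel = rel, traits = traits),
            class = "mme_system")
}

# kron(G0inv, Kinv) placed at gen_off within an n_eq system
gen_block <- function(G0inv, Kinv, gen_off, n_eq) {
  Kg <- Matrix::kronecker(methods::as(as.matrix(G0inv), "CsparseMatrix"),
                          methods::as(Kinv, "CsparseMatrix"))
  Kg <- methods::as(Kg, "TsparseMatrix")
  Matrix::sparseMatrix(i = Kg@i + 1L + gen_off, j = Kg@j + 1L + gen_off,
                       x = Kg@x, dims = c(n_eq, n_eq))
}

diag_block <- function(w, n, off, n_eq) {
  if (n == 0L) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                           x = numeric(0), dims = c(n_eq, n_eq)))
  Matrix::sparseMatrix(i = off + seq_len(n), j = off + seq_len(n),
                       x = rep(w, n), dims = c(n_eq, n_eq))
}

#' Solve a mixed-model system
#'
#' Sparse Cholesky factorisation by default; a Jacobi-preconditioned
#' conjugate-gradient solver is available and used automatically above
#' `pcg_above` equations.
#'
#' @param system an `mme_system` (or list with `LHS`, `rhs`).
#' @param method `"auto"`, `"cholesky"` or `"pcg"`.
#' @param tol relative-residual convergence tolerance (PCG).
#' @param max_iter PCG iteration cap.
#' @param pcg_above equation count beyond which `"auto"` switches to PCG.
#' @return list of class `mme_solution`: `x`, `relative_residual`, `method`,
#'   `iterations`.
#' @export
solve_mme <- function(system, method = c("auto", "cholesky", "pcg"),
                      tol = 1e-10, max_iter = 5000L, pcg_above = 150000L) {
  method <- match.arg(method)
  A <- Matrix::forceSymmetric(system$LHS)
  b <- system$rhs
  if (method == "auto")
    method <- if (nrow(A) > pcg_above) "pcg" else "cholesky"
  iters <- 0L
  if (!any(b != 0)) {
    x <- numeric(length(b))
  } else if (method == "cholesky") {
    ch <- tryCatch(Matrix::Cholesky(A, LDL = TRUE, perm = TRUE),
                   error = function(e) NULL)
    x <- if (!is.null(ch)) as.vector(Matrix::solve(ch, b)) else
      as.vector(Matrix::solve(A, b))
  } else {
    Ac <- methods::as(A, "CsparseMatrix")
    pre <- 1 / Matrix::diag(Ac)
    x <- numeric(length(b))
    r <- b
    z <- pre * r
    p <- z
    rz <- sum(r * z)
    bn <- sqrt(sum(b^2))
    repeat {
      iters <- iters + 1L
      Ap <- as.vector(Ac %*% p)
      alpha <- rz / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      if (sqrt(sum(r^2)) / bn <= tol) break
      if (iters >= max_iter)
        stop("PCG failed to converge in ", max_iter,
             " iterations (relative residual ",
             signif(sqrt(sum(r^2)) / bn, 3), ")")
      z <- pre * r
      rz_new <- sum(r * z)
      p <- z + (rz_new / rz) * p
      rz <- rz_new
    }
  }
  res <- sqrt(sum((as.vector(A %*% x) - b)^2)) / max(sqrt(sum(b^2)), 1e-300)
  if (any(b != 0) && res > 1e-6)
    warning("large relative residual after solve: ", signif(res, 3))
  structure(list(x = x, relative_residual = res, method = method,
                 iterations = iters), class = "mme_solution")
}

#' Run a complete (ss)GBLUP evaluation
#'
#' Builds the relationship structure required by the model specification,
#' assembles the multitrait system, solves it, and unpacks the solutions.
#' Under the UPG/QP parameterisation the animal equations already carry the
#' group contributions, so the returned EBVs are total breeding values for
#' every grouping method.
#'
#' @param dataset list with `pedigree`, `phenotypes`, and optionally
#'   `genotypes`.
#' @param spec a [model_spec()].
#' @param varcomp a [varcomp()] (default [default_varcomp()]).
#' @param relationship optional precomputed [build_relationship()] output
#'   (reused across partial/whole runs of one scenario).
#' @param solver passed to [solve_mme()].
#' @return list of class `evaluation`: `ebv` (animals x genetic slots,
#'   total), `groups` (UPG or metafounder solutions per slot), `fixed`,
#'   `mpe`, `sfy`, `solution` (solver diagnostics), `rel`.
#' @export
run_evaluation <- function(dataset, spec, varcomp = default_varcomp(),
                           relationship = NULL, solver = "auto") {
  ped <- dataset$pedigree
  rel <- if (is.null(relationship))
    build_relationship(ped, dataset$genotypes, spec) else relationship
  sys <- build_mme(dataset$phenotypes, rel, varcomp, spec$traits)
  sol <- solve_mme(sys, method = solver)
  lay <- sys$layout
  x <- sol$x
  ns <- length(lay$slots)
  gen <- matrix(x[lay$gen_off + seq_len(ns * lay$n_e)], lay$n_e, ns,
                dimnames = list(rel$entity_ids, lay$slots))
  ebv <- gen[rel$animal_idx, , drop = FALSE]
  rownames(ebv) <- rel$entity_ids[rel$animal_idx]
  grp <- gen[setdiff(seq_len(lay$n_e), rel$animal_idx), , drop = FALSE]
  fixed <- lapply(names(lay$cg_levels), function(t)
    setNames(x[lay$cg_off[t] + seq_along(lay$cg_levels[[t]])],
             lay$cg_levels[[t]]))
  names(fixed) <- names(lay$cg_levels)
  mpe <- lapply(names(lay$mpe_off), function(t)
    setNames(x[lay$mpe_off[t] + seq_along(lay$mpe_levels)], lay$mpe_levels))
  names(mpe) <- names(lay$mpe_off)
  sfy <- lapply(names(lay$sfy_off), function(t)
    setNames(x[lay$sfy_off[t] + seq_along(lay$sfy_levels)], lay$sfy_levels))
  names(sfy) <- names(lay$sfy_off)
  structure(list(ebv = ebv, groups = grp, fixed = fixed, mpe = mpe, sfy = sfy,
                 solution = sol, rel = rel, spec = spec),
            class = "evaluation")
}

#' @exportS3Method base::print
print.evaluation <- function(x, ...) {
  cat("evaluation:", x$spec$method, "/", x$spec$grouping, "-",
      nrow(x$ebv), "animals,", ncol(x$ebv), "genetic slots; solver",
      x$solution$method, sprintf("(rel. residual %.2e)\n",
                                 x$solution$relative_residual))
  invisible(x)
}
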