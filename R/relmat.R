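# Pedigree, genomic and single-step relationship matrices and inverses.

#' Pedigree inbreeding coefficients
#'
#' Meuwissen & Luo style algorithm: for each animal the row of the Cholesky
#' factor of A over its ancestors is accumulated, giving
#' \eqn{1 + F_i = \sum_j L_{ij}^2 D_j}. Unknown parents are treated as
#' unrelated, non-inbred base animals.
#'
#' @param pedigree sorted pedigree (`id`, `sire`, `dam`).
#' @return numeric vector of inbreeding coefficients `F`, one per animal.
#' @export
pedigree_inbreeding <- function(pedigree) {
  validate_pedigree(pedigree)
  pr <- ped_parent_rows(pedigree)
  s <- pr$s; d <- pr$d
  n <- nrow(pedigree)
  F <- numeric(n)
  Dv <- numeric(n)  # mendelian sampling variance of each animal
  L <- numeric(n)
  for (i in seq_len(n)) {
    fs <- if (is.na(s[i])) -1 else F[s[i]]
    fd <- if (is.na(d[i])) -1 else F[d[i]]
    Dv[i] <- 0.5 - 0.25 * (fs + fd)
    if (is.na(s[i]) || is.na(d[i])) next
    touched <- i
    L[i] <- 1
    acc <- 0
    # process ancestors in decreasing row order
    stack <- i
    inq <- logical(n); inq[i] <- TRUE
    while (length(stack)) {
      j <- max(stack)
      stack <- stack[stack != j]
      inq[j] <- FALSE
      lj <- L[j]
      acc <- acc + lj * lj * Dv[j]
      for (p in c(s[j], d[j])) {
        if (is.na(p)) next
        if (L[p] == 0 && !inq[p]) { stack <- c(stack, p); inq[p] <- TRUE; touched <- c(touched, p) }
        else if (!inq[p]) { stack <- c(stack, p); inq[p] <- TRUE }
        L[p] <- L[p] + 0.5 * lj
      }
    }
    F[i] <- acc - 1
    L[touched] <- 0
  }
  names(F) <- pedigree$id
  F
}

#' Sparse inverse of the pedigree relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' \eqn{(e_i - \tfrac12 \sum_{p} e_p)(\cdot)'/D_i} with
#' \eqn{D_i = \tfrac12 - \tfrac14(F_s + F_d)} (an unknown parent contributes
#' \eqn{F = -1}, i.e. \eqn{D_i = 1} for founders).
#'
#' @param pedigree sorted pedigree.
#' @return object of class `ped_relationship`: sparse `Ainv`, inbreeding `F`,
#'   mendelian sampling variances `D`, and the animal `ids`.
#' @export
a_inverse <- function(pedigree) {
  F <- pedigree_inbreeding(pedigree)
  pr <- ped_parent_rows(pedigree)
  n <- nrow(pedigree)
  fs <- ifelse(is.na(pr$s), -1, F[pr$s])
  fd <- ifelse(is.na(pr$d), -1, F[pr$d])
  D <- 0.5 - 0.25 * (fs + fd)
  Ainv <- henderson_inverse(n, seq_len(n), pr$s, pr$d, D)
  dimnames(Ainv) <- list(pedigree$id, pedigree$id)
  structure(list(Ainv = Ainv, F = F, D = D, ids = as.integer(pedigree$id)),
            class = "ped_relationship")
}

# assemble sum over animals of (1/D_i)(e_i - .5 e_s - .5 e_d)(...)' plus an
# optional precision block on the base entities; `self`, `s`, `d` are entity
# indices into a system of dimension `dim_n` (NA = no such parent)
henderson_inverse <- function(dim_n, self, s, d, D, base_block = NULL) {
  n <- length(self)
  ii <- jj <- xx <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- c(self[i], s[i], d[i])
    co <- c(1, -0.5, -0.5)[!is.na(idx)]
    idx <- idx[!is.na(idx)]
    cp <- outer(co, co) / D[i]
    ii[[i]] <- rep(idx, each = length(idx))
    jj[[i]] <- rep(idx, times = length(idx))
    xx[[i]] <- as.vector(cp)
  }
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(dim_n, dim_n))
  if (!is.null(base_block)) {
    nb <- nrow(base_block)
    M <- M + Matrix::bdiag(methods::as(as.matrix(base_block), "CsparseMatrix"),
                           Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                x = numeric(0),
                                                dims = c(dim_n - nb, dim_n - nb)))
  }
  Matrix::forceSymmetric(M)
}

#' Dense pedigree relationship matrix (tabular method)
#'
#' @param pedigree sorted pedigree.
#' @param max_n guard against accidental huge dense allocations.
#' @return dense numerator relationship matrix A.
#' @export
a_matrix <- function(pedigree, max_n = 8000L) {
  validate_pedigree(pedigree)
  n <- nrow(pedigree)
  if (n > max_n) stop("dense A requested for ", n, " animals (> ", max_n, ")")
  pr <- ped_parent_rows(pedigree)
  A <- matrix(0, n, n, dimnames = list(pedigree$id, pedigree$id))
  for (i in seq_len(n)) {
    s <- pr$s[i]; d <- pr$d[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (!is.na(s)) v <- v + 0.5 * A[s, prev]
      if (!is.na(d)) v <- v + 0.5 * A[d, prev]
      A[i, prev] <- v
      A[prev, i] <- v
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Metafounder-augmented pedigree relationship
#'
#' Metafounders enter the pedigree as pseudo-parents: the base block of the
#' tabular recursion is the ancestral relationship matrix Gamma, every
#' missing parent slot is replaced by the metafounder of the animal's
#' population x cohort, and the recursion is otherwise standard, so a founder
#' assigned to metafounder g has self-relationship \eqn{1 + \Gamma_{gg}/2}.
#' The sparse inverse uses the generalised Henderson rules with
#' \eqn{D_i = a_{ii} - \tfrac14(a_{ss} + a_{dd} + 2a_{sd})} and
#' \eqn{\Gamma^{-1}} on the metafounder block.
#'
#' @param pedigree sorted pedigree with `pop` and `year`.
#' @param groupdef a [group_definition] from [assign_groups()].
#' @param gamma a `gamma_matrix` (see [check_gamma()]) whose rows follow
#'   `groupdef$groups$group`.
#' @param max_n dense-recursion gate.
#' @return object of class `ped_relationship_gamma`: dense `A` over entities
#'   (metafounders first, then animals), sparse `Ainv` when Gamma is
#'   invertible, self-relationships, classical-scale inbreeding `F` of the
#'   non-augmented pedigree, entity ids and the genotype-ready index map.
#' @export
a_gamma <- function(pedigree, groupdef, gamma, max_n = 8000L) {
  validate_pedigree(pedigree, require_year = TRUE, require_pop = TRUE)
  G <- as.matrix(if (inherits(gamma, "gamma_matrix")) gamma$values else gamma)
  groups <- groupdef$groups$group
  stopifnot(nrow(G) == length(groups))
  ng <- length(groups)
  n <- nrow(pedigree)
  if (n + ng > max_n) stop("dense recursion gate exceeded (", n + ng, " entities)")
  # map each missing parent slot to its metafounder entity
  gidx <- map_unknown_parents(pedigree, groupdef)  # list(s=, d=) metafounder index or NA
  pr <- ped_parent_rows(pedigree)
  s <- ifelse(is.na(pr$s), gidx$s, pr$s + ng)
  d <- ifelse(is.na(pr$d), gidx$d, pr$d + ng)
  N <- ng + n
  A <- matrix(0, N, N)
  A[seq_len(ng), seq_len(ng)] <- G
  for (k in seq_len(n)) {
    i <- ng + k
    prev <- seq_len(i - 1L)
    v <- 0.5 * (A[s[k], prev] + A[d[k], prev])
    A[i, prev] <- v
    A[prev, i] <- v
    A[i, i] <- 1 + 0.5 * A[s[k], d[k]]
  }
  ids <- c(paste0("MF:", groups), pedigree$id)
  dimnames(A) <- list(ids, ids)
  D <- A[cbind(ng + seq_len(n), ng + seq_len(n))] -
    0.25 * (A[cbind(s, s)] + A[cbind(d, d)] + 2 * A[cbind(s, d)])
  Ainv <- NULL
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > 1e-10) {
    Ginv <- solve(G)
    Ainv <- henderson_inverse(N, ng + seq_len(n), s, d, D, base_block = Ginv)
    dimnames(Ainv) <- list(ids, ids)
  }
  structure(list(A = A, Ainv = Ainv, D = D,
                 self = diag(A)[ng + seq_len(n)],
                 F = pedigree_inbreeding(pedigree),
                 ids = ids, n_groups = ng, animal_ids = as.integer(pedigree$id)),
            class = "ped_relationship_gamma")
}

#' VanRaden genomic relationship matrix
#'
#' \eqn{G = ZZ'/s} with \eqn{Z = M - 2p} and scaling
#' \eqn{s = 2\sum p_i(1-p_i)} under observed frequencies, or \eqn{p = 0.5}
#' and \eqn{s = m/2} under the metafounder convention.
#'
#' @param g a [genotype_set()] with complete calls.
#' @param freq_convention `"observed"` or `"0.5"`.
#' @return object of class `genomic_relationship`: dense `G`, frequencies
#'   used, convention tag, ids, and the monomorphic markers excluded from the
#'   observed-frequency scaling.
#' @export
g_vanraden <- function(g, freq_convention = c("observed", "0.5")) {
  stopifnot(inherits(g, "genotype_set"))
  freq_convention <- match.arg(freq_convention)
  if (anyNA(g$calls)) stop("complete calls required (run QC / simulate without missingness)")
  M <- g$calls
  m <- ncol(M)
  if (freq_convention == "observed") {
    p <- colMeans(M) / 2
    mono <- g$marker_ids[p <= 0 | p >= 1]
    s <- 2 * sum(p * (1 - p))
  } else {
    p <- rep(0.5, m)
    mono <- character(0)
    s <- m / 2
  }
  Z <- sweep(M, 2L, 2 * p)
  G <- tcrossprod(Z) / s
  dimnames(G) <- list(g$animal_ids, g$animal_ids)
  structure(list(G = G, p = p, freq_convention = freq_convention,
                 ids = g$animal_ids, monomorphic = mono),
            class = "genomic_relationship")
}

#' Blend genomic and pedigree relationship matrices
#'
#' `wG * G + wA * A_block`, the standard guard making G invertible in
#' single-step systems.
#'
#' @param G genomic relationship (matrix or `genomic_relationship`).
#' @param A_ref_block matching pedigree block (A22 or its Gamma analogue).
#' @param wG,wA blending weights, must sum to 1.
#' @return dense blended matrix.
#' @export
blend_g <- function(G, A_ref_block, wG = 0.95, wA = 0.05) {
  if (inherits(G, "genomic_relationship")) G <- G$G
  A_ref_block <- as.matrix(A_ref_block)
  stopifnot(abs(wG + wA - 1) < 1e-12)
  if (!all(dim(G) == dim(A_ref_block))) stop("dimension mismatch between G and A block")
  wG * G + wA * A_ref_block
}

# embed a dense block at (rows, cols) of an N x N sparse matrix
block_embed <- function(B, rows, cols, N) {
  B <- as.matrix(B)
  Matrix::sparseMatrix(i = rep(rows, times = ncol(B)),
                       j = rep(cols, each = nrow(B)),
                       x = as.vector(B), dims = c(N, N))
}

# inverse of a dense SPD matrix with an informative failure
spd_inverse <- function(M, what = "matrix") {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch))
    stop(what, " is singular or not positive definite; consider blending with the pedigree block")
  chol2inv(ch)
}

#' Single-step H-inverse under the UPG (QP) model
#'
#' Adds \eqn{G^{-1} - A_{22}^{-1}} on the genotyped block of the
#' group-augmented pedigree inverse, with the coupling blocks
#' \eqn{-(G^{-1}-A_{22}^{-1})Q_2} and \eqn{Q_2'(G^{-1}-A_{22}^{-1})Q_2}
#' against the group equations.
#'
#' @param A_inv_aug group-augmented pedigree inverse over
#'   `c(animals, groups)` (see [upg_augmented_inverse()]).
#' @param G05 blended genomic matrix of the genotyped animals.
#' @param A22_inv inverse of the pedigree block of the genotyped animals.
#' @param geno_idx positions of the genotyped animals among the animal
#'   entities.
#' @param Q2 group-fraction rows of the genotyped animals (may have zero
#'   columns when there are no groups).
#' @return sparse symmetric H-inverse over `c(animals, groups)`.
#' @export
h_inverse_upg <- function(A_inv_aug, G05, A22_inv, geno_idx, Q2) {
  N <- nrow(A_inv_aug)
  ng <- ncol(Q2)
  n2 <- length(geno_idx)
  if (n2 == 0L) return(A_inv_aug)
  Ginv <- spd_inverse(G05, "blended G")
  W <- Ginv - A22_inv
  add <- block_embed(W, geno_idx, geno_idx, N)
  if (ng > 0) {
    gcols <- N - ng + seq_len(ng)
    WQ <- W %*% as.matrix(Q2)
    add <- add + block_embed(-WQ, geno_idx, gcols, N) +
      block_embed(-t(WQ), gcols, geno_idx, N) +
      block_embed(crossprod(as.matrix(Q2), WQ), gcols, gcols, N)
  }
  Matrix::forceSymmetric(as(A_inv_aug, "CsparseMatrix") + add)
}

#' Single-step H-inverse under the metafounder model
#'
#' \eqn{H_\Gamma^{-1} = A_\Gamma^{-1} + [G_{05}^{-1} - A_{\Gamma 22}^{-1}]}
#' on the genotyped block; no group coupling blocks because the metafounders
#' live inside \eqn{A_\Gamma}.
#'
#' @param A_gamma_inv sparse Gamma-augmented pedigree inverse (metafounders
#'   first).
#' @param G05 blended genomic matrix (0.5-frequency convention).
#' @param A_g22_inv inverse of the Gamma-augmented pedigree block of the
#'   genotyped animals.
#' @param geno_idx positions of the genotyped animals among the entities.
#' @return sparse symmetric H-inverse over the entities.
#' @export
h_inverse_mf <- function(A_gamma_inv, G05, A_g22_inv, geno_idx) {
  if (length(geno_idx) == 0L) return(A_gamma_inv)
  Ginv <- spd_inverse(G05, "blended G")
  N <- nrow(A_gamma_inv)
  add <- block_embed(Ginv - A_g22_inv, geno_idx, geno_idx, N)
  Matrix::forceSymmetric(as(A_gamma_inv, "CsparseMatrix") + add)
}

#' Group-augmented pedigree inverse for the UPG model
#'
#' Precision of the joint vector `(u, g)` when `u = Qg + u*`,
#' `Var(u*) = A` and the groups are random with identity covariance:
#' \deqn{\begin{pmatrix} A^{-1} & -A^{-1}Q \\ -Q'A^{-1} & Q'A^{-1}Q + I
#' \end{pmatrix}.}
#'
#' @param Ainv sparse pedigree inverse (animals only).
#' @param Q animals x groups expected group fractions (zero columns allowed).
#' @return sparse symmetric matrix over `c(animals, groups)`.
#' @export
upg_augmented_inverse <- function(Ainv, Q) {
  n <- nrow(Ainv)
  ng <- ncol(Q)
  if (ng == 0L) return(Matrix::forceSymmetric(as(Ainv, "CsparseMatrix")))
  Qs <- as(Q, "CsparseMatrix")
  AQ <- Ainv %*% Qs
  top <- cbind(as(Ainv, "CsparseMatrix"), -AQ)
  bot <- cbind(-t(AQ), crossprod(Qs, AQ) + Matrix::Diagonal(ng))
  Matrix::forceSymmetric(rbind(top, bot))
}
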