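# Independent brute-force oracles: written with naive per-element loops so
# they share no code path with the package implementations.

# tabular relationship matrix, element by element; `base` optionally gives a
# relationship block for the first nb entities (metafounder base), in which
# case sire/dam columns must reference entity indices and be complete
oracle_A <- function(ped, base = NULL) {
  id <- ped$id
  n <- nrow(ped)
  s <- match(ped$sire, id)
  d <- match(ped$dam, id)
  nb <- if (is.null(base)) 0L else nrow(base)
  N <- nb + n
  A <- matrix(0, N, N)
  if (nb) A[1:nb, 1:nb] <- base
  si <- ifelse(is.na(s), ped$sire_base %||% NA, s + nb)
  di <- ifelse(is.na(d), ped$dam_base %||% NA, d + nb)
  for (k in 1:n) {
    i <- nb + k
    for (j in seq_len(i - 1L)) {
      v <- 0
      if (!is.na(si[k])) v <- v + 0.5 * A[si[k], j]
      if (!is.na(di[k])) v <- v + 0.5 * A[di[k], j]
      A[i, j] <- A[j, i] <- v
    }
    A[i, i] <- 1 + if (!is.na(si[k]) && !is.na(di[k])) 0.5 * A[si[k], di[k]] else 0
  }
  A
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# recursive expected-fraction oracle (breed or group fractions)
oracle_fractions <- function(ped, cols, unknown_col_of) {
  id <- ped$id
  s <- match(ped$sire, id)
  d <- match(ped$dam, id)
  out <- matrix(0, nrow(ped), length(cols), dimnames = list(id, cols))
  rec <- function(i) {
    if (any(out[i, ] != 0)) return(out[i, ])
    row <- numeric(length(cols))
    for (p in c(s[i], d[i])) {
      if (is.na(p)) {
        u <- unknown_col_of(i)
        row[u] <- row[u] + 0.5
      } else row <- row + 0.5 * rec(p)
    }
    if (all(row == 0)) {  # founder with both parents unknown
      u <- unknown_col_of(i)
      row[u] <- 1
    }
    out[i, ] <<- row
    row
  }
  for (i in seq_len(nrow(ped))) rec(i)
  out
}

# random sorted pedigree with optional unknown dams
random_pedigree <- function(n, n_founders = 10, missing_dam = 0, seed = 1,
                            years = NULL) {
  set.seed(seed)
  sire <- dam <- integer(n)
  for (i in (n_founders + 1):n) {
    sire[i] <- sample(max(1, i - 40):(i - 1), 1)
    dam[i] <- sample(max(1, i - 40):(i - 1), 1)
    if (dam[i] == sire[i]) dam[i] <- 0L
    if (runif(1) < missing_dam) dam[i] <- 0L
  }
  ped <- data.frame(id = 1:n, sire = sire, dam = dam)
  if (!is.null(years))
    ped$year <- sort(sample(years, n, replace = TRUE))
  ped
}

# dense multitrait MME oracle via stacked GLS with explicit incidence rows
oracle_mme_solution <- function(phe, Kinv_dense, entity_ids, animal_idx,
                                varcomp, traits) {
  tcols <- paste0("t", traits)
  G0 <- varcomp$G0
  dir_slots <- paste0("dir", traits)
  mat_traits <- traits[paste0("mat", traits) %in% rownames(G0)]
  slots <- c(dir_slots, if (length(mat_traits)) paste0("mat", mat_traits))
  G0s <- G0[slots, slots, drop = FALSE]
  full_mat <- as.integer(sub("mat", "", grep("^mat", rownames(G0), value = TRUE)))
  M0d <- if (length(full_mat)) diag(as.matrix(varcomp$M0)) else numeric(0)
  S0d <- if (length(full_mat)) diag(as.matrix(varcomp$S0)) else numeric(0)
  n_e <- length(entity_ids)

  phe <- phe[rowSums(!is.na(phe[, tcols, drop = FALSE])) > 0, ]
  cg_levels <- lapply(tcols, function(tc) sort(unique(phe$cg[!is.na(phe[[tc]])])))
  names(cg_levels) <- tcols
  dam_ok <- !is.na(phe$dam) & phe$dam > 0
  sire_ok <- !is.na(phe$sire) & phe$sire > 0
  mpe_levels <- sort(unique(phe$dam[dam_ok]))
  sfy_code <- ifelse(sire_ok, paste(phe$sire, phe$flock, phe$year, sep = "_"), NA)
  sfy_levels <- sort(unique(sfy_code[!is.na(sfy_code)]))
  mpe_traits <- mat_traits[M0d[match(mat_traits, full_mat)] > 0]
  sfy_traits <- mat_traits[S0d[match(mat_traits, full_mat)] > 0]

  off <- 0L
  cg_off <- setNames(integer(length(tcols)), tcols)
  for (tc in tcols) { cg_off[tc] <- off; off <- off + length(cg_levels[[tc]]) }
  gen_off <- off; off <- off + length(slots) * n_e
  mpe_off <- setNames(integer(length(mpe_traits)), mpe_traits)
  for (t in as.character(mpe_traits)) { mpe_off[t] <- off; off <- off + length(mpe_levels) }
  sfy_off <- setNames(integer(length(sfy_traits)), sfy_traits)
  for (t in as.character(sfy_traits)) { sfy_off[t] <- off; off <- off + length(sfy_levels) }
  n_eq <- off

  apos <- animal_idx[match(as.character(phe$id), entity_ids[animal_idx])]
  dpos <- animal_idx[match(as.character(phe$dam), entity_ids[animal_idx])]
  # stacked observation rows
  rows <- list(); yobs <- numeric(0); rec_of <- integer(0); trait_of <- integer(0)
  for (r in seq_len(nrow(phe))) for (k in seq_along(traits)) {
    t <- traits[k]; tc <- tcols[k]
    if (is.na(phe[[tc]][r])) next
    w <- numeric(n_eq)
    w[cg_off[tc] + match(phe$cg[r], cg_levels[[tc]])] <- 1
    w[gen_off + (match(paste0("dir", t), slots) - 1L) * n_e + apos[r]] <- 1
    if (t %in% mat_traits && dam_ok[r])
      w[gen_off + (match(paste0("mat", t), slots) - 1L) * n_e + dpos[r]] <- 1
    if (t %in% mpe_traits && dam_ok[r])
      w[mpe_off[as.character(t)] + match(phe$dam[r], mpe_levels)] <- 1
    if (t %in% sfy_traits && sire_ok[r])
      w[sfy_off[as.character(t)] + match(sfy_code[r], sfy_levels)] <- 1
    rows[[length(rows) + 1L]] <- w
    yobs <- c(yobs, phe[[tc]][r]); rec_of <- c(rec_of, r); trait_of <- c(trait_of, k)
  }
  W <- do.call(rbind, rows)
  R0 <- as.matrix(varcomp$R0)[traits, traits, drop = FALSE]
  Rbig <- matrix(0, length(yobs), length(yobs))
  for (r in unique(rec_of)) {
    o <- which(rec_of == r)
    Rbig[o, o] <- R0[trait_of[o], trait_of[o]]
  }
  Rinv <- solve(Rbig)
  LHS <- t(W) %*% Rinv %*% W
  rhs <- t(W) %*% Rinv %*% yobs
  gidx <- gen_off + seq_len(length(slots) * n_e)
  LHS[gidx, gidx] <- LHS[gidx, gidx] + kronecker(solve(G0s), as.matrix(Kinv_dense))
  for (t in as.character(mpe_traits)) {
    o <- mpe_off[t] + seq_along(mpe_levels)
    LHS[cbind(o, o)] <- LHS[cbind(o, o)] + 1 / M0d[match(as.numeric(t), full_mat)]
  }
  for (t in as.character(sfy_traits)) {
    o <- sfy_off[t] + seq_along(sfy_levels)
    LHS[cbind(o, o)] <- LHS[cbind(o, o)] + 1 / S0d[match(as.numeric(t), full_mat)]
  }
  x <- solve(LHS, rhs)
  gen <- matrix(x[gidx], n_e, length(slots), dimnames = list(entity_ids, slots))
  list(x = as.vector(x), ebv = gen[animal_idx, , drop = FALSE], n_eq = n_eq)
}

# exhaustive opposing-homozygote scan over all genotyped parent-offspring pairs
oracle_mendel_conflicts <- function(ped, geno) {
  ids <- geno$animal_ids
  conf <- 0L
  for (r in seq_len(nrow(ped))) {
    o <- match(ped$id[r], ids)
    if (is.na(o)) next
    for (p in c(ped$sire[r], ped$dam[r])) {
      pp <- match(p, ids)
      if (is.na(pp) || p == 0) next
      a <- geno$calls[o, ]; b <- geno$calls[pp, ]
      conf <- conf + sum((a == 0 & b == 2) | (a == 2 & b == 0), na.rm = TRUE)
    }
  }
  conf
}

single_trait_varcomp <- function(h2 = 0.38) {
  varcomp(matrix(h2, dimnames = list("dir1", "dir1")),
          matrix(numeric(0), 0, 0), matrix(numeric(0), 0, 0),
          matrix(1 - h2, dimnames = list("t1", "t1")))
}
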