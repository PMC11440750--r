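# Population structure: genotype QC, allele frequencies, pairwise Fst,
# genotype PCA and PCA-boundary breed assignment.

#' Construct a genotype set
#'
#' Holds SNP calls coded 0/1/2 (copies of the alternate allele), animals in
#' rows and markers in columns, with `NA` for missing calls.
#'
#' @param calls numeric/integer matrix, animals x markers.
#' @param animal_ids integer vector of animal ids (defaults to rownames).
#' @param marker_ids character vector of marker ids (defaults to colnames).
#' @return an object of class `genotype_set`.
#' @export
genotype_set <- function(calls, animal_ids = NULL, marker_ids = NULL) {
  calls <- as.matrix(calls)
  if (is.null(animal_ids)) animal_ids <- as.integer(rownames(calls))
  if (is.null(marker_ids)) {
    marker_ids <- colnames(calls)
    if (is.null(marker_ids)) marker_ids <- paste0("SNP_", seq_len(ncol(calls)))
  }
  animal_ids <- as.integer(animal_ids)
  stopifnot(length(animal_ids) == nrow(calls), length(marker_ids) == ncol(calls))
  if (anyDuplicated(animal_ids)) stop("duplicated animal ids")
  if (anyDuplicated(marker_ids)) stop("duplicated marker ids")
  ok <- calls %in% c(0, 1, 2) | is.na(calls)
  if (!all(ok)) stop("genotype calls must be 0, 1, 2 or NA")
  dimnames(calls) <- list(animal_ids, marker_ids)
  structure(list(calls = calls, animal_ids = animal_ids, marker_ids = marker_ids),
            class = "genotype_set")
}

#' @exportS3Method base::print
print.genotype_set <- function(x, ...) {
  cat("genotype_set:", length(x$animal_ids), "animals x",
      length(x$marker_ids), "markers;",
      sprintf("%.2f%% missing\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

subset_genotypes <- function(g, animals = NULL, markers = NULL) {
  a <- if (is.null(animals)) seq_along(g$animal_ids) else match(animals, g$animal_ids)
  m <- if (is.null(markers)) seq_along(g$marker_ids) else match(markers, g$marker_ids)
  if (anyNA(a)) stop("unknown animal ids in subset")
  if (anyNA(m)) stop("unknown marker ids in subset")
  genotype_set(g$calls[a, m, drop = FALSE], g$animal_ids[a], g$marker_ids[m])
}

#' Genotype quality control
#'
#' Filters animals first (call rate, then heterozygosity), then markers
#' (minor allele frequency computed on retained animals, then markers with an
#' excess of Mendelian conflicts when a pedigree is supplied). A parent /
#' offspring pair conflicts at a marker when they are opposing homozygotes.
#'
#' @param g a [genotype_set()].
#' @param min_call_rate minimum per-animal call rate.
#' @param max_het maximum per-animal heterozygosity.
#' @param min_maf minimum minor allele frequency.
#' @param pedigree optional pedigree for Mendelian-conflict screening.
#' @param conflict_tol drop a marker when conflicts exceed this fraction of
#'   checkable parent-offspring pairs.
#' @return list with the filtered `genotypes` and a `report` (class
#'   `qc_report`) listing every removal with its reason.
#' @export
qc_genotypes <- function(g, min_call_rate = 0.90, max_het = 0.50,
                         min_maf = 0.05, pedigree = NULL, conflict_tol = 0.01) {
  stopifnot(inherits(g, "genotype_set"),
            min_call_rate >= 0, min_call_rate <= 1,
            max_het >= 0, max_het <= 1, min_maf >= 0, min_maf <= 1)
  calls <- g$calls
  m <- ncol(calls)
  obs <- !is.na(calls)
  call_rate <- rowMeans(obs)
  het <- rowSums(calls == 1, na.rm = TRUE) / pmax(rowSums(obs), 1L)
  bad_cr <- call_rate < min_call_rate
  bad_het <- !bad_cr & het > max_het
  removed_animals <- data.frame(
    id = g$animal_ids[bad_cr | bad_het],
    reason = c(rep("call_rate", sum(bad_cr)), rep("heterozygosity", sum(bad_het)))[
      order(c(which(bad_cr), which(bad_het)))],
    stringsAsFactors = FALSE)
  keep_a <- !(bad_cr | bad_het)
  if (!any(keep_a)) stop("no data retained: all animals removed by QC")
  calls_a <- calls[keep_a, , drop = FALSE]
  ids_a <- g$animal_ids[keep_a]

  p <- colMeans(calls_a, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  bad_maf <- is.nan(maf) | maf < min_maf

  bad_conf <- rep(FALSE, m)
  if (!is.null(pedigree)) {
    validate_pedigree(pedigree)
    pr <- ped_parent_rows(pedigree)
    gi <- match(pedigree$id, ids_a)
    pairs_o <- integer(0); pairs_p <- integer(0)
    for (side in pr) {
      ok <- !is.na(gi) & !is.na(side) & !is.na(gi[side])
      pairs_o <- c(pairs_o, gi[ok]); pairs_p <- c(pairs_p, gi[side][ok])
    }
    if (length(pairs_o)) {
      conf <- integer(m); checkable <- integer(m)
      for (k in seq_along(pairs_o)) {
        a <- calls_a[pairs_o[k], ]; b <- calls_a[pairs_p[k], ]
        cc <- !is.na(a) & !is.na(b)
        checkable <- checkable + cc
        conf <- conf + (cc & ((a == 0 & b == 2) | (a == 2 & b == 0)))
      }
      bad_conf <- checkable > 0 & conf / pmax(checkable, 1L) > conflict_tol
    }
  }
  bad_conf <- bad_conf & !bad_maf
  removed_markers <- data.frame(
    marker = c(g$marker_ids[bad_maf], g$marker_ids[bad_conf]),
    reason = c(rep("maf", sum(bad_maf)), rep("mendelian_conflict", sum(bad_conf))),
    stringsAsFactors = FALSE)
  keep_m <- !(bad_maf | bad_conf)
  if (!any(keep_m)) stop("no data retained: all markers removed by QC")

  report <- structure(list(
    removed_animals = removed_animals,
    removed_markers = removed_markers,
    thresholds = list(min_call_rate = min_call_rate, max_het = max_het,
                      min_maf = min_maf, conflict_tol = conflict_tol),
    n_animals = c(before = length(g$animal_ids), after = sum(keep_a)),
    n_markers = c(before = m, after = sum(keep_m))), class = "qc_report")
  list(genotypes = genotype_set(calls_a[, keep_m, drop = FALSE],
                                ids_a, g$marker_ids[keep_m]),
       report = report)
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat("QC report: animals", x$n_animals["before"], "->", x$n_animals["after"],
      "; markers", x$n_markers["before"], "->", x$n_markers["after"], "\n")
  if (nrow(x$removed_animals)) print(table(x$removed_animals$reason))
  if (nrow(x$removed_markers)) print(table(x$removed_markers$reason))
  invisible(x)
}

#' Per-marker allele frequencies
#'
#' Mean call / 2 over non-missing entries, optionally on a subset of animals.
#' Markers with no observed calls in the subset are returned as `NA` and
#' flagged in the `"all_missing"` attribute.
#'
#' @param g a [genotype_set()].
#' @param animal_subset optional vector of animal ids.
#' @return named numeric vector of alternate-allele frequencies.
#' @export
allele_frequencies <- function(g, animal_subset = NULL) {
  stopifnot(inherits(g, "genotype_set"))
  if (!is.null(animal_subset)) {
    if (!length(animal_subset)) stop("empty animal subset")
    g <- subset_genotypes(g, animals = animal_subset)
  }
  p <- colMeans(g$calls, na.rm = TRUE) / 2
  bad <- is.nan(p)
  p[bad] <- NA_real_
  attr(p, "all_missing") <- g$marker_ids[bad]
  p
}

#' Pairwise Fst between two allele-frequency vectors
#'
#' Ratio of the mean squared frequency difference to the mean
#' cross-heterozygosity, \eqn{\sum_i (p'_i - p_i)^2 / \sum_i [p'_i(1-p_i) +
#' p_i(1-p'_i)]}, both sums over the loci with frequencies available in both
#' populations.
#'
#' @param p_b,p_bp allele-frequency vectors of the two populations.
#' @return Fst estimate in \[0, 1\].
#' @export
fst_pair <- function(p_b, p_bp) {
  stopifnot(length(p_b) == length(p_bp))
  keep <- !is.na(p_b) & !is.na(p_bp)
  p1 <- p_b[keep]; p2 <- p_bp[keep]
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  den <- mean(p2 * (1 - p1) + p1 * (1 - p2))
  if (!length(p1) || den <= 0)
    stop("Fst undefined: both populations fixed for the same allele at every locus")
  mean((p2 - p1)^2) / den
}

#' Pairwise Fst matrix over labelled populations
#'
#' @param g a [genotype_set()].
#' @param population_labels vector of labels aligned with the animals of `g`.
#' @return symmetric population x population matrix with zero diagonal;
#'   pairs involving a population with fewer than 2 animals are `NA` (with a
#'   warning).
#' @export
fst_matrix <- function(g, population_labels) {
  stopifnot(inherits(g, "genotype_set"),
            length(population_labels) == length(g$animal_ids))
  pops <- unique(as.character(population_labels))
  if (length(pops) < 2) stop("need at least two populations")
  small <- pops[table(factor(population_labels, pops))[pops] < 2]
  if (length(small))
    warning("populations with < 2 animals skipped: ", paste(small, collapse = ", "))
  freqs <- lapply(pops, function(p)
    if (p %in% small) NULL else
      allele_frequencies(g, g$animal_ids[population_labels == p]))
  names(freqs) <- pops
  out <- matrix(NA_real_, length(pops), length(pops), dimnames = list(pops, pops))
  diag(out) <- 0
  for (i in seq_along(pops)[-1]) for (j in seq_len(i - 1L)) {
    if (is.null(freqs[[i]]) || is.null(freqs[[j]])) next
    out[i, j] <- out[j, i] <- fst_pair(freqs[[j]], freqs[[i]])
  }
  out
}

#' PCA of genotype calls
#'
#' Principal components of the column-centred (optionally standardised) call
#' matrix, computed from the eigendecomposition of the animal x animal Gram
#' matrix so only the leading `k` components are ever formed densely.
#'
#' @param g a [genotype_set()] with no missing calls (run QC first).
#' @param k number of components.
#' @param scale divide each marker by its standard deviation.
#' @return object of class `pca_scores`: `coordinates` (animals x k, columns
#'   `PC1..PCk`), `explained_variance_fraction`, `animal_ids`.
#' @export
genotype_pca <- function(g, k = 2, scale = FALSE) {
  stopifnot(inherits(g, "genotype_set"))
  if (anyNA(g$calls)) stop("missing calls: run qc_genotypes / imputation first")
  x <- scale(g$calls, center = TRUE, scale = scale)
  x[is.nan(x)] <- 0  # monomorphic markers under scaling
  n <- nrow(x)
  k0 <- min(k, n - 1L, ncol(x))
  if (k0 < k) warning("k reduced to ", k0, " (matrix rank limit)")
  e <- eigen(tcrossprod(x), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  tot <- sum(ev)
  coords <- e$vectors[, seq_len(k0), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k0)]), k0)
  dimnames(coords) <- list(g$animal_ids, paste0("PC", seq_len(k0)))
  structure(list(coordinates = coords,
                 explained_variance_fraction = ev[seq_len(k0)] / tot,
                 animal_ids = g$animal_ids),
            class = "pca_scores")
}

#' Assign breed labels from PCA coordinates
#'
#' Animals are labelled `M` when `PC2 - a*PC1 + offset_upper >= 0`, `D` when
#' `PC2 - a*PC1 + offset_lower <= 0`, and `C` (crossbred) otherwise. The
#' default constants reproduce the published boundaries; because PCA axes are
#' sign- and scale-indeterminate, fitted offsets from
#' [fit_breed_boundaries()] should be used on any other data set.
#'
#' @param scores a `pca_scores` object (or data frame with PC1, PC2).
#' @param boundary_a slope of the discriminant `PC2 - a*PC1`.
#' @param offset_upper,offset_lower boundary offsets; `offset_lower` must
#'   exceed `offset_upper` or the two regions would overlap.
#' @param flip multiply the discriminant by -1 (PCA sign indeterminacy).
#' @return character vector of labels in `{M, C, D}` named by animal id.
#' @export
assign_breed <- function(scores, boundary_a = 0.40, offset_upper = 5,
                         offset_lower = 42, flip = FALSE) {
  co <- if (inherits(scores, "pca_scores")) scores$coordinates else as.matrix(scores)
  stopifnot(all(c("PC1", "PC2") %in% colnames(co)))
  if (offset_lower <= offset_upper)
    stop("offset_lower must exceed offset_upper (regions would overlap)")
  d <- co[, "PC2"] - boundary_a * co[, "PC1"]
  if (flip) d <- -d
  lab <- rep("C", nrow(co))
  lab[d + offset_upper >= 0] <- "M"
  lab[d + offset_lower <= 0] <- "D"
  names(lab) <- rownames(co)
  lab
}

#' Fit breed-assignment boundaries from labelled purebreds
#'
#' Computes the discriminant `PC2 - a*PC1`, orients it so the `M` group lies
#' above the `D` group, and places the two offsets at quantile midpoints
#' between adjacent groups. With `boundary_a = NULL` (default) the slope is
#' fitted as the Fisher discriminant direction between the labelled `M` and
#' `D` purebreds, since the separating axis of a PCA is data-dependent.
#'
#' @param scores a `pca_scores` object.
#' @param labels known labels (`M`, `C`, `D`) aligned with the scored animals.
#' @param boundary_a discriminant slope; `NULL` to fit it.
#' @param q edge quantile used for the midpoints.
#' @return list with `boundary_a`, `offset_upper`, `offset_lower`, `flip`,
#'   directly usable as arguments of [assign_breed()].
#' @export
fit_breed_boundaries <- function(scores, labels, boundary_a = NULL, q = 0.02) {
  co <- scores$coordinates
  stopifnot(length(labels) == nrow(co), all(c("M", "D") %in% labels))
  if (is.null(boundary_a)) {
    x <- co[labels %in% c("M", "D"), c("PC1", "PC2"), drop = FALSE]
    gl <- labels[labels %in% c("M", "D")]
    Sw <- (cov(x[gl == "M", , drop = FALSE]) * (sum(gl == "M") - 1) +
           cov(x[gl == "D", , drop = FALSE]) * (sum(gl == "D") - 1)) /
      (nrow(x) - 2)
    w <- solve(Sw, colMeans(x[gl == "M", , drop = FALSE]) -
                 colMeans(x[gl == "D", , drop = FALSE]))
    # express w1*PC1 + w2*PC2 as PC2 - a*PC1 (scaled by w2)
    if (abs(w[2]) < 1e-6 * abs(w[1])) w[2] <- sign(w[2] + 1e-300) * 1e-6 * abs(w[1])
    boundary_a <- -w[1] / w[2]
  }
  d <- co[, "PC2"] - boundary_a * co[, "PC1"]
  flip <- mean(d[labels == "M"]) < mean(d[labels == "D"])
  if (flip) d <- -d
  dM <- d[labels == "M"]; dD <- d[labels == "D"]; dC <- d[labels == "C"]
  upper_break <- if (length(dC))
    (quantile(dM, q) + quantile(dC, 1 - q)) / 2 else
    (quantile(dM, q) + quantile(dD, 1 - q)) / 2
  lower_break <- if (length(dC))
    (quantile(dC, q) + quantile(dD, 1 - q)) / 2 else upper_break - 1e-8
  list(boundary_a = unname(boundary_a),
       offset_upper = -as.numeric(upper_break),
       offset_lower = -as.numeric(lower_break),
       flip = flip)
}

#' Pedigree-expected breed fractions
#'
#' Founder rows (both parents unknown) are unit vectors for their labelled
#' population; every other row is the average of the parental rows, an
#' unknown parent contributing a unit vector on the animal's own population
#' label.
#'
#' @param pedigree sorted pedigree with a `pop` column (founder labels).
#' @param populations optional label universe; defaults to labels present.
#' @param unknown_label label used for founders without a population label.
#' @return animals x populations matrix; rows sum to 1.
#' @export
breed_fractions <- function(pedigree, populations = NULL, unknown_label = "unknown") {
  validate_pedigree(pedigree)
  lab <- as.character(pedigree$pop)
  if (any(is.na(lab) | lab == "")) {
    warning("unlabelled animals assigned to population '", unknown_label, "'")
    lab[is.na(lab) | lab == ""] <- unknown_label
  }
  pops <- if (is.null(populations)) unique(lab) else
    union(populations, unique(lab))
  pr <- ped_parent_rows(pedigree)
  n <- nrow(pedigree)
  fr <- matrix(0, n, length(pops), dimnames = list(pedigree$id, pops))
  unit <- diag(length(pops))
  li <- match(lab, pops)
  for (i in seq_len(n)) {
    s <- pr$s[i]; d <- pr$d[i]
    rs <- if (is.na(s)) unit[li[i], ] else fr[s, ]
    rd <- if (is.na(d)) unit[li[i], ] else fr[d, ]
    fr[i, ] <- (rs + rd) / 2
  }
  fr
}
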