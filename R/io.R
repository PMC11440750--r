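# Plain-text interchange: PLINK .raw-style genotypes, optional VCF ingestion,
# and simulation fixture bundles.

#' Write / read genotypes in PLINK .raw-style text
#'
#' Columns `FID IID PAT MAT SEX PHENOTYPE SNP_1 ... SNP_m` with 0/1/2
#' alternate-allele dosages and `NA` for missing calls.
#'
#' @param g a [genotype_set()].
#' @param path file path.
#' @return `read_genotypes_raw()` returns a [genotype_set()].
#' @export
write_genotypes_raw <- function(g, path) {
  stopifnot(inherits(g, "genotype_set"))
  df <- data.frame(FID = g$animal_ids, IID = g$animal_ids, PAT = 0L, MAT = 0L,
                   SEX = 0L, PHENOTYPE = -9L)
  out <- cbind(df, as.data.frame(g$calls))
  names(out) <- c(names(df), g$marker_ids)
  write.table(out, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_raw
#' @export
read_genotypes_raw <- function(path) {
  raw <- read.table(path, header = TRUE, check.names = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  snp_cols <- setdiff(names(raw), meta)
  genotype_set(as.matrix(raw[, snp_cols, drop = FALSE]),
               animal_ids = raw$IID, marker_ids = snp_cols)
}

#' Read genotypes from a VCF file
#'
#' Converts diploid GT fields to 0/1/2 alternate-allele dosages; any call
#' with a missing allele becomes `NA`. Requires the `vcfR` package.
#'
#' @param path path to an (uncompressed or gzipped) VCF.
#' @return a [genotype_set()] (animals = VCF samples, ids taken as integers
#'   when possible, else ranked).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF ingestion requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_real_)
    al <- strsplit(x, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(as.numeric(al) > 0)
  })
  ids <- suppressWarnings(as.integer(colnames(gt)))
  if (anyNA(ids)) ids <- seq_len(ncol(gt))
  mk <- rownames(gt)
  if (is.null(mk)) mk <- paste0("SNP_", seq_len(nrow(gt)))
  genotype_set(t(dose), animal_ids = ids, marker_ids = mk)
}

#' Write / read a simulation fixture bundle
#'
#' Writes `pedigree.csv` (0 = unknown parent, sorted parents-first),
#' `genotypes.raw`, `phenotypes.csv` and `truth.csv` (true breeding values
#' per genetic slot) into a directory.
#'
#' @param pop a `sim_population` with phenotypes.
#' @param dir output directory (created if needed).
#' @return `read_sim_bundle()` returns a list with `pedigree`, `genotypes`,
#'   `phenotypes`, `tbv`.
#' @export
write_sim_bundle <- function(pop, dir) {
  stopifnot(inherits(pop, "sim_population"), !is.null(pop$phenotypes))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(pop$pedigree, file.path(dir, "pedigree.csv"), row.names = FALSE)
  write_genotypes_raw(pop$genotypes, file.path(dir, "genotypes.raw"))
  write.csv(pop$phenotypes, file.path(dir, "phenotypes.csv"), row.names = FALSE)
  write.csv(data.frame(id = rownames(pop$tbv), pop$tbv, check.names = FALSE),
            file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_sim_bundle
#' @export
read_sim_bundle <- function(dir) {
  ped <- read.csv(file.path(dir, "pedigree.csv"), stringsAsFactors = FALSE)
  phe <- read.csv(file.path(dir, "phenotypes.csv"), stringsAsFactors = FALSE)
  tb <- read.csv(file.path(dir, "truth.csv"), check.names = FALSE)
  tbv <- as.matrix(tb[, -1, drop = FALSE])
  rownames(tbv) <- tb$id
  list(pedigree = ped, genotypes = read_genotypes_raw(file.path(dir, "genotypes.raw")),
       phenotypes = phe, tbv = tbv)
}

#' Write a QC report as TSV
#'
#' Two sections (animal and marker removals) with reasons, preceded by
#' commented threshold metadata.
#'
#' @param report a `qc_report` from [qc_genotypes()].
#' @param path file path.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  con <- file(path, "w")
  on.exit(close(con))
  th <- report$thresholds
  writeLines(sprintf("# min_call_rate=%g max_het=%g min_maf=%g conflict_tol=%g",
                     th$min_call_rate, th$max_het, th$min_maf, th$conflict_tol),
             con)
  rows <- rbind(
    data.frame(kind = "animal",
               item = as.character(report$removed_animals$id),
               reason = report$removed_animals$reason),
    data.frame(kind = "marker",
               item = report$removed_markers$marker,
               reason = report$removed_markers$reason))
  write.table(rows, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write PCA scores as CSV
#'
#' Columns `id, PC1..PCk` plus a commented header with the explained
#' variance fractions.
#'
#' @param scores a `pca_scores` from [genotype_pca()].
#' @param path file path.
#' @export
write_pca_scores <- function(scores, path) {
  stopifnot(inherits(scores, "pca_scores"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# explained_variance_fraction: ",
                    paste(signif(scores$explained_variance_fraction, 6),
                          collapse = ",")), con)
  write.csv(data.frame(id = scores$animal_ids, scores$coordinates,
                       check.names = FALSE), con, row.names = FALSE)
  invisible(path)
}

#' Write / read a relationship matrix in coordinate (triplet) format
#'
#' Writes the non-zero upper triangle as `i j value` rows against an id-map
#' sidecar (`<path>.ids`), the conventional exchange format for sparse
#' relationship inverses.
#'
#' @param M matrix (dense or sparse) with dimnames.
#' @param path file path; ids go to `<path>.ids`.
#' @return `read_relationship_triplets()` returns a sparse symmetric Matrix.
#' @export
write_relationship_triplets <- function(M, path) {
  ids <- rownames(M)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(M)))
  Mt <- methods::as(methods::as(as(M, "CsparseMatrix"), "generalMatrix"),
                    "TsparseMatrix")
  keep <- Mt@i <= Mt@j
  df <- data.frame(i = Mt@i[keep] + 1L, j = Mt@j[keep] + 1L, value = Mt@x[keep])
  write.table(df, path, row.names = FALSE, quote = FALSE)
  writeLines(ids, paste0(path, ".ids"))
  invisible(path)
}

#' @rdname write_relationship_triplets
#' @export
read_relationship_triplets <- function(path) {
  df <- read.table(path, header = TRUE)
  ids <- readLines(paste0(path, ".ids"))
  n <- length(ids)
  M <- Matrix::sparseMatrix(i = df$i, j = df$j, x = df$value, dims = c(n, n),
                            symmetric = TRUE, dimnames = list(ids, ids))
  M
}
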