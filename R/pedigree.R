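# Pedigree container and validation shared by all downstream modules.

#' Validate and normalise a pedigree table
#'
#' A pedigree is a data frame with integer columns `id`, `sire`, `dam`
#' (0 = unknown parent) and, for most operations, `year` (birth year),
#' `flock` and `pop` (population / line label). Animals must be sorted so
#' that parents appear before their offspring.
#'
#' @param ped data frame with at least `id`, `sire`, `dam`.
#' @param require_year require a `year` column.
#' @param require_pop require a `pop` column.
#' @return the validated pedigree (invisibly unchanged).
#' @export
validate_pedigree <- function(ped, require_year = FALSE, require_pop = FALSE) {
  stopifnot(is.data.frame(ped), all(c("id", "sire", "dam") %in% names(ped)))
  id <- as.integer(ped$id)
  if (anyDuplicated(id)) stop("duplicated animal ids in pedigree")
  if (any(id <= 0L)) stop("animal ids must be positive integers")
  pos <- match(c(ped$sire, ped$dam), id)
  row <- rep(seq_len(nrow(ped)), 2L)
  known <- !is.na(pos)
  if (any(pos[known] >= row[known]))
    stop("pedigree not sorted parents-before-offspring (or self-parenting)")
  miss <- c(ped$sire, ped$dam) != 0L & !known
  if (any(miss))
    stop("parents referenced but absent from pedigree: ",
         paste(unique(c(ped$sire, ped$dam)[miss]), collapse = ", "))
  if (require_year && (is.null(ped$year) || anyNA(ped$year)))
    stop("every animal needs a birth year")
  if (require_pop && (is.null(ped$pop) || anyNA(ped$pop)))
    stop("every animal needs a population label")
  invisible(ped)
}

# sire/dam columns as row indices (NA = unknown), after validation
ped_parent_rows <- function(ped) {
  list(s = match(ped$sire, ped$id), d = match(ped$dam, ped$id))
}
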