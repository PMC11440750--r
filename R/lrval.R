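# Reference-population scenarios and LR-method validation metrics.

#' Define a validation scenario
#'
#' A scenario names the breed composition of the phenotyped + genotyped
#' reference population (pre-cutoff) while the validation population (all
#' genotyped + phenotyped animals born at or after the cutoff year, of all
#' breeds) stays fixed.
#'
#' @param reference one of `"All"`, `"M"`, `"C"`, `"D"`, `"M+C"`, `"C+D"`.
#' @param cutoff_year first birth year of the validation population.
#' @return list of class `scenario_def`.
#' @export
scenario_def <- function(reference = c("All", "M", "C", "D", "M+C", "C+D"),
                         cutoff_year) {
  reference <- match.arg(reference)
  comp <- switch(reference, All = c("M", "C", "D"), M = "M", C = "C", D = "D",
                 "M+C" = c("M", "C"), "C+D" = c("C", "D"))
  structure(list(reference = reference, composition = comp,
                 cutoff_year = cutoff_year), class = "scenario_def")
}

#' Build the partial and whole datasets of a scenario
#'
#' Partial: phenotypes AND genotypes of pre-cutoff genotyped animals whose
#' breed label is outside the reference composition are removed; phenotypes
#' of every validation animal (genotyped + phenotyped, born at or after the
#' cutoff) are removed while their genotypes are kept; phenotypes of
#' non-genotyped animals are always retained (they carry no breed label).
#' Whole: partial plus the validation phenotypes.
#'
#' @param dataset list with `pedigree`, `phenotypes`, `genotypes`.
#' @param scenario a [scenario_def()].
#' @param breed_labels named labels (`M`/`C`/`D`) for the genotyped animals,
#'   e.g. from [assign_breed()].
#' @return list with `partial`, `whole` (datasets), `validation` (data frame
#'   `id`, `label`), `reference_ids`.
#' @export
make_scenario_datasets <- function(dataset, scenario, breed_labels) {
  phe <- dataset$phenotypes
  geno <- dataset$genotypes
  stopifnot(inherits(scenario, "scenario_def"), !is.null(geno))
  gids <- geno$animal_ids
  lab <- breed_labels[as.character(gids)]
  if (anyNA(lab)) stop("breed labels missing for some genotyped animals")
  yr <- dataset$pedigree$year[match(gids, dataset$pedigree$id)]
  phenotyped <- gids %in% phe$id
  is_val <- phenotyped & yr >= scenario$cutoff_year
  pre <- gids[phenotyped & yr < scenario$cutoff_year]
  in_ref <- lab[match(pre, gids)] %in% scenario$composition
  drop_geno <- pre[!in_ref]
  reference_ids <- pre[in_ref]
  if (!length(reference_ids)) stop("empty reference population after masking")
  val_ids <- gids[is_val]

  keep_g <- setdiff(gids, drop_geno)
  geno_p <- subset_genotypes(geno, animals = keep_g)
  tcols <- grep("^t[0-9]+$", names(phe), value = TRUE)
  phe_p <- phe
  phe_p[phe_p$id %in% c(drop_geno, val_ids), tcols] <- NA
  phe_w <- phe
  phe_w[phe_w$id %in% drop_geno, tcols] <- NA

  partial <- list(pedigree = dataset$pedigree, phenotypes = phe_p,
                  genotypes = geno_p)
  whole <- list(pedigree = dataset$pedigree, phenotypes = phe_w,
                genotypes = geno_p)
  list(partial = partial, whole = whole,
       validation = data.frame(id = val_ids,
                               label = lab[match(val_ids, gids)]),
       reference_ids = reference_ids)
}

#' LR-method validation metrics
#'
#' Compares partial (`u_p`) and whole (`u_w`) (G)EBVs of the focal
#' individuals: bias \eqn{\hat\Delta_p = \bar u_p - \bar u_w}; dispersion
#' \eqn{b_p = cov(u_w, u_p)/var(u_p)}; accuracy ratio \eqn{\rho =
#' cor(u_p, u_w)}; and accuracy \eqn{acc = \sqrt{cov(u_p, u_w)/den}} with
#' denominator \eqn{(1-\bar F + \overline{diag(QQ')} - \overline{QQ'})
#' \sigma^2_a} for UPG models and \eqn{(1-\bar F)\sigma^2_a} for metafounder
#' models (the Gamma scale factor cancels internally there). The genetic
#' variance of the not-yet-selected validation cohort is taken equal to the
#' base genetic variance.
#'
#' @param u_p,u_w aligned partial and whole (G)EBV vectors of the focal
#'   individuals.
#' @param model_kind `"upg"` or `"mf"` (choice of accuracy denominator;
#'   `"none"` behaves like `"mf"` with no group terms).
#' @param F_bar mean classical pedigree inbreeding of the focal individuals.
#' @param sigma2_a additive genetic variance of the trait.
#' @param Q_focal focal rows of the group-fraction matrix (UPG kind only).
#' @return list of class `lr_metrics`: `delta_p`, `b_p`, `rho`, `acc`, `n`,
#'   plus the denominator used.
#' @export
lr_metrics <- function(u_p, u_w, model_kind = c("mf", "upg", "none"),
                       F_bar = 0, sigma2_a = 1, Q_focal = NULL) {
  model_kind <- match.arg(model_kind)
  stopifnot(length(u_p) == length(u_w), sigma2_a > 0)
  n <- length(u_p)
  if (n < 2) stop("need at least two focal individuals")
  vp <- var(u_p)
  if (vp <= 0) stop("zero variance of partial values; slope undefined")
  cv <- cov(u_p, u_w)
  den <- if (model_kind == "upg") {
    if (is.null(Q_focal)) stop("UPG accuracy needs the focal group fractions")
    QQ <- tcrossprod(as.matrix(Q_focal))
    (1 - F_bar + mean(diag(QQ)) - mean(QQ)) * sigma2_a
  } else (1 - F_bar) * sigma2_a
  acc <- if (cv >= 0) sqrt(cv / den) else NA_real_
  structure(list(delta_p = mean(u_p) - mean(u_w),
                 b_p = cv / vp,
                 rho = cor(u_p, u_w),
                 acc = acc, denominator = den, n = n,
                 model_kind = model_kind), class = "lr_metrics")
}

#' Confidence intervals for the LR bias and slope
#'
#' Ordinary least-squares regression of `u_w` on `u_p`; the slope interval
#' comes from the regression standard error and the bias interval from the
#' standard error of the mean paired difference, both with t quantiles.
#' The approximation treats focal animals as unrelated with equal accuracy.
#'
#' @param u_p,u_w focal partial and whole values.
#' @param level confidence level.
#' @return list with `delta_p` and `b_p`, each `c(estimate, lo, hi)`.
#' @export
regression_ci <- function(u_p, u_w, level = 0.95) {
  n <- length(u_p)
  stopifnot(n == length(u_w))
  if (n < 3) stop("need at least 3 focal animals")
  if (var(u_p) <= 0) stop("degenerate regression: partial values constant")
  fit <- lm(u_w ~ u_p)
  ci <- confint(fit, "u_p", level = level)
  dif <- u_p - u_w
  se <- sd(dif) / sqrt(n)
  tq <- qt(1 - (1 - level) / 2, df = n - 1)
  list(delta_p = c(estimate = mean(dif), lo = mean(dif) - tq * se,
                   hi = mean(dif) + tq * se),
       b_p = c(estimate = unname(coef(fit)["u_p"]), lo = ci[1], hi = ci[2]))
}

#' Run a grid of scenarios and model variants
#'
#' For every scenario and model variant: build the scenario's partial and
#' whole datasets, solve both evaluations (sharing one relationship
#' structure), and compute LR metrics per validation breed group.
#'
#' @param dataset list with `pedigree`, `phenotypes`, `genotypes`.
#' @param scenarios list of [scenario_def()]s.
#' @param model_variants named list of [model_spec()]s.
#' @param breed_labels labels of the genotyped animals.
#' @param varcomp variance components.
#' @param trait trait index whose direct EBV is validated.
#' @return data frame keyed validation - reference - model with columns
#'   `n_focal`, `delta_p(_lo/_hi)` (plus `delta_p_scaled`, the bias in
#'   genetic standard deviations), `b_p(_lo/_hi)`, `rho`, `acc`.
#' @export
run_scenario_grid <- function(dataset, scenarios, model_variants, breed_labels,
                              varcomp = default_varcomp(), trait = 1) {
  out <- list()
  for (sc in scenarios) {
    sd_ <- make_scenario_datasets(dataset, sc, breed_labels)
    if (!nrow(sd_$validation)) {
      warning("no validation animals for scenario ", sc$reference)
      next
    }
    for (mv in names(model_variants)) {
      spec <- model_variants[[mv]]
      rel <- build_relationship(sd_$partial$pedigree, sd_$partial$genotypes, spec)
      ev_p <- run_evaluation(sd_$partial, spec, varcomp, relationship = rel)
      ev_w <- run_evaluation(sd_$whole, spec, varcomp, relationship = rel)
      slot <- paste0("dir", trait)
      sig2 <- varcomp$G0[slot, slot]
      for (vg in unique(sd_$validation$label)) {
        ids <- as.character(sd_$validation$id[sd_$validation$label == vg])
        up <- ev_p$ebv[ids, slot]
        uw <- ev_w$ebv[ids, slot]
        fbar <- mean(rel$F[match(as.integer(ids), dataset$pedigree$id)])
        kind <- if (spec$grouping == "upg") "upg" else "mf"
        Qf <- if (kind == "upg")
          rel$Q[match(as.integer(ids), dataset$pedigree$id), , drop = FALSE]
        else NULL
        m <- lr_metrics(up, uw, kind, fbar, sig2, Qf)
        ci <- regression_ci(up, uw)
        out[[length(out) + 1L]] <- data.frame(
          scenario = paste0(vg, "-", sc$reference), reference = sc$reference,
          validation_group = vg, model = mv, trait = trait,
          n_focal = m$n, delta_p = m$delta_p,
          delta_p_scaled = m$delta_p / sqrt(sig2),
          delta_p_lo = ci$delta_p["lo"], delta_p_hi = ci$delta_p["hi"],
          b_p = m$b_p, b_p_lo = ci$b_p["lo"], b_p_hi = ci$b_p["hi"],
          rho = m$rho, acc = m$acc, row.names = NULL)
      }
    }
  }
  do.call(rbind, out)
}
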