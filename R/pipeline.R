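#' Run the full cross-generational genomic-selection experiment
#'
#' Orchestrates the complete chain on a synthetic RRS breeding program:
#' simulate (pedigree, genotypes, phenotypes) -> genotype QC and imputation
#' -> growth-curve age adjustment -> ABLUP evaluation (additive and
#' additive-dominance) -> pseudo-phenotypes -> kinship construction (G_A,
#' G_D, H) -> GBLUP / GBLUP_G+D / HBLUP per training-set combination ->
#' realized-predictive-ability assessment. Stages are gated by the requested
#' models: an ABLUP-only run builds no genomic matrices. All randomness
#' derives from the configuration seed through [child_seed()], so a rerun
#' with the same configuration reproduces the report exactly.
#'
#' ABLUP pseudo-phenotypes for training come from a fit of the prior (G1)
#' generation only, and the reference EBVs/EGVs of the G2 candidates come
#' from a fit of the G2 trial, so training never sees target-generation
#' data. Both fits use the nominal pedigree (polymix sires unknown), as a
#' breeder would.
#'
#' @param config a [sim_config()].
#' @param models subset of `c("ablup", "ablup-ad", "gblup", "gblup-gd",
#'   "hblup")`; ABLUP stages run whenever any model needs pseudo-phenotypes.
#' @param training_sets training-set combinations for
#'   [build_training_set()].
#' @param proportions selected proportions for coincidence rates.
#' @param reference_ages common ages the growth curves are adjusted to.
#' @param adjust_model growth model used for age adjustment.
#' @param min_marker_call_rate,min_maf,sample_call_rate QC thresholds.
#' @param missing_rate fraction of genotype calls masked before QC (to
#'   exercise imputation, as real array data are incomplete).
#' @param uncle_genotyped_fraction,g2_genotyped_fraction fractions of the
#'   pure-species G1 cohort and of the G2 candidates that are genotyped
#'   (hybrid G1 trees and the G2 parents are always genotyped).
#' @param output_dir optional directory; when given, every stage's artifacts
#'   plus a manifest (stage, file hashes, seed) are written there.
#' @return list of class `rrs_pipeline`: `report` (tidy data frame of
#'   metrics per model x training set x age), `family_report`, `h2_table`,
#'   `cohorts`, `fits`, `program`, `adjusted`, and `paths` when writing.
#' @export
run_pipeline <- function(config = sim_config(),
                         models = c("ablup", "ablup-ad", "gblup", "gblup-gd",
                                    "hblup"),
                         training_sets = c("H", "P", "U", "H+P", "H+U",
                                           "P+U", "H+P+U"),
                         proportions = c(0.025, 0.05, 0.10, 0.20),
                         reference_ages = c(2.76, 5.40),
                         adjust_model = "logistic1",
                         min_marker_call_rate = 0.90, min_maf = 0.01,
                         sample_call_rate = 0.85, missing_rate = 0.02,
                         uncle_genotyped_fraction = 0.15,
                         g2_genotyped_fraction = 0.30,
                         output_dir = NULL) {
  models <- match.arg(models, c("ablup", "ablup-ad", "gblup", "gblup-gd",
                                "hblup"), several.ok = TRUE)
  genomic <- intersect(models, c("gblup", "gblup-gd", "hblup"))
  need_ad <- any(c("ablup-ad", "gblup-gd") %in% models)

  program <- simulate_breeding_program(config)
  pheno <- simulate_phenotypes(program)
  ped <- program$nominal_pedigree

  # cohort bookkeeping
  g2 <- ped$id[ped$generation == "G2"]
  parents <- unique(c(ped$sire[ped$generation == "G2"],
                      ped$dam[ped$generation == "G2"]))
  parents <- parents[!is.na(parents)]
  hybrids_g1 <- ped$id[ped$cohort == "HPT_G1"]
  uncles <- setdiff(ped$id[ped$cohort == "PSPT"], parents)
  set.seed(child_seed(config$seed, "genotyping"))
  gt_uncles <- sort(sample(uncles, max(2, round(uncle_genotyped_fraction *
                                                  length(uncles)))))
  gt_g2 <- sort(sample(g2, max(3, round(g2_genotyped_fraction * length(g2)))))
  genotyped <- c(hybrids_g1, parents, gt_uncles, gt_g2)
  cohorts <- list(hybrids = hybrids_g1, parents = parents, uncles = gt_uncles)

  geno_qc <- NULL
  if (length(genomic)) {
    geno <- program$genotypes[genotyped, , drop = FALSE]
    if (missing_rate > 0) {
      set.seed(child_seed(config$seed, "missingness"))
      mask <- which(stats::runif(length(geno)) < missing_rate)
      geno[mask] <- NA
    }
    geno <- filter_samples(geno, sample_call_rate)
    geno <- filter_markers(geno, min_marker_call_rate, min_maf)
    geno_qc <- impute_missing(geno)
  }

  # growth-curve age adjustment to the common reference ages
  gfit <- fit_growth_model(pheno[, c("id", "trial", "age", "volume")],
                           model = adjust_model)
  adjusted <- adjust_to_reference_ages(gfit, reference_ages,
                                       stems_per_ha = config$stems_per_ha)

  g1_pheno_ids <- c(hybrids_g1, setdiff(ped$id[ped$cohort == "PSPT"], character(0)))
  A <- build_A(ped)
  D <- if (need_ad) build_D_pedigree(ped, A = A) else NULL

  ablup <- list()
  h2_rows <- list()
  for (age in reference_ages) {
    adj <- adjusted[adjusted$age == age, ]
    dat <- data.frame(id = adj$id, mai = adj$mai, stringsAsFactors = FALSE)
    dat$trial <- ped$trial[match(dat$id, ped$id)]
    dat$block <- ped$block[match(dat$id, ped$id)]
    train_dat <- dat[dat$id %in% g1_pheno_ids, ]
    ref_dat <- dat[dat$id %in% g2, ]
    for (variant in unique(c("ablup", if (need_ad) "ablup-ad"))) {
      dom <- variant == "ablup-ad"
      key <- paste(variant, age, sep = "@")
      ablup[[paste0("train@", key)]] <-
        fit_ablup(train_dat, ped, response = "mai", dominance = dom,
                  A = A, D = D, compute_pev = TRUE)
      ablup[[paste0("ref@", key)]] <-
        fit_ablup(ref_dat, ped, response = "mai", dominance = dom,
                  A = A, D = D, compute_pev = FALSE)
      h2 <- ablup[[paste0("ref@", key)]]$h2
      h2_rows[[key]] <- data.frame(model = variant, age = age,
                                   scope = "G2 trial",
                                   h2_narrow = h2$h2_narrow,
                                   h2_broad = h2$h2_broad)
    }
  }

  GA <- GD <- H <- NULL
  if (length(genomic)) {
    GA <- build_GA(geno_qc)
    if ("gblup-gd" %in% genomic) GD <- build_GD(geno_qc)
    if ("hblup" %in% genomic) H <- build_H(A, GA, rownames(geno_qc))
  }

  rows <- list(); fam_rows <- list()
  fits <- list()
  if (length(genomic)) {
    fam_map <- stats::setNames(ped$family, ped$id)
    g2_genotyped <- intersect(gt_g2, rownames(geno_qc))
    for (age in reference_ages) {
      for (model in genomic) {
        variant <- if (model == "gblup-gd") "ablup-ad" else "ablup"
        tfit <- ablup[[paste0("train@", variant, "@", age)]]
        rfit <- ablup[[paste0("ref@", variant, "@", age)]]
        pseudo_all <- if (model == "gblup-gd") tfit$egv else tfit$ebv
        reference <- if (model == "gblup-gd") rfit$egv[g2] else rfit$ebv[g2]
        for (combo in training_sets) {
          ts <- build_training_set(cohorts, combo)
          train_ids <- ts$ids
          if (model != "hblup") train_ids <- intersect(train_ids, rownames(GA))
          if (length(train_ids) < 3) next
          pseudo <- data.frame(id = train_ids,
                               value = as.numeric(pseudo_all[train_ids]),
                               stringsAsFactors = FALSE)
          gfit2 <- switch(model,
            "gblup" = fit_gblup(pseudo, GA),
            "gblup-gd" = fit_gblup(pseudo, GA, KD = GD),
            "hblup" = fit_hblup(pseudo, H))
          fits[[paste(model, combo, age, sep = "@")]] <- gfit2
          pred_ids <- if (model == "hblup") g2 else g2_genotyped
          pred <- if (model == "gblup-gd") gfit2$gegv[pred_ids] else
            gfit2$gebv[pred_ids]
          refv <- reference[pred_ids]
          co <- vapply(proportions,
                       function(p) coincidence_rate(pred, refv, p), 0)
          rows[[length(rows) + 1L]] <- data.frame(
            model = model, training_set = combo, age = age,
            n_train = length(train_ids), n_pred = length(pred_ids),
            rpa = realized_predictive_ability(pred, refv),
            bias = prediction_bias(pred, refv),
            spearman = rank_concordance(pred, refv),
            t(stats::setNames(co, paste0("coincidence_",
                                         100 * proportions))),
            stringsAsFactors = FALSE)
          fam <- family_assessment(pred, refv, fam_map[pred_ids])
          fam_rows[[length(fam_rows) + 1L]] <- data.frame(
            model = model, training_set = combo, age = age,
            family_rpa = fam$rpa, family_spearman = fam$spearman,
            n_families = nrow(fam$table), stringsAsFactors = FALSE)
        }
      }
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else data.frame()
  fam_report <- if (length(fam_rows)) do.call(rbind, fam_rows) else data.frame()
  h2_table <- do.call(rbind, h2_rows); rownames(h2_table) <- NULL

  out <- list(report = report, family_report = fam_report,
              h2_table = h2_table, cohorts = cohorts,
              genotyped = list(uncles = gt_uncles, g2 = gt_g2),
              fits = c(ablup, fits), program = program, adjusted = adjusted,
              config = config)
  if (!is.null(output_dir)) {
    out$paths <- .write_pipeline(out, pheno, geno_qc, output_dir,
                                 wrote_kinship = length(genomic) > 0,
                                 GA = GA, H = H)
  }
  class(out) <- "rrs_pipeline"
  out
}

.write_pipeline <- function(out, pheno, geno_qc, dir, wrote_kinship, GA, H) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_breeding_program(out$program, pheno, dir)
  p <- function(f) file.path(dir, f)
  utils::write.csv(out$adjusted, p("adjusted_phenotypes.csv"), row.names = FALSE)
  utils::write.csv(out$h2_table, p("heritabilities.csv"), row.names = FALSE)
  if (nrow(out$report)) {
    utils::write.csv(out$report, p("assessment.csv"), row.names = FALSE)
    utils::write.csv(out$family_report, p("assessment_families.csv"),
                     row.names = FALSE)
  }
  if (wrote_kinship) {
    write_dosage_matrix(geno_qc, p("genotypes_qc.csv"))
    utils::write.csv(data.frame(id = rownames(GA), GA, check.names = FALSE),
                     p("kinship_GA.csv"), row.names = FALSE)
    if (!is.null(H)) {
      utils::write.csv(data.frame(id = rownames(H), H, check.names = FALSE),
                       p("kinship_H.csv"), row.names = FALSE)
    }
  }
  files <- list.files(dir, full.names = TRUE)
  manifest <- list(seed = out$config$seed,
                   stages = c("simulate", "qc", "adjust", "ablup",
                              if (wrote_kinship) c("kinship", "genomic"),
                              "assess"),
                   files = lapply(stats::setNames(files, basename(files)),
                                  function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  c(paths, dir = dir)
}

#' @export
print.rrs_pipeline <- function(x, ...) {
  cat("RRS genomic-selection pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("heritabilities (G2 trial):\n")
  print(x$h2_table, digits = 3)
  if (nrow(x$report)) {
    cat("\nassessment (first rows):\n")
    print(utils::head(x$report), digits = 3)
  }
  invisible(x)
}
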