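#' Heritability parameter-recovery experiment
#'
#' Simulates replicate pure-species breeding populations from a single
#' random-mating base (no founder divergence, so the calibrated founder
#' variance is the within-population variance the analysis sees), fits the
#' individual-tree ABLUP model with the true pedigree by REML, and reports
#' the narrow-sense heritability estimates against the simulation target.
#' The default design gives 2,000 phenotyped trees per replicate (2 species
#' x 40 polymix families x 25 offspring).
#'
#' @param target_h2 true narrow-sense heritability of the generator.
#' @param n_replicates number of simulation replicates, default 20.
#' @param seed master seed; replicate seeds derive from it.
#' @param n_families_per_species,offspring_per_family,n_snps design knobs.
#' @return list with `estimates` (per replicate), `mean_h2`, `target_h2`
#'   and `n_phenotyped`.
#' @export
heritability_recovery_experiment <- function(target_h2, n_replicates = 20,
                                             seed = 1,
                                             n_families_per_species = 40,
                                             offspring_per_family = 25,
                                             n_snps = 400) {
  est <- numeric(n_replicates)
  n_pheno <- NA_integer_
  for (r in seq_len(n_replicates)) {
    cfg <- sim_config(
      n_founders_per_species = n_families_per_species, n_snps = n_snps,
      fst = 0, n_psp_families_per_species = n_families_per_species,
      offspring_per_family = offspring_per_family,
      n_hybrid_families_g1 = 1, n_hybrid_families_g2 = 1,
      target_h2 = target_h2, target_d2 = 0, n_trials = 2,
      n_blocks_per_trial = 8,
      seed = child_seed(seed, paste0("h2rec", target_h2, "_", r)))
    prog <- simulate_breeding_program(cfg)
    ph <- simulate_phenotypes(prog)
    ped <- prog$pedigree
    keep <- ped$cohort[match(ph$id, ped$id)] == "PSPT" &
      ph$nominal_age == max(cfg$measurement_ages)
    a <- ph[keep, ]
    dat <- data.frame(id = a$id, mai = compute_mai(a$volume, a$age),
                      trial = ped$trial[match(a$id, ped$id)],
                      block = ped$block[match(a$id, ped$id)],
                      stringsAsFactors = FALSE)
    n_pheno <- nrow(dat)
    fit <- fit_ablup(dat, ped, blocks = "fixed", compute_pev = FALSE)
    est[r] <- fit$h2$h2_narrow
  }
  list(estimates = est, mean_h2 = mean(est), target_h2 = target_h2,
       n_phenotyped = n_pheno)
}

#' Empirical full-sib / half-sib genomic relationships
#'
#' Gene-drops SNP genotypes through full-sib pairs (distinct parent couples)
#' and paternal half-sib pairs (shared sire, different dams) from a
#' Hardy-Weinberg base population, builds the additive genomic relationship
#' matrix, and returns the mean within-pair off-diagonals, whose pedigree
#' expectations are 0.5 and 0.25.
#'
#' @param n_pairs sib pairs per type, default 30.
#' @param n_snps number of SNPs, default 5000.
#' @param seed integer seed.
#' @return named vector with `fullsib` and `halfsib` mean G_A entries.
#' @export
sib_ga_experiment <- function(n_pairs = 30, n_snps = 5000, seed = 1) {
  set.seed(seed)
  n_parents <- 2 * n_pairs + 3 * n_pairs
  freqs <- stats::runif(n_snps, 0.1, 0.9)
  founders <- matrix(stats::rbinom(n_parents * n_snps, 2,
                                   rep(freqs, each = n_parents)),
                     n_parents, n_snps,
                     dimnames = list(sprintf("par%03d", seq_len(n_parents)),
                                     sprintf("snp%05d", seq_len(n_snps))))
  pid <- rownames(founders)
  id <- pid; sire <- rep(NA_character_, n_parents); dam <- sire
  for (k in seq_len(n_pairs)) {  # full sibs: parents 2k-1, 2k
    id <- c(id, sprintf("fs%03d_1", k), sprintf("fs%03d_2", k))
    sire <- c(sire, rep(pid[2 * k - 1], 2))
    dam <- c(dam, rep(pid[2 * k], 2))
  }
  base <- 2 * n_pairs
  for (k in seq_len(n_pairs)) {  # half sibs: shared sire, two dams
    id <- c(id, sprintf("hs%03d_1", k), sprintf("hs%03d_2", k))
    sire <- c(sire, rep(pid[base + 3 * k - 2], 2))
    dam <- c(dam, pid[base + 3 * k - 1], pid[base + 3 * k])
  }
  ped <- pedigree(data.frame(id = id, sire = sire, dam = dam,
                             stringsAsFactors = FALSE))
  geno <- drop_gametes(ped, founders, seed = child_seed(seed, "sibdrop"))
  GA <- build_GA(filter_markers(geno, min_maf = 0.01))
  fs <- vapply(seq_len(n_pairs), function(k)
    GA[sprintf("fs%03d_1", k), sprintf("fs%03d_2", k)], 0)
  hs <- vapply(seq_len(n_pairs), function(k)
    GA[sprintf("hs%03d_1", k), sprintf("hs%03d_2", k)], 0)
  c(fullsib = mean(fs), halfsib = mean(hs))
}

#' Relatedness-ordering experiment for cross-generation prediction
#'
#' For each replicate, simulates a G0 -> G2 RRS program, derives training
#' pseudo-phenotypes (EBVs) from a G1-only ABLUP fit and reference EBVs from
#' a G2-only fit, then trains GBLUP either on the direct G1 parents of the
#' G2 candidates or on an equally accessible but unrelated pure-species
#' cohort (G1 families that contributed no parent), and computes the
#' realized predictive ability of each. Across replicates the direct-parent
#' training is expected to dominate — the central relatedness effect in
#' cross-generational genomic selection.
#'
#' @param n_replicates number of replicates, default 10.
#' @param seed master seed.
#' @param max_unrelated cap on the unrelated-cohort size.
#' @return list with `per_replicate` (matrix with rows `parents`,
#'   `unrelated`), `mean_rpa_parents`, `mean_rpa_unrelated` and
#'   `n_candidates`.
#' @export
relatedness_rpa_experiment <- function(n_replicates = 10, seed = 1,
                                       max_unrelated = 60) {
  res <- matrix(NA_real_, 2, n_replicates,
                dimnames = list(c("parents", "unrelated"), NULL))
  n_cand <- NA_integer_
  for (r in seq_len(n_replicates)) {
    cfg <- sim_config(n_founders_per_species = 12, n_snps = 1200,
                      n_psp_families_per_species = 12,
                      offspring_per_family = 15,
                      n_hybrid_families_g1 = 6, n_hybrid_families_g2 = 16,
                      target_h2 = 0.5, target_d2 = 0.15, n_trials = 2,
                      n_blocks_per_trial = 5,
                      g2_parent_selection = "random",
                      seed = child_seed(seed, paste0("relrpa", r)))
    prog <- simulate_breeding_program(cfg)
    ph <- simulate_phenotypes(prog)
    ped <- prog$nominal_pedigree
    a <- ph[ph$nominal_age == max(cfg$measurement_ages), ]
    dat <- data.frame(id = a$id, mai = compute_mai(a$volume, a$age),
                      trial = ped$trial[match(a$id, ped$id)],
                      block = ped$block[match(a$id, ped$id)],
                      stringsAsFactors = FALSE)
    g2 <- ped$id[ped$generation == "G2"]
    parents <- unique(stats::na.omit(c(ped$sire[ped$generation == "G2"],
                                       ped$dam[ped$generation == "G2"])))
    parent_fams <- unique(ped$family[ped$id %in% parents])
    unrelated <- ped$id[ped$cohort == "PSPT" &
                          !(ped$family %in% parent_fams)]
    A <- build_A(ped)
    train_fit <- fit_ablup(dat[!(dat$id %in% g2), ], ped, A = A,
                           compute_pev = FALSE)
    ref_fit <- fit_ablup(dat[dat$id %in% g2, ], ped, A = A,
                         compute_pev = FALSE)
    set.seed(child_seed(seed, paste0("relpick", r)))
    unrel <- sample(unrelated, min(max_unrelated, length(unrelated)))
    geno <- prog$genotypes[c(parents, unrel, g2), , drop = FALSE]
    GA <- build_GA(filter_markers(geno))
    rpa_for <- function(train_ids) {
      train_ids <- intersect(train_ids, rownames(GA))
      pseudo <- data.frame(id = train_ids,
                           value = as.numeric(train_fit$ebv[train_ids]),
                           stringsAsFactors = FALSE)
      fit <- fit_gblup(pseudo, GA)
      realized_predictive_ability(fit$gebv[g2], ref_fit$ebv[g2])
    }
    res["parents", r] <- rpa_for(parents)
    res["unrelated", r] <- rpa_for(unrel)
    n_cand <- length(g2)
  }
  list(per_replicate = res,
       mean_rpa_parents = mean(res["parents", ]),
       mean_rpa_unrelated = mean(res["unrelated", ]),
       n_candidates = n_cand)
}
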