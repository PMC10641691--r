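#' Configuration for the synthetic RRS breeding-program generator
#'
#' Defines the study conditions the generator emulates: two divergent founder
#' species (G0), polymix half-sib pure-species G1 families, interspecific
#' hybrid G1 families, full-sib hybrid G2 families from selected G1
#' pure-species parents, an additive + dominance trait architecture for
#' volume growth, randomized complete block trials, and measurements at two
#' ages near 3 and 6 years with per-trial age jitter.
#'
#' Defaults are a desk-scale rendition of an operational eucalypt RRS
#' program: 30 founders per species, 3,000 unlinked SNPs, founder divergence
#' Fst = 0.15, family sizes of 20, narrow-sense heritability 0.4 and
#' dominance fraction 0.15 of phenotypic variance. Variances are expressed at
#' the asymptote (mature-volume) scale; see the methods vignette.
#'
#' @param n_founders_per_species G0 parents per species.
#' @param n_snps number of biallelic SNPs.
#' @param fst divergence between the two founder species in `[0, 1)`
#'   (Balding-Nichols model).
#' @param n_psp_families_per_species polymix half-sib families per species in
#'   the G1 pure-species progeny trials.
#' @param offspring_per_family offspring per family (all family types).
#' @param n_hybrid_families_g1 interspecific polymix hybrid families in G1.
#' @param n_hybrid_families_g2 full-sib hybrid families in the G2 target
#'   trial.
#' @param target_h2 narrow-sense heritability of the simulated trait.
#' @param target_d2 dominance fraction of phenotypic variance; requires
#'   `target_h2 + target_d2 < 1`.
#' @param n_trials pure-species trials per species (families are spread
#'   across them).
#' @param n_blocks_per_trial blocks per trial (randomized complete block).
#' @param block_variance,residual_variance variances of block and residual
#'   effects at the asymptote scale (m^3 squared).
#' @param phenotypic_variance optional explicit phenotypic variance at the
#'   asymptote scale; by default derived as
#'   `residual_variance / (1 - target_h2 - target_d2)`. Required when
#'   `residual_variance = 0` (noise-free simulations).
#' @param asymptote_mean mean mature stem volume (m^3).
#' @param growth_beta0,growth_beta1 logistic growth-curve shape parameters;
#'   the fraction of mature volume at age x is `1 / (1 + b0 * exp(b1 * x))`.
#' @param measurement_ages nominal measurement ages in years (strictly
#'   increasing).
#' @param age_jitter half-width (years) of the uniform per-trial measurement
#'   age offset.
#' @param taper,stems_per_ha volume form factor and stocking used when
#'   back-deriving DBH/height and MAI.
#' @param g2_parent_selection how G1 pure-species parents of the G2 hybrid
#'   families are chosen: `"truncation"` (highest true breeding values, the
#'   operational behaviour of a breeding program) or `"random"` (useful for
#'   validation experiments where truncation on the unobservable true values
#'   would restrict the range seen by the estimators).
#' @param seed integer master seed; all stage seeds derive from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders_per_species = 30,
                       n_snps = 3000,
                       fst = 0.15,
                       n_psp_families_per_species = 30,
                       offspring_per_family = 20,
                       n_hybrid_families_g1 = 20,
                       n_hybrid_families_g2 = 15,
                       target_h2 = 0.4,
                       target_d2 = 0.15,
                       n_trials = 2,
                       n_blocks_per_trial = 10,
                       block_variance = 0.003,
                       residual_variance = 0.008,
                       phenotypic_variance = NULL,
                       asymptote_mean = 0.55,
                       growth_beta0 = 41.3,
                       growth_beta1 = -0.846,
                       measurement_ages = c(2.76, 5.40),
                       age_jitter = 0.2,
                       taper = 0.45,
                       stems_per_ha = 1200,
                       g2_parent_selection = c("truncation", "random"),
                       seed = 42) {
  g2_parent_selection <- match.arg(g2_parent_selection)
  cfg <- as.list(environment())
  counts <- c("n_founders_per_species", "n_snps", "n_psp_families_per_species",
              "offspring_per_family", "n_hybrid_families_g1",
              "n_hybrid_families_g2", "n_trials", "n_blocks_per_trial")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 1) stop(nm, " must be a count >= 1")
  }
  if (!is.finite(fst) || fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  if (target_h2 <= 0 || target_h2 >= 1) stop("target_h2 must be in (0, 1)")
  if (target_d2 < 0 || target_h2 + target_d2 >= 1) {
    stop("target_h2 + target_d2 must be < 1")
  }
  if (any(diff(measurement_ages) <= 0) || any(measurement_ages <= 0)) {
    stop("measurement_ages must be strictly increasing and positive")
  }
  if (block_variance < 0 || residual_variance < 0) stop("variances must be >= 0")
  if (residual_variance == 0 && is.null(phenotypic_variance)) {
    stop("phenotypic_variance must be given when residual_variance is 0")
  }
  if (!is.null(phenotypic_variance) && phenotypic_variance <= 0) {
    stop("phenotypic_variance must be positive")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Derive a reproducible per-stage child seed
#'
#' Stable integer hash of (seed, label) so that adding a pipeline stage never
#' perturbs the random stream of earlier stages.
#'
#' @param seed integer master seed.
#' @param label stage label.
#' @return integer seed below 2^31.
#' @export
child_seed <- function(seed, label) {
  h <- 0
  for (u in utf8ToInt(label)) h <- (h * 131 + u) %% 1000003
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919 + 1) %% 2147483647)
}

#' Simulate divergent founder genotypes for two species
#'
#' Per-SNP ancestral allele frequencies are drawn uniformly on
#' `[0.05, 0.95]`; each species' frequency is then drawn from the
#' Balding-Nichols beta distribution
#' `Beta(p0 (1 - fst) / fst, (1 - p0)(1 - fst) / fst)` (equal to `p0` when
#' `fst = 0`), and genotypes are sampled in Hardy-Weinberg proportions within
#' species.
#'
#' @param n_per_species founders per species.
#' @param n_snps number of SNPs.
#' @param fst divergence parameter in `[0, 1)`.
#' @param seed integer seed; identical inputs give bit-identical output.
#' @param species_labels names of the two species.
#' @return list with `genotypes` (dosage matrix, both species stacked),
#'   `species` (label per row), `freq` (2 x SNP matrix of within-species
#'   frequencies) and `ancestral_freq`.
#' @export
simulate_founder_genotypes <- function(n_per_species, n_snps, fst, seed,
                                       species_labels = c("grandis", "urophylla")) {
  if (!is.finite(fst) || fst < 0 || fst >= 1) stop("fst must be finite and in [0, 1)")
  stopifnot(n_snps >= 1, n_per_species >= 1)
  set.seed(seed)
  p0 <- stats::runif(n_snps, 0.05, 0.95)
  freq <- matrix(NA_real_, 2, n_snps,
                 dimnames = list(species_labels,
                                 sprintf("snp%05d", seq_len(n_snps))))
  for (s in 1:2) {
    if (fst == 0) {
      freq[s, ] <- p0
    } else {
      a <- p0 * (1 - fst) / fst
      b <- (1 - p0) * (1 - fst) / fst
      freq[s, ] <- stats::rbeta(n_snps, a, b)
    }
  }
  tags <- c("GRA", "URO")
  geno <- matrix(NA_real_, 2 * n_per_species, n_snps)
  ids <- character(2 * n_per_species)
  species <- character(2 * n_per_species)
  for (s in 1:2) {
    rows <- (s - 1) * n_per_species + seq_len(n_per_species)
    geno[rows, ] <- matrix(
      stats::rbinom(n_per_species * n_snps, 2, rep(freq[s, ], each = n_per_species)),
      n_per_species, n_snps)
    ids[rows] <- sprintf("G0_%s_%03d", tags[s], seq_len(n_per_species))
    species[rows] <- species_labels[s]
  }
  dimnames(geno) <- list(ids, colnames(freq))
  list(genotypes = geno, species = stats::setNames(species, ids),
       freq = freq, ancestral_freq = p0)
}

#' Simulate an additive + dominance trait architecture
#'
#' Each SNP receives an additive effect acting on the centred dosage
#' `x - 2 p` and a dominance effect acting on the centred heterozygosity
#' indicator. Effects are scaled so that, in the founder population, the
#' variance of true additive values is `target_h2` of the phenotypic
#' variance and the variance of dominance deviations is `target_d2` of it,
#' where phenotypic variance = additive + dominance + `residual_variance`
#' (block variance excluded, matching the heritability definition used for
#' evaluation). When founder `genotypes` are supplied the scaling uses their
#' realized sample variances; otherwise Hardy-Weinberg expectations at the
#' supplied frequencies.
#'
#' @param marker_freqs per-SNP allele frequencies of the founder population
#'   (pooled); monomorphic SNPs get zero effects.
#' @param target_h2,target_d2 variance fractions, `target_h2 + target_d2 < 1`.
#' @param residual_variance residual variance fixing the phenotypic scale.
#' @param seed integer seed.
#' @param genotypes optional founder dosage matrix for empirical scaling.
#' @return list of class `trait_architecture` with per-SNP `additive` and
#'   `dominance` effects, centring constants, and the target variance
#'   components `var_additive`, `var_dominance`, `residual_variance`.
#' @export
simulate_trait_architecture <- function(marker_freqs, target_h2, target_d2,
                                        residual_variance = 0.008, seed = 1,
                                        genotypes = NULL,
                                        phenotypic_variance = NULL) {
  if (target_h2 + target_d2 >= 1) stop("target_h2 + target_d2 must be < 1")
  if (is.null(phenotypic_variance) && residual_variance <= 0) {
    stop("residual_variance must be positive unless phenotypic_variance is given")
  }
  p <- marker_freqs
  m <- length(p)
  poly <- p > 0 & p < 1
  set.seed(seed)
  a <- stats::rnorm(m)
  d <- if (target_d2 > 0) stats::rnorm(m) else numeric(m)
  a[!poly] <- 0
  d[!poly] <- 0
  vp <- phenotypic_variance %||% (residual_variance / (1 - target_h2 - target_d2))
  va_target <- target_h2 * vp
  vd_target <- target_d2 * vp
  center_geno <- 2 * p
  center_het <- 2 * p * (1 - p)
  if (!is.null(genotypes)) {
    center_geno <- colMeans(genotypes)
    center_het <- colMeans(genotypes == 1)
    bv_raw <- as.numeric(sweep(genotypes, 2, center_geno, "-") %*% a)
    va_raw <- stats::var(bv_raw)
    if (target_d2 > 0) {
      dd_raw <- as.numeric(sweep((genotypes == 1) * 1, 2, center_het, "-") %*% d)
      vd_raw <- stats::var(dd_raw)
    } else vd_raw <- 1
  } else {
    va_raw <- sum(a^2 * 2 * p * (1 - p))
    vd_raw <- if (target_d2 > 0) sum(d^2 * 2 * p * (1 - p) * (1 - 2 * p * (1 - p))) else 1
  }
  if (va_raw <= 0) stop("no polymorphic SNPs to carry additive variance")
  a <- a * sqrt(va_target / va_raw)
  if (target_d2 > 0) d <- d * sqrt(vd_target / vd_raw)
  structure(list(additive = a, dominance = d,
                 center_geno = center_geno, center_het = center_het,
                 var_additive = va_target, var_dominance = vd_target,
                 residual_variance = residual_variance),
            class = "trait_architecture")
}

#' True genetic values under a simulated architecture
#'
#' @param arch a [simulate_trait_architecture()] object.
#' @param geno complete dosage matrix.
#' @return data frame with `individual_id`, `true_additive_value`,
#'   `true_dominance_deviation` and `true_genetic_value` (their sum).
#' @export
true_values <- function(arch, geno) {
  bv <- as.numeric(sweep(geno, 2, arch$center_geno, "-") %*% arch$additive)
  dd <- as.numeric(sweep((geno == 1) * 1, 2, arch$center_het, "-") %*% arch$dominance)
  data.frame(individual_id = rownames(geno),
             true_additive_value = bv,
             true_dominance_deviation = dd,
             true_genetic_value = bv + dd,
             stringsAsFactors = FALSE)
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Unlinked-locus gene dropping: at every SNP each offspring receives one
#' allele from each parent, drawn uniformly from that parent's two alleles
#' (a Bernoulli draw with probability dosage/2), independently across loci.
#' Output contains no missing values and, by construction, no
#' opposing-homozygote conflict between a true parent and its offspring.
#'
#' @param ped a [pedigree()] (true pedigree: both parents of every
#'   non-founder known).
#' @param founder_genotypes dosage matrix covering at least all individuals
#'   without genotyped parents.
#' @param seed integer seed.
#' @return dosage matrix for all pedigree individuals, pedigree row order.
#' @export
drop_gametes <- function(ped, founder_genotypes, seed) {
  ped <- .as_pedigree(ped)
  set.seed(seed)
  m <- ncol(founder_genotypes)
  ord <- attr(ped, "top_order")
  geno <- matrix(NA_real_, nrow(ped), m,
                 dimnames = list(ped$id, colnames(founder_genotypes)))
  known <- intersect(ped$id, rownames(founder_genotypes))
  geno[known, ] <- founder_genotypes[known, ]
  for (i in ord) {
    id <- ped$id[i]
    if (!anyNA(geno[id, 1])) next
    s <- ped$sire[i]; dm <- ped$dam[i]
    if (is.na(s) || is.na(dm)) {
      stop("individual ", id, " has an unknown parent and no supplied genotype")
    }
    gs <- geno[s, ]; gd <- geno[dm, ]
    if (anyNA(gs) || anyNA(gd)) stop("parent of ", id, " not yet genotyped")
    geno[id, ] <- stats::rbinom(m, 1, gs / 2) + stats::rbinom(m, 1, gd / 2)
  }
  geno
}

#' Simulate a complete RRS breeding program with known ground truth
#'
#' Builds the G0 -> G1 -> G2 population: divergent G0 founders of two
#' species; G1 pure-species polymix half-sib families (true sire recorded
#' internally, exported as unknown in the nominal pedigree); G1 interspecific
#' polymix hybrid families; and G2 full-sib hybrid families whose parents are
#' the G1 pure-species individuals with the highest true breeding values
#' (emulating between/within-family selection). Genotypes for all
#' individuals are gene-dropped from the founders; true additive values and
#' dominance deviations are recorded for every tree.
#'
#' @param config a [sim_config()].
#' @return list with elements `pedigree` (true, both parents known),
#'   `nominal_pedigree` (polymix sires recorded as unknown), `genotypes`,
#'   `truth`, `architecture`, `founders` and `config`.
#' @export
simulate_breeding_program <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  tags <- c("GRA", "URO")
  spp <- c("grandis", "urophylla")
  founders <- simulate_founder_genotypes(
    cfg$n_founders_per_species, cfg$n_snps, cfg$fst,
    seed = child_seed(cfg$seed, "founders"), species_labels = spp)
  pooled_freq <- allele_freq(founders$genotypes)
  arch <- simulate_trait_architecture(
    pooled_freq, cfg$target_h2, cfg$target_d2,
    residual_variance = cfg$residual_variance,
    seed = child_seed(cfg$seed, "architecture"),
    genotypes = founders$genotypes,
    phenotypic_variance = cfg$phenotypic_variance)

  fid <- function(sp) rownames(founders$genotypes)[founders$species == spp[sp]]
  rows <- list()
  add_row <- function(id, sire, dam, generation, species, cohort, trial,
                      block, family) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, sire = sire, dam = dam, generation = generation,
      species = species, cohort = cohort, trial = trial, block = block,
      family = family, stringsAsFactors = FALSE)
  }
  add_row(rownames(founders$genotypes), NA_character_, NA_character_, "G0",
          unname(founders$species), "FOUNDER", NA_character_, NA_integer_,
          NA_character_)

  set.seed(child_seed(cfg$seed, "matings"))
  off <- cfg$offspring_per_family
  # G1 pure-species polymix half-sib families
  for (sp in 1:2) {
    fo <- fid(sp)
    for (f in seq_len(cfg$n_psp_families_per_species)) {
      dam <- fo[(f - 1L) %% length(fo) + 1L]
      sires <- sample(setdiff(fo, dam), off, replace = TRUE)
      j <- seq_len(off)
      add_row(sprintf("G1_%s_F%02d_%03d", tags[sp], f, j),
              sires, dam, "G1", spp[sp], "PSPT",
              sprintf("PSPT_%s_%d", tags[sp], (j - 1L) %% cfg$n_trials + 1L),
              ((j - 1L) %/% cfg$n_trials) %% cfg$n_blocks_per_trial + 1L,
              sprintf("PSP_%s_F%02d", tags[sp], f))
    }
  }
  # G1 interspecific polymix hybrid families (reciprocal directions)
  for (f in seq_len(cfg$n_hybrid_families_g1)) {
    dam_sp <- if (f %% 2L == 1L) 1L else 2L
    sire_sp <- 3L - dam_sp
    dam <- fid(dam_sp)[(f - 1L) %% length(fid(dam_sp)) + 1L]
    sires <- sample(fid(sire_sp), off, replace = TRUE)
    j <- seq_len(off)
    add_row(sprintf("G1_HYB_F%02d_%03d", f, j),
            sires, dam, "G1", "hybrid", "HPT_G1", "HPT_G1",
            (j - 1L) %% cfg$n_blocks_per_trial + 1L,
            sprintf("HYB1_F%02d", f))
  }
  ped_g1 <- pedigree(do.call(rbind, rows))
  geno_g1 <- drop_gametes(ped_g1, founders$genotypes,
                          seed = child_seed(cfg$seed, "gametes_g1"))

  # select G2 parents: top true breeding values among G1 pure-species trees
  tv_g1 <- true_values(arch, geno_g1)
  np <- max(2L, ceiling(sqrt(cfg$n_hybrid_families_g2)))
  set.seed(child_seed(cfg$seed, "parent_selection"))
  top_parent <- function(sp) {
    cand <- ped_g1$id[ped_g1$generation == "G1" & ped_g1$species == spp[sp]]
    k <- min(np, length(cand))
    if (cfg$g2_parent_selection == "random") return(sample(cand, k))
    bv <- tv_g1$true_additive_value[match(cand, tv_g1$individual_id)]
    cand[order(-bv)][seq_len(k)]
  }
  pg <- top_parent(1); pu <- top_parent(2)
  pairs <- expand.grid(g = pg, u = pu, stringsAsFactors = FALSE)
  if (nrow(pairs) < cfg$n_hybrid_families_g2) {
    pairs <- pairs[rep(seq_len(nrow(pairs)),
                       length.out = cfg$n_hybrid_families_g2), ]
  }
  for (f in seq_len(cfg$n_hybrid_families_g2)) {
    j <- seq_len(off)
    add_row(sprintf("G2_HYB_F%02d_%03d", f, j),
            pairs$g[f], pairs$u[f], "G2", "hybrid", "HPT_G2", "HPT_G2",
            (j - 1L) %% cfg$n_blocks_per_trial + 1L,
            sprintf("HYB2_F%02d", f))
  }
  ped_true <- pedigree(do.call(rbind, rows))
  geno <- drop_gametes(ped_true, geno_g1,
                       seed = child_seed(cfg$seed, "gametes_g2"))

  nominal <- as.data.frame(ped_true)
  polymix <- nominal$cohort %in% c("PSPT", "HPT_G1")
  nominal$sire[polymix] <- NA_character_
  nominal <- pedigree(nominal)

  tv <- true_values(arch, geno)
  truth <- cbind(tv,
                 species_or_hybrid = ped_true$species[match(tv$individual_id, ped_true$id)],
                 generation = ped_true$generation[match(tv$individual_id, ped_true$id)],
                 stringsAsFactors = FALSE)
  list(pedigree = ped_true, nominal_pedigree = nominal, genotypes = geno,
       truth = truth, architecture = arch, founders = founders, config = cfg)
}

#' Logistic growth-curve fraction of mature size at a given age
#' @param age age in years.
#' @param b0,b1 curve parameters (`b0 > 0`, `b1 < 0` for growth).
#' @return fraction in (0, 1).
#' @export
logistic1_curve <- function(age, b0, b1) 1 / (1 + b0 * exp(b1 * age))

#' Simulate multi-trial phenotypes at several ages
#'
#' Each tree's volume trajectory is a logistic growth curve whose asymptote
#' is `asymptote_mean + true genetic value`; block effects (shared by trees
#' of the same trial x block) and residuals are added at the asymptote scale
#' and expressed through the same curve, so heritability is constant across
#' ages. Trials are measured at the nominal ages plus a per-trial uniform
#' jitter, emulating heterogeneous measurement ages across experiments.
#' Height follows the same curve and DBH is back-derived so that the taper
#' volume formula reproduces the simulated volume exactly.
#'
#' @param program a [simulate_breeding_program()] result.
#' @param config optional [sim_config()]; defaults to `program$config`.
#' @return data frame with one row per tree x age: `id`, `trial`, `block`,
#'   `family`, `nominal_age`, `age`, `dbh` (cm), `height` (m), `volume`
#'   (m^3).
#' @export
simulate_phenotypes <- function(program, config = program$config) {
  cfg <- config
  ped <- program$pedigree
  meas <- ped[!is.na(ped$trial), c("id", "trial", "block", "family")]
  if (nrow(meas) == 0L) stop("no individuals assigned to a trial/block")
  g <- program$truth$true_genetic_value[match(meas$id, program$truth$individual_id)]
  set.seed(child_seed(cfg$seed, "phenotypes"))
  trials <- sort(unique(meas$trial))
  ages <- cfg$measurement_ages
  offset <- matrix(stats::runif(length(trials) * length(ages),
                                -cfg$age_jitter, cfg$age_jitter),
                   length(trials), length(ages), dimnames = list(trials, NULL))
  bl_key <- paste(meas$trial, meas$block)
  bl_lev <- unique(bl_key)
  bl_eff <- stats::setNames(stats::rnorm(length(bl_lev), 0, sqrt(cfg$block_variance)),
                            bl_lev)
  out <- vector("list", length(ages))
  for (k in seq_along(ages)) {
    age <- ages[k] + offset[meas$trial, k]
    L <- logistic1_curve(age, cfg$growth_beta0, cfg$growth_beta1)
    e <- stats::rnorm(nrow(meas), 0, sqrt(cfg$residual_variance))
    vol <- pmax(L * (cfg$asymptote_mean + g + bl_eff[bl_key] + e), 1e-4)
    height <- 1.3 + (32 - 1.3) * L
    dbh <- 100 * sqrt(4 * vol / (pi * height * cfg$taper))
    out[[k]] <- data.frame(id = meas$id, trial = meas$trial,
                           block = meas$block, family = meas$family,
                           nominal_age = ages[k], age = age,
                           dbh = dbh, height = height, volume = vol,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  res[order(res$id, res$nominal_age), , drop = FALSE]
}

#' Write a simulated breeding program to plain-text files
#'
#' Writes nominal and true pedigree CSVs, a dosage matrix, phenotype and
#' truth CSVs, plus the configuration (JSON) and a small log recording the
#' seed and an MD5 of the config.
#'
#' @param program a [simulate_breeding_program()] result.
#' @param phenotypes a [simulate_phenotypes()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
write_breeding_program <- function(program, phenotypes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(pedigree = file.path(dir, "pedigree.csv"),
             pedigree_true = file.path(dir, "pedigree_true.csv"),
             genotypes = file.path(dir, "genotypes.csv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "config.json"))
  utils::write.csv(as.data.frame(program$nominal_pedigree), paths["pedigree"],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(program$pedigree), paths["pedigree_true"],
                   row.names = FALSE)
  write_dosage_matrix(program$genotypes, paths["genotypes"])
  utils::write.csv(phenotypes, paths["phenotypes"], row.names = FALSE)
  utils::write.csv(program$truth, paths["truth"], row.names = FALSE)
  cfg <- program$config
  jsonlite::write_json(unclass(cfg), paths["config"], auto_unbox = TRUE,
                       digits = NA)
  writeLines(c(paste("seed:", cfg$seed),
               paste("config_md5:", unname(tools::md5sum(paths["config"])))),
             file.path(dir, "simulation_log.txt"))
  invisible(paths)
}
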