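test_that("founder divergence follows the Balding-Nichols target", {
  f0 <- simulate_founder_genotypes(200, 5000, fst = 0, seed = 1)
  gg <- f0$genotypes[f0$species == "grandis", ]
  gu <- f0$genotypes[f0$species == "urophylla", ]
  expect_lt(abs(hudson_fst(gg, gu)), 0.02)

  f3 <- simulate_founder_genotypes(200, 5000, fst = 0.3, seed = 2)
  est <- hudson_fst(f3$genotypes[f3$species == "grandis", ],
                    f3$genotypes[f3$species == "urophylla", ])
  expect_equal(est, 0.3, tolerance = 0.05 / 0.3)

  expect_error(simulate_founder_genotypes(10, 100, fst = 1, seed = 1), "fst")
  expect_error(simulate_founder_genotypes(10, 100, fst = NaN, seed = 1), "fst")
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_founder_genotypes(20, 300, 0.2, seed = 9)
  b <- simulate_founder_genotypes(20, 300, 0.2, seed = 9)
  expect_identical(a, b)

  cfg <- tiny_config(seed = 13)
  p1 <- simulate_breeding_program(cfg)
  p2 <- simulate_breeding_program(cfg)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$truth, p2$truth)
  expect_identical(simulate_phenotypes(p1), simulate_phenotypes(p2))
})

test_that("trait architecture hits the target variance fractions", {
  f <- simulate_founder_genotypes(1000, 1500, fst = 0, seed = 3)
  p <- allele_freq(f$genotypes)

  arch0 <- simulate_trait_architecture(p, 0.4, 0, seed = 4,
                                       genotypes = f$genotypes)
  expect_true(all(arch0$dominance == 0))

  arch <- simulate_trait_architecture(p, 0.5, 0.2, residual_variance = 0.008,
                                      seed = 4, genotypes = f$genotypes)
  tv <- true_values(arch, f$genotypes)
  vp <- stats::var(tv$true_additive_value) +
    stats::var(tv$true_dominance_deviation) + 0.008
  expect_equal(stats::var(tv$true_additive_value) / vp, 0.5, tolerance = 0.1)
  expect_equal(stats::var(tv$true_dominance_deviation) / vp, 0.2,
               tolerance = 0.15)

  arch_b <- simulate_trait_architecture(p, 0.5, 0.2, residual_variance = 0.008,
                                        seed = 5, genotypes = f$genotypes)
  expect_false(any(arch$additive[1:10] == arch_b$additive[1:10]))
  expect_equal(arch$var_additive, arch_b$var_additive)

  expect_error(simulate_trait_architecture(p, 0.7, 0.3, seed = 1), "< 1")
})

test_that("gene dropping follows Mendelian transmission", {
  ped <- pedigree(data.frame(
    id = c("p1", "p2", sprintf("o%03d", 1:400)),
    sire = c(NA, NA, rep("p1", 400)),
    dam = c(NA, NA, rep("p2", 400))))
  founder <- matrix(c(0, 0, 2, 0, 1, 1), 2, 3,
                    dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
  g <- drop_gametes(ped, founder, seed = 11)
  off <- g[-(1:2), ]
  expect_true(all(off[, "s1"] == 0))      # (0,0) -> 0 always
  expect_true(all(off[, "s2"] == 1))      # (2,0) -> 1 always
  frq <- table(factor(off[, "s3"], levels = 0:2)) / 400
  expect_equal(as.numeric(frq), c(0.25, 0.5, 0.25), tolerance = 0.05 / 0.25)

  # opposing-homozygote conflicts are impossible with true parents
  cfg <- tiny_config(seed = 21)
  prog <- simulate_breeding_program(cfg)
  rep_ <- verify_parentage(prog$genotypes, prog$pedigree)
  expect_true(all(rep_$conflict_rate == 0))
})

test_that("breeding-program structure matches the RRS design", {
  cfg <- tiny_config(seed = 17)
  prog <- simulate_breeding_program(cfg)
  ped <- prog$pedigree

  psp <- ped[ped$cohort == "PSPT", ]
  for (sp in c("grandis", "urophylla")) {
    expect_equal(length(unique(psp$family[psp$species == sp])),
                 cfg$n_psp_families_per_species)
  }
  # every G2 hybrid has one grandis and one urophylla parent
  g2 <- ped[ped$generation == "G2", ]
  sp_of <- stats::setNames(ped$species, ped$id)
  expect_true(all(sort(c(sp_of[g2$sire[1]], sp_of[g2$dam[1]])) ==
                    c("grandis", "urophylla")))
  expect_true(all(sp_of[g2$sire] != sp_of[g2$dam]))
  # true pedigree has all parents, nominal hides polymix sires
  expect_true(all(!is.na(ped$sire[ped$generation != "G0"])))
  nom <- prog$nominal_pedigree
  expect_true(all(is.na(nom$sire[nom$cohort == "PSPT"])))
  expect_true(all(!is.na(nom$sire[nom$generation == "G2"])))

  # nominal half-sib family: A coefficient is 0.25 within family
  An <- build_A(nom)
  fam1 <- nom$id[which(nom$family == psp$family[1])][1:2]
  expect_equal(An[fam1[1], fam1[2]], 0.25)
})

test_that("phenotypes reflect genetic ranks and age jitter bounds", {
  cfg0 <- tiny_config(seed = 23, residual_variance = 0,
                      phenotypic_variance = 0.018, block_variance = 0,
                      n_trials = 1, n_blocks_per_trial = 1)
  prog <- simulate_breeding_program(cfg0)
  ph <- simulate_phenotypes(prog)
  a1 <- ph[ph$nominal_age == ph$nominal_age[1] & ph$trial == "HPT_G2", ]
  g <- prog$truth$true_genetic_value[match(a1$id, prog$truth$individual_id)]
  expect_equal(order(a1$volume), order(g))

  cfg <- tiny_config(seed = 29, age_jitter = 0.2)
  ph2 <- simulate_phenotypes(simulate_breeding_program(cfg))
  expect_true(all(abs(ph2$age - ph2$nominal_age) <= 0.2))
  # volume consistent with dbh/height through the taper formula
  expect_equal(compute_tree_volume(ph2$dbh, ph2$height, cfg$taper),
               ph2$volume, tolerance = 1e-10)
})

test_that("simulated programs round-trip through the plain-text writers", {
  cfg <- tiny_config(seed = 31)
  prog <- simulate_breeding_program(cfg)
  ph <- simulate_phenotypes(prog)
  dir <- tempfile("simout")
  paths <- write_breeding_program(prog, ph, dir)
  expect_true(all(file.exists(paths)))
  geno <- read_dosage_matrix(paths["genotypes"])
  expect_equal(geno, prog$genotypes, ignore_attr = TRUE)
  ped_back <- utils::read.csv(paths["pedigree"])
  expect_equal(nrow(ped_back), nrow(prog$pedigree))
  unlink(dir, recursive = TRUE)
})
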