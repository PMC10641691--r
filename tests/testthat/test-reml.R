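test_that("null-signal data drive the genetic variance to the boundary", {
  # with pure-noise phenotypes the additive component of a pedigree model
  # collapses to the boundary
  ped <- random_pedigree(50, 500, seed = 1)
  A <- build_A(ped)
  set.seed(1)
  y <- rnorm(500)
  fit <- reml_estimate(y, random = list(additive = list(Z = diag(500), K = A)),
                       compute_pev = FALSE)
  h2 <- fit$components[["additive"]] / sum(fit$components)
  expect_lt(h2, 0.05)
})

test_that("REML matches a brute-force restricted-likelihood grid", {
  set.seed(2)
  ped <- random_pedigree(8, 30, seed = 3)
  A <- build_A(ped)
  L <- chol(A + diag(1e-8, 30))
  u <- as.numeric(t(L) %*% rnorm(30)) * sqrt(2)
  y <- 5 + u + rnorm(30, 0, 1)
  X <- matrix(1, 30, 1)
  fit <- reml_estimate(y, X, random = list(additive = list(Z = diag(30), K = A)),
                       compute_pev = FALSE)
  # independent dense restricted log-likelihood
  rll <- function(s2a, s2e) {
    V <- s2a * A + s2e * diag(30)
    Vi <- solve(V)
    M <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(M) %*% t(X) %*% Vi
    -0.5 * as.numeric(determinant(V)$modulus + determinant(M)$modulus +
                        t(y) %*% P %*% y)
  }
  grid <- expand.grid(s2a = seq(0.05, 6, length.out = 45),
                      s2e = seq(0.05, 6, length.out = 45))
  ll <- mapply(rll, grid$s2a, grid$s2e)
  best <- grid[which.max(ll), ]
  step <- c(diff(unique(grid$s2a))[1], diff(unique(grid$s2e))[1])
  expect_lt(abs(fit$components[["additive"]] - best$s2a), step[1])
  expect_lt(abs(fit$components[["residual"]] - best$s2e), step[2])
  # and the REML optimum is at least as good as the best grid point
  expect_gte(rll(fit$components[["additive"]], fit$components[["residual"]]),
             max(ll) - 1e-6)
})

test_that("REML recovers heritability from half-sib family data", {
  cfg <- sim_config(n_founders_per_species = 20, n_snps = 300, fst = 0,
                    n_psp_families_per_species = 20, offspring_per_family = 25,
                    n_hybrid_families_g1 = 1, n_hybrid_families_g2 = 1,
                    target_h2 = 0.5, target_d2 = 0, n_trials = 1,
                    n_blocks_per_trial = 5, seed = 101)
  prog <- simulate_breeding_program(cfg)
  ph <- simulate_phenotypes(prog)
  ped <- prog$pedigree
  a <- ph[ph$nominal_age == 5.40 &
            ped$cohort[match(ph$id, ped$id)] == "PSPT", ]
  dat <- data.frame(id = a$id, mai = compute_mai(a$volume, a$age),
                    trial = ped$trial[match(a$id, ped$id)],
                    block = ped$block[match(a$id, ped$id)])
  fit <- fit_ablup(dat, ped, blocks = "fixed", compute_pev = FALSE)
  expect_gt(fit$h2$h2_narrow, 0.35)
  expect_lt(fit$h2$h2_narrow, 0.65)
})

test_that("MME solutions equal closed-form ridge regression", {
  set.seed(4)
  n <- 60
  Z <- diag(n); colnames(Z) <- sprintf("u%02d", 1:n)
  y <- rnorm(n, 3, 1)
  s2u <- 0.8; s2e <- 1.7
  lam <- s2e / s2u
  sol <- solve_mme(y, random = list(g = list(Z = Z, Kinv = NULL,
                                             variance = s2u)),
                   residual_variance = s2e)
  # closed-form ridge with intercept
  C <- cbind(1, Z)
  pen <- diag(c(0, rep(lam, n)))
  ref <- solve(crossprod(C) + pen, crossprod(C, y))
  expect_equal(unname(sol$beta), ref[1], tolerance = 1e-10)
  expect_equal(unname(sol$g$u), unname(ref[-1]), tolerance = 1e-10)

  # shrinkage limit: variance -> 0 sends all BLUPs to 0
  tiny <- solve_mme(y, random = list(g = list(Z = Z, Kinv = NULL,
                                              variance = 1e-12)),
                    residual_variance = s2e)
  expect_lt(max(abs(tiny$g$u)), 1e-9)
})

test_that("GBLUP predictions equal RR-BLUP marker-effect predictions", {
  set.seed(5)
  n <- 50; m <- 100
  p <- runif(m, 0.1, 0.9)
  geno <- hwe_genotypes(n, p, seed = 6)
  y <- rnorm(n, 10, 2)
  G <- build_GA(geno)
  fit <- fit_gblup(data.frame(id = rownames(geno), value = y), G)
  s2a <- fit$components[["additive"]]; s2e <- fit$components[["residual"]]
  pf <- allele_freq(geno)
  W <- sweep(geno, 2, 2 * pf, "-")
  W <- sweep(W, 2, sqrt(2 * pf * (1 - pf)), "/")
  # ridge on markers with matched penalty, intercept unpenalized
  C <- cbind(1, W)
  pen <- diag(c(0, rep(m * s2e / s2a, m)))
  sol <- solve(crossprod(C) + pen, crossprod(C, y))
  expect_lt(max(abs(fit$gebv - as.numeric(W %*% sol[-1]))), 1e-6)
})

test_that("single-step fits collapse to pedigree fits without genomic data", {
  ped <- random_pedigree(10, 60, seed = 7)
  A <- build_A(ped)
  set.seed(8)
  L <- chol(A + diag(1e-8, 60))
  y <- 2 + as.numeric(t(L) %*% rnorm(60)) + rnorm(60, 0, 0.8)
  train <- data.frame(id = ped$id[1:45], value = y[1:45])
  gids <- ped$id[50:60]
  H <- build_H(A, A[gids, gids], gids)  # GA := A22, no genomic information
  fa <- fit_gblup(train, A)
  fh <- fit_hblup(train, H)
  expect_equal(fh$components, fa$components, tolerance = 1e-6)
  expect_equal(fh$gebv, fa$gebv, tolerance = 1e-5)
})

test_that("ungenotyped full sibs share identical single-step GEBVs", {
  cfg <- tiny_config(seed = 37)
  prog <- simulate_breeding_program(cfg)
  ped <- prog$nominal_pedigree
  A <- build_A(ped)
  g2 <- ped$id[ped$generation == "G2"]
  genotyped <- setdiff(ped$id[ped$cohort %in% c("HPT_G1", "PSPT")], g2)
  GA <- build_GA(filter_markers(prog$genotypes[genotyped, ]))
  H <- build_H(A, GA, rownames(GA))
  set.seed(9)
  train <- data.frame(id = rownames(GA),
                      value = rnorm(nrow(GA)))
  fit <- fit_hblup(train, H)
  fam <- split(g2, ped$family[match(g2, ped$id)])
  for (f in fam[1:3]) {
    expect_lt(diff(range(fit$gebv[f])), 1e-8)
  }
})

test_that("heritability, de-regression and reliability follow their formulas", {
  h <- heritability(c(additive = 2, dominance = 0, residual = 2))
  expect_equal(h$h2_narrow, h$h2_broad)
  expect_error(heritability(c(additive = 0, residual = 0)), "zero total")
  # block variance excluded from the denominator
  h2 <- heritability(c(additive = 1, block = 100, residual = 1))
  expect_equal(h2$h2_narrow, 0.5)

  expect_equal(deregress(10, 0.5), 20)
  expect_equal(deregress(c(3, -2), 1), c(3, -2))
  expect_error(deregress(1, 0), "\\(0, 1\\]")
  ebv <- c(a = 1, b = 2, c = 4)
  expect_equal(stats::cor(ebv, deregress(ebv, 0.8)), 1)

  expect_equal(reliability(c(0.5, 2), 2), c(0.75, 0))
})

test_that("reliability increases when offspring records are added", {
  ped <- pedigree(data.frame(
    id   = c("p", "m", sprintf("k%d", 1:5), sprintf("q%d", 1:5)),
    sire = c(NA, NA, rep("p", 5), rep(NA, 5)),
    dam  = c(NA, NA, sprintf("q%d", 1:5), rep(NA, 5))))
  A <- build_A(ped)
  Ainv <- build_A_inverse(ped)
  s2a <- 1; s2e <- 1
  run <- function(rec_ids) {
    set.seed(10)
    y <- rnorm(length(rec_ids), 5, 1)
    Z <- incidence(rec_ids, ped$id)
    sol <- solve_mme(y, random = list(a = list(Z = Z, Kinv = Ainv,
                                               variance = s2a)),
                     residual_variance = s2e)
    reliability(sol$a$pev, s2a)["p"]
  }
  r_own <- run(c("p", "m"))
  r_off <- run(c("p", "m", sprintf("k%d", 1:5)))
  expect_gt(r_off, r_own)
})
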