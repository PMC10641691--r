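test_that("pedigree construction validates structure", {
  expect_error(pedigree(data.frame(id = c("a", "a"), sire = NA, dam = NA)),
               "duplicated")
  expect_error(pedigree(data.frame(id = "a", sire = "ghost", dam = NA)),
               "unknown sire")
  expect_error(pedigree(data.frame(id = c("a", "b"), sire = c("b", "a"),
                                   dam = NA)), "cycle")
  ped <- pedigree(data.frame(id = c("o", "s", "d"), sire = c("s", NA, NA),
                             dam = c("d", NA, NA)))
  expect_equal(attr(ped, "top_order")[1:2], c(2L, 3L))
  expect_equal(is_founder(ped), c(FALSE, TRUE, TRUE))
})

test_that("A matrix reproduces classical kinship coefficients", {
  founders <- pedigree(data.frame(id = letters[1:4], sire = NA, dam = NA))
  expect_equal(unname(build_A(founders)), diag(4), ignore_attr = TRUE)

  ped <- pedigree(data.frame(
    id   = c("s", "d", "d2", "o1", "o2", "h"),
    sire = c(NA, NA, NA, "s", "s", "s"),
    dam  = c(NA, NA, NA, "d", "d", "d2")))
  A <- build_A(ped)
  expect_equal(A["s", "o1"], 0.5)    # parent-offspring
  expect_equal(A["o1", "o2"], 0.5)   # full sibs
  expect_equal(A["o1", "h"], 0.25)   # half sibs
  expect_equal(diag(A)[c("o1", "h")], c(o1 = 1, h = 1))

  # offspring of full sibs: F = 0.25, diagonal 1.25
  inc <- pedigree(data.frame(
    id   = c("s", "d", "o1", "o2", "q"),
    sire = c(NA, NA, "s", "s", "o1"),
    dam  = c(NA, NA, "d", "d", "o2")))
  expect_equal(build_A(inc)["q", "q"], 1.25)
  expect_equal(unname(inbreeding(inc)["q"]), 0.25)
})

test_that("A-inverse follows Henderson's rules and inverts A", {
  founders <- pedigree(data.frame(id = letters[1:3], sire = NA, dam = NA))
  expect_equal(unname(build_A_inverse(founders)), diag(3), ignore_attr = TRUE)

  trio <- pedigree(data.frame(id = c("s", "d", "o"), sire = c(NA, NA, "s"),
                              dam = c(NA, NA, "d")))
  Ai <- build_A_inverse(trio)
  expect_equal(unname(Ai),
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3, 3),
               tolerance = 1e-12, ignore_attr = TRUE)

  ped <- random_pedigree(10, 50, seed = 42)
  A <- build_A(ped)
  Ai <- build_A_inverse(ped)
  expect_lt(max(abs(Ai %*% A - diag(50))), 1e-8)
  # dense numerical inverse as independent oracle
  expect_lt(max(abs(Ai - solve(A))), 1e-8)
})

test_that("pedigree dominance matrix gives classical values", {
  ped <- pedigree(data.frame(
    id   = c("s", "d", "o1", "o2"),
    sire = c(NA, NA, "s", "s"),
    dam  = c(NA, NA, "d", "d")))
  D <- build_D_pedigree(ped)
  expect_equal(D["o1", "o2"], 0.25)  # full sibs
  expect_equal(D["s", "o1"], 0)      # parent-offspring
  expect_equal(diag(D), nv(rep(1, 4), ped$id))
  expect_equal(D["s", "d"], 0)       # founders mutually 0

  # double first cousins: both sib pairs full sibs -> d = 1/16
  dfc <- pedigree(data.frame(
    id   = c("a", "b", "c", "e", "s1", "s2", "d1", "d2", "i", "j"),
    sire = c(NA, NA, NA, NA, "a", "a", "c", "c", "s1", "s2"),
    dam  = c(NA, NA, NA, NA, "b", "b", "e", "e", "d1", "d2")))
  expect_equal(build_D_pedigree(dfc)["i", "j"], 0.0625)
})

test_that("genomic additive matrix matches hand computation and theory", {
  g <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "s1"))
  G <- build_GA(g)
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # duplicated individual: off-diagonal equals both diagonals
  g2 <- hwe_genotypes(10, runif(50, 0.3, 0.7), seed = 2)
  g2[2, ] <- g2[1, ]
  G2 <- build_GA(g2)
  expect_equal(G2[1, 2], G2[1, 1])
  expect_equal(G2[1, 2], G2[2, 2])

  # HWE founder sample: mean diagonal -> 1
  gh <- hwe_genotypes(200, runif(5000, 0.1, 0.9), seed = 3)
  expect_equal(mean(diag(build_GA(gh))), 1, tolerance = 0.02)

  expect_error(build_GA(matrix(c(0, 0), 2, 1,
                               dimnames = list(c("a", "b"), "s1"))),
               "monomorphic")
})

test_that("genomic dominance matrix matches hand computation and scaling", {
  g <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(build_GD(g)), matrix(1, 2, 2), tolerance = 1e-12,
               ignore_attr = TRUE)

  g2 <- matrix(c(1, 0), 2, 1, dimnames = list(c("a", "b"), "s1"))
  GD <- build_GD(g2, freq = 0.5)
  # k = (0.5, -0.5), denominator 2 * 0.25 * 0.5 = 0.25
  expect_equal(GD["a", "b"], -1, tolerance = 1e-12)
  expect_equal(GD["a", "a"], 1, tolerance = 1e-12)

  gh <- hwe_genotypes(200, runif(5000, 0.1, 0.9), seed = 4)
  expect_equal(mean(diag(build_GD(gh))), 1, tolerance = 0.05)
})

test_that("single-step H matrix degenerates and blends correctly", {
  ped <- random_pedigree(8, 40, seed = 5)
  A <- build_A(ped)
  gids <- ped$id[seq(17, 40)]  # 60/40 split

  # GA := A22 -> H = A exactly
  H <- build_H(A, A[gids, gids], gids)
  expect_equal(unname(H), unname(A), tolerance = 1e-10, ignore_attr = TRUE)

  # all genotyped -> H = GA
  GAfull <- A + diag(0.05, 40)
  dimnames(GAfull) <- dimnames(A)
  Hfull <- build_H(A, GAfull, ped$id)
  expect_equal(unname(Hfull), unname(GAfull), tolerance = 1e-12,
               ignore_attr = TRUE)

  # brute-force block oracle for a perturbed GA
  set.seed(6)
  Epert <- matrix(rnorm(length(gids)^2, 0, 0.03), length(gids))
  GA <- A[gids, gids] + crossprod(Epert) / 10
  dimnames(GA) <- list(gids, gids)
  H2 <- build_H(A, GA, gids)
  ung <- setdiff(ped$id, gids)
  A22i <- solve(A[gids, gids])
  H11 <- A[ung, ung] +
    A[ung, gids] %*% A22i %*% (GA - A[gids, gids]) %*% A22i %*% A[gids, ung]
  H12 <- A[ung, gids] %*% A22i %*% GA
  expect_equal(H2[ung, ung], H11, tolerance = 1e-10)
  expect_equal(unname(H2[ung, gids]), unname(H12), tolerance = 1e-10)
  expect_equal(H2[gids, gids], GA, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(H2, t(H2), ignore_attr = TRUE)

  # H-inverse identity and dense-inversion oracle
  Ai <- build_A_inverse(ped)
  Hi0 <- build_H_inverse(Ai, A22i, A22i, gids)          # GAinv = A22inv
  expect_equal(unname(Hi0), unname(Ai), tolerance = 1e-12, ignore_attr = TRUE)
  Hi_tau0 <- build_H_inverse(Ai, A22i, solve(GA), gids, tau = 0)
  expect_equal(unname(Hi_tau0), unname(Ai), tolerance = 1e-12,
               ignore_attr = TRUE)
  Hi <- build_H_inverse(Ai, A22i, solve(GA), gids)
  expect_lt(max(abs(Hi - solve(H2))), 1e-6)
})

test_that("genomic relationships estimate pedigree expectations", {
  # gene-dropped pedigree at 5,000 SNPs: mean(GA - A) near zero
  set.seed(8)
  founders <- hwe_genotypes(50, runif(5000, 0.15, 0.85), seed = 8, prefix = "f")
  n_off <- 80
  ids <- c(rownames(founders), sprintf("o%03d", seq_len(n_off)))
  sire <- c(rep(NA, 50), sample(rownames(founders), n_off, replace = TRUE))
  dam <- c(rep(NA, 50), rep(NA, n_off))
  for (i in seq_len(n_off)) {
    dam[50 + i] <- sample(setdiff(rownames(founders), sire[50 + i]), 1)
  }
  ped <- pedigree(data.frame(id = ids, sire = sire, dam = dam))
  geno <- drop_gametes(ped, founders, seed = 9)
  A <- build_A(ped)
  GA <- build_GA(filter_markers(geno, min_maf = 0.01))
  expect_lt(abs(mean(GA - A[rownames(GA), rownames(GA)])), 0.05)
})
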