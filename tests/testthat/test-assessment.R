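test_that("training-set assembly follows the seven canonical combinations", {
  cohorts <- list(hybrids = sprintf("h%d", 1:5), parents = sprintf("p%d", 1:2),
                  uncles = sprintf("u%d", 1:3))
  expect_equal(length(build_training_set(cohorts, "H")$ids), 5)
  expect_equal(length(build_training_set(cohorts, "H+P")$ids), 7)
  expect_equal(length(build_training_set(cohorts, "H+P+U")$ids), 10)
  ts <- build_training_set(cohorts, "P+U")
  expect_equal(unname(ts$cohort[ts$ids]),
               c(rep("parents", 2), rep("uncles", 3)))
  expect_error(build_training_set(cohorts, "H+X"), "unknown")
  empty <- cohorts; empty$parents <- character(0)
  expect_error(build_training_set(empty, "P"), "empty")
  overlap <- cohorts; overlap$uncles[1] <- "h1"
  expect_error(build_training_set(overlap, "H+U"), "overlap")
})

test_that("realized predictive ability is an id-paired Pearson correlation", {
  v <- nv(c(1, 2, 3, 4), letters[1:4])
  expect_equal(realized_predictive_ability(v, v), 1)
  expect_equal(realized_predictive_ability(-v, v), -1)
  # hand Pearson: r = 11 / sqrt(5 * 26)
  w <- nv(c(2, 4, 5, 9), letters[1:4])
  expect_equal(realized_predictive_ability(v, w), 11 / sqrt(130))
  expect_equal(realized_predictive_ability(v, w), 0.9648, tolerance = 1e-4)
  # pairing is by id, not position
  expect_equal(realized_predictive_ability(v, rev(w)), 11 / sqrt(130))
  expect_warning(out <- realized_predictive_ability(nv(rep(1, 4), letters[1:4]), w),
                 "zero variance")
  expect_true(is.na(out))
  expect_error(realized_predictive_ability(v[1:2], w[1:2]), "fewer than 3")
})

test_that("bias equals one minus the OLS slope of reference on genomic", {
  v <- nv(c(1, 2, 3, 4), letters[1:4])
  expect_equal(prediction_bias(v, v), 0)
  expect_equal(prediction_bias(v, 2 * v), -1)
  set.seed(1)
  g <- nv(rnorm(30), sprintf("i%d", 1:30))
  r <- nv(0.6 * g + rnorm(30, 0, 0.3), names(g))
  b_ols <- sum((g - mean(g)) * (r - mean(r))) / sum((g - mean(g))^2)
  expect_equal(prediction_bias(g, r), 1 - b_ols)
})

test_that("rank concordance mid-ranks ties and tracks monotone transforms", {
  v <- nv(c(0.2, 1.5, 3.1, 7), letters[1:4])
  expect_equal(rank_concordance(exp(v), v), 1)
  expect_equal(rank_concordance(-v, v), -1)
  g <- nv(c(1, 2, 2, 3, 5), sprintf("i%d", 1:5))
  r <- nv(c(2, 1, 4, 3, 5), sprintf("i%d", 1:5))
  # brute-force mid-ranks: g -> 1, 2.5, 2.5, 4, 5
  rg <- c(1, 2.5, 2.5, 4, 5); rr <- c(2, 1, 4, 3, 5)
  expect_equal(rank_concordance(g, r), stats::cor(rg, rr))
})

test_that("coincidence rates use nearest-integer top-k with deterministic ties", {
  expect_equal(selection_count(197, 0.025), 5L)
  expect_equal(selection_count(197, 0.05), 10L)
  expect_equal(selection_count(10, 0.01), 1L)  # minimum 1
  set.seed(2)
  v <- nv(rnorm(197), sprintf("i%03d", 1:197))
  expect_equal(coincidence_rate(v, v, 0.025), 100)
  expect_equal(coincidence_rate(v, v, 1), 100)
  # disjoint top-k by construction
  u <- nv(seq_len(20), sprintf("i%02d", 1:20))
  expect_equal(coincidence_rate(u, -u, 0.25), 0)
  # metrics invariant to common shifts and positive rescaling
  w <- nv(rnorm(20), names(u))
  expect_equal(coincidence_rate(u + 5, w + 5, 0.2),
               coincidence_rate(u, w, 0.2))
  expect_equal(realized_predictive_ability(2 * u + 1, 3 * w - 2),
               realized_predictive_ability(u, w))
  expect_equal(rank_concordance(2 * u + 1, w), rank_concordance(u, w))
})

test_that("family assessment aggregates to family means", {
  set.seed(3)
  n <- 81
  fam <- nv(rep(sprintf("f%02d", 1:27), each = 3), sprintf("i%02d", 1:n))
  g <- nv(rnorm(n), names(fam))
  r <- nv(g + rnorm(n, 0, 0.5), names(fam))
  fa <- family_assessment(g, r, fam)
  expect_equal(nrow(fa$table), 27)
  # groupby means by brute force
  bf <- tapply(g, fam, mean)
  expect_equal(fa$table$genomic_mean[match(names(bf), fa$table$family)],
               as.numeric(bf))
  gm <- nv(fa$table$genomic_mean, fa$table$family)
  rm_ <- nv(fa$table$reference_mean, fa$table$family)
  expect_equal(fa$rpa, realized_predictive_ability(gm, rm_))

  # singleton families reproduce the individual-level RPA
  fam1 <- nv(paste0("s", seq_len(20)), sprintf("j%02d", 1:20))
  g1 <- nv(rnorm(20), names(fam1)); r1 <- nv(rnorm(20), names(fam1))
  fa1 <- family_assessment(g1, r1, fam1)
  expect_equal(fa1$rpa, realized_predictive_ability(g1, r1))
})

test_that("cross-validation partitions ids and respects family strata", {
  set.seed(4)
  n <- 60
  ids <- sprintf("i%02d", 1:n)
  fam <- nv(rep(sprintf("f%02d", 1:20), each = 3), ids)
  geno <- hwe_genotypes(n, runif(300, 0.2, 0.8), seed = 5)
  rownames(geno) <- ids
  G <- build_GA(geno)
  pseudo <- data.frame(id = ids, value = as.numeric(G %*% rnorm(n)) +
                         rnorm(n, 0, 0.5))
  cv <- cross_validate(pseudo, G, k = 5, seed = 6, family = fam)
  expect_equal(sort(names(cv$folds)), sort(ids))
  expect_equal(length(unique(cv$folds)), 5)
  # families never straddle folds under stratification
  expect_true(all(tapply(cv$folds, fam[names(cv$folds)],
                         function(x) length(unique(x))) == 1))
  expect_true(is.finite(cv$mean_pa))
  expect_error(cross_validate(pseudo, G, k = n), "smaller")
  expect_error(cross_validate(pseudo, G, k = 1), ">= 2")

  tr <- pseudo[1:40, ]; te <- pseudo[41:60, ]
  pa <- direct_validate(tr, te, G)
  expect_true(abs(pa) <= 1)
  expect_error(direct_validate(pseudo, te, G), "disjoint")
})
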