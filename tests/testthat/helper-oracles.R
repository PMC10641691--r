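# Independent oracles and small fixture builders used across the suite.

# Hudson-type Fst estimator (ratio of averages, sampling-corrected with
# allele counts), written independently of the package.
hudson_fst <- function(g1, g2) {
  p1 <- colMeans(g1) / 2
  p2 <- colMeans(g2) / 2
  n1 <- 2 * nrow(g1)
  n2 <- 2 * nrow(g2)
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(N) / sum(D)
}

# Hardy-Weinberg genotypes at given frequencies.
hwe_genotypes <- function(n, freqs, seed = 1, prefix = "ind") {
  set.seed(seed)
  m <- length(freqs)
  g <- matrix(stats::rbinom(n * m, 2, rep(freqs, each = n)), n, m)
  dimnames(g) <- list(sprintf("%s%04d", prefix, seq_len(n)),
                      sprintf("snp%04d", seq_len(m)))
  g
}

# Random acyclic pedigree: individuals can only have earlier-indexed parents.
random_pedigree <- function(n_founders, n_total, seed = 1) {
  set.seed(seed)
  id <- sprintf("i%04d", seq_len(n_total))
  sire <- dam <- rep(NA_character_, n_total)
  for (i in seq(n_founders + 1, n_total)) {
    pr <- sample(seq_len(i - 1), 2)
    sire[i] <- id[pr[1]]
    dam[i] <- id[pr[2]]
  }
  pedigree(data.frame(id = id, sire = sire, dam = dam,
                      stringsAsFactors = FALSE))
}

# Small named-vector convenience.
nv <- function(x, ids) stats::setNames(x, ids)

# Tiny breeding-program configuration used by several tests.
tiny_config <- function(seed = 7, ...) {
  defaults <- list(n_founders_per_species = 8, n_snps = 400,
                   n_psp_families_per_species = 8, offspring_per_family = 6,
                   n_hybrid_families_g1 = 4, n_hybrid_families_g2 = 6,
                   n_trials = 2, n_blocks_per_trial = 4, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
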