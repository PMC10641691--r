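#' Reference variance components for MAI in a G2 hybrid progeny trial
#'
#' Variance components for mean annual increment (MAI, Logistic 1
#' age-adjusted data, 1,400 trees) reported for an operational "urograndis"
#' G2 hybrid progeny trial under three individual-tree models: additive
#' pedigree (`A`), additive single-step with 197 genotyped trees (`H`), and
#' additive + dominance pedigree (`A+D`), at ages 3 and 6 years. Used as
#' worked-example inputs for [heritability()].
#'
#' @return data frame with columns `model`, `age`, `n`, `additive`,
#'   `dominance` (NA for additive-only models) and `residual`.
#' @export
reference_variance_components <- function() {
  data.frame(
    model = c("A", "H", "A+D", "A", "H", "A+D"),
    age = c(3, 3, 3, 6, 6, 6),
    n = 1400L,
    additive = c(305.16, 232.49, 207.31, 403.71, 157.79, 285.87),
    dominance = c(NA, NA, 81.90, NA, NA, 103.15),
    residual = c(211.18, 279.42, 193.16, 356.03, 517.88, 330.70),
    stringsAsFactors = FALSE)
}

#' Reference G1 training-cohort sizes
#'
#' Numbers of genotyped prior-generation individuals available to train
#' genomic models in the operational RRS experiment: 1,842 hybrid trees
#' (`H`), the 18 direct parents of the G2 trial (`P`), and 214 pure-species
#' relatives from the same progeny trials as the parents (`U`).
#'
#' @return named integer vector with elements `hybrids`, `parents`,
#'   `uncles`.
#' @export
reference_cohort_sizes <- function() {
  c(hybrids = 1842L, parents = 18L, uncles = 214L)
}
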