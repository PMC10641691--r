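#' Assemble a training set from cohort id lists
#'
#' The seven canonical combinations of the prior-generation cohorts are
#' `H` (hybrids), `P` (parents), `U` (uncles) and their unions `H+P`, `H+U`,
#' `P+U`, `H+P+U`. Cohorts must be disjoint; provenance labels are kept.
#'
#' @param cohorts named list with elements `hybrids`, `parents`, `uncles`
#'   (character id vectors; unused cohorts may be empty).
#' @param combo one of `"H"`, `"P"`, `"U"`, `"H+P"`, `"H+U"`, `"P+U"`,
#'   `"H+P+U"`.
#' @return list of class `training_set` with `name`, `ids`, and per-id
#'   `cohort` labels.
#' @export
build_training_set <- function(cohorts, combo) {
  key <- c(H = "hybrids", P = "parents", U = "uncles")
  parts <- strsplit(combo, "+", fixed = TRUE)[[1]]
  if (!length(parts) || !all(parts %in% names(key))) {
    stop("unknown training-set combination: ", combo)
  }
  if (!all(key[parts] %in% names(cohorts))) {
    stop("cohorts must be a named list with elements: ",
         paste(key[parts], collapse = ", "))
  }
  all_pairs <- utils::combn(names(cohorts), 2, simplify = FALSE)
  for (pr in all_pairs) {
    ov <- intersect(cohorts[[pr[1]]], cohorts[[pr[2]]])
    if (length(ov)) {
      stop("cohorts overlap (", pr[1], "/", pr[2], "): ",
           paste(utils::head(ov, 3), collapse = ", "))
    }
  }
  ids <- character(0); lab <- character(0)
  for (p in parts) {
    x <- cohorts[[key[p]]]
    ids <- c(ids, x)
    lab <- c(lab, rep(key[p], length(x)))
  }
  if (length(ids) == 0L) stop("training set '", combo, "' is empty")
  structure(list(name = combo, ids = ids,
                 cohort = stats::setNames(lab, ids)),
            class = "training_set")
}

.align_by_id <- function(genomic, reference, min_n = 3) {
  if (is.null(names(genomic)) || is.null(names(reference))) {
    stop("value vectors must be named by individual id")
  }
  ids <- intersect(names(genomic), names(reference))
  if (length(ids) < min_n) stop("fewer than ", min_n, " paired individuals")
  list(g = genomic[ids], r = reference[ids], ids = ids)
}

#' Realized predictive ability
#'
#' Pearson correlation between genomic predictions (GEBV/GEGV) and the
#' reference values (EBV/EGV) of the same individuals, paired strictly by
#' id.
#'
#' @param genomic,reference named numeric vectors.
#' @return correlation, or `NA` (with a warning) if either side has zero
#'   variance.
#' @export
realized_predictive_ability <- function(genomic, reference) {
  al <- .align_by_id(genomic, reference)
  if (stats::sd(al$g) == 0 || stats::sd(al$r) == 0) {
    warning("zero variance in one of the value vectors; RPA undefined")
    return(NA_real_)
  }
  stats::cor(al$g, al$r)
}

#' Bias of genomic predictions, 1 - b
#'
#' `b` is the ordinary-least-squares slope of the regression of the
#' reference values (EBV/EGV) on the genomic values (GEBV/GEGV); the bias is
#' `1 - b`. A slope `b > 1` indicates underestimation of the dispersion of
#' genomic predictions, `b < 1` overestimation.
#'
#' @inheritParams realized_predictive_ability
#' @return `1 - b`, or `NA` with a warning on zero variance.
#' @export
prediction_bias <- function(genomic, reference) {
  al <- .align_by_id(genomic, reference)
  vg <- stats::var(al$g)
  if (vg == 0) {
    warning("zero variance in genomic values; bias undefined")
    return(NA_real_)
  }
  b <- stats::cov(al$g, al$r) / vg
  1 - b
}

#' Spearman rank concordance
#'
#' Pearson correlation of mid-ranked (ties averaged) value ranks.
#'
#' @inheritParams realized_predictive_ability
#' @return Spearman's rho.
#' @export
rank_concordance <- function(genomic, reference) {
  al <- .align_by_id(genomic, reference)
  if (stats::sd(al$g) == 0 || stats::sd(al$r) == 0) {
    warning("zero variance; rank concordance undefined")
    return(NA_real_)
  }
  stats::cor(rank(al$g), rank(al$r))
}

#' Coincidence rate of top-ranked selections
#'
#' Percent overlap between the top `k` individuals by genomic value and the
#' top `k` by reference value, with `k = round(proportion * n)` (nearest
#' integer, minimum 1). Ties are broken deterministically by id order.
#'
#' @inheritParams realized_predictive_ability
#' @param selected_proportion selected fraction in `(0, 1]`.
#' @return coincidence rate in percent.
#' @export
coincidence_rate <- function(genomic, reference, selected_proportion) {
  stopifnot(selected_proportion > 0, selected_proportion <= 1)
  al <- .align_by_id(genomic, reference, min_n = 1)
  n <- length(al$ids)
  k <- max(1L, as.integer(floor(selected_proportion * n + 0.5)))
  topg <- al$ids[order(-al$g, al$ids)][seq_len(k)]
  topr <- al$ids[order(-al$r, al$ids)][seq_len(k)]
  100 * length(intersect(topg, topr)) / k
}

#' Top-k count implied by a selected proportion
#'
#' @param n number of candidates.
#' @param selected_proportion fraction in `(0, 1]`.
#' @return integer k (nearest integer, minimum 1).
#' @export
selection_count <- function(n, selected_proportion) {
  if (n < 1) stop("n must be positive")
  max(1L, as.integer(floor(selected_proportion * n + 0.5)))
}

#' Family-level prediction assessment
#'
#' Aggregates genomic and reference values to family means and recomputes
#' the realized predictive ability, rank concordance and (optionally)
#' coincidence rates on the means. Families with no scored members are
#' skipped with a message.
#'
#' @inheritParams realized_predictive_ability
#' @param family named character vector mapping individual id to family.
#' @param proportions selected proportions for family-level coincidence
#'   rates (default none).
#' @return list with `table` (family means), `rpa`, `spearman`, and
#'   `coincidence` (named by proportion) computed on family means.
#' @export
family_assessment <- function(genomic, reference, family,
                              proportions = numeric(0)) {
  al <- .align_by_id(genomic, reference)
  fam <- family[al$ids]
  if (anyNA(fam)) stop("family mapping missing for some individuals")
  empty <- setdiff(unique(family), fam)
  if (length(empty)) message(length(empty), " family(ies) with no scored members skipped")
  gm <- tapply(al$g, fam, mean)
  rm_ <- tapply(al$r, fam, mean)
  if (length(gm) < 2) stop("need at least 2 families")
  g <- stats::setNames(as.numeric(gm), names(gm))
  r <- stats::setNames(as.numeric(rm_), names(rm_))
  co <- vapply(proportions, function(p) coincidence_rate(g, r, p), 0)
  names(co) <- as.character(proportions)
  list(table = data.frame(family = names(gm), genomic_mean = as.numeric(gm),
                          reference_mean = as.numeric(rm_),
                          n = as.numeric(table(fam)[names(gm)]),
                          stringsAsFactors = FALSE, row.names = NULL),
       rpa = realized_predictive_ability(g, r),
       spearman = rank_concordance(g, r),
       coincidence = co)
}

#' k-fold cross-validated predictive ability of a genomic model
#'
#' Partitions the training individuals into `k` near-equal folds (by
#' default whole families are kept in the same fold, preventing full sibs
#' from appearing on both sides of a split), refits the genomic model on the
#' remaining folds, and reports the mean of the per-fold Pearson
#' correlations between predictions and the held-out values. Folds whose
#' held-out values have zero variance are skipped and reported.
#'
#' @param pseudo data frame `id`, `value` (pseudo-phenotypes of all
#'   individuals entering CV).
#' @param K relationship matrix covering all `pseudo$id`.
#' @param k number of folds (>= 2; `k = n` is rejected because a single
#'   held-out point has no defined correlation).
#' @param seed integer seed for the fold assignment.
#' @param family optional named vector id -> family for stratified folds.
#' @param stratify keep families intact across folds (default TRUE when
#'   `family` is given).
#' @param ... passed to [fit_gblup()].
#' @return list with `mean_pa`, `per_fold`, `folds` (id -> fold), and
#'   `skipped`.
#' @export
cross_validate <- function(pseudo, K, k = 10, seed = 1, family = NULL,
                           stratify = !is.null(family), ...) {
  n <- nrow(pseudo)
  if (k < 2) stop("k must be >= 2")
  if (k >= n) stop("k must be smaller than the number of individuals ",
                   "(per-fold correlation is undefined on a single point)")
  set.seed(seed)
  if (stratify && !is.null(family)) {
    fam <- family[pseudo$id]
    if (anyNA(fam)) stop("family mapping missing for some individuals")
    ufam <- sample(unique(fam))
    fam_fold <- stats::setNames(rep(seq_len(k), length.out = length(ufam)), ufam)
    fold <- fam_fold[fam]
  } else {
    fold <- sample(rep(seq_len(k), length.out = n))
  }
  fold <- stats::setNames(as.integer(fold), pseudo$id)
  pa <- rep(NA_real_, k)
  skipped <- integer(0)
  for (f in seq_len(k)) {
    test <- pseudo$id[fold == f]
    train <- pseudo[fold != f, , drop = FALSE]
    if (length(test) < 2 || nrow(train) < 3) { skipped <- c(skipped, f); next }
    fit <- fit_gblup(train, K, ...)
    obs <- stats::setNames(pseudo$value[match(test, pseudo$id)], test)
    if (stats::sd(obs) == 0 || stats::sd(fit$gebv[test]) == 0) {
      skipped <- c(skipped, f); next
    }
    pa[f] <- stats::cor(fit$gebv[test], obs)
  }
  if (length(skipped)) message("fold(s) skipped: ", paste(skipped, collapse = ", "))
  list(mean_pa = mean(pa, na.rm = TRUE), per_fold = pa, folds = fold,
       skipped = skipped)
}

#' Direct validation across disjoint populations
#'
#' Trains on one population and computes a single Pearson correlation
#' between predictions and reference values of a disjoint test population.
#'
#' @param train data frame `id`, `value` of the training population.
#' @param test data frame `id`, `value` of the test population (disjoint).
#' @param K relationship matrix covering both.
#' @param ... passed to [fit_gblup()].
#' @return the predictive ability (single correlation).
#' @export
direct_validate <- function(train, test, K, ...) {
  if (length(intersect(train$id, test$id))) {
    stop("training and test populations must be disjoint")
  }
  fit <- fit_gblup(train, K, ...)
  obs <- stats::setNames(test$value, test$id)
  realized_predictive_ability(fit$gebv[test$id], obs)
}
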