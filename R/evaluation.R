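#' Pedigree-based BLUP (ABLUP) individual-tree model
#'
#' Fits the univariate individual-tree mixed model
#' `y = X beta + W alpha + Z a (+ Q d) + e` with fixed trial effects, random
#' block-within-trial effects (`alpha ~ N(0, sigma2_b I)`), random additive
#' genetic effects (`a ~ N(0, sigma2_a A)`) and, for the additive-dominance
#' variant, random dominance effects (`d ~ N(0, sigma2_d D)`), by REML.
#' Residual and block variances are homogeneous across trials (the
#' parsimonious model). Breeding values (EBV) are returned for every
#' pedigree individual, phenotyped or not; EGV = EBV + dominance deviation.
#'
#' @param pheno data frame with columns `id`, `trial`, `block` and the
#'   response column.
#' @param ped a [pedigree()] covering all `pheno$id`.
#' @param response name of the response column, default `"mai"`.
#' @param dominance include the dominance term (A+D model).
#' @param A,D optional precomputed relationship matrices for `ped`.
#' @param blocks treat blocks as `"random"` (default), `"fixed"`, or drop
#'   them (`"none"`).
#' @param ... passed to [reml_estimate()].
#' @return object of class `gs_fit`: the underlying `reml_fit` plus named
#'   vectors `ebv`, `egv`, `reliability`, the variance `components` and
#'   heritabilities `h2`.
#' @export
fit_ablup <- function(pheno, ped, response = "mai", dominance = FALSE,
                      A = NULL, D = NULL, blocks = c("random", "fixed", "none"),
                      ...) {
  blocks <- match.arg(blocks)
  ped <- .as_pedigree(ped)
  stopifnot(all(c("id", "trial", "block", response) %in% names(pheno)))
  missing_ids <- setdiff(pheno$id, ped$id)
  if (length(missing_ids)) {
    stop("phenotyped ids missing from pedigree: ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  if (is.null(A)) A <- build_A(ped)
  y <- pheno[[response]]
  trial <- factor(pheno$trial)
  X <- if (nlevels(trial) > 1) stats::model.matrix(~trial) else
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  blk <- factor(paste(pheno$trial, pheno$block, sep = ":"))
  if (blocks == "fixed" && nlevels(blk) > 1) {
    X <- cbind(X, stats::model.matrix(~blk)[, -1, drop = FALSE])
  }
  random <- list()
  if (blocks == "random" && nlevels(blk) > 1) {
    random$block <- list(Z = incidence(blk, levels(blk)), K = NULL)
  }
  Zind <- incidence(pheno$id, ped$id)
  random$additive <- list(Z = Zind, K = A)
  if (dominance) {
    if (is.null(D)) D <- build_D_pedigree(ped, A = A)
    random$dominance <- list(Z = Zind, K = D)
  }
  fit <- reml_estimate(y, X, random, ...)
  ebv <- fit$random$additive$u
  dd <- if (dominance) fit$random$dominance$u else 0
  rel <- if (!is.null(fit$random$additive$pev)) {
    reliability(fit$random$additive$pev, fit$components[["additive"]])
  } else NULL
  comp <- fit$components
  structure(list(fit = fit, ebv = ebv, egv = ebv + dd,
                 reliability = rel, components = comp,
                 h2 = heritability(comp),
                 model = if (dominance) "ablup-ad" else "ablup"),
            class = "gs_fit")
}

#' Genomic BLUP (GBLUP) on pseudo-phenotypes
#'
#' Second stage of the two-stage genomic evaluation: the response is the
#' vector of EBVs (additive model) or EGVs (additive-dominance model) from a
#' prior ABLUP fit, the only fixed effect is the overall mean, and the
#' additive genomic effect has covariance `sigma2_a G_A` (plus
#' `sigma2_d G_D` when `KD` is supplied). Raw phenotypes may equally be
#' passed as `pseudo$value` for sensitivity work. GEBVs (and GEGVs) are
#' returned for every individual indexed by the relationship matrix, trained
#' or not.
#'
#' @param pseudo data frame with columns `id` and `value` (the training
#'   pseudo-phenotypes).
#' @param K additive relationship matrix (G_A, or H for [fit_hblup()])
#'   covering training individuals and prediction candidates.
#' @param KD optional dominance relationship matrix (G_D) for the
#'   additive-dominance variant.
#' @param model label stored on the fit.
#' @param compute_pev compute prediction error variances (off by default for
#'   speed; predictions do not need them).
#' @param ... passed to [reml_estimate()].
#' @return object of class `gs_fit` with `gebv` (all `K` ids), `gegv`,
#'   variance `components`, genomic heritabilities `h2`.
#' @export
fit_gblup <- function(pseudo, K, KD = NULL, model = if (is.null(KD)) "gblup"
                      else "gblup-gd", compute_pev = FALSE, ...) {
  stopifnot(all(c("id", "value") %in% names(pseudo)))
  ids <- rownames(K)
  missing_ids <- setdiff(pseudo$id, ids)
  if (length(missing_ids)) {
    stop("training ids missing from the relationship matrix: ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  Z <- incidence(pseudo$id, ids)
  random <- list(additive = list(Z = Z, K = K))
  if (!is.null(KD)) random$dominance <- list(Z = Z, K = KD)
  fit <- reml_estimate(pseudo$value, X = NULL, random,
                       compute_pev = compute_pev, ...)
  gebv <- fit$random$additive$u
  dd <- if (!is.null(KD)) fit$random$dominance$u else 0
  structure(list(fit = fit, gebv = gebv, gegv = gebv + dd,
                 components = fit$components,
                 h2 = heritability(fit$components), model = model),
            class = "gs_fit")
}

#' Single-step genomic BLUP (HBLUP)
#'
#' Additive-only GBLUP whose covariance is the blended single-step matrix H,
#' so training sets may mix genotyped and ungenotyped individuals and
#' predictions cover every pedigree member. Ungenotyped candidates of the
#' same full-sib family (with no own record in training) receive identical
#' GEBVs, as only pedigree information distinguishes them.
#'
#' @inheritParams fit_gblup
#' @param H single-step relationship matrix from [build_H()].
#' @return a `gs_fit`, as [fit_gblup()].
#' @export
fit_hblup <- function(pseudo, H, ...) {
  fit_gblup(pseudo, K = H, KD = NULL, model = "hblup", ...)
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(toupper(x$model), "fit\n")
  cat("variance components:\n")
  print(round(x$components, 6))
  cat(sprintf("h2 narrow = %.3f, broad = %.3f\n",
              x$h2$h2_narrow, x$h2$h2_broad))
  invisible(x)
}
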