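#' Additive (numerator) relationship matrix from a pedigree
#'
#' Wright's numerator relationship matrix A by the tabular (recursive) method:
#' processing individuals in topological order,
#' `a_ij = (a_{j,sire(i)} + a_{j,dam(i)}) / 2` for `j` preceding `i`, and
#' `a_ii = 1 + a_{sire(i),dam(i)} / 2`; unknown parents contribute zero.
#' Inbreeding is fully accounted for, so `diag(A) = 1 + F`.
#'
#' @param ped a [pedigree()].
#' @return dense symmetric matrix with ids as dimnames and attribute
#'   `flavor = "A"`, in the pedigree's row order.
#' @export
build_A <- function(ped) {
  ped <- .as_pedigree(ped)
  ord <- attr(ped, "top_order")
  id <- ped$id[ord]
  si <- match(ped$sire[ord], id)
  di <- match(ped$dam[ord], id)
  n <- length(id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (!is.na(s)) v <- v + A[j, s]
      if (!is.na(d)) v <- v + A[j, d]
      v <- v / 2
      A[j, i] <- v
      A[i, j] <- v
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
  }
  dimnames(A) <- list(id, id)
  back <- match(ped$id, id)
  A <- A[back, back, drop = FALSE]
  attr(A, "flavor") <- "A"
  A
}

.as_pedigree <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped) else ped
}

#' Inverse of the additive relationship matrix by Henderson's rules
#'
#' Direct construction of A-inverse accounting for inbreeding through the
#' Mendelian sampling variances `d_i = 1/2 - (F_sire + F_dam)/4` (both parents
#' known), `3/4 - F_parent/4` (one parent known) or 1 (founder).
#'
#' @param ped a [pedigree()].
#' @return dense symmetric matrix (ids as dimnames, attribute `flavor =
#'   "Ainv"`) whose product with [build_A()] is the identity.
#' @export
build_A_inverse <- function(ped) {
  ped <- .as_pedigree(ped)
  id <- ped$id
  Fi <- inbreeding(ped)
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  n <- length(id)
  Ainv <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    ds <- if (!is.na(s)) Fi[s] else NA_real_
    dd <- if (!is.na(d)) Fi[d] else NA_real_
    mend <- if (!is.na(s) && !is.na(d)) {
      0.5 - 0.25 * (ds + dd)
    } else if (!is.na(s)) {
      0.75 - 0.25 * ds
    } else if (!is.na(d)) {
      0.75 - 0.25 * dd
    } else 1
    b <- 1 / mend
    Ainv[i, i] <- Ainv[i, i] + b
    for (p in c(s, d)) {
      if (is.na(p)) next
      Ainv[p, i] <- Ainv[p, i] - b / 2
      Ainv[i, p] <- Ainv[i, p] - b / 2
    }
    if (!is.na(s) && !is.na(d)) {
      Ainv[s, s] <- Ainv[s, s] + b / 4
      Ainv[d, d] <- Ainv[d, d] + b / 4
      Ainv[s, d] <- Ainv[s, d] + b / 4
      Ainv[d, s] <- Ainv[d, s] + b / 4
    } else if (!is.na(s)) {
      Ainv[s, s] <- Ainv[s, s] + b / 4
    } else if (!is.na(d)) {
      Ainv[d, d] <- Ainv[d, d] + b / 4
    }
  }
  dimnames(Ainv) <- list(id, id)
  attr(Ainv, "flavor") <- "Ainv"
  Ainv
}

#' Dominance relationship matrix from a pedigree
#'
#' Classical (non-inbred) dominance relationships:
#' `d_ij = (a_{s(i)s(j)} a_{d(i)d(j)} + a_{s(i)d(j)} a_{d(i)s(j)}) / 4` for
#' distinct individuals, `d_ii = 1`, and zero wherever a parent is unknown.
#' Inbreeding is ignored in D (appropriate for outbred polymix/full-sib
#' family designs); see the methods vignette for this limitation.
#'
#' @param ped a [pedigree()].
#' @param A optional precomputed [build_A()] matrix for `ped`.
#' @return dense symmetric matrix, attribute `flavor = "D"`.
#' @export
build_D_pedigree <- function(ped, A = NULL) {
  ped <- .as_pedigree(ped)
  if (is.null(A)) A <- build_A(ped)
  id <- ped$id
  n <- length(id)
  # augment with a zero row/column standing for "unknown parent"
  A1 <- rbind(cbind(A, 0), 0)
  s <- match(ped$sire, id); s[is.na(s)] <- n + 1L
  d <- match(ped$dam, id); d[is.na(d)] <- n + 1L
  D <- 0.25 * (A1[s, s] * A1[d, d] + A1[s, d] * A1[d, s])
  diag(D) <- 1
  dimnames(D) <- list(id, id)
  attr(D, "flavor") <- "D"
  D
}

#' Additive genomic relationship matrix (VanRaden, standardized loci)
#'
#' `G_A = W W' / M` where `w_ij = (x_ij - 2 p_j) / sqrt(2 p_j q_j)`, `x_ij`
#' the 0/1/2 dosage, `p_j` the B-allele frequency of SNP `j` computed from the
#' supplied genotypes, and `M` the number of SNPs.
#'
#' @param geno complete (imputed) dosage matrix, individuals in rows.
#' @param freq optional externally supplied per-SNP allele frequencies.
#' @return dense symmetric matrix, attribute `flavor = "GA"`.
#' @export
build_GA <- function(geno, freq = NULL) {
  geno <- .check_complete_dosages(geno)
  p <- if (is.null(freq)) allele_freq(geno) else freq
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic SNP present (allele frequency 0 or 1); filter markers first")
  }
  W <- sweep(geno, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(W) / ncol(geno)
  dimnames(G) <- list(rownames(geno), rownames(geno))
  attr(G, "flavor") <- "GA"
  G
}

#' Dominance genomic relationship matrix
#'
#' `G_D = K K' / (2 * sum_j p_j q_j (1 - 2 p_j q_j))` with per-SNP entries
#' `k_ij = 1 - 2 p_j q_j` for heterozygotes and `-2 p_j q_j` for either
#' homozygote. Under Hardy-Weinberg proportions the diagonal averages to one.
#'
#' @inheritParams build_GA
#' @return dense symmetric matrix, attribute `flavor = "GD"`.
#' @export
build_GD <- function(geno, freq = NULL) {
  geno <- .check_complete_dosages(geno)
  p <- if (is.null(freq)) allele_freq(geno) else freq
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic SNP present (allele frequency 0 or 1); filter markers first")
  }
  tpq <- 2 * p * (1 - p)
  het <- (geno == 1) * 1
  K <- sweep(het, 2, tpq, "-")
  denom <- 2 * sum(p * (1 - p) * (1 - tpq))
  if (denom <= 0) stop("dominance scaling denominator is zero")
  G <- tcrossprod(K) / denom
  dimnames(G) <- list(rownames(geno), rownames(geno))
  attr(G, "flavor") <- "GD"
  G
}

.check_complete_dosages <- function(geno) {
  geno <- as.matrix(geno)
  if (anyNA(geno)) stop("dosage matrix contains missing values; impute first")
  if (ncol(geno) < 1L) stop("at least one SNP required")
  if (is.null(rownames(geno))) stop("dosage matrix must have individual ids as rownames")
  geno
}

#' Single-step blended relationship matrix H
#'
#' Combines expected pedigree relationships (A) with realized genomic
#' relationships (G_A) of the genotyped subset. With individuals partitioned
#' into ungenotyped (1) and genotyped (2):
#' \deqn{H_{11} = A_{11} + A_{12} A_{22}^{-1} (G_A - A_{22}) A_{22}^{-1} A_{21}}
#' \deqn{H_{12} = A_{12} A_{22}^{-1} G_A, \quad H_{22} = G_A}
#' The result is returned in A's id order.
#'
#' @param A pedigree relationship matrix over all individuals ([build_A()]).
#' @param GA genomic relationship matrix over the genotyped individuals.
#' @param genotyped_ids ids (subset of A's ids) that index `GA`.
#' @return dense symmetric matrix, attribute `flavor = "H"` and attribute
#'   `genotyped` holding `genotyped_ids`.
#' @export
build_H <- function(A, GA, genotyped_ids) {
  ids <- rownames(A)
  if (!all(genotyped_ids %in% ids)) {
    stop("genotyped_ids not all present in A: ",
         paste(utils::head(setdiff(genotyped_ids, ids), 3), collapse = ", "))
  }
  GA <- GA[genotyped_ids, genotyped_ids, drop = FALSE]
  ung <- setdiff(ids, genotyped_ids)
  A22 <- A[genotyped_ids, genotyped_ids, drop = FALSE]
  A22inv <- .solve_checked(A22, "A22")
  if (length(ung) == 0L) {
    H <- GA[ids, ids, drop = FALSE]
  } else {
    A11 <- A[ung, ung, drop = FALSE]
    A12 <- A[ung, genotyped_ids, drop = FALSE]
    T12 <- A12 %*% A22inv
    H11 <- A11 + T12 %*% (GA - A22) %*% t(T12)
    H12 <- T12 %*% GA
    H <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    H[ung, ung] <- H11
    H[ung, genotyped_ids] <- H12
    H[genotyped_ids, ung] <- t(H12)
    H[genotyped_ids, genotyped_ids] <- GA
  }
  H <- (H + t(H)) / 2
  attr(H, "flavor") <- "H"
  attr(H, "genotyped") <- genotyped_ids
  H
}

#' Inverse of the single-step relationship matrix
#'
#' `H^-1 = A^-1 + [0 0; 0 tau * (G_A^-1 - A_22^-1)]` padded into the
#' genotyped block, with scaling factor `tau` defaulting to one (use the full
#' genomic contribution). A small ridge can be added to G_A before inversion
#' when it is numerically singular.
#'
#' @param Ainv inverse pedigree relationship matrix over all individuals.
#' @param A22inv inverse of the genotyped block of A.
#' @param GAinv inverse genomic relationship matrix (genotyped individuals).
#' @param genotyped_ids ids indexing `GAinv`/`A22inv` within `Ainv`.
#' @param tau scaling factor on the genomic correction, default 1.
#' @return dense symmetric matrix, attribute `flavor = "Hinv"`.
#' @seealso [invert_kinship()] to form the inverses with an optional ridge.
#' @export
build_H_inverse <- function(Ainv, A22inv, GAinv, genotyped_ids, tau = 1) {
  ids <- rownames(Ainv)
  if (!all(genotyped_ids %in% ids)) stop("genotyped_ids not all present in Ainv")
  Hinv <- Ainv
  g <- genotyped_ids
  Hinv[g, g] <- Hinv[g, g] +
    tau * (GAinv[g, g, drop = FALSE] - A22inv[g, g, drop = FALSE])
  Hinv <- (Hinv + t(Hinv)) / 2
  attr(Hinv, "flavor") <- "Hinv"
  attr(Hinv, "genotyped") <- genotyped_ids
  Hinv
}

#' Invert a relationship matrix, optionally with a ridge
#'
#' @param K symmetric relationship matrix.
#' @param ridge value added to the diagonal before inversion (default 0; use
#'   e.g. `1e-6` for genomic matrices that are singular because individuals
#'   outnumber independently segregating loci).
#' @return the dense inverse, dimnames preserved.
#' @export
invert_kinship <- function(K, ridge = 0) {
  if (ridge > 0) K <- K + diag(ridge, nrow(K))
  .solve_checked(K, attr(K, "flavor") %||% "kinship matrix")
}

.solve_checked <- function(M, label) {
  out <- tryCatch(solve(M), error = function(e) {
    stop(label, " is singular or near-singular (reciprocal condition number ",
         format(rcond(M), digits = 3),
         "); consider a ridge (see invert_kinship)", call. = FALSE)
  })
  dimnames(out) <- dimnames(M)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
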