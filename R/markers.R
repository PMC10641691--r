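#' Per-SNP B-allele frequency
#'
#' Dosage-counted frequency of the B allele, computed per SNP over
#' non-missing calls.
#'
#' @param geno dosage matrix (individuals x SNPs, values 0/1/2 or NA).
#' @return named numeric vector of frequencies in `[0, 1]` (NaN for SNPs with
#'   zero calls).
#' @export
allele_freq <- function(geno) {
  colMeans(geno, na.rm = TRUE) / 2
}

.check_dosages <- function(geno) {
  geno <- as.matrix(geno)
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  geno
}

#' Filter SNPs on call rate and minor allele frequency
#'
#' Retains exactly the SNPs whose non-missing fraction is at least
#' `min_call_rate` and whose minor allele frequency is at least `min_maf`
#' (both comparisons inclusive). SNP order is preserved. SNPs with no calls
#' at all are always removed.
#'
#' @param geno dosage matrix (individuals x SNPs).
#' @param min_call_rate minimum fraction of non-missing calls, default 0.90.
#' @param min_maf minimum minor allele frequency, default 0.01.
#' @return the filtered dosage matrix.
#' @export
filter_markers <- function(geno, min_call_rate = 0.90, min_maf = 0.01) {
  geno <- .check_dosages(geno)
  stopifnot(min_call_rate >= 0, min_call_rate <= 1, min_maf >= 0, min_maf <= 1)
  cr <- colMeans(!is.na(geno))
  p <- allele_freq(geno)
  maf <- pmin(p, 1 - p)
  keep <- cr >= min_call_rate & !is.nan(maf) & maf >= min_maf
  if (!any(keep)) warning("no SNPs pass the filters")
  geno[, keep, drop = FALSE]
}

#' Filter samples on genotype call rate
#'
#' @param geno dosage matrix (individuals x SNPs).
#' @param min_call_rate minimum fraction of non-missing calls per sample,
#'   default 0.85.
#' @return the filtered dosage matrix; an error if no sample survives.
#' @export
filter_samples <- function(geno, min_call_rate = 0.85) {
  geno <- .check_dosages(geno)
  stopifnot(min_call_rate >= 0, min_call_rate <= 1)
  cr <- rowMeans(!is.na(geno))
  keep <- cr >= min_call_rate
  if (!any(keep)) stop("all samples removed by the call-rate filter")
  geno[keep, , drop = FALSE]
}

#' Impute missing dosages to the expected genotype
#'
#' Each missing call is replaced by the genotype expected from the SNP's
#' B-allele frequency `p`: homozygote 0 when `2p < 2/3`, heterozygote 1 when
#' `2/3 <= 2p < 4/3`, homozygote 2 when `2p >= 4/3` (intervals closed on the
#' left). Non-missing calls are untouched; the rule is deterministic and
#' idempotent.
#'
#' @param geno dosage matrix (individuals x SNPs).
#' @return complete dosage matrix of the same dimensions.
#' @export
impute_missing <- function(geno) {
  geno <- .check_dosages(geno)
  p <- allele_freq(geno)
  if (any(is.nan(p))) {
    stop("SNP(s) with zero calls cannot be imputed; filter markers first: ",
         paste(utils::head(colnames(geno)[is.nan(p)], 3), collapse = ", "))
  }
  if (!anyNA(geno)) return(geno)
  ev <- 2 * p
  fill <- ifelse(ev < 2 / 3, 0, ifelse(ev < 4 / 3, 1, 2))
  idx <- which(is.na(geno), arr.ind = TRUE)
  geno[idx] <- fill[idx[, 2]]
  geno
}

#' Merge two genotype panels on their shared SNPs
#'
#' Used to consolidate data genotyped on different SNP platforms: columns are
#' restricted to the intersection of SNP ids (kept in the first panel's
#' order) and rows concatenated. Individual id sets must be disjoint.
#' Allele frequencies of the merged panel are whatever [allele_freq()]
#' recomputes on the pooled calls.
#'
#' @param a,b dosage matrices with SNP ids as colnames and individual ids as
#'   rownames.
#' @return merged dosage matrix.
#' @export
intersect_platforms <- function(a, b) {
  a <- .check_dosages(a); b <- .check_dosages(b)
  dup <- intersect(rownames(a), rownames(b))
  if (length(dup)) {
    stop("duplicate individual ids across platforms: ",
         paste(utils::head(dup, 3), collapse = ", "))
  }
  shared <- intersect(colnames(a), colnames(b))
  if (length(shared) == 0L) stop("no shared SNPs between the two panels")
  shared <- colnames(a)[colnames(a) %in% shared]
  rbind(a[, shared, drop = FALSE], b[, shared, drop = FALSE])
}

#' Verify recorded parentage by opposing-homozygote counts
#'
#' For every genotyped parent-offspring pair in the pedigree, the conflict
#' rate is the fraction of SNPs (non-missing in both) where one member is
#' homozygous 0 and the other homozygous 2 - an impossibility under Mendelian
#' inheritance. Pairs whose rate exceeds `max_conflict_rate` are flagged.
#' Pairs with an ungenotyped member are skipped with a message.
#'
#' @param geno dosage matrix.
#' @param ped a [pedigree()].
#' @param max_conflict_rate flagging threshold, default 0.01.
#' @return data frame with one row per checked pair: `id`, `parent`,
#'   `relation`, `n_compared`, `conflict_rate`, `flagged`.
#' @export
verify_parentage <- function(geno, ped, max_conflict_rate = 0.01) {
  ped <- .as_pedigree(ped)
  geno <- .check_dosages(geno)
  gids <- rownames(geno)
  rows <- list()
  skipped <- 0L
  for (rel in c("sire", "dam")) {
    sub <- ped[!is.na(ped[[rel]]), c("id", rel)]
    for (k in seq_len(nrow(sub))) {
      id <- sub$id[k]; par <- sub[[rel]][k]
      if (!(id %in% gids)) next
      if (!(par %in% gids)) { skipped <- skipped + 1L; next }
      x <- geno[id, ]; y <- geno[par, ]
      ok <- !is.na(x) & !is.na(y)
      conf <- (x == 0 & y == 2) | (x == 2 & y == 0)
      n <- sum(ok)
      rate <- if (n > 0) sum(conf[ok]) / n else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, parent = par, relation = rel, n_compared = n,
        conflict_rate = rate, flagged = !is.na(rate) & rate > max_conflict_rate,
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L) {
    message(skipped, " pair(s) skipped: parent not genotyped")
  }
  if (length(rows) == 0L) {
    return(data.frame(id = character(), parent = character(),
                      relation = character(), n_compared = integer(),
                      conflict_rate = numeric(), flagged = logical()))
  }
  do.call(rbind, rows)
}

#' Read / write a delimited dosage matrix
#'
#' Plain-text exchange format: header row of SNP ids, first column the
#' individual id, missing dosages coded `NA` or `-9`.
#'
#' @param path file path.
#' @param sep field separator, default comma.
#' @return `read_dosage_matrix`: a dosage matrix with dimnames.
#' @export
read_dosage_matrix <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  m[m == -9] <- NA
  rownames(m) <- ids
  .check_dosages(m)
}

#' @param geno dosage matrix to write.
#' @rdname read_dosage_matrix
#' @export
write_dosage_matrix <- function(geno, path, sep = ",") {
  df <- data.frame(id = rownames(geno), geno, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the PLINK .raw additive-dosage dialect
#'
#' The `.raw` layout (as written by `plink --recode A`): whitespace-separated
#' with columns FID IID PAT MAT SEX PHENOTYPE followed by one 0/1/2 column per
#' SNP, missing coded NA. The IID column is used as individual id.
#'
#' @param path file path.
#' @return `read_plink_raw`: a dosage matrix.
#' @export
read_plink_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(df))) {
    stop(".raw file must have columns ", paste(meta, collapse = " "))
  }
  m <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$IID)
  .check_dosages(m)
}

#' @param geno dosage matrix to write.
#' @rdname read_plink_raw
#' @export
write_plink_raw <- function(geno, path) {
  df <- data.frame(FID = rownames(geno), IID = rownames(geno),
                   PAT = 0, MAT = 0, SEX = 0, PHENOTYPE = -9,
                   geno, check.names = FALSE)
  utils::write.table(df, path, sep = " ", row.names = FALSE, quote = FALSE)
  invisible(path)
}
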