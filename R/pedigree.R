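#' Construct a validated pedigree
#'
#' A pedigree is a data frame of parentage records with columns `id`, `sire`
#' and `dam` (unknown parents coded `NA`). Any further columns (generation,
#' species, trial, block, family, ...) are carried along untouched. The
#' constructor checks that ids are unique, that every recorded parent is
#' itself a record, and that the parentage graph is acyclic; a topological
#' order (parents before offspring) is attached as an attribute.
#'
#' @param x data frame with at least columns `id`, `sire`, `dam`.
#' @return an object of class `pedigree` (a data frame).
#' @examples
#' ped <- pedigree(data.frame(id = c("s", "d", "o"),
#'                            sire = c(NA, NA, "s"),
#'                            dam  = c(NA, NA, "d")))
#' build_A(ped)
#' @export
pedigree <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(x))) {
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  }
  x$id <- as.character(x$id)
  x$sire <- .na_if_unknown(x$sire)
  x$dam <- .na_if_unknown(x$dam)
  if (anyDuplicated(x$id)) {
    stop("duplicated individual ids in pedigree: ",
         paste(unique(x$id[duplicated(x$id)])[1:3], collapse = ", "))
  }
  for (p in c("sire", "dam")) {
    bad <- !is.na(x[[p]]) & !(x[[p]] %in% x$id)
    if (any(bad)) {
      stop("unknown ", p, " referenced in pedigree: ",
           paste(utils::head(unique(x[[p]][bad]), 3), collapse = ", "))
    }
  }
  ord <- .ped_topological_order(x$id, x$sire, x$dam)
  attr(x, "top_order") <- ord
  class(x) <- c("pedigree", "data.frame")
  x
}

.na_if_unknown <- function(p) {
  p <- as.character(p)
  p[p %in% c("", "0", "NA", ".")] <- NA_character_
  p
}

#' @keywords internal
.ped_topological_order <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  placed <- logical(n)
  ord <- integer(0)
  while (length(ord) < n) {
    ok_s <- is.na(si)
    ok_s[!ok_s] <- placed[si[!ok_s]]
    ok_d <- is.na(di)
    ok_d[!ok_d] <- placed[di[!ok_d]]
    ready <- which(!placed & ok_s & ok_d)
    if (length(ready) == 0L) {
      stop("pedigree contains a cycle (individual is its own ancestor)")
    }
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  ord
}

#' Is an individual a founder (both parents unknown)?
#' @param ped a [pedigree()].
#' @return logical vector in pedigree row order.
#' @export
is_founder <- function(ped) {
  is.na(ped$sire) & is.na(ped$dam)
}

#' Inbreeding coefficients from a pedigree
#'
#' Computed as the diagonal of the additive relationship matrix minus one
#' (tabular method).
#'
#' @param ped a [pedigree()].
#' @return named numeric vector of inbreeding coefficients F.
#' @export
inbreeding <- function(ped) {
  A <- build_A(ped)
  diag(A) - 1
}
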