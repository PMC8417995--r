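#' Percentage of a count, rounded for reporting
#'
#' Reporting helper used by the annotation and network summaries: computes
#' \code{100 * num / den} rounded to \code{digits} decimals.
#'
#' @param num numerator count.
#' @param den denominator count (> 0).
#' @param digits decimals to keep (default 2).
#' @return numeric percentage.
#' @examples
#' percentOf(28227, 37009)
#' @export
percentOf <- function(num, den, digits = 2) {
  stopifnot(is.numeric(num), is.numeric(den), den > 0)
  round(100 * num / den, digits)
}

## minimal union-find over 1..n; path compression only (n is small everywhere
## this is used: merging mono-exonic transcripts, locus components)
.ufNew <- function(n) seq_len(n)

.ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

.ufUnion <- function(parent, i, j) {
  ri <- .ufFind(parent, i)
  rj <- .ufFind(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

.ufComponents <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) .ufFind(parent, i), integer(1))
  match(roots, unique(roots))
}

.assertScalarString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string")
  invisible(x)
}

## deterministic seed derivation: keeps derived seeds < 2^31
.deriveSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
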