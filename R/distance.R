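#' Null-aware elementary allele distance
#'
#' Distance between two single allele observations over `{0, 1, NA}`:
#' 1 when both are observed and differ, 0 otherwise.  A comparison against a
#' null (uncovered) position never counts as a mismatch.  Vectorised.
#'
#' @param x,y allele values in `{0, 1, NA}` (recycled to common length).
#' @return integer vector of 0/1 mismatch indicators.
#' @export
elementary_distance <- function(x, y) {
  as.integer(!is.na(x) & !is.na(y) & x != y)
}

#' Windowed null-aware Hamming distance
#'
#' `hd_distance(X, Y, s, e)` sums the elementary distance over positions
#' `s..e` (1-based, inclusive).  This is the distance used both to score
#' candidate phasings against covering fragments and to compute the MEC score
#' of a reconstruction.
#'
#' @param X,Y allele sequences of equal length: integer vectors over
#'   `{0, 1, NA}` or allele strings over `0`, `1`, `-`.
#' @param s,e window bounds, `1 <= s <= e <= length(X)`.  Default: the full
#'   sequence.
#' @return non-negative integer mismatch count.
#' @examples
#' hd_distance("10-011", "01010-", 2, 5)  # 3
#' @export
hd_distance <- function(X, Y, s = 1L, e = NULL) {
  if (is.character(X)) X <- decode_alleles(X)
  if (is.character(Y)) Y <- decode_alleles(Y)
  if (length(X) != length(Y)) {
    stop("sequences have different lengths (", length(X), " vs ", length(Y), ")")
  }
  if (is.null(e)) e <- length(X)
  s <- as.integer(s); e <- as.integer(e)
  if (s < 1L || e > length(X) || s > e) {
    stop("window [", s, ", ", e, "] out of range for length ", length(X))
  }
  idx <- s:e
  sum(elementary_distance(X[idx], Y[idx]))
}

#' Fragment coverage index sets
#'
#' For a SNP fragment matrix, computes `l(i)`, the column index of the
#' leftmost covered SNP of each fragment, and `r(j)`, the set of fragment
#' rows covering each column.
#'
#' @param M a SNP fragment matrix (see [snp_matrix()]); rows must each cover
#'   at least one site.
#' @return a list with `l` (integer vector, per row) and `r` (list of integer
#'   row-index vectors, per column).
#' @export
compute_index_sets <- function(M) {
  obs <- !is.na(M)
  if (any(rowSums(obs) == 0L)) {
    stop("row(s) ", paste(which(rowSums(obs) == 0L), collapse = ", "),
         " cover no SNP site; remove all-null rows before indexing")
  }
  l <- apply(obs, 1L, which.max)   # first TRUE per row
  r <- lapply(seq_len(ncol(M)), function(j) unname(which(obs[, j])))
  list(l = unname(as.integer(l)), r = r)
}

#' Genotype compatibility of a haplotype triple
#'
#' A haplotype triple is compatible with a genotype when, at every SNP
#' column, the three haplotype alleles sum to the genotype's allele sum.
#' Compatibility is invariant under any permutation of the three haplotypes.
#'
#' @param h a `3 x n` haplotype triple ([haplotype_triple()]).
#' @param G a genotype ([as_genotype()]) of the same number of columns.
#' @return `TRUE` or `FALSE`.
#' @export
is_compatible <- function(h, G) {
  G <- as_genotype(G)
  if (ncol(h) != length(G$sums)) {
    stop("haplotype length ", ncol(h), " does not match genotype length ",
         length(G$sums))
  }
  all(colSums(h) == G$sums)
}
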