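#' SNP fragment matrices, genotypes and haplotype triples
#'
#' The package works on three elementary data structures:
#'
#' * a *SNP fragment matrix*: an `m x n` integer matrix over `{0, 1, NA}`,
#'   one row per aligned sequencing fragment, one column per SNP site.
#'   `NA` marks sites the fragment does not cover (rendered `-` in text
#'   formats).
#' * a *genotype*: the phase-free conflation of the three haplotype alleles
#'   at each site, stored as the per-column allele sum `s_j` in `{0, 1, 2, 3}`
#'   (optionally with the full unordered triples).  Sums 1 and 2 mark
#'   heterozygous sites, 0 and 3 homozygous ones.
#' * a *haplotype triple*: a `3 x L` binary matrix, one row per chromosome
#'   copy.
#'
#' @name snp-data
#' @keywords internal
NULL

#' Construct and validate a SNP fragment matrix
#'
#' @param x an integer or numeric matrix over `{0, 1, NA}`, or a character
#'   vector of equal-length strings over `0`, `1`, `-` (one per fragment).
#' @param row_ids optional stable fragment identifiers; defaults to existing
#'   rownames or `f1..fm`.
#' @return an integer matrix with entries in `{0L, 1L, NA}` and rownames set
#'   to the fragment identifiers.
#' @examples
#' snp_matrix(c("10-011", "01010-"))
#' @export
snp_matrix <- function(x, row_ids = NULL) {
  if (is.character(x)) {
    x <- do.call(rbind, lapply(x, decode_alleles))
  }
  if (!is.matrix(x)) stop("`x` must be a matrix or a character vector of rows")
  storage.mode(x) <- "integer"
  bad <- !(x %in% c(0L, 1L, NA_integer_))
  if (any(bad)) {
    stop("SNP matrix entries must be 0, 1 or NA; found ", x[which(bad)[1L]])
  }
  if (nrow(x) < 1L || ncol(x) < 1L) stop("SNP matrix must be at least 1 x 1")
  if (is.null(row_ids)) {
    row_ids <- if (!is.null(rownames(x))) rownames(x) else paste0("f", seq_len(nrow(x)))
  }
  rownames(x) <- row_ids
  x
}

#' Decode an allele string to an integer vector
#'
#' Maps `"0" -> 0L`, `"1" -> 1L`, `"-" -> NA` position by position.
#'
#' @param s a single string over the alphabet `0`, `1`, `-`.
#' @return an integer vector with `NA` at null positions.
#' @export
decode_alleles <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- !ch %in% c("0", "1", "-")
  if (any(bad)) {
    stop("invalid allele character '", ch[which(bad)[1L]], "' at position ",
         which(bad)[1L])
  }
  out <- rep(NA_integer_, length(ch))
  out[ch == "0"] <- 0L
  out[ch == "1"] <- 1L
  out
}

#' Encode an integer allele vector as a string
#'
#' Inverse of [decode_alleles()]: `NA` becomes `-`.
#'
#' @param x integer vector over `{0, 1, NA}`.
#' @return a single string.
#' @export
encode_alleles <- function(x) {
  ch <- ifelse(is.na(x), "-", as.character(x))
  paste(ch, collapse = "")
}

#' Construct a haplotype triple
#'
#' @param h1,h2,h3 binary vectors (or allele strings) of common length, or
#'   `h1` alone may be a `3 x L` binary matrix.
#' @return a `3 x L` integer matrix with rownames `hap1`, `hap2`, `hap3`.
#' @export
haplotype_triple <- function(h1, h2 = NULL, h3 = NULL) {
  if (is.matrix(h1) && is.null(h2)) {
    h <- h1
    if (nrow(h) != 3L) stop("a haplotype triple must have exactly 3 rows")
  } else {
    conv <- function(v) if (is.character(v)) decode_alleles(v) else v
    h1 <- conv(h1); h2 <- conv(h2); h3 <- conv(h3)
    if (length(h1) != length(h2) || length(h2) != length(h3)) {
      stop("the three haplotypes must have identical length")
    }
    h <- rbind(h1, h2, h3)
  }
  storage.mode(h) <- "integer"
  if (anyNA(h) || !all(h %in% c(0L, 1L))) {
    stop("haplotype entries must be 0 or 1")
  }
  dimnames(h) <- list(c("hap1", "hap2", "hap3"), NULL)
  h
}

#' Coerce to a genotype
#'
#' A genotype records, per SNP column, the unordered conflation of the three
#' haplotype alleles.  It is represented as a list with elements `sums`
#' (integer vector of per-column allele sums in 0..3) and `triples`
#' (a `3 x n` 0/1 matrix, or `NULL` when only sums are known).
#'
#' @param g a genotype object, an integer vector of allele sums in `0..3`,
#'   or a `3 x n` binary matrix of per-column allele triples.
#' @return an object of class `"genotype"`.
#' @export
as_genotype <- function(g) {
  if (inherits(g, "genotype")) return(g)
  if (is.matrix(g)) {
    if (nrow(g) != 3L) stop("a genotype triple matrix must have 3 rows")
    storage.mode(g) <- "integer"
    if (!all(g %in% c(0L, 1L))) stop("genotype triple entries must be 0 or 1")
    return(structure(list(sums = as.integer(colSums(g)), triples = unname(g)),
                     class = "genotype"))
  }
  s <- as.integer(g)
  if (anyNA(s) || !all(s %in% 0:3)) stop("genotype sums must lie in 0..3")
  structure(list(sums = s, triples = NULL), class = "genotype")
}

#' @export
length.genotype <- function(x) length(x$sums)

#' @export
print.genotype <- function(x, ...) {
  n <- length(x$sums)
  het <- sum(x$sums %in% 1:2)
  cat("genotype over ", n, " SNP sites (", het, " heterozygous)\n", sep = "")
  cat("column sums: ", paste(utils::head(x$sums, 40L), collapse = ""),
      if (n > 40L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Heterozygous columns of a genotype
#'
#' @param G coerced via [as_genotype()].
#' @return integer indices of columns with allele sum 1 or 2.
#' @export
het_sites <- function(G) {
  G <- as_genotype(G)
  which(G$sums %in% 1:2)
}
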