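#' @rdname enumerate_column_values
#' @format NULL
#' @keywords internal
.candidate_triples <- list(
  # allele sum 1: exactly one haplotype carries the minor allele
  `1` = matrix(c(0L, 0L, 1L,
                 0L, 1L, 0L,
                 1L, 0L, 0L), nrow = 3L, byrow = TRUE),
  # allele sum 2: exactly one haplotype carries the major allele
  `2` = matrix(c(0L, 1L, 1L,
                 1L, 0L, 1L,
                 1L, 1L, 0L), nrow = 3L, byrow = TRUE)
)

#' Candidate allele assignments at a heterozygous column
#'
#' At a heterozygous SNP column with genotype allele sum `s_j`, exactly three
#' unordered-to-ordered assignments of alleles to the three haplotypes are
#' genotype-compatible.  They are returned in a fixed, documented order (the
#' order used for deterministic tie-breaking): for `s_j = 1`,
#' `(0,0,1), (0,1,0), (1,0,0)`; for `s_j = 2`, `(0,1,1), (1,0,1), (1,1,0)`.
#'
#' @param s_j genotype allele sum; must be 1 or 2.
#' @return a `3 x 3` integer matrix, one candidate per row.
#' @export
enumerate_column_values <- function(s_j) {
  s_j <- as.integer(s_j)
  if (length(s_j) != 1L || is.na(s_j) || !s_j %in% 1:2) {
    stop("candidate enumeration is defined only for heterozygous columns ",
         "(allele sum 1 or 2); got ", s_j)
  }
  .candidate_triples[[as.character(s_j)]]
}

#' Preprocess a fragment matrix and genotype for phasing
#'
#' Homozygous SNP columns carry no phase information: they are removed from
#' both the fragment matrix and the genotype, and their (single) allele value
#' is recorded for later re-insertion.  Fragment rows left without any
#' covered site are dropped.  Remaining rows are sorted by the column index
#' of their leftmost covered SNP (`l(i)`, ascending, stable), and the
#' coverage index sets are computed on the reduced matrix.
#'
#' @param M a SNP fragment matrix ([snp_matrix()]).
#' @param G a genotype of matching length ([as_genotype()]).
#' @return an object of class `"ehtld_instance"`: a list with
#'   `M_het` (reduced matrix, rows sorted), `s_het` (het-column allele sums),
#'   `l`, `r` (index sets on `M_het`), `n_het`,
#'   `column_map` (list with `n`, `het_cols`, `hom_allele`), and
#'   `dropped_rows` (ids of rows removed as uninformative).
#' @export
preprocess <- function(M, G) {
  M <- snp_matrix(M)
  G <- as_genotype(G)
  if (ncol(M) != length(G$sums)) {
    stop("fragment matrix has ", ncol(M), " columns but genotype has ",
         length(G$sums))
  }
  het <- which(G$sums %in% 1:2)
  if (length(het) == 0L) {
    stop("all SNP columns are homozygous; there is nothing to phase ",
         "(the haplotypes are determined by the genotype alone)")
  }
  hom_allele <- rep(NA_integer_, ncol(M))
  hom <- setdiff(seq_len(ncol(M)), het)
  hom_allele[hom] <- G$sums[hom] %/% 3L   # all-0 column -> 0, all-1 -> 1

  M_het <- M[, het, drop = FALSE]
  covered <- rowSums(!is.na(M_het)) > 0L
  dropped <- rownames(M_het)[!covered]
  M_het <- M_het[covered, , drop = FALSE]
  if (nrow(M_het) == 0L) {
    stop("no fragment covers a heterozygous column")
  }
  obs <- !is.na(M_het)
  l <- as.integer(apply(obs, 1L, which.max))
  ord <- order(l)                          # radix sort: stable on ties
  M_het <- M_het[ord, , drop = FALSE]
  idx <- compute_index_sets(M_het)

  structure(list(
    M_het = M_het,
    s_het = G$sums[het],
    l = idx$l,
    r = idx$r,
    n_het = length(het),
    column_map = list(n = ncol(M), het_cols = het, hom_allele = hom_allele),
    dropped_rows = dropped
  ), class = "ehtld_instance")
}

#' @export
print.ehtld_instance <- function(x, ...) {
  cat("phasing instance: ", nrow(x$M_het), " fragments x ", x$n_het,
      " heterozygous sites (of ", x$column_map$n, " total)\n", sep = "")
  invisible(x)
}

#' Minimum-difference score of a candidate column assignment
#'
#' Scores a candidate allele triple for column `j` against every fragment
#' covering that column: for each such fragment `i`, the best (minimum over
#' the three haplotypes) windowed distance between the fragment and the
#' haplotype prefix extended by the candidate, over the window from the
#' fragment's leftmost covered site `l(i)` up to `j`.  The score is the sum
#' of these per-fragment minima.  Fragment positions right of `j` are
#' ignored.
#'
#' This is the direct, definitional evaluation; the solver uses an
#' incremental computation whose results are identical.
#'
#' @param h_prefix `3 x (j-1)` matrix: haplotype alleles already assigned to
#'   het columns `1..j-1` (may have 0 columns when `j = 1`).
#' @param candidate integer triple of candidate alleles at column `j`.
#' @param j het-column index under consideration.
#' @param inst a preprocessed instance ([preprocess()]).
#' @return non-negative integer score.
#' @export
score_assignment <- function(h_prefix, candidate, j, inst) {
  stopifnot(inherits(inst, "ehtld_instance"))
  j <- as.integer(j)
  if (ncol(h_prefix) < j - 1L) {
    stop("haplotype prefix has ", ncol(h_prefix), " columns; need ", j - 1L)
  }
  rows <- inst$r[[j]]
  if (any(inst$l[rows] > j)) {
    stop("index-set invariant violated: a fragment covering column ", j,
         " starts right of it")
  }
  total <- 0L
  for (i in rows) {
    frag <- inst$M_het[i, seq_len(j)]
    best <- Inf
    for (k in 1:3) {
      hk <- c(h_prefix[k, seq_len(j - 1L)], candidate[k])
      best <- min(best, hd_distance(hk, frag, inst$l[i], j))
    }
    total <- total + best
  }
  as.integer(total)
}

#' Reconstruct the heterozygous-site haplotypes
#'
#' Fills the three haplotypes column by column, left to right, over the
#' heterozygous sites of a preprocessed instance.  The first column is set
#' to the canonical genotype-compatible assignment that places the minor
#' alleles in the highest-numbered haplotypes (`(1,0,0)` for allele sum 1,
#' `(1,1,0)` for sum 2); all three choices are equivalent up to haplotype
#' relabelling, to which every downstream measure is invariant.  At each
#' later column the three candidate assignments of
#' [enumerate_column_values()] are scored with the minimum-difference score
#' (see [score_assignment()]) and the best is kept; ties are broken towards
#' the first candidate in enumeration order, so the solver is fully
#' deterministic.
#'
#' @param inst a preprocessed instance ([preprocess()]).
#' @param quiet suppress the warning emitted when some columns are covered
#'   by no fragment (their phase is unconstrained).
#' @return a `3 x n_het` haplotype triple over the heterozygous sites.
#' @export
reconstruct_het_haplotypes <- function(inst, quiet = FALSE) {
  stopifnot(inherits(inst, "ehtld_instance"))
  M <- inst$M_het
  k_het <- inst$n_het
  h <- matrix(0L, nrow = 3L, ncol = k_het,
              dimnames = list(c("hap1", "hap2", "hap3"), NULL))
  # running HD(h_k, fragment i, l(i), j) for the columns processed so far
  H <- matrix(0L, nrow = nrow(M), ncol = 3L)
  uncovered <- integer(0)

  for (j in seq_len(k_het)) {
    cands <- enumerate_column_values(inst$s_het[j])
    rows <- inst$r[[j]]
    if (length(rows) == 0L) uncovered <- c(uncovered, j)
    if (j == 1L) {
      choice <- 3L                      # canonical: (1,0,0) / (1,1,0)
    } else if (length(rows) == 0L) {
      choice <- 1L                      # unconstrained; first in order
    } else {
      mj <- M[rows, j]
      D <- vapply(1:3, function(ci) {
        add <- cbind(mj != cands[ci, 1L], mj != cands[ci, 2L],
                     mj != cands[ci, 3L])
        sc <- H[rows, , drop = FALSE] + add
        sum(pmin(sc[, 1L], sc[, 2L], sc[, 3L]))
      }, numeric(1))
      choice <- which.min(D)            # first minimum on ties
    }
    a <- cands[choice, ]
    h[, j] <- a
    if (length(rows) > 0L) {
      mj <- M[rows, j]
      H[rows, ] <- H[rows, , drop = FALSE] +
        cbind(mj != a[1L], mj != a[2L], mj != a[3L])
    }
  }
  if (!quiet && length(uncovered) > 0L) {
    warning(length(uncovered), " heterozygous column(s) covered by no ",
            "fragment; their phase is arbitrary (columns ",
            paste(utils::head(uncovered, 10L), collapse = ", "),
            if (length(uncovered) > 10L) ", ..." else "", ")")
  }
  h
}

#' Re-insert homozygous columns into a phased triple
#'
#' Expands a haplotype triple defined on the heterozygous columns back to
#' full length: each homozygous column carries its recorded genotype allele
#' in all three haplotypes, and the heterozygous columns reappear in their
#' original order.
#'
#' @param h_het `3 x n_het` triple over heterozygous sites.
#' @param column_map the `column_map` element of a preprocessed instance.
#' @return a `3 x n` full-length haplotype triple.
#' @export
augment <- function(h_het, column_map) {
  if (ncol(h_het) != length(column_map$het_cols)) {
    stop("phased triple has ", ncol(h_het), " columns but the column map ",
         "records ", length(column_map$het_cols), " heterozygous sites")
  }
  h <- matrix(0L, nrow = 3L, ncol = column_map$n,
              dimnames = list(c("hap1", "hap2", "hap3"), NULL))
  hom <- which(!is.na(column_map$hom_allele))
  if (length(hom) > 0L) {
    h[, hom] <- rep(column_map$hom_allele[hom], each = 3L)
  }
  h[, column_map$het_cols] <- h_het
  h
}

#' Phase a triploid individual from SNP fragments (EHTLD)
#'
#' End-to-end greedy enumeration phaser for the MEC/GI model: preprocess
#' (drop homozygous columns, sort fragments), reconstruct the heterozygous
#' sites left to right by scoring the three genotype-compatible candidate
#' assignments per column against the covering fragments, then re-insert the
#' homozygous columns.  The output is always compatible with the genotype,
#' and identical inputs always produce bit-identical output.
#'
#' @param M a SNP fragment matrix ([snp_matrix()]).
#' @param G a genotype of matching length ([as_genotype()]).
#' @param quiet suppress the unconstrained-column warning.
#' @return a `3 x n` haplotype triple.
#' @examples
#' M <- snp_matrix(c("001-", "-011", "110-", "-100"))
#' G <- as_genotype(c(1L, 1L, 2L, 2L))
#' ehtld(M, G)
#' @export
ehtld <- function(M, G, quiet = FALSE) {
  inst <- preprocess(M, G)
  h_het <- reconstruct_het_haplotypes(inst, quiet = quiet)
  augment(h_het, inst$column_map)
}
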