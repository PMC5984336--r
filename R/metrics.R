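#' @keywords internal
.perms3 <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                 c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

#' Reconstruction rate
#'
#' Fraction of correctly phased alleles between a true and a reconstructed
#' haplotype triple, maximised over the six relabellings of the
#' reconstructed haplotypes:
#' `1 - min_pi sum_k HD(h_k, hhat_pi(k), 1, n) / (3 n)`.
#' Equals 1 exactly when the reconstruction is a permutation of the truth.
#'
#' @param truth,recon `3 x n` haplotype triples of equal length.
#' @return a fraction in `[0, 1]`.
#' @export
reconstruction_rate <- function(truth, recon) {
  if (ncol(truth) != ncol(recon)) {
    stop("triples have different lengths (", ncol(truth), " vs ",
         ncol(recon), ")")
  }
  n <- ncol(truth)
  best <- min(apply(.perms3, 1L, function(p) sum(truth != recon[p, , drop = FALSE])))
  1 - best / (3 * n)
}

#' MEC score of a reconstruction against a fragment matrix
#'
#' Sums, over fragments, the minimum null-aware Hamming distance between the
#' fragment and the three reconstructed haplotypes: the number of matrix
#' entries that must be corrected for every fragment to agree perfectly with
#' its best-matching haplotype.
#'
#' @param M a SNP fragment matrix with `n` columns.
#' @param recon a `3 x n` haplotype triple.
#' @return a non-negative integer.
#' @export
mec_score <- function(M, recon) {
  if (ncol(M) != ncol(recon)) {
    stop("fragment matrix has ", ncol(M), " columns but reconstruction has ",
         ncol(recon))
  }
  m <- nrow(M)
  d <- matrix(0L, nrow = m, ncol = 3L)
  for (k in 1:3) {
    mism <- M != matrix(recon[k, ], nrow = m, ncol = ncol(M), byrow = TRUE)
    mism[is.na(mism)] <- FALSE
    d[, k] <- as.integer(rowSums(mism))
  }
  sum(pmin(d[, 1L], d[, 2L], d[, 3L]))
}

#' Vector error (minimum switch count) of a reconstruction
#'
#' Generalises the diploid switch error to three haplotypes: the minimum
#' number of switch points needed to partition the heterozygous columns into
#' segments such that, within each segment, the reconstructed triple equals
#' a fixed permutation of the true triple.  Zero exactly when the
#' reconstruction is a global relabelling of the truth over the heterozygous
#' sites.  Homozygous columns carry no phase and are skipped.
#'
#' Both triples must be compatible with the same genotype (guaranteed for
#' phaser output); a column at which no permutation matches signals an error.
#'
#' @param truth,recon `3 x n` haplotype triples of equal length.
#' @return a non-negative integer switch count.
#' @export
vector_error <- function(truth, recon) {
  if (ncol(truth) != ncol(recon)) {
    stop("triples have different lengths (", ncol(truth), " vs ",
         ncol(recon), ")")
  }
  het <- which(colSums(truth) %in% 1:2)
  if (length(het) == 0L) return(0L)
  Tm <- truth[, het, drop = FALSE]
  Rm <- recon[, het, drop = FALSE]
  k <- length(het)
  # ok[p, j]: does permutation p map the true column j onto the reconstructed
  # column (recon_i = truth_{p(i)})?  Repeated alleles make several p match.
  ok <- matrix(FALSE, nrow = 6L, ncol = k)
  for (p in 1:6) {
    ok[p, ] <- colSums(Rm != Tm[.perms3[p, ], , drop = FALSE]) == 0L
  }
  if (any(colSums(ok) == 0L)) {
    stop("column ", het[which(colSums(ok) == 0L)[1L]], " admits no matching ",
         "haplotype permutation; the triples are not genotype-compatible")
  }
  # DP over columns: cost[p] = min switches so far ending in permutation p
  cost <- ifelse(ok[, 1L], 0, Inf)
  for (j in seq_len(k)[-1L]) {
    best_prev <- min(cost)
    cost <- ifelse(ok[, j], pmin(cost, best_prev + 1), Inf)
  }
  as.integer(min(cost))
}

#' Evaluate a phasing against the truth and the fragment matrix
#'
#' Convenience wrapper computing the three standard accuracy measures in one
#' call.
#'
#' @param truth,recon `3 x n` haplotype triples.
#' @param M the SNP fragment matrix the reconstruction was phased from.
#' @return a one-row `data.frame` with columns `rr`, `ve`, `mec`.
#' @export
evaluate_phasing <- function(truth, recon, M) {
  data.frame(rr = reconstruction_rate(truth, recon),
             ve = vector_error(truth, recon),
             mec = mec_score(M, recon))
}
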