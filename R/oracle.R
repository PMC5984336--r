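#' Exact MEC/GI solver by exhaustive enumeration
#'
#' Finds a genotype-compatible haplotype triple minimising the MEC score by
#' enumerating every compatible assignment over the heterozygous columns
#' (three candidates per column; the first column is fixed to the canonical
#' assignment to quotient out haplotype relabelling, to which the MEC score
#' is invariant).  Intended as a ground-truth oracle on small instances, not
#' as a scalable solver: the search space is `3^(n_het - 1)`.
#'
#' @param M a SNP fragment matrix.
#' @param G a genotype of matching length.
#' @param max_het refuse instances with more heterozygous columns than this
#'   (default 10).
#' @return a list with `best_mec` (the optimum MEC score against `M`),
#'   `best_haplotypes` (one optimal full-length triple) and `num_optima`
#'   (number of enumerated assignments attaining the optimum).
#' @export
exact_mecgi <- function(M, G, max_het = 10L) {
  inst <- preprocess(M, G)
  k <- inst$n_het
  if (k > max_het) {
    stop("instance has ", k, " heterozygous columns; exhaustive search is ",
         "limited to max_het = ", max_het)
  }
  M <- snp_matrix(M)
  cands <- lapply(inst$s_het, enumerate_column_values)

  # Index grid over columns 2..k; column 1 fixed to the canonical candidate.
  if (k == 1L) {
    idx <- matrix(integer(0), nrow = 1L, ncol = 0L)
  } else {
    idx <- as.matrix(expand.grid(rep(list(1:3), k - 1L), KEEP.OUT.ATTRS = FALSE))
  }
  A <- nrow(idx)

  # Haplotype allele matrices, one per chromosome copy: A x k.
  Hk <- lapply(1:3, function(kk) {
    H <- matrix(0L, nrow = A, ncol = k)
    H[, 1L] <- cands[[1L]][3L, kk]
    for (j in seq_len(k)[-1L]) H[, j] <- cands[[j]][idx[, j - 1L], kk]
    H
  })

  # Mismatch counts against the reduced matrix, vectorised over assignments:
  # allele 1 vs observed 0 and allele 0 vs observed 1.
  Mh <- inst$M_het
  N0 <- t(!is.na(Mh) & Mh == 0L) * 1L     # k x m
  N1 <- t(!is.na(Mh) & Mh == 1L) * 1L
  per_row_min <- NULL
  for (kk in 1:3) {
    mism <- Hk[[kk]] %*% N0 + (1L - Hk[[kk]]) %*% N1   # A x m
    per_row_min <- if (is.null(per_row_min)) mism else pmin(per_row_min, mism)
  }
  mec_red <- rowSums(per_row_min)

  best <- which(mec_red == min(mec_red))
  a <- best[1L]
  h_het <- rbind(Hk[[1L]][a, ], Hk[[2L]][a, ], Hk[[3L]][a, ])
  h_full <- augment(h_het, inst$column_map)

  list(best_mec = mec_score(M, h_full),
       best_haplotypes = h_full,
       num_optima = length(best))
}
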