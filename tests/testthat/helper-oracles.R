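# Independent brute-force reference implementations used as oracles.
# Deliberately written as plain nested loops over the definitions, sharing
# no code with the package internals they check.

# windowed null-aware Hamming distance, elementary two-case rule inlined
hd_brute <- function(X, Y, s, e) {
  total <- 0L
  for (j in s:e) {
    if (!is.na(X[j]) && !is.na(Y[j]) && X[j] != Y[j]) total <- total + 1L
  }
  total
}

# minimum-difference score of a candidate column assignment (sum over
# covering fragments of the per-fragment best windowed distance)
score_brute <- function(h_prefix, candidate, j, inst) {
  total <- 0L
  for (i in seq_len(nrow(inst$M_het))) {
    if (is.na(inst$M_het[i, j])) next
    best <- Inf
    for (k in 1:3) {
      hk <- c(h_prefix[k, seq_len(j - 1L)], candidate[k])
      best <- min(best, hd_brute(hk, inst$M_het[i, seq_len(j)], inst$l[i], j))
    }
    total <- total + best
  }
  total
}

# MEC score by triple loop over (fragment, haplotype, column)
mec_brute <- function(M, h) {
  total <- 0L
  for (i in seq_len(nrow(M))) {
    best <- Inf
    for (k in 1:3) {
      d <- 0L
      for (j in seq_len(ncol(M))) {
        if (!is.na(M[i, j]) && M[i, j] != h[k, j]) d <- d + 1L
      }
      best <- min(best, d)
    }
    total <- total + best
  }
  as.integer(total)
}

all_perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                   c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

# reconstruction rate by explicit minimisation over the six relabellings
rr_brute <- function(truth, recon) {
  n <- ncol(truth)
  best <- Inf
  for (p in all_perms3) {
    d <- 0L
    for (k in 1:3) d <- d + hd_brute(truth[k, ], recon[p[k], ], 1L, n)
    best <- min(best, d)
  }
  1 - best / (3 * n)
}

# vector error by exhaustive enumeration of per-column permutation
# sequences (6^n_het); feasible only for a handful of het columns
ve_brute <- function(truth, recon) {
  het <- which(colSums(truth) %in% 1:2)
  if (length(het) == 0L) return(0L)
  k <- length(het)
  seqs <- expand.grid(rep(list(1:6), k))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    ok <- TRUE
    for (j in seq_len(k)) {
      p <- all_perms3[[seqs[r, j]]]
      if (any(recon[, het[j]] != truth[p, het[j]])) { ok <- FALSE; break }
    }
    if (!ok) next
    switches <- sum(diff(as.integer(seqs[r, ])) != 0L)
    best <- min(best, switches)
  }
  as.integer(best)
}

# random small instance: truth with n_het heterozygous sites, m fragments
# of random span and haplotype of origin, optional planted errors
make_small_instance <- function(seed, n = 10L, n_het = 6L, m = 10L,
                                len_range = c(2L, 5L), n_errors = 0L) {
  set.seed(seed)
  truth <- generate_haplotypes(n, n_het / n)
  M <- matrix(NA_integer_, nrow = m, ncol = n)
  for (i in seq_len(m)) {
    len <- sample(len_range[1L]:len_range[2L], 1L)
    start <- sample.int(n - len + 1L, 1L)
    hap <- sample.int(3L, 1L)
    M[i, start:(start + len - 1L)] <- truth[hap, start:(start + len - 1L)]
  }
  if (n_errors > 0L) {
    obs <- which(!is.na(M))
    flip <- sample(obs, min(n_errors, length(obs)))
    M[flip] <- 1L - M[flip]
  }
  list(truth = truth, M = snp_matrix(M), G = derive_genotype(truth))
}

# error-free instance whose heterozygous columns are chain-connected:
# length-3 fragments from all three haplotypes tiled at step 2 (plus a
# closing window), so adjacent columns are always co-covered with m <= 12
make_connected_instance <- function(seed, n = 8L, n_het = 5L) {
  set.seed(seed)
  truth <- generate_haplotypes(n, n_het / n)
  starts <- unique(c(seq(1L, n - 2L, by = 2L), n - 2L))
  rows <- list()
  for (hap in 1:3) {
    for (s in starts) {
      r <- rep(NA_integer_, n)
      r[s:(s + 2L)] <- truth[hap, s:(s + 2L)]
      rows[[length(rows) + 1L]] <- r
    }
  }
  list(truth = truth, M = snp_matrix(do.call(rbind, rows)),
       G = derive_genotype(truth))
}
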