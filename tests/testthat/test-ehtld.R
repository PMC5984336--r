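test_that("preprocessing drops homozygous columns and uninformative rows", {
  M <- snp_matrix(c("01-", "-10"))
  G <- as_genotype(c(1L, 3L, 2L))
  inst <- preprocess(M, G)
  expect_identical(inst$column_map$het_cols, c(1L, 3L))
  expect_identical(inst$column_map$hom_allele, c(NA, 1L, NA))
  expect_identical(inst$s_het, c(1L, 2L))
  expect_identical(unname(inst$M_het),
                   rbind(c(0L, NA), c(NA, 0L)))

  # a row observed only in homozygous columns is removed
  M2 <- snp_matrix(c("01-", "-1-", "-10"))
  inst2 <- preprocess(M2, G)
  expect_identical(nrow(inst2$M_het), 2L)
  expect_identical(inst2$dropped_rows, "f2")
})

test_that("preprocessing sorts rows by leftmost site and signals edge cases", {
  M <- snp_matrix(c("--11", "01--", "-011"))
  G <- as_genotype(c(1L, 2L, 2L, 1L))
  inst <- preprocess(M, G)
  expect_identical(inst$l, sort(inst$l))
  expect_identical(rownames(inst$M_het), c("f2", "f3", "f1"))

  expect_error(preprocess(snp_matrix("01"), as_genotype(c(0L, 3L))),
               "homozygous")
  expect_error(preprocess(snp_matrix("01"), as_genotype(c(1L, 1L, 1L))),
               "genotype")
})

test_that("candidate enumeration lists the genotype-compatible triples in order", {
  expect_identical(enumerate_column_values(1L),
                   matrix(c(0L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 0L),
                          nrow = 3L, byrow = TRUE))
  expect_identical(enumerate_column_values(2L),
                   matrix(c(0L, 1L, 1L, 1L, 0L, 1L, 1L, 1L, 0L),
                          nrow = 3L, byrow = TRUE))
  expect_error(enumerate_column_values(0L), "heterozygous")
  expect_error(enumerate_column_values(3L), "heterozygous")
  # every candidate sums to the genotype value
  expect_true(all(rowSums(enumerate_column_values(1L)) == 1L))
  expect_true(all(rowSums(enumerate_column_values(2L)) == 2L))
})

test_that("column scores match the definitional brute-force evaluation", {
  set.seed(23)
  for (rep in 1:20) {
    sim <- make_small_instance(rep, n = 9L, n_het = 6L, m = 8L, n_errors = 2L)
    inst <- preprocess(sim$M, sim$G)
    j <- sample(2:inst$n_het, 1L)
    prefix <- matrix(sample(0:1, 3L * (j - 1L), replace = TRUE), nrow = 3L)
    cands <- enumerate_column_values(inst$s_het[j])
    for (ci in 1:3) {
      expect_identical(score_assignment(prefix, cands[ci, ], j, inst),
                       as.integer(score_brute(prefix, cands[ci, ], j, inst)))
    }
  }
})

test_that("a column covered by no fragment scores zero for every candidate", {
  M <- snp_matrix(c("0-1", "1-0"))
  G <- as_genotype(c(1L, 2L, 1L))
  inst <- preprocess(M, G)
  cands <- enumerate_column_values(inst$s_het[2L])
  prefix <- matrix(c(0L, 0L, 1L), nrow = 3L)
  for (ci in 1:3) {
    expect_identical(score_assignment(prefix, cands[ci, ], 2L, inst), 0L)
  }
  expect_warning(reconstruct_het_haplotypes(inst), "covered by no")
})

test_that("a single heterozygous column gets the canonical assignment", {
  M <- snp_matrix(c("10", "00"))
  G <- as_genotype(c(1L, 0L))
  h <- ehtld(M, G)
  expect_identical(unname(h[, 1L]), c(1L, 0L, 0L))
  M2 <- snp_matrix(c("11", "01"))
  G2 <- as_genotype(c(2L, 3L))
  expect_identical(unname(ehtld(M2, G2)[, 1L]), c(1L, 1L, 0L))
})

test_that("augmenting restores homozygous columns and original order", {
  # identity when nothing was removed
  cm <- list(n = 3L, het_cols = 1:3, hom_allele = rep(NA_integer_, 3))
  h_het <- haplotype_triple("010", "001", "100")
  expect_identical(augment(h_het, cm), h_het)

  # all-homozygous map replicates the recorded alleles
  cm2 <- list(n = 4L, het_cols = integer(0),
              hom_allele = c(1L, 0L, 0L, 1L))
  h0 <- haplotype_triple(matrix(integer(0), nrow = 3))
  expect_identical(unname(augment(h0, cm2)),
                   matrix(rep(c(1L, 0L, 0L, 1L), each = 3L), nrow = 3L))

  expect_error(augment(h_het, cm2), "column map")

  # round trip: the het sub-projection of the output equals the input
  set.seed(5)
  for (rep in 1:10) {
    n <- 8L
    het <- sort(sample.int(n, sample(2:6, 1)))
    hom_allele <- rep(NA_integer_, n)
    hom_allele[-het] <- sample(0:1, n - length(het), replace = TRUE)
    cm <- list(n = n, het_cols = het, hom_allele = hom_allele)
    hh <- haplotype_triple(matrix(sample(0:1, 3 * length(het), replace = TRUE),
                                  nrow = 3))
    out <- augment(hh, cm)
    expect_identical(out[, het, drop = FALSE], hh)
    expect_true(all(out[1L, -het] == out[2L, -het]))
    expect_true(all(out[2L, -het] == out[3L, -het]))
  }
})

test_that("the phaser output is genotype-compatible and deterministic", {
  set.seed(41)
  for (rep in 1:15) {
    sim <- make_small_instance(rep + 100, n = 12L, n_het = 7L, m = 12L,
                               n_errors = sample(0:3, 1))
    h1 <- suppressWarnings(ehtld(sim$M, sim$G))
    h2 <- suppressWarnings(ehtld(sim$M, sim$G))
    expect_identical(h1, h2)
    expect_true(is_compatible(h1, sim$G))
  }
})

test_that("error-free chain-connected instances are phased with zero MEC", {
  # the output need not equal the truth bit for bit: inside a run where two
  # haplotypes agree, relabelling them is invisible to every fragment, so
  # several zero-MEC phasings can coexist — the guarantee is on the MEC
  for (seed in 1:25) {
    sim <- make_connected_instance(seed)
    h <- ehtld(sim$M, sim$G, quiet = TRUE)
    expect_identical(mec_score(sim$M, h), 0L)
    expect_true(is_compatible(h, sim$G))
  }
})

test_that("incremental solver agrees with stepwise definitional rescoring", {
  # replay the greedy on a noisy instance, checking each chosen column's
  # score against the brute-force Eq-style evaluation of all candidates
  sim <- make_small_instance(77, n = 10L, n_het = 6L, m = 10L, n_errors = 3L)
  inst <- preprocess(sim$M, sim$G)
  h <- reconstruct_het_haplotypes(inst, quiet = TRUE)
  for (j in 2:inst$n_het) {
    cands <- enumerate_column_values(inst$s_het[j])
    D <- vapply(1:3, function(ci) {
      score_brute(h[, seq_len(j - 1L), drop = FALSE], cands[ci, ], j, inst)
    }, numeric(1))
    chosen <- which(apply(cands, 1L, function(a) all(a == h[, j])))
    # the chosen candidate attains the minimum and is first among ties
    expect_equal(D[chosen], min(D))
    if (chosen > 1L) expect_true(all(D[seq_len(chosen - 1L)] > D[chosen]))
  }
})
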