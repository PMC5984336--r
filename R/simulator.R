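#' Round half away from zero
#' @noRd
half_up <- function(x) floor(x + 0.5)

#' Simulation configuration
#'
#' Bundles and validates the parameters of the two fragment simulators.
#'
#' Shotgun (`mode = "celsim"`) emulates a whole-genome shotgun run: single
#' fragments with lengths uniform on `[f_min, f_max]` SNP sites and
#' mate-pair fragments of nominal length `n/10` (two reads of `floor(n/10)`
#' sites around a `floor(n/10)`-site null gap), each class contributing
#' nominal coverage `c/2`.
#'
#' 454-style (`mode = "metasim"`) emulates a pyrosequencing run: a fraction
#' `p_m` of fragments are mate-pairs (two reads of length `f_len` from the
#' same haplotype separated by a null gap, total span `3 f_len`), the rest
#' single reads of length `f_len`; the fragment count is chosen so that
#' `(m1 + 2 m2) f_len / (3 n) = c`.
#'
#' @param mode `"celsim"` or `"metasim"`.
#' @param n haplotype length (number of SNP sites).
#' @param d target divergence of the first two haplotypes, as a fraction of
#'   `n`: they differ at exactly `round(d * n)` sites.
#' @param c total fragment coverage.
#' @param p_s per-entry read error probability, `0 <= p_s < 0.5`.
#' @param f_min,f_max single-fragment length bounds (shotgun mode).
#' @param f_len read length (454 mode).
#' @param p_m mate-pair fraction (454 mode).
#' @param seed optional RNG seed for full reproducibility.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(mode = c("celsim", "metasim"), n, d, c, p_s,
                       f_min = 3L, f_max = 7L, f_len = 5L, p_m = 0.25,
                       seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, d >= 0, d <= 1, c > 0, p_s >= 0, p_s < 0.5,
            p_m >= 0, p_m <= 1)
  if (mode == "celsim") {
    stopifnot(f_min >= 1, f_min <= f_max, f_max <= n)
    if (floor(n / 10) < 2) stop("mate-pair read length n/10 = ",
                                floor(n / 10), " is too small; need n >= 20")
  } else {
    stopifnot(f_len >= 1)
    if (3 * f_len > n) stop("mate-pair span 3*f_len = ", 3 * f_len,
                            " exceeds the haplotype length ", n)
  }
  structure(list(mode = mode, n = as.integer(n), d = d, c = c, p_s = p_s,
                 f_min = as.integer(f_min), f_max = as.integer(f_max),
                 f_len = as.integer(f_len), p_m = p_m, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("simulation config [", x$mode, "]: n=", x$n, " d=", x$d, " c=", x$c,
      " p_s=", x$p_s, "\n", sep = "")
  invisible(x)
}

#' Simulate a triploid haplotype triple with controlled divergence
#'
#' The first haplotype is uniform random; the second differs from it at
#' exactly `round(d * n)` uniformly chosen sites; each site of the third
#' copies the first or the second haplotype with probability 1/2.
#' Consequently the heterozygous sites are exactly those where the first two
#' haplotypes differ.
#'
#' @param n haplotype length.
#' @param d divergence fraction in `[0, 1]`.
#' @param seed optional RNG seed; when `NULL` the current RNG stream is used.
#' @return a `3 x n` haplotype triple.
#' @export
generate_haplotypes <- function(n, d, seed = NULL) {
  stopifnot(n >= 1, d >= 0, d <= 1)
  if (!is.null(seed)) set.seed(seed)
  h1 <- sample(0:1, n, replace = TRUE)
  n_flip <- half_up(d * n)
  h2 <- h1
  if (n_flip > 0) {
    flip <- sample.int(n, n_flip)
    h2[flip] <- 1L - h2[flip]
  }
  take2 <- sample(c(FALSE, TRUE), n, replace = TRUE)
  h3 <- ifelse(take2, h2, h1)
  haplotype_triple(rbind(h1, h2, h3))
}

#' Genotype of a haplotype triple
#'
#' The phase-free conflation of the three haplotypes: per column, the
#' unordered allele triple and its sum.
#'
#' @param truth a `3 x n` haplotype triple.
#' @return a `"genotype"` object carrying both triples and sums.
#' @export
derive_genotype <- function(truth) {
  as_genotype(truth)
}

#' Plant read errors into a fragment matrix
#'
#' Flips each covered (non-null) entry independently with probability `p_s`
#' and records the flipped positions.
#'
#' @param M_clean an error-free SNP fragment matrix.
#' @param p_s flip probability, `0 <= p_s < 0.5`.
#' @param seed optional RNG seed.
#' @return a list with `M` (corrupted matrix) and `errors` (a `data.frame`
#'   with columns `row`, `col` of flipped entries).
#' @export
plant_errors <- function(M_clean, p_s, seed = NULL) {
  stopifnot(p_s >= 0, p_s < 0.5)
  if (!is.null(seed)) set.seed(seed)
  obs <- which(!is.na(M_clean))
  flip <- obs[stats::runif(length(obs)) < p_s]
  M <- M_clean
  M[flip] <- 1L - M[flip]
  errors <- data.frame(
    row = ((flip - 1L) %% nrow(M_clean)) + 1L,
    col = ((flip - 1L) %/% nrow(M_clean)) + 1L
  )
  list(M = M, errors = errors[order(errors$row, errors$col), , drop = FALSE])
}

#' Materialise fragment rows from a coverage layout
#'
#' @param layout data.frame with columns hap, and per fragment a list of
#'   covered intervals (start1, end1, start2, end2; NA for absent 2nd read)
#' @noRd
build_fragments <- function(layout, truth) {
  n <- ncol(truth)
  m <- nrow(layout)
  M <- matrix(NA_integer_, nrow = m, ncol = n,
              dimnames = list(paste0("f", seq_len(m)), NULL))
  for (i in seq_len(m)) {
    s1 <- layout$start1[i]; e1 <- layout$end1[i]
    M[i, s1:e1] <- truth[layout$hap[i], s1:e1]
    if (!is.na(layout$start2[i])) {
      s2 <- layout$start2[i]; e2 <- layout$end2[i]
      M[i, s2:e2] <- truth[layout$hap[i], s2:e2]
    }
  }
  M
}

#' @noRd
finish_instance <- function(cfg, truth, layout) {
  M_clean <- build_fragments(layout, truth)
  planted <- plant_errors(M_clean, cfg$p_s)
  structure(list(
    truth = truth,
    M = planted$M,
    M_clean = M_clean,
    G = derive_genotype(truth),
    provenance = list(fragments = layout, errors = planted$errors),
    config = cfg
  ), class = "sim_instance")
}

#' @export
print.sim_instance <- function(x, ...) {
  cat("simulated ", x$config$mode, " instance: ", nrow(x$M), " fragments x ",
      ncol(x$M), " SNP sites, ", nrow(x$provenance$errors),
      " planted errors\n", sep = "")
  invisible(x)
}

#' Simulate a shotgun-sequencing fragment matrix
#'
#' Generates a haplotype triple (see [generate_haplotypes()]) and a fragment
#' matrix emulating a shotgun run: `m1` single fragments with lengths
#' uniform on `[f_min, f_max]` and `m2` mate-pair fragments, each consisting
#' of two reads of `floor(n/10)` sites from the same haplotype separated by
#' a `floor(n/10)`-site null gap (total span `3 * floor(n/10)`, the same
#' read/gap/read geometry as the 454 mode).  Fragment counts are derived
#' from the nominal fragment lengths so that each class carries coverage
#' `c/2`: `m1 = round((c/2) n / mean(f_min, f_max))` and
#' `m2 = round((c/2) n / floor(n/10))`.  Because a mate-pair's two reads
#' together cover twice its nominal length, the realized covered entries
#' total about `1.5 c n`.  Fragment start positions and haplotypes of
#' origin are uniform.  Read errors are planted entry-wise with probability
#' `p_s`.
#'
#' @param cfg a [sim_config()] with `mode = "celsim"`.
#' @return an object of class `"sim_instance"`: a list with `truth`, `M`
#'   (corrupted), `M_clean`, `G`, `provenance` (fragment layout and planted
#'   error positions) and `config`.
#' @export
simulate_celsim <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$mode == "celsim")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n
  truth <- generate_haplotypes(n, cfg$d)

  read_len <- floor(n / 10)
  span <- 3L * read_len
  m1 <- max(1L, half_up((cfg$c / 2) * n / ((cfg$f_min + cfg$f_max) / 2)))
  m2 <- max(1L, half_up((cfg$c / 2) * n / read_len))

  len1 <- sample(cfg$f_min:cfg$f_max, m1, replace = TRUE)
  start1 <- vapply(len1, function(L) sample.int(n - L + 1L, 1L), integer(1))
  singles <- data.frame(
    type = "single", hap = sample.int(3L, m1, replace = TRUE),
    start1 = start1, end1 = start1 + len1 - 1L,
    start2 = NA_integer_, end2 = NA_integer_
  )
  mp_start <- sample.int(n - span + 1L, m2, replace = TRUE)
  mates <- data.frame(
    type = "mate", hap = sample.int(3L, m2, replace = TRUE),
    start1 = mp_start, end1 = mp_start + read_len - 1L,
    start2 = mp_start + 2L * read_len, end2 = mp_start + span - 1L
  )
  finish_instance(cfg, truth, rbind(singles, mates))
}

#' Simulate a 454-style fragment matrix
#'
#' Generates a haplotype triple and `m = round(3 n c / ((1 + p_m) f_len))`
#' fragments: a fraction `p_m` are mate-pairs (two reads of `f_len` sites
#' from the same haplotype separated by an `f_len`-site null gap, total span
#' `3 f_len`), the rest single reads of `f_len` sites, so that the coverage
#' identity `(m1 + 2 m2) f_len / (3 n) = c` holds up to rounding.
#'
#' @param cfg a [sim_config()] with `mode = "metasim"`.
#' @return a `"sim_instance"`, as for [simulate_celsim()].
#' @export
simulate_metasim <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$mode == "metasim")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n
  truth <- generate_haplotypes(n, cfg$d)

  f_len <- cfg$f_len
  m <- max(1L, half_up(3 * n * cfg$c / ((1 + cfg$p_m) * f_len)))
  m2 <- half_up(cfg$p_m * m)
  if (cfg$p_m > 0) m2 <- max(1L, m2)
  m1 <- m - m2

  layout <- NULL
  if (m1 > 0) {
    s1 <- sample.int(n - f_len + 1L, m1, replace = TRUE)
    layout <- data.frame(
      type = "single", hap = sample.int(3L, m1, replace = TRUE),
      start1 = s1, end1 = s1 + f_len - 1L,
      start2 = NA_integer_, end2 = NA_integer_
    )
  }
  if (m2 > 0) {
    span <- 3L * f_len
    s <- sample.int(n - span + 1L, m2, replace = TRUE)
    mates <- data.frame(
      type = "mate", hap = sample.int(3L, m2, replace = TRUE),
      start1 = s, end1 = s + f_len - 1L,
      start2 = s + 2L * f_len, end2 = s + span - 1L
    )
    layout <- rbind(layout, mates)
  }
  finish_instance(cfg, truth, layout)
}

#' Simulate an instance according to a configuration
#'
#' Dispatches to [simulate_celsim()] or [simulate_metasim()] by
#' `cfg$mode`.
#'
#' @param cfg a [sim_config()].
#' @return a `"sim_instance"`.
#' @export
simulate_instance <- function(cfg) {
  switch(cfg$mode,
         celsim = simulate_celsim(cfg),
         metasim = simulate_metasim(cfg))
}
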