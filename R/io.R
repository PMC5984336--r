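#' Read a SNP fragment matrix from a text file
#'
#' One fragment per line, characters from `0`, `1`, `-`, no separators.
#' All lines must have equal length; an empty file or a malformed character
#' is an error naming the offending line and column.
#'
#' @param path file path.
#' @return a SNP fragment matrix ([snp_matrix()]).
#' @export
read_fragment_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty fragment matrix file: ", path)
  widths <- nchar(lines)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop("ragged fragment matrix: line ", bad, " has ", widths[bad],
         " characters, expected ", widths[1L])
  }
  rows <- lapply(seq_along(lines), function(i) {
    tryCatch(decode_alleles(lines[i]),
             error = function(e) stop("line ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  snp_matrix(do.call(rbind, rows))
}

#' Write a SNP fragment matrix to a text file
#'
#' @param M a SNP fragment matrix.
#' @param path file path.
#' @export
write_fragment_matrix <- function(M, path) {
  writeLines(apply(M, 1L, encode_alleles), path)
}

#' Read a genotype file
#'
#' One line per SNP column.  Two dialects are accepted (not mixed): three
#' characters from `{0,1}` giving the unordered allele triple of the column,
#' or a single digit `0..3` giving the column allele sum directly.
#'
#' @param path file path.
#' @return a `"genotype"` object (with `triples` populated in the
#'   three-character dialect).
#' @export
read_genotype <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty genotype file: ", path)
  widths <- unique(nchar(lines))
  if (identical(widths, 3L)) {
    if (!all(grepl("^[01]{3}$", lines))) {
      bad <- which(!grepl("^[01]{3}$", lines))[1L]
      stop("line ", bad, ": expected three characters from {0,1}")
    }
    triples <- vapply(strsplit(lines, "", fixed = TRUE),
                      function(x) as.integer(x), integer(3))
    as_genotype(triples)
  } else if (identical(widths, 1L)) {
    if (!all(grepl("^[0-3]$", lines))) {
      bad <- which(!grepl("^[0-3]$", lines))[1L]
      stop("line ", bad, ": expected a single digit 0..3")
    }
    as_genotype(as.integer(lines))
  } else {
    stop("genotype lines must all have 1 (allele sum) or 3 (triple) ",
         "characters")
  }
}

#' Write a genotype file
#'
#' @param G a `"genotype"` object or anything [as_genotype()] accepts.
#' @param path file path.
#' @param format `"triples"` (default when triples are known) or `"sums"`.
#' @export
write_genotype <- function(G, path, format = c("auto", "triples", "sums")) {
  G <- as_genotype(G)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (is.null(G$triples)) "sums" else "triples"
  }
  if (format == "triples") {
    if (is.null(G$triples)) stop("genotype carries only allele sums")
    writeLines(apply(G$triples, 2L, paste, collapse = ""), path)
  } else {
    writeLines(as.character(G$sums), path)
  }
}

#' Read a haplotype triple
#'
#' Accepts either three plain lines over `{0,1}` or FASTA-style records
#' (`>hap1` .. `>hap3`, sequence possibly wrapped).
#'
#' @param path file path.
#' @return a `3 x n` haplotype triple.
#' @export
read_haplotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty haplotype file: ", path)
  if (startsWith(lines[1L], ">")) {
    hdr <- grep("^>", lines)
    if (length(hdr) != 3L) stop("expected exactly 3 FASTA records, found ",
                                length(hdr))
    bounds <- c(hdr, length(lines) + 1L)
    seqs <- vapply(1:3, function(i) {
      paste(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = "")
    }, character(1))
  } else {
    if (length(lines) != 3L) stop("expected exactly 3 haplotype lines, found ",
                                  length(lines))
    seqs <- lines
  }
  haplotype_triple(seqs[1L], seqs[2L], seqs[3L])
}

#' Write a haplotype triple
#'
#' @param h a `3 x n` haplotype triple.
#' @param path file path.
#' @param format `"plain"` (three lines) or `"fasta"` (`>hap1..>hap3`).
#' @export
write_haplotypes <- function(h, path, format = c("plain", "fasta")) {
  format <- match.arg(format)
  seqs <- apply(h, 1L, paste, collapse = "")
  if (format == "plain") {
    writeLines(seqs, path)
  } else {
    writeLines(as.vector(rbind(paste0(">hap", 1:3), seqs)), path)
  }
}

#' Read a HapCUT-style fragment file
#'
#' Import dialect for the fragment format used by HapCUT-family tools: one
#' fragment per line, whitespace-separated fields
#' `n_blocks fragment_id (start allele_string)...`, optionally followed by a
#' trailing quality string (ignored).  Block starts are 1-based SNP column
#' indices; allele strings are over `{0,1}`.
#'
#' @param path file path.
#' @param n_sites total number of SNP columns; when `NULL`, inferred as the
#'   rightmost covered column.
#' @return a SNP fragment matrix with row ids taken from the fragment ids.
#' @export
read_hapcut_fragments <- function(path, n_sites = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty fragment file: ", path)
  parsed <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    nb <- suppressWarnings(as.integer(tok[1L]))
    if (is.na(nb) || nb < 1L) stop("line ", i, ": invalid block count '",
                                   tok[1L], "'")
    if (length(tok) < 2L + 2L * nb) {
      stop("line ", i, ": expected ", nb, " (start, alleles) block pairs")
    }
    id <- tok[2L]
    starts <- integer(nb); seqs <- character(nb)
    for (b in seq_len(nb)) {
      starts[b] <- suppressWarnings(as.integer(tok[2L * b + 1L]))
      seqs[b] <- tok[2L * b + 2L]
      if (is.na(starts[b]) || starts[b] < 1L) {
        stop("line ", i, ": invalid block start '", tok[2L * b + 1L], "'")
      }
      if (!grepl("^[01]+$", seqs[b])) {
        stop("line ", i, ": invalid allele string '", seqs[b], "'")
      }
    }
    list(id = id, starts = starts, seqs = seqs,
         end = max(starts + nchar(seqs) - 1L))
  })
  n_max <- max(vapply(parsed, `[[`, integer(1), "end"))
  if (is.null(n_sites)) n_sites <- n_max
  if (n_max > n_sites) stop("fragment extends to column ", n_max,
                            " beyond n_sites = ", n_sites)
  M <- matrix(NA_integer_, nrow = length(parsed), ncol = n_sites)
  for (i in seq_along(parsed)) {
    p <- parsed[[i]]
    for (b in seq_along(p$starts)) {
      al <- as.integer(strsplit(p$seqs[b], "", fixed = TRUE)[[1L]])
      M[i, p$starts[b]:(p$starts[b] + length(al) - 1L)] <- al
    }
  }
  snp_matrix(M, row_ids = vapply(parsed, `[[`, character(1), "id"))
}
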