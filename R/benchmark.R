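#' Define a benchmark grid
#'
#' A grid sweeps one simulation parameter over a set of values, holding the
#' others fixed, with a number of replicate instances per setting.
#' Replicate seeds are derived deterministically from the base seed, so two
#' runs of the same grid produce identical tables.
#'
#' @param mode `"celsim"` or `"metasim"`.
#' @param vary name of the swept [sim_config()] parameter (e.g. `"p_s"`).
#' @param values numeric vector of settings for the swept parameter.
#' @param fixed named list of the remaining simulation parameters.
#' @param replicates instances per setting (default 100).
#' @param base_seed integer base seed.
#' @return an object of class `"benchmark_grid"`.
#' @export
benchmark_grid <- function(mode, vary, values, fixed = list(),
                           replicates = 100L, base_seed = 1L) {
  stopifnot(is.character(vary), length(vary) == 1L, length(values) >= 1L,
            replicates >= 1L)
  structure(list(mode = mode, vary = vary, values = values, fixed = fixed,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed)),
            class = "benchmark_grid")
}

#' Run a benchmark grid
#'
#' For every cell of the grid, simulates `replicates` instances, phases each
#' with [ehtld()], evaluates it against the generating haplotypes and the
#' corrupted fragment matrix, and averages the three accuracy measures.
#' Individual replicate failures are caught, counted and excluded from the
#' averages.
#'
#' @param grid a [benchmark_grid()].
#' @param quiet passed to [ehtld()] (default `TRUE`: suppress
#'   unconstrained-column warnings inside sweeps).
#' @return a `data.frame` with one row per cell: the swept parameter value,
#'   `mean_rr`, `mean_ve`, `mean_mec`, `replicates` (evaluated) and
#'   `failed`.
#' @export
run_benchmark <- function(grid, quiet = TRUE) {
  stopifnot(inherits(grid, "benchmark_grid"))
  n_cells <- length(grid$values)
  set.seed(grid$base_seed)
  seeds <- matrix(sample.int(.Machine$integer.max, n_cells * grid$replicates),
                  nrow = n_cells)
  out <- vector("list", n_cells)
  for (cell in seq_len(n_cells)) {
    args <- grid$fixed
    args[[grid$vary]] <- grid$values[cell]
    args$mode <- grid$mode
    res <- matrix(NA_real_, nrow = grid$replicates, ncol = 3L)
    failed <- 0L
    for (rep in seq_len(grid$replicates)) {
      args$seed <- seeds[cell, rep]
      r <- tryCatch({
        sim <- simulate_instance(do.call(sim_config, args))
        recon <- ehtld(sim$M, sim$G, quiet = quiet)
        evaluate_phasing(sim$truth, recon, sim$M)
      }, error = function(e) NULL)
      if (is.null(r)) failed <- failed + 1L else res[rep, ] <- unlist(r)
    }
    if (failed > 0L) {
      warning("cell ", grid$vary, " = ", grid$values[cell], ": ", failed,
              " replicate(s) failed and were excluded")
    }
    out[[cell]] <- data.frame(
      value = grid$values[cell],
      mean_rr = mean(res[, 1L], na.rm = TRUE),
      mean_ve = mean(res[, 2L], na.rm = TRUE),
      mean_mec = mean(res[, 3L], na.rm = TRUE),
      replicates = grid$replicates - failed,
      failed = failed
    )
  }
  tbl <- do.call(rbind, out)
  names(tbl)[1L] <- grid$vary
  tbl
}

#' Write a benchmark table as TSV
#'
#' Writes the table with the conventional report precision: mean RR to two
#' decimals, mean VE and mean MEC rounded to integers.
#'
#' @param tbl a table from [run_benchmark()].
#' @param path file path.
#' @export
write_benchmark <- function(tbl, path) {
  tbl$mean_rr <- sprintf("%.2f", tbl$mean_rr)
  tbl$mean_ve <- as.integer(round(tbl$mean_ve))
  tbl$mean_mec <- as.integer(round(tbl$mean_mec))
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
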