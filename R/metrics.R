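#' Success rate of a set of runs
#'
#' Fraction of runs whose best energy lies within `threshold` (default
#' 1 kcal/mol, roughly chemical accuracy) of the reference energy. The
#' boundary counts as a success (`<=` convention).
#'
#' @param run_energies numeric vector of per-run best energies (kcal/mol).
#' @param reference_energy reference conformer energy (kcal/mol).
#' @param threshold success margin (kcal/mol).
#' @return Fraction in `[0, 1]`.
#' @export
success_rate <- function(run_energies, reference_energy, threshold = 1.0) {
  if (!length(run_energies)) stop("at least one run is required")
  mean(run_energies - reference_energy <= threshold)
}

#' Energy residuals of a run
#'
#' `residual = run - reference`; the normalized residual divides by the
#' number of atoms.
#'
#' @param run_energy best energy of a run (kcal/mol).
#' @param reference_energy reference conformer energy (kcal/mol).
#' @param n_atoms number of atoms (>= 1).
#' @return Named numeric vector `c(residual = , normalized = )`.
#' @export
residuals_energy <- function(run_energy, reference_energy, n_atoms) {
  if (n_atoms < 1) stop("n_atoms must be at least 1")
  r <- run_energy - reference_energy
  c(residual = r, normalized = r / n_atoms)
}

# nearest-rank percentile: smallest value with cumulative rank >= p
nearest_rank <- function(x, p) {
  x <- sort(x)
  if (p <= 0) return(x[1L])
  x[ceiling(p * length(x))]
}

#' Benchmark a set of search methods on a set of molecules
#'
#' Runs `n_runs` seeded searches per method and molecule, each terminated
#' early once within `target_tol` (0.1 kcal/mol) of the molecule's
#' reference energy, and tabulates the success rate (within 1 kcal/mol of
#' the reference), mean energy-evaluation count, and nearest-rank min /
#' median / 75th-percentile residuals, normalized residuals, and wall
#' times. The whole table is a pure function of the configuration and
#' `base_seed`.
#'
#' @param models named list of [energy_model()] objects.
#' @param methods character subset of `c("vnd", "ls", "lsvnd", "ptmc")`.
#' @param config a [search_config()] (used by vnd/ls/lsvnd).
#' @param n_runs runs per cell.
#' @param base_seed integer; per-run seeds are derived deterministically.
#' @param references named list of reference energies (kcal/mol), or
#'   `NULL` to compute them: exhaustively when `d^M <= exhaustive_limit`,
#'   otherwise by [generate_reference()].
#' @param ptmc_cfg a [ptmc_config()] for the `"ptmc"` method.
#' @param target_tol per-run early-stop tolerance (kcal/mol).
#' @param exhaustive_limit grid-size bound for exhaustive references.
#' @param reference_cfg [ptmc_config()] for PTMC-generated references.
#' @return A data frame of class `benchmark_table`, one row per
#'   method-molecule cell.
#' @export
run_benchmark <- function(models, methods = c("vnd", "ls"),
                          config = search_config(), n_runs = 25,
                          base_seed = 1, references = NULL,
                          ptmc_cfg = ptmc_config(),
                          target_tol = 0.1, exhaustive_limit = 1e5,
                          reference_cfg = ptmc_config(sweeps = 2000)) {
  stopifnot(length(models) >= 1, all(methods %in% c("vnd", "ls", "lsvnd", "ptmc")))
  if (is.null(names(models))) names(models) <- paste0("mol", seq_along(models))
  grid <- angle_grid(config$d)
  if (is.null(references)) {
    references <- lapply(models, function(m) {
      M <- m$graph$n_torsions
      if (grid$d^M <= exhaustive_limit) exhaustive_reference(m, grid)$energy
      else {
        cfg <- reference_cfg; cfg$seed <- base_seed
        generate_reference(m, cfg, grid)$energy
      }
    })
  }
  if (!all(names(models) %in% names(references)))
    stop("missing reference energy for some molecule")
  rows <- list()
  cell <- 0L
  for (method in methods) for (mol in names(models)) {
    cell <- cell + 1L
    model <- models[[mol]]
    ref <- references[[mol]]
    energies <- evals <- times <- numeric(n_runs)
    for (run in seq_len(n_runs)) {
      seed <- as.integer(base_seed + 1000L * cell + run)
      res <- switch(method,
        vnd = {
          cfg <- config; cfg$seed <- seed
          cfg$target_energy <- ref; cfg$target_tol <- target_tol
          vnd(model, cfg)
        },
        ls = {
          cfg <- config; cfg$seed <- seed
          cfg$target_energy <- ref; cfg$target_tol <- target_tol
          local_search(model, cfg)
        },
        lsvnd = {
          cfg <- config; cfg$seed <- seed
          cfg$target_energy <- ref; cfg$target_tol <- target_tol
          ls_vnd(model, cfg)
        },
        ptmc = {
          pcfg <- ptmc_cfg; pcfg$seed <- seed
          ptmc_search(model, pcfg, grid, target_energy = ref,
                      target_tol = target_tol)
        })
      energies[run] <- res$best_energy
      evals[run] <- res$n_evals
      times[run] <- res$elapsed
    }
    resid <- energies - ref
    rows[[cell]] <- data.frame(
      method = method, molecule = mol,
      n_atoms = model$system$n_atoms, n_torsions = model$graph$n_torsions,
      reference = ref, n_runs = n_runs,
      success_rate = success_rate(energies, ref),
      mean_evals = mean(evals),
      res_min = nearest_rank(resid, 0),
      res_p50 = nearest_rank(resid, 0.5),
      res_p75 = nearest_rank(resid, 0.75),
      nres_min = nearest_rank(resid, 0) / model$system$n_atoms,
      nres_p50 = nearest_rank(resid, 0.5) / model$system$n_atoms,
      nres_p75 = nearest_rank(resid, 0.75) / model$system$n_atoms,
      tts_min = nearest_rank(times, 0),
      tts_p50 = nearest_rank(times, 0.5),
      tts_p75 = nearest_rank(times, 0.75))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("benchmark_table", "data.frame")
  out
}

#' @export
print.benchmark_table <- function(x, digits = 3, ...) {
  cat("Conformational search benchmark (success = within 1 kcal/mol of reference)\n")
  df <- as.data.frame(x)
  df$mean_evals <- format(signif(df$mean_evals, 3), big.mark = ",")
  print.data.frame(df[, c("method", "molecule", "n_torsions", "success_rate",
                          "mean_evals", "res_min", "res_p50", "res_p75",
                          "nres_p50", "tts_p50")],
                   digits = digits, row.names = FALSE)
  invisible(x)
}
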