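#' Search run configuration
#'
#' Parameters shared by the descent searchers. `d` is the number of grid
#' angles per torsion, `s` the QUBO variable budget per neighbourhood
#' (`sum |Theta_i| <= s`), `A` the maximum number of consecutive
#' non-improving iterations before stopping, `B` the iteration cap,
#' `gamma` the one-hot penalty multiplier. When `target_energy` is
#' supplied, a run also stops as soon as its best energy is within
#' `target_tol` (default 0.1 kcal/mol) of the target.
#'
#' @param d grid resolution (>= 2).
#' @param s neighbourhood variable budget (>= 2).
#' @param A stall limit (>= 1).
#' @param B iteration cap (>= 1).
#' @param gamma penalty multiplier for [choose_penalty()].
#' @param penalty_floor penalty floor (kcal/mol).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param solver `"exact"` or `"sa"`.
#' @param sa_schedule an [sa_schedule()] (used when `solver = "sa"`).
#' @param sa_reads anneal restarts per subproblem.
#' @param target_energy optional reference energy (kcal/mol).
#' @param target_tol early-stop tolerance around `target_energy`.
#' @return A list of class `search_config`.
#' @export
search_config <- function(d = 6, s = 12, A = 10, B = 150, gamma = 2,
                          penalty_floor = 1, seed = NULL,
                          solver = c("exact", "sa"),
                          sa_schedule = vndconf::sa_schedule(),
                          sa_reads = 25,
                          target_energy = NULL, target_tol = 0.1) {
  solver <- match.arg(solver)
  if (d < 2) stop("d must be >= 2")
  if (s < 2) stop("s must be >= 2")
  if (A < 1) stop("A must be >= 1")
  if (B < 1) stop("B must be >= 1")
  structure(list(d = as.integer(d), s = as.integer(s), A = as.integer(A),
                 B = as.integer(B), gamma = gamma,
                 penalty_floor = penalty_floor, seed = seed, solver = solver,
                 sa_schedule = sa_schedule, sa_reads = sa_reads,
                 target_energy = target_energy, target_tol = target_tol),
            class = "search_config")
}

#' Random initial torsion vector
#'
#' Each entry drawn uniformly from the grid. Uses R's RNG.
#'
#' @param grid an [angle_grid()].
#' @param M number of torsions.
#' @return Numeric torsion vector of length `M`.
#' @export
random_initial_solution <- function(grid, M) {
  grid$values[sample.int(grid$d, M, replace = TRUE)]
}

new_conf_search <- function(method, model, best_t, best_energy, iterations,
                            trace, stop_reason, ledger, elapsed, config) {
  structure(list(method = method, molecule = model$system$name,
                 n_atoms = model$system$n_atoms,
                 n_torsions = model$graph$n_torsions,
                 best_t = best_t, best_energy = best_energy,
                 iterations = iterations, trace = trace,
                 stop_reason = stop_reason, n_evals = ledger_count(ledger),
                 elapsed = elapsed, config = config),
            class = "conf_search")
}

hit_target <- function(energy, config) {
  !is.null(config$target_energy) &&
    (energy - config$target_energy) <= config$target_tol
}

#' Variable neighbourhood descent conformational search
#'
#' The main loop: at each iteration a 2-torsion-dependent neighbourhood is
#' sampled along a random torsion ordering ([sample_neighbourhood()]), its
#' QUBO is built from pre-evaluated coefficients and solved (exactly or by
#' simulated annealing), and the decoded torsion vector is accepted only
#' if it strictly lowers the energy. The torsion ordering is reshuffled
#' once exhausted. Stops at `B` iterations, after `A` consecutive
#' non-improving iterations, or once within `target_tol` of
#' `target_energy`.
#'
#' @param model an [energy_model()].
#' @param config a [search_config()].
#' @param t_init optional initial torsion vector (grid values); random by
#'   default.
#' @param ledger optional shared [energy_ledger()]; created when missing.
#' @return An object of class `conf_search`: best torsion vector and
#'   energy, accepted-energy trace (non-increasing), iteration count,
#'   energy-evaluation count, stop reason, elapsed seconds.
#' @export
vnd <- function(model, config = search_config(), t_init = NULL, ledger = NULL) {
  stopifnot(inherits(model, "energy_model"), inherits(config, "search_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(ledger)) ledger <- energy_ledger()
  t0 <- Sys.time()
  grid <- angle_grid(config$d)
  M <- model$graph$n_torsions
  if (is.null(t_init)) t_init <- random_initial_solution(grid, M)
  if (length(t_init) != M) stop("t_init has wrong length")
  t_cur <- t_init
  e_cur <- total_energy(model, t_cur, ledger)
  trace <- e_cur
  stall <- 0L; iter <- 0L
  stop_reason <- "max_iter"
  phi <- sample.int(M); pos <- 1L
  if (hit_target(e_cur, config)) stop_reason <- "target"
  while (iter < config$B && stop_reason != "target") {
    iter <- iter + 1L
    spec <- sample_neighbourhood(model$graph, phi, pos, t_cur, grid, config$s)
    pos <- pos + 1L
    if (pos > M) { phi <- sample.int(M); pos <- 1L }
    coeffs <- qubo_coefficients(model, spec, t_cur, ledger)
    p <- choose_penalty(coeffs, config$gamma, config$penalty_floor)
    qubo <- build_qubo(coeffs, p)
    res <- if (config$solver == "exact") solve_exact(qubo)
           else solve_sa(qubo, config$sa_schedule, config$sa_reads)
    improved <- FALSE
    if (isTRUE(res$feasible)) {
      t_cand <- decode_solution(res$x, qubo, t_cur)
      e_cand <- res$energy
      if (e_cand < e_cur) {
        t_cur <- t_cand; e_cur <- e_cand; improved <- TRUE
      }
    }
    trace <- c(trace, e_cur)
    if (improved) stall <- 0L else stall <- stall + 1L
    if (hit_target(e_cur, config)) { stop_reason <- "target"; break }
    if (stall >= config$A) { stop_reason <- "stalled"; break }
  }
  new_conf_search("vnd", model, t_cur, e_cur, iter, trace, stop_reason,
                  ledger, as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  config)
}

#' Single-torsion local search
#'
#' Steepest-descent local search over the neighbourhood of torsion vectors
#' differing in exactly one angle: each sweep evaluates all
#' `M * (d - 1)` single-torsion moves and applies the best one if it
#' strictly lowers the energy; the search terminates when no neighbouring
#' solution is lower, i.e. at a single-torsion local optimum (or at the
#' iteration cap `B`, counting one sweep per iteration).
#'
#' @inheritParams vnd
#' @return A `conf_search` object (`method = "ls"`).
#' @export
local_search <- function(model, config = search_config(), t_init = NULL,
                         ledger = NULL) {
  stopifnot(inherits(model, "energy_model"), inherits(config, "search_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(ledger)) ledger <- energy_ledger()
  t0 <- Sys.time()
  grid <- angle_grid(config$d)
  M <- model$graph$n_torsions
  if (is.null(t_init)) t_init <- random_initial_solution(grid, M)
  t_cur <- t_init
  e_cur <- total_energy(model, t_cur, ledger)
  trace <- e_cur
  iter <- 0L
  stop_reason <- "max_iter"
  if (hit_target(e_cur, config)) stop_reason <- "target"
  while (iter < config$B && stop_reason != "target") {
    iter <- iter + 1L
    best_e <- e_cur; best_i <- NA_integer_; best_th <- NA_real_
    for (i in seq_len(M)) for (k in seq_len(grid$d)) {
      th <- grid$values[k]
      if (angle_eq(th, t_cur[i])) next
      tt <- t_cur; tt[i] <- th
      e <- total_energy(model, tt, ledger)
      if (e < best_e) { best_e <- e; best_i <- i; best_th <- th }
    }
    if (is.na(best_i)) { stop_reason <- "local_optimum"; break }
    t_cur[best_i] <- best_th
    e_cur <- best_e
    trace <- c(trace, e_cur)
    if (hit_target(e_cur, config)) { stop_reason <- "target"; break }
  }
  new_conf_search("ls", model, t_cur, e_cur, iter, trace, stop_reason,
                  ledger, as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  config)
}

angle_eq <- function(a, b, tol = 1e-9) {
  d <- abs(a - b) %% (2 * pi)
  min(d, 2 * pi - d) <= tol
}

#' Local search followed by variable neighbourhood descent
#'
#' Optimizes a (random) initial conformation with [local_search()], then
#' passes the result to [vnd()] for further descent. The combined energy
#' trace is non-increasing and the final energy is never above the
#' LS-only energy for the same initialization; evaluation counts are
#' additive across the two phases.
#'
#' @inheritParams vnd
#' @return A `conf_search` object (`method = "lsvnd"`).
#' @export
ls_vnd <- function(model, config = search_config(), t_init = NULL,
                   ledger = NULL) {
  if (is.null(ledger)) ledger <- energy_ledger()
  t0 <- Sys.time()
  ls_res <- local_search(model, config, t_init, ledger)
  cfg_vnd <- config
  cfg_vnd$seed <- NULL  # keep the RNG stream continuous across phases
  if (ls_res$stop_reason == "target") {
    out <- ls_res
  } else {
    vnd_res <- vnd(model, cfg_vnd, t_init = ls_res$best_t, ledger = ledger)
    out <- new_conf_search("lsvnd", model, vnd_res$best_t, vnd_res$best_energy,
                           ls_res$iterations + vnd_res$iterations,
                           c(ls_res$trace, vnd_res$trace[-1L]),
                           vnd_res$stop_reason, ledger,
                           as.numeric(difftime(Sys.time(), t0, units = "secs")),
                           config)
    out$ls_energy <- ls_res$best_energy
    return(out)
  }
  out$method <- "lsvnd"
  out$ls_energy <- ls_res$best_energy
  out
}

#' Exhaustive grid reference
#'
#' Evaluates every torsion vector on the `d^M` grid and returns the global
#' grid minimum. Only sensible for small `d^M`; larger systems should use
#' [generate_reference()].
#'
#' @param model an [energy_model()].
#' @param grid an [angle_grid()].
#' @param ledger optional [energy_ledger()].
#' @param size_limit refuse enumeration beyond this many points.
#' @return List with `t`, `energy`, `n_evals`.
#' @export
exhaustive_reference <- function(model, grid, ledger = NULL, size_limit = 1e6) {
  M <- model$graph$n_torsions
  if (grid$d^M > size_limit) stop("grid too large for exhaustive enumeration")
  idx <- do.call(expand.grid, rep(list(seq_len(grid$d)), M))
  vals <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    vals[r] <- total_energy(model, grid$values[as.integer(idx[r, ])], ledger)
  }
  best <- do.call(order, c(list(vals), as.list(idx)))[1L]
  list(t = grid$values[as.integer(idx[best, ])], energy = vals[best],
       n_evals = nrow(idx))
}
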