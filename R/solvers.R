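#' Exact QUBO solver over the feasible one-hot space
#'
#' Enumerates the product space of the per-torsion angle subsets (size
#' `S_k = prod |Theta_i|`) rather than all `2^n` bitstrings: every
#' feasible one-hot assignment corresponds to one slot tuple, and the
#' unconstrained penalty terms vanish on feasible assignments, so the
#' feasible optimum is the global QUBO optimum for a sufficient penalty.
#' Deterministic; ties are broken by the lexicographically smallest slot
#' tuple.
#'
#' @param qubo a [build_qubo()] result.
#' @param size_limit refuse enumeration beyond this many tuples.
#' @return An object of class `solver_result`: `x` (bitstring),
#'   `objective` (QUBO objective incl. offset), `energy`
#'   (`objective + constant`, absolute kcal/mol), `slots` (winning slot
#'   tuple), `n_examined`, `feasible`.
#' @export
solve_exact <- function(qubo, size_limit = 1e7) {
  stopifnot(inherits(qubo, "qubo_problem"))
  sizes <- vapply(qubo$blocks, length, integer(1))
  S <- prod(sizes)
  if (S > size_limit) stop("neighbourhood too large for exact enumeration")
  m <- length(sizes)
  grid_idx <- do.call(expand.grid, lapply(sizes, seq_len))
  # on feasible one-hot assignments the penalty terms cancel exactly, so the
  # objective is evaluated from the penalty-free coefficient tables
  vals <- numeric(nrow(grid_idx))
  varidx <- matrix(0L, nrow(grid_idx), m)
  for (q in seq_len(m)) {
    varidx[, q] <- qubo$blocks[[q]][grid_idx[, q]]
    vals <- vals + qubo$raw_linear[[q]][grid_idx[, q]]
  }
  for (pidx in seq_along(qubo$raw_pairs)) {
    pr <- qubo$raw_pairs[[pidx]]
    vals <- vals + qubo$raw_quad[[pidx]][cbind(grid_idx[, pr[1]], grid_idx[, pr[2]])]
  }
  # lexicographic tie-break on the slot tuple
  best <- do.call(order, c(list(vals), as.list(grid_idx)))[1L]
  x <- integer(qubo$n_vars)
  x[varidx[best, ]] <- 1L
  structure(list(x = x, objective = vals[best],
                 energy = vals[best] + qubo$constant,
                 slots = as.integer(grid_idx[best, ]),
                 n_examined = S, feasible = TRUE),
            class = "solver_result")
}

#' Simulated-annealing schedule
#'
#' Geometric inverse-temperature ramp used by [solve_sa()].
#'
#' @param beta0,beta1 initial and final inverse temperatures (1/(kcal/mol)).
#' @param sweeps number of full single-spin-flip sweeps per read.
#' @return A list of class `sa_schedule`.
#' @export
sa_schedule <- function(beta0 = 0.1, beta1 = 50, sweeps = 2000) {
  stopifnot(beta0 > 0, beta1 >= beta0, sweeps >= 1)
  structure(list(beta0 = beta0, beta1 = beta1, sweeps = as.integer(sweeps)),
            class = "sa_schedule")
}

#' Simulated-annealing QUBO solver
#'
#' Single-spin-flip Metropolis annealing over the full binary space with a
#' geometric inverse-temperature schedule, restarted `n_reads` times from
#' random bitstrings; a stochastic stand-in for hardware annealers. The
#' best *feasible* (one-hot) sample encountered is returned; infeasible
#' samples are discarded, never repaired. Uses R's RNG; seed upstream for
#' reproducibility.
#'
#' @param qubo a [build_qubo()] result.
#' @param schedule an [sa_schedule()].
#' @param n_reads number of independent anneals (>= 1).
#' @return A `solver_result`; `feasible = FALSE` when no one-hot sample
#'   was seen (the `x`/`energy` fields are then `NULL`).
#' @export
solve_sa <- function(qubo, schedule = sa_schedule(), n_reads = 25) {
  stopifnot(inherits(qubo, "qubo_problem"), n_reads >= 1)
  n <- qubo$n_vars
  m <- length(qubo$blocks)
  betas <- exp(seq(log(schedule$beta0), log(schedule$beta1),
                   length.out = schedule$sweeps))
  block_of <- qubo$var_map$torsion
  block_pos <- match(block_of, qubo$spec$torsions)
  best_obj <- Inf; best_x <- NULL
  examined <- 0L
  for (read in seq_len(n_reads)) {
    x <- as.integer(stats::runif(n) < 0.5)
    field <- as.vector(qubo$quad %*% x)  # sum_j Q_vj x_j
    block_sums <- vapply(qubo$blocks, function(b) sum(x[b]), integer(1))
    obj <- qubo_value(qubo, x)
    if (all(block_sums == 1L) && obj < best_obj) { best_obj <- obj; best_x <- x }
    for (sw in seq_len(schedule$sweeps)) {
      beta <- betas[sw]
      for (v in sample.int(n)) {
        delta <- (1 - 2 * x[v]) * (qubo$linear[v] + field[v])
        if (delta <= 0 || stats::runif(1) < exp(-beta * delta)) {
          sgn <- 1L - 2L * x[v]
          x[v] <- x[v] + sgn
          field <- field + sgn * qubo$quad[, v]
          block_sums[block_pos[v]] <- block_sums[block_pos[v]] + sgn
          obj <- obj + delta
          examined <- examined + 1L
          if (obj < best_obj && all(block_sums == 1L)) {
            best_obj <- obj; best_x <- x
          }
        }
      }
    }
    if (all(block_sums == 1L) && obj < best_obj) { best_obj <- obj; best_x <- x }
  }
  if (is.null(best_x))
    return(structure(list(x = NULL, objective = NA_real_, energy = NA_real_,
                          slots = NULL, n_examined = examined, feasible = FALSE),
                     class = "solver_result"))
  # re-evaluate the winning feasible bitstring from the penalty-free tables:
  # the incrementally tracked objective accumulates rounding at the penalty
  # scale, while feasible assignments have an exact penalty-free value
  slots <- vapply(seq_len(m), function(q) which(best_x[qubo$blocks[[q]]] == 1L),
                  integer(1))
  best_obj <- sum(vapply(seq_len(m), function(q) qubo$raw_linear[[q]][slots[q]],
                         numeric(1)))
  for (pidx in seq_along(qubo$raw_pairs)) {
    pr <- qubo$raw_pairs[[pidx]]
    best_obj <- best_obj + qubo$raw_quad[[pidx]][slots[pr[1]], slots[pr[2]]]
  }
  structure(list(x = best_x, objective = best_obj,
                 energy = best_obj + qubo$constant,
                 slots = slots,
                 n_examined = examined, feasible = TRUE),
            class = "solver_result")
}

#' @export
print.solver_result <- function(x, ...) {
  if (x$feasible)
    cat(sprintf("<solver_result> objective %.6f, energy %.6f kcal/mol, %d states examined\n",
                x$objective, x$energy, x$n_examined))
  else cat("<solver_result> no feasible one-hot sample found\n")
  invisible(x)
}

#' Direct neighbourhood enumeration oracle
#'
#' Evaluates the full molecular energy at every one of the
#' `S_k = prod |Theta_i|` grid points of a neighbourhood (charging the
#' ledger once per point) and returns the minimum. Independent of the QUBO
#' route; used as a cross-check and as a reference solver. Ties are broken
#' by the lexicographically smallest slot tuple.
#'
#' @param model an [energy_model()].
#' @param spec a `neighbourhood_spec`.
#' @param t_incumbent incumbent torsion vector.
#' @param ledger optional [energy_ledger()].
#' @param size_limit refuse enumeration beyond this many points.
#' @return List with `t` (best torsion vector), `energy`, `n_evals`.
#' @export
brute_force_neighbourhood <- function(model, spec, t_incumbent, ledger = NULL,
                                      size_limit = 1e7) {
  stopifnot(inherits(spec, "neighbourhood_spec"))
  sizes <- vapply(spec$angles, length, integer(1))
  if (prod(sizes) > size_limit) stop("neighbourhood too large for enumeration")
  grid_idx <- do.call(expand.grid, lapply(sizes, seq_len))
  vals <- numeric(nrow(grid_idx))
  for (r in seq_len(nrow(grid_idx))) {
    tt <- t_incumbent
    for (q in seq_along(spec$torsions))
      tt[spec$torsions[q]] <- spec$angles[[q]][grid_idx[r, q]]
    vals[r] <- total_energy(model, tt, ledger)
  }
  best <- do.call(order, c(list(vals), as.list(grid_idx)))[1L]
  t_best <- t_incumbent
  for (q in seq_along(spec$torsions))
    t_best[spec$torsions[q]] <- spec$angles[[q]][grid_idx[best, q]]
  list(t = t_best, energy = vals[best], n_evals = nrow(grid_idx))
}
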