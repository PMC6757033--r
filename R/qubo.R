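#' One-hot QUBO encoding of a neighbourhood subproblem
#'
#' Each selected torsion `i` gets one binary variable `x_ik` per angle in
#' its subset `Theta_i`; a feasible assignment sets exactly one bit per
#' torsion. The objective is the pre-evaluated interaction energy plus the
#' quadratic penalty `p * sum_i (sum_k x_ik - 1)^2` that enforces the
#' one-hot constraints; the constraint expansion uses `x^2 = x`, folding
#' the constant `p * |T_k|` into the offset. For any feasible one-hot
#' assignment, `objective + constant` equals the absolute molecular energy
#' of the decoded torsion vector.
#'
#' @param coeffs a [qubo_coefficients()] result.
#' @param penalty one-hot penalty `p` in kcal/mol (> 0); see
#'   [choose_penalty()].
#' @return An object of class `qubo_problem`: `n_vars`, `linear`, `quad`
#'   (symmetric, zero diagonal), `offset`, `constant`, `penalty`,
#'   `var_map` (data frame: variable, torsion, slot, angle), `blocks`
#'   (per-torsion variable index lists), `spec`.
#' @export
build_qubo <- function(coeffs, penalty) {
  stopifnot(inherits(coeffs, "qubo_coeffs"))
  if (penalty <= 0) stop("penalty must be positive")
  spec <- coeffs$spec
  sizes <- vapply(spec$angles, length, integer(1))
  n <- sum(sizes)
  m <- length(sizes)
  offsets <- cumsum(c(0L, sizes[-m]))
  blocks <- lapply(seq_len(m), function(q) offsets[q] + seq_len(sizes[q]))
  linear <- numeric(n)
  quad <- matrix(0, n, n)
  var_map <- data.frame(variable = seq_len(n),
                        torsion = rep(spec$torsions, sizes),
                        slot = unlist(lapply(sizes, seq_len)),
                        angle = unlist(spec$angles))
  for (q in seq_len(m)) {
    idx <- blocks[[q]]
    linear[idx] <- coeffs$linear[[q]] - penalty
    quad[idx, idx] <- 2 * penalty
  }
  diag(quad) <- 0
  for (pidx in seq_along(coeffs$pairs)) {
    pr <- coeffs$pairs[[pidx]]
    bi <- blocks[[pr[1]]]; bj <- blocks[[pr[2]]]
    quad[bi, bj] <- quad[bi, bj] + coeffs$quadratic[[pidx]]
    quad[bj, bi] <- quad[bj, bi] + t(coeffs$quadratic[[pidx]])
  }
  structure(list(n_vars = n, linear = linear, quad = quad,
                 offset = penalty * m, constant = coeffs$constant,
                 penalty = penalty, var_map = var_map, blocks = blocks,
                 spec = spec,
                 # penalty-free coefficient tables; on feasible assignments the
                 # penalty cancels exactly, so the exact solver works from
                 # these to avoid catastrophic cancellation when the LJ
                 # coefficient range (1/r^12 clashes) dwarfs the energies
                 raw_linear = coeffs$linear, raw_quad = coeffs$quadratic,
                 raw_pairs = coeffs$pairs),
            class = "qubo_problem")
}

#' @export
print.qubo_problem <- function(x, ...) {
  cat(sprintf("<qubo_problem> %d variables, %d torsions, penalty %.4g kcal/mol\n",
              x$n_vars, length(x$blocks), x$penalty))
  invisible(x)
}

#' Evaluate the QUBO objective for a bitstring
#'
#' Returns `linear . x + (1/2) x' Q x + offset` (the penalty-expanded
#' objective). Add `qubo$constant` for the absolute energy scale.
#'
#' @param qubo a [build_qubo()] result.
#' @param x 0/1 vector of length `n_vars`.
#' @return Objective value (kcal/mol).
#' @export
qubo_value <- function(qubo, x) {
  stopifnot(length(x) == qubo$n_vars)
  x <- as.numeric(x)
  sum(qubo$linear * x) + 0.5 * as.numeric(x %*% qubo$quad %*% x) + qubo$offset
}

#' Penalty coefficient for the one-hot constraints
#'
#' `p = gamma * (max coefficient - min coefficient)`, floored at
#' `floor_value`: a penalty exceeding the spread of the energy
#' coefficients makes every one-hot-violating assignment lie above the
#' feasible optimum.
#'
#' @param coeffs a [qubo_coefficients()] result.
#' @param gamma scale multiplier (default 2).
#' @param floor_value minimum penalty in kcal/mol (default 1).
#' @return Penalty `p` (kcal/mol).
#' @export
choose_penalty <- function(coeffs, gamma = 2, floor_value = 1) {
  vals <- c(unlist(coeffs$linear), unlist(coeffs$quadratic))
  if (!length(vals)) stop("no coefficients to scale the penalty from")
  max(gamma * (max(vals) - min(vals)), floor_value)
}

#' Decode a binary solution into a torsion vector
#'
#' Selected torsions are set to the angle of their single active one-hot
#' bit; unselected torsions keep their incumbent values. Any torsion block
#' with a bit sum different from one raises an infeasibility error
#' (condition class `vndconf_infeasible`), and the caller discards the
#' sample.
#'
#' @param x 0/1 vector of length `n_vars`.
#' @param qubo a [build_qubo()] result.
#' @param t_incumbent incumbent torsion vector.
#' @return Torsion vector with the decoded angles substituted.
#' @export
decode_solution <- function(x, qubo, t_incumbent) {
  stopifnot(length(x) == qubo$n_vars)
  t_out <- t_incumbent
  spec <- qubo$spec
  for (q in seq_along(qubo$blocks)) {
    bits <- x[qubo$blocks[[q]]]
    if (sum(bits) != 1L)
      stop(structure(class = c("vndconf_infeasible", "error", "condition"),
                     list(message = sprintf(
                       "one-hot row for torsion %d has bit sum %d (expected 1)",
                       spec$torsions[q], sum(bits)), call = sys.call(-1))))
    t_out[spec$torsions[q]] <- spec$angles[[q]][which(bits == 1L)]
  }
  t_out
}

#' One-hot encoding of a torsion vector
#'
#' Inverse of [decode_solution()] for vectors whose selected angles all
#' belong to their angle subsets.
#'
#' @inheritParams decode_solution
#' @param t torsion vector to encode.
#' @return 0/1 vector of length `n_vars`.
#' @export
encode_solution <- function(t, qubo) {
  spec <- qubo$spec
  x <- integer(qubo$n_vars)
  for (q in seq_along(qubo$blocks)) {
    a <- t[spec$torsions[q]] %% (2 * pi)
    diffs <- abs(spec$angles[[q]] - a)
    diffs <- pmin(diffs, 2 * pi - diffs)
    k <- which.min(diffs)
    if (diffs[k] > 1e-9) stop("angle not present in the neighbourhood angle subset")
    x[qubo$blocks[[q]][k]] <- 1L
  }
  x
}

#' Export a QUBO in coordinate text format
#'
#' Writes one line per nonzero term: `i j value`, with `i == j` for linear
#' terms and `i < j` for quadratic terms (the full symmetric coefficient,
#' i.e. the coefficient of `x_i x_j` in the objective). Header comment
#' lines record the offset and frozen constant.
#'
#' @param qubo a [build_qubo()] result.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
export_qubo <- function(qubo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# qubo n_vars %d", qubo$n_vars),
               sprintf("# offset %.17g", qubo$offset),
               sprintf("# constant %.17g", qubo$constant)), con)
  for (i in seq_len(qubo$n_vars)) {
    if (qubo$linear[i] != 0)
      writeLines(sprintf("%d %d %.17g", i, i, qubo$linear[i]), con)
    js <- which(qubo$quad[i, ] != 0)
    js <- js[js > i]
    for (j in js) writeLines(sprintf("%d %d %.17g", i, j, qubo$quad[i, j]), con)
  }
  invisible(path)
}
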