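#' Lennard-Jones 6-12 pair potential
#'
#' `eps * ((sigma/r)^12 - 2 * (sigma/r)^6)`: the well has depth `-eps` at
#' `r = sigma` and crosses zero at `r = sigma * 2^(-1/6)`.
#'
#' @param eps well depth (kcal/mol, > 0).
#' @param sigma van der Waals bond length: position of the minimum (Å).
#' @param r interatomic distance (Å, > 0). Vectorized over `r`.
#' @return Pair energy in kcal/mol.
#' @export
#' @examples
#' lj_pair(0.105, 3.851, 3.851)        # -eps
#' lj_pair(0.105, 3.851, 3.851 * 2^(-1/6))  # 0
lj_pair <- function(eps, sigma, r) {
  if (any(r <= 0)) stop("r must be positive (overlapping atoms)")
  x <- (sigma / r)^6
  eps * (x * x - 2 * x)
}

#' Load a Lennard-Jones parameter table
#'
#' Reads a plain whitespace/tab-separated table with columns `element`,
#' `eps` (kcal/mol), `sigma` (Å); lines starting with `#` are comments.
#'
#' @param path file path.
#' @param rule combination rule tag (only `"geometric"` is supported).
#' @return An object of class `ff_params`.
#' @export
read_ff_table <- function(path, rule = "geometric") {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("element", "eps", "sigma") %in% names(tab)))
    stop("force-field table needs columns: element, eps, sigma")
  if (any(tab$eps <= 0) || any(tab$sigma <= 0))
    stop("eps and sigma must be positive for every element")
  structure(list(eps = stats::setNames(tab$eps, tab$element),
                 sigma = stats::setNames(tab$sigma, tab$element),
                 rule = match.arg(rule, "geometric")),
            class = "ff_params")
}

#' Built-in UFF Lennard-Jones subset
#'
#' Well depths and van der Waals lengths for H, C, N, O, P, S, and Cl from
#' the Universal Force Field nonbonded parameters, shipped as a versioned
#' data file. Other elements require a user-supplied table
#' ([read_ff_table()]).
#'
#' @return An object of class `ff_params`.
#' @export
uff_params <- function() {
  path <- system.file("extdata", "uff_lj.tsv", package = "vndconf", mustWork = TRUE)
  read_ff_table(path)
}

#' Combine per-element parameters for an atom pair
#'
#' Geometric-mean combination (UFF convention):
#' `eps_ab = sqrt(eps_a * eps_b)`, `sigma_ab = sqrt(sigma_a * sigma_b)`.
#'
#' @param elem_a,elem_b element symbols.
#' @param params an `ff_params` table.
#' @return Named numeric vector `c(eps = , sigma = )`.
#' @export
combine_params <- function(elem_a, elem_b, params) {
  stopifnot(inherits(params, "ff_params"))
  missing <- setdiff(c(elem_a, elem_b), names(params$eps))
  if (length(missing))
    stop(sprintf("unknown element(s) %s; supported: %s",
                 paste(missing, collapse = ", "),
                 paste(names(params$eps), collapse = ", ")))
  c(eps = sqrt(params$eps[[elem_a]] * params$eps[[elem_b]]),
    sigma = sqrt(params$sigma[[elem_a]] * params$sigma[[elem_b]]))
}

#' Pairwise Lennard-Jones energy model for a molecule
#'
#' Precomputes the list of included nonbonded atom pairs and their combined
#' parameters. Atom pairs separated by one or two bonds (1-2 and 1-3
#' neighbours) are excluded, standard force-field practice: at bonded
#' distances the repulsive wall would otherwise dominate the landscape.
#' 1-4 pairs and beyond are included.
#'
#' @param system a [molecular_system()].
#' @param graph the matching [partition_rigid_bodies()] result.
#' @param params an `ff_params` table, default [uff_params()].
#' @param exclude_below_separation pairs closer than this bond-graph
#'   distance are excluded; default 3 (excludes 1-2 and 1-3 pairs).
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(system, graph, params = uff_params(),
                         exclude_below_separation = 3L) {
  stopifnot(inherits(system, "molecular_system"), inherits(graph, "rigid_body_graph"))
  n <- system$n_atoms
  g <- igraph::graph_from_edgelist(system$bonds, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  sep <- igraph::distances(g)
  ii <- which(upper.tri(sep) & sep >= exclude_below_separation, arr.ind = TRUE)
  ea <- system$elements[ii[, 1]]; eb <- system$elements[ii[, 2]]
  missing <- setdiff(unique(c(ea, eb)), names(params$eps))
  if (length(missing))
    stop(sprintf("unknown element(s) %s; supported: %s",
                 paste(missing, collapse = ", "),
                 paste(names(params$eps), collapse = ", ")))
  structure(
    list(system = system, graph = graph, params = params,
         pair_i = ii[, 1], pair_j = ii[, 2],
         eps = sqrt(params$eps[ea] * params$eps[eb]),
         sigma = sqrt(params$sigma[ea] * params$sigma[eb]),
         exclude_below_separation = exclude_below_separation),
    class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model> LJ 6-12 (%s combination), %d included pairs, %s\n",
              x$params$rule, length(x$pair_i), x$system$name))
  invisible(x)
}

# vector of per-pair LJ energies at given coordinates
pair_energy_terms <- function(model, coords) {
  d <- coords[model$pair_i, , drop = FALSE] - coords[model$pair_j, , drop = FALSE]
  r2 <- d[, 1]^2 + d[, 2]^2 + d[, 3]^2
  if (any(r2 <= 0)) stop("overlapping atoms: pair distance <= 0")
  x <- (model$sigma^2 / r2)^3
  model$eps * (x * x - 2 * x)
}

#' Total molecular energy of a torsion vector
#'
#' Sums the Lennard-Jones pair potential over all included atom pairs at
#' the coordinates reconstructed for `t`. Equivalent to the rigid-body
#' decomposition: the sum of all intra-body terms (rotation-invariant) plus
#' all body-body cross terms, which depend only on the torsions on the
#' connecting tree path. Charges one unit to `ledger` per call.
#'
#' @param model an [energy_model()].
#' @param t torsion vector (radians), length `M`.
#' @param ledger optional [energy_ledger()].
#' @return Energy in kcal/mol.
#' @export
total_energy <- function(model, t, ledger = NULL) {
  coords <- build_coordinates(model$system, model$graph, t)
  ledger_add(ledger, 1)
  sum(pair_energy_terms(model, coords))
}

# total energy at explicit coordinates (no ledger charge; internal)
energy_at_coords <- function(model, coords) sum(pair_energy_terms(model, coords))

#' Interaction energy between two atom groups
#'
#' Sum of the included Lennard-Jones cross terms with one atom in
#' `atoms_a` and the other in `atoms_b` (rigid bodies or unions of rigid
#' bodies). Pairs excluded from the model (1-2, 1-3) contribute nothing.
#'
#' @param model an [energy_model()].
#' @param coords `n x 3` coordinate matrix.
#' @param atoms_a,atoms_b disjoint atom index vectors.
#' @return Energy in kcal/mol.
#' @export
body_pair_energy <- function(model, coords, atoms_a, atoms_b) {
  in_a <- logical(model$system$n_atoms); in_a[atoms_a] <- TRUE
  in_b <- logical(model$system$n_atoms); in_b[atoms_b] <- TRUE
  sel <- (in_a[model$pair_i] & in_b[model$pair_j]) |
         (in_b[model$pair_i] & in_a[model$pair_j])
  if (!any(sel)) return(0)
  sum(pair_energy_terms_subset(model, coords, which(sel)))
}

pair_energy_terms_subset <- function(model, coords, idx) {
  pi <- model$pair_i[idx]; pj <- model$pair_j[idx]
  d <- coords[pi, , drop = FALSE] - coords[pj, , drop = FALSE]
  r2 <- d[, 1]^2 + d[, 2]^2 + d[, 3]^2
  if (any(r2 <= 0)) stop("overlapping atoms: pair distance <= 0")
  x <- (model$sigma[idx]^2 / r2)^3
  model$eps[idx] * (x * x - 2 * x)
}

#' QUBO coefficients for a 2-torsion-dependent neighbourhood
#'
#' Pre-evaluates the energy coefficients of the neighbourhood subproblem.
#' Contracting all torsion edges outside the selected subset merges the
#' rigid bodies into super-bodies forming a star; `U_i(theta)` is the
#' interaction of the star centre with the leaf super-body attached through
#' torsion `i` (a one-torsion path), and `U_ij(theta, theta')` is the
#' interaction of the two leaves attached through torsions `i` and `j` (a
#' two-torsion path through the centre). All unselected torsions stay
#' frozen at their incumbent values. The constant term collects the frozen
#' intra-super-body energy so that reconstructed neighbourhood energies are
#' absolute.
#'
#' The ledger is charged one unit per pre-evaluated coefficient: exactly
#' `sum_{i<j} |Theta_i||Theta_j| + s` units, which grows more slowly than
#' the neighbourhood size `prod |Theta_i|` as the subset grows.
#'
#' @param model an [energy_model()].
#' @param spec a [neighbourhood_spec] (see [sample_neighbourhood()]).
#' @param t incumbent torsion vector (radians).
#' @param ledger optional [energy_ledger()].
#' @return A list of class `qubo_coeffs`: `linear` (per selected torsion, a
#'   numeric vector over its angle subset), `quadratic` (per unordered
#'   torsion pair, a matrix), `constant` (frozen energy, kcal/mol), `spec`.
#' @export
qubo_coefficients <- function(model, spec, t, ledger = NULL) {
  stopifnot(inherits(spec, "neighbourhood_spec"))
  graph <- model$graph
  cg <- contract_complement(graph, spec$torsions)
  if (!is_star(cg))
    stop("neighbourhood subset is not 2-torsion dependent")
  torsions <- spec$torsions
  m <- length(torsions)

  # star centre: the component of maximal degree (root-side component for a
  # single edge), deterministic
  deg <- tabulate(c(cg$edges$comp_a, cg$edges$comp_b), nbins = cg$n_vertices)
  center <- if (max(deg) > 1L) which.max(deg) else cg$comp[graph$root]
  # atoms of each super-body
  comp_of_atom <- cg$comp[graph$body_of]
  comp_atoms <- split(seq_len(model$system$n_atoms), comp_of_atom)
  leaf <- integer(m)
  for (q in seq_len(m)) {
    e <- cg$edges[cg$edges$torsion == torsions[q], ]
    ends <- c(e$comp_a, e$comp_b)
    if (!center %in% ends) stop("internal error: torsion edge not incident to star centre")
    leaf[q] <- if (ends[1] == center) ends[2] else ends[1]
  }

  # classify included pairs once
  pc_i <- comp_of_atom[model$pair_i]
  pc_j <- comp_of_atom[model$pair_j]
  intra_idx <- which(pc_i == pc_j)
  group_ci <- lapply(seq_len(m), function(q)
    which((pc_i == center & pc_j == leaf[q]) | (pc_j == center & pc_i == leaf[q])))
  pair_list <- if (m >= 2) utils::combn(m, 2, simplify = FALSE) else list()
  group_ll <- lapply(pair_list, function(pr)
    which((pc_i == leaf[pr[1]] & pc_j == leaf[pr[2]]) |
          (pc_j == leaf[pr[1]] & pc_i == leaf[pr[2]])))

  coords0 <- build_coordinates(model$system, graph, t)
  constant <- if (length(intra_idx))
    sum(pair_energy_terms_subset(model, coords0, intra_idx)) else 0

  linear <- vector("list", m)
  for (q in seq_len(m)) {
    th <- spec$angles[[q]]
    vals <- numeric(length(th))
    for (k in seq_along(th)) {
      tt <- t; tt[torsions[q]] <- th[k]
      coords <- build_coordinates(model$system, graph, tt)
      vals[k] <- if (length(group_ci[[q]]))
        sum(pair_energy_terms_subset(model, coords, group_ci[[q]])) else 0
      ledger_add(ledger, 1)
    }
    linear[[q]] <- vals
  }

  quadratic <- vector("list", length(pair_list))
  for (pidx in seq_along(pair_list)) {
    pr <- pair_list[[pidx]]
    th_i <- spec$angles[[pr[1]]]; th_j <- spec$angles[[pr[2]]]
    mat <- matrix(0, length(th_i), length(th_j))
    for (ki in seq_along(th_i)) for (kj in seq_along(th_j)) {
      tt <- t
      tt[torsions[pr[1]]] <- th_i[ki]
      tt[torsions[pr[2]]] <- th_j[kj]
      coords <- build_coordinates(model$system, graph, tt)
      mat[ki, kj] <- if (length(group_ll[[pidx]]))
        sum(pair_energy_terms_subset(model, coords, group_ll[[pidx]])) else 0
      ledger_add(ledger, 1)
    }
    quadratic[[pidx]] <- mat
  }
  names(quadratic) <- vapply(pair_list, function(pr)
    paste(torsions[pr[1]], torsions[pr[2]], sep = "-"), character(1))

  structure(list(linear = linear, quadratic = quadratic, pairs = pair_list,
                 constant = constant, spec = spec, center = center),
            class = "qubo_coeffs")
}
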