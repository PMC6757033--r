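#' Contract the complement of a torsion subset
#'
#' Contracts every torsion edge of the rigid-body tree that is *not* in
#' `subset`. The vertices of the resulting multigraph are the connected
#' components ("super-bodies") of the tree with the subset edges removed;
#' its edges are exactly the subset edges. For a tree and a subset of `k`
#' edges the contraction always has `k + 1` vertices.
#'
#' @param graph a [partition_rigid_bodies()] result.
#' @param subset integer vector of torsion indices.
#' @return A list of class `contracted_graph`: `n_vertices`, `comp`
#'   (body id -> contracted vertex id), `edges` (data frame `torsion`,
#'   `comp_a`, `comp_b`).
#' @export
contract_complement <- function(graph, subset) {
  stopifnot(inherits(graph, "rigid_body_graph"))
  subset <- as.integer(subset)
  if (length(subset) && (any(subset < 1L) || any(subset > graph$n_torsions)))
    stop("subset contains unknown torsion indices")
  keep <- setdiff(seq_len(graph$n_torsions), subset)
  # union-find over bodies through the kept (contracted) edges
  parent <- seq_len(graph$n_bodies)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in keep) {
    ra <- find(graph$edges$body_from[i]); rb <- find(graph$edges$body_to[i])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(graph$n_bodies), find, integer(1))
  comp <- match(roots, unique(roots))
  edges <- data.frame(torsion = subset,
                      comp_a = comp[graph$edges$body_from[subset]],
                      comp_b = comp[graph$edges$body_to[subset]])
  structure(list(n_vertices = length(unique(roots)), comp = comp, edges = edges),
            class = "contracted_graph")
}

#' Star-graph test
#'
#' A star is a tree with at most one vertex of degree greater than one
#' (this includes a single vertex, a single edge, and `K_{1,k}`). Errors on
#' non-tree input.
#'
#' @param graph a `contracted_graph` (from [contract_complement()]), or any
#'   list with fields `n_vertices` and `edges` (`comp_a`, `comp_b`).
#' @return `TRUE` or `FALSE`.
#' @export
is_star <- function(graph) {
  nv <- graph$n_vertices
  ne <- nrow(graph$edges)
  if (ne != nv - 1L) stop("input graph is not a tree (edge count != vertex count - 1)")
  if (ne > 0L) {
    # connectivity check via union-find
    parent <- seq_len(nv)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (r in seq_len(ne)) {
      ra <- find(graph$edges$comp_a[r]); rb <- find(graph$edges$comp_b[r])
      if (ra == rb) stop("input graph is not a tree (cycle detected)")
      parent[ra] <- rb
    }
  }
  deg <- tabulate(c(graph$edges$comp_a, graph$edges$comp_b), nbins = nv)
  sum(deg > 1L) <= 1L
}

#' 2-torsion-dependency test
#'
#' A torsion subset is 2-torsion dependent when contracting all other
#' torsion edges yields a star graph: any two super-bodies are then
#' separated by at most two of the selected torsions, so all cross-body
#' interaction terms are at most quadratic in the selected angles and the
#' restricted energy minimization maps exactly onto a QUBO problem.
#'
#' @inheritParams contract_complement
#' @return `TRUE` or `FALSE`.
#' @export
is_two_torsion_dependent <- function(graph, subset) {
  is_star(contract_complement(graph, subset))
}

#' Enumerate maximal 2-torsion-dependent torsion subsets
#'
#' Every 2-torsion-dependent subset is the edge boundary `delta(C)` of a
#' connected set `C` of rigid bodies (the star centre); this enumerates all
#' connected vertex sets of the rigid-body tree, collects their distinct
#' edge boundaries, and keeps the inclusion-maximal ones. Results are
#' returned in sorted lexicographic order. Intended for graphs of modest
#' size; larger molecules should use [sample_neighbourhood()].
#'
#' @param graph a [partition_rigid_bodies()] result with at most
#'   `max_edges` torsion edges.
#' @param max_edges exhaustive-enumeration size guard (default 20).
#' @return List of sorted integer vectors of torsion indices.
#' @export
enumerate_maximal_subsets <- function(graph, max_edges = 20L) {
  stopifnot(inherits(graph, "rigid_body_graph"))
  M <- graph$n_torsions
  if (M > max_edges)
    stop("too many torsion edges for exhaustive enumeration; use sample_neighbourhood()")
  if (M == 0L) return(list())
  nb <- graph$n_bodies
  # adjacency: body -> (neighbour body, torsion)
  adj <- vector("list", nb)
  for (i in seq_len(M)) {
    a <- graph$edges$body_from[i]; b <- graph$edges$body_to[i]
    adj[[a]] <- rbind(adj[[a]], c(b, i))
    adj[[b]] <- rbind(adj[[b]], c(a, i))
  }
  boundaries <- new.env(parent = emptyenv())
  # enumerate connected vertex sets whose minimum vertex is v, growing only
  # through vertices > v; record each set's edge boundary
  for (v in seq_len(nb)) {
    seen <- new.env(parent = emptyenv())
    stack <- list(sort(v))
    while (length(stack)) {
      members <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      mkey <- paste(members, collapse = ",")
      if (!is.null(seen[[mkey]])) next
      seen[[mkey]] <- TRUE
      be <- boundary_edges(members, adj)
      if (length(be)) {
        bkey <- paste(be, collapse = ",")
        if (is.null(boundaries[[bkey]])) boundaries[[bkey]] <- be
      }
      nbrs <- unique(unlist(lapply(members, function(b)
        if (is.null(adj[[b]])) integer(0) else adj[[b]][, 1])))
      for (w in setdiff(nbrs[nbrs > v], members))
        stack[[length(stack) + 1L]] <- sort(c(members, w))
    }
  }
  subsets <- as.list(boundaries)
  subsets <- unname(subsets[vapply(subsets, length, integer(1)) > 0L])
  # keep inclusion-maximal boundaries; scan in decreasing size order
  ord <- order(vapply(subsets, length, integer(1)), decreasing = TRUE)
  subsets <- subsets[ord]
  maximal <- list()
  for (s in subsets) {
    contained <- any(vapply(maximal, function(mx) all(s %in% mx), logical(1)))
    if (!contained) maximal[[length(maximal) + 1L]] <- s
  }
  keys <- vapply(maximal, function(s) paste(sprintf("%06d", s), collapse = ","), character(1))
  maximal[order(keys)]
}

# sorted torsion indices with exactly one endpoint in `members`
boundary_edges <- function(members, adj) {
  inside <- members
  out <- integer(0)
  for (b in inside) {
    nb <- adj[[b]]
    if (is.null(nb)) next
    sel <- !(nb[, 1] %in% inside)
    out <- c(out, nb[sel, 2])
  }
  sort(unique(out))
}

#' Neighbour relation under a torsion subset
#'
#' Two torsion vectors are neighbours under the neighbourhood structure of
#' subset `subset` when they differ (modulo `2*pi`) only in the angles of
#' torsions in the subset.
#'
#' @param t,t_prime torsion vectors (radians), equal length.
#' @param subset integer vector of torsion indices.
#' @param tol angle comparison tolerance (radians).
#' @return `TRUE` or `FALSE`.
#' @export
is_neighbour <- function(t, t_prime, subset, tol = 1e-9) {
  stopifnot(length(t) == length(t_prime))
  outside <- setdiff(seq_along(t), subset)
  diffs <- (t[outside] - t_prime[outside]) %% (2 * pi)
  all(pmin(diffs, 2 * pi - diffs) <= tol)
}

#' Sample a budgeted neighbourhood specification
#'
#' Grows a 2-torsion-dependent torsion subset greedily along a random
#' torsion ordering `phi`, starting from position `start_pos`: subsequent
#' torsions in `phi`-order are added while the subset stays 2-torsion
#' dependent and its cardinality stays within `floor(s/2)` (each torsion
#' needs at least two angle values to be meaningful). Angle subsets
#' `Theta_i` are then drawn from the grid, as equal in size as possible
#' under the total variable budget `sum |Theta_i| <= s`, each always
#' containing the incumbent angle `t_i` so that the incumbent belongs to
#' its own neighbourhood (guaranteeing descent); the remaining values are
#' drawn uniformly without replacement. Uses R's RNG; seed upstream for
#' reproducibility.
#'
#' @param graph a [partition_rigid_bodies()] result.
#' @param phi integer permutation of `1:M` (the random torsion ordering).
#' @param start_pos position in `phi` of the first torsion of the subset.
#' @param t incumbent torsion vector; every entry must be a grid value.
#' @param grid an [angle_grid()].
#' @param s variable budget (>= 2).
#' @return An object of class `neighbourhood_spec`: `torsions` (sorted
#'   subset), `angles` (per torsion, sorted angle values), `angle_idx`
#'   (grid indices), `incumbent` (per torsion, incumbent angle), `s_budget`,
#'   `s_used`, `size` (`prod |Theta_i|`).
#' @export
sample_neighbourhood <- function(graph, phi, start_pos, t, grid, s) {
  stopifnot(inherits(graph, "rigid_body_graph"), inherits(grid, "angle_grid"))
  M <- graph$n_torsions
  if (s < 2) stop("budget s must be at least 2")
  if (length(phi) != M || !setequal(phi, seq_len(M))) stop("phi must be a permutation of 1:M")
  if (start_pos < 1L || start_pos > M) stop("start_pos out of range")
  max_card <- max(1L, floor(s / 2))
  subset <- phi[start_pos]
  if (start_pos < M) for (q in (start_pos + 1L):M) {
    if (length(subset) >= max_card) break
    cand <- c(subset, phi[q])
    if (is_two_torsion_dependent(graph, cand)) subset <- cand
  }
  subset <- sort(subset)
  m <- length(subset)
  # near-equal split of the budget, capped at d
  sizes <- rep(floor(s / m), m)
  extra <- s - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes <- pmin(sizes, grid$d)
  angles <- vector("list", m)
  angle_idx <- vector("list", m)
  incumbent <- numeric(m)
  for (q in seq_len(m)) {
    ti <- t[subset[q]]
    k0 <- match_grid_index(ti, grid)
    if (is.na(k0)) stop("incumbent torsion angle is not a grid value")
    others <- setdiff(seq_len(grid$d), k0)
    extra_k <- if (sizes[q] > 1L) sample_vec(others, sizes[q] - 1L) else integer(0)
    idx <- sort(c(k0, extra_k))
    angle_idx[[q]] <- idx
    angles[[q]] <- grid$values[idx]
    incumbent[q] <- ti
  }
  structure(list(torsions = subset, angles = angles, angle_idx = angle_idx,
                 incumbent = incumbent, s_budget = s, s_used = sum(sizes),
                 size = prod(sizes)),
            class = "neighbourhood_spec")
}

# sample() without its scalar-x surprise
sample_vec <- function(x, size) x[sample.int(length(x), size)]

match_grid_index <- function(angle, grid, tol = 1e-9) {
  a <- angle %% (2 * pi)
  d <- abs(grid$values - a)
  d <- pmin(d, 2 * pi - d)
  k <- which.min(d)
  if (d[k] <= tol) k else NA_integer_
}

#' Number of solutions in a neighbourhood
#'
#' `S_k = prod |Theta_i|`. For a fixed budget `s` the product is maximized
#' by the equal split `|Theta_i| = s / |T_k|`, giving `(s/|T_k|)^{|T_k|}`.
#'
#' @param spec a `neighbourhood_spec`.
#' @return Integer count.
#' @export
neighbourhood_size <- function(spec) {
  stopifnot(inherits(spec, "neighbourhood_spec"))
  prod(vapply(spec$angles, length, integer(1)))
}

#' @export
print.neighbourhood_spec <- function(x, ...) {
  cat(sprintf("<neighbourhood_spec> torsions {%s}, |Theta| = %s, S_k = %d (budget s = %d)\n",
              paste(x$torsions, collapse = ", "),
              paste(vapply(x$angles, length, integer(1)), collapse = ", "),
              neighbourhood_size(x), x$s_budget))
  invisible(x)
}
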