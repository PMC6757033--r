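#' Molecular system with designated rotatable bonds
#'
#' Bundles a reference geometry (Cartesian coordinates in Angstroms), a bond
#' list, and an ordered set of rotatable (torsion) bonds. The bond graph must
#' be connected and every torsion bond must be a bridge of the bond graph
#' (i.e. not part of any ring), so that the induced rigid-body graph is a
#' tree.
#'
#' @param elements character vector of element symbols, one per atom.
#' @param coords numeric matrix, `n x 3`, reference Cartesian positions (Å).
#' @param bonds integer matrix with two columns; each row is an unordered
#'   bonded atom pair (1-based indices).
#' @param torsion_bonds integer matrix with two columns; ordered list of the
#'   `M` rotatable bonds. Each row must also appear in `bonds`.
#' @param name optional molecule label.
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(elements, coords, bonds, torsion_bonds, name = "molecule") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(elements)
  if (nrow(coords) != n || ncol(coords) != 3)
    stop("coords must be an n x 3 matrix matching length(elements)")
  bonds <- matrix(as.integer(bonds), ncol = 2)
  torsion_bonds <- matrix(as.integer(torsion_bonds), ncol = 2)
  if (any(bonds < 1L) || any(bonds > n)) stop("bond indices out of range")
  bkey <- bond_keys(bonds)
  if (anyDuplicated(bkey)) stop("duplicate bonds")
  tkey <- bond_keys(torsion_bonds)
  if (anyDuplicated(tkey)) stop("torsion bonds must be distinct")
  if (!all(tkey %in% bkey)) stop("every torsion bond must be a bond")
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  if (igraph::components(g)$no != 1L) stop("bond graph must be connected")
  br <- igraph::bridges(g)
  bridge_keys <- bond_keys(igraph::as_edgelist(g)[as.integer(br), , drop = FALSE])
  if (!all(tkey %in% bridge_keys))
    stop("ring torsion: every torsion bond must be a bridge of the bond graph")
  structure(
    list(elements = elements, coords = coords, bonds = bonds,
         torsion_bonds = torsion_bonds, n_atoms = n,
         n_torsions = nrow(torsion_bonds), name = name),
    class = "molecular_system")
}

# canonical "a-b" key with a < b for unordered bond pairs
bond_keys <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]), sep = "-")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("<molecular_system> %s: %d atoms, %d bonds, %d torsions\n",
              x$name, x$n_atoms, nrow(x$bonds), x$n_torsions))
  invisible(x)
}

#' Partition a molecule into rigid bodies
#'
#' Removing the `M` torsion bonds from the bond graph leaves `M + 1`
#' connected components, the rigid bodies: atom sets whose internal geometry
#' is invariant under every torsion rotation. The rigid-body graph has one
#' vertex per body and one edge per torsion, and is always a tree. The tree
#' is rooted at the body containing atom 1, and every edge is oriented from
#' its proximal (root-side) atom to its distal atom.
#'
#' @param system a [molecular_system()].
#' @return An object of class `rigid_body_graph` with components:
#'   `bodies` (list of atom-index vectors), `body_of` (atom -> body id),
#'   `edges` (data frame: `torsion`, `body_from`, `body_to`, `atom_from`,
#'   `atom_to`, with `body_from` proximal), `root`, `parent` (body-level
#'   parent pointers), `parent_edge`, `edge_order` (root-out processing
#'   order), and `subtree_atoms` (per torsion, the distal atom set).
#' @export
partition_rigid_bodies <- function(system) {
  stopifnot(inherits(system, "molecular_system"))
  n <- system$n_atoms
  M <- system$n_torsions
  tkey <- bond_keys(system$torsion_bonds)
  keep <- !(bond_keys(system$bonds) %in% tkey)
  g <- igraph::graph_from_edgelist(system$bonds[keep, , drop = FALSE], directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)
  if (comp$no != M + 1L)
    stop("ring torsion: expected M+1 rigid bodies after removing torsion bonds")
  body_of <- as.integer(comp$membership)
  bodies <- split(seq_len(n), body_of)
  root <- body_of[1L]

  # body-level tree: one edge per torsion
  eb <- cbind(body_of[system$torsion_bonds[, 1]], body_of[system$torsion_bonds[, 2]])
  adj <- vector("list", M + 1L)
  for (i in seq_len(M)) {
    adj[[eb[i, 1]]] <- rbind(adj[[eb[i, 1]]], c(eb[i, 2], i))
    adj[[eb[i, 2]]] <- rbind(adj[[eb[i, 2]]], c(eb[i, 1], i))
  }
  parent <- rep(NA_integer_, M + 1L)
  parent_edge <- rep(NA_integer_, M + 1L)
  depth <- rep(NA_integer_, M + 1L)
  order_bodies <- integer(0)
  queue <- root; depth[root] <- 0L; visited <- rep(FALSE, M + 1L); visited[root] <- TRUE
  while (length(queue)) {
    b <- queue[1L]; queue <- queue[-1L]
    order_bodies <- c(order_bodies, b)
    nb <- adj[[b]]
    if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
      ch <- nb[r, 1]
      if (!visited[ch]) {
        visited[ch] <- TRUE
        parent[ch] <- b; parent_edge[ch] <- nb[r, 2]; depth[ch] <- depth[b] + 1L
        queue <- c(queue, ch)
      }
    }
  }
  if (!all(visited)) stop("rigid-body graph is not connected")

  # orient each torsion edge proximal -> distal
  edges <- data.frame(torsion = seq_len(M), body_from = NA_integer_,
                      body_to = NA_integer_, atom_from = NA_integer_,
                      atom_to = NA_integer_)
  for (i in seq_len(M)) {
    a1 <- system$torsion_bonds[i, 1]; a2 <- system$torsion_bonds[i, 2]
    b1 <- body_of[a1]; b2 <- body_of[a2]
    if (!is.na(parent[b2]) && parent[b2] == b1) {
      edges[i, 2:5] <- c(b1, b2, a1, a2)
    } else if (!is.na(parent[b1]) && parent[b1] == b2) {
      edges[i, 2:5] <- c(b2, b1, a2, a1)
    } else stop("internal error: torsion edge not in BFS tree")
  }

  # distal atom sets: atoms of all bodies in the subtree below each edge
  children <- split(seq_len(M + 1L)[!is.na(parent)], parent[!is.na(parent)])
  subtree_bodies <- function(b) {
    out <- b; stack <- b
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      ch <- children[[as.character(cur)]]
      if (!is.null(ch)) { out <- c(out, ch); stack <- c(stack, ch) }
    }
    out
  }
  subtree_atoms <- lapply(seq_len(M), function(i)
    sort(unlist(bodies[subtree_bodies(edges$body_to[i])], use.names = FALSE)))
  edge_order <- order(depth[edges$body_to])

  structure(
    list(bodies = bodies, body_of = body_of, edges = edges, root = root,
         parent = parent, parent_edge = parent_edge, depth = depth,
         n_bodies = M + 1L, n_torsions = M,
         subtree_atoms = subtree_atoms, edge_order = edge_order),
    class = "rigid_body_graph")
}

#' @export
print.rigid_body_graph <- function(x, ...) {
  cat(sprintf("<rigid_body_graph> %d bodies, %d torsion edges, root body %d\n",
              x$n_bodies, x$n_torsions, x$root))
  invisible(x)
}

#' Torsions on the tree path between two rigid bodies
#'
#' Returns the torsion indices along the unique path connecting body `a` to
#' body `b` in the rigid-body tree, in path order from `a` to `b`. The
#' relative geometry of bodies `a` and `b` depends on exactly these torsion
#' angles.
#'
#' @param graph a [partition_rigid_bodies()] result.
#' @param a,b body ids.
#' @return Integer vector of torsion indices (empty when `a == b`).
#' @export
path_torsions <- function(graph, a, b) {
  stopifnot(inherits(graph, "rigid_body_graph"))
  nb <- graph$n_bodies
  if (!(a %in% seq_len(nb)) || !(b %in% seq_len(nb))) stop("unknown body id")
  if (a == b) return(integer(0))
  # walk both ends up to the lowest common ancestor
  up_a <- integer(0); up_b <- integer(0)
  xa <- a; xb <- b
  while (graph$depth[xa] > graph$depth[xb]) { up_a <- c(up_a, graph$parent_edge[xa]); xa <- graph$parent[xa] }
  while (graph$depth[xb] > graph$depth[xa]) { up_b <- c(up_b, graph$parent_edge[xb]); xb <- graph$parent[xb] }
  while (xa != xb) {
    up_a <- c(up_a, graph$parent_edge[xa]); xa <- graph$parent[xa]
    up_b <- c(up_b, graph$parent_edge[xb]); xb <- graph$parent[xb]
  }
  c(up_a, rev(up_b))
}

#' Uniform torsion-angle grid
#'
#' The discretization Theta of the torsion circle: `d` angles in
#' `[0, 2*pi)`, by default equally spaced starting at 0. Torsion angles are
#' offsets relative to the reference geometry, so angle 0 always reproduces
#' the reference.
#'
#' @param d number of grid values (>= 1).
#' @param values optional explicit angles (radians, strictly increasing,
#'   all in `[0, 2*pi)`); default `2*pi*(0:(d-1))/d`.
#' @return An object of class `angle_grid` with fields `d` and `values`.
#' @export
angle_grid <- function(d, values = NULL) {
  d <- as.integer(d)
  if (d < 1L) stop("d must be a positive integer")
  if (is.null(values)) values <- 2 * pi * (seq_len(d) - 1L) / d
  if (length(values) != d) stop("length(values) must equal d")
  if (any(values < 0 | values >= 2 * pi)) stop("grid angles must lie in [0, 2*pi)")
  if (d > 1L && any(diff(values) <= 0)) stop("grid angles must be strictly increasing")
  structure(list(d = d, values = as.numeric(values)), class = "angle_grid")
}

#' @export
print.angle_grid <- function(x, ...) {
  cat(sprintf("<angle_grid> d = %d: %s deg\n", x$d,
              paste(round(x$values * 180 / pi, 2), collapse = ", ")))
  invisible(x)
}

# Rodrigues rotation of point rows X about the axis through `origin` with
# unit direction `u`, by angle theta (right-handed).
rotate_about_axis <- function(X, origin, u, theta) {
  ct <- cos(theta); st <- sin(theta)
  V <- sweep(X, 2, origin)
  dotu <- as.vector(V %*% u)
  cross <- cbind(u[2] * V[, 3] - u[3] * V[, 2],
                 u[3] * V[, 1] - u[1] * V[, 3],
                 u[1] * V[, 2] - u[2] * V[, 1])
  Vr <- V * ct + cross * st + outer(dotu * (1 - ct), u)
  sweep(Vr, 2, origin, `+`)
}

#' Cartesian coordinates for a torsion vector
#'
#' Reconstructs atom positions from the reference geometry and a vector of
#' torsion offsets. The root body stays at its reference position; for each
#' torsion, processed from the root outward, the whole distal subtree is
#' rotated right-handedly about the bond axis oriented from the proximal to
#' the distal bond atom. `t = 0` reproduces the reference geometry exactly,
#' and all intra-body distances are preserved for every `t`.
#'
#' @param system a [molecular_system()].
#' @param graph the matching [partition_rigid_bodies()] result.
#' @param t numeric torsion vector of length `M` (radians).
#' @return `n x 3` coordinate matrix (Å).
#' @export
build_coordinates <- function(system, graph, t) {
  stopifnot(inherits(system, "molecular_system"), inherits(graph, "rigid_body_graph"))
  if (length(t) != graph$n_torsions)
    stop("torsion vector has wrong length")
  X <- system$coords
  for (i in graph$edge_order) {
    th <- t[i]
    if (th == 0) next
    p <- X[graph$edges$atom_from[i], ]
    q <- X[graph$edges$atom_to[i], ]
    u <- q - p
    u <- u / sqrt(sum(u * u))
    idx <- graph$subtree_atoms[[i]]
    X[idx, ] <- rotate_about_axis(X[idx, , drop = FALSE], p, u, th)
  }
  X
}
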