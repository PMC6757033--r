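# Synthetic molecule generators: desk-scale systems with the chain and star
# rigid-body topologies the search methods are benchmarked on, built from
# idealized geometry (C-C 1.54 A, C-H 1.09 A, tetrahedral angles).

CC_BOND <- 1.54
CH_BOND <- 1.09
TET_COS <- -1 / 3  # cos(109.4712 deg)

unit <- function(v) v / sqrt(sum(v * v))
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

perp_basis <- function(e) {
  ref <- if (abs(e[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  p1 <- unit(cross3(ref, e))
  list(p1 = p1, p2 = cross3(e, p1))
}

# complete every carbon to 4 bonds with hydrogens placed tetrahedrally
add_hydrogens <- function(elements, coords, bonds) {
  n_heavy <- length(elements)
  adj <- vector("list", n_heavy)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds[r, 1]]] <- c(adj[[bonds[r, 1]]], bonds[r, 2])
    adj[[bonds[r, 2]]] <- c(adj[[bonds[r, 2]]], bonds[r, 1])
  }
  h_coords <- NULL
  h_bonds <- NULL
  sin_tet <- sqrt(1 - TET_COS^2)     # component perpendicular to the axis
  half <- acos(TET_COS) / 2          # half the H-C-H angle
  for (a in seq_len(n_heavy)) {
    if (elements[a] != "C") next
    nbrs <- adj[[a]]
    k <- length(nbrs)
    if (k >= 4L) next
    dirs <- NULL
    if (k == 1L) {
      e <- unit(coords[nbrs[1], ] - coords[a, ])
      pb <- perp_basis(e)
      for (alpha in c(0, 2 * pi / 3, 4 * pi / 3))
        dirs <- rbind(dirs, TET_COS * e +
                        sin_tet * (cos(alpha) * pb$p1 + sin(alpha) * pb$p2))
    } else if (k == 2L) {
      e1 <- unit(coords[nbrs[1], ] - coords[a, ])
      e2 <- unit(coords[nbrs[2], ] - coords[a, ])
      bis <- unit(e1 + e2)
      nrm <- unit(cross3(e1, e2))
      dirs <- rbind(-cos(half) * bis + sin(half) * nrm,
                    -cos(half) * bis - sin(half) * nrm)
    } else if (k == 3L) {
      e1 <- unit(coords[nbrs[1], ] - coords[a, ])
      e2 <- unit(coords[nbrs[2], ] - coords[a, ])
      e3 <- unit(coords[nbrs[3], ] - coords[a, ])
      dirs <- rbind(-unit(e1 + e2 + e3))
    }
    for (r in seq_len(nrow(dirs))) {
      h_coords <- rbind(h_coords, coords[a, ] + CH_BOND * dirs[r, ])
      h_bonds <- rbind(h_bonds, c(a, n_heavy + NROW(h_coords)))
    }
  }
  list(elements = c(elements, rep("H", NROW(h_coords))),
       coords = rbind(coords, h_coords),
       bonds = rbind(bonds, h_bonds))
}

#' Idealized all-atom n-alkane
#'
#' Builds CH3-(CH2)-...-CH3 with idealized geometry (C-C 1.54 Å, C-H
#' 1.09 Å, tetrahedral angles) in the all-anti backbone conformation, which
#' serves as the reference geometry. Rotatable bonds are the internal C-C
#' bonds excluding the two terminal ones (terminal methyl rotors are
#' excluded), giving `M = n_carbons - 3` torsions and a path-shaped
#' rigid-body graph.
#'
#' @param n_carbons chain length (>= 4).
#' @return A [molecular_system()].
#' @export
make_alkane <- function(n_carbons) {
  n_carbons <- as.integer(n_carbons)
  if (n_carbons < 4L) stop("n_carbons must be at least 4")
  dx <- CC_BOND * sqrt(2 / 3)
  dy <- CC_BOND / sqrt(3)
  coords <- cbind((seq_len(n_carbons) - 1L) * dx,
                  (seq_len(n_carbons) %% 2L) * dy,
                  0)
  elements <- rep("C", n_carbons)
  bonds <- cbind(seq_len(n_carbons - 1L), 2:n_carbons)
  full <- add_hydrogens(elements, coords, bonds)
  torsion <- cbind(2:(n_carbons - 2L), 3:(n_carbons - 1L))
  molecular_system(full$elements, full$coords, full$bonds, torsion,
                   name = sprintf("n-alkane C%d", n_carbons))
}

# evenly spread unit vectors: tetrahedral directions for <= 4 arms,
# golden-spiral points otherwise
arm_directions <- function(n_arms) {
  if (n_arms <= 4L) {
    tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    return(tet[seq_len(n_arms), , drop = FALSE])
  }
  k <- seq_len(n_arms)
  z <- 1 - (2 * k - 1) / n_arms
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (k - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Star-branched synthetic molecule
#'
#' A central carbon with `n_arms` alkane-like arms; the rotatable bonds
#' are the centre-arm bonds, so the rigid-body graph is a star with a
#' degree-`n_arms` hub and the hub's incident edges form a single maximal
#' 2-torsion-dependent set of size `n_arms`. A topology stand-in for
#' star-like molecules whose pairwise arm interactions create multi-torsion
#' energy traps. Hypervalent centres (`n_arms > 4`) are allowed; the
#' generator aims for topology, not chemical realizability.
#'
#' @param n_arms number of arms (>= 3; use [make_alkane()] for chains).
#' @param arm_length carbons per arm (>= 1).
#' @return A [molecular_system()].
#' @export
make_star_molecule <- function(n_arms, arm_length = 2) {
  n_arms <- as.integer(n_arms); arm_length <- as.integer(arm_length)
  if (n_arms < 3L) stop("n_arms must be at least 3 (a 2-arm star is a chain; use make_alkane)")
  if (arm_length < 1L) stop("arm_length must be at least 1")
  a <- acos(sqrt(1 / 3))  # tilt giving tetrahedral angles along the arm
  dirs <- arm_directions(n_arms)
  coords <- matrix(0, 1, 3)
  elements <- "C"
  bonds <- NULL
  for (arm in seq_len(n_arms)) {
    u <- dirs[arm, ]
    pb <- perp_basis(u)
    vplus <- cos(a) * u + sin(a) * pb$p1
    vminus <- cos(a) * u - sin(a) * pb$p1
    prev <- 1L
    pos <- coords[1L, ]
    for (k in seq_len(arm_length)) {
      v <- if (k %% 2L == 1L) vplus else vminus
      pos <- pos + CC_BOND * v
      coords <- rbind(coords, pos)
      elements <- c(elements, "C")
      cur <- nrow(coords)
      bonds <- rbind(bonds, c(prev, cur))
      prev <- cur
    }
  }
  full <- add_hydrogens(elements, coords, bonds)
  arm_first <- 1L + (seq_len(n_arms) - 1L) * arm_length + 1L
  torsion <- cbind(1L, arm_first)
  molecular_system(full$elements, full$coords, full$bonds, torsion,
                   name = sprintf("star %d x C%d", n_arms, arm_length))
}

#' Analytic two-body toy with one torsion
#'
#' Two CH fragments joined by a single rotatable C-C bond: the only
#' included nonbonded pair is H...H (a 1-4 pair), so the exact energy
#' landscape over the angle grid has a closed form, computed here directly
#' from the rotated H-H distance without going through the coordinate
#' builder. Used as an independent oracle for the search methods.
#'
#' @param d grid resolution (>= 2).
#' @param params force-field table (default [uff_params()]).
#' @return List with `system` (a [molecular_system()]), `grid`
#'   ([angle_grid()]), and `landscape` (energy at each grid angle,
#'   kcal/mol).
#' @export
make_two_body_toy <- function(d, params = uff_params()) {
  if (d < 2) stop("d must be at least 2")
  sin_tet <- sqrt(1 - TET_COS^2)
  c1 <- c(0, 0, 0); c2 <- c(CC_BOND, 0, 0)
  h1 <- c1 + CH_BOND * c(TET_COS, sin_tet, 0)
  h2 <- c2 + CH_BOND * c(-TET_COS, sin_tet, 0)
  system <- molecular_system(
    c("C", "C", "H", "H"),
    rbind(c1, c2, h1, h2),
    bonds = rbind(c(1, 2), c(1, 3), c(2, 4)),
    torsion_bonds = matrix(c(1, 2), 1),
    name = sprintf("two-body toy d=%d", d))
  grid <- angle_grid(d)
  pp <- combine_params("H", "H", params)
  # rotate H2 about the x-axis (the C1-C2 bond): closed-form H-H distance
  landscape <- vapply(grid$values, function(th) {
    h2r <- c(h2[1], h2[2] * cos(th), h2[2] * sin(th))
    lj_pair(pp[["eps"]], pp[["sigma"]], sqrt(sum((h2r - h1)^2)))
  }, numeric(1))
  list(system = system, grid = grid, landscape = landscape)
}
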