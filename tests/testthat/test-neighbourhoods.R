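test_that("contracting the complement merges bodies as expected", {
  g <- partition_rigid_bodies(make_alkane(6))  # 3-edge path
  # all edges selected: graph unchanged
  cg <- contract_complement(g, 1:3)
  expect_equal(cg$n_vertices, 4)
  expect_equal(nrow(cg$edges), 3)
  # empty subset: everything contracts to one vertex
  cg0 <- contract_complement(g, integer(0))
  expect_equal(cg0$n_vertices, 1)
  expect_equal(nrow(cg0$edges), 0)
  # a k-edge subset always leaves k+1 super-bodies
  cg2 <- contract_complement(g, c(1, 3))
  expect_equal(cg2$n_vertices, 3)
  expect_error(contract_complement(g, 99), "unknown torsion")
})

test_that("the star test accepts single edges and hubs, rejects long paths", {
  g3 <- partition_rigid_bodies(make_alkane(6))
  expect_true(is_star(contract_complement(g3, 1L)))          # single edge
  expect_false(is_star(contract_complement(g3, 1:3)))        # 3-edge path
  star <- partition_rigid_bodies(make_star_molecule(4, 1))   # K_{1,4}
  expect_true(is_star(contract_complement(star, 1:4)))
  bad <- list(n_vertices = 3,
              edges = data.frame(torsion = 1:3, comp_a = c(1, 2, 3),
                                 comp_b = c(2, 3, 1)))
  expect_error(is_star(bad), "not a tree")
})

test_that("2-torsion dependency on the 3-edge path matches the worked pattern", {
  g <- partition_rigid_bodies(make_alkane(6))
  expect_true(is_two_torsion_dependent(g, c(1, 3)))
  expect_true(is_two_torsion_dependent(g, c(1, 2)))
  expect_true(is_two_torsion_dependent(g, c(2, 3)))
  expect_false(is_two_torsion_dependent(g, 1:3))
  for (i in 1:3) expect_true(is_two_torsion_dependent(g, i))
})

test_that("maximal subset enumeration agrees with subset brute force on small trees", {
  # paths of increasing length
  for (n in 5:9) {
    g <- partition_rigid_bodies(make_alkane(n))
    got <- enumerate_maximal_subsets(g)
    expect_identical(got, brute_force_maximal_subsets(g))
    M <- g$n_torsions
    if (M >= 2) expect_length(got, choose(M, 2))  # all unordered pairs
  }
  # stars: one maximal set containing every hub edge
  for (k in 3:5) {
    g <- partition_rigid_bodies(make_star_molecule(k, 1))
    got <- enumerate_maximal_subsets(g)
    expect_identical(got, brute_force_maximal_subsets(g))
    expect_length(got, 1)
    expect_equal(got[[1]], seq_len(k))
  }
  # a branched tree: star with longer arms mixes hub and in-arm edges
  sys <- make_star_molecule(3, 2)
  extra <- rbind(sys$torsion_bonds,
                 cbind(sys$torsion_bonds[, 2], sys$torsion_bonds[, 2] + 1L))
  sys2 <- molecular_system(sys$elements, sys$coords, sys$bonds, extra,
                           name = "branched")
  g2 <- partition_rigid_bodies(sys2)
  expect_identical(enumerate_maximal_subsets(g2), brute_force_maximal_subsets(g2))
})

test_that("the neighbour relation compares angles only outside the subset", {
  deg <- pi / 180
  t <- c(5, 10, 20) * deg
  expect_true(is_neighbour(t, c(0, 10, 90) * deg, c(1, 3)))
  expect_false(is_neighbour(t, c(5, 15, 20) * deg, c(1, 3)))
  # modulo-2*pi comparison outside the subset
  expect_true(is_neighbour(t, c(5, 10 + 360, 90) * deg, c(1, 3)))
})

test_that("sampled neighbourhoods are valid, budgeted, and contain the incumbent", {
  sys <- make_alkane(9)
  g <- partition_rigid_bodies(sys)
  grid <- angle_grid(8)
  set.seed(5)
  for (rep in 1:25) {
    t <- grid$values[sample.int(8, g$n_torsions, replace = TRUE)]
    phi <- sample.int(g$n_torsions)
    s <- sample(4:12, 1)
    spec <- sample_neighbourhood(g, phi, sample.int(g$n_torsions, 1), t, grid, s)
    expect_true(is_two_torsion_dependent(g, spec$torsions))
    expect_lte(spec$s_used, s)
    expect_lte(length(spec$torsions), max(1, floor(s / 2)))
    for (q in seq_along(spec$torsions)) {
      expect_true(any(abs(spec$angles[[q]] - t[spec$torsions[q]]) < 1e-12))
      expect_false(is.unsorted(spec$angle_idx[[q]], strictly = TRUE))
    }
    expect_equal(neighbourhood_size(spec),
                 prod(lengths(spec$angles)))
  }
})

test_that("single-torsion molecules get the whole budget on one torsion", {
  g <- partition_rigid_bodies(make_alkane(4))
  grid <- angle_grid(6)
  set.seed(1)
  spec <- sample_neighbourhood(g, 1L, 1L, 0, grid, 4)
  expect_equal(spec$torsions, 1L)
  expect_length(spec$angles[[1]], 4)
  # budget beyond d is capped at d
  spec2 <- sample_neighbourhood(g, 1L, 1L, 0, grid, 20)
  expect_length(spec2$angles[[1]], 6)
})

test_that("the equal split maximizes the neighbourhood size over all compositions", {
  # exhaustive over integer compositions of s into m positive parts
  compositions <- function(s, m) {
    if (m == 1) return(matrix(s, 1, 1))
    out <- NULL
    for (first in 1:(s - m + 1)) {
      rest <- compositions(s - first, m - 1)
      out <- rbind(out, cbind(first, rest))
    }
    out
  }
  for (s in c(6, 9, 17, 30)) for (m in 2:4) {
    if (s < m) next
    comp <- compositions(s, m)
    best <- max(apply(comp, 1, prod))
    sizes <- rep(floor(s / m), m)
    extra <- s - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    expect_equal(prod(sizes), best)
    if (s %% m == 0) expect_equal(best, (s / m)^m)  # the closed-form maximum
  }
})
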