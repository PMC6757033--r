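test_that("the pair potential has its well at sigma and crosses zero at sigma/2^(1/6)", {
  eps <- 0.105; sigma <- 3.851
  expect_equal(lj_pair(eps, sigma, sigma), -eps)
  expect_equal(lj_pair(eps, sigma, sigma * 2^(-1 / 6)), 0, tolerance = 1e-12)
  r <- seq(sigma, 5 * sigma, length.out = 200)
  v <- lj_pair(eps, sigma, r)
  expect_true(all(diff(v) > 0))          # monotone rise past the well
  expect_true(all(v <= 0))               # from below
  expect_lt(abs(lj_pair(eps, sigma, 50 * sigma)), 1e-9)
  expect_error(lj_pair(eps, sigma, 0), "positive")
})

test_that("geometric-mean combination and unknown-element errors", {
  params <- uff_params()
  same <- combine_params("C", "C", params)
  expect_equal(unname(same["eps"]), params$eps[["C"]])
  expect_equal(unname(same["sigma"]), params$sigma[["C"]])
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("element\teps\tsigma", "A\t0.1\t2.0", "B\t0.4\t4.5"), tmp)
  tab <- read_ff_table(tmp)
  expect_equal(unname(combine_params("A", "B", tab)["eps"]), 0.2)
  expect_equal(unname(combine_params("A", "B", tab)["sigma"]), 3.0)
  expect_error(combine_params("Xx", "C", params), "supported")
})

test_that("total energy equals the flat all-pairs LJ sum with standard exclusions", {
  model <- hexane_model()
  sys <- model$system
  set.seed(11)
  for (rep in 1:5) {
    t <- runif(sys$n_torsions, 0, 2 * pi)
    coords <- build_coordinates(sys, model$graph, t)
    expect_equal(total_energy(model, t), flat_lj_energy(sys, coords),
                 tolerance = 1e-10)
  }
})

test_that("energy is invariant under whole-molecule rigid motion", {
  model <- hexane_model()
  t <- rep(pi / 3, model$graph$n_torsions)
  coords <- build_coordinates(model$system, model$graph, t)
  e0 <- vndconf:::energy_at_coords(model, coords)
  shifted <- sweep(coords, 2, c(3.2, -1.5, 0.7), `+`)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rotated <- coords %*% t(R)
  expect_equal(vndconf:::energy_at_coords(model, shifted), e0, tolerance = 1e-10)
  expect_equal(vndconf:::energy_at_coords(model, rotated), e0, tolerance = 1e-10)
})

test_that("rotating a leaf body changes only cross terms touching it", {
  model <- heptane_model()
  g <- model$graph
  M <- g$n_torsions
  t1 <- rep(0, M)
  t2 <- t1; t2[M] <- 2 * pi / 3   # rotate the last (leaf-side) torsion only
  c1 <- build_coordinates(model$system, g, t1)
  c2 <- build_coordinates(model$system, g, t2)
  moved <- g$subtree_atoms[[M]]
  for (a in seq_len(g$n_bodies - 1)) for (b in (a + 1):g$n_bodies) {
    e1 <- body_pair_energy(model, c1, g$bodies[[a]], g$bodies[[b]])
    e2 <- body_pair_energy(model, c2, g$bodies[[a]], g$bodies[[b]])
    touches <- any(g$bodies[[a]] %in% moved) != any(g$bodies[[b]] %in% moved)
    if (!touches) expect_identical(e1, e2)
  }
})

test_that("body pair energy matches a brute-force double loop and is symmetric", {
  model <- hexane_model()
  g <- model$graph
  set.seed(3)
  t <- runif(g$n_torsions, 0, 2 * pi)
  coords <- build_coordinates(model$system, g, t)
  params <- model$params
  sep <- igraph::distances(igraph::graph_from_edgelist(model$system$bonds,
                                                       directed = FALSE))
  for (a in 1:(g$n_bodies - 1)) for (b in (a + 1):g$n_bodies) {
    A <- g$bodies[[a]]; B <- g$bodies[[b]]
    direct <- 0
    for (i in A) for (j in B) {
      if (sep[i, j] < 3) next
      pp <- combine_params(model$system$elements[i], model$system$elements[j], params)
      direct <- direct + lj_pair(pp[["eps"]], pp[["sigma"]],
                                 sqrt(sum((coords[i, ] - coords[j, ])^2)))
    }
    expect_equal(body_pair_energy(model, coords, A, B), direct, tolerance = 1e-10)
    expect_equal(body_pair_energy(model, coords, B, A),
                 body_pair_energy(model, coords, A, B))
  }
  # adjacent bodies whose cross pairs are all bonded-excluded contribute zero
  tri <- molecular_system(c("C", "C", "C"),
                          rbind(c(0, 0, 0), c(1.54, 0, 0), c(2.3, 1.2, 0)),
                          bonds = rbind(c(1, 2), c(2, 3)),
                          torsion_bonds = matrix(c(1, 2), 1))
  gt <- partition_rigid_bodies(tri)
  mt <- energy_model(tri, gt)
  expect_identical(body_pair_energy(mt, tri$coords, gt$bodies[[1]], gt$bodies[[2]]), 0)
})

test_that("single-rigid-body energy is torsion-independent and the ledger counts calls", {
  led <- energy_ledger()
  model <- hexane_model()
  e1 <- total_energy(model, rep(0, 3), led)
  e2 <- total_energy(model, rep(1, 3), led)
  expect_equal(ledger_count(led), 2)
  expect_false(isTRUE(all.equal(e1, e2)))
  ledger_add(led, 5)
  expect_equal(ledger_count(led), 7)
})

test_that("neighbourhood coefficient pre-evaluation reconstructs the exact energy", {
  model <- heptane_model()
  g <- model$graph
  grid <- angle_grid(6)
  set.seed(21)
  t <- grid$values[sample.int(6, g$n_torsions, replace = TRUE)]
  spec <- manual_spec(c(1L, 3L), list(c(1L, 3L, 5L), c(2L, 4L, 6L, 1L)), grid, t)
  led <- energy_ledger()
  coeffs <- qubo_coefficients(model, spec, t, led)
  # ledger increment: sum_{i<j} |Theta_i||Theta_j| + s
  expect_equal(ledger_count(led), 3 * 4 + 7)
  # reconstruction at every neighbourhood grid point
  for (ki in 1:3) for (kj in 1:4) {
    tt <- t
    tt[1] <- spec$angles[[1]][ki]
    tt[3] <- spec$angles[[2]][kj]
    reconstructed <- coeffs$constant + coeffs$linear[[1]][ki] +
      coeffs$linear[[2]][kj] + coeffs$quadratic[[1]][ki, kj]
    expect_equal(reconstructed, total_energy(model, tt), tolerance = 1e-9)
  }
})

test_that("single-torsion neighbourhoods cost exactly s pre-evaluations", {
  model <- hexane_model()
  grid <- angle_grid(6)
  t <- rep(0, 3)
  spec <- manual_spec(2L, list(c(1L, 2L, 4L, 6L)), grid, t)
  led <- energy_ledger()
  coeffs <- qubo_coefficients(model, spec, t, led)
  expect_equal(ledger_count(led), 4)
  expect_length(coeffs$quadratic, 0)
})
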