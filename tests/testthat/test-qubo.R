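test_that("feasible one-hot assignments reproduce absolute energies exactly", {
  model <- heptane_model()
  grid <- angle_grid(6)
  set.seed(13)
  t <- grid$values[sample.int(6, 4, replace = TRUE)]
  spec <- manual_spec(c(2L, 4L), list(c(1L, 2L, 5L), c(3L, 4L, 6L)), grid, t)
  coeffs <- qubo_coefficients(model, spec, t)
  qubo <- build_qubo(coeffs, choose_penalty(coeffs))
  expect_equal(qubo$n_vars, spec$s_used)
  # every feasible assignment: objective + constant == total energy of decode
  for (ki in 1:3) for (kj in 1:3) {
    x <- integer(qubo$n_vars)
    x[qubo$blocks[[1]][ki]] <- 1L
    x[qubo$blocks[[2]][kj]] <- 1L
    t_dec <- decode_solution(x, qubo, t)
    expect_equal(qubo_value(qubo, x) + qubo$constant, total_energy(model, t_dec),
                 tolerance = 1e-9)
  }
})

test_that("the all-zeros assignment pays the full constraint penalty", {
  model <- hexane_model()
  grid <- angle_grid(6)
  t <- rep(0, 3)
  spec <- manual_spec(c(1L, 2L), list(1:3, 1:3), grid, t)
  coeffs <- qubo_coefficients(model, spec, t)
  p <- 7.5
  qubo <- build_qubo(coeffs, p)
  expect_equal(qubo_value(qubo, integer(qubo$n_vars)), p * 2)
  expect_error(build_qubo(coeffs, 0), "positive")
})

test_that("penalty scales with the coefficient range and respects the floor", {
  fake <- structure(list(linear = list(c(0, 10)), quadratic = list(), pairs = list(),
                         constant = 0, spec = NULL), class = "qubo_coeffs")
  expect_equal(choose_penalty(fake, gamma = 2), 20)
  flat <- structure(list(linear = list(c(3, 3, 3)), quadratic = list(), pairs = list(),
                         constant = 0, spec = NULL), class = "qubo_coeffs")
  expect_equal(choose_penalty(flat), 1)
})

test_that("decode is the inverse of encode and flags infeasible rows", {
  model <- hexane_model()
  grid <- angle_grid(6)
  set.seed(2)
  t <- grid$values[sample.int(6, 3, replace = TRUE)]
  spec <- manual_spec(c(1L, 3L), list(c(1L, 4L, match_idx(t[1], grid)),
                                      c(2L, 5L, match_idx(t[3], grid))), grid, t)
  spec$angle_idx <- lapply(spec$angle_idx, function(k) sort(unique(k)))
  spec$angles <- lapply(spec$angle_idx, function(k) grid$values[k])
  coeffs <- qubo_coefficients(model, spec, t)
  qubo <- build_qubo(coeffs, choose_penalty(coeffs))
  x <- encode_solution(t, qubo)
  expect_equal(decode_solution(x, qubo, t), t)
  # decoded vectors differ from the incumbent only on the selected torsions
  x2 <- integer(qubo$n_vars)
  x2[qubo$blocks[[1]][1]] <- 1L
  x2[qubo$blocks[[2]][2]] <- 1L
  t2 <- decode_solution(x2, qubo, t)
  expect_equal(t2[2], t[2])
  expect_true(is_neighbour(t, t2, spec$torsions))
  # row sums 0 and 2 are infeasible
  bad0 <- x; bad0[qubo$blocks[[1]]] <- 0L
  expect_error(decode_solution(bad0, qubo, t), class = "vndconf_infeasible")
  bad2 <- x; bad2[qubo$blocks[[1]][1:2]] <- 1L
  expect_error(decode_solution(bad2, qubo, t), class = "vndconf_infeasible")
})

test_that("the chosen penalty makes the unconstrained optimum one-hot feasible", {
  model <- heptane_model()
  grid <- angle_grid(6)
  set.seed(31)
  done <- 0L
  while (done < 10L) {
    t <- grid$values[sample.int(6, 4, replace = TRUE)]
    spec <- random_path_spec(model$graph, grid, t, max_size = 3L)
    coeffs <- qubo_coefficients(model, spec, t)
    p <- choose_penalty(coeffs)
    # the 2^n double-precision sweep is only meaningful when the penalty does
    # not drown the energy scale (severely clashed grid points excluded)
    if (p > 1e8) next
    done <- done + 1L
    qubo <- build_qubo(coeffs, p)
    n <- qubo$n_vars
    expect_lte(n, 16)
    # exhaustive sweep of all 2^n bitstrings
    best_val <- Inf; best_x <- NULL
    for (mask in 0:(2^n - 1)) {
      x <- as.integer(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
      v <- qubo_value(qubo, x)
      if (v < best_val) { best_val <- v; best_x <- x }
    }
    feasible <- all(vapply(qubo$blocks, function(b) sum(best_x[b]) == 1L, logical(1)))
    expect_true(feasible)
    expect_equal(best_val, solve_exact(qubo)$objective, tolerance = 1e-7)
  }
})

test_that("QUBO coordinate export round-trips the coefficients", {
  model <- hexane_model()
  grid <- angle_grid(4)
  t <- rep(0, 3)
  spec <- manual_spec(c(1L, 2L), list(1:2, 1:2), grid, t)
  coeffs <- qubo_coefficients(model, spec, t)
  qubo <- build_qubo(coeffs, 5)
  tmp <- withr::local_tempfile(fileext = ".qubo")
  export_qubo(qubo, tmp)
  lines <- readLines(tmp)
  body <- do.call(rbind, lapply(strsplit(grep("^#", lines, value = TRUE,
                                              invert = TRUE), " "), as.numeric))
  lin <- body[body[, 1] == body[, 2], , drop = FALSE]
  quad <- body[body[, 1] != body[, 2], , drop = FALSE]
  expect_equal(lin[order(lin[, 1]), 3], qubo$linear[qubo$linear != 0])
  for (r in seq_len(nrow(quad)))
    expect_equal(quad[r, 3], qubo$quad[quad[r, 1], quad[r, 2]])
})
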