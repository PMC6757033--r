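# Shared fixtures, built fresh in code at test time.

hexane_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sys <- make_alkane(6)
      g <- partition_rigid_bodies(sys)
      cache <<- energy_model(sys, g)
    }
    cache
  }
})

heptane_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sys <- make_alkane(7)
      g <- partition_rigid_bodies(sys)
      cache <<- energy_model(sys, g)
    }
    cache
  }
})

# brute-force oracle: all edge subsets passing the star test, kept if maximal
brute_force_maximal_subsets <- function(graph) {
  M <- graph$n_torsions
  all_subsets <- lapply(seq_len(2^M - 1L), function(mask)
    which(bitwAnd(mask, 2^(seq_len(M) - 1L)) > 0L))
  dep <- Filter(function(s) is_two_torsion_dependent(graph, s), all_subsets)
  maximal <- Filter(function(s)
    !any(vapply(dep, function(o) length(o) > length(s) && all(s %in% o), logical(1))),
    dep)
  keys <- vapply(maximal, function(s) paste(sprintf("%06d", s), collapse = ","),
                 character(1))
  maximal[order(keys)]
}

# independent flat all-pairs LJ sum with 1-2/1-3 exclusion, via a double loop
flat_lj_energy <- function(system, coords, params = uff_params()) {
  n <- system$n_atoms
  adj <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(system$bonds))) {
    adj[system$bonds[r, 1], system$bonds[r, 2]] <- TRUE
    adj[system$bonds[r, 2], system$bonds[r, 1]] <- TRUE
  }
  total <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (adj[i, j]) next
    if (any(adj[i, ] & adj[j, ])) next  # 1-3: shared bonded neighbour
    pp <- combine_params(system$elements[i], system$elements[j], params)
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    total <- total + lj_pair(pp[["eps"]], pp[["sigma"]], r)
  }
  total
}

match_idx <- function(angle, grid) {
  d <- abs(grid$values - (angle %% (2 * pi)))
  which.min(pmin(d, 2 * pi - d))
}

# a hand-sized neighbourhood_spec without going through the sampler
manual_spec <- function(torsions, angle_idx, grid, t_incumbent) {
  angles <- lapply(angle_idx, function(k) grid$values[k])
  structure(list(torsions = torsions, angles = angles, angle_idx = angle_idx,
                 incumbent = t_incumbent[torsions],
                 s_budget = sum(lengths(angle_idx)),
                 s_used = sum(lengths(angle_idx)),
                 size = prod(lengths(angle_idx))),
            class = "neighbourhood_spec")
}

# random 2-torsion-dependent spec on a path-shaped rigid-body graph
random_path_spec <- function(graph, grid, t, max_size = 4L) {
  M <- graph$n_torsions
  pair <- sort(sample.int(M, 2L))
  angle_idx <- lapply(pair, function(i) {
    k0 <- which.min(abs(grid$values - (t[i] %% (2 * pi))))
    size <- sample(2:max_size, 1L)
    sort(unique(c(k0, sample.int(grid$d, size - 1L))))
  })
  manual_spec(pair, angle_idx, grid, t)
}
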