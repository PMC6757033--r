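Package: vndconf
Title: Variable Neighbourhood Descent Conformational Search with QUBO
    Neighbourhood Subproblems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete conformational search for flexible molecules by
    variable neighbourhood descent (VND) over torsion-angle grids. The
    molecule is partitioned into rigid bodies connected by rotatable
    bonds; at each iteration a 2-torsion-dependent subset of torsions is
    selected from the rigid-body graph, the restricted energy
    minimization is encoded as a one-hot quadratic unconstrained binary
    optimization (QUBO) problem, and the subproblem is solved exactly or
    by simulated annealing. Includes a single-torsion local search, an
    LS-VND hybrid, a parallel tempering Monte Carlo reference searcher,
    a Lennard-Jones/UFF pairwise energy model with rigid-body
    decomposition and energy-evaluation accounting, synthetic molecule
    generators (n-alkanes, star-branched molecules, analytic two-body
    toys), and a benchmark harness reporting success rates, residuals,
    and energy-evaluation counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
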