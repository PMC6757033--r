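---
title: "Conformational search by variable neighbourhood descent over QUBO subproblems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational search by variable neighbourhood descent over QUBO subproblems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vndconf)
```

## The model

`vndconf` treats conformational search as a discrete optimization problem
over torsion angles. Bond lengths, bond angles, and ring geometries are
frozen; the only degrees of freedom are rotations about a user-designated
set of `M` rotatable bonds, each angle restricted to a grid `Θ` of `d`
values on `[0, 2π)`. A conformation is a torsion vector `t ∈ Θ^M` and the
search space has `d^M` points.

Angles are **offsets relative to the reference geometry**: `t = 0`
reproduces the input coordinates exactly. This avoids committing to an
absolute dihedral origin, which would require choosing reference
substituent atoms for every bond. Rotations are right-handed about the
bond axis oriented from the proximal (root-side) to the distal bond atom,
with the root fixed as the rigid body containing atom 1 — all
conventions chosen once so that runs are bit-reproducible.

Removing the `M` torsion bonds partitions the atoms into `M + 1` *rigid
bodies*. Every torsion bond must be a *bridge* of the bond graph (a bond
on a ring cannot rotate freely), which makes the rigid-body graph — one
vertex per body, one edge per torsion — a tree. Coordinates for any `t`
are reconstructed by rotating distal subtrees about their bond axes from
the root outward; intra-body geometry is preserved to machine precision.

The energy is a Lennard-Jones 6–12 sum over nonbonded atom pairs,

$$V(\alpha,\beta) = \varepsilon_{\alpha\beta}\left[
  \left(\frac{\sigma_{\alpha\beta}}{r_{\alpha\beta}}\right)^{12}
  - 2\left(\frac{\sigma_{\alpha\beta}}{r_{\alpha\beta}}\right)^{6}\right],$$

in kcal/mol with distances in Å, so the well has depth
`−ε` at `r = σ`. Per-element `ε` and `σ` follow the UFF nonbonded
parameters (H, C, N, O, P, S, Cl shipped in
`inst/extdata/uff_lj.tsv`; other elements via a user table), combined by
geometric means. Atom pairs separated by one or two bonds are excluded:
the model is silent about bonded interactions, and without the exclusion
the `1/r^{12}` wall at bonded distances dominates everything. Both the
exclusion separation and the parameter table are arguments of
`energy_model()`. Torsional, bending, and electrostatic terms are out of
scope; the LJ-only surface is a proof-of-concept energy, not a production
force field.

Because intra-body geometry never changes, the energy splits into a
rotation-invariant constant plus body–body interaction terms, each
depending only on the torsions along the tree path between the two
bodies. That locality is what the neighbourhood construction exploits.

## Neighbourhoods and the QUBO encoding

A torsion subset `𝒯_k` is *2-torsion dependent* when contracting all
other edges of the rigid-body tree leaves a star graph (at most one
vertex of degree above one). Any two contracted super-bodies are then at
most two selected torsions apart, so every cross term is at most
quadratic in the selected angles: restricted to such a subset (all other
torsions frozen), the energy is exactly representable by a one-hot QUBO.
`enumerate_maximal_subsets()` lists the inclusion-maximal such subsets —
they are precisely the edge boundaries of connected vertex sets of the
tree — while searches use the randomized sampler described below.

For selected torsions with angle subsets `Θ_i ⊆ Θ`, the QUBO assigns one
binary variable per (torsion, angle) pair. Coefficients are
pre-evaluated from the star: `U_i(θ)` is the centre–leaf interaction
through torsion `i`, `U_ij(θ, θ')` the leaf–leaf interaction through the
centre. The frozen intra-super-body energy is carried as a separate
constant so decoded energies are absolute and comparable across
iterations. The pre-evaluation cost, `Σ_{i<j}|Θ_i||Θ_j| + s` with
`s = Σ|Θ_i|`, is the quantity tracked by the energy-evaluation ledger;
it grows more slowly than the neighbourhood size `S_k = Π|Θ_i|` once
three or more torsions are optimized jointly. For a pair of torsions
there is no saving (the count is `S_k + s`), which is why star-shaped
molecules — whose hubs admit large 2-torsion-dependent subsets — are the
interesting case for hardware QUBO solvers.

The one-hot constraints are enforced by a quadratic penalty
`p · Σ_i (Σ_θ x_iθ − 1)²`. The default `p = γ (max U − min U)` with
`γ = 2` (floor 1 kcal/mol) exceeds any energy advantage an infeasible
assignment could gain; no principled magnitude is prescribed by the
method itself, so `γ` is exposed in `search_config()`.

### Neighbourhood change

The neighbourhood-change rule is the package's own reconstruction,
documented here as such. A random torsion ordering `φ` is drawn; each
iteration starts a subset at the next torsion in `φ` and greedily tries
to add subsequent `φ`-order torsions while the subset stays 2-torsion
dependent and its cardinality stays within `⌊s/2⌋` (each torsion needs
at least two angle values to be worth selecting). When `φ` is exhausted
it is reshuffled. After an accepted improvement the search simply
advances in `φ` rather than restarting at the first structure. Angle
subsets are split as equally as possible (the split that maximizes
`S_k`), always contain the incumbent angle — so the incumbent belongs to
its own neighbourhood and descent is guaranteed — and fill the rest with
uniform draws from the grid without replacement.

## Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `d` | grid values per torsion | 6 | 60° spacing puts anti and gauche states on-grid for sp³ chains |
| `s` | QUBO variable budget per iteration | 12 | full `d × d` pair neighbourhoods at `d = 6`; scaled-down analogue of hardware budgets |
| `A` | consecutive non-improving iterations before stopping | 10 | `≈ 2×` the pair-subset count of short chains; stalling longer rarely helps |
| `B` | iteration cap | 150 | safety net; runs stop earlier via `A` or the target |
| `gamma` | penalty multiplier | 2 | one coefficient range above sufficiency |
| `target_tol` | early-stop margin around a supplied reference | 0.1 kcal/mol | matches the run-termination convention used in benchmarking |
| SA schedule | geometric `β` 0.1 → 50, 2000 sweeps, 25 reads | — | generic anneal; exposed because no hardware schedule is modelled |
| PTMC ladder | 8 replicas, `kT` 0.2–5 kcal/mol geometric, swap every sweep | — | spans freezing to barrier-hopping temperatures for kcal/mol landscapes |

All angles are degrees in files and at the command line, radians
internally; energies are kcal/mol, coordinates Å; atom indices are
1-based everywhere (R convention), including input files.

## Solvers

`solve_exact()` enumerates the `S_k` feasible one-hot assignments
directly instead of sweeping `2^n` bitstrings — the optimum is identical
(a sufficient penalty makes the unconstrained optimum feasible, which the
test suite verifies by exhaustive `2^n` sweeps on small instances) and
the cost exponentially lower. Ties break toward the lexicographically
smallest slot tuple, so results are deterministic.

`solve_sa()` is a single-spin-flip Metropolis anneal over the full binary
space, restarted from random bitstrings, returning the best feasible
sample; infeasible samples are discarded, never repaired, and an
iteration with no feasible sample keeps the incumbent. It stands in for
stochastic QUBO hardware and inherits the weaknesses of its kind: when
clashed grid points inflate the coefficient range, the penalty scales
with it and the anneal can no longer traverse between one-hot states.

### Numerical choices

The LJ `1/r^{12}` term makes coefficient ranges enormous whenever a
candidate grid point clashes two atoms — `p` can reach `10^{10}` and
beyond. Evaluating the *penalized* objective then loses up to
`p · ε_{machine}` kcal/mol to cancellation. The exact solver therefore
scores assignments from the penalty-free coefficient tables (on feasible
assignments the penalty cancels exactly, in algebra rather than in
floating point), and the SA solver re-evaluates its returned sample the
same way. Acceptance of a VND move compares absolute energies
reconstructed as `constant + Σ U_i + Σ U_ij`; acceptance requires a
strict decrease, and equal-energy moves are rejected so the `A` counter
has clean semantics.

## The synthetic molecule generators

The package is fully testable offline through three generators:

* `make_alkane(n)` — idealized all-atom n-alkanes (C–C 1.54 Å, C–H
  1.09 Å, tetrahedral angles), all-anti reference, torsions on internal
  C–C bonds excluding the terminal (methyl) rotors; the rigid-body graph
  is a path. These emulate chain-like molecules.
* `make_star_molecule(k, len)` — a central carbon with `k` alkane arms
  and torsions on the centre–arm bonds; the rigid-body graph is a star
  whose hub edges form one maximal 2-torsion-dependent set of size `k`.
  These emulate star-like molecules whose arm–arm interactions create
  traps that no single-torsion move escapes. Centres with more than four
  arms are geometrically valid but chemically hypervalent; the generator
  targets topology, not synthesizability.
* `make_two_body_toy(d)` — two CH fragments on one rotatable bond whose
  only nonbonded pair is the 1-4 H···H contact, giving a closed-form
  `d`-point landscape used as an independent oracle.

What they do **not** emulate: real force-field torsional profiles,
electrostatics, polarizable or metal centres, ring conformers, and the
specific organometallic and oligomer systems studied with this class of
method on hardware annealers. Passing tests on these generators
demonstrate the correctness of the machinery (encodings, solvers,
counters, descent semantics) and qualitative topology effects, not
quantitative accuracy on real molecules.

## Benchmark scales

The packaged benchmark reproductions run at desk scale, chosen once as
the package's own study conditions: scaled n-alkane analogues
(n-heptane, n-octane, n-nonane; `M` = 4–6) at `d = 6`, `s = 12`, with
references from exhaustive grid enumeration; 25 seeded runs per cell;
success defined as ending within 1 kcal/mol of the reference and runs
terminating early within 0.1 kcal/mol of it. The qualitative method
contrasts use a C14 chain at `d = 16` (evaluation-count comparison,
where local search's `M(d−1)` sweep cost overtakes VND's fixed per-
iteration budget) and a 4-arm star (solution-quality comparison, where
VND's joint arm moves escape traps local search cannot). Percentiles in
benchmark tables use the nearest-rank convention; wall times are
recorded but never asserted, being hardware-dependent.

## Known limitations

* The energy model is LJ-only; numbers are not comparable to full force
  fields, and reference geometries are idealized.
* Maximal-subset enumeration is exponential in unfavourable topologies
  and guarded at 20 edges; searches never need it (the sampler scales).
* The SA solver is a generic anneal, not a model of any specific
  annealer: no graph embedding, chain breaks, or integrated control
  error; hardware-specific results cannot be reproduced with it.
* PTMC ladder and sweep defaults are reasonable for kcal/mol landscapes
  of the generated systems; real applications should tune them.
* With extreme coefficient ranges (clashed grid points), the penalized
  QUBO objective is ill-conditioned in double precision; the package
  sidesteps this internally (see Numerical choices) but exported QUBO
  files inherit the conditioning.
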