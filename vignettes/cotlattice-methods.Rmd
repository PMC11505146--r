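---
title: "Methods: organizations, lattices and persistence in cotlattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organizations, lattices and persistence in cotlattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`cotlattice` analyzes reaction networks: species plus reactions given
as reactant/product multisets with integer stoichiometry. Boundary
species (constant pools: `EmptySet`, amino acids, ATP, phosphate — any
species flagged `boundaryCondition`/`constant` in SBML or matching the
configurable boundary name list) are treated as environment: they get
no row in the stoichiometric matrix N, and a reaction whose reactant
(product) multiset is empty after boundary removal is an inflow
(outflow). Reversible SBML reactions are split into forward and
reverse irreversible reactions before any analysis; every reaction
count in the package refers to the post-split list. Kinetic laws and
SBML modifiers are ignored: everything below is purely stoichiometric.

An *organization* is identified by its set of active reactions R and
must satisfy, for some partition of its species into k pairwise
disjoint compartments:

1. **closedness per compartment** — each compartment's active
   reactions (all non-inflow reactions with support inside the
   compartment, plus any chosen inflows producing into it) create
   nothing outside the compartment;
2. **coverage** — the compartment active-reaction sets union to R;
3. **self-maintenance** — some flux v with `v_j > 0` exactly on R has
   `(N·v)_s ≥ 0` for every species s touched by R.

The species of an organization are *derived* from R (every reactive
species occurring in a member reaction); species inert under R never
appear. The empty reaction set is always an organization (inflows are
optional, so nothing is mandatory on the empty species set); it is
assigned k = 0 compartments — a convention that affects no reported
statistic, since the multi-compartment fraction counts k ≥ 2.

## Key structural fact used by the algorithm

Because each compartment is closed, the N-columns of a compartment's
reactions touch only that compartment's rows. The global feasibility
LP therefore separates across compartments, with two consequences that
the implementation exploits and the test suite re-derives:

- a reaction set is an organization with k compartments **iff** it is
  the union of k species-disjoint *single-compartment* organizations;
- every compartment of a valid compartmentalization is itself an
  organization.

The second point has a visible corollary: whenever a lattice contains
an organization whose minimal compartmentalization has k ≥ 2, its k
blocks are incomparable organizations, so the lattice width is at
least 2. A published record claiming both "width 1" and "an
organization requiring 2 compartments" cannot be reproduced under
these definitions for any network (see *Known limitations*).

## Enumeration algorithm

1. **Closed sets.** All species sets closed under mandatory (non-
   inflow) product addition are enumerated with Ganter's NextClosure
   over the closure operator (output-sensitive; a `max_closed_sets`
   guard flags truncation instead of stalling).
2. **Single-compartment candidates.** Each closed set S, together
   with each admissible inflow subset (inflows producing inside S),
   yields a candidate reaction set; candidates are reduced to the
   species their reactions actually touch and deduplicated.
3. **Feasibility.** Each candidate is tested by linear programming.
   Strict positivity `v_j > 0` is normalized to `v_j ≥ 1` (the
   feasible cone is scale invariant). The LP is a phase-1 simplex
   run in exact rational arithmetic with Bland's rule — infeasibility
   answers are exact, not tolerance-dependent — and every accepted
   witness is re-checked exactly.
4. **Unions.** Multi-compartment organizations are formed as disjoint
   unions of feasible single-compartment candidates up to `k_max`
   blocks (no further LP needed, by separability; witnesses overlay).
5. **Minimal compartmentalization.** For each organization, the
   minimum k is found by exact-cover search over the feasible
   single-compartment blocks, by increasing k; block lists are
   canonicalized lexicographically so output is reproducible.

This bottom-up scheme differs from a seed-and-merge heuristic: it is
complete by construction relative to the definitions above, and a
literal brute-force oracle (`brute_force_organizations`: all species
subsets × set partitions × inflow subsets, guarded to ≤ 10 species and
≤ 12 reactions) is kept as an independent implementation; the suite
checks equality on hundreds of seeded random networks.

The Hasse lattice is the transitive reduction of reaction-set
inclusion. Layers default to longest-chain depth from the empty
organization; `layering = "nreactions"` switches to raw reaction-count
layering (both reproduce the worked cell-cycle example's height 4 and
width 2, but reaction-count ties across incomparable organizations
make depth layering the robust default). Persistence is the reaction
count of the largest organization divided by n (1 iff the entire
network is an organization; 0 when only the empty one exists; a
network with n = 0 is assigned 1 with a warning).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `tol` | 1e-9 | flux | classifying user-supplied numeric fluxes as positive (the internal LP is exact and ignores it) |
| `k_max` | 4 | compartments | cap on compartment search; required k above 3 is rare |
| `timeout` | 600 | s | wall budget per enumeration; expiry returns a partial result flagged `incomplete` |
| `max_closed_sets` | 1e5 | sets | guard against closed-set explosion, same flag |
| `tail_fraction` | 0.2 | — | trajectory tail window for persistence extraction |
| `threshold` | 1e-6 | conc. | absolute persistence floor |
| `trend_cut`, `trend_ratio` | 1e-2, 0.8 | conc., — | decay-trend test (below) |
| `substeps` | 20 | — | RK4 substeps per output interval |

## Dynamics validation and its stated world

`mass_action_simulate` integrates `dc/dt = N v(c)` with mass-action
fluxes by fixed-step classical RK4 (deterministic; tiny negative
excursions are clamped to 0; non-finite states abort with context).
`persistent_set` operationalizes "non-vanishing": a species is
persistent when its tail-window minimum exceeds `threshold` *and* it
is not both small (`< trend_cut`) and still shrinking relative to the
mid-trajectory window (`< trend_ratio ×` mid minimum). The trend test
exists because sub-exponential decay (e.g. `c ~ 1/t` from second-order
self-consumption) sits above any fixed threshold at finite horizons.

The theorem property — the persistent reaction set of a trajectory is
always an enumerated organization — is validated on random networks in
a **dissipative regime**: no mass-increasing reactions, a first-order
decay reaction for every species, and optional constant inflows
(`generator_config(bounded = TRUE, dissipative = TRUE)`). In this
regime trajectories are provably bounded, vanishing species vanish at
least exponentially fast (every species has a linear sink), and
inflow-fed species stay bounded away from zero, so the asymptotic
notion is observable at the simulated horizon. Outside this regime the
theorem still holds asymptotically, but no finite-horizon heuristic
can classify, say, `c ~ 1/log t` decay (such trajectories arise
already in 6-species random networks), and unbounded trajectories
escape the integrator; a green dynamics suite therefore certifies the
extraction machinery in its stated world, not on arbitrary kinetics.

## The synthetic data

`random_network` samples uniform reactant/product multisets (1-2
species per side, coefficients geometric up to `max_stoich`, inflow/
outflow probabilities per reaction); identical configs give identical
networks and the caller's RNG stream is untouched. It emulates the
combinatorics of small biochemical networks — not their degree
distributions, conservation structure or kinetics; a green
oracle-equivalence run certifies the enumeration logic, not biological
realism. `planted_network(k)` builds k disjoint two-species cycles
(each a single-compartment organization by construction) plus bridge
reactions spanning block pairs whose product lies outside all blocks,
so the all-blocks union is an organization needing exactly k
compartments while any merge activates a bridge and breaks closedness;
with the default one bridge per consecutive pair (cycling) every block
pair is bridged for k ≤ 3, which is what the completeness probe uses.

`markevich2004_synthetic` is a 16-species / 27-reaction *synthetic*
reconstruction of an elementary-step dual phosphorylation MAPK cycle
(random-order kinase and phosphatase mechanisms, product complexes,
two dead-end enzyme-substrate complexes). It matches the published
model's size and mechanism class, not its exact reaction list, which
is not redistributable here; results on it are a stand-in.

## Design decisions on genuinely open points

- **Organization identity is the reaction set.** Species follow from
  reactions; reaction-inert species are never part of an
  organization. The alternative (species-set identity, allowing inert
  species carried along in extra compartments) would multiply
  organizations combinatorially and was rejected.
- **Inflow optionality** is realized by enumerating inflow subsets
  during candidate generation; non-inflow active reactions are always
  mandatory. This is what makes the empty organization universal.
- **Empty organization**: k = 0 compartments (no compartment is
  needed to host no reaction); inflows with no reactive product are
  treated as hostable by any compartment.
- **Fractional SBML stoichiometry** is rejected by default with an
  explicit `fractional = "scale"` escape hatch (smallest integer
  rescale), keeping N integral for the exact LP.

## Known limitations

- The published Markevich-model record (4 organizations in a chain of
  width 1 *and* a two-compartment organization) is jointly
  unsatisfiable under the definitions implemented here, by the width
  corollary above; the corresponding acceptance assertions fail by
  design against any input, including the stand-in, and are left
  failing rather than weakened. On the stand-in this implementation
  finds the two dead-end binding cycles as organizations, their
  two-compartment union, the empty and the full organization.
- Closed-set enumeration and the union search are exponential in the
  worst case; guards (`max_closed_sets`, `timeout`, `k_max`) keep
  results honest via the `incomplete` flag rather than silently
  truncating.
- The integrator is non-stiff and fixed-step; it is a validation tool
  for the theorem property, not a production ODE solver.
- Survey-scale statistics (hundreds of models) are supported by the
  batch machinery but no published survey numbers are asserted
  anywhere: they depend on a curated model collection that cannot be
  shipped.
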