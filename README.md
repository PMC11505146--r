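# cotlattice

Chemical organization theory (COT) analysis of biochemical reaction
networks in R: enumerate all **organizations** of a model — the closed,
self-maintaining subnetworks, possibly distributed over several
compartments — arrange them in a Hasse lattice, and derive structural
complexity parameters that let models be compared without knowing a
single rate constant.

## Who this is for

Systems biologists and modelers working with reaction-network models
(e.g. SBML models of the cell cycle or signalling cascades) who want to
know *which subsystems of a model can persist dynamically* before — or
instead of — fitting kinetics. The lattice of organizations is a purely
stoichiometric fingerprint of a model: every set of species/reactions
that keeps strictly positive concentrations/fluxes in **any** solution
of the associated ODE/PDE system is one of the enumerated
organizations, whatever the rate laws, parameters or initial
conditions.

## The mathematics in brief

A reaction network with m reactive species and n reactions has the
stoichiometric matrix N ∈ Z^(m×n), `N[s, j] = products(s, j) −
reactants(s, j)`. For a species set S, the *active* reactions are those
whose support (reactant set) lies in S; inflow reactions (empty
support) are optionally active. A flux v ∈ R₊ⁿ is *feasible* for a
reaction set R when `v_j > 0 ⇔ j ∈ R`.

A reaction set R is an **organization** when its species can be split
into pairwise disjoint compartments S₁,…,S_k such that

1. each S_i is closed — its active reactions create no species or
   reaction outside the compartment;
2. the compartment active-reaction sets union to R;
3. a global feasible flux exists with `(N·v)_s ≥ 0` for every species
   s of R (self-maintenance).

The feasibility test is an exact rational phase-1 simplex (no floating
tolerance enters the decision), and every reported witness is
re-verified in exact arithmetic. The **minimal compartmentalization**
uses as few compartments as possible; its block count k is unique.
Per-model parameters: number of organizations, lattice **height**
(layers) and **width** (maximal layer occupancy), **persistence** (=
reactions of the largest organization / n), the fraction of
organizations needing k ≥ 2, and the maximal k.

## Worked example: the Tyson (1991) cell-cycle oscillator

The six-variable cyclin/cdc2 model ships as a built-in fixture
(`tyson_fixture()`, also as SBML under `inst/extdata/tyson1991.xml`):

```r
library(cotlattice)
net <- tyson_fixture()
pars <- compute_parameters(net)
print(pars)
#> <model_parameters>
#>   n_species                   6
#>   n_reactions                 9
#>   n_organizations             5
#>   height                      4
#>   width                       2
#>   persistence                 1
#>   fraction_multi_compartment  0.2
#>   max_compartments            2
#>   runtime_ms                  20
#>   incomplete                  FALSE
print(pars$organizations)
#> <organization_set> 5 organizations
#> <organization> {} on {}, compartments [-]
#> <organization> {Reaction2,Reaction3} on {C2,CP}, compartments [C2,CP]
#> <organization> {Reaction6,Reaction7} on {Y}, compartments [Y]
#> <organization> {Reaction2,Reaction3,Reaction6,Reaction7} on {C2,CP,Y}, compartments [C2,CP | Y]
#> <organization> {Reaction1,...,Reaction9} on {C2,CP,pM,M,Y,YP}, compartments [C2,CP,pM,M,Y,YP]
```

Reading: besides the empty organization, the cyclin turnover cycle
(`Reaction6/7` on {Y}) and the cdc2 phosphorylation cycle
(`Reaction2/3` on {C2, CP}) can each persist alone; they can coexist
side by side only when kept in *two* compartments (`C2,CP | Y` — mixing
them activates preMPF formation and pulls in the whole network), and
the full nine-reaction network is itself an organization, so the model
as a whole is persistent (persistence 1). `to_dot(pars$lattice)`
renders the Hasse diagram (rectangles = one compartment, ellipses =
compartmentalized).

Validation hooks: `brute_force_organizations()` applies the definition
literally on small networks and must agree with the fast enumeration;
`theorem_check()` simulates mass-action kinetics and verifies that the
persistent subnetwork of the trajectory is one of the enumerated
organizations.

## Command line

```sh
Rscript inst/cli/cotlattice analyze inst/extdata/tyson1991.xml \
        --json report.json --dot lattice.dot
Rscript inst/cli/cotlattice batch models/ --csv summary.csv
```

Exit codes: 0 success, 2 parse/input error, 3 timeout (outputs written,
flagged `incomplete`).

## Notes

- `inst/extdata/markevich2004_synthetic.xml` is a *synthetic*
  16-species / 27-reaction reconstruction of the elementary-step dual
  phosphorylation MAPK mechanism (the original BioModels file is not
  redistributable here); see the methods vignette for what it does and
  does not establish.
- The methods vignette (`vignettes/cotlattice-methods.Rmd`) documents
  the model, the algorithm, all tunable parameters and the known
  limitations.
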