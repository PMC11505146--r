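# Random and planted-structure test networks.  All generators are
# deterministic functions of their config (seeded, caller RNG state is
# preserved).

#' Configuration for the random network generator
#'
#' @param n_species,n_reactions network size (positive).
#' @param max_stoich maximum stoichiometric coefficient (default 2).
#' @param p_inflow,p_outflow per-reaction probability of being a pure
#'   inflow / outflow.
#' @param bounded when `TRUE`, generate mass-bounded networks: no
#'   inflows and every reaction's total product stoichiometry at most
#'   its total reactant stoichiometry, so all mass-action trajectories
#'   stay bounded (total mass is nonincreasing).  This is the regime
#'   used for dynamics property tests, where the persistence theorem's
#'   asymptotics must be observable at a finite horizon.
#' @param dissipative when `TRUE`, additionally append one first-order
#'   decay reaction `S -> 0` per species (ids `D1`, `D2`, ...).
#'   Together with `bounded = TRUE` this yields the fully dissipative
#'   regime: every trajectory is bounded, every vanishing species
#'   vanishes at least exponentially fast (it has a linear sink), and
#'   every species fed by a constant inflow stays bounded away from
#'   zero — so finite-horizon persistence extraction is reliable.
#' @param seed integer RNG seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_species = 6L, n_reactions = 8L,
                             max_stoich = 2L, p_inflow = 0.1,
                             p_outflow = 0.2, bounded = FALSE,
                             dissipative = FALSE, seed = 1L) {
  if (bounded && !dissipative) p_inflow <- 0
  stopifnot(n_species >= 1L, n_reactions >= 1L, max_stoich >= 1L,
            p_inflow >= 0, p_outflow >= 0, p_inflow + p_outflow <= 1)
  structure(list(n_species = as.integer(n_species),
                 n_reactions = as.integer(n_reactions),
                 max_stoich = as.integer(max_stoich),
                 p_inflow = p_inflow, p_outflow = p_outflow,
                 bounded = isTRUE(bounded),
                 dissipative = isTRUE(dissipative),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a random reaction network
#'
#' Reactant and product multisets are sampled uniformly: 1-2 distinct
#' species per side with coefficients up to `max_stoich`; a reaction
#' becomes a pure inflow (empty reactant side) with probability
#' `p_inflow` and a pure outflow with probability `p_outflow`.
#' Identical configs give identical networks.
#'
#' @param config a [generator_config()].
#' @return a `reaction_network`.
#' @export
random_network <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    ids <- sprintf("S%d", seq_len(config$n_species))
    side <- function() {
      picks <- sample(ids, sample(1:2, 1L, prob = c(0.6, 0.4)))
      structure(sample.int(config$max_stoich, length(picks),
                           replace = TRUE, prob = 2^(-seq_len(config$max_stoich))),
                names = picks)
    }
    rx <- vector("list", config$n_reactions)
    for (j in seq_len(config$n_reactions)) {
      u <- stats::runif(1)
      rid <- sprintf("R%d", j)
      rx[[j]] <- if (u < config$p_inflow) {
        reaction(rid, integer(), side())
      } else if (u < config$p_inflow + config$p_outflow) {
        reaction(rid, side(), integer())
      } else {
        lhs <- side()
        rhs <- side()
        if (config$bounded) {
          for (try in 1:50) {
            if (sum(rhs) <= sum(lhs)) break
            rhs <- side()
          }
          if (sum(rhs) > sum(lhs))
            rhs <- structure(1L, names = names(rhs)[1L])
        }
        reaction(rid, lhs, rhs)
      }
    }
    if (config$dissipative)
      for (i in seq_along(ids))
        rx[[length(rx) + 1L]] <-
          reaction(sprintf("D%d", i), structure(1L, names = ids[i]),
                   integer())
    build_network(lapply(ids, species), rx)
  })
}

#' Generate a planted-structure network
#'
#' Builds `k_blocks` disjoint two-species interconversion cycles
#' `A_i <-> B_i` (each a closed, self-maintaining single-compartment
#' organization by construction) plus `bridge_reactions` reactions
#' whose support spans two blocks and whose product is a fresh species
#' outside all blocks.  The disjoint union of all blocks is then an
#' organization requiring `k_blocks` compartments, while merging any
#' two bridged blocks into one compartment activates the bridge,
#' produces the outside species and destroys closedness (and the
#' resulting closure loses self-maintenance because bridge consumption
#' is uncompensated).
#'
#' @param k_blocks number of planted blocks (>= 1).
#' @param bridge_reactions number of bridge reactions (ignored when
#'   `k_blocks == 1`; bridges connect consecutive block pairs,
#'   cycling).
#' @param seed RNG seed (kept for interface symmetry; construction is
#'   deterministic).
#' @return a `reaction_network`.
#' @export
planted_network <- function(k_blocks, bridge_reactions = k_blocks,
                            seed = 1L) {
  stopifnot(k_blocks >= 1L)
  if (k_blocks == 1L) bridge_reactions <- 0L
  lines <- character()
  for (i in seq_len(k_blocks)) {
    lines <- c(lines,
               sprintf("cyc%d_f: A%d -> B%d", i, i, i),
               sprintf("cyc%d_r: B%d -> A%d", i, i, i))
  }
  for (b in seq_len(bridge_reactions)) {
    i <- ((b - 1L) %% k_blocks) + 1L
    j <- (i %% k_blocks) + 1L
    lines <- c(lines,
               sprintf("bridge%d: A%d + A%d -> X%d", b, i, j, b))
  }
  read_reaction_text(paste(lines, collapse = "\n"))
}
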