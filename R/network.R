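# Reaction-network representation and stoichiometric primitives.
#
# A network holds an ordered species table, an ordered reaction list and
# the integer stoichiometric matrix N over the *reactive* (non-boundary)
# species: N[s, j] = products(s, j) - reactants(s, j).  Boundary species
# (constant pools such as EmptySet, amino acids, ATP, Pi) have no row.

DEFAULT_BOUNDARY_IDS <- c("EmptySet", "Ø", "empty")

#' Declare a species
#'
#' @param id short unique identifier.
#' @param name free-text name (defaults to `id`).
#' @param is_boundary is this a constant source/sink pool (no row in the
#'   stoichiometric matrix)?
#' @return a one-row species record (plain list).
#' @export
species <- function(id, name = id, is_boundary = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  list(id = id, name = name, is_boundary = isTRUE(is_boundary))
}

#' Declare a reaction
#'
#' Reactant/product multisets are named integer vectors mapping species
#' ids to (nonnegative) stoichiometric counts.  Whether a reaction is an
#' inflow or outflow is *derived* later, once the boundary species are
#' known: a reaction is an inflow when its boundary-stripped reactant
#' multiset is empty, an outflow when its boundary-stripped product
#' multiset is empty.
#'
#' @param id short unique identifier.
#' @param reactants,products named integer vectors of counts.
#' @param label free-text description.
#' @return a reaction record (plain list).
#' @export
reaction <- function(id, reactants = integer(), products = integer(),
                     label = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  reactants <- tidy_multiset(reactants, id, "reactant")
  products <- tidy_multiset(products, id, "product")
  if (length(reactants) == 0L && length(products) == 0L)
    stop("reaction '", id, "': both reactant and product multisets are empty")
  list(id = id, label = label, reactants = reactants, products = products)
}

tidy_multiset <- function(x, rid, side) {
  if (length(x) == 0L) return(structure(integer(), names = character()))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("reaction '", rid, "': unnamed ", side, " counts")
  if (any(x != round(x)))
    stop("reaction '", rid, "': fractional ", side,
         " stoichiometry is not supported")
  if (any(x < 0)) stop("reaction '", rid, "': negative ", side, " count")
  x <- x[x > 0]
  out <- tapply(as.integer(x), names(x), sum)   # merge duplicate ids
  structure(as.integer(out), names = names(out))
}

#' Build a reaction network
#'
#' Computes the stoichiometric matrix over reactive species, derives
#' inflow/outflow flags and the per-reaction reactive support.
#'
#' @param species_list list of [species()] records.
#' @param reaction_list list of [reaction()] records.
#' @param boundary_ids additional species ids/names treated as boundary
#'   regardless of their flag (defaults cover the EmptySet conventions).
#' @return an object of class `reaction_network` with fields `species`
#'   (data frame), `reactions` (list), `N` (integer matrix, reactive
#'   species x reactions), `reactive` (character), `inflow`/`outflow`
#'   (logical per reaction).
#' @export
build_network <- function(species_list, reaction_list,
                          boundary_ids = DEFAULT_BOUNDARY_IDS) {
  ids <- vapply(species_list, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate species id: ",
                               ids[duplicated(ids)][1L])
  names_ <- vapply(species_list, `[[`, "", "name")
  boundary <- vapply(species_list, `[[`, NA, "is_boundary") |
    ids %in% boundary_ids | names_ %in% boundary_ids

  rids <- vapply(reaction_list, `[[`, "", "id")
  if (anyDuplicated(rids)) stop("duplicate reaction id: ",
                                rids[duplicated(rids)][1L])
  for (r in reaction_list) {
    undeclared <- setdiff(c(names(r$reactants), names(r$products)), ids)
    if (length(undeclared))
      stop("reaction '", r$id, "' references undeclared species: ",
           paste(undeclared, collapse = ", "))
  }

  reactive <- ids[!boundary]
  m <- length(reactive)
  n <- length(reaction_list)
  N <- matrix(0L, nrow = m, ncol = n, dimnames = list(reactive, rids))
  supp <- prod_ <- vector("list", n)
  inflow <- outflow <- logical(n)
  for (j in seq_len(n)) {
    r <- reaction_list[[j]]
    rr <- r$reactants[names(r$reactants) %in% reactive]
    pp <- r$products[names(r$products) %in% reactive]
    if (length(rr)) N[names(rr), j] <- N[names(rr), j] - rr
    if (length(pp)) N[names(pp), j] <- N[names(pp), j] + pp
    supp[[j]] <- iset(match(names(rr), reactive))
    prod_[[j]] <- iset(match(names(pp), reactive))
    inflow[j] <- length(rr) == 0L
    outflow[j] <- length(pp) == 0L
    reaction_list[[j]]$is_inflow <- inflow[j]
    reaction_list[[j]]$is_outflow <- outflow[j]
  }

  sp <- data.frame(id = ids, name = names_, is_boundary = boundary,
                   stringsAsFactors = FALSE)
  sp$index <- NA_integer_
  sp$index[!boundary] <- seq_len(m)

  structure(list(species = sp, reactions = reaction_list, N = N,
                 reactive = reactive, supp = supp, prods = prod_,
                 inflow = inflow, outflow = outflow,
                 boundary_ids = boundary_ids),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", length(x$reactive), " reactive species (",
      sum(x$species$is_boundary), " boundary), ",
      length(x$reactions), " reactions, ",
      sum(x$inflow), " inflow / ", sum(x$outflow), " outflow\n", sep = "")
  invisible(x)
}

n_reactions <- function(net) length(net$reactions)

reaction_ids <- function(net) vapply(net$reactions, `[[`, "", "id")

# indices of reactions / species by id, with validation
ridx <- function(net, ids) {
  i <- match(ids, reaction_ids(net))
  if (anyNA(i)) stop("unknown reaction id: ", ids[is.na(i)][1L])
  iset(i)
}

sidx <- function(net, ids) {
  i <- match(ids, net$reactive)
  if (anyNA(i)) stop("not a reactive species of the network: ",
                     ids[is.na(i)][1L])
  iset(i)
}

# species indices touched (reactive support or product) by reaction set
touched_species <- function(net, rset) {
  iset(unlist(c(net$supp[rset], net$prods[rset]), use.names = FALSE))
}

#' Active reactions of a species set
#'
#' Every non-inflow reaction whose support (reactive reactant set) lies
#' inside `S`, plus the chosen subset of inflow reactions.  Inflow
#' reactions have an empty support and are therefore optional rather
#' than mandatory.
#'
#' @param net a [build_network()] result.
#' @param S character vector of reactive species ids.
#' @param inflow_subset character vector of inflow reaction ids to treat
#'   as active (default: none).
#' @return character vector of reaction ids (document order).
#' @export
active_reactions <- function(net, S, inflow_subset = character()) {
  s <- sidx(net, S)
  j_in <- ridx(net, inflow_subset)
  if (length(j_in) && !all(net$inflow[j_in]))
    stop("inflow_subset contains a non-inflow reaction: ",
         reaction_ids(net)[j_in[!net$inflow[j_in]]][1L])
  reaction_ids(net)[iset_union(mandatory_active(net, s), j_in)]
}

# internal, index based: non-inflow reactions with support within s
mandatory_active <- function(net, s) {
  memb <- logical(length(net$reactive))
  memb[s] <- TRUE
  which(!net$inflow &
          vapply(net$supp, function(sp) all(memb[sp]), NA))
}

#' Is a flux vector feasible for a reaction set?
#'
#' Feasible means strictly positive (above tolerance) exactly on the
#' chosen active set and zero elsewhere.
#'
#' @param net a reaction network.
#' @param v numeric flux vector of length `n` (one rate per reaction,
#'   arbitrary units).
#' @param R character vector of reaction ids the flux should support.
#' @param tol positivity tolerance.
#' @return logical scalar.
#' @export
is_feasible_flux <- function(net, v, R, tol = 1e-9) {
  if (length(v) != n_reactions(net))
    stop("flux vector has length ", length(v), ", expected ",
         n_reactions(net))
  if (any(v < -tol)) return(FALSE)
  iset_equal(iset(which(v > tol)), ridx(net, R))
}
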