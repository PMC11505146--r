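# Minimal compartmentalizations and compartment statistics.
#
# A compartmentalization of a reaction set R splits the species touched
# by R into pairwise disjoint blocks, each closed with respect to its
# own active reactions, such that the block active-reaction sets union
# to R and one global self-maintenance flux exists.  The minimal one
# uses as few blocks as possible; its block count k is unique even when
# the partition is not.

#' Is a block partition a valid compartmentalization of R?
#'
#' @param net a reaction network.
#' @param blocks list of character vectors of reactive species ids.
#' @param R character vector of reaction ids.
#' @param control a [cot_control()] list.
#' @return logical scalar (overlapping blocks give `FALSE`, not an
#'   error).
#' @export
is_valid_compartmentalization <- function(net, blocks, R,
                                          control = cot_control()) {
  control <- as_cot_control(control)
  r <- ridx(net, R)
  bidx <- lapply(blocks, function(b) sidx(net, b))
  flat <- unlist(bidx, use.names = FALSE)
  if (anyDuplicated(flat)) return(FALSE)
  if (!iset_equal(iset(flat), touched_species(net, r))) return(FALSE)
  covered <- integer()
  for (b in bidx) {
    mand <- mandatory_active(net, b)
    if (!iset_subset(mand, r)) return(FALSE)
    prods <- iset(unlist(net$prods[mand], use.names = FALSE))
    if (!iset_subset(prods, b)) return(FALSE)
    opt <- r[net$inflow[r] &
               vapply(net$prods[r], function(p) iset_subset(p, b), NA)]
    covered <- iset_union(covered, iset_union(mand, opt))
  }
  ghost <- r[net$inflow[r] & vapply(net$prods[r], length, 0L) == 0L]
  if (!iset_subset(setdiff(r, ghost), covered)) return(FALSE)
  !is.null(witness_idx(net, r))
}

#' Minimal compartmentalization of a reaction set
#'
#' Searches by increasing block count for a valid compartmentalization
#' of `R` with at most `k_max` blocks.  Among equal-k solutions any one
#' may be returned (blocks canonicalized lexicographically), but the
#' minimal k itself is unique.
#'
#' @inheritParams is_valid_compartmentalization
#' @return a list of class `compartmentalization` with fields `blocks`
#'   (list of character vectors) and `k`, or `NULL` when `R` is not an
#'   organization within `k_max` compartments.  The empty reaction set
#'   yields `k = 0` (no compartment needed).
#' @export
minimal_compartmentalization <- function(net, R, control = cot_control()) {
  control <- as_cot_control(control)
  r <- ridx(net, R)
  if (is.null(witness_idx(net, r))) return(NULL)
  cs <- closed_sets_idx(net, control$max_closed_sets)
  cands <- single_block_candidates(net, cs$sets)
  feas <- Filter(function(cand) !is.null(witness_idx(net, cand$r)), cands)
  comp <- min_cover_idx(net, r, feas, control$k_max)
  if (is.null(comp)) return(NULL)
  structure(list(blocks = lapply(comp, function(s) net$reactive[s]),
                 k = length(comp)),
            class = "compartmentalization")
}

#' @export
print.compartmentalization <- function(x, ...) {
  cat("<compartmentalization> k = ", x$k, ": ",
      paste(vapply(x$blocks, paste, "", collapse = ","), collapse = " | "),
      "\n", sep = "")
  invisible(x)
}

#' Compartment statistics over an organization set
#'
#' @param organizations an `organization_set` (each organization carries
#'   its minimal compartmentalization).
#' @return list with `fraction_multi` (share of organizations needing
#'   at least two compartments; the empty organization counts in the
#'   denominator) and `max_required` (maximum block count, 0 when only
#'   the empty organization exists).
#' @export
compartment_stats <- function(organizations) {
  if (length(organizations) == 0L)
    stop("empty organization set (the empty organization is always ",
         "an organization, so this indicates a bug upstream)")
  k <- vapply(organizations, `[[`, 0L, "k")
  list(fraction_multi = sum(k >= 2L) / length(k),
       max_required = max(k))
}
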