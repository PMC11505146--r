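# Organization enumeration.
#
# An organization is identified by its set of active reactions R.  It
# must admit a compartmentalization into pairwise disjoint species
# blocks, each closed with respect to its own active reactions, whose
# active-reaction sets union to R, together with one global flux v with
# v_j >= 1 on R (strict positivity is scale invariant, so >= 1 loses
# nothing), v_j = 0 off R, and (N v)_s >= 0 for every species s of R.
#
# Because every block is closed, the columns of a block's reactions only
# touch that block's rows, so the global LP separates across blocks:
# multi-compartment organizations are exactly the disjoint unions of
# single-compartment ones.  Enumeration therefore proceeds:
#   1. all closed species sets (Ganter's NextClosure over the
#      product-closure operator, no inflows);
#   2. single-compartment candidates = (closed set, admissible inflow
#      subset), reduced to the species their reactions actually touch;
#   3. LP feasibility test per candidate;
#   4. disjoint unions of feasible candidates up to k_max blocks;
#   5. a minimal compartmentalization per organization by exact cover
#      over the feasible single-compartment blocks.

#' Is (S, R) closed?
#'
#' Closed means nothing new is created or activated: every product of
#' every reaction in `R` already belongs to `S`, and `R` contains every
#' non-inflow reaction whose support lies in `S`.
#'
#' @param net a reaction network.
#' @param S character vector of reactive species ids.
#' @param R character vector of reaction ids.
#' @return logical scalar.
#' @export
is_closed <- function(net, S, R) {
  s <- sidx(net, S)
  r <- ridx(net, R)
  prods <- iset(unlist(net$prods[r], use.names = FALSE))
  iset_subset(prods, s) && iset_subset(mandatory_active(net, s), r)
}

#' Closure of a species set
#'
#' Smallest superset of `S` closed under the products of its mandatory
#' active reactions plus the selected inflow reactions; the fixpoint of
#' repeated product addition.  Monotone and idempotent.
#'
#' @inheritParams is_closed
#' @param inflow_subset inflow reaction ids treated as active.
#' @return character vector of reactive species ids.
#' @export
closure <- function(net, S, inflow_subset = character()) {
  s <- sidx(net, S)
  j_in <- ridx(net, inflow_subset)
  if (length(j_in) && !all(net$inflow[j_in]))
    stop("inflow_subset contains a non-inflow reaction")
  s <- iset_union(s, iset(unlist(net$prods[j_in], use.names = FALSE)))
  net$reactive[closure0_idx(net, s)]
}

# index-based closure under mandatory reactions only
closure0_idx <- function(net, s) {
  repeat {
    r <- mandatory_active(net, s)
    s2 <- iset_union(s, iset(unlist(net$prods[r], use.names = FALSE)))
    if (length(s2) == length(s)) return(s)
    s <- s2
  }
}

# all closed species sets via NextClosure (lectic order);
# returns list(sets = list of index vectors, complete = logical)
closed_sets_idx <- function(net, max_sets = 100000L, deadline = NULL) {
  m <- length(net$reactive)
  out <- list(integer())                  # cl0(empty) is always empty
  if (m == 0L) return(list(sets = out, complete = TRUE))
  A <- integer()
  repeat {
    nxt <- NULL
    for (i in rev(seq_len(m))) {
      if (i %in% A) {
        A <- A[A != i]
      } else {
        B <- closure0_idx(net, iset_union(A, i))
        if (!any(B < i & !(B %in% A))) { nxt <- B; break }
      }
    }
    if (is.null(nxt)) return(list(sets = out, complete = TRUE))
    out[[length(out) + 1L]] <- nxt
    A <- nxt
    if (length(out) >= max_sets || deadline_reached(deadline))
      return(list(sets = out, complete = FALSE))
  }
}

#' Self-maintenance witness flux for a reaction set
#'
#' Searches (exactly, by rational phase-1 simplex) for a flux with
#' `v_j >= 1` on `R`, `v_j = 0` elsewhere, and nonnegative net
#' production `(N v)_s >= 0` for every reactive species touched by `R`.
#' The scale of the witness is arbitrary.
#'
#' @inheritParams is_closed
#' @return a numeric flux vector of length `n` (named by reaction id)
#'   with attributes `num`/`den` carrying the exact rational values, or
#'   `NULL` when the LP is infeasible.  The empty set yields the zero
#'   flux, which is trivially self-maintaining.
#' @export
self_maintenance_witness <- function(net, R) {
  r <- ridx(net, R)
  w <- witness_idx(net, r)
  if (is.null(w)) return(NULL)
  v <- w$num / w$den
  names(v) <- reaction_ids(net)
  attr(v, "num") <- w$num
  attr(v, "den") <- w$den
  v
}

# index-based LP; returns list(num, den) of length n or NULL
witness_idx <- function(net, r) {
  n <- n_reactions(net)
  if (length(r) == 0L)
    return(list(num = rep(0, n), den = rep(1, n)))
  s <- touched_species(net, r)
  A <- net$N[s, r, drop = FALSE]
  # v = u + 1, u >= 0:  A u >= -A 1
  b <- -rowSums(A)
  sol <- lp_feasible(A, b)
  if (!sol$feasible) return(NULL)
  stopifnot(lp_check_exact(A, b, sol$x_num, sol$x_den))
  num <- rep(0, n); den <- rep(1, n)
  # v_j = u_j + 1 = (x_num + x_den) / x_den
  num[r] <- sol$x_num + sol$x_den
  den[r] <- sol$x_den
  list(num = num, den = den)
}

new_organization <- function(net, r, compartments_idx, witness) {
  rid <- reaction_ids(net)
  structure(list(
    reactions = rid[r],
    species = net$reactive[touched_species(net, r)],
    compartments = lapply(compartments_idx, function(s) net$reactive[s]),
    k = length(compartments_idx),
    flux_witness = {
      v <- witness$num / witness$den
      names(v) <- rid
      v
    },
    witness_num = witness$num,
    witness_den = witness$den
  ), class = "organization")
}

#' @export
print.organization <- function(x, ...) {
  blocks <- if (x$k == 0L) "-" else
    paste(vapply(x$compartments, paste, "", collapse = ","),
          collapse = " | ")
  cat("<organization> {", paste(x$reactions, collapse = ","),
      "} on {", paste(x$species, collapse = ","),
      "}, compartments [", blocks, "]\n", sep = "")
  invisible(x)
}

#' @export
print.organization_set <- function(x, ...) {
  cat("<organization_set> ", length(x), " organizations",
      if (isTRUE(attr(x, "incomplete"))) " (INCOMPLETE)", "\n", sep = "")
  for (o in x) print(o)
  invisible(x)
}

# single-compartment candidates: list of list(s =, r =) index vectors,
# deduplicated by reaction set.  `s` is exactly the touched species.
single_block_candidates <- function(net, closed, deadline = NULL) {
  seen <- new.env(hash = TRUE, parent = emptyenv())
  cands <- list()
  inflows <- which(net$inflow)
  for (S in closed) {
    if (deadline_reached(deadline)) break
    mand <- mandatory_active(net, S)
    opt <- inflows[vapply(net$prods[inflows],
                          function(p) iset_subset(p, S), NA)]
    if (length(opt) > 16L)
      stop("more than 16 optional inflow reactions for one closed set; ",
           "inflow-subset enumeration is not tractable")
    for (bits in seq_len(2^length(opt)) - 1L) {
      J <- opt[bitwAnd(bits, 2^(seq_along(opt) - 1L)) > 0L]
      r <- iset_union(mand, J)
      key <- set_key(r)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      cands[[length(cands) + 1L]] <- list(s = touched_species(net, r), r = r)
    }
  }
  cands
}

#' Enumerate all organizations of a network
#'
#' @param net a reaction network.
#' @param control a [cot_control()] list (tolerance, `k_max`, timeout,
#'   closed-set guard).
#' @return an `organization_set`: a list of `organization` objects in
#'   canonical order (by reaction count, then lexicographically), with
#'   attribute `incomplete` set to `TRUE` when the timeout or the
#'   closed-set guard truncated the search.  The empty organization is
#'   always present.
#' @export
enumerate_organizations <- function(net, control = cot_control()) {
  control <- as_cot_control(control)
  deadline <- proc.time()[["elapsed"]] + control$timeout
  incomplete <- FALSE

  cs <- closed_sets_idx(net, control$max_closed_sets, deadline)
  if (!cs$complete) incomplete <- TRUE
  cands <- single_block_candidates(net, cs$sets, deadline)

  # feasible single-compartment organizations
  singles <- list()
  for (cand in cands) {
    if (deadline_reached(deadline)) { incomplete <- TRUE; break }
    w <- witness_idx(net, cand$r)
    if (!is.null(w)) {
      cand$w <- w
      singles[[length(singles) + 1L]] <- cand
    }
  }

  # disjoint unions of feasible singles, up to k_max blocks; witnesses
  # compose by overlay because block reaction sets touch disjoint rows
  found <- new.env(hash = TRUE, parent = emptyenv())
  m <- length(net$reactive)
  empty_w <- list(num = rep(0, n_reactions(net)),
                  den = rep(1, n_reactions(net)))
  found[[set_key(integer())]] <- list(r = integer(), w = empty_w)
  nonempty <- Filter(function(cand) length(cand$s) > 0L ||
                       length(cand$r) > 0L, singles)
  record <- function(r, w) {
    key <- set_key(r)
    if (is.null(found[[key]])) found[[key]] <- list(r = r, w = w)
  }
  overlay <- function(w1, w2, r2) {
    w1$num[r2] <- w2$num[r2]
    w1$den[r2] <- w2$den[r2]
    w1
  }
  dfs <- function(start, s_mask, r, w, depth) {
    if (deadline_reached(deadline)) { incomplete <<- TRUE; return() }
    for (i in seq(from = start, length.out = length(nonempty) - start + 1L)) {
      cand <- nonempty[[i]]
      if (any(s_mask[cand$s])) next
      s2 <- s_mask; s2[cand$s] <- TRUE
      r2 <- iset_union(r, cand$r)
      w2 <- overlay(w, cand$w, cand$r)
      record(r2, w2)
      if (depth + 1L < control$k_max)
        dfs(i + 1L, s2, r2, w2, depth + 1L)
    }
  }
  if (length(nonempty)) dfs(1L, logical(m), integer(), empty_w, 0L)

  keys <- ls(found)
  orgs <- lapply(keys, function(k) found[[k]])
  # minimal compartmentalization per organization
  blocks <- lapply(singles, function(cand) cand[c("s", "r")])
  out <- lapply(orgs, function(o) {
    comp <- min_cover_idx(net, o$r, blocks, control$k_max)
    if (is.null(comp)) return(NULL)    # cannot happen for found orgs
    new_organization(net, o$r, comp, o$w)
  })
  out <- Filter(Negate(is.null), out)
  sort_organizations(out, incomplete)
}

sort_organizations <- function(orgs, incomplete = FALSE) {
  key <- vapply(orgs, function(o)
    sprintf("%04d|%s", length(o$reactions),
            paste(o$reactions, collapse = ",")), "")
  structure(orgs[order(key)], class = "organization_set",
            incomplete = incomplete)
}

# minimal exact cover of species(R) by disjoint blocks from `blocks`
# (list of list(s =, r =)), with union of block reactions equal to R up
# to inflows having no reactive product (those fit in any compartment).
# Returns list of species-index blocks in canonical order, or NULL.
min_cover_idx <- function(net, r, blocks, k_max) {
  s_all <- touched_species(net, r)
  ghost <- r[net$inflow[r] &
               vapply(net$prods[r], length, 0L) == 0L]
  r_need <- setdiff(r, ghost)
  usable <- Filter(function(b)
    iset_subset(b$s, s_all) && iset_subset(b$r, r), blocks)
  if (length(s_all) == 0L)
    return(if (length(r_need) == 0L) list() else NULL)
  usable <- usable[vapply(usable, function(b) length(b$s) > 0L, NA)]
  for (k in seq_len(k_max)) {
    hit <- cover_dfs(s_all, r_need, usable, k)
    if (!is.null(hit)) {
      key <- vapply(hit, function(s) paste(net$reactive[s], collapse = ","), "")
      return(hit[order(key)])
    }
  }
  NULL
}

cover_dfs <- function(s_left, r_left, usable, k) {
  if (length(s_left) == 0L)
    return(if (length(r_left) == 0L) list() else NULL)
  if (k == 0L) return(NULL)
  target <- s_left[1L]
  for (b in usable) {
    if (!(target %in% b$s)) next
    if (!iset_subset(b$s, s_left)) next
    rest <- cover_dfs(setdiff(s_left, b$s), setdiff(r_left, b$r),
                      usable, k - 1L)
    if (!is.null(rest)) return(c(list(b$s), rest))
  }
  NULL
}

#' Brute-force organization oracle
#'
#' Applies the definition literally: iterates over every subset of
#' reactive species, every set partition of it into at most `k_max`
#' blocks, and every admissible inflow subset, keeping the reaction sets
#' whose blocks are all closed and whose global self-maintenance LP is
#' feasible.  Exponential; guarded to at most 10 reactive species and
#' 12 reactions.  Same output contract as [enumerate_organizations()].
#'
#' @inheritParams enumerate_organizations
#' @return an `organization_set`.
#' @export
brute_force_organizations <- function(net, control = cot_control()) {
  control <- as_cot_control(control)
  m <- length(net$reactive)
  n <- n_reactions(net)
  if (m > 10L || n > 12L)
    stop("brute-force oracle guard: at most 10 reactive species and ",
         "12 reactions (got ", m, " / ", n, ")")

  supp_mask <- vapply(net$supp, mask_of, 0L)
  prod_mask <- vapply(net$prods, mask_of, 0L)
  touch_mask <- bitwOr(supp_mask, prod_mask)
  inflow <- net$inflow

  # per species-mask memo: closed flag, mandatory reaction mask,
  # admissible inflow mask
  info <- vector("list", 2^m)
  block_info <- function(mask) {
    ii <- mask + 1L
    if (!is.null(info[[ii]])) return(info[[ii]])
    mand <- 0L; closed <- TRUE
    for (j in seq_len(n)) {
      if (!inflow[j] && bitwAnd(supp_mask[j], mask) == supp_mask[j]) {
        mand <- bitwOr(mand, bitwShiftL(1L, j - 1L))
        if (bitwAnd(prod_mask[j], bitwNot(mask)) != 0L) closed <- FALSE
      }
    }
    opt <- 0L
    for (j in which(inflow))
      if (bitwAnd(prod_mask[j], bitwNot(mask)) == 0L)
        opt <- bitwOr(opt, bitwShiftL(1L, j - 1L))
    res <- list(closed = closed, mand = mand, opt = opt)
    info[[ii]] <<- res
    res
  }

  lp_memo <- new.env(hash = TRUE, parent = emptyenv())
  lp_of <- function(rmask) {
    key <- as.character(rmask)
    got <- lp_memo[[key]]
    if (!is.null(got)) return(got)
    r <- iset(which(bitwAnd(rmask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L))
    w <- witness_idx(net, r)
    res <- list(ok = !is.null(w), w = w, r = r)
    lp_memo[[key]] <- res
    res
  }

  best <- new.env(hash = TRUE, parent = emptyenv())   # rmask -> min k, blocks
  consider <- function(rmask, blocks_masks) {
    # organization species must be exactly the species its reactions touch
    touched <- Reduce(bitwOr, touch_mask[
      which(bitwAnd(rmask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)], 0L)
    smask <- Reduce(bitwOr, blocks_masks, 0L)
    if (touched != smask) return()
    lp <- lp_of(rmask)
    if (!lp$ok) return()
    key <- as.character(rmask)
    got <- best[[key]]
    if (is.null(got) || length(blocks_masks) < got$k)
      best[[key]] <- list(k = length(blocks_masks), blocks = blocks_masks,
                          r = lp$r, w = lp$w)
  }

  eval_partition <- function(blocks_masks) {
    infos <- lapply(blocks_masks, block_info)
    if (!all(vapply(infos, `[[`, NA, "closed"))) return()
    r_base <- Reduce(bitwOr, lapply(infos, `[[`, "mand"), 0L)
    opt <- Reduce(bitwOr, lapply(infos, `[[`, "opt"), 0L)
    optbits <- which(bitwAnd(opt, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
    for (bits in seq_len(2^length(optbits)) - 1L) {
      jmask <- 0L
      for (t in seq_along(optbits))
        if (bitwAnd(bits, bitwShiftL(1L, t - 1L)) > 0L)
          jmask <- bitwOr(jmask, bitwShiftL(1L, optbits[t] - 1L))
      consider(bitwOr(r_base, jmask), blocks_masks)
    }
  }

  # empty species set (zero blocks)
  eval_partition(list())

  partitions <- function(elts, blocks) {
    if (length(elts) == 0L) {
      if (length(blocks)) eval_partition(blocks)
      return(invisible())
    }
    e <- elts[1L]; rest <- elts[-1L]
    for (b in seq_along(blocks)) {
      blocks2 <- blocks
      blocks2[[b]] <- bitwOr(blocks2[[b]], bitwShiftL(1L, e - 1L))
      partitions(rest, blocks2)
    }
    if (length(blocks) < control$k_max)
      partitions(rest, c(blocks, list(bitwShiftL(1L, e - 1L))))
  }
  for (smask in seq_len(2^m - 1L))
    partitions(which(bitwAnd(smask, bitwShiftL(1L, seq_len(m) - 1L)) > 0L),
               list())

  keys <- ls(best)
  out <- lapply(keys, function(k) {
    o <- best[[k]]
    comp <- lapply(o$blocks, function(msk)
      iset(which(bitwAnd(msk, bitwShiftL(1L, seq_len(m) - 1L)) > 0L)))
    key <- vapply(comp, function(s) paste(net$reactive[s], collapse = ","), "")
    new_organization(net, o$r, comp[order(key)], o$w)
  })
  sort_organizations(out)
}

mask_of <- function(idx) {
  Reduce(bitwOr, bitwShiftL(1L, idx - 1L), 0L)
}

#' Re-validate an organization against the definition
#'
#' Checks block disjointness, per-block closedness, block partition of
#' the organization's species, reaction coverage and the exact
#' rational self-maintenance inequality of the stored witness.
#'
#' @param net a reaction network.
#' @param org an `organization`.
#' @return `TRUE`, or a character scalar describing the first violated
#'   condition.
#' @export
validate_organization <- function(net, org) {
  r <- ridx(net, org$reactions)
  s <- touched_species(net, r)
  blocks <- lapply(org$compartments, function(b) sidx(net, b))
  all_block <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(all_block)) return("blocks overlap")
  if (!iset_equal(iset(all_block), s)) return("blocks do not partition species")
  covered <- integer()
  for (b in blocks) {
    mand <- mandatory_active(net, b)
    if (!iset_subset(mand, r)) return("block activates a reaction outside R")
    prods <- iset(unlist(net$prods[mand], use.names = FALSE))
    if (!iset_subset(prods, b)) return("block not closed")
    opt <- r[net$inflow[r] &
               vapply(net$prods[r], function(p) iset_subset(p, b), NA)]
    covered <- iset_union(covered, iset_union(mand, opt))
  }
  ghost <- r[net$inflow[r] & vapply(net$prods[r], length, 0L) == 0L]
  if (!iset_subset(setdiff(r, ghost), covered))
    return("blocks do not cover the reaction set")
  # exact witness check: v > 0 exactly on R and (N v)_s >= 0 on species
  num <- org$witness_num; den <- org$witness_den
  if (!iset_equal(iset(which(num != 0)), r)) return("witness support wrong")
  if (length(s)) {
    A <- net$N[s, r, drop = FALSE]
    if (!lp_check_exact(A, rep(0, length(s)), num[r], den[r]))
      return("witness violates self-maintenance")
  }
  TRUE
}
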