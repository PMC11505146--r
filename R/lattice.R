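# Hasse lattice of organizations and per-model complexity parameters.

#' Build the Hasse lattice of an organization set
#'
#' Organizations are partially ordered by inclusion of their reaction
#' sets.  Hasse edges are the covering pairs (no third organization
#' strictly between); layers are assigned by longest-chain depth from
#' the bottom (the empty organization), or by reaction count when
#' `control$layering == "nreactions"`.
#'
#' @param organizations an `organization_set` (distinct reaction sets).
#' @param control a [cot_control()] list.
#' @return an object of class `organization_lattice`: list with
#'   `organizations`, `edges` (two-column integer matrix of
#'   lower/upper indices), `layers` (integer per organization, bottom
#'   layer = 0).
#' @export
build_lattice <- function(organizations, control = cot_control()) {
  control <- as_cot_control(control)
  keys <- vapply(organizations, function(o)
    paste(sort(o$reactions), collapse = ","), "")
  if (anyDuplicated(keys)) stop("duplicate organization reaction sets")
  n <- length(organizations)
  rsets <- lapply(organizations, `[[`, "reactions")
  below <- matrix(FALSE, n, n)   # below[i, j]: R_i strictly subset of R_j
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && length(rsets[[i]]) < length(rsets[[j]]) &&
        all(rsets[[i]] %in% rsets[[j]]))
      below[i, j] <- TRUE
  }
  edges <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (below[i, j] && !any(below[i, ] & below[, j]))
      edges <- rbind(edges, c(i, j))
  }
  if (is.null(edges)) edges <- matrix(integer(), 0L, 2L)
  colnames(edges) <- c("lower", "upper")

  if (control$layering == "nreactions") {
    nr <- vapply(rsets, length, 0L)
    layers <- match(nr, sort(unique(nr))) - 1L
  } else {
    layers <- integer(n)   # longest chain from bottom, via |R| order
    for (i in order(vapply(rsets, length, 0L))) {
      lower <- which(below[, i])
      layers[i] <- if (length(lower)) max(layers[lower]) + 1L else 0L
    }
  }
  structure(list(organizations = organizations, edges = edges,
                 layers = layers),
            class = "organization_lattice")
}

#' @export
print.organization_lattice <- function(x, ...) {
  cat("<organization_lattice> ", length(x$organizations),
      " organizations, ", nrow(x$edges), " Hasse edges, height ",
      lattice_height(x), ", width ", lattice_width(x), "\n", sep = "")
  invisible(x)
}

#' Lattice height and width
#'
#' Height is the number of layers (the node length of the longest
#' chain); width is the maximum number of organizations within one
#' layer.
#'
#' @param lattice an `organization_lattice`.
#' @return integer scalar.
#' @export
lattice_height <- function(lattice) {
  if (!length(lattice$layers)) return(0L)
  max(lattice$layers) + 1L
}

#' @rdname lattice_height
#' @export
lattice_width <- function(lattice) {
  if (!length(lattice$layers)) return(0L)
  max(tabulate(lattice$layers + 1L))
}

#' Persistence of a model
#'
#' Reaction count of the largest organization divided by the total
#' number of reactions.  1 means the entire network can persist; 0
#' means only the empty organization exists.
#'
#' @param net a reaction network.
#' @param organizations its `organization_set`.
#' @return numeric in `[0, 1]`.  A network with zero reactions yields 1
#'   by convention (flagged with a warning).
#' @export
persistence <- function(net, organizations) {
  if (length(organizations) == 0L) stop("empty organization set")
  n <- n_reactions(net)
  if (n == 0L) {
    warning("network has no reactions; persistence defined as 1")
    return(1)
  }
  max(vapply(organizations, function(o) length(o$reactions), 0L)) / n
}

#' Compute the full per-model parameter record
#'
#' Enumerates the organizations, builds the lattice and assembles the
#' complexity parameters: network size, organization count, lattice
#' height/width, persistence, and compartmentalization statistics.
#' Runtime is measured and reported but carries no correctness claim.
#'
#' @param net a reaction network.
#' @param control a [cot_control()] list.
#' @return a list of class `model_parameters`.
#' @export
compute_parameters <- function(net, control = cot_control()) {
  control <- as_cot_control(control)
  t0 <- proc.time()[["elapsed"]]
  orgs <- enumerate_organizations(net, control)
  lat <- build_lattice(orgs, control)
  cs <- compartment_stats(orgs)
  runtime_ms <- (proc.time()[["elapsed"]] - t0) * 1000
  structure(list(
    n_species = length(net$reactive),
    n_reactions = n_reactions(net),
    n_organizations = length(orgs),
    height = lattice_height(lat),
    width = lattice_width(lat),
    persistence = persistence(net, orgs),
    fraction_multi_compartment = cs$fraction_multi,
    max_compartments = cs$max_required,
    runtime_ms = runtime_ms,
    incomplete = isTRUE(attr(orgs, "incomplete")),
    organizations = orgs,
    lattice = lat
  ), class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  flds <- c("n_species", "n_reactions", "n_organizations", "height",
            "width", "persistence", "fraction_multi_compartment",
            "max_compartments", "runtime_ms", "incomplete")
  for (f in flds) cat(sprintf("  %-27s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Render a lattice as Graphviz DOT
#'
#' One node per organization, labelled with its reactions, species and
#' compartment string (blocks separated by `|`).  Single-compartment
#' organizations (k <= 1) are drawn as rectangles, multi-compartment
#' ones as ellipses.  Reactions appearing for the first time relative
#' to all sub-organizations are shown in green.
#'
#' @param lattice an `organization_lattice`.
#' @param name graph name.
#' @return character scalar of DOT source.
#' @export
to_dot <- function(lattice, name = "organizations") {
  orgs <- lattice$organizations
  rsets <- lapply(orgs, `[[`, "reactions")
  lines <- c(sprintf("digraph \"%s\" {", name),
             "  rankdir=BT;",
             "  node [fontsize=10];")
  esc <- function(x) gsub("&", "&amp;",
                          gsub("<", "&lt;", gsub(">", "&gt;", x)))
  if (length(orgs) == 0L)
    lines <- c(lines, "  empty [shape=box, label=\"(no organizations)\"];")
  for (i in seq_along(orgs)) {
    o <- orgs[[i]]
    inherited <- unique(unlist(rsets[vapply(rsets, function(s)
      length(s) < length(rsets[[i]]) && all(s %in% rsets[[i]]), NA)]))
    rlab <- vapply(o$reactions, function(r)
      if (r %in% inherited) esc(r)
      else sprintf("<font color=\"green\">%s</font>", esc(r)), "")
    rline <- if (length(rlab)) paste(rlab, collapse = ",") else "&#8709;"
    sline <- if (length(o$species))
      esc(paste(o$species, collapse = ",")) else "&#8709;"
    cline <- if (o$k == 0L) "&#8709;" else
      esc(paste(vapply(o$compartments, paste, "", collapse = ","),
                collapse = " | "))
    shape <- if (o$k >= 2L) "ellipse" else "box"
    lines <- c(lines, sprintf(
      "  o%d [shape=%s, label=<%s<br/>%s<br/>%s>];",
      i, shape, rline, sline, cline))
  }
  if (nrow(lattice$edges))
    lines <- c(lines, sprintf("  o%d -> o%d;",
                              lattice$edges[, 1L], lattice$edges[, 2L]))
  paste(c(lines, "}"), collapse = "\n")
}

#' Export an organization set as JSON
#'
#' @param organizations an `organization_set`.
#' @param path optional file to write to.
#' @return JSON string (invisibly when `path` given).
#' @export
organizations_to_json <- function(organizations, path = NULL) {
  payload <- list(
    incomplete = isTRUE(attr(organizations, "incomplete")),
    organizations = lapply(organizations, function(o) list(
      reactions = as.list(o$reactions),
      species = as.list(o$species),
      compartments = lapply(o$compartments, as.list),
      k = o$k,
      flux_witness = as.list(unname(o$flux_witness))
    ))
  )
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                          pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
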